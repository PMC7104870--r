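#' Relative synonymous codon usage (RSCU)
#'
#' For codon `j` of an amino-acid family `i` with observed family total
#' `X_i > 0` and degeneracy `m_i`, `RSCU_ij = x_ij / (X_i / m_i)`: the
#' observed count divided by its expectation under uniform synonymous usage.
#' Family values therefore sum to the degeneracy (mean 1). Stop codons and
#' the singleton families (Met, Trp under the standard code) are excluded,
#' leaving the 59 informative codons. Codons of families with no observed
#' codon are undefined and returned as `NA`.
#'
#' @param cds A CDS tibble.
#' @param pooled If `TRUE`, compute one RSCU table on the summed codon counts
#'   of all genes (`gene_id = "pooled"`); otherwise one per gene.
#' @param table_id NCBI translation table identifier.
#' @return A tibble with columns `gene_id`, `codon`, `aa`, `count`, `rscu`;
#'   59 rows per gene for the standard code.
#' @examples
#' cds <- tibble::tibble(gene_id = "g", sequence = "TTTTTTTTTTTC")
#' dplyr::filter(rscu(cds), aa == "F")
#' @export
rscu <- function(cds, pooled = FALSE, table_id = 1L) {
  counts <- count_codons(cds, by_gene = !pooled, table_id = table_id)
  code <- genetic_code(table_id)
  info <- informative_codons(code)
  counts |>
    dplyr::filter(.data$codon %in% info) |>
    dplyr::left_join(code[, c("codon", "degeneracy")], by = "codon") |>
    dplyr::group_by(.data$gene_id, .data$aa) |>
    dplyr::mutate(
      rscu = {
        tot <- sum(.data$count)
        if (tot > 0) {
          .data$count / (tot / .data$degeneracy)
        } else {
          rep(NA_real_, dplyr::n())
        }
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "codon", "aa", "count", "rscu")
}

#' Wright's expected ENc under GC3 alone
#'
#' The null curve of the ENc-GC3 plot: the effective number of codons a gene
#' would have if its codon usage bias were driven solely by its
#' third-position GC content `s`,
#' `ENc = 2 + s + 29 / (s^2 + (1 - s)^2)`.
#'
#' @param gc3 GC3 fraction(s) in `[0, 1]`; vectorised.
#' @return Expected ENc value(s).
#' @examples
#' expected_enc(c(0, 0.5, 1)) # 31, 60.5, 32
#' @export
expected_enc <- function(gc3) {
  stopifnot(all(gc3 >= 0 & gc3 <= 1, na.rm = TRUE))
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}

#' Effective number of codons (ENc)
#'
#' Wright's ENc summarises how many codons a gene effectively uses: 20 means
#' one codon per amino acid (maximal bias), 61 means uniform synonymous usage
#' (no bias, standard code). Per synonymous family with observed total `n`
#' and within-family frequencies `p_j`, the homozygosity is estimated with
#' the finite-sample correction `F = (n * sum(p_j^2) - 1) / (n - 1)`; class
#' averages over families of equal degeneracy are combined as
#' `ENc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`.
#'
#' `method = "novembre"` instead estimates each family's homozygosity from
#' the chi-square deviation of its codon counts from the expectation under a
#' background nucleotide composition,
#' `F = (X^2 + n - m) / (m * (n - 1))`, which corrects ENc for compositional
#' bias. The default background is each gene's own mononucleotide
#' composition; supply `background` (named `A`/`C`/`G`/`T` frequencies) to
#' use e.g. a genome-wide composition.
#'
#' Families with fewer than 2 observed codons are dropped from their class
#' mean. A missing threefold class is imputed as `(F2 + F4)/2`; any other
#' missing class renormalises ENc over the amino acids actually represented.
#' The final value is clamped to `[20, 61]`. A gene with no usable family
#' gets `NA`; if every gene is unusable an error is raised.
#'
#' @param cds A CDS tibble.
#' @param method `"wright"` or `"novembre"`.
#' @param background Optional named numeric vector of `A`,`C`,`G`,`T`
#'   frequencies for the Novembre correction.
#' @param pooled Compute on pooled counts instead of per gene.
#' @param table_id NCBI translation table identifier.
#' @return A tibble with columns `gene_id`, `enc`, `method`.
#' @references Wright (1990) Gene 87:23-29; Novembre (2002) Mol Biol Evol
#'   19:1390-1394.
#' @export
enc <- function(cds, method = c("wright", "novembre"), background = NULL,
                pooled = FALSE, table_id = 1L) {
  method <- match.arg(method)
  code <- genetic_code(table_id)
  mat <- codon_count_matrix(cds$sequence)
  colnames(mat) <- all_codons()
  if (pooled) {
    mat <- matrix(colSums(mat), nrow = 1,
                  dimnames = list("pooled", all_codons()))
    ids <- "pooled"
  } else {
    ids <- cds$gene_id
  }
  if (!is.null(background)) {
    background <- background[c("A", "C", "G", "T")] / sum(background)
  }
  vals <- vapply(seq_len(nrow(mat)), function(i) {
    enc_one(mat[i, ], code, method, background)
  }, numeric(1))
  if (all(is.na(vals))) {
    stop("ENc undefined for every gene (no synonymous family with >= 2 codons)",
         call. = FALSE)
  }
  tibble::tibble(gene_id = ids, enc = vals, method = method)
}

# ENc for one 64-codon count vector.
enc_one <- function(x, code, method, background) {
  fams <- split(code$codon[!is.na(code$degeneracy)],
                code$family[!is.na(code$degeneracy)])
  deg <- vapply(fams, length, integer(1))
  n_single <- sum(deg == 1L)

  if (is.null(background) && method == "novembre") {
    background <- base_composition(x, code)
  }

  f_hat <- rep(NA_real_, length(fams))
  for (k in seq_along(fams)) {
    m <- deg[[k]]
    if (m == 1L) next
    cnt <- x[fams[[k]]]
    n <- sum(cnt)
    if (n < 2) next
    if (method == "wright") {
      p <- cnt / n
      f_hat[k] <- (n * sum(p^2) - 1) / (n - 1)
    } else {
      e <- family_expected_freq(fams[[k]], background)
      chi2 <- sum((cnt - n * e)^2 / (n * e))
      f_hat[k] <- (chi2 + n - m) / (m * (n - 1))
    }
  }

  classes <- sort(unique(deg[deg > 1L]))
  fbar <- vapply(classes, function(m) {
    v <- f_hat[deg == m & !is.na(f_hat)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  names(fbar) <- classes
  # non-positive class means cannot enter 1/F terms
  fbar[!is.na(fbar) & fbar <= 0] <- NA_real_

  # Wright's imputation for a missing threefold class
  if ("3" %in% names(fbar) && is.na(fbar[["3"]]) &&
      !is.na(fbar["2"]) && !is.na(fbar["4"])) {
    fbar[["3"]] <- (fbar[["2"]] + fbar[["4"]]) / 2
  }

  n_fam <- vapply(classes, function(m) sum(deg == m), numeric(1))
  ok <- !is.na(fbar)
  if (!any(ok)) return(NA_real_)
  partial <- n_single + sum(n_fam[ok] / fbar[ok])
  aa_covered <- n_single + sum(n_fam[ok])
  aa_total <- n_single + sum(n_fam)
  value <- partial * aa_total / aa_covered
  min(max(value, 20), 61)
}

# Mononucleotide composition of the codons backing a count vector.
base_composition <- function(x, code) {
  bases <- c(A = 0, C = 0, G = 0, T = 0)
  for (cod in names(x)[x > 0]) {
    for (b in strsplit(cod, "", fixed = TRUE)[[1]]) {
      bases[b] <- bases[b] + x[[cod]]
    }
  }
  bases / sum(bases)
}

# Within-family expected codon frequencies under a background composition.
family_expected_freq <- function(codons, background) {
  e <- vapply(codons, function(cod) {
    prod(background[strsplit(cod, "", fixed = TRUE)[[1]]])
  }, numeric(1))
  e <- e / sum(e)
  pmax(e, 1e-12)
}

#' Synonymous codon usage orderliness (SCUO)
#'
#' An entropy-based index of codon usage bias. For each multi-codon family
#' `i` with observed total `X_i > 0`, the normalised entropy deficit is
#' `O_i = (log m_i - H_i) / log m_i` with `H_i = -sum p_ij log p_ij`;
#' SCUO is the codon-share-weighted mean `sum F_i O_i` where
#' `F_i = X_i / sum X` over contributing families. 0 means perfectly uniform
#' synonymous usage, 1 means a single codon per family.
#'
#' @inheritParams rscu
#' @return A tibble with columns `gene_id`, `scuo` (in `[0, 1]`, `NA` when no
#'   multi-codon family is observed).
#' @references Wan et al. (2004) BMC Evol Biol 4:19.
#' @export
scuo <- function(cds, pooled = FALSE, table_id = 1L) {
  code <- genetic_code(table_id)
  mat <- codon_count_matrix(cds$sequence)
  colnames(mat) <- all_codons()
  if (pooled) {
    mat <- matrix(colSums(mat), nrow = 1,
                  dimnames = list("pooled", all_codons()))
    ids <- "pooled"
  } else {
    ids <- cds$gene_id
  }
  fams <- split(code$codon[!is.na(code$degeneracy) & code$degeneracy > 1L],
                code$family[!is.na(code$degeneracy) & code$degeneracy > 1L])
  vals <- vapply(seq_len(nrow(mat)), function(i) {
    x <- mat[i, ]
    tot <- vapply(fams, function(f) sum(x[f]), numeric(1))
    use <- tot > 0
    if (!any(use)) return(NA_real_)
    o <- vapply(which(use), function(k) {
      p <- x[fams[[k]]] / tot[[k]]
      p <- p[p > 0]
      h <- -sum(p * log(p))
      (log(length(fams[[k]])) - h) / log(length(fams[[k]]))
    }, numeric(1))
    sum(tot[use] / sum(tot[use]) * o)
  }, numeric(1))
  tibble::tibble(gene_id = ids, scuo = vals)
}
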