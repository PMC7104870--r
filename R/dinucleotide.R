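DINUCS <- as.vector(t(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0)))

# sequence string -> integer base codes 1..4 (A,C,G,T)
base_ints <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
}

# overlapping dinucleotide tally of an integer base vector -> 16 counts
dinuc_tab <- function(x) {
  n <- length(x)
  tabulate(4L * (x[-n] - 1L) + x[-1L], nbins = 16L)
}

#' Observed dinucleotide counts
#'
#' Overlapping dinucleotide counts across the whole sequence, codon-junction
#' dinucleotides included: a sequence of length `L` contributes `L - 1`
#' windows.
#'
#' @param cds A CDS tibble.
#' @return A tibble with columns `gene_id`, `dinucleotide`, `count`
#'   (16 rows per gene).
#' @export
dinucleotide_counts <- function(cds) {
  if (any(nchar(cds$sequence) < 2L)) {
    stop("dinucleotide counts need sequences of length >= 2", call. = FALSE)
  }
  m <- t(vapply(cds$sequence, function(s) dinuc_tab(base_ints(s)),
                integer(16), USE.NAMES = FALSE))
  tibble::tibble(
    gene_id = rep(cds$gene_id, each = 16L),
    dinucleotide = rep(DINUCS, times = nrow(cds)),
    count = as.integer(t(m))
  )
}

# One shuffle of an integer base vector under a null model.
# bases: int vector; cod: int codon index vector (codons as 1..64);
# fam_pos: list mapping family -> positions in the codon vector;
# cmat: 64 x 3 matrix of base ints per codon.
shuffle_ints <- function(bases, cod, fam_pos, cmat, model, with_replacement) {
  if (model == "base") {
    return(if (with_replacement) {
      bases[sample.int(length(bases), replace = TRUE)]
    } else {
      bases[sample.int(length(bases))]
    })
  }
  if (model == "codon") {
    idx <- if (with_replacement) {
      sample.int(length(cod), replace = TRUE)
    } else {
      sample.int(length(cod))
    }
    return(as.vector(t(cmat[cod[idx], , drop = FALSE])))
  }
  # syncodon: permute codons within each synonymous family, protein unchanged
  newcod <- cod
  for (pos in fam_pos) {
    if (length(pos) > 1L || with_replacement) {
      newcod[pos] <- if (with_replacement) {
        cod[pos][sample.int(length(pos), replace = TRUE)]
      } else {
        cod[pos][sample.int(length(pos))]
      }
    }
  }
  as.vector(t(cmat[newcod, , drop = FALSE]))
}

#' Shuffle coding sequences under a null model
#'
#' Generates one randomised version of each sequence under one of three
#' shuffling models: `"base"` permutes all bases (preserving mononucleotide
#' counts), `"codon"` permutes whole codons (preserving the codon multiset),
#' and `"syncodon"` permutes codons within each synonymous family
#' (preserving the encoded protein and, without replacement, the per-family
#' codon counts). With `replacement = "with"`, positions are instead filled
#' by i.i.d. draws from the observed base/codon/family multiset, so the
#' conserved quantities hold in expectation only.
#'
#' @param cds A CDS tibble.
#' @param model `"base"`, `"codon"` or `"syncodon"`.
#' @param replacement `"without"` (permutation, default) or `"with"`.
#' @param table_id NCBI translation table (used by `"syncodon"`).
#' @return A CDS tibble with the same `gene_id`s and shuffled sequences.
#' @export
shuffle_cds <- function(cds, model = c("base", "codon", "syncodon"),
                        replacement = c("without", "with"), table_id = 1L) {
  model <- match.arg(model)
  replacement <- match.arg(replacement)
  prep <- dinuc_prep(cds, model, table_id)
  shuffled <- vapply(prep, function(g) {
    y <- shuffle_ints(g$bases, g$cod, g$fam_pos, prep_cmat(),
                      model, replacement == "with")
    paste(c("A", "C", "G", "T")[y], collapse = "")
  }, character(1))
  tibble::tibble(gene_id = cds$gene_id, sequence = unname(shuffled),
                 n_codons = nchar(shuffled) %/% 3L)
}

# 64 x 3 matrix: base ints of each codon in all_codons() order.
prep_cmat <- function() {
  t(vapply(all_codons(), base_ints, integer(3)))
}

# Per-gene precomputation for the shuffling models.
dinuc_prep <- function(cds, model, table_id) {
  aa <- codon_to_aa(genetic_code(table_id))
  codons <- all_codons()
  lapply(cds$sequence, function(s) {
    bases <- base_ints(s)
    cod <- NULL
    fam_pos <- NULL
    if (model != "base") {
      if (length(bases) %% 3L != 0L) {
        stop("codon-level shuffling needs in-frame sequences", call. = FALSE)
      }
      cod <- match(codon_split(s), codons)
      if (model == "syncodon") {
        fam_pos <- split(seq_along(cod), aa[codons[cod]])
      }
    }
    list(bases = bases, cod = cod, fam_pos = fam_pos)
  })
}

#' Dinucleotide over/under-representation z-scores
#'
#' For each gene and each of the 16 dinucleotides, compares the observed
#' overlapping count with its Monte-Carlo null distribution under a
#' shuffling model (see [shuffle_cds()]):
#' `z = (observed - null mean) / null sd` with the sample (`n - 1`) standard
#' deviation over `n_perm` shuffles. A dinucleotide whose null sd is zero
#' (e.g. any dinucleotide of a homopolymer under the base model) gets
#' `z = NA`. Results are fully reproducible given `(seed, n_perm, model,
#' replacement)`; the caller's RNG state is left untouched.
#'
#' @inheritParams shuffle_cds
#' @param n_perm Number of permutations (>= 2); default 500.
#' @param seed Integer seed for the null-model RNG.
#' @return A tibble with columns `gene_id`, `dinucleotide`, `observed`,
#'   `null_mean`, `null_sd`, `z` (16 rows per gene), carrying `model`,
#'   `n_perm` and `seed` as attributes.
#' @export
dinuc_zscore <- function(cds, model = c("base", "codon", "syncodon"),
                         n_perm = 500L, seed = 1L,
                         replacement = c("without", "with"), table_id = 1L) {
  model <- match.arg(model)
  replacement <- match.arg(replacement)
  stopifnot(n_perm >= 2L)
  with_repl <- replacement == "with"
  prep <- dinuc_prep(cds, model, table_id)
  cmat <- prep_cmat()

  out <- local_seed(seed, {
    lapply(seq_along(prep), function(i) {
      g <- prep[[i]]
      obs <- dinuc_tab(g$bases)
      sums <- numeric(16)
      sqs <- numeric(16)
      for (p in seq_len(n_perm)) {
        y <- shuffle_ints(g$bases, g$cod, g$fam_pos, cmat, model, with_repl)
        tab <- dinuc_tab(y)
        sums <- sums + tab
        sqs <- sqs + tab^2
      }
      mu <- sums / n_perm
      sd <- sqrt(pmax(sqs - n_perm * mu^2, 0) / (n_perm - 1))
      tibble::tibble(
        gene_id = cds$gene_id[[i]],
        dinucleotide = DINUCS,
        observed = as.integer(obs),
        null_mean = mu,
        null_sd = sd,
        z = ifelse(sd > 0, (obs - mu) / sd, NA_real_)
      )
    })
  })
  out <- dplyr::bind_rows(out)
  attr(out, "model") <- model
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "replacement") <- replacement
  out
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
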