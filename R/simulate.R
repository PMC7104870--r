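#' Within-family codon preference weights
#'
#' Builds a table of per-codon sampling weights, normalised within each
#' synonymous family, for the synthetic CDS generator. With `alpha = Inf`
#' (default) every family is uniform; a finite `alpha` draws each family's
#' weights from a symmetric Dirichlet with that concentration (small values
#' give strongly skewed codon preference, the hallmark of a biased genome);
#' `one_hot = TRUE` collapses each family onto its highest-weight codon,
#' producing maximal bias (ENc 20, SCUO 1).
#'
#' Weights are drawn from the current RNG state; seed the caller (e.g. via
#' [simulate_cds()]'s `seed`) for reproducibility.
#'
#' @param alpha Dirichlet concentration (`Inf` = uniform).
#' @param one_hot Collapse each family onto one codon.
#' @param table_id NCBI translation table identifier.
#' @return A tibble with columns `codon`, `aa`, `weight`; weights sum to 1
#'   within each family (stop codons form their own family `"*"`).
#' @export
codon_weights <- function(alpha = Inf, one_hot = FALSE, table_id = 1L) {
  code <- genetic_code(table_id)
  w <- unlist(lapply(split(code$codon, code$aa), function(cods) {
    m <- length(cods)
    v <- if (is.finite(alpha)) {
      g <- stats::rgamma(m, shape = alpha)
      if (sum(g) == 0) rep(1 / m, m) else g / sum(g)
    } else {
      rep(1 / m, m)
    }
    stats::setNames(v, cods)
  }), use.names = TRUE)
  names(w) <- sub("^.*\\.", "", names(w))
  out <- code[, c("codon", "aa")]
  out$weight <- unname(w[out$codon])
  if (one_hot) {
    out <- out |>
      dplyr::group_by(.data$aa) |>
      dplyr::mutate(weight = as.numeric(seq_along(.data$weight) ==
                                          which.max(.data$weight))) |>
      dplyr::ungroup()
  }
  out
}

#' Invert codon preferences
#'
#' Reverses the within-family preference ranking: each family's weight
#' multiset is kept but reassigned so the least preferred codon becomes the
#' most preferred. Used to construct a maximally deoptimized virus from host
#' weights.
#'
#' @param weights A weight tibble from [codon_weights()].
#' @return A weight tibble of the same shape.
#' @export
invert_codon_weights <- function(weights) {
  weights |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(weight = {
      o <- order(.data$weight)
      v <- .data$weight
      v[o] <- rev(.data$weight[o])
      v
    }) |>
    dplyr::ungroup()
}

#' Mix two codon-weight tables
#'
#' Family-wise convex combination `(1 - delta) * a + delta * b`; with
#' `b = invert_codon_weights(a)` this interpolates from a fully host-adapted
#' codon usage (`delta = 0`) to a fully deoptimized one (`delta = 1`).
#'
#' @param a,b Weight tibbles on the same codon set.
#' @param delta Mixing proportion in `[0, 1]`.
#' @return A weight tibble.
#' @export
mix_codon_weights <- function(a, b, delta) {
  stopifnot(delta >= 0, delta <= 1, identical(a$codon, b$codon))
  out <- a
  out$weight <- (1 - delta) * a$weight + delta * b$weight
  out
}

#' GC3-driven codon weights (Wright's mutational null)
#'
#' Weights in which the only force on synonymous choice is third-position
#' composition: each codon's weight is proportional to `s/2` if its third
#' base is G or C and `(1 - s)/2` otherwise, renormalised within family.
#' Genes generated under these weights scatter around Wright's expected
#' ENc-GC3 curve.
#'
#' @param s Target third-position GC fraction in `[0, 1]`.
#' @param table_id NCBI translation table identifier.
#' @return A weight tibble as in [codon_weights()].
#' @export
gc3_codon_weights <- function(s, table_id = 1L) {
  stopifnot(s >= 0, s <= 1)
  w <- codon_weights(table_id = table_id)
  gc3 <- substr(w$codon, 3L, 3L) %in% c("G", "C")
  raw <- pmax(ifelse(gc3, s / 2, (1 - s) / 2), 1e-12)
  w |>
    dplyr::mutate(weight = raw) |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(weight = .data$weight / sum(.data$weight)) |>
    dplyr::ungroup()
}

# Expected GC3 of a codon draw under `weights` tilted by theta^[GC3],
# averaging amino acids uniformly.
tilted_gc3 <- function(weights, theta) {
  gc3 <- substr(weights$codon, 3L, 3L) %in% c("G", "C")
  w <- weights$weight * ifelse(gc3, theta, 1)
  fam <- split(seq_len(nrow(weights)), weights$aa)
  fam <- fam[names(fam) != "*"]
  mean(vapply(fam, function(idx) {
    if (sum(w[idx]) == 0) return(mean(gc3[idx]))
    sum(w[idx] * gc3[idx]) / sum(w[idx])
  }, numeric(1)))
}

# Tilt weights toward a target expected GC3 via a one-parameter exponential
# reweighting; errors when the target is unreachable given the support.
target_gc3_weights <- function(weights, gc3_target) {
  lo <- tilted_gc3(weights, exp(-18))
  hi <- tilted_gc3(weights, exp(18))
  if (gc3_target < lo - 1e-9 || gc3_target > hi + 1e-9) {
    stop(sprintf(
      "gc3_target %.3f infeasible for these weights (achievable range %.3f-%.3f)",
      gc3_target, lo, hi), call. = FALSE)
  }
  root <- stats::uniroot(
    function(lt) tilted_gc3(weights, exp(lt)) - gc3_target,
    lower = -18, upper = 18, tol = 1e-10
  )
  theta <- exp(root$root)
  gc3 <- substr(weights$codon, 3L, 3L) %in% c("G", "C")
  weights |>
    dplyr::mutate(weight = .data$weight * ifelse(gc3, theta, 1)) |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(weight = .data$weight / sum(.data$weight)) |>
    dplyr::ungroup()
}

#' Simulate a synthetic CDS set
#'
#' Generates multi-gene coding sequences with controllable codon-usage
#' structure: amino acids are drawn uniformly (or taken from a fixed
#' protein), synonymous codons are drawn per family from a weight table, and
#' every gene starts with ATG and ends with a stop codon. Identical
#' arguments (including `seed`) give byte-identical output; the caller's
#' RNG state is untouched.
#'
#' @param n_genes Number of genes.
#' @param length_range Two-element integer range of gene lengths in codons
#'   (start and stop included); a single value fixes the length.
#' @param weights A weight tibble ([codon_weights()] and friends); default
#'   uniform. Overrides `alpha`.
#' @param alpha Dirichlet concentration used to draw weights when `weights`
#'   is `NULL`; `Inf` (default) = uniform synonymous usage.
#' @param gc3_target Optional target third-position GC fraction; the weights
#'   are exponentially tilted to reach it (error if unreachable).
#' @param protein Optional amino-acid string (one-letter, no stops) used for
#'   every gene instead of random amino acids.
#' @param seed Integer seed.
#' @param table_id NCBI translation table identifier.
#' @return A CDS tibble (`gene_id`, `sequence`, `n_codons`).
#' @examples
#' cds <- simulate_cds(n_genes = 3, length_range = c(50, 80), seed = 7)
#' cds$n_codons
#' @export
simulate_cds <- function(n_genes = 50, length_range = c(200, 500),
                         weights = NULL, alpha = Inf, gc3_target = NULL,
                         protein = NULL, seed = 1, table_id = 1L) {
  local_seed(seed, {
    if (is.null(weights)) weights <- codon_weights(alpha, table_id = table_id)
    if (!is.null(gc3_target)) {
      weights <- target_gc3_weights(weights, gc3_target)
    }
    fam <- split(weights[, c("codon", "weight")], weights$aa)
    aa20 <- setdiff(names(fam), "*")
    draw_codons <- function(aas) {
      out <- character(length(aas))
      for (a in unique(aas)) {
        idx <- which(aas == a)
        f <- fam[[a]]
        out[idx] <- if (nrow(f) == 1L) f$codon else
          sample(f$codon, length(idx), replace = TRUE, prob = f$weight)
      }
      out
    }
    lens <- if (length(length_range) == 1L || length_range[1] == length_range[2]) {
      rep(length_range[1], n_genes)
    } else {
      sample(length_range[1]:length_range[2], n_genes, replace = TRUE)
    }
    seqs <- vapply(seq_len(n_genes), function(i) {
      aas <- if (is.null(protein)) {
        n_body <- lens[i] - 2L
        if (n_body < 0L) stop("length_range must allow >= 2 codons",
                              call. = FALSE)
        sample(aa20, n_body, replace = TRUE)
      } else {
        strsplit(protein, "", fixed = TRUE)[[1]]
      }
      stop_codon <- draw_codons("*")
      paste(c("ATG", draw_codons(aas), stop_codon), collapse = "")
    }, character(1))
    tibble::tibble(
      gene_id = sprintf("gene_%04d", seq_len(n_genes)),
      sequence = seqs,
      n_codons = nchar(seqs) %/% 3L
    )
  })
}

#' Simulate a co-adapted virus/host CDS pair
#'
#' Draws a skewed host codon preference (Dirichlet concentration `alpha`)
#' and builds the virus preference as the convex combination
#' `(1 - delta) * host + delta * inverted host`, where the inverted weights
#' reverse each family's preference ranking. `delta = 0` yields a maximally
#' host-adapted virus (SiD near 0, RCDI near 1, CAI near its maximum);
#' `delta = 1` a maximally deoptimized one.
#'
#' @param delta Divergence mixing proportion in `[0, 1]`.
#' @param n_host_genes,n_virus_genes Gene counts.
#' @param length_range Gene length range in codons.
#' @param alpha Host Dirichlet concentration (default 0.5: strong, realistic
#'   within-family skew).
#' @param seed Integer seed.
#' @param table_id NCBI translation table identifier.
#' @return A list with CDS tibbles `virus` and `host`, the two weight
#'   tables, and `delta`.
#' @export
simulate_virus_host <- function(delta, n_host_genes = 100, n_virus_genes = 30,
                                length_range = c(200, 500), alpha = 0.5,
                                seed = 1, table_id = 1L) {
  stopifnot(delta >= 0, delta <= 1)
  host_w <- local_seed(seed, codon_weights(alpha, table_id = table_id))
  virus_w <- mix_codon_weights(host_w, invert_codon_weights(host_w), delta)
  host <- simulate_cds(n_host_genes, length_range, weights = host_w,
                       seed = seed + 1L, table_id = table_id)
  virus <- simulate_cds(n_virus_genes, length_range, weights = virus_w,
                        seed = seed + 2L, table_id = table_id)
  virus$gene_id <- sub("^gene_", "vgene_", virus$gene_id)
  list(virus = virus, host = host,
       host_weights = host_w, virus_weights = virus_w, delta = delta)
}

#' Simulate CpG-depleted sequences
#'
#' Generates uniform-random sequences and then destroys a fraction of their
#' CpG dinucleotides by swapping `CG` to `GC` (which preserves the
#' mononucleotide counts exactly, so a base-permutation null sees a genuine
#' CpG deficit). Used to exercise dinucleotide signal detection.
#'
#' @param n_genes Number of sequences.
#' @param n_bases Sequence length (rounded down to a multiple of 3).
#' @param depletion Probability that each CpG occurrence is destroyed.
#' @param seed Integer seed.
#' @return A CDS-shaped tibble (`gene_id`, `sequence`, `n_codons`).
#' @export
simulate_cpg_depleted <- function(n_genes = 1, n_bases = 3000,
                                  depletion = 0.7, seed = 1) {
  n_bases <- (n_bases %/% 3L) * 3L
  local_seed(seed, {
    seqs <- vapply(seq_len(n_genes), function(i) {
      x <- sample(c("A", "C", "G", "T"), n_bases, replace = TRUE)
      hits <- which(x[-n_bases] == "C" & x[-1] == "G")
      for (h in hits) {
        if (stats::runif(1) < depletion) {
          x[h] <- "G"
          x[h + 1L] <- "C"
        }
      }
      paste(x, collapse = "")
    }, character(1))
    tibble::tibble(
      gene_id = sprintf("cpg_%04d", seq_len(n_genes)),
      sequence = seqs,
      n_codons = nchar(seqs) %/% 3L
    )
  })
}
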