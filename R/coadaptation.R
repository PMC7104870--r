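#' Relative codon deoptimization index (RCDI)
#'
#' Measures how far a viral gene's within-amino-acid codon frequencies
#' deviate from its host's (Mueller et al. 2006):
#' `RCDI = sum_j (CiF_a_j / CiF_h_j) * N_j / N`, where `CiF_a_j` is codon
#' `j`'s relative frequency within its amino acid in the viral gene,
#' `CiF_h_j` the same in the pooled host, `N_j` the codon's count in the
#' gene and `N` the gene's codon total. Stop codons are excluded. RCDI is 1
#' when the gene's synonymous usage is fully host-like and grows above 1
#' with deoptimization. Host codons never observed receive a pseudo-count
#' of 0.5 before frequencies, so every ratio is finite.
#'
#' @param virus_cds,host_cds CDS tibbles for the virus genes and the host
#'   gene set (the host is always pooled).
#' @param pooled Compute a single RCDI on the pooled virus counts instead of
#'   per virus gene.
#' @param table_id NCBI translation table identifier.
#' @return A tibble with columns `gene_id`, `rcdi` (`>= 1`).
#' @references Mueller et al. (2006) J Virol 80:9687-9696.
#' @export
rcdi <- function(virus_cds, host_cds, pooled = FALSE, table_id = 1L) {
  code <- genetic_code(table_id)
  sense <- code$codon[!is.na(code$degeneracy)]
  aa <- codon_to_aa(code)

  host <- count_codons(host_cds, by_gene = FALSE, table_id = table_id)
  host <- host[host$codon %in% sense, ]
  hc <- ifelse(host$count == 0, 0.5, host$count)
  fam_tot <- tapply(hc, host$aa, sum)
  cif_h <- stats::setNames(hc / as.numeric(fam_tot[host$aa]), host$codon)

  counts <- count_codons(virus_cds, by_gene = !pooled, table_id = table_id)
  counts <- counts[counts$codon %in% sense, ]
  counts |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      rcdi = {
        n <- sum(.data$count)
        fam <- tapply(.data$count, .data$aa, sum)
        cif_a <- .data$count / as.numeric(fam[.data$aa])
        used <- .data$count > 0
        sum(cif_a[used] / cif_h[.data$codon[used]] * .data$count[used]) / n
      },
      .groups = "drop"
    ) |>
    dplyr::left_join(x = dplyr::distinct(counts, .data$gene_id),
                     by = "gene_id")
}

#' Codon usage similarity index (SiD) between a virus and its host
#'
#' The cosine dissimilarity between the pooled RSCU vectors of the virus and
#' the host over the informative sense codons:
#' `R = sum(a_i b_i) / sqrt(sum(a_i^2) * sum(b_i^2))`, `SiD = (1 - R) / 2`,
#' where `a` is the virus RSCU and `b` the host RSCU. Higher values indicate
#' a larger distance between the viral codon usage and the host's — i.e. a
#' weaker dominating effect of the host on the virus's codon choice.
#' For non-negative RSCU vectors `R >= 0`, so SiD lies in `[0, 0.5]`
#' (published descriptions quote the nominal range `[0, 1]`). Undefined RSCU
#' entries (families a genome never uses) are treated as 0.
#'
#' @param virus_cds,host_cds CDS tibbles; RSCU is computed on pooled codon
#'   counts of each.
#' @param table_id NCBI translation table identifier.
#' @return A one-row tibble with columns `sid`, `cosine_similarity`,
#'   `n_codons` (size of the shared codon set).
#' @seealso [sid_from_rscu()] to compute SiD from precomputed RSCU tables.
#' @export
sid <- function(virus_cds, host_cds, table_id = 1L) {
  sid_from_rscu(
    rscu(virus_cds, pooled = TRUE, table_id = table_id),
    rscu(host_cds, pooled = TRUE, table_id = table_id)
  )
}

#' SiD from precomputed RSCU tables
#'
#' @param virus_rscu,host_rscu Pooled RSCU tibbles with columns `codon` and
#'   `rscu` (one row per codon, e.g. `rscu(x, pooled = TRUE)`).
#' @return A one-row tibble as for [sid()].
#' @export
sid_from_rscu <- function(virus_rscu, host_rscu) {
  if (anyDuplicated(virus_rscu$codon) || anyDuplicated(host_rscu$codon)) {
    stop("RSCU tables must be pooled: one row per codon ",
         "(use rscu(x, pooled = TRUE))", call. = FALSE)
  }
  shared <- intersect(virus_rscu$codon, host_rscu$codon)
  a <- stats::setNames(virus_rscu$rscu, virus_rscu$codon)[shared]
  b <- stats::setNames(host_rscu$rscu, host_rscu$codon)[shared]
  a[is.na(a)] <- 0
  b[is.na(b)] <- 0
  na2 <- sum(a^2)
  nb2 <- sum(b^2)
  if (na2 == 0 || nb2 == 0) {
    stop("SiD undefined: an RSCU vector has zero norm", call. = FALSE)
  }
  r <- sum(a * b) / sqrt(na2 * nb2)
  tibble::tibble(sid = (1 - r) / 2, cosine_similarity = r,
                 n_codons = length(shared))
}
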