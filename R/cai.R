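#' Select a CAI reference set from host ENc values
#'
#' The reference gene set for the codon adaptation index is taken from the
#' host: the fraction of host genes with the lowest effective number of
#' codons, i.e. the most biased genes, the standard proxy for high
#' expression. Ties are broken deterministically by `(enc, gene_id)`.
#'
#' @param host_enc A tibble with columns `gene_id`, `enc` (as from [enc()]);
#'   genes with `NA` ENc are ignored.
#' @param fraction Proportion of (defined-ENc) genes to select, in `(0, 1]`;
#'   `ceiling(fraction * N)` genes are returned. Default 0.05.
#' @return Character vector of selected `gene_id`s.
#' @export
select_reference_set <- function(host_enc, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  tbl <- dplyr::filter(host_enc, !is.na(.data$enc))
  if (nrow(tbl) == 0L) {
    stop("no host gene has a defined ENc; cannot build a reference set",
         call. = FALSE)
  }
  tbl <- dplyr::arrange(tbl, .data$enc, .data$gene_id)
  tbl$gene_id[seq_len(ceiling(fraction * nrow(tbl)))]
}

#' CAI relative-adaptiveness weights
#'
#' Relative adaptiveness of each informative sense codon, derived from the
#' pooled codon counts of a reference gene set:
#' `w_ij = RSCU_ij / max_j' RSCU_ij'` (Sharp & Li 1987). Codons absent from
#' the reference receive a pseudo-count of 0.5 before RSCU so every weight is
#' strictly positive; a family entirely unobserved in the reference falls
#' back to uniform weights of 1 through the same rule. Stop codons and
#' singleton families (Met, Trp) carry no weight.
#'
#' @param cds A CDS tibble holding (at least) the reference genes.
#' @param reference_ids Optional character vector of gene ids forming the
#'   reference set (e.g. from [select_reference_set()]); default all genes.
#' @param table_id NCBI translation table identifier.
#' @return A tibble with columns `codon`, `aa`, `w` (in `(0, 1]`, maximum 1
#'   within each family), carrying the zero-count rule and reference ids as
#'   attributes.
#' @references Sharp & Li (1987) Nucleic Acids Res 15:1281-1295.
#' @export
cai_weights <- function(cds, reference_ids = NULL, table_id = 1L) {
  if (!is.null(reference_ids)) {
    cds <- dplyr::filter(cds, .data$gene_id %in% reference_ids)
    if (nrow(cds) == 0L) {
      stop("none of the reference ids are present in `cds`", call. = FALSE)
    }
  }
  counts <- count_codons(cds, by_gene = FALSE, table_id = table_id)
  code <- genetic_code(table_id)
  info <- informative_codons(code)
  out <- counts |>
    dplyr::filter(.data$codon %in% info) |>
    dplyr::left_join(code[, c("codon", "degeneracy")], by = "codon") |>
    dplyr::mutate(count_adj = ifelse(.data$count == 0, 0.5, .data$count)) |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(
      rscu = .data$count_adj / (sum(.data$count_adj) / .data$degeneracy),
      w = .data$rscu / max(.data$rscu)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("codon", "aa", "w")
  attr(out, "zero_count_rule") <- "pseudo-count 0.5 on zero reference counts"
  attr(out, "reference_ids") <- if (is.null(reference_ids)) cds$gene_id else reference_ids
  out
}

#' Codon adaptation index (CAI)
#'
#' The geometric mean of the reference-derived relative-adaptiveness weights
#' over a gene's codons, excluding stop codons and the singleton families
#' (Met, Trp), following the Sharp & Li convention. 1 means every codon is
#' the reference set's preferred one.
#'
#' @param cds A CDS tibble.
#' @param weights A weight table from [cai_weights()].
#' @param pooled Compute a single CAI on pooled counts instead of per gene.
#' @param table_id NCBI translation table identifier.
#' @return A tibble with columns `gene_id`, `cai` (in `(0, 1]`, `NA` for a
#'   gene with no weighted codon).
#' @export
cai <- function(cds, weights, pooled = FALSE, table_id = 1L) {
  counts <- count_codons(cds, by_gene = !pooled, table_id = table_id)
  w <- stats::setNames(weights$w, weights$codon)
  counts |>
    dplyr::filter(.data$codon %in% names(w)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      cai = {
        n <- sum(.data$count)
        if (n == 0) NA_real_ else
          exp(sum(.data$count * log(w[.data$codon])) / n)
      },
      .groups = "drop"
    ) |>
    dplyr::left_join(x = dplyr::distinct(counts, .data$gene_id),
                     by = "gene_id")
}
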