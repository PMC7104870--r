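#' Positional GC content
#'
#' Overall GC fraction and the GC fraction at each of the three codon
#' positions, per gene. All codons of the record contribute, so for an
#' in-frame CDS the overall value is exactly the mean of the three
#' positional values.
#'
#' In addition to the plain positional values, `gc3s` reports the
#' silent-site variant of GC3: third-position GC over the codons of
#' multi-codon families only (stop codons and the non-degenerate ATG/TGG
#' excluded). This is the `s` of Wright's expected-ENc curve and the
#' x-coordinate of the ENc-GC3 plot; the always-G third positions of Met and
#' Trp would otherwise inflate it.
#'
#' @param cds A CDS tibble (`gene_id`, `sequence`).
#' @param table_id NCBI translation table identifier (used for `gc3s`).
#' @return A tibble with columns `gene_id`, `gc_overall`, `gc1`, `gc2`,
#'   `gc3`, `gc3s`, all fractions in `[0, 1]` (`gc3s` is `NA` for a gene
#'   with no multi-codon-family codon).
#' @examples
#' cds <- tibble::tibble(gene_id = "g", sequence = "ATGGCT")
#' gc_content(cds)
#' @export
gc_content <- function(cds, table_id = 1L) {
  info <- informative_codons(genetic_code(table_id))
  prof <- function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    gc <- b == "G" | b == "C"
    pos <- rep_len(1:3, length(b))
    cods <- codon_split(s)
    silent3 <- gc[pos == 3][cods %in% info]
    c(mean(gc), vapply(1:3, function(k) mean(gc[pos == k]), numeric(1)),
      if (length(silent3)) mean(silent3) else NA_real_)
  }
  m <- t(vapply(cds$sequence, prof, numeric(5), USE.NAMES = FALSE))
  tibble::tibble(
    gene_id = cds$gene_id,
    gc_overall = m[, 1], gc1 = m[, 2], gc2 = m[, 3], gc3 = m[, 4],
    gc3s = m[, 5]
  )
}

#' Parity-rule-2 coordinates
#'
#' Third-position base counts over the fourfold-degenerate codon families and
#' the PR2 biases: `at_bias = A3 / (A3 + T3)` and `gc_bias = G3 / (G3 + C3)`.
#' Under parity rule 2 (no strand-asymmetric mutation/selection pressure)
#' both biases sit at 0.5. A bias whose denominator is zero is undefined and
#' returned as `NA`, never silently zero.
#'
#' @param cds A CDS tibble.
#' @param include_sixfold_boxes Count the fourfold boxes of sixfold families
#'   (CGN Arg, CTN Leu, TCN Ser) as fourfold-degenerate (default `TRUE`,
#'   the usual Sueoka convention); set `FALSE` to restrict to the five
#'   strictly fourfold amino acids.
#' @param table_id NCBI translation table identifier.
#' @return A tibble with columns `gene_id`, `a3`, `t3`, `g3`, `c3`,
#'   `at_bias`, `gc_bias`.
#' @export
pr2_coordinates <- function(cds, include_sixfold_boxes = TRUE, table_id = 1L) {
  code <- genetic_code(table_id)
  ff <- fourfold_codons(code, include_sixfold_boxes)
  third <- stats::setNames(substr(ff, 3L, 3L), ff)
  one <- function(s) {
    cods <- codon_split(s)
    b3 <- third[cods[cods %in% ff]]
    vapply(c("A", "T", "G", "C"), function(x) sum(b3 == x), numeric(1))
  }
  m <- t(vapply(cds$sequence, one, numeric(4), USE.NAMES = FALSE))
  a3 <- m[, 1]; t3 <- m[, 2]; g3 <- m[, 3]; c3 <- m[, 4]
  tibble::tibble(
    gene_id = cds$gene_id,
    a3 = as.integer(a3), t3 = as.integer(t3),
    g3 = as.integer(g3), c3 = as.integer(c3),
    at_bias = ifelse(a3 + t3 > 0, a3 / (a3 + t3), NA_real_),
    gc_bias = ifelse(g3 + c3 > 0, g3 / (g3 + c3), NA_real_)
  )
}
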