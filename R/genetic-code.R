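#' Genetic code table
#'
#' Returns the genetic code as a tidy tibble: one row per codon, with the
#' encoded amino acid, the synonymous-family label, and the family degeneracy
#' (the number of synonymous codons for that amino acid under the chosen
#' translation table). Stop codons carry `aa = "*"` and `degeneracy = NA`.
#'
#' The table is the substrate every codon-usage index in the package consults:
#' RSCU divides observed counts by the uniform within-family expectation
#' `X_i / m_i`, ENc groups families by their degeneracy class, and CAI/RCDI/SiD
#' restrict themselves to the informative sense codons (families with
#' degeneracy greater than one).
#'
#' @param table_id NCBI translation table identifier (integer; 1 = standard
#'   code, the default).
#' @return A tibble with columns `codon`, `aa` (one-letter symbol, `"*"` for
#'   stop), `family` (amino-acid symbol of the synonymous family, `NA` for
#'   stops) and `degeneracy` (family size, `NA` for stops). Exactly 64 rows.
#' @examples
#' gc <- genetic_code()
#' dplyr::count(gc, degeneracy)
#' @export
genetic_code <- function(table_id = 1L) {
  code <- Biostrings::getGeneticCode(as.character(table_id))
  # getGeneticCode() names are RNA or DNA depending on version; normalise to DNA
  codons <- chartr("U", "T", names(code))
  tbl <- tibble::tibble(codon = codons, aa = unname(code))
  deg <- table(tbl$aa[tbl$aa != "*"])
  tbl$family <- ifelse(tbl$aa == "*", NA_character_, tbl$aa)
  tbl$degeneracy <- ifelse(tbl$aa == "*", NA_integer_,
                           as.integer(deg[tbl$aa]))
  attr(tbl, "table_id") <- as.integer(table_id)
  tbl
}

# All 64 codons in fixed lexicographic order (TCAG-free, plain ACGT order).
all_codons <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b3 = b, b2 = b, b1 = b, stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

#' Informative sense codons
#'
#' The sense codons of multi-codon synonymous families (59 under the
#' standard code: 61 sense codons minus ATG and TGG). This is the codon set
#' over which RSCU, CAI weights and SiD are defined.
#'
#' @param code A genetic-code tibble from [genetic_code()].
#' @return Character vector of codons.
#' @export
informative_codons <- function(code = genetic_code()) {
  code$codon[!is.na(code$degeneracy) & code$degeneracy > 1L]
}

# Named vector codon -> aa for fast lookup.
codon_to_aa <- function(code = genetic_code()) {
  stats::setNames(code$aa, code$codon)
}

# Amino acids whose family is strictly fourfold-degenerate at the third
# position (NNA/NNC/NNG/NNT all synonymous). For the standard code these are
# the five fourfold amino acids plus the fourfold boxes (CGN of Arg, CTN of
# Leu, TCN of Ser) when include_sixfold_boxes = TRUE.
fourfold_codons <- function(code = genetic_code(), include_sixfold_boxes = TRUE) {
  aa <- codon_to_aa(code)
  prefixes <- unique(substr(names(aa), 1L, 2L))
  keep <- character(0)
  for (p in prefixes) {
    cods <- paste0(p, c("A", "C", "G", "T"))
    fam <- unique(aa[cods])
    if (length(fam) == 1L && fam != "*") {
      deg <- sum(aa == fam)
      if (deg == 4L || (deg > 4L && include_sixfold_boxes)) {
        keep <- c(keep, cods)
      }
    }
  }
  keep
}
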