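# Test fixture helpers. raw_cds() builds genes by direct base-R sampling of
# sense codons, independent of the package's own generator.

SENSE_CODONS <- local({
  code <- Biostrings::getGeneticCode("1")
  names(code) <- chartr("U", "T", names(code))
  names(code)[code != "*"]
})

cds_tbl <- function(...) {
  seqs <- c(...)
  tibble::tibble(
    gene_id = if (is.null(names(seqs))) {
      paste0("g", seq_along(seqs))
    } else {
      names(seqs)
    },
    sequence = unname(seqs),
    n_codons = nchar(seqs) %/% 3L
  )
}

# n_codons sense codons sampled with the given per-codon probabilities
# (uniform by default), no start/stop structure.
raw_gene <- function(n_codons, prob = NULL) {
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE, prob = prob),
        collapse = "")
}

raw_cds <- function(n_genes, n_codons, seed, skew = NULL) {
  withr::with_seed(seed, {
    prob <- if (is.null(skew)) NULL else {
      p <- rgamma(length(SENSE_CODONS), shape = skew)
      p / sum(p)
    }
    cds_tbl(stats::setNames(
      vapply(seq_len(n_genes), function(i) raw_gene(n_codons, prob),
             character(1)),
      paste0("g", seq_len(n_genes))
    ))
  })
}

write_fasta_tmp <- function(cds) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(paste0(">", cds$gene_id, "\n", cds$sequence), path)
  path
}

# one uniform draw under a private seed, caller RNG untouched
local_unif <- function(seed, lo, hi) {
  withr::with_seed(seed, runif(1, lo, hi))
}
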