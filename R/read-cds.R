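#' Read coding sequences from a FASTA file
#'
#' Parses a (possibly gzipped) multi-FASTA file of coding sequences into a
#' tidy tibble, validating each record against basic CDS hygiene rules.
#' Sequences are uppercased and `U` is mapped to `T` before validation.
#' The identifier is the header token up to the first whitespace.
#'
#' Under the default `policy = "strict"`, records whose length is not a
#' positive multiple of 3 or that contain characters outside `ACGT` are
#' rejected and listed in the rejection log (see [cds_rejections()]).
#' Under `policy = "lenient"`, a trailing incomplete codon is trimmed and
#' codons containing ambiguity characters are dropped from the record; such
#' repairs are logged with `action = "repaired"`. Records containing internal
#' stop codons are kept under both policies but flagged in the log
#' (`action = "flagged"`): viral CDS annotations vary and downstream indices
#' ignore stop codons anyway.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @param policy `"strict"` (reject malformed records) or `"lenient"`
#'   (repair them where possible).
#' @param table_id NCBI translation table used to locate stop codons.
#' @return A tibble with columns `gene_id`, `sequence` and `n_codons`, in
#'   input order, carrying the rejection log as an attribute.
#' @seealso [cds_rejections()], [write_cds()], [read_virus_host_pair()]
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 a toy gene", "ATGGCTTAA"), fa)
#' read_cds(fa)
#' @export
read_cds <- function(path, policy = c("strict", "lenient"), table_id = 1L) {
  policy <- match.arg(policy)
  if (!file.exists(path)) {
    stop("cannot read FASTA file: ", path, call. = FALSE)
  }
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    stop("no FASTA records found in ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(raw))
  seqs <- chartr("u", "t", tolower(as.character(raw)))
  seqs <- toupper(chartr("u", "t", seqs))

  code <- genetic_code(table_id)
  stops <- code$codon[code$aa == "*"]

  kept_id <- character(0)
  kept_seq <- character(0)
  log_id <- character(0)
  log_reason <- character(0)
  log_action <- character(0)

  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    id <- ids[[i]]
    n <- nchar(s)
    bad_len <- n == 0L || n %% 3L != 0L
    has_ambig <- grepl("[^ACGT]", s)
    if (policy == "strict" && (bad_len || has_ambig)) {
      log_id <- c(log_id, id)
      log_reason <- c(log_reason, if (bad_len) {
        "length not multiple of 3"
      } else {
        "non-ACGT characters"
      })
      log_action <- c(log_action, "rejected")
      next
    }
    if (policy == "lenient" && (bad_len || has_ambig)) {
      if (n %% 3L != 0L) s <- substr(s, 1L, n - n %% 3L)
      cods <- codon_split(s)
      clean <- cods[!grepl("[^ACGT]", cods)]
      if (length(clean) == 0L) {
        log_id <- c(log_id, id)
        log_reason <- c(log_reason, "no intact codons after repair")
        log_action <- c(log_action, "rejected")
        next
      }
      reason <- paste(c(
        if (bad_len) "trimmed trailing partial codon",
        if (has_ambig) sprintf("dropped %d ambiguous codons",
                               length(cods) - length(clean))
      ), collapse = "; ")
      if (nzchar(reason)) {
        log_id <- c(log_id, id)
        log_reason <- c(log_reason, reason)
        log_action <- c(log_action, "repaired")
      }
      s <- paste(clean, collapse = "")
    }
    cods <- codon_split(s)
    internal_stop <- any(cods[-length(cods)] %in% stops)
    if (internal_stop) {
      log_id <- c(log_id, id)
      log_reason <- c(log_reason, "internal stop codon")
      log_action <- c(log_action, "flagged")
    }
    kept_id <- c(kept_id, id)
    kept_seq <- c(kept_seq, s)
  }

  if (length(kept_id) == 0L) {
    stop("no valid CDS records in ", path, " under policy '", policy, "'",
         call. = FALSE)
  }
  out <- tibble::tibble(
    gene_id = kept_id,
    sequence = kept_seq,
    n_codons = nchar(kept_seq) %/% 3L
  )
  attr(out, "rejections") <- tibble::tibble(
    gene_id = log_id, reason = log_reason, action = log_action
  )
  attr(out, "table_id") <- as.integer(table_id)
  out
}

#' Rejection log of a CDS tibble
#'
#' @param cds A tibble returned by [read_cds()].
#' @return A tibble with columns `gene_id`, `reason`, `action` (`"rejected"`,
#'   `"repaired"` or `"flagged"`). Empty when every record parsed cleanly.
#' @export
cds_rejections <- function(cds) {
  rej <- attr(cds, "rejections")
  if (is.null(rej)) {
    rej <- tibble::tibble(gene_id = character(0), reason = character(0),
                          action = character(0))
  }
  rej
}

#' Read a virus/host pair of CDS FASTA files
#'
#' @param virus_path,host_path FASTA paths, as for [read_cds()].
#' @inheritParams read_cds
#' @return A named list with elements `virus` and `host`, each a CDS tibble.
#' @export
read_virus_host_pair <- function(virus_path, host_path,
                                 policy = c("strict", "lenient"),
                                 table_id = 1L) {
  policy <- match.arg(policy)
  virus <- tryCatch(
    read_cds(virus_path, policy, table_id),
    error = function(e) stop("virus CDS file: ", conditionMessage(e),
                             call. = FALSE)
  )
  host <- tryCatch(
    read_cds(host_path, policy, table_id),
    error = function(e) stop("host CDS file: ", conditionMessage(e),
                             call. = FALSE)
  )
  list(virus = virus, host = host)
}

#' Write a CDS tibble to FASTA
#'
#' @param cds A CDS tibble (`gene_id`, `sequence`).
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_cds <- function(cds, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(cds$sequence, cds$gene_id))
  Biostrings::writeXStringSet(x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

# Split an in-frame sequence into its codons.
codon_split <- function(s) {
  n <- nchar(s)
  substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Tally codon usage
#'
#' Counts occurrences of each of the 64 codons, per gene or pooled over the
#' whole gene set. Pooled counts are the column sums of the per-gene counts:
#' pooling is always by codon-count summation, never by averaging per-gene
#' indices.
#'
#' @param cds A CDS tibble from [read_cds()] or [simulate_cds()].
#' @param by_gene If `TRUE` (default) return one row per gene and codon; if
#'   `FALSE` return pooled counts over all genes (`gene_id = "pooled"`).
#' @param table_id NCBI translation table identifier.
#' @return A tibble with columns `gene_id`, `codon`, `aa`, `count`; every
#'   gene contributes exactly 64 rows (zero counts included).
#' @examples
#' cds <- tibble::tibble(gene_id = "g", sequence = "ATGGCTGCTTAA")
#' dplyr::filter(count_codons(cds), count > 0)
#' @export
count_codons <- function(cds, by_gene = TRUE, table_id = 1L) {
  if (nrow(cds) == 0L) stop("no CDS records to count", call. = FALSE)
  codons <- all_codons()
  code <- genetic_code(table_id)
  aa <- codon_to_aa(code)
  mat <- codon_count_matrix(cds$sequence, codons)
  rownames(mat) <- cds$gene_id
  if (!by_gene) {
    mat <- matrix(colSums(mat), nrow = 1,
                  dimnames = list("pooled", codons))
  }
  tibble::tibble(
    gene_id = rep(rownames(mat), each = length(codons)),
    codon = rep(codons, times = nrow(mat)),
    aa = unname(aa[codon]),
    count = as.integer(t(mat))
  )
}

# genes x 64 integer matrix of codon counts; the fast path shared by all
# indices.
codon_count_matrix <- function(sequences, codons = all_codons()) {
  t(vapply(sequences, function(s) {
    cods <- codon_split(s)
    tabulate(match(cods, codons), nbins = length(codons))
  }, integer(length(codons)), USE.NAMES = FALSE))
}
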