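test_that("FASTA parsing tokenizes codons and preserves input order", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1 some description", "ATGGCTTAA",
               ">g2", "atggtt", "taa"), fa)
  cds <- read_cds(fa)
  expect_equal(cds$gene_id, c("g1", "g2"))
  expect_equal(cds$sequence[1], "ATGGCTTAA")
  expect_equal(cds$sequence[2], "ATGGTTTAA") # uppercased, lines joined
  expect_equal(cds$n_codons, c(3L, 3L))
  expect_equal(nrow(cds_rejections(cds)), 0L)
})

test_that("strict policy rejects frame violations and ambiguity codes", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ok9", "ATGGCTTAA",
               ">bad10", "ATGGCTTAAG",
               ">ok12", "ATGGCTGCTTAA",
               ">ambig", "ATGGNTTAA"), fa)
  cds <- read_cds(fa, policy = "strict")
  expect_equal(cds$gene_id, c("ok9", "ok12"))
  rej <- cds_rejections(cds)
  expect_equal(nrow(rej) + nrow(cds), 4L)
  expect_equal(rej$reason[rej$gene_id == "bad10"], "length not multiple of 3")
  expect_equal(rej$reason[rej$gene_id == "ambig"], "non-ACGT characters")
  expect_true(all(rej$action == "rejected"))
})

test_that("lenient policy trims partial codons and masks ambiguous ones", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">trim", "ATGGCTTAAG",
               ">mask", "ATGGNTGCTTAA"), fa)
  cds <- read_cds(fa, policy = "lenient")
  expect_equal(cds$sequence[cds$gene_id == "trim"], "ATGGCTTAA")
  expect_equal(cds$sequence[cds$gene_id == "mask"], "ATGGCTTAA")
  rej <- cds_rejections(cds)
  expect_true(all(rej$action == "repaired"))
})

test_that("internal stop codons are kept but flagged", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">istop", "ATGTAAGCTTAA"), fa)
  cds <- read_cds(fa)
  expect_equal(nrow(cds), 1L)
  log <- cds_rejections(cds)
  expect_equal(log$action, "flagged")
  expect_match(log$reason, "internal stop")
})

test_that("U is mapped to T and gzip input is accepted", {
  fa <- withr::local_tempfile(fileext = ".fasta.gz")
  con <- gzfile(fa, "w")
  writeLines(c(">rna", "AUGGCUUAA"), con)
  close(con)
  cds <- read_cds(fa)
  expect_equal(cds$sequence, "ATGGCTTAA")
})

test_that("unreadable or empty inputs raise errors, labelled by role for pairs", {
  expect_error(read_cds(tempfile()), "cannot read")
  fa_empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), fa_empty)
  fa_ok <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g", "ATGTAA"), fa_ok)
  expect_error(read_virus_host_pair(fa_empty, fa_ok), "virus CDS file")
  expect_error(read_virus_host_pair(fa_ok, fa_empty), "host CDS file")
  pair <- read_virus_host_pair(fa_ok, fa_ok)
  expect_identical(pair$virus$sequence, pair$host$sequence)
})

test_that("FASTA round-trip preserves id/sequence pairs", {
  cds <- raw_cds(5, 40, seed = 11)
  out <- withr::local_tempfile(fileext = ".fasta")
  write_cds(cds, out)
  back <- read_cds(out)
  expect_equal(back$gene_id, cds$gene_id)
  expect_equal(back$sequence, cds$sequence)
})

test_that("codon counting matches direct tallies and is additive", {
  cds <- cds_tbl(g1 = "ATGGCTGCTTAA")
  cnt <- count_codons(cds)
  expect_equal(nrow(cnt), 64L)
  expect_equal(sum(cnt$count), 4L)
  byc <- stats::setNames(cnt$count, cnt$codon)
  expect_equal(byc[["ATG"]], 1L)
  expect_equal(byc[["GCT"]], 2L)
  expect_equal(byc[["TAA"]], 1L)

  # pooling two copies doubles every count
  two <- cds_tbl(a = "ATGGCTGCTTAA", b = "ATGGCTGCTTAA")
  pooled <- count_codons(two, by_gene = FALSE)
  expect_equal(pooled$count, 2L * cnt$count)

  # additivity over an arbitrary partition of a random gene set
  cds <- raw_cds(6, 50, seed = 3)
  whole <- count_codons(cds, by_gene = FALSE)$count
  part <- count_codons(cds[1:2, ], by_gene = FALSE)$count +
    count_codons(cds[3:6, ], by_gene = FALSE)$count
  expect_equal(part, whole)
  expect_equal(sum(whole), 6L * 50L)
})
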