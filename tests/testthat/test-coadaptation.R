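test_that("reference-set selection takes the lowest-ENc fraction deterministically", {
  henc <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:100),
    enc = c(rep(30, 3), rep(55, 97))
  )
  expect_equal(select_reference_set(henc, 0.03), c("g001", "g002", "g003"))
  expect_equal(length(select_reference_set(henc, 0.05)), 5L)
  expect_setequal(select_reference_set(henc, 1), henc$gene_id)
  # selected genes never have higher ENc than any excluded gene
  ref <- select_reference_set(henc, 0.05)
  expect_lte(max(henc$enc[henc$gene_id %in% ref]),
             min(henc$enc[!henc$gene_id %in% ref]))
  expect_error(select_reference_set(dplyr::mutate(henc, enc = NA_real_)),
               "reference")
})

test_that("CAI weights follow the Sharp-Li RSCU ratios with 0.5 pseudo-counts", {
  # uniform family -> all weights 1
  w <- cai_weights(cds_tbl("TTTTTC"))
  expect_equal(w$w[w$aa == "F"], c(1, 1))

  # Phe 9:1 -> weights 1 and 1/9
  w <- cai_weights(cds_tbl(paste(c(rep("TTT", 9), "TTC"), collapse = "")))
  expect_equal(w$w[w$codon == "TTT"], 1)
  expect_equal(w$w[w$codon == "TTC"], 1 / 9, tolerance = 1e-12)

  # absent codon gets the pseudo-count weight 0.5 / max count, strictly > 0
  w <- cai_weights(cds_tbl(paste(rep("GGG", 8), collapse = "")))
  gly <- w[w$aa == "G", ]
  expect_equal(gly$w[gly$codon == "GGG"], 1)
  expect_equal(gly$w[gly$codon != "GGG"], rep(0.5 / 8, 3), tolerance = 1e-12)
  expect_true(all(w$w > 0 & w$w <= 1))

  # per-family maximum weight is 1 even for unobserved families (uniform fallback)
  maxima <- tapply(w$w, w$aa, max)
  expect_equal(as.numeric(maxima), rep(1, length(maxima)))
})

test_that("CAI is the geometric mean of weights over informative codons", {
  w <- cai_weights(cds_tbl(paste(c(rep("TTT", 3), "TTC"), collapse = "")))
  # gene of optimal codons only
  expect_equal(cai(cds_tbl("TTTTTT"), w)$cai, 1)
  # two codons with weights 1 and 1/3 -> sqrt(1/3)
  expect_equal(cai(cds_tbl("TTTTTC"), w)$cai, sqrt(1 / 3), tolerance = 1e-12)
  # Met/Trp/stop carry no weight
  expect_true(is.na(cai(cds_tbl("ATGTGGTAA"), w)$cai))
})

test_that("reference genes score higher CAI than uniform usage under their own weights", {
  host <- simulate_cds(30, c(150, 250), alpha = 0.3, seed = 31)
  henc <- enc(host)
  ref <- select_reference_set(henc, 0.2)
  w <- cai_weights(host, reference_ids = ref)
  ref_cai <- cai(host[host$gene_id %in% ref, ], w, pooled = TRUE)$cai
  uniform <- cds_tbl(paste(rep(SENSE_CODONS, each = 5), collapse = ""))
  expect_gt(ref_cai, cai(uniform, w)$cai)
  expect_true(ref_cai <= 1)
})

test_that("RCDI is 1 for host-identical usage and matches hand-computed toys", {
  host <- raw_cds(5, 200, seed = 41, skew = 0.5)
  # ensure every sense codon is observed so no pseudo-count perturbs the host
  host <- dplyr::bind_rows(
    host, cds_tbl(cover = paste(SENSE_CODONS, collapse = "")))
  # a virus that reuses the host sequences has identical frequencies
  virus <- cds_tbl(paste(host$sequence, collapse = ""))
  expect_equal(rcdi(virus, host)$rcdi, 1, tolerance = 1e-9)

  # single family toy: host Phe (0.9, 0.1), virus all-TTT
  host1 <- cds_tbl(paste(c(rep("TTT", 9), "TTC"), collapse = ""))
  virus1 <- cds_tbl("TTTTTT")
  expect_equal(rcdi(virus1, host1)$rcdi, 1 / 0.9, tolerance = 1e-12)
})

test_that("SiD hits its analytic extremes", {
  cds <- raw_cds(3, 120, seed = 51, skew = 0.4)
  expect_equal(sid(cds, cds)$sid, 0, tolerance = 1e-12)

  # disjoint support: one genome all-GGG Gly, the other all-GGA
  a <- cds_tbl(paste(rep("GGG", 10), collapse = ""))
  b <- cds_tbl(paste(rep("GGA", 10), collapse = ""))
  expect_equal(sid(a, b)$sid, 0.5, tolerance = 1e-12)
})

test_that("sid_from_rscu consumes pooled RSCU tables and rejects per-gene ones", {
  pair <- simulate_virus_host(0.4, n_host_genes = 10, n_virus_genes = 5,
                              length_range = c(100, 150), seed = 6)
  direct <- sid(pair$virus, pair$host)
  via_tables <- sid_from_rscu(rscu(pair$virus, pooled = TRUE),
                              rscu(pair$host, pooled = TRUE))
  expect_equal(via_tables$sid, direct$sid, tolerance = 1e-12)
  expect_equal(via_tables$n_codons, 59L)
  expect_error(sid_from_rscu(rscu(pair$virus), rscu(pair$host, pooled = TRUE)),
               "pooled")
})
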