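test_that("RSCU matches hand-derived family ratios", {
  r <- rscu(cds_tbl("TTTTTC")) # one each of Phe's codons
  phe <- r[r$aa == "F", ]
  expect_equal(phe$rscu, c(1, 1), ignore_attr = TRUE)

  r <- rscu(cds_tbl("TTTTTTTTTTTC")) # TTT x3, TTC x1
  expect_equal(r$rscu[r$codon == "TTT"], 1.5)
  expect_equal(r$rscu[r$codon == "TTC"], 0.5)

  r <- rscu(cds_tbl("GGGGGG")) # only GGG among Gly's 4 codons
  expect_equal(r$rscu[r$codon == "GGG"], 4)
  expect_equal(r$rscu[r$codon %in% c("GGA", "GGC", "GGT")], c(0, 0, 0))

  # unobserved families are NA, stop/Met/Trp absent, 59 codons
  expect_true(all(is.na(r$rscu[r$aa == "F"])))
  expect_equal(nrow(r), 59L)
  expect_false(any(r$codon %in% c("ATG", "TGG", "TAA", "TAG", "TGA")))
})

test_that("observed-family RSCU values sum to the family degeneracy", {
  code <- genetic_code()
  for (seed in 1:25) {
    cds <- raw_cds(1, 120, seed = seed, skew = 0.3)
    r <- rscu(cds)
    r <- r[!is.na(r$rscu), ]
    sums <- dplyr::summarise(dplyr::group_by(r, aa), s = sum(rscu))
    deg <- code$degeneracy[match(sums$aa, code$aa)]
    expect_equal(sums$s, as.numeric(deg), tolerance = 1e-12)
  }
})

test_that("Wright's expected ENc curve hits its anchor values", {
  expect_equal(expected_enc(0.5), 60.5, tolerance = 1e-12)
  expect_equal(expected_enc(0), 31, tolerance = 1e-12)
  expect_equal(expected_enc(1), 32, tolerance = 1e-12)
  expect_error(expected_enc(1.2))
})

test_that("ENc attains its analytic extremes", {
  # one codon per family, large n -> maximal bias, ENc 20
  one_hot <- simulate_cds(2, 400, weights = codon_weights(one_hot = TRUE),
                          seed = 1)
  expect_equal(enc(one_hot)$enc, c(20, 20))

  # every sense codon equally used -> uncapped value slightly above 61
  u <- cds_tbl(paste(rep(SENSE_CODONS, each = 100), collapse = ""))
  expect_equal(enc(u)$enc, 61)
  expect_true(all(enc(raw_cds(10, 100, seed = 4))$enc >= 20))
  expect_true(all(enc(raw_cds(10, 100, seed = 4))$enc <= 61))
})

test_that("ENc decreases as within-family skew grows", {
  alphas <- c(50, 5, 1, 0.3, 0.1, 0.02)
  encs <- vapply(seq_along(alphas), function(i) {
    cds <- simulate_cds(1, 3000, alpha = alphas[i], seed = 100 + i)
    enc(cds)$enc
  }, numeric(1))
  expect_true(all(diff(encs) <= 0))
  expect_lt(encs[length(encs)], 25)
  expect_gt(encs[1], 55)
})

test_that("Novembre's ENc responds to the background composition", {
  cds <- simulate_cds(3, 500, alpha = 1, seed = 8)
  own <- enc(cds, method = "novembre")
  expect_true(all(own$enc >= 20 & own$enc <= 61))
  skewed_bg <- c(A = 0.4, C = 0.1, G = 0.1, T = 0.4)
  other <- enc(cds, method = "novembre", background = skewed_bg)
  expect_false(isTRUE(all.equal(own$enc, other$enc)))
})

test_that("ENc errors when no synonymous family is usable", {
  expect_error(enc(cds_tbl("ATGTGG")), "undefined")
})

test_that("SCUO spans [0, 1] with the entropy extremes attained", {
  u <- cds_tbl(paste(rep(SENSE_CODONS, each = 10), collapse = ""))
  expect_equal(scuo(u)$scuo, 0, tolerance = 1e-12)
  one_hot <- simulate_cds(1, 300, weights = codon_weights(one_hot = TRUE),
                          seed = 2)
  expect_equal(scuo(one_hot)$scuo, 1, tolerance = 1e-12)

  # single Phe family with p = (0.75, 0.25)
  phe <- cds_tbl(paste(c(rep("TTT", 3), "TTC"), collapse = ""))
  h <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(scuo(phe)$scuo, 1 - h / log(2), tolerance = 1e-12)
  expect_equal(round(scuo(phe)$scuo, 4), 0.1887)

  vals <- scuo(raw_cds(10, 80, seed = 5, skew = 0.5))$scuo
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("pooled indices use summed counts, not averaged per-gene values", {
  cds <- raw_cds(4, 90, seed = 14, skew = 0.4)
  pooled_counts <- count_codons(cds, by_gene = FALSE)
  via_one_gene <- cds_tbl(paste(cds$sequence, collapse = ""))
  expect_equal(rscu(cds, pooled = TRUE)$rscu,
               rscu(via_one_gene)$rscu)
  expect_equal(enc(cds, pooled = TRUE)$enc, enc(via_one_gene)$enc)
  expect_equal(scuo(cds, pooled = TRUE)$scuo, scuo(via_one_gene)$scuo)
  expect_equal(sum(pooled_counts$count), sum(cds$n_codons))
})
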