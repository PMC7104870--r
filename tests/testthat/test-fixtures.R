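test_that("the generator is byte-deterministic and emits valid CDS", {
  a <- simulate_cds(5, c(50, 80), alpha = 0.5, seed = 9)
  b <- simulate_cds(5, c(50, 80), alpha = 0.5, seed = 9)
  expect_identical(a, b)
  fa <- withr::local_tempfile(fileext = ".fasta")
  fb <- withr::local_tempfile(fileext = ".fasta")
  write_cds(a, fa); write_cds(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  expect_false(identical(a$sequence,
                         simulate_cds(5, c(50, 80), alpha = 0.5,
                                      seed = 10)$sequence))

  stops <- c("TAA", "TAG", "TGA")
  for (s in a$sequence) {
    expect_equal(nchar(s) %% 3, 0)
    cods <- oracle_split(s)
    expect_equal(cods[1], "ATG")
    expect_true(cods[length(cods)] %in% stops)
    expect_false(any(cods[-length(cods)] %in% stops))
  }
})

test_that("uniform weights give pooled RSCU near 1 everywhere", {
  cds <- simulate_cds(400, 500, seed = 12)
  r <- rscu(cds, pooled = TRUE)
  expect_true(all(abs(r$rscu - 1) <= 0.1))
})

test_that("one-hot weights give the maximal-bias extremes", {
  cds <- simulate_cds(10, 200, weights = codon_weights(one_hot = TRUE),
                      seed = 3)
  expect_equal(enc(cds, pooled = TRUE)$enc, 20)
  expect_equal(scuo(cds, pooled = TRUE)$scuo, 1)
})

test_that("generated per-family codon frequencies recover the weights", {
  w <- local({
    set.seed(44)
    codon_weights(alpha = 0.8)
  })
  cds <- simulate_cds(40, 900, weights = w, seed = 45)
  counts <- count_codons(cds, by_gene = FALSE)
  counts <- counts[counts$aa != "*" & !counts$codon %in% c("ATG", "TGG"), ]
  merged <- dplyr::inner_join(counts, w, by = c("codon", "aa"))
  fam_tot <- tapply(merged$count, merged$aa, sum)
  n <- as.numeric(fam_tot[merged$aa])
  p_hat <- merged$count / n
  se <- sqrt(merged$weight * (1 - merged$weight) / n)
  expect_true(all(abs(p_hat - merged$weight) <= 3 * se + 1e-9))
})

test_that("GC3 targeting reaches feasible targets and rejects infeasible ones", {
  cds <- simulate_cds(30, 400, gc3_target = 0.7, seed = 17)
  gc3 <- mean(gc_content(cds)$gc3)
  expect_lt(abs(gc3 - 0.7), 0.05)
  expect_error(
    simulate_cds(2, 100, weights = codon_weights(one_hot = TRUE),
                 gc3_target = 0.9, seed = 1),
    "infeasible"
  )
})

test_that("weight inversion reverses each family's preference ranking", {
  w <- local({
    set.seed(5)
    codon_weights(alpha = 0.5)
  })
  inv <- invert_codon_weights(w)
  for (a in unique(w$aa)) {
    ww <- w$weight[w$aa == a]
    vv <- inv$weight[inv$aa == a]
    expect_equal(sort(ww), sort(vv))
    expect_equal(rank(vv), length(ww) + 1 - rank(ww))
  }
  # delta mixing interpolates between the two
  expect_equal(mix_codon_weights(w, inv, 0)$weight, w$weight)
  expect_equal(mix_codon_weights(w, inv, 1)$weight, inv$weight)
})

test_that("virus divergence delta steers SiD, RCDI and CAI as designed", {
  p0 <- simulate_virus_host(0, n_host_genes = 40, n_virus_genes = 15,
                            length_range = c(150, 250), seed = 88)
  p1 <- simulate_virus_host(1, n_host_genes = 40, n_virus_genes = 15,
                            length_range = c(150, 250), seed = 88)
  expect_identical(p0$host, p1$host)
  expect_lt(sid(p0$virus, p0$host)$sid, 0.05)
  expect_gt(sid(p1$virus, p1$host)$sid, sid(p0$virus, p0$host)$sid)
  expect_lt(mean(rcdi(p0$virus, p0$host)$rcdi), 1.5)
  expect_gt(mean(rcdi(p1$virus, p1$host)$rcdi),
            mean(rcdi(p0$virus, p0$host)$rcdi))
})
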