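# Independent naive reimplementations of every index, written as plain loops
# against their published definitions. They share no code with the package
# internals and serve as brute-force oracles.

ORACLE_CODE <- local({
  code <- Biostrings::getGeneticCode("1")
  names(code) <- chartr("U", "T", names(code))
  code
})

oracle_split <- function(s) {
  n <- nchar(s)
  out <- character(n %/% 3)
  for (i in seq_along(out)) out[i] <- substr(s, 3 * i - 2, 3 * i)
  out
}

oracle_families <- function(multi_only = TRUE) {
  sense <- ORACLE_CODE[ORACLE_CODE != "*"]
  fams <- list()
  for (a in unique(sense)) {
    cods <- names(sense)[sense == a]
    if (!multi_only || length(cods) > 1) fams[[a]] <- cods
  }
  fams
}

oracle_counts <- function(seqs) {
  counts <- stats::setNames(rep(0, 64), names(ORACLE_CODE))
  for (s in seqs) {
    for (cod in oracle_split(s)) counts[cod] <- counts[cod] + 1
  }
  counts
}

# RSCU over the 59 informative codons; NA for unobserved families.
oracle_rscu <- function(seqs) {
  x <- oracle_counts(seqs)
  fams <- oracle_families()
  out <- c()
  for (a in names(fams)) {
    cods <- fams[[a]]
    tot <- sum(x[cods])
    for (cod in cods) {
      out[cod] <- if (tot > 0) x[cod] / (tot / length(cods)) else NA_real_
    }
  }
  out
}

# Wright's ENc with the package's stated conventions (families with < 2
# codons dropped; missing threefold class imputed; renormalisation over
# represented amino acids; clamp to [20, 61]).
oracle_enc_wright <- function(seqs) {
  x <- oracle_counts(seqs)
  fams <- oracle_families()
  f_by_class <- list()
  for (a in names(fams)) {
    cods <- fams[[a]]
    n <- sum(x[cods])
    if (n < 2) next
    p <- x[cods] / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    key <- as.character(length(cods))
    f_by_class[[key]] <- c(f_by_class[[key]], f)
  }
  n_per_class <- c("2" = 9, "3" = 1, "4" = 5, "6" = 3)
  fbar <- c()
  for (m in names(n_per_class)) {
    v <- f_by_class[[m]]
    fbar[m] <- if (is.null(v) || mean(v) <= 0) NA_real_ else mean(v)
  }
  if (is.na(fbar["3"]) && !is.na(fbar["2"]) && !is.na(fbar["4"])) {
    fbar["3"] <- (fbar["2"] + fbar["4"]) / 2
  }
  ok <- !is.na(fbar)
  if (!any(ok)) return(NA_real_)
  partial <- 2 + sum(n_per_class[ok] / fbar[ok])
  covered <- 2 + sum(n_per_class[ok])
  val <- partial * 20 / covered
  unname(min(max(val, 20), 61))
}

# Novembre's composition-corrected ENc, background = the gene's own base
# composition.
oracle_enc_novembre <- function(seqs) {
  x <- oracle_counts(seqs)
  bg <- c(A = 0, C = 0, G = 0, T = 0)
  for (cod in names(x)) {
    if (x[cod] == 0) next
    for (b in c(substr(cod, 1, 1), substr(cod, 2, 2), substr(cod, 3, 3))) {
      bg[b] <- bg[b] + x[cod]
    }
  }
  bg <- bg / sum(bg)
  fams <- oracle_families()
  f_by_class <- list()
  for (a in names(fams)) {
    cods <- fams[[a]]
    m <- length(cods)
    n <- sum(x[cods])
    if (n < 2) next
    e <- numeric(m)
    for (k in seq_len(m)) {
      e[k] <- bg[substr(cods[k], 1, 1)] * bg[substr(cods[k], 2, 2)] *
        bg[substr(cods[k], 3, 3)]
    }
    e <- pmax(e / sum(e), 1e-12)
    chi2 <- 0
    for (k in seq_len(m)) chi2 <- chi2 + (x[cods[k]] - n * e[k])^2 / (n * e[k])
    f <- (chi2 + n - m) / (m * (n - 1))
    key <- as.character(m)
    f_by_class[[key]] <- c(f_by_class[[key]], f)
  }
  n_per_class <- c("2" = 9, "3" = 1, "4" = 5, "6" = 3)
  fbar <- c()
  for (m in names(n_per_class)) {
    v <- f_by_class[[m]]
    fbar[m] <- if (is.null(v) || mean(v) <= 0) NA_real_ else mean(v)
  }
  if (is.na(fbar["3"]) && !is.na(fbar["2"]) && !is.na(fbar["4"])) {
    fbar["3"] <- (fbar["2"] + fbar["4"]) / 2
  }
  ok <- !is.na(fbar)
  if (!any(ok)) return(NA_real_)
  partial <- 2 + sum(n_per_class[ok] / fbar[ok])
  covered <- 2 + sum(n_per_class[ok])
  val <- partial * 20 / covered
  unname(min(max(val, 20), 61))
}

oracle_scuo <- function(seqs) {
  x <- oracle_counts(seqs)
  fams <- oracle_families()
  tot_all <- 0
  contrib <- list()
  for (a in names(fams)) {
    n <- sum(x[fams[[a]]])
    if (n > 0) {
      contrib[[a]] <- n
      tot_all <- tot_all + n
    }
  }
  if (tot_all == 0) return(NA_real_)
  val <- 0
  for (a in names(contrib)) {
    cods <- fams[[a]]
    n <- contrib[[a]]
    h <- 0
    for (cod in cods) {
      p <- x[cod] / n
      if (p > 0) h <- h - p * log(p)
    }
    o <- (log(length(cods)) - h) / log(length(cods))
    val <- val + (n / tot_all) * o
  }
  unname(val)
}

# CAI weights from pooled reference sequences (0.5 pseudo-count on zeroes).
oracle_cai_weights <- function(ref_seqs) {
  x <- oracle_counts(ref_seqs)
  fams <- oracle_families()
  w <- c()
  for (a in names(fams)) {
    cods <- fams[[a]]
    cnt <- x[cods]
    cnt[cnt == 0] <- 0.5
    rscu <- cnt / (sum(cnt) / length(cods))
    for (cod in cods) w[cod] <- rscu[cod] / max(rscu)
  }
  w
}

# Geometric mean of weights over a gene's informative codons (log domain).
oracle_cai <- function(seqs, w) {
  acc <- 0
  n <- 0
  for (s in seqs) {
    for (cod in oracle_split(s)) {
      if (cod %in% names(w)) {
        acc <- acc + log(w[cod])
        n <- n + 1
      }
    }
  }
  if (n == 0) NA_real_ else unname(exp(acc / n))
}

oracle_rcdi <- function(virus_seqs, host_seqs) {
  sense <- names(ORACLE_CODE)[ORACLE_CODE != "*"]
  hx <- oracle_counts(host_seqs)[sense]
  hx[hx == 0] <- 0.5
  vx <- oracle_counts(virus_seqs)[sense]
  cif_h <- c()
  cif_a <- c()
  for (a in unique(ORACLE_CODE[sense])) {
    cods <- sense[ORACLE_CODE[sense] == a]
    for (cod in cods) {
      cif_h[cod] <- hx[cod] / sum(hx[cods])
      cif_a[cod] <- if (sum(vx[cods]) > 0) vx[cod] / sum(vx[cods]) else 0
    }
  }
  n <- sum(vx)
  val <- 0
  for (cod in sense) {
    if (vx[cod] > 0) val <- val + (cif_a[cod] / cif_h[cod]) * vx[cod] / n
  }
  unname(val)
}

oracle_sid <- function(virus_seqs, host_seqs) {
  a <- oracle_rscu(virus_seqs)
  b <- oracle_rscu(host_seqs)
  b <- b[names(a)]
  a[is.na(a)] <- 0
  b[is.na(b)] <- 0
  r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  unname((1 - r) / 2)
}

oracle_gc <- function(s) {
  b <- strsplit(s, "")[[1]]
  gc <- b %in% c("G", "C")
  pos <- rep(1:3, length.out = length(b))
  c(overall = mean(gc), gc1 = mean(gc[pos == 1]),
    gc2 = mean(gc[pos == 2]), gc3 = mean(gc[pos == 3]))
}

oracle_dinuc <- function(s) {
  dn <- c()
  for (a in c("A", "C", "G", "T")) for (b in c("A", "C", "G", "T")) {
    dn[paste0(a, b)] <- 0
  }
  ch <- strsplit(s, "")[[1]]
  for (i in seq_len(length(ch) - 1)) {
    d <- paste0(ch[i], ch[i + 1])
    dn[d] <- dn[d] + 1
  }
  dn
}
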