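# Small fixtures built in code, shared across test files.

# deterministic random genotype matrix with optional missingness
random_geno <- function(n = 10, j = 50, miss = 0, seed = 1) {
  set.seed(seed)
  calls <- matrix(sample(0:2, n * j, replace = TRUE), nrow = n)
  if (miss > 0) calls[runif(n * j) < miss] <- NA_integer_
  geno_matrix(calls)
}

# write a small hand-built VCF file, returning its path
write_fixture_vcf <- function(lines, dir = tempdir()) {
  path <- tempfile("fixture_", tmpdir = dir, fileext = ".vcf")
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", samples
    ), collapse = "\t")
  )
}

vcf_record <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
    collapse = "\t"
  )
}

# three-population outbred cohort used by several structure tests
three_pop_cohort <- function(n_per = 20, n_sites = 2000, drift = 0.2,
                             seed = 11, ...) {
  cfg <- sim_config(
    n_sites = n_sites, K = 3, drift = rep(drift, 3),
    groups = data.frame(
      label = c("P1", "P2", "P3"), size = n_per,
      mode = "outbred", founder_pop = 1:3
    ),
    seed = seed, ...
  )
  simulate_cohort(cfg)
}

# mean silhouette width for a labelled embedding (euclidean)
silhouette_mean <- function(coords, labels) {
  d <- as.matrix(stats::dist(coords))
  n <- nrow(d)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(
      setdiff(unique(labels), labels[i]),
      function(l) mean(d[i, labels == l]), numeric(1)
    ))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# literal per-site transcription of the 1984 variance-component formulas,
# evaluated by explicit loops on tiny instances
oracle_theta <- function(calls1, calls2) {
  r <- 2
  num <- 0
  den <- 0
  for (j in seq_len(ncol(calls1))) {
    g1 <- calls1[, j]
    g2 <- calls2[, j]
    g1 <- g1[!is.na(g1)]
    g2 <- g2[!is.na(g2)]
    if (length(g1) < 2 || length(g2) < 2) next
    n_i <- c(length(g1), length(g2))
    p_i <- c(sum(g1) / (2 * length(g1)), sum(g2) / (2 * length(g2)))
    h_i <- c(mean(g1 == 1), mean(g2 == 1))
    pbar_all <- sum(n_i * p_i) / sum(n_i)
    if (pbar_all <= 0 || pbar_all >= 1) next
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
      ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

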