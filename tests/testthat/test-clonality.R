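# brute-force per-site classification used as the oracle for the pair
# statistic: enumerate the four alleles of the pair at each shared site
oracle_pair <- function(ga, gb) {
  shared <- which(!is.na(ga) & !is.na(gb))
  n_var <- 0L
  n_cons <- 0L
  for (j in shared) {
    alleles_a <- c(rep(0L, 2 - ga[j]), rep(1L, ga[j]))
    alleles_b <- c(rep(0L, 2 - gb[j]), rep(1L, gb[j]))
    if (length(unique(c(alleles_a, alleles_b))) > 1) n_var <- n_var + 1L
    if (ga[j] == 1L && gb[j] == 1L) n_cons <- n_cons + 1L
  }
  c(n_var, n_cons)
}

test_that("pair statistic matches brute-force allele enumeration", {
  a <- c(1L, 1L, 0L, 2L, 0L)
  b <- c(1L, 2L, 0L, 2L, 2L)
  m <- geno_matrix(rbind(a = a, b = b))
  pc <- pair_conservation(m)
  expect_equal(c(pc$n_variable, pc$n_conserved_het), c(3L, 1L))
  expect_equal(pc$percent, 33.3)

  set.seed(31)
  for (i in 1:20) {
    ga <- sample(c(0:2, NA), 40, replace = TRUE)
    gb <- sample(c(0:2, NA), 40, replace = TRUE)
    m <- geno_matrix(rbind(x = ga, y = gb))
    pc <- pair_conservation(m, min_variable = 0)
    expect_equal(
      c(pc$n_variable, pc$n_conserved_het),
      as.integer(oracle_pair(ga, gb))
    )
  }
})

test_that("published count pairs reproduce their printed percentages", {
  expect_equal(conservation_percent(9726, 5065), 52.1)
  expect_equal(conservation_percent(16321, 7997), 49.0)
  expect_equal(conservation_percent(100, 0), 0.0)
  expect_error(conservation_percent(0, 0), "undefined")
})

test_that("conservation is symmetric and ignores half-missing sites", {
  m <- random_geno(6, 200, miss = 0.2, seed = 8)
  pc <- pair_conservation(m)
  swapped <- pair_conservation(
    m, pairs = data.frame(a = pc$sample_b, b = pc$sample_a)
  )
  expect_equal(pc$n_variable, swapped$n_variable)
  expect_equal(pc$n_conserved_het, swapped$n_conserved_het)

  # appending sites missing in one member never changes the statistic
  extra <- cbind(
    m$calls,
    matrix(NA_integer_, nrow = 6, ncol = 30)
  )
  extra[1, 201:230] <- 2L # present in sample 1 only
  colnames(extra) <- NULL
  m2 <- geno_matrix(extra)
  expect_equal(pair_conservation(m2)$percent_raw, pc$percent_raw)
})

test_that("identical clones give exactly 100%, zero variable pairs are inconclusive", {
  g <- c(1L, 1L, 0L, 2L, 1L)
  m <- geno_matrix(rbind(c1 = g, c2 = g))
  expect_equal(pair_conservation(m)$percent, 100)

  mono <- geno_matrix(rbind(a = c(0L, 2L), b = c(0L, 2L)))
  pc <- pair_conservation(mono)
  expect_true(is.na(pc$percent))
  expect_equal(pc$n_variable, 0L)
})

test_that("closed-form clonal conservation is exact and matched by Monte Carlo", {
  expect_equal(expected_clonal_conservation(0), 100)
  expect_equal(expected_clonal_conservation(0.35), 45.007, tolerance = 1e-4)

  set.seed(12)
  founder <- rep(1L, 50000)
  noisy <- function(d) apply_genotyping_noise(founder, d, 0)
  for (d in c(0.2, 0.35)) {
    m <- geno_matrix(rbind(a = noisy(d), b = noisy(d)))
    expect_equal(
      pair_conservation(m)$percent_raw,
      expected_clonal_conservation(d),
      tolerance = 0.5 / 45
    )
  }
})

test_that("conservation decreases monotonically with dropout", {
  pct_at <- function(d) {
    cfg <- sim_config(20000, 1, 0.2,
      groups = data.frame(label = "X", size = 2, mode = "clonal", founder_pop = 1),
      dropout_d = d, seed = 17
    )
    pair_conservation(simulate_cohort(cfg)$geno)$percent_raw
  }
  v <- vapply(c(0, 0.1, 0.2, 0.35), pct_at, numeric(1))
  expect_true(all(diff(v) < 0))
  expect_equal(v[1], 100)
})

test_that("unrelated outbred pairs at p = 0.5 sit near the HWE expectation", {
  # brute-force site probabilities at HWE, p = q = 0.5:
  # P(both het) = (2pq)^2; P(variable) = 1 - P(same homozygote both)
  p_same_hom <- 2 * (0.25)^2
  expected <- 100 * (0.5 * 0.5)^2 * 4 / (1 - p_same_hom)
  expect_equal(expected, 28.571, tolerance = 1e-3)

  set.seed(23)
  g <- function() rbinom(30000, 1, 0.5) + rbinom(30000, 1, 0.5)
  m <- geno_matrix(rbind(a = g(), b = g()))
  expect_equal(pair_conservation(m)$percent_raw, expected, tolerance = 0.035)
})

test_that("threshold calibration takes the weakest replicate minus margin", {
  cfg <- calibrate_threshold(c(49.0, 47.6, 43.9), margin = 4)
  expect_equal(cfg$threshold, 40, tolerance = 0.1)

  expect_warning(none <- calibrate_threshold(numeric()), "default")
  expect_equal(none$threshold, 40)

  expect_equal(calibrate_threshold(c(100, 100), margin = 4)$threshold, 96)
})

test_that("clonal groups are connected components above the threshold", {
  pairs <- tibble::tibble(
    sample_a = c("a", "b", "a", "a", "b", "c", "d", "d", "e"),
    sample_b = c("b", "c", "c", "d", "d", "d", "e", "f", "f"),
    n_variable = 100L, n_conserved_het = 50L,
    percent = c(45, 42, 39.6, 10, 12, 8, 11, 9, 50),
    percent_raw = c(45, 42, 39.6, 10, 12, 8, 11, 9, 50)
  )
  res <- call_clonal_groups(pairs, threshold = 40, margin = 4)
  memb <- setNames(res$membership$clone_id, res$membership$sample_id)
  # a-b, b-c direct; a-c borderline (39.6) annotated but still linked
  expect_equal(unname(memb[c("a", "b", "c")]), rep("clone_1", 3))
  expect_equal(unname(memb[c("e", "f")]), rep("clone_2", 2))
  expect_true(is.na(memb["d"]))
  expect_equal(
    res$edges$verdict[res$edges$percent == 39.6], "borderline"
  )

  # without borderline edges the 39.6 pair does not link
  res2 <- call_clonal_groups(
    pairs[pairs$percent %in% c(39.6, 50), ],
    threshold = 40, margin = 4, include_borderline = FALSE
  )
  memb2 <- setNames(res2$membership$clone_id, res2$membership$sample_id)
  expect_true(is.na(memb2["a"]))

  none <- call_clonal_groups(
    pairs[pairs$percent < 35, ],
    threshold = 40
  )
  expect_true(all(is.na(none$membership$clone_id)))
})

test_that("inconclusive pairs never form edges", {
  pairs <- tibble::tibble(
    sample_a = "a", sample_b = "b",
    n_variable = 0L, n_conserved_het = 0L,
    percent = NA_real_, percent_raw = NA_real_
  )
  res <- call_clonal_groups(pairs, threshold = 40)
  expect_equal(res$edges$verdict, "inconclusive")
  expect_true(all(is.na(res$membership$clone_id)))
})

test_that("simulated clonal trio is recovered among outbred samples", {
  groups <- data.frame(
    label = c("K", "O"), size = c(3L, 5L),
    mode = c("clonal", "outbred"), founder_pop = 1L
  )
  cfg <- sim_config(4000, 1, 0.2,
    groups = groups, dropout_d = 0.3, seed = 27
  )
  s <- simulate_cohort(cfg)
  res <- call_clonal_groups(pair_conservation(s$geno), threshold = 40)
  memb <- res$membership
  called <- memb$sample_id[!is.na(memb$clone_id)]
  expect_setequal(called, c("K_1", "K_2", "K_3"))
  expect_equal(length(unique(memb$clone_id[!is.na(memb$clone_id)])), 1L)
})
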