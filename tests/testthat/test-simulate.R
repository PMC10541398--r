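test_that("sim_config validates group specifications", {
  expect_error(
    sim_config(100, 2, c(0.1, 0.1),
      groups = data.frame(label = "X", size = 2, mode = "clonal", founder_pop = 5)
    ),
    "absent founder"
  )
  expect_error(
    sim_config(100, 2, c(0.1, 0.1),
      groups = tibble::tibble(
        label = "X", size = 2, mode = "admixed",
        q = list(c(0.5, 0.2))
      )
    ),
    "summing to 1"
  )
})

test_that("Balding-Nichols frequencies have the configured moments", {
  # zero-drift limit: population frequency equals the ancestral frequency
  cfg0 <- sim_config(500, 1, 0,
    groups = data.frame(label = "X", size = 1, mode = "outbred", founder_pop = 1),
    seed = 5
  )
  fr0 <- draw_population_frequencies(cfg0)
  expect_equal(as.vector(fr0$freqs), fr0$ancestral, tolerance = 1e-12)

  # F = 0.2: empirical variance of (freq - ancestral) is F * p * (1 - p)
  cfg <- sim_config(20000, 1, 0.2,
    groups = data.frame(label = "X", size = 1, mode = "outbred", founder_pop = 1),
    seed = 5
  )
  fr <- draw_population_frequencies(cfg)
  ratio <- (fr$freqs[1, ] - fr$ancestral)^2 /
    (fr$ancestral * (1 - fr$ancestral))
  expect_equal(mean(ratio), 0.2, tolerance = 0.05)
  expect_true(all(fr$freqs > 0 & fr$freqs < 1))
})

test_that("simulate_individual draws the two-copy admixture model", {
  freqs1 <- matrix(1, nrow = 1, ncol = 200)
  set.seed(1)
  expect_equal(simulate_individual(1, freqs1), rep(2L, 200))

  # q one-hot, f = 0.5: het fraction near 2pq = 0.5
  set.seed(2)
  g <- simulate_individual(1, matrix(0.5, 1, 10000))
  expect_equal(mean(g == 1), 0.5, tolerance = 0.015)

  # q = (0.5, 0.5) with f1 = 0, f2 = 1: each copy alt w.p. 0.5
  set.seed(3)
  g <- simulate_individual(c(0.5, 0.5), rbind(rep(0, 10000), rep(1, 10000)))
  expect_equal(mean(g == 1), 0.5, tolerance = 0.02)
  expect_equal(mean(g), 1, tolerance = 0.03)
})

test_that("clonal_replicate applies loss of heterozygosity at rate mu", {
  founder <- rep(c(0L, 1L, 2L), c(200, 1000, 300))
  set.seed(4)
  expect_identical(clonal_replicate(founder, 0), founder)
  g1 <- clonal_replicate(founder, 1)
  expect_equal(sum(g1 == 1L), 0)
  expect_identical(g1[founder != 1L], founder[founder != 1L])
  g <- clonal_replicate(founder, 0.05)
  expect_equal(sum(g == 1L), 950, tolerance = 0.025)
})

test_that("genotyping noise follows the dropout/error model", {
  g <- rep(c(0L, 1L, 2L), c(500, 1000, 500))
  set.seed(6)
  expect_identical(apply_genotyping_noise(g, 0, 0), g)
  g1 <- apply_genotyping_noise(g, 1, 0)
  expect_equal(sum(g1 == 1L), 0)
  # errors only touch homozygotes; dropout only touches heterozygotes
  g2 <- apply_genotyping_noise(g, 0, 1)
  expect_true(all(g2[g == 0L | g == 2L] == 1L))
  expect_identical(g2[g == 1L], g[g == 1L])
})

test_that("simulate_cohort is deterministic and writes coherent truth", {
  cfg <- sim_preset("garlic", n_sites = 300, seed = 9)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$geno$calls, s2$geno$calls)

  p1 <- tempfile(fileext = ".vcf")
  p2 <- tempfile(fileext = ".vcf")
  write_vcf(s1$geno, p1)
  write_vcf(s2$geno, p2)
  expect_identical(readLines(p1), readLines(p2))

  expect_equal(unname(rowSums(s1$truth$q)), rep(1, nrow(s1$truth$q)))
  expect_equal(nrow(s1$geno$calls), 49 + 3) # Table-1-like sizes + replicates
  reps <- s1$geno$samples[!is.na(s1$geno$samples$replicate_of), ]
  expect_equal(nrow(reps), 3)
  # clone members share a founder: noise-free run conserves het positions
  cfg0 <- sim_config(500, 2, c(0.2, 0.2),
    groups = data.frame(
      label = c("K1", "K2"), size = 3, mode = "clonal",
      founder_pop = 1:2
    ),
    seed = 2
  )
  s0 <- simulate_cohort(cfg0)
  expect_true(all(
    s0$truth$samples$clone_id == s0$truth$samples$group
  ))
})

test_that("noise-free clone pairs conserve 100% of heterozygous positions", {
  cfg <- sim_config(800, 1, 0.2,
    groups = data.frame(label = "X", size = 3, mode = "clonal", founder_pop = 1),
    seed = 3
  )
  s <- simulate_cohort(cfg)
  pc <- pair_conservation(s$geno)
  expect_true(all(pc$percent == 100))
})

test_that("empirical Fst increases with configured drift", {
  fst_at <- function(f) {
    cfg <- sim_config(1500, 2, c(f, f),
      groups = data.frame(
        label = c("P1", "P2"), size = 25, mode = "outbred",
        founder_pop = 1:2
      ),
      seed = 13
    )
    s <- simulate_cohort(cfg)
    pairwise_fst(
      s$geno,
      stats::setNames(s$truth$samples$group, s$truth$samples$sample_id),
      "P1", "P2"
    )
  }
  ests <- vapply(c(0.05, 0.15, 0.3), fst_at, numeric(1))
  expect_true(all(diff(ests) > 0))
})

test_that("MCAR missingness does not bias the conservation percentage", {
  conserve_at <- function(m, seed) {
    cfg <- sim_config(20000, 1, 0.2,
      groups = data.frame(label = "X", size = 2, mode = "clonal", founder_pop = 1),
      dropout_d = 0.3, missing_m = m, seed = seed
    )
    pair_conservation(simulate_cohort(cfg)$geno)$percent_raw
  }
  v0 <- conserve_at(0, 21)
  v5 <- conserve_at(0.5, 22)
  expect_equal(v0, v5, tolerance = 0.02)
})
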