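test_that("identical samples get identical PCA coordinates", {
  set.seed(71)
  base <- sample(0:2, 60, replace = TRUE)
  calls <- rbind(a = base, b = base, c = sample(0:2, 60, replace = TRUE))
  pca <- genotype_pca(geno_matrix(calls))
  expect_equal(
    unlist(pca$scores[1, -1]), unlist(pca$scores[2, -1]),
    tolerance = 1e-9
  )
})

test_that("PCA contribution ratios sum to 100% over full rank", {
  m <- random_geno(8, 100, seed = 73)
  pca <- genotype_pca(m, n_components = 8)
  expect_equal(sum(pca$contrib), 100, tolerance = 1e-8)
  expect_true(all(diff(pca$contrib) <= 1e-12)) # sorted decreasing
})

test_that("PCA separates three drifted populations", {
  s <- three_pop_cohort(n_per = 15, n_sites = 1500, drift = 0.15, seed = 79,
    missing_m = 0.1)
  pca <- genotype_pca(s$geno, n_components = 2)
  sil <- silhouette_mean(
    as.matrix(pca$scores[, c("PC1", "PC2")]),
    s$truth$samples$group
  )
  expect_gt(sil, 0.5)
})

test_that("PCA coordinates are invariant to sample order up to sign", {
  m <- random_geno(10, 200, miss = 0.1, seed = 83)
  p1 <- genotype_pca(m, 2)
  set.seed(1)
  perm <- sample(10)
  p2 <- genotype_pca(m[perm, ], 2)
  reord <- p2$scores[match(p1$scores$sample_id, p2$scores$sample_id), ]
  for (comp in c("PC1", "PC2")) {
    expect_true(
      isTRUE(all.equal(reord[[comp]], p1$scores[[comp]], tolerance = 1e-6)) ||
        isTRUE(all.equal(reord[[comp]], -p1$scores[[comp]], tolerance = 1e-6))
    )
  }
})

test_that("IBS distance matches hand-computed cases", {
  m <- geno_matrix(rbind(a = c(0L, 1L, 2L), b = c(1L, 1L, 0L)))
  d <- ibs_dist(m)
  expect_equal(d["a", "b"], 1 - mean(c(0.5, 1, 0)))

  same <- geno_matrix(rbind(x = c(0L, 1L, 2L), y = c(0L, 1L, 2L)))
  expect_equal(ibs_dist(same)["x", "y"], 0)

  opposite <- geno_matrix(rbind(x = rep(0L, 5), y = rep(2L, 5)))
  expect_equal(ibs_dist(opposite)["x", "y"], 1)
})

test_that("IBS distance is a metric on complete data", {
  brute_ibs <- function(gi, gj) mean(abs(gi - gj) / 2)
  set.seed(89)
  for (rep in 1:5) {
    m <- random_geno(8, 60, seed = 89 + rep)
    d <- unclass(ibs_dist(m))
    # against brute force
    for (i in 1:7) {
      for (j in (i + 1):8) {
        expect_equal(d[i, j], brute_ibs(m$calls[i, ], m$calls[j, ]))
      }
    }
    expect_equal(d, t(d))
    # triangle inequality over all ordered triples
    for (i in 1:8) {
      for (j in 1:8) {
        for (k in 1:8) {
          expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
        }
      }
    }
  }
})

test_that("pairs sharing no genotyped site are flagged", {
  calls <- rbind(
    a = c(1L, NA, NA),
    b = c(NA, 1L, 2L)
  )
  expect_warning(d <- ibs_dist(geno_matrix(calls)), "zero genotyped")
  expect_true(is.na(d["a", "b"]))
  expect_error(classical_mds(d), "undefined")
})

test_that("classical MDS exactly recovers planar configurations", {
  # equilateral triangle
  tri <- matrix(1, 3, 3) - diag(3)
  dimnames(tri) <- list(letters[1:3], letters[1:3])
  emb <- classical_mds(tri, k = 2)
  rec <- as.matrix(dist(as.matrix(emb$scores[, -1])))
  expect_equal(unname(rec), unname(tri), tolerance = 1e-9)

  # random planar points
  set.seed(97)
  pts <- matrix(rnorm(20), ncol = 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:10), paste0("s", 1:10))
  emb2 <- classical_mds(d, k = 2)
  rec2 <- as.matrix(dist(as.matrix(emb2$scores[, -1])))
  expect_equal(unname(rec2), unname(d), tolerance = 1e-9)
})

test_that("MDS of IBS distances separates populations like the PCA", {
  s <- three_pop_cohort(n_per = 12, n_sites = 1200, drift = 0.15, seed = 101)
  emb <- suppressMessages(classical_mds(ibs_dist(s$geno), k = 2))
  sil <- silhouette_mean(
    as.matrix(emb$scores[, c("PC1", "PC2")]),
    s$truth$samples$group
  )
  expect_gt(sil, 0.5)
})

test_that("UPGMA reproduces ultrametric input exactly", {
  two <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- upgma_tree(two)
  expect_equal(ape::write.tree(tr), "(A:0.2,B:0.2);")

  # 4-leaf ultrametric built by construction: ((a,b),(c,d))
  um <- matrix(0.8, 4, 4)
  um[1, 2] <- um[2, 1] <- 0.2
  um[3, 4] <- um[4, 3] <- 0.4
  diag(um) <- 0
  dimnames(um) <- list(letters[1:4], letters[1:4])
  tr4 <- upgma_tree(um)
  coph <- ape::cophenetic.phylo(tr4)[letters[1:4], letters[1:4]]
  expect_equal(unname(coph), unname(um), tolerance = 1e-12)
})

test_that("UPGMA is invariant to input permutation and clusters clones", {
  groups <- data.frame(
    label = c("K1", "K2", "O"), size = c(3L, 3L, 4L),
    mode = c("clonal", "clonal", "outbred"), founder_pop = c(1L, 2L, 1L)
  )
  cfg <- sim_config(1000, 2, c(0.2, 0.2), groups = groups,
    dropout_d = 0.1, seed = 103)
  s <- simulate_cohort(cfg)
  d <- ibs_dist(s$geno)
  t1 <- upgma_tree(d)
  set.seed(2)
  perm <- sample(nrow(d))
  t2 <- upgma_tree(d[perm, perm])
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))

  coph <- ape::cophenetic.phylo(t1)
  within <- c(coph["K1_1", "K1_2"], coph["K1_1", "K1_3"], coph["K2_1", "K2_2"])
  between <- coph["K1_1", "K2_1"]
  expect_true(all(within < between))
})

test_that("trait PCA standardizes, drops constants and places groups apart", {
  tab <- radclone_example("garlic_morphology.csv")
  anc <- tab[tab$group %in% c("A", "B", "C1"), ]
  pca <- trait_pca(anc[, -2])
  expect_equal(nrow(pca$scores), 10)

  centroids <- cbind(pca$scores[, c("PC1", "PC2")], grp = anc$group) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(dplyr::across(c("PC1", "PC2"), mean))
  spread <- cbind(pca$scores[, c("PC1", "PC2")], grp = anc$group) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(s = sqrt(mean((PC1 - mean(PC1))^2 + (PC2 - mean(PC2))^2)))
  dmin <- min(dist(as.matrix(centroids[, -1])))
  expect_gt(dmin, max(spread$s))

  # duplicated rows coincide; zero-variance traits are dropped
  dup <- data.frame(x = c(1, 1, 3), y = c(2, 2, 5), z = 1)
  expect_warning(p2 <- trait_pca(dup), "zero-variance")
  expect_equal(unlist(p2$scores[1, -1]), unlist(p2$scores[2, -1]))

  # near-identity covariance: roughly equal contributions
  set.seed(107)
  iso <- as.data.frame(matrix(rnorm(4000), ncol = 4))
  p3 <- trait_pca(iso, n_components = 4)
  expect_true(all(p3$contrib > 15 & p3$contrib < 35))
})
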