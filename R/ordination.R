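#' Genotype principal component analysis
#'
#' PCA of the dosage matrix with allele-frequency normalization: missing
#' entries are imputed to the site mean dosage, each site is centered by
#' its mean and scaled by `sqrt(2 * p * (1 - p))` (the binomial standard
#' deviation at the site's allele frequency), the convention of SNP-PCA
#' tooling. Monomorphic sites are dropped. The contribution ratio of
#' component i is `lambda_i / sum(lambda)` as a percent.
#'
#' @param m A [geno_matrix()].
#' @param n_components Number of components to retain.
#' @return An `ordination` object: `scores` (tibble `sample_id`,
#'   `PC1`...), `contrib` (percent variance per retained component),
#'   `eigenvalues` (all), `method = "pca"`.
#' @export
genotype_pca <- function(m, n_components = 2) {
  validate_geno_matrix(m)
  if (nrow(m$calls) < 2) stop("need at least 2 samples", call. = FALSE)
  x <- m$calls
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- mu[idx[, 2]]
  p <- mu / 2
  keep <- !is.na(p) & p > 0 & p < 1
  if (sum(keep) < 2) stop("fewer than 2 polymorphic sites", call. = FALSE)
  x <- x[, keep, drop = FALSE]
  x <- sweep(x, 2, mu[keep], "-")
  x <- sweep(x, 2, sqrt(2 * p[keep] * (1 - p[keep])), "/")
  ordination_from_matrix(x, m$samples$sample_id, n_components, "pca")
}

#' PCA of a numeric trait table
#'
#' Standardizes each trait to zero mean and unit variance (z-scores) and
#' runs a PCA, for e.g. morphological measurements. Zero-variance traits
#' are dropped with a warning.
#'
#' @param table Data frame: one row per sample, numeric trait columns; an
#'   optional `sample_id` column (or row names) labels samples.
#' @param n_components Number of components to retain.
#' @return An `ordination` object (see [genotype_pca()]).
#' @export
trait_pca <- function(table, n_components = 2) {
  table <- as.data.frame(table)
  if ("sample_id" %in% names(table)) {
    ids <- as.character(table$sample_id)
    table$sample_id <- NULL
  } else {
    ids <- rownames(table)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(table)))
  }
  x <- as.matrix(table)
  stopifnot(is.numeric(x))
  if (anyNA(x)) stop("trait table must have no missing values", call. = FALSE)
  if (nrow(x) < 2) stop("need at least 2 samples", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(
      "dropping zero-variance trait(s): ",
      paste(colnames(x)[sds == 0], collapse = ", ")
    )
    x <- x[, sds > 0, drop = FALSE]
  }
  x <- scale(x)
  ordination_from_matrix(x, ids, n_components, "pca")
}

ordination_from_matrix <- function(x, ids, n_components, method) {
  sv <- svd(x)
  lambda <- sv$d^2 / (nrow(x) - 1)
  k <- min(n_components, sum(sv$d > 1e-12))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("PC", seq_len(k))
  new_ordination(
    scores = tibble::as_tibble(scores) |>
      dplyr::mutate(sample_id = ids, .before = 1),
    contrib = 100 * lambda[seq_len(k)] / sum(lambda),
    eigenvalues = lambda,
    method = method
  )
}

new_ordination <- function(scores, contrib, eigenvalues, method) {
  structure(
    list(
      scores = scores, contrib = contrib,
      eigenvalues = eigenvalues, method = method
    ),
    class = "ordination"
  )
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf(
    "<ordination: %s> %d samples, %d components (%s)\n",
    x$method, nrow(x$scores), length(x$contrib),
    paste(sprintf("%.1f%%", x$contrib), collapse = ", ")
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy ordination
#' @export
tidy.ordination <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -"sample_id",
    names_to = "component", values_to = "score"
  )
}

#' Identity-by-state distance matrix
#'
#' Per sample pair, over the sites genotyped in both: allele-sharing
#' similarity `s = mean((2 - |g_i - g_j|) / 2)` and distance `1 - s`.
#' Pairs with zero shared sites get `NA` and a warning.
#'
#' @param m A [geno_matrix()].
#' @return A symmetric matrix of class `c("ibs_dist", "matrix")` with
#'   sample IDs as dimnames and a zero diagonal.
#' @export
ibs_dist <- function(m) {
  validate_geno_matrix(m)
  x <- m$calls
  n <- nrow(x)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  obs <- !is.na(x)
  x0 <- x
  x0[!obs] <- 0L
  # sum over shared sites of |gi - gj| decomposed by dosage-class cross counts
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  shared <- obs %*% t(obs)
  ind <- list(
    `0` = (x0 == 0L) & obs,
    `1` = (x0 == 1L) & obs,
    `2` = (x0 == 2L) & obs
  )
  cross <- function(a, b) ind[[a]] %*% t(ind[[b]])
  absdiff <- cross("0", "1") + cross("1", "0") +
    cross("1", "2") + cross("2", "1") +
    2 * (cross("0", "2") + cross("2", "0"))
  d <- absdiff / (2 * shared)
  if (any(shared[upper.tri(shared)] == 0)) {
    warning("sample pair(s) share zero genotyped sites; distance set to NA")
    d[shared == 0] <- NA_real_
  }
  diag(d) <- 0
  class(d) <- c("ibs_dist", "matrix")
  d
}

#' Classical (metric) multidimensional scaling
#'
#' Torgerson scaling of a distance matrix via [stats::cmdscale()]:
#' double-centering of squared distances, top-k eigenvectors scaled by
#' the square root of their eigenvalues. Negative eigenvalues (non-
#' Euclidean input) are dropped with a message; `k` is reduced with a
#' warning if fewer positive eigenvalues exist.
#'
#' @param d Symmetric distance matrix (e.g. from [ibs_dist()]).
#' @param k Number of dimensions.
#' @return An `ordination` object with `method = "mds"`; contributions
#'   are percentages of the positive eigenvalue total.
#' @export
classical_mds <- function(d, k = 2) {
  d <- unclass(d)
  stopifnot(is.matrix(d), isSymmetric(unname(d)))
  if (anyNA(d)) stop("distance matrix contains undefined entries", call. = FALSE)
  fit <- stats::cmdscale(stats::as.dist(d), k = min(k, nrow(d) - 1), eig = TRUE)
  eig <- fit$eig
  n_pos <- sum(eig > 1e-9)
  if (any(eig < -1e-9)) {
    message(sum(eig < -1e-9), " negative eigenvalue(s) dropped (non-Euclidean input)")
  }
  if (n_pos < k) {
    warning("only ", n_pos, " positive eigenvalue(s); k reduced")
  }
  kk <- min(k, n_pos)
  scores <- fit$points[, seq_len(kk), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(kk))
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(d)))
  new_ordination(
    scores = tibble::as_tibble(scores) |>
      dplyr::mutate(sample_id = ids, .before = 1),
    contrib = 100 * eig[seq_len(kk)] / sum(eig[eig > 0]),
    eigenvalues = eig,
    method = "mds"
  )
}

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomerative clustering. Input rows are reordered
#' lexicographically by sample ID first, making the result invariant to
#' input permutation (ties are then broken identically). Returned as an
#' `ape` `phylo` tree with ultrametric branch lengths (leaf depth equals
#' half the merge distance), exportable as Newick via
#' [ape::write.tree()].
#'
#' @param d Symmetric distance matrix with sample IDs as dimnames.
#' @return A `phylo` object.
#' @export
upgma_tree <- function(d) {
  d <- unclass(d)
  stopifnot(is.matrix(d), nrow(d) >= 2)
  if (anyNA(d)) {
    bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    stop(
      "undefined distances for pair(s): ",
      paste(rownames(d)[bad[, 1]], colnames(d)[bad[, 2]],
        sep = "/", collapse = ", "
      ),
      call. = FALSE
    )
  }
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ape::as.phylo(hc)
}
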