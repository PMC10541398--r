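EPS_FREQ <- 1e-6

#' Log-likelihood of the admixture model
#'
#' The binomial admixture likelihood: each allele copy of sample `i` at
#' site `j` is the alternate allele with probability
#' `pi_ij = sum_k Q[i,k] * F[k,j]`. Over non-missing dosages `g`,
#' `loglik = sum(g * log(pi) + (2 - g) * log(1 - pi))`. Frequencies are
#' clamped to `[1e-6, 1 - 1e-6]` so `pi` stays inside (0, 1).
#'
#' @param m A [geno_matrix()] (or a dosage matrix).
#' @param Q Samples x K ancestry matrix, rows on the simplex.
#' @param F_mat K x sites allele-frequency matrix.
#' @return Scalar log-likelihood.
#' @export
admix_loglik <- function(m, Q, F_mat) {
  G <- if (inherits(m, "geno_matrix")) m$calls else as.matrix(m)
  stopifnot(nrow(Q) == nrow(G), ncol(Q) == nrow(F_mat), ncol(F_mat) == ncol(G))
  F_mat <- pmin(pmax(F_mat, EPS_FREQ), 1 - EPS_FREQ)
  Pi <- Q %*% F_mat
  W <- !is.na(G)
  G0 <- ifelse(W, G, 0)
  G2 <- ifelse(W, 2 - G, 0)
  sum(G0 * log(Pi)) + sum(G2 * log(1 - Pi))
}

rdirichlet_rows <- function(n, k) {
  x <- matrix(stats::rgamma(n * k, shape = 1), nrow = n)
  x / rowSums(x)
}

# One EM update of (Q, F) in matrix-multiplication form: with R1 = g/pi
# and R2 = (2-g)/(1-pi) (zero at missing calls), the expected
# allele-origin counts collapse to
#   Qnew = Q * (R1 F' + R2 (1-F)') / (2 n_obs)
#   Fnew = F * (Q'R1) / (F * (Q'R1) + (1-F) * (Q'R2))
em_update <- function(Q, F_mat, G0, G2, n_obs) {
  Pi <- Q %*% F_mat
  R1 <- G0 / Pi
  R2 <- G2 / (1 - Pi)
  T1 <- crossprod(Q, R1) # K x J
  T2 <- crossprod(Q, R2)
  Qnew <- Q * (R1 %*% t(F_mat) + R2 %*% t(1 - F_mat)) / (2 * n_obs)
  num <- F_mat * T1
  Fnew <- num / pmax(num + (1 - F_mat) * T2, 1e-300)
  list(
    Q = Qnew / rowSums(Qnew), # exact simplex renormalization (numerical)
    F_mat = pmin(pmax(Fnew, EPS_FREQ), 1 - EPS_FREQ)
  )
}

# project an extrapolated step back to the feasible region
project_qf <- function(Q, F_mat) {
  Q <- pmax(Q, 0)
  rs <- rowSums(Q)
  rs[rs == 0] <- 1
  list(
    Q = Q / rs,
    F_mat = pmin(pmax(F_mat, EPS_FREQ), 1 - EPS_FREQ)
  )
}

# EM with squared extrapolation (SQUAREM) acceleration and a monotonicity
# safeguard. Plain multiplicative EM approaches simplex boundaries only
# sublinearly -- ancestry fractions that are truly zero decay slowly
# while the log-likelihood is already flat -- so a loglik-only stopping
# rule leaves spurious stray ancestry of several percent. Each cycle
# takes two EM steps, extrapolates (theta0 - 2a r + a^2 v with
# steplength a = -|r|/|v|, capped at -1), projects to the feasible
# region and stabilizes with one further EM step; if the extrapolated
# point is worse than the plain double-EM point the cycle falls back to
# the latter, so the per-cycle log-likelihood trace is non-decreasing
# (asserted). Convergence additionally requires the Q update to have
# stalled in parameter space.
em_one_start <- function(G, K, max_iter, tol, start_seed) {
  set.seed(start_seed)
  N <- nrow(G)
  J <- ncol(G)
  W <- !is.na(G)
  G0 <- ifelse(W, G, 0)
  G2 <- ifelse(W, 2 - G, 0)
  n_obs <- rowSums(W)
  Q <- rdirichlet_rows(N, K)
  F_mat <- matrix(stats::runif(K * J, 0.05, 0.95), nrow = K)
  ll_of <- function(Q, F_mat) {
    Pi <- Q %*% F_mat
    sum(G0 * log(Pi)) + sum(G2 * log(1 - Pi))
  }
  trace <- ll_of(Q, F_mat)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s1 <- em_update(Q, F_mat, G0, G2, n_obs)
    s2 <- em_update(s1$Q, s1$F_mat, G0, G2, n_obs)
    rQ <- s1$Q - Q
    rF <- s1$F_mat - F_mat
    vQ <- s2$Q - s1$Q - rQ
    vF <- s2$F_mat - s1$F_mat - rF
    vnorm <- sqrt(sum(vQ^2) + sum(vF^2))
    cand <- s2
    if (vnorm > 0) {
      alpha <- min(-sqrt(sum(rQ^2) + sum(rF^2)) / vnorm, -1)
      acc <- project_qf(
        Q - 2 * alpha * rQ + alpha^2 * vQ,
        F_mat - 2 * alpha * rF + alpha^2 * vF
      )
      acc <- em_update(acc$Q, acc$F_mat, G0, G2, n_obs) # stabilization step
      if (ll_of(acc$Q, acc$F_mat) >= ll_of(s2$Q, s2$F_mat)) cand <- acc
    }
    ll <- ll_of(cand$Q, cand$F_mat)
    prev <- trace[length(trace)]
    if (ll < prev - 1e-6) {
      stop("EM log-likelihood decreased; this indicates an internal error")
    }
    delta_q <- max(abs(cand$Q - Q))
    Q <- cand$Q
    F_mat <- cand$F_mat
    trace <- c(trace, ll)
    if (ll - prev < tol && delta_q < 1e-4) {
      converged <- TRUE
      break
    }
  }
  list(
    Q = Q, F_mat = F_mat, loglik = trace[length(trace)], trace = trace,
    converged = converged
  )
}

#' Fit the admixture model by EM
#'
#' Maximum-likelihood estimation of ancestry proportions `Q` and
#' population allele frequencies `F` under the binomial admixture model,
#' using the classical EM (FRAPPE-style) multiplicative updates under
#' SQUAREM squared-extrapolation acceleration with a monotonicity
#' safeguard, so the log-likelihood is non-decreasing across cycles
#' (asserted) while simplex-boundary entries (truly absent ancestry)
#' actually reach zero instead of stalling at a few percent. The best of
#' `n_starts` random restarts is returned.
#' Missing calls are simply omitted from all sums. Deterministic under a
#' fixed `seed`.
#'
#' @param m A [geno_matrix()].
#' @param K Number of ancestral populations (>= 1, <= number of samples).
#' @param n_starts Random restarts (default 8).
#' @param max_iter,tol Stopping rule: stop when the per-cycle
#'   log-likelihood improvement drops below `tol` and the Q update has
#'   stalled, or after `max_iter` acceleration cycles (each cycle spends
#'   about three EM updates).
#' @param seed Integer seed.
#' @return An `admix_fit` object: `Q` (samples x K, row names = sample
#'   IDs), `F_mat` (K x sites), `loglik`, `trace` (per-iteration
#'   log-likelihood of the winning start), `K`, `converged`.
#' @export
admix_fit <- function(m, K, n_starts = 8, max_iter = 500, tol = 1e-6,
                      seed = 1L) {
  validate_geno_matrix(m)
  G <- m$calls
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (K > nrow(G)) stop("K exceeds the number of samples", call. = FALSE)
  fits <- lapply(seq_len(n_starts), function(s) {
    em_one_start(G, K, max_iter, tol, stage_seed(seed, paste0("em_start", s)))
  })
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  rownames(best$Q) <- m$samples$sample_id
  colnames(best$Q) <- paste0("pop", seq_len(K))
  structure(
    list(
      Q = best$Q, F_mat = best$F_mat, loglik = best$loglik,
      trace = best$trace, K = K, converged = best$converged,
      n_starts = n_starts, seed = seed,
      sample_id = m$samples$sample_id
    ),
    class = "admix_fit"
  )
}

#' @export
print.admix_fit <- function(x, ...) {
  cat(sprintf(
    "<admix_fit> K = %d, %d samples, loglik = %.2f (%s after %d iterations)\n",
    x$K, nrow(x$Q), x$loglik,
    if (x$converged) "converged" else "iteration limit", length(x$trace)
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy admix_fit
#' @export
tidy.admix_fit <- function(x, ...) {
  tibble::as_tibble(x$Q) |>
    dplyr::mutate(sample_id = rownames(x$Q), .before = 1) |>
    tidyr::pivot_longer(-"sample_id",
      names_to = "cluster", values_to = "proportion"
    )
}

#' @importFrom generics glance
#' @method glance admix_fit
#' @export
glance.admix_fit <- function(x, ...) {
  tibble::tibble(
    K = x$K, loglik = x$loglik, n_iter = length(x$trace),
    n_starts = x$n_starts, converged = x$converged
  )
}

#' Align cluster labels between two ancestry matrices
#'
#' The admixture likelihood is invariant under simultaneous permutation of
#' Q columns and F rows, so fitted labels are arbitrary. Finds the column
#' permutation of `Q` minimizing the mean absolute difference to `Q_ref`
#' (exhaustive over permutations for K <= 7, greedy beyond).
#'
#' @param Q,Q_ref Samples x K matrices.
#' @return List: `Q` (permuted), `perm` (such that `Q[, perm]` aligns).
#' @export
align_clusters <- function(Q, Q_ref) {
  K <- ncol(Q)
  stopifnot(ncol(Q_ref) == K, nrow(Q_ref) == nrow(Q))
  cost <- function(perm) mean(abs(Q[, perm, drop = FALSE] - Q_ref))
  if (K <= 7) {
    perms <- permutations_of(K)
    best <- perms[[which.min(vapply(perms, cost, numeric(1)))]]
  } else {
    d <- matrix(0, K, K)
    for (a in seq_len(K)) {
      for (b in seq_len(K)) d[a, b] <- mean(abs(Q[, a] - Q_ref[, b]))
    }
    best <- integer(K)
    for (step in seq_len(K)) {
      idx <- which(d == min(d), arr.ind = TRUE)[1, ]
      best[idx[2]] <- idx[1]
      d[idx[1], ] <- Inf
      d[, idx[2]] <- Inf
    }
  }
  list(Q = Q[, best, drop = FALSE], perm = best)
}

permutations_of <- function(k) {
  if (k == 1) {
    return(list(1L))
  }
  sub <- permutations_of(k - 1)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(k)) {
      out <- c(out, list(append(p, k, after = pos - 1)))
    }
  }
  out
}

#' Cross-validated choice of K by masked-entry prediction
#'
#' For each fold, a fraction of the non-missing calls is masked (set
#' missing), the model is refit on the masked data, and the held-out
#' error is the mean squared deviation between the masked dosage `g` and
#' its prediction `2 * pi_hat`. Errors are averaged over folds; the
#' selected K attains the minimum of the CV curve. If a mask would leave
#' a sample with no observed calls, the mask is redrawn (bounded
#' retries).
#'
#' @param m A [geno_matrix()].
#' @param K_grid Integer vector of K values (non-empty).
#' @param mask_fraction Fraction of observed entries to hold out
#'   (in (0, 1)).
#' @param n_folds Number of independent masks.
#' @param seed Integer seed.
#' @param n_starts,max_iter,tol Passed to the EM fits (lighter defaults
#'   than [admix_fit()]: the CV curve needs relative, not absolute,
#'   likelihood precision).
#' @return An `admix_cv` object: `curve` (tibble `K`, `cv_error`),
#'   `selected_K`, `folds` (per-fold errors).
#' @export
admix_cv <- function(m, K_grid, mask_fraction = 0.1, n_folds = 5,
                     seed = 1L, n_starts = 2, max_iter = 100, tol = 1e-4) {
  validate_geno_matrix(m)
  if (length(K_grid) == 0) stop("K_grid must be non-empty", call. = FALSE)
  if (mask_fraction <= 0 || mask_fraction >= 1) {
    stop("mask_fraction must be in (0, 1)", call. = FALSE)
  }
  G <- m$calls
  obs_idx <- which(!is.na(G))
  errs <- matrix(NA_real_, nrow = n_folds, ncol = length(K_grid),
    dimnames = list(NULL, paste0("K", K_grid)))
  for (fold in seq_len(n_folds)) {
    set.seed(stage_seed(seed, paste0("cvmask", fold)))
    for (try in seq_len(20)) {
      mask <- sample(obs_idx, size = max(1, round(mask_fraction * length(obs_idx))))
      Gm <- G
      Gm[mask] <- NA_integer_
      if (all(rowSums(!is.na(Gm)) > 0)) break
      if (try == 20) stop("masking repeatedly left a sample with no data", call. = FALSE)
    }
    mm <- m
    mm$calls <- Gm
    for (ki in seq_along(K_grid)) {
      fit <- admix_fit(mm, K_grid[ki],
        n_starts = n_starts, max_iter = max_iter, tol = tol,
        seed = stage_seed(seed, paste0("cvfit", fold, "_", ki))
      )
      Pi <- fit$Q %*% fit$F_mat
      errs[fold, ki] <- mean((G[mask] - 2 * Pi[mask])^2)
    }
  }
  curve <- tibble::tibble(K = K_grid, cv_error = colMeans(errs))
  structure(
    list(
      curve = curve,
      selected_K = K_grid[which.min(curve$cv_error)],
      folds = errs
    ),
    class = "admix_cv"
  )
}

#' @export
print.admix_cv <- function(x, ...) {
  cat(sprintf("<admix_cv> selected K = %d\n", x$selected_K))
  print(x$curve)
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy admix_cv
#' @export
tidy.admix_cv <- function(x, ...) x$curve
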