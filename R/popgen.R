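#' Per-site expected heterozygosity
#'
#' `He = 1 - p^2 - q^2` with the allele frequency estimated from
#' non-missing diploid calls.
#'
#' @param calls Integer dosage vector (one site, one population).
#' @return He in \[0, 1\]; `NA` if every call is missing.
#' @export
site_he <- function(calls) {
  obs <- calls[!is.na(calls)]
  if (length(obs) == 0) {
    return(NA_real_)
  }
  p <- sum(obs) / (2 * length(obs))
  1 - p^2 - (1 - p)^2
}

#' Per-site nucleotide diversity (unbiased)
#'
#' Mean pairwise allele difference over the `n` non-missing alleles:
#' `pi = 2 * n_ref * n_alt / (n * (n - 1))`.
#'
#' @param calls Integer dosage vector (one site, one population).
#' @return pi in \[0, 1\]; `NA` when fewer than 2 alleles observed.
#' @export
site_pi <- function(calls) {
  obs <- calls[!is.na(calls)]
  n <- 2 * length(obs)
  if (n < 2) {
    return(NA_real_)
  }
  n_alt <- sum(obs)
  2 * n_alt * (n - n_alt) / (n * (n - 1))
}

#' Per-site inbreeding coefficient
#'
#' `Fis = 1 - Ho / He`, `Ho` being the observed heterozygote fraction.
#' Negative values indicate an excess of heterozygotes over the
#' Hardy-Weinberg expectation (e.g. fixed heterozygosity in clonal
#' lineages); positive values indicate inbreeding.
#'
#' @param calls Integer dosage vector (one site, one population).
#' @return Fis in \[-1, 1\]; `NA` when the site is monomorphic (He = 0).
#' @export
site_fis <- function(calls) {
  obs <- calls[!is.na(calls)]
  he <- site_he(calls)
  if (is.na(he) || he == 0) {
    return(NA_real_)
  }
  ho <- mean(obs == 1L)
  1 - ho / he
}

# Weir-Cockerham (1984) per-site variance components for r populations.
# p: per-pop alt frequency, n: per-pop diploid sample size, h: per-pop
# observed het fraction. Returns c(a, b, c) for one site.
wc_components <- function(p, n, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Pairwise Weir-Cockerham Fst between two populations
#'
#' Per-site variance components a (among populations), b (among
#' individuals within populations) and c (within individuals) are
#' combined across sites as a ratio of sums, `theta = sum(a) / sum(a+b+c)`.
#' Sites are used when both populations have at least 2 genotyped
#' individuals and the site is polymorphic across the pooled pair;
#' negative per-site components are retained in the sums (standard for
#' the unbiased estimator), so slightly negative totals are possible and
#' are reported as computed.
#'
#' @param m A [geno_matrix()].
#' @param assignment Named character vector or tibble
#'   (`sample_id`, `population`) mapping samples to populations.
#' @param pop1,pop2 Population labels to compare.
#' @return Scalar theta estimate.
#' @export
pairwise_fst <- function(m, assignment, pop1, pop2) {
  validate_geno_matrix(m)
  assignment <- as_assignment(assignment, m)
  g1 <- m$calls[names(assignment)[assignment == pop1], , drop = FALSE]
  g2 <- m$calls[names(assignment)[assignment == pop2], , drop = FALSE]
  if (nrow(g1) < 2 || nrow(g2) < 2) {
    stop("each population needs at least 2 individuals", call. = FALSE)
  }
  n1 <- colSums(!is.na(g1))
  n2 <- colSums(!is.na(g2))
  p1 <- ifelse(n1 > 0, colSums(g1, na.rm = TRUE) / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, colSums(g2, na.rm = TRUE) / (2 * n2), NA_real_)
  h1 <- ifelse(n1 > 0, colSums(g1 == 1L, na.rm = TRUE) / n1, NA_real_)
  h2 <- ifelse(n2 > 0, colSums(g2 == 1L, na.rm = TRUE) / n2, NA_real_)

  pooled_p <- (2 * n1 * p1 + 2 * n2 * p2) / (2 * (n1 + n2))
  use <- n1 >= 2 & n2 >= 2 & !is.na(pooled_p) & pooled_p > 0 & pooled_p < 1
  if (!any(use)) {
    stop("no shared polymorphic sites between ", pop1, " and ", pop2,
      call. = FALSE
    )
  }
  comp <- vapply(
    which(use),
    function(j) wc_components(c(p1[j], p2[j]), c(n1[j], n2[j]), c(h1[j], h2[j])),
    numeric(3)
  )
  sum(comp[1, ]) / sum(comp)
}

as_assignment <- function(assignment, m) {
  if (is.data.frame(assignment)) {
    assignment <- stats::setNames(
      as.character(assignment$population),
      assignment$sample_id
    )
  }
  if (is.null(names(assignment))) {
    stop("assignment must be named by sample_id", call. = FALSE)
  }
  assignment <- assignment[names(assignment) %in% m$samples$sample_id]
  assignment[!is.na(assignment)]
}

#' Per-population diversity summary and pairwise Fst matrix
#'
#' For each population, He and pi are averaged over the analyzed variant
#' sites passing a per-population presence filter (default 0.7), and Fis
#' over the subset of those sites polymorphic within the population (its
#' precondition). Averaging He/pi over all analyzed sites — not only
#' within-population polymorphic ones — is what makes clonal lineages,
#' where most sites are invariant copies of one founder, show the low
#' diversity they actually have. Populations with fewer than 2 members
#' are excluded with a warning.
#'
#' @param m A [geno_matrix()].
#' @param assignment Named character vector or tibble
#'   (`sample_id`, `population`).
#' @param min_presence Per-population site presence threshold.
#' @return A list of class `pop_stats`: `stats` (tibble `population`,
#'   `n_samples`, `n_sites`, `mean_he`, `mean_pi`, `mean_fis`) and `fst`
#'   (symmetric matrix of pairwise theta; empty for a single population).
#' @export
population_summary <- function(m, assignment, min_presence = 0.7) {
  validate_geno_matrix(m)
  assignment <- as_assignment(assignment, m)
  pops <- sort(unique(assignment))
  sizes <- table(assignment)
  small <- pops[sizes[pops] < 2]
  if (length(small)) {
    warning(
      "excluding population(s) with < 2 members: ",
      paste(small, collapse = ", ")
    )
    pops <- setdiff(pops, small)
  }
  if (length(pops) == 0) stop("no population with >= 2 members", call. = FALSE)

  stats_tbl <- purrr::map_dfr(pops, function(pop) {
    g <- m$calls[names(assignment)[assignment == pop], , drop = FALSE]
    ok <- colMeans(!is.na(g)) >= min_presence
    g <- g[, ok, drop = FALSE]
    he <- apply(g, 2, site_he)
    pi <- apply(g, 2, site_pi)
    fis <- apply(g, 2, site_fis)
    tibble::tibble(
      population = pop,
      n_samples = nrow(g),
      n_sites = sum(ok),
      mean_he = mean(he, na.rm = TRUE),
      mean_pi = mean(pi, na.rm = TRUE),
      mean_fis = mean(fis, na.rm = TRUE)
    )
  })

  fst <- matrix(0,
    nrow = length(pops), ncol = length(pops),
    dimnames = list(pops, pops)
  )
  if (length(pops) >= 2) {
    for (i in seq_along(pops)[-length(pops)]) {
      for (j in seq((i + 1), length(pops))) {
        theta <- pairwise_fst(m, assignment, pops[i], pops[j])
        fst[i, j] <- theta
        fst[j, i] <- theta
      }
    }
  } else {
    fst <- fst[0, 0, drop = FALSE]
  }
  structure(list(stats = stats_tbl, fst = fst), class = "pop_stats")
}

#' @export
print.pop_stats <- function(x, ...) {
  cat("<pop_stats>\n")
  print(x$stats)
  if (nrow(x$fst)) {
    cat("pairwise Fst:\n")
    print(round(x$fst, 4))
  }
  invisible(x)
}
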