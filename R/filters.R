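#' Genotype-level site filters
#'
#' Applies the standard RAD-Seq genotype filters: minimum presence
#' (fraction of samples with a non-missing call), one SNP per locus, and
#' minimum minor allele frequency. Defaults mirror common reduced-
#' representation practice (`min_presence = 0.5`, `min_maf = 0.05`,
#' single SNP per locus on).
#'
#' MAF is computed from allele counts over non-missing diploid calls; a
#' site at exactly `min_maf` is retained (`>=` comparison). A site with
#' every call missing is removed by any positive presence threshold. The
#' order of application is presence, then single-SNP, then MAF —
#' locus-level selection before the site-frequency screen — and is
#' configurable via `order`. Filtering only drops sites; surviving calls
#' are never altered, so the operation is idempotent.
#'
#' @param m A [geno_matrix()].
#' @param min_presence Minimum fraction of samples genotyped at a site.
#' @param min_maf Minimum minor allele frequency in \[0, 0.5\].
#' @param single_snp_per_locus Keep only the lowest-position SNP per locus?
#' @param order Character vector permutation of
#'   `c("presence", "single_snp", "maf")` giving the application order.
#' @return The filtered `geno_matrix`, with an `attrition` attribute: a
#'   tibble of sites removed per filter step.
#' @export
filter_genotypes <- function(m, min_presence = 0.5, min_maf = 0.05,
                             single_snp_per_locus = TRUE,
                             order = c("presence", "single_snp", "maf")) {
  validate_geno_matrix(m)
  stopifnot(
    min_presence >= 0, min_presence <= 1,
    min_maf >= 0, min_maf <= 0.5,
    setequal(order, c("presence", "single_snp", "maf"))
  )
  attrition <- tibble::tibble(step = character(), removed = integer())
  for (step in order) {
    keep <- switch(step,
      presence = colMeans(!is.na(m$calls)) >= min_presence,
      single_snp = if (single_snp_per_locus) {
        !duplicated_with_min_position(m$sites)
      } else {
        rep(TRUE, ncol(m$calls))
      },
      maf = site_maf(m$calls) >= min_maf
    )
    keep[is.na(keep)] <- FALSE
    attrition <- dplyr::bind_rows(
      attrition,
      tibble::tibble(step = step, removed = sum(!keep))
    )
    if (!any(keep)) {
      stop(
        "all sites removed by filtering; attrition: ",
        paste(attrition$step, attrition$removed, sep = "=", collapse = ", "),
        call. = FALSE
      )
    }
    m <- m[, keep]
  }
  attr(m, "attrition") <- attrition
  m
}

# TRUE for sites that are not the lowest-position SNP of their locus
duplicated_with_min_position <- function(sites) {
  ord <- order(sites$locus_id, sites$position)
  first_of_locus <- !duplicated(sites$locus_id[ord])
  keep <- logical(nrow(sites))
  keep[ord] <- first_of_locus
  !keep
}

#' Per-site minor allele frequency
#'
#' @param calls Dosage matrix (samples x sites) with `NA` for missing.
#' @return Numeric vector of MAF per site; `NA` for all-missing sites.
#' @export
site_maf <- function(calls) {
  n_obs <- colSums(!is.na(calls))
  alt <- colSums(calls, na.rm = TRUE)
  p_alt <- ifelse(n_obs > 0, alt / (2 * n_obs), NA_real_)
  pmin(p_alt, 1 - p_alt)
}

#' Per-sample heterozygosity ratio
#'
#' The fraction of non-missing calls that are heterozygous, computed per
#' sample. Individuals with a ratio below `flag_below` (default 0.2) are
#' flagged: in a largely outbred cohort such a shift toward homozygosity
#' marks individuals whose recent history (selfing, inbreeding after
#' hybridization) departs from the rest.
#'
#' @param m A [geno_matrix()].
#' @param sample_id Optional single sample ID; default all samples.
#' @param flag_below Flag threshold on the ratio.
#' @return A tibble with columns `sample_id`, `n_obs`, `n_het`,
#'   `het_ratio`, `low_het` (logical flag).
#' @export
het_ratio <- function(m, sample_id = NULL, flag_below = 0.2) {
  validate_geno_matrix(m)
  calls <- m$calls
  if (!is.null(sample_id)) {
    if (!all(sample_id %in% m$samples$sample_id)) {
      stop("unknown sample ID(s): ",
        paste(setdiff(sample_id, m$samples$sample_id), collapse = ", "),
        call. = FALSE
      )
    }
    calls <- calls[sample_id, , drop = FALSE]
  }
  n_obs <- rowSums(!is.na(calls))
  if (any(n_obs == 0L)) {
    stop("sample(s) with zero non-missing calls: ",
      paste(rownames(calls)[n_obs == 0L], collapse = ", "),
      call. = FALSE
    )
  }
  n_het <- rowSums(calls == 1L, na.rm = TRUE)
  tibble::tibble(
    sample_id = rownames(calls),
    n_obs = as.integer(n_obs),
    n_het = as.integer(n_het),
    het_ratio = n_het / n_obs,
    low_het = n_het / n_obs < flag_below
  )
}
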