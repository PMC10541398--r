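#' Round half away from zero to a fixed number of decimals
#'
#' Tabular conservation percentages are conventionally printed to one
#' decimal with halves rounded up, unlike base R's banker's rounding; a
#' `"truncate"` mode is available because some published tables truncate.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @param mode `"half-up"` (default) or `"truncate"`.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1, mode = c("half-up", "truncate")) {
  mode <- match.arg(mode)
  f <- 10^digits
  switch(mode,
    "half-up" = floor(x * f + 0.5 + 1e-9) / f,
    "truncate" = floor(x * f + 1e-9) / f
  )
}

#' Conservation percentage from site counts
#'
#' The clonality statistic for a sample pair: the number of sites
#' heterozygous in both samples divided by the number of pairwise-variable
#' sites, times 100.
#'
#' @param n_variable Count of pairwise-variable sites (>= 1).
#' @param n_conserved_het Count of sites heterozygous in both samples.
#' @param digits Decimals for the reported percentage.
#' @param mode Rounding mode, see [round_half_up()].
#' @return Percentage in \[0, 100\], rounded for tabular display.
#' @export
conservation_percent <- function(n_variable, n_conserved_het, digits = 1,
                                 mode = "half-up") {
  if (any(n_variable < 1)) {
    stop("conservation percentage undefined for zero variable sites",
      call. = FALSE
    )
  }
  stopifnot(all(n_conserved_het >= 0), all(n_conserved_het <= n_variable))
  round_half_up(100 * n_conserved_het / n_variable, digits, mode)
}

#' Pairwise conservation of heterozygous-locus positions
#'
#' For each sample pair, restricted to sites genotyped in *both* samples
#' (the complete-presence contract of a two-sample extraction): a site is
#' *pairwise-variable* when the pair's four alleles are not all identical
#' (i.e. the two calls are not the same homozygote), and *conserved
#' heterozygous* when both calls are heterozygous. Clonal pairs retain
#' heterozygous positions; sexually related pairs reshuffle them.
#'
#' Pairs with fewer than `min_variable` variable sites are marked
#' inconclusive (`percent` is `NA`), distinguishable from a true 0%.
#'
#' @param m A [geno_matrix()].
#' @param pairs Optional two-column data frame / matrix of sample IDs; by
#'   default all unordered pairs.
#' @param min_variable Minimum variable-site count for a conclusive pair.
#' @param digits,mode Tabular rounding, see [conservation_percent()].
#' @return A tibble with columns `sample_a`, `sample_b`, `n_variable`,
#'   `n_conserved_het`, `percent` (rounded; `NA` when inconclusive) and
#'   `percent_raw` (unrounded).
#' @export
pair_conservation <- function(m, pairs = NULL, min_variable = 1,
                              digits = 1, mode = "half-up") {
  validate_geno_matrix(m)
  ids <- m$samples$sample_id
  if (is.null(pairs)) {
    if (length(ids) < 2) stop("need at least two samples", call. = FALSE)
    idx <- utils::combn(length(ids), 2)
    pairs <- tibble::tibble(sample_a = ids[idx[1, ]], sample_b = ids[idx[2, ]])
  } else {
    pairs <- tibble::as_tibble(as.data.frame(pairs, stringsAsFactors = FALSE))
    names(pairs)[1:2] <- c("sample_a", "sample_b")
    unknown <- setdiff(c(pairs$sample_a, pairs$sample_b), ids)
    if (length(unknown)) {
      stop("unknown sample ID(s): ", paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    if (any(pairs$sample_a == pairs$sample_b)) {
      stop("a pair must consist of two distinct samples", call. = FALSE)
    }
  }
  calls <- m$calls
  res <- purrr::pmap(pairs[c("sample_a", "sample_b")], function(sample_a, sample_b) {
    ga <- calls[sample_a, ]
    gb <- calls[sample_b, ]
    shared <- !is.na(ga) & !is.na(gb)
    ga <- ga[shared]
    gb <- gb[shared]
    variable <- !(ga == gb & ga != 1L)
    tibble::tibble(
      n_variable = sum(variable),
      n_conserved_het = sum(ga == 1L & gb == 1L)
    )
  })
  out <- dplyr::bind_cols(pairs, dplyr::bind_rows(res))
  out$percent_raw <- ifelse(out$n_variable > 0,
    100 * out$n_conserved_het / out$n_variable, NA_real_
  )
  out$percent <- ifelse(out$n_variable >= max(min_variable, 1),
    round_half_up(out$percent_raw, digits, mode), NA_real_
  )
  out
}

#' Expected clone-pair conservation under allele dropout
#'
#' Closed form for the conservation percentage between two independently
#' genotyped copies of the same genotype when each true heterozygote drops
#' out to a random homozygote with probability `d` (equal probability to
#' either homozygote): at a founder-het site the pair is conserved-het with
#' probability `(1-d)^2` and non-variable (same homozygote on both sides)
#' with probability `d^2/2`, hence
#' `100 * (1-d)^2 / (1 - d^2/2)`.
#' At `d = 0.35` this gives about 45%, inside the 40-50% band observed
#' between technical replicates in de novo RAD genotyping.
#'
#' @param dropout_d Dropout probability in \[0, 1).
#' @return Expected conservation percentage.
#' @export
expected_clonal_conservation <- function(dropout_d) {
  stopifnot(all(dropout_d >= 0), all(dropout_d < 1))
  100 * (1 - dropout_d)^2 / (1 - dropout_d^2 / 2)
}

#' Calibrate the clonality threshold from technical replicates
#'
#' Technical replicates are known clones, so their conservation values
#' bound what genotyping noise alone does to a clone pair. The threshold
#' is `max(default, min(replicate values) - margin)`; with no replicates
#' the default is used with a warning.
#'
#' @param replicate_percents Numeric vector of replicate-pair conservation
#'   percentages (possibly empty).
#' @param default Fallback threshold (percent).
#' @param margin Safety margin (percentage points) below the weakest
#'   replicate, absorbing somatic mutation in true clones.
#' @return A list of class `clonality_config`: `threshold`, `margin`,
#'   `replicates` (the calibration values).
#' @export
calibrate_threshold <- function(replicate_percents = numeric(),
                                default = 40, margin = 4) {
  replicate_percents <- replicate_percents[!is.na(replicate_percents)]
  if (length(replicate_percents) == 0) {
    warning("no replicate pairs: falling back to default threshold ", default)
    thr <- default
  } else {
    thr <- max(default, min(replicate_percents) - margin)
  }
  structure(
    list(threshold = thr, margin = margin, replicates = replicate_percents),
    class = "clonality_config"
  )
}

#' @export
print.clonality_config <- function(x, ...) {
  cat(sprintf(
    "<clonality_config> threshold %.1f%% (margin %.1f; %d replicate pair(s)%s)\n",
    x$threshold, x$margin, length(x$replicates),
    if (length(x$replicates)) {
      paste0(": ", paste(sprintf("%.1f", sort(x$replicates)), collapse = ", "))
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Call clonal groups from pairwise conservation
#'
#' Builds a graph over samples whose edges are pairs at or above the
#' threshold; clonal groups are the connected components of size >= 2
#' (clone membership is transitive, so a lineage is accepted when its
#' members chain together even if not every pair clears the bar). Pairs
#' within `margin` percentage points below the threshold are annotated
#' `"borderline"` — somatic mutation during asexual propagation can pull a
#' true clone pair slightly under — and by default still contribute edges,
#' surfaced in the output rather than silently dropped. Inconclusive pairs
#' (`percent` `NA`) never form edges and are listed separately.
#'
#' @param pairs A tibble from [pair_conservation()].
#' @param threshold Conservation percentage cutoff (default 40), or a
#'   `clonality_config` from [calibrate_threshold()].
#' @param margin Borderline band width in percentage points.
#' @param include_borderline Should borderline pairs form edges?
#' @return A list of class `clonal_groups`: `membership` (tibble
#'   `sample_id`, `clone_id`; `NA` clone for singletons), `edges` (the
#'   input pairs with a `verdict` column: clonal / borderline / distinct /
#'   inconclusive), `threshold`.
#' @export
call_clonal_groups <- function(pairs, threshold = 40, margin = 4,
                               include_borderline = TRUE) {
  if (inherits(threshold, "clonality_config")) {
    margin <- threshold$margin
    threshold <- threshold$threshold
  }
  pairs <- tibble::as_tibble(pairs)
  p <- pairs$percent
  pairs$verdict <- dplyr::case_when(
    is.na(p) ~ "inconclusive",
    p >= threshold ~ "clonal",
    p >= threshold - margin ~ "borderline",
    TRUE ~ "distinct"
  )
  edge_ok <- pairs$verdict == "clonal" |
    (include_borderline & pairs$verdict == "borderline")
  ids <- sort(unique(c(pairs$sample_a, pairs$sample_b)))
  g <- igraph::graph_from_data_frame(
    pairs[edge_ok, c("sample_a", "sample_b")],
    directed = FALSE,
    vertices = ids
  )
  comp <- igraph::components(g)
  comp_id <- comp$membership
  sizes <- comp$csize[comp_id]
  clone_id <- ifelse(sizes >= 2, paste0("clone_", comp_id), NA_character_)
  # renumber clones by order of first appearance for stable labels
  seen <- unique(clone_id[!is.na(clone_id)])
  clone_id <- ifelse(is.na(clone_id), NA_character_,
    paste0("clone_", match(clone_id, seen))
  )
  structure(
    list(
      membership = tibble::tibble(sample_id = names(comp_id), clone_id = clone_id),
      edges = pairs,
      threshold = threshold
    ),
    class = "clonal_groups"
  )
}

#' @export
print.clonal_groups <- function(x, ...) {
  n_clone <- length(unique(stats::na.omit(x$membership$clone_id)))
  cat(sprintf(
    "<clonal_groups> %d clonal group(s) at threshold %.1f%% over %d samples\n",
    n_clone, x$threshold, nrow(x$membership)
  ))
  invisible(x)
}
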