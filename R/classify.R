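#' Identify anchor clusters (A, B, C) from a K = 3 admixture fit
#'
#' The two ancestry clusters whose members are near-pure (dominant
#' ancestry proportion >= `purity`) *and* coincide with called clonal
#' groups are labeled A and B — clonal propagation plus absence of
#' admixture marks the isolated lineages; the remaining cluster anchors C.
#' The A/B ordering is deterministic: the smaller cluster (by member
#' count, ties by cluster index) is A. When fewer than two clusters
#' qualify, labels fall back to purity alone with a warning; when no
#' cluster qualifies on purity either, assignment degrades to cluster
#' size with a warning.
#'
#' @param fit An [admix_fit()] with K = 3, or a samples x 3 Q matrix with
#'   sample IDs as row names.
#' @param clones A [call_clonal_groups()] result (or its `membership`
#'   tibble); optional but recommended.
#' @param purity Dominant-ancestry threshold for "pure".
#' @return Named integer vector `c(A = , B = , C = )` mapping labels to
#'   Q column indices.
#' @export
identify_anchor_clusters <- function(fit, clones = NULL, purity = 0.95) {
  Q <- if (inherits(fit, "admix_fit")) fit$Q else as.matrix(fit)
  if (ncol(Q) != 3) stop("anchor identification requires K = 3", call. = FALSE)
  clone_tbl <- NULL
  if (!is.null(clones)) {
    clone_tbl <- if (inherits(clones, "clonal_groups")) clones$membership else tibble::as_tibble(clones)
  }
  dominant <- max.col(Q, ties.method = "first")
  pure <- Q[cbind(seq_len(nrow(Q)), dominant)] >= purity

  qualifies <- logical(3)
  n_pure <- integer(3)
  size <- tabulate(dominant, nbins = 3)
  for (k in 1:3) {
    members <- rownames(Q)[dominant == k & pure]
    n_pure[k] <- length(members)
    if (is.null(clone_tbl) || length(members) < 2) next
    cl <- clone_tbl$clone_id[match(members, clone_tbl$sample_id)]
    cl <- cl[!is.na(cl)]
    # cluster backs a clonal lineage when most of its pure members sit in
    # one clonal group
    qualifies[k] <- length(cl) >= 2 &&
      max(table(cl)) >= 0.5 * length(members)
  }
  if (sum(qualifies) >= 2) {
    cand <- which(qualifies)
  } else if (sum(n_pure >= 2) >= 2) {
    warning("fewer than two pure clonal clusters; anchors assigned by purity alone")
    cand <- order(n_pure, decreasing = TRUE)[1:2]
  } else {
    warning("no pure anchor clusters found; anchors assigned by cluster size")
    cand <- order(size)[1:2]
  }
  cand <- cand[order(size[cand], cand)] # smaller cluster is A
  anchors <- c(A = cand[1], B = cand[2], C = setdiff(1:3, cand[1:2]))
  anchors
}

#' Classify samples into major groups and gene-flow subgroups
#'
#' Major group is the anchor label (A, B or C) of each sample's dominant
#' ancestry cluster. Samples anchored to C are split by detected gene
#' flow at threshold `tau` on their ancestry fractions from the A and B
#' clusters: neither >= `tau` gives C1 (no gene flow), only A gives C2,
#' only B gives C3, both give C4. The four predicates are mutually
#' exclusive and exhaustive, and raising `tau` can only move samples
#' toward C1. `tau` is a reporting threshold the analyst must own — it is
#' echoed in the output.
#'
#' @param fit An [admix_fit()] with K = 3, or a samples x 3 Q matrix.
#' @param anchors Named map from [identify_anchor_clusters()].
#' @param tau Gene-flow detection threshold on ancestry proportions.
#' @return A tibble: `sample_id`, `group` (A/B/C), `subgroup` (C1-C4, or
#'   `NA` outside group C), `q_A`, `q_B`, `q_C`; attribute `tau`.
#' @export
classify_subgroups <- function(fit, anchors, tau = 0.05) {
  Q <- if (inherits(fit, "admix_fit")) fit$Q else as.matrix(fit)
  stopifnot(ncol(Q) == 3, all(c("A", "B", "C") %in% names(anchors)))
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)", call. = FALSE)
  q_A <- Q[, anchors[["A"]]]
  q_B <- Q[, anchors[["B"]]]
  q_C <- Q[, anchors[["C"]]]
  lab <- c("A", "B", "C")[max.col(cbind(q_A, q_B, q_C), ties.method = "first")]
  subgroup <- dplyr::case_when(
    lab != "C" ~ NA_character_,
    q_A >= tau & q_B < tau ~ "C2",
    q_A < tau & q_B >= tau ~ "C3",
    q_A >= tau & q_B >= tau ~ "C4",
    TRUE ~ "C1"
  )
  ids <- rownames(Q)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(Q)))
  out <- tibble::tibble(
    sample_id = ids, group = lab, subgroup = subgroup,
    q_A = unname(q_A), q_B = unname(q_B), q_C = unname(q_C)
  )
  attr(out, "tau") <- tau
  out
}

#' Cross-tabulate groups against regions with a permutation test
#'
#' Descriptive check of whether genetic groups cluster by geographic
#' region: a chi-squared statistic on the group x region table, with a
#' permutation null built by shuffling region labels. A small p-value
#' indicates association between groups and regions; a flat geographic
#' signal (groups spread over regions) yields large p. Rows with missing
#' region labels are excluded and counted.
#'
#' @param assignment Tibble with `sample_id` and a grouping column
#'   (default `group`).
#' @param regions Named character vector (`sample_id` -> region) or a
#'   tibble with `sample_id` and `region_label`.
#' @param group_col Column of `assignment` to tabulate.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A list of class `region_report`: `table` (cross-tab),
#'   `statistic`, `p_value` (`NA` when the test is degenerate),
#'   `n_excluded`, `note`.
#' @export
regional_structure_report <- function(assignment, regions,
                                      group_col = "group",
                                      n_perm = 999, seed = 1L) {
  assignment <- tibble::as_tibble(assignment)
  if (is.data.frame(regions)) {
    regions <- stats::setNames(
      as.character(regions$region_label), regions$sample_id
    )
  }
  reg <- regions[assignment$sample_id]
  grp <- assignment[[group_col]]
  keep <- !is.na(reg) & !is.na(grp)
  n_excluded <- sum(!keep)
  reg <- reg[keep]
  grp <- grp[keep]
  tab <- table(group = grp, region = reg)
  chisq_stat <- function(t) {
    e <- outer(rowSums(t), colSums(t)) / sum(t)
    sum((t - e)^2 / ifelse(e > 0, e, 1))
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    return(structure(
      list(
        table = tab, statistic = NA_real_, p_value = NA_real_,
        n_excluded = n_excluded,
        note = "test skipped: fewer than two groups or regions"
      ),
      class = "region_report"
    ))
  }
  stat <- chisq_stat(tab)
  set.seed(stage_seed(seed, "regionperm"))
  perm <- vapply(seq_len(n_perm), function(i) {
    chisq_stat(table(grp, sample(reg)))
  }, numeric(1))
  p <- (1 + sum(perm >= stat - 1e-12)) / (n_perm + 1)
  structure(
    list(
      table = tab, statistic = stat, p_value = p,
      n_excluded = n_excluded, note = NULL
    ),
    class = "region_report"
  )
}

#' @export
print.region_report <- function(x, ...) {
  cat("<region_report>\n")
  print(x$table)
  if (!is.null(x$note)) {
    cat(x$note, "\n")
  } else {
    cat(sprintf(
      "chi-squared = %.2f, permutation p = %.4f (%d excluded)\n",
      x$statistic, x$p_value, x$n_excluded
    ))
  }
  invisible(x)
}
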