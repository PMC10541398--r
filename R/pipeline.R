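#' Build a pipeline configuration
#'
#' A config has exactly one input source: a VCF path or a simulation
#' preset. All stage parameters are echoed into the run report so a run
#' is auditable and exactly reproducible from its config and seed.
#'
#' @param vcf Path to an input VCF (mutually exclusive with `preset`).
#' @param preset Simulation preset name for [sim_preset()].
#' @param sample_meta Optional path to a sample-metadata CSV
#'   (`sample_id,region_label,replicate_of`, extra columns kept).
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed for every stochastic stage.
#' @param filters List: `min_presence`, `min_maf`, `single_snp_per_locus`.
#' @param clonality List: `threshold` (`NULL` = calibrate from replicate
#'   pairs), `margin`, `min_variable`.
#' @param k_grid Integer vector of K values for cross-validation.
#' @param tau Gene-flow threshold for subgroup classification.
#' @param n_sites Sites for the simulation input (ignored for VCF input).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(vcf = NULL, preset = NULL, sample_meta = NULL,
                            out_dir = tempfile("radclone_run_"), seed = 1L,
                            filters = list(), clonality = list(),
                            k_grid = 1:5, tau = 0.05, n_sites = 5848) {
  if (is.null(vcf) == is.null(preset)) {
    stop("exactly one of `vcf` or `preset` must be given", call. = FALSE)
  }
  structure(
    list(
      vcf = vcf, preset = preset, sample_meta = sample_meta,
      out_dir = out_dir, seed = as.integer(seed),
      filters = modifyList(
        list(min_presence = 0.5, min_maf = 0.05, single_snp_per_locus = TRUE),
        filters
      ),
      clonality = modifyList(
        list(threshold = NULL, margin = 4, min_variable = 1),
        clonality
      ),
      k_grid = as.integer(k_grid), tau = tau, n_sites = as.integer(n_sites)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

write_stage <- function(x, path) {
  if (is.matrix(x)) {
    write.csv(as.data.frame(x), path, row.names = TRUE)
  } else {
    readr::write_csv(tibble::as_tibble(x), path)
  }
  path
}

#' Run the full analysis pipeline
#'
#' Stages: load or simulate genotypes; genotype-level filters;
#' heterozygosity screen; pairwise conservation, replicate calibration
#' and clonal-group calling; PCA, IBS distances, MDS and UPGMA;
#' admixture cross-validation over the K grid plus a K = 3 fit;
#' anchor/subgroup classification (when K = 3 is in the grid); regional
#' cross-tabulation (when region labels exist); per-group diversity
#' statistics; and a markdown report. Every table is written under
#' `cfg$out_dir`; re-running an identical config reproduces identical
#' outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return A `run_report` list: `manifest` (tibble `file`, `stage`),
#'   `params` (config echo), `timings` (per-stage seconds), `results`
#'   (in-memory stage outputs), `notes` (stage warnings/notices).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- tibble::tibble(file = character(), stage = character())
  timings <- c()
  notes <- character()
  results <- list()
  out <- function(name) file.path(cfg$out_dir, name)
  add <- function(path, stage) {
    manifest <<- dplyr::bind_rows(manifest,
      tibble::tibble(file = path, stage = stage))
  }
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    v
  }

  # --- input -----------------------------------------------------------
  geno <- timed("input", {
    if (!is.null(cfg$preset)) {
      sim <- simulate_cohort(sim_preset(cfg$preset,
        n_sites = cfg$n_sites, seed = cfg$seed
      ))
      results$truth <- sim$truth
      write_vcf(sim$geno, out("genotypes.vcf"))
      add(out("genotypes.vcf"), "input")
      write_stage(sim$truth$samples |>
        dplyr::mutate(!!!stats::setNames(
          lapply(seq_len(ncol(sim$truth$q)), function(k) sim$truth$q[, k]),
          paste0("true_q", seq_len(ncol(sim$truth$q)))
        )), out("truth_samples.csv"))
      add(out("truth_samples.csv"), "input")
      sim$geno
    } else {
      read_vcf(cfg$vcf)
    }
  })
  if (!is.null(cfg$sample_meta)) {
    geno <- set_sample_meta(
      geno, readr::read_csv(cfg$sample_meta, show_col_types = FALSE)
    )
  }

  # --- filters ---------------------------------------------------------
  geno <- timed("filter", filter_genotypes(geno,
    min_presence = cfg$filters$min_presence,
    min_maf = cfg$filters$min_maf,
    single_snp_per_locus = cfg$filters$single_snp_per_locus
  ))
  results$attrition <- attr(geno, "attrition")
  results$geno <- geno

  # --- heterozygosity screen ------------------------------------------
  results$het <- timed("het_ratio", het_ratio(geno))
  add(write_stage(results$het, out("het_ratio.csv")), "het_ratio")

  # --- clonality -------------------------------------------------------
  results$pairs <- timed("conservation", pair_conservation(geno,
    min_variable = cfg$clonality$min_variable
  ))
  rep_pairs <- geno$samples |>
    dplyr::filter(!is.na(.data$replicate_of))
  thr <- cfg$clonality$threshold
  if (is.null(thr)) {
    if (nrow(rep_pairs) == 0) {
      notes <- c(notes, "no replicate pairs: clonality threshold fell back to default 40")
      thr <- withCallingHandlers(
        calibrate_threshold(numeric(), margin = cfg$clonality$margin),
        warning = function(w) invokeRestart("muffleWarning")
      )
    } else {
      key <- function(a, b) paste(pmin(a, b), pmax(a, b))
      rp <- results$pairs |>
        dplyr::filter(key(.data$sample_a, .data$sample_b) %in%
          key(rep_pairs$sample_id, rep_pairs$replicate_of))
      thr <- calibrate_threshold(rp$percent, margin = cfg$clonality$margin)
    }
  } else {
    thr <- structure(
      list(
        threshold = thr, margin = cfg$clonality$margin,
        replicates = numeric()
      ),
      class = "clonality_config"
    )
  }
  results$clonality_config <- thr
  results$clones <- timed("clonality", call_clonal_groups(results$pairs, thr))
  readr::write_tsv(
    results$clones$edges |>
      dplyr::select("sample_a", "sample_b", "n_variable",
        "n_conserved_het", "percent", "verdict"),
    out("conservation_pairs.tsv")
  )
  add(out("conservation_pairs.tsv"), "clonality")
  add(write_stage(results$clones$membership, out("clonal_groups.csv")), "clonality")

  # --- ordination and clustering --------------------------------------
  results$pca <- timed("pca", genotype_pca(geno, n_components = 5))
  add(write_stage(results$pca$scores, out("pca_scores.csv")), "pca")
  results$ibs <- timed("ibs", ibs_dist(geno))
  results$mds <- timed("mds", classical_mds(results$ibs, k = 2))
  add(write_stage(results$mds$scores, out("mds_scores.csv")), "mds")
  tree <- timed("upgma", upgma_tree(results$ibs))
  ape::write.tree(tree, out("upgma.nwk"))
  add(out("upgma.nwk"), "upgma")
  results$tree <- tree

  # --- admixture -------------------------------------------------------
  k_grid <- cfg$k_grid
  if (max(k_grid) > nrow(geno$calls)) {
    notes <- c(notes, sprintf(
      "K grid truncated to <= %d (number of samples)", nrow(geno$calls)
    ))
    k_grid <- k_grid[k_grid <= nrow(geno$calls)]
  }
  results$cv <- timed("admixture_cv", admix_cv(geno, k_grid, seed = cfg$seed))
  add(write_stage(results$cv$curve, out("cv_errors.csv")), "admixture_cv")
  fit_k <- if (3 %in% k_grid) 3L else results$cv$selected_K
  results$fit <- timed("admixture_fit", admix_fit(geno, fit_k, seed = cfg$seed))
  qtab <- apply(results$fit$Q, 1, paste, collapse = " ")
  writeLines(unname(qtab), out(sprintf("admixture_K%d.Q", fit_k)))
  add(out(sprintf("admixture_K%d.Q", fit_k)), "admixture_fit")

  # --- classification --------------------------------------------------
  if (fit_k == 3) {
    results$anchors <- timed(
      "anchors",
      identify_anchor_clusters(results$fit, results$clones)
    )
    results$assignment <- timed(
      "classify",
      classify_subgroups(results$fit, results$anchors, tau = cfg$tau)
    )
    add(write_stage(results$assignment, out("group_assignment.csv")), "classify")
    regions <- stats::setNames(
      geno$samples$region_label, geno$samples$sample_id
    )
    if (any(!is.na(regions))) {
      results$region_report <- timed("regions", regional_structure_report(
        results$assignment, regions, n_perm = 999, seed = cfg$seed
      ))
      add(write_stage(
        as.data.frame(results$region_report$table),
        out("region_crosstab.csv")
      ), "regions")
    }
    pop_of <- results$assignment
    pop_of$population <- ifelse(pop_of$group == "C" & !is.na(pop_of$subgroup),
      pop_of$subgroup, pop_of$group
    )
    results$pop_stats <- timed("pop_stats", population_summary(
      geno, stats::setNames(pop_of$population, pop_of$sample_id)
    ))
    add(write_stage(results$pop_stats$stats, out("pop_stats.csv")), "pop_stats")
    add(write_stage(results$pop_stats$fst, out("fst_matrix.csv")), "pop_stats")
  } else {
    notes <- c(notes, "K = 3 not in grid: classification and per-group statistics skipped")
  }

  report <- structure(
    list(
      manifest = manifest, params = unclass(cfg),
      timings = unlist(timings), results = results, notes = notes
    ),
    class = "run_report"
  )
  writeLines(make_report(report), out("report.md"))
  report$manifest <- dplyr::bind_rows(
    manifest, tibble::tibble(file = out("report.md"), stage = "report")
  )
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    "<run_report> %d artifact(s) in %s\n",
    nrow(x$manifest), x$params$out_dir
  ))
  invisible(x)
}

#' Render a run report as markdown text
#'
#' A single human-readable summary: parameter echo, filter attrition,
#' clonality table and called clonal groups, CV curve, group/subgroup
#' assignments, and per-population statistics. Regenerating the report
#' from the same `run_report` is byte-identical.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @return Character vector of markdown lines.
#' @export
make_report <- function(report) {
  r <- report$results
  p <- report$params
  fmt_tbl <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 5))
    c(
      paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, paste, collapse = " | ")
    )
  }
  lines <- c(
    "# radclone run report",
    "",
    sprintf("- input: %s", if (!is.null(p$preset)) {
      sprintf("simulation preset '%s' (%d sites)", p$preset, p$n_sites)
    } else {
      p$vcf
    }),
    sprintf("- seed: %d", p$seed),
    sprintf(
      "- filters: min_presence = %g, min_maf = %g, single SNP per locus = %s",
      p$filters$min_presence, p$filters$min_maf,
      p$filters$single_snp_per_locus
    ),
    sprintf("- gene-flow threshold tau = %g", p$tau),
    ""
  )
  if (!is.null(r$attrition)) {
    lines <- c(lines, "## Filter attrition", "", fmt_tbl(r$attrition), "")
  }
  lines <- c(
    lines, "## Clonality", "",
    sprintf(
      "Threshold %.1f%% (%s).", r$clonality_config$threshold,
      if (length(r$clonality_config$replicates)) {
        sprintf(
          "calibrated from replicate pairs: %s",
          paste(sprintf("%.1f", sort(r$clonality_config$replicates)),
            collapse = ", "
          )
        )
      } else {
        "default; no replicate calibration"
      }
    ), ""
  )
  memb <- r$clones$membership
  n_cl <- unique(stats::na.omit(memb$clone_id))
  if (length(n_cl) == 0) {
    lines <- c(lines, "No clonal groups detected.", "")
  } else {
    for (cl in n_cl) {
      lines <- c(lines, sprintf(
        "- %s: %s", cl,
        paste(sort(memb$sample_id[which(memb$clone_id == cl)]), collapse = ", ")
      ))
    }
    lines <- c(lines, "")
  }
  lines <- c(
    lines, "## Admixture", "",
    sprintf("CV-selected K = %d.", r$cv$selected_K), "",
    fmt_tbl(r$cv$curve), ""
  )
  if (!is.null(r$assignment)) {
    tab <- table(ifelse(r$assignment$group == "C",
      r$assignment$subgroup, r$assignment$group
    ))
    lines <- c(
      lines, "## Groups", "",
      paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "),
      ""
    )
  }
  if (!is.null(r$pop_stats)) {
    lines <- c(
      lines, "## Population statistics", "",
      fmt_tbl(r$pop_stats$stats), "",
      "### Pairwise Fst", "",
      fmt_tbl(cbind(
        population = rownames(r$pop_stats$fst),
        as.data.frame(r$pop_stats$fst)
      )), ""
    )
  }
  if (length(report$notes)) {
    lines <- c(lines, "## Notes", "", paste0("- ", report$notes), "")
  }
  lines
}
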