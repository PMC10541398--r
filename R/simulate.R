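#' Simulation configuration for synthetic RAD-Seq cohorts
#'
#' Describes a cohort generated from `K` ancestral populations under a
#' Balding-Nichols model: per-site ancestral frequencies drawn uniformly on
#' `ancestral_freq_range`, population frequencies Beta-distributed around
#' them with variance `F_k * p * (1 - p)` (the drift parameter `F_k` plays
#' the role of an Fst-like divergence). Individuals are outbred members of
#' one population, admixed with a fixed ancestry vector, or members of a
#' clonal lineage copied from a single founder genotype with per-site
#' loss-of-heterozygosity at rate `somatic_mu`. Genotyping noise follows
#' the RAD-Seq error model: allele dropout turns a true heterozygote into
#' a random homozygote with probability `dropout_d`, miscalls turn a true
#' homozygote into a heterozygote with probability `error_e`, and each
#' call is independently missing with probability `missing_m`.
#'
#' @param n_sites Number of biallelic sites.
#' @param K Number of ancestral populations.
#' @param drift Numeric vector of length `K`; per-population drift in \[0, 1\].
#' @param groups Data frame with columns `label`, `size`,
#'   `mode` (one of `"outbred"`, `"clonal"`, `"admixed"`),
#'   `founder_pop` (population index; used by outbred/clonal) and,
#'   for admixed groups, a list-column `q` of length-`K` ancestry vectors.
#' @param dropout_d,error_e,missing_m,somatic_mu Noise rates in \[0, 1\].
#' @param ancestral_freq_range Interval within (0, 1) for ancestral
#'   frequencies.
#' @param replicate_samples Integer indices (in assembled sample order) of
#'   individuals to re-genotype as technical replicates: the replicate
#'   shares the true genotype and receives independent noise/missingness.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   full configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sites, K, drift, groups,
                       dropout_d = 0, error_e = 0, missing_m = 0,
                       somatic_mu = 0,
                       ancestral_freq_range = c(0.1, 0.9),
                       replicate_samples = integer(),
                       seed = 1L) {
  groups <- tibble::as_tibble(groups)
  stopifnot(
    n_sites >= 1, K >= 1, length(drift) == K,
    all(drift >= 0), all(drift <= 1),
    all(c("label", "size", "mode") %in% names(groups)),
    all(groups$mode %in% c("outbred", "clonal", "admixed")),
    all(groups$size >= 1),
    all(c(dropout_d, error_e, missing_m, somatic_mu) >= 0),
    all(c(dropout_d, error_e, missing_m, somatic_mu) <= 1),
    length(ancestral_freq_range) == 2,
    ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1
  )
  if (!"q" %in% names(groups)) groups$q <- vector("list", nrow(groups))
  if (!"founder_pop" %in% names(groups)) groups$founder_pop <- NA_integer_
  for (i in seq_len(nrow(groups))) {
    if (groups$mode[i] == "admixed") {
      qi <- groups$q[[i]]
      if (is.null(qi) || length(qi) != K || abs(sum(qi) - 1) > 1e-8) {
        stop("admixed group '", groups$label[i],
          "' needs a length-K ancestry vector q summing to 1",
          call. = FALSE
        )
      }
    } else {
      fp <- groups$founder_pop[i]
      if (is.na(fp) || fp < 1 || fp > K) {
        stop("group '", groups$label[i], "' cites absent founder population",
          call. = FALSE
        )
      }
    }
  }
  structure(
    list(
      n_sites = as.integer(n_sites), K = as.integer(K), drift = drift,
      groups = groups, dropout_d = dropout_d, error_e = error_e,
      missing_m = missing_m, somatic_mu = somatic_mu,
      ancestral_freq_range = ancestral_freq_range,
      replicate_samples = as.integer(replicate_samples),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Bundled cohort preset
#'
#' `"garlic"` emulates the structure of a wild Japanese garlic
#' (*Allium macrostemon*) ddRAD survey: three ancestral populations; two
#' clonal lineages (groups A, 6 members, and B, 9 members) propagated from
#' single founders; an outbred ancestral group C1 (10); and admixed
#' subgroups C2 (4, gene flow from A only), C3 (9, from B only) and C4
#' (11, from both); three technical-replicate pairs. Allele dropout is set
#' to 0.35, which places expected clone-pair conservation of heterozygous
#' sites near 45% — the 40-50% band typical of de novo RAD genotyping of
#' known clones (see [expected_clonal_conservation()]).
#'
#' @param name Preset name; currently `"garlic"`.
#' @param n_sites Number of sites (default 5848, the variant count of the
#'   survey this preset emulates).
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
sim_preset <- function(name = "garlic", n_sites = 5848, seed = 1L) {
  name <- match.arg(name)
  groups <- tibble::tibble(
    label = c("A", "B", "C1", "C2", "C3", "C4"),
    size = c(6L, 9L, 10L, 4L, 9L, 11L),
    mode = c("clonal", "clonal", "outbred", "admixed", "admixed", "admixed"),
    founder_pop = c(1L, 2L, 3L, NA, NA, NA),
    q = list(
      NULL, NULL, NULL,
      c(0.20, 0.00, 0.80),
      c(0.00, 0.25, 0.75),
      c(0.15, 0.25, 0.60)
    )
  )
  sim_config(
    n_sites = n_sites, K = 3, drift = c(0.30, 0.30, 0.10),
    groups = groups,
    dropout_d = 0.35, error_e = 0.005, missing_m = 0.2, somatic_mu = 0.01,
    replicate_samples = c(7L, 8L, 39L), # two group-B members, one C4 member
    seed = seed
  )
}

# deterministic per-stage substream seeds (kept below 2^31; double
# arithmetic avoids 32-bit overflow for large user seeds)
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 1009 + h) %% 2147483647)
}

#' Draw population allele frequencies (Balding-Nichols)
#'
#' For each site an ancestral frequency `p` is drawn uniformly on the
#' configured range; population `k`'s frequency is Beta with mean `p` and
#' variance `F_k * p * (1 - p)`. `F_k = 0` degenerates to the ancestral
#' frequency itself; `F_k = 1` to a fixed 0/1 draw with probability `p`.
#'
#' @param cfg A [sim_config()].
#' @return List with `freqs` (K x n_sites matrix in (0,1)) and
#'   `ancestral` (length n_sites).
#' @export
draw_population_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "freqs"))
  J <- cfg$n_sites
  p <- stats::runif(J, cfg$ancestral_freq_range[1], cfg$ancestral_freq_range[2])
  eps <- 1e-6
  freqs <- matrix(NA_real_, nrow = cfg$K, ncol = J)
  for (k in seq_len(cfg$K)) {
    f <- cfg$drift[k]
    if (f <= 0) {
      freqs[k, ] <- p
    } else if (f >= 1) {
      freqs[k, ] <- stats::rbinom(J, 1, p)
    } else {
      shape1 <- p * (1 - f) / f
      shape2 <- (1 - p) * (1 - f) / f
      freqs[k, ] <- stats::rbeta(J, shape1, shape2)
    }
  }
  freqs <- pmin(pmax(freqs, eps), 1 - eps)
  list(freqs = freqs, ancestral = p)
}

#' Simulate one individual's genotype from an ancestry vector
#'
#' Each of the two allele copies at site `j` is the alternate allele with
#' probability `sum(q * freqs[, j])`, independently — the generative model
#' the admixture likelihood assumes.
#'
#' @param q Length-K ancestry vector summing to 1.
#' @param freqs K x n_sites population frequency matrix.
#' @return Integer dosage vector (0/1/2).
#' @export
simulate_individual <- function(q, freqs) {
  stopifnot(abs(sum(q) - 1) < 1e-8, length(q) == nrow(freqs))
  p <- as.vector(q %*% freqs)
  stats::rbinom(ncol(freqs), 1, p) + stats::rbinom(ncol(freqs), 1, p)
}

#' Copy a founder genotype with somatic loss of heterozygosity
#'
#' Each heterozygous site of the founder is independently converted to a
#' random homozygote with probability `somatic_mu`; homozygous sites are
#' copied unchanged. Models mutation during asexual (bulb) propagation.
#'
#' @param founder Integer dosage vector.
#' @param somatic_mu Per-site LOH probability.
#' @return Integer dosage vector.
#' @export
clonal_replicate <- function(founder, somatic_mu) {
  g <- founder
  het <- which(g == 1L)
  if (length(het) && somatic_mu > 0) {
    hit <- het[stats::runif(length(het)) < somatic_mu]
    g[hit] <- 2L * stats::rbinom(length(hit), 1, 0.5)
  }
  g
}

#' Apply RAD-Seq genotyping noise to a genotype vector
#'
#' True heterozygotes drop out to a random homozygote (equal probability
#' hom-ref / hom-alt) with probability `dropout_d`; true homozygotes are
#' miscalled heterozygous with probability `error_e`.
#'
#' @param g Integer dosage vector (0/1/2; `NA` passed through).
#' @param dropout_d,error_e Noise probabilities.
#' @return Integer dosage vector.
#' @export
apply_genotyping_noise <- function(g, dropout_d, error_e) {
  out <- g
  het <- which(!is.na(g) & g == 1L)
  if (length(het) && dropout_d > 0) {
    hit <- het[stats::runif(length(het)) < dropout_d]
    out[hit] <- 2L * stats::rbinom(length(hit), 1, 0.5)
  }
  hom <- which(!is.na(g) & g != 1L)
  if (length(hom) && error_e > 0) {
    hit <- hom[stats::runif(length(hom)) < error_e]
    out[hit] <- 1L
  }
  out
}

#' Simulate a full cohort with truth tables
#'
#' Assembles the groups of `cfg` (drawing founders for clonal lineages and
#' copying them with LOH), appends technical replicates, then applies
#' genotyping noise and finally missingness (each call `NA` independently
#' with probability `missing_m`). Deterministic under a fixed config.
#'
#' @param cfg A [sim_config()].
#' @return A list with `geno` (a [geno_matrix()]; replicate samples carry
#'   `replicate_of`), and `truth`: `q` (samples x K true ancestry),
#'   `samples` (tibble `sample_id`, `group`, `clone_id`), `freqs`
#'   (K x n_sites), `ancestral` (length n_sites).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  fr <- draw_population_frequencies(cfg)

  set.seed(stage_seed(cfg$seed, "genotypes"))
  ids <- character()
  grp <- character()
  clone <- character()
  qrows <- list()
  gvecs <- list()
  for (i in seq_len(nrow(cfg$groups))) {
    g <- cfg$groups[i, ]
    q_true <- if (g$mode == "admixed") {
      g$q[[1]]
    } else {
      replace(numeric(cfg$K), g$founder_pop, 1)
    }
    founder <- NULL
    if (g$mode == "clonal") founder <- simulate_individual(q_true, fr$freqs)
    for (member in seq_len(g$size)) {
      ids <- c(ids, paste0(g$label, "_", member))
      grp <- c(grp, g$label)
      clone <- c(clone, if (g$mode == "clonal") g$label else NA_character_)
      qrows <- c(qrows, list(q_true))
      gvecs <- c(gvecs, list(
        if (g$mode == "clonal") {
          clonal_replicate(founder, cfg$somatic_mu)
        } else {
          simulate_individual(q_true, fr$freqs)
        }
      ))
    }
  }
  rep_of <- rep(NA_character_, length(ids))
  for (idx in cfg$replicate_samples) {
    if (idx < 1 || idx > length(ids)) {
      stop("replicate_samples index out of range: ", idx, call. = FALSE)
    }
    ids <- c(ids, paste0(ids[idx], "_rep"))
    grp <- c(grp, grp[idx])
    clone <- c(clone, clone[idx])
    qrows <- c(qrows, list(qrows[[idx]]))
    gvecs <- c(gvecs, list(gvecs[[idx]]))
    rep_of <- c(rep_of, ids[idx])
  }

  set.seed(stage_seed(cfg$seed, "noise"))
  gvecs <- lapply(gvecs, apply_genotyping_noise,
    dropout_d = cfg$dropout_d, error_e = cfg$error_e
  )

  calls <- do.call(rbind, gvecs)
  set.seed(stage_seed(cfg$seed, "missing"))
  if (cfg$missing_m > 0) {
    calls[matrix(stats::runif(length(calls)) < cfg$missing_m,
      nrow = nrow(calls)
    )] <- NA_integer_
  }

  geno <- geno_matrix(
    calls,
    samples = tibble::tibble(
      sample_id = ids,
      region_label = NA_character_,
      replicate_of = rep_of
    ),
    sites = tibble::tibble(
      locus_id = sprintf("locus_%05d", seq_len(cfg$n_sites)),
      position = 1L,
      ref = "A", alt = "T"
    )
  )
  q_mat <- do.call(rbind, qrows)
  rownames(q_mat) <- ids
  list(
    geno = geno,
    truth = list(
      q = q_mat,
      samples = tibble::tibble(sample_id = ids, group = grp, clone_id = clone),
      freqs = fr$freqs,
      ancestral = fr$ancestral
    )
  )
}
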