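#' Genotype matrix container
#'
#' `geno_matrix()` builds the central data structure of the package: a
#' samples-by-sites matrix of biallelic SNP genotypes coded as
#' alternate-allele dosage (0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternate, `NA` = missing), together with per-sample and
#' per-site metadata tibbles. Missing is a distinct code and is never
#' conflated with dosage 0.
#'
#' @param calls Integer matrix (samples x sites) over \{0, 1, 2, NA\}.
#'   Row names, when present, seed the sample IDs.
#' @param samples Optional tibble/data.frame with columns `sample_id` and
#'   optionally `region_label` and `replicate_of`. `replicate_of`, when set,
#'   must name another sample in the matrix.
#' @param sites Optional tibble/data.frame with columns `locus_id`,
#'   `position` (1-based within locus), `ref` and `alt` (single bases,
#'   ref != alt). Defaults are generated when omitted.
#'
#' @return An object of class `geno_matrix`: a list with elements `calls`,
#'   `samples`, `sites`.
#' @export
geno_matrix <- function(calls, samples = NULL, sites = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  n <- nrow(calls)
  j <- ncol(calls)

  if (is.null(samples)) {
    ids <- rownames(calls)
    if (is.null(ids)) ids <- sprintf("S%02d", seq_len(n))
    samples <- tibble::tibble(sample_id = ids)
  }
  samples <- tibble::as_tibble(samples)
  if (!"region_label" %in% names(samples)) samples$region_label <- NA_character_
  if (!"replicate_of" %in% names(samples)) samples$replicate_of <- NA_character_
  samples$sample_id <- as.character(samples$sample_id)

  if (is.null(sites)) {
    ids <- colnames(calls)
    if (is.null(ids)) ids <- sprintf("L%05d", seq_len(j))
    sites <- tibble::tibble(
      locus_id = ids, position = 1L,
      ref = "A", alt = "T"
    )
  }
  sites <- tibble::as_tibble(sites)
  sites$position <- as.integer(sites$position)

  rownames(calls) <- samples$sample_id
  colnames(calls) <- paste0(sites$locus_id, ":", sites$position)

  out <- structure(
    list(calls = calls, samples = samples, sites = sites),
    class = "geno_matrix"
  )
  validate_geno_matrix(out)
  out
}

validate_geno_matrix <- function(m) {
  stopifnot(inherits(m, "geno_matrix"))
  calls <- m$calls
  if (nrow(calls) != nrow(m$samples)) {
    stop("number of call rows does not match sample metadata", call. = FALSE)
  }
  if (ncol(calls) != nrow(m$sites)) {
    stop("number of call columns does not match site metadata", call. = FALSE)
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("genotype calls must be 0, 1, 2 or NA (alternate-allele dosage)",
      call. = FALSE
    )
  }
  if (anyDuplicated(m$samples$sample_id)) {
    stop("sample IDs must be unique", call. = FALSE)
  }
  key <- paste0(m$sites$locus_id, ":", m$sites$position)
  if (anyDuplicated(key)) stop("site keys (locus, position) must be unique", call. = FALSE)
  if (any(m$sites$position < 1L)) stop("site positions are 1-based (>= 1)", call. = FALSE)
  if (any(m$sites$ref == m$sites$alt)) {
    stop("ref and alt alleles must differ at every site", call. = FALSE)
  }
  rep_of <- m$samples$replicate_of
  known <- rep_of[!is.na(rep_of)]
  if (length(known) && !all(known %in% m$samples$sample_id)) {
    stop("replicate_of must name another sample in the matrix", call. = FALSE)
  }
  invisible(m)
}

#' @export
print.geno_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$calls))
  cat(sprintf(
    "<geno_matrix> %d samples x %d biallelic sites (%.1f%% missing)\n",
    nrow(x$calls), ncol(x$calls), 100 * n_miss / length(x$calls)
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by sample and/or site index
#'
#' @param x A [geno_matrix()].
#' @param i Sample index (integer, logical, or sample IDs).
#' @param j Site index (integer or logical).
#' @param ... Ignored.
#' @return A `geno_matrix` restricted to the selected rows/columns.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  geno_matrix(
    x$calls[i, j, drop = FALSE],
    samples = x$samples[i, , drop = FALSE],
    sites = x$sites[j, , drop = FALSE]
  )
}

#' Convert a genotype matrix to a long tibble
#'
#' One row per (sample, site) call; convenient for dplyr/ggplot2 work.
#'
#' @param x A [geno_matrix()].
#' @param ... Ignored.
#' @return A tibble with columns `sample_id`, `locus_id`, `position`, `dosage`.
#' @importFrom generics tidy
#' @method tidy geno_matrix
#' @export
tidy.geno_matrix <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(x$samples$sample_id, times = ncol(x$calls)),
    locus_id = rep(x$sites$locus_id, each = nrow(x$calls)),
    position = rep(x$sites$position, each = nrow(x$calls)),
    dosage = as.integer(x$calls)
  )
}

#' Attach sample metadata from a data frame
#'
#' Joins region labels and replicate structure onto an existing matrix by
#' `sample_id`. The metadata CSV convention is columns
#' `sample_id,region_label,replicate_of`.
#'
#' @param m A [geno_matrix()].
#' @param meta Data frame with a `sample_id` column and any of
#'   `region_label`, `replicate_of`, `group`.
#' @return The matrix with updated `samples` metadata (extra metadata
#'   columns are carried along).
#' @export
set_sample_meta <- function(m, meta) {
  validate_geno_matrix(m)
  meta <- tibble::as_tibble(meta)
  stopifnot("sample_id" %in% names(meta))
  meta$sample_id <- as.character(meta$sample_id)
  keep <- setdiff(names(m$samples), setdiff(names(meta), "sample_id"))
  merged <- dplyr::left_join(m$samples[keep], meta, by = "sample_id")
  m$samples <- merged
  validate_geno_matrix(m)
  m
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a VCF 4.x file (plain or gzipped) and retains only biallelic SNP
#' records. Multiallelic records and non-SNP variants (indels, symbolic
#' alleles) are skipped and the skipped count is reported via `message()`.
#' Phased (`|`) and unphased (`/`) genotype separators are treated
#' identically; `./.` (and half-missing calls) map to `NA`.
#'
#' @param path Path to a VCF file.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read VCF: no such file: ", path, call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  is_snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!is_snp)
  if (n_skip > 0) {
    message(n_skip, " non-biallelic-SNP record(s) skipped")
  }
  if (!any(is_snp)) {
    stop("no biallelic SNP records retained from ", path, call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]

  first <- substr(gt, 1, 1)
  second <- substr(gt, 3, 3)
  dos <- suppressWarnings(as.integer(first) + as.integer(second))
  dosage <- matrix(dos, nrow = nrow(gt), dimnames = dimnames(gt))

  geno_matrix(
    t(dosage),
    samples = tibble::tibble(sample_id = colnames(gt)),
    sites = tibble::tibble(
      locus_id = fix$CHROM,
      position = as.integer(fix$POS),
      ref = fix$REF,
      alt = fix$ALT
    )
  )
}

#' Write a genotype matrix to a plain-text VCF file
#'
#' Emits a minimal VCF 4.2 file with one GT-only FORMAT field, re-readable
#' by [read_vcf()] with identical calls. Output is uncompressed text so
#' files can be diffed and checksummed; missing calls are written `./.`.
#'
#' @param m A [geno_matrix()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(m, path) {
  validate_geno_matrix(m)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  calls_chr <- matrix("./.", nrow = nrow(m$calls), ncol = ncol(m$calls))
  obs <- !is.na(m$calls)
  calls_chr[obs] <- gt_code[as.character(m$calls[obs])]

  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", m$samples$sample_id
    ), collapse = "\t")
  )
  body <- paste(
    m$sites$locus_id, m$sites$position, ".",
    m$sites$ref, m$sites$alt, ".", "PASS", ".", "GT",
    apply(calls_chr, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot write VCF to ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
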