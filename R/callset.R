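#' Cohort callset container
#'
#' A `cohort_callset` holds a polarized (or polarizable) genotype matrix for a
#' multi-sample cohort: one row per biallelic SNP site, one column per sample,
#' entries counting copies of the focal allele (the derived allele once
#' polarized, the ALT allele before), with `NA` for missing genotypes.
#'
#' @param sites data.frame with columns `chrom` (character), `pos` (1-based
#'   integer), and allele columns: `ref`/`alt` always, `anc`/`der` once
#'   polarized (`NA` before). Extra columns are carried along.
#' @param G integer matrix, `nrow(sites)` x `length(samples)`, values in
#'   `{0, 1, 2, NA}`.
#' @param samples character vector of sample names (column order of `G`).
#' @param populations character vector, population label per sample.
#' @param callable_bp numeric vector, per-sample callable length in bp used as
#'   the denominator of per-bp rates. Defaults to the number of sites, the
#'   fallback when no per-base coverage model exists.
#' @param polarized logical; `TRUE` when `G` counts derived alleles.
#' @param meta optional list of per-record/per-genotype fields used by the
#'   filters (`qual`, `dp`, `ad_ref`, `indels`, `mean_depth`).
#'
#' @return An object of class `cohort_callset`.
#' @export
cohort_callset <- function(sites, G, samples, populations,
                           callable_bp = NULL, polarized = FALSE,
                           meta = list()) {
  sites <- as.data.frame(sites)
  stopifnot(is.matrix(G), nrow(G) == nrow(sites), ncol(G) == length(samples))
  if (length(populations) != length(samples)) {
    stop("`populations` must give one label per sample")
  }
  if (is.null(callable_bp)) callable_bp <- rep(nrow(sites), length(samples))
  callable_bp <- rep_len(as.numeric(callable_bp), length(samples))
  storage.mode(G) <- "integer"
  colnames(G) <- samples
  if (!all(c("chrom", "pos") %in% names(sites))) {
    stop("`sites` needs `chrom` and `pos` columns")
  }
  if (!"anc" %in% names(sites)) sites$anc <- NA_character_
  if (!"der" %in% names(sites)) sites$der <- NA_character_
  x <- structure(
    list(sites = sites, G = G, samples = samples,
         populations = stats::setNames(populations, samples),
         callable_bp = stats::setNames(callable_bp, samples),
         polarized = polarized, meta = meta),
    class = "cohort_callset"
  )
  validate_callset(x)
  x
}

#' @rdname cohort_callset
#' @param x a `cohort_callset`.
#' @export
validate_callset <- function(x) {
  stopifnot(inherits(x, "cohort_callset"))
  bad <- !(x$G %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  o <- order(x$sites$chrom, x$sites$pos)
  if (!identical(o, seq_len(nrow(x$sites)))) {
    stop("sites must be sorted by (chrom, pos)")
  }
  if (anyDuplicated(x$sites[c("chrom", "pos")])) {
    stop("duplicate (chrom, pos) in sites")
  }
  invisible(x)
}

#' @export
print.cohort_callset <- function(x, ...) {
  cat(sprintf("cohort_callset: %d sites x %d samples (%s)\n",
              nrow(x$sites), length(x$samples),
              if (x$polarized) "polarized" else "ALT-dosage"))
  tab <- table(x$populations)
  cat("populations:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  cat(sprintf("chromosomes: %d; missing genotypes: %d\n",
              length(unique(x$sites$chrom)), sum(is.na(x$G))))
  invisible(x)
}

# internal: keep a row subset, preserving order and all parallel structures
subset_sites <- function(x, keep) {
  x$sites <- x$sites[keep, , drop = FALSE]
  rownames(x$sites) <- NULL
  x$G <- x$G[keep, , drop = FALSE]
  for (f in c("qual", "dp", "ad_ref")) {
    if (!is.null(x$meta[[f]])) {
      if (is.matrix(x$meta[[f]])) {
        x$meta[[f]] <- x$meta[[f]][keep, , drop = FALSE]
      } else {
        x$meta[[f]] <- x$meta[[f]][keep]
      }
    }
  }
  x
}

#' Restrict a callset to complete-case sites
#'
#' Keeps only sites genotyped in every sample, the complete-case restriction
#' applied before all load and frequency computations so that allele-count
#' denominators are constant across sites.
#'
#' @param callset a [cohort_callset()].
#' @return The callset with only zero-missingness sites; the number of
#'   dropped sites is recorded in `attr(, "n_dropped_incomplete")`.
#' @export
restrict_complete_cases <- function(callset) {
  validate_callset(callset)
  keep <- rowSums(is.na(callset$G)) == 0L
  out <- subset_sites(callset, keep)
  attr(out, "n_dropped_incomplete") <- sum(!keep)
  if (nrow(out$sites) == 0L && nrow(callset$sites) > 0L) {
    warning("no complete-case sites remain")
  }
  out
}

#' Per-site derived-allele frequencies by population
#'
#' Tabulates, for every site and population, the derived-allele count `d`,
#' the number of called alleles `n`, and the frequency `f = d/n`.
#'
#' @param callset a polarized [cohort_callset()].
#' @param complete_only drop sites with any missing genotype first
#'   (default `TRUE`, so `n` is constant within a population).
#' @return An object of class `freq_table`: list with `sites` (chrom, pos),
#'   and matrices `d`, `n`, `f` (sites x populations).
#' @export
freq_table <- function(callset, complete_only = TRUE) {
  if (!callset$polarized) {
    stop("callset must be polarized before computing derived-allele frequencies")
  }
  if (complete_only) callset <- restrict_complete_cases(callset)
  pops <- unique(unname(callset$populations))
  d <- n <- matrix(0, nrow(callset$sites), length(pops),
                   dimnames = list(NULL, pops))
  for (p in pops) {
    gp <- callset$G[, callset$populations == p, drop = FALSE]
    d[, p] <- rowSums(gp, na.rm = TRUE)
    n[, p] <- 2L * rowSums(!is.na(gp))
  }
  f <- ifelse(n > 0, d / n, NA_real_)
  structure(list(sites = callset$sites[c("chrom", "pos")],
                 d = d, n = n, f = f, populations = pops),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("freq_table: %d sites x %d populations (%s)\n",
              nrow(x$sites), length(x$populations),
              paste(x$populations, collapse = ", ")))
  invisible(x)
}
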