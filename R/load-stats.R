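#' GERP score bins
#'
#' The conservation-score categories used for relative load: interior
#' half-open bins `[0,1)` ("neutral"), `[1,3)`, `[3,5)`, then `>5`, with a
#' top category for scores above the top-1% threshold (default 5.88) that
#' overrides `>5`. Negative scores are labelled `"negative"` and excluded
#' from load computations (putatively unconstrained sites).
#'
#' @param edges increasing lower edges of the interior bins.
#' @param top_threshold top-percentile threshold; scores strictly above it
#'   fall in the top category.
#' @return A list of class `gerp_bins` with the category `labels`.
#' @export
gerp_bins <- function(edges = c(0, 1, 3, 5), top_threshold = 5.88) {
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be strictly increasing")
  if (top_threshold < edges[length(edges)]) {
    stop("top threshold must be at or above the last edge")
  }
  k <- length(edges)
  labels <- c(paste0(edges[-k], "-", edges[-1L]),
              paste0(">", edges[k]),
              paste0(">", top_threshold))
  structure(list(edges = edges, top_threshold = top_threshold,
                 labels = labels), class = "gerp_bins")
}

#' Assign GERP scores to categories
#'
#' @param score numeric conservation score(s).
#' @param bins a [gerp_bins()].
#' @return Character category labels (`"negative"` below the first edge,
#'   `NA` for missing scores).
#' @export
gerp_category <- function(score, bins = gerp_bins()) {
  stopifnot(inherits(bins, "gerp_bins"))
  k <- length(bins$edges)
  idx <- findInterval(score, bins$edges)
  lab <- rep(NA_character_, length(score))
  lab[!is.na(idx) & idx == 0L] <- "negative"
  ok <- !is.na(idx) & idx >= 1L
  lab[ok] <- bins$labels[idx[ok]]
  lab[!is.na(score) & score > bins$top_threshold] <- bins$labels[k + 1L]
  lab
}

# internal: dosage vector for one sample at an index of sites
sample_dosage <- function(callset, sample) {
  if (!sample %in% callset$samples) stop("unknown sample: ", sample)
  callset$G[, sample]
}

check_annot <- function(callset, annot) {
  if (nrow(annot) != nrow(callset$sites) ||
      !all(annot$chrom == callset$sites$chrom & annot$pos == callset$sites$pos)) {
    stop("annotation must be aligned to callset sites; see load_annotations(callset = ...)")
  }
  invisible(annot)
}

#' GERP-weighted relative mutational load
#'
#' For a sample and score category: the sum of GERP scores of its derived
#' alleles (homozygous sites counted twice) divided by its number of
#' derived alleles (heterozygous = one allele, homozygous = two). A
#' dosage-weighted mean conservation score: higher values mean the
#' sample's derived alleles sit at more constrained sites.
#'
#' @param callset a polarized, complete-case [cohort_callset()].
#' @param sample sample name.
#' @param annot annotation aligned to the callset (see
#'   [load_annotations()]) with a `gerp` column.
#' @param category a category label of `bins` (default the top-1% bin).
#' @param bins a [gerp_bins()].
#' @return The ratio, or `NA` when the sample has no derived alleles in
#'   the category (undefined, distinct from 0).
#' @export
relative_load_gerp <- function(callset, sample, annot,
                               category = gerp_bins()$labels[5],
                               bins = gerp_bins()) {
  check_annot(callset, annot)
  cat_lab <- gerp_category(annot$gerp, bins)
  d <- sample_dosage(callset, sample)
  use <- !is.na(cat_lab) & cat_lab == category & !is.na(d) & d > 0L
  if (!any(use)) return(NA_real_)
  sum(annot$gerp[use] * d[use]) / sum(d[use])
}

#' Total mutational load in coding regions
#'
#' Per-individual burden of derived variants of an impact category,
#' irrespective of zygosity (masked plus expressed). `mode = "sites"`
#' counts sites carrying at least one derived allele; `mode = "alleles"`
#' counts derived alleles (homozygotes twice).
#'
#' @param callset a polarized [cohort_callset()].
#' @param sample sample name.
#' @param annot aligned annotation with an `impact` column.
#' @param category impact category (`"LOW"`, `"MODERATE"`, `"HIGH"`).
#' @param mode counting mode.
#' @return Integer count.
#' @export
total_load <- function(callset, sample, annot,
                       category = c("HIGH", "MODERATE", "LOW"),
                       mode = c("sites", "alleles")) {
  category <- match.arg(category)
  mode <- match.arg(mode)
  check_annot(callset, annot)
  d <- sample_dosage(callset, sample)
  use <- !is.na(annot$impact) & annot$impact == category & !is.na(d)
  if (mode == "sites") sum(d[use] > 0L) else sum(d[use])
}

# internal: segregating category sites (0 < derived count < max) in the
# cohort or within a population
segregating_sites <- function(callset, annot, category,
                              denominator = c("cohort", "population"),
                              population = NULL) {
  denominator <- match.arg(denominator)
  cols <- if (denominator == "population") {
    if (is.null(population)) stop("population required for per-population denominator")
    callset$samples[callset$populations == population]
  } else callset$samples
  g <- callset$G[, cols, drop = FALSE]
  d <- rowSums(g, na.rm = TRUE)
  nmax <- 2L * rowSums(!is.na(g))
  which(!is.na(annot$impact) & annot$impact == category & d > 0L & d < nmax)
}

#' Realised (expressed) mutational load
#'
#' The number of category sites at which the sample is homozygous derived,
#' divided by twice the number of segregating category sites; segregation
#' is assessed on the cohort complete-case callset by default so that
#' values are comparable across individuals (per-population denominators
#' are available). Bounded by 0.5, attained when the sample is homozygous
#' at every segregating category site.
#'
#' @inheritParams total_load
#' @param denominator `"cohort"` (default) or `"population"` segregating
#'   sites.
#' @param population population label when `denominator = "population"`.
#' @return Fraction in `[0, 0.5]`, or `NA` when no category site segregates.
#' @export
realised_load <- function(callset, sample, annot,
                          category = c("HIGH", "MODERATE", "LOW"),
                          denominator = c("cohort", "population"),
                          population = NULL) {
  category <- match.arg(category)
  check_annot(callset, annot)
  seg <- segregating_sites(callset, annot, category, denominator, population)
  if (!length(seg)) return(NA_real_)
  d <- sample_dosage(callset, sample)[seg]
  sum(!is.na(d) & d == 2L) / (2 * length(seg))
}

#' Heterozygous/homozygous counts of derived category variants
#'
#' @inheritParams total_load
#' @param category impact category or, with `bins`, a GERP category label.
#' @param bins optional [gerp_bins()]; when given, `category` is matched
#'   against GERP categories of `annot$gerp` instead of `annot$impact`.
#' @return Named integer vector `c(n_het, n_hom)`.
#' @export
zygosity_counts <- function(callset, sample, annot, category, bins = NULL) {
  check_annot(callset, annot)
  lab <- if (is.null(bins)) annot$impact else gerp_category(annot$gerp, bins)
  d <- sample_dosage(callset, sample)
  use <- !is.na(lab) & lab == category & !is.na(d)
  c(n_het = sum(d[use] == 1L), n_hom = sum(d[use] == 2L))
}

#' Per-sample, per-category load summary table
#'
#' One row per (sample, category) over the impact categories and GERP
#' bins: zygosity breakdown, total load in both counting modes, realised
#' load (impact categories) and relative load (GERP categories).
#'
#' @param callset a polarized, complete-case [cohort_callset()].
#' @param annot aligned annotation with `gerp` and `impact` columns.
#' @param bins a [gerp_bins()].
#' @param impact_categories impact classes to summarise.
#' @return data.frame of class `load_summary`.
#' @export
load_summary <- function(callset, annot, bins = gerp_bins(),
                         impact_categories = c("LOW", "MODERATE", "HIGH")) {
  check_annot(callset, annot)
  gerp_lab <- gerp_category(annot$gerp, bins)
  rows <- list()
  for (sm in callset$samples) {
    d <- callset$G[, sm]
    for (cat in impact_categories) {
      use <- !is.na(annot$impact) & annot$impact == cat & !is.na(d)
      n_het <- sum(d[use] == 1L); n_hom <- sum(d[use] == 2L)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sm, population = unname(callset$populations[sm]),
        category = cat, kind = "impact",
        n_sites_derived = n_het + n_hom,
        n_derived_alleles = n_het + 2L * n_hom,
        n_het = n_het, n_hom = n_hom,
        total_load_sites = n_het + n_hom,
        total_load_alleles = n_het + 2L * n_hom,
        realised_load = realised_load(callset, sm, annot, cat),
        relative_load = NA_real_, stringsAsFactors = FALSE)
    }
    for (cat in bins$labels) {
      use <- !is.na(gerp_lab) & gerp_lab == cat & !is.na(d)
      n_het <- sum(d[use] == 1L); n_hom <- sum(d[use] == 2L)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sm, population = unname(callset$populations[sm]),
        category = cat, kind = "gerp",
        n_sites_derived = n_het + n_hom,
        n_derived_alleles = n_het + 2L * n_hom,
        n_het = n_het, n_hom = n_hom,
        total_load_sites = n_het + n_hom,
        total_load_alleles = n_het + 2L * n_hom,
        realised_load = NA_real_,
        relative_load = relative_load_gerp(callset, sm, annot, cat, bins),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("load_summary", class(out))
  out
}
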