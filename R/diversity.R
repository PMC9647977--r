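#' Per-sample heterozygosity in heterozygous sites per 1,000 bp
#'
#' Counts dosage-1 sites per sample and scales by the callable length:
#' `het_per_kb = n_het / callable_bp * 1000`.
#'
#' @param callset a [cohort_callset()].
#' @param sample sample name(s); default all samples.
#' @param callable_bp per-sample callable length; defaults to the
#'   `callable_bp` stored on the callset (itself defaulting to the number
#'   of sites passing filters when no coverage model exists).
#' @return Named numeric vector of rates.
#' @export
het_per_kb <- function(callset, sample = NULL, callable_bp = NULL) {
  if (is.null(sample)) sample <- callset$samples
  if (is.null(callable_bp)) callable_bp <- callset$callable_bp[sample]
  callable_bp <- rep_len(callable_bp, length(sample))
  if (any(callable_bp <= 0)) stop("callable_bp must be > 0")
  g <- callset$G[, sample, drop = FALSE]
  n_het <- colSums(g == 1L, na.rm = TRUE)
  stats::setNames(n_het / callable_bp * 1000, sample)
}

#' Windowed nucleotide diversity
#'
#' Computes pi in non-overlapping windows as the per-bp average pairwise
#' difference: per site, `2 * p * (1 - p) * n / (n - 1)` with `n` the
#' non-missing haplotypes and `p` the derived-allele frequency, summed per
#' window and divided by the window span. Sites with fewer than two called
#' haplotypes are skipped.
#'
#' @param callset a polarized [cohort_callset()].
#' @param window_bp window span (default 10 kb tiles).
#' @param by_population compute per population (default) or jointly.
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive),
#'   `population` (`"all"` when joint), `pi`.
#' @export
pi_windows <- function(callset, window_bp = 10000, by_population = TRUE) {
  if (window_bp <= 0) stop("window_bp must be > 0")
  groups <- if (by_population) {
    split(callset$samples, unname(callset$populations))
  } else {
    list(all = callset$samples)
  }
  s <- callset$sites
  out <- list()
  for (gname in names(groups)) {
    g <- callset$G[, groups[[gname]], drop = FALSE]
    n <- 2 * rowSums(!is.na(g))
    d <- rowSums(g, na.rm = TRUE)
    ok <- n >= 2
    term <- numeric(nrow(g))
    p <- d[ok] / n[ok]
    term[ok] <- 2 * p * (1 - p) * n[ok] / (n[ok] - 1)
    win <- (s$pos - 1) %/% window_bp
    for (cc in unique(s$chrom)) {
      here <- s$chrom == cc
      wmax <- max(win[here])
      tot <- vapply(0:wmax, function(w) sum(term[here & win == w]), numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        chrom = cc, start = (0:wmax) * window_bp + 1,
        end = (1:(wmax + 1)) * window_bp,
        population = gname, pi = tot / window_bp,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Tukey HSD comparison of a per-sample statistic between groups
#'
#' Pairwise honestly-significant-difference tests from a one-way ANOVA,
#' the standard way to contrast heterozygosity, F_ROH or load between
#' historical and modern populations.
#'
#' @param values numeric per-sample statistic.
#' @param groups group label per value.
#' @return data.frame `group1`, `group2`, `diff` (group1 - group2), `lwr`,
#'   `upr`, `p_adj`.
#' @export
pairwise_group_test <- function(values, groups) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups")
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    stop("groups with fewer than 2 values: ", paste(small, collapse = ", "))
  }
  fit <- stats::aov(values ~ g, data = data.frame(values = values,
                                                  g = factor(groups)))
  tk <- stats::TukeyHSD(fit)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(group1 = vapply(pairs, `[`, character(1), 1L),
             group2 = vapply(pairs, `[`, character(1), 2L),
             diff = unname(tk[, "diff"]), lwr = unname(tk[, "lwr"]),
             upr = unname(tk[, "upr"]), p_adj = unname(tk[, "p adj"]),
             stringsAsFactors = FALSE)
}
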