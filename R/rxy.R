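#' R_xy derived-allele frequency ratio
#'
#' For a variant category C and populations x and y,
#' `Freq_x(C) = sum over included sites of f_x * (1 - f_y)` and
#' symmetrically for y; `R_xy = Freq_x / Freq_y`. A value of 1 means no
#' frequency change between the populations; below 1, category C derived
#' alleles are relatively rarer in x than in y.
#'
#' Site inclusion (`site_rule`): `"pooled"` (default) keeps sites with at
#' least one derived allele in the pooled x+y sample; `"each"` is the
#' stricter rule requiring at least one derived allele in each population
#' (which excludes population-unique variants).
#'
#' @param freqs a [freq_table()].
#' @param pop_x,pop_y population names in `freqs`.
#' @param sites optional logical/integer site subset (e.g. an impact
#'   category mask aligned to `freqs$sites`); default all sites.
#' @param site_rule site-inclusion rule.
#' @return A list of class `rxy_summary` with `freq_x`, `freq_y`, `rxy`
#'   (`Inf` when `freq_y` is 0 with `freq_x > 0`; `NA` when both are 0),
#'   and `n_sites` included.
#' @export
rxy_point <- function(freqs, pop_x, pop_y, sites = NULL,
                      site_rule = c("pooled", "each")) {
  site_rule <- match.arg(site_rule)
  stopifnot(inherits(freqs, "freq_table"),
            all(c(pop_x, pop_y) %in% freqs$populations))
  keep <- rxy_included_sites(freqs, pop_x, pop_y, sites, site_rule)
  fx <- freqs$f[keep, pop_x]
  fy <- freqs$f[keep, pop_y]
  freq_x <- sum(fx * (1 - fy))
  freq_y <- sum(fy * (1 - fx))
  rxy <- if (freq_y > 0) {
    freq_x / freq_y
  } else if (freq_x > 0) Inf else NA_real_
  structure(list(pop_x = pop_x, pop_y = pop_y, freq_x = freq_x,
                 freq_y = freq_y, rxy = rxy, n_sites = length(keep),
                 site_rule = site_rule),
            class = "rxy_summary")
}

# internal: indices of sites included under the site rule
rxy_included_sites <- function(freqs, pop_x, pop_y, sites, site_rule) {
  idx <- if (is.null(sites)) {
    seq_len(nrow(freqs$sites))
  } else if (is.logical(sites)) which(sites) else as.integer(sites)
  dx <- freqs$d[idx, pop_x]
  dy <- freqs$d[idx, pop_y]
  if (site_rule == "pooled") idx[dx + dy >= 1] else idx[dx >= 1 & dy >= 1]
}

#' @rdname rxy_point
#'
#' @details
#' `rxy_jackknife()` adds a delete-one-chromosome jack-knife: `R_xy` is
#' recomputed leaving out each chromosome that contributes included sites,
#' yielding leave-one-out estimates, pseudo-values
#' (`J * rxy - (J - 1) * rxy_(-j)`), and the jack-knife mean and standard
#' error. At least two chromosomes must contribute.
#'
#' @export
rxy_jackknife <- function(freqs, pop_x, pop_y, sites = NULL,
                          site_rule = c("pooled", "each")) {
  site_rule <- match.arg(site_rule)
  point <- rxy_point(freqs, pop_x, pop_y, sites, site_rule)
  keep <- rxy_included_sites(freqs, pop_x, pop_y, sites, site_rule)
  chroms <- unique(freqs$sites$chrom[keep])
  if (length(chroms) < 2L) {
    stop("jack-knife needs included sites on at least 2 chromosomes (got ",
         length(chroms), ")")
  }
  loo <- vapply(chroms, function(cc) {
    fx <- freqs$f[keep, pop_x][freqs$sites$chrom[keep] != cc]
    fy <- freqs$f[keep, pop_y][freqs$sites$chrom[keep] != cc]
    sum(fx * (1 - fy)) / sum(fy * (1 - fx))
  }, numeric(1))
  names(loo) <- chroms
  J <- length(chroms)
  pseudo <- J * point$rxy - (J - 1) * loo
  point$chromosomes <- chroms
  point$loo <- loo
  point$pseudovalues <- pseudo
  point$jackknife_mean <- mean(pseudo)
  point$jackknife_se <- stats::sd(pseudo) / sqrt(J)
  point
}

#' @export
print.rxy_summary <- function(x, ...) {
  cat(sprintf("R_xy(%s, %s) = %.4f  [Freq_x %.4f / Freq_y %.4f; %d sites]\n",
              x$pop_x, x$pop_y, x$rxy, x$freq_x, x$freq_y, x$n_sites))
  if (!is.null(x$jackknife_mean)) {
    cat(sprintf("jack-knife over %d chromosomes: mean %.4f, se %.4f\n",
                length(x$chromosomes), x$jackknife_mean, x$jackknife_se))
  }
  invisible(x)
}

#' Between-population variant sharing and fixation summary
#'
#' Counts, over the given sites, variants present (`f > 0`) in each
#' population, shared between both, unique to each, fixed (`f = 1`) in
#' each and in both, and the number of sites whose derived frequency
#' increased or decreased from `pop_a` to `pop_b`.
#'
#' @param freqs a [freq_table()].
#' @param pop_a,pop_b population names (a = source, b = comparison).
#' @param sites optional site subset as in [rxy_point()].
#' @return Named integer/numeric vector of counts.
#' @export
sharing_summary <- function(freqs, pop_a, pop_b, sites = NULL) {
  stopifnot(inherits(freqs, "freq_table"),
            all(c(pop_a, pop_b) %in% freqs$populations))
  idx <- seq_len(nrow(freqs$sites))
  if (is.logical(sites)) idx <- which(sites) else if (!is.null(sites)) idx <- sites
  fa <- freqs$f[idx, pop_a]
  fb <- freqs$f[idx, pop_b]
  pa <- fa > 0
  pb <- fb > 0
  any_present <- pa | pb
  c(total_a = sum(pa), total_b = sum(pb),
    shared = sum(pa & pb),
    unique_a = sum(pa & !pb), unique_b = sum(pb & !pa),
    fixed_a = sum(fa == 1), fixed_b = sum(fb == 1),
    fixed_both = sum(fa == 1 & fb == 1),
    increased = sum(any_present & fb > fa),
    decreased = sum(any_present & fb < fa))
}
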