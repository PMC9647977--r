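#' Parameters for sliding-window ROH detection
#'
#' Mirrors the PLINK-style homozygosity scan. A window of `window_snp`
#' consecutive SNPs is called homozygous when it contains at most
#' `window_het` heterozygous and `window_missing` missing calls; a SNP is
#' ROH-eligible when at least `window_threshold` of the full windows
#' containing it are homozygous; maximal runs of eligible SNPs are split at
#' inter-SNP gaps above `gap_kb` and kept when they have at least `min_snp`
#' SNPs, span at least `min_kb`, average at most `density_kb` per SNP, and
#' contain at most `max_het_in_segment` heterozygous calls.
#'
#' @param window_snp SNPs per sliding window.
#' @param window_het maximum heterozygous calls per homozygous window.
#' @param window_missing maximum missing calls per homozygous window
#'   (0 by default: the analysis callset is complete-case).
#' @param window_threshold minimum fraction of homozygous windows.
#' @param min_snp minimum SNPs per segment.
#' @param min_kb minimum segment span in kb.
#' @param density_kb maximum kb per SNP within a segment.
#' @param gap_kb maximum gap between neighbouring SNPs in kb.
#' @param max_het_in_segment maximum heterozygous calls per segment.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snp = 500, window_het = 5, window_missing = 0,
                       window_threshold = 0.05, min_snp = 25, min_kb = 100,
                       density_kb = 50, gap_kb = 1000,
                       max_het_in_segment = 750) {
  stopifnot(window_snp >= 1, window_het >= 0, window_missing >= 0,
            window_threshold > 0, window_threshold <= 1,
            min_snp >= 0, min_kb > 0, density_kb > 0, gap_kb > 0,
            max_het_in_segment >= 0)
  structure(list(window_snp = as.integer(window_snp),
                 window_het = as.integer(window_het),
                 window_missing = as.integer(window_missing),
                 window_threshold = window_threshold,
                 min_snp = as.integer(min_snp), min_kb = min_kb,
                 density_kb = density_kb, gap_kb = gap_kb,
                 max_het_in_segment = as.integer(max_het_in_segment)),
            class = "roh_params")
}

#' @rdname roh_params
#' @param name preset name: `"main"` (window 500 SNPs / 5 het, the headline
#'   setting) or the alternates `"w100"` (100/1) and `"w250"` (250/3).
#' @export
roh_preset <- function(name = c("main", "w100", "w250", "w500")) {
  name <- match.arg(name)
  switch(name,
         main = ,
         w500 = roh_params(window_snp = 500, window_het = 5),
         w250 = roh_params(window_snp = 250, window_het = 3),
         w100 = roh_params(window_snp = 100, window_het = 1))
}

# core scan for one chromosome: dosage vector `d` (0/1/2/NA) at sorted
# positions `pos`; returns data.frame(start, end, n_snps, n_het)
scan_roh_chrom <- function(d, pos, p) {
  n <- length(d)
  if (n == 0L) return(NULL)
  w <- p$window_snp
  if (n < w) return(NULL)  # no full window: all SNPs ineligible
  het <- !is.na(d) & d == 1L
  mis <- is.na(d)
  nwin <- n - w + 1L
  cs_h <- c(0L, cumsum(het))
  cs_m <- c(0L, cumsum(mis))
  homwin <- (cs_h[(w + 1L):(n + 1L)] - cs_h[1:nwin]) <= p$window_het &
    (cs_m[(w + 1L):(n + 1L)] - cs_m[1:nwin]) <= p$window_missing
  cw <- c(0L, cumsum(homwin))
  i <- seq_len(n)
  j1 <- pmax(1L, i - w + 1L)
  j2 <- pmin(i, nwin)
  frac <- (cw[j2 + 1L] - cw[j1]) / (j2 - j1 + 1L)
  eligible <- frac >= p$window_threshold

  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    # split at large gaps
    brk <- which(diff(pos[idx]) > p$gap_kb * 1000)
    grp <- cumsum(c(1L, seq_along(idx)[-1L] %in% (brk + 1L)))
    for (sub in split(idx, grp)) {
      n_snps <- length(sub)
      span <- pos[sub[n_snps]] - pos[sub[1L]] + 1
      n_het <- sum(het[sub])
      if (n_snps >= p$min_snp && span >= p$min_kb * 1000 &&
          span / n_snps <= p$density_kb * 1000 &&
          n_het <= p$max_het_in_segment) {
        segs[[length(segs) + 1L]] <- c(pos[sub[1L]], pos[sub[n_snps]],
                                       n_snps, n_het)
      }
    }
  }
  if (!length(segs)) return(NULL)
  m <- do.call(rbind, segs)
  data.frame(start_bp = m[, 1L], end_bp = m[, 2L], n_snps = m[, 3L],
             n_het = m[, 4L])
}

#' Detect runs of homozygosity
#'
#' Sliding-window ROH scan (see [roh_params()]) over each chromosome of
#' each requested sample. Segment spans are measured between the first and
#' last SNP of the run (inclusive).
#'
#' @param callset a [cohort_callset()] with sorted sites.
#' @param sample sample name(s); default all.
#' @param params a [roh_params()] or preset name for [roh_preset()].
#' @return data.frame with one row per segment: `sample`, `chrom`,
#'   `start_bp`, `end_bp`, `length_bp`, `n_snps`, `n_het`.
#' @export
detect_roh <- function(callset, sample = NULL, params = roh_preset("main")) {
  if (is.character(params)) params <- roh_preset(params)
  stopifnot(inherits(params, "roh_params"))
  validate_callset(callset)
  if (is.null(sample)) sample <- callset$samples
  s <- callset$sites
  out <- list()
  for (sm in sample) {
    d_all <- callset$G[, sm]
    for (cc in unique(s$chrom)) {
      here <- which(s$chrom == cc)
      segs <- scan_roh_chrom(d_all[here], s$pos[here], params)
      if (!is.null(segs)) {
        segs <- cbind(data.frame(sample = sm, chrom = cc,
                                 stringsAsFactors = FALSE), segs)
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sample = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      length_bp = numeric(0), n_snps = integer(0),
                      n_het = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$length_bp <- res$end_bp - res$start_bp + 1
  rownames(res) <- NULL
  res[c("sample", "chrom", "start_bp", "end_bp", "length_bp",
        "n_snps", "n_het")]
}

#' Genomic inbreeding coefficient from ROH
#'
#' `F_ROH` = total length of segments at or above `min_length_bp`, divided
#' by the analysed (autosomal) genome length.
#'
#' @param segments segment data.frame from [detect_roh()] (one sample).
#' @param genome_bp total analysed genome length in bp.
#' @param min_length_bp minimum segment length retained (100 kb default).
#' @return Fraction in `[0, 1]`.
#' @export
compute_froh <- function(segments, genome_bp, min_length_bp = 1e5) {
  if (genome_bp <= 0) stop("genome_bp must be > 0")
  if (is.null(segments) || nrow(segments) == 0L) return(0)
  len <- segments$end_bp - segments$start_bp + 1
  sum(len[len >= min_length_bp]) / genome_bp
}

#' @rdname compute_froh
#' @param callset,params,sample as in [detect_roh()].
#' @param min_lengths_bp vector of minimum lengths, one F_ROH column each.
#' @return `froh_table`: data.frame with `sample`, `population` and one
#'   `froh_*` column per threshold.
#' @export
froh_table <- function(callset, genome_bp, params = roh_preset("main"),
                       sample = NULL, min_lengths_bp = c(1e5, 2e6)) {
  if (is.null(sample)) sample <- callset$samples
  segs <- detect_roh(callset, sample, params)
  res <- data.frame(sample = sample,
                    population = unname(callset$populations[sample]),
                    stringsAsFactors = FALSE)
  for (ml in min_lengths_bp) {
    col <- sprintf("froh_%s", format(ml, scientific = FALSE, trim = TRUE))
    res[[col]] <- vapply(sample, function(sm) {
      compute_froh(segs[segs$sample == sm, , drop = FALSE], genome_bp, ml)
    }, numeric(1))
  }
  res
}

#' Length spectrum of ROH segments
#'
#' Histogram of segment lengths over half-open bins `[lo, hi)` defined by
#' `bin_edges_bp`; a segment exactly on an edge is assigned to the bin
#' whose lower edge it equals.
#'
#' @param segments segment data.frame from [detect_roh()].
#' @param bin_edges_bp increasing bin edges in bp.
#' @return data.frame `bin_lo`, `bin_hi`, `count`.
#' @export
roh_spectrum <- function(segments, bin_edges_bp) {
  if (is.unsorted(bin_edges_bp, strictly = TRUE)) {
    stop("bin edges must be strictly increasing")
  }
  k <- length(bin_edges_bp) - 1L
  counts <- integer(k)
  if (!is.null(segments) && nrow(segments) > 0L) {
    len <- segments$end_bp - segments$start_bp + 1
    b <- findInterval(len, bin_edges_bp)
    b <- b[b >= 1L & b <= k]
    counts <- tabulate(b, nbins = k)
  }
  data.frame(bin_lo = bin_edges_bp[-length(bin_edges_bp)],
             bin_hi = bin_edges_bp[-1L], count = counts)
}
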