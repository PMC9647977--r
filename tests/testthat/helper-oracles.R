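# Independent brute-force oracles. These re-derive expected values with
# naive enumeration and must stay independent of the package internals.

# ROH oracle: explicit window loops and run enumeration following the
# four detection rules directly.
roh_oracle <- function(d, pos, p) {
  n <- length(d)
  if (n < p$window_snp) return(NULL)
  w <- p$window_snp
  het <- !is.na(d) & d == 1L
  mis <- is.na(d)
  nwin <- n - w + 1L
  hom_cover <- integer(n)
  tot_cover <- integer(n)
  for (j in seq_len(nwin)) {
    idx <- j:(j + w - 1L)
    is_hom <- sum(het[idx]) <= p$window_het && sum(mis[idx]) <= p$window_missing
    hom_cover[idx] <- hom_cover[idx] + as.integer(is_hom)
    tot_cover[idx] <- tot_cover[idx] + 1L
  }
  eligible <- tot_cover > 0L & hom_cover / pmax(tot_cover, 1L) >= p$window_threshold
  segs <- list()
  i <- 1L
  while (i <= n) {
    if (!eligible[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && eligible[j + 1L] && pos[j + 1L] - pos[j] <= p$gap_kb * 1000) {
      j <- j + 1L
    }
    n_snps <- j - i + 1L
    span <- pos[j] - pos[i] + 1
    n_het <- sum(het[i:j])
    if (n_snps >= p$min_snp && span >= p$min_kb * 1000 &&
        span / n_snps <= p$density_kb * 1000 &&
        n_het <= p$max_het_in_segment) {
      segs[[length(segs) + 1L]] <- c(pos[i], pos[j], n_snps, n_het)
    }
    i <- j + 1L
  }
  if (!length(segs)) return(NULL)
  m <- do.call(rbind, segs)
  data.frame(start_bp = m[, 1], end_bp = m[, 2], n_snps = m[, 3],
             n_het = m[, 4])
}

# Windowed pi oracle: exhaustive average pairwise difference per site over
# all allele pairs across individuals, skipping missing genotypes.
pi_oracle <- function(G, pos, window_bp) {
  site_pi <- vapply(seq_len(nrow(G)), function(i) {
    d <- G[i, ]
    d <- d[!is.na(d)]
    alleles <- unlist(lapply(d, function(x) c(rep(1L, x), rep(0L, 2L - x))))
    if (length(alleles) < 2L) return(0)
    pr <- utils::combn(length(alleles), 2L)
    mean(alleles[pr[1L, ]] != alleles[pr[2L, ]])
  }, numeric(1))
  win <- (pos - 1) %/% window_bp
  vapply(sort(unique(win)), function(w) sum(site_pi[win == w]) / window_bp,
         numeric(1))
}

# Tukey HSD oracle from the studentized-range distribution.
tukey_oracle_p <- function(values, groups, g1, g2) {
  groups <- as.character(groups)
  k <- length(unique(groups))
  n_tot <- length(values)
  mse <- sum(unlist(lapply(split(values, groups),
                           function(v) (v - mean(v))^2))) / (n_tot - k)
  m <- tapply(values, groups, mean)
  n <- tapply(values, groups, length)
  q_obs <- abs(m[g1] - m[g2]) / sqrt(mse / 2 * (1 / n[g1] + 1 / n[g2]))
  unname(1 - stats::ptukey(q_obs, nmeans = k, df = n_tot - k))
}

# Random dosage map with planted homozygous stretches, for ROH
# property tests.
random_roh_instance <- function(n_snps, seed) {
  set.seed(seed)
  pos <- sort(sample.int(n_snps * sample(c(2000L, 8000L, 40000L), 1L), n_snps))
  d <- sample(0:2, n_snps, replace = TRUE, prob = c(0.35, 0.3, 0.35))
  # plant 0-3 homozygous stretches
  for (k in seq_len(sample(0:3, 1L))) {
    a <- sample.int(n_snps, 1L)
    b <- min(n_snps, a + sample(c(30L, 120L, 600L), 1L))
    d[a:b] <- sample(c(0L, 2L), b - a + 1L, replace = TRUE)
    # sprinkle rare hets inside
    hit <- which(stats::runif(b - a + 1L) < 0.005)
    d[a - 1L + hit] <- 1L
  }
  list(d = d, pos = pos)
}
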