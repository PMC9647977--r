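# Fixtures are built in code at test time; nothing binary is stored.

# A hand-sized polarized callset for arithmetic checks.
toy_callset <- function(G, chrom = NULL, pos = NULL,
                        populations = NULL, callable_bp = NULL) {
  G <- as.matrix(G)
  ns <- nrow(G)
  if (is.null(chrom)) chrom <- rep("chr1", ns)
  if (is.null(pos)) pos <- seq_len(ns) * 100L
  samples <- colnames(G)
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(G)))
  if (is.null(populations)) populations <- rep("pop1", ncol(G))
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = "A", alt = "G", anc = "A", der = "G",
                      stringsAsFactors = FALSE)
  cohort_callset(sites, G, samples, populations,
                 callable_bp = callable_bp, polarized = TRUE)
}

# Aligned annotation for a toy callset.
toy_annot <- function(callset, gerp = NULL, impact = NULL) {
  ns <- nrow(callset$sites)
  data.frame(chrom = callset$sites$chrom, pos = callset$sites$pos,
             gerp = if (is.null(gerp)) rep(NA_real_, ns) else gerp,
             impact = if (is.null(impact)) rep(NA_character_, ns) else impact,
             stringsAsFactors = FALSE)
}

# A small, fast simulation configuration for structural tests.
small_sim_config <- function(seed = 1, n_init_sites = 1200, ...) {
  sim_config(
    n_chromosomes = 4, chrom_length_bp = 5e5, n_init_sites = n_init_sites,
    demography = list(
      epoch("source", 5, 60),
      sample_event("source", "historical", 6),
      epoch("source", 3, 20),
      bottleneck_to_pair("source"),
      epoch("source", 5, 30, ramp = TRUE),
      split_event("source", "translocated", 10),
      epoch("source", 5, 20),
      epoch("translocated", 5, 10),
      sample_event("source", "popA", 6),
      sample_event("translocated", "popB", 6)),
    seed = seed, ...)
}

# Freq table built directly from count matrices (bypasses cohort_callset).
manual_freq_table <- function(chrom, d, n, pops = colnames(d)) {
  d <- as.matrix(d); n <- as.matrix(n)
  colnames(d) <- colnames(n) <- pops
  structure(list(sites = data.frame(chrom = chrom,
                                    pos = seq_along(chrom) * 10L),
                 d = d, n = n, f = d / n, populations = pops),
            class = "freq_table")
}
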