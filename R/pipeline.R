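#' Pipeline run configuration
#'
#' Exactly one input mode is enabled per run: a simulation config (the
#' synthetic cohort generator) or a VCF plus sample-population map. All
#' analysis stages consume the polarized, filtered, complete-case callset.
#'
#' @param simulation a [sim_config()], or `NULL` for VCF input.
#' @param vcf path to a multi-sample VCF, or `NULL` for simulation input.
#' @param sample_map data.frame or TSV path mapping `sample` to
#'   `population` (required with `vcf`).
#' @param gerp_tsv,impact annotation sources for [load_annotations()];
#'   `NULL` skips the load stage (simulation input provides its own).
#' @param outgroup outgroup alleles for [polarize_to_ancestral()] (`NULL`
#'   uses the VCF's `AA` tag; simulated callsets are already polarized).
#' @param filters a [filter_spec()], or `NULL` to skip filtering.
#' @param roh a [roh_params()] or preset name.
#' @param bins a [gerp_bins()].
#' @param genome_bp analysed genome length (F_ROH denominator, het/kb
#'   denominator); inferred from the simulation config when `NULL`.
#' @param window_bp pi window span.
#' @param stages character subset of
#'   `c("diversity", "roh", "load", "rxy")`.
#' @param out_dir output directory for TSVs and the manifest; `NULL`
#'   computes in memory only.
#' @param seed integer seed for the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulation = NULL, vcf = NULL, sample_map = NULL,
                       gerp_tsv = NULL, impact = NULL, outgroup = NULL,
                       filters = NULL, roh = roh_preset("main"),
                       bins = gerp_bins(), genome_bp = NULL,
                       window_bp = 10000,
                       stages = c("diversity", "roh", "load", "rxy"),
                       out_dir = NULL, seed = 1L) {
  if (is.null(simulation) == is.null(vcf)) {
    stop("exactly one of `simulation` or `vcf` must be given")
  }
  if (!is.null(vcf) && is.null(sample_map)) {
    stop("config key `sample_map` (populations) is required with a VCF input")
  }
  if (is.character(roh)) roh <- roh_preset(roh)
  structure(list(simulation = simulation, vcf = vcf, sample_map = sample_map,
                 gerp_tsv = gerp_tsv, impact = impact, outgroup = outgroup,
                 filters = filters, roh = roh, bins = bins,
                 genome_bp = genome_bp, window_bp = window_bp,
                 stages = stages, out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate or read,
#' filter, polarize, restrict to complete cases, then diversity, ROH,
#' load and R_xy/sharing — and (optionally) writes one TSV per result
#' plus a run manifest with the seed and per-stage site/sample counts.
#' Identical (config, seed) runs produce identical outputs.
#'
#' @param config a [run_config()].
#' @return A list of class `pipeline_result` with the callset, annotation
#'   and all stage tables; written file paths in `$paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  counts <- list()

  if (!is.null(config$simulation)) {
    sim <- simulate_cohort(config$simulation, seed = config$seed)
    callset <- sim$callset
    annot <- sim$annotation
    counts$simulated_sites <- nrow(callset$sites)
    genome_bp <- config$genome_bp
    if (is.null(genome_bp)) {
      genome_bp <- config$simulation$n_chromosomes *
        config$simulation$chrom_length_bp
    }
  } else {
    callset <- read_cohort_vcf(config$vcf, config$sample_map)
    counts$vcf_sites <- nrow(callset$sites)
    if (!is.null(config$filters)) {
      callset <- apply_site_filters(callset, config$filters)
      counts$filtered_sites <- nrow(callset$sites)
    }
    callset <- polarize_to_ancestral(callset, config$outgroup)
    counts$polarized_sites <- nrow(callset$sites)
    annot <- if (!is.null(config$gerp_tsv) || !is.null(config$impact)) {
      load_annotations(config$gerp_tsv, config$impact, callset = callset)
    } else NULL
    genome_bp <- if (is.null(config$genome_bp)) nrow(callset$sites) else
      config$genome_bp
  }

  callset <- restrict_complete_cases(callset)
  counts$complete_case_sites <- nrow(callset$sites)
  counts$samples <- length(callset$samples)
  if (!is.null(annot)) {
    annot <- load_annotations(annot[c("chrom", "pos", "gerp")],
                              annot[c("chrom", "pos", "impact")],
                              callset = callset)
  }

  res <- list(callset = callset, annotation = annot, config = config)
  pops <- unique(unname(callset$populations))
  pop_sizes <- table(callset$populations)

  if ("diversity" %in% config$stages) {
    het <- het_per_kb(callset)
    res$het <- data.frame(sample = names(het),
                          population = unname(callset$populations[names(het)]),
                          het_per_kb = unname(het), stringsAsFactors = FALSE)
    res$pi <- pi_windows(callset, window_bp = config$window_bp)
    if (length(pops) >= 2L && all(pop_sizes >= 2L)) {
      res$het_test <- pairwise_group_test(res$het$het_per_kb,
                                          res$het$population)
    }
  }
  if ("roh" %in% config$stages) {
    res$roh <- detect_roh(callset, params = config$roh)
    res$froh <- froh_table(callset, genome_bp = genome_bp,
                           params = config$roh)
    if (length(pops) >= 2L && all(pop_sizes >= 2L)) {
      res$froh_test <- pairwise_group_test(res$froh$froh_100000,
                                           res$froh$population)
    }
  }
  if ("load" %in% config$stages && !is.null(annot)) {
    res$load <- load_summary(callset, annot, bins = config$bins)
  }
  if ("rxy" %in% config$stages && !is.null(annot) && length(pops) >= 2L) {
    freqs <- freq_table(callset)
    pairs <- utils::combn(pops, 2L)
    rxy_rows <- list(); pseudo_rows <- list(); share_rows <- list()
    for (cat in c("MODERATE", "HIGH")) {
      mask <- !is.na(annot$impact) & annot$impact == cat
      for (k in seq_len(ncol(pairs))) {
        y <- pairs[1L, k]; x <- pairs[2L, k]  # x = later population vs y
        rj <- tryCatch(rxy_jackknife(freqs, x, y, sites = mask),
                       error = function(e) rxy_point(freqs, x, y, sites = mask))
        rxy_rows[[length(rxy_rows) + 1L]] <- data.frame(
          category = cat, pop_x = x, pop_y = y, n_sites = rj$n_sites,
          freq_x = rj$freq_x, freq_y = rj$freq_y, rxy = rj$rxy,
          jackknife_mean = rj$jackknife_mean %||% NA_real_,
          jackknife_se = rj$jackknife_se %||% NA_real_,
          stringsAsFactors = FALSE)
        if (!is.null(rj$pseudovalues)) {
          pseudo_rows[[length(pseudo_rows) + 1L]] <- data.frame(
            category = cat, pop_x = x, pop_y = y,
            chrom = rj$chromosomes,
            loo = unname(rj$loo), pseudovalue = unname(rj$pseudovalues),
            stringsAsFactors = FALSE)
        }
        share_rows[[length(share_rows) + 1L]] <- data.frame(
          category = cat, pop_a = y, pop_b = x,
          t(sharing_summary(freqs, y, x, sites = mask)),
          stringsAsFactors = FALSE)
      }
    }
    res$rxy <- do.call(rbind, rxy_rows)
    res$rxy_pseudovalues <- if (length(pseudo_rows)) do.call(rbind, pseudo_rows)
    res$sharing <- do.call(rbind, share_rows)
  }

  res$manifest <- data.frame(
    key = c("package_version", "seed", "genome_bp", "stages",
            paste0("n_", names(counts))),
    value = c(as.character(utils::packageVersion("rohload")),
              config$seed, genome_bp,
              paste(config$stages, collapse = ","),
              unlist(counts, use.names = FALSE)),
    stringsAsFactors = FALSE)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    for (nm in c("het", "pi", "het_test", "roh", "froh", "froh_test",
                 "load", "rxy", "rxy_pseudovalues", "sharing", "manifest")) {
      if (!is.null(res[[nm]])) {
        p <- file.path(config$out_dir, paste0(nm, ".tsv"))
        write_hash_tsv(as.data.frame(res[[nm]]), p)
        paths[nm] <- p
      }
    }
    res$paths <- paths
  }
  class(res) <- "pipeline_result"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  for (i in seq_len(nrow(x$manifest))) {
    cat(sprintf("  %s: %s\n", x$manifest$key[i], x$manifest$value[i]))
  }
  invisible(x)
}
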