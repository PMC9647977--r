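#' Read a multi-sample VCF into a cohort callset
#'
#' Loads biallelic SNP records (dosages encoded against ALT until
#' [polarize_to_ancestral()] is applied). Multi-allelic and non-SNP
#' records are skipped with logged counts; indel positions are retained
#' for the proximity filter. Per-record QUAL and per-genotype DP/AD are
#' kept for [apply_site_filters()] when present in the file.
#'
#' @param path VCF v4.2 file (plain text or bgzipped).
#' @param sample_pop_table data.frame with columns `sample` and
#'   `population`, or path to such a TSV. Every VCF sample must appear.
#' @return A [cohort_callset()] (unpolarized) with `attr(, "skip_log")`
#'   counting skipped records.
#' @export
read_cohort_vcf <- function(path, sample_pop_table) {
  if (is.character(sample_pop_table)) {
    sample_pop_table <- read_hash_tsv(sample_pop_table)
  }
  if (!all(c("sample", "population") %in% names(sample_pop_table))) {
    stop("sample table needs `sample` and `population` columns")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1L]
  missing <- setdiff(samples, sample_pop_table$sample)
  if (length(missing)) {
    stop("samples in VCF absent from population table: ",
         paste(missing, collapse = ", "))
  }
  pops <- sample_pop_table$population[match(samples, sample_pop_table$sample)]

  alt <- fix$ALT
  ref <- fix$REF
  multi <- grepl(",", alt, fixed = TRUE)
  snp <- !multi & !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  indel <- !snp & !multi
  skip_log <- c(multiallelic = sum(multi), non_snp = sum(indel))
  indels <- data.frame(chrom = fix$CHROM[indel],
                       pos = as.integer(fix$POS[indel]),
                       stringsAsFactors = FALSE)

  keep <- which(snp)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  G <- matrix(NA_integer_, length(keep), length(samples))
  called <- !is.na(gt) & a1 %in% c("0", "1") & a2 %in% c("0", "1")
  G[called] <- (a1[called] == "1") + (a2[called] == "1")

  fmt <- if (ncol(v@gt) > 0) v@gt[1L, 1L] else ""
  meta <- list(indels = indels,
               qual = suppressWarnings(as.numeric(fix$QUAL[keep])))
  if (grepl("DP", fmt)) {
    meta$dp <- suppressWarnings(
      vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))[keep, , drop = FALSE]
  }
  if (grepl("AD", fmt)) {
    ad <- vcfR::extract.gt(v, element = "AD")[keep, , drop = FALSE]
    meta$ad_ref <- suppressWarnings(
      matrix(as.numeric(sub(",.*", "", ad)), nrow(ad), ncol(ad)))
  }
  aa <- regmatches(fix$INFO[keep], regexpr("AA=[ACGTacgt]", fix$INFO[keep]))
  aa_full <- rep(NA_character_, length(keep))
  has_aa <- grepl("AA=[ACGTacgt]", fix$INFO[keep])
  aa_full[has_aa] <- toupper(sub("AA=", "", aa))

  sites <- data.frame(chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
                      ref = ref[keep], alt = alt[keep], aa = aa_full,
                      stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  G <- G[ord, , drop = FALSE]
  meta$qual <- meta$qual[ord]
  if (!is.null(meta$dp)) meta$dp <- meta$dp[ord, , drop = FALSE]
  if (!is.null(meta$ad_ref)) meta$ad_ref <- meta$ad_ref[ord, , drop = FALSE]

  out <- cohort_callset(sites = sites, G = G, samples = samples,
                        populations = pops, polarized = FALSE, meta = meta)
  attr(out, "skip_log") <- skip_log
  out
}

#' Polarize a callset against an outgroup
#'
#' Reassigns ancestral/derived status per site from an outgroup base and
#' recodes dosages to count derived alleles. If the outgroup carries the
#' currently counted allele the dosage flips (`d -> 2 - d`, missing stays
#' missing); if it carries the other allele the dosage is unchanged; if it
#' matches neither allele (or is missing) the site is dropped and counted.
#'
#' @param callset a [cohort_callset()].
#' @param outgroup_alleles per-site outgroup base: a character vector
#'   aligned with the callset sites, a data.frame (`chrom`, `pos`, `base`),
#'   or `NULL` to use the `AA` INFO tag captured at read time.
#' @return The polarized callset with `attr(, "n_dropped_polarize")`.
#' @export
polarize_to_ancestral <- function(callset, outgroup_alleles = NULL) {
  s <- callset$sites
  out_base <- if (is.null(outgroup_alleles)) {
    if (is.null(s$aa)) stop("no outgroup bases: callset has no AA tag and none supplied")
    s$aa
  } else if (is.data.frame(outgroup_alleles)) {
    key <- paste(s$chrom, s$pos)
    outgroup_alleles$base[match(key, paste(outgroup_alleles$chrom,
                                           outgroup_alleles$pos))]
  } else {
    rep_len(outgroup_alleles, nrow(s))
  }
  out_base <- toupper(out_base)
  counted <- if (callset$polarized) s$der else s$alt
  other <- ifelse(counted == s$alt, s$ref, s$alt)
  flip <- !is.na(out_base) & out_base == counted
  keep_same <- !is.na(out_base) & out_base == other
  keep <- flip | keep_same
  callset$G[flip, ] <- 2L - callset$G[flip, , drop = FALSE]
  callset$sites$anc <- out_base
  callset$sites$der <- ifelse(flip, other, counted)
  n_dropped <- sum(!keep)
  callset <- subset_sites(callset, keep)
  callset$polarized <- TRUE
  attr(callset, "n_dropped_polarize") <- n_dropped
  callset
}

#' Site- and genotype-level filter specification
#'
#' Defaults follow a conservative resequencing pipeline: site QUAL >= 30,
#' SNPs within 5 bp of an indel removed, per-genotype depth at least 1/3 of
#' (and at most twice) the sample's mean depth, and heterozygotes kept only
#' when the REF-read fraction lies within \[0.2, 0.8\]. Set an element to
#' `NULL` to disable that filter.
#'
#' @param min_qual phred site-quality threshold.
#' @param min_depth_frac per-genotype minimum depth as a fraction of the
#'   sample mean depth.
#' @param max_depth_mult per-genotype maximum depth as a multiple of the
#'   sample mean depth.
#' @param indel_pad_bp exclusion distance around indels.
#' @param ab_low,ab_high allelic-balance (REF reads / total reads) bounds
#'   for heterozygous genotypes.
#' @param mask_beds list of BED mask files or data.frames (`chrom`,
#'   `start`, `end`; 0-based half-open) for repeats/CpG.
#' @param excluded_scaffolds scaffolds removed outright (e.g. sex-linked).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(min_qual = 30, min_depth_frac = 1 / 3,
                        max_depth_mult = 2, indel_pad_bp = 5,
                        ab_low = 0.2, ab_high = 0.8,
                        mask_beds = list(), excluded_scaffolds = character(0)) {
  if (!is.null(ab_low) && !is.null(ab_high) &&
      (ab_low < 0 || ab_low >= ab_high || ab_high > 1)) {
    stop("allelic-balance bounds need 0 <= ab_low < ab_high <= 1")
  }
  if (!is.null(indel_pad_bp) && indel_pad_bp < 0) stop("indel_pad_bp must be >= 0")
  structure(list(min_qual = min_qual, min_depth_frac = min_depth_frac,
                 max_depth_mult = max_depth_mult, indel_pad_bp = indel_pad_bp,
                 ab_low = ab_low, ab_high = ab_high, mask_beds = mask_beds,
                 excluded_scaffolds = excluded_scaffolds),
            class = "filter_spec")
}

read_bed <- function(x) {
  if (is.character(x)) {
    x <- utils::read.table(x, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#")[, 1:3]
    names(x) <- c("chrom", "start", "end")
  }
  x
}

#' Apply site- and genotype-level filters
#'
#' Removes sites failing QUAL, indel-proximity, mask and scaffold-exclusion
#' filters; sets individual genotypes missing when their depth leaves the
#' per-sample bounds or a heterozygote's allelic balance falls outside the
#' configured interval. Depth filtering is per genotype (not per site) so a
#' single low-coverage sample does not delete a site before complete-case
#' restriction. Applying the same spec twice is a no-op: per-sample mean
#' depths are computed once and cached on the callset.
#'
#' @param callset a [cohort_callset()] from [read_cohort_vcf()].
#' @param spec a [filter_spec()].
#' @param mean_depth optional named per-sample mean depths; computed from
#'   the DP matrix otherwise.
#' @return The filtered callset; `attr(, "filter_log")` counts removals per
#'   filter (sites for site-level filters, genotype cells for depth/balance).
#' @export
apply_site_filters <- function(callset, spec, mean_depth = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  log <- c(excluded_scaffold = 0, masked = 0, qual = 0, indel_pad = 0,
           depth_cells = 0, ab_cells = 0)

  if (length(spec$excluded_scaffolds)) {
    drop <- callset$sites$chrom %in% spec$excluded_scaffolds
    log[["excluded_scaffold"]] <- sum(drop)
    callset <- subset_sites(callset, !drop)
  }
  if (length(spec$mask_beds)) {
    masked <- rep(FALSE, nrow(callset$sites))
    for (b in spec$mask_beds) {
      bed <- read_bed(b)
      for (i in seq_len(nrow(bed))) {
        masked <- masked | (callset$sites$chrom == bed$chrom[i] &
                              callset$sites$pos > bed$start[i] &
                              callset$sites$pos <= bed$end[i])
      }
    }
    log[["masked"]] <- sum(masked)
    callset <- subset_sites(callset, !masked)
  }
  if (!is.null(spec$min_qual)) {
    if (is.null(callset$meta$qual)) stop("QUAL filter enabled but field `qual` is absent")
    drop <- !is.na(callset$meta$qual) & callset$meta$qual < spec$min_qual
    log[["qual"]] <- sum(drop)
    callset <- subset_sites(callset, !drop)
  }
  if (!is.null(spec$indel_pad_bp)) {
    if (is.null(callset$meta$indels)) stop("indel filter enabled but field `indels` is absent")
    ind <- callset$meta$indels
    if (nrow(ind)) {
      drop <- rep(FALSE, nrow(callset$sites))
      for (cc in unique(ind$chrom)) {
        ip <- sort(ind$pos[ind$chrom == cc])
        here <- which(callset$sites$chrom == cc)
        if (!length(here)) next
        p <- callset$sites$pos[here]
        j <- findInterval(p, ip)
        d_left <- ifelse(j >= 1L, p - ip[pmax(j, 1L)], Inf)
        d_right <- ifelse(j < length(ip), ip[pmin(j + 1L, length(ip))] - p, Inf)
        drop[here] <- pmin(d_left, d_right) <= spec$indel_pad_bp
      }
      log[["indel_pad"]] <- sum(drop)
      callset <- subset_sites(callset, !drop)
    }
  }
  if (!is.null(spec$min_depth_frac) || !is.null(spec$max_depth_mult)) {
    if (is.null(callset$meta$dp)) stop("depth filter enabled but field `dp` is absent")
    dp <- callset$meta$dp
    if (is.null(mean_depth)) mean_depth <- callset$meta$mean_depth
    if (is.null(mean_depth)) mean_depth <- colMeans(dp, na.rm = TRUE)
    callset$meta$mean_depth <- mean_depth
    lo <- if (is.null(spec$min_depth_frac)) rep(-Inf, ncol(dp)) else
      spec$min_depth_frac * mean_depth
    hi <- if (is.null(spec$max_depth_mult)) rep(Inf, ncol(dp)) else
      spec$max_depth_mult * mean_depth
    bad <- !is.na(dp) & (sweep(dp, 2L, lo, `<`) | sweep(dp, 2L, hi, `>`))
    bad <- bad & !is.na(callset$G)
    log[["depth_cells"]] <- sum(bad)
    callset$G[bad] <- NA_integer_
  }
  if (!is.null(spec$ab_low)) {
    if (is.null(callset$meta$ad_ref) || is.null(callset$meta$dp)) {
      stop("allelic-balance filter enabled but field `ad_ref`/`dp` is absent")
    }
    ab <- callset$meta$ad_ref / callset$meta$dp
    het <- !is.na(callset$G) & callset$G == 1L
    bad <- het & !is.na(ab) & (ab < spec$ab_low | ab > spec$ab_high)
    log[["ab_cells"]] <- sum(bad)
    callset$G[bad] <- NA_integer_
  }
  attr(callset, "filter_log") <- log
  callset
}

#' Load per-site conservation scores and impact categories
#'
#' Joins a GERP score TSV (`chrom`, `pos`, `gerp`) with impact categories
#' from either a TSV (`chrom`, `pos`, `impact`) or a SnpEff-annotated VCF
#' (impact parsed from the third `|`-field of the `ANN` INFO key).
#'
#' @param gerp_tsv path or data.frame with columns `chrom`, `pos`, `gerp`.
#' @param impact_source path to a TSV or SnpEff VCF, or a data.frame with
#'   columns `chrom`, `pos`, `impact`.
#' @param callset optional [cohort_callset()]; when given, the result is
#'   aligned to its sites and unannotated sites are flagged.
#' @return data.frame `chrom`, `pos`, `gerp`, `impact` (and `annotated`
#'   when aligned to a callset).
#' @export
load_annotations <- function(gerp_tsv, impact_source, callset = NULL) {
  if (is.null(gerp_tsv)) {
    gerp_tsv <- data.frame(chrom = character(0), pos = integer(0),
                           gerp = numeric(0))
  }
  if (is.null(impact_source)) {
    impact_source <- data.frame(chrom = character(0), pos = integer(0),
                                impact = character(0))
  }
  gerp <- if (is.character(gerp_tsv)) read_hash_tsv(gerp_tsv) else gerp_tsv
  gerp <- gerp[c("chrom", "pos", "gerp")]
  if (anyDuplicated(gerp[c("chrom", "pos")])) {
    stop("duplicate (chrom, pos) rows in GERP table")
  }
  imp <- if (is.data.frame(impact_source)) {
    impact_source
  } else if (grepl("\\.vcf(\\.gz)?$", impact_source)) {
    v <- vcfR::read.vcfR(impact_source, verbose = FALSE)
    info <- v@fix[, "INFO"]
    ann <- sub(".*ANN=([^;]*).*", "\\1", info)
    has <- grepl("ANN=", info)
    impact <- rep(NA_character_, length(info))
    impact[has] <- vapply(strsplit(ann[has], "\\|"), function(x) {
      if (length(x) >= 3L) x[3L] else NA_character_
    }, character(1))
    data.frame(chrom = v@fix[, "CHROM"], pos = as.integer(v@fix[, "POS"]),
               impact = impact, stringsAsFactors = FALSE)
  } else {
    read_hash_tsv(impact_source)
  }
  imp <- imp[c("chrom", "pos", "impact")]
  if (anyDuplicated(imp[c("chrom", "pos")])) {
    stop("duplicate (chrom, pos) rows in impact table")
  }
  tab <- merge(gerp, imp, by = c("chrom", "pos"), all = TRUE)
  if (!is.null(callset)) {
    key <- paste(callset$sites$chrom, callset$sites$pos)
    j <- match(key, paste(tab$chrom, tab$pos))
    tab <- data.frame(chrom = callset$sites$chrom, pos = callset$sites$pos,
                      gerp = tab$gerp[j], impact = tab$impact[j],
                      annotated = !is.na(j), stringsAsFactors = FALSE)
  }
  tab[order(tab$chrom, tab$pos), , drop = FALSE]
}
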