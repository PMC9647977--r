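#' Write a cohort callset as VCF v4.2
#'
#' Emits biallelic SNP records with `GT` genotypes and the ancestral allele
#' in the `AA` INFO key. By default the REF column carries the ancestral
#' allele; `prop_ref_derived` randomly swaps REF/ALT at that proportion of
#' sites (recoding genotypes accordingly) to emulate a reference assembly
#' that carries the derived allele, which downstream polarization must undo.
#'
#' @param callset a polarized [cohort_callset()].
#' @param path output path (plain text).
#' @param chrom_lengths named vector of contig lengths for the header;
#'   defaults to the maximum observed position per chromosome.
#' @param prop_ref_derived proportion of sites written with REF = derived
#'   (draws from the current RNG stream).
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(callset, path, chrom_lengths = NULL,
                             prop_ref_derived = 0) {
  stopifnot(inherits(callset, "cohort_callset"))
  s <- callset$sites
  n <- nrow(s)
  chroms <- unique(s$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(cc) max(s$pos[s$chrom == cc], 1L), numeric(1))
  }
  swap <- rep(FALSE, n)
  if (prop_ref_derived > 0 && n > 0) swap <- stats::runif(n) < prop_ref_derived
  ref <- ifelse(swap, s$der, s$anc)
  alt <- ifelse(swap, s$anc, s$der)
  G <- callset$G
  G[swap, ] <- 2L - G[swap, , drop = FALSE]
  gt <- matrix("./.", n, ncol(G))
  gt[!is.na(G) & G == 0L] <- "0/0"
  gt[!is.na(G) & G == 1L] <- "0/1"
  gt[!is.na(G) & G == 2L] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rohload_simulate_cohort",
    sprintf("##contig=<ID=%s,length=%d>", chroms,
            as.integer(chrom_lengths[chroms])),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", callset$samples), collapse = "\t"))
  body <- if (n > 0) {
    paste(s$chrom, s$pos, ".", ref, alt, ".", "PASS",
          sprintf("AA=%s", s$anc), "GT",
          apply(gt, 1L, paste, collapse = "\t"),
          sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

# shared: write a data.frame as TSV with a "#"-prefixed header line
write_hash_tsv <- function(df, path) {
  writeLines(paste0("#", paste(names(df), collapse = "\t")), path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, append = TRUE)
  invisible(path)
}

# shared: read a TSV whose header line starts with "#"
read_hash_tsv <- function(path, col_names = NULL) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    nm <- strsplit(sub("^#+", "", first), "\t")[[1L]]
    df <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = nm, comment.char = "")
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, comment.char = "#")
  }
  if (!is.null(col_names)) names(df) <- col_names
  df
}

#' Write all artifacts of a simulated cohort
#'
#' Writes the VCF, site-annotation TSV (`chrom`, `pos`, `gerp`, `impact`),
#' sample-to-population TSV, and ground-truth TSVs into `dir`.
#'
#' @param sim a `sim_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param prop_ref_derived passed to [write_cohort_vcf()].
#' @return Named vector of written paths, invisibly.
#' @export
write_sim_cohort <- function(sim, dir, prop_ref_derived = 0) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(dir, "cohort.vcf"),
    annotation = file.path(dir, "annotation.tsv"),
    samples = file.path(dir, "samples.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_individuals = file.path(dir, "truth_individuals.tsv"))
  write_cohort_vcf(sim$callset, paths[["vcf"]],
                   chrom_lengths = stats::setNames(
                     rep(sim$config$chrom_length_bp, sim$config$n_chromosomes),
                     sprintf("chr%d", seq_len(sim$config$n_chromosomes))),
                   prop_ref_derived = prop_ref_derived)
  write_hash_tsv(sim$annotation, paths[["annotation"]])
  write_hash_tsv(data.frame(sample = sim$callset$samples,
                            population = unname(sim$callset$populations)),
                 paths[["samples"]])
  write_hash_tsv(sim$truth$sites, paths[["truth_sites"]])
  write_hash_tsv(sim$truth$individuals, paths[["truth_individuals"]])
  invisible(paths)
}
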