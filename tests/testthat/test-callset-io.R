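# A crafted VCF exercising parsing, skipping and every filter.
write_test_vcf <- function(path,
                           records,
                           samples = c("s1", "s2"),
                           format = "GT:DP:AD") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##contig=<ID=chrZ,length=100000>",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

rec <- function(chrom, pos, ref, alt, qual, info, ...) {
  paste(chrom, pos, ".", ref, alt, qual, "PASS", info, "GT:DP:AD", ...,
        sep = "\t")
}

pop_map <- data.frame(sample = c("s1", "s2"),
                      population = c("p1", "p2"),
                      stringsAsFactors = FALSE)

test_that("VCF parsing keeps biallelic SNPs and skips the rest", {
  f <- tempfile(fileext = ".vcf")
  write_test_vcf(f, c(
    rec("chr1", 100, "A", "G", 50, "AA=A", "0/1:20:10,10", "1/1:22:0,22"),
    rec("chr1", 200, "A", "G,T", 50, ".", "1/2:20:5,10", "0/0:20:20,0"),
    rec("chr1", 300, "AT", "A", 50, ".", "0/1:20:10,10", "0/0:20:20,0"),
    rec("chr1", 400, "C", "T", 50, "AA=C", "./.:.:.", "0/1:18:9,9")))
  cs <- read_cohort_vcf(f, pop_map)
  expect_equal(nrow(cs$sites), 2L)
  expect_equal(cs$sites$pos, c(100L, 400L))
  expect_equal(unname(cs$G[1, ]), c(1L, 2L))
  expect_true(is.na(cs$G[2, "s1"]))
  expect_equal(cs$G[2, "s2"], c(s2 = 1L))
  expect_equal(attr(cs, "skip_log"),
               c(multiallelic = 1L, non_snp = 1L))
  expect_equal(nrow(cs$meta$indels), 1L)
  expect_error(read_cohort_vcf(f, pop_map[1, ]), "s2")
})

test_that("polarization flips, keeps or drops sites as the outgroup dictates", {
  G <- rbind(c(0L, 2L), c(1L, 1L), c(2L, 0L))
  cs <- toy_callset(G)
  cs$polarized <- FALSE
  cs$sites$anc <- cs$sites$der <- NA_character_
  # outgroup = REF at site 1 (identity), ALT at site 2 (flip),
  # neither at site 3 (drop)
  out <- polarize_to_ancestral(cs, c("A", "G", "C"))
  expect_equal(nrow(out$sites), 2L)
  expect_equal(unname(out$G[1, ]), c(0L, 2L))
  expect_equal(unname(out$G[2, ]), c(1L, 1L))   # flip of (1,1) is (1,1)
  expect_equal(out$sites$anc, c("A", "G"))
  expect_equal(out$sites$der, c("G", "A"))
  expect_equal(attr(out, "n_dropped_polarize"), 1L)
  expect_true(out$polarized)

  # hom-REF with outgroup = ALT becomes derived dosage 2
  cs2 <- toy_callset(rbind(c(0L, 0L)))
  cs2$polarized <- FALSE
  out2 <- polarize_to_ancestral(cs2, "G")
  expect_equal(unname(out2$G[1, ]), c(2L, 2L))
})

test_that("polarizing twice with flipped assignments is an involution", {
  set.seed(9)
  G <- matrix(sample(c(0:2, NA), 40, replace = TRUE), 10, 4)
  cs <- toy_callset(G)
  cs$polarized <- FALSE
  p1 <- polarize_to_ancestral(cs, rep("G", 10))  # anc = ALT: flip all
  expect_equal(unname(p1$G), unname(2L - G))
  p2 <- polarize_to_ancestral(p1, rep("A", 10))  # flip back
  expect_equal(unname(p2$G), unname(G))
})

test_that("site filters follow QUAL, indel-pad, balance and depth rules", {
  f <- tempfile(fileext = ".vcf")
  write_test_vcf(f, c(
    # QUAL 25 < 30: dropped
    rec("chr1", 100, "A", "G", 25, "AA=A", "0/1:20:10,10", "0/0:20:20,0"),
    # indel at 200; SNP at 203 within 5 bp: dropped
    rec("chr1", 200, "AT", "A", 50, ".", "0/0:20:20,0", "0/0:20:20,0"),
    rec("chr1", 203, "C", "T", 50, "AA=C", "0/1:20:10,10", "0/0:20:20,0"),
    # het with allelic balance 2/20 = 0.1: set missing for s1
    rec("chr1", 300, "A", "G", 50, "AA=A", "0/1:20:2,18", "0/1:20:10,10"),
    # s2 depth 4 < (1/3) * mean: set missing
    rec("chr1", 400, "A", "G", 50, "AA=A", "0/1:20:10,10", "0/1:4:2,2"),
    # clean site on an excluded scaffold
    rec("chrZ", 500, "A", "G", 50, "AA=A", "0/1:20:10,10", "0/0:20:20,0"),
    # clean site, kept intact
    rec("chr1", 600, "A", "G", 90, "AA=A", "0/1:20:12,8", "1/1:20:0,20")))
  cs <- read_cohort_vcf(f, pop_map)
  spec <- filter_spec(excluded_scaffolds = "chrZ")
  out <- apply_site_filters(cs, spec)
  log <- attr(out, "filter_log")
  expect_equal(out$sites$pos, c(300L, 400L, 600L))
  expect_equal(log[["qual"]], 1)
  expect_equal(log[["indel_pad"]], 1)
  expect_equal(log[["excluded_scaffold"]], 1)
  expect_equal(log[["ab_cells"]], 1)
  expect_true(is.na(out$G[out$sites$pos == 300, "s1"]))
  expect_false(is.na(out$G[out$sites$pos == 300, "s2"]))
  expect_gte(log[["depth_cells"]], 1)
  expect_true(is.na(out$G[out$sites$pos == 400, "s2"]))
  # idempotence: a second application changes nothing
  again <- apply_site_filters(out, spec)
  expect_identical(again$G, out$G)
  expect_identical(again$sites, out$sites)
  expect_true(all(attr(again, "filter_log")[c("qual", "indel_pad",
                                              "excluded_scaffold",
                                              "ab_cells", "depth_cells")] == 0))
})

test_that("BED masks are interpreted 0-based half-open", {
  G <- rbind(c(0L, 1L), c(1L, 1L), c(2L, 0L))
  cs <- toy_callset(G, pos = c(100L, 150L, 200L))
  cs$meta$qual <- rep(99, 3)
  cs$meta$indels <- data.frame(chrom = character(0), pos = integer(0))
  # mask [99, 150): covers 1-based positions 100..150
  bed <- data.frame(chrom = "chr1", start = 99L, end = 150L)
  out <- apply_site_filters(cs, filter_spec(min_depth_frac = NULL,
                                            max_depth_mult = NULL,
                                            ab_low = NULL, ab_high = NULL,
                                            mask_beds = list(bed)))
  expect_equal(out$sites$pos, 200L)
  expect_equal(attr(out, "filter_log")[["masked"]], 2)
})

test_that("an enabled filter with a missing field names the field", {
  cs <- toy_callset(rbind(c(0L, 1L)))
  expect_error(apply_site_filters(cs, filter_spec()), "qual")
})

test_that("complete-case restriction removes exactly the sites with missingness", {
  G <- rbind(c(0L, 1L), c(1L, NA), c(2L, 0L))
  cs <- toy_callset(G)
  out <- restrict_complete_cases(cs)
  expect_equal(out$sites$pos, c(100L, 300L))
  expect_equal(attr(out, "n_dropped_incomplete"), 1L)
  expect_equal(sum(is.na(out$G)), 0L)
  # identity when nothing is missing
  cs2 <- toy_callset(rbind(c(0L, 1L), c(2L, 2L)))
  expect_identical(restrict_complete_cases(cs2)$G, cs2$G)
  # degenerate: everything missing
  cs3 <- toy_callset(rbind(c(NA, 1L)))
  expect_warning(out3 <- restrict_complete_cases(cs3), "no complete-case")
  expect_equal(nrow(out3$sites), 0L)
})

test_that("annotations join on coordinates and flag unannotated sites", {
  gerp <- data.frame(chrom = "chr1", pos = c(100L, 200L), gerp = c(6.1, 0.5))
  imp <- data.frame(chrom = "chr1", pos = c(100L, 200L),
                    impact = c("HIGH", "LOW"))
  tab <- load_annotations(gerp, imp)
  expect_equal(tab$gerp, c(6.1, 0.5))
  expect_equal(tab$impact, c("HIGH", "LOW"))

  cs <- toy_callset(rbind(c(0L, 1L), c(1L, 1L), c(2L, 0L)),
                    pos = c(100L, 200L, 300L))
  tab2 <- load_annotations(gerp, imp, callset = cs)
  expect_equal(nrow(tab2), 3L)
  expect_equal(tab2$annotated, c(TRUE, TRUE, FALSE))

  expect_error(load_annotations(rbind(gerp, gerp[1, ]), imp), "duplicate")
})

test_that("impact categories parse from SnpEff-style ANN fields", {
  f <- tempfile(fileext = ".vcf")
  write_test_vcf(f, c(
    rec("chr1", 100, "A", "G", 50, "ANN=G|missense_variant|MODERATE|gene1",
        "0/1:20:10,10", "0/0:20:20,0"),
    rec("chr1", 200, "C", "T", 50, "ANN=T|stop_gained|HIGH|gene2",
        "0/1:20:10,10", "0/0:20:20,0")))
  gerp <- data.frame(chrom = "chr1", pos = c(100L, 200L), gerp = c(3, 6))
  tab <- load_annotations(gerp, f)
  expect_equal(tab$impact, c("MODERATE", "HIGH"))
})
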