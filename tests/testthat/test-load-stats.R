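test_that("GERP categories respect bin edges and the top-1% override", {
  b <- gerp_bins()
  expect_equal(gerp_category(6.5, b), ">5.88")
  expect_equal(gerp_category(0.5, b), "0-1")
  expect_equal(gerp_category(3.0, b), "3-5")     # [lo, hi) convention
  expect_equal(gerp_category(1.0, b), "1-3")
  expect_equal(gerp_category(5.2, b), ">5")
  expect_equal(gerp_category(5.88, b), ">5")     # strictly above for top bin
  expect_equal(gerp_category(-0.4, b), "negative")
  expect_error(gerp_bins(edges = c(1, 0)), "increasing")
  expect_error(gerp_bins(edges = c(0, 1), top_threshold = 0.5), "top threshold")
})

test_that("relative load reproduces hand-evaluated ratios", {
  # het at score 6.0 plus hom at 7.0: (6 + 14) / 3
  cs <- toy_callset(cbind(s1 = c(1L, 2L)))
  an <- toy_annot(cs, gerp = c(6.0, 7.0))
  expect_equal(relative_load_gerp(cs, "s1", an, ">5.88"), 20 / 3)
  # all-hom collapses to the mean score
  cs2 <- toy_callset(cbind(s1 = c(2L, 2L)))
  an2 <- toy_annot(cs2, gerp = c(6, 8))
  expect_equal(relative_load_gerp(cs2, "s1", an2, ">5.88"), 7.0)
  # no derived alleles in the category: undefined, not zero
  cs3 <- toy_callset(cbind(s1 = c(0L, 0L)))
  expect_true(is.na(relative_load_gerp(cs3, "s1", an2, ">5.88")))
})

test_that("relative load is order-invariant and recombines across chromosomes", {
  set.seed(31)
  n <- 40
  G <- cbind(s1 = sample(0:2, n, replace = TRUE))
  gerp <- runif(n, 5.9, 11)
  chrom <- rep(c("chr1", "chr2"), each = n / 2)
  cs <- toy_callset(G, chrom = chrom, pos = rep(seq_len(n / 2) * 50L, 2))
  an <- toy_annot(cs, gerp = gerp)
  full <- relative_load_gerp(cs, "s1", an, ">5.88")
  # split by chromosome and recombine as a dosage-weighted mean
  parts <- lapply(c("chr1", "chr2"), function(cc) {
    keep <- cs$sites$chrom == cc
    cs_c <- toy_callset(G[keep, , drop = FALSE], pos = cs$sites$pos[keep])
    an_c <- toy_annot(cs_c, gerp = gerp[keep])
    w <- sum(G[keep, 1][G[keep, 1] > 0])
    c(relative_load_gerp(cs_c, "s1", an_c, ">5.88"), w)
  })
  m <- do.call(rbind, parts)
  expect_equal(full, sum(m[, 1] * m[, 2]) / sum(m[, 2]), tolerance = 1e-12)
})

test_that("total load counts sites or alleles as requested", {
  # 3 het + 2 hom HIGH sites
  cs <- toy_callset(cbind(s1 = c(1L, 1L, 1L, 2L, 2L, 0L)))
  an <- toy_annot(cs, impact = c(rep("HIGH", 5), "HIGH"))
  expect_equal(total_load(cs, "s1", an, "HIGH", mode = "sites"), 5L)
  expect_equal(total_load(cs, "s1", an, "HIGH", mode = "alleles"), 7L)
  cs0 <- toy_callset(cbind(s1 = c(0L, 0L)))
  an0 <- toy_annot(cs0, impact = c("HIGH", "HIGH"))
  expect_equal(total_load(cs0, "s1", an0, "HIGH"), 0L)
  expect_error(total_load(cs, "s1", an, "FATAL"), "arg")
})

test_that("realised load follows the segregating-site denominator", {
  # 10 segregating HIGH sites in a 2-sample cohort; s1 homozygous at 5
  G <- cbind(s1 = c(rep(2L, 5), rep(0L, 5)),
             s2 = c(rep(0L, 5), rep(1L, 5)))
  cs <- toy_callset(G)
  an <- toy_annot(cs, impact = rep("HIGH", 10))
  expect_equal(realised_load(cs, "s1", an, "HIGH"), 5 / 20)
  expect_equal(realised_load(cs, "s2", an, "HIGH"), 0)
  # all sites homozygous in the sample: the attainable maximum 0.5
  G2 <- cbind(s1 = rep(2L, 10), s2 = c(rep(0L, 9), 1L))
  cs2 <- toy_callset(G2)
  expect_equal(realised_load(cs2, "s1", toy_annot(cs2, impact = rep("HIGH", 10)),
                             "HIGH"), 0.5)
  # no segregating sites of the category: undefined
  an_none <- toy_annot(cs, impact = rep("LOW", 10))
  expect_true(is.na(realised_load(cs, "s1", an_none, "HIGH")))
})

test_that("realised load never exceeds 0.5 on randomized callsets", {
  for (sd in 1:25) {
    set.seed(sd)
    ns <- sample(10:60, 1); nm <- sample(3:8, 1)
    G <- matrix(sample(0:2, ns * nm, replace = TRUE), ns, nm)
    cs <- toy_callset(G)
    an <- toy_annot(cs, impact = sample(c("HIGH", "MODERATE", "LOW"),
                                        ns, replace = TRUE))
    for (sm in cs$samples) {
      for (cat in c("HIGH", "MODERATE", "LOW")) {
        rl <- realised_load(cs, sm, an, cat)
        if (!is.na(rl)) {
          expect_gte(rl, 0)
          expect_lte(rl, 0.5)
        }
      }
    }
  }
})

test_that("zygosity counts agree with an independent tally", {
  cs <- toy_callset(cbind(s1 = c(0L, 1L, 1L, 2L)))
  an <- toy_annot(cs, impact = rep("MODERATE", 4))
  expect_equal(zygosity_counts(cs, "s1", an, "MODERATE"),
               c(n_het = 2L, n_hom = 1L))
  expect_equal(zygosity_counts(cs, "s1", an, "HIGH"),
               c(n_het = 0L, n_hom = 0L))
  # n_derived_alleles = n_het + 2 * n_hom against a recount
  set.seed(41)
  G <- matrix(sample(0:2, 200, replace = TRUE), 50, 4)
  cs2 <- toy_callset(G)
  an2 <- toy_annot(cs2, impact = rep("HIGH", 50))
  for (sm in cs2$samples) {
    zc <- zygosity_counts(cs2, sm, an2, "HIGH")
    expect_equal(unname(zc["n_het"] + 2L * zc["n_hom"]),
                 sum(cs2$G[, sm]))
  }
})

test_that("GERP-bin allele counts add up to the unbinned total", {
  set.seed(51)
  ns <- 80
  G <- cbind(a = sample(0:2, ns, TRUE), b = sample(0:2, ns, TRUE),
             c = sample(0:2, ns, TRUE), d = sample(0:2, ns, TRUE))
  cs <- toy_callset(G)
  an <- toy_annot(cs, gerp = runif(ns, -1, 9),
                  impact = sample(c("LOW", "MODERATE", "HIGH"), ns, TRUE))
  ls <- load_summary(cs, an)
  gl <- ls[ls$kind == "gerp" & ls$category != "negative", ]
  for (sm in cs$samples) {
    expect_equal(sum(gl$n_derived_alleles[gl$sample == sm]),
                 sum(cs$G[an$gerp >= 0, sm]))
  }
  # invariant within the table: alleles = het + 2 hom
  expect_true(all(ls$n_derived_alleles == ls$n_het + 2L * ls$n_hom))
  expect_true(all(ls$realised_load[!is.na(ls$realised_load)] <= 0.5))
})
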