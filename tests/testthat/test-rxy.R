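test_that("identical frequencies give R_xy = 1 and hand values check out", {
  ft <- manual_freq_table(rep("chr1", 3),
                          d = cbind(x = c(2L, 4L, 1L), y = c(1L, 2L, 1L)),
                          n = cbind(x = c(10L, 10L, 10L), y = c(5L, 5L, 10L)))
  # f_x = f_y at every site
  r <- rxy_point(ft, "x", "y")
  expect_equal(r$rxy, 1.0, tolerance = 1e-12)

  # printed-formula hand evaluation
  ft2 <- manual_freq_table(rep("chr1", 2),
                           d = cbind(x = c(1L, 2L), y = c(3L, 4L)),
                           n = cbind(x = c(10L, 10L), y = c(10L, 10L)))
  r2 <- rxy_point(ft2, "x", "y")
  expect_equal(r2$freq_x, 0.1 * 0.7 + 0.2 * 0.6)
  expect_equal(r2$freq_y, 0.3 * 0.9 + 0.4 * 0.8)
  expect_equal(r2$rxy, 0.19 / 0.59)

  # degenerate contracts
  ft3 <- manual_freq_table("chr1", d = cbind(x = 1L, y = 0L),
                           n = cbind(x = 2L, y = 2L))
  expect_equal(rxy_point(ft3, "x", "y")$rxy, Inf)
  ft4 <- manual_freq_table("chr1", d = cbind(x = 0L, y = 0L),
                           n = cbind(x = 2L, y = 2L))
  expect_true(is.na(rxy_point(ft4, "x", "y")$rxy))
})

test_that("sites with no derived alleles in the pool do not move R_xy", {
  set.seed(61)
  d <- cbind(x = rpois(30, 2), y = rpois(30, 2))
  n <- cbind(x = rep(20L, 30), y = rep(20L, 30))
  ft <- manual_freq_table(rep("chr1", 30), d, n)
  base <- rxy_point(ft, "x", "y")$rxy
  # append 10 sites with zero derived alleles in both populations
  ft2 <- manual_freq_table(rep("chr1", 40), rbind(d, matrix(0L, 10, 2,
                           dimnames = list(NULL, c("x", "y")))),
                           rbind(n, matrix(20L, 10, 2,
                           dimnames = list(NULL, c("x", "y")))))
  expect_equal(rxy_point(ft2, "x", "y")$rxy, base, tolerance = 1e-15)
})

test_that("reciprocity: rxy(x,y) * rxy(y,x) = 1 on random tables", {
  set.seed(71)
  for (k in 1:100) {
    ns <- sample(5:40, 1)
    ft <- manual_freq_table(
      sample(c("chr1", "chr2"), ns, replace = TRUE),
      d = cbind(x = sample(0:10, ns, TRUE), y = sample(0:10, ns, TRUE)),
      n = cbind(x = rep(10L, ns), y = rep(10L, ns)))
    fwd <- rxy_point(ft, "x", "y")$rxy
    rev <- rxy_point(ft, "y", "x")$rxy
    if (is.finite(fwd) && is.finite(rev)) {
      expect_equal(fwd * rev, 1, tolerance = 1e-12)
    }
  }
})

test_that("the chromosome jack-knife matches manual leave-one-out recomputation", {
  # two chromosomes with identical content: both LOO values equal the point
  ft <- manual_freq_table(rep(c("chr1", "chr2"), each = 2),
                          d = cbind(x = c(1L, 2L, 1L, 2L), y = c(3L, 4L, 3L, 4L)),
                          n = matrix(10L, 4, 2, dimnames = list(NULL, c("x", "y"))))
  rj <- rxy_jackknife(ft, "x", "y")
  expect_equal(unname(rj$loo), rep(rj$rxy, 2), tolerance = 1e-12)
  expect_equal(rj$jackknife_mean, rj$rxy, tolerance = 1e-12)

  # three-chromosome toy table vs from-scratch recomputation
  set.seed(81)
  chrom <- rep(c("chr1", "chr2", "chr3"), times = c(4, 3, 5))
  d <- cbind(x = sample(0:8, 12, TRUE), y = sample(1:8, 12, TRUE))
  n <- matrix(8L, 12, 2, dimnames = list(NULL, c("x", "y")))
  ft2 <- manual_freq_table(chrom, d, n)
  rj2 <- rxy_jackknife(ft2, "x", "y")
  fx <- d[, "x"] / 8; fy <- d[, "y"] / 8
  keep <- d[, "x"] + d[, "y"] >= 1
  for (cc in c("chr1", "chr2", "chr3")) {
    use <- keep & chrom != cc
    manual <- sum(fx[use] * (1 - fy[use])) / sum(fy[use] * (1 - fx[use]))
    expect_equal(unname(rj2$loo[cc]), manual, tolerance = 1e-12)
  }
  J <- 3
  expect_equal(unname(rj2$pseudovalues),
               unname(J * rj2$rxy - (J - 1) * rj2$loo))
  expect_equal(rj2$jackknife_se, sd(rj2$pseudovalues) / sqrt(J))

  # a category confined to one chromosome cannot be jack-knifed
  ft3 <- manual_freq_table(rep("chr1", 4),
                           d = cbind(x = 1:4, y = 1:4),
                           n = matrix(8L, 4, 2, dimnames = list(NULL, c("x", "y"))))
  expect_error(rxy_jackknife(ft3, "x", "y"), "2 chromosomes")
})

test_that("the strict both-populations site rule excludes unique variants", {
  ft <- manual_freq_table(rep("chr1", 3),
                          d = cbind(x = c(2L, 0L, 1L), y = c(1L, 3L, 0L)),
                          n = matrix(10L, 3, 2, dimnames = list(NULL, c("x", "y"))))
  expect_equal(rxy_point(ft, "x", "y", site_rule = "pooled")$n_sites, 3L)
  expect_equal(rxy_point(ft, "x", "y", site_rule = "each")$n_sites, 1L)
})

test_that("sharing summary reproduces the hand count and its identities", {
  ft <- manual_freq_table(rep("chr1", 3),
                          d = cbind(a = c(4L, 2L, 0L), b = c(5L, 0L, 1L)),
                          n = cbind(a = c(4L, 4L, 4L), b = c(5L, 5L, 5L)))
  sh <- sharing_summary(ft, "a", "b")
  expect_equal(sh[["total_a"]], 2)
  expect_equal(sh[["total_b"]], 2)
  expect_equal(sh[["shared"]], 1)
  expect_equal(sh[["unique_a"]], 1)
  expect_equal(sh[["unique_b"]], 1)
  expect_equal(sh[["fixed_both"]], 1)
  expect_equal(sh[["decreased"]], 1)   # site 2: 0.5 -> 0
  expect_equal(sh[["increased"]], 1)   # site 3: 0 -> 0.2

  # identical frequency vectors
  ft2 <- manual_freq_table(rep("chr1", 4),
                           d = cbind(a = c(2L, 0L, 4L, 1L), b = c(2L, 0L, 4L, 1L)),
                           n = matrix(4L, 4, 2, dimnames = list(NULL, c("a", "b"))))
  sh2 <- sharing_summary(ft2, "a", "b")
  expect_equal(sh2[["increased"]], 0)
  expect_equal(sh2[["decreased"]], 0)
  expect_equal(sh2[["shared"]], sh2[["total_a"]])

  # counting identities over random tables
  set.seed(91)
  for (k in 1:100) {
    ns <- sample(3:30, 1)
    ftk <- manual_freq_table(rep("chr1", ns),
                             d = cbind(a = sample(0:6, ns, TRUE),
                                       b = sample(0:6, ns, TRUE)),
                             n = matrix(6L, ns, 2,
                                        dimnames = list(NULL, c("a", "b"))))
    shk <- sharing_summary(ftk, "a", "b")
    expect_equal(shk[["shared"]] + shk[["unique_a"]], shk[["total_a"]])
    expect_equal(shk[["shared"]] + shk[["unique_b"]], shk[["total_b"]])
  }
})
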