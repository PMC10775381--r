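test_that("pair enumeration is exhaustive per scope and excludes ineligible samples", {
  # one block, 3 scored cores -> C(3,2) = 3 intra-tumoral pairs
  co <- toy_cohort(c(100, 0, 50))
  expect_equal(nrow(enumerate_pairs(co, "M", "intra_tumoral")), 3)

  # one patient, blocks of sizes {2, 1} -> cross-block pairs only: 2*1 = 2
  co2 <- toy_cohort(c(100, 0, 50), site = c("S1", "S1", "S2"))
  inter <- enumerate_pairs(co2, "M", "inter_tumoral")
  expect_equal(nrow(inter), 2)
  expect_equal(nrow(enumerate_pairs(co2, "M", "intra_tumoral")), 1)

  # samples missing the marker are excluded from the pool
  co3 <- toy_cohort(c(100, 0, NA))
  expect_equal(nrow(enumerate_pairs(co3, "M", "intra_tumoral")), 1)

  # singleton blocks leave the intra-tumoral pool empty
  co4 <- toy_cohort(c(100, 0), site = c("S1", "S2"))
  expect_error(enumerate_pairs(co4, "M", "intra_tumoral"),
               class = "tmahet_empty_pool_error")
})

test_that("exact discordance matches brute-force enumeration on a k-of-n block", {
  # block of 4 with 2 positives: enumerate the 6 pairs by hand
  h <- c(100, 150, 0, 5)
  pairs <- combn(4, 2)
  brute <- mean(apply(pairs, 2, function(ij) (h[ij[1]] >= 20) != (h[ij[2]] >= 20)))
  expect_equal(brute, 2 / 3)
  pool <- enumerate_pairs(toy_cohort(h), "M", "intra_tumoral")
  expect_equal(heterogeneity_exact(pool), 2 / 3)
  # hypergeometric identity: concordant fraction (C(k,2)+C(n-k,2))/C(n,2)
  expect_equal(1 - (choose(2, 2) + choose(2, 2)) / choose(4, 2), 2 / 3)

  # all-concordant blocks have zero discordance
  expect_equal(heterogeneity_exact(
    enumerate_pairs(toy_cohort(c(100, 150, 30)), "M", "intra_tumoral")), 0)
  expect_equal(heterogeneity_exact(
    enumerate_pairs(toy_cohort(c(0, 0, 10)), "M", "intra_tumoral")), 0)
})

test_that("pair and group weighting differ exactly as the pair counts dictate", {
  # two blocks: discordance 0 (2 concordant cores) and 2/3 (4 cores, k=2)
  co <- toy_cohort(c(100, 150, 100, 150, 0, 5),
                   site = c("S1", "S1", "S2", "S2", "S2", "S2"))
  pool <- enumerate_pairs(co, "M", "intra_tumoral")
  expect_equal(heterogeneity_exact(pool, weighting = "group"), 1 / 3)
  # pair weighting pools 1 + 6 pairs, 4 discordant
  expect_equal(heterogeneity_exact(pool, weighting = "pair"), 4 / 7)
})

test_that("discordance is invariant under flipping every sample's label", {
  set.seed(23)
  for (i in 1:20) {
    h <- sample(c(0, 5, 50, 200), 8, replace = TRUE)
    co <- toy_cohort(h, site = rep(c("S1", "S2"), each = 4))
    # swap every sample's binarized label
    co_flip <- toy_cohort(ifelse(h >= 20, 0, 100),
                          site = rep(c("S1", "S2"), each = 4))
    for (sc in c("intra_tumoral", "inter_tumoral")) {
      expect_equal(
        heterogeneity_exact(enumerate_pairs(co, "M", sc)),
        heterogeneity_exact(enumerate_pairs(co_flip, "M", sc)))
    }
  }
})

test_that("larger between-block positivity spread yields larger inter-tumoral index", {
  uniform <- toy_cohort(rep(c(100, 110), 4),
                        site = rep(sprintf("S%d", 1:4), each = 2))
  spread <- toy_cohort(c(100, 110, 0, 5, 100, 120, 0, 0),
                       site = rep(sprintf("S%d", 1:4), each = 2))
  expect_gt(
    heterogeneity_exact(enumerate_pairs(spread, "M", "inter_tumoral")),
    heterogeneity_exact(enumerate_pairs(uniform, "M", "inter_tumoral")))
})

test_that("bootstrap is seed-reproducible and converges on the exact index", {
  set.seed(19)
  h <- c(rep(100, 6), rep(0, 6))
  co <- toy_cohort(h[sample(12)], site = rep(sprintf("S%d", 1:3), each = 4))
  pool <- enumerate_pairs(co, "M", "intra_tumoral")
  ex <- heterogeneity_exact(pool)

  e1 <- heterogeneity_bootstrap(pool, n_pairs = 1000, n_boot = 2000, seed = 5)
  e2 <- heterogeneity_bootstrap(pool, n_pairs = 1000, n_boot = 2000, seed = 5)
  expect_identical(summary(e1), summary(e2))

  mc_se <- e1$replicate_sd / sqrt(e1$n_boot)
  expect_lt(abs(e1$point_estimate - ex), 3 * mc_se)
  expect_true(e1$ci_low <= e1$point_estimate && e1$point_estimate <= e1$ci_high)
  expect_true(e1$ci_low >= 0 && e1$ci_high <= 1)
})

test_that("an all-concordant pool gives estimate 0 with a flagged degenerate CI", {
  pool <- enumerate_pairs(toy_cohort(rep(100, 5)), "M", "intra_tumoral")
  est <- heterogeneity_bootstrap(pool, seed = 3)
  expect_equal(est$point_estimate, 0)
  expect_equal(c(est$ci_low, est$ci_high), c(0, 0))
  expect_true(est$degenerate)
})

test_that("group resampling respects clustering and stays in bounds", {
  co <- toy_cohort(c(100, 0, 100, 100, 0, 0),
                   patient = rep(c("A", "B", "C"), each = 2),
                   site = rep(c("S1", "S2", "S3"), each = 2))
  pool <- enumerate_pairs(co, "M", "intra_tumoral")
  est <- heterogeneity_bootstrap(pool, n_pairs = 200, n_boot = 500, seed = 9,
                                 resample_unit = "group")
  expect_true(est$ci_low >= 0 && est$ci_high <= 1)
  expect_true(est$ci_low <= est$point_estimate + 1e-12)
})

test_that("configuration errors on bootstrap sizes are raised", {
  pool <- enumerate_pairs(toy_cohort(c(100, 0)), "M", "intra_tumoral")
  expect_error(heterogeneity_bootstrap(pool, n_pairs = 0, seed = 1),
               class = "tmahet_config_error")
  expect_error(heterogeneity_bootstrap(pool, n_boot = 0, seed = 1),
               class = "tmahet_config_error")
})

test_that("BCa reduces to the percentile interval when z0 = 0 and a = 0", {
  set.seed(31)
  reps <- rnorm(2000)
  reps <- c(reps, -reps)  # exactly symmetric around 0
  ci <- bca_interval(reps, observed = 0, jackknife = NULL)
  srt <- sort(reps)
  expect_equal(attr(ci, "z0"), 0)
  expect_equal(attr(ci, "acceleration"), 0)
  expect_equal(ci[1], srt[ceiling(0.025 * length(reps))])
  expect_equal(ci[2], srt[ceiling(0.975 * length(reps))])
})

test_that("BCa endpoints follow from direct evaluation of the formulas", {
  reps <- c(rep(0.1, 500), rep(0.2, 500))
  jack <- c(rep(0.12, 6), rep(0.18, 4))
  ci <- bca_interval(reps, observed = 0.15, jackknife = jack)

  z0 <- qnorm(mean(reps < 0.15))  # = 0
  d <- mean(jack) - jack
  a <- sum(d^3) / (6 * sum(d^2)^1.5)
  adj <- function(alpha) pnorm(z0 + (z0 + qnorm(alpha)) / (1 - a * (z0 + qnorm(alpha))))
  srt <- sort(reps)
  expect_equal(z0, 0)
  expect_equal(ci[1], srt[ceiling(adj(0.025) * 1000)])
  expect_equal(ci[2], srt[ceiling(adj(0.975) * 1000)])
})

test_that("BCa agrees with the boot package on a smooth statistic", {
  skip_if_not_installed("boot")
  set.seed(77)
  x <- rnorm(40, mean = 1)
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 4000)
  ref <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  jack <- vapply(seq_along(x), function(i) mean(x[-i]), numeric(1))
  ci <- bca_interval(as.numeric(bt$t), observed = mean(x), jackknife = jack)
  # conventions differ (interpolated vs raw order statistics): loose check
  expect_equal(as.numeric(ci), ref, tolerance = 0.02)
})

test_that("identical replicates collapse to a flagged point interval", {
  ci <- bca_interval(rep(0.3, 100), observed = 0.3)
  expect_equal(as.numeric(ci), c(0.3, 0.3))
  expect_true(attr(ci, "degenerate"))
  # observed outside replicate range: percentile fallback, flagged
  ci2 <- bca_interval(c(rep(0.2, 50), rep(0.4, 50)), observed = 0.1)
  expect_true(attr(ci2, "degenerate"))
  expect_equal(as.numeric(ci2), c(0.2, 0.4))
})
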