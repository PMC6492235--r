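test_that("soft calibration densities integrate to one with the stated
           tail masses", {
  dens <- function(cal, supportMax = Inf) {
    f <- photoclock:::.calDensity(cal, supportMax)
    function(t) exp(vapply(t, f, numeric(1)))
  }
  # two-sided soft bound, 2.5% per tail
  cal <- calibration("x", minAge = 0.124, maxAge = 0.248, style = "soft")
  d <- dens(cal)
  expect_equal(integrate(d, 0, 50, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-6)
  expect_equal(integrate(d, 0, 0.124, rel.tol = 1e-10)$value, 0.025,
               tolerance = 1e-6)
  expect_equal(integrate(d, 0.248, 50, rel.tol = 1e-10)$value, 0.025,
               tolerance = 1e-6)
  # continuity at the bounds
  expect_equal(d(0.124 - 1e-9), d(0.124 + 1e-9), tolerance = 1e-6)
  expect_equal(d(0.248 - 1e-9), d(0.248 + 1e-9), tolerance = 1e-6)

  # minimum-only soft bound, 5% below
  cal1 <- calibration("x", minAge = 1.6, style = "soft")
  expect_equal(cal1@tailLow, 0.05)
  d1 <- dens(cal1, supportMax = 3.75)
  expect_equal(integrate(d1, 0, 3.75, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-6)
  expect_equal(integrate(d1, 0, 1.6, rel.tol = 1e-10)$value, 0.05,
               tolerance = 1e-6)
})

test_that("hard calibrations are uniform inside and impossible outside", {
  cal <- calibration("x", minAge = 1.6, maxAge = 2.0, style = "hard",
                     tailLow = 0, tailHigh = 0)
  expect_identical(calibrationLogDensity(cal, 1.5), -Inf)
  expect_equal(calibrationLogDensity(cal, 1.8), log(1 / 0.4))
  expect_equal(calibrationLogDensity(cal, 1.7),
               calibrationLogDensity(cal, 1.9))
})

test_that("the root prior is a truncated normal with the expected ratios", {
  rp <- rootPrior(3.5, 0.05)
  expect_equal(rootLogDensity(rp, 3.5) - rootLogDensity(rp, 3.6), 2,
               tolerance = 1e-10)  # log ratio (0.1)^2/(2*0.05^2)
  expect_identical(rootLogDensity(rp, -1), -Inf)
  expect_identical(rootLogDensity(rp, 1, truncMin = 2), -Inf)
  # beyond one sd, a wider prior dominates
  expect_gt(rootLogDensity(rootPrior(3.5, 0.4), 4.3),
            rootLogDensity(rootPrior(3.5, 0.05), 4.3))
})

test_that("node-time prior: ordering violations are impossible, and
           uncalibrated configurations are equal given the root", {
  tr <- fourTipTree(rates = NULL)
  cs <- calibrationSet(list(), rootPrior(2, 0.1))
  badAges <- nodeAges(tr); badAges[6] <- 2.5  # child older than root
  bad <- tr; bad@ages <- badAges
  expect_identical(nodeTimeLogPrior(bad, cs), -Inf)

  # same root, different internal ages -> same density (uniform given root)
  lp1 <- nodeTimeLogPrior(tr, cs)
  a2 <- nodeAges(tr); a2[6] <- 0.4; a2[7] <- 1.9
  tr2 <- tr; tr2@ages <- a2
  expect_equal(nodeTimeLogPrior(tr2, cs), lp1, tolerance = 1e-12)

  # finite-difference probe: density moves only when a calibrated node
  # crosses into its bound region
  cal <- calibration(c("A", "B"), minAge = 0.8, maxAge = 1.2)
  csc <- calibrationSet(list(cal), rootPrior(2, 0.1))
  inCore <- function(x) {
    t <- tr; aa <- nodeAges(tr); aa[6] <- x; t@ages <- aa
    nodeTimeLogPrior(t, csc)
  }
  expect_equal(inCore(0.9), inCore(1.1), tolerance = 1e-12)  # flat core
  expect_gt(inCore(0.9), inCore(0.5))                        # lower tail
  expect_gt(inCore(0.9), inCore(1.5))                        # upper tail
})

test_that("rate priors: autocorrelated edge terms equal the log-normal pdf
           and limits collapse to a single rate", {
  tr <- fourTipTree()
  cm <- clockModel("acln", sigma2 = 0.2, rootRate = 0.5)
  lp <- rateLogPrior(tr, cm)
  # independent evaluation edge by edge
  phy <- asPhylo(tr); ages <- nodeAges(tr); r <- nodeRates(tr)
  manual <- dlnorm(r[5], log(0.5), 1, log = TRUE)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    dt <- ages[p] - ages[ch]
    manual <- manual + dlnorm(r[ch], log(r[p]) - 0.2 * dt / 2,
                              sqrt(0.2 * dt), log = TRUE)
  }
  expect_equal(lp, manual, tolerance = 1e-12)

  # strict-clock limit: unequal rates become impossibly unlikely
  tight <- clockModel("acln", sigma2 = 1e-8, rootRate = 0.5)
  eq <- tr; nodeRates(eq) <- rep(0.5, 7)
  expect_gt(rateLogPrior(eq, tight) - rateLogPrior(tr, tight), 1e4)

  # uncorrelated gamma with shape 1 is an exponential branch-rate prior
  ug <- clockModel("ugam", shape = 1, rootRate = 1)
  one <- tr; nodeRates(one) <- rep(1, 7)
  expect_equal(rateLogPrior(one, ug), 6 * dgamma(1, 1, 1, log = TRUE),
               tolerance = 1e-12)
  expect_equal(dgamma(1, 1, 1, log = TRUE), -1)
  # shape -> infinity collapses to the global rate
  ugTight <- clockModel("ugam", shape = 1e8, rootRate = 1)
  off <- tr; nodeRates(off) <- c(rep(1, 6), 1.05)
  expect_gt(rateLogPrior(one, ugTight) - rateLogPrior(off, ugTight), 1e3)

  neg <- tr
  neg@rates <- c(rep(0.5, 6), -0.1)
  expect_identical(rateLogPrior(neg, cm), -Inf)
})

test_that("autocorrelated prior is consistent under edge subdivision", {
  # integrating out a midpoint rate reproduces the one-edge density:
  # Monte-Carlo check of the child-rate moments
  set.seed(17)
  rp <- 0.4; s2 <- 0.2; dt <- 1
  n <- 2e5
  direct <- exp(rnorm(n, log(rp) - s2 * dt / 2, sqrt(s2 * dt)))
  mid <- exp(rnorm(n, log(rp) - s2 * dt / 4, sqrt(s2 * dt / 2)))
  twostep <- exp(rnorm(n, log(mid) - s2 * dt / 4, sqrt(s2 * dt / 2)))
  expect_equal(mean(twostep), mean(direct), tolerance = 0.02)
  expect_equal(sd(log(twostep)), sd(log(direct)), tolerance = 0.02)
  # and the mean correction keeps E[r_child] = r_parent
  expect_equal(mean(direct), rp, tolerance = 0.02)
})

test_that("calibration files round-trip through the key-value format", {
  f <- tempfile()
  writeLines(c("root_mean: 3.5", "root_sd: 0.05", "",
               "name: demo", "tips: A, B", "min: 0.8", "max: 1.2",
               "style: soft", "",
               "name: floor", "tips: C, D", "min: 1.4"), f)
  cs <- readCalibrations(f)
  expect_equal(cs@root@mean, 3.5)
  expect_length(cs@calibrations, 2)
  expect_equal(cs@calibrations[[1]]@clade, c("A", "B"))
  expect_equal(cs@calibrations[[2]]@tailLow, 0.05)  # min-only default
  expect_true(is.na(cs@calibrations[[2]]@maxAge))
})

test_that("calibration validity constraints hold", {
  expect_error(calibration("x"), "at least one bound")
  expect_error(calibration("x", minAge = 2, maxAge = 1), "minAge")
  expect_error(calibration("x", minAge = 1, maxAge = 2, tailLow = 0.7),
               "tail masses")
})
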