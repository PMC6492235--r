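# minimal posterior trace with prescribed node summaries, for exercising
# the derived statistics without a full MCMC run
syntheticTrace <- function(tree, ages, rates, n = 40, jitter = 0.01,
                           seed = 1) {
  set.seed(seed)
  nn <- length(nodeAges(tree))
  ntip <- length(tipNames(tree))
  cols <- list()
  for (j in (ntip + 1):nn)
    cols[[paste0("age_", j)]] <- ages[j] + rnorm(n, 0, jitter)
  for (j in 1:nn)
    cols[[paste0("rate_", j)]] <- pmax(1e-6, rates[j] + rnorm(n, 0, jitter))
  cols$sigma2 <- rep(0.1, n); cols$alpha <- rep(1, n)
  cols$log_prior <- rep(0, n); cols$log_likelihood <- rep(0, n)
  new("PosteriorTrace", samples = as.data.frame(cols), tree = tree,
      chainId = 1L, seed = as.integer(seed), iterations = as.integer(n * 2),
      burnin = 0L, thinning = 2L, nodeLabels = character(0))
}

test_that("Delta-T arithmetic reproduces the reported rows and is
           antisymmetric", {
  # reported root-prior scan: D0 minus ancestral standard D1
  tab <- recomputeDeltaT(reportedAgeTable("rootPrior"))
  cat38 <- tab[tab$model == "CAT+GTR+G" & tab$x == 3.8, ]
  expect_equal(cat38$dt_calc, 1.17)
  lg32 <- tab[tab$model == "LG+G" & tab$x == 3.2, ]
  expect_equal(lg32$dt_calc, 0.68)

  for (scan in c("rootPrior", "rootSd")) {
    tab <- recomputeDeltaT(reportedAgeTable(scan))
    ok <- tab[tab$flag == "ok", ]
    expect_true(all(abs(ok$dt_calc - ok$dt) <= 0.0100001))
    expect_true(all(abs(ok$dt_high_calc - ok$dt_high) <= 0.0600001))
    expect_true(all(abs(ok$dt_low_calc - ok$dt_low) <= 0.0300001))
    # flagged rows: printed Delta-T and range must at least agree with
    # each other through the range midpoint (documented source mistypes)
    fl <- tab[tab$flag != "ok", ]
    if (nrow(fl)) {
      mid <- (fl$dt_high + fl$dt_low) / 2
      swapped <- abs(fl$dt_calc - fl$dt_high) <= 0.0100001  # transposed row
      nearMeans <- abs(fl$dt_calc - fl$dt) <= 0.0500001     # unrounded means
      midOk <- abs(mid - fl$dt) <= 0.0100001                # mistyped mean
      expect_true(all(swapped | nearMeans | midOk))
    }
  }
})

test_that("computeDeltaT combines means and sd envelopes as documented", {
  tr <- fourTipTree(rates = NULL)
  ages <- nodeAges(tr); rates <- rep(0.5, 7)
  trc <- syntheticTrace(tr, ages, rates, jitter = 1e-9)
  sm <- summarizeNodes(trc)
  dt <- computeDeltaT(sm, tr, c("A", "B", "C", "D"), c("A", "B"))
  expect_equal(dt$mean, 1.0, tolerance = 1e-6)
  rev <- computeDeltaT(sm, tr, c("A", "B"), c("A", "B", "C", "D"))
  expect_equal(rev$mean, -dt$mean, tolerance = 1e-12)
  expect_equal(rev$range_low, -dt$range_high, tolerance = 1e-12)
  expect_equal(rev$range_high, -dt$range_low, tolerance = 1e-12)

  same <- computeDeltaT(sm, tr, c("A", "B"), c("A", "B"))
  expect_equal(same$mean, 0)
  expect_equal(same$range_high, -same$range_low, tolerance = 1e-12)

  # quantile mode brackets the sd mode on near-normal samples
  dtq <- computeDeltaT(sm, tr, c("A", "B", "C", "D"), c("A", "B"),
                       mode = "quantile", trace = trc)
  expect_equal(dtq$mean, dt$mean, tolerance = 1e-6)
  expect_error(computeDeltaT(sm, tr, c("A", "Z"), c("A", "B")),
               "clade-resolution")
})

test_that("rate series extraction respects subsets and strict-clock runs
           give flat series", {
  tr <- fourTipTree(rates = NULL)
  trc <- syntheticTrace(tr, nodeAges(tr), rep(0.4, 7), jitter = 1e-4)
  all <- extractRateSeries(trc)
  expect_equal(nrow(all), 7)
  expect_lt(diff(range(all$rate)), 1e-3)
  two <- extractRateSeries(trc, subset = c("A", "B"))
  expect_equal(nrow(two), 3)  # A, B, their ancestor
  expect_error(extractRateSeries(trc, subset = character(0)),
               "empty node subset")
})

test_that("nu extrema average baseline node means and keep posterior sds", {
  tr <- fourTipTree(rates = NULL)
  rates <- c(0.10, 0.14, 0.3, 0.3, 5.0, 0.12, 0.3)
  trc <- syntheticTrace(tr, nodeAges(tr), rates, jitter = 1e-9)
  nu <- nuExtrema(trc, maxClade = c("A", "B", "C", "D"),
                  baselineClades = list(c("A", "B")))
  expect_equal(nu$nu_max, 5.0, tolerance = 1e-5)
  expect_equal(nu$nu_min, mean(c(0.10, 0.14, 0.12)), tolerance = 1e-5)
  single <- nuExtrema(trc, maxClade = c("A", "B", "C", "D"),
                      baselineClades = list("A"))
  expect_equal(single$nu_min, 0.10, tolerance = 1e-5)
  expect_equal(single$nu_min_sd, 0)
})

test_that("rate ratios and waiting times reproduce the worked examples", {
  slow <- rateRatioAndWaitingTimes(1, 0.12)
  expect_equal(round(slow$waiting_b_Ga), 8)
  expect_equal(slow$waiting_b_Ga, 8.333, tolerance = 1e-3)
  fast <- rateRatioAndWaitingTimes(17, 0.12)
  expect_equal(round(fast$ratio / 10) * 10, 140)
  expect_equal(fast$ratio, 141.7, tolerance = 1e-3)
  expect_equal(round(fast$waiting_a_Ma / 10) * 10, 60)
  expect_equal(rateRatioAndWaitingTimes(0.5, 0.5)$ratio, 1)
  expect_error(rateRatioAndWaitingTimes(0, 1), "contract error")
})

test_that("exponential-decay fitting recovers exact and noisy truth and
           flags degenerate input", {
  ages <- seq(0, 3.5, length.out = 8)
  y <- 0.12 + 4.91 * exp(-(3.5 - ages) / 0.5)
  fit <- fitExponentialDecay(data.frame(age = ages, rate = y), tRoot = 3.5)
  expect_equal(fit$y_inf, 0.12, tolerance = 1e-6)
  expect_equal(fit$amplitude, 4.91, tolerance = 1e-6)
  expect_equal(fit$tau, 0.5, tolerance = 1e-6)

  set.seed(21)
  ages2 <- seq(0, 3.5, length.out = 30)
  y2 <- 0.12 + 4.91 * exp(-(3.5 - ages2) / 0.5) + rnorm(30, 0, 0.05)
  fit2 <- fitExponentialDecay(data.frame(age = ages2, rate = y2),
                              tRoot = 3.5)
  expect_lt(abs(fit2$tau - 0.5) / 0.5, 0.15)
  expect_lt(abs(fit2$amplitude - 4.91) / 4.91, 0.15)

  flat <- fitExponentialDecay(data.frame(age = ages, rate = rep(0.2, 8)))
  expect_true(flat$degenerate)
  expect_equal(flat$y_inf, 0.2)

  # scale equivariance: rescaling time rescales tau
  fitG <- fitExponentialDecay(data.frame(age = ages * 1000, rate = y),
                              tRoot = 3500)
  expect_equal(fitG$tau, 500, tolerance = 1e-4)
})

test_that("power-law fits are exact on power-law data and match the
           log-log OLS oracle under noise", {
  dt <- c(0.1, 0.3, 1, 2)
  pts <- data.frame(delta_t = dt, nu_max = 5 * dt^-1)
  fit <- fitPowerLaw(pts)
  expect_equal(fit$a, 5, tolerance = 1e-9)
  expect_equal(fit$b, -1, tolerance = 1e-9)
  grid <- fit$predict(seq(0.1, 2, 0.1))
  expect_true(all(diff(grid) < 0))  # monotone decreasing for b < 0

  set.seed(31)
  noisy <- data.frame(delta_t = dt,
                      nu_max = exp(log(5) - 1 * log(dt) + rnorm(4, 0, 0.1)))
  nf <- fitPowerLaw(noisy)
  lx <- log(noisy$delta_t); ly <- log(noisy$nu_max)
  oracle <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  expect_equal(nf$b, oracle, tolerance = 1e-10)
  expect_lt(abs(nf$b - (-1)), 0.1)
  expect_error(fitPowerLaw(data.frame(delta_t = c(1, 2, -1),
                                      nu_max = c(1, 1, 1))), "contract")

  # scale equivariance: delta_t in Ma leaves the exponent, rescales a
  ma <- fitPowerLaw(data.frame(delta_t = dt * 1000, nu_max = 5 * dt^-1))
  expect_equal(ma$b, -1, tolerance = 1e-9)
  expect_equal(ma$a, 5 * 1000, tolerance = 1e-6)
})

test_that("time-to-identity inverts the closed form and is monotone", {
  m <- substitutionModel("poisson", nCategories = 1)
  expect_equal(timeToIdentity(5, m, 100), 0)
  t50 <- timeToIdentity(5.03, m, 50)
  expect_equal(t50, (19 / 40) * log(0.95 / 0.45) / 5.03, tolerance = 1e-6)
  # strictly decreasing in rate and in target identity
  expect_gt(timeToIdentity(1, m, 50), t50)
  expect_lt(timeToIdentity(5.03, m, 70), timeToIdentity(5.03, m, 50))
  expect_error(timeToIdentity(5.03, m, 4), "no-solution")

  # a decaying trajectory that everywhere dominates its floor reaches the
  # target no later than the constant-floor clock
  decay <- structure(list(y_inf = 0.12, amplitude = 4.91, tau = 0.5,
                          rss = 0, t_root = 3.5, degenerate = FALSE),
                     class = "DecayFit")
  expect_lte(timeToIdentity(decay, m, 50), timeToIdentity(0.12, m, 50))
})

test_that("the root-prior scan re-dates the tree per grid point", {
  tt <- readTimeTree("((A:1,B:1):2,(C:1,D:1):2);")
  cal <- calibration(c("A", "B"), minAge = 0.8, maxAge = 1.2)
  cs <- calibrationSet(list(cal), rootPrior(3.0, 0.05))
  scan <- scanRootPriors(NULL, tt, substitutionModel("poisson"),
                         clockModel("acln", sigma2 = 0.1, rootRate = 0.5),
                         cs,
                         mcmcConfig(iterations = 2000, burnin = 500,
                                    thinning = 5, seed = 9,
                                    priorOnly = TRUE),
                         rootMeans = c(2.5, 3.5), rootSd = 0.05,
                         cladeA = c("A", "B", "C", "D"),
                         cladeB = c("A", "B"))
  expect_equal(nrow(scan), 2)
  # the posterior root tracks the prior grid in prior-only mode
  expect_equal(scan$root_mean, c(2.5, 3.5), tolerance = 0.02)
  # Delta-T grows with the root prior while the calibrated node stays put
  expect_lt(scan$delta_t[1], scan$delta_t[2])
  expect_equal(scan$b_mean, c(1, 1), tolerance = 0.1)
})
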