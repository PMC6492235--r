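# shared small prior-only setup: balanced 4-tip tree, one soft calibration
priorOnlySetup <- function() {
  tt <- readTimeTree("((A:1,B:1):2,(C:1,D:1):2);")
  cal <- calibration(c("A", "B"), minAge = 0.8, maxAge = 1.2, style = "soft")
  list(tree = tt,
       cal = cal,
       calset = calibrationSet(list(cal), rootPrior(3.0, 0.02)),
       clock = clockModel("acln", sigma2 = 0.1, rootRate = 0.5),
       model = substitutionModel("poisson"))
}

test_that("chains are bit-reproducible from (seed, config)", {
  s <- priorOnlySetup()
  cfg <- mcmcConfig(iterations = 400, burnin = 100, thinning = 4, seed = 2,
                    priorOnly = TRUE)
  t1 <- runChain(NULL, s$tree, s$model, s$clock, s$calset, cfg)
  t2 <- runChain(NULL, s$tree, s$model, s$clock, s$calset, cfg)
  expect_identical(traceSamples(t1), traceSamples(t2))
  expect_equal(nrow(traceSamples(t1)), (400 - 100) %/% 4)

  f <- tempfile(fileext = ".tsv")
  writeTrace(t1, f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(as.matrix(back), as.matrix(traceSamples(t1)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("every recorded state satisfies age ordering and rate
           positivity", {
  s <- priorOnlySetup()
  tr <- runChain(NULL, s$tree, s$model, s$clock, s$calset,
                 mcmcConfig(iterations = 2000, burnin = 200, thinning = 2,
                            seed = 3, priorOnly = TRUE))
  sm <- traceSamples(tr)
  expect_true(all(sm$age_5 > sm$age_6 & sm$age_5 > sm$age_7))
  expect_true(all(as.matrix(sm[grep("^rate_", names(sm))]) > 0))
  expect_true(all(sm$age_6 > 0 & sm$age_7 > 0))
})

test_that("prior-only marginal at a calibrated node matches the
           calibration density (KS)", {
  s <- priorOnlySetup()
  tr <- runChain(NULL, s$tree, s$model, s$clock, s$calset,
                 mcmcConfig(iterations = 26000, burnin = 6000, thinning = 4,
                            seed = 5, priorOnly = TRUE))
  x <- traceSamples(tr)[[paste0("age_", mrcaNode(s$tree, c("A", "B")))]]
  expect_length(x, 5000)
  f <- photoclock:::.calDensity(s$cal, 3.1)
  dens <- function(t) exp(vapply(t, f, numeric(1)))
  Z <- integrate(dens, 0, 3.0)$value
  cdf <- function(q) vapply(q, function(qq)
    integrate(dens, 0, min(qq, 3.0))$value / Z, numeric(1))
  expect_gt(suppressWarnings(ks.test(x, cdf))$p.value, 0.01)
})

test_that("a long prior-only run preserves the sigma2 hyperprior moments", {
  s <- priorOnlySetup()
  tr <- runChain(NULL, s$tree, s$model, s$clock, s$calset,
                 mcmcConfig(iterations = 20000, burnin = 4000, thinning = 4,
                            seed = 6, priorOnly = TRUE))
  draws <- traceSamples(tr)$sigma2
  # hyperprior is log-normal(log 0.1, 1); compare log-scale moments
  expect_equal(mean(log(draws)), log(0.1), tolerance = 0.1)
  expect_equal(sd(log(draws)), 1, tolerance = 0.1)
})

test_that("contradictory hard calibrations fail initialization by name", {
  tt <- readTimeTree("((A:1,B:1):2,(C:1,D:1):2);")
  cals <- list(
    calibration(c("A", "B"), minAge = 2.4, maxAge = 2.8, style = "hard",
                tailLow = 0, tailHigh = 0, label = "inner-too-old"),
    calibration(c("A", "B", "C", "D"), minAge = 1.0, maxAge = 2.0,
                style = "hard", tailLow = 0, tailHigh = 0, label = "root-cap"))
  cs <- calibrationSet(cals, rootPrior(1.8, 0.05))
  expect_error(
    runChain(NULL, tt, substitutionModel("poisson"),
             clockModel("acln"), cs,
             mcmcConfig(iterations = 10, seed = 1, priorOnly = TRUE)),
    "initialization error")
})

test_that("multi-chain seeds differ by fixed offsets and convergence
           assessment passes on the prior-only fixture", {
  s <- priorOnlySetup()
  traces <- runChains(NULL, s$tree, s$model, s$clock, s$calset,
                      nChains = 4, seed = 11, iterations = 40000,
                      burnin = 8000, thinning = 4, priorOnly = TRUE)
  expect_equal(vapply(traces, function(x) x@seed, integer(1)),
               11L + (0:3) * 1009L)
  rep <- assessConvergence(traces)
  expect_true(rep@pass)
  expect_lt(rep@maxAgeDiscrepancy, 0.05)
})

test_that("convergence diagnostics behave at the degenerate extremes", {
  s <- priorOnlySetup()
  cfg <- mcmcConfig(iterations = 300, burnin = 100, thinning = 2, seed = 7,
                    priorOnly = TRUE)
  t1 <- runChain(NULL, s$tree, s$model, s$clock, s$calset, cfg)
  # identical chains: R-hat exactly 1, zero discrepancy, pass
  rep <- assessConvergence(list(t1, t1), ess = 1)
  expect_true(all(rep@perParameter$rhat == 1))
  expect_equal(rep@maxAgeDiscrepancy, 0)

  # disjoint constant chains: R-hat infinite, fail
  t2 <- t1
  t2@samples$age_5 <- t1@samples$age_5 * 0 + 1
  t3 <- t1
  t3@samples$age_5 <- t1@samples$age_5 * 0 + 2
  bad <- assessConvergence(list(t2, t3))
  expect_false(bad@pass)
  expect_identical(max(bad@perParameter$rhat), Inf)

  expect_error(assessConvergence(list(t1)), "insufficient-chains")
})

test_that("node summaries use the documented estimators", {
  s <- priorOnlySetup()
  cfg <- mcmcConfig(iterations = 44, burnin = 40, thinning = 2, seed = 8,
                    priorOnly = TRUE)
  tr <- runChain(NULL, s$tree, s$model, s$clock, s$calset, cfg)
  tr@samples$age_5 <- c(3.0, 3.4)
  sm <- summarizeNodes(tr)
  row <- sm[sm$node == 5, ]
  expect_equal(row$mean_age, 3.2)
  expect_equal(row$sd_age, sd(c(3, 3.4)))  # sample estimator, 0.283
  smp <- summarizeNodes(tr, estimator = "population")
  expect_equal(smp$sd_age[smp$node == 5], 0.2)

  const <- tr
  const@samples$age_5 <- rep(3.1, 2)
  smc <- summarizeNodes(const)
  expect_equal(smc$sd_age[smc$node == 5], 0)
  expect_equal(smc$ci_low[smc$node == 5], smc$ci_high[smc$node == 5])

  empty <- tr
  empty@samples <- tr@samples[0, ]
  expect_error(summarizeNodes(empty), "empty trace")
})

test_that("the posterior matches 1-D quadrature on a two-tip fixed-rate
           problem", {
  m1 <- substitutionModel("poisson", gammaShape = 1, nCategories = 1)
  tt <- readTimeTree("(A:1.2,B:1.2);")
  nodeRates(tt) <- rep(0.5, 3)
  aln <- simulateAlignment(tt, m1, 100, seed = 42)
  x <- sum(strsplit(aln@seqs[1], "")[[1]] == strsplit(aln@seqs[2], "")[[1]])
  r <- 0.5
  lik <- function(t) {
    pii <- poissonPii(2 * r * t)
    (pii / 20)^x * ((1 - pii) / 19 / 20)^(100 - x)
  }
  post <- function(t) dnorm(t, 1.2, 0.15) * lik(t)
  Z <- integrate(post, 0, 5)$value
  mq <- integrate(function(t) t * post(t), 0, 5)$value / Z
  sq <- sqrt(integrate(function(t) t^2 * post(t), 0, 5)$value / Z - mq^2)

  cs <- calibrationSet(list(), rootPrior(1.2, 0.15))
  cm <- clockModel("acln", sigma2 = 0.1, rootRate = 0.5)
  tr <- runChain(aln, tt, m1, cm, cs,
                 mcmcConfig(iterations = 30000, burnin = 5000, thinning = 5,
                            seed = 3, sampleAlpha = FALSE,
                            sampleRates = FALSE))
  draws <- traceSamples(tr)$age_3
  expect_lt(abs(mean(draws) - mq) / mq, 0.02)
  expect_lt(abs(sd(draws) - sq) / sq, 0.02)
})
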