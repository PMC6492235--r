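#' Delta-T: interval between two dated nodes
#'
#' The span between the posterior mean age of node A (e.g. the D1/D2
#' duplication, `D0`) and node B (e.g. the ancestral standard D1). The
#' reported range combines the two +/- 1 sd envelopes:
#' `high = (mean_a + sd_a) - (mean_b - sd_b)` and
#' `low = (mean_a - sd_a) - (mean_b + sd_b)`. A quantile mode instead
#' takes equal-tailed quantiles of the per-sample age difference.
#'
#' @param summary node summary from [summarizeNodes()].
#' @param tree the [TimeTree-class] the summary refers to.
#' @param cladeA,cladeB tip sets resolving (by MRCA) to the two nodes.
#' @param mode `"sd"` (envelope range) or `"quantile"`.
#' @param trace required for `mode = "quantile"`: the
#'   [PosteriorTrace-class] (or list) behind the summary.
#' @param level quantile level for `mode = "quantile"`.
#' @return A `DeltaT` list: `mean`, `range_low`, `range_high`, node ids.
#' @export
computeDeltaT <- function(summary, tree, cladeA, cladeB,
                          mode = c("sd", "quantile"), trace = NULL,
                          level = 0.95) {
  mode <- match.arg(mode)
  na <- mrcaNode(tree, cladeA)
  nb <- mrcaNode(tree, cladeB)
  rowA <- summary[summary$node == na, ]
  rowB <- summary[summary$node == nb, ]
  if (!nrow(rowA) || !nrow(rowB))
    stop("clade-resolution error: node not present in the summary")
  m <- rowA$mean_age - rowB$mean_age
  if (mode == "sd") {
    hi <- (rowA$mean_age + rowA$sd_age) - (rowB$mean_age - rowB$sd_age)
    lo <- (rowA$mean_age - rowA$sd_age) - (rowB$mean_age + rowB$sd_age)
  } else {
    traces <- if (is.list(trace) && !is(trace, "PosteriorTrace")) trace else
      list(trace)
    s <- do.call(rbind, lapply(traces, function(x) x@samples))
    d <- s[[paste0("age_", na)]] - s[[paste0("age_", nb)]]
    q <- quantile(d, c((1 - level) / 2, 1 - (1 - level) / 2))
    lo <- unname(q[1]); hi <- unname(q[2])
  }
  out <- list(mean = m, range_low = lo, range_high = hi,
              node_a = na, node_b = nb)
  class(out) <- "DeltaT"
  out
}

#' @export
print.DeltaT <- function(x, ...) {
  cat(sprintf("Delta-T: %.2f Ga (%.2f-%.2f)\n", x$mean, x$range_high,
              x$range_low))
  invisible(x)
}

#' Per-node (age, rate) series from a posterior trace
#'
#' Posterior mean age and rate per node, restricted to the nodes whose
#' descendant tips all fall inside `subset` (the whole tree when `NULL`).
#'
#' @param trace a [PosteriorTrace-class] or list of them.
#' @param subset optional character vector of tip labels naming a clade or
#'   tip collection.
#' @param includeTips include tip nodes (age 0) in the series.
#' @return A `RateSeries` data.frame: `node`, `label`, `age`, `rate`,
#'   `sd_age`, `sd_rate`.
#' @export
extractRateSeries <- function(trace, subset = NULL, includeTips = TRUE) {
  traces <- if (is.list(trace)) trace else list(trace)
  tree <- traces[[1]]@tree
  sm <- summarizeNodes(traces)
  sm <- sm[!is.na(sm$mean_rate), ]
  n <- length(tree@phylo$tip.label)
  if (!is.null(subset)) {
    keep <- vapply(sm$node, function(j)
      all(cladeTips(tree, j) %in% subset), logical(1))
    sm <- sm[keep, ]
  }
  if (!includeTips) sm <- sm[sm$node > n, ]
  if (!nrow(sm)) stop("contract error: empty node subset")
  out <- data.frame(node = sm$node, label = sm$label, age = sm$mean_age,
                    rate = sm$mean_rate, sd_age = sm$sd_age,
                    sd_rate = sm$sd_rate)
  class(out) <- c("RateSeries", "data.frame")
  out
}

#' Maximum and baseline rates of a rate series
#'
#' `nu_max` is the posterior mean rate at one named node (conventionally
#' the duplication node D0, with its posterior sd); `nu_min` is the
#' unweighted mean of the per-node mean rates over baseline clades
#' (conventionally Group 4 D1 and D2), with the sd of that set of node
#' means.
#'
#' @param trace a [PosteriorTrace-class] or list.
#' @param maxClade tip set resolving to the `nu_max` node.
#' @param baselineClades character vector or list of tip sets pooled into
#'   the baseline.
#' @param includeTips include tip nodes in the baseline pool.
#' @return List with `nu_max`, `nu_max_sd`, `nu_min`, `nu_min_sd`,
#'   `n_baseline`.
#' @export
nuExtrema <- function(trace, maxClade, baselineClades, includeTips = TRUE) {
  traces <- if (is.list(trace)) trace else list(trace)
  tree <- traces[[1]]@tree
  sm <- summarizeNodes(traces)
  node <- mrcaNode(tree, maxClade)
  rowMax <- sm[sm$node == node, ]
  if (!nrow(rowMax)) stop("clade-resolution error: max node not in summary")
  if (!is.list(baselineClades)) baselineClades <- list(baselineClades)
  base <- do.call(rbind, lapply(baselineClades, function(tips)
    extractRateSeries(traces, subset = tips, includeTips = includeTips)))
  base <- base[!duplicated(base$node), ]
  if (!nrow(base)) stop("contract error: empty baseline subset")
  list(nu_max = rowMax$mean_rate, nu_max_sd = rowMax$sd_rate,
       nu_min = mean(base$rate),
       nu_min_sd = if (nrow(base) > 1) sd(base$rate) else 0,
       n_baseline = nrow(base))
}

#' Rate ratio and per-site waiting times
#'
#' The waiting time `1/nu` is the expected time for each position to have
#' changed once at rate `nu` (substitutions/site/Ga).
#'
#' @param nuA,nuB rates in substitutions/site/Ga (> 0).
#' @return List with `ratio` (`nuA/nuB`), `waiting_a_Ga`, `waiting_b_Ga`,
#'   and the same waiting times in Ma.
#' @examples
#' rateRatioAndWaitingTimes(17, 0.12)$ratio  # ~141.7
#' @export
rateRatioAndWaitingTimes <- function(nuA, nuB) {
  if (nuA <= 0 || nuB <= 0) stop("contract error: rates must be > 0")
  list(ratio = nuA / nuB,
       waiting_a_Ga = 1 / nuA, waiting_b_Ga = 1 / nuB,
       waiting_a_Ma = 1000 / nuA, waiting_b_Ma = 1000 / nuB)
}

#' Fit a single-component exponential decay to a rate-versus-age series
#'
#' Least squares of `rate = y_inf + amplitude * exp(-x / tau)` with
#' `x = t_root - age` (time since the root), multi-start over a grid of
#' `tau` values. A series with (near-)constant rates is flagged degenerate
#' with `y_inf` the mean and `tau` unidentifiable.
#'
#' @param series a `RateSeries` or data.frame with `age` and `rate`
#'   (>= 4 points spanning distinct ages).
#' @param tRoot origin of the decay (default the oldest age present).
#' @return A `DecayFit` list: `y_inf`, `amplitude`, `tau` (Ga), `rss`,
#'   `t_root`, `degenerate`.
#' @export
fitExponentialDecay <- function(series, tRoot = NULL) {
  x0 <- series$age; y <- series$rate
  keep <- is.finite(x0) & is.finite(y)
  x0 <- x0[keep]; y <- y[keep]
  if (length(x0) < 4L || length(unique(x0)) < 4L)
    stop("at least 4 points at distinct ages are required")
  if (is.null(tRoot)) tRoot <- max(x0)
  x <- tRoot - x0
  if (sd(y) < 1e-12 * max(1, abs(mean(y)))) {
    out <- list(y_inf = mean(y), amplitude = 0, tau = NA_real_, rss = 0,
                t_root = tRoot, degenerate = TRUE)
    class(out) <- "DecayFit"
    return(out)
  }
  span <- diff(range(x))
  best <- NULL
  for (tau0 in span * c(0.05, 0.1, 0.25, 0.5, 1, 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ yi + A * exp(-x / tau),
                        start = list(yi = min(y),
                                     A = max(y) - min(y), tau = tau0),
                        lower = c(0, 0, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(coef = coef(fit), rss = rss)
  }
  if (is.null(best))
    stop("fit-failure error: exponential decay did not converge from any start")
  out <- list(y_inf = unname(best$coef["yi"]),
              amplitude = unname(best$coef["A"]),
              tau = unname(best$coef["tau"]), rss = best$rss,
              t_root = tRoot, degenerate = FALSE)
  class(out) <- "DecayFit"
  out
}

#' @export
print.DecayFit <- function(x, ...) {
  if (x$degenerate)
    cat(sprintf("DecayFit (degenerate): constant rate %.4g\n", x$y_inf))
  else
    cat(sprintf(
      "DecayFit: y_inf %.4g + %.4g * exp(-(t_root - t)/%.4g Ga), rss %.4g\n",
      x$y_inf, x$amplitude, x$tau, x$rss))
  invisible(x)
}

#' Power-law fit of nu_max against Delta-T
#'
#' Log-log least squares `log(nu_max) = log(a) + b * log(delta_t)`, used
#' to project the maximum rate required under hypothetical shorter or
#' longer duplication-to-standard-form spans.
#'
#' @param points data.frame with positive columns `delta_t` and `nu_max`
#'   (>= 3 points).
#' @return A `PowerLawFit` list: `a`, `b`, `predict(delta_t)`, `domain`.
#' @export
fitPowerLaw <- function(points) {
  x <- points$delta_t; y <- points$nu_max
  if (length(x) < 3L) stop("at least 3 points are required")
  if (any(x <= 0) || any(y <= 0))
    stop("contract error: power-law fit needs positive values")
  fit <- lm(log(y) ~ log(x))
  a <- exp(unname(coef(fit)[1])); b <- unname(coef(fit)[2])
  out <- list(a = a, b = b,
              predict = function(delta_t) a * delta_t^b,
              domain = range(x),
              r_squared = suppressWarnings(summary(fit)$r.squared))
  class(out) <- "PowerLawFit"
  out
}

#' @export
print.PowerLawFit <- function(x, ...) {
  cat(sprintf("PowerLawFit: nu_max = %.4g * delta_t^%.4g (r^2 %.3f)\n",
              x$a, x$b, x$r_squared))
  invisible(x)
}

#' Time for two diverging lineages to decay to a target identity
#'
#' Expected observable identity between two lineages that split t Ga ago,
#' each accumulating per-lineage distance `d(t)` (the integral of the rate
#' trajectory): `I(t) = 100 * sum_j pi_j [P(2 d(t))]_jj`. For the Poisson
#' model this is the closed form
#' `1/20 + (19/20) exp(-(40/19) d(t))`. Solved for `I = target` by
#' root-finding; no identity below the equilibrium
#' `100 * sum_j pi_j^2` is reachable.
#'
#' @param nu a constant rate (substitutions/site/Ga) or a `DecayFit`
#'   (trajectory `y_inf + amplitude * exp(-s/tau)` in time `s` since the
#'   split).
#' @param model a [SubstitutionModel-class].
#' @param target target percent identity.
#' @return Time in Ga.
#' @export
timeToIdentity <- function(nu, model, target) {
  pi <- model@frequencies
  eq <- 100 * sum(pi^2)
  if (target <= eq)
    stop(sprintf(
      "no-solution error: target %.3g%% is at or below the equilibrium %.3g%%",
      target, eq))
  if (target >= 100) return(0)
  dist <- if (inherits(nu, "DecayFit")) {
    function(t) nu$y_inf * t + nu$amplitude * nu$tau * (1 - exp(-t / nu$tau))
  } else {
    if (nu <= 0) stop("contract error: rate must be > 0")
    function(t) nu * t
  }
  e <- .eigenQ(model)
  ident <- function(t) {
    P2 <- e$U %*% diag(exp(e$lambda * 2 * dist(t))) %*% e$Uinv
    100 * sum(pi * diag(P2))
  }
  hi <- 1
  while (ident(hi) > target && hi < 1e6) hi <- hi * 2
  uniroot(function(t) ident(t) - target, c(0, hi), tol = 1e-10)$root
}

#' Scan root priors, re-dating the tree for each
#'
#' Re-runs the dating chain across a grid of root-prior means (the
#' sensitivity layout of the analysis: how Delta-T responds to the assumed
#' age of the most ancestral protein), summarizing the root, node A and
#' node B ages and Delta-T per row.
#'
#' @param alignment,tree,model,clock,calset,config as [runChain()];
#'   `config$seed` seeds every row (offset by the row index).
#' @param rootMeans grid of root-prior means in Ga.
#' @param rootSd root-prior sd in Ga.
#' @param cladeA,cladeB Delta-T clade specs.
#' @return data.frame with one row per root prior.
#' @export
scanRootPriors <- function(alignment, tree, model, clock, calset, config,
                           rootMeans = c(3.2, 3.5, 3.8, 4.1), rootSd = 0.05,
                           cladeA, cladeB) {
  rows <- lapply(seq_along(rootMeans), function(i) {
    cs <- calibrationSet(calset@calibrations,
                         rootPrior(rootMeans[i], rootSd))
    cfg <- config
    cfg$seed <- config$seed + i
    tr <- runChain(alignment, tree, model, clock, cs, cfg)
    sm <- summarizeNodes(tr)
    dt <- computeDeltaT(sm, tree, cladeA, cladeB)
    rootRow <- sm[sm$node == length(tree@phylo$tip.label) + 1L, ]
    data.frame(root_prior = rootMeans[i], root_mean = rootRow$mean_age,
               root_sd = rootRow$sd_age,
               a_mean = sm$mean_age[sm$node == dt$node_a],
               a_sd = sm$sd_age[sm$node == dt$node_a],
               b_mean = sm$mean_age[sm$node == dt$node_b],
               b_sd = sm$sd_age[sm$node == dt$node_b],
               delta_t = dt$mean, delta_t_low = dt$range_low,
               delta_t_high = dt$range_high)
  })
  do.call(rbind, rows)
}
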