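#' Sampler configuration
#'
#' @param iterations total MCMC sweeps (one sweep proposes every node age,
#'   every node rate, and each hyperparameter once).
#' @param burnin sweeps discarded before recording (default 25% of
#'   `iterations`); proposal scales are auto-tuned to a 20-45% acceptance
#'   rate during burn-in and frozen afterwards.
#' @param thinning record every `thinning`-th sweep.
#' @param seed mandatory RNG seed; a run is bit-reproducible from
#'   `(config, inputs)`.
#' @param priorOnly replace the likelihood by a constant (sampling the
#'   prior; used for prior-predictive checks and validation).
#' @param sampleAlpha sample the gamma site-rate shape (log-normal
#'   hyperprior centred on the model's shape) or keep it fixed.
#' @param sampleRates sample node rates (set `FALSE` to run a fixed-rate
#'   strict clock at the clock model's `rootRate`, e.g. for validation
#'   against low-dimensional quadrature).
#' @return A config list for [runChain()].
#' @export
mcmcConfig <- function(iterations = 20000L, burnin = NULL, thinning = 10L,
                       seed, priorOnly = FALSE, sampleAlpha = TRUE,
                       sampleRates = TRUE) {
  iterations <- as.integer(iterations)
  if (is.null(burnin)) burnin <- iterations %/% 4L
  list(iterations = iterations, burnin = as.integer(burnin),
       thinning = as.integer(thinning), seed = as.integer(seed),
       priorOnly = isTRUE(priorOnly), sampleAlpha = isTRUE(sampleAlpha),
       sampleRates = isTRUE(sampleRates))
}

# initial ages: scale node heights to the root prior mean, then repair
# hard-calibration violations
.initAges <- function(tree, calset) {
  phy <- tree@phylo
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  kids <- .childrenList(phy)
  par <- .parentVec(phy)
  height <- numeric(nn)
  for (j in rev(.preorderNodes(phy)))
    height[j] <- if (j <= n) 0 else 1 + max(height[kids[[j]]])
  ages <- calset@root@mean * height / height[n + 1L]
  for (cl in calset@calibrations) {
    if (cl@style != "hard") next
    node <- mrcaNode(tree, cl@clade, requireMonophyly = TRUE)
    lo0 <- if (is.na(cl@minAge)) 0 else cl@minAge
    hi0 <- if (is.na(cl@maxAge)) Inf else cl@maxAge
    lo <- max(lo0, max(ages[kids[[node]]]) + 1e-6)
    hi <- min(hi0, if (is.na(par[node])) Inf else ages[par[node]] - 1e-6)
    if (lo > hi)
      stop("initialization error: calibration '", cl@label,
           "' [", lo0, ", ", hi0, "] Ga conflicts with the surrounding ",
           "node ages; no admissible initial state")
    if (ages[node] < lo || ages[node] > hi) ages[node] <- (lo + hi) / 2
  }
  dur <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  if (any(dur <= 0))
    stop("initialization error: calibrations are mutually contradictory ",
         "on this topology")
  ages
}

#' Run one Metropolis-Hastings dating chain
#'
#' Samples node ages, node rates and hyperparameters targeting
#' prior x likelihood on the fixed topology. The move set: node-age
#' sliding window uniform on `[max child age, parent age]`; root-age
#' multiplier; single-node rate multipliers; hyperparameter multipliers
#' (`sigma2` or the branch-rate shape, the site-rate shape `alpha`, and
#' the global rate for the uncorrelated clock); and a rate-time
#' compensating move that shifts an internal age while rescaling its rate
#' to preserve the parent-edge expected length.
#'
#' @param alignment a [ProteinAlignment-class] (ignored in prior-only
#'   mode, where it may be `NULL`).
#' @param tree a [TimeTree-class] giving the fixed topology (its ages are
#'   used only to shape the initial state).
#' @param model a [SubstitutionModel-class].
#' @param clock a [ClockModel-class].
#' @param calset a [CalibrationSet-class].
#' @param config from [mcmcConfig()].
#' @param chainId integer chain label.
#' @return A [PosteriorTrace-class].
#' @export
runChain <- function(alignment, tree, model, clock, calset, config,
                     chainId = 1L) {
  set.seed(config$seed)
  phy <- tree@phylo
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  rootN <- n + 1L
  kids <- .childrenList(phy)
  par <- .parentVec(phy)
  internal <- setdiff((n + 1L):nn, rootN)
  acln <- clock@kind == "acln"
  brMode <- if (acln) "mean" else "node"

  # --- state ---
  if (is.null(config$sampleRates)) config$sampleRates <- TRUE
  ages <- .initAges(tree, calset)
  rates <- rep(clock@rootRate, nn)
  if (acln && config$sampleRates) {
    # draw the initial rates from the autocorrelated prior so the chain
    # does not start in the measure-zero strict-clock corner
    for (p in .preorderNodes(phy)) for (j in kids[[p]]) {
      dt <- ages[p] - ages[j]
      rates[j] <- exp(log(rates[p]) - clock@sigma2 * dt / 2 +
                        rnorm(1, 0, sqrt(clock@sigma2 * dt)))
    }
  }
  sigma2 <- if (acln) clock@sigma2 else clock@shape  # generic dispersion
  mu <- clock@rootRate                               # ugam global rate
  alpha <- model@gammaShape

  supportMax <- calset@root@mean + 5 * calset@root@sd
  calNodes <- integer(0); calFuns <- list()
  for (cl in calset@calibrations) {
    calNodes <- c(calNodes, mrcaNode(tree, cl@clade, requireMonophyly = TRUE))
    calFuns[[length(calFuns) + 1L]] <- .calDensity(cl, supportMax)
  }
  hardmins <- vapply(calset@calibrations, function(cl)
    if (cl@style == "hard" && !is.na(cl@minAge)) cl@minAge else 0, numeric(1))
  truncMin <- if (length(hardmins)) max(0, hardmins) else 0
  mFree <- phy$Nnode - 1L
  edgePa <- phy$edge[, 1]; edgeCh <- phy$edge[, 2]

  lpTime <- function(a) {
    lp <- rootLogDensity(calset@root, a[rootN], truncMin) -
      mFree * log(a[rootN])
    for (k in seq_along(calNodes)) {
      lp <- lp + calFuns[[k]](a[calNodes[k]])
      if (!is.finite(lp)) return(-Inf)
    }
    lp
  }
  lpRate <- function(a, r, s2, gmu) {
    if (acln) {
      dt <- a[edgePa] - a[edgeCh]
      sum(dlnorm(r[edgeCh], log(r[edgePa]) - s2 * dt / 2, sqrt(s2 * dt),
                 log = TRUE)) +
        dlnorm(r[rootN], log(clock@rootRate), 1, log = TRUE)
    } else {
      sum(dgamma(r[edgeCh], shape = s2, rate = s2 / gmu, log = TRUE))
    }
  }
  lpHyper <- function(s2, al, gmu) {
    lp <- .hyperLogPrior(s2, if (acln) clock@sigma2 else clock@shape) +
      .hyperLogPrior(al, model@gammaShape)
    if (!acln) lp <- lp + .hyperLogPrior(gmu, clock@rootRate)
    lp
  }

  # --- likelihood engine ---
  eng <- NULL
  edgeLen <- function(a, r, j) {
    dt <- a[par[j]] - a[j]
    if (acln) (r[par[j]] + r[j]) / 2 * dt else r[j] * dt
  }
  L <- numeric(nn)
  catr <- gammaCategoryRates(alpha, model@nCategories)
  if (!config$priorOnly) {
    em <- .makeEngine(alignment, TimeTree(phy, ages), model)
    eng <- em$ptr
    for (j in seq_len(nn)) if (!is.na(par[j])) L[j] <- edgeLen(ages, rates, j)
    ll <- .le_full(eng, L, catr)
  } else ll <- 0
  lpT <- lpTime(ages); lpR <- lpRate(ages, rates, sigma2, mu)
  lpH <- lpHyper(sigma2, alpha, mu)
  if (!is.finite(lpT + lpR + lpH))
    stop("initialization error: initial state has zero prior density")

  # likelihood of a proposal touching the edges above `touched`
  propLik <- function(touched, a, r, newcat = catr) {
    if (config$priorOnly) return(0)
    Lp <- L
    for (j in touched) Lp[j] <- edgeLen(a, r, j)
    .le_propose(eng, as.integer(touched), Lp, newcat)
  }
  commitLik <- function(touched, a, r) {
    if (config$priorOnly) return(invisible())
    for (j in touched) L[j] <<- edgeLen(a, r, j)
    .le_accept(eng)
  }
  dropLik <- function() if (!config$priorOnly) .le_reject(eng)

  # --- tuning ---
  scales <- c(root = 0.05, rate = 0.5, hyper = 0.5, alpha = 0.5, comp = 0.1)
  accN <- rejN <- setNames(numeric(5), names(scales))
  tuneTick <- function() {
    for (k in names(scales)) {
      tot <- accN[k] + rejN[k]
      if (tot < 20) next
      p <- accN[k] / tot
      if (p > 0.45) scales[k] <<- scales[k] * 1.3
      if (p < 0.20) scales[k] <<- scales[k] / 1.3
      accN[k] <<- rejN[k] <<- 0
    }
  }
  bump <- function(k, acc) if (acc) accN[k] <<- accN[k] + 1 else
    rejN[k] <<- rejN[k] + 1

  mh <- function(logRatio) is.finite(logRatio) && log(runif(1)) < logRatio

  nrec <- (config$iterations - config$burnin) %/% config$thinning
  ageCols <- c(rootN, internal)
  rateCols <- if (acln) seq_len(nn) else setdiff(seq_len(nn), rootN)
  ncol_extra <- if (acln) 4L else 5L
  rec <- matrix(NA_real_, nrec,
                length(ageCols) + length(rateCols) + ncol_extra)
  ri <- 0L

  rateMoveNodes <- if (acln) seq_len(nn) else setdiff(seq_len(nn), rootN)

  for (iter in seq_len(config$iterations)) {
    ## 1. internal node ages: uniform window on the admissible interval
    for (j in internal) {
      lo <- max(ages[kids[[j]]]); hi <- ages[par[j]]
      anew <- ages; anew[j] <- runif(1, lo, hi)
      touched <- c(j, kids[[j]])
      lpT2 <- lpTime(anew)
      if (!is.finite(lpT2)) next
      lpR2 <- lpRate(anew, rates, sigma2, mu)
      ll2 <- propLik(touched, anew, rates)
      if (mh(lpT2 + lpR2 + ll2 - lpT - lpR - ll)) {
        commitLik(touched, anew, rates)
        ages <- anew; lpT <- lpT2; lpR <- lpR2; ll <- ll2
      } else dropLik()
    }
    ## 2. root-age multiplier
    {
      f <- exp(scales["root"] * (runif(1) - 0.5))
      anew <- ages; anew[rootN] <- ages[rootN] * f
      ok <- anew[rootN] > max(ages[kids[[rootN]]])
      if (ok) {
        touched <- kids[[rootN]]
        lpT2 <- lpTime(anew)
        lpR2 <- lpRate(anew, rates, sigma2, mu)
        ll2 <- propLik(touched, anew, rates)
        if (mh(lpT2 + lpR2 + ll2 - lpT - lpR - ll + log(f))) {
          commitLik(touched, anew, rates)
          ages <- anew; lpT <- lpT2; lpR <- lpR2; ll <- ll2
          bump("root", TRUE)
        } else { dropLik(); bump("root", FALSE) }
      } else bump("root", FALSE)
    }
    ## 3. node-rate multipliers
    if (config$sampleRates) for (j in rateMoveNodes) {
      f <- exp(scales["rate"] * (runif(1) - 0.5))
      rnew <- rates; rnew[j] <- rates[j] * f
      touched <- c(if (!is.na(par[j])) j,
                   if (acln && j > n) kids[[j]])
      lpR2 <- lpRate(ages, rnew, sigma2, mu)
      ll2 <- if (length(touched)) propLik(touched, ages, rnew) else ll
      if (mh(lpR2 + ll2 - lpR - ll + log(f))) {
        if (length(touched)) commitLik(touched, ages, rnew)
        rates <- rnew; lpR <- lpR2; ll <- ll2
        bump("rate", TRUE)
      } else { if (length(touched)) dropLik(); bump("rate", FALSE) }
    }
    ## 4. dispersion (sigma2 / shape) multiplier; prior-side only, so
    ## several cheap proposals per sweep help its mixing
    for (rep4 in 1:4) {
      f <- exp(scales["hyper"] * (runif(1) - 0.5))
      s2new <- sigma2 * f
      lpR2 <- lpRate(ages, rates, s2new, mu)
      lpH2 <- lpHyper(s2new, alpha, mu)
      if (mh(lpR2 + lpH2 - lpR - lpH + log(f))) {
        sigma2 <- s2new; lpR <- lpR2; lpH <- lpH2
        bump("hyper", TRUE)
      } else bump("hyper", FALSE)
    }
    ## 4b. global rate (uncorrelated kind)
    if (!acln) {
      f <- exp(scales["hyper"] * (runif(1) - 0.5))
      munew <- mu * f
      lpR2 <- lpRate(ages, rates, sigma2, munew)
      lpH2 <- lpHyper(sigma2, alpha, munew)
      if (mh(lpR2 + lpH2 - lpR - lpH + log(f))) {
        mu <- munew; lpR <- lpR2; lpH <- lpH2
      }
    }
    ## 5. site-rate shape alpha (full likelihood recompute)
    if (config$sampleAlpha && !config$priorOnly) {
      f <- exp(scales["alpha"] * (runif(1) - 0.5))
      alnew <- alpha * f
      catr2 <- gammaCategoryRates(alnew, model@nCategories)
      lpH2 <- lpHyper(sigma2, alnew, mu)
      ll2 <- .le_propose(eng, integer(0), L, catr2)
      if (mh(lpH2 + ll2 - lpH - ll + log(f))) {
        .le_accept(eng)
        alpha <- alnew; catr <- catr2; lpH <- lpH2; ll <- ll2
        bump("alpha", TRUE)
      } else { .le_reject(eng); bump("alpha", FALSE) }
    }
    ## 6. rate-time compensating move on a random internal node
    if (config$sampleRates && length(internal)) {
      j <- internal[sample.int(length(internal), 1L)]
      lo <- max(ages[kids[[j]]]); hi <- ages[par[j]]
      delta <- scales["comp"] * (runif(1) - 0.5)
      tnew <- ages[j] + delta
      if (tnew > lo && tnew < hi) {
        anew <- ages; anew[j] <- tnew
        rnew <- rates
        rnew[j] <- rates[j] * (hi - ages[j]) / (hi - tnew)
        touched <- c(j, kids[[j]])
        lpT2 <- lpTime(anew)
        lpR2 <- lpRate(anew, rnew, sigma2, mu)
        ll2 <- propLik(touched, anew, rnew)
        ljac <- log((hi - ages[j]) / (hi - tnew))
        if (mh(lpT2 + lpR2 + ll2 - lpT - lpR - ll + ljac)) {
          commitLik(touched, anew, rnew)
          ages <- anew; rates <- rnew; lpT <- lpT2; lpR <- lpR2; ll <- ll2
          bump("comp", TRUE)
        } else { dropLik(); bump("comp", FALSE) }
      } else bump("comp", FALSE)
    }

    if (iter <= config$burnin) {
      if (iter %% 50L == 0L) tuneTick()
    } else if ((iter - config$burnin) %% config$thinning == 0L) {
      ri <- ri + 1L
      stopifnot(all(ages[edgePa] > ages[edgeCh]), all(rates > 0))
      rec[ri, ] <- c(ages[ageCols], rates[rateCols], sigma2, alpha,
                     if (!acln) mu, lpT + lpR + lpH, ll)
    }
  }

  cn <- c(paste0("age_", ageCols), paste0("rate_", rateCols),
          if (acln) "sigma2" else "shape", "alpha",
          if (!acln) "mu", "log_prior", "log_likelihood")
  samples <- as.data.frame(rec)
  names(samples) <- cn
  labs <- vapply(ageCols, function(j) .nodeLabel(tree, j), character(1))
  new("PosteriorTrace", samples = samples, tree = tree,
      chainId = as.integer(chainId), seed = config$seed,
      iterations = config$iterations, burnin = config$burnin,
      thinning = config$thinning, nodeLabels = labs)
}

#' Run several chains with seeds derived from one master seed
#'
#' Chain `k` runs with seed `seed + (k - 1) * 1009` (fixed offsets from
#' the master seed).
#'
#' @inheritParams runChain
#' @param nChains number of chains (the conventional choice is 4).
#' @param seed master seed.
#' @param ... passed to [mcmcConfig()].
#' @return List of [PosteriorTrace-class] objects.
#' @export
runChains <- function(alignment, tree, model, clock, calset, nChains = 4L,
                      seed, ...) {
  lapply(seq_len(nChains), function(k)
    runChain(alignment, tree, model, clock, calset,
             mcmcConfig(seed = seed + (k - 1L) * 1009L, ...),
             chainId = k))
}

#' Write a trace as TSV (with a JSON run manifest when jsonlite is there)
#'
#' @param trace a [PosteriorTrace-class].
#' @param path output TSV; a `.json` manifest is written alongside.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path) {
  write.table(trace@samples, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- list(chainId = trace@chainId, seed = trace@seed,
                   iterations = trace@iterations, burnin = trace@burnin,
                   thinning = trace@thinning,
                   nodeLabels = as.list(trace@nodeLabels))
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(manifest,
                         paste0(sub("\\.tsv$", "", path), ".manifest.json"),
                         auto_unbox = TRUE)
  invisible(path)
}

#' Posterior node summaries
#'
#' Per-node posterior mean and standard deviation of age and rate, and an
#' equal-tailed credible interval for the age. Several traces are pooled.
#'
#' @param trace a [PosteriorTrace-class] or list of them (same run setup).
#' @param level credible level (default 0.95).
#' @param estimator `"sample"` (n-1 denominator, default) or
#'   `"population"` for the standard deviations.
#' @return data.frame with one row per node that appears in the trace:
#'   `node`, `label`, `mean_age`, `sd_age`, `ci_low`, `ci_high`,
#'   `mean_rate`, `sd_rate`.
#' @export
summarizeNodes <- function(trace, level = 0.95,
                           estimator = c("sample", "population")) {
  estimator <- match.arg(estimator)
  traces <- if (is.list(trace)) trace else list(trace)
  s <- do.call(rbind, lapply(traces, function(x) x@samples))
  if (!nrow(s)) stop("contract error: empty trace")
  tr <- traces[[1]]
  sdev <- function(x) {
    if (estimator == "sample") sd(x) else sqrt(mean((x - mean(x))^2))
  }
  ageIdx <- grep("^age_", names(s))
  rateIdx <- grep("^rate_", names(s))
  nodes <- sort(unique(c(as.integer(sub("age_", "", names(s)[ageIdx])),
                         as.integer(sub("rate_", "", names(s)[rateIdx])))))
  a <- (1 - level) / 2
  n <- length(tr@tree@phylo$tip.label)
  out <- lapply(nodes, function(j) {
    ac <- s[[paste0("age_", j)]]
    rc <- s[[paste0("rate_", j)]]
    if (is.null(ac)) ac <- rep(0, nrow(s))  # tips: age 0 by contract
    data.frame(node = j,
               label = if (j > n) .nodeLabel(tr@tree, j) else
                 tr@tree@phylo$tip.label[j],
               mean_age = mean(ac), sd_age = sdev(ac),
               ci_low = unname(quantile(ac, a)),
               ci_high = unname(quantile(ac, 1 - a)),
               mean_rate = if (is.null(rc)) NA_real_ else mean(rc),
               sd_rate = if (is.null(rc)) NA_real_ else sdev(rc))
  })
  do.call(rbind, out)
}
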