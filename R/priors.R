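#' Log-density of a calibration at a node age
#'
#' Hard style is uniform inside the bounds and `-Inf` outside. Soft style
#' is a proper, continuous density: a uniform core on `[min, max]` carrying
#' `1 - tailLow - tailHigh` of the mass, a power-shaped lower tail on
#' `(0, min)` holding exactly `tailLow`, and an exponential upper tail
#' above `max` holding exactly `tailHigh`, both matched for continuity at
#' the bounds (the construction the 2.5%/5% tail-probability convention
#' describes). A minimum-only soft calibration needs a finite upper
#' support limit, `supportMax`, for its core (in full priors this is
#' implied by the root support).
#'
#' @param cal a [Calibration-class].
#' @param age node age in Ga (> 0); vectorized.
#' @param supportMax upper core limit for one-sided minimum calibrations.
#' @return Log-density value(s).
#' @export
calibrationLogDensity <- function(cal, age, supportMax = Inf) {
  f <- .calDensity(cal, supportMax)
  vapply(age, f, numeric(1))
}

# returns function(age) -> log density
.calDensity <- function(cal, supportMax = Inf) {
  lo <- cal@minAge; hi <- cal@maxAge
  tl <- cal@tailLow; th <- cal@tailHigh
  if (is.na(hi)) {
    if (!is.finite(supportMax))
      stop("a minimum-only calibration needs a finite supportMax for its core")
    hi <- supportMax; th <- 0
  }
  if (is.na(lo)) { lo <- 0; tl <- 0 }
  if (cal@style == "hard") {
    h <- 1 / (hi - lo)
    return(function(t) if (t >= lo && t <= hi) log(h) else -Inf)
  }
  h <- (1 - tl - th) / (hi - lo)       # core height
  theta <- if (tl > 0) h * lo / tl - 1 else NA_real_
  s <- if (th > 0) th / h else NA_real_  # exponential tail scale
  function(t) {
    if (t <= 0) return(-Inf)
    if (t < lo) {
      if (tl <= 0) return(-Inf)
      return(log(h) + theta * (log(t) - log(lo)))
    }
    if (t <= hi) return(log(h))
    if (th <= 0) return(-Inf)
    log(h) - (t - hi) / s
  }
}

#' Log-density of the root prior at an age
#'
#' Normal in age, renormalized over the admissible range `(truncMin, Inf)`;
#' `-Inf` at or below the truncation point.
#'
#' @param prior a [RootPrior-class].
#' @param age root age in Ga; vectorized.
#' @param truncMin lower truncation (0, or the oldest hard minimum among
#'   root-spanning constraints).
#' @return Log-density value(s).
#' @export
rootLogDensity <- function(prior, age, truncMin = 0) {
  lognorm <- pnorm(truncMin, prior@mean, prior@sd, lower.tail = FALSE,
                   log.p = TRUE)
  out <- dnorm(age, prior@mean, prior@sd, log = TRUE) - lognorm
  out[age <= truncMin] <- -Inf
  out
}

#' Joint log-prior of the node times of a chronogram
#'
#' Root term (truncated-normal root prior) plus the calibration densities
#' at their MRCA nodes plus a uniform density for the uncalibrated
#' internal ages given the ordering constraints. The uniform-given-root
#' term contributes `-m log(t_root)` (with `m` free internal nodes), the
#' volume scaling of the order-constrained simplex.
#'
#' @param tree a [TimeTree-class] (its current ages are evaluated).
#' @param calset a [CalibrationSet-class] (root prior + calibrations).
#' @return The log-density; `-Inf` for inadmissible configurations.
#' @export
nodeTimeLogPrior <- function(tree, calset) {
  phy <- tree@phylo
  ages <- tree@ages
  dur <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  if (any(dur <= 0)) return(-Inf)
  n <- length(phy$tip.label)
  troot <- ages[n + 1L]
  hardmins <- vapply(calset@calibrations, function(cl)
    if (cl@style == "hard" && !is.na(cl@minAge)) cl@minAge else 0, numeric(1))
  truncMin <- if (length(hardmins)) max(0, hardmins) else 0
  lp <- rootLogDensity(calset@root, troot, truncMin = truncMin)
  if (!is.finite(lp)) return(-Inf)
  m <- phy$Nnode - 1L
  lp <- lp - m * log(troot)
  supportMax <- calset@root@mean + 5 * calset@root@sd
  for (cl in calset@calibrations) {
    node <- mrcaNode(tree, cl@clade, requireMonophyly = TRUE)
    lp <- lp + .calDensity(cl, supportMax)(ages[node])
    if (!is.finite(lp)) return(-Inf)
  }
  lp
}

#' Log-prior of the node rates under a relaxed-clock model
#'
#' Autocorrelated log-normal kind: for each child node `j` with parent
#' `p`, `log r_j ~ Normal(log r_p - sigma2*dt/2, sigma2*dt)` where `dt` is
#' the edge duration (the half-variance correction keeps
#' `E[r_j] = r_p`); the root's rate has a broad log-normal hyperprior
#' centred on the clock's `rootRate` with unit log-scale sd. Uncorrelated
#' gamma kind: each non-root node's rate is i.i.d.
#' `Gamma(shape, shape/rootRate)` (mean `rootRate`).
#'
#' @param tree a [TimeTree-class] with ages and rates.
#' @param clock a [ClockModel-class].
#' @return The log-density; `-Inf` for nonpositive rates.
#' @export
rateLogPrior <- function(tree, clock) {
  rates <- tree@rates
  if (!length(rates)) stop("tree has no rates")
  if (any(rates <= 0)) return(-Inf)
  phy <- tree@phylo
  n <- length(phy$tip.label)
  if (clock@kind == "acln") {
    lp <- dlnorm(rates[n + 1L], log(clock@rootRate), 1, log = TRUE)
    pa <- phy$edge[, 1]; ch <- phy$edge[, 2]
    dt <- tree@ages[pa] - tree@ages[ch]
    sdlog <- sqrt(clock@sigma2 * dt)
    meanlog <- log(rates[pa]) - clock@sigma2 * dt / 2
    lp + sum(dlnorm(rates[ch], meanlog, sdlog, log = TRUE))
  } else {
    ch <- phy$edge[, 2]
    sum(dgamma(rates[ch], shape = clock@shape,
               rate = clock@shape / clock@rootRate, log = TRUE))
  }
}

# broad proper hyperprior used for sigma2/shape/alpha/rootRate:
# log-normal, unit sd on the log scale, centred on `median`
.hyperLogPrior <- function(value, median) {
  dlnorm(value, meanlog = log(median), sdlog = 1, log = TRUE)
}

#' Read calibrations and a root prior from a key-value text file
#'
#' Blocks separated by blank lines; each calibration block has `name:`,
#' `tips:` (comma-separated), optional `min:`/`max:` (Ga), `style:`
#' (hard/soft, default soft), optional `tail_low:`/`tail_high:`. A block
#' with `root_mean:`/`root_sd:` sets the root prior.
#'
#' @param path file to read.
#' @param rootMean,rootSd fallback root prior when the file has no root
#'   block.
#' @return A [CalibrationSet-class].
#' @export
readCalibrations <- function(path, rootMean = NULL, rootSd = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  cals <- list()
  for (b in blocks) {
    b <- b[nzchar(trimws(b))]
    if (!length(b)) next
    kv <- strsplit(b, ":", fixed = TRUE)
    keys <- trimws(vapply(kv, `[`, character(1), 1))
    vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"),
                          character(1)))
    rec <- setNames(as.list(vals), keys)
    if (!is.null(rec$root_mean)) {
      rootMean <- as.numeric(rec$root_mean)
      rootSd <- as.numeric(rec$root_sd)
      next
    }
    num <- function(k) if (is.null(rec[[k]])) NA_real_ else as.numeric(rec[[k]])
    cals[[length(cals) + 1L]] <- calibration(
      clade = trimws(strsplit(rec$tips, ",")[[1]]),
      minAge = num("min"), maxAge = num("max"),
      style = if (is.null(rec$style)) "soft" else rec$style,
      tailLow = if (is.null(rec$tail_low)) NULL else as.numeric(rec$tail_low),
      tailHigh = if (is.null(rec$tail_high)) NULL else as.numeric(rec$tail_high),
      label = if (is.null(rec$name)) "" else rec$name)
  }
  if (is.null(rootMean) || is.null(rootSd))
    stop("no root prior: supply a root_mean/root_sd block or arguments")
  calibrationSet(cals, rootPrior(rootMean, rootSd))
}
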