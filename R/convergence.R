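# between-chain potential scale reduction (Gelman-Rubin R-hat), floored at
# 1 so that identical chains give exactly 1 and sampling noise cannot push
# it below; disjoint constant chains give Inf
.rhat <- function(chains) {
  N <- length(chains[[1]])
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, var, numeric(1))
  W <- mean(vars)
  B <- N * var(means)
  if (W == 0) return(if (B == 0 || is.na(B)) 1 else Inf)
  max(1, sqrt(((N - 1) / N * W + B / N) / W))
}

# effective sample size over pooled chains: Geyer initial-positive-pair
# truncation of the autocorrelation sum, averaged across chains
.ess <- function(chains) {
  N <- length(chains[[1]])
  M <- length(chains)
  if (all(vapply(chains, function(x) var(x) == 0 || is.na(var(x)),
                 logical(1))))
    return(M * N)
  rho <- rowMeans(vapply(chains, function(x) {
    a <- acf(x, lag.max = min(N - 1L, 200L), plot = FALSE)$acf[, 1, 1]
    length(a) <- min(N, 201L)
    a
  }, numeric(min(N, 201L))), na.rm = TRUE)
  s <- 0
  t <- 2L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
    t <- t + 2L
  }
  M * N / (1 + 2 * s)
}

#' Multi-chain convergence assessment
#'
#' Between-chain R-hat (potential scale reduction, floored at 1) and
#' effective sample size per recorded parameter, plus the largest
#' cross-chain discrepancy of node-age posterior means. The run passes
#' when every node-age parameter has R-hat below the threshold and ESS
#' above it, and the age-mean discrepancy is below `ageDiscrepancy`
#' (defaults operationalize "run until convergence" at the precision
#' divergence ages are reported to).
#'
#' @param traces list of at least two equal-length [PosteriorTrace-class]
#'   objects.
#' @param rhat R-hat threshold.
#' @param ess effective-sample-size threshold.
#' @param ageDiscrepancy cross-chain node-age mean threshold in Ga.
#' @return A [ConvergenceReport-class].
#' @export
assessConvergence <- function(traces, rhat = 1.05, ess = 100,
                              ageDiscrepancy = 0.05) {
  if (!is.list(traces) || length(traces) < 2L)
    stop("insufficient-chains error: at least two chains are required")
  ns <- vapply(traces, function(x) nrow(x@samples), integer(1))
  if (length(unique(ns)) != 1L)
    stop("chains must have equal post-burn-in length")
  pars <- setdiff(names(traces[[1]]@samples), c("log_prior", "log_likelihood"))
  per <- do.call(rbind, lapply(pars, function(p) {
    ch <- lapply(traces, function(x) x@samples[[p]])
    data.frame(parameter = p, rhat = .rhat(ch), ess = .ess(ch))
  }))
  ageP <- grep("^age_", pars, value = TRUE)
  disc <- max(vapply(ageP, function(p) {
    m <- vapply(traces, function(x) mean(x@samples[[p]]), numeric(1))
    diff(range(m))
  }, numeric(1)))
  agerows <- per$parameter %in% ageP
  pass <- all(per$rhat[agerows] < rhat) && all(per$ess[agerows] > ess) &&
    disc < ageDiscrepancy
  new("ConvergenceReport", perParameter = per, maxAgeDiscrepancy = disc,
      pass = pass,
      thresholds = list(rhat = rhat, ess = ess,
                        ageDiscrepancy = ageDiscrepancy))
}
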