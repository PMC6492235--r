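setOldClass("phylo")

#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard residues in the conventional (PAML-style) order used for
#' exchangeability matrices, plus the gap symbol `-` and the missing-data
#' symbol `X`.
#' @return Character vector of the 20 residue one-letter codes.
#' @export
aminoAcids <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

.ALPHABET <- function() c(aminoAcids(), "-", "X")

#' ProteinAlignment: an aligned set of amino-acid sequences
#'
#' Holds equal-length rows over the 20 standard residues plus the gap
#' symbol `-` and the unknown symbol `X` (both treated as missing data in
#' likelihood computations). Input is case-normalized to upper case.
#'
#' @slot ids unique sequence labels.
#' @slot seqs character vector of aligned rows, parallel to `ids`.
#' @export
setClass("ProteinAlignment",
  representation(ids = "character", seqs = "character"),
  validity = function(object) {
    if (length(object@ids) != length(object@seqs))
      return("ids and seqs must have equal length")
    if (length(object@seqs) < 1L) return("alignment must contain sequences")
    if (anyDuplicated(object@ids)) return("sequence ids must be unique")
    ns <- unique(nchar(object@seqs))
    if (length(ns) != 1L)
      return(sprintf("alignment-length error: rows have unequal lengths (%s)",
                     paste(ns, collapse = ", ")))
    if (ns < 1L) return("alignment must have at least one column")
    ok <- .ALPHABET()
    for (i in seq_along(object@seqs)) {
      ch <- strsplit(object@seqs[i], "")[[1]]
      bad <- setdiff(unique(ch), ok)
      if (length(bad))
        return(sprintf("alphabet error: illegal symbol '%s' in row '%s'",
                       bad[1], object@ids[i]))
    }
    TRUE
  })

#' Construct a ProteinAlignment
#'
#' @param ids unique sequence labels.
#' @param seqs character vector of equal-length aligned rows (any case).
#' @return A validated [ProteinAlignment-class] object.
#' @examples
#' aln <- ProteinAlignment(c("s1", "s2"), c("ACDEF", "ACDEG"))
#' nSites(aln)
#' @export
ProteinAlignment <- function(ids, seqs) {
  new("ProteinAlignment", ids = as.character(ids),
      seqs = toupper(as.character(seqs)))
}

#' TimeTree: a rooted, strictly bifurcating chronogram
#'
#' Couples an `ape` phylo topology with absolute node ages (Ga before
#' present; tips are contemporaneous at age 0) and, optionally, per-node
#' evolutionary rates (substitutions/site/Ga). Node indexing follows the
#' `ape` convention: tips `1..n`, root `n+1`.
#'
#' @slot phylo the rooted binary topology (class `phylo`).
#' @slot ages numeric vector of node ages in Ga, one per node.
#' @slot rates numeric vector of node rates (length 0 when unset).
#' @export
setClass("TimeTree",
  representation(phylo = "phylo", ages = "numeric", rates = "numeric"),
  validity = function(object) {
    phy <- object@phylo
    n <- length(phy$tip.label)
    if (n < 2L) return("topology error: at least two tips are required")
    if (!ape::is.binary(phy) || !ape::is.rooted(phy))
      return("topology error: tree must be rooted and strictly bifurcating")
    nn <- n + phy$Nnode
    if (length(object@ages) != nn)
      return(sprintf("ages must have one entry per node (%d)", nn))
    if (any(abs(object@ages[seq_len(n)]) > 1e-8))
      return("age error: all tips must be contemporaneous at age 0")
    if (object@ages[n + 1L] <= 0) return("age error: root age must be > 0")
    dur <- object@ages[phy$edge[, 1]] - object@ages[phy$edge[, 2]]
    if (any(dur <= 0))
      return("age error: every parent must be strictly older than its child")
    if (length(object@rates)) {
      if (length(object@rates) != nn)
        return("rates must have one entry per node")
      if (any(object@rates <= 0)) return("rates must be > 0")
    }
    TRUE
  })

#' Construct a TimeTree from a phylo and node ages
#'
#' @param phylo rooted binary `ape` phylo object.
#' @param ages node ages in Ga (ape node order; tips must be 0).
#' @param rates optional per-node rates in substitutions/site/Ga.
#' @return A validated [TimeTree-class].
#' @export
TimeTree <- function(phylo, ages, rates = numeric(0)) {
  n <- length(phylo$tip.label)
  ages[seq_len(n)] <- 0
  new("TimeTree", phylo = phylo, ages = as.numeric(ages),
      rates = as.numeric(rates))
}

#' SubstitutionModel: amino-acid substitution process
#'
#' A time-reversible 20-state model defined by symmetric exchangeabilities
#' `S`, equilibrium frequencies `pi`, and discrete-gamma rate heterogeneity.
#' The rate matrix is `q_ij = S_ij * pi_j` with the diagonal set so rows sum
#' to zero, normalized to one expected substitution per site per unit
#' branch length.
#'
#' @slot name model name ("poisson", "lg", or a file path label).
#' @slot exchangeabilities symmetric 20 x 20 nonnegative matrix.
#' @slot frequencies equilibrium frequencies summing to 1.
#' @slot gammaShape shape of the discrete-gamma site-rate distribution.
#' @slot nCategories number of equal-probability gamma categories.
#' @export
setClass("SubstitutionModel",
  representation(name = "character", exchangeabilities = "matrix",
                 frequencies = "numeric", gammaShape = "numeric",
                 nCategories = "integer"),
  validity = function(object) {
    S <- object@exchangeabilities
    if (!all(dim(S) == c(20L, 20L))) return("exchangeabilities must be 20x20")
    if (any(S < 0)) return("exchangeabilities must be nonnegative")
    if (max(abs(S - t(S))) > 1e-8) return("exchangeabilities must be symmetric")
    p <- object@frequencies
    if (length(p) != 20L || any(p < 0) || abs(sum(p) - 1) > 1e-6)
      return("frequencies must be 20 nonnegative values summing to 1")
    if (object@gammaShape <= 0) return("gammaShape must be > 0")
    if (object@nCategories < 1L) return("nCategories must be >= 1")
    TRUE
  })

#' Calibration: a clade-anchored age constraint
#'
#' An age bound on the most recent common ancestor of a set of tips, with
#' hard or soft style. Soft bounds place a stated probability mass outside
#' each boundary (2.5% per two-sided boundary, 5% for a single minimum, in
#' the conventional parameterization).
#'
#' @slot clade tip labels whose MRCA is constrained.
#' @slot minAge minimum age in Ga (`NA` if absent).
#' @slot maxAge maximum age in Ga (`NA` if absent).
#' @slot style `"hard"` or `"soft"`.
#' @slot tailLow probability mass below the minimum (soft style).
#' @slot tailHigh probability mass above the maximum (soft style).
#' @slot label optional calibration name.
#' @export
setClass("Calibration",
  representation(clade = "character", minAge = "numeric", maxAge = "numeric",
                 style = "character", tailLow = "numeric",
                 tailHigh = "numeric", label = "character"),
  validity = function(object) {
    if (is.na(object@minAge) && is.na(object@maxAge))
      return("at least one bound must be present")
    if (!is.na(object@minAge) && !is.na(object@maxAge) &&
        object@minAge >= object@maxAge)
      return("minAge must be < maxAge")
    if (!object@style %in% c("hard", "soft"))
      return("style must be 'hard' or 'soft'")
    if (object@tailLow < 0 || object@tailLow >= 0.5 ||
        object@tailHigh < 0 || object@tailHigh >= 0.5)
      return("tail masses must be in [0, 0.5)")
    TRUE
  })

#' Construct a Calibration
#'
#' @param clade character vector of tip labels (the constrained node is
#'   their MRCA).
#' @param minAge,maxAge bounds in Ga; `NA` for an absent bound.
#' @param style `"hard"` or `"soft"`.
#' @param tailLow,tailHigh soft-tail masses. Defaults follow the
#'   convention: 0.025 per boundary when both are present, 0.05 for a
#'   single minimum bound.
#' @param label optional name.
#' @return A [Calibration-class].
#' @export
calibration <- function(clade, minAge = NA_real_, maxAge = NA_real_,
                        style = "soft", tailLow = NULL, tailHigh = NULL,
                        label = "") {
  single_min <- !is.na(minAge) && is.na(maxAge)
  if (is.null(tailLow)) tailLow <- if (single_min) 0.05 else 0.025
  if (is.null(tailHigh)) tailHigh <- 0.025
  if (is.na(minAge)) tailLow <- 0
  if (is.na(maxAge)) tailHigh <- 0
  new("Calibration", clade = as.character(clade), minAge = as.numeric(minAge),
      maxAge = as.numeric(maxAge), style = style,
      tailLow = as.numeric(tailLow), tailHigh = as.numeric(tailHigh),
      label = label)
}

#' RootPrior: truncated-normal prior on the root age
#'
#' @slot mean prior mean in Ga.
#' @slot sd prior standard deviation in Ga.
#' @export
setClass("RootPrior",
  representation(mean = "numeric", sd = "numeric"),
  validity = function(object) {
    if (object@mean <= 0) return("root prior mean must be > 0")
    if (object@sd <= 0) return("root prior sd must be > 0")
    TRUE
  })

#' Construct a RootPrior
#' @param mean,sd normal prior mean and standard deviation in Ga.
#' @return A [RootPrior-class].
#' @export
rootPrior <- function(mean, sd) new("RootPrior", mean = mean, sd = sd)

#' CalibrationSet: calibrations plus the root prior
#'
#' @slot calibrations list of [Calibration-class] objects.
#' @slot root the [RootPrior-class].
#' @export
setClass("CalibrationSet",
  representation(calibrations = "list", root = "RootPrior"),
  validity = function(object) {
    ok <- vapply(object@calibrations, function(x) is(x, "Calibration"),
                 logical(1))
    if (length(ok) && !all(ok)) return("calibrations must be Calibration objects")
    TRUE
  })

#' Construct a CalibrationSet
#' @param calibrations list of [Calibration-class] objects.
#' @param root a [RootPrior-class].
#' @return A [CalibrationSet-class].
#' @export
calibrationSet <- function(calibrations = list(), root) {
  new("CalibrationSet", calibrations = calibrations, root = root)
}

#' ClockModel: the relaxed-clock rate process
#'
#' Either an autocorrelated log-normal process (`"acln"`; a node's log-rate
#' is normal around its parent's with variance `sigma2 * dt`, with the
#' half-variance mean correction that keeps `E[r_child] = r_parent`), or an
#' uncorrelated gamma process (`"ugam"`; i.i.d. mean-one gamma multipliers
#' times a global rate).
#'
#' Hyperpriors on `sigma2` (or the gamma shape), the site-rate shape
#' `alpha`, and the root/global rate are log-normal with unit standard
#' deviation on the log scale, centred on the values stored here.
#'
#' @slot kind `"acln"` or `"ugam"`.
#' @slot sigma2 autocorrelation variance per Ga (acln kind).
#' @slot shape branch-rate gamma shape (ugam kind).
#' @slot rootRate root (acln) or global (ugam) rate, substitutions/site/Ga.
#' @export
setClass("ClockModel",
  representation(kind = "character", sigma2 = "numeric", shape = "numeric",
                 rootRate = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("acln", "ugam"))
      return("kind must be 'acln' or 'ugam'")
    if (object@kind == "acln" && object@sigma2 <= 0)
      return("sigma2 must be > 0")
    if (object@kind == "ugam" && object@shape <= 0)
      return("shape must be > 0")
    if (object@rootRate <= 0) return("rootRate must be > 0")
    TRUE
  })

#' Construct a ClockModel
#' @param kind `"acln"` (autocorrelated log-normal) or `"ugam"`
#'   (uncorrelated gamma).
#' @param sigma2 autocorrelation variance per Ga (acln).
#' @param shape branch-rate gamma shape (ugam).
#' @param rootRate root/global rate in substitutions/site/Ga.
#' @return A [ClockModel-class].
#' @export
clockModel <- function(kind = c("acln", "ugam"), sigma2 = 0.1, shape = 1,
                       rootRate = 0.5) {
  kind <- match.arg(kind)
  new("ClockModel", kind = kind, sigma2 = sigma2, shape = shape,
      rootRate = rootRate)
}

#' PosteriorTrace: MCMC samples from a dating run
#'
#' One row per recorded iteration; columns hold internal-node ages
#' (`age_<node>`), node rates (`rate_<node>`), hyperparameters, and the
#' log-prior/log-likelihood. Node columns are identified by internal node
#' number in the fixed topology, with tip-set labels stored alongside.
#'
#' @slot samples data.frame of recorded states.
#' @slot tree the fixed [TimeTree-class] topology the run used.
#' @slot chainId chain identifier.
#' @slot seed master seed used for this chain.
#' @slot iterations,burnin,thinning sampler configuration.
#' @slot nodeLabels per-internal-node tip-set labels.
#' @export
setClass("PosteriorTrace",
  representation(samples = "data.frame", tree = "TimeTree",
                 chainId = "integer", seed = "integer",
                 iterations = "integer", burnin = "integer",
                 thinning = "integer", nodeLabels = "character"),
  validity = function(object) {
    expected <- (object@iterations - object@burnin) %/% object@thinning
    if (nrow(object@samples) != expected)
      return("record count must equal (iterations - burnin)/thinning")
    TRUE
  })

#' ConvergenceReport: multi-chain diagnostics
#'
#' @slot perParameter data.frame with between-chain R-hat and effective sample size
#'   per parameter.
#' @slot maxAgeDiscrepancy largest cross-chain difference of node-age
#'   posterior means (Ga).
#' @slot pass TRUE when all thresholds are met.
#' @slot thresholds the thresholds applied.
#' @export
setClass("ConvergenceReport",
  representation(perParameter = "data.frame", maxAgeDiscrepancy = "numeric",
                 pass = "logical", thresholds = "list"))
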