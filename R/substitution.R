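#' Build an amino-acid substitution model
#'
#' `"poisson"` uses equal exchangeabilities and equal frequencies (1/20).
#' `"lg"` uses the LG empirical exchangeabilities and frequencies (taken
#' from the model tables distributed with \pkg{phangorn}). A file path is
#' read with [readModelFile()] (PAML layout). Site-rate heterogeneity is
#' discrete-gamma with `nCategories` equal-probability categories.
#'
#' @param name `"poisson"`, `"lg"`, or a path to a PAML-format model file.
#' @param gammaShape shape `alpha` of the gamma site-rate distribution.
#' @param nCategories number of discrete categories (4 is the conventional
#'   choice).
#' @param frequencies optional length-20 override of the equilibrium
#'   frequencies (e.g. observed frequencies).
#' @return A [SubstitutionModel-class].
#' @examples
#' m <- substitutionModel("poisson", gammaShape = 0.5)
#' transitionMatrix(m, 0)[1, 1]  # identity at zero distance
#' @export
substitutionModel <- function(name = "poisson", gammaShape = 1,
                              nCategories = 4L, frequencies = NULL) {
  if (name == "poisson") {
    S <- matrix(1, 20, 20); diag(S) <- 0
    pi <- rep(1 / 20, 20)
  } else if (name == "lg") {
    lg <- .lgConstants()
    S <- .lowerToSym(lg$Q)
    pi <- lg$bf
  } else {
    mf <- readModelFile(name)
    S <- mf$exchangeabilities
    pi <- mf$frequencies
    name <- basename(name)
  }
  if (!is.null(frequencies)) {
    stopifnot(length(frequencies) == 20L)
    pi <- frequencies / sum(frequencies)
  }
  dimnames(S) <- list(aminoAcids(), aminoAcids())
  names(pi) <- aminoAcids()
  new("SubstitutionModel", name = name, exchangeabilities = S,
      frequencies = as.numeric(pi) / sum(pi), gammaShape = gammaShape,
      nCategories = as.integer(nCategories))
}

# LG exchangeabilities/frequencies from phangorn's amino-acid model tables
.lgConstants <- function() {
  getter <- get("getModelAA", envir = asNamespace("phangorn"))
  local({
    getter("LG", bf = TRUE, Q = TRUE)
    list(Q = Q, bf = bf)
  })
}

# 190 lower-triangle values (row-wise, rows 2..20) -> symmetric 20x20
.lowerToSym <- function(vals) {
  S <- matrix(0, 20, 20)
  S[upper.tri(S)] <- 0
  k <- 1L
  for (i in 2:20) for (j in 1:(i - 1)) {
    S[i, j] <- S[j, i] <- vals[k]
    k <- k + 1L
  }
  S
}

#' Read a substitution-model file (PAML layout)
#'
#' Whitespace-separated numbers: the 190 lower-triangle exchangeabilities
#' (rows 2..20 of the symmetric matrix, row-wise) followed by the 20
#' equilibrium frequencies, in the standard residue order
#' (`aminoAcids()`).
#'
#' @param path file to read.
#' @return List with `exchangeabilities` (20 x 20 symmetric matrix) and
#'   `frequencies`.
#' @export
readModelFile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#")
  if (length(vals) < 210L)
    stop("model file must contain 190 exchangeabilities + 20 frequencies; ",
         "found ", length(vals), " numbers")
  S <- .lowerToSym(vals[1:190])
  pi <- vals[191:210]
  if (any(pi < 0) || sum(pi) <= 0) stop("invalid frequencies in model file")
  list(exchangeabilities = S, frequencies = pi / sum(pi))
}

# normalized rate matrix Q with one expected substitution per unit length
.rateMatrix <- function(model) {
  S <- model@exchangeabilities
  pi <- model@frequencies
  Q <- S * rep(pi, each = 20)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# eigen decomposition of Q via the symmetrized form (reversible models)
.eigenQ <- function(model) {
  pi <- model@frequencies
  Q <- .rateMatrix(model)
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = diag(1 / d) %*% e$vectors, Uinv = t(e$vectors) %*% diag(d),
       lambda = e$values)
}

#' Transition-probability matrix P = exp(Q d)
#'
#' @param model a [SubstitutionModel-class].
#' @param branchLength expected substitutions per site (>= 0).
#' @return A 20 x 20 stochastic matrix (rows sum to 1).
#' @export
transitionMatrix <- function(model, branchLength) {
  if (branchLength < 0) stop("contract error: branch length must be >= 0")
  e <- .eigenQ(model)
  P <- e$U %*% diag(exp(e$lambda * branchLength)) %*% e$Uinv
  P[P < 0] <- 0
  dimnames(P) <- list(aminoAcids(), aminoAcids())
  P
}

#' Discrete-gamma category rates
#'
#' Mean-one discretization by equal-probability categories; each category's
#' rate is the mean of Gamma(`alpha`, `alpha`) over its quantile bin.
#'
#' @param alpha gamma shape (> 0).
#' @param nCategories number of categories (>= 1).
#' @return Numeric vector of `nCategories` rates with mean 1.
#' @export
gammaCategoryRates <- function(alpha, nCategories) {
  stopifnot(alpha > 0, nCategories >= 1)
  n <- as.integer(nCategories)
  if (n == 1L) return(1)
  q <- qgamma(seq(0, 1, length.out = n + 1L), shape = alpha, rate = alpha)
  cdf1 <- pgamma(q, shape = alpha + 1, rate = alpha)
  r <- n * diff(cdf1)
  r / mean(r)  # guard rounding; the analytic mean is already 1
}

# --- pruning engine plumbing -------------------------------------------

# integer states for an alignment in tree tip order; 0..19 residues,
# 20 = gap/unknown (missing data)
.tipStates <- function(alignment, tree) {
  ids <- alignmentIds(alignment)
  tips <- tipNames(tree)
  if (!setequal(ids, tips) || length(ids) != length(tips))
    stop("mapping error: alignment ids and tree tips differ (",
         paste(symdiff <- union(setdiff(ids, tips), setdiff(tips, ids)),
               collapse = ", "), ")")
  m <- as.matrix(alignment)[tips, , drop = FALSE]
  code <- match(m, aminoAcids())
  code[is.na(code)] <- 21L
  matrix(code - 1L, nrow = length(tips))  # tips x sites, 0-based
}

# collapse identical site patterns; returns list(states = npat x ntip,
# weights, map = site -> pattern)
.compressPatterns <- function(states01) {
  keys <- apply(states01, 2, paste, collapse = ",")
  u <- unique(keys)
  map <- match(keys, u)
  w <- tabulate(map, nbins = length(u))
  list(states = t(states01[, match(u, keys), drop = FALSE]),
       weights = as.numeric(w), map = map)
}

.makeEngine <- function(alignment, tree, model) {
  states <- .tipStates(alignment, tree)     # ntip x nsite
  pat <- .compressPatterns(states)
  phy <- tree@phylo
  par <- .parentVec(phy)
  par0 <- ifelse(is.na(par), -1L, par - 1L)
  eng <- .le_create(length(phy$tip.label), as.integer(par0),
                    matrix(as.integer(pat$states), nrow = nrow(pat$states)),
                    pat$weights, model@nCategories)
  e <- .eigenQ(model)
  .le_set_model(eng, e$U, e$Uinv, e$lambda, model@frequencies)
  list(ptr = eng, map = pat$map, weights = pat$weights)
}

# expected substitutions/site on the edge above each node;
# branchRates "mean": arithmetic mean of endpoint node rates (autocorrelated
# convention); "node": the child node's own rate (uncorrelated convention)
.edgeLengths <- function(tree, ages = NULL, rates = NULL,
                         branchRates = c("mean", "node")) {
  branchRates <- match.arg(branchRates)
  phy <- tree@phylo
  if (is.null(ages)) ages <- tree@ages
  if (is.null(rates)) rates <- tree@rates
  if (!length(rates)) stop("tree has no rates; set nodeRates() first")
  par <- .parentVec(phy)
  nn <- length(ages)
  L <- numeric(nn)
  for (j in seq_len(nn)) {
    if (is.na(par[j])) next
    dt <- ages[par[j]] - ages[j]
    br <- if (branchRates == "mean") (rates[par[j]] + rates[j]) / 2 else rates[j]
    L[j] <- br * dt
  }
  L
}

#' Pruning log-likelihood of an alignment on a dated, rated tree
#'
#' Felsenstein pruning over sites with equal-weight averaging over the
#' discrete-gamma categories. Gap and `X` characters contribute a vector of
#' ones at the tip (missing data). Branch lengths in expected
#' substitutions/site are `branch_rate * (t_parent - t_child)`, with the
#' branch rate the arithmetic mean of the endpoint node rates by default.
#'
#' @param alignment a [ProteinAlignment-class]; ids must match tree tips.
#' @param tree a [TimeTree-class] with ages and rates.
#' @param model a [SubstitutionModel-class].
#' @param branchRates `"mean"` (autocorrelated-clock convention) or
#'   `"node"` (the child's own rate).
#' @return A `LikelihoodResult` list: `log_likelihood` and `per_site`
#'   (natural-log site likelihoods summing to the total).
#' @export
logLikelihood <- function(alignment, tree, model,
                          branchRates = c("mean", "node")) {
  branchRates <- match.arg(branchRates)
  eng <- .makeEngine(alignment, tree, model)
  L <- .edgeLengths(tree, branchRates = branchRates)
  catr <- gammaCategoryRates(model@gammaShape, model@nCategories)
  total <- .le_full(eng$ptr, L, catr)
  patl <- .le_pattern_loglik(eng$ptr)
  res <- list(log_likelihood = total, per_site = patl[eng$map])
  class(res) <- "LikelihoodResult"
  res
}

#' @export
print.LikelihoodResult <- function(x, ...) {
  cat(sprintf("log-likelihood: %.6f over %d sites\n", x$log_likelihood,
              length(x$per_site)))
  invisible(x)
}
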