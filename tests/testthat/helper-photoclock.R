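# shared builders; everything is generated in code at test time

poissonModel <- function(nCategories = 1L, alpha = 1) {
  substitutionModel("poisson", gammaShape = alpha,
                    nCategories = nCategories)
}

# a random symmetric exchangeability model written through the PAML-format
# reader, so tests exercise the file path too
randomModel <- function(seed, nCategories = 1L, alpha = 1) {
  set.seed(seed)
  S <- matrix(runif(400, 0.1, 2), 20)
  S <- (S + t(S)) / 2
  pv <- runif(20, 0.5, 2); pv <- pv / sum(pv)
  f <- tempfile(fileext = ".paml")
  lower <- numeric(0)
  for (i in 2:20) for (j in 1:(i - 1)) lower <- c(lower, S[i, j])
  writeLines(c(paste(format(lower, digits = 17), collapse = " "),
               paste(format(pv, digits = 17), collapse = " ")), f)
  substitutionModel(f, gammaShape = alpha, nCategories = nCategories)
}

fourTipTree <- function(rates = c(0.3, 0.5, 0.9, 0.2, 0.7, 0.4, 0.6)) {
  tr <- readTimeTree("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  if (!is.null(rates)) nodeRates(tr) <- rates
  tr
}

randomAlignment <- function(ids, nSites, seed, withGaps = FALSE) {
  set.seed(seed)
  pool <- if (withGaps) c(aminoAcids(), "-", "X") else aminoAcids()
  ProteinAlignment(ids, vapply(ids, function(i)
    paste(sample(pool, nSites, replace = TRUE), collapse = ""), character(1)))
}

# independent Poisson same-state transition probability (equal-frequency
# closed form)
poissonPii <- function(d) 1 / 20 + (19 / 20) * exp(-20 * d / 19)

# brute-force pruning oracle: exhaustive enumeration over internal states
# of the fixed 4-tip topology ((A,B),(C,D)) with gamma averaging
bruteForceLoglik <- function(aln, tree, model) {
  ages <- nodeAges(tree); rates <- nodeRates(tree)
  br <- function(p, c) (rates[p] + rates[c]) / 2 * (ages[p] - ages[c])
  catr <- gammaCategoryRates(model@gammaShape, model@nCategories)
  pv <- model@frequencies
  aa <- aminoAcids()
  X <- as.matrix(aln)[c("A", "B", "C", "D"), , drop = FALSE]
  tipvec <- function(ch) if (ch %in% aa) as.numeric(aa == ch) else rep(1, 20)
  total <- 0
  for (s in seq_len(ncol(X))) {
    likc <- 0
    for (cc in seq_along(catr)) {
      P61 <- transitionMatrix(model, br(6, 1) * catr[cc])
      P62 <- transitionMatrix(model, br(6, 2) * catr[cc])
      P73 <- transitionMatrix(model, br(7, 3) * catr[cc])
      P74 <- transitionMatrix(model, br(7, 4) * catr[cc])
      P56 <- transitionMatrix(model, br(5, 6) * catr[cc])
      P57 <- transitionMatrix(model, br(5, 7) * catr[cc])
      v <- tipvec(X[1, s]); w <- tipvec(X[2, s])
      x <- tipvec(X[3, s]); y <- tipvec(X[4, s])
      m6 <- (P61 %*% v) * (P62 %*% w)
      m7 <- (P73 %*% x) * (P74 %*% y)
      lik <- 0
      for (r5 in 1:20)
        lik <- lik + pv[r5] * sum(P56[r5, ] * m6) * sum(P57[r5, ] * m7)
      likc <- likc + lik / length(catr)
    }
    total <- total + log(likc)
  }
  total
}

# soft calibrations centred on the true ages of k deep clades
trueAgeCalibrations <- function(tree, k = 3, width = 0.1) {
  n <- length(tipNames(tree))
  ages <- nodeAges(tree)
  internal <- (n + 1L):(2L * n - 1L)
  ord <- internal[order(ages[internal], decreasing = TRUE)]
  picks <- ord[round(seq(2, length(ord) - 2, length.out = k))]
  lapply(picks, function(j)
    calibration(cladeTips(tree, j), minAge = (1 - width) * ages[j],
                maxAge = (1 + width) * ages[j], style = "soft"))
}
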