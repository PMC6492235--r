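#' Pairwise percent identity between two aligned rows
#'
#' Identity is 100 times the number of columns where both rows carry the
#' same non-gap residue, divided by the larger of the two non-gap lengths
#' (the longest sequence is taken as 100%, applied column-wise on the
#' master alignment). `X` never matches and does not count as a gap.
#'
#' @param a,b aligned rows: equal-length character strings, or two ids
#'   into `alignment`.
#' @param alignment optional [ProteinAlignment-class] to look `a`/`b` up
#'   in.
#' @param mask optional logical/integer column mask restricting the
#'   comparison (e.g. to the trimmed core of the alignment).
#' @return Percent identity in `[0, 100]`; symmetric in its arguments.
#' @examples
#' percentIdentity("ACDEF", "ACDE-")  # 80: 4 matches / longest length 5
#' @export
percentIdentity <- function(a, b, alignment = NULL, mask = NULL) {
  if (!is.null(alignment)) {
    a <- alignment@seqs[match(a, alignment@ids)]
    b <- alignment@seqs[match(b, alignment@ids)]
    if (anyNA(c(a, b))) stop("mapping error: id not found in alignment")
  }
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  if (length(va) != length(vb))
    stop("alignment-length error: rows must come from the same alignment")
  if (!is.null(mask)) { va <- va[mask]; vb <- vb[mask] }
  ga <- va != "-"; gb <- vb != "-"
  la <- sum(ga); lb <- sum(gb)
  if (la == 0 && lb == 0)
    stop("undefined-identity error: both rows are all-gap")
  matches <- sum(ga & gb & va == vb & va != "X")
  100 * matches / max(la, lb)
}

#' Identity table for labelled pairs on one alignment
#'
#' @param alignment a [ProteinAlignment-class].
#' @param pairs data.frame with columns `label_a`, `label_b` and
#'   `divergence_time_Ga` (an existing `identity` column is kept as-is).
#' @param mask optional column mask passed to [percentIdentity()].
#' @return The input data.frame with an `identity` column.
#' @export
identityPairTable <- function(alignment, pairs, mask = NULL) {
  if (is.null(pairs$identity))
    pairs$identity <- mapply(function(a, b)
      percentIdentity(a, b, alignment = alignment, mask = mask),
      pairs$label_a, pairs$label_b)
  pairs
}

#' Linear regression of percent identity on divergence time
#'
#' Ordinary least squares of identity (%) on time (Ga); the slope is in
#' percent per Ga (divide by 10 for percent per 100 Ma).
#'
#' @param pairs data.frame with columns `identity` and
#'   `divergence_time_Ga` (or `time`).
#' @return A `LinearFit` list: `slope`, `intercept`, `r_squared`, `n`.
#' @export
fitIdentityRegression <- function(pairs) {
  t <- if (!is.null(pairs$divergence_time_Ga)) pairs$divergence_time_Ga else
    pairs$time
  y <- pairs$identity
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(t) < 2L) stop("at least 2 pairs are required")
  if (diff(range(t)) == 0)
    stop("singular-fit error: all divergence times are equal")
  fit <- lm(y ~ t)
  out <- list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
              r_squared = suppressWarnings(summary(fit)$r.squared),
              n = length(t),
              residuals = unname(fit$residuals), times = t)
  class(out) <- "LinearFit"
  out
}

#' @export
print.LinearFit <- function(x, ...) {
  cat(sprintf(
    "identity ~ time: slope %.3f %%/Ga (%.3f %%/100 Ma), intercept %.2f %%, r^2 %.3f, n = %d\n",
    x$slope, x$slope / 10, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Extrapolate a linear identity decay to a target identity
#'
#' Solves `target = intercept + slope * t` for `t`; used to show that
#' constant Proterozoic-style rates cannot reach deep-divergence identity
#' levels (e.g. 29% or 17%) within the age of the Earth.
#'
#' @param fit a `LinearFit` from [fitIdentityRegression()] (slope must be
#'   negative).
#' @param targetIdentity percent identity to reach.
#' @return Time in Ga.
#' @export
extrapolateTimeToIdentity <- function(fit, targetIdentity) {
  if (fit$slope >= 0)
    stop("no-crossing error: slope must be negative to reach the target")
  (targetIdentity - fit$intercept) / fit$slope
}

#' Read an identity-pair table (TSV)
#'
#' @param path TSV with columns `label_a`, `label_b`,
#'   `divergence_time_Ga`, and optionally `identity`.
#' @return data.frame.
#' @export
readIdentityPairs <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
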