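#' @name accessors
#' @title Accessors for photoclock classes
#' @param x,object an object.
#' @param value replacement value.
#' @param ... unused.
#' @return The slot contents (or the modified object for setters).
NULL

#' @rdname accessors
#' @export
setGeneric("alignmentIds", function(x) standardGeneric("alignmentIds"))
#' @rdname accessors
#' @export
setMethod("alignmentIds", "ProteinAlignment", function(x) x@ids)

#' @rdname accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname accessors
#' @export
setMethod("nSites", "ProteinAlignment", function(x) nchar(x@seqs[1]))

#' @rdname accessors
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))
#' @rdname accessors
#' @export
setMethod("nSequences", "ProteinAlignment", function(x) length(x@ids))

#' Character matrix view of an alignment (rows = sequences)
#' @param x a [ProteinAlignment-class].
#' @param ... unused.
#' @return A character matrix with rownames set to the sequence ids.
#' @export
setMethod("as.matrix", "ProteinAlignment", function(x, ...) {
  m <- do.call(rbind, strsplit(x@seqs, ""))
  rownames(m) <- x@ids
  m
})

#' @rdname accessors
#' @export
setGeneric("nodeAges", function(x) standardGeneric("nodeAges"))
#' @rdname accessors
#' @export
setMethod("nodeAges", "TimeTree", function(x) x@ages)

#' @rdname accessors
#' @export
setGeneric("nodeRates", function(x) standardGeneric("nodeRates"))
#' @rdname accessors
#' @export
setMethod("nodeRates", "TimeTree", function(x)
  if (length(x@rates)) x@rates else NULL)

#' @rdname accessors
#' @export
setGeneric("nodeRates<-", function(x, value) standardGeneric("nodeRates<-"))
#' @rdname accessors
#' @export
setMethod("nodeRates<-", "TimeTree", function(x, value) {
  x@rates <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setGeneric("tipNames", function(x) standardGeneric("tipNames"))
#' @rdname accessors
#' @export
setMethod("tipNames", "TimeTree", function(x) x@phylo$tip.label)

#' @rdname accessors
#' @export
setGeneric("rootAge", function(x) standardGeneric("rootAge"))
#' @rdname accessors
#' @export
setMethod("rootAge", "TimeTree", function(x)
  x@ages[length(x@phylo$tip.label) + 1L])

#' @rdname accessors
#' @export
setGeneric("asPhylo", function(x) standardGeneric("asPhylo"))
#' @rdname accessors
#' @export
setMethod("asPhylo", "TimeTree", function(x) x@phylo)

#' @rdname accessors
#' @export
setGeneric("traceSamples", function(x) standardGeneric("traceSamples"))
#' @rdname accessors
#' @export
setMethod("traceSamples", "PosteriorTrace", function(x) x@samples)

setMethod("show", "ProteinAlignment", function(object) {
  cat(sprintf("ProteinAlignment: %d sequences x %d sites\n",
              nSequences(object), nSites(object)))
  ids <- head(object@ids, 5)
  cat("  ids:", paste(ids, collapse = ", "),
      if (nSequences(object) > 5) "..." else "", "\n")
})

setMethod("show", "TimeTree", function(object) {
  cat(sprintf("TimeTree: %d tips, root age %.3f Ga%s\n",
              length(object@phylo$tip.label), rootAge(object),
              if (length(object@rates)) ", rates set" else ""))
})

setMethod("show", "SubstitutionModel", function(object) {
  cat(sprintf("SubstitutionModel '%s': +G (alpha = %.3g, %d categories)\n",
              object@name, object@gammaShape, object@nCategories))
})

setMethod("show", "Calibration", function(object) {
  b <- c(if (!is.na(object@minAge)) sprintf("min %.3g Ga", object@minAge),
         if (!is.na(object@maxAge)) sprintf("max %.3g Ga", object@maxAge))
  cat(sprintf("Calibration%s [%s, %s] on MRCA of %d tips\n",
              if (nzchar(object@label)) paste0(" '", object@label, "'") else "",
              object@style, paste(b, collapse = ", "),
              length(object@clade)))
})

setMethod("show", "CalibrationSet", function(object) {
  cat(sprintf("CalibrationSet: %d calibrations, root prior N(%.3g, %.3g) Ga\n",
              length(object@calibrations), object@root@mean, object@root@sd))
})

setMethod("show", "PosteriorTrace", function(object) {
  cat(sprintf(
    "PosteriorTrace: chain %d, %d recorded states (%d iter, burn-in %d, thin %d)\n",
    object@chainId, nrow(object@samples), object@iterations, object@burnin,
    object@thinning))
})

setMethod("show", "ConvergenceReport", function(object) {
  cat(sprintf("ConvergenceReport: %s\n",
              if (object@pass) "PASS" else "FAIL"))
  cat(sprintf("  max R-hat        %.4f (threshold %.2f)\n",
              max(object@perParameter$rhat, na.rm = TRUE),
              object@thresholds$rhat))
  cat(sprintf("  min ESS          %.0f (threshold %.0f)\n",
              min(object@perParameter$ess, na.rm = TRUE),
              object@thresholds$ess))
  cat(sprintf("  max age-mean gap %.4f Ga (threshold %.2f)\n",
              object@maxAgeDiscrepancy, object@thresholds$ageDiscrepancy))
})
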