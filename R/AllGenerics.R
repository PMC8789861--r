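# Generics, accessors and show methods.

#' Extract spacer sequences
#' @param x a [GuideSet]
#' @return named character vector of 20-nt spacers
#' @export
setGeneric("spacers", function(x) standardGeneric("spacers"))

#' @rdname spacers
#' @export
setMethod("spacers", "GuideSet", function(x) setNames(x@spacers, x@ids))

#' Guide identifiers
#' @param x a [GuideSet]
#' @export
setGeneric("guideIds", function(x) standardGeneric("guideIds"))

#' @rdname guideIds
#' @export
setMethod("guideIds", "GuideSet", function(x) x@ids)

#' Number of elements
#' @param x a [GuideSet] or [OligoLibrary]
#' @export
setMethod("length", "GuideSet", function(x) length(x@spacers))

#' Subset a GuideSet
#' @param x a [GuideSet]
#' @param i index
#' @param j,...,drop ignored
#' @export
setMethod("[", "GuideSet", function(x, i, j, ..., drop = TRUE) {
  new("GuideSet", spacers = x@spacers[i], ids = x@ids[i])
})

#' Designs of an oligo library
#' @param x an [OligoLibrary]
#' @return the underlying data.frame, one row per construct
#' @export
setGeneric("designs", function(x) standardGeneric("designs"))

#' @rdname designs
#' @export
setMethod("designs", "OligoLibrary", function(x) x@designs)

#' @export
setMethod("length", "OligoLibrary", function(x) nrow(x@designs))

#' Transition matrix of a cleavage model
#' @param x a [CleavageModel]
#' @return the 4 x 5 row-stochastic matrix
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))

#' @rdname transitionMatrix
#' @export
setMethod("transitionMatrix", "CleavageModel", function(x) x@P)

#' Numeric values of a parameter matrix
#' @param x a [MismatchMatrix] or [CombinatorialMatrix]
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname values
#' @export
setMethod("values", "MismatchMatrix", function(x) x@values)

#' @rdname values
#' @export
setMethod("values", "CombinatorialMatrix", function(x) x@values)

setMethod("show", "GuideSet", function(object) {
  cat("GuideSet with", length(object), "guides\n")
  n <- min(3L, length(object))
  if (n > 0L)
    cat(paste0("  ", object@ids[seq_len(n)], ": ",
               object@spacers[seq_len(n)], collapse = "\n"), "\n")
  if (length(object) > n) cat("  ...\n")
})

setMethod("show", "TargetSite", function(object) {
  cat("TargetSite ", object@protospacer, "|", object@pam,
      if (!is.na(object@start))
        sprintf(" (%s:%d-%d%s)", object@contig, object@start, object@end,
                object@strand), "\n", sep = "")
})

setMethod("show", "OligoLibrary", function(object) {
  d <- object@designs
  cat("OligoLibrary with", nrow(d), "constructs (",
      paste(names(table(d$layout)), table(d$layout), collapse = ", "), ")\n")
})

setMethod("show", "CleavageModel", function(object) {
  cat("CleavageModel (4 states x 5 outcomes)\n")
  print(round(object@P, 3))
})

setMethod("show", "MismatchMatrix", function(object) {
  v <- object@values
  cat("MismatchMatrix (M1): 12 pairings x 20 positions; range ",
      sprintf("%.3g-%.3g\n", min(v), max(v)), sep = "")
})

setMethod("show", "CombinatorialMatrix", function(object) {
  ok <- !is.na(object@values[upper.tri(object@values)])
  cat("CombinatorialMatrix (M2/delta): 20 x 20,", sum(ok),
      "of 190 position pairs observed\n")
})

setMethod("show", "GmtModel", function(object) {
  cat("GmtModel:", nrow(object@W), "dinucleotide kernel(s), dense 19 ->",
      "1 output (log-GMT scale)\n")
})

setMethod("show", "EnergyTable", function(object) {
  cat("EnergyTable [", object@label, "]: 16 dinucleotide steps,",
      "DNA:DNA and RNA:DNA\n")
})

setMethod("show", "KineticParameters", function(object) {
  cat(sprintf(paste0("KineticParameters: PAM gain %.2f, match gain %.2f,",
                     " mismatch cost %.2f (isolated) / %.2f (bubble ext.),",
                     " attempt rate %.2f [kB*T]\n"),
              object@pamGain, object@matchGain, object@mismatchCost,
              object@bubbleExtensionCost, object@attemptRate))
})

setMethod("show", "FreeEnergyLandscape", function(object) {
  cat("FreeEnergyLandscape (", object@mode, "): ", length(object@G),
      " states, max barrier ", sprintf("%.2f", maxBarrier(object)),
      " kB*T\n", sep = "")
})

setMethod("show", "MoffParameters", function(object) {
  cat("MoffParameters v", object@version, ": M1 + M2",
      if (is.null(object@gmtModel)) " (no GMT model)" else " + GMT model",
      ", c = ", object@c, "\n", sep = "")
})
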