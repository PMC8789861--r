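# S4 classes for the central data objects.

#' A set of 20-nt guide (spacer) sequences
#'
#' Spacers are stored as DNA-alphabet strings (U is accepted on input and
#' converted to T); position 1 of a spacer, in the PAM-proximal coordinate
#' system used throughout the package, is the \emph{last} character of the
#' string (the 3' end, adjacent to the PAM).
#'
#' @slot spacers character vector of 20-nt sequences over \{A,C,G,T\}
#' @slot ids character vector of unique identifiers, same length
#' @export
setClass("GuideSet", representation(spacers = "character", ids = "character"))

setValidity("GuideSet", function(object) {
  if (length(object@spacers) != length(object@ids))
    return("spacers and ids must have equal length")
  if (any(nchar(object@spacers) != 20L))
    return("every spacer must be exactly 20 nt")
  if (any(grepl("[^ACGT]", object@spacers)))
    return("spacers must be over the alphabet {A,C,G,T} (U is mapped to T)")
  if (anyDuplicated(object@ids))
    return("guide ids must be unique")
  TRUE
})

#' A 23-bp PAM-endowed target site
#'
#' @slot protospacer 20-nt DNA string (protospacer strand, 5'->3';
#'   PAM-proximal position 1 is the last character)
#' @slot pam 3-nt PAM immediately 3' of the protospacer
#' @slot contig,start,end,strand optional genomic coordinates
#'   (0-based half-open; end - start = 23)
#' @export
setClass("TargetSite", representation(
  protospacer = "character", pam = "character",
  contig = "character", start = "integer", end = "integer",
  strand = "character"))

setValidity("TargetSite", function(object) {
  if (nchar(object@protospacer) != 20L) return("protospacer must be 20 nt")
  if (nchar(object@pam) != 3L) return("pam must be 3 nt")
  if (grepl("[^ACGT]", paste0(object@protospacer, object@pam)))
    return("target sequence must be over {A,C,G,T}")
  if (!object@strand %in% c("+", "-", "*")) return("strand must be +, - or *")
  if (!is.na(object@start) && !is.na(object@end) &&
      object@end - object@start != 23L)
    return("end - start must equal 23")
  TRUE
})

#' An oligonucleotide library of dual-target (or single/target-only) designs
#'
#' Backed by a data.frame with one row per construct; see
#' [designDualTargetLibrary()] for the columns.
#'
#' @slot designs data.frame of construct descriptions
#' @export
setClass("OligoLibrary", representation(designs = "data.frame"))

setValidity("OligoLibrary", function(object) {
  need <- c("construct_id", "guide_id", "design_type", "layout",
            "barcode1", "barcode2", "off_target", "on_target", "spacer")
  miss <- setdiff(need, names(object@designs))
  if (length(miss)) return(paste("missing design columns:",
                                 paste(miss, collapse = ", ")))
  key <- paste(object@designs$barcode1, object@designs$barcode2)
  if (anyDuplicated(key)) return("barcode pairs must be unique")
  TRUE
})

#' The cleavage-editing transition model
#'
#' A 4 x 5 row-stochastic matrix P; rows are the cleavage states
#' (no_cleavage, off_only, on_only, both), columns the five editing-outcome
#' categories (wt_wt, indel_wt, wt_indel, indel_indel, large_deletion).
#' Structural zeros: state off_only can only produce indel_wt; on_only can
#' produce wt_indel or large_deletion; both can produce indel_indel or
#' large_deletion.
#'
#' @slot P 4 x 5 numeric matrix
#' @export
setClass("CleavageModel", representation(P = "matrix"))

OUTCOME_LEVELS <- c("wt_wt", "indel_wt", "wt_indel", "indel_indel",
                    "large_deletion")
STATE_LEVELS <- c("no_cleavage", "off_only", "on_only", "both")

# TRUE where an entry of P is allowed to be nonzero
P_MASK <- rbind(
  no_cleavage = c(TRUE,  TRUE,  TRUE,  TRUE,  TRUE),
  off_only    = c(FALSE, TRUE,  FALSE, FALSE, FALSE),
  on_only     = c(FALSE, FALSE, TRUE,  FALSE, TRUE),
  both        = c(FALSE, FALSE, FALSE, TRUE,  TRUE))
colnames(P_MASK) <- OUTCOME_LEVELS

setValidity("CleavageModel", function(object) {
  P <- object@P
  if (!all(dim(P) == c(4L, 5L))) return("P must be 4 x 5")
  if (any(P < 0)) return("P entries must be non-negative")
  if (any(abs(rowSums(P) - 1) > 1e-9)) return("rows of P must sum to 1")
  if (any(P[!P_MASK] != 0)) return("structural zeros of P violated")
  TRUE
})

#' Single-mismatch effect matrix (M1)
#'
#' 12 x 20 matrix of multiplicative single-mismatch effects; rows are the
#' twelve non-Watson-Crick rX:dY pairings (X the crRNA base, Y the base on
#' the complementary target DNA strand), columns are protospacer positions
#' 1..20 counted from the PAM-proximal end.
#'
#' @slot values 12 x 20 numeric matrix, entries > 0
#' @export
setClass("MismatchMatrix", representation(values = "matrix"))

setValidity("MismatchMatrix", function(object) {
  v <- object@values
  if (!all(dim(v) == c(12L, 20L))) return("values must be 12 x 20")
  if (any(!is.finite(v)) || any(v <= 0)) return("entries must be finite and > 0")
  if (!identical(rownames(v), mismatchPairLabels()))
    return("rows must be labelled with the 12 rX:dY pairings in canonical order")
  TRUE
})

#' Pairwise combinatorial-effect matrix (M2 / delta)
#'
#' Symmetric 20 x 20 matrix of pairwise combinatorial effects delta_ij
#' (deviation from multiplicative independence of two mismatches at
#' positions i and j); `n` records how many pooled observations informed
#' each cell (0 marks a missing entry, stored as NA in `values`).
#'
#' @slot values 20 x 20 numeric matrix (NA where unobserved)
#' @slot n 20 x 20 integer matrix of pooled observation counts
#' @export
setClass("CombinatorialMatrix", representation(values = "matrix", n = "matrix"))

setValidity("CombinatorialMatrix", function(object) {
  v <- object@values; n <- object@n
  if (!all(dim(v) == c(20L, 20L)) || !all(dim(n) == c(20L, 20L)))
    return("values and n must be 20 x 20")
  if (!isTRUE(all.equal(v, t(v)))) return("values must be symmetric")
  if (any(n < 0)) return("n must be non-negative")
  if (any(is.na(v) & n > 0)) return("cells with observations cannot be NA")
  ok <- !is.na(v)
  if (any(v[ok] <= 0)) return("observed delta entries must be > 0")
  TRUE
})

#' Dinucleotide convolutional GMT regression model
#'
#' One convolution layer of `k` kernels spanning the full 16-row
#' dinucleotide encoding with width one position pair, followed by a dense
#' layer terminating in a single neuron; the output is on the log-GMT scale.
#'
#' @slot W k x 16 kernel weights (one column per dinucleotide row)
#' @slot V k x 19 dense weights (one column per position pair)
#' @slot bias intercept
#' @slot meta list of training metadata (seed, epochs, lr, loss, cv)
#' @export
setClass("GmtModel", representation(W = "matrix", V = "matrix",
                                    bias = "numeric", meta = "list"))

setValidity("GmtModel", function(object) {
  if (ncol(object@W) != 16L) return("W must have 16 columns")
  if (ncol(object@V) != 19L) return("V must have 19 columns")
  if (nrow(object@W) != nrow(object@V)) return("W and V kernel counts differ")
  if (length(object@bias) != 1L) return("bias must be scalar")
  TRUE
})

#' Dinucleotide stacking-energy table
#'
#' Stacking energies (units kB*T) for all 16 dinucleotide steps, for
#' DNA:DNA and RNA:DNA duplexes. The package default is a synthetic,
#' documented toy table; published parameter sets can be supplied as JSON.
#'
#' @slot dd named numeric(16): DNA:DNA stacking energies
#' @slot rd named numeric(16): RNA:DNA stacking energies
#' @slot label provenance label
#' @export
setClass("EnergyTable", representation(dd = "numeric", rd = "numeric",
                                       label = "character"))

setValidity("EnergyTable", function(object) {
  dn <- dinucleotideOrder()
  if (!setequal(names(object@dd), dn) || !setequal(names(object@rd), dn))
    return("dd and rd must name all 16 dinucleotides")
  TRUE
})

#' Parameters of the multi-state kinetic cleavage model
#'
#' Energies in units of kB*T. A mismatch costs `mismatchCost` when
#' isolated and only `bubbleExtensionCost` when it extends an existing
#' bubble (the preceding hybrid position is also mismatched).
#'
#' @slot pamGain energy gained on PAM binding (default 5)
#' @slot matchGain energy gained per correctly matched hybrid bp (0.25)
#' @slot mismatchCost cost of an isolated mismatch (4)
#' @slot bubbleExtensionCost cost of a bubble-extending mismatch (3)
#' @slot attemptRate attempt rate of the Arrhenius hops (arbitrary units)
#' @export
setClass("KineticParameters", representation(
  pamGain = "numeric", matchGain = "numeric", mismatchCost = "numeric",
  bubbleExtensionCost = "numeric", attemptRate = "numeric"))

setValidity("KineticParameters", function(object) {
  if (object@mismatchCost < 0 || object@bubbleExtensionCost < 0)
    return("mismatch costs must be >= 0")
  if (object@attemptRate <= 0) return("attemptRate must be > 0")
  TRUE
})

#' Free-energy landscape of R-loop formation
#'
#' Free energies of the states unbound, PAM-bound and hybrid lengths
#' 1..20, with G(unbound) fixed at 0.
#'
#' @slot G named numeric vector of state free energies (kB*T)
#' @slot mode "parametric" or "sequence"
#' @export
setClass("FreeEnergyLandscape", representation(G = "numeric", mode = "character"))

setValidity("FreeEnergyLandscape", function(object) {
  if (length(object@G) < 3L) return("landscape needs at least 3 states")
  if (abs(object@G[[1L]]) > 1e-12) return("G(unbound) must be 0")
  if (any(!is.finite(object@G))) return("free energies must be finite")
  TRUE
})

#' Parameter bundle for MOFF scoring
#'
#' @slot m1 a [MismatchMatrix]
#' @slot m2 a [CombinatorialMatrix]
#' @slot gmtModel a [GmtModel], or NULL to use s_GMT = 1
#' @slot c pseudo-count used on the log off-on ratio scale (default 0.01)
#' @slot version free-form version string
#' @export
setClass("MoffParameters", representation(
  m1 = "MismatchMatrix", m2 = "CombinatorialMatrix", gmtModel = "ANY",
  c = "numeric", version = "character"))

setValidity("MoffParameters", function(object) {
  if (!(is.null(object@gmtModel) || is(object@gmtModel, "GmtModel")))
    return("gmtModel must be NULL or a GmtModel")
  if (object@c < 0) return("c must be >= 0")
  TRUE
})
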