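# Guide and target-site constructors, mismatch descriptors and variant
# enumeration.
#
# Position convention: protospacer positions are counted from the
# PAM-proximal end (position 1 is the base immediately 5' of the PAM on
# the protospacer strand, position 20 is PAM-distal). Because sequences
# are stored 5'->3', position p maps to string index 21 - p.

#' Construct a set of guide sequences
#'
#' @param spacers character vector of 20-nt spacer sequences; RNA alphabet
#'   is accepted (U is converted to T), case-insensitive
#' @param ids optional identifiers (default `guide_1`, ...)
#' @return a [GuideSet]
#' @examples
#' g <- guideSet(c("ACGUACGUACGUACGUACGU", "GGGGTTTTCCCCAAAAGGGG"))
#' spacers(g)
#' @export
guideSet <- function(spacers, ids = NULL) {
  if (is.null(ids)) {
    ids <- names(spacers)
    if (is.null(ids)) ids <- paste0("guide_", seq_along(spacers))
  }
  spacers <- toupper(as.character(spacers))
  spacers <- gsub("U", "T", spacers, fixed = TRUE)
  new("GuideSet", spacers = unname(spacers), ids = as.character(ids))
}

#' Construct a target site
#'
#' @param protospacer 20-nt DNA sequence (protospacer strand, 5'->3')
#' @param pam 3-nt PAM immediately 3' of the protospacer
#' @param contig,start,end,strand optional genomic coordinates (0-based,
#'   half-open)
#' @return a [TargetSite]
#' @export
targetSite <- function(protospacer, pam = "AGG", contig = NA_character_,
                       start = NA_integer_, end = NA_integer_,
                       strand = "*") {
  new("TargetSite", protospacer = toupper(protospacer), pam = toupper(pam),
      contig = contig, start = as.integer(start), end = as.integer(end),
      strand = strand)
}

#' 23-bp sequence of a target site
#' @param site a [TargetSite] or a 23-bp string
#' @return the protospacer followed by the PAM
#' @export
targetSequence <- function(site) {
  if (is(site, "TargetSite")) return(paste0(site@protospacer, site@pam))
  site <- toupper(site)
  stopifnot(nchar(site) == 23L)
  site
}

# coerce a 23-bp string or TargetSite to (protospacer, pam)
asTarget <- function(site) {
  s <- targetSequence(site)
  list(protospacer = substr(s, 1L, 20L), pam = substr(s, 21L, 23L))
}

#' Canonical rX:dY pairing labels
#'
#' The twelve non-Watson-Crick pairings of a crRNA base X with a base Y on
#' the complementary target DNA strand, ordered by RNA base (A, C, G, U)
#' then DNA base alphabetically.
#' @return character(12)
#' @export
mismatchPairLabels <- function() {
  rna <- c("A", "C", "G", "U")
  wc <- c(A = "T", C = "G", G = "C", U = "A")
  unlist(lapply(rna, function(r) {
    paste0("r", r, ":d", setdiff(c("A", "C", "G", "T"), wc[[r]]))
  }))
}

#' Enumerate the 240 single-mismatch categories
#'
#' The cross product of the 12 non-Watson-Crick rX:dY pairings with the 20
#' protospacer positions, in deterministic position-major order.
#'
#' @return data.frame with columns `position` (1..20, PAM-proximal = 1),
#'   `rna`, `dna` and `label` (e.g. `"rA:dC@5"`)
#' @examples
#' nrow(enumerateMismatchTypes())  # 240
#' @export
enumerateMismatchTypes <- function() {
  pairs <- mismatchPairLabels()
  rna <- substr(pairs, 2L, 2L)
  dna <- substr(pairs, 5L, 5L)
  out <- data.frame(
    position = rep(1:20, each = length(pairs)),
    rna = rep(rna, 20L), dna = rep(dna, 20L),
    stringsAsFactors = FALSE)
  out$pairing <- paste0("r", out$rna, ":d", out$dna)
  out$label <- paste0(out$pairing, "@", out$position)
  out
}

#' Mismatch profile between a guide and a target site
#'
#' One descriptor per protospacer position where the guide base is not
#' Watson-Crick paired with the target. The DNA base reported is the base
#' on the complementary target strand (the strand the crRNA pairs with),
#' following the rX:dY convention.
#'
#' @param guide a 20-nt spacer string (or single-guide [GuideSet])
#' @param site a [TargetSite] or 23-bp (or 20-bp) target string
#' @return data.frame with columns `position`, `rna`, `dna`, `pairing`,
#'   `label`; zero rows for a perfect match
#' @examples
#' mismatchProfile("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGAAGG")
#' @export
mismatchProfile <- function(guide, site) {
  if (is(guide, "GuideSet")) guide <- spacers(guide)[[1L]]
  guide <- gsub("U", "T", toupper(guide), fixed = TRUE)
  proto <- if (is(site, "TargetSite")) site@protospacer
           else substr(toupper(site), 1L, 20L)
  stopifnot(nchar(guide) == 20L, nchar(proto) == 20L)
  g <- chars(guide); p <- chars(proto)
  idx <- which(g != p)                     # string indices (5'->3')
  pos <- 21L - idx                         # PAM-proximal coordinates
  rna <- sub("T", "U", g[idx])
  dna <- unname(complementBase(p[idx]))
  o <- order(pos)
  out <- data.frame(position = pos[o], rna = rna[o], dna = dna[o],
                    stringsAsFactors = FALSE)
  if (nrow(out)) {
    out$pairing <- paste0("r", out$rna, ":d", out$dna)
    out$label <- paste0(out$pairing, "@", out$position)
  } else {
    out$pairing <- character(0)
    out$label <- character(0)
  }
  out
}

# positions of the 22 mutable bases inside a 23-bp target: the 20
# protospacer string indices plus the two PAM guanines (indices 22, 23);
# the PAM N (index 21) is never mutated.
MUTABLE_IDX <- c(1:20, 22L, 23L)

#' Enumerate target variants at a fixed mismatch count
#'
#' All distinct 23-bp sequences that differ from the target at exactly `k`
#' of the 22 mutable positions (the 20 protospacer bases and the two PAM
#' guanines; the PAM N is never mutated), with 3 alternative bases per
#' position: `choose(22, k) * 3^k` variants.
#'
#' @param target a [TargetSite] or 23-bp string
#' @param k number of substitutions, 0..6
#' @param maxVariants optional cap; when the full enumeration exceeds it a
#'   seeded random subset of positions/bases is drawn instead
#' @param seed seed used only when subsampling
#' @return character vector of 23-bp variant sequences
#' @examples
#' t <- paste0(strrep("ACGT", 5), "AGG")
#' length(enumerateTargetVariants(t, 1))  # 66
#' @export
enumerateTargetVariants <- function(target, k, maxVariants = Inf, seed = 1L) {
  s <- targetSequence(target)
  k <- as.integer(k)
  if (k < 0L || k > 6L) stop("k must be between 0 and 6")
  if (k == 0L) return(s)
  base <- chars(s)
  total <- choose(22, k) * 3^k
  if (total <= maxVariants) {
    posSets <- combn(MUTABLE_IDX, k)
    alt <- lapply(MUTABLE_IDX, function(i) setdiff(DNA_BASES, base[i]))
    names(alt) <- as.character(MUTABLE_IDX)
    out <- character(total)
    j <- 0L
    for (ci in seq_len(ncol(posSets))) {
      pos <- posSets[, ci]
      grids <- expand.grid(lapply(as.character(pos), function(p) alt[[p]]),
                           stringsAsFactors = FALSE)
      for (gi in seq_len(nrow(grids))) {
        v <- base
        v[pos] <- unlist(grids[gi, ], use.names = FALSE)
        j <- j + 1L
        out[j] <- paste(v, collapse = "")
      }
    }
    out
  } else {
    withSeed(seed, {
      vapply(seq_len(maxVariants), function(i) {
        pos <- sample(MUTABLE_IDX, k)
        v <- base
        for (p in pos) v[p] <- sample(setdiff(DNA_BASES, base[p]), 1L)
        paste(v, collapse = "")
      }, character(1))
    })
  }
}

#' Read guides from a FASTA file
#' @param path FASTA file of 20-nt spacers
#' @return a [GuideSet]
#' @export
readGuides <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  guideSet(as.character(x), ids = names(x))
}

#' Write guides to a FASTA file
#' @param guides a [GuideSet]
#' @param path output path
#' @export
writeGuides <- function(guides, path) {
  x <- Biostrings::DNAStringSet(setNames(guides@spacers, guides@ids))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
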