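# Read processing: overlap merging, barcode demultiplexing, alignment and
# 5-way editing-outcome classification.

#' Affine alignment scoring parameters
#'
#' Match +2, mismatch -2, affine gap penalties with open 8 and extend 1
#' (a gap of length L costs open + L * extend).
#'
#' @param match,mismatch match score and mismatch score
#' @param gapOpen,gapExtend non-negative gap penalties
#' @return a list of class `alignment_scoring`
#' @export
alignmentScoring <- function(match = 2, mismatch = -2, gapOpen = 8,
                             gapExtend = 1) {
  stopifnot(match > 0, gapOpen >= 0, gapExtend >= 0)
  structure(list(match = match, mismatch = mismatch, gapOpen = gapOpen,
                 gapExtend = gapExtend), class = "alignment_scoring")
}

substMatrix <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                           mismatch = scoring$mismatch,
                                           baseOnly = FALSE)
}

#' Merge a read pair by ungapped overlap
#'
#' Reverse-complements the second read and scans all ungapped overlaps
#' between `minOverlap` and `maxOverlap`; the merge with the fewest
#' mismatches (ties broken toward the longest overlap) is returned if its
#' mismatch density is at most `maxMismatchDensity`, otherwise failure is
#' returned as a value.
#'
#' @param r1,r2 forward and reverse reads (r2 in sequencing orientation)
#' @param minOverlap,maxOverlap overlap bounds in nt
#' @param maxMismatchDensity maximum fraction of mismatching overlap bases
#' @return list with `ok`, `merged`, `overlap`, `mismatches`
#' @export
mergeReadPair <- function(r1, r2, minOverlap = 20L, maxOverlap = 150L,
                          maxMismatchDensity = 0.1) {
  r1 <- toupper(r1)
  r2c <- reverseComplement1(toupper(r2))
  n1 <- nchar(r1); n2 <- nchar(r2c)
  a <- chars(r1); b <- chars(r2c)
  best <- NULL
  # offset o: r2c starts at position o + 1 of the merged sequence
  for (o in seq(0L, n1 - 1L)) {
    ov <- min(n1 - o, n2)
    if (ov < minOverlap || ov > maxOverlap) next
    mm <- sum(a[(o + 1L):(o + ov)] != b[seq_len(ov)])
    if (mm / ov > maxMismatchDensity) next
    if (is.null(best) || mm < best$mismatches ||
        (mm == best$mismatches && ov > best$overlap))
      best <- list(o = o, overlap = ov, mismatches = mm)
  }
  if (is.null(best))
    return(list(ok = FALSE, merged = NA_character_, overlap = NA_integer_,
                mismatches = NA_integer_))
  merged <- paste0(substr(r1, 1L, best$o), r2c)
  list(ok = TRUE, merged = merged, overlap = best$overlap,
       mismatches = best$mismatches)
}

#' Assign merged reads to library constructs by exact barcode match
#'
#' A read is assigned when the 10-nt barcode 1 and the last 10 nt of
#' barcode 2, extracted at their layout positions (barcode 1 after the
#' left primer; barcode 2 at the read end, reads being trimmed to the
#' amplicon), both match a construct exactly. Any error in either barcode
#' leaves the read unassigned (`NA`).
#'
#' @param reads character vector of merged reads
#' @param lib an [OligoLibrary] (dual layout)
#' @return character vector of construct ids, `NA` where unassigned
#' @export
assignReads <- function(reads, lib) {
  d <- if (is(lib, "OligoLibrary")) designs(lib) else lib
  map <- dualLayoutMap()
  key <- paste0(d$barcode1, substr(d$barcode2, nchar(d$barcode2) - 9L,
                                   nchar(d$barcode2)))
  if (anyDuplicated(key)) stop("library barcode keys are not unique")
  lookup <- setNames(d$construct_id, key)
  n <- nchar(reads)
  rkey <- paste0(substr(reads, map$bc1[1L], map$bc1[1L] + 9L),
                 substr(reads, n - 9L, n))
  unname(lookup[rkey])
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' @param query,reference sequences
#' @param scoring an [alignmentScoring()] list
#' @return list with `score`, `patternStart`, `subjectStart` and the
#'   aligned strings (`alignedQuery`, `alignedReference`)
#' @examples
#' alignLocal("ACGT", "ACTT")$score
#' @export
alignLocal <- function(query, reference, scoring = alignmentScoring()) {
  pa <- Biostrings::pairwiseAlignment(
    query, reference, type = "local", substitutionMatrix = substMatrix(scoring),
    gapOpening = scoring$gapOpen, gapExtension = scoring$gapExtend)
  list(score = Biostrings::score(pa),
       patternStart = Biostrings::start(Biostrings::pattern(pa)),
       subjectStart = Biostrings::start(Biostrings::subject(pa)),
       alignedQuery = as.character(Biostrings::alignedPattern(pa)),
       alignedReference = as.character(Biostrings::alignedSubject(pa)))
}

# Global (end-anchored) alignment of a full amplicon read against its
# designed reference, returning indels in reference coordinates.
# Deletions are ranges of reference positions absent from the read;
# insertions are (boundary position, length) with the boundary being the
# last reference position preceding the inserted bases. Backed by the
# compiled Gotoh aligner.
alignAmplicon <- function(queries, reference, scoring = alignmentScoring()) {
  raw <- cppAlignGlobal(queries, reference, scoring$match,
                        scoring$mismatch, scoring$gapOpen,
                        scoring$gapExtend)
  lapply(raw, function(x)
    list(score = x$score, deletions = as.data.frame(x$deletions),
         insertions = as.data.frame(x$insertions)))
}

parseAlignedPair <- function(alnQuery, alnRef) {
  q <- chars(alnQuery); r <- chars(alnRef)
  refpos <- cumsum(r != "-")
  delCols <- q == "-"
  insCols <- r == "-"
  dels <- NULL
  if (any(delCols)) {
    rl <- rle(delCols)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    dels <- data.frame(start = refpos[starts[keep]],
                       end = refpos[ends[keep]])
  } else dels <- data.frame(start = integer(0), end = integer(0))
  ins <- NULL
  if (any(insCols)) {
    rl <- rle(insCols)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    ins <- data.frame(pos = ifelse(starts[keep] == 1L, 0L,
                                   refpos[starts[keep] - 1L]),
                      length = rl$lengths[keep])
  } else ins <- data.frame(pos = integer(0), length = integer(0))
  list(deletions = dels, insertions = ins)
}

# does any indel fall inside the 10-bp window centered on the cut
# (positions cut-4 .. cut+5, the cut being between cut and cut+1)?
# An insertion reported at boundary b could equivalently be placed
# anywhere up to b + length when it duplicates adjacent sequence (the
# common templated-insertion outcome), so the interval [b, b + length]
# is tested against the window.
indelInWindow <- function(indels, cut, window = 10L) {
  lo <- cut - window %/% 2L + 1L
  hi <- cut + window %/% 2L
  d <- indels$deletions
  i <- indels$insertions
  any(d$start <= hi & d$end >= lo) ||
    any(i$pos <= hi & i$pos + i$length >= lo - 1L)
}

#' Classify the editing outcome of one aligned amplicon
#'
#' Large deletion if any single deletion exceeds `largeDelThreshold` bp;
#' otherwise indel presence is tested within a 10-bp window centered on
#' each target's cut site (3 bp 5' of the PAM) and the 2 x 2 presence
#' pattern maps to wt_wt / indel_wt / wt_indel / indel_indel, with
#' indel_wt meaning an indel at the (left) off-target only.
#'
#' @param indels indel list as produced by the amplicon alignment
#'   (components `deletions`, `insertions` in reference coordinates)
#' @param layoutMap layout feature map (defaults to the dual layout)
#' @param window window size in bp
#' @param largeDelThreshold deletion length above which the read is a
#'   large deletion (default 32)
#' @return one of the five outcome category names
#' @export
classifyEditingOutcome <- function(indels, layoutMap = dualLayoutMap(),
                                   window = 10L, largeDelThreshold = 32L) {
  d <- indels$deletions
  if (nrow(d) && any(d$end - d$start + 1L > largeDelThreshold))
    return("large_deletion")
  offHit <- indelInWindow(indels, layoutMap$off_cut, window)
  onHit <- indelInWindow(indels, layoutMap$on_cut, window)
  if (offHit && onHit) "indel_indel"
  else if (offHit) "indel_wt"
  else if (onHit) "wt_indel"
  else "wt_wt"
}

#' Classify merged reads against a dual-target library
#'
#' Assigns reads by barcode, aligns each distinct read sequence once
#' against its construct's designed amplicon (global alignment under the
#' affine scoring) and classifies the five editing outcomes.
#'
#' @param reads character vector of merged reads
#' @param lib an [OligoLibrary]
#' @param scoring an [alignmentScoring()]
#' @param window,largeDelThreshold see [classifyEditingOutcome()]
#' @return data.frame with one row per read: `construct_id`, `outcome`
#'   (NA for unassigned reads)
#' @export
classifyReads <- function(reads, lib, scoring = alignmentScoring(),
                          window = 10L, largeDelThreshold = 32L) {
  d <- designs(lib)
  map <- dualLayoutMap()
  refs <- substr(renderOligo(lib), 1L, map$amplicon_end)
  names(refs) <- d$construct_id
  cid <- assignReads(reads, lib)
  outcome <- rep(NA_character_, length(reads))
  for (id in unique(cid[!is.na(cid)])) {
    idx <- which(!is.na(cid) & cid == id)
    ref <- refs[[id]]
    uq <- unique(reads[idx])
    cls <- character(length(uq))
    exact <- uq == ref
    cls[exact] <- "wt_wt"
    if (any(!exact)) {
      indels <- alignAmplicon(uq[!exact], ref, scoring)
      cls[!exact] <- vapply(indels, classifyEditingOutcome,
                            character(1), layoutMap = map, window = window,
                            largeDelThreshold = largeDelThreshold)
    }
    outcome[idx] <- cls[match(reads[idx], uq)]
  }
  data.frame(construct_id = cid, outcome = outcome, stringsAsFactors = FALSE)
}

#' Count editing outcomes per construct
#'
#' @param classified data.frame from [classifyReads()] (or any data.frame
#'   with `construct_id` and `outcome` columns)
#' @param constructIds optional construct ids fixing the row order (and
#'   including constructs with zero reads)
#' @return integer matrix, one row per construct, columns the five
#'   outcome categories c1..c5
#' @export
countOutcomes <- function(classified, constructIds = NULL) {
  keep <- !is.na(classified$construct_id) & !is.na(classified$outcome)
  cl <- classified[keep, , drop = FALSE]
  if (is.null(constructIds)) constructIds <- sort(unique(cl$construct_id))
  tab <- table(factor(cl$construct_id, levels = constructIds),
               factor(cl$outcome, levels = OUTCOME_LEVELS))
  m <- matrix(as.integer(tab), nrow = length(constructIds),
              dimnames = list(constructIds, OUTCOME_LEVELS))
  m
}
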