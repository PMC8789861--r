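# MOFF scoring: per-site MOFF-target score, genome scanning and the
# genome-wide MOFF-aggregate score.

#' Bundle MOFF scoring parameters
#'
#' @param m1 a [MismatchMatrix] of single-mismatch effects
#' @param m2 a [CombinatorialMatrix] of pairwise combinatorial effects
#' @param gmtModel a [GmtModel], or NULL for s_GMT = 1
#' @param c pseudo-count used as the aggregate floor (default 0.01)
#' @param version version string
#' @return a [MoffParameters]
#' @export
moffParameters <- function(m1, m2, gmtModel = NULL, c = 0.01,
                           version = "1") {
  new("MoffParameters", m1 = m1, m2 = m2, gmtModel = gmtModel, c = c,
      version = version)
}

deltaLookup <- function(m2, pos_i, pos_j) {
  v <- values(m2)[cbind(pos_i, pos_j)]
  v[is.na(v)] <- 1           # missing combinatorial entries impute to 1
  v
}

#' MOFF-target score of a gRNA / off-target pair
#'
#' The log predicted off-on ratio
#' S = sum_i log(s_i) + (2/k) * sum_{i<j} log(delta_ij) + k * log(s_GMT),
#' where k is the mismatch count, s_i the single-mismatch effects from
#' the M1 matrix, delta_ij the pairwise combinatorial effects by
#' position, and s_GMT the guide-intrinsic mismatch tolerance predicted
#' from the guide sequence. A perfect match scores 0 (ratio 1); for k = 3
#' the pairwise construction equals the geometric mean of the three
#' sequential two-mismatch extensions. Natural logs throughout.
#'
#' @param guide 20-nt guide sequence (or single-guide [GuideSet])
#' @param site a [TargetSite] or 23-bp target sequence
#' @param params a [MoffParameters]
#' @param requirePam reject sites whose PAM is not NGG (NAG also accepted
#'   when `allowNAG`)
#' @param allowNAG accept NAG PAMs (default FALSE)
#' @param sGMT optional override of the predicted GMT effect
#' @return list with `score` (log scale), `ratio` (= exp(score)), `k`,
#'   `profile`, `s_gmt`
#' @examples
#' m1 <- mismatchMatrix(matrix(0.5, 12, 20))
#' m2 <- combinatorialMatrix(matrix(0.8, 20, 20))
#' p <- moffParameters(m1, m2)
#' moffTarget("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGAAGG", p)$score
#' @export
moffTarget <- function(guide, site, params, requirePam = TRUE,
                       allowNAG = FALSE, sGMT = NULL) {
  if (is(guide, "GuideSet")) guide <- unname(spacers(guide))[[1L]]
  guide <- checkGuide20(guide)[[1L]]
  tgt <- asTarget(site)
  if (requirePam) {
    ok <- grepl("^[ACGT]GG$", tgt$pam) ||
      (allowNAG && grepl("^[ACGT]AG$", tgt$pam))
    if (!ok) stop("site PAM ", tgt$pam, " is not NGG",
                  if (allowNAG) "/NAG")
  }
  prof <- mismatchProfile(guide, tgt$protospacer)
  k <- nrow(prof)
  if (is.null(sGMT)) {
    sGMT <- if (is.null(params@gmtModel)) 1
            else predictGmt(params@gmtModel, guide)$gmt
  }
  score <- 0
  if (k > 0L) {
    score <- sum(log(m1Lookup(params@m1, prof))) + k * log(sGMT)
    if (k > 1L) {
      pairs <- combn(prof$position, 2L)
      score <- score +
        (2 / k) * sum(log(deltaLookup(params@m2, pairs[1L, ], pairs[2L, ])))
    }
  }
  list(score = score, ratio = exp(score), k = k, profile = prof,
       s_gmt = sGMT)
}

#' Scan a genome for candidate off-target sites
#'
#' Finds every 23-mer on either strand whose 20-nt protospacer is within
#' `maxMm` Hamming mismatches of the guide and whose PAM matches NGG.
#' Coordinates are 0-based half-open on the forward strand of each
#' contig, ordered by contig, start, strand; perfect (0-MM) sites are
#' flagged as on-target.
#'
#' @param genome a named character vector / `DNAStringSet` of contig
#'   sequences, or a FASTA path
#' @param guide 20-nt guide sequence
#' @param maxMm maximum mismatch count (default 6)
#' @param allowNAG also accept NAG PAMs
#' @return data.frame with `contig`, `start`, `end`, `strand`,
#'   `protospacer`, `pam`, `k`, `profile` (rX:dY@pos, comma-separated),
#'   `on_target`
#' @export
scanGenome <- function(genome, guide, maxMm = 6L, allowNAG = FALSE) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (!is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome)))
    names(genome) <- paste0("contig_", seq_along(genome))
  guide <- checkGuide20(guide)[[1L]]
  pat <- Biostrings::DNAString(guide)
  pamRe <- if (allowNAG) "^[ACGT](GG|AG)$" else "^[ACGT]GG$"
  rows <- list()
  for (ci in seq_along(genome)) {
    seqF <- genome[[ci]]
    L <- length(seqF)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seqF else Biostrings::reverseComplement(seqF)
      hits <- Biostrings::matchPattern(pat, s, max.mismatch = maxMm,
                                       with.indels = FALSE)
      st <- Biostrings::start(hits)
      st <- st[st + 22L <= L]
      if (!length(st)) next
      proto <- as.character(Biostrings::extractAt(
        s, IRanges::IRanges(st, st + 19L)))
      pam <- as.character(Biostrings::extractAt(
        s, IRanges::IRanges(st + 20L, st + 22L)))
      keep <- grepl(pamRe, pam)
      if (!any(keep)) next
      st <- st[keep]; proto <- proto[keep]; pam <- pam[keep]
      start0 <- if (strand == "+") st - 1L else L - (st + 22L)
      profs <- vapply(proto, function(p)
        paste(mismatchProfile(guide, p)$label, collapse = ","), character(1))
      gvec <- chars(guide)
      k <- vapply(proto, function(p) sum(chars(p) != gvec), integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        contig = names(genome)[ci], start = start0, end = start0 + 23L,
        strand = strand, protospacer = unname(proto), pam = unname(pam),
        k = unname(k), profile = unname(profs),
        on_target = unname(k) == 0L, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      protospacer = character(0), pam = character(0),
                      k = integer(0), profile = character(0),
                      on_target = logical(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Genome-wide MOFF-aggregate score of a guide
#'
#' The natural logarithm of the summed predicted off-on ratios
#' (exp(S_MOFF)) over all candidate off-target sites with 1..`maxMm`
#' mismatches; perfect (0-MM) sites are excluded as on-targets. When no
#' candidate site exists the aggregate is floored at log(c).
#'
#' @inheritParams scanGenome
#' @param params a [MoffParameters]
#' @return list with `aggregate`, `nSites`, `sites` (per-site scores)
#' @export
moffAggregate <- function(guide, genome, params, maxMm = 6L,
                          allowNAG = FALSE) {
  sites <- scanGenome(genome, guide, maxMm = maxMm, allowNAG = allowNAG)
  off <- sites[!sites$on_target, , drop = FALSE]
  if (nrow(off) == 0L)
    return(list(aggregate = log(params@c), nSites = 0L, sites = off))
  sGMT <- if (is.null(params@gmtModel)) 1
          else predictGmt(params@gmtModel, guide)$gmt
  off$score <- vapply(seq_len(nrow(off)), function(i)
    moffTarget(guide, paste0(off$protospacer[i], off$pam[i]), params,
               requirePam = FALSE, sGMT = sGMT)$score, numeric(1))
  off$ratio <- exp(off$score)
  list(aggregate = log(sum(off$ratio)), nSites = nrow(off), sites = off)
}

#' Write MOFF parameters to JSON
#' @param params a [MoffParameters]
#' @param path output path
#' @export
writeMoffParameters <- function(params, path) {
  gm <- params@gmtModel
  jsonlite::write_json(list(
    m1 = values(params@m1), m2 = values(params@m2), m2_n = params@m2@n,
    gmt = if (is.null(gm)) NULL else
      list(W = gm@W, V = gm@V, bias = gm@bias),
    c = params@c, version = params@version),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor",
    na = "null")
  invisible(path)
}

#' Read MOFF parameters from JSON
#' @param path a file written by [writeMoffParameters()]
#' @return a [MoffParameters]
#' @export
readMoffParameters <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gm <- NULL
  if (!is.null(x$gmt) && length(x$gmt) > 0)
    gm <- new("GmtModel", W = as.matrix(x$gmt$W), V = as.matrix(x$gmt$V),
              bias = as.numeric(x$gmt$bias), meta = list())
  moffParameters(mismatchMatrix(as.matrix(x$m1)),
                 combinatorialMatrix(as.matrix(x$m2),
                                     matrix(as.integer(as.matrix(x$m2_n)),
                                            20L, 20L)),
                 gmtModel = gm, c = x$c, version = as.character(x$version))
}
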