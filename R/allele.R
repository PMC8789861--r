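# MOFF-allele: design of allele-discriminating mismatched guides for a
# heterozygous point variant.

# all NGG-adjacent 20-mers (either strand) of `locus` whose protospacer
# covers position `varPos` (1-based); returns data.frame of seed guides
seedGuides <- function(locus, varPos) {
  locus <- toupper(locus)
  L <- nchar(locus)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") locus else reverseComplement1(locus)
    vp <- if (strand == "+") varPos else L - varPos + 1L
    cc <- chars(s)
    # protospacer start p..p+19, PAM p+20..p+22 must be NGG
    for (p in seq_len(L - 22L)) {
      if (!(vp >= p && vp <= p + 19L)) next
      if (cc[p + 21L] == "G" && cc[p + 22L] == "G") {
        proto <- substr(s, p, p + 19L)
        out[[length(out) + 1L]] <- data.frame(
          spacer = proto, strand = strand, start = p,
          pam = substr(s, p + 20L, p + 22L),
          var_string_pos = vp - p + 1L,           # 1..20, 5'->3'
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame(spacer = character(0)))
  do.call(rbind, out)
}

#' Design allele-discriminating mismatched guides
#'
#' Given the local sequences of the wildtype and mutant alleles (which
#' must differ at exactly one base), finds all seed guides -- NGG-adjacent
#' 20-mers on either strand of the mutant allele covering the variant,
#' hence perfectly matched to the mutant and single-mismatched to the
#' wildtype -- then introduces every possible additional single mismatch
#' to each seed to obtain candidates differing by 1 nt from the mutant
#' and 2 nt from the wildtype. Each candidate is scored with
#' [moffTarget()] against both alleles on the ratio scale; candidates
#' pass when the mutant ratio exceeds `effMin` (efficiency) and the
#' wildtype/mutant ratio is below `selMax` (selectivity), and are ranked
#' by ascending selectivity ratio.
#'
#' @param wtLocus,mutLocus equal-length DNA strings differing at one base
#' @param params a [MoffParameters]
#' @param effMin minimum predicted mutant-allele ratio (default 0.5)
#' @param selMax maximum wildtype/mutant ratio (default 0.2)
#' @return list with `candidates` (data.frame of all scored candidates,
#'   `pass` flagging the selected ones) and `reason` (set when empty)
#' @export
moffAllele <- function(wtLocus, mutLocus, params, effMin = 0.5,
                       selMax = 0.2) {
  wtLocus <- toupper(wtLocus); mutLocus <- toupper(mutLocus)
  if (nchar(wtLocus) != nchar(mutLocus))
    stop("wildtype and mutant loci must have equal length")
  diffPos <- which(chars(wtLocus) != chars(mutLocus))
  if (length(diffPos) != 1L)
    stop("loci must differ at exactly one base (found ", length(diffPos),
         " differences)")
  seeds <- seedGuides(mutLocus, diffPos)
  if (nrow(seeds) == 0L)
    return(list(candidates = data.frame(), reason = "no seed guide"))
  wtRc <- reverseComplement1(wtLocus)
  L <- nchar(wtLocus)
  rows <- list()
  for (si in seq_len(nrow(seeds))) {
    seed <- seeds[si, ]
    wtStrand <- if (seed$strand == "+") wtLocus else wtRc
    wtSite <- paste0(substr(wtStrand, seed$start, seed$start + 19L),
                     seed$pam)
    mutSite <- paste0(seed$spacer, seed$pam)
    wtBaseAtVar <- substr(wtStrand, seed$start + seed$var_string_pos - 1L,
                          seed$start + seed$var_string_pos - 1L)
    for (p in 1:20) {
      orig <- substr(seed$spacer, p, p)
      for (alt in setdiff(DNA_BASES, orig)) {
        # skip candidates that recreate the wildtype base at the variant
        # position: those match the wildtype allele perfectly
        if (p == seed$var_string_pos && alt == wtBaseAtVar) next
        cand <- seed$spacer
        substr(cand, p, p) <- alt
        sMut <- moffTarget(cand, mutSite, params, requirePam = FALSE)
        sWt <- moffTarget(cand, wtSite, params, requirePam = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          guide = cand, seed = seed$spacer, strand = seed$strand,
          mm_string_pos = p, mm_base = alt,
          ratio_mut = sMut$ratio, ratio_wt = sWt$ratio,
          selectivity = sWt$ratio / sMut$ratio,
          k_mut = sMut$k, k_wt = sWt$k, stringsAsFactors = FALSE)
      }
    }
  }
  cand <- do.call(rbind, rows)
  cand$pass <- cand$ratio_mut > effMin & cand$selectivity < selMax
  cand <- cand[order(cand$selectivity), ]
  rownames(cand) <- NULL
  list(candidates = cand, reason = NULL)
}
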