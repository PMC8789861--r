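# Oligonucleotide library design: barcode construction, layout constants,
# the 7-designs-per-guide dual-target scheme and PAM-control constructs.

# ---- barcode construction -------------------------------------------------
#
# Barcodes are drawn uniformly at random (seeded) from a shortened Hamming
# code over GF(4), which guarantees a minimum pairwise Hamming distance of
# 3 between any two barcodes of the same set without quadratic rejection
# sampling. GF(4) elements are encoded 0..3 and mapped to A, C, G, T.

GF4_MUL <- matrix(c(0, 0, 0, 0,
                    0, 1, 2, 3,
                    0, 2, 3, 1,
                    0, 3, 1, 2), 4, 4, byrow = TRUE)

# the 21 projective points of GF(4)^3; identity columns kept last so the
# code is systematic in the first n - 3 positions
gf4Points <- function() {
  pts <- list()
  for (b in 0:3) for (c0 in 0:3) pts[[length(pts) + 1L]] <- c(1, b, c0)
  for (c0 in 0:3) pts[[length(pts) + 1L]] <- c(0, 1, c0)
  pts[[length(pts) + 1L]] <- c(0, 0, 1)
  pts <- pts[!vapply(pts, function(p)
    identical(p, c(1, 0, 0)) || identical(p, c(0, 1, 0)) ||
    identical(p, c(0, 0, 1)), logical(1))]
  c(pts, list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
}

#' Generate distance-3 barcodes
#'
#' Draws `n` distinct barcodes of the given width, uniformly at random
#' from a shortened GF(4) Hamming code, so that any two barcodes differ at
#' three or more positions.
#'
#' @param n number of barcodes
#' @param width barcode length in nt (4..21)
#' @param seed RNG seed
#' @return character vector of `n` barcodes
#' @export
generateBarcodes <- function(n, width, seed = 1L) {
  stopifnot(width >= 4L, width <= 21L)
  k <- width - 3L
  pts <- gf4Points()
  Hinfo <- vapply(pts[seq_len(k)], identity, numeric(3))   # 3 x k
  m <- as.integer(n)
  withSeed(seed, {
    if (4^k <= .Machine$integer.max) {
      if (m > 4^k) stop("more barcodes requested than the code contains")
      idx <- sample.int(4^k, m) - 1
      U <- matrix(0L, m, k)
      for (i in seq_len(k)) {
        U[, i] <- as.integer(idx %% 4)
        idx <- idx %/% 4
      }
    } else {
      U <- matrix(sample(0:3, m * k, replace = TRUE), m, k)
      key <- apply(U, 1L, paste, collapse = "")
      while (anyDuplicated(key)) {
        dup <- which(duplicated(key))
        U[dup, ] <- sample(0:3, length(dup) * k, replace = TRUE)
        key <- apply(U, 1L, paste, collapse = "")
      }
    }
    P <- matrix(0L, m, 3L)
    for (j in 1:3) {
      acc <- integer(m)
      for (i in seq_len(k)) {
        acc <- bitwXor(acc, GF4_MUL[cbind(U[, i] + 1L, Hinfo[j, i] + 1L)])
      }
      P[, j] <- acc
    }
    cw <- cbind(U, P)
    bases <- matrix(DNA_BASES[cw + 1L], m, width)
    apply(bases, 1L, paste, collapse = "")
  })
}

# ---- layout constants -----------------------------------------------------
#
# Fixed primer/linker sequences. The lengths follow the construct layouts
# (dual 190 nt, single 157 nt, target-only 109 nt); the sequences
# themselves are package constants chosen to be GC-balanced and free of
# GG/CC dinucleotides so that no accidental NGG PAM is created on either
# strand.

OLIGO_CONST <- list(
  left_primer18   = "ATCGATGCATGACTGAGT",
  linker15        = "ATGCATACGTATGCA",
  cloning_linker45 = "ATCGATACGATGCTAGCTAGTACGTAGCATGCATGACTGATCGAT",
  right_primer20  = "ATGACTGCATGCATACGTCA",
  left_primer25   = "ATGCATGACTGCATACGATCGTACA",
  right_primer27  = "ATGCTAGCATGCATACGATGCATGACT",
  target_flank5   = "AT",
  target_flank3   = "CA")

#' Total oligo length of a layout
#' @param layout one of `"dual"`, `"single"`, `"target_only"`
#' @return integer length in nt (190, 157 or 109)
#' @export
layoutLength <- function(layout) {
  c(dual = 190L, single = 157L, target_only = 109L)[[layout]]
}

# offsets of key features within the rendered dual oligo (1-based)
dualLayoutMap <- function() {
  list(bc1 = c(19L, 28L), off = c(29L, 51L), on = c(67L, 89L),
       bc2 = c(90L, 104L),
       # blunt cut 3 bp 5' of the PAM (between protospacer positions 3 and
       # 4 counted PAM-proximal)
       off_cut = 45L,   # cut between 45 and 46
       on_cut = 83L,
       amplicon_end = 104L)
}

# ---- design operations ----------------------------------------------------

tHomopolymerRun <- function(x) {
  m <- gregexpr("T+", x)
  vapply(m, function(r) if (r[1L] == -1L) 0L else max(attr(r, "match.length")),
         integer(1))
}

mutateAt <- function(seqs, idx, bases) {
  # replace character idx of each string
  substr(seqs, idx, idx) <- bases
  seqs
}

#' Design the dual-target library (7 off-target designs per guide)
#'
#' For each guide: three distinct single-mismatch (1-MM) off-targets with
#' mismatches at three distinct positions, the three pairwise combinations
#' of those mismatches as 2-MM designs, and their three-way union as the
#' 3-MM design, so that every 2-MM/3-MM mismatch set is composed of the
#' 1-MM mismatches. Each construct carries a unique (barcode1, barcode2)
#' pair; barcode sets have minimum pairwise Hamming distance 3.
#'
#' Guides containing a thymine homopolymer longer than three nucleotides
#' are rejected (library synthesis filter).
#'
#' @param guides a [GuideSet]
#' @param seed RNG seed controlling mismatch draws and barcodes
#' @return an [OligoLibrary] with 7 rows per guide and columns
#'   `construct_id`, `guide_id`, `design_type`, `layout`, `barcode1`,
#'   `barcode2`, `off_target`, `on_target`, `spacer`, `mm_positions`,
#'   `pam_type`
#' @examples
#' lib <- designDualTargetLibrary(guideSet("ACGTACGTACGTACGTACGT"), seed = 1)
#' designs(lib)$design_type
#' @export
designDualTargetLibrary <- function(guides, seed = 1L) {
  sp <- spacers(guides)
  bad <- tHomopolymerRun(sp) > 3L
  if (any(bad))
    stop("guides with thymine homopolymers longer than 3 nt: ",
         paste(names(sp)[bad], collapse = ", "))
  n <- length(sp)
  withSeed(seed, {
    pamN <- sample(DNA_BASES, n, replace = TRUE)
    pam <- paste0(pamN, "GG")
    on_target <- paste0(unname(sp), pam)
    # three distinct mismatch positions per guide, random alternative base
    mmPos <- vapply(seq_len(n), function(i) sample.int(20L, 3L), integer(3))
    mmBase <- vapply(seq_len(n), function(i) {
      vapply(1:3, function(j) {
        p <- mmPos[j, i]
        orig <- substr(sp[i], 21L - p, 21L - p)
        sample(setdiff(DNA_BASES, orig), 1L)
      }, character(1))
    }, character(3))
    combos <- list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L), 1:3)
    types <- c("1MM_a", "1MM_b", "1MM_c", "2MM_ab", "2MM_ac", "2MM_bc",
               "3MM_abc")
    rows <- vector("list", 7L)
    for (ci in seq_along(combos)) {
      off <- on_target
      for (j in combos[[ci]]) off <- mutateAt(off, 21L - mmPos[j, ],
                                              mmBase[j, ])
      rows[[ci]] <- data.frame(
        guide_id = names(sp), design_type = types[ci],
        off_target = off, on_target = on_target, spacer = unname(sp),
        mm_positions = vapply(seq_len(n), function(i)
          paste(sort(mmPos[combos[[ci]], i]), collapse = ","), character(1)),
        stringsAsFactors = FALSE)
    }
    d <- do.call(rbind, rows)
    d <- d[order(match(d$guide_id, names(sp)), d$design_type), ]
    d$layout <- "dual"
    d$pam_type <- "NGG+NGG"
    d$barcode1 <- generateBarcodes(nrow(d), 10L, seed = sample.int(2^30, 1))
    d$barcode2 <- generateBarcodes(nrow(d), 15L, seed = sample.int(2^30, 1))
    d$construct_id <- paste(d$guide_id, d$design_type, sep = ".")
    rownames(d) <- NULL
    new("OligoLibrary", designs = d[, c(
      "construct_id", "guide_id", "design_type", "layout", "barcode1",
      "barcode2", "off_target", "on_target", "spacer", "mm_positions",
      "pam_type")])
  })
}

#' Design PAM-control dual-target constructs
#'
#' For each guide, four constructs with identical left (off) and right (on)
#' protospacers equal to the guide's perfect target, with cleavage turned
#' on/off per target by an NGG or NTT PAM: the four combinations NTT+NTT
#' (no cleavage), NGG+NTT (off only), NTT+NGG (on only) and NGG+NGG (both).
#'
#' @param guides a [GuideSet]
#' @param seed RNG seed for barcodes and the PAM N
#' @return an [OligoLibrary] with a `pam_type` column
#' @export
designControlLibrary <- function(guides, seed = 1L) {
  sp <- spacers(guides)
  n <- length(sp)
  withSeed(seed, {
    pamN <- sample(DNA_BASES, n, replace = TRUE)
    combos <- c("NTT+NTT", "NGG+NTT", "NTT+NGG", "NGG+NGG")
    rows <- lapply(combos, function(cmb) {
      sides <- strsplit(cmb, "+", fixed = TRUE)[[1L]]
      pamOf <- function(side) paste0(pamN, substr(side, 2L, 3L))
      data.frame(
        guide_id = names(sp), design_type = "control",
        off_target = paste0(unname(sp), pamOf(sides[1L])),
        on_target = paste0(unname(sp), pamOf(sides[2L])),
        spacer = unname(sp), mm_positions = "", pam_type = cmb,
        stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    d$layout <- "dual"
    d$barcode1 <- generateBarcodes(nrow(d), 10L, seed = sample.int(2^30, 1))
    d$barcode2 <- generateBarcodes(nrow(d), 15L, seed = sample.int(2^30, 1))
    d$construct_id <- paste(d$guide_id, gsub("[+]", "_", d$pam_type),
                            sep = ".")
    rownames(d) <- NULL
    new("OligoLibrary", designs = d[, c(
      "construct_id", "guide_id", "design_type", "layout", "barcode1",
      "barcode2", "off_target", "on_target", "spacer", "mm_positions",
      "pam_type")])
  })
}

#' Render full oligonucleotide sequences
#'
#' Concatenates the layout components of every construct: for the dual
#' layout, left primer (18), barcode 1 (10), off-target (23), linker (15),
#' on-target (23), barcode 2 (15), cloning linker (45), g + spacer (21)
#' and right primer (20), totalling 190 nt. Single-target constructs are
#' 157 nt (20-nt barcode 2, no linker or second target) and target-only
#' constructs 109 nt.
#'
#' @param lib an [OligoLibrary] (or its `designs()` data.frame)
#' @return character vector of rendered oligos, one per construct
#' @export
renderOligo <- function(lib) {
  d <- if (is(lib, "OligoLibrary")) designs(lib) else lib
  K <- OLIGO_CONST
  out <- character(nrow(d))
  for (ly in unique(d$layout)) {
    i <- d$layout == ly
    out[i] <- switch(ly,
      dual = paste0(K$left_primer18, d$barcode1[i], d$off_target[i],
                    K$linker15, d$on_target[i], d$barcode2[i],
                    K$cloning_linker45, "G", d$spacer[i], K$right_primer20),
      single = paste0(K$left_primer18, d$barcode1[i], d$off_target[i],
                      d$barcode2[i], K$cloning_linker45, "G", d$spacer[i],
                      K$right_primer20),
      target_only = paste0(K$left_primer25, d$barcode1[i], K$target_flank5,
                           d$off_target[i], K$target_flank3, d$barcode2[i],
                           K$right_primer27),
      stop("unknown layout: ", ly))
    want <- layoutLength(ly)
    if (any(nchar(out[i]) != want))
      stop("component length mismatch: ", ly, " oligos must be ", want, " nt")
  }
  setNames(out, d$construct_id)
}

#' Write an oligo library to TSV
#' @param lib an [OligoLibrary]
#' @param path output path
#' @export
writeOligoLibrary <- function(lib, path) {
  d <- designs(lib)
  d$oligo_seq <- renderOligo(lib)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an oligo library from TSV
#' @param path a TSV written by [writeOligoLibrary()]
#' @return an [OligoLibrary]
#' @export
readOligoLibrary <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  d$oligo_seq <- NULL
  new("OligoLibrary", designs = d)
}
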