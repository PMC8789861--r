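# Sequence types, mismatch descriptors, variant enumeration and the
# oligonucleotide library designer.

test_that("guide sets validate length, alphabet and RNA input", {
  g <- guideSet(c(a = "ACGUACGUACGUACGUACGU"))
  expect_identical(unname(spacers(g)), "ACGTACGTACGTACGTACGT")
  expect_error(guideSet("ACGT"), "20")
  expect_error(guideSet(strrep("N", 20)), "alphabet")
  expect_error(guideSet(c(x = "ACGTACGTACGTACGTACGT",
                          x = "ACGTACGTACGTACGTACGT")), "unique")
})

test_that("the 240 mismatch categories are the full non-WC cross product", {
  types <- enumerateMismatchTypes()
  expect_equal(nrow(types), 240L)
  # position-major deterministic order
  expect_equal(types$position, rep(1:20, each = 12L))
  # every position contributes exactly 12 categories
  expect_true(all(table(types$position) == 12L))
  # admitted DNA partners exclude the Watson-Crick match
  admitted <- split(types$dna, types$rna)
  expect_setequal(unique(admitted$A), c("A", "C", "G"))
  expect_setequal(unique(admitted$C), c("A", "C", "T"))
  expect_setequal(unique(admitted$G), c("A", "G", "T"))
  expect_setequal(unique(admitted$U), c("C", "G", "T"))
})

test_that("mismatch profiles flag exactly the 12 non-WC pairings", {
  # enumerate all 16 guide-base x protospacer-base combinations at one
  # position and check which are flagged
  base <- "ACGTACGTACGTACGTACGT"
  flagged <- 0L
  for (gb in c("A", "C", "G", "T")) for (pb in c("A", "C", "G", "T")) {
    guide <- base; target <- base
    substr(guide, 5, 5) <- gb               # position 16 (PAM-proximal)
    substr(target, 5, 5) <- pb
    prof <- mismatchProfile(guide, paste0(target, "AGG"))
    if (gb == pb) {
      expect_equal(nrow(prof), 0L)
    } else {
      flagged <- flagged + 1L
      expect_equal(prof$position, 16L)
      expect_equal(prof$rna, sub("T", "U", gb))
      # reported DNA base is on the complementary strand
      expect_equal(prof$dna, c(A = "T", C = "G", G = "C", T = "A")[[pb]])
    }
  }
  expect_equal(flagged, 12L)
})

test_that("variant enumeration matches the closed-form counts and a brute force", {
  t1 <- paste0(strrep("ACGT", 5), "AGG")
  expect_identical(enumerateTargetVariants(t1, 0), t1)
  v1 <- enumerateTargetVariants(t1, 1)
  v2 <- enumerateTargetVariants(t1, 2)
  expect_equal(length(v1), 66L)      # 22 * 3
  expect_equal(length(v2), 2079L)    # choose(22, 2) * 9
  expect_false(anyDuplicated(v1) > 0)
  expect_false(anyDuplicated(v2) > 0)
  expect_error(enumerateTargetVariants(t1, 7), "between 0 and 6")
  # independent brute force for k = 1: mutate every position of the
  # 23-mer to every base, keep Hamming-1 neighbours that leave the PAM N
  # and the PAM GG rule intact
  bf <- character(0)
  for (i in 1:23) for (b in c("A", "C", "G", "T")) {
    v <- t1
    substr(v, i, i) <- b
    if (v != t1 && i != 21) bf <- c(bf, v)
  }
  expect_setequal(v1, bf)
  # profiles of k-MM variants have length k (PAM mutations excluded from
  # the protospacer profile)
  guide <- strrep("ACGT", 5)
  protoOnly <- v2[substr(v2, 21, 23) == "AGG"]
  lens <- vapply(protoOnly[1:50], function(v)
    nrow(mismatchProfile(guide, v)), integer(1))
  expect_true(all(lens == 2L))
})

test_that("variant enumeration round-trips through mismatchProfile", {
  guide <- "GGATCACTGTACGTTCAGAC"
  v1 <- enumerateTargetVariants(paste0(guide, "TGG"), 1)
  inProto <- v1[substr(v1, 21, 23) == "TGG"]
  expect_equal(length(inProto), 60L)
  labels <- vapply(inProto, function(v) mismatchProfile(guide, v)$label,
                   character(1))
  expect_false(anyDuplicated(labels) > 0)
  expect_equal(sort(unique(vapply(inProto, function(v)
    nrow(mismatchProfile(guide, v)), integer(1)))), 1L)
})

test_that("the dual-target designer emits 7 nested designs per guide", {
  g <- simulateGuides(5, seed = 31)
  lib <- designDualTargetLibrary(g, seed = 7)
  d <- designs(lib)
  expect_equal(nrow(d), 35L)
  expect_true(all(table(d$guide_id) == 7L))
  # per guide: the 2-MM mismatch sets are pairs of the 1-MM mismatches
  # and subsets of the 3-MM set
  for (id in guideIds(g)) {
    di <- d[d$guide_id == id, ]
    posOf <- function(type) as.integer(strsplit(
      di$mm_positions[di$design_type == type], ",")[[1]])
    singles <- sort(c(posOf("1MM_a"), posOf("1MM_b"), posOf("1MM_c")))
    expect_equal(length(unique(singles)), 3L)
    expect_setequal(posOf("3MM_abc"), singles)
    for (tp in c("2MM_ab", "2MM_ac", "2MM_bc")) {
      expect_true(all(posOf(tp) %in% singles))
      expect_equal(length(posOf(tp)), 2L)
    }
    # the realized off-target mismatches equal the declared positions
    prof <- mismatchProfile(di$spacer[1],
                            di$off_target[di$design_type == "3MM_abc"])
    expect_setequal(prof$position, singles)
  }
  # determinism
  lib2 <- designDualTargetLibrary(g, seed = 7)
  expect_identical(designs(lib2), d)
  # barcode pairs unique; guides with T homopolymers > 3 nt rejected
  expect_false(anyDuplicated(paste(d$barcode1, d$barcode2)) > 0)
  bad <- guideSet("ACGTTTTTACGTACGTACGT")
  expect_error(designDualTargetLibrary(bad), "homopolymer")
})

test_that("barcode sets keep pairwise Hamming distance >= 3", {
  bc <- generateBarcodes(400, 10, seed = 5)
  m <- do.call(rbind, strsplit(bc, ""))
  dmin <- 10L
  for (i in seq_len(nrow(m) - 1)) {
    d <- rowSums(sweep(m[(i + 1):nrow(m), , drop = FALSE], 2, m[i, ],
                       FUN = "!="))
    dmin <- min(dmin, d)
  }
  expect_gte(dmin, 3L)
  expect_identical(generateBarcodes(50, 15, seed = 9),
                   generateBarcodes(50, 15, seed = 9))
})

test_that("rendered oligos have the layout lengths 190 / 157 / 109", {
  g <- simulateGuides(3, seed = 2)
  lib <- designDualTargetLibrary(g, seed = 3)
  expect_true(all(nchar(renderOligo(lib)) == 190L))
  d <- designs(lib)[1:3, ]
  d$layout <- "single"
  d$barcode2 <- generateBarcodes(3, 20, seed = 4)
  expect_true(all(nchar(renderOligo(d)) == 157L))
  d$layout <- "target_only"
  expect_true(all(nchar(renderOligo(d)) == 109L))
  # component length mismatch is an error
  dbad <- designs(lib)
  dbad$barcode1[1] <- "ACGT"
  expect_error(renderOligo(dbad), "length mismatch")
})

test_that("oligo libraries survive a TSV round trip", {
  g <- simulateGuides(2, seed = 11)
  lib <- designDualTargetLibrary(g, seed = 12)
  path <- tempfile(fileext = ".tsv")
  writeOligoLibrary(lib, path)
  lib2 <- readOligoLibrary(path)
  expect_identical(designs(lib2), designs(lib))
  unlink(path)
})

test_that("guides survive a FASTA round trip", {
  g <- simulateGuides(4, seed = 21)
  path <- tempfile(fileext = ".fa")
  writeGuides(g, path)
  g2 <- readGuides(path)
  expect_identical(spacers(g2), spacers(g))
  unlink(path)
})
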