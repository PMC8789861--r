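# Read merging, barcode assignment, alignment and outcome
# classification.

test_that("read pairs merge by best ungapped overlap", {
  set.seed(4)
  s <- paste(sample(c("A", "C", "G", "T"), 105, replace = TRUE),
             collapse = "")
  r1 <- substr(s, 1, 75)
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(s, 31, 105))))
  m <- mergeReadPair(r1, r2)
  expect_true(m$ok)
  expect_equal(nchar(m$merged), 105L)
  expect_identical(m$merged, s)
  expect_equal(m$overlap, 45L)

  # overlap with > 10% mismatches fails
  r2bad <- substr(s, 31, 105)
  mm <- ceiling(0.12 * 75)
  for (i in seq_len(mm)) {
    orig <- substr(r2bad, i * 5, i * 5)
    substr(r2bad, i * 5, i * 5) <- setdiff(c("A", "C", "G", "T"), orig)[1]
  }
  r2bad <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(r2bad)))
  mb <- mergeReadPair(r1, r2bad)
  expect_false(mb$ok)
  expect_true(is.na(mb$merged))

  # planted 40-nt overlap with one error is recovered at the right offset
  set.seed(5)
  left <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
  truth <- paste0(left, right)
  r1p <- substr(truth, 1, 60 + 40)
  tail <- substr(truth, 61, 120)
  substr(r1p, 75, 75) <- setdiff(c("A", "C", "G", "T"),
                                 substr(r1p, 75, 75))[1]
  mp <- mergeReadPair(r1p, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(tail))))
  expect_true(mp$ok)
  expect_equal(mp$overlap, 40L)
  expect_equal(mp$mismatches, 1L)
  expect_equal(nchar(mp$merged), 120L)
})

test_that("reads assign only on exact barcode matches", {
  g <- simulateGuides(3, seed = 41)
  lib <- designDualTargetLibrary(g, seed = 42)
  refs <- substr(renderOligo(lib), 1, 104)
  ids <- designs(lib)$construct_id
  expect_identical(assignReads(refs, lib), ids)
  # a 1-nt error in barcode 1 leaves the read unassigned
  r <- refs[[7]]
  orig <- substr(r, 20, 20)
  substr(r, 20, 20) <- setdiff(c("A", "C", "G", "T"), orig)[1]
  expect_true(is.na(assignReads(r, lib)))
  # simulated error-free reads: 100% of intact barcodes recovered
  S <- matrix(rep(c(0.4, 0.1, 0.4, 0.1), each = nrow(designs(lib))), ncol = 4)
  rownames(S) <- ids
  sim <- simulateReads(lib, toyCleavageModel(), S, depth = 150, seed = 43)
  asg <- assignReads(sim$reads, lib)
  n <- nchar(sim$reads)
  intact <- substr(sim$reads, 19, 28) ==
    designs(lib)$barcode1[match(sim$truth$construct_id, ids)] &
    substr(sim$reads, n - 9, n) ==
    substr(designs(lib)$barcode2, 6, 15)[match(sim$truth$construct_id, ids)]
  expect_true(all(asg[intact] == sim$truth$construct_id[intact]))
})

test_that("local alignment matches the exhaustive DP oracle", {
  sc <- alignmentScoring()
  expect_equal(alignLocal("ACGTACGT", "ACGTACGT", sc)$score, 16)
  expect_equal(alignLocal("ACGT", "ACTT", sc)$score, 4)
  # exhaustive small cases over a 2-letter alphabet
  seqs <- unlist(lapply(1:4, allSeqs))
  for (q in seqs[seq(1, length(seqs), by = 3)]) {
    for (r in seqs[seq(2, length(seqs), by = 7)]) {
      expect_equal(alignLocal(q, r, sc)$score, dpLocal(q, r),
                   info = paste(q, r))
    }
  }
  # random longer pairs
  set.seed(6)
  for (i in 1:40) {
    q <- paste(sample(c("A", "C"), sample(5:8, 1), replace = TRUE),
               collapse = "")
    r <- paste(sample(c("A", "C"), sample(5:8, 1), replace = TRUE),
               collapse = "")
    expect_equal(alignLocal(q, r, sc)$score, dpLocal(q, r),
                 info = paste(q, r))
  }
})

test_that("a planted deletion is reported as one affine gap", {
  set.seed(7)
  ref <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
               collapse = "")
  q <- paste0(substr(ref, 1, 35), substr(ref, 46, 80))   # 10-nt deletion
  a <- alignAmplicon(q, ref)[[1]]
  expect_equal(nrow(a$deletions), 1L)
  expect_equal(a$deletions$end - a$deletions$start + 1L, 10L)
  expect_equal(a$score, 70 * 2 - (8 + 10))
  # and the compiled global aligner agrees with a DP oracle on small cases
  seqs <- unlist(lapply(2:4, allSeqs))
  for (q2 in seqs[seq(1, length(seqs), by = 4)]) {
    for (r2 in seqs[seq(3, length(seqs), by = 6)]) {
      expect_equal(alignAmplicon(q2, r2)[[1]]$score, dpGlobal(q2, r2),
                   info = paste(q2, r2))
    }
  }
})

test_that("editing outcomes classify by window and deletion size", {
  g <- simulateGuides(1, seed = 51)
  lib <- designDualTargetLibrary(g, seed = 52)
  lib@designs <- designs(lib)[1, , drop = FALSE]
  ref <- substr(renderOligo(lib), 1, 104)[[1]]
  classifyOne <- function(read) classifyReads(read, lib)$outcome
  expect_identical(classifyOne(ref), "wt_wt")
  # 3-nt deletion at the on-target cut (ref position 83) only
  readOn <- paste0(substr(ref, 1, 81), substr(ref, 85, 104))
  expect_identical(classifyOne(readOn), "wt_indel")
  # 3-nt deletion at the off-target cut (ref position 45) only
  readOff <- paste0(substr(ref, 1, 43), substr(ref, 47, 104))
  expect_identical(classifyOne(readOff), "indel_wt")
  # both
  readBoth <- paste0(substr(ref, 1, 43), substr(ref, 47, 81),
                     substr(ref, 85, 104))
  expect_identical(classifyOne(readBoth), "indel_indel")
  # 40-nt deletion spanning both cut sites
  readLarge <- paste0(substr(ref, 1, 44), substr(ref, 85, 104))
  expect_identical(classifyOne(readLarge), "large_deletion")
  # a 33-nt deletion exceeds the default 32-bp threshold; 32 does not
  read33 <- paste0(substr(ref, 1, 44), substr(ref, 78, 104))
  expect_identical(classifyOne(read33), "large_deletion")
  read32 <- paste0(substr(ref, 1, 44), substr(ref, 77, 104))
  expect_false(identical(classifyOne(read32), "large_deletion"))
})

test_that("outcome counts are exact, order-invariant and conserved", {
  g <- simulateGuides(3, seed = 61)
  lib <- designDualTargetLibrary(g, seed = 62)
  d <- designs(lib)
  S <- matrix(rep(c(0.25, 0.25, 0.25, 0.25), each = nrow(d)), ncol = 4)
  rownames(S) <- d$construct_id
  sim <- simulateReads(lib, toyCleavageModel(), S, depth = 120, seed = 63)
  cl <- classifyReads(sim$reads, lib)
  cnt <- countOutcomes(cl, d$construct_id)
  # counts equal the truth-label counts wherever reads were assigned
  okRows <- !is.na(cl$construct_id)
  truthCnt <- countOutcomes(data.frame(construct_id = sim$truth$construct_id,
                                       outcome = sim$truth$outcome)[okRows, ],
                            d$construct_id)
  agree <- mean(cl$outcome[okRows] == sim$truth$outcome[okRows])
  expect_gte(agree, 0.99)
  # conservation: classified + unassigned = total
  expect_equal(sum(cnt) + sum(is.na(cl$construct_id)), length(sim$reads))
  # permutation invariance
  perm <- sample(length(sim$reads))
  cntPerm <- countOutcomes(classifyReads(sim$reads[perm], lib),
                           d$construct_id)
  expect_identical(cnt, cntPerm)
  # empty input gives a zero matrix
  empty <- countOutcomes(data.frame(construct_id = character(0),
                                    outcome = character(0)),
                         d$construct_id)
  expect_true(all(empty == 0L))
})
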