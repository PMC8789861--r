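# MOFF-target, genome scanning, MOFF-aggregate and MOFF-allele.

test_that("MOFF-target evaluates the pairwise log-linear score", {
  guide <- "ACGTACGTACGTACGTACGT"
  p <- toyMoffParams()
  # perfect match scores 0, ratio 1
  s0 <- moffTarget(guide, paste0(guide, "TGG"), p)
  expect_equal(s0$score, 0)
  expect_equal(s0$ratio, 1)
  expect_equal(s0$k, 0L)
  # hand evaluation with heterogeneous toy parameters, k = 2:
  # S = log s1 + log s2 + log delta12 + 2 log sGMT
  m1v <- matrix(0.5, 12, 20)
  target <- paste0(guide, "TGG")
  substr(target, 20, 20) <- "A"        # position 1 mismatch (rU:dT)
  substr(target, 15, 15) <- "C"        # position 6 mismatch (rC:dG?)
  prof <- mismatchProfile(guide, target)
  m1v[cbind(match(prof$pairing, mismatchPairLabels()), prof$position)] <-
    c(0.5, 0.2)[rank(prof$position)]
  m2v <- matrix(0.9, 20, 20)
  m2v[prof$position[1], prof$position[2]] <-
    m2v[prof$position[2], prof$position[1]] <- 0.5
  pars <- moffParameters(mismatchMatrix(m1v), combinatorialMatrix(m2v))
  s2 <- moffTarget(guide, target, pars, sGMT = 0.8)
  expect_equal(s2$k, 2L)
  expect_equal(s2$score, log(0.5) + log(0.2) + log(0.5) + 2 * log(0.8),
               tolerance = 1e-12)
  # sites without an NGG PAM are rejected unless NAG is allowed
  expect_error(moffTarget(guide, paste0(guide, "TAG"), p), "PAM")
  expect_silent(moffTarget(guide, paste0(guide, "TAG"), p,
                           allowNAG = TRUE))
})

test_that("k = 3 equals the geometric mean over sequential orderings", {
  guide <- "GGATCACTGTACGTTCAGAC"
  set.seed(17)
  m1v <- matrix(runif(240, 0.05, 1), 12, 20)
  m2v <- matrix(0, 20, 20)
  m2v[upper.tri(m2v)] <- runif(190, 0.1, 1)
  m2v <- m2v + t(m2v); diag(m2v) <- NA
  pars <- moffParameters(mismatchMatrix(m1v), combinatorialMatrix(m2v))
  target <- paste0(guide, "AGG")
  for (pos in list(c(2, 9, 16), c(1, 5, 6))) {
    t3 <- target
    for (pp in pos) {
      i <- 21 - pp
      orig <- substr(t3, i, i)
      substr(t3, i, i) <- setdiff(c("A", "C", "G", "T"), orig)[1]
    }
    prof <- mismatchProfile(guide, t3)
    s <- m1Lookup(pars@m1, prof)
    d12 <- values(pars@m2)[prof$position[1], prof$position[2]]
    d13 <- values(pars@m2)[prof$position[1], prof$position[3]]
    d23 <- values(pars@m2)[prof$position[2], prof$position[3]]
    sGMT <- 0.9
    # the three sequential orderings of adding the third mismatch
    orders <- c(d12 * sqrt(d13 * d23), d13 * sqrt(d12 * d23),
                d23 * sqrt(d12 * d13))
    geo <- prod(s) * prod(orders)^(1 / 3) * sGMT^3
    got <- moffTarget(guide, t3, pars, sGMT = sGMT)
    expect_equal(got$score, log(geo), tolerance = 1e-12)
    # equivalently the closed form with exponent 2/3 on the delta product
    expect_equal(exp(got$score),
                 prod(s) * (d12 * d13 * d23)^(2 / 3) * sGMT^3,
                 tolerance = 1e-12)
  }
})

test_that("with delta and GMT at 1 the score is the product of M1 entries", {
  guide <- "GGATCACTGTACGTTCAGAC"
  set.seed(18)
  m1v <- matrix(runif(240, 0.05, 1), 12, 20)
  pars <- moffParameters(mismatchMatrix(m1v),
                         combinatorialMatrix(matrix(1, 20, 20)))
  for (k in 1:4) {
    for (rep in 1:5) {
      pos <- sample(1:20, k)
      t2 <- paste0(guide, "AGG")
      for (pp in pos) {
        i <- 21 - pp
        orig <- substr(t2, i, i)
        substr(t2, i, i) <- sample(setdiff(c("A", "C", "G", "T"), orig), 1)
      }
      prof <- mismatchProfile(guide, t2)
      expect_equal(moffTarget(guide, t2, pars, sGMT = 1)$ratio,
                   prod(m1Lookup(pars@m1, prof)), tolerance = 1e-12)
    }
  }
})

test_that("scores are monotone and permutation-symmetric", {
  guide <- "GGATCACTGTACGTTCAGAC"
  pars <- toyMoffParams(0.5, 0.8)
  # adding a mismatch (s < 1, delta <= 1, sGMT <= 1) never raises the score
  t1 <- paste0(guide, "AGG")
  scores <- numeric(0)
  for (pp in c(3, 8, 13, 17)) {
    i <- 21 - pp
    orig <- substr(t1, i, i)
    substr(t1, i, i) <- setdiff(c("A", "C", "G", "T"), orig)[1]
    scores <- c(scores, moffTarget(guide, t1, pars, sGMT = 0.9)$score)
  }
  expect_true(all(diff(scores) < 0))
  # the score depends on the mismatch set, not its discovery order
  # (recompute from a site built by mutating in reverse order)
  t2 <- paste0(guide, "AGG")
  for (pp in rev(c(3, 8, 13, 17))) {
    i <- 21 - pp
    orig <- substr(t2, i, i)
    substr(t2, i, i) <- setdiff(c("A", "C", "G", "T"), orig)[1]
  }
  expect_equal(moffTarget(guide, t2, pars, sGMT = 0.9)$score,
               scores[length(scores)])
})

test_that("genome scanning finds planted sites and matches brute force", {
  guide <- "ACGTTGCAGCATGACTGCAT"
  gen <- simulateGenome(30000, seed = 19,
                        plants = data.frame(guide = guide, k = c(0, 2, 3),
                                            strand = c("+", "-", "+")))
  hits <- scanGenome(gen$genome, guide, maxMm = 3)
  expect_equal(nrow(hits), 3L)
  m <- gen$manifest[order(gen$manifest$start), ]
  h <- hits[order(hits$start), ]
  expect_equal(h$start, m$start)
  expect_equal(h$strand, m$strand)
  expect_equal(h$k, m$k)
  expect_true(h$on_target[h$k == 0])
  # profile of the reverse-strand plant matches the planted site
  rev <- h[h$strand == "-", ]
  expect_equal(nrow(mismatchProfile(guide, rev$protospacer)), rev$k)
  # brute force on a small genome: slide over every position and strand
  gen2 <- simulateGenome(3000, seed = 20,
                         plants = data.frame(guide = guide, k = 1,
                                             strand = "-"))
  seqF <- gen2$genome[[1]]
  seqR <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seqF)))
  bf <- 0L
  for (s in c(seqF, seqR)) {
    cc <- strsplit(s, "")[[1]]
    gg <- strsplit(guide, "")[[1]]
    for (st in 1:(nchar(s) - 22)) {
      if (cc[st + 21] == "G" && cc[st + 22] == "G" &&
          sum(cc[st:(st + 19)] != gg) <= 4) bf <- bf + 1L
    }
  }
  expect_equal(nrow(scanGenome(gen2$genome, guide, maxMm = 4)), bf)
  # no spurious perfect hits in random background
  gen3 <- simulateGenome(10000, seed = 21)
  expect_equal(nrow(scanGenome(gen3$genome, guide, maxMm = 0)), 0L)
})

test_that("MOFF-aggregate is the log-sum of per-site predicted ratios", {
  guide <- "ACGTTGCAGCATGACTGCAT"
  pars <- toyMoffParams()
  # genome with only the perfect site: floored at log(c)
  gen0 <- simulateGenome(5000, seed = 22,
                         plants = data.frame(guide = guide, k = 0,
                                             strand = "+"))
  agg0 <- moffAggregate(guide, gen0$genome, pars, maxMm = 3)
  expect_equal(agg0$aggregate, log(0.01))
  expect_equal(agg0$nSites, 0L)
  # a single 1-MM site: the aggregate equals that site's score
  gen1 <- simulateGenome(5000, seed = 23,
                         plants = data.frame(guide = guide, k = 1,
                                             strand = "+"))
  agg1 <- moffAggregate(guide, gen1$genome, pars, maxMm = 3)
  expect_equal(agg1$nSites, 1L)
  site <- paste0(agg1$sites$protospacer, agg1$sites$pam)
  expect_equal(agg1$aggregate,
               moffTarget(guide, site, pars, requirePam = FALSE)$score)
  # many planted sites: log-sum-exp of independently computed scores
  gen10 <- simulateGenome(60000, seed = 24,
                          plants = data.frame(guide = guide,
                                              k = rep(c(1, 2, 3), c(3, 4, 3)),
                                              strand = rep(c("+", "-"), 5)))
  agg10 <- moffAggregate(guide, gen10$genome, pars, maxMm = 3)
  expect_equal(agg10$nSites, 10L)
  each <- vapply(seq_len(nrow(agg10$sites)), function(i)
    moffTarget(guide, paste0(agg10$sites$protospacer[i],
                             agg10$sites$pam[i]), pars,
               requirePam = FALSE)$score, numeric(1))
  expect_equal(agg10$aggregate, log(sum(exp(each))), tolerance = 1e-12)
})

test_that("MOFF-allele enumerates and filters mismatched guides", {
  pars <- toyMoffParams(0.6, 1)     # delta = 1 everywhere
  wt  <- "TTACGAATCTGACTGCATACGATCAAGGTCATGCATACGA"
  mut <- "TTACGAATCTGACTGCATACCATCAAGGTCATGCATACGA"
  res <- moffAllele(wt, mut, pars, effMin = 0, selMax = Inf)
  # one seed guide, 60 single-mismatch variants minus the one recreating
  # the wildtype base at the variant position
  expect_equal(nrow(res$candidates), 59L)
  expect_false(any(res$candidates$ratio_wt == 1))
  # independence limit (delta = 1, sGMT = 1): the selectivity ratio is the
  # M1 effect of the second (variant) mismatch
  cand <- res$candidates[res$candidates$k_wt == 2, ]
  expect_equal(cand$selectivity,
               rep(0.6, nrow(cand)), tolerance = 1e-12)
  # no NGG near the variant: empty with a reason
  res2 <- moffAllele("AAATTTAAATTTAAATTTAAATTTAAA",
                     "AAATTTAAATTTAAATCTAAATTTAAA", pars)
  expect_equal(nrow(res2$candidates), 0L)
  expect_equal(res2$reason, "no seed guide")
  # malformed input
  expect_error(moffAllele(wt, wt, pars), "exactly one")
  expect_error(moffAllele("ACGT", mut, pars), "equal length")
})

test_that("MOFF parameter bundles survive a JSON round trip", {
  set.seed(25)
  m1 <- mismatchMatrix(matrix(runif(240, 0.05, 1), 12, 20))
  m2v <- matrix(0, 20, 20)
  m2v[upper.tri(m2v)] <- runif(190, 0.2, 1)
  m2v <- m2v + t(m2v); diag(m2v) <- NA
  g <- simulateGuides(60, seed = 26)
  gmtTab <- simulateGmt(g, seed = 27)
  mod <- trainGmt(g, gmtTab$log_g, seed = 28, epochs = 200)
  pars <- moffParameters(m1, combinatorialMatrix(m2v), gmtModel = mod)
  path <- tempfile(fileext = ".json")
  writeMoffParameters(pars, path)
  pars2 <- readMoffParameters(path)
  guide <- unname(spacers(g))[1]
  t2 <- paste0(guide, "AGG")
  substr(t2, 4, 4) <- setdiff(c("A", "C", "G", "T"), substr(t2, 4, 4))[1]
  substr(t2, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                substr(t2, 11, 11))[1]
  expect_equal(moffTarget(guide, t2, pars2)$score,
               moffTarget(guide, t2, pars)$score, tolerance = 1e-9)
  # a bundle without a GMT model round-trips too (s_GMT = 1)
  parsNoGmt <- moffParameters(m1, combinatorialMatrix(m2v))
  writeMoffParameters(parsNoGmt, path)
  pars3 <- readMoffParameters(path)
  expect_null(pars3@gmtModel)
  expect_equal(moffTarget(guide, t2, pars3)$score,
               moffTarget(guide, t2, parsNoGmt)$score, tolerance = 1e-9)
  unlink(path)
})
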