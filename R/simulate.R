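# Seeded synthetic-data generators. Every generator is a pure function
# of (parameters, seed) and returns its ground truth alongside the data.

#' Simulate random guide sequences
#'
#' I.i.d. bases per position with configurable GC content; guides with
#' thymine homopolymers longer than 3 nt are redrawn (library synthesis
#' filter), so base frequencies are approximately even at `gcBias` 0.5.
#'
#' @param n number of guides
#' @param seed RNG seed
#' @param gcBias probability of drawing G or C at each position (0.5 for
#'   uniform composition)
#' @return a [GuideSet]
#' @export
simulateGuides <- function(n, seed = 1L, gcBias = 0.5) {
  probs <- c(A = (1 - gcBias) / 2, C = gcBias / 2, G = gcBias / 2,
             T = (1 - gcBias) / 2)
  withSeed(seed, {
    draw <- function(m) {
      apply(matrix(sample(DNA_BASES, 20L * m, replace = TRUE,
                          prob = probs[DNA_BASES]), m, 20L),
            1L, paste, collapse = "")
    }
    sp <- draw(n)
    bad <- which(tHomopolymerRun(sp) > 3L)
    while (length(bad)) {
      sp[bad] <- draw(length(bad))
      bad <- bad[tHomopolymerRun(sp[bad]) > 3L]
    }
    guideSet(sp, ids = sprintf("sg%04d", seq_len(n)))
  })
}

#' Simulate a random M1 matrix
#'
#' Single-mismatch effects with the canonical position trend: seed-region
#' mismatches (positions 1..10, PAM-proximal) are poorly tolerated, PAM-
#' distal ones well tolerated, with per-pairing jitter; entries in (0, 1].
#'
#' @param seed RNG seed
#' @param seedRegionMean,distalMean mean effects in each region
#' @param sdLog lognormal jitter (log scale)
#' @return a [MismatchMatrix]
#' @export
simulateM1 <- function(seed = 1L, seedRegionMean = 0.1, distalMean = 0.5,
                       sdLog = 0.4) {
  withSeed(seed, {
    base <- c(rep(log(seedRegionMean), 10L), rep(log(distalMean), 10L))
    v <- exp(matrix(base, 12L, 20L, byrow = TRUE) +
             matrix(rnorm(240L, sd = sdLog), 12L, 20L))
    v <- pmin(v, 1)
    v[v <= 0.005] <- 0.005
    mismatchMatrix(v)
  })
}

#' Simulate guide-intrinsic mismatch tolerances
#' @param guides a [GuideSet]
#' @param seed RNG seed
#' @param sdLog spread of log g (default 0.5); log g is centered
#' @return data.frame `guide_id`, `g`, `log_g`
#' @export
simulateGmt <- function(guides, seed = 1L, sdLog = 0.5) {
  withSeed(seed, {
    lg <- rnorm(length(guides), sd = sdLog)
    lg <- lg - mean(lg)
    data.frame(guide_id = guideIds(guides), g = exp(lg), log_g = lg,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a smooth pairwise combinatorial-effect matrix
#'
#' delta_ij varies smoothly with position: strong epistasis (small delta)
#' for seed-region pairs, weak (near 1) when a mismatch sits PAM-distal;
#' values in (0, 1].
#'
#' @param seed RNG seed (jitter)
#' @param sdLog lognormal jitter applied symmetrically
#' @return a [CombinatorialMatrix]
#' @export
simulateDelta <- function(seed = 1L, sdLog = 0) {
  v <- matrix(NA_real_, 20L, 20L)
  for (i in 1:19) for (j in (i + 1):20) {
    v[i, j] <- v[j, i] <- 0.25 + 0.7 * ((i + j - 3) / 37)^1.5
  }
  if (sdLog > 0) {
    withSeed(seed, {
      jit <- matrix(0, 20L, 20L)
      jit[upper.tri(jit)] <- rnorm(190L, sd = sdLog)
      jit <- jit + t(jit)
      v <- exp(log(v) + jit)
    })
  }
  v <- pmin(v, 1)
  combinatorialMatrix(v)
}

#' Simulate outcome counts for one construct
#'
#' Reads are allocated to cleavage states by a multinomial draw with
#' probabilities proportional to `S`, then to outcome categories by the
#' rows of P, so E\[C\] = depth-scaled P^T S.
#'
#' @param model a [CleavageModel]
#' @param S true state vector (any positive scale)
#' @param depth total read count
#' @param seed RNG seed
#' @return integer vector of outcome counts c1..c5
#' @export
simulateCounts <- function(model, S, depth, seed = 1L) {
  P <- transitionMatrix(model)
  withSeed(seed, {
    nState <- as.vector(rmultinom(1L, depth, S / sum(S)))
    counts <- numeric(5L)
    for (st in 1:4) if (nState[st] > 0L)
      counts <- counts + as.vector(rmultinom(1L, nState[st], P[st, ]))
    setNames(as.integer(counts), OUTCOME_LEVELS)
  })
}

#' Simulate an off-on ratio observation table
#'
#' Generates, per guide, three 1-MM observations (r = m_j * g_i * eps),
#' three 2-MM observations (x = y * z * delta_ij * eps, with y and z the
#' noise-free parents times their own noise) and one 3-MM observation
#' following the pairwise geometric-mean extension; eps is lognormal with
#' log-scale standard deviation `sigma`. Mismatch positions are drawn
#' distinct per guide, mirroring the 7-designs-per-guide library.
#'
#' @param guides a [GuideSet]
#' @param m1 a [MismatchMatrix] (truth)
#' @param gmt data.frame `guide_id`, `g` (truth; see [simulateGmt()])
#' @param delta a [CombinatorialMatrix] (truth)
#' @param sigma lognormal noise (log scale)
#' @param seed RNG seed
#' @param clip optional ratio range (e.g. c(0.02, 1)) applied to the
#'   observed ratios; NULL to disable
#' @return list with `obs1` (1-MM rows: `guide_id`, `position`,
#'   `pairing`, `r`, `r_true`), `obs2` (2-MM rows: `pos_i`, `pos_j`, `x`,
#'   `y`, `z`, `delta_true`), `obs3` (3-MM rows) and `truth`
#' @export
simulateOffOnTable <- function(guides, m1, gmt, delta, sigma = 0.2,
                               seed = 1L, clip = NULL) {
  sp <- spacers(guides)
  v1 <- values(m1)
  vd <- values(delta)
  types <- enumerateMismatchTypes()
  withSeed(seed, {
    n <- length(sp)
    g <- gmt$g[match(names(sp), gmt$guide_id)]
    obs1 <- vector("list", n); obs2 <- vector("list", n)
    obs3 <- vector("list", n)
    for (i in seq_len(n)) {
      pos <- sort(sample.int(20L, 3L))
      # pairing determined by the guide base and a random alternative
      pairing <- character(3L); m <- numeric(3L)
      for (t in 1:3) {
        gb <- substr(sp[i], 21L - pos[t], 21L - pos[t])
        alt <- sample(setdiff(DNA_BASES, gb), 1L)
        pr <- paste0("r", sub("T", "U", gb), ":d", complementBase(alt))
        pairing[t] <- pr
        m[t] <- v1[pr, pos[t]]
      }
      rt1 <- m * g[i]
      r1 <- rt1 * exp(rnorm(3L, sd = sigma))
      combos <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
      d2 <- vd[cbind(pos[combos[, 1L]], pos[combos[, 2L]])]
      xt <- rt1[combos[, 1L]] * rt1[combos[, 2L]] * d2
      x <- xt * exp(rnorm(3L, sd = sigma))
      d3 <- (vd[pos[1L], pos[2L]] * vd[pos[1L], pos[3L]] *
             vd[pos[2L], pos[3L]])^(2 / 3)
      rt3 <- prod(rt1) * d3
      r3 <- rt3 * exp(rnorm(1L, sd = sigma))
      if (!is.null(clip)) {
        r1 <- pmin(pmax(r1, clip[1L]), clip[2L])
        x <- pmin(pmax(x, clip[1L]), clip[2L])
        r3 <- pmin(pmax(r3, clip[1L]), clip[2L])
      }
      obs1[[i]] <- data.frame(guide_id = names(sp)[i], position = pos,
                              pairing = pairing, r = r1, r_true = rt1,
                              stringsAsFactors = FALSE)
      obs2[[i]] <- data.frame(guide_id = names(sp)[i],
                              pos_i = pos[combos[, 1L]],
                              pos_j = pos[combos[, 2L]],
                              x = x, y = r1[combos[, 1L]],
                              z = r1[combos[, 2L]], delta_true = d2,
                              stringsAsFactors = FALSE)
      obs3[[i]] <- data.frame(guide_id = names(sp)[i],
                              positions = paste(pos, collapse = ","),
                              r = r3, r_true = rt3,
                              stringsAsFactors = FALSE)
    }
    list(obs1 = do.call(rbind, obs1), obs2 = do.call(rbind, obs2),
         obs3 = do.call(rbind, obs3),
         truth = list(m1 = m1, gmt = gmt, delta = delta, sigma = sigma,
                      seed = seed))
  })
}

# realize one editing outcome on a reference amplicon; insertions are
# templated duplications of the adjacent reference sequence
realizeOutcome <- function(ref, outcome, map, seed = NULL) {
  applySmallIndel <- function(s, cut) {
    len <- min(rgeom(1L, 0.3) + 1L, 15L)
    if (runif(1L) < 0.6) {              # deletion
      start <- cut - sample.int(len, 1L) + 1L
      start <- max(start, cut - 4L)
      end <- min(start + len - 1L, nchar(s))
      paste0(substr(s, 1L, start - 1L), substr(s, end + 1L, nchar(s)))
    } else {                             # templated insertion
      at <- cut + sample(-2:2, 1L)
      dup <- substr(s, at - len + 1L, at)
      paste0(substr(s, 1L, at), dup, substr(s, at + 1L, nchar(s)))
    }
  }
  switch(outcome,
    wt_wt = ref,
    indel_wt = applySmallIndel(ref, map$off_cut),
    wt_indel = applySmallIndel(ref, map$on_cut),
    indel_indel = applySmallIndel(applySmallIndel(ref, map$on_cut),
                                  map$off_cut),
    large_deletion = {
      start <- map$off_cut + sample(-6:2, 1L)
      # the deletion must not reach the last 10 nt of barcode 2, which
      # anchor read assignment
      maxLen <- (map$bc2[2L] - 10L) - start + 1L
      len <- sample(33:min(80L, maxLen), 1L)
      paste0(substr(ref, 1L, start - 1L),
             substr(ref, start + len, nchar(ref)))
    },
    stop("unknown outcome ", outcome))
}

#' Simulate merged amplicon reads with ground-truth labels
#'
#' For every construct of a dual-target library, draws cleavage states
#' with probabilities proportional to its true state vector, outcomes per
#' state from the transition model, realizes outcomes as sequence edits
#' (small 1-15 nt indels inside the cut windows, with insertions as
#' templated duplications; large deletions of 33-80 nt spanning from the
#' off-target cut), and applies uniform substitution errors.
#'
#' @param lib an [OligoLibrary] (dual layout)
#' @param model a [CleavageModel] (truth)
#' @param S matrix of true state vectors, one row per construct (rownames
#'   = construct ids), any positive scale
#' @param depth reads per construct
#' @param errorRate per-base substitution error rate
#' @param seed RNG seed
#' @return list with `reads` (character), `truth` (data.frame
#'   `construct_id`, `state`, `outcome` per read) and `groundTruth`
#'   (model, S, depth, errorRate, seed)
#' @export
simulateReads <- function(lib, model, S, depth, errorRate = 0,
                          seed = 1L) {
  d <- designs(lib)
  map <- dualLayoutMap()
  refs <- substr(renderOligo(lib), 1L, map$amplicon_end)
  P <- transitionMatrix(model)
  withSeed(seed, {
    allReads <- vector("list", nrow(d))
    allTruth <- vector("list", nrow(d))
    for (ci in seq_len(nrow(d))) {
      id <- d$construct_id[ci]
      if (depth == 0L) next
      sVec <- S[id, ]
      nState <- as.vector(rmultinom(1L, depth, sVec / sum(sVec)))
      states <- rep(STATE_LEVELS, nState)
      outcomes <- unlist(lapply(1:4, function(st) {
        if (nState[st] == 0L) return(character(0))
        sample(OUTCOME_LEVELS, nState[st], replace = TRUE, prob = P[st, ])
      }))
      reads <- vapply(outcomes, realizeOutcome, character(1),
                      ref = refs[[id]], map = map)
      if (errorRate > 0) {
        nerr <- rbinom(length(reads), nchar(reads), errorRate)
        for (ri in which(nerr > 0L)) {
          at <- sample.int(nchar(reads[ri]), nerr[ri])
          for (a in at) {
            orig <- substr(reads[ri], a, a)
            substr(reads[ri], a, a) <- sample(setdiff(DNA_BASES, orig), 1L)
          }
        }
      }
      allReads[[ci]] <- unname(reads)
      allTruth[[ci]] <- data.frame(construct_id = id, state = states,
                                   outcome = unname(outcomes),
                                   stringsAsFactors = FALSE)
    }
    list(reads = unlist(allReads), truth = do.call(rbind, allTruth),
         groundTruth = list(model = model, S = S, depth = depth,
                            errorRate = errorRate, seed = seed))
  })
}

#' Simulate a genome with planted target sites
#'
#' Random background sequence with 23-bp sites (protospacer + NGG PAM)
#' planted at recorded, non-overlapping coordinates on either strand.
#'
#' @param length genome length in bp
#' @param seed RNG seed
#' @param plants data.frame with columns `guide` (20-nt), `k` (mismatch
#'   count), `strand` ("+"/"-"); one planted site per row. NULL plants
#'   nothing.
#' @return list with `genome` (named character of one contig) and
#'   `manifest` (data.frame `start`, `end`, `strand`, `k`, `site`)
#' @export
simulateGenome <- function(length, seed = 1L, plants = NULL) {
  withSeed(seed, {
    g <- paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
    manifest <- data.frame(start = integer(0), end = integer(0),
                           strand = character(0), k = integer(0),
                           site = character(0))
    if (!is.null(plants) && nrow(plants)) {
      used <- integer(0)
      rows <- list()
      for (i in seq_len(nrow(plants))) {
        spacer <- checkGuide20(plants$guide[i])[[1L]]
        site <- paste0(spacer, sample(DNA_BASES, 1L), "GG")
        if (plants$k[i] > 0L) {
          pos <- sample.int(20L, plants$k[i])
          for (p in pos) {
            orig <- substr(site, 21L - p, 21L - p)
            substr(site, 21L - p, 21L - p) <-
              sample(setdiff(DNA_BASES, orig), 1L)
          }
        }
        placed <- FALSE
        for (try in 1:1000) {
          st <- sample.int(length - 23L, 1L)          # 0-based start
          if (any(st < used + 23L & st + 23L > used)) next
          ins <- if (plants$strand[i] == "+") site
                 else reverseComplement1(site)
          substr(g, st + 1L, st + 23L) <- ins
          used <- c(used, st)
          rows[[length(rows) + 1L]] <- data.frame(
            start = st, end = st + 23L, strand = plants$strand[i],
            k = plants$k[i], site = site, stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed) stop("could not place plant ", i,
                          " without overlap; genome too small")
      }
      manifest <- do.call(rbind, rows)
    }
    list(genome = c(contig_1 = g), manifest = manifest)
  })
}
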