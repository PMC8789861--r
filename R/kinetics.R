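# Free-energy landscapes of R-loop formation and the multi-state kinetic
# model: Cas9 editing as sequential transitions among unbinding, PAM
# recognition, stepwise R-loop extension (hybrid lengths 1..20) and
# cleavage. Implemented as an absorbing nearest-neighbour Markov chain
# with Arrhenius hop rates satisfying detailed balance against the
# landscape; splitting probabilities are solved exactly by first-step
# analysis.

#' Kinetic model parameters
#' @param pamGain energy gained on PAM binding (kB*T, default 5)
#' @param matchGain energy gained per matched hybrid bp (0.25)
#' @param mismatchCost cost of an isolated mismatch (4)
#' @param bubbleExtensionCost cost of a mismatch extending an existing
#'   bubble (3)
#' @param attemptRate Arrhenius attempt rate (arbitrary units, 1)
#' @return a [KineticParameters]
#' @export
kineticParameters <- function(pamGain = 5, matchGain = 0.25,
                              mismatchCost = 4, bubbleExtensionCost = 3,
                              attemptRate = 1) {
  new("KineticParameters", pamGain = pamGain, matchGain = matchGain,
      mismatchCost = mismatchCost, bubbleExtensionCost = bubbleExtensionCost,
      attemptRate = attemptRate)
}

#' Synthetic default dinucleotide stacking-energy table
#'
#' A documented toy table (units kB*T) whose DNA:DNA minus RNA:DNA
#' differences follow the qualitative pattern of published
#' nearest-neighbour parameters: G/C-rich steps favour the RNA:DNA hybrid
#' (negative difference, easier R-loop progression) and A/T-rich steps
#' disfavour it. It is synthetic: published stacking parameter sets can
#' be loaded with [readEnergyTable()] instead.
#'
#' @return an [EnergyTable]
#' @export
defaultEnergyTable <- function() {
  dn <- dinucleotideOrder()
  gc <- vapply(dn, function(d) sum(chars(d) %in% c("G", "C")), numeric(1))
  # toy stacking energies: stronger (more negative) stacking with GC
  dd <- -1.0 - 0.45 * gc
  # the hybrid is modelled as relatively more stable for GC-rich steps
  rd <- -0.8 - 0.75 * gc
  new("EnergyTable", dd = setNames(dd, dn), rd = setNames(rd, dn),
      label = "synthetic-toy")
}

#' Read an energy table from JSON
#' @param path JSON file with fields `dd`, `rd` (named by dinucleotide)
#'   and optionally `label`
#' @return an [EnergyTable]
#' @export
readEnergyTable <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("EnergyTable", dd = unlist(x$dd), rd = unlist(x$rd),
      label = if (is.null(x$label)) "user" else x$label)
}

#' Write an energy table to JSON
#' @param table an [EnergyTable]
#' @param path output path
#' @export
writeEnergyTable <- function(table, path) {
  jsonlite::write_json(list(dd = as.list(table@dd), rd = as.list(table@rd),
                            label = table@label),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Build a free-energy landscape of R-loop formation
#'
#' Parametric mode: starting from G(unbound) = 0, PAM binding lowers the
#' energy by `pamGain`; each hybrid extension over a matched base pair
#' lowers it by `matchGain`; extension over a mismatched position raises
#' it by `mismatchCost` when the preceding position is matched and by
#' `bubbleExtensionCost` when it extends an existing bubble. Mismatch
#' positions are counted PAM-proximal = 1 (the order in which the R-loop
#' encounters them).
#'
#' Sequence mode (see [sequenceLandscape()]): increments are the
#' dinucleotide stacking-energy differences DNA:DNA - RNA:DNA.
#'
#' @param mismatchPositions integer vector of mismatched protospacer
#'   positions (1..20), possibly empty
#' @param params a [KineticParameters]
#' @return a [FreeEnergyLandscape] over states unbound, pam, h1..h20
#' @examples
#' buildLandscape(c(10, 11))
#' @export
buildLandscape <- function(mismatchPositions = integer(0),
                           params = kineticParameters()) {
  mp <- sort(unique(as.integer(mismatchPositions)))
  if (length(mp) && (min(mp) < 1L || max(mp) > 20L))
    stop("mismatch positions must be in 1..20")
  isMm <- rep(FALSE, 20L)
  isMm[mp] <- TRUE
  step <- numeric(20L)
  for (p in 1:20) {
    step[p] <- if (!isMm[p]) -params@matchGain
    else if (p > 1L && isMm[p - 1L]) params@bubbleExtensionCost
    else params@mismatchCost
  }
  G <- c(0, -params@pamGain, -params@pamGain + cumsum(step))
  names(G) <- c("unbound", "pam", paste0("h", 1:20))
  new("FreeEnergyLandscape", G = G, mode = "parametric")
}

#' Sequence-based free-energy landscape
#'
#' Landscape increments are the differences of dinucleotide stacking
#' energy between the DNA:DNA duplex being opened and the RNA:DNA hybrid
#' being formed, accumulated along the protospacer from the PAM-proximal
#' end. The PAM-binding gain of `params` anchors the bound branch.
#'
#' @param protospacer 20-nt protospacer (or guide) sequence, 5'->3'
#' @param energyTable an [EnergyTable]
#' @param params a [KineticParameters] (only `pamGain` is used)
#' @return a [FreeEnergyLandscape] over unbound, pam, h1..h20
#' @export
sequenceLandscape <- function(protospacer, energyTable = defaultEnergyTable(),
                              params = kineticParameters()) {
  protospacer <- checkGuide20(protospacer)[[1L]]
  cc <- chars(protospacer)
  # the R-loop proceeds PAM-proximal (string end) to PAM-distal
  di <- paste0(rev(cc)[1:19], rev(cc)[2:20])
  bad <- setdiff(di, dinucleotideOrder())
  if (length(bad)) stop("unknown dinucleotide: ", paste(bad, collapse = ", "))
  inc <- energyTable@dd[di] - energyTable@rd[di]
  G <- c(0, -params@pamGain, -params@pamGain + c(0, unname(cumsum(inc))))
  names(G) <- c("unbound", "pam", paste0("h", 1:20))
  new("FreeEnergyLandscape", G = G, mode = "sequence")
}

#' Count mismatch bubbles
#'
#' A bubble is a maximal run of consecutive mismatched positions in the
#' RNA:DNA hybrid; adjacent mismatches share one bubble.
#'
#' @param positions integer vector of mismatched positions
#' @return integer bubble count
#' @examples
#' countBubbles(c(2, 5, 6, 9))  # 3
#' @export
countBubbles <- function(positions) {
  p <- sort(unique(as.integer(positions)))
  if (length(p) == 0L) return(0L)
  sum(diff(c(-10L, p)) > 1L)
}

#' Maximum barrier of a landscape
#'
#' The height of the largest free-energy barrier met during R-loop
#' extension, relative to the barrier to unbinding: with G(unbound) fixed
#' at 0, this is the maximum free energy over the bound states. A
#' negative value means cleavage is downhill relative to unbinding.
#'
#' @param landscape a [FreeEnergyLandscape]
#' @return numeric, kB*T
#' @export
maxBarrier <- function(landscape) {
  max(landscape@G[-1L])
}

# Arrhenius hop rates between adjacent bound states (detailed balance):
# k(i -> j) = attemptRate * exp(-max(0, G_j - G_i))
hopRates <- function(G, attemptRate = 1) {
  n <- length(G)
  fwd <- attemptRate * exp(-pmax(0, G[-1L] - G[-n]))   # i -> i+1
  bwd <- attemptRate * exp(-pmax(0, G[-n] - G[-1L]))   # i+1 -> i
  list(fwd = fwd, bwd = bwd)
}

#' Probability of cleavage before unbinding
#'
#' Splitting probability of the absorbing nearest-neighbour chain:
#' absorbing at the unbound state on the left and at cleavage (beyond the
#' full 20-bp hybrid) on the right; hops have Arrhenius rates satisfying
#' detailed balance against the landscape, the final cleavage step is
#' taken barrierless. Started from the first bound state (PAM-bound) and
#' solved exactly as a linear system by first-step analysis.
#'
#' @param landscape a [FreeEnergyLandscape]
#' @param params a [KineticParameters] (attempt rate)
#' @return probability in [0, 1]
#' @export
cleavageProbability <- function(landscape, params = kineticParameters()) {
  G <- unname(landscape@G)
  n <- length(G)                     # states 1..n; 1 = unbound
  r <- hopRates(G, params@attemptRate)
  # first-step analysis on the jump chain: u_i = P(cleave | start i)
  m <- n - 1L                        # interior states
  pr <- numeric(m)
  for (i in seq_len(m)) {
    st <- i + 1L
    kf <- if (st < n) r$fwd[st] else params@attemptRate
    kb <- r$bwd[st - 1L]
    pr[i] <- kf / (kf + kb)
  }
  # tridiagonal solve: u_i = pr_i * u_{i+1} + (1 - pr_i) * u_{i-1},
  # u_0 = 0 (unbound), u_{m+1} = 1 (cleaved)
  A <- diag(m)
  b <- numeric(m)
  for (i in seq_len(m)) {
    if (i > 1L) A[i, i - 1L] <- -(1 - pr[i])
    if (i < m) A[i, i + 1L] <- -pr[i]
    if (i == m) b[i] <- pr[i]
  }
  u <- solve(A, b)
  min(max(u[1L], 0), 1)
}

#' Simulate the kinetic chain (jump-chain Monte Carlo)
#'
#' Stochastic counterpart of [cleavageProbability()]: trajectories of the
#' embedded jump chain, started at the PAM-bound state, run until
#' absorption at unbinding or cleavage.
#'
#' @param landscape a [FreeEnergyLandscape]
#' @param n number of trajectories
#' @param seed RNG seed
#' @param params a [KineticParameters]
#' @param maxSteps safety cap per trajectory
#' @return list with `pCleave`, `se` (binomial standard error), `n`
#' @export
simulateCleavage <- function(landscape, n = 1e5, seed = 1L,
                             params = kineticParameters(),
                             maxSteps = 1e6L) {
  G <- unname(landscape@G)
  ns <- length(G)
  pr <- numeric(ns)                  # P(step right | at state), states 2..ns
  r <- hopRates(G, params@attemptRate)
  for (st in 2:ns) {
    kf <- if (st < ns) r$fwd[st] else params@attemptRate
    kb <- r$bwd[st - 1L]
    pr[st] <- kf / (kf + kb)
  }
  withSeed(seed, {
    state <- rep(2L, n)              # PAM-bound
    done <- logical(n)
    cleaved <- logical(n)
    steps <- 0L
    while (!all(done) && steps < maxSteps) {
      steps <- steps + 1L
      act <- which(!done)
      up <- runif(length(act)) < pr[state[act]]
      state[act] <- state[act] + ifelse(up, 1L, -1L)
      newCleaved <- state[act] > ns
      newLost <- state[act] < 2L
      cleaved[act[newCleaved]] <- TRUE
      done[act[newCleaved | newLost]] <- TRUE
    }
    p <- mean(cleaved)
    list(pCleave = p, se = sqrt(p * (1 - p) / n), n = n)
  })
}

#' Model-predicted combinatorial-effect heatmap
#'
#' For every position pair (i, j), the deviation from independence under
#' the kinetic model:
#' delta_model(i, j) = P(i, j) * P(0) / (P(i) * P(j)),
#' where P(.) is the cleavage probability of the landscape carrying the
#' given mismatches.
#'
#' @param params a [KineticParameters]
#' @return symmetric 20 x 20 matrix (diagonal NA)
#' @export
expectedDeltaHeatmap <- function(params = kineticParameters()) {
  p0 <- cleavageProbability(buildLandscape(integer(0), params), params)
  p1 <- vapply(1:20, function(i)
    cleavageProbability(buildLandscape(i, params), params), numeric(1))
  out <- matrix(NA_real_, 20L, 20L,
                dimnames = list(paste0("pos", 1:20), paste0("pos", 1:20)))
  for (i in 1:19) for (j in (i + 1):20) {
    pij <- cleavageProbability(buildLandscape(c(i, j), params), params)
    out[i, j] <- out[j, i] <- pij * p0 / (p1[i] * p1[j])
  }
  out
}
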