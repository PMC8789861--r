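# Cleavage-state inference: transition-matrix estimation from PAM
# controls, non-negative least-squares state deconvolution and off-on
# ratios.

#' Construct a cleavage-editing model
#' @param P 4 x 5 row-stochastic matrix honouring the structural zeros
#' @return a [CleavageModel]
#' @export
cleavageModel <- function(P) {
  dimnames(P) <- list(STATE_LEVELS, OUTCOME_LEVELS)
  new("CleavageModel", P = P)
}

#' Estimate the cleavage-editing transition matrix from PAM controls
#'
#' Controls are dual-target constructs whose two identical protospacers
#' are silenced (NTT) or active (NGG) per target, giving the four
#' cleavage types. The no-cleavage row is the pooled, normalized NTT+NTT
#' outcome distribution (background noise). Rows 2 and 3 are solved from
#' their control groups as two-component mixtures of the noise row and
#' the state row: outcome categories structurally closed to the state
#' identify the noise weight, the remainder is attributed to the state
#' row on its admissible categories. Row 4 is solved from the NGG+NGG
#' group, whose reads mix all four states (either target may escape
#' cleavage), by explicit linear equations using the already-estimated
#' rows 1-3. Negative solutions are clipped to 0 and rows renormalized.
#'
#' @param counts integer matrix of pooled or per-construct outcome counts
#'   (columns c1..c5)
#' @param pamType character vector (one per row of `counts`) in
#'   `"NTT+NTT"`, `"NGG+NTT"`, `"NTT+NGG"`, `"NGG+NGG"`
#' @return a [CleavageModel]
#' @export
estimateTransitionMatrix <- function(counts, pamType) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 5L, nrow(counts) == length(pamType))
  groups <- c("NTT+NTT", "NGG+NTT", "NTT+NGG", "NGG+NGG")
  miss <- setdiff(groups, pamType)
  if (length(miss))
    stop("missing control groups: ", paste(miss, collapse = ", "))
  pooled <- t(vapply(groups, function(g)
    colSums(counts[pamType == g, , drop = FALSE]), numeric(5)))
  P1 <- pooled[1L, ] / sum(pooled[1L, ])
  P <- matrix(0, 4L, 5L)
  P[1L, ] <- P1
  # rows 2 and 3: two-component mixture (noise + state)
  for (st in 2:3) {
    f <- pooled[st, ] / sum(pooled[st, ])
    open <- P_MASK[st, ]                 # admissible outcome categories
    denom <- sum(P1[!open])
    if (denom <= 0)
      stop("controls indistinguishable from noise: no closed category ",
           "carries noise mass for state ", STATE_LEVELS[st])
    noiseWeight <- min(sum(f[!open]) / denom, 1) # (1 - w), w = state frac.
    w <- 1 - noiseWeight
    if (w <= 1e-8)
      stop("controls indistinguishable from noise for state ",
           STATE_LEVELS[st], ": no cleavage signal above background")
    row <- (f - noiseWeight * P1) / w
    row[!open] <- 0
    row[row < 0] <- 0
    if (sum(row) <= 0)
      stop("degenerate state row for ", STATE_LEVELS[st])
    P[st, ] <- row / sum(row)
  }
  # row 4: NGG+NGG reads mix all four states; with rows 1-3 known the
  # five category equations determine the state weights and the two free
  # entries p44, p45 exactly
  f <- pooled[4L, ] / sum(pooled[4L, ])
  if (P1[1L] <= 0)
    stop("noise row carries no wt_wt mass; cannot separate state weights")
  w1 <- f[1L] / P1[1L]
  w3 <- (f[3L] - w1 * P1[3L]) / P[3L, 3L]
  w3 <- max(w3, 0)
  u4 <- f[4L] - w1 * P1[4L]              # w4 * p44
  v4 <- f[5L] - w1 * P1[5L] - w3 * P[3L, 5L]  # w4 * p45
  u4 <- max(u4, 0); v4 <- max(v4, 0)
  if (u4 + v4 <= 0)
    stop("controls indistinguishable from noise for state both: ",
         "no cleavage signal above background")
  P[4L, 4:5] <- c(u4, v4) / (u4 + v4)
  cleavageModel(P)
}

#' Infer cleavage-state read counts by non-negative least squares
#'
#' Minimizes || P^T S - C ||^2 subject to S >= 0 (Lawson-Hanson NNLS).
#'
#' @param C numeric vector of outcome counts c1..c5 (or a matrix with one
#'   construct per row)
#' @param model a [CleavageModel]
#' @return numeric vector S = (s1..s4) of expected reads per cleavage
#'   state (or a matrix, one row per construct)
#' @export
inferStates <- function(C, model) {
  A <- t(transitionMatrix(model))        # 5 x 4
  solve1 <- function(cvec) {
    if (all(cvec == 0)) return(setNames(numeric(4L), STATE_LEVELS))
    s <- pracma::lsqnonneg(A, as.numeric(cvec))$x
    setNames(s, STATE_LEVELS)
  }
  if (is.matrix(C)) {
    out <- t(apply(C, 1L, solve1))
    colnames(out) <- STATE_LEVELS
    out
  } else solve1(C)
}

#' Off-on ratio from cleavage-state counts
#'
#' r = (s2 + s4) / (s3 + s4): reads cleaved at the off-target relative to
#' reads cleaved at the on-target. Pairs with fewer than `minEdited`
#' on-target-edited reads are flagged as failing the depth filter; the
#' log ratio is log(r + c) (natural log) with pseudo-count `c`.
#'
#' @param S numeric state vector (s1..s4) or matrix (one row per
#'   construct) from [inferStates()]
#' @param minEdited minimum s3 + s4 (default 100)
#' @param c pseudo-count on the ratio scale (default 0.01)
#' @return data.frame with `r`, `log_r`, `edited_on`, `passed_filter`
#' @export
offOnRatio <- function(S, minEdited = 100, c = 0.01) {
  if (!is.matrix(S)) S <- matrix(S, nrow = 1L,
                                 dimnames = list(NULL, STATE_LEVELS))
  editedOn <- S[, 3L] + S[, 4L]
  r <- ifelse(editedOn > 0, (S[, 2L] + S[, 4L]) / editedOn, NA_real_)
  data.frame(r = r, log_r = log(r + c), edited_on = editedOn,
             passed_filter = !is.na(r) & editedOn >= minEdited,
             row.names = rownames(S))
}

#' Infer off-on ratios for a matrix of outcome counts
#'
#' Convenience wrapper: [inferStates()] followed by [offOnRatio()],
#' returning one row per construct with the state estimates attached.
#'
#' @inheritParams inferStates
#' @inheritParams offOnRatio
#' @return data.frame with columns s1..s4, `r`, `log_r`, `edited_on`,
#'   `passed_filter`
#' @export
inferOffOnRatios <- function(C, model, minEdited = 100, c = 0.01) {
  S <- inferStates(C, model)
  if (!is.matrix(S)) S <- matrix(S, nrow = 1L,
                                 dimnames = list(NULL, STATE_LEVELS))
  cbind(as.data.frame(S), offOnRatio(S, minEdited = minEdited, c = c))
}
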