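# Decomposition of off-on ratios: the multiplicative single-mismatch /
# guide-intrinsic model (M1 + GMT), the pairwise combinatorial effects
# (M2 / delta) and the relative co-occurrence score (RCS).

#' Build a MismatchMatrix
#' @param values 12 x 20 numeric matrix (rows in [mismatchPairLabels()]
#'   order, columns positions 1..20)
#' @return a [MismatchMatrix]
#' @export
mismatchMatrix <- function(values) {
  dimnames(values) <- list(mismatchPairLabels(), paste0("pos", 1:20))
  new("MismatchMatrix", values = values)
}

#' Look up single-mismatch effects
#' @param m1 a [MismatchMatrix]
#' @param profile a mismatch profile data.frame ([mismatchProfile()])
#' @return numeric vector of effects, one per mismatch
#' @export
m1Lookup <- function(m1, profile) {
  if (nrow(profile) == 0L) return(numeric(0))
  values(m1)[cbind(match(profile$pairing, mismatchPairLabels()),
                   profile$position)]
}

#' Fit the multiplicative single-mismatch / GMT model
#'
#' Decomposes log off-on ratios of single-mismatch targets into a
#' mismatch-dependent effect m_j (by rX:dY pairing and position; the M1
#' matrix) and a guide-intrinsic mismatch tolerance g_i, by full-batch
#' gradient descent on the least-squares objective
#' sum (log(r + c) - log m_j - log g_i)^2. The multiplicative gauge
#' freedom is fixed by centering log g to mean zero over the fitted
#' guides, so M1 is interpretable as the effect for a guide of average
#' tolerance.
#'
#' @param obs data.frame with columns `guide_id`, `pairing` (rX:dY),
#'   `position` (1..20) and `r` (off-on ratio, linear scale)
#' @param c pseudo-count added before the log (default 0.01)
#' @param lr learning rate of the full-batch gradient descent
#' @param maxIter,tol iteration cap and objective-change tolerance
#' @return list with `m1` (a [MismatchMatrix]), `gmt` (data.frame
#'   `guide_id`, `g`, `log_g`), `objective`, `iterations`, `converged`
#' @export
fitM1Gmt <- function(obs, c = 0.01, lr = 0.3, maxIter = 20000L,
                     tol = 1e-10) {
  stopifnot(all(c("guide_id", "pairing", "position", "r") %in% names(obs)))
  type <- paste0(obs$pairing, "@", obs$position)
  typeLevels <- enumerateMismatchTypes()$label
  j <- match(type, typeLevels)
  if (anyNA(j)) stop("unknown mismatch type(s): ",
                     paste(unique(type[is.na(j)]), collapse = ", "))
  guides <- unique(obs$guide_id)
  i <- match(obs$guide_id, guides)
  y <- log(obs$r + c)
  # connectivity check on the guide/type bipartite graph
  comp <- bipartiteComponents(i, j, length(guides), length(typeLevels))
  if (comp > 1L)
    warning("observation graph has ", comp, " connected components; ",
            "the gauge is ambiguous across components")
  nj <- tabulate(j, length(typeLevels))
  ni <- tabulate(i, length(guides))
  a <- numeric(length(typeLevels))       # log m_j, zero-initialized
  b <- numeric(length(guides))           # log g_i
  obj <- Inf
  iter <- 0L
  converged <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    resid <- y - a[j] - b[i]
    newObj <- sum(resid^2)
    if (is.finite(obj) && abs(obj - newObj) < tol * max(1, obj)) {
      converged <- TRUE
      obj <- newObj
      break
    }
    obj <- newObj
    # gradient step, per-parameter scaled by its observation count
    ga <- rowsum(resid, j, reorder = FALSE)
    a[unique(j)] <- a[unique(j)] + lr * ga[, 1L] / nj[unique(j)]
    resid <- y - a[j] - b[i]
    gb <- rowsum(resid, i, reorder = FALSE)
    b[unique(i)] <- b[unique(i)] + lr * gb[, 1L] / ni[unique(i)]
  }
  # gauge: mean log g = 0
  shift <- mean(b)
  b <- b - shift
  a <- a + shift
  types <- enumerateMismatchTypes()
  vals <- matrix(NA_real_, 12L, 20L)
  vals[cbind(match(types$pairing, mismatchPairLabels()), types$position)] <-
    exp(a)
  unobserved <- matrix(FALSE, 12L, 20L)
  unobserved[cbind(match(types$pairing, mismatchPairLabels()),
                   types$position)[nj == 0L, , drop = FALSE]] <- TRUE
  vals[unobserved] <- 1                  # unobserved types default to 1
  list(m1 = mismatchMatrix(vals),
       gmt = data.frame(guide_id = guides, g = exp(b), log_g = b,
                        stringsAsFactors = FALSE),
       objective = obj, iterations = iter, converged = converged)
}

# number of connected components of the bipartite observation graph
bipartiteComponents <- function(i, j, nGuide, nType) {
  seen <- unique(cbind(i, j))
  parent <- seq_len(nGuide + nType)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(nrow(seen))) {
    a <- find(seen[k, 1L]); b <- find(nGuide + seen[k, 2L])
    if (a != b) parent[a] <- b
  }
  used <- c(unique(i), nGuide + unique(j))
  length(unique(vapply(used, find, integer(1))))
}

#' Estimate pairwise combinatorial effects (M2 / delta)
#'
#' For each position pair (i, j) the estimator pools 2-MM observations
#' with mismatches at (i, j) and the four adjacent pairs (i, j-1),
#' (i, j+1), (i-1, j), (i+1, j) (clipped at positions 1 and 20), and
#' applies the closed-form least-squares solution
#' delta_ij = sum(x y z) / sum((y z)^2), where x is the 2-MM off-on ratio
#' and y, z the off-on ratios of its two constituent 1-MM targets, all on
#' the linear scale.
#'
#' @param obs data.frame with columns `pos_i`, `pos_j` (mismatch
#'   positions, 1..20), `x` (2-MM ratio), `y`, `z` (parent 1-MM ratios)
#' @return a [CombinatorialMatrix]
#' @export
estimateDelta <- function(obs) {
  stopifnot(all(c("pos_i", "pos_j", "x", "y", "z") %in% names(obs)))
  lo <- pmin(obs$pos_i, obs$pos_j)
  hi <- pmax(obs$pos_i, obs$pos_j)
  vals <- matrix(NA_real_, 20L, 20L)
  nmat <- matrix(0L, 20L, 20L)
  for (i in 1:19) for (j in (i + 1):20) {
    neigh <- rbind(c(i, j), c(i, j - 1L), c(i, j + 1L), c(i - 1L, j),
                   c(i + 1L, j))
    neigh <- neigh[neigh[, 1L] >= 1L & neigh[, 2L] <= 20L &
                   neigh[, 1L] < neigh[, 2L], , drop = FALSE]
    sel <- rep(FALSE, nrow(obs))
    for (k in seq_len(nrow(neigh)))
      sel <- sel | (lo == neigh[k, 1L] & hi == neigh[k, 2L])
    if (!any(sel)) next
    yz <- obs$y[sel] * obs$z[sel]
    denom <- sum(yz^2)
    if (denom <= 0) next
    est <- sum(obs$x[sel] * yz) / denom
    vals[i, j] <- vals[j, i] <- max(est, .Machine$double.eps)
    nmat[i, j] <- nmat[j, i] <- sum(sel)
  }
  dimnames(vals) <- dimnames(nmat) <- list(paste0("pos", 1:20),
                                           paste0("pos", 1:20))
  new("CombinatorialMatrix", values = vals, n = nmat)
}

#' Build a CombinatorialMatrix from a plain matrix
#' @param values symmetric 20 x 20 numeric matrix (NA allowed)
#' @param n optional observation-count matrix
#' @return a [CombinatorialMatrix]
#' @export
combinatorialMatrix <- function(values, n = NULL) {
  if (is.null(n)) n <- matrix(ifelse(is.na(values), 0L, 1L), 20L, 20L)
  dimnames(values) <- dimnames(n) <- list(paste0("pos", 1:20),
                                          paste0("pos", 1:20))
  new("CombinatorialMatrix", values = values, n = n)
}

#' Relative co-occurrence score of mismatch position pairs
#'
#' For each guide with n detected off-target sites,
#' RCS(i, j) = a_ij * n / (b_i * c_j), where a_ij counts sites with
#' mismatches at both positions and b_i, c_j sites with a mismatch at
#' each position; the per-guide matrices are averaged over guides
#' (cells with b_i * c_j = 0 are missing for that guide).
#'
#' @param profiles list (one element per guide) of lists of integer
#'   mismatch-position vectors, one vector per off-target site
#' @return 20 x 20 numeric matrix of averaged RCS values (NaN where no
#'   guide informs a cell)
#' @export
computeRcs <- function(profiles) {
  acc <- matrix(0, 20L, 20L)
  cnt <- matrix(0L, 20L, 20L)
  for (sites in profiles) {
    n <- length(sites)
    if (n == 0L) next
    ind <- matrix(0L, n, 20L)
    for (s in seq_len(n)) ind[s, sites[[s]]] <- 1L
    b <- colSums(ind)
    a <- crossprod(ind)                  # a[i, j] = sites with both
    denom <- outer(b, b)
    ok <- denom > 0
    rcs <- matrix(NA_real_, 20L, 20L)
    rcs[ok] <- a[ok] * n / denom[ok]
    acc[ok] <- acc[ok] + rcs[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  out <- acc / cnt
  dimnames(out) <- list(paste0("pos", 1:20), paste0("pos", 1:20))
  out
}
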