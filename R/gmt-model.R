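# GMT prediction from guide sequence: mono/dinucleotide one-hot
# encodings and a small convolutional regression (k kernels spanning the
# full encoding row dimension, width one position pair, followed by a
# dense layer terminating in a single neuron).

#' Row order of the dinucleotide encoding
#' @return character(16) in the canonical order
#' @export
dinucleotideOrder <- function() {
  c("AT", "AC", "AG", "AA", "TT", "TA", "TG", "TC",
    "CC", "CA", "CG", "CT", "GG", "GA", "GT", "GC")
}

checkGuide20 <- function(guide) {
  guide <- gsub("U", "T", toupper(guide), fixed = TRUE)
  if (any(nchar(guide) != 20L) || any(grepl("[^ACGT]", guide)))
    stop("guides must be 20 nt over {A,C,G,T,U}")
  guide
}

#' Mononucleotide one-hot encoding of a guide
#' @param guide 20-nt guide sequence
#' @return 4 x 20 binary matrix; rows A, T, C, G, columns positions 5'->3'
#' @export
encodeMono <- function(guide) {
  guide <- checkGuide20(guide)[[1L]]
  bases <- c("A", "T", "C", "G")
  m <- matrix(0L, 4L, 20L, dimnames = list(bases, NULL))
  m[cbind(match(chars(guide), bases), 1:20)] <- 1L
  m
}

#' Dinucleotide one-hot encoding of a guide
#' @param guide 20-nt guide sequence
#' @return 16 x 19 binary matrix; rows in [dinucleotideOrder()], columns
#'   the 19 consecutive position pairs 5'->3'
#' @export
encodeDi <- function(guide) {
  idx <- diIndices(checkGuide20(guide)[[1L]])
  m <- matrix(0L, 16L, 19L, dimnames = list(dinucleotideOrder(), NULL))
  m[cbind(idx, 1:19)] <- 1L
  m
}

# integer dinucleotide row indices (length 19) for each guide
diIndices <- function(guide) {
  cc <- chars(guide)
  di <- paste0(cc[1:19], cc[2:20])
  match(di, dinucleotideOrder())
}

# n x 19 matrix of dinucleotide indices for a vector of guides
diIndexMatrix <- function(guides) {
  guides <- checkGuide20(guides)
  t(vapply(guides, diIndices, integer(19)))
}

# sparse n x (16*19) design matrix; column (t-1)*16 + d flags
# dinucleotide d at position pair t
diDesignMatrix <- function(idx) {
  n <- nrow(idx)
  jj <- as.vector(t(idx) + 16L * (seq_len(19L) - 1L))
  ii <- rep(seq_len(n), each = 19L)
  Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, 16L * 19L))
}

# effective dense weight matrix: M[d, t] contribution of dinucleotide d
# at pair t; prediction = sum_t M[d_t, t] + bias
effectiveWeights <- function(model) t(model@W) %*% model@V

gmtForward <- function(Z, M, bias) as.numeric(Z %*% as.vector(M)) + bias

# One training run of the factorized linear convolutional regression.
# Full-batch gradient descent with backtracking: a step that increases
# the loss is reverted and the learning rate halved, which keeps the
# jointly-trained kernel/dense factors from diverging.
gmtFit <- function(Z, y, kernels, epochs, lr, seed) {
  n <- nrow(Z)
  withSeed(seed, {
    W <- matrix(rnorm(kernels * 16L, sd = 0.1), kernels, 16L)
    V <- matrix(rnorm(kernels * 19L, sd = 0.1), kernels, 19L)
  })
  bias <- mean(y)
  Zt <- Matrix::t(Z)
  loss <- mean((y - gmtForward(Z, t(W) %*% V, bias))^2)
  for (e in seq_len(epochs)) {
    M <- t(W) %*% V
    resid <- y - gmtForward(Z, M, bias)
    dM <- matrix(as.numeric(Zt %*% resid), 16L, 19L) * (2 / n)
    Wn <- W + lr * (V %*% t(dM))
    Vn <- V + lr * (Wn %*% dM)
    biasn <- bias + lr * 2 * mean(resid)
    lossn <- mean((y - gmtForward(Z, t(Wn) %*% Vn, biasn))^2)
    if (is.finite(lossn) && lossn <= loss * (1 + 1e-9)) {
      W <- Wn; V <- Vn; bias <- biasn; loss <- lossn
    } else {
      lr <- lr / 2
      if (lr < 1e-8) break
    }
  }
  list(W = W, V = V, bias = bias, loss = loss)
}

#' Train the dinucleotide convolutional GMT regression
#'
#' Fits log-GMT targets with a one-convolution-layer, one-dense-layer
#' regression: each of `kernels` kernels spans all 16 dinucleotide rows
#' with width one position pair, so kernels act as learned
#' dinucleotide-weight profiles; the dense layer combines the 19 kernel
#' activations into a single output neuron. Training is full-batch
#' gradient descent on mean squared error; all randomness
#' (initialization, fold assignment) is seed-controlled. Cross-validated
#' performance is reported as the per-fold Spearman correlation between
#' predicted and held-out log-GMT; the returned model is refit on all
#' data.
#'
#' @param guides character vector of 20-nt guides (or a [GuideSet])
#' @param logGmt numeric vector of log-scale GMT targets
#' @param kernels number of convolution kernels (default 3)
#' @param folds cross-validation folds (default 5)
#' @param seed RNG seed
#' @param epochs,lr gradient-descent schedule
#' @return a [GmtModel]; `model@meta$cv` holds the fold report
#' @export
trainGmt <- function(guides, logGmt, kernels = 3L, folds = 5L, seed = 1L,
                     epochs = 1500L, lr = 0.05) {
  if (is(guides, "GuideSet")) guides <- unname(spacers(guides))
  n <- length(guides)
  stopifnot(length(logGmt) == n)
  if (n < 10L * folds)
    stop("need at least ", 10L * folds, " training pairs for ", folds,
         "-fold cross-validation")
  if (stats::sd(logGmt) == 0) stop("degenerate targets: zero variance")
  Z <- diDesignMatrix(diIndexMatrix(guides))
  foldId <- withSeed(seed, sample(rep_len(seq_len(folds), n)))
  cv <- data.frame(fold = seq_len(folds), spearman = NA_real_)
  for (f in seq_len(folds)) {
    tr <- foldId != f
    fit <- gmtFit(Z[tr, , drop = FALSE], logGmt[tr], kernels, epochs, lr,
                  seed = seed + f)
    pred <- gmtForward(Z[!tr, , drop = FALSE],
                       t(fit$W) %*% fit$V, fit$bias)
    cv$spearman[f] <- stats::cor(pred, logGmt[!tr], method = "spearman")
  }
  fit <- gmtFit(Z, logGmt, kernels, epochs, lr, seed = seed)
  new("GmtModel", W = fit$W, V = fit$V, bias = fit$bias,
      meta = list(seed = seed, epochs = epochs, lr = lr, kernels = kernels,
                  folds = folds, loss = fit$loss, cv = cv))
}

#' Predict GMT for guides
#'
#' @param model a [GmtModel]
#' @param guides character vector of 20-nt guides (or a [GuideSet])
#' @return data.frame with `guide`, `log_gmt` and `gmt` (= exp(log_gmt))
#' @export
predictGmt <- function(model, guides) {
  if (is(guides, "GuideSet")) guides <- unname(spacers(guides))
  Z <- diDesignMatrix(diIndexMatrix(guides))
  lg <- gmtForward(Z, effectiveWeights(model), model@bias)
  data.frame(guide = guides, log_gmt = lg, gmt = exp(lg),
             stringsAsFactors = FALSE)
}

#' Kernel-derived dinucleotide weights
#'
#' The position-averaged contribution of each dinucleotide to the
#' prediction, summarizing what the kernels learned.
#'
#' @param model a [GmtModel]
#' @return named numeric(16)
#' @export
dinucWeights <- function(model) {
  M <- effectiveWeights(model)
  setNames(rowMeans(M), dinucleotideOrder())
}

#' Contrast mean free-energy landscapes of two guide sets
#'
#' Per-position mean cumulative stacking-energy difference
#' (DNA:DNA - RNA:DNA) along the guide, for a high-GMT and a low-GMT
#' guide set.
#'
#' @param highSet,lowSet character vectors of 20-nt guides
#' @param energyTable an [EnergyTable]
#' @return data.frame with `position` (1..19 dinucleotide steps, 5'->3'),
#'   `mean_high`, `mean_low`
#' @export
landscapeContrast <- function(highSet, lowSet, energyTable = defaultEnergyTable()) {
  curve <- function(set) {
    idx <- diIndexMatrix(set)
    d <- energyTable@dd[dinucleotideOrder()] -
         energyTable@rd[dinucleotideOrder()]
    steps <- matrix(d[idx], nrow = nrow(idx))
    colMeans(t(apply(steps, 1L, cumsum)))
  }
  data.frame(position = 1:19, mean_high = curve(highSet),
             mean_low = curve(lowSet))
}

#' Serialize a GmtModel to JSON
#' @param model a [GmtModel]
#' @param path output path
#' @export
writeGmtModel <- function(model, path) {
  jsonlite::write_json(list(W = model@W, V = model@V, bias = model@bias,
                            meta = model@meta[c("seed", "epochs", "lr",
                                                "kernels", "folds")]),
                       path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read a GmtModel from JSON
#' @param path a file written by [writeGmtModel()]
#' @return a [GmtModel]
#' @export
readGmtModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("GmtModel", W = as.matrix(x$W), V = as.matrix(x$V),
      bias = as.numeric(x$bias), meta = as.list(x$meta))
}
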