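#' Supervised PLS component extraction
#'
#' Extracts `k` orthogonal partial least squares components from a
#' standardised indicator block `X` against a target `y`.  The first
#' component's weights are proportional to the covariances of the columns of
#' `X` with `y` -- the direction maximising covariance with the target --
#' and subsequent components repeat the construction on the deflated block,
#' so successive score vectors are mutually orthogonal.  This is the
#' single-response NIPALS scheme used to summarise strongly collinear
#' intensity-spectrum blocks.
#'
#' @param X Numeric matrix (n x p) with standardised columns.
#' @param y Numeric target vector, standardised, length n.
#' @param k Number of components; must not exceed the rank of `X`.
#' @param tol Weight norm below which the covariance direction is declared
#'   degenerate (target uncorrelated with the block).
#' @return A list with `scores` (n x k, columns orthogonal), `weights`
#'   (p x k, deflated-space weights, unit norm), `loadings` (p x k),
#'   `projection` (p x k matrix `W (P'W)^{-1}` so `scores = X %*% projection`)
#'   and a logical `degenerate` flag.
#' @export
pls_components <- function(X, y, k, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) abort("`y` must have one value per row of `X`.")
  if (n <= k) abort("Need more observations than components.")
  rank_x <- qr(X)$rank
  if (k > rank_x) {
    abort(sprintf("k = %d exceeds the rank of X (%d).", k, rank_x))
  }
  W <- P <- matrix(0, p, k)
  Tm <- matrix(0, n, k)
  Xd <- X
  degenerate <- FALSE
  for (j in seq_len(k)) {
    w <- drop(crossprod(Xd, y)) / (n - 1)
    nw <- sqrt(sum(w^2))
    if (nw < tol) {
      degenerate <- TRUE
      warn(sprintf("Component %d: target covariance ~ 0; block degenerate.", j))
      # fall back to the dominant variance direction so scores stay defined
      w <- svd(Xd, nu = 0, nv = 1)$v[, 1]
      nw <- 1
    }
    w <- w / nw
    t_j <- drop(Xd %*% w)
    pj <- drop(crossprod(Xd, t_j)) / sum(t_j^2)
    Xd <- Xd - tcrossprod(t_j, pj)
    W[, j] <- w; P[, j] <- pj; Tm[, j] <- t_j
  }
  projection <- W %*% solve(crossprod(P, W))
  list(scores = Tm, weights = W, loadings = P, projection = projection,
       degenerate = degenerate)
}

# standardise matrix columns; optionally drop zero-variance columns with a
# warning (names reported).  Returns list(x, dropped, center, scale).
standardize_columns <- function(X, drop_constant = TRUE) {
  X <- as.matrix(X)
  cen <- colMeans(X)
  scl <- apply(X, 2, sd)
  bad <- !is.finite(scl) | scl == 0
  if (any(bad)) {
    if (!drop_constant) abort(paste0(
      "Zero-variance indicator(s): ", paste(colnames(X)[bad], collapse = ", ")
    ))
    warn(paste0("Dropping zero-variance indicator(s): ",
                paste(colnames(X)[bad], collapse = ", ")))
  }
  keep <- which(!bad)
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, cen[keep]), 2, scl[keep], "/")
  list(x = Xs, dropped = colnames(X)[bad], center = cen[keep], scale = scl[keep])
}
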