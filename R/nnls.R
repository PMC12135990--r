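#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves \eqn{\min_w \|A w - b\|_2} subject to \eqn{w \ge 0} with the
#' Lawson-Hanson active-set algorithm, which terminates at the exact
#' Karush-Kuhn-Tucker point: the residual is orthogonal to every active
#' (positive-weight) column and the gradient is non-positive on every
#' zero-weight column.  Ties in the column-selection step resolve to the
#' lowest column index, making the solve deterministic for duplicate
#' columns.  Columns are normalized to unit 2-norm internally (the problem
#' is scale-equivariant), which keeps the active-set iteration
#' well-conditioned for near-duplicate columns such as adjacent
#' trajectory frames.
#'
#' @param A numeric matrix (n x m).
#' @param b numeric right-hand side of length n.
#' @param tol tolerance for the dual feasibility (optimality) test, on the
#'   unit-column scale; defaults to \code{10 * eps * max(n, m) * ||b||}.
#' @return list with \code{x} (the weight vector, length m),
#'   \code{residual} (b - A x) and \code{deviance} (squared residual norm).
#' @export
nnls <- function(A, b, tol = NULL) {
  A <- as.matrix(A)
  n <- nrow(A); m <- ncol(A)
  stopifnot(length(b) == n)
  nrm <- sqrt(colSums(A^2))
  live <- nrm > 0
  As <- A
  As[, live] <- sweep(A[, live, drop = FALSE], 2, nrm[live], "/")
  if (is.null(tol))
    tol <- 10 * .Machine$double.eps * max(n, m) * sqrt(sum(b^2))
  x <- numeric(m)
  passive <- rep(FALSE, m)
  barred <- !live                          # columns ineligible to enter
  w_dual <- as.vector(crossprod(As, b))
  iter <- 0L
  max_iter <- 50L * max(m, 10L)
  repeat {
    eligible <- !passive & !barred
    if (!any(eligible) || max(w_dual[eligible]) <= tol) break
    cand <- which(eligible)
    j <- cand[which.max(w_dual[cand])]
    passive[j] <- TRUE
    repeat {
      iter <- iter + 1L
      if (iter > max_iter)
        stop("NNLS failed to converge after ", max_iter, " iterations")
      p_idx <- which(passive)
      s <- numeric(m)
      s[p_idx] <- .ls_solve(As[, p_idx, drop = FALSE], b)
      if (min(s[p_idx]) > 0) {
        x <- s
        barred <- !live                    # progress: clear the bar list
        break
      }
      ## some passive weight went non-positive: step back to the boundary
      neg <- p_idx[s[p_idx] <= 0]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      if (!is.finite(alpha) || alpha < 0) alpha <- 0
      x <- x + alpha * (s - x)
      dropped <- p_idx[x[p_idx] <= .Machine$double.eps * max(abs(x), 1e-300)]
      passive[dropped] <- FALSE
      x[!passive] <- 0
      if (j %in% dropped) {
        ## the entering column is numerically dependent on the current
        ## passive set; bar it until the solution next changes
        barred[j] <- TRUE
        break
      }
    }
    w_dual <- as.vector(crossprod(As, b - As %*% x))
  }
  x[live] <- x[live] / nrm[live]
  resid <- as.vector(b - A %*% x)
  list(x = x, residual = resid, deviance = sum(resid^2))
}

## Unconstrained least squares via QR with pivoting; coefficients of
## numerically dependent columns come back NA and are zeroed.
.ls_solve <- function(A, b) {
  fit <- qr.coef(qr(A, LAPACK = FALSE), b)
  fit[is.na(fit)] <- 0
  as.vector(fit)
}
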