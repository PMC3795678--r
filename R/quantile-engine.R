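#' Weighted sum of absolute deviations (check / pinball loss)
#'
#' The asymmetric absolute-deviation criterion of quantile regression:
#' deviations of observations falling below their predicted quantile are
#' weighted by \code{1 - tau}, deviations above by \code{tau}.  Observations
#' equal to their predicted quantile contribute nothing.
#'
#' @param y numeric vector of observed responses (daily counts).
#' @param q numeric vector of predicted conditional quantiles, same length
#'   as \code{y} (a scalar is recycled).
#' @param tau quantile level, strictly between 0 and 1. Default 0.9.
#' @return A single non-negative number: the WSAD of the predictions.
#' @examples
#' wsad_loss(c(1, 2, 3), c(2, 2, 2), tau = 0.9)  # 0.1*1 + 0.9*1 = 1
#' @export
wsad_loss <- function(y, q, tau = 0.9) {
  check_tau(tau)
  if (length(q) == 1L) q <- rep(q, length(y))
  if (length(y) != length(q)) {
    stop("`y` (length ", length(y), ") and `q` (length ", length(q),
         ") must have the same length", call. = FALSE)
  }
  if (anyNA(y) || anyNA(q)) {
    stop("`y` and `q` must not contain missing values", call. = FALSE)
  }
  r <- y - q
  sum((tau - (r < 0)) * r)
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
      tau <= 0 || tau >= 1) {
    stop("`tau` must be a single number strictly inside (0, 1)",
         call. = FALSE)
  }
  invisible(tau)
}

#' Exact check-loss minimization by vertex exchange
#'
#' Minimizes the check-loss criterion over linear coefficients by the
#' classical exchange (specialized simplex) algorithm: every basic solution
#' interpolates exactly \code{p} observations, and the algorithm pivots
#' between such vertices of the underlying linear program until every edge
#' direction has a non-negative directional derivative, i.e. until the
#' simplex optimality certificate holds.  Observations with zero residual
#' that are not in the interpolation set (ubiquitous with tied integer
#' counts) carry a persistent side label, and pivots of zero step length
#' walk through such degenerate vertices rather than stopping at them.
#' This is the exact LP solution, not a smoothed approximation, so flat
#' optima are resolved to a vertex: for an intercept-only design with
#' \code{n * tau} integer the reported solution is the lower of the two
#' optimal order statistics.
#'
#' @param X numeric design matrix, \code{n x p}, with column names.
#' @param y numeric response of length \code{n}.
#' @param tau quantile level in (0, 1).
#' @param tol optimality tolerance on directional derivatives (default 1e-9).
#' @param max_iter pivot cap before declaring non-convergence.
#' @return List with \code{coefficients} (named), \code{fitted},
#'   \code{residuals}, \code{wsad}, \code{iterations}, \code{basis}
#'   (row indices interpolated by the solution).
#' @keywords internal
rq_exchange <- function(X, y, tau, tol = 1e-9, max_iter = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("`y` length must equal nrow(X)", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("design and response must be complete",
                                 call. = FALSE)
  if (n < p + 1L) {
    stop("need at least ", p + 1L, " rows to fit ", p, " coefficients",
         call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  qrX <- qr(X, tol = 1e-10)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(max_iter)) max_iter <- 500L + 100L * n

  # residual classification tolerance, scaled to the data
  ztol <- 1e-9 * max(1, max(abs(y)))

  # initial basis: p rows of smallest LS residual that are jointly nonsingular
  beta0 <- qr.coef(qrX, y)
  r0 <- y - drop(X %*% beta0)
  ord <- order(abs(r0))
  basis <- integer(0)
  for (i in ord) {
    cand <- c(basis, i)
    if (qr(X[cand, , drop = FALSE], tol = 1e-10)$rank == length(cand)) {
      basis <- cand
      if (length(basis) == p) break
    }
  }
  if (length(basis) < p) stop("could not find a nonsingular starting basis",
                              call. = FALSE)

  # side labels for non-interpolated observations: +1 means the residual is
  # treated as lying (weakly) above the fit, -1 below; for zero residuals
  # the label is the simplex bookkeeping that resolves degeneracy
  lab <- rep(1L, n)
  degen_run <- 0L

  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop("check-loss solver failed to converge within ", max_iter,
           " pivots (status: iteration limit)", call. = FALSE)
    }
    B <- X[basis, , drop = FALSE]
    G <- solve(B)
    beta <- drop(G %*% y[basis])
    r <- y - drop(X %*% beta)
    r[basis] <- 0
    A <- X %*% G  # column h: residual-change rates for basis direction h

    inbasis <- logical(n)
    inbasis[basis] <- TRUE
    # labels follow residual signs wherever the sign is unambiguous
    lab[!inbasis & r > ztol] <- 1L
    lab[!inbasis & r < -ztol] <- -1L
    posL <- !inbasis & lab == 1L
    negL <- !inbasis & lab == -1L

    cp <- colSums(A[posL, , drop = FALSE])
    cn <- colSums(A[negL, , drop = FALSE])
    # derivative of the loss along +g_h / -g_h (g_h drives the residual of
    # basis observation h to -t / +t while the other basic residuals stay 0)
    Dplus <- (1 - tau) - tau * cp + (1 - tau) * cn
    Dminus <- tau + tau * cp - (1 - tau) * cn

    D <- c(Dplus, Dminus)
    if (degen_run > max(300L, n)) {
      # Bland-style anti-cycling: lowest eligible basis-observation index
      elig <- which(D < -tol)
      if (length(elig) == 0L) break
      key <- basis[((elig - 1L) %% p) + 1L] * 2L + (elig > p)
      j <- elig[which.min(key)]
    } else {
      j <- which.min(D)
      if (D[j] >= -tol) break  # simplex optimality certificate
    }

    h <- ((j - 1L) %% p) + 1L
    s <- if (j <= p) 1 else -1
    a <- s * A[, h]

    # basic u (label +) blocks when its residual decreases, basic v
    # (label -) when its residual increases
    blocking <- (posL & a > ztol) | (negL & a < -ztol)
    bidx <- which(blocking)
    if (length(bidx) == 0L) {
      stop("check-loss objective is unbounded below along a design direction",
           call. = FALSE)
    }
    ti <- r[bidx] / a[bidx]
    dg <- abs(r[bidx]) <= ztol
    if (any(dg)) {
      # degenerate pivot: swap at zero step length, coefficients unchanged
      enter <- min(bidx[dg])
      degen_run <- degen_run + 1L
    } else {
      # long step: pass breakpoints while the derivative stays negative;
      # crossing observation i flips its side and adds |a_i| to the slope
      o <- order(ti, bidx)
      cum <- D[j] + cumsum(abs(a[bidx][o]))
      m <- which(cum >= 0)[1L]
      if (is.na(m)) {
        stop("check-loss objective is unbounded below along a design ",
             "direction", call. = FALSE)
      }
      if (m > 1L) {
        crossed <- bidx[o][seq_len(m - 1L)]
        lab[crossed] <- -lab[crossed]
      }
      enter <- bidx[o][m]
      degen_run <- 0L
    }
    lab[basis[h]] <- -s
    basis[h] <- enter
  }

  fitted <- drop(X %*% beta)
  names(beta) <- colnames(X)
  list(coefficients = beta,
       fitted = fitted,
       residuals = y - fitted,
       wsad = wsad_loss(y, fitted, tau),
       iterations = iter,
       basis = sort(basis))
}

#' Fit a linear conditional-quantile model
#'
#' Estimates coefficients minimizing the weighted sum of absolute
#' deviations (the check loss at level \code{tau}) for the supplied design
#' matrix, via the exact exchange algorithm of \code{\link{rq_exchange}}.
#' Counts may optionally be jittered with small additive uniform noise
#' before fitting, a standard device when applying quantile regression to
#' integer responses; the default is no jittering.
#'
#' @param design a \code{design_matrix} from \code{\link{assemble_design}},
#'   or any list with elements \code{X} (named matrix) and \code{y}.
#' @param tau quantile level in (0, 1); default 0.9, the level used for
#'   higher-than-expected daily death surveillance.
#' @param jitter \code{NULL} (default, no jittering) or a list with
#'   \code{amount} (half-width of the uniform noise, e.g. 0.1) and
#'   \code{seed} (integer controlling the noise draw).
#' @return An object of class \code{quantile_fit}: \code{tau}, named
#'   \code{coefficients}, \code{n_used}, \code{train_wsad} (criterion value
#'   at the optimum, on the response actually fitted), \code{fitted},
#'   and \code{jitter} metadata.
#' @examples
#' d <- list(X = cbind(intercept = rep(1, 10)), y = 1:10)
#' qr_fit(d, tau = 0.9)$coefficients  # empirical 0.9-quantile vertex: 9
#' @export
qr_fit <- function(design, tau = 0.9, jitter = NULL) {
  check_tau(tau)
  X <- design$X
  y <- design$y
  if (is.null(X) || is.null(y)) {
    stop("`design` must contain elements `X` and `y`", call. = FALSE)
  }
  y_fit <- y
  jit <- list(applied = FALSE, amount = NA_real_, seed = NA_integer_)
  if (!is.null(jitter)) {
    if (is.null(jitter$amount) || is.null(jitter$seed)) {
      stop("`jitter` must be a list with `amount` and `seed`", call. = FALSE)
    }
    y_fit <- y + local_runif(length(y), -jitter$amount, jitter$amount,
                             seed = jitter$seed)
    jit <- list(applied = TRUE, amount = jitter$amount,
                seed = as.integer(jitter$seed))
  }
  sol <- rq_exchange(X, y_fit, tau)
  structure(list(tau = tau,
                 coefficients = sol$coefficients,
                 n_used = nrow(X),
                 train_wsad = sol$wsad,
                 fitted = sol$fitted,
                 basis = sol$basis,
                 iterations = sol$iterations,
                 jitter = jit,
                 column_names = colnames(X)),
            class = "quantile_fit")
}

#' @export
print.quantile_fit <- function(x, ...) {
  cat(sprintf("Conditional quantile fit (tau = %g)\n", x$tau))
  cat(sprintf("  n = %d days, train WSAD = %.4f%s\n", x$n_used, x$train_wsad,
              if (x$jitter$applied)
                sprintf(" (response jittered +/-%g)", x$jitter$amount)
              else ""))
  cat("  coefficients:\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Predict conditional quantiles from a fitted model
#'
#' Evaluates \code{x'beta} for every row of a new design; no re-estimation
#' takes place, so applying a model fitted on the development sample to the
#' later cross-validation sample is a genuine forecast.
#'
#' @param object a \code{quantile_fit}.
#' @param design a \code{design_matrix} (or list with matrix \code{X}) whose
#'   column names exactly match the fit's coefficient names.
#' @param ... unused.
#' @return Numeric vector of predicted conditional quantiles, one per row.
#' @export
predict.quantile_fit <- function(object, design, ...) {
  X <- design$X
  if (is.null(X)) stop("`design` must contain a matrix `X`", call. = FALSE)
  if (!identical(colnames(X), object$column_names)) {
    stop("design columns [", paste(colnames(X), collapse = ", "),
         "] do not match fit coefficients [",
         paste(object$column_names, collapse = ", "), "]", call. = FALSE)
  }
  drop(X %*% object$coefficients)
}

#' Unconditional (intercept-only) quantile of a count series
#'
#' The single constant minimizing the check loss at level \code{tau}: the
#' empirical quantile under the lower-vertex convention, i.e. the
#' \code{ceiling(n * tau)}-th order statistic, or the \code{n * tau}-th when
#' \code{n * tau} is an integer and the optimum is a flat interval.  This is
#' exactly the intercept that \code{\link{qr_fit}} reports on an
#' intercept-only design, exposed as a fast path.
#'
#' @param y numeric vector, non-empty, no missing values.
#' @param tau quantile level in (0, 1).
#' @return A single number.
#' @examples
#' unconditional_quantile(1:10, 0.9)  # 9: lower vertex of the flat optimum
#' @export
unconditional_quantile <- function(y, tau = 0.9) {
  check_tau(tau)
  if (length(y) == 0L) stop("`y` must be non-empty", call. = FALSE)
  if (anyNA(y)) stop("`y` must not contain missing values", call. = FALSE)
  n <- length(y)
  h <- n * tau
  k <- if (abs(h - round(h)) < 1e-9) round(h) else ceiling(h)
  k <- min(max(k, 1L), n)
  sort(y, partial = k)[k]
}

# draw uniform noise from a private RNG stream, leaving the caller's
# random-number state untouched
local_runif <- function(n, lo, hi, seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  stats::runif(n, lo, hi)
}
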