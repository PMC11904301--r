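#' Maximize a scalar function on an interval (Brent)
#'
#' Thin wrapper around [stats::optimize()] (Brent's combined golden-section /
#' parabolic-interpolation search) oriented for maximization, used to refine
#' one weight or curve parameter at a time. The interval endpoints and the
#' incoming point are also evaluated so a boundary or the status quo is never
#' lost to the interior search.
#'
#' @param f Scalar function to maximize; must return finite values.
#' @param lower,upper Finite interval bounds.
#' @param tol Convergence tolerance on the argument (default 1e-4).
#' @return list(argmax, max).
#' @export
brent_maximize <- function(f, lower, upper, tol = 1e-4) {
  stopifnot(is.finite(lower), is.finite(upper), lower < upper)
  fr <- function(x) {
    y <- f(x)
    if (!is.finite(y)) stop("non-finite objective value at x = ", x)
    y
  }
  opt <- stats::optimize(fr, c(lower, upper), maximum = TRUE, tol = tol)
  cand_x <- c(opt$maximum, lower, upper)
  cand_y <- c(opt$objective, fr(lower), fr(upper))
  best <- which.max(cand_y)
  list(argmax = cand_x[best], max = cand_y[best])
}

#' Maximize a multivariate function by Nelder-Mead simplex ascent
#'
#' Wraps [stats::optim()]'s Nelder-Mead implementation (reflection /
#' expansion / contraction / shrink) for maximization with box bounds:
#' the starting point is clipped into the box and every evaluation projects
#' its argument onto the box, so the returned vertex always respects the
#' bounds.
#'
#' @param f Function of a numeric vector; must return finite values.
#' @param x0 Starting vector.
#' @param lower,upper Bound vectors (recycled).
#' @param tol Relative convergence tolerance (default 1e-5).
#' @param max_iter Maximum iterations (default 500).
#' @return list(argmax, max).
#' @export
nelder_mead_maximize <- function(f, x0, lower = -Inf, upper = Inf,
                                 tol = 1e-5, max_iter = 500) {
  n <- length(x0)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  clip <- function(x) pmin(pmax(x, lower), upper)
  x0 <- clip(x0)
  fr <- function(x) {
    y <- f(clip(x))
    if (!is.finite(y)) stop("non-finite objective value")
    y
  }
  if (n == 1L) {
    # the simplex method degenerates in 1-D; Brent is the scalar counterpart
    res <- brent_maximize(function(x) fr(x), lower, upper, tol = tol)
    return(res)
  }
  # restart once from the converged vertex: a fresh simplex polishes the
  # solution well beyond the first pass's stopping point
  par <- x0
  val <- fr(x0)
  for (pass in 1:2) {
    opt <- suppressWarnings(
      stats::optim(par, fr, method = "Nelder-Mead",
                   control = list(fnscale = -1, reltol = tol,
                                  maxit = max_iter)))
    cand <- clip(opt$par)
    cval <- fr(cand)
    if (cval <= val + abs(val) * tol && pass > 1) break
    if (cval > val) { par <- cand; val <- cval }
  }
  f0 <- fr(x0)
  if (f0 >= val) { par <- x0; val <- f0 }  # never return worse than the start
  list(argmax = par, max = val)
}
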