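#' @keywords internal
"_PACKAGE"

#' @importFrom stats median approx lm coef nls uniroot optim setNames
#' @importFrom utils head tail modifyList write.csv read.csv
NULL

clip01 <- function(x) pmin(1, pmax(0, x))

## central-difference gradient of scalar function fn at x (vector)
num_grad <- function(fn, x, h) {
  if (length(h) == 1L) h <- rep(h, length(x))
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h[i]
    (fn(x + e) - fn(x - e)) / (2 * h[i])
  }, numeric(1))
}

## central-difference Jacobian of vector function fn at x
num_jac <- function(fn, x, h) {
  if (length(h) == 1L) h <- rep(h, length(x))
  f0 <- fn(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (i in seq_along(x)) {
    e <- numeric(length(x)); e[i] <- h[i]
    J[, i] <- (fn(x + e) - fn(x - e)) / (2 * h[i])
  }
  J
}

## damped Newton for square systems; returns list(x, converged, fnorm)
newton_solve <- function(fn, x0, h, tol = 1e-10, maxit = 50) {
  x <- x0
  for (it in seq_len(maxit)) {
    fx <- fn(x)
    fnorm <- max(abs(fx))
    if (!is.finite(fnorm)) return(list(x = x, converged = FALSE, fnorm = Inf))
    if (fnorm < tol) return(list(x = x, converged = TRUE, fnorm = fnorm))
    J <- num_jac(fn, x, h)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      return(list(x = x, converged = FALSE, fnorm = fnorm))
    lam <- 1
    repeat {
      xn <- x + lam * step
      fn_new <- fn(xn)
      if (all(is.finite(fn_new)) && max(abs(fn_new)) < fnorm * (1 - 0.25 * lam) + tol)
        break
      lam <- lam / 2
      if (lam < 1e-4) { xn <- x + lam * step; break }
    }
    x <- xn
  }
  fx <- fn(x)
  list(x = x, converged = max(abs(fx)) < tol, fnorm = max(abs(fx)))
}

## indices of strict local maxima of a series above a floor value
local_maxima <- function(x, floor = -Inf) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  i[x[i] > floor]
}

## linear interpolation of the time at which series crosses level upward
upcross_times <- function(t, x, level, min_sep = 0) {
  s <- x >= level
  idx <- which(!s[-length(s)] & s[-1L])
  if (!length(idx)) return(numeric(0))
  tc <- t[idx] + (level - x[idx]) * (t[idx + 1L] - t[idx]) / (x[idx + 1L] - x[idx])
  if (min_sep > 0 && length(tc) > 1L) {
    keep <- c(TRUE, diff(tc) >= min_sep)
    ## greedy refractory filter
    out <- tc[1]
    for (v in tc[-1]) if (v - out[length(out)] >= min_sep) out <- c(out, v)
    tc <- out
  }
  tc
}
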