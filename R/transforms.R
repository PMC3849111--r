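# Numerical inverse Laplace transform and time-domain stimulus responses.
#
# Two independent inversion schemes are provided: the primary one is the
# Euler-accelerated Bromwich--Fourier series (binomially averaged partial
# sums of the trapezoidal Bromwich integral), the fallback a fixed-Talbot
# deformed contour.  All kernels of this package are analytic to the right of
# the negative real axis (the inductive poles of gamma and gamma_s and the
# branch cut of the square root all sit on Re(omega) < 0), so both contours
# are safe by construction; the Talbot contour additionally stays off the
# negative real axis itself.

.euler_weights <- function(M) {
  xi <- numeric(2 * M + 1)
  xi[1] <- 0.5
  xi[2:(M + 1)] <- 1
  xi[2 * M + 1] <- 2^(-M)
  for (k in 1:(M - 1)) {
    xi[2 * M + 1 - k] <- xi[2 * M + 2 - k] + 2^(-M) * choose(M, k)
  }
  (-1)^(0:(2 * M)) * xi
}

.ilt_euler <- function(f, t, M = 32, sigma0 = 0) {
  eta <- .euler_weights(M)
  beta <- M * log(10) / 3 + 1i * pi * (0:(2 * M))
  # all evaluation points in one call: omega[k, j] = beta_k / t_j (+ shift)
  om <- outer(beta, 1 / t) + sigma0
  fv <- matrix(f(as.vector(om)), nrow = length(beta))
  vals <- as.vector(eta %*% Re(fv)) * 10^(M / 3) / t
  if (sigma0 != 0) vals <- vals * exp(sigma0 * t)
  vals
}

.ilt_talbot <- function(f, t, M = 64, sigma0 = 0) {
  k <- 1:(M - 1)
  theta <- k * pi / M
  cot <- cos(theta) / sin(theta)
  vals <- numeric(length(t))
  # r and the contour scale with 1/t; batch all t into one evaluation
  r <- 2 * M / (5 * t)
  s0 <- outer(rep(1, length(theta)), r) * (theta * (cot + 1i)) # M-1 x nt
  sig <- theta + (theta * cot - 1) * cot
  om <- rbind(s0, matrix(r, nrow = 1)) + sigma0
  fv <- matrix(f(as.vector(om)), nrow = M)
  for (j in seq_along(t)) {
    inner <- sum(Re(exp(t[j] * s0[, j]) * fv[1:(M - 1), j] * (1 + 1i * sig)))
    vals[j] <- (r[j] / M) * (0.5 * exp(r[j] * t[j]) * Re(fv[M, j]) + inner)
  }
  if (sigma0 != 0) vals <- vals * exp(sigma0 * t)
  vals
}

#' Numerical inverse Laplace transform
#'
#' Inverts a Laplace-domain function (contract: complex vector in, complex
#' vector out) on a grid of times.  Values at `t <= 0` are returned as 0
#' (all transforms handled here are causal).  The achieved accuracy is
#' estimated by re-running the quadrature at a lower order; if the estimate
#' exceeds `tol` relative to the largest value, a warning is issued and the
#' estimate attached as attribute `error_estimate`.
#'
#' @param f a Laplace-domain function of a complex vector.
#' @param t numeric vector of times (ms).
#' @param method `"bromwich"` (Euler-accelerated Fourier series, default) or
#'   `"talbot"` (fixed-Talbot contour).
#' @param M quadrature order (terms/nodes); defaults 16 (bromwich) or
#'   20 (talbot).
#' @param tol target relative accuracy, measured against the largest value on
#'   the grid.
#' @param sigma0 abscissa shift when `f` has singularities with positive real
#'   part (all kernels of this package have none; default 0).
#' @param estimate_error logical; set `FALSE` to skip the second quadrature
#'   pass (halves the number of evaluations of `f`).
#' @return Numeric vector of `f`'s inverse transform on `t`.
#' @examples
#' ilt <- inverse_laplace(function(w) 1 / (w + 0.5), t = c(1, 2, 5))
#' max(abs(ilt - exp(-0.5 * c(1, 2, 5))))
#' @export
inverse_laplace <- function(f, t, tol = 1e-8,
                            method = c("bromwich", "talbot"),
                            M = NULL, sigma0 = 0, estimate_error = TRUE) {
  method <- match.arg(method)
  stopifnot(is.numeric(t), length(t) >= 1, tol > 0)
  out <- numeric(length(t))
  pos <- which(t > 0)
  if (!length(pos)) return(out)
  tp <- t[pos]
  # Default orders sit at the double-precision optimum of each scheme: the
  # binomial weights of the Euler acceleration grow like 10^(M/3) and the
  # Talbot contour factor like exp(2M/5), so raising M further amplifies
  # roundoff faster than it shrinks the truncation error.
  if (method == "bromwich") {
    if (is.null(M)) M <- 16
    vals <- .ilt_euler(f, tp, M = M, sigma0 = sigma0)
    est <- if (estimate_error) {
      abs(vals - .ilt_euler(f, tp, M = M - 2, sigma0 = sigma0))
    }
  } else {
    if (is.null(M)) M <- 20
    vals <- .ilt_talbot(f, tp, M = M, sigma0 = sigma0)
    est <- if (estimate_error) {
      abs(vals - .ilt_talbot(f, tp, M = M - 4, sigma0 = sigma0))
    }
  }
  out[pos] <- vals
  if (estimate_error) {
    scale <- max(abs(vals))
    rel <- if (scale > 0) max(est) / scale else 0
    attr(out, "error_estimate") <- rel
    if (rel > tol) {
      warning(sprintf("inverse Laplace transform: estimated relative accuracy %.2e exceeds tol = %.2e",
                      rel, tol), call. = FALSE)
    }
  }
  out
}

# ---------------------------------------------------------------------------
# stimuli

#' Stimulus descriptors
#'
#' Tagged current stimuli: an ideal impulse (`delta`), a rectangular pulse of
#' strength `eta0` nA and duration `tau_R` ms, or a chirp
#' `I(t) = A sin(omega_rate t^2)` whose instantaneous angular frequency
#' `2 omega_rate t` sweeps upward through the resonance.
#'
#' @param kind `"delta"`, `"rectangular"` or `"chirp"`.
#' @param eta0 rectangular pulse strength (nA).
#' @param tau_R rectangular pulse duration (ms).
#' @param A chirp amplitude (nA).
#' @param omega_rate chirp rate (rad/ms^2).
#' @return An object of class `stimulus`.
#' @export
stimulus <- function(kind = c("delta", "rectangular", "chirp"),
                     eta0 = 2, tau_R = 5, A = 1, omega_rate = 0.003) {
  kind <- match.arg(kind)
  if (kind == "rectangular") {
    stopifnot(eta0 >= 0, tau_R > 0)
  }
  if (kind == "chirp") stopifnot(A >= 0, omega_rate > 0)
  structure(list(kind = kind, eta0 = eta0, tau_R = tau_R, A = A,
                 omega_rate = omega_rate), class = "stimulus")
}

#' @export
print.stimulus <- function(x, ...) {
  msg <- switch(x$kind,
    delta = "<stimulus> delta impulse",
    rectangular = sprintf("<stimulus> rectangular pulse, eta0 = %g nA, tau_R = %g ms",
                          x$eta0, x$tau_R),
    chirp = sprintf("<stimulus> chirp, A = %g nA, rate = %g rad/ms^2",
                    x$A, x$omega_rate))
  cat(msg, "\n")
  invisible(x)
}

#' Laplace transform of a stimulus
#'
#' `delta` transforms to 1 and the rectangular pulse to
#' `eta0 (1 - exp(-omega tau_R)) / omega` (with the removable singularity at
#' `omega = 0` handled by its series).  The chirp has no convenient closed
#' transform; use [voltage_response()], which convolves in the time domain.
#'
#' @param s a [stimulus()].
#' @param omega complex vector (1/ms).
#' @return Complex vector.
#' @export
stimulus_laplace <- function(s, omega) {
  stopifnot(inherits(s, "stimulus"))
  omega <- as.complex(omega)
  switch(s$kind,
    delta = rep(1 + 0i, length(omega)),
    rectangular = {
      z <- omega * s$tau_R
      out <- complex(length(omega))
      small <- abs(z) < 1e-6
      out[small] <- s$eta0 * s$tau_R * (1 - z[small] / 2 + z[small]^2 / 6)
      out[!small] <- s$eta0 * (1 - exp(-z[!small])) / omega[!small]
      out
    },
    chirp = stop("the chirp stimulus has no closed-form Laplace transform; use voltage_response(), which convolves in the time domain",
                 call. = FALSE))
}

#' Time-domain voltage response to a stimulus
#'
#' Computes `V(t)` at a location whose Laplace-domain Green's function is
#' `ghat` (from [greens_laplace()]/[greens_function()], [two_cell_ghat()] or
#' [word_series_ghat()], partially applied over `omega`).  Delta stimuli
#' return the time-domain Green's function itself; rectangular pulses are
#' inverted as a difference of two step responses `L^-1[ghat/omega]` (smooth,
#' so the pulse edge costs no accuracy); chirps are handled by FFT
#' convolution of the time-domain Green's function with the current on a grid
#' refined to at least 20 samples per period of the highest instantaneous
#' frequency reached.
#'
#' @param ghat function of a complex vector: the frequency-domain response.
#' @param s a [stimulus()].
#' @param t numeric time grid (ms).
#' @param tol,method,M passed to [inverse_laplace()].
#' @return Numeric vector `V(t)` (mV when `ghat` is in the package's units).
#' @export
voltage_response <- function(ghat, s, t, tol = 1e-5,
                             method = c("bromwich", "talbot"), M = NULL) {
  stopifnot(inherits(s, "stimulus"), is.numeric(t))
  method <- match.arg(method)
  if (s$kind == "delta") {
    return(inverse_laplace(ghat, t, tol = tol, method = method, M = M))
  }
  if (s$kind == "rectangular") {
    step <- function(tt) {
      inverse_laplace(function(w) ghat(w) / w, tt, tol = tol,
                      method = method, M = M)
    }
    u1 <- step(t)
    u2 <- step(t - s$tau_R)
    return(as.vector(s$eta0 * (u1 - u2)))
  }
  # chirp: time-domain convolution
  tmax <- max(t)
  omega_max <- 2 * s$omega_rate * tmax
  dt <- min(2 * pi / omega_max / 20, tmax / 500)
  n <- ceiling(tmax / dt)
  tg <- seq(0, tmax, length.out = n + 1)
  dt <- tg[2] - tg[1]
  G <- inverse_laplace(ghat, tg, tol = tol, method = method, M = M,
                       estimate_error = FALSE)
  I <- s$A * sin(s$omega_rate * tg^2)
  conv <- stats::convolve(as.vector(G), rev(I), type = "open")[seq_len(n + 1)]
  V <- dt * conv # trapezoid: both end samples are zero (G(0)=I(0)=0)
  stats::approx(tg, V, xout = pmax(t, 0), rule = 2)$y * (t > 0)
}
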