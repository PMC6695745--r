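# Digital Butterworth design (bilinear transform of the analog prototype) and
# zero-phase filtering. The pre-installed stack has no DSP package, so the few
# primitives needed by the processing chain live here.

# expand a polynomial from its (possibly complex) roots; returns real coefs
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  if (max(abs(Im(p))) > 1e-8 * max(abs(p), 1)) {
    warning("polynomial from roots has non-negligible imaginary part")
  }
  Re(p)
}

#' Design a digital Butterworth filter
#'
#' Bilinear-transform design of a low-pass or band-pass Butterworth filter.
#' For `type = "band"`, `order` is the order of the resulting band-pass filter
#' (it must be even; the analog low-pass prototype has `order/2` poles).
#'
#' @param order filter order (total number of poles).
#' @param fc cut-off frequency in Hz (low-pass) or length-2 band edges
#'   `c(low, high)` in Hz (band-pass).
#' @param fs sampling rate in Hz.
#' @param type `"low"` or `"band"`.
#' @return list with numerator `b`, denominator `a` (both normalised so
#'   `a[1] == 1`), plus the design parameters.
#' @examples
#' f <- butter_design(4, c(0.29, 10), fs = 30, type = "band")
#' abs(filter_gain(f, 5))   # pass band, close to 1
#' @export
butter_design <- function(order, fc, fs, type = c("low", "band")) {
  type <- match.arg(type)
  stopifnot(fs > 0, order >= 1)
  if (type == "band") {
    if (length(fc) != 2L || !(0 < fc[1] && fc[1] < fc[2]))
      stop("band-pass design needs fc = c(low, high) with 0 < low < high")
    if (fc[2] >= fs / 2)
      stop("invalid band: upper edge must be below the Nyquist frequency")
    if (order %% 2 != 0) stop("band-pass order must be even")
    n <- order / 2
  } else {
    if (length(fc) != 1L || fc <= 0 || fc >= fs / 2)
      stop("low-pass cut-off must lie in (0, fs/2)")
    n <- order
  }

  # analog low-pass prototype poles on the unit circle, left half plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))

  fs2 <- 2 * fs
  warp <- function(f) fs2 * tan(pi * f / fs)   # bilinear pre-warp

  if (type == "low") {
    wc <- warp(fc)
    poles <- p * wc
    zeros <- complex(0)
    gain <- wc^n
  } else {
    w1 <- warp(fc[1]); w2 <- warp(fc[2])
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    plp <- p * bw / 2
    poles <- c(plp + sqrt(plp^2 - w0^2), plp - sqrt(plp^2 - w0^2))
    zeros <- rep(0 + 0i, n)
    gain <- bw^n
  }

  # bilinear transform s -> z
  zp <- (fs2 + poles) / (fs2 - poles)
  zz <- (fs2 + zeros) / (fs2 - zeros)
  gain <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  # poles/zeros at s = Inf map to z = -1
  zz <- c(zz, rep(-1 + 0i, length(zp) - length(zz)))

  b <- gain * poly_from_roots(zz)
  a <- poly_from_roots(zp)
  list(b = b / a[1], a = a / a[1], order = order, fc = fc, fs = fs, type = type)
}

#' Complex gain of a designed filter at given frequencies
#'
#' Evaluates the transfer function H(z) on the unit circle. After
#' [filtfilt()] the effective amplitude gain is `abs(filter_gain(...))^2`
#' with zero phase; this is the analytic oracle used by the filter tests.
#'
#' @param filt result of [butter_design()].
#' @param f frequencies in Hz.
#' @return complex vector of gains.
#' @export
filter_gain <- function(filt, f) {
  z <- exp(-1i * 2 * pi * f / filt$fs)
  num <- vapply(z, function(zz) sum(filt$b * zz^(seq_along(filt$b) - 1)), complex(1))
  den <- vapply(z, function(zz) sum(filt$a * zz^(seq_along(filt$a) - 1)), complex(1))
  num / den
}

# steady-state initial filter state for a unit-amplitude step input
# (direct-form II transposed), so filtfilt has no start-up transient
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  if (n == 1) return(numeric(0))
  bb <- c(b, rep(0, n - length(b)))
  aa <- c(a, rep(0, n - length(a)))
  bb <- bb / aa[1]; aa <- aa / aa[1]
  # companion matrix of aa, transposed
  A <- matrix(0, n - 1, n - 1)
  A[1, ] <- -aa[-1]
  if (n > 2) A[cbind(2:(n - 1), 1:(n - 2))] <- 1
  B <- bb[-1] - aa[-1] * bb[1]
  solve(diag(n - 1) - t(A), B)
}

#' Zero-phase IIR filtering (forward-backward)
#'
#' Applies the filter forward then backward so the net phase shift is zero and
#' the amplitude response is squared. The signal is extended at both ends by
#' odd reflection and each pass starts from the step steady state, following
#' the standard practice for transient suppression.
#'
#' @param filt result of [butter_design()] (or any list with `b` and `a`).
#' @param x numeric signal.
#' @return filtered signal, same length as `x`.
#' @export
filtfilt <- function(filt, x) {
  b <- filt$b; a <- filt$a
  n <- max(length(a), length(b))
  padlen <- 3 * (n - 1)
  if (length(x) <= padlen)
    stop("signal must be longer than 3 * (filter order) samples")
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[length(x)] - x[(length(x) - 1):(length(x) - padlen)])
  zi <- lfilter_zi(b, a)
  y <- iir_filter_cpp(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- iir_filter_cpp(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + length(x))]
}
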