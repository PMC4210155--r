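#' LMS identification of a contact-to-envelope impulse response
#'
#' Identifies the FIR impulse response from a heel FSR channel to an EMG
#' linear envelope with the least-mean-squares adaptive filter. At every
#' sample the filter output `y(n) = sum_k h_k x(n-k)` is compared with the
#' desired envelope `d(n)`; the error `e(n) = d(n) - y(n)` drives the
#' coefficient update. The filter length is two mean stride durations and
#' the record is swept for a fixed number of full iterations (default 100,
#' where the filter has converged). By default the normalized variant is
#' used: the step at sample `n` is `mu / (||x_n||^2 + eps)`, which keeps the
#' update stable across input amplitude scales.
#'
#' @param x input channel (heel FSR), numeric.
#' @param d desired signal: an `envelope_signal` or numeric vector at the
#'   same rate and length as `x`.
#' @param stride_s mean stride duration in seconds.
#' @param rate sampling rate in Hz.
#' @param mu learning rate (normalized step size when `normalized`).
#' @param iterations number of full passes over the record.
#' @param normalized use the normalized (input-power scaled) step.
#' @param eps regularizer in the normalized step denominator.
#' @return An object of class `impulse_response`: `h` (coefficients), `lag`
#'   (s), `rate`, `mu`, `iterations`, `mse` (per-iteration trace) and
#'   `final_mse`.
#' @export
lms_identify <- function(x, d, stride_s, rate, mu = 0.01, iterations = 100,
                         normalized = TRUE, eps = 1e-8) {
  if (inherits(d, "envelope_signal")) {
    if (!missing(rate) && d$rate != rate)
      stop("envelope rate disagrees with 'rate'")
    rate <- d$rate
    d <- d$values
  }
  x <- as.numeric(x); d <- as.numeric(d)
  if (length(x) != length(d)) stop("x and d must have the same length")
  if (stride_s <= 0) stop("stride duration must be positive")
  L <- round(2 * stride_s * rate)
  if (L < 1L || L > length(x)) stop("record shorter than the filter length")
  fit <- lms_core(x, d, L, mu, as.integer(iterations), normalized, eps)
  structure(list(h = as.numeric(fit$h), lag = (seq_len(L) - 1) / rate,
                 rate = rate, stride_s = stride_s, mu = mu,
                 iterations = as.integer(iterations),
                 mse = as.numeric(fit$mse),
                 final_mse = as.numeric(fit$mse)[iterations]),
            class = "impulse_response")
}

#' @export
print.impulse_response <- function(x, ...) {
  cat(sprintf("<impulse_response> %d taps @ %g Hz (2 x %.3f s stride), mu=%g, %d iterations, final MSE %.4g\n",
              length(x$h), x$rate, x$stride_s, x$mu, x$iterations,
              x$final_mse))
  invisible(x)
}

#' Truncate an impulse response with a half-Hanning taper
#'
#' Keeps the coefficients that generate a muscle activation one stride
#' duration long after a heel-contact input and smoothly tapers the kept
#' tail to zero. The default (`mode = "multiply"`) multiplies the second
#' half of the kept stride with a decaying half-Hanning window, which
#' selects coefficients; `mode = "convolve"` instead convolves the response
#' with a half-Hanning window of one stride, the literal smearing reading,
#' and then truncates.
#'
#' @param h an [lms_identify()] result (or numeric coefficients).
#' @param stride_s stride duration in seconds.
#' @param rate sampling rate in Hz (taken from `h` when available).
#' @param mode `"multiply"` (default) or `"convolve"`.
#' @return Numeric coefficients, one stride long, tapering to zero.
#' @export
apply_half_hanning <- function(h, stride_s, rate = NULL,
                               mode = c("multiply", "convolve")) {
  mode <- match.arg(mode)
  if (inherits(h, "impulse_response")) {
    rate <- h$rate
    if (missing(stride_s)) stride_s <- h$stride_s
    h <- h$h
  }
  if (is.null(rate)) stop("'rate' required for plain numeric input")
  L1 <- round(stride_s * rate)
  if (L1 > length(h)) stop("stride longer than the impulse response")
  if (mode == "multiply") {
    out <- h[seq_len(L1)]
    half <- floor(L1 / 2)
    tail_len <- L1 - half
    i <- seq_len(tail_len)
    out[half + i] <- out[half + i] * 0.5 * (1 + cos(pi * i / tail_len))
    out
  } else {
    w <- 0.5 * (1 + cos(pi * (seq_len(L1) - 1) / (L1 - 1)))
    w <- w / sum(w)
    fir_predict(w, h)[seq_len(L1)]
  }
}

#' Predict with an identified response
#'
#' Runs the identified FIR response over an input channel:
#' `y(n) = sum_k h_k x(n-k)`. When the desired signal is supplied the
#' prediction error `e(n) = d(n) - y(n)` is attached.
#'
#' @param h an [lms_identify()] result or numeric coefficients.
#' @param x input channel.
#' @param d optional desired signal of the same length.
#' @return An object of class `prediction_result` with `estimate` and
#'   (when `d` is given) `error`.
#' @export
lms_predict <- function(h, x, d = NULL) {
  hh <- if (inherits(h, "impulse_response")) h$h else as.numeric(h)
  y <- fir_predict(hh, as.numeric(x))
  err <- NULL
  if (!is.null(d)) {
    d <- if (inherits(d, "envelope_signal")) d$values else as.numeric(d)
    if (length(d) != length(y)) stop("length mismatch between d and x")
    err <- d - y
  }
  structure(list(estimate = y, error = err), class = "prediction_result")
}

#' Final mean square error of a response on a record
#'
#' Mean of the squared prediction residual, skipping the filter-length
#' warm-up at the start of the record.
#'
#' @inheritParams lms_predict
#' @param skip_warmup drop the first `length(h) - 1` samples.
#' @return Scalar MSE.
#' @export
final_mse <- function(h, x, d, skip_warmup = TRUE) {
  hh <- if (inherits(h, "impulse_response")) h$h else as.numeric(h)
  p <- lms_predict(hh, x, d)
  e <- p$error
  if (skip_warmup && length(e) > length(hh)) e <- e[-seq_len(length(hh) - 1L)]
  mean(e^2)
}

#' Batch Wiener (least-squares) solution
#'
#' Solves the normal equations `R h = p` for the length-`L` FIR filter
#' minimizing the mean squared prediction error, with `R` the Toeplitz
#' autocorrelation matrix of the input and `p` the input/desired
#' cross-correlation, both computed by FFT. Serves as the batch reference
#' against which the sample-sequential adaptive solution is compared.
#'
#' @param x input channel.
#' @param d desired signal (numeric or `envelope_signal`).
#' @param L filter length in samples.
#' @param lambda ridge regularizer added to the diagonal, as a fraction of
#'   the zero-lag autocorrelation.
#' @return Numeric coefficient vector of length `L`.
#' @export
wiener_solution <- function(x, d, L, lambda = 1e-8) {
  x <- as.numeric(x)
  d <- if (inherits(d, "envelope_signal")) d$values else as.numeric(d)
  n <- length(x)
  stopifnot(length(d) == n, L >= 1L, L <= n)
  nf <- stats::nextn(2L * n)
  X <- fft(c(x, numeric(nf - n)))
  r <- Re(fft(X * Conj(X), inverse = TRUE)) / nf
  p <- Re(fft(fft(c(d, numeric(nf - n))) * Conj(X), inverse = TRUE)) / nf
  R <- toeplitz(r[seq_len(L)] / n)
  as.numeric(solve(R + diag(lambda * R[1, 1], L), p[seq_len(L)] / n))
}

#' Normalized root-mean-square difference of two coefficient vectors
#'
#' `||a - b|| / ||b||`, after zero-padding the shorter vector. Used to
#' compare identified responses with reference or ground-truth kernels.
#'
#' @param a,b numeric vectors.
#' @return Scalar NRMSE (relative to `b`).
#' @export
nrmse <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  sqrt(sum((a - b)^2) / sum(b^2))
}
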