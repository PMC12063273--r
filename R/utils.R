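#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rbinom runif rlnorm qnorm ppoints sd shapiro.test
#'   fitted residuals coef approx setNames aggregate complete.cases
#' @importFrom utils read.csv write.csv head tail
NULL

stop_propulsr <- function(msg, class) {
  stop(structure(
    class = c(class, "propulsr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

format_error <- function(msg) stop_propulsr(msg, "propulsr_format_error")
parameter_error <- function(msg) stop_propulsr(msg, "propulsr_parameter_error")
detection_error <- function(msg) stop_propulsr(msg, "propulsr_detection_error")
unsupported_file_error <- function(msg) stop_propulsr(msg, "propulsr_unsupported_file_error")

assert_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    parameter_error(sprintf("`%s` must be a positive scalar", name))
  invisible(x)
}

#' Trapezoidal integral of a uniformly sampled series
#'
#' Signed trapezoid rule with spacing `1/fs` seconds, the elementary
#' quadrature used for propulsion impulses.
#'
#' @param x numeric vector of samples.
#' @param fs sampling rate in Hz.
#' @return the integral in units of `x` times seconds.
#' @export
trapz_series <- function(x, fs) {
  assert_scalar_positive(fs, "fs")
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-n] + x[-1L]) / 2) / fs
}

#' Derive a reproducible child seed
#'
#' Maps a base seed and an index to a new seed below 2^31, so replicate
#' streams can be derived from one user-facing seed.
#'
#' @param seed base integer seed.
#' @param index replicate index.
#' @return an integer seed.
#' @export
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 100003 + as.double(index) * 7919) %% 2147483629)
}
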