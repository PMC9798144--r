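# Noise calibration: background-derived detection thresholds of the form
# mean + k * SD, with k = 3 for the single-score chemistries (bisulfite
# NonConv, AlkAnilineSeq stop ratio) and k = 2 for the RiboMethSeq
# dual-score rule (Score A and Score Angle must both exceed their
# thresholds).

#' Construct a noise model from summary statistics
#'
#' @param mean background mean.
#' @param sd background standard deviation (>= 0).
#' @param k threshold multiplier (3 for NonConv / stop ratio, 2 for the
#'   RiboMethSeq scores).
#' @param source free-text descriptor of the background source (e.g.
#'   `"unmodified decoy family C positions"`).
#' @param n number of background values behind the estimate, if known.
#' @return object of class `noise_model` with fields `mean`, `sd`, `k`,
#'   `threshold = mean + k * sd`, `source`, `n`.
#' @export
#' @examples
#' noise_model(0.0252, 0.0677, k = 3)$threshold  # 0.2283
noise_model <- function(mean, sd, k, source = "summary", n = NA_integer_) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0, is.numeric(k), k > 0)
  structure(
    list(mean = mean, sd = sd, k = k, threshold = mean + k * sd,
         source = source, n = n),
    class = "noise_model"
  )
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf(
    "<noise_model> mean %.4g, SD %.4g, k = %g -> threshold %.4g (%s%s)\n",
    x$mean, x$sd, x$k, x$threshold, x$source,
    if (is.na(x$n)) "" else sprintf(", n = %d", x$n)))
  invisible(x)
}

#' Estimate a noise model from background scores
#'
#' `method = "gaussian"` uses the sample mean and SD (n - 1 denominator) of
#' the background values; `method = "robust"` uses median and MAD
#' (consistency constant 1.4826), resisting contamination by true sites
#' when the background is the genome-wide score distribution rather than a
#' designated unmodified control.
#'
#' @param values numeric background scores (non-finite values dropped); at
#'   least 10 required.
#' @param k threshold multiplier.
#' @param method `"gaussian"` or `"robust"`.
#' @inheritParams noise_model
#' @return a [noise_model()].
#' @export
estimate_noise <- function(values, k, method = c("gaussian", "robust"),
                           source = NULL) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (length(values) < 10) {
    stop("insufficient calibration: ", length(values),
         " background values (need >= 10)", call. = FALSE)
  }
  if (is.null(source)) {
    source <- sprintf("%s fit to %d background values", method, length(values))
  }
  if (method == "gaussian") {
    noise_model(mean(values), sd(values), k, source, length(values))
  } else {
    noise_model(median(values), mad(values), k, source, length(values))
  }
}

#' Fraction of Gaussian noise excluded by a mean + k SD threshold
#'
#' The standard normal CDF at k, as a percentage: with k = 2 a Gaussian
#' noise model is excluded at 97.7%, accepting the remaining 2.3% as the
#' false-positive baseline.
#'
#' @param k threshold multiplier (>= 0 for the usual interpretation).
#' @return percentage in \[0, 100\].
#' @export
#' @examples
#' gaussian_exclusion(2)  # 97.7
gaussian_exclusion <- function(k) {
  100 * pnorm(k)
}
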