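#' Empirical logit of a binomial count
#'
#' Computes `log((k + c) / (n - k + c))`, the logit of a proportion with a
#' small-count correction so boundary outcomes (no survivors, no deaths)
#' remain finite. This is the first of the two label transformations applied
#' to bioassay mortality and allele-frequency observations before modelling.
#'
#' @param successes Number of successes (e.g. dead mosquitoes), `0 <= k <= n`.
#' @param trials Number of trials (mosquitoes tested), `>= 1`.
#' @param c Positive smoothing constant; the default 0.5 is the standard
#'   half-count correction.
#' @return Numeric vector on the logit scale; finite for all valid inputs.
#' @examples
#' empirical_logit(5, 10)            # 0: symmetric case
#' empirical_logit(0, 10)            # finite despite zero successes
#' @export
empirical_logit <- function(successes, trials, c = 0.5) {
  stopifnot(is.numeric(successes), is.numeric(trials), length(c) == 1L, c > 0)
  if (any(trials < 1)) stop("`trials` must be >= 1")
  if (any(successes < 0)) stop("`successes` must be >= 0")
  if (any(successes > trials)) stop("`successes` must not exceed `trials`")
  log((successes + c) / (trials - successes + c))
}

#' Inverse hyperbolic sine transform
#'
#' `ihs(x) = log(x + sqrt(x^2 + 1)) = asinh(x)`. An odd, strictly increasing
#' map applied on top of the empirical logit to damp the influence of extreme
#' transformed proportions.
#'
#' @param x Finite numeric vector.
#' @return `asinh(x)`.
#' @export
ihs <- function(x) asinh(x)

#' Forward label transformation: empirical logit then IHS
#'
#' Converts an observed proportion (bioassay mortality or combined *Vgsc*
#' allele frequency) into the modelling scale. The proportion is first turned
#' into an integer success count by rounding `proportion * n`, then passed
#' through [empirical_logit()] and [ihs()], in that order.
#'
#' @param proportion Observed proportion in `[0, 1]`.
#' @param n Number of trials behind the proportion.
#' @param c Smoothing constant passed to [empirical_logit()].
#' @return Value on the transformed (modelling) scale.
#' @export
transform_label <- function(proportion, n, c = 0.5) {
  stopifnot(all(proportion >= 0 & proportion <= 1))
  ihs(empirical_logit(round(proportion * n), n, c))
}

#' Inverse label transformation back to a proportion
#'
#' Inverts [ihs()] and then the empirical logit under a continuous
#' relaxation with a fixed reference trial count: given
#' `z = log((p*n + c) / ((1-p)*n + c))` the exact solution is
#' `p = (E*(n + c) - c) / (n*(1 + E))` with `E = exp(z)`, clamped to
#' `[0, 1]`. Used to report prediction surfaces as mean proportional
#' mortality on the natural scale.
#'
#' @param value Value(s) on the transformed scale.
#' @param c Smoothing constant used in the forward transform.
#' @param n_ref Reference trial count for the continuous relaxation; maps
#'   report mean proportions, not counts, so a single reference size is used.
#' @return Proportion(s) in `[0, 1]`.
#' @export
inverse_transform <- function(value, c = 0.5, n_ref = 100) {
  z <- sinh(value)
  e <- exp(z)
  p <- (e * (n_ref + c) - c) / (n_ref * (1 + e))
  # exp overflow for very large z means certain 1.0
  p[is.nan(p) & z > 0] <- 1
  pmin(pmax(p, 0), 1)
}
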