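#' Convert a median rate ratio to a log-scale random-effect standard deviation
#'
#' The median rate ratio (MRR) is the expected rate ratio between two randomly
#' sampled patients (or practices) with otherwise identical characteristics,
#' always expressed as the higher rate over the lower, so it is >= 1. Under
#' lognormal random effects with standard deviation `sigma` on the log-rate
#' scale, the median of the pairwise ratio satisfies
#' \deqn{MRR = \exp(\sqrt{2}\,\sigma\,\Phi^{-1}(0.75)),}
#' Larsen's median-rate-ratio identity, so
#' \eqn{\sigma = \log(MRR) / (\sqrt{2}\,\Phi^{-1}(0.75))}.
#'
#' @param mrr Median rate ratio, a dimensionless value >= 1. `mrr = 1` means a
#'   homogeneous population and maps to `sigma = 0`.
#' @return Standard deviation of the normal random effect on the log-rate
#'   scale (>= 0).
#' @seealso [sd_to_mrr()] for the inverse.
#' @examples
#' mrr_to_sd(2)    # ~0.7267
#' mrr_to_sd(1.2)  # ~0.1911
#' @export
mrr_to_sd <- function(mrr) {
  if (!is.numeric(mrr) || anyNA(mrr) || any(mrr < 1)) {
    stop("`mrr` must be numeric and >= 1 (ratio of higher to lower risk)",
         call. = FALSE)
  }
  log(mrr) / (sqrt(2) * stats::qnorm(0.75))
}

#' Convert a log-scale random-effect standard deviation to a median rate ratio
#'
#' Inverse of [mrr_to_sd()]: `MRR = exp(sqrt(2) * sigma * qnorm(0.75))`.
#'
#' @param sigma Standard deviation on the log-rate scale, >= 0.
#' @return Median rate ratio >= 1.
#' @export
sd_to_mrr <- function(sigma) {
  if (!is.numeric(sigma) || anyNA(sigma) || any(sigma < 0)) {
    stop("`sigma` must be numeric and >= 0", call. = FALSE)
  }
  exp(sqrt(2) * sigma * stats::qnorm(0.75))
}
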