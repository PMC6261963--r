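#' Parameter-scale transforms
#'
#' Learning rates live in (0, 1) and are modelled on the probit scale
#' (standard-normal quantile); the exploration parameter beta is positive
#' and modelled on the log scale. These helpers map between the sampling
#' scale and the natural scale.
#'
#' @param x real value(s) on the probit (for `to_natural`) or log
#'   (for `to_natural_beta`) scale.
#' @param alpha,beta value(s) on the natural scale.
#' @return transformed value(s).
#' @examples
#' to_natural(0)        # 0.5
#' to_natural_beta(0)   # 1
#' @name transforms
NULL

#' @rdname transforms
#' @export
to_natural <- function(x) stats::pnorm(x)

#' @rdname transforms
#' @export
to_probit <- function(alpha) stats::qnorm(alpha)

#' @rdname transforms
#' @export
to_natural_beta <- function(x) exp(x)

#' @rdname transforms
#' @export
to_log_beta <- function(beta) log(beta)
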