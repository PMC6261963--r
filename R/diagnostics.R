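# split-chain Gelman-Rubin statistic for one parameter
# x: iterations x chains matrix
rhat_matrix <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (ncol(x) < 2L && n < 8L) stop("rhat needs >= 2 chains or enough draws to split")
  half <- n %/% 2L
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(sp); nn <- nrow(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (!is.finite(W) || W <= .Machine$double.eps * max(1, mean(means)^2))
    return(1)  # constant chains: defined as 1 by convention
  var_plus <- (nn - 1) / nn * W + B / nn
  sqrt(var_plus / W)
}

#' Split-chain Gelman-Rubin diagnostic (R-hat)
#'
#' Each chain is split in half before computing the classic potential
#' scale reduction factor, so within-chain drift also inflates the
#' statistic. Chains with (numerically) zero variance return 1 by
#' convention.
#'
#' @param x an `rl_fit`, a 3-d array `iter x chains x params`, or an
#'   `iter x chains` matrix for a single parameter; at least 2 chains (or
#'   enough draws to split) and >= 4 draws each.
#' @return named numeric vector of R-hat values (scalar for a matrix).
#' @export
rhat <- function(x) {
  if (inherits(x, "rl_fit")) return(x$rhat)
  if (is.matrix(x)) {
    if (ncol(x) < 2L) stop("rhat requires at least two chains")
    if (nrow(x) < 4L) stop("rhat requires at least 4 draws per chain")
    return(rhat_matrix(x))
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    out <- apply(x, 3, rhat_matrix)
    names(out) <- dimnames(x)[[3]]
    return(out)
  }
  stop("x must be an rl_fit, a 3-d draws array, or an iter x chains matrix")
}

#' Highest-density interval of a sample
#'
#' Narrowest contiguous interval containing the requested posterior mass;
#' assumes a unimodal marginal (the usual situation for these posteriors).
#'
#' @param x numeric sample (>= 50 draws).
#' @param mass probability mass in (0, 1), default 0.95.
#' @return numeric `c(lower, upper)`.
#' @export
hdi <- function(x, mass = 0.95) {
  stopifnot(is.numeric(x), mass > 0, mass < 1)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 50L) stop("hdi needs at least 50 draws, got ", n)
  xs <- sort(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(xs[1], xs[n]))
  starts <- seq_len(n - m)
  widths <- xs[starts + m] - xs[starts]
  i <- which.min(widths)
  c(xs[i], xs[i + m])
}

#' Effective sample size per parameter
#'
#' Thin wrapper over [coda::effectiveSize()] applied chain-wise.
#'
#' @param fit an `rl_fit`.
#' @return named numeric vector.
#' @export
ess <- function(fit) {
  stopifnot(inherits(fit, "rl_fit"))
  d <- dim(fit$draws)
  ml <- coda::mcmc.list(lapply(seq_len(d[2]), function(ch)
    coda::mcmc(fit$draws[, ch, ])))
  out <- coda::effectiveSize(ml)
  names(out) <- dimnames(fit$draws)[[3]]
  out
}
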