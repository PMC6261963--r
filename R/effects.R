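#' Posterior summary of the day and day-by-group effects
#'
#' One row per group and model parameter with the posterior mean and 95%
#' highest-density interval of the corresponding shift coefficient, on the
#' transformed scales (probit for learning rates, log for beta). The
#' baseline row ("NHG") holds the common day-2 effect — what the natural
#' history group experiences — and the other rows hold the extra
#' group-specific effects.
#'
#' @param fit an `rl_fit` of a model with day/group effects (M2 or M3).
#' @param mass HDI mass, default 0.95.
#' @return data.frame with columns `group`, `parameter`, `mean`, `lower`,
#'   `upper`.
#' @export
summarize_effects <- function(fit, mass = 0.95) {
  stopifnot(inherits(fit, "rl_fit"))
  model <- fit$model
  if (model$variant == "M1_single_alpha")
    stop("model has no day/group effects; fit M2_day_group or M3_full")
  m <- as_draws_matrix(fit)
  pars <- if (model$K == 3L) c("alphaG", "alphaL", "beta") else
    c("alpha", "beta")
  rows <- list()
  for (p in pars) {
    nm <- paste0("b_", p)
    if (!nm %in% colnames(m)) stop("missing coefficient ", nm)
    h <- hdi(m[, nm], mass)
    rows[[length(rows) + 1L]] <-
      data.frame(group = "NHG", parameter = p, mean = mean(m[, nm]),
                 lower = h[1], upper = h[2], stringsAsFactors = FALSE)
    for (g in model$grp_levels) {
      nmg <- paste0("b_", p, "_", g)
      if (!nmg %in% colnames(m)) stop("missing coefficient ", nmg)
      h <- hdi(m[, nmg], mass)
      rows[[length(rows) + 1L]] <-
        data.frame(group = g, parameter = p, mean = mean(m[, nmg]),
                   lower = h[1], upper = h[2], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(match(out$group, c("NHG", RL_GROUPS))), c("group", "parameter",
                                                      "mean", "lower",
                                                      "upper")]
}
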