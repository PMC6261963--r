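pair_index0 <- function(pair_id) {
  idx <- match(pair_id, c("AB", "CD", "EF")) - 1L
  if (anyNA(idx)) stop("unknown pair_id values: ",
                       paste(unique(pair_id[is.na(idx)]), collapse = ", "))
  idx
}

#' Pointwise choice log-likelihood for one subject-day
#'
#' Replays the Q trajectory deterministically from the recorded choices
#' and rewards and returns the log softmax probability of each recorded
#' choice. Q starts at zero and is reset at every `task_label` change
#' (each task uses its own symbols); only the chosen symbol's value is
#' updated. Trials without a choice (`chosen_better` missing) carry no
#' feedback: they are excluded and do not advance Q.
#'
#' @param records data.frame of ordered trial records for a single
#'   subject-day with columns `task_label`, `pair_id`, `chosen_better`,
#'   `reward`.
#' @param params an [agent_params()] object.
#' @return numeric vector, one log-likelihood per included trial; its sum
#'   is the subject-day log-likelihood.
#' @export
trial_loglik <- function(records, params) {
  stopifnot(inherits(params, "agent_params"))
  req <- c("task_label", "pair_id", "chosen_better", "reward")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  records <- records[!is.na(records$chosen_better), , drop = FALSE]
  if (nrow(records) == 0L) return(numeric(0))
  if (anyNA(records$reward) || !all(records$reward %in% c(0L, 1L)))
    stop("all included trials must have rewards in {0, 1}")
  segs <- rle(records$task_label)
  seg_len <- segs$lengths
  seg_start <- cumsum(c(0L, seg_len[-length(seg_len)]))
  res <- rl_loglik_grad_cpp(pair_index0(records$pair_id),
                            as.integer(records$chosen_better),
                            as.integer(records$reward),
                            as.integer(seg_start), as.integer(seg_len),
                            rep(0L, length(seg_len)),
                            params$alpha_G, params$alpha_L, params$beta)
  res$pointwise
}
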