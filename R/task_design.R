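#' Built-in session designs of the probabilistic selection task
#'
#' The task presents three fixed pairs of symbols (labelled AB, CD, EF); in
#' each pair one symbol is rewarded with higher probability than the other.
#' The default sessions use contingencies 80/20, 70/30 and 60/40 over four
#' blocks (240 trials); the manipulated second-day-one sessions use two
#' blocks (120 trials) with easier (90/10, 90/10, 80/20) or harder
#' (60/40, 60/40, 55/45) contingencies. Within every block each pair is
#' presented 20 times, counterbalanced for presentation side.
#'
#' @param task_label one of `"task1_default"`, `"task2_placebo"`,
#'   `"task2_nocebo"`, `"task3_default"`.
#' @return a `session_design` object; see [session_design()].
#' @examples
#' d <- make_design("task1_default")
#' n_trials(d) # 240
#' @export
make_design <- function(task_label) {
  designs <- list(
    task1_default = list(n_blocks = 4L,
                         p_better = c(0.80, 0.70, 0.60),
                         p_worse  = c(0.20, 0.30, 0.40)),
    task2_placebo = list(n_blocks = 2L,
                         p_better = c(0.90, 0.90, 0.80),
                         p_worse  = c(0.10, 0.10, 0.20)),
    task2_nocebo  = list(n_blocks = 2L,
                         p_better = c(0.60, 0.60, 0.55),
                         p_worse  = c(0.40, 0.40, 0.45)),
    task3_default = list(n_blocks = 4L,
                         p_better = c(0.80, 0.70, 0.60),
                         p_worse  = c(0.20, 0.30, 0.40))
  )
  if (!is.character(task_label) || length(task_label) != 1L ||
      !task_label %in% names(designs)) {
    stop("unknown task label ", deparse(task_label),
         "; valid labels are: ", paste(names(designs), collapse = ", "))
  }
  d <- designs[[task_label]]
  session_design(task_label = task_label, n_blocks = d$n_blocks,
                 reps_per_pair_per_block = 20L,
                 p_better = d$p_better, p_worse = d$p_worse)
}

#' Construct a (possibly custom) session design
#'
#' @param task_label character label for the session.
#' @param n_blocks number of blocks.
#' @param reps_per_pair_per_block presentations of each pair per block;
#'   must be even so that presentation side can be exactly counterbalanced.
#' @param p_better,p_worse length-3 reward probabilities of the better and
#'   worse symbol of pairs AB, CD, EF; must satisfy
#'   `0 <= p_worse < p_better <= 1` pairwise.
#' @param timing stimulus timing metadata in seconds (not used by the
#'   simulator, retained for completeness).
#' @return an object of class `session_design`.
#' @export
session_design <- function(task_label, n_blocks, reps_per_pair_per_block,
                           p_better, p_worse,
                           timing = list(fixation_s = 0.3, deadline_s = 1.7,
                                         highlight_s = 0.5, feedback_s = 0.5)) {
  n_blocks <- as.integer(n_blocks)
  reps <- as.integer(reps_per_pair_per_block)
  stopifnot(length(n_blocks) == 1L, n_blocks >= 1L,
            length(reps) == 1L, reps >= 1L,
            length(p_better) == 3L, length(p_worse) == 3L)
  if (reps %% 2L != 0L)
    stop("reps_per_pair_per_block must be even for exact side counterbalancing")
  if (any(p_worse < 0 | p_better > 1 | p_worse >= p_better))
    stop("each pair needs 0 <= p_worse < p_better <= 1")
  structure(list(task_label = task_label,
                 n_blocks = n_blocks,
                 reps_per_pair_per_block = reps,
                 pairs = data.frame(pair_id = c("AB", "CD", "EF"),
                                    p_better = as.numeric(p_better),
                                    p_worse = as.numeric(p_worse),
                                    stringsAsFactors = FALSE),
                 timing = timing),
            class = "session_design")
}

#' @export
print.session_design <- function(x, ...) {
  cat("Session design:", x$task_label, "\n")
  cat(sprintf("  %d blocks x 3 pairs x %d reps = %d trials\n",
              x$n_blocks, x$reps_per_pair_per_block, n_trials(x)))
  cat(sprintf("  contingencies: %s\n",
              paste(sprintf("%s %.0f/%.0f%%", x$pairs$pair_id,
                            100 * x$pairs$p_better, 100 * x$pairs$p_worse),
                    collapse = ", ")))
  invisible(x)
}

#' Total trial count of a session design
#' @param design a `session_design`.
#' @export
n_trials <- function(design) {
  design$n_blocks * 3L * design$reps_per_pair_per_block
}

with_preserved_seed <- function(seed, code) {
  # run `code` under set.seed(seed) without disturbing the caller's RNG
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a randomized, counterbalanced trial schedule
#'
#' Within each block every pair appears `reps_per_pair_per_block` times,
#' the better symbol on the left in exactly half of those presentations;
#' the within-block trial order is a uniformly random permutation.
#'
#' @param design a `session_design`.
#' @param seed optional integer; with a seed the schedule is deterministic
#'   and the caller's RNG state is left untouched.
#' @return data.frame with columns `block`, `trial_in_session`, `pair_id`,
#'   `better_on_left`.
#' @export
generate_session <- function(design, seed = NULL) {
  stopifnot(inherits(design, "session_design"))
  reps <- design$reps_per_pair_per_block
  if (reps %% 2L != 0L) stop("side counterbalancing impossible: odd reps")
  with_preserved_seed(seed, {
    blocks <- lapply(seq_len(design$n_blocks), function(b) {
      pair_id <- rep(design$pairs$pair_id, each = reps)
      left <- rep(c(rep(TRUE, reps %/% 2L), rep(FALSE, reps %/% 2L)), times = 3L)
      ord <- sample.int(length(pair_id))
      data.frame(block = b, pair_id = pair_id[ord],
                 better_on_left = left[ord], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, blocks)
    out$trial_in_session <- seq_len(nrow(out))
    out[, c("block", "trial_in_session", "pair_id", "better_on_left")]
  })
}

#' Sample probabilistic feedback for choices
#'
#' Bernoulli reward with probability `p_better` of the pair if the better
#' symbol was chosen, `p_worse` otherwise. Vectorized over trials.
#'
#' @param design a `session_design`.
#' @param pair_id character vector of pair labels ("AB", "CD", "EF").
#' @param chose_better logical vector, same length.
#' @return integer vector of rewards in {0, 1}.
#' @export
sample_feedback <- function(design, pair_id, chose_better) {
  stopifnot(inherits(design, "session_design"),
            length(pair_id) == length(chose_better))
  idx <- match(pair_id, design$pairs$pair_id)
  if (anyNA(idx)) stop("unknown pair_id values: ",
                       paste(unique(pair_id[is.na(idx)]), collapse = ", "))
  p <- ifelse(chose_better, design$pairs$p_better[idx],
              design$pairs$p_worse[idx])
  as.integer(stats::rbinom(length(p), 1L, p))
}
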