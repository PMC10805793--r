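# Trial-level simulation of dual-task observers.
#
# Three processing regimes on dual-task trials:
#   serial          — exactly one side is processed per trial (top with
#                     probability p_top); the other response is a guess.
#   fixed_capacity  — both sides processed, sensitivity scaled by the square
#                     root of the attention share (sample-size model):
#                     d'_top * sqrt(w_top), d'_bottom * sqrt(1 - w_top).
#   independent     — both sides processed at full sensitivity.
# Single-task trials always process the cued side at full sensitivity.
#
# Evidence for a processed stimulus is equal-variance Gaussian,
# N(+d'/2, 1) for signal-present and N(-d'/2, 1) for signal-absent, mapped
# to a 1-4 confidence rating by three criteria (1 = "sure absent",
# 4 = "sure present"). A binary response is correct when
# (rating >= 3) <=> signal-present.

#' Observer parameters
#'
#' Bundle and validate the generative parameters of a simulated observer.
#'
#' @param regime `"serial"`, `"fixed_capacity"`, or `"independent"`.
#' @param dprime_top,dprime_bottom equal-variance sensitivity per side.
#' @param p_top probability that the serial observer processes the top
#'   stimulus on a dual-task trial.
#' @param w_top attention share of the top side for the fixed-capacity
#'   observer; the bottom side receives `1 - w_top`.
#' @param criteria three strictly increasing evidence thresholds mapping
#'   evidence to ratings 1-4.
#' @param guess_dist probability vector over ratings 1-4 used for
#'   unprocessed stimuli, or `NULL` (default) to use each side's marginal
#'   rating distribution under processing, i.e. the average of the
#'   signal-present and signal-absent rating distributions at that side's
#'   d'. With the marginal default, guessed responses carry no signal and
#'   the serial observer's rating-ROC accuracy mixes linearly in p_top, so
#'   the simulated serial observer lies on the serial AOC prediction.
#' @param selection_error_rate probability of reporting the side opposite
#'   the (post)cue: on dual trials the two reports are swapped; on
#'   single-task trials the observer processes and reports the uncued
#'   stimulus.
#' @param fixation_break_rate probability a trial is flagged for exclusion.
#' @return an object of class `observer_params`.
#' @export
observer_params <- function(regime = c("serial", "fixed_capacity", "independent"),
                            dprime_top = dprime_for_pc(0.8),
                            dprime_bottom = dprime_top,
                            p_top = 0.74,
                            w_top = 0.5,
                            criteria = c(-1, 0, 1),
                            guess_dist = NULL,
                            selection_error_rate = 0,
                            fixation_break_rate = 0) {
  regime <- match.arg(regime)
  stopifnot(
    length(criteria) == 3L, all(diff(criteria) > 0),
    dprime_top >= 0, dprime_bottom >= 0,
    p_top >= 0, p_top <= 1, w_top >= 0, w_top <= 1,
    selection_error_rate >= 0, selection_error_rate <= 1,
    fixation_break_rate >= 0, fixation_break_rate <= 1
  )
  if (!is.null(guess_dist)) {
    if (length(guess_dist) != 4L || any(guess_dist < 0) ||
        abs(sum(guess_dist) - 1) > 1e-8) {
      stop("guess_dist must be 4 nonnegative probabilities summing to 1",
           call. = FALSE)
    }
  }
  structure(
    list(regime = regime, dprime_top = dprime_top,
         dprime_bottom = dprime_bottom, p_top = p_top, w_top = w_top,
         criteria = criteria, guess_dist = guess_dist,
         selection_error_rate = selection_error_rate,
         fixation_break_rate = fixation_break_rate),
    class = "observer_params"
  )
}

#' Sensitivity for a target proportion correct
#'
#' Inverts the equal-variance binary-choice relation `pc = pnorm(d'/2)`,
#' which holds for an unbiased observer collapsing ratings at the middle
#' criterion.
#'
#' @param pc target single-task proportion correct in (0.5, 1).
#' @return d'.
#' @export
dprime_for_pc <- function(pc) {
  stopifnot(pc > 0.5, pc < 1)
  2 * qnorm(pc)
}

# rating distribution of a processed stimulus: rows = (present, absent)
rating_dist_processed <- function(dprime, criteria) {
  cuts <- c(-Inf, criteria, Inf)
  present <- diff(pnorm(cuts, mean = dprime / 2))
  absent <- diff(pnorm(cuts, mean = -dprime / 2))
  rbind(present = present, absent = absent)
}

# guess distribution actually used for a side: explicit, or marginal
guess_dist_for <- function(params, dprime) {
  if (!is.null(params$guess_dist)) return(params$guess_dist)
  colMeans(rating_dist_processed(dprime, params$criteria))
}

#' Experiment design for simulation
#'
#' Blocks are arranged in sets of four (two dual-task, one single-task top,
#' one single-task bottom, randomly ordered within each set), 20 trials per
#' block; 60 blocks yield 1,200 trials of which 600 are dual-task.
#'
#' @param n_blocks total number of blocks (rounded up to a multiple of 4).
#' @param trials_per_block trials per block.
#' @param isi_ms nominal interstimulus interval recorded on each trial.
#' @return a list of class `trial_design`.
#' @export
trial_design <- function(n_blocks = 60, trials_per_block = 20, isi_ms = 84) {
  stopifnot(n_blocks >= 1, trials_per_block >= 1)
  n_sets <- ceiling(n_blocks / 4)
  structure(list(n_blocks = 4L * n_sets, trials_per_block = trials_per_block,
                 isi_ms = isi_ms, n_sets = n_sets),
            class = "trial_design")
}

rate_evidence <- function(n, dprime, present, criteria) {
  x <- rnorm(n, mean = ifelse(present, dprime / 2, -dprime / 2))
  1L + (x > criteria[1]) + (x > criteria[2]) + (x > criteria[3])
}

sample_ratings <- function(n, dist) {
  if (n == 0L) return(integer(0))
  sample.int(4L, n, replace = TRUE, prob = dist)
}

#' Simulate one observer's trials
#'
#' Generates a full experiment for one observer: stimulus categories are
#' sampled independently per side (p = 0.5), evidence for processed stimuli
#' follows the equal-variance Gaussian model, ratings for unprocessed
#' stimuli are drawn from the guess distribution, selection errors swap the
#' two sides' reports, and fixation breaks are flagged at random.
#'
#' @param params an [observer_params()] object.
#' @param design a [trial_design()] object.
#' @param seed integer seed; output is bit-reproducible given the seed.
#' @param subject subject identifier stored in the `subject` column.
#' @return a tibble of trials with the documented trial-CSV columns plus
#'   bookkeeping columns `proc_top`/`proc_bottom` (whether the rating
#'   reported for that side was generated by processing that side's
#'   stimulus).
#' @export
simulate_observer <- function(params, design = trial_design(), seed,
                              subject = "s01") {
  stopifnot(inherits(params, "observer_params"),
            inherits(design, "trial_design"))
  set.seed(seed)
  tpb <- design$trials_per_block

  block_type <- as.vector(vapply(
    seq_len(design$n_sets),
    function(i) sample(c("dual", "dual", "single_top", "single_bottom")),
    character(4)
  ))
  cue <- rep(block_type, each = tpb)
  n <- length(cue)
  block <- rep(seq_len(design$n_blocks), each = tpb)
  trial <- rep(seq_len(tpb), times = design$n_blocks)

  cat_top <- sample(c("present", "absent"), n, replace = TRUE)
  cat_bottom <- sample(c("present", "absent"), n, replace = TRUE)
  is_dual <- cue == "dual"

  # which side(s) are processed, and at what effective sensitivity
  proc_top <- logical(n)
  proc_bottom <- logical(n)
  d_top <- rep(params$dprime_top, n)
  d_bottom <- rep(params$dprime_bottom, n)

  sel_err <- rbinom(n, 1L, params$selection_error_rate) == 1L

  # single-task: process the cued side; under a selection error the
  # observer attends (and reports) the wrong side
  st <- cue == "single_top"
  sb <- cue == "single_bottom"
  proc_top[st & !sel_err] <- TRUE
  proc_bottom[st & sel_err] <- TRUE
  proc_bottom[sb & !sel_err] <- TRUE
  proc_top[sb & sel_err] <- TRUE

  if (params$regime == "serial") {
    top_first <- rbinom(n, 1L, params$p_top) == 1L
    proc_top[is_dual & top_first] <- TRUE
    proc_bottom[is_dual & !top_first] <- TRUE
  } else {
    proc_top[is_dual] <- TRUE
    proc_bottom[is_dual] <- TRUE
    if (params$regime == "fixed_capacity") {
      d_top[is_dual] <- params$dprime_top * sqrt(params$w_top)
      d_bottom[is_dual] <- params$dprime_bottom * sqrt(1 - params$w_top)
    }
  }

  resp_top <- rep(NA_integer_, n)
  resp_bottom <- rep(NA_integer_, n)
  resp_top[proc_top] <- rate_evidence(sum(proc_top), d_top[proc_top],
                                      cat_top[proc_top] == "present",
                                      params$criteria)
  resp_bottom[proc_bottom] <- rate_evidence(sum(proc_bottom),
                                            d_bottom[proc_bottom],
                                            cat_bottom[proc_bottom] == "present",
                                            params$criteria)

  # unprocessed side of a dual trial: guess
  guess_top <- is_dual & !proc_top
  guess_bottom <- is_dual & !proc_bottom
  resp_top[guess_top] <- sample_ratings(
    sum(guess_top), guess_dist_for(params, params$dprime_top))
  resp_bottom[guess_bottom] <- sample_ratings(
    sum(guess_bottom), guess_dist_for(params, params$dprime_bottom))

  # selection error on dual trials: the two reports are swapped
  swap <- is_dual & sel_err
  tmp <- resp_top[swap]
  resp_top[swap] <- resp_bottom[swap]
  resp_bottom[swap] <- tmp
  tmp <- proc_top[swap]
  proc_top[swap] <- proc_bottom[swap]
  proc_bottom[swap] <- tmp
  proc_top[swap] <- FALSE  # a swapped report never reflects its own stimulus
  proc_bottom[swap] <- FALSE

  # single-task trials: the report lands on the cued response slot
  move <- st & sel_err
  resp_top[move] <- resp_bottom[move]
  resp_bottom[move] <- NA_integer_
  proc_bottom[move] <- FALSE
  move <- sb & sel_err
  resp_bottom[move] <- resp_top[move]
  resp_top[move] <- NA_integer_
  proc_top[move] <- FALSE

  first_response_side <- rep(NA_character_, n)
  first_response_side[is_dual] <- sample(c("top", "bottom"), sum(is_dual),
                                         replace = TRUE)

  tibble::tibble(
    subject = subject, block = block, trial = trial, cue = cue,
    cat_top = cat_top, cat_bottom = cat_bottom,
    resp_top = resp_top, resp_bottom = resp_bottom,
    first_response_side = first_response_side,
    isi_ms = design$isi_ms,
    fixation_break = rbinom(n, 1L, params$fixation_break_rate) == 1L,
    proc_top = proc_top, proc_bottom = proc_bottom
  )
}

#' Simulate a multi-subject experiment
#'
#' @param n_subjects number of simulated observers.
#' @param params a single [observer_params()] object shared by all
#'   subjects, or a list of one per subject.
#' @param design a [trial_design()] object.
#' @param seed integer seed; per-subject seeds are derived from it.
#' @return a tibble of trials for all subjects.
#' @export
simulate_experiment <- function(n_subjects, params, design = trial_design(),
                                seed = 1) {
  stopifnot(n_subjects >= 1)
  if (inherits(params, "observer_params")) {
    params <- rep(list(params), n_subjects)
  }
  stopifnot(length(params) == n_subjects)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_subjects)
  dplyr::bind_rows(lapply(seq_len(n_subjects), function(i) {
    simulate_observer(params[[i]], design, seed = seeds[i],
                      subject = sprintf("s%02d", i))
  }))
}
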