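# Stimulus-processing trade-offs.
#
# The serial model predicts a negative interdependence between the two
# responses of a dual-task trial: a response is more likely to be correct
# when the response to the *other* side was incorrect (because only one
# side was processed). Every dual-task response is assigned to one of two
# exhaustive sets — other-side-correct vs other-side-incorrect — and A_g is
# compared between the sets. Parallel models predict no difference.

response_correct <- function(resp, cat) {
  (resp >= 3L) == (cat == "present")
}

#' Per-subject stimulus-processing trade-off
#'
#' Pools both sides' dual-task responses within subject, partitions them by
#' the correctness of the same trial's other-side response, and computes
#' A_g (and raw proportion correct) within each partition. Binary
#' correctness of a response is `(rating >= 3) <=> signal-present`.
#'
#' @param trials a trial tibble; only `cue == "dual"` rows are used.
#' @return a tibble with one row per subject: A_g and proportion correct in
#'   the other-incorrect and other-correct sets, their A_g `difference`
#'   (other-incorrect minus other-correct), partition counts, and a
#'   `flagged` column marking subjects with a degenerate partition (an
#'   empty set or a set missing one stimulus class), whose A_g values are
#'   `NA` and who should be excluded from group tests.
#' @export
tradeoff_analysis <- function(trials) {
  dual <- trials[trials$cue == "dual" &
                   !is.na(trials$resp_top) & !is.na(trials$resp_bottom), ,
                 drop = FALSE]
  if (nrow(dual) == 0L) stop("no complete dual-task trials", call. = FALSE)
  rows <- lapply(split(dual, dual$subject), function(tr) {
    ok_top <- response_correct(tr$resp_top, tr$cat_top)
    ok_bottom <- response_correct(tr$resp_bottom, tr$cat_bottom)
    # pooled responses: each row is one response with its own category and
    # the correctness of the other side on the same trial
    resp <- c(tr$resp_top, tr$resp_bottom)
    cat <- c(tr$cat_top, tr$cat_bottom)
    other_ok <- c(ok_bottom, ok_top)
    part_ag <- function(keep) {
      counts <- list(
        present_counts = tabulate(resp[keep & cat == "present"], 4L),
        absent_counts = tabulate(resp[keep & cat == "absent"], 4L)
      )
      tryCatch(ag(counts), error = function(e) NA_real_)
    }
    ag_oi <- part_ag(!other_ok)
    ag_oc <- part_ag(other_ok)
    tibble::tibble(
      subject = tr$subject[1],
      ag_other_incorrect = ag_oi,
      ag_other_correct = ag_oc,
      difference = ag_oi - ag_oc,
      pc_other_incorrect = mean(response_correct(resp, cat)[!other_ok]),
      pc_other_correct = mean(response_correct(resp, cat)[other_ok]),
      n_other_incorrect = sum(!other_ok),
      n_other_correct = sum(other_ok),
      flagged = is.na(ag_oi) || is.na(ag_oc)
    )
  })
  out <- dplyr::bind_rows(rows)
  for (s in out$subject[out$flagged]) {
    warning("subject ", s, " has a degenerate trade-off partition; flagged",
            call. = FALSE)
  }
  out
}

#' Serial-model trade-off curve
#'
#' Traces the trade-off predicted by the all-or-none serial model across
#' single-task difficulty: for each single-task accuracy level, a serial
#' observer is simulated and run through [tradeoff_analysis()]. As
#' single-task accuracy grows, the gap between accuracy on
#' other-side-incorrect and other-side-correct responses widens (processed
#' responses get better while unprocessed responses stay at chance).
#'
#' @param single_accuracy_grid single-task proportions correct, in
#'   (0.5, 1).
#' @param p_top serial top-side processing bias used for the simulation.
#' @param n_dual_trials number of simulated dual-task trials per level.
#' @param seed integer seed.
#' @return a tibble: `single_pc`, `ag_other_incorrect`, `ag_other_correct`,
#'   `difference`.
#' @export
serial_tradeoff_curve <- function(single_accuracy_grid, p_top = 0.5,
                                  n_dual_trials = 20000, seed = 1) {
  stopifnot(all(single_accuracy_grid > 0.5), all(single_accuracy_grid < 1))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(single_accuracy_grid))
  # dual-task blocks only: the trade-off uses no single-task trials
  n_blocks <- 4L * ceiling(n_dual_trials / (2 * 20))
  design <- trial_design(n_blocks = n_blocks, trials_per_block = 20)
  rows <- lapply(seq_along(single_accuracy_grid), function(i) {
    pc <- single_accuracy_grid[i]
    params <- observer_params("serial", dprime_top = dprime_for_pc(pc),
                              p_top = p_top)
    tr <- simulate_observer(params, design, seed = seeds[i])
    res <- tradeoff_analysis(tr)
    tibble::tibble(single_pc = pc,
                   ag_other_incorrect = res$ag_other_incorrect,
                   ag_other_correct = res$ag_other_correct,
                   difference = res$difference)
  })
  dplyr::bind_rows(rows)
}
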