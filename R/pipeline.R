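# End-to-end orchestration: trial CSV IO, exclusions, per-subject and
# group-level AOC / trade-off / congruency / response-order analyses, and a
# serializable report.

TRIAL_COLUMNS <- c("subject", "block", "trial", "cue", "cat_top",
                   "cat_bottom", "resp_top", "resp_bottom",
                   "first_response_side", "isi_ms", "fixation_break")
CUE_LEVELS <- c("single_top", "single_bottom", "dual")

#' Analysis configuration
#'
#' @param experiment 1 (vowel detection) or 2 (pronounceability); recorded
#'   in the report.
#' @param accuracy_window single-task block-accuracy bounds; runs of blocks
#'   outside the window are discarded.
#' @param min_run_length minimum number of consecutive blocks for the
#'   block-accuracy exclusion rule.
#' @param n_boot bootstrap resamples for CIs.
#' @param seed integer seed for all stochastic steps (bootstrap).
#' @param first_response_only when `TRUE`, dual-task trials contribute only
#'   the first response to the AOC analysis.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(experiment = 1, accuracy_window = c(0.70, 0.90),
                            min_run_length = 4, n_boot = 1000, seed = 1,
                            first_response_only = FALSE) {
  stopifnot(experiment %in% c(1, 2), length(accuracy_window) == 2L,
            accuracy_window[1] < accuracy_window[2], min_run_length >= 1)
  structure(
    list(experiment = experiment, accuracy_window = accuracy_window,
         min_run_length = min_run_length, n_boot = n_boot, seed = seed,
         first_response_only = first_response_only),
    class = "analysis_config"
  )
}

#' Write trials to the trial CSV dialect
#'
#' Columns: subject, block, trial, cue, cat_top, cat_bottom, resp_top,
#' resp_bottom, first_response_side, isi_ms, fixation_break. Missing
#' responses (the uncued side of single-task trials) are empty fields.
#' Simulation bookkeeping columns are dropped.
#'
#' @param trials trial tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  out <- as.data.frame(trials[, TRIAL_COLUMNS])
  out$fixation_break <- ifelse(out$fixation_break, "TRUE", "FALSE")
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read and validate a trial CSV
#'
#' Validates the documented dialect row by row; malformed rows are reported
#' with their file line numbers.
#'
#' @param path CSV path with the documented header (see [write_trials()]);
#'   an optional `session` column is honored by [apply_exclusions()].
#' @return a validated trial tibble.
#' @export
read_trials <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(subject = "character"), na.strings = "")
  missing_cols <- setdiff(TRIAL_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  raw$fixation_break <- as.logical(raw$fixation_break)
  raw$isi_ms <- as.numeric(raw$isi_ms)
  line <- seq_len(nrow(raw)) + 1L  # header is line 1

  bad <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    if (any(cond)) {
      stop("invalid trial rows (", msg, ") at line",
           if (sum(cond) > 1L) "s " else " ",
           paste(head(line[cond], 5L), collapse = ", "),
           if (sum(cond) > 5L) ", ..." else "", call. = FALSE)
    }
  }
  ok_rating <- function(r) is.na(r) | (r %in% 1:4)
  bad(!(raw$cue %in% CUE_LEVELS), "unknown cue")
  bad(!(raw$cat_top %in% c("present", "absent")) |
        !(raw$cat_bottom %in% c("present", "absent")), "unknown category")
  bad(!ok_rating(raw$resp_top) | !ok_rating(raw$resp_bottom),
      "rating outside 1-4")
  is_dual <- raw$cue == "dual"
  bad(is_dual & (is.na(raw$resp_top) | is.na(raw$resp_bottom)),
      "dual trial lacking a response")
  bad(is_dual & !(raw$first_response_side %in% c("top", "bottom")),
      "dual trial lacking first_response_side")
  bad(raw$cue == "single_top" & (is.na(raw$resp_top) | !is.na(raw$resp_bottom)),
      "single_top trial must have exactly the top response")
  bad(raw$cue == "single_bottom" &
        (is.na(raw$resp_bottom) | !is.na(raw$resp_top)),
      "single_bottom trial must have exactly the bottom response")
  bad(is.na(raw$fixation_break), "fixation_break not TRUE/FALSE")
  tibble::as_tibble(raw)
}

block_single_pc <- function(tr) {
  st <- tr[tr$cue == "single_top", ]
  sb <- tr[tr$cue == "single_bottom", ]
  ok <- c(response_correct(st$resp_top, st$cat_top),
          response_correct(sb$resp_bottom, sb$cat_bottom))
  if (length(ok) == 0L) NA_real_ else mean(ok)
}

# maximal runs of >= min_len consecutive blocks whose single-task blocks
# are all out of window on the same side; dual-only blocks inside a run are
# carried along. Returns block ids to drop.
out_of_window_runs <- function(blocks, pc, lo, hi, min_len) {
  state <- ifelse(is.na(pc), "none", ifelse(pc > hi, "high",
                                            ifelse(pc < lo, "low", "ok")))
  drop <- character(0)
  for (side in c("high", "low")) {
    compatible <- state %in% c(side, "none")
    r <- rle(compatible)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      idx <- starts[k]:ends[k]
      # trim leading/trailing dual-only blocks: a run is anchored by
      # out-of-window single-task blocks
      anchors <- idx[state[idx] == side]
      if (length(anchors) == 0L) next
      idx <- idx[idx >= min(anchors) & idx <= max(anchors)]
      if (length(idx) < min_len) next
      pooled <- pc[idx]
      pooled <- mean(pooled, na.rm = TRUE)
      if (pooled > hi || pooled < lo) drop <- c(drop, blocks[idx])
    }
  }
  unique(drop)
}

#' Apply trial and block exclusions
#'
#' Removes (1) fixation-break trials and (2) all trials in any run of at
#' least `min_run_length` consecutive blocks (per subject and session,
#' ordered by block index) whose single-task proportion correct is outside
#' the accuracy window — blocks without single-task trials inside such a
#' run are removed with it. Block accuracy uses binary correctness
#' (`rating >= 3` <=> signal-present), not A_g.
#'
#' @param trials trial tibble; a `session` column is honored if present,
#'   otherwise each subject's blocks form one session.
#' @param config an [analysis_config()].
#' @return a list with `trials` (kept rows) and `report` (counts per rule:
#'   `n_input`, `n_fixation_break`, `n_block_rule`, `n_kept`, and the
#'   dropped `blocks` per subject).
#' @export
apply_exclusions <- function(trials, config = analysis_config()) {
  n_input <- nrow(trials)
  fb <- trials$fixation_break
  kept <- trials[!fb, , drop = FALSE]

  lo <- config$accuracy_window[1]
  hi <- config$accuracy_window[2]
  session <- if ("session" %in% names(kept)) kept$session else 1L
  key <- paste(kept$subject, session, sep = "\r")
  dropped_blocks <- list()
  drop_row <- rep(FALSE, nrow(kept))
  for (k in unique(key)) {
    rows <- which(key == k)
    tr <- kept[rows, , drop = FALSE]
    blocks <- sort(unique(tr$block))
    pc <- vapply(blocks, function(b) block_single_pc(tr[tr$block == b, ]),
                 numeric(1))
    bad_blocks <- out_of_window_runs(as.character(blocks), pc, lo, hi,
                                     config$min_run_length)
    if (length(bad_blocks) > 0L) {
      dropped_blocks[[tr$subject[1]]] <- c(dropped_blocks[[tr$subject[1]]],
                                           as.numeric(bad_blocks))
      drop_row[rows] <- as.character(tr$block) %in% bad_blocks
    }
  }
  out <- kept[!drop_row, , drop = FALSE]
  list(
    trials = out,
    report = list(n_input = n_input, n_fixation_break = sum(fb),
                  n_block_rule = sum(drop_row), n_kept = nrow(out),
                  blocks = dropped_blocks)
  )
}

#' Congruency analysis
#'
#' "Congruent" trials present the same category on both sides. Computes
#' per-subject A_g within congruent and incongruent subsets, separately for
#' single-task and dual-task conditions (responses pooled over sides), and
#' the group-level congruency x cue-condition repeated-measures interaction.
#'
#' @param trials trial tibble (post-exclusion).
#' @return a list with `table` (subject x cue_type x congruency A_g, plus a
#'   `flagged` marker for subjects with an empty cell) and `tests` (main
#'   effect of congruency on the congruent-minus-incongruent difference per
#'   cue condition, and the interaction test), computed over unflagged
#'   subjects.
#' @export
congruency_analysis <- function(trials) {
  tr <- trials
  tr$congruency <- ifelse(tr$cat_top == tr$cat_bottom, "congruent",
                          "incongruent")
  tr$cue_type <- ifelse(tr$cue == "dual", "dual", "single")
  cells <- expand.grid(cue_type = c("single", "dual"),
                       congruency = c("congruent", "incongruent"),
                       stringsAsFactors = FALSE)
  rows <- lapply(split(tr, tr$subject), function(d) {
    vals <- mapply(function(ct, cg) {
      sub <- d[d$cue_type == ct & d$congruency == cg, , drop = FALSE]
      # pool responses over sides; single-task trials contribute the cued side
      resp <- c(sub$resp_top, sub$resp_bottom)
      cat <- c(sub$cat_top, sub$cat_bottom)
      keep <- !is.na(resp)
      counts <- list(present_counts = tabulate(resp[keep & cat == "present"], 4L),
                     absent_counts = tabulate(resp[keep & cat == "absent"], 4L))
      tryCatch(ag(counts), error = function(e) NA_real_)
    }, cells$cue_type, cells$congruency)
    tibble::tibble(subject = d$subject[1], cue_type = cells$cue_type,
                   congruency = cells$congruency, ag = unname(vals),
                   flagged = anyNA(vals))
  })
  tab <- dplyr::bind_rows(rows)
  for (s in unique(tab$subject[tab$flagged])) {
    warning("subject ", s, " has an empty congruency cell; flagged",
            call. = FALSE)
  }
  usable <- tab[!tab$flagged, , drop = FALSE]
  tests <- NULL
  if (length(unique(usable$subject)) >= 2L) {
    wide <- function(ct) {
      d <- usable[usable$cue_type == ct, ]
      con <- d$ag[d$congruency == "congruent"]
      inc <- d$ag[d$congruency == "incongruent"]
      con - inc
    }
    tests <- list(
      single = one_sample_t(wide("single")),
      dual = one_sample_t(wide("dual")),
      interaction = rm_interaction_test(usable, value = "ag",
                                        subject = "subject",
                                        f1 = "congruency", f2 = "cue_type")
    )
  }
  list(table = tab, tests = tests)
}

#' Response-order analysis
#'
#' On dual-task trials the two sides are reported in a randomly chosen
#' order. Computes per-subject A_g for first vs second responses (pooled
#' over sides) and a paired test of the difference; optionally reruns the
#' AOC analysis using only each dual trial's first response.
#'
#' @param trials trial tibble (post-exclusion).
#' @param config an [analysis_config()]; when `first_response_only` is
#'   `TRUE` the AOC rerun is included.
#' @return a list with `table` (subject, ag_first, ag_second, difference),
#'   `test` (paired inference on first minus second), and `aoc_first_only`
#'   (an [aoc_summary()] tibble, or `NULL`).
#' @export
response_order_analysis <- function(trials, config = analysis_config()) {
  dual <- trials[trials$cue == "dual", , drop = FALSE]
  if (nrow(dual) == 0L) stop("no dual-task trials", call. = FALSE)
  if (anyNA(dual$first_response_side)) {
    stop("dual trials with missing first_response_side", call. = FALSE)
  }
  if (length(unique(dual$first_response_side)) == 1L) {
    warning("first_response_side is constant; order should be balanced ",
            "by design", call. = FALSE)
  }
  first_top <- dual$first_response_side == "top"
  rows <- lapply(split(seq_len(nrow(dual)), dual$subject), function(ix) {
    d <- dual[ix, ]
    ft <- first_top[ix]
    pick <- function(first) {
      use_top <- if (first) ft else !ft
      resp <- ifelse(use_top, d$resp_top, d$resp_bottom)
      cat <- ifelse(use_top, d$cat_top, d$cat_bottom)
      counts <- list(present_counts = tabulate(resp[cat == "present"], 4L),
                     absent_counts = tabulate(resp[cat == "absent"], 4L))
      tryCatch(ag(counts), error = function(e) NA_real_)
    }
    a1 <- pick(TRUE)
    a2 <- pick(FALSE)
    tibble::tibble(subject = d$subject[1], ag_first = a1, ag_second = a2,
                   difference = a1 - a2)
  })
  tab <- dplyr::bind_rows(rows)
  ok <- !is.na(tab$difference)
  test <- if (sum(ok) >= 2L) {
    effect_test(tab$difference[ok], n_boot = config$n_boot,
                seed = config$seed)
  } else NULL

  aoc_first <- NULL
  if (isTRUE(config$first_response_only)) {
    reduced <- trials
    is_dual <- reduced$cue == "dual"
    ft <- is_dual & reduced$first_response_side == "top"
    fb <- is_dual & reduced$first_response_side == "bottom"
    reduced$resp_bottom[ft] <- NA_integer_
    reduced$resp_top[fb] <- NA_integer_
    aoc_first <- aoc_summary(reduced)
  }
  list(table = tab, test = test, aoc_first_only = aoc_first)
}

model_verdict <- function(p) if (p < 0.05) "rejected" else "not rejected"

#' Run the full dual-task analysis
#'
#' Orchestrates exclusions, per-subject AOC summaries, group tests of the
#' signed distance to each capacity model (t, percentile bootstrap CI, JZS
#' Bayes factor), the side x cue-condition interaction, the
#' stimulus-processing trade-off with its group test, the congruency
#' analysis, and the response-order analysis (with a first-response-only
#' AOC rerun when configured).
#'
#' A model is "rejected" when the group t test of its signed distances
#' against zero has p < 0.05.
#'
#' @param trials trial tibble (e.g. from [read_trials()] or
#'   [simulate_experiment()]).
#' @param config an [analysis_config()].
#' @return a nested report list (serializable with [write_report()]).
#' @export
run_experiment <- function(trials, config = analysis_config()) {
  if (is.null(trials) || nrow(trials) == 0L) {
    stop("empty trial input", call. = FALSE)
  }
  excl <- apply_exclusions(trials, config)
  kept <- excl$trials

  aoc <- aoc_summary(kept)
  model_cols <- c(serial = "dist_serial",
                  fixed_capacity = "dist_fixed_capacity",
                  independent = "dist_independent")
  model_tests <- lapply(model_cols, function(cl) {
    res <- effect_test(aoc[[cl]], n_boot = config$n_boot, seed = config$seed)
    c(unclass(res), list(verdict = model_verdict(res$p)))
  })

  side_cue <- tibble::tibble(
    subject = rep(aoc$subject, 4),
    side = rep(c("top", "bottom", "top", "bottom"), each = nrow(aoc)),
    cue = rep(c("single", "single", "dual", "dual"), each = nrow(aoc)),
    ag = c(aoc$ag_single_top, aoc$ag_single_bottom,
           aoc$ag_dual_top, aoc$ag_dual_bottom)
  )
  side_cue_interaction <- rm_interaction_test(side_cue, value = "ag",
                                              subject = "subject",
                                              f1 = "side", f2 = "cue")

  trade <- tradeoff_analysis(kept)
  trade_ok <- !trade$flagged
  trade_test <- if (sum(trade_ok) >= 2L) {
    effect_test(trade$difference[trade_ok], n_boot = config$n_boot,
                seed = config$seed)
  } else NULL

  congruency <- congruency_analysis(kept)
  order <- response_order_analysis(kept, config)

  list(
    config = unclass(config),
    exclusions = excl$report,
    aoc = list(
      per_subject = aoc,
      model_tests = model_tests,
      p_top = list(mean = mean(aoc$p_top_hat),
                   sem = sd(aoc$p_top_hat) / sqrt(nrow(aoc))),
      side_cue_interaction = side_cue_interaction
    ),
    tradeoff = list(per_subject = trade,
                    test = if (is.null(trade_test)) NULL
                           else unclass(trade_test)),
    congruency = list(per_subject = congruency$table,
                      tests = congruency$tests),
    response_order = list(
      per_subject = order$table,
      test = if (is.null(order$test)) NULL else unclass(order$test),
      aoc_first_only = order$aoc_first_only
    )
  )
}

#' Write a report directory
#'
#' Emits `report.json` plus the per-subject tables as CSV files.
#'
#' @param report a report list from [run_experiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(aoc = report$aoc$per_subject,
                 tradeoff = report$tradeoff$per_subject,
                 congruency = report$congruency$per_subject,
                 response_order = report$response_order$per_subject)
  for (nm in names(tables)) {
    write.csv(tables[[nm]], file.path(dir, paste0(nm, "_per_subject.csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Validate a report against the published schema
#'
#' Checks the report's structure against the schema shipped at
#' `inst/extdata/report-schema.json` (required keys and their types,
#' recursively).
#'
#' @param report a report list from [run_experiment()].
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  schema_path <- system.file("extdata", "report-schema.json",
                             package = "dualcap")
  schema <- jsonlite::read_json(schema_path)
  check <- function(node, spec, path) {
    type <- spec$type
    if (identical(type, "object")) {
      if (!is.list(node)) stop("report$", path, " must be an object",
                               call. = FALSE)
      for (key in names(spec$required)) {
        if (!(key %in% names(node))) {
          stop("report$", path, " missing required field '", key, "'",
               call. = FALSE)
        }
        check(node[[key]], spec$required[[key]],
              paste0(path, if (nzchar(path)) "$" else "", key))
      }
    } else if (identical(type, "number")) {
      if (!is.numeric(node) || length(node) != 1L) {
        stop("report$", path, " must be a single number", call. = FALSE)
      }
    } else if (identical(type, "table")) {
      if (!is.data.frame(node)) stop("report$", path, " must be a table",
                                     call. = FALSE)
      miss <- setdiff(unlist(spec$columns), names(node))
      if (length(miss) > 0L) {
        stop("report$", path, " missing columns: ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
    }
    invisible(TRUE)
  }
  check(report, schema, "")
  invisible(TRUE)
}
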