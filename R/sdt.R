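# Rating-ROC accuracy.
#
# A_g is the trapezoidal area under the empirical ROC traced by the three
# rating criteria, with (0,0) and (1,1) appended. It equals the concordance
# probability P(rating_present > rating_absent) + 0.5 P(tie) and can be read
# as a bias-corrected proportion correct: 0.5 = chance, 1.0 = perfect.

#' Tabulate ratings by true stimulus category
#'
#' Builds the 2 x 4 table of rating counts (ratings 1-4 for signal-present
#' and signal-absent stimuli) for one side of the display, over a subset of
#' trials.
#'
#' @param trials a trial tibble (see [read_trials()] for the columns).
#' @param side `"top"` or `"bottom"`.
#' @param condition_filter either a character vector of cue conditions to
#'   keep (e.g. `"dual"`) or a predicate function mapping the trial tibble
#'   to a logical vector.
#' @return an object of class `rating_counts`: a list with integer vectors
#'   `present_counts` and `absent_counts`.
#' @export
rating_counts <- function(trials, side = c("top", "bottom"),
                          condition_filter = NULL) {
  side <- match.arg(side)
  if (!is.null(condition_filter)) {
    keep <- if (is.function(condition_filter)) {
      condition_filter(trials)
    } else {
      trials$cue %in% condition_filter
    }
    trials <- trials[keep, , drop = FALSE]
  }
  resp <- trials[[paste0("resp_", side)]]
  cat <- trials[[paste0("cat_", side)]]
  ok <- !is.na(resp)
  resp <- resp[ok]
  cat <- cat[ok]
  if (length(resp) == 0L) {
    stop("no scored responses on the ", side,
         " side after filtering", call. = FALSE)
  }
  tab <- function(r) tabulate(r, nbins = 4L)
  structure(
    list(present_counts = tab(resp[cat == "present"]),
         absent_counts = tab(resp[cat == "absent"])),
    class = "rating_counts"
  )
}

#' Area under the rating ROC (A_g)
#'
#' Computes the trapezoidal area under the empirical ROC built from
#' cumulative hit and false-alarm rates across the three rating criteria.
#' Ties receive half credit (the trapezoid rule), equivalent to the
#' concordance probability. Values below 0.5 are returned as computed.
#'
#' @param counts a `rating_counts` object, or a list with
#'   `present_counts`/`absent_counts`.
#' @return A_g in `[0, 1]`.
#' @export
ag <- function(counts) {
  p <- counts$present_counts
  a <- counts$absent_counts
  stopifnot(length(p) == 4L, length(a) == 4L, all(p >= 0), all(a >= 0))
  np <- sum(p)
  na <- sum(a)
  if (np == 0L || na == 0L) {
    stop("A_g requires at least one trial in each stimulus category",
         call. = FALSE)
  }
  # "yes at criterion k" = rating >= k, k = 4, 3, 2; ROC from (0,0) to (1,1)
  hit <- c(0, cumsum(rev(p)) / np, 1)
  fa <- c(0, cumsum(rev(a)) / na, 1)
  sum(diff(fa) * (head(hit, -1) + hit[-1]) / 2)
}

#' A_g for a trial subset
#'
#' Convenience wrapper: tabulate then compute [ag()].
#'
#' @inheritParams rating_counts
#' @return A_g.
#' @export
ag_for <- function(trials, side, condition_filter = NULL) {
  ag(rating_counts(trials, side, condition_filter))
}
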