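# Attention operating characteristics and capacity-model predictions.
#
# An AOC places dual-task accuracy for the two stimuli as a point in
# (bottom accuracy, top accuracy) space, with single-task accuracies
# pinned to the axes. Three models predict where the dual-task point can
# lie, given the single-task accuracies:
#   serial          — straight segment between (acc_bottom_single, 0.5) and
#                     (0.5, acc_top_single), traced by the probability p of
#                     processing the top stimulus;
#   fixed_capacity  — sample-size locus: each accuracy is converted to d',
#                     d' scales with the square root of the attention share
#                     w, and is converted back;
#   independent     — the single point (acc_bottom_single, acc_top_single).

#' An AOC point
#'
#' @param acc_bottom accuracy for the bottom stimulus (x-axis).
#' @param acc_top accuracy for the top stimulus (y-axis).
#' @return named numeric vector of class `aoc_point`.
#' @export
aoc_point <- function(acc_bottom, acc_top) {
  stopifnot(is.finite(acc_bottom), is.finite(acc_top))
  structure(c(acc_bottom = acc_bottom, acc_top = acc_top),
            class = "aoc_point")
}

new_model_curve <- function(model, acc_top_single, acc_bottom_single, locus) {
  structure(
    list(model = model, acc_top_single = acc_top_single,
         acc_bottom_single = acc_bottom_single, locus = locus),
    class = "model_curve"
  )
}

check_anchor <- function(acc, what) {
  if (acc < 0.5) {
    warning(what, " accuracy ", signif(acc, 4),
            " is below chance; used as-is", call. = FALSE)
  }
  acc
}

#' All-or-none serial model prediction
#'
#' The serial observer processes the top stimulus on a fraction p of
#' dual-task trials and the bottom stimulus on the rest; the unprocessed
#' side is at chance. The locus is the straight segment
#' ((1-p) acc_bottom_single + p/2, p acc_top_single + (1-p)/2), p in [0,1].
#'
#' @param acc_top_single,acc_bottom_single single-task accuracies.
#' @return a `model_curve` whose `locus(p)` returns a 2-column matrix of
#'   (acc_bottom, acc_top) coordinates.
#' @export
serial_prediction <- function(acc_top_single, acc_bottom_single) {
  at <- check_anchor(acc_top_single, "single-task top")
  ab <- check_anchor(acc_bottom_single, "single-task bottom")
  locus <- function(p) {
    cbind(acc_bottom = (1 - p) * ab + p * 0.5,
          acc_top = p * at + (1 - p) * 0.5)
  }
  new_model_curve("serial", at, ab, locus)
}

#' Fixed-capacity parallel (sample-size) model prediction
#'
#' Both stimuli are processed while sharing a fixed resource: with share w
#' on the top side, effective sensitivity is d' sqrt(w) (top) and
#' d' sqrt(1-w) (bottom), where d' is recovered from each single-task
#' accuracy via the equal-variance mapping acc = pnorm(d'/2).
#'
#' @inheritParams serial_prediction
#' @return a `model_curve` whose `locus(w)` returns (acc_bottom, acc_top)
#'   coordinates; `w` is the top side's attention share.
#' @export
fixed_capacity_prediction <- function(acc_top_single, acc_bottom_single) {
  at <- check_anchor(acc_top_single, "single-task top")
  ab <- check_anchor(acc_bottom_single, "single-task bottom")
  clamp <- function(a, what) {
    if (a >= 1) {
      warning(what, " accuracy of 1 implies infinite d'; clamped to 1 - 1e-6",
              call. = FALSE)
      1 - 1e-6
    } else a
  }
  zt <- qnorm(clamp(at, "single-task top"))
  zb <- qnorm(clamp(ab, "single-task bottom"))
  locus <- function(w) {
    cbind(acc_bottom = pnorm(sqrt(1 - w) * zb),
          acc_top = pnorm(sqrt(w) * zt))
  }
  new_model_curve("fixed_capacity", at, ab, locus)
}

#' Independent (unlimited-capacity) parallel model prediction
#'
#' Dual-task accuracy equals single-task accuracy on both sides: the locus
#' is the single point (acc_bottom_single, acc_top_single).
#'
#' @inheritParams serial_prediction
#' @return a `model_curve`; its `locus()` ignores the parameter.
#' @export
independent_prediction <- function(acc_top_single, acc_bottom_single) {
  at <- check_anchor(acc_top_single, "single-task top")
  ab <- check_anchor(acc_bottom_single, "single-task bottom")
  locus <- function(w) {
    cbind(acc_bottom = rep(ab, length(w)), acc_top = rep(at, length(w)))
  }
  new_model_curve("independent", at, ab, locus)
}

#' Signed minimum distance from a dual-task point to a model locus
#'
#' Finds the nearest point on the model locus (dense parameter grid plus
#' local refinement) and returns the Euclidean distance, signed positive
#' when the dual-task point lies on the far side of the locus from chance
#' (0.5, 0.5) — i.e. the observer outperforms the model — and negative when
#' it falls short. For the serial model the locus parameter of the nearest
#' point estimates p_top.
#'
#' @param dual_point an [aoc_point()] or numeric `c(acc_bottom, acc_top)`.
#' @param curve a `model_curve`.
#' @param n_grid grid resolution for the initial search.
#' @return a list of class `distance_result` with elements `model`,
#'   `signed_distance`, `nearest_point`, and `param_hat` (for the serial
#'   model this is `p_top_hat`, clamped to `[0, 1]`).
#' @export
signed_distance <- function(dual_point, curve, n_grid = 1001L) {
  stopifnot(inherits(curve, "model_curve"), length(dual_point) == 2L)
  x <- as.numeric(dual_point)
  d2 <- function(par) {
    q <- curve$locus(par)
    (q[, 1] - x[1])^2 + (q[, 2] - x[2])^2
  }
  grid <- seq(0, 1, length.out = n_grid)
  i <- which.min(d2(grid))
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  par_hat <- if (hi > lo) {
    opt <- optimize(d2, c(lo, hi), tol = 1e-10)
    if (opt$objective <= d2(grid[i])) opt$minimum else grid[i]
  } else grid[i]
  par_hat <- min(max(par_hat, 0), 1)
  q <- drop(curve$locus(par_hat))
  dist <- sqrt(sum((x - q)^2))
  v <- q - c(0.5, 0.5)
  if (sqrt(sum(v^2)) < 1e-12) v <- c(1, 1)
  s <- sign(sum((x - q) * v))
  structure(
    list(model = curve$model,
         signed_distance = if (s == 0) 0 else s * dist,
         nearest_point = aoc_point(q[[1]], q[[2]]),
         param_hat = par_hat),
    class = "distance_result"
  )
}

#' Per-subject AOC summary
#'
#' For each subject: single-task A_g per side (the AOC anchors), the
#' dual-task A_g point, the signed distance to each capacity model's
#' prediction, and the serial model's estimate of the top-side processing
#' bias p_top. Subjects missing a usable condition (e.g. no signal-absent
#' trials in a cell) are dropped with a warning.
#'
#' @param trials a trial tibble covering single-task and dual-task trials
#'   (fixation-break trials should already be excluded).
#' @return a tibble with one row per usable subject: `subject`,
#'   `ag_single_top`, `ag_single_bottom`, `ag_dual_top`, `ag_dual_bottom`,
#'   `dist_serial`, `dist_fixed_capacity`, `dist_independent`, `p_top_hat`.
#' @export
aoc_summary <- function(trials) {
  rows <- lapply(split(trials, trials$subject), function(tr) {
    subj <- tr$subject[1]
    vals <- tryCatch(
      list(st = ag_for(tr, "top", "single_top"),
           sb = ag_for(tr, "bottom", "single_bottom"),
           dt = ag_for(tr, "top", "dual"),
           db = ag_for(tr, "bottom", "dual")),
      error = function(e) {
        warning("subject ", subj, " excluded from AOC summary: ",
                conditionMessage(e), call. = FALSE)
        NULL
      }
    )
    if (is.null(vals)) return(NULL)
    dual <- aoc_point(vals$db, vals$dt)
    ser <- signed_distance(dual, serial_prediction(vals$st, vals$sb))
    fix <- signed_distance(dual, fixed_capacity_prediction(vals$st, vals$sb))
    ind <- signed_distance(dual, independent_prediction(vals$st, vals$sb))
    tibble::tibble(
      subject = subj,
      ag_single_top = vals$st, ag_single_bottom = vals$sb,
      ag_dual_top = vals$dt, ag_dual_bottom = vals$db,
      dist_serial = ser$signed_distance,
      dist_fixed_capacity = fix$signed_distance,
      dist_independent = ind$signed_distance,
      p_top_hat = ser$param_hat
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) stop("no subject had all usable conditions", call. = FALSE)
  out
}
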