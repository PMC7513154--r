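# Structural comparison metrics (A / D / I / C / SHD) and run-level
# summaries (mean result MR, best result BR).

#' Structural difference between a learned and a reference structure
#'
#' Per unordered node pair: an arc present in the reference and learned
#' with the same direction is correct (C); present in both but reversed
#' is inverted (I); present only in the reference is deleted (D); present
#' only in the learned structure is added (A).  The structural Hamming
#' distance is `SHD = A + D + I`.
#'
#' @param learned,truth `bn_dag` objects over the same variables.
#' @return list of class `structural_diff` with integer fields `added`,
#'   `deleted`, `inverted`, `correct`, `shd`.
#' @export
structural_diff <- function(learned, truth) {
  if (!setequal(learned$nodes, truth$nodes))
    stop("structures must share the same variables")
  # compare in the reference's node ordering
  st_l <- pair_states(dag(truth$nodes, learned$arcs))
  st_t <- pair_states(truth)
  added    <- sum(st_t == 3L & st_l != 3L)
  deleted  <- sum(st_t != 3L & st_l == 3L)
  inverted <- sum(st_t != 3L & st_l != 3L & st_l != st_t)
  correct  <- sum(st_t != 3L & st_l == st_t)
  structure(list(added = added, deleted = deleted, inverted = inverted,
                 correct = correct, shd = added + deleted + inverted),
            class = "structural_diff")
}

#' @export
print.structural_diff <- function(x, ...) {
  cat(sprintf("A=%d D=%d I=%d C=%d SHD=%d\n",
              x$added, x$deleted, x$inverted, x$correct, x$shd))
  invisible(x)
}

#' Summarize repeated learning runs
#'
#' MR (mean result) is the arithmetic mean of every metric over runs;
#' BR (best result) is the minimum SHD and, when scores are supplied, the
#' maximum score.
#'
#' @param diffs list of `structural_diff` objects (>= 1).
#' @param scores optional numeric vector of learned-structure scores,
#'   same length as `diffs`.
#' @return list with `mr` (named numeric: shd, deleted, added, inverted,
#'   correct, and score when given), `br_shd`, and `br_score` (when
#'   given).
#' @export
summarize_runs <- function(diffs, scores = NULL) {
  if (length(diffs) < 1L) stop("at least one run is required")
  m <- function(f) mean(vapply(diffs, `[[`, numeric(1), f))
  mr <- c(shd = m("shd"), deleted = m("deleted"), added = m("added"),
          inverted = m("inverted"), correct = m("correct"))
  out <- list(mr = mr,
              br_shd = min(vapply(diffs, `[[`, numeric(1), "shd")))
  if (!is.null(scores)) {
    out$mr <- c(out$mr, score = mean(scores))
    out$br_score <- max(scores)
  }
  out
}
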