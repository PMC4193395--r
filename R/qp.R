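#' Quality parameter of an event detector
#'
#' The pipeline's central statistic.  Given detected event times and
#' per-movement target spans, an event is a true positive when it falls in
#' some span.  With `p` the true-positive fraction of events (the
#' "probability of movement", also read as probability of correct
#' stimulation) and `d` the fraction of movements that received at least
#' one true positive, the quality parameter is the geometric mean
#' `qp = 100 * sqrt(p * d)` in percent.  The geometric mean forces *both*
#' precision and coverage to be high; the raw product `p * d` is available
#' via `combine = "product"`.
#'
#' @param events Numeric vector of event times in ms.
#' @param spans A data frame with columns `lo`, `hi`: one target interval
#'   `[lo, hi)` per movement.
#' @param combine `"geometric"` (default) or `"product"`.
#' @return An object of class `qp_result`: list with `p`, `d`, `qp`
#'   (percent), `n_events`, `n_movements`.
#' @examples
#' qp_score(c(3500, 4200, 9000), spans = data.frame(lo = c(3000, 6000),
#'                                                  hi = c(5000, 8000)))
#' @export
qp_score <- function(events, spans, combine = c("geometric", "product")) {
  combine <- match.arg(combine)
  n_mov <- nrow(spans)
  if (is.null(n_mov) || n_mov == 0) {
    stop("quality parameter undefined without movements", call. = FALSE)
  }
  events <- sort(as.numeric(events))
  in_span <- function(t) t >= spans$lo & t < spans$hi
  tp_flags <- vapply(events, function(t) any(in_span(t)), logical(1))
  tp <- sum(tp_flags)
  p <- if (length(events) > 0) tp / length(events) else 0
  hit <- vapply(seq_len(n_mov), function(i) {
    any(events >= spans$lo[i] & events < spans$hi[i])
  }, logical(1))
  d <- sum(hit) / n_mov
  qp <- if (combine == "geometric") 100 * sqrt(p * d) else 100 * p * d
  structure(
    list(p = p, d = d, qp = qp, n_events = length(events),
         n_movements = n_mov, combine = combine),
    class = "qp_result"
  )
}

#' @export
print.qp_result <- function(x, ...) {
  cat(sprintf(
    "<qp_result> qp = %.1f%%  (p = %.3f over %d events, d = %.3f over %d movements)\n",
    x$qp, x$p, x$n_events, x$d, x$n_movements))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname qp_score
#' @param x A `qp_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.qp_result <- function(x, ...) {
  tibble::tibble(p = x$p, d = x$d, qp = x$qp, n_events = x$n_events,
                 n_movements = x$n_movements)
}

#' @rdname qp_score
#' @exportS3Method generics::glance
glance.qp_result <- function(x, ...) tidy(x)

#' EEG quality parameter from ratiogram events
#'
#' Matches detected ratio-peak events against the 2-s pre-movement windows
#' of the movement list.  Events inside the movement window itself (i.e.
#' during execution, not preparation) count as false positives by default,
#' since the module predicts intention; set `count_in_movement = TRUE` to
#' accept them as true positives.
#'
#' @param events Numeric vector of event times in ms.
#' @param movements A `movement_windows` tibble (must be sorted).
#' @param premovement_ms Pre-movement window length (default 2000 ms).
#' @param count_in_movement Also accept events inside `[start, end)`.
#' @param combine Passed to [qp_score()].
#' @return A `qp_result`.
#' @export
eeg_quality_parameter <- function(events, movements, premovement_ms = 2000,
                                  count_in_movement = FALSE,
                                  combine = "geometric") {
  spans <- data.frame(
    lo = pmax(0, movements$start - premovement_ms),
    hi = if (count_in_movement) movements$end else movements$start
  )
  qp_score(events, spans, combine = combine)
}
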