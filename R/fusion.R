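#' Build a probability tree of detector statistics
#'
#' Collects per-channel quality parameters (or probabilities of
#' stimulation) from all modules into one hierarchical summary -- the
#' "probability tree" used to pick the best predictor or association of
#' predictors for a given patient.  Leaves are grouped by module and
#' ordered deterministically (module name, then source name).
#'
#' @param leaves A data frame with columns `module`, `source` and either a
#'   list column `result` of `qp_result` objects or numeric columns
#'   `p`, `d`, `qp`; an optional `statistic` column labels the quantity
#'   (`"qp"` or `"stimulation_probability"`).  Alternatively a named list
#'   `module.source -> qp_result`.
#' @return A tibble of class `probability_tree` with columns `module`,
#'   `source`, `statistic`, `p`, `d`, `qp` (percentages stored in `qp`).
#' @export
build_tree <- function(leaves) {
  if (!is.data.frame(leaves)) {
    nm <- names(leaves)
    if (is.null(nm) || any(!nzchar(nm))) {
      stop("leaves must be named 'module.source'", call. = FALSE)
    }
    parts <- strsplit(nm, ".", fixed = TRUE)
    leaves <- tibble::tibble(
      module = vapply(parts, `[`, character(1), 1),
      source = vapply(parts, function(p) paste(p[-1], collapse = "."),
                      character(1)),
      result = unname(leaves)
    )
  }
  if ("result" %in% names(leaves)) {
    stats <- dplyr::bind_rows(lapply(leaves$result, tidy))
    leaves <- dplyr::bind_cols(
      dplyr::select(leaves, -"result"),
      stats[, c("p", "d", "qp")]
    )
  }
  if (!"statistic" %in% names(leaves)) leaves$statistic <- "qp"
  id <- paste(leaves$module, leaves$source)
  if (anyDuplicated(id)) {
    stop(sprintf("duplicate leaf source: %s", id[duplicated(id)][1]),
         call. = FALSE)
  }
  out <- leaves |>
    dplyr::select("module", "source", "statistic", "p", "d", "qp") |>
    dplyr::arrange(.data$module, .data$source)
  class(out) <- c("probability_tree", class(out))
  out
}

#' @export
print.probability_tree <- function(x, ...) {
  cat("<probability_tree>\n")
  for (m in unique(x$module)) {
    cat(sprintf("  %s\n", m))
    sub <- x[x$module == m, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("    %-14s %5.1f%%  (%s; p = %.2f, d = %.2f)\n",
                  sub$source[i], sub$qp[i], sub$statistic[i], sub$p[i],
                  sub$d[i]))
    }
  }
  invisible(x)
}

#' Combine several predictors' event streams
#'
#' Merges the event times of two or more detectors and rescores the merged
#' stream.  `union` keeps every event (deduplicated within `dedup_ms`):
#' coverage `d` can only grow, but spurious events from a weak predictor
#' dilute precision `p` -- associating predictors can genuinely worsen the
#' statistic.  `intersection` keeps only events on which all streams agree
#' within `tol_ms`: precision tends to grow, coverage can only shrink.
#'
#' @param event_sets List of numeric event-time vectors (ms).
#' @param movements A `movement_windows` tibble.
#' @param mode `"union"` (default) or `"intersection"`.
#' @param spans Optional data frame (`lo`, `hi`) of true-positive spans;
#'   default: the 2-s pre-movement windows of `movements`.
#' @param tol_ms Co-occurrence tolerance for intersection (default 100 ms).
#' @param dedup_ms Events closer than this collapse to one in union mode
#'   (default 6 ms, one frame step at the EEG defaults).
#' @return A `qp_result` for the merged event set, with the merged times
#'   attached as attribute `"events"`.
#' @export
combine_predictors <- function(event_sets, movements,
                               mode = c("union", "intersection"),
                               spans = NULL, tol_ms = 100, dedup_ms = 6) {
  mode <- match.arg(mode)
  if (length(event_sets) == 0) {
    stop("need at least one event set", call. = FALSE)
  }
  if (mode == "union") {
    ev <- sort(unlist(event_sets, use.names = FALSE))
    if (length(ev) > 1) {
      keep <- c(TRUE, diff(ev) >= dedup_ms)
      ev <- ev[keep]
    }
  } else {
    ev <- sort(unique(event_sets[[1]]))
    for (other in event_sets[-1]) {
      ev <- ev[vapply(ev, function(t) any(abs(other - t) <= tol_ms),
                      logical(1))]
    }
  }
  if (is.null(spans)) {
    pre <- premovement_window(movements$start)
    spans <- data.frame(lo = pre$pre_start, hi = pre$pre_end)
  }
  res <- qp_score(ev, spans)
  attr(res, "events") <- ev
  res
}

#' Rank tree leaves and predictor associations
#'
#' Orders leaves (and optional combination rows) by decreasing quality
#' parameter.  Ties break toward the smaller predictor set, then
#' lexicographically by source name, so the ranking is a deterministic
#' total order.
#'
#' @param tree A `probability_tree` (possibly containing combination rows
#'   whose `source` is a `"+"`-joined set of leaf names).
#' @param top_k Number of rows to return (default all).
#' @return A tibble with columns `rank`, `module`, `source`, `qp`,
#'   `set_size`.
#' @export
rank_tree <- function(tree, top_k = Inf) {
  stopifnot(nrow(tree) >= 1)
  out <- tree |>
    dplyr::mutate(
      set_size = vapply(strsplit(.data$source, "+", fixed = TRUE),
                        length, integer(1))
    ) |>
    dplyr::arrange(dplyr::desc(.data$qp), .data$set_size, .data$source) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1) |>
    dplyr::select("rank", "module", "source", "qp", "set_size")
  utils::head(out, top_k)
}
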