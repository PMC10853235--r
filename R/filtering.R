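#' Read-support filter specification
#'
#' Thresholds applied to each call: minimum total supporting reads
#' (SR + DP), minimum split/clipped reads, an optional minimum call quality
#' (calls with no quality value are exempt), and a set of flags that cause a
#' call to be dropped (e.g. `"ac0"`).
#'
#' @param min_total_support minimum SR + DP (non-negative integer).
#' @param min_split_reads minimum SR.
#' @param min_quality optional quality floor; `NULL` disables it.
#' @param drop_flags character vector of flags that disqualify a call.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(min_total_support = 0L, min_split_reads = 0L,
                        min_quality = NULL, drop_flags = character()) {
  stopifnot(min_total_support >= 0, min_split_reads >= 0)
  structure(list(min_total_support = as.integer(min_total_support),
                 min_split_reads = as.integer(min_split_reads),
                 min_quality = if (is.null(min_quality)) NULL else as.numeric(min_quality),
                 drop_flags = as.character(drop_flags)),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("filter_spec: total support >= %d, SR >= %d%s%s\n",
              x$min_total_support, x$min_split_reads,
              if (is.null(x$min_quality)) "" else
                sprintf(", quality >= %g", x$min_quality),
              if (length(x$drop_flags))
                paste0(", drop flags {", paste(x$drop_flags, collapse = ","), "}")
              else ""))
  invisible(x)
}

#' The common (fixed) read-support filter
#'
#' The uniform strategy applied identically to every caller: at least five
#' supporting reads of which two split reads for exome samples, at least ten
#' supporting reads of which two split reads for genome samples.
#'
#' @param assay `"ES"` or `"GS"`.
#' @return A [filter_spec()].
#' @export
common_filter_spec <- function(assay = c("ES", "GS")) {
  assay <- match.arg(assay)
  if (assay == "ES") filter_spec(5L, 2L) else filter_spec(10L, 2L)
}

#' Apply a read-support filter to a call set
#'
#' Retains calls with `total_support >= min_total_support`,
#' `split_reads >= min_split_reads`, quality absent or `>= min_quality`, and
#' no flag in `drop_flags`. Order is preserved; the operation is idempotent.
#'
#' @param x a [callset()].
#' @param spec a [filter_spec()].
#' @return The filtered [callset()].
#' @export
apply_filter <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (nrow(x) == 0L) return(x)
  keep <- x$total_support >= spec$min_total_support &
    x$split_reads >= spec$min_split_reads
  if (!is.null(spec$min_quality))
    keep <- keep & (is.na(x$quality) | x$quality >= spec$min_quality)
  if (length(spec$drop_flags)) {
    flagged <- vapply(strsplit(x$flags, ","),
                      function(f) any(f %in% spec$drop_flags), logical(1))
    keep <- keep & !flagged
  }
  as_callset_like(as.data.frame(x)[keep, , drop = FALSE], x)
}

#' Default threshold grid for filter optimisation
#'
#' Crossed grid over `min_total_support` in {2, 3, 5, 8, 10} and
#' `min_split_reads` in {0, 1, 2, 4}; when `quality` values are supplied,
#' each combination is additionally crossed with {no quality floor, median
#' quality of the data}.
#'
#' @param quality optional numeric quality values of the training calls.
#' @param drop_flags flags applied at every grid point.
#' @return list of [filter_spec()] objects.
#' @export
default_filter_grid <- function(quality = NULL, drop_flags = character()) {
  totals <- c(2L, 3L, 5L, 8L, 10L)
  srs <- c(0L, 1L, 2L, 4L)
  quals <- list(NULL)
  if (!is.null(quality) && any(!is.na(quality)))
    quals <- list(NULL, stats::median(quality, na.rm = TRUE))
  grid <- list()
  for (q in quals) for (t in totals) for (s in srs)
    grid[[length(grid) + 1L]] <- filter_spec(t, s, q, drop_flags)
  grid
}

#' F-score-optimised filter selection (grid search)
#'
#' The optimised strategy: every candidate threshold combination is applied
#' to the training call set, the survivors are benchmarked against the
#' training truth set, and the combination with the highest F-score wins.
#' Ties are broken by higher precision, then lower `min_total_support`, then
#' lower `min_split_reads`.
#'
#' @param train_calls a [callset()].
#' @param train_truth a [reference_mei()] data frame.
#' @param grid list of [filter_spec()] candidates (default
#'   [default_filter_grid()]).
#' @inheritParams match_calls
#' @return An object of class `grid_search`: list with `best_spec`,
#'   `best_f`, and `table` (one row of thresholds + metrics per grid point).
#' @export
optimize_filter <- function(train_calls, train_truth,
                            grid = default_filter_grid(train_calls$quality),
                            require_class = TRUE,
                            tsd_pad = 10L, fallback_pad = 50L) {
  stopifnot(length(grid) > 0L)
  rows <- lapply(grid, function(spec) {
    kept <- apply_filter(train_calls, spec)
    met <- compute_metrics(match_calls(kept, train_truth, require_class,
                                       tsd_pad, fallback_pad))
    data.frame(min_total_support = spec$min_total_support,
               min_split_reads = spec$min_split_reads,
               min_quality = if (is.null(spec$min_quality)) NA_real_ else spec$min_quality,
               n_retained = nrow(kept),
               precision = met$precision, sensitivity = met$sensitivity,
               f_score = met$f_score)
  })
  tab <- do.call(rbind, rows)
  prec <- ifelse(is.na(tab$precision), -1, tab$precision)
  best <- order(-tab$f_score, -prec, tab$min_total_support,
                tab$min_split_reads)[1L]
  structure(list(best_spec = grid[[best]], best_f = tab$f_score[best],
                 best_index = best, table = tab),
            class = "grid_search")
}

#' @export
print.grid_search <- function(x, ...) {
  cat(sprintf("filter grid search over %d specs; best F-score %.4f with:\n",
              nrow(x$table), x$best_f))
  print(x$best_spec)
  invisible(x)
}

#' Evaluate a trained filter on held-out data
#'
#' Applies a fixed [filter_spec()] (e.g. the winner of [optimize_filter()]
#' on the training benchmark) to an independent call set and reports metrics
#' against its truth set, with no refitting.
#'
#' @param spec a [filter_spec()].
#' @param test_calls a [callset()].
#' @param test_truth a [reference_mei()] data frame.
#' @inheritParams match_calls
#' @return list with `precision`, `sensitivity`, `f_score`.
#' @export
evaluate_on_holdout <- function(spec, test_calls, test_truth,
                                require_class = TRUE,
                                tsd_pad = 10L, fallback_pad = 50L) {
  kept <- apply_filter(test_calls, spec)
  compute_metrics(match_calls(kept, test_truth, require_class,
                              tsd_pad, fallback_pad))
}
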