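#' Matching window around a reference insertion
#'
#' A predicted call matches a reference insertion when its breakpoint lies in
#' this window: `tsd_pad` bp around the target site duplication (TSD)
#' interval when the TSD is known, else `fallback_pad` bp around the
#' reference breakpoint. Bounds are inclusive.
#'
#' @param ref a [reference_mei()] data frame (vectorised over rows).
#' @param tsd_pad pad around a known TSD interval, bp (default 10).
#' @param fallback_pad pad around the bare breakpoint when the TSD is
#'   unknown, bp (default 50).
#' @return data frame with columns `low`, `high` (1-based, inclusive).
#' @export
match_window <- function(ref, tsd_pad = 10L, fallback_pad = 50L) {
  has_tsd <- !is.na(ref$tsd_start) & !is.na(ref$tsd_end)
  low <- ifelse(has_tsd, ref$tsd_start - tsd_pad, ref$breakpoint - fallback_pad)
  high <- ifelse(has_tsd, ref$tsd_end + tsd_pad, ref$breakpoint + fallback_pad)
  data.frame(low = as.integer(low), high = as.integer(high))
}

#' Match predicted calls against a reference set
#'
#' Each prediction is assigned to at most one reference: among references on
#' the same chromosome whose [match_window()] contains the predicted
#' breakpoint (and, when `require_class = TRUE`, whose element class equals
#' the prediction's, `"unknown"` predictions matching any class), the one
#' with the smallest `|prediction breakpoint - reference breakpoint|` is
#' chosen, ties going to the lower reference coordinate. A reference may
#' absorb several predictions — all of them count as true-positive
#' predictions, while the reference counts as detected once.
#'
#' @param predictions a [callset()].
#' @param references a [reference_mei()] data frame.
#' @param require_class require element-class agreement (default `TRUE`).
#' @inheritParams match_window
#' @return An object of class `mei_match`: a list with counts
#'   `tp_predictions`, `detected_references`, `fp`, `fn`, the assignment
#'   `pairs` (`pred_idx`, `ref_idx`), and the input sizes.
#' @export
match_calls <- function(predictions, references, require_class = TRUE,
                        tsd_pad = 10L, fallback_pad = 50L) {
  n_pred <- nrow(predictions)
  n_ref <- nrow(references)
  pairs <- data.frame(pred_idx = integer(), ref_idx = integer())
  if (n_pred > 0L && n_ref > 0L) {
    win <- match_window(references, tsd_pad, fallback_pad)
    pch <- norm_chrom(predictions$chrom)
    rch <- norm_chrom(references$chrom)
    cand_p <- integer(0); cand_r <- integer(0)
    for (ch in unique(pch)) {
      pi <- which(pch == ch)
      ri <- which(rch == ch)
      if (!length(ri)) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(start = predictions$breakpoint[pi], width = 1L),
        IRanges::IRanges(start = win$low[ri], end = win$high[ri]))
      cand_p <- c(cand_p, pi[S4Vectors::queryHits(hits)])
      cand_r <- c(cand_r, ri[S4Vectors::subjectHits(hits)])
    }
    if (require_class && length(cand_p)) {
      ok <- predictions$mei_class[cand_p] == "unknown" |
        predictions$mei_class[cand_p] == references$mei_class[cand_r]
      cand_p <- cand_p[ok]; cand_r <- cand_r[ok]
    }
    if (length(cand_p)) {
      dist <- abs(predictions$breakpoint[cand_p] - references$breakpoint[cand_r])
      # per prediction: nearest reference breakpoint, ties to the lower
      # reference coordinate, then lower reference index (determinism)
      ord <- order(cand_p, dist, references$breakpoint[cand_r], cand_r)
      first <- !duplicated(cand_p[ord])
      pairs <- data.frame(pred_idx = cand_p[ord][first],
                          ref_idx = cand_r[ord][first])
      pairs <- pairs[order(pairs$pred_idx), , drop = FALSE]
      rownames(pairs) <- NULL
    }
  }
  tp <- nrow(pairs)
  det <- length(unique(pairs$ref_idx))
  structure(list(tp_predictions = tp, detected_references = det,
                 fp = n_pred - tp, fn = n_ref - det, pairs = pairs,
                 n_predictions = n_pred, n_references = n_ref),
            class = "mei_match")
}

#' @export
print.mei_match <- function(x, ...) {
  cat(sprintf("MEI match: %d/%d predictions TP, %d FP; %d/%d references detected, %d FN\n",
              x$tp_predictions, x$n_predictions, x$fp,
              x$detected_references, x$n_references, x$fn))
  invisible(x)
}

#' Precision, sensitivity and F-score from a match result
#'
#' Precision is computed at the prediction level
#' (`tp_predictions / (tp_predictions + fp)`), sensitivity at the reference
#' level (`detected_references / (detected_references + fn)`), and the
#' F-score is their harmonic mean, 0 when the denominator is 0. With zero
#' predictions the precision is `NA` (undefined) and F is 0; likewise
#' sensitivity with zero references.
#'
#' @param m an `mei_match` from [match_calls()].
#' @return list with `precision`, `sensitivity`, `f_score`.
#' @export
compute_metrics <- function(m) {
  precision <- if (m$n_predictions == 0L) NA_real_ else
    m$tp_predictions / (m$tp_predictions + m$fp)
  sensitivity <- if (m$n_references == 0L) NA_real_ else
    m$detected_references / (m$detected_references + m$fn)
  f <- f_score(precision, sensitivity)
  list(precision = precision, sensitivity = sensitivity, f_score = f)
}

f_score <- function(precision, sensitivity) {
  if (is.na(precision) || is.na(sensitivity)) return(0)
  d <- precision + sensitivity
  if (d <= 0) 0 else 2 * precision * sensitivity / d
}

#' Benchmark a call set against a truth set
#'
#' Runs [match_calls()] and [compute_metrics()] overall and per element
#' class (each class evaluated on the class-restricted prediction and
#' reference subsets).
#'
#' @inheritParams match_calls
#' @return An object of class `mei_benchmark`: list with `metrics` (overall),
#'   `per_class` (data frame), and `match` (the overall `mei_match`).
#' @examples
#' truth <- reference_mei(data.frame(chrom = "1", breakpoint = c(100, 500),
#'                                   mei_class = c("Alu", "L1")))
#' preds <- callset(data.frame(chrom = "1", breakpoint = c(102, 800),
#'                             mei_class = c("Alu", "Alu")))
#' benchmark_calls(preds, truth)
#' @export
benchmark_calls <- function(predictions, references, require_class = TRUE,
                            tsd_pad = 10L, fallback_pad = 50L) {
  m <- match_calls(predictions, references, require_class, tsd_pad, fallback_pad)
  overall <- compute_metrics(m)
  classes <- intersect(REF_CLASSES,
                       union(references$mei_class, predictions$mei_class))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    p_sub <- as_callset_like(
      as.data.frame(predictions)[predictions$mei_class == cl, , drop = FALSE],
      predictions)
    r_sub <- references[references$mei_class == cl, , drop = FALSE]
    mm <- match_calls(p_sub, r_sub, require_class, tsd_pad, fallback_pad)
    met <- compute_metrics(mm)
    data.frame(mei_class = cl, n_predictions = mm$n_predictions,
               n_references = mm$n_references, precision = met$precision,
               sensitivity = met$sensitivity, f_score = met$f_score,
               stringsAsFactors = FALSE)
  }))
  structure(list(metrics = overall, per_class = per_class, match = m),
            class = "mei_benchmark")
}

#' @export
print.mei_benchmark <- function(x, digits = 3, ...) {
  cat("MEI benchmark\n")
  cat(sprintf("  precision   %s\n  sensitivity %s\n  F-score     %s\n",
              format(x$metrics$precision, digits = digits),
              format(x$metrics$sensitivity, digits = digits),
              format(x$metrics$f_score, digits = digits)))
  if (!is.null(x$per_class) && nrow(x$per_class)) {
    cat("  per class:\n")
    print.data.frame(x$per_class, digits = digits, row.names = FALSE)
  }
  invisible(x)
}

#' Recall of a set of known polymorphic sites
#'
#' Fraction of known sites (e.g. catalogued human retrotransposon insertion
#' polymorphisms) detected by the predictions under [match_calls()]
#' semantics.
#'
#' @param predictions a [callset()].
#' @param known_sites a [reference_mei()] data frame.
#' @inheritParams match_calls
#' @return recall in `[0, 1]`, or `NA` for an empty site list.
#' @export
recall_against_known_sites <- function(predictions, known_sites,
                                       require_class = TRUE,
                                       tsd_pad = 10L, fallback_pad = 50L) {
  if (nrow(known_sites) == 0L) return(NA_real_)
  m <- match_calls(predictions, known_sites, require_class, tsd_pad, fallback_pad)
  m$detected_references / m$n_references
}
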