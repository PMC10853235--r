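# Independent oracles and small fixture builders. The oracles deliberately
# avoid the package's interval-indexed code paths: matching is plain
# per-prediction scans, merging is union-find over all close pairs, Fisher
# is full hypergeometric enumeration.

# Brute-force window matching: per prediction, scan every reference (no
# interval index), keep in-window candidates, pick the nearest breakpoint
# (ties: lower reference coordinate, then lower index).
brute_match <- function(predictions, references, require_class = TRUE,
                        tsd_pad = 10L, fallback_pad = 50L) {
  np <- nrow(predictions); nr <- nrow(references)
  strip <- function(x) sub("^chr", "", as.character(x))
  has_tsd <- !is.na(references$tsd_start)
  lo <- ifelse(has_tsd, references$tsd_start - tsd_pad,
               references$breakpoint - fallback_pad)
  hi <- ifelse(has_tsd, references$tsd_end + tsd_pad,
               references$breakpoint + fallback_pad)
  rch <- strip(references$chrom)
  pch <- strip(predictions$chrom)
  p_idx <- integer(0); r_idx <- integer(0)
  for (i in seq_len(np)) {
    bp <- predictions$breakpoint[i]
    ok <- rch == pch[i] & bp >= lo & bp <= hi
    if (require_class && predictions$mei_class[i] != "unknown")
      ok <- ok & references$mei_class == predictions$mei_class[i]
    if (!any(ok)) next
    cand <- which(ok)
    d <- abs(bp - references$breakpoint[cand])
    sel <- cand[order(d, references$breakpoint[cand], cand)][1]
    p_idx <- c(p_idx, i); r_idx <- c(r_idx, sel)
  }
  pairs <- data.frame(pred_idx = p_idx, ref_idx = r_idx)
  list(pairs = pairs, tp = nrow(pairs),
       detected = length(unique(pairs$ref_idx)),
       fp = np - nrow(pairs), fn = nr - length(unique(pairs$ref_idx)))
}

# Full hypergeometric enumeration of 2x2 tables with the observed margins;
# two-sided p sums probabilities <= the observed table's.
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1.0)
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Naive single-linkage clustering: union-find over every pair of calls at
# distance <= tolerance (same chromosome, and same class when class-aware).
naive_single_linkage <- function(chrom, bp, cls, tolerance, class_aware = TRUE) {
  n <- length(bp)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (chrom[i] != chrom[j]) next
    if (class_aware && cls[i] != cls[j]) next
    if (abs(bp[i] - bp[j]) <= tolerance) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, 1L)
}

# Random matching instance: truth sites with optional TSDs plus predictions
# scattered near and far from them.
random_match_instance <- function(n_ref = 20L, n_pred = 30L, span = 5000L) {
  ref_bp <- sort(sample.int(span, n_ref))
  has_tsd <- runif(n_ref) < 0.6
  tsd_len <- sample(5:20, n_ref, replace = TRUE)
  refs <- reference_mei(data.frame(
    chrom = sample(c("1", "2"), n_ref, replace = TRUE),
    breakpoint = ref_bp,
    tsd_start = ifelse(has_tsd, ref_bp, NA),
    tsd_end = ifelse(has_tsd, ref_bp + tsd_len, NA),
    mei_class = sample(c("Alu", "L1", "SVA"), n_ref, replace = TRUE,
                       prob = c(0.88, 0.09, 0.03))))
  near <- sample.int(n_ref, ceiling(n_pred / 2), replace = TRUE)
  pred_bp <- c(refs$breakpoint[near] + sample(-60:60, length(near), replace = TRUE),
               sample.int(span, n_pred - length(near)))
  preds <- callset(data.frame(
    chrom = c(refs$chrom[near],
              sample(c("1", "2"), n_pred - length(near), replace = TRUE)),
    breakpoint = pmax(1L, pred_bp),
    mei_class = sample(c("Alu", "L1", "SVA", "unknown"), n_pred,
                       replace = TRUE),
    split_reads = sample(0:10, n_pred, replace = TRUE),
    discordant_pairs = sample(0:10, n_pred, replace = TRUE)))
  list(preds = preds, refs = refs)
}

expect_match_equal <- function(m, oracle) {
  expect_equal(m$tp_predictions, oracle$tp)
  expect_equal(m$detected_references, oracle$detected)
  expect_equal(m$fp, oracle$fp)
  expect_equal(m$fn, oracle$fn)
  expect_equal(as.data.frame(m$pairs), as.data.frame(oracle$pairs))
}

# A small truth + callset pair used by several tests.
toy_truth <- function() {
  reference_mei(data.frame(
    chrom = c("1", "1", "2"), breakpoint = c(100L, 500L, 800L),
    tsd_start = c(100L, NA, NA), tsd_end = c(115L, NA, NA),
    mei_class = c("Alu", "L1", "Alu")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
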