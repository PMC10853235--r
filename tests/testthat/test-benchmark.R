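test_that("match_window pads the TSD when known, else the breakpoint", {
  ref <- reference_mei(data.frame(chrom = "1", breakpoint = c(105L, 500L),
                                  tsd_start = c(100L, NA),
                                  tsd_end = c(115L, NA),
                                  mei_class = c("Alu", "L1")))
  w <- match_window(ref)
  expect_equal(w$low, c(90L, 450L))
  expect_equal(w$high, c(125L, 550L))
  # degenerate: zero pad on a single-base TSD
  ref0 <- reference_mei(data.frame(chrom = "1", breakpoint = 100L,
                                   tsd_start = 100L, tsd_end = 100L,
                                   mei_class = "Alu"))
  w0 <- match_window(ref0, tsd_pad = 0L)
  expect_equal(c(w0$low, w0$high), c(100L, 100L))
})

test_that("window bounds are inclusive and define TP/FP/FN", {
  ref <- reference_mei(data.frame(chrom = "1", breakpoint = 105L,
                                  tsd_start = 100L, tsd_end = 115L,
                                  mei_class = "Alu"))
  inside <- callset(data.frame(chrom = "1", breakpoint = 92L, mei_class = "Alu"))
  m <- match_calls(inside, ref)
  expect_equal(c(m$tp_predictions, m$fp, m$fn), c(1L, 0L, 0L))

  outside <- callset(data.frame(chrom = "1", breakpoint = 89L, mei_class = "Alu"))
  m2 <- match_calls(outside, ref)
  expect_equal(c(m2$tp_predictions, m2$fp, m2$fn), c(0L, 1L, 1L))
})

test_that("identical predictions and references give perfect metrics", {
  truth <- toy_truth()
  preds <- callset(data.frame(chrom = truth$chrom,
                              breakpoint = truth$breakpoint,
                              mei_class = truth$mei_class))
  met <- compute_metrics(match_calls(preds, truth))
  expect_equal(met$precision, 1)
  expect_equal(met$sensitivity, 1)
  expect_equal(met$f_score, 1)
})

test_that("a reference absorbs multiple predictions; conservation holds", {
  truth <- toy_truth()
  preds <- callset(data.frame(chrom = "1", breakpoint = c(98L, 104L, 110L),
                              mei_class = "Alu"))
  m <- match_calls(preds, truth)
  expect_equal(m$tp_predictions, 3L)
  expect_equal(m$detected_references, 1L)
  expect_equal(m$tp_predictions + m$fp, m$n_predictions)
  expect_equal(m$detected_references + m$fn, m$n_references)
})

test_that("class agreement is required by default and can be disabled", {
  truth <- toy_truth()
  wrong <- callset(data.frame(chrom = "1", breakpoint = 100L,
                              mei_class = "L1"))
  expect_equal(match_calls(wrong, truth)$tp_predictions, 0L)
  expect_equal(match_calls(wrong, truth, require_class = FALSE)$tp_predictions, 1L)
  # an unknown-class prediction matches any reference class
  unk <- callset(data.frame(chrom = "1", breakpoint = 100L,
                            mei_class = "unknown"))
  expect_equal(match_calls(unk, truth)$tp_predictions, 1L)
})

test_that("interval-indexed matching equals the brute-force oracle", {
  set.seed(11)
  for (rep in 1:200) {
    inst <- random_match_instance(n_ref = sample(5:20, 1),
                                  n_pred = sample(5:30, 1))
    for (rc in c(TRUE, FALSE)) {
      m <- match_calls(inst$preds, inst$refs, require_class = rc)
      expect_match_equal(m, brute_match(inst$preds, inst$refs,
                                        require_class = rc))
    }
  }
})

test_that("adding predictions never decreases detected references", {
  set.seed(12)
  for (rep in 1:20) {
    inst <- random_match_instance()
    m_all <- match_calls(inst$preds, inst$refs)
    drop <- as.data.frame(inst$preds)[-sample.int(nrow(inst$preds), 1), ]
    m_less <- match_calls(callset(drop), inst$refs)
    expect_gte(m_all$detected_references, m_less$detected_references)
    expect_lte(m_all$fn, m_less$fn)
  }
})

test_that("metric formulas and degenerate markers behave as defined", {
  m <- list(tp_predictions = 7L, detected_references = 7L, fp = 0L, fn = 3L,
            n_predictions = 7L, n_references = 10L)
  expect_equal(compute_metrics(m)$sensitivity, 0.70)
  m$detected_references <- 8L; m$fn <- 2L; m$tp_predictions <- 8L
  m$n_predictions <- 8L
  expect_equal(compute_metrics(m)$sensitivity, 0.80)

  # F equals the common value when precision == sensitivity
  expect_equal(meibench:::f_score(0.5, 0.5), 0.5)

  truth <- toy_truth()
  empty <- callset(NULL)
  met <- compute_metrics(match_calls(empty, truth))
  expect_true(is.na(met$precision))
  expect_equal(met$f_score, 0)
  m_e <- match_calls(empty, truth)
  expect_equal(m_e$fn, nrow(truth))

  no_truth <- compute_metrics(match_calls(
    callset(data.frame(chrom = "1", breakpoint = 5L, mei_class = "Alu")),
    toy_truth()[0, ]))
  expect_true(is.na(no_truth$sensitivity))
})

test_that("per-class metrics are computed on class-restricted subsets", {
  truth <- toy_truth()
  preds <- callset(data.frame(chrom = c("1", "1", "2"),
                              breakpoint = c(100L, 500L, 2000L),
                              mei_class = c("Alu", "L1", "Alu")))
  bm <- benchmark_calls(preds, truth)
  alu <- bm$per_class[bm$per_class$mei_class == "Alu", ]
  expect_equal(alu$sensitivity, 0.5)  # 1 of 2 Alu references detected
  expect_equal(alu$precision, 0.5)    # 1 of 2 Alu predictions matched
  l1 <- bm$per_class[bm$per_class$mei_class == "L1", ]
  expect_equal(l1$f_score, 1)
})

test_that("recall against known sites counts detected references", {
  truth <- toy_truth()
  all_hit <- callset(data.frame(chrom = truth$chrom,
                                breakpoint = truth$breakpoint,
                                mei_class = truth$mei_class))
  expect_equal(recall_against_known_sites(all_hit, truth), 1.0)
  none <- callset(data.frame(chrom = "1", breakpoint = 99999L,
                             mei_class = "Alu"))
  expect_equal(recall_against_known_sites(none, truth), 0.0)
  expect_true(is.na(recall_against_known_sites(all_hit, truth[0, ])))

  # synthetic set where exactly 69 of 100 known sites carry a prediction
  bp <- seq(1000L, by = 1000L, length.out = 100L)
  known <- reference_mei(data.frame(chrom = "1", breakpoint = bp,
                                    mei_class = "Alu"))
  hit <- callset(data.frame(chrom = "1", breakpoint = bp[1:69] + 3L,
                            mei_class = "Alu"))
  expect_equal(recall_against_known_sites(hit, known), 0.69)
})
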