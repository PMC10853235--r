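make_calls <- function(total, sr, quality = NA_real_, flags = "") {
  callset(data.frame(chrom = "1",
                     breakpoint = seq(100L, by = 1000L,
                                      length.out = length(total)),
                     mei_class = "Alu", split_reads = sr,
                     discordant_pairs = total - sr, quality = quality,
                     flags = flags))
}

test_that("common filter thresholds are 5+2 reads for ES, 10+2 for GS", {
  es <- common_filter_spec("ES")
  expect_equal(c(es$min_total_support, es$min_split_reads), c(5L, 2L))
  gs <- common_filter_spec("GS")
  expect_equal(c(gs$min_total_support, gs$min_split_reads), c(10L, 2L))
})

test_that("apply_filter is boundary-inclusive, flag- and quality-aware", {
  cs <- make_calls(total = c(5L, 4L, 8L, 8L), sr = c(2L, 2L, 1L, 4L),
                   quality = c(NA, NA, NA, 2),
                   flags = c("", "", "", "ac0"))
  es <- common_filter_spec("ES")
  kept <- apply_filter(cs, es)
  expect_equal(kept$breakpoint, cs$breakpoint[c(1, 4)])  # >= is inclusive

  # vacuous spec passes everything; idempotence
  expect_equal(nrow(apply_filter(cs, filter_spec(0L, 0L))), nrow(cs))
  again <- apply_filter(kept, es)
  expect_equal(as.data.frame(again), as.data.frame(kept))

  # flag and quality handling: NA quality is exempt from the floor
  drop_ac0 <- filter_spec(0L, 0L, drop_flags = "ac0")
  expect_equal(nrow(apply_filter(cs, drop_ac0)), 3L)
  qual <- filter_spec(0L, 0L, min_quality = 5)
  expect_equal(apply_filter(cs, qual)$breakpoint, cs$breakpoint[1:3])
})

test_that("raising any threshold never increases retained calls", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(10:80, 1)
    total <- sample(0:20, n, replace = TRUE)
    sr <- pmin(sample(0:6, n, replace = TRUE), total)
    cs <- make_calls(total = total, sr = sr)
    counts <- vapply(c(0L, 2L, 5L, 10L), function(t)
      nrow(apply_filter(cs, filter_spec(t, 2L))), 1L)
    expect_true(all(diff(counts) <= 0))
    expect_lte(nrow(apply_filter(cs, filter_spec(5L, 3L))),
               nrow(apply_filter(cs, filter_spec(5L, 2L))))
  }
})

test_that("grid search argmax matches exhaustive independent re-evaluation", {
  set.seed(32)
  cfg <- sim_config(seed = 32, n_truth = 120,
                    genome = data.frame(chrom = "1", length = 2e7))
  truth <- simulate_truth(cfg)
  grid <- list()
  for (t in c(2L, 5L, 10L)) for (s in c(0L, 2L, 4L))
    grid <- c(grid, list(filter_spec(t, s)),
              list(filter_spec(t, s, drop_flags = "ac0")))
  for (rep in 1:10) {
    cs <- simulate_tool_calls(truth, tool_params(), seed = 1000L + rep,
                              genome = cfg$genome)
    gs <- optimize_filter(cs, truth, grid = grid)
    # independent loop: manual subset + brute-force matcher + formulas
    best_f <- -1; best_i <- NA
    fs <- numeric(length(grid))
    for (i in seq_along(grid)) {
      g <- grid[[i]]
      keep <- cs$total_support >= g$min_total_support &
        cs$split_reads >= g$min_split_reads &
        !vapply(strsplit(cs$flags, ","),
                function(f) any(f %in% g$drop_flags), logical(1))
      sub <- callset(as.data.frame(cs)[keep, ])
      o <- brute_match(sub, truth)
      p <- if (nrow(sub) == 0) NA else o$tp / (o$tp + o$fp)
      s <- o$detected / (o$detected + o$fn)
      f <- if (is.na(p) || p + s == 0) 0 else 2 * p * s / (p + s)
      fs[i] <- f
      if (f > best_f) { best_f <- f; best_i <- i }
    }
    expect_equal(gs$best_f, best_f)
    expect_equal(gs$table$f_score, fs)
  }
})

test_that("grid-search edge cases and tie-breaking", {
  truth <- toy_truth()
  preds <- callset(data.frame(chrom = truth$chrom,
                              breakpoint = truth$breakpoint,
                              mei_class = truth$mei_class,
                              split_reads = 3L, discordant_pairs = 3L))
  one <- optimize_filter(preds, truth, grid = list(filter_spec(2L, 1L)))
  expect_equal(one$best_spec$min_total_support, 2L)

  # a spec that removes everything scores F = 0 and loses to any F > 0
  gs <- optimize_filter(preds, truth,
                        grid = list(filter_spec(100L, 0L), filter_spec(2L, 1L)))
  expect_equal(gs$best_spec$min_total_support, 2L)
  expect_equal(gs$table$f_score[1], 0)

  # F ties resolve to the lower thresholds
  tie <- optimize_filter(preds, truth,
                         grid = list(filter_spec(5L, 2L), filter_spec(2L, 1L)))
  expect_equal(tie$best_spec$min_total_support, 2L)
})

test_that("the optimised filter never scores below the common filter", {
  cfg <- sim_config(seed = 33, n_truth = 150,
                    genome = data.frame(chrom = "1", length = 2e7))
  truth <- simulate_truth(cfg)
  cs <- simulate_tool_calls(truth, tool_params(), seed = 34,
                            genome = cfg$genome)
  grid <- c(default_filter_grid(), list(common_filter_spec("ES")))
  gs <- optimize_filter(cs, truth, grid = grid)
  common_f <- evaluate_on_holdout(common_filter_spec("ES"), cs, truth)$f_score
  expect_gte(gs$best_f, common_f)
})

test_that("holdout evaluation refits nothing and degrades under noise shift", {
  truth <- toy_truth()
  perfect <- callset(data.frame(chrom = truth$chrom,
                                breakpoint = truth$breakpoint,
                                mei_class = truth$mei_class))
  expect_equal(evaluate_on_holdout(filter_spec(0L, 0L), perfect, truth)$f_score, 1)

  # train == test: holdout F equals the training best
  cfg <- sim_config(seed = 35, n_truth = 100,
                    genome = data.frame(chrom = "1", length = 2e7))
  tr <- simulate_truth(cfg)
  cs <- simulate_tool_calls(tr, tool_params(), seed = 36, genome = cfg$genome)
  gs <- optimize_filter(cs, tr)
  expect_equal(evaluate_on_holdout(gs$best_spec, cs, tr)$f_score, gs$best_f)

  # noisier holdout data: median holdout F across seeds does not beat train
  deltas <- vapply(1:20, function(s) {
    tr_i <- simulate_truth(sim_config(seed = 100 + s, n_truth = 80,
                                      genome = cfg$genome))
    train <- simulate_tool_calls(tr_i, tool_params(), seed = 200 + s,
                                 genome = cfg$genome)
    te_i <- simulate_truth(sim_config(seed = 300 + s, n_truth = 80,
                                      genome = cfg$genome))
    noisier <- tool_params(fp_per_mb = 4, support_mean = 8)
    test <- simulate_tool_calls(te_i, noisier, seed = 400 + s,
                                genome = cfg$genome)
    g <- optimize_filter(train, tr_i)
    evaluate_on_holdout(g$best_spec, test, te_i)$f_score - g$best_f
  }, numeric(1))
  expect_lte(median(deltas), 0)
})
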