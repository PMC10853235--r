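# A handcrafted mini-cohort: 4 samples, 3 sites.
mini_cohort <- function() {
  calls <- callset(data.frame(
    sample_id = c("P1", "P1", "P2", "U1"),
    chrom = "1",
    breakpoint = c(5100L, 9000L, 5110L, 9020L),
    mei_class = "Alu", tool = "MELT"))
  sites <- merge_callsets(calls, tolerance = 50L)
  samples <- data.frame(
    sample_id = c("P1", "P2", "U1", "P3"),
    family_id = c("F1", "F2", "F1", "F3"),
    affected = c(TRUE, TRUE, FALSE, TRUE),
    panel = c("neuro", "neuro", NA, "neuro"))
  list(sites = sites, cohort = cohort_table(samples, sites))
}

test_that("carrier frequency is carriers over all samples, threshold strict", {
  x <- mini_cohort()
  f <- carrier_frequency(x$sites$site_id, x$cohort)
  expect_equal(sort(f), sort(c(2 / 4, 2 / 4)))

  # boundary semantics of the rare-variant cutoff: < is strict
  big <- cohort_table(
    data.frame(sample_id = sprintf("S%05d", 1:10000),
               family_id = sprintf("F%05d", 1:10000),
               affected = TRUE),
    occurrences = data.frame(site_id = c(rep("site_a", 3), rep("site_b", 2)),
                             sample_id = sprintf("S%05d", 1:5)))
  f2 <- carrier_frequency(c("site_a", "site_b", "site_c"), big)
  expect_equal(f2, c(0.0003, 0.0002, 0))
  expect_false(f2[1] < 0.0003)  # 3/10000 = 0.03% is NOT retained
  expect_true(f2[2] < 0.0003)   # 2/10000 is
})

test_that("known-site exclusion is +/- pad, class-aware, identity on empty", {
  x <- mini_cohort()
  known_at <- reference_mei(data.frame(chrom = "1", breakpoint = 5100L,
                                       mei_class = "Alu"))
  expect_equal(nrow(exclude_known_sites(x$sites, known_at)), 1L)
  known_far <- reference_mei(data.frame(chrom = "1", breakpoint = 5151L,
                                        mei_class = "Alu"))
  expect_equal(nrow(exclude_known_sites(x$sites, known_far)), 2L)
  known_other_class <- reference_mei(data.frame(chrom = "1",
                                                breakpoint = 5100L,
                                                mei_class = "L1"))
  expect_equal(nrow(exclude_known_sites(x$sites, known_other_class)), 2L)
  expect_equal(nrow(exclude_known_sites(x$sites, known_at[0, ])), 2L)
  expect_equal(nrow(exclude_known_sites(x$sites, NULL)), 2L)
})

test_that("sites carried by any unaffected sample are removed", {
  x <- mini_cohort()
  kept <- exclude_unaffected_carriers(x$sites, x$cohort)
  # the 9000/9020 site is carried by unaffected U1 and must go
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$breakpoint, 5100L)

  all_affected <- cohort_table(
    within(x$cohort$samples, affected <- TRUE), x$sites)
  expect_equal(nrow(exclude_unaffected_carriers(x$sites, all_affected)), 2L)

  bad <- x$cohort
  bad$samples$affected[3] <- NA
  expect_error(exclude_unaffected_carriers(x$sites, bad), "U1")
})

test_that("panel filter requires a carrier panel gene, optionally exonic/splice", {
  x <- mini_cohort()
  genes <- gene_annotation(data.frame(
    chrom = "1",
    start = c(5000L, 5000L, 5200L, 8000L),
    end = c(5199L, 5049L, 5999L, 8900L),
    gene = c("GENEX", "GENEX", "GENEX", "GENEY"),
    feature = c("intron", "exon", "intron", "exon")))
  panels <- list(neuro = "GENEX", onco = "GENEY")

  both <- panel_filter(x$sites, x$cohort, genes, panels)
  expect_equal(both$breakpoint, 5100L)  # site at 9000 hits no panel gene
  # 5100 is in a deep-intron position relative to the exon at 5000-5049
  none <- panel_filter(x$sites, x$cohort, genes, panels,
                       exonic_splice_only = TRUE, pad = 0L)
  expect_equal(nrow(none), 0L)
  # with the +/- 50 bp slack the exon at 5000-5049 is back in reach
  near <- panel_filter(x$sites, x$cohort, genes, panels,
                       exonic_splice_only = TRUE, pad = 51L)
  expect_equal(near$breakpoint, 5100L)

  bad_meta <- x$cohort
  bad_meta$samples$panel[1] <- "nonexistent"
  expect_error(panel_filter(x$sites, bad_meta, genes, panels), "nonexistent")
})

test_that("the cascade is monotone decreasing and ordered as specified", {
  cfg <- sim_config(seed = 51, cohort = list(
    n_samples = 60L, n_affected = 30L, n_polymorphic_sites = 20L,
    site_frequency_range = c(0.02, 0.1), n_pathogenic_spikes = 2L,
    genome = data.frame(chrom = "1", length = 5e6)))
  sim <- simulate_cohort(cfg)
  sites <- merge_callsets(sim$callsets)
  cohort <- cohort_table(sim$samples, sites)
  res <- prioritize(sites, cohort, sim$targets, sim$known_sites, sim$genes,
                    sim$panels, max_freq = 2 / 60)
  expect_equal(names(res$stage_log),
               c("input", "target_regions", "affected_only",
                 "not_known_polymorphism", "rare", "panel"))
  expect_true(all(diff(res$stage_log) <= 0))
  # frequency-filter consistency: anything retained at t survives t' > t
  res_loose <- prioritize(sites, cohort, sim$targets, sim$known_sites,
                          sim$genes, sim$panels, max_freq = 10 / 60)
  expect_true(all(res$candidates$site_id %in% res_loose$candidates$site_id))
})

test_that("a spiked pathogenic insertion is recovered; unaffected carriage kills it", {
  cfg <- sim_config(seed = 52)
  sim <- simulate_cohort(cfg)
  sites <- merge_callsets(sim$callsets)
  cohort <- cohort_table(sim$samples, sites)
  res <- prioritize(sites, cohort, sim$targets, sim$known_sites, sim$genes,
                    sim$panels, max_freq = 0.003)
  sp <- sim$bookkeeping$spikes
  expect_true(sp$emitted)
  expect_equal(res$candidates$sample_id, sp$sample_id)
  expect_equal(res$candidates$gene, sp$gene)
  expect_lt(abs(res$candidates$breakpoint - sp$breakpoint), 50)

  # inject the same site into an unaffected sample: zero candidates
  unaff <- sim$samples$sample_id[!sim$samples$affected][1]
  extra <- callset(data.frame(sample_id = unaff, chrom = sp$chrom,
                              breakpoint = sp$breakpoint, mei_class = "Alu",
                              tool = "toolA"))
  sites2 <- merge_callsets(c(sim$callsets, list(extra)))
  cohort2 <- cohort_table(sim$samples, sites2)
  res2 <- prioritize(sites2, cohort2, sim$targets, sim$known_sites,
                     sim$genes, sim$panels, max_freq = 0.003)
  expect_equal(nrow(res2$candidates), 0L)
})

test_that("an all-pass configuration returns every target-region site", {
  x <- mini_cohort()
  # neutralise every stage: all samples affected and panelled, no known
  # sites, a panel gene spanning everything, frequency cap above 1
  samples <- within(x$cohort$samples, {affected <- TRUE; panel <- "neuro"})
  cohort <- cohort_table(samples, x$sites)
  genes <- gene_annotation(data.frame(chrom = "1", start = 1L, end = 10000L,
                                      gene = "GENEX", feature = "exon"))
  panels <- list(neuro = "GENEX")
  targets <- target_regions(data.frame(chrom = "1", start = 0L, end = 10000L))
  res <- prioritize(x$sites, cohort, targets, known = NULL, genes, panels,
                    max_freq = 1.01)
  expect_equal(sort(unique(res$candidates$site_id)), sort(x$sites$site_id))
})
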