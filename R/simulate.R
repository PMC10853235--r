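#' Per-tool behaviour parameters for the call-set simulator
#'
#' Describes an MEI caller as the benchmark sees it: class-specific
#' sensitivity, breakpoint jitter, false-positive density, and read-support
#' distribution. Read support is negative-binomial (over-dispersed, as in
#' capture data), split between split reads and discordant pairs by
#' `sr_fraction`; false positives draw their support from a distribution
#' with mean `fp_support_mean` (default half the true-call mean, reflecting
#' the sparser evidence behind spurious calls).
#'
#' @param sens_by_class named per-class detection probabilities
#'   (`Alu`, `L1`, `SVA`).
#' @param fp_per_mb expected false-positive calls per megabase.
#' @param breakpoint_sd breakpoint jitter sd in bp (default 2; split-read
#'   callers are near-base-precise).
#' @param support_mean,support_dispersion negative-binomial mean and size
#'   of the total read support of true calls.
#' @param sr_fraction expected fraction of support that is split reads.
#' @param fp_support_mean mean total support of false positives
#'   (default `support_mean / 2`).
#' @return A `tool_params` list.
#' @export
tool_params <- function(sens_by_class = c(Alu = 0.7, L1 = 0.6, SVA = 0.5),
                        fp_per_mb = 2, breakpoint_sd = 2,
                        support_mean = 12, support_dispersion = 3,
                        sr_fraction = 0.4, fp_support_mean = NULL) {
  stopifnot(all(sens_by_class >= 0 & sens_by_class <= 1), fp_per_mb >= 0,
            breakpoint_sd >= 0, support_mean > 0, sr_fraction >= 0,
            sr_fraction <= 1)
  structure(list(sens_by_class = sens_by_class, fp_per_mb = fp_per_mb,
                 breakpoint_sd = breakpoint_sd, support_mean = support_mean,
                 support_dispersion = support_dispersion,
                 sr_fraction = sr_fraction,
                 fp_support_mean = fp_support_mean %||% (support_mean / 2)),
            class = "tool_params")
}

#' Simulation configuration
#'
#' Study conditions for the synthetic generators. The default element-class
#' mix (88% Alu, 9% L1, 3% SVA) mirrors the composition of germline MEI
#' truth sets; the default cohort is 500 samples (300 affected), 50
#' polymorphic sites segregating at 0.5–5% carrier frequency, and one
#' pathogenic spike-in assigned to an affected sample.
#'
#' @param seed integer seed; the same seed reproduces every generator
#'   output exactly.
#' @param genome data frame (`chrom`, `length`).
#' @param n_truth number of truth insertions.
#' @param class_mix named probabilities over `Alu`, `L1`, `SVA` (sums to 1).
#' @param tsd_length_range min/max target-site-duplication length, bp.
#' @param tsd_known_prob probability a truth site has a known TSD interval.
#' @param tools named list of [tool_params()].
#' @param cohort list: `n_samples`, `n_affected`, `n_polymorphic_sites`,
#'   `site_frequency_range` (carrier-frequency range of polymorphic sites),
#'   `n_pathogenic_spikes`, and `genome` (the exome-scale region the cohort
#'   simulation runs on; default 10 Mb, which keeps per-sample call counts
#'   in the tens as on real capture data).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome = data.frame(chrom = "1", length = 1e8),
                       n_truth = 1000L,
                       class_mix = c(Alu = 0.88, L1 = 0.09, SVA = 0.03),
                       tsd_length_range = c(5L, 20L),
                       tsd_known_prob = 0.8,
                       tools = list(
                         toolA = tool_params(),
                         toolB = tool_params(
                           sens_by_class = c(Alu = 0.65, L1 = 0.5, SVA = 0.6),
                           sr_fraction = 0.6)),
                       cohort = list(n_samples = 500L, n_affected = 300L,
                                     n_polymorphic_sites = 50L,
                                     site_frequency_range = c(0.005, 0.05),
                                     n_pathogenic_spikes = 1L,
                                     genome = data.frame(chrom = "1",
                                                         length = 1e7))) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-8,
            all(class_mix >= 0),
            setequal(names(class_mix), REF_CLASSES),
            cohort$n_affected <= cohort$n_samples,
            cohort$n_pathogenic_spikes <= cohort$n_affected)
  structure(list(seed = as.integer(seed), genome = genome,
                 n_truth = as.integer(n_truth), class_mix = class_mix,
                 tsd_length_range = as.integer(tsd_length_range),
                 tsd_known_prob = tsd_known_prob, tools = tools,
                 cohort = cohort),
            class = "sim_config")
}

# Draw n distinct positions on the genome, uniform over chromosomes by
# length, keeping `margin` bp clear of chromosome ends and `min_gap` bp
# between any two drawn positions (and from `avoid` positions).
draw_positions <- function(genome, n, margin = 1000L, min_gap = 0L,
                           avoid = NULL) {
  placeable <- sum(pmax(0, genome$length - 2 * margin))
  if (n > placeable / max(1, min_gap + 1))
    stop("cannot place ", n, " site(s) on this genome")
  chrom <- sample(as.character(genome$chrom), n, replace = TRUE,
                  prob = genome$length / sum(genome$length))
  pos <- integer(n)
  taken <- avoid
  if (is.null(taken))
    taken <- data.frame(chrom = character(), pos = integer())
  for (i in seq_len(n)) {
    len <- genome$length[match(chrom[i], as.character(genome$chrom))]
    for (try in 1:1000) {
      p <- as.integer(floor(runif(1, margin, len - margin)))
      near <- taken$chrom == chrom[i] & abs(taken$pos - p) <= min_gap
      if (!any(near)) break
      if (try == 1000) stop("could not place site ", i, " with min_gap ", min_gap)
    }
    pos[i] <- p
    taken <- rbind(taken, data.frame(chrom = chrom[i], pos = p))
  }
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Simulate a truth set of reference MEIs
#'
#' Places `n_truth` insertions uniformly on the genome, draws element
#' classes from `class_mix`, and attaches a TSD interval (length uniform in
#' `tsd_length_range`, containing the breakpoint) with probability
#' `tsd_known_prob`. Deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A [reference_mei()] data frame, sorted by (chrom, breakpoint).
#' @export
simulate_truth <- function(config) {
  with_seed(config$seed, {
    loc <- draw_positions(config$genome, config$n_truth, min_gap = 200L)
    cls <- sample(names(config$class_mix), config$n_truth, replace = TRUE,
                  prob = config$class_mix)
    has_tsd <- runif(config$n_truth) < config$tsd_known_prob
    tsd_len <- sample(config$tsd_length_range[1]:config$tsd_length_range[2],
                      config$n_truth, replace = TRUE)
    offset <- vapply(tsd_len, function(l) sample.int(l, 1L) - 1L, 1L)
    tsd_start <- ifelse(has_tsd, loc$pos - offset, NA_integer_)
    tsd_end <- ifelse(has_tsd, tsd_start + tsd_len - 1L, NA_integer_)
    out <- data.frame(chrom = loc$chrom, breakpoint = loc$pos,
                      tsd_start = tsd_start, tsd_end = tsd_end,
                      mei_class = cls, stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$breakpoint), , drop = FALSE]
    rownames(out) <- NULL
    reference_mei(out)
  })
}

#' Simulate one tool's call set over a truth set
#'
#' Each truth insertion is emitted with its class-specific sensitivity; the
#' emitted breakpoint is the true breakpoint plus rounded normal jitter
#' (`breakpoint_sd`), so near-boundary jitter is the mechanism producing
#' residual false negatives/positives at the matching window. Read support
#' is negative-binomial split into SR/DP. False positives are placed
#' uniformly at `fp_per_mb`, at least `fp_clearance` bp away from every
#' truth site (and outside `fp_exclude` intervals, if given) so the
#' ground-truth label of every emitted call is unambiguous.
#'
#' @param truth a [reference_mei()] data frame.
#' @param params a [tool_params()].
#' @param seed integer seed.
#' @param sample_id,tool,assay provenance of the emitted [callset()].
#' @param genome data frame (`chrom`, `length`) used for FP placement.
#' @param fp_clearance minimum distance of a false positive from any truth
#'   breakpoint, bp (default `100 + 6 * breakpoint_sd`).
#' @param fp_exclude optional data frame (`chrom`, `lo`, `hi`) of 1-based
#'   closed intervals false positives must avoid.
#' @return A [callset()] sorted by (chrom, breakpoint), carrying the
#'   generator's bookkeeping: `attr(, "truth_idx")` (row index into `truth`
#'   per call, `NA` for false positives) and `attr(, "emitted")` (logical
#'   per truth row).
#' @export
simulate_tool_calls <- function(truth, params, seed, sample_id = "S1",
                                tool = "toolA", assay = "ES",
                                genome = data.frame(chrom = "1", length = 1e8),
                                fp_clearance = NULL, fp_exclude = NULL) {
  stopifnot(inherits(params, "tool_params"))
  clearance <- fp_clearance %||% as.integer(100 + ceiling(6 * params$breakpoint_sd))
  with_seed(seed, {
    n <- nrow(truth)
    sens <- params$sens_by_class[truth$mei_class]
    sens[is.na(sens)] <- 0
    emitted <- runif(n) < sens
    idx <- which(emitted)
    draw_support <- function(k, mu) {
      tot <- pmax(1L, rnbinom(k, mu = mu, size = params$support_dispersion))
      sr <- rbinom(k, tot, params$sr_fraction)
      data.frame(total = tot, sr = sr, dp = tot - sr)
    }
    tp <- NULL
    if (length(idx)) {
      jitter <- as.integer(round(rnorm(length(idx), 0, params$breakpoint_sd)))
      supp <- draw_support(length(idx), params$support_mean)
      tp <- data.frame(chrom = truth$chrom[idx],
                       breakpoint = pmax(1L, truth$breakpoint[idx] + jitter),
                       mei_class = truth$mei_class[idx],
                       split_reads = supp$sr, discordant_pairs = supp$dp,
                       truth_idx = idx, stringsAsFactors = FALSE)
    }
    # false positives, uniform per chromosome at fp_per_mb
    fp <- NULL
    n_fp_total <- 0L
    if (params$fp_per_mb > 0) {
      for (ci in seq_len(nrow(genome))) {
        ch <- as.character(genome$chrom[ci])
        n_fp <- stats::rpois(1, params$fp_per_mb * genome$length[ci] / 1e6)
        if (n_fp == 0L) next
        t_pos <- truth$breakpoint[norm_chrom(truth$chrom) == norm_chrom(ch)]
        pos <- integer(0)
        guard <- 0L
        while (length(pos) < n_fp && guard < 50L * n_fp + 1000L) {
          p <- as.integer(floor(runif(n_fp, 1, genome$length[ci])))
          ok <- rep(TRUE, length(p))
          if (length(t_pos))
            ok <- vapply(p, function(q) all(abs(t_pos - q) > clearance),
                         logical(1))
          if (!is.null(fp_exclude)) {
            excl <- points_in_intervals(rep(ch, length(p)), p,
                                        fp_exclude$chrom, fp_exclude$lo,
                                        fp_exclude$hi)
            ok <- ok & !excl
          }
          pos <- c(pos, p[ok])
          guard <- guard + length(p)
        }
        pos <- pos[seq_len(min(n_fp, length(pos)))]
        if (!length(pos)) next
        supp <- draw_support(length(pos), params$fp_support_mean)
        fp <- rbind(fp, data.frame(
          chrom = ch, breakpoint = pos,
          mei_class = sample(names(params$sens_by_class), length(pos),
                             replace = TRUE),
          split_reads = supp$sr, discordant_pairs = supp$dp,
          truth_idx = NA_integer_, stringsAsFactors = FALSE))
        n_fp_total <- n_fp_total + length(pos)
      }
    }
    all_calls <- rbind(tp, fp)
    if (is.null(all_calls))
      all_calls <- data.frame(chrom = character(), breakpoint = integer(),
                              mei_class = character(), split_reads = integer(),
                              discordant_pairs = integer(),
                              truth_idx = integer(), stringsAsFactors = FALSE)
    ord <- order(all_calls$chrom, all_calls$breakpoint)
    all_calls <- all_calls[ord, , drop = FALSE]
    cs <- if (nrow(all_calls) == 0L) {
      callset(NULL, assay = assay, provenance = sprintf("simulated:%s", tool))
    } else {
      callset(data.frame(
        sample_id = sample_id, chrom = all_calls$chrom,
        breakpoint = all_calls$breakpoint, mei_class = all_calls$mei_class,
        split_reads = all_calls$split_reads,
        discordant_pairs = all_calls$discordant_pairs,
        tool = tool, stringsAsFactors = FALSE), assay = assay,
        provenance = sprintf("simulated:%s", tool))
    }
    attr(cs, "truth_idx") <- all_calls$truth_idx
    attr(cs, "emitted") <- emitted
    cs
  })
}

#' Simulate a rare-disease cohort with polymorphic and pathogenic MEIs
#'
#' Builds a synthetic exome cohort: a gene model (genes with exons, splice
#' regions and introns), capture target regions over the exons, two gene
#' panels, polymorphic MEI sites segregating at the configured carrier
#' frequencies, and rare pathogenic spike-ins placed inside exons of
#' panel genes of distinct affected samples. Every sample's calls are then
#' generated per tool with [simulate_tool_calls()]; cohort false positives
#' are placed outside target regions so ground-truth candidate labels stay
#' unambiguous.
#'
#' @param config a [sim_config()].
#' @return list with `samples` (cohort metadata), `callsets` (one
#'   [callset()] per sample x tool), `known_sites` (the polymorphic sites,
#'   standing in for a dbRIP-style catalogue), `targets`, `genes`,
#'   `panels`, and `bookkeeping` (`spikes`: per-spike sample, position,
#'   gene, class, and whether any tool emitted it; `polymorphic`: per-site
#'   frequency and carriers).
#' @export
simulate_cohort <- function(config) {
  co <- config$cohort
  with_seed(config$seed + 1L, {
    # cohort uses an exome-scale region so per-sample call counts are in the
    # tens, as callers produce on capture data
    genome <- co$genome %||% data.frame(chrom = "1", length = 1e7)
    # gene model: 30 genes of 20 kb, 5 exons of 200 bp each
    n_genes <- 30L
    gene_len <- 20000L
    exon_len <- 200L
    splice_pad <- 8L
    gene_start <- as.integer(seq(1e5, genome$length[1] - gene_len - 1e5,
                                 length.out = n_genes))
    gene_chrom <- rep(as.character(genome$chrom[1]), n_genes)
    ann <- NULL
    exon_tab <- NULL
    for (g in seq_len(n_genes)) {
      ex_start <- gene_start[g] + as.integer(seq(0, gene_len - exon_len,
                                                 length.out = 5))
      ex_end <- ex_start + exon_len - 1L
      gname <- sprintf("GENE%02d", g)
      ann <- rbind(ann,
        data.frame(chrom = gene_chrom[g], start = ex_start, end = ex_end,
                   gene = gname, feature = "exon", stringsAsFactors = FALSE),
        data.frame(chrom = gene_chrom[g],
                   start = c(ex_start - splice_pad, ex_end + 1L),
                   end = c(ex_start - 1L, ex_end + splice_pad),
                   gene = gname, feature = "splice_region",
                   stringsAsFactors = FALSE),
        data.frame(chrom = gene_chrom[g], start = gene_start[g],
                   end = gene_start[g] + gene_len - 1L, gene = gname,
                   feature = "intron", stringsAsFactors = FALSE))
      exon_tab <- rbind(exon_tab, data.frame(
        chrom = gene_chrom[g], start = ex_start, end = ex_end, gene = gname,
        stringsAsFactors = FALSE))
    }
    genes <- gene_annotation(ann)
    targets <- target_regions(data.frame(chrom = exon_tab$chrom,
                                         start = exon_tab$start - 1L,
                                         end = exon_tab$end), window_bp = 50L)
    panels <- list(panel_A = sprintf("GENE%02d", 1:15),
                   panel_B = sprintf("GENE%02d", 16:30))

    # samples: one family per sample, random affected subset, random panel
    n <- co$n_samples
    sample_id <- sprintf("S%04d", seq_len(n))
    affected <- logical(n)
    affected[sample(n, co$n_affected)] <- TRUE
    samples <- data.frame(sample_id = sample_id,
                          family_id = sprintf("F%04d", seq_len(n)),
                          affected = affected,
                          panel = sample(names(panels), n, replace = TRUE),
                          stringsAsFactors = FALSE)

    # polymorphic sites (the known-polymorphism catalogue)
    poly_loc <- draw_positions(genome, co$n_polymorphic_sites, min_gap = 500L)
    poly <- reference_mei(data.frame(
      chrom = poly_loc$chrom, breakpoint = poly_loc$pos,
      mei_class = sample(names(config$class_mix), co$n_polymorphic_sites,
                         replace = TRUE, prob = config$class_mix),
      stringsAsFactors = FALSE))
    poly_freq <- runif(co$n_polymorphic_sites, co$site_frequency_range[1],
                       co$site_frequency_range[2])
    carrier_mat <- matrix(runif(n * co$n_polymorphic_sites) <
                            rep(poly_freq, each = n),
                          nrow = n)

    # pathogenic spikes: distinct affected samples, exon interior of a gene
    # from the carrier's own panel, well clear of polymorphic sites
    spike_samples <- sample(samples$sample_id[samples$affected],
                            co$n_pathogenic_spikes)
    spikes <- NULL
    used_genes <- character(0)
    for (sid in spike_samples) {
      pn <- samples$panel[samples$sample_id == sid]
      cand <- exon_tab[exon_tab$gene %in% setdiff(panels[[pn]], used_genes), ]
      repeat {
        ex <- cand[sample.int(nrow(cand), 1L), ]
        bp <- as.integer(ex$start + 35L +
                           sample.int(exon_len - 70L, 1L) - 1L)
        clear <- all(!(norm_chrom(poly$chrom) == norm_chrom(ex$chrom) &
                         abs(poly$breakpoint - bp) <= 150L))
        if (!is.null(spikes))
          clear <- clear && all(abs(spikes$breakpoint - bp) > 150L)
        if (clear) break
      }
      used_genes <- c(used_genes, ex$gene)
      spikes <- rbind(spikes, data.frame(
        sample_id = sid, chrom = ex$chrom, breakpoint = bp, gene = ex$gene,
        mei_class = "Alu", stringsAsFactors = FALSE))
    }

    # per-sample, per-tool call sets; FPs kept off-target
    fp_excl <- data.frame(chrom = targets$chrom,
                          lo = targets$start + 1L - 200L,
                          hi = targets$end + 200L)
    callsets <- list()
    spike_emitted <- setNames(rep(FALSE, length(spike_samples)), spike_samples)
    k <- 0L
    for (i in seq_len(n)) {
      carried <- which(carrier_mat[i, ])
      tr <- data.frame(chrom = poly$chrom[carried],
                       breakpoint = poly$breakpoint[carried],
                       mei_class = poly$mei_class[carried],
                       stringsAsFactors = FALSE)
      is_spike <- logical(nrow(tr))
      sp <- if (is.null(spikes)) NULL else
        spikes[spikes$sample_id == sample_id[i], , drop = FALSE]
      if (!is.null(sp) && nrow(sp)) {
        tr <- rbind(tr, sp[, c("chrom", "breakpoint", "mei_class")])
        is_spike <- c(is_spike, rep(TRUE, nrow(sp)))
      }
      truth_i <- reference_mei(tr)
      for (tl in names(config$tools)) {
        k <- k + 1L
        cs <- simulate_tool_calls(
          truth_i, config$tools[[tl]],
          seed = (config$seed + 7L * i + 131L * k) %% .Machine$integer.max,
          sample_id = sample_id[i], tool = tl, assay = "ES",
          genome = genome, fp_exclude = fp_excl)
        if (any(is_spike) && any(attr(cs, "emitted") & is_spike))
          spike_emitted[sample_id[i]] <- TRUE
        callsets[[k]] <- cs
      }
    }
    if (!is.null(spikes)) spikes$emitted <- spike_emitted[spikes$sample_id]
    list(samples = samples, callsets = callsets, known_sites = poly,
         targets = targets, genes = genes, panels = panels,
         bookkeeping = list(
           spikes = spikes,
           polymorphic = data.frame(
             site = seq_len(co$n_polymorphic_sites),
             chrom = poly$chrom, breakpoint = poly$breakpoint,
             frequency = poly_freq, carriers = colSums(carrier_mat))))
  })
}
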