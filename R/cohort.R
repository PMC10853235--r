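#' Cohort occurrence table
#'
#' Links merged MEI sites to the cohort samples carrying them, alongside
#' sample metadata (family, affected status, requested gene panel). Carrier
#' frequency and the prioritisation cascade operate on this structure.
#'
#' @param samples data frame with columns `sample_id`, `family_id`,
#'   `affected` (logical) and optionally `panel` (panel name or `NA`).
#' @param sites a `merged_sites` object from [merge_callsets()]; carriers
#'   are derived from its membership table. Alternatively pass
#'   `occurrences` directly.
#' @param occurrences optional data frame (`site_id`, `sample_id`)
#'   overriding derivation from `sites`.
#' @return An object of class `cohort_table`: list with `samples` and
#'   `occurrences`.
#' @export
cohort_table <- function(samples, sites = NULL, occurrences = NULL) {
  stopifnot(all(c("sample_id", "family_id", "affected") %in% names(samples)))
  samples <- as.data.frame(samples)
  if (!"panel" %in% names(samples)) samples$panel <- NA_character_
  if (is.null(occurrences)) {
    stopifnot(inherits(sites, "merged_sites"))
    mem <- site_members(sites)
    occurrences <- unique(mem[, c("site_id", "sample_id")])
  }
  occurrences <- unique(as.data.frame(occurrences)[, c("site_id", "sample_id")])
  rownames(occurrences) <- NULL
  unknown <- setdiff(occurrences$sample_id, samples$sample_id)
  if (length(unknown))
    stop("occurrence sample(s) missing from cohort metadata: ",
         paste(unknown, collapse = ", "))
  structure(list(samples = samples, occurrences = occurrences),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort: %d samples (%d affected), %d site occurrences at %d sites\n",
              nrow(x$samples), sum(x$samples$affected),
              nrow(x$occurrences), length(unique(x$occurrences$site_id))))
  invisible(x)
}

#' Carrier frequency of merged sites in a cohort
#'
#' Number of samples carrying a call at the site divided by the total number
#' of cohort samples (affected and unaffected). Rendered as percent in
#' reports; returned as a fraction.
#'
#' @param site_ids character vector of site ids.
#' @param cohort a [cohort_table()].
#' @return numeric vector of carrier fractions along `site_ids`.
#' @export
carrier_frequency <- function(site_ids, cohort) {
  stopifnot(inherits(cohort, "cohort_table"), nrow(cohort$samples) > 0L)
  carriers <- table(cohort$occurrences$site_id)
  n <- as.numeric(carriers[site_ids])
  n[is.na(n)] <- 0
  n / nrow(cohort$samples)
}

#' Exclude sites matching known polymorphic insertions
#'
#' Removes merged sites whose representative breakpoint lies within `pad` bp
#' of a catalogued insertion polymorphism (dbRIP-style list) of the same
#' element class (class-aware by default; `"unknown"` sites match any
#' class).
#'
#' @param sites a `merged_sites` object.
#' @param known a [reference_mei()] data frame of known polymorphic sites.
#' @param pad matching distance in bp (default 50).
#' @param class_aware require class agreement (default `TRUE`).
#' @return The filtered `merged_sites` object.
#' @export
exclude_known_sites <- function(sites, known, pad = 50L, class_aware = TRUE) {
  if (nrow(sites) == 0L || is.null(known) || nrow(known) == 0L) return(sites)
  sch <- norm_chrom(sites$chrom)
  kch <- norm_chrom(known$chrom)
  drop <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    near <- kch == sch[i] & abs(known$breakpoint - sites$breakpoint[i]) <= pad
    if (class_aware && sites$mei_class[i] != "unknown")
      near <- near & known$mei_class == sites$mei_class[i]
    drop[i] <- any(near)
  }
  subset_sites(sites, !drop)
}

#' Exclude sites carried by unaffected samples
#'
#' Removes every site carried by at least one unaffected sample (e.g. a
#' healthy parent), the strongest interpretation of restricting candidates
#' to affected cases. Errors if a carrier's affected status is unknown.
#'
#' @param sites a `merged_sites` object.
#' @param cohort a [cohort_table()].
#' @return The filtered `merged_sites` object.
#' @export
exclude_unaffected_carriers <- function(sites, cohort) {
  if (nrow(sites) == 0L) return(sites)
  occ <- cohort$occurrences[cohort$occurrences$site_id %in% sites$site_id, ]
  status <- cohort$samples$affected[match(occ$sample_id,
                                          cohort$samples$sample_id)]
  if (anyNA(status))
    stop("carrier(s) with unknown affected status: ",
         paste(unique(occ$sample_id[is.na(status)]), collapse = ", "))
  bad <- unique(occ$site_id[!status])
  subset_sites(sites, !sites$site_id %in% bad)
}

#' Gene annotation table
#'
#' Intervals (1-based, inclusive) labelled with a gene symbol and a feature
#' class: `exon`, `splice_region` (within `splice_pad` bp of an exon
#' boundary) or `intron`.
#'
#' @param df data frame with columns `chrom`, `start`, `end`, `gene`,
#'   `feature`.
#' @return A `gene_annotation` data frame.
#' @export
gene_annotation <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "gene", "feature") %in% names(df)))
  stopifnot(all(df$feature %in% c("exon", "splice_region", "intron")))
  stopifnot(all(df$start <= df$end))
  structure(as.data.frame(df), class = c("gene_annotation", "data.frame"))
}

#' Gene-panel filter
#'
#' Keeps sites overlapping (within `pad` bp) an interval of a gene that is
#' in the requested gene panel of at least one carrier. With
#' `exonic_splice_only = TRUE` the overlapped feature must additionally be
#' an exon or splice region.
#'
#' @param sites a `merged_sites` object.
#' @param cohort a [cohort_table()].
#' @param genes a [gene_annotation()] table.
#' @param panels named list: panel name -> character vector of gene symbols.
#' @param exonic_splice_only restrict to exonic/splice-region hits.
#' @param pad overlap slack in bp (default 50).
#' @return The filtered `merged_sites` object.
#' @export
panel_filter <- function(sites, cohort, genes, panels,
                         exonic_splice_only = FALSE, pad = 50L) {
  if (nrow(sites) == 0L) return(sites)
  occ <- cohort$occurrences
  samp <- cohort$samples
  keep <- logical(nrow(sites))
  gch <- norm_chrom(genes$chrom)
  feat_ok <- if (exonic_splice_only)
    genes$feature %in% c("exon", "splice_region") else rep(TRUE, nrow(genes))
  for (i in seq_len(nrow(sites))) {
    carriers <- occ$sample_id[occ$site_id == sites$site_id[i]]
    pns <- unique(samp$panel[samp$sample_id %in% carriers])
    pns <- pns[!is.na(pns)]
    if (!length(pns)) next
    miss <- setdiff(pns, names(panels))
    if (length(miss))
      stop("unknown gene panel(s): ", paste(miss, collapse = ", "))
    gene_set <- unique(unlist(panels[pns], use.names = FALSE))
    hit <- gch == norm_chrom(sites$chrom[i]) & genes$gene %in% gene_set &
      feat_ok &
      sites$breakpoint[i] >= genes$start - pad &
      sites$breakpoint[i] <= genes$end + pad
    keep[i] <- any(hit)
  }
  subset_sites(sites, keep)
}

# Overlapping gene/feature label for a site (first panel gene hit), for the
# candidate report.
site_gene_hits <- function(site, genes, gene_set, exonic_splice_only, pad = 50L) {
  hit <- norm_chrom(genes$chrom) == norm_chrom(site$chrom) &
    genes$gene %in% gene_set &
    site$breakpoint >= genes$start - pad & site$breakpoint <= genes$end + pad
  if (exonic_splice_only)
    hit <- hit & genes$feature %in% c("exon", "splice_region")
  g <- genes[hit, , drop = FALSE]
  if (nrow(g) == 0L) return(c(gene = NA_character_, feature = NA_character_))
  pref <- order(match(g$feature, c("exon", "splice_region", "intron")))
  c(gene = g$gene[pref[1]], feature = g$feature[pref[1]])
}

#' Rare-disease MEI prioritisation cascade
#'
#' Applies, in order: (1) restriction to exome target regions (breakpoint
#' within `window_bp` of a capture interval), (2) removal of sites carried
#' by unaffected samples, (3) exclusion of known insertion polymorphisms,
#' (4) carrier-frequency filter (strictly below `max_freq`, computed over
#' all cohort samples), (5) gene-panel filter, optionally restricted to
#' exonic/splice-region hits. Surviving (site, affected carrier) pairs are
#' reported as candidates, and the count surviving each stage is logged.
#'
#' @param sites a `merged_sites` object over the whole cohort.
#' @param cohort a [cohort_table()].
#' @param targets a [target_regions()] object.
#' @param known a [reference_mei()] data frame of known polymorphisms
#'   (`NULL` to skip).
#' @param genes a [gene_annotation()] table.
#' @param panels named list of gene panels.
#' @param max_freq carrier-frequency upper bound as a fraction (strict
#'   `<`); the default 0.0003 corresponds to 0.03 %.
#' @param exonic_splice_only restrict candidates to exonic/splice-region
#'   sites.
#' @param pad overlap slack for known-site and gene matching, bp.
#' @return An object of class `mei_candidates`: list with `candidates` (one
#'   row per sample x site, sorted by sample, chrom, position), `stage_log`
#'   (named integer vector of surviving site counts) and `sites` (the
#'   surviving `merged_sites`).
#' @export
prioritize <- function(sites, cohort, targets, known, genes, panels,
                       max_freq = 0.0003, exonic_splice_only = FALSE,
                       pad = 50L) {
  stopifnot(inherits(sites, "merged_sites"), inherits(cohort, "cohort_table"))
  log <- c(input = nrow(sites))

  in_targets <- points_in_intervals(
    sites$chrom, sites$breakpoint, targets$chrom,
    targets$start + 1L - attr(targets, "window_bp"),
    targets$end + attr(targets, "window_bp"))
  sites <- subset_sites(sites, in_targets)
  log <- c(log, target_regions = nrow(sites))

  sites <- exclude_unaffected_carriers(sites, cohort)
  log <- c(log, affected_only = nrow(sites))

  sites <- exclude_known_sites(sites, known, pad = pad)
  log <- c(log, not_known_polymorphism = nrow(sites))

  freq <- carrier_frequency(sites$site_id, cohort)
  sites <- subset_sites(sites, freq < max_freq)
  log <- c(log, rare = nrow(sites))

  sites <- panel_filter(sites, cohort, genes, panels,
                        exonic_splice_only = exonic_splice_only, pad = pad)
  log <- c(log, panel = nrow(sites))

  occ <- cohort$occurrences[cohort$occurrences$site_id %in% sites$site_id, ]
  mem <- site_members(sites)
  cand <- NULL
  if (nrow(occ)) {
    idx <- match(occ$site_id, sites$site_id)
    carriers_n <- table(cohort$occurrences$site_id)
    rows <- lapply(seq_len(nrow(occ)), function(k) {
      s <- sites[idx[k], ]
      pn <- cohort$samples$panel[match(occ$sample_id[k],
                                       cohort$samples$sample_id)]
      gene_set <- if (is.na(pn)) character() else panels[[pn]]
      gh <- site_gene_hits(s, genes, gene_set, exonic_splice_only, pad)
      supp <- mem[mem$site_id == s$site_id & mem$sample_id == occ$sample_id[k], ]
      data.frame(sample_id = occ$sample_id[k], site_id = s$site_id,
                 chrom = s$chrom, breakpoint = s$breakpoint,
                 mei_class = s$mei_class, gene = gh[["gene"]],
                 feature = gh[["feature"]],
                 n_tools = length(unique(supp$tool)),
                 carriers = as.integer(carriers_n[s$site_id]),
                 carrier_frequency = as.numeric(carriers_n[s$site_id]) /
                   nrow(cohort$samples),
                 stringsAsFactors = FALSE)
    })
    cand <- do.call(rbind, rows)
    cand <- cand[order(cand$sample_id, cand$chrom, cand$breakpoint), ,
                 drop = FALSE]
    rownames(cand) <- NULL
  } else {
    cand <- data.frame(sample_id = character(), site_id = character(),
                       chrom = character(), breakpoint = integer(),
                       mei_class = character(), gene = character(),
                       feature = character(), n_tools = integer(),
                       carriers = integer(), carrier_frequency = numeric(),
                       stringsAsFactors = FALSE)
  }
  structure(list(candidates = cand, stage_log = log, sites = sites),
            class = "mei_candidates")
}

#' @export
print.mei_candidates <- function(x, ...) {
  cat("MEI prioritisation cascade\n  sites surviving each stage:\n")
  for (nm in names(x$stage_log))
    cat(sprintf("    %-24s %d\n", nm, x$stage_log[[nm]]))
  cat(sprintf("  candidates: %d\n", nrow(x$candidates)))
  if (nrow(x$candidates)) print.data.frame(x$candidates)
  invisible(x)
}

#' Readers for cohort side inputs
#'
#' `read_cohort_meta()` reads sample metadata (`sample_id`, `family_id`,
#' `affected` as TRUE/FALSE, optional `panel`); `read_panels()` reads a
#' two-column `panel`/`gene` table into a named list; and
#' `read_gene_annotation()` reads a `chrom`/`start`/`end`/`gene`/`feature`
#' table (1-based inclusive intervals).
#'
#' @param path tab-separated file with a header line.
#' @return See each function's description.
#' @export
read_cohort_meta <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  df$affected <- as.logical(df$affected)
  df
}

#' @rdname read_cohort_meta
#' @export
read_panels <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("panel", "gene") %in% names(df)))
  split(df$gene, df$panel)
}

#' @rdname read_cohort_meta
#' @export
read_gene_annotation <- function(path) {
  gene_annotation(read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE))
}
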