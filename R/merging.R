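#' Merge MEI call sets across tools and samples
#'
#' Single-linkage clustering of breakpoints per chromosome (and per element
#' class when `class_aware = TRUE`, the default): breakpoints are sorted and
#' a new site starts whenever the gap to the previous breakpoint exceeds
#' `tolerance`. Two calls at exactly `tolerance` bp therefore share a site.
#' Because linkage is transitive, a chained site can span more than
#' `tolerance` end-to-end; consecutive sorted member breakpoints are always
#' within `tolerance`.
#'
#' The representative breakpoint is the lower median of the member
#' breakpoints. In class-agnostic mode the site class is the majority vote
#' over members, ties giving `"unknown"`.
#'
#' @param callsets a [callset()] or list of them.
#' @param tolerance maximum gap between consecutive member breakpoints, bp
#'   (default 50).
#' @param class_aware keep element classes in separate sites (default
#'   `TRUE`).
#' @return An object of class `merged_sites`: a data frame with one row per
#'   unique site (`site_id`, `chrom`, `breakpoint`, `mei_class`,
#'   `n_members`, `n_samples`, `n_tools`, `tools`), ordered by
#'   `(chrom, breakpoint)`, with the per-call membership table in
#'   `attr(, "members")`.
#' @export
merge_callsets <- function(callsets, tolerance = 50L, class_aware = TRUE) {
  if (inherits(callsets, "callset")) callsets <- list(callsets)
  pooled <- do.call(rbind, lapply(callsets, function(cs)
    data.frame(sample_id = cs$sample_id, tool = cs$tool,
               chrom = norm_chrom(cs$chrom), breakpoint = cs$breakpoint,
               mei_class = cs$mei_class, stringsAsFactors = FALSE)))
  if (is.null(pooled) || nrow(pooled) == 0L) {
    sites <- data.frame(site_id = character(), chrom = character(),
                        breakpoint = integer(), mei_class = character(),
                        n_members = integer(), n_samples = integer(),
                        n_tools = integer(), tools = character(),
                        stringsAsFactors = FALSE)
    members <- data.frame(site_id = character(), sample_id = character(),
                          tool = character(), breakpoint = integer(),
                          mei_class = character(), stringsAsFactors = FALSE)
    return(structure(sites, class = c("merged_sites", "data.frame"),
                     members = members, tolerance = as.integer(tolerance),
                     class_aware = class_aware))
  }
  key <- if (class_aware) paste(pooled$chrom, pooled$mei_class, sep = "\r")
         else pooled$chrom
  ord <- order(key, pooled$breakpoint)
  pooled <- pooled[ord, , drop = FALSE]
  key <- key[ord]
  new_site <- c(TRUE, key[-1] != key[-length(key)] |
                  diff(pooled$breakpoint) > tolerance)
  cluster <- cumsum(new_site)
  n_clust <- cluster[length(cluster)]
  starts <- which(new_site)
  size <- diff(c(starts, nrow(pooled) + 1L))
  # member breakpoints are already sorted within a cluster: lower median
  reps <- pooled$breakpoint[starts + (size + 1L) %/% 2L - 1L]
  chrom <- pooled$chrom[starts]
  cls <- if (class_aware) pooled$mei_class[starts] else
    vapply(split(pooled$mei_class, cluster), function(cl) {
      tab <- sort(table(cl), decreasing = TRUE)
      if (length(tab) > 1L && tab[1] == tab[2]) "unknown" else names(tab)[1]
    }, character(1))
  uniq_in_cluster <- function(v) !duplicated(paste(cluster, v, sep = "\r"))
  su <- uniq_in_cluster(pooled$sample_id)
  tu <- uniq_in_cluster(pooled$tool)
  tools_str <- vapply(split(pooled$tool[tu], cluster[tu]),
                      function(t) paste(sort(t), collapse = ","), "")
  site_ord <- order(chrom, reps, cls)
  rank <- match(seq_len(n_clust), site_ord)
  ids <- sprintf("site_%05d", rank)
  members <- data.frame(site_id = ids[cluster], sample_id = pooled$sample_id,
                        tool = pooled$tool, breakpoint = pooled$breakpoint,
                        mei_class = pooled$mei_class, stringsAsFactors = FALSE)
  members <- members[order(members$site_id, members$breakpoint), , drop = FALSE]
  rownames(members) <- NULL
  sites <- data.frame(
    site_id = ids[site_ord], chrom = chrom[site_ord],
    breakpoint = reps[site_ord], mei_class = cls[site_ord],
    n_members = size[site_ord],
    n_samples = tabulate(cluster[su], nbins = n_clust)[site_ord],
    n_tools = tabulate(cluster[tu], nbins = n_clust)[site_ord],
    tools = tools_str[site_ord],
    stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  structure(sites, class = c("merged_sites", "data.frame"),
            members = members, tolerance = as.integer(tolerance),
            class_aware = class_aware)
}

#' @export
print.merged_sites <- function(x, ...) {
  cat(sprintf("merged MEI sites: %d site(s) from %d call(s), tolerance %d bp\n",
              nrow(x), nrow(site_members(x)), attr(x, "tolerance")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' @rdname merge_callsets
#' @param sites a `merged_sites` object.
#' @export
site_members <- function(sites) attr(sites, "members")

# Subset a merged_sites object, keeping membership in sync.
subset_sites <- function(sites, keep) {
  df <- as.data.frame(sites)[keep, , drop = FALSE]
  rownames(df) <- NULL
  mem <- site_members(sites)
  mem <- mem[mem$site_id %in% df$site_id, , drop = FALSE]
  rownames(mem) <- NULL
  structure(df, class = c("merged_sites", "data.frame"), members = mem,
            tolerance = attr(sites, "tolerance"),
            class_aware = attr(sites, "class_aware"))
}

#' Concordance between two tools over merged sites
#'
#' Among sites supported by either tool, counts those supported by tool A
#' only, tool B only, and both; the overlap fraction is
#' `both / (a_only + b_only + both)`.
#'
#' @param merged a `merged_sites` object from [merge_callsets()].
#' @param tool_a,tool_b tool names as recorded in the call sets.
#' @return list with `overlap_fraction` and `counts`
#'   (`a_only`, `b_only`, `both`). `overlap_fraction` is `NA` when neither
#'   tool supports any site.
#' @export
concordance <- function(merged, tool_a, tool_b) {
  mem <- site_members(merged)
  has_a <- unique(mem$site_id[mem$tool == tool_a])
  has_b <- unique(mem$site_id[mem$tool == tool_b])
  both <- length(intersect(has_a, has_b))
  a_only <- length(setdiff(has_a, has_b))
  b_only <- length(setdiff(has_b, has_a))
  tot <- a_only + b_only + both
  list(overlap_fraction = if (tot == 0L) NA_real_ else both / tot,
       counts = c(a_only = a_only, b_only = b_only, both = both))
}

#' Detection rate of a merged (multi-tool) call set against a truth set
#'
#' A truth insertion counts as detected when any member breakpoint of any
#' merged site falls inside its [match_window()] (class agreement as in
#' [match_calls()]); the union of tools therefore detects at least as much
#' as any single tool.
#'
#' @param merged a `merged_sites` object.
#' @param truth a [reference_mei()] data frame.
#' @inheritParams match_calls
#' @return list with `detected`, `total`, `rate`.
#' @export
combined_detection_rate <- function(merged, truth, require_class = TRUE,
                                    tsd_pad = 10L, fallback_pad = 50L) {
  stopifnot(nrow(truth) > 0L)
  mem <- site_members(merged)
  site_chrom <- setNames(merged$chrom, merged$site_id)
  pseudo <- callset(data.frame(
    sample_id = mem$sample_id, chrom = site_chrom[mem$site_id],
    breakpoint = mem$breakpoint, mei_class = mem$mei_class,
    tool = mem$tool, stringsAsFactors = FALSE))
  m <- match_calls(pseudo, truth, require_class, tsd_pad, fallback_pad)
  list(detected = m$detected_references, total = m$n_references,
       rate = m$detected_references / m$n_references)
}
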