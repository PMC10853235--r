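#' Unified MEI call-set container
#'
#' A `callset` is a data frame of mobile element insertion (MEI) calls with a
#' fixed column contract, one row per predicted insertion in one sample from
#' one tool. Breakpoints are single 1-based positions; BED-style inputs are
#' converted on read. Read support is split into split/clipped reads (SR) and
#' discordant pairs (DP); `total_support = split_reads + discordant_pairs`.
#'
#' @param calls data frame with (a subset of) the columns `sample_id`,
#'   `chrom`, `breakpoint`, `mei_class`, `strand`, `split_reads`,
#'   `discordant_pairs`, `total_support`, `quality`, `tool`, `flags`.
#'   Missing evidence columns default to 0, `quality` to `NA`, `strand` to
#'   `"*"`, `flags` to `""` (comma-separated tokens, e.g. `"ac0"`).
#' @param assay `"ES"` (exome) or `"GS"` (genome); stored as an attribute and
#'   used to pick the common read-support filter.
#' @param provenance free-text origin note.
#' @return An object of class `callset` (a data frame).
#' @examples
#' cs <- callset(data.frame(sample_id = "S1", chrom = "1", breakpoint = 100,
#'                          mei_class = "Alu", split_reads = 3,
#'                          discordant_pairs = 4, tool = "toolA"))
#' cs$total_support  # 7
#' @export
callset <- function(calls = NULL, assay = c("ES", "GS"), provenance = "") {
  assay <- match.arg(assay)
  tmpl <- data.frame(
    sample_id = character(), chrom = character(), breakpoint = integer(),
    mei_class = character(), strand = character(),
    split_reads = integer(), discordant_pairs = integer(),
    total_support = integer(), quality = numeric(),
    tool = character(), flags = character(),
    stringsAsFactors = FALSE)
  if (is.null(calls) || nrow(calls) == 0L) {
    out <- tmpl
  } else {
    n <- nrow(calls)
    get_col <- function(nm, default) {
      if (nm %in% names(calls)) calls[[nm]] else rep(default, n)
    }
    out <- data.frame(
      sample_id = as.character(get_col("sample_id", "sample")),
      chrom = as.character(get_col("chrom", NA_character_)),
      breakpoint = as.integer(get_col("breakpoint", NA_integer_)),
      mei_class = as.character(get_col("mei_class", "unknown")),
      strand = as.character(get_col("strand", "*")),
      split_reads = as.integer(get_col("split_reads", 0L)),
      discordant_pairs = as.integer(get_col("discordant_pairs", 0L)),
      total_support = NA_integer_,
      quality = as.numeric(get_col("quality", NA_real_)),
      tool = as.character(get_col("tool", "tool")),
      flags = as.character(get_col("flags", "")),
      stringsAsFactors = FALSE)
    out$total_support <- if ("total_support" %in% names(calls)) {
      as.integer(calls$total_support)
    } else {
      out$split_reads + out$discordant_pairs
    }
    out$flags[is.na(out$flags)] <- ""
  }
  validate_callset(structure(out, class = c("callset", "data.frame"),
                             assay = assay, provenance = provenance))
}

validate_callset <- function(x) {
  stopifnot(is.data.frame(x))
  if (nrow(x)) {
    if (anyNA(x$breakpoint) || any(x$breakpoint < 1L))
      stop("breakpoints must be integers >= 1 (1-based)", call. = FALSE)
    bad <- !x$mei_class %in% MEI_CLASSES
    if (any(bad))
      stop("invalid mei_class value(s): ",
           paste(unique(x$mei_class[bad]), collapse = ", "), call. = FALSE)
    if (any(x$split_reads < 0L) || any(x$discordant_pairs < 0L))
      stop("read-support counts must be non-negative", call. = FALSE)
    known <- !is.na(x$split_reads) & !is.na(x$discordant_pairs) &
      !is.na(x$total_support)
    if (any(known & x$total_support != x$split_reads + x$discordant_pairs))
      stop("total_support must equal split_reads + discordant_pairs",
           call. = FALSE)
  }
  x
}

#' @export
print.callset <- function(x, ...) {
  cat(sprintf("MEI call set: %d call(s), assay %s\n", nrow(x), callset_assay(x)))
  if (nzchar(attr(x, "provenance")))
    cat("provenance:", attr(x, "provenance"), "\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more call(s)\n")
  invisible(x)
}

#' @rdname callset
#' @param x a `callset`.
#' @export
callset_assay <- function(x) attr(x, "assay") %||% "ES"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rebuild a callset around a plain data frame, keeping metadata.
as_callset_like <- function(df, template) {
  structure(as.data.frame(df), class = c("callset", "data.frame"),
            assay = callset_assay(template),
            provenance = attr(template, "provenance") %||% "")
}

#' Reference (truth) MEI set
#'
#' One row per true insertion: chromosome, 1-based breakpoint, optional
#' target site duplication (TSD) interval and element class. The TSD, when
#' known, localises the insertion more precisely than the breakpoint and
#' widens the benchmark matching window around the whole duplicated tract.
#'
#' @param df data frame with columns `chrom`, `breakpoint`, `mei_class` and
#'   optionally `tsd_start`, `tsd_end` (both present or both `NA` per row).
#' @return A `reference_mei` data frame.
#' @export
reference_mei <- function(df) {
  stopifnot(all(c("chrom", "breakpoint", "mei_class") %in% names(df)))
  out <- data.frame(
    chrom = as.character(df$chrom),
    breakpoint = as.integer(df$breakpoint),
    tsd_start = if ("tsd_start" %in% names(df)) as.integer(df$tsd_start) else
      rep(NA_integer_, nrow(df)),
    tsd_end = if ("tsd_end" %in% names(df)) as.integer(df$tsd_end) else
      rep(NA_integer_, nrow(df)),
    mei_class = as.character(df$mei_class),
    stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (any(out$breakpoint < 1L)) stop("breakpoints must be >= 1")
    if (!all(out$mei_class %in% REF_CLASSES))
      stop("reference mei_class must be one of ", paste(REF_CLASSES, collapse = "/"))
    one_sided <- xor(is.na(out$tsd_start), is.na(out$tsd_end))
    if (any(one_sided)) stop("tsd_start/tsd_end must be both present or both absent")
    has <- !is.na(out$tsd_start)
    if (any(has & (out$tsd_start > out$tsd_end |
                   out$breakpoint < out$tsd_start | out$breakpoint > out$tsd_end)))
      stop("TSD interval must contain the breakpoint and satisfy tsd_start <= tsd_end")
  }
  structure(out, class = c("reference_mei", "data.frame"))
}

#' Exome target regions
#'
#' Capture/exon intervals in BED convention (0-based, half-open) plus the
#' window (default 50 bp) by which each interval is expanded on both sides
#' when deciding whether a call is "on target".
#'
#' @param intervals data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open, as in BED).
#' @param window_bp flank added to each side, in bp.
#' @return A `target_regions` object.
#' @export
target_regions <- function(intervals, window_bp = 50L) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  out <- data.frame(chrom = as.character(intervals$chrom),
                    start = as.integer(intervals$start),
                    end = as.integer(intervals$end),
                    stringsAsFactors = FALSE)
  if (nrow(out) && any(out$start >= out$end))
    stop("target intervals require start < end (BED half-open)")
  structure(out, class = c("target_regions", "data.frame"),
            window_bp = as.integer(window_bp))
}

#' @rdname target_regions
#' @param path BED file (3+ columns, tab-separated, no header).
#' @export
read_targets <- function(path, window_bp = 50L) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  target_regions(data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]]),
                 window_bp = window_bp)
}

#' Read an MEI call set from VCF, BED or TSV
#'
#' Normalises the heterogeneous formats MEI callers emit into a [callset()]:
#'
#' * `vcf`: `POS` is taken as the 1-based breakpoint. The element class is
#'   read from a symbolic ALT allele of the form `<INS:ME:ALU>` when present,
#'   else from the INFO key `class_field`. SR/DP come from INFO keys
#'   `sr_field`/`dp_field` (0 when absent), `QUAL` becomes `quality`, and
#'   non-`PASS` FILTER tokens (e.g. `ac0`) become flags.
#' * `bed`: 4+ columns `chrom start end [class [score [strand]]]`, 0-based
#'   half-open. Single-base records convert as `start + 1`; wider intervals
#'   (as some callers report) use the interval midpoint as the breakpoint.
#' * `tsv`: the tab-separated dialect written by [write_callset()]; column
#'   names can be remapped through `col_map` and `one_based = FALSE` declares
#'   0-based input positions.
#'
#' Unrecognised class labels map to `"unknown"` with a warning; malformed
#' records raise an error naming the offending line.
#'
#' @param path input file.
#' @param format one of `"vcf"`, `"bed"`, `"tsv"`.
#' @param sample_id,tool provenance attached to every call (overrides any
#'   columns of the same name for `bed`/`vcf` input).
#' @param assay `"ES"` or `"GS"`.
#' @param class_field,sr_field,dp_field INFO keys used for VCF input.
#' @param col_map named character vector mapping the canonical column names
#'   to the file's column names, for `tsv` input.
#' @param one_based for `tsv` input: positions are 1-based (default) or
#'   0-based.
#' @return A [callset()].
#' @export
read_callset <- function(path, format = c("tsv", "vcf", "bed"),
                         sample_id = "sample", tool = "tool",
                         assay = c("ES", "GS"),
                         class_field = "MEICLASS", sr_field = "SR",
                         dp_field = "DP", col_map = NULL, one_based = TRUE) {
  format <- match.arg(format)
  assay <- match.arg(assay)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    vcf = read_callset_vcf(path, sample_id, tool, assay,
                           class_field, sr_field, dp_field),
    bed = read_callset_bed(path, sample_id, tool, assay),
    tsv = read_callset_tsv(path, sample_id, tool, assay, col_map, one_based))
}

read_callset_vcf <- function(path, sample_id, tool, assay,
                             class_field, sr_field, dp_field) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(callset(NULL, assay = assay, provenance = path))
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos))
    stop("unparseable POS in VCF record ", which(is.na(pos))[1], " of ", path)
  # class: symbolic ALT <INS:ME:XXX> preferred, INFO key as fallback
  alt_cls <- rep(NA_character_, nrow(fix))
  m <- regmatches(fix$ALT, regexec("<INS:ME:([^:>]+)>?", fix$ALT))
  found <- vapply(m, length, 1L) == 2L
  alt_cls[found] <- vapply(m[found], `[`, "", 2L)
  info_cls <- vcfR::extract.info(v, element = class_field)
  raw_cls <- ifelse(is.na(alt_cls), info_cls, alt_cls)
  sr <- suppressWarnings(as.integer(vcfR::extract.info(v, element = sr_field)))
  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, element = dp_field)))
  sr[is.na(sr)] <- 0L
  dp[is.na(dp)] <- 0L
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  filt <- fix$FILTER
  filt[is.na(filt) | filt %in% c(".", "PASS")] <- ""
  callset(data.frame(
    sample_id = sample_id, chrom = fix$CHROM, breakpoint = pos,
    mei_class = map_mei_class(raw_cls), strand = "*",
    split_reads = sr, discordant_pairs = dp, quality = qual,
    tool = tool, flags = gsub(";", ",", filt),
    stringsAsFactors = FALSE), assay = assay, provenance = path)
}

read_callset_bed <- function(path, sample_id, tool, assay) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bed) < 3L) stop("BED input needs >= 3 columns: ", path)
  start <- suppressWarnings(as.integer(bed[[2]]))
  end <- suppressWarnings(as.integer(bed[[3]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("unparseable BED coordinates at line ", bad[1], " of ", path)
  # single-base feature -> start+1; wider interval -> midpoint of the
  # 1-based closed interval [start+1, end] (TEMP2-style interval calls)
  bp <- as.integer(floor((start + 1L + end) / 2))
  cls <- if (ncol(bed) >= 4L) map_mei_class(bed[[4]]) else "unknown"
  strand <- if (ncol(bed) >= 6L) ifelse(bed[[6]] %in% c("+", "-"), bed[[6]], "*") else "*"
  callset(data.frame(
    sample_id = sample_id, chrom = bed[[1]], breakpoint = bp,
    mei_class = cls, strand = strand, tool = tool,
    stringsAsFactors = FALSE), assay = assay, provenance = path)
}

read_callset_tsv <- function(path, sample_id, tool, assay, col_map, one_based) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, comment.char = "",
                   na.strings = c("NA", "."), quote = "")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(df))
        stop("mapped column '", col_map[[canon]], "' absent from ", path)
      names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  need <- c("chrom", "breakpoint")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("TSV input lacks required column(s): ", paste(miss, collapse = ", "))
  bp <- suppressWarnings(as.integer(df$breakpoint))
  bad <- which(is.na(bp) & !is.na(df$breakpoint) | is.na(df$breakpoint))
  if (length(bad))
    stop("unparseable breakpoint at data line ", bad[1], " of ", path)
  df$breakpoint <- if (one_based) bp else bp + 1L
  if (!"sample_id" %in% names(df)) df$sample_id <- sample_id
  if (!"tool" %in% names(df)) df$tool <- tool
  if ("mei_class" %in% names(df)) df$mei_class <- map_mei_class(df$mei_class)
  callset(df, assay = assay, provenance = path)
}

#' Write a call set to TSV or a minimal VCF
#'
#' The TSV dialect round-trips all fields through
#' `read_callset(format = "tsv")`; the VCF output stores class, SR and DP in
#' INFO and flags in FILTER.
#'
#' @param x a [callset()].
#' @param path output file.
#' @param format `"tsv"` or `"vcf"`.
#' @export
write_callset <- function(x, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- as.data.frame(x)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
  } else {
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=MEICLASS,Number=1,Type=String,Description=\"Mobile element class\">",
             "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Split/clipped read support\">",
             "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Discordant pair support\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    rows <- character(0)
    if (nrow(x)) {
      alt <- sprintf("<INS:ME:%s>", toupper(ifelse(x$mei_class == "unknown",
                                                   "UNK", x$mei_class)))
      filt <- ifelse(nzchar(x$flags), gsub(",", ";", x$flags), "PASS")
      qual <- ifelse(is.na(x$quality), ".", format(x$quality, trim = TRUE))
      info <- sprintf("MEICLASS=%s;SR=%d;DP=%d", x$mei_class,
                      x$split_reads, x$discordant_pairs)
      rows <- sprintf("%s\t%d\t.\tN\t%s\t%s\t%s\t%s",
                      x$chrom, x$breakpoint, alt, qual, filt, info)
    }
    writeLines(c(hdr, rows), path)
  }
  invisible(path)
}

#' Restrict calls to exome target regions
#'
#' Keeps the calls whose breakpoint falls within any target interval expanded
#' by `window_bp` on each side, i.e. within the 1-based closed interval
#' `[start + 1 - window_bp, end + window_bp]`. Order is preserved and the
#' operation is idempotent.
#'
#' @param x a [callset()].
#' @param targets a [target_regions()] object.
#' @return The filtered [callset()].
#' @export
restrict_to_target_regions <- function(x, targets) {
  stopifnot(inherits(targets, "target_regions"))
  if (nrow(targets) == 0L) stop("target region set is empty")
  if (nrow(x) == 0L) return(x)
  w <- attr(targets, "window_bp")
  keep <- points_in_intervals(x$chrom, x$breakpoint, targets$chrom,
                              targets$start + 1L - w, targets$end + w)
  as_callset_like(as.data.frame(x)[keep, , drop = FALSE], x)
}

#' Read/write a reference MEI set as TSV
#'
#' Tab-separated with header columns `chrom`, `breakpoint`, `tsd_start`,
#' `tsd_end`, `mei_class` (`NA` for unknown TSDs).
#'
#' @param path file path.
#' @return [reference_mei()] data frame.
#' @export
read_reference_mei <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("NA", "."))
  reference_mei(df)
}

#' @rdname read_reference_mei
#' @param x a [reference_mei()] data frame.
#' @export
write_reference_mei <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}
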