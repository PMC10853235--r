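# Internal helpers shared across modules.

#' @importFrom stats median qnorm rbinom rnbinom rnorm runif setNames complete.cases
#' @importFrom utils read.table write.table
NULL

MEI_CLASSES <- c("Alu", "L1", "SVA", "unknown")
REF_CLASSES <- c("Alu", "L1", "SVA")

# Strip the "chr" prefix so GRCh37 dialects compare equal.
norm_chrom <- function(x) sub("^chr", "", as.character(x))

# Map free-text element labels onto the canonical classes; anything
# unrecognised becomes "unknown" (callers use heterogeneous vocabularies).
map_mei_class <- function(x, warn = TRUE) {
  key <- toupper(trimws(as.character(x)))
  out <- rep("unknown", length(key))
  out[key %in% c("ALU", "ALUY", "ALUYA5", "ALUYB8", "SINE/ALU")] <- "Alu"
  out[key %in% c("L1", "LINE1", "LINE-1", "LINE/L1", "L1HS")] <- "L1"
  out[key %in% c("SVA", "SVA_E", "SVA_F", "RETROPOSON/SVA")] <- "SVA"
  bad <- out == "unknown" & !key %in% c("UNKNOWN", "", "NA", ".")
  if (warn && any(bad)) {
    warning(sprintf("unrecognised MEI class label(s) mapped to 'unknown': %s",
                    paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  out
}

# Half-up rounding of a proportion rendered as percent with `digits` decimals.
round_half_up <- function(x, digits = 3) {
  floor(x * 10^digits + 0.5) / 10^digits
}

percent_str <- function(p, digits = 3) {
  sprintf(paste0("%.", digits, "f%%"), round_half_up(100 * p, digits))
}

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so simulators are deterministic and isolated.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Membership of 1-based points in a set of closed 1-based intervals,
# chromosome-aware. Overlapping intervals are merged, then membership is a
# sorted lookup (findInterval); called in per-sample inner loops, so kept
# allocation-light.
points_in_intervals <- function(chrom, pos, int_chrom, int_lo, int_hi) {
  hit <- logical(length(pos))
  if (length(pos) == 0L || length(int_lo) == 0L) return(hit)
  chrom <- norm_chrom(chrom)
  int_chrom <- norm_chrom(int_chrom)
  int_hi <- pmax(int_lo, int_hi)
  for (ch in unique(chrom)) {
    pi <- which(chrom == ch)
    ii <- which(int_chrom == ch)
    if (length(ii) == 0L) next
    o <- order(int_lo[ii])
    lo <- int_lo[ii][o]
    hi <- int_hi[ii][o]
    run_hi <- cummax(hi)
    new_grp <- c(TRUE, lo[-1] > run_hi[-length(hi)] + 0)
    mlo <- lo[new_grp]
    mhi <- run_hi[c(which(new_grp)[-1] - 1L, length(hi))]
    idx <- findInterval(pos[pi], mlo)
    hit[pi] <- idx >= 1L & pos[pi] <= mhi[pmax(idx, 1L)]
  }
  hit
}
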