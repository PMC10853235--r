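#' Diagnostic yield with a Wald (normal-approximation) 95% CI
#'
#' Proportion `successes / n` with the normal-approximation interval
#' `p +/- z * sqrt(p (1 - p) / n)`, the lower bound clipped at 0. Percent
#' rendering uses half-up rounding to 3 decimals, e.g.
#' `wald_ci(3, 6247)` prints `0.048% [0.000%-0.102%]`.
#'
#' @param successes number of successes (e.g. new diagnoses).
#' @param n number of trials (e.g. cohort size), `> 0`.
#' @param level confidence level (default 0.95).
#' @return An object of class `proportion_estimate`: list with `successes`,
#'   `n`, `proportion`, `ci_low`, `ci_high`, `level`.
#' @export
wald_ci <- function(successes, n, level = 0.95) {
  if (n <= 0) stop("n must be positive")
  if (successes < 0 || successes > n) stop("need 0 <= successes <= n")
  p <- successes / n
  hw <- qnorm(1 - (1 - level) / 2) * sqrt(p * (1 - p) / n)
  structure(list(successes = as.integer(successes), n = as.integer(n),
                 proportion = p, ci_low = max(0, p - hw), ci_high = p + hw,
                 level = level),
            class = "proportion_estimate")
}

#' @rdname wald_ci
#' @param x a `proportion_estimate`.
#' @param digits decimals of the percent rendering (default 3).
#' @param ... unused.
#' @export
format.proportion_estimate <- function(x, digits = 3, ...) {
  sprintf("%s [%s–%s]", percent_str(x$proportion, digits),
          percent_str(x$ci_low, digits), percent_str(x$ci_high, digits))
}

#' @export
print.proportion_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%d/%d = %s (Wald %g%% CI)\n", x$successes, x$n,
              format(x, digits = digits), 100 * x$level))
  invisible(x)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Probability-mass definition of the two-sided p value: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed the observed table's (the classical
#' convention, as in [stats::fisher.test()]). A degenerate margin gives
#' p = 1.
#'
#' @param a,b,c,d cell counts, row-wise: `rbind(c(a, b), c(c, d))`.
#' @return two-sided p value.
#' @examples
#' fisher_exact_2x2(3, 6244, 7, 33502)  # > 0.05
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    return(1.0)
  stats::fisher.test(matrix(counts, nrow = 2, byrow = TRUE))$p.value
}

#' Clinical sensitivity per tool and tool concordance
#'
#' Given the sets of validated disease-causing cases each tool detected,
#' returns the fraction of cases detected per tool and the concordance: the
#' fraction of cases detected by every tool simultaneously.
#'
#' @param detections named list: tool -> character vector of detected case
#'   ids (must be a subset of `cases`).
#' @param cases character vector of all validated case ids.
#' @return list with `sensitivity` (named numeric per tool) and
#'   `concordance`.
#' @export
clinical_sensitivity <- function(detections, cases) {
  if (length(cases) == 0L) stop("empty case set")
  stray <- setdiff(unlist(detections, use.names = FALSE), cases)
  if (length(stray))
    stop("detected case(s) outside the case set: ", paste(stray, collapse = ", "))
  sens <- vapply(detections, function(d) length(unique(d)) / length(cases),
                 numeric(1))
  shared <- Reduce(intersect, detections)
  list(sensitivity = sens, concordance = length(shared) / length(cases))
}
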