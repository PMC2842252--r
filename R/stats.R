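# Statistical procedures: one-sided Fisher exact enrichment with Bonferroni
# correction, one-sided Wilcoxon-Mann-Whitney comparisons, orthologue
# conservation observed/expected.

#' One-sided Fisher exact enrichment test with Bonferroni correction
#'
#' Tests whether the proportion `k_set / n_set` is enriched (or depleted)
#' relative to `k_rest / n_rest` via the one-sided Fisher exact test on the
#' 2x2 table `[[k_set, n_set - k_set], [k_rest, n_rest - k_rest]]`. The
#' Bonferroni family size `m` must be stated explicitly (there is no
#' defensible default for a family of tests).
#'
#' @param k_set,n_set Count and total in the gene set of interest.
#' @param k_rest,n_rest Count and total in the comparison set.
#' @param side `"enriched"` or `"depleted"` (the alternative).
#' @param m Bonferroni family size (default 1 = no correction).
#' @return An object of class `enrichment_result`: percentages, raw and
#'   adjusted p, direction, significance at adjusted 0.05.
#' @export
enrichment_test <- function(k_set, n_set, k_rest, n_rest,
                            side = c("enriched", "depleted"), m = 1) {
  side <- match.arg(side)
  counts <- c(k_set, n_set, k_rest, n_rest)
  if (any(counts < 0) || k_set > n_set || k_rest > n_rest)
    stop("invalid counts: need 0 <= k <= n in both groups")
  if (m < 1) stop("'m' must be >= 1")
  tab <- matrix(c(k_set, n_set - k_set, k_rest, n_rest - k_rest),
                nrow = 2, byrow = TRUE)
  p <- fisher.test(tab, alternative =
                     if (side == "enriched") "greater" else "less")$p.value
  structure(list(percent_in_set = 100 * k_set / n_set,
                 percent_in_rest = 100 * k_rest / n_rest,
                 p_raw = p, p_bonferroni = min(1, m * p),
                 direction = side,
                 significant = min(1, m * p) < 0.05, m = m,
                 table = tab),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%.1f%% vs %.1f%% (%s): p = %.3g, Bonferroni (m=%d) p = %.3g %s\n",
              x$percent_in_set, x$percent_in_rest, x$direction, x$p_raw,
              x$m, x$p_bonferroni,
              if (x$significant) "*" else "(NS)"))
  invisible(x)
}

#' One-sided Wilcoxon-Mann-Whitney rank comparison
#'
#' Uses the exact null distribution whenever there are no ties and the
#' combined sample size is moderate (at most 200; the exact tail is what a
#' permutation of the ranks converges to), and the normal approximation
#' with continuity and tie correction otherwise. `side = "greater"` tests
#' whether `x` tends to be larger than `y`.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param side `"greater"` or `"less"`.
#' @return The one-sided p-value.
#' @export
rank_comparison_test <- function(x, y, side = c("greater", "less")) {
  side <- match.arg(side)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  exact <- (length(x) + length(y)) <= 200 && !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, alternative = side, exact = exact,
                correct = TRUE)$p.value)
}

#' Orthologue conservation of a promoter-element class
#'
#' Given, over `n_pairs` orthologous gene pairs, the number `a` of pairs
#' where only species A carries the element class, `b` where only species B
#' does, and `c` where both do, computes the observed conservation
#' `100 * c / (a + c)` (how often the element in A is also found in the B
#' orthologue) against the conservation expected by chance
#' `100 * b / (n_pairs - a - c)` (how often the element appears in the B
#' orthologue of an A gene lacking it), and a one-sided Fisher exact p for
#' enrichment of the co-occurrence.
#'
#' @param a,b,c Pair counts as above (or a list with fields `a`, `b`, `c`,
#'   `n_pairs` as first argument).
#' @param n_pairs Total orthologous pairs.
#' @return An object of class `conservation_result` with fields
#'   `observed_pct`, `expected_pct`, `p_value` and the inputs.
#' @examples
#' conservation_stats(393, 343, 82, 5805)  # observed 17%, expected 6%
#' @export
conservation_stats <- function(a, b = NULL, c = NULL, n_pairs = 5805) {
  if (is.list(a)) {
    n_pairs <- a$n_pairs %||% n_pairs
    b <- a$b; c <- a$c; a <- a$a
  }
  if (any(c(a, b, c) < 0) || a + b + c > n_pairs)
    stop("need a, b, c >= 0 and a + b + c <= n_pairs")
  if (a + c == 0) stop("a + c must be positive (no element in species A)")
  if (n_pairs - a - c == 0) stop("n_pairs - a - c must be positive")
  observed <- 100 * c / (a + c)
  expected <- 100 * b / (n_pairs - a - c)
  p <- enrichment_test(c, a + c, b, n_pairs - a - c, "enriched")$p_raw
  structure(list(a = a, b = b, c = c, n_pairs = n_pairs,
                 observed_pct = observed, expected_pct = expected,
                 p_value = p),
            class = "conservation_result")
}

#' @export
print.conservation_result <- function(x, ...) {
  cat(sprintf("conservation: observed %d%% vs expected %d%% (a=%d, b=%d, c=%d, N=%d); p = %.1g\n",
              round(x$observed_pct), round(x$expected_pct),
              x$a, x$b, x$c, x$n_pairs, x$p_value))
  invisible(x)
}
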