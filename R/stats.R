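#' Chi-square test of homogeneity between two shell distributions
#'
#' Pearson chi-square on the 2 x K contingency table of shell counts for
#' two conditions, expected counts from the margins, no continuity
#' correction, df = K - 1 (reduced when zero-total shells are dropped).
#' This is the comparison applied to each chromosome's centromere shell
#' distribution in the myoblast vs myocyte contrast.
#'
#' @param countsA,countsB length-K non-negative integer count vectors
#'   (innermost shell first), same K.
#' @param simulate_p if TRUE, a Monte-Carlo p-value is computed instead of
#'   the asymptotic one (B replicates).
#' @param B Monte-Carlo replicates.
#' @return object of class \code{chi_square_result}: statistic, df,
#'   p_value, expected (2 x K kept columns), warning_low_expected.
#' @export
chi_square_homogeneity <- function(countsA, countsB, simulate_p = FALSE,
                                   B = 10000L) {
  stopifnot(length(countsA) == length(countsB),
            all(countsA >= 0), all(countsB >= 0))
  if (sum(countsA) == 0 || sum(countsB) == 0)
    stop("both distributions must have a positive total")
  tab <- rbind(A = as.numeric(countsA), B = as.numeric(countsB))
  drop <- colSums(tab) == 0
  if (any(drop)) {
    warning(sum(drop), " zero-total shell(s) dropped; df reduced")
    tab <- tab[, !drop, drop = FALSE]
  }
  if (ncol(tab) < 2) stop("fewer than 2 informative shells")
  ct <- suppressWarnings(
    stats::chisq.test(tab, correct = FALSE, simulate.p.value = simulate_p,
                      B = B))
  structure(list(statistic = unname(ct$statistic),
                 df = if (simulate_p) NA_integer_ else unname(ct$parameter),
                 p_value = ct$p.value,
                 expected = ct$expected,
                 warning_low_expected = any(ct$expected < 5)),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("chi-square homogeneity: X2 = %.3f, df = %s, p = %.4g%s\n",
              x$statistic, format(x$df), x$p_value,
              if (x$warning_low_expected) " (expected count < 5 present)"
              else ""))
  invisible(x)
}

#' Mann-Whitney U test (two-sided)
#'
#' Wraps the Wilcoxon rank-sum test: exact enumeration when
#' \code{n1 + n2 <= 12} and there are no ties, normal approximation with
#' mid-rank tie correction otherwise. Used for nuclear volume and
#' flattening comparisons, which are typically non-normal.
#'
#' @param x,y numeric samples.
#' @return object of class \code{rank_test_result}: U, p_value, n1, n2,
#'   alternative.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = FALSE))
  structure(list(U = unname(wt$statistic), p_value = wt$p.value,
                 n1 = length(x), n2 = length(y),
                 exact = exact, alternative = "two.sided"),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), %s p = %.4g\n",
              x$U, x$n1, x$n2, if (x$exact) "exact" else "approx",
              x$p_value))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Documents the normality gate applied before falling back to rank tests
#' for morphometry. Errors outside 3 <= n <= 5000 or on constant input.
#'
#' @param x numeric sample.
#' @return list with statistic W and p_value.
#' @export
shapiro_wilk <- function(x) {
  n <- length(x)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")")
  if (length(unique(x)) == 1L)
    stop("degenerate input: all values identical")
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p_value = sw$p.value)
}

#' Reconstruct integer counts from a 2-decimal percentage row
#'
#' Printed shell tables report percentages to two decimals but not the
#' underlying signal counts. This searches exhaustively for the smallest
#' total n <= \code{n_max} such that counts \code{c_k = round(n * p_k /
#' 100)} sum to n and reproduce every percentage exactly at two decimals
#' (round-half-away-from-zero). If no n matches, \code{exact = FALSE} is
#' returned with the least-squares-best n.
#'
#' @param percentages length-K percentage vector summing to 100 +/- 0.05.
#' @param n_max largest total to try.
#' @return object of class \code{count_reconstruction}: percentages, n,
#'   counts, exact.
#' @export
reconstruct_counts <- function(percentages, n_max = 1000L) {
  stopifnot(all(percentages >= 0))
  if (abs(sum(percentages) - 100) > 0.05)
    stop("percentages must sum to 100 within 0.05 (got ",
         sprintf("%.2f", sum(percentages)), ")")
  best <- NULL; bestsse <- Inf
  for (n in seq_len(n_max)) {
    ck <- floor(n * percentages / 100 + 0.5)
    if (sum(ck) != n) {
      sse <- sum((100 * ck / max(sum(ck), 1) - percentages)^2)
      if (sse < bestsse) { bestsse <- sse; best <- list(n = n, counts = ck) }
      next
    }
    if (all(abs(round2(100 * ck / n) - percentages) < 1e-9)) {
      return(structure(list(percentages = percentages, n = as.integer(n),
                            counts = as.integer(ck), exact = TRUE),
                       class = "count_reconstruction"))
    }
    sse <- sum((round2(100 * ck / n) - percentages)^2)
    if (sse < bestsse) { bestsse <- sse; best <- list(n = n, counts = ck) }
  }
  structure(list(percentages = percentages, n = as.integer(best$n),
                 counts = as.integer(best$counts), exact = FALSE),
            class = "count_reconstruction")
}

#' @export
print.count_reconstruction <- function(x, ...) {
  cat("count_reconstruction: n =", x$n, if (x$exact) "(exact)" else
    "(no exact match; least-squares best)", "counts:",
    paste(x$counts, collapse = ", "), "\n")
  invisible(x)
}

#' Fusion index
#'
#' Ratio of the number of nuclei found inside differentiated myotubes to
#' the number of nuclei in undifferentiated cells: FI = Nd / Nud. A
#' measure of in vitro differentiation efficiency.
#'
#' @param n_nuclei_in_myotubes Nd.
#' @param n_nuclei_undiff Nud (> 0).
#' @return the ratio.
#' @export
fusion_index <- function(n_nuclei_in_myotubes, n_nuclei_undiff) {
  stopifnot(n_nuclei_in_myotubes >= 0)
  if (n_nuclei_undiff <= 0)
    stop("number of undifferentiated nuclei must be positive")
  n_nuclei_in_myotubes / n_nuclei_undiff
}

#' Compare shell distributions between two conditions, per probe
#'
#' Runs the 2 x K chi-square homogeneity test for every probe present in
#' both conditions of a shell-distribution table. Per-probe p-values are
#' reported unadjusted (matching per-chromosome reporting practice); an
#' optional Benjamini-Hochberg column can be added.
#'
#' @param dist a \code{shell_distribution} data.frame (two conditions).
#' @param adjust if TRUE, append BH-adjusted p-values.
#' @return data.frame: probe, statistic, df, p_value, significant (< 0.05),
#'   low_expected, and optionally q_value.
#' @export
compare_shell_distributions <- function(dist, adjust = FALSE) {
  conds <- unique(dist$condition)
  if (length(conds) != 2)
    stop("expected exactly 2 conditions, got ", length(conds))
  probes <- intersect(dist$probe[dist$condition == conds[1]],
                      dist$probe[dist$condition == conds[2]])
  cnt <- shell_counts(dist)
  rows <- lapply(probes, function(p) {
    a <- cnt[dist$probe == p & dist$condition == conds[1], ]
    b <- cnt[dist$probe == p & dist$condition == conds[2], ]
    r <- chi_square_homogeneity(a, b)
    data.frame(probe = p, statistic = r$statistic, df = r$df,
               p_value = r$p_value, significant = r$p_value < 0.05,
               low_expected = r$warning_low_expected)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$q_value <- stats::p.adjust(out$p_value, "BH")
  out
}
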