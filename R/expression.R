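#' Quantile-normalize a log2 expression matrix
#'
#' Forces every sample (column) to share the identical value distribution:
#' each column's sorted values are replaced by the row-wise mean of all
#' columns' sorted values; rank ties receive the mean of the tied target
#' values. Delegates to \code{limma::normalizeQuantiles}.
#'
#' @param matrix genes x samples numeric matrix on the log2 scale.
#' @return the normalized matrix (same dimnames).
#' @export
quantile_normalize <- function(matrix) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 2, all(is.finite(matrix)))
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  out
}

# vectorized per-gene Welch (or pooled) two-sample t-test on log2 values
row_t_test <- function(m, g1, g2, pooled = FALSE) {
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(m[, g1, drop = FALSE])
  m2 <- rowMeans(m[, g2, drop = FALSE])
  v1 <- apply(m[, g1, drop = FALSE], 1, var)
  v2 <- apply(m[, g2, drop = FALSE], 1, var)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, nrow(m))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  }
  tstat <- (m2 - m1) / sqrt(se2)
  p <- 2 * pt(-abs(tstat), df)
  # degenerate genes: zero variance in both groups
  degen <- se2 == 0
  if (any(degen)) p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  list(log2_fc = m2 - m1, t = tstat, df = df, p = p,
       n_degenerate = sum(degen))
}

#' Differential expression with a 2-fold filter and BH adjustment
#'
#' Per-gene two-sample t-test (pooled-variance Student t by default;
#' \code{pooled = FALSE} gives Welch) on log2 values,
#' Benjamini-Hochberg adjustment across all tested genes, and
#' classification: \code{up} iff log2 fold change >= \code{fc_threshold}
#' and adjusted p < \code{alpha}; \code{down} iff log2 fold change <=
#' -\code{fc_threshold} and adjusted p < \code{alpha}; otherwise \code{ns}.
#' Fold change is group 2 minus group 1 mean.
#'
#' @param matrix genes x samples log2 matrix with rownames.
#' @param groups two-level factor or vector, one entry per column.
#' @param fc_threshold absolute log2 fold-change cutoff (1 = 2-fold).
#' @param alpha significance level applied to the BH-adjusted p-value (set
#'   \code{adjust = FALSE} to threshold raw p-values instead).
#' @param pooled use the pooled-variance Student t (default). With the
#'   typical triplicate design, Welch's degrees of freedom can drop to 2
#'   and no gene can reach stringent BH-adjusted thresholds regardless of
#'   effect size; the pooled test (df = n1 + n2 - 2) matches classical
#'   microarray practice. Set FALSE for Welch.
#' @param adjust apply BH adjustment (default TRUE).
#' @return data.frame of class \code{de_table}: gene, log2_fc, p, q,
#'   direction.
#' @export
differential_expression <- function(matrix, groups, fc_threshold = 1,
                                    alpha = 0.01, pooled = TRUE,
                                    adjust = TRUE) {
  stopifnot(is.matrix(matrix), ncol(matrix) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  g1 <- which(groups == levels(groups)[1])
  g2 <- which(groups == levels(groups)[2])
  tt <- row_t_test(matrix, g1, g2, pooled = pooled)
  if (tt$n_degenerate > 0)
    message(tt$n_degenerate, " gene(s) with zero variance in both groups")
  q <- if (adjust) p.adjust(tt$p, "BH") else tt$p
  direction <- rep("ns", nrow(matrix))
  direction[tt$log2_fc >= fc_threshold & q < alpha] <- "up"
  direction[tt$log2_fc <= -fc_threshold & q < alpha] <- "down"
  out <- data.frame(gene = rownames(matrix) %||%
                      sprintf("gene%05d", seq_len(nrow(matrix))),
                    log2_fc = tt$log2_fc, p = tt$p, q = q,
                    direction = direction, row.names = NULL)
  class(out) <- c("de_table", "data.frame")
  out
}

#' @export
print.de_table <- function(x, ...) {
  cat("de_table:", nrow(x), "genes;", sum(x$direction == "up"), "up,",
      sum(x$direction == "down"), "down\n")
  NextMethod()
}

#' Map differentially expressed genes onto chromosomes
#'
#' Left-joins gene positions (gene, chromosome, optional cytoband) onto a
#' DE table and tallies up- and down-regulated genes per chromosome, as
#' used to draw ideograms of expression change. Genes without a position
#' are tallied as unmapped.
#'
#' @param records a \code{de_table} from [differential_expression()].
#' @param positions data.frame with columns gene, chromosome and optional
#'   cytoband; gene ids must be unique.
#' @return list with \code{genes} (the annotated per-gene table, ns genes
#'   excluded), \code{tally} (chromosome, up, down), \code{unmapped}.
#' @export
map_to_chromosomes <- function(records, positions) {
  stopifnot(all(c("gene", "chromosome") %in% names(positions)))
  if (anyDuplicated(positions$gene))
    stop("gene ids in the position table must be unique")
  de <- records[records$direction != "ns", , drop = FALSE]
  i <- match(de$gene, positions$gene)
  de$chromosome <- positions$chromosome[i]
  de$cytoband <- if ("cytoband" %in% names(positions))
    positions$cytoband[i] else NA_character_
  unmapped <- sum(is.na(de$chromosome))
  mapped <- de[!is.na(de$chromosome), , drop = FALSE]
  if (nrow(mapped)) {
    tal <- as.data.frame(table(chromosome = mapped$chromosome,
                               direction = factor(mapped$direction,
                                                  c("up", "down"))))
    tally <- stats::reshape(tal, idvar = "chromosome",
                            timevar = "direction", direction = "wide")
    names(tally) <- c("chromosome", "up", "down")
    tally$chromosome <- as.character(tally$chromosome)
    rownames(tally) <- NULL
  } else {
    tally <- data.frame(chromosome = character(), up = integer(),
                        down = integer())
  }
  list(genes = mapped, tally = tally, unmapped = unmapped)
}
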