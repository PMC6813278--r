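#' Per-gene differential expression between marker-high and marker-low
#'
#' Two-sided unpaired t-test per gene (pooled-variance Student t by
#' default, Welch-Satterthwaite optionally), Benjamini-Hochberg adjustment
#' across all tested genes, and the DEG call `q < q_threshold` (default
#' 1e-4, i.e. FDR q < 0.01%). Genes with zero variance in both groups get
#' p = 1 by convention rather than being dropped, which keeps the BH
#' family size stable and is conservative.
#'
#' @param expr An [expression_matrix()].
#' @param strat A `StratificationResult` (see [stratify_by_marker()]).
#' @param variance_mode `"pooled"` (default) or `"welch"`.
#' @param q_threshold DEG threshold on the BH q-value.
#' @return A data.frame of class `DEGTable`, one row per gene, columns
#'   `gene`, `mean_high`, `mean_low`, `delta` (mean_high - mean_low,
#'   log2), `t_stat`, `df`, `p`, `q`, `is_deg`, `direction` ("up"/"down"
#'   in the high group); sorted by `q` ascending then `|delta|`
#'   descending then gene symbol.
#' @export
run_deg <- function(expr, strat, variance_mode = c("pooled", "welch"),
                    q_threshold = 1e-4) {
  variance_mode <- match.arg(variance_mode)
  hi <- strat$high_samples; lo <- strat$low_samples
  if (length(intersect(hi, lo)))
    stop("high and low groups overlap")
  if (length(hi) < 2 || length(lo) < 2)
    stop("both groups need >= 2 samples")
  miss <- setdiff(c(hi, lo), expr$sample_ids)
  if (length(miss))
    stop("samples missing from expression matrix: ",
         paste(utils::head(miss, 3), collapse = ", "))
  xh <- expr$values[, hi, drop = FALSE]
  xl <- expr$values[, lo, drop = FALSE]
  n1 <- length(hi); n2 <- length(lo)
  m1 <- rowMeans(xh); m2 <- rowMeans(xl)
  v1 <- rowSums((xh - m1)^2) / (n1 - 1)
  v2 <- rowSums((xl - m2)^2) / (n2 - 1)
  delta <- m1 - m2
  if (variance_mode == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(delta))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t_stat <- delta / se
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  zerovar <- se == 0 | !is.finite(t_stat)
  t_stat[zerovar] <- 0; p[zerovar] <- 1; df[zerovar & is.na(df)] <- n1 + n2 - 2
  q <- bh_adjust(p)
  out <- data.frame(
    gene = expr$gene_ids, mean_high = m1, mean_low = m2, delta = delta,
    t_stat = t_stat, df = df, p = p, q = q,
    is_deg = q < q_threshold,
    direction = ifelse(delta >= 0, "up", "down"),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$q, -abs(out$delta), out$gene), ]
  rownames(out) <- NULL
  attr(out, "q_threshold") <- q_threshold
  attr(out, "variance_mode") <- variance_mode
  class(out) <- c("DEGTable", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjusted q-values
#'
#' Thin, validated front for `stats::p.adjust(method = "BH")`:
#' `q_i = min over j with p_(j) >= p_(i) of (m * p_(j) / j)`, clipped to 1
#' and mapped back to input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("validation error: p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Volcano export of a DEG table
#'
#' Deterministic table for volcano plots/reports: log2 fold change against
#' -log10 q. Zero q-values are floored to (smallest positive q among the
#' records) / 10 before the log. `common_flag` is a placeholder filled by
#' [cross_cohort_overlap()].
#'
#' @param records A `DEGTable` from [run_deg()].
#' @return data.frame with columns `gene`, `delta`, `neg_log10_q`,
#'   `is_deg`, `common_flag`, sorted by gene symbol.
#' @export
volcano_table <- function(records) {
  if (nrow(records) == 0) stop("DEG table is empty")
  q <- records$q
  floor_q <- if (any(q > 0)) min(q[q > 0]) / 10 else .Machine$double.xmin
  q[q == 0] <- floor_q
  out <- data.frame(gene = records$gene, delta = records$delta,
                    neg_log10_q = -log10(q), is_deg = records$is_deg,
                    common_flag = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$gene), ]
  rownames(out) <- NULL
  out
}
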