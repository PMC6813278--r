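#' Split a cohort into marker-high and marker-low groups
#'
#' Samples are sorted by marker expression descending (ties broken by
#' sample id ascending); the high group is the first `floor(q * n)`
#' samples and the low group is everything else. This mirrors the usual
#' "top q% by marker" stratification (e.g. 30% KIT-high in an n = 88
#' neuroblastoma cohort gives 26 high vs 62 low).
#'
#' @param expr An [expression_matrix()].
#' @param marker Gene symbol present in `expr`.
#' @param q High-group fraction, 0 < q < 1 with `floor(q*n) >= 2`.
#' @return A list of class `StratificationResult`: `marker`, `q_strat`,
#'   `high_samples`, `low_samples`, `n_high`, `n_low`, `history`
#'   (empty data.frame for fixed-q mode), `converged` (TRUE).
#' @export
stratify_by_marker <- function(expr, marker, q) {
  marker <- toupper(marker)
  if (!marker %in% expr$gene_ids)
    stop(sprintf("unknown gene: marker '%s' not in expression matrix", marker))
  if (q <= 0 || q >= 1) stop("q must be strictly between 0 and 1")
  n <- length(expr$sample_ids)
  n_high <- floor(q * n)
  if (n_high < 2 || n - n_high < 2)
    stop("degenerate group size: both groups need >= 2 samples")
  vals <- expr$values[marker, ]
  ord <- order(-vals, expr$sample_ids)
  ids <- expr$sample_ids[ord]
  structure(
    list(marker = marker, q_strat = q,
         high_samples = ids[seq_len(n_high)],
         low_samples = ids[-seq_len(n_high)],
         n_high = n_high, n_low = n - n_high,
         history = data.frame(q = numeric(0), deg_count = integer(0)),
         converged = TRUE),
    class = "StratificationResult")
}

#' @export
print.StratificationResult <- function(x, ...) {
  cat(sprintf("Stratification by %s: q = %.2f, %d high / %d low%s\n",
              x$marker, x$q_strat, x$n_high, x$n_low,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  if (nrow(x$history))
    cat("  adaptive history:",
        paste(sprintf("%.2f:%d", x$history$q, x$history$deg_count),
              collapse = " "), "\n")
  invisible(x)
}

#' Adaptive percentile search for the marker-high fraction
#'
#' Evaluates high-group fractions `q0, q0+step, ...` up to `q_max` and
#' stops at the first fraction whose DEG count reaches `m_min` ("selected
#' starting from 10 with 5% increments until a considerable number of DEGs
#' were identified" — the count deemed considerable is exposed as
#' `m_min`). If no fraction reaches `m_min`, the fraction with the largest
#' count is returned (smallest q on ties) and `converged` is FALSE.
#'
#' @param expr An [expression_matrix()].
#' @param marker Gene symbol.
#' @param deg_counter Function mapping a `StratificationResult` to a DEG
#'   count; must be deterministic for a given split. See
#'   [make_deg_counter()].
#' @param q0,step,q_max Search grid (defaults 0.10, 0.05, 0.50).
#' @param m_min Minimum DEG count considered "considerable" (default 50).
#' @return A `StratificationResult` whose `history` records every
#'   (q, deg_count) visited.
#' @export
adaptive_stratify <- function(expr, marker, deg_counter, q0 = 0.10,
                              step = 0.05, m_min = 50, q_max = 0.50) {
  if (m_min < 1) stop("config error: m_min must be >= 1")
  if (q0 >= q_max) stop("config error: q0 must be < q_max")
  qs <- seq(q0, q_max, by = step)
  history <- data.frame(q = numeric(0), deg_count = integer(0))
  chosen <- NULL
  for (q in qs) {
    s <- stratify_by_marker(expr, marker, q)
    cnt <- as.integer(deg_counter(s))
    history <- rbind(history, data.frame(q = q, deg_count = cnt))
    if (cnt >= m_min) { chosen <- q; break }
  }
  converged <- !is.null(chosen)
  if (!converged)
    chosen <- history$q[which.max(history$deg_count)]  # ties -> smaller q
  out <- stratify_by_marker(expr, marker, chosen)
  out$history <- history
  out$converged <- converged
  out
}

#' Standard DEG counter for the adaptive search
#'
#' Returns a closure counting genes with BH q below `q_threshold` under
#' [run_deg()] for a given split.
#'
#' @param expr An [expression_matrix()].
#' @param q_threshold FDR threshold (default 1e-4, i.e. q < 0.01%).
#' @param variance_mode `"pooled"` or `"welch"`.
#' @return `function(strat) -> integer`.
#' @export
make_deg_counter <- function(expr, q_threshold = 1e-4,
                             variance_mode = c("pooled", "welch")) {
  variance_mode <- match.arg(variance_mode)
  function(strat) {
    deg <- run_deg(expr, strat, variance_mode = variance_mode,
                   q_threshold = q_threshold)
    sum(deg$is_deg)
  }
}
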