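#' Kaplan-Meier product-limit estimate
#'
#' Classical product-limit estimator over distinct death times: at each
#' time with at least one death, S is multiplied by (1 - d_i/n_i).
#' Censored-only times shrink the risk set but add no step.
#'
#' @param times Positive survival times.
#' @param events Event flags (1 = death, 0 = censored).
#' @return A list of class `SurvivalCurve`: `event_times` (distinct times
#'   with >= 1 death), `at_risk`, `deaths`, `survival` (S just after each
#'   event time), plus `n` and a `survival_at(t)` convenience via
#'   [km_survival_at()].
#' @export
km_estimate <- function(times, events) {
  if (length(times) != length(events) || length(times) < 1)
    stop("times and events must be equal-length, non-empty")
  if (any(!is.finite(times)) || any(times <= 0))
    stop("validation error: times must be positive")
  if (!all(events %in% c(0, 1)))
    stop("validation error: events must be 0/1")
  ord <- order(times)
  t_s <- times[ord]; e_s <- events[ord]
  dt <- sort(unique(t_s[e_s == 1]))
  n_at <- vapply(dt, function(x) sum(t_s >= x), numeric(1))
  d <- vapply(dt, function(x) sum(t_s == x & e_s == 1), numeric(1))
  S <- cumprod(1 - d / n_at)
  structure(list(event_times = dt, at_risk = n_at, deaths = d,
                 survival = S, n = length(times)),
            class = "SurvivalCurve")
}

#' Evaluate a survival curve at given times
#' @param curve A `SurvivalCurve`.
#' @param t Times at which to evaluate S(t).
#' @return S(t), with S = 1 before the first death.
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(x) {
    i <- sum(curve$event_times <= x)
    if (i == 0) 1 else curve$survival[i]
  }, numeric(1))
}

#' @export
print.SurvivalCurve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d death times, S(last) = %.4f\n",
              x$n, length(x$event_times),
              if (length(x$survival)) x$survival[length(x$survival)] else 1))
  invisible(x)
}

#' @export
plot.SurvivalCurve <- function(x, xlab = "Time (days)",
                               ylab = "Survival probability", ...) {
  tt <- c(0, rep(x$event_times, each = 2))
  ss <- c(1, 1, rep(x$survival, each = 2)[-(2 * length(x$survival))])
  plot(tt, ss, type = "l", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' At each distinct death time the hypergeometric expectation and variance
#' of group-A deaths are accumulated; the statistic is
#' `(O1 - E1)^2 / V` with an upper-tail 1-df chi-squared p-value. A totally
#' uninformative comparison (V = 0) returns p = 1 by convention.
#'
#' @param timesA,eventsA,timesB,eventsB Per-group times and event flags.
#' @return A list of class `LogRankResult`: `observed` (O1), `expected`
#'   (E1), `variance` (V), `chi2`, `p`.
#' @export
logrank_test <- function(timesA, eventsA, timesB, eventsB) {
  if (length(timesA) < 1 || length(timesB) < 1)
    stop("both groups must be non-empty")
  times <- c(timesA, timesB); events <- c(eventsA, eventsB)
  if (sum(events) < 1) stop("at least one death required overall")
  grp1 <- c(rep(TRUE, length(timesA)), rep(FALSE, length(timesB)))
  dt <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (x in dt) {
    at <- times >= x
    n_i <- sum(at); n1_i <- sum(at & grp1)
    d_i <- sum(times == x & events == 1)
    d1_i <- sum(times == x & events == 1 & grp1)
    O1 <- O1 + d1_i
    E1 <- E1 + d_i * n1_i / n_i
    if (n_i > 1)
      V <- V + d_i * (n1_i / n_i) * (1 - n1_i / n_i) * (n_i - d_i) / (n_i - 1)
  }
  chi2 <- if (V > 0) (O1 - E1)^2 / V else 0
  p <- if (V > 0) stats::pchisq(chi2, df = 1, lower.tail = FALSE) else 1
  structure(list(observed = O1, expected = E1, variance = V,
                 chi2 = chi2, p = p),
            class = "LogRankResult")
}

#' @export
print.LogRankResult <- function(x, ...) {
  cat(sprintf("Log-rank: O1 = %g, E1 = %.3f, chi2 = %.3f, p = %.4g\n",
              x$observed, x$expected, x$chi2, x$p))
  invisible(x)
}

#' Kaplan-Meier cutoff scan for one gene
#'
#' Scans every admissible expression cutoff of a gene (midpoints between
#' consecutive distinct sorted values leaving at least `min_group` samples
#' on each side), log-rank-tests high (`x > cutoff`) versus low at each,
#' and Bonferroni-corrects the smallest p by the number of cutoffs
#' actually evaluated. Direction comes from the sign of observed minus
#' expected deaths in the high group at the best cutoff: more deaths than
#' expected = unfavorable.
#'
#' Internally all cutoffs are evaluated at once: with samples ordered by
#' expression descending, the high group at successive cutoffs grows by
#' one sample, so group-1 at-risk and death counts at every death time are
#' column cumulative sums — the whole scan is a few matrix products.
#'
#' @param gene_values Named per-sample expression values (names = sample
#'   ids) or an unnamed vector aligned to `clinical`.
#' @param clinical A [clinical_table()].
#' @param min_group Minimum samples on each side of a cutoff. Default
#'   `max(8, ceiling(0.1 * n))`.
#' @param alpha Significance level on the Bonferroni-corrected p.
#' @return A list of class `KaplanScanRecord`: `gene`, `best_cutoff`,
#'   `n_high`, `n_low`, `k_tests`, `p_min`, `p_bonf`, `significant`,
#'   `direction` ("unfavorable"/"favorable"/NA), `evaluable`.
#' @export
kaplan_scan <- function(gene_values, clinical, min_group = NULL,
                        alpha = 0.05, gene = "gene") {
  n <- nrow(clinical)
  if (is.null(min_group)) min_group <- max(8, ceiling(0.1 * n))
  if (min_group < 2) stop("min_group must be >= 2")
  if (!is.null(names(gene_values))) {
    miss <- setdiff(clinical$sample_id, names(gene_values))
    if (length(miss))
      stop("misaligned sample ids between expression and clinical")
    gene_values <- gene_values[clinical$sample_id]
  } else if (length(gene_values) != n) {
    stop("misaligned sample ids between expression and clinical")
  }
  not_eval <- structure(
    list(gene = gene, best_cutoff = NA_real_, n_high = NA_integer_,
         n_low = NA_integer_, k_tests = 0L, p_min = NA_real_,
         p_bonf = NA_real_, significant = FALSE, direction = NA_character_,
         evaluable = FALSE),
    class = "KaplanScanRecord")
  ord <- order(-gene_values, clinical$sample_id)
  x <- gene_values[ord]
  t_s <- clinical$os_time[ord]; e_s <- clinical$os_event[ord]
  # admissible high-group sizes: j in [min_group, n - min_group] at a
  # distinct-value boundary (a cutoff never splits tied samples)
  boundary <- which(x[-n] > x[-1])           # high = first j sorted samples
  js <- boundary[boundary >= min_group & boundary <= n - min_group]
  if (length(js) == 0 || sum(e_s) == 0) return(not_eval)
  dt <- sort(unique(t_s[e_s == 1]))
  Y <- outer(t_s, dt, ">=") * 1               # n x m at-risk indicators
  D <- outer(t_s, dt, "==") * e_s             # n x m death indicators
  N1 <- apply(Y, 2, cumsum)                   # group-1 at risk for every j
  D1 <- apply(D, 2, cumsum)
  n_i <- N1[n, ]; d_i <- D1[n, ]
  O1 <- rowSums(D1[js, , drop = FALSE])
  E1 <- as.vector(N1[js, , drop = FALSE] %*% (d_i / n_i))
  w <- ifelse(n_i > 1, d_i * (n_i - d_i) / (n_i^2 * (n_i - 1)), 0)
  V <- as.vector(N1[js, , drop = FALSE] %*% (w * n_i) -
                 (N1[js, , drop = FALSE]^2) %*% w)
  chi2 <- ifelse(V > 0, (O1 - E1)^2 / V, 0)
  p <- ifelse(V > 0, stats::pchisq(chi2, df = 1, lower.tail = FALSE), 1)
  k <- length(js)
  best <- which.min(p)
  j_best <- js[best]
  p_min <- p[best]
  p_bonf <- min(1, k * p_min)
  structure(
    list(gene = gene,
         best_cutoff = (x[j_best] + x[j_best + 1]) / 2,
         n_high = j_best, n_low = n - j_best, k_tests = k,
         p_min = p_min, p_bonf = p_bonf,
         significant = p_bonf < alpha,
         direction = if (O1[best] > E1[best]) "unfavorable" else "favorable",
         evaluable = TRUE),
    class = "KaplanScanRecord")
}

#' @export
print.KaplanScanRecord <- function(x, ...) {
  if (!x$evaluable) {
    cat(sprintf("Kaplan scan [%s]: not evaluable\n", x$gene))
  } else {
    cat(sprintf(
      "Kaplan scan [%s]: cutoff %.3f (%d high/%d low), %d cutoffs, p_min %.3g, Bonferroni p %.3g%s (%s)\n",
      x$gene, x$best_cutoff, x$n_high, x$n_low, x$k_tests, x$p_min, x$p_bonf,
      if (x$significant) " *" else "", x$direction))
  }
  invisible(x)
}

#' Kaplan-Meier cutoff scan over many genes
#'
#' @param expr An [expression_matrix()].
#' @param clinical A [clinical_table()]; sample ids must all be present in
#'   `expr`.
#' @param genes Gene symbols to scan (default all).
#' @inheritParams kaplan_scan
#' @return data.frame of class `KaplanScanTable`, one row per gene with
#'   the `KaplanScanRecord` fields, in the order of `genes`.
#' @export
kaplan_scan_all <- function(expr, clinical, genes = NULL, min_group = NULL,
                            alpha = 0.05) {
  if (is.null(genes)) genes <- expr$gene_ids
  miss <- setdiff(clinical$sample_id, expr$sample_ids)
  if (length(miss))
    stop("misaligned sample ids between expression and clinical")
  vals <- expr$values[, clinical$sample_id, drop = FALSE]
  rows <- lapply(genes, function(g)
    as.data.frame(unclass(kaplan_scan(unname(vals[g, ]), clinical,
                                      min_group = min_group, alpha = alpha,
                                      gene = g)),
                  stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("KaplanScanTable", "data.frame")
  out
}

#' Label genes by prognosis from a Kaplan-scan table
#'
#' Scan-significant genes (Bonferroni p < `alpha`) keep their direction
#' label; everything else is "ns".
#'
#' @param records A `KaplanScanTable` (or list of `KaplanScanRecord`s).
#' @param alpha Significance level.
#' @return Named character vector gene -> "unfavorable"/"favorable"/"ns",
#'   with an attribute `counts` giving the per-label tally.
#' @export
prognostic_classify <- function(records, alpha = 0.05) {
  if (!is.data.frame(records))
    records <- do.call(rbind, lapply(records, function(r)
      as.data.frame(unclass(r), stringsAsFactors = FALSE)))
  sig <- records$evaluable & records$p_bonf < alpha
  lab <- ifelse(sig, records$direction, "ns")
  out <- setNames(lab, records$gene)
  attr(out, "counts") <- c(unfavorable = sum(lab == "unfavorable"),
                           favorable = sum(lab == "favorable"),
                           ns = sum(lab == "ns"))
  out
}
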