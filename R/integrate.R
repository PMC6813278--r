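#' Per-set prognostic value from Kaplan-scan labels
#'
#' A gene "correlates with prognosis" when its scan label is not "ns"
#' (Bonferroni p < alpha, either direction). Each set scores the
#' percentage of its measured members that are prognostic, then a min-max
#' normalization across all scored sets maps the percents to [0, 1] — the
#' cyan-to-pink value channel of the landscape. When every set has the
#' same percent, all normalized scores are 0 (with a warning).
#'
#' @param sets A [gene_set_collection()].
#' @param scan_labels Named gene -> label vector from
#'   [prognostic_classify()].
#' @param universe Measured gene symbols (default: names of
#'   `scan_labels`).
#' @param low_support Sets with fewer measured members than this are
#'   flagged (default 5).
#' @return data.frame of class `SetPrognosticScore`: `set_name`,
#'   `n_measured`, `n_prognostic`, `percent`, `normalized`,
#'   `low_support`; sets with no measured member are skipped with a
#'   message. Sorted by set name.
#' @export
set_prognostic_value <- function(sets, scan_labels, universe = NULL,
                                 low_support = 5) {
  if (is.null(universe)) universe <- names(scan_labels)
  rows <- lapply(names(sets$sets), function(nm) {
    members <- intersect(sets$sets[[nm]], universe)
    if (length(members) == 0) return(NULL)
    lab <- scan_labels[members]
    n_prog <- sum(!is.na(lab) & lab != "ns")
    data.frame(set_name = nm, n_measured = length(members),
               n_prognostic = n_prog,
               percent = 100 * n_prog / length(members),
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0)
    message(sprintf("set_prognostic_value: %d set(s) with no measured member skipped",
                    skipped))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no set intersects the measured universe")
  rng <- range(out$percent)
  if (diff(rng) == 0) {
    warning("all sets have identical prognostic percent; normalized scores set to 0")
    out$normalized <- 0
  } else {
    out$normalized <- (out$percent - rng[1]) / diff(rng)
  }
  out$low_support <- out$n_measured < low_support
  out <- out[order(out$set_name), ]
  rownames(out) <- NULL
  class(out) <- c("SetPrognosticScore", "data.frame")
  out
}

#' Cross-cohort DEG overlap report
#'
#' Intersects DEG lists across conditions by (uppercased) gene symbol and
#' marks, per condition, which DEGs are shared with every other condition
#' — the "common DEGs marked red" view of paired volcano plots.
#'
#' @param deg_tables Named list: condition -> `DEGTable` (or a character
#'   vector of DEG symbols).
#' @return A list of class `OverlapReport`: `conditions`, `deg_lists`
#'   (named list of DEG symbol vectors), `comparisons` (data.frame of
#'   pairs with `n_common`), `common_genes` (named list per pair,
#'   sorted), `membership` (per condition, data.frame gene/common_flag).
#' @export
cross_cohort_overlap <- function(deg_tables) {
  if (length(deg_tables) < 2) stop("need at least two conditions")
  if (is.null(names(deg_tables)) || any(names(deg_tables) == ""))
    stop("conditions must be named")
  deg_lists <- lapply(deg_tables, function(tab) {
    if (is.data.frame(tab)) sort(toupper(tab$gene[tab$is_deg]))
    else sort(toupper(as.character(tab)))
  })
  empty <- names(deg_lists)[lengths(deg_lists) == 0]
  if (length(empty))
    warning("condition(s) with empty DEG list: ", paste(empty, collapse = ", "))
  conds <- names(deg_lists)
  pairs <- utils::combn(conds, 2)
  common <- list(); comp <- NULL
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    key <- paste(a, b, sep = " vs ")
    common[[key]] <- sort(intersect(deg_lists[[a]], deg_lists[[b]]))
    comp <- rbind(comp, data.frame(condition_a = a, condition_b = b,
                                   n_common = length(common[[key]]),
                                   stringsAsFactors = FALSE))
  }
  shared_all <- Reduce(intersect, deg_lists)
  membership <- lapply(deg_lists, function(g)
    data.frame(gene = g, common_flag = g %in% shared_all,
               stringsAsFactors = FALSE))
  structure(list(conditions = conds, deg_lists = deg_lists,
                 comparisons = comp, common_genes = common,
                 membership = membership),
            class = "OverlapReport")
}

#' @export
print.OverlapReport <- function(x, ...) {
  cat(sprintf("DEG overlap across %d conditions (%s)\n",
              length(x$conditions), paste(x$conditions, collapse = ", ")))
  for (j in seq_len(nrow(x$comparisons)))
    cat(sprintf("  %s vs %s: %d common DEGs\n",
                x$comparisons$condition_a[j], x$comparisons$condition_b[j],
                x$comparisons$n_common[j]))
  invisible(x)
}

#' Prognosis-direction distribution of a DEG list
#'
#' @param deg_list Character vector of DEG symbols.
#' @param scan_labels Named gene -> label vector from
#'   [prognostic_classify()]. DEGs with no label count as "ns" (with a
#'   warning).
#' @return Named integer vector `c(unfavorable, favorable, ns)` summing to
#'   `length(deg_list)`.
#' @export
prognosis_distribution <- function(deg_list, scan_labels) {
  deg_list <- toupper(deg_list)
  lab <- scan_labels[deg_list]
  if (anyNA(lab)) {
    warning(sprintf("%d DEG(s) without a scan label counted as ns", sum(is.na(lab))))
    lab[is.na(lab)] <- "ns"
  }
  c(unfavorable = sum(lab == "unfavorable"),
    favorable = sum(lab == "favorable"),
    ns = sum(lab == "ns"))
}

#' Spearman association between two genes
#'
#' Rank correlation with average ranks for ties; the p-value comes from
#' `stats::cor.test(method = "spearman")` (exact for small untied samples,
#' the usual approximation otherwise).
#'
#' @param expr An [expression_matrix()].
#' @param gene_a,gene_b Gene symbols.
#' @return List with `rho` and `p`.
#' @export
marker_association <- function(expr, gene_a, gene_b) {
  gene_a <- toupper(gene_a); gene_b <- toupper(gene_b)
  for (g in c(gene_a, gene_b))
    if (!g %in% expr$gene_ids) stop(sprintf("unknown gene '%s'", g))
  xa <- expr$values[gene_a, ]; xb <- expr$values[gene_b, ]
  if (length(xa) < 5) stop("need at least 5 samples")
  if (stats::sd(xa) == 0 || stats::sd(xb) == 0)
    stop("constant gene: Spearman correlation undefined")
  ct <- suppressWarnings(stats::cor.test(xa, xb, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Compare a gene's expression between two clinical subgroups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test via
#' `stats::wilcox.test`: exact when both subgroups have at most 8 samples
#' and no ties, tie-corrected normal approximation otherwise.
#'
#' @param expr An [expression_matrix()].
#' @param clinical A [clinical_table()] with subgroup labels.
#' @param gene Gene symbol.
#' @param group_a,group_b Subgroup labels to compare.
#' @return List with `U` (the Mann-Whitney statistic for `group_a`),
#'   `p`, `n_a`, `n_b`.
#' @export
subgroup_compare <- function(expr, clinical, gene, group_a, group_b) {
  gene <- toupper(gene)
  if (!gene %in% expr$gene_ids) stop(sprintf("unknown gene '%s'", gene))
  for (g in c(group_a, group_b))
    if (!g %in% clinical$subgroup)
      stop(sprintf("unknown subgroup label '%s'", g))
  ids_a <- clinical$sample_id[clinical$subgroup == group_a]
  ids_b <- clinical$sample_id[clinical$subgroup == group_b]
  xa <- expr$values[gene, ids_a]; xb <- expr$values[gene, ids_b]
  exact <- length(xa) <= 8 && length(xb) <= 8
  wt <- suppressWarnings(stats::wilcox.test(xa, xb, exact = exact,
                                            correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value,
       n_a = length(xa), n_b = length(xb))
}
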