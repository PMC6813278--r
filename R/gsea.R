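#' Rank all genes by Pearson correlation with a phenotype vector
#'
#' The continuous-phenotype ranking used here correlates every gene with a
#' per-sample phenotype (typically the marker gene's own expression). When
#' `exclude` names the marker, its row is dropped from the ranked list —
#' its self-correlation of 1 would trivially dominate any set containing
#' it. Zero-variance genes get r = 0. Ordering is metric descending with
#' ties broken by gene symbol ascending.
#'
#' @param expr An [expression_matrix()].
#' @param phenotype Per-sample numeric vector aligned to
#'   `expr$sample_ids` (or named by sample id).
#' @param exclude Gene symbols to drop from the ranked list (default none).
#' @return A list of class `RankedList`: `genes` (ordered), `metric`
#'   (Pearson r per gene, same order), `phenotype`.
#' @export
rank_by_pearson <- function(expr, phenotype, exclude = character(0)) {
  if (!is.null(names(phenotype))) {
    if (!all(expr$sample_ids %in% names(phenotype)))
      stop("phenotype names do not cover all samples")
    phenotype <- phenotype[expr$sample_ids]
  }
  if (length(phenotype) != length(expr$sample_ids))
    stop("phenotype length must match the number of samples")
  if (stats::sd(phenotype) == 0)
    stop("constant phenotype: Pearson ranking undefined")
  keep <- setdiff(expr$gene_ids, toupper(exclude))
  v <- expr$values[keep, , drop = FALSE]
  r <- suppressWarnings(as.vector(stats::cor(t(v), phenotype)))
  r[!is.finite(r)] <- 0  # zero-variance genes
  ord <- order(-r, keep)
  structure(list(genes = keep[ord], metric = r[ord], phenotype = phenotype),
            class = "RankedList")
}

#' Weighted running-sum enrichment score for one gene set
#'
#' Kolmogorov-Smirnov-like statistic: walking down the ranked list, the
#' running sum gains `|r|^p_w / sum(|r_hits|^p_w)` at member genes and
#' loses `1/(N - N_hit)` elsewhere; ES is the running-sum value of maximal
#' absolute deviation, sign retained (positive ties win). The leading edge
#' is the members at or before the maximum (at or after the minimum for
#' negative ES).
#'
#' @param ranked A [rank_by_pearson()] result.
#' @param members Character vector of member gene symbols.
#' @param p_w Weight exponent (default 1; 0 gives the classical
#'   unweighted KS statistic).
#' @return List with `ES`, `running_sum` (length N), `leading_edge`,
#'   `size_measured`; or `NULL` (with a warning) when the set has no
#'   member in — or covers all of — the ranked list.
#' @export
enrichment_score <- function(ranked, members, p_w = 1) {
  N <- length(ranked$genes)
  hit <- ranked$genes %in% toupper(members)
  N_hit <- sum(hit)
  if (N_hit == 0) { warning("set skipped: no member in ranked list"); return(NULL) }
  if (N_hit == N) { warning("set skipped: covers every ranked gene"); return(NULL) }
  w <- abs(ranked$metric)^p_w
  denom <- sum(w[hit])
  inc <- numeric(N)
  if (denom > 0) inc[hit] <- w[hit] / denom else inc[hit] <- 1 / N_hit
  inc[!hit] <- -1 / (N - N_hit)
  rs <- cumsum(inc)
  i_max <- which.max(rs); i_min <- which.min(rs)
  ES <- if (rs[i_max] >= -rs[i_min]) rs[i_max] else rs[i_min]
  le <- if (ES >= 0) ranked$genes[seq_len(i_max)][hit[seq_len(i_max)]]
        else ranked$genes[i_min:N][hit[i_min:N]]
  list(ES = ES, running_sum = rs, leading_edge = le, size_measured = N_hit)
}

#' Phenotype-permutation null ES samples for every set
#'
#' Each permutation shuffles the phenotype vector across samples, re-ranks
#' every gene by Pearson correlation against the shuffled phenotype, and
#' recomputes each set's enrichment score. Seeded and reproducible.
#'
#' @param expr An [expression_matrix()].
#' @param phenotype Per-sample phenotype vector.
#' @param sets A [gene_set_collection()].
#' @param B Number of permutations (>= 10; default 100 — at which FDR
#'   granularity is coarse, as warned).
#' @param seed Integer seed.
#' @param p_w Weight exponent.
#' @param exclude Genes excluded from ranking (the marker row).
#' @return Matrix `length(sets) x B` of null ES values (rownames = set
#'   names); sets skipped in the observed ranking carry NA rows.
#' @export
permutation_null <- function(expr, phenotype, sets, B = 100, seed = 1L,
                             p_w = 1, exclude = character(0)) {
  if (B < 10) stop("config error: B must be >= 10")
  set.seed(seed)
  nullES <- matrix(NA_real_, length(sets$sets), B,
                   dimnames = list(names(sets$sets), NULL))
  phenotype <- unname(phenotype)  # keep the shuffle: no re-alignment by id
  n <- length(phenotype)
  for (b in seq_len(B)) {
    ph <- phenotype[sample.int(n)]
    rk <- rank_by_pearson(expr, ph, exclude = exclude)
    for (s in names(sets$sets)) {
      es <- suppressWarnings(enrichment_score(rk, sets$sets[[s]], p_w = p_w))
      if (!is.null(es)) nullES[s, b] <- es$ES
    }
  }
  nullES
}

#' Normalize ES, permutation p-values and GSEA-style FDR
#'
#' NES divides each ES by the mean magnitude of that set's same-sign null
#' ES values. The nominal p is the add-one permutation tail probability
#' over same-sign nulls. FDR q follows the usual positive/negative-side
#' scheme: the fraction of all null NES at least as extreme divided by the
#' fraction of observed NES at least as extreme, clipped to [0, 1] and
#' monotonized from the extreme inward. The enriched flag is
#' `p_nominal < p_cut` and `fdr_q < q_cut` (defaults 0.05 and 0.25).
#'
#' @param observed Named numeric vector of observed ES per set.
#' @param null Matrix of null ES (sets x B) from [permutation_null()].
#' @param sizes Optional named vector of measured set sizes.
#' @param p_cut,q_cut Significance thresholds on nominal p and FDR q.
#' @return data.frame of class `EnrichmentTable`: `set_name`,
#'   `size_measured`, `ES`, `NES`, `p_nominal`, `fdr_q`, `enriched`,
#'   `evaluable`; rows sorted by `p_nominal` then set name.
#' @export
normalize_and_fdr <- function(observed, null, sizes = NULL,
                              p_cut = 0.05, q_cut = 0.25) {
  sets <- names(observed)
  if (is.null(sets) || !all(sets %in% rownames(null)))
    stop("every observed set needs a matching row of null samples")
  NES <- p_nom <- rep(NA_real_, length(sets))
  names(NES) <- names(p_nom) <- sets
  nes_null <- matrix(NA_real_, length(sets), ncol(null),
                     dimnames = dimnames(null))
  evaluable <- rep(TRUE, length(sets)); names(evaluable) <- sets
  for (s in sets) {
    es <- observed[[s]]; ns <- null[s, ]; ns <- ns[!is.na(ns)]
    pos_m <- mean(ns[ns >= 0]); neg_m <- mean(abs(ns[ns < 0]))
    # normalize the null itself for the FDR pool
    nn <- null[s, ]
    nes_null[s, ] <- ifelse(is.na(nn), NA,
                            ifelse(nn >= 0,
                                   if (is.finite(pos_m) && pos_m > 0) nn / pos_m else NA,
                                   if (is.finite(neg_m) && neg_m > 0) nn / neg_m else NA))
    if (is.na(es)) { evaluable[s] <- FALSE; next }
    if (es == 0) { NES[s] <- 0; p_nom[s] <- 1; next }
    same <- if (es >= 0) ns[ns >= 0] else ns[ns < 0]
    if (length(same) == 0) { evaluable[s] <- FALSE; next }
    scale_m <- mean(abs(same))
    if (!is.finite(scale_m) || scale_m == 0) { evaluable[s] <- FALSE; next }
    NES[s] <- es / scale_m
    p_nom[s] <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  }
  # GSEA FDR on the NES scale, positive and negative sides separately
  fdr <- rep(NA_real_, length(sets)); names(fdr) <- sets
  all_null <- as.vector(nes_null); all_null <- all_null[!is.na(all_null)]
  obs_nes <- NES[evaluable & !is.na(NES)]
  for (s in sets) {
    if (!evaluable[s] || is.na(NES[s])) next
    nes <- NES[s]
    if (nes >= 0) {
      denom_null <- sum(all_null >= 0)
      num <- if (denom_null > 0) sum(all_null >= nes) / denom_null else 0
      denom_obs <- sum(obs_nes >= 0)
      den <- if (denom_obs > 0) sum(obs_nes >= nes) / denom_obs else 1
    } else {
      denom_null <- sum(all_null < 0)
      num <- if (denom_null > 0) sum(all_null <= nes) / denom_null else 0
      denom_obs <- sum(obs_nes < 0)
      den <- if (denom_obs > 0) sum(obs_nes <= nes) / denom_obs else 1
    }
    fdr[s] <- min(1, max(0, if (den > 0) num / den else 0))
  }
  # step-up monotonization: a more extreme NES never has a larger q
  # (each q becomes the min over all equally-or-less-extreme sets' raw q)
  for (sgn in c(1, -1)) {
    idx <- which(evaluable & !is.na(NES) & (if (sgn > 0) NES >= 0 else NES < 0))
    if (length(idx) > 1) {
      ord <- order(if (sgn > 0) -NES[idx] else NES[idx])
      fdr[idx[ord]] <- rev(cummin(rev(fdr[idx[ord]])))
    }
  }
  if (is.null(sizes)) sizes <- setNames(rep(NA_integer_, length(sets)), sets)
  out <- data.frame(
    set_name = sets, size_measured = as.integer(sizes[sets]),
    ES = as.numeric(observed[sets]), NES = NES[sets],
    p_nominal = p_nom[sets], fdr_q = fdr[sets],
    enriched = !is.na(p_nom[sets]) & !is.na(fdr[sets]) &
      p_nom[sets] < p_cut & fdr[sets] < q_cut,
    evaluable = evaluable[sets],
    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p_nominal, out$set_name), ]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}

#' Continuous-phenotype GSEA against a marker gene
#'
#' End-to-end enrichment: Pearson ranking against the marker's expression
#' (marker row excluded from the list), weighted ES per set, a
#' phenotype-permutation null of `B` shuffles, NES, add-one nominal p and
#' GSEA-style FDR. The significance rule is nominal p < 0.05 with
#' FDR < 0.25; permutations default to 100.
#'
#' @param expr An [expression_matrix()].
#' @param marker Marker gene symbol used as the phenotype.
#' @param sets A [gene_set_collection()].
#' @param B Number of phenotype permutations.
#' @param seed Integer seed for the permutation null.
#' @param p_w Weight exponent on |r| (default 1).
#' @param p_cut,q_cut Thresholds for the enriched flag.
#' @return An `EnrichmentTable` (see [normalize_and_fdr()]).
#' @export
run_gsea <- function(expr, marker, sets, B = 100, seed = 1L, p_w = 1,
                     p_cut = 0.05, q_cut = 0.25) {
  marker <- toupper(marker)
  if (!marker %in% expr$gene_ids)
    stop(sprintf("unknown gene: marker '%s' not in expression matrix", marker))
  phenotype <- expr$values[marker, ]
  ranked <- rank_by_pearson(expr, phenotype, exclude = marker)
  observed <- sapply(names(sets$sets), function(s) {
    es <- suppressWarnings(enrichment_score(ranked, sets$sets[[s]], p_w = p_w))
    if (is.null(es)) NA_real_ else es$ES
  })
  sizes <- sapply(names(sets$sets), function(s)
    sum(ranked$genes %in% sets$sets[[s]]))
  nullES <- permutation_null(expr, phenotype, sets, B = B, seed = seed,
                             p_w = p_w, exclude = marker)
  normalize_and_fdr(observed, nullES, sizes = sizes,
                    p_cut = p_cut, q_cut = q_cut)
}
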