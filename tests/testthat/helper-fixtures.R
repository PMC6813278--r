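# Shared fixtures and independent oracles. Every oracle here is coded
# directly from the textbook definition, separately from the package path
# it checks.

make_expr <- function(values, genes = NULL, samples = NULL, name = "test") {
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, dataset_name = name)
}

make_strat <- function(high, low, marker = "M", q = NA_real_) {
  structure(list(marker = marker, q_strat = q, high_samples = high,
                 low_samples = low, n_high = length(high),
                 n_low = length(low),
                 history = data.frame(q = numeric(0), deg_count = integer(0)),
                 converged = TRUE),
            class = "StratificationResult")
}

make_ranked <- function(genes, metric) {
  structure(list(genes = genes, metric = metric, phenotype = NULL),
            class = "RankedList")
}

# --- Benjamini-Hochberg step-up, brute force --------------------------
bh_oracle <- function(p) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in seq_len(m)) {
      if (p[j] >= p[i]) {
        rank_j <- sum(p <= p[j])  # step-up rank of p_(j)
        cand <- min(cand, m * p[j] / rank_j)
      }
    }
    q[i] <- min(1, cand)
  }
  q
}

# --- product-limit estimator, brute force -----------------------------
km_oracle <- function(times, events) {
  dt <- sort(unique(times[events == 1]))
  S <- 1
  out <- numeric(length(dt))
  for (i in seq_along(dt)) {
    n_i <- sum(times >= dt[i])
    d_i <- sum(times == dt[i] & events == 1)
    S <- S * (1 - d_i / n_i)
    out[i] <- S
  }
  list(event_times = dt, survival = out)
}

# --- classical unweighted KS enrichment statistic, brute force --------
ks_es_oracle <- function(N, hit_positions) {
  Nh <- length(hit_positions)
  rs <- 0; best <- 0
  for (i in seq_len(N)) {
    rs <- rs + if (i %in% hit_positions) 1 / Nh else -1 / (N - Nh)
    if (abs(rs) > abs(best) ||
        (abs(rs) == abs(best) && rs > best)) best <- rs
  }
  best
}

# --- Resnik similarity by explicit ancestor enumeration ---------------
ancestors_oracle <- function(onto, term) {
  out <- term
  repeat {
    more <- unique(unlist(onto$parents[out]))
    more <- setdiff(more, out)
    if (!length(more)) return(out)
    out <- c(out, more)
  }
}

resnik_oracle <- function(t1, t2, onto) {
  # IC recomputed here from scratch by descendant enumeration
  desc <- function(t) {
    out <- t
    frontier <- t
    while (length(frontier)) {
      frontier <- unique(unlist(onto$children[frontier]))
      frontier <- setdiff(frontier, out)
      out <- c(out, frontier)
    }
    out
  }
  closure <- function(t) unique(unlist(onto$annotations[desc(t)]))
  total <- length(closure(onto$root))
  ic <- function(t) {
    k <- length(closure(t))
    if (k == 0) NA_real_ else -log(k / total)
  }
  common <- intersect(ancestors_oracle(onto, t1), ancestors_oracle(onto, t2))
  vals <- vapply(common, ic, numeric(1))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) 0 else max(vals)
}

# --- all permutations of 1..n (for exact rank-test oracles) -----------
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (i in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  out
}

# mean silhouette width of a labelled 2D embedding
silhouette_mean <- function(coords, labels) {
  D <- as.matrix(dist(coords))
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i]); own <- setdiff(own, i)
    a <- if (length(own)) mean(D[i, own]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
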