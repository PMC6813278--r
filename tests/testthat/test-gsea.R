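test_that("Pearson ranking orders genes by correlation with the phenotype", {
  set.seed(14)
  ph <- rnorm(20)
  vals <- rbind(SELF = ph, ANTI = -ph, FLAT = rep(1, 20),
                matrix(rnorm(5 * 20), 5, 20,
                       dimnames = list(sprintf("R%d", 1:5), NULL)))
  colnames(vals) <- sprintf("S%03d", 1:20)
  ex <- expression_matrix(vals, dataset_name = "t")
  rk <- rank_by_pearson(ex, ph)
  expect_equal(rk$genes[1], "SELF"); expect_equal(rk$metric[1], 1)
  expect_equal(rk$genes[length(rk$genes)], "ANTI")
  expect_equal(rk$metric[length(rk$metric)], -1)
  expect_equal(rk$metric[rk$genes == "FLAT"], 0)
  # marker exclusion drops the phenotype's own row
  rk2 <- rank_by_pearson(ex, ph, exclude = "SELF")
  expect_false("SELF" %in% rk2$genes)
  # consistent sample permutation leaves the list unchanged
  shuf <- sample(20)
  ex2 <- expression_matrix(vals[, shuf], dataset_name = "t2")
  rk3 <- rank_by_pearson(ex2, ph[shuf])
  expect_identical(rk3$genes, rk$genes)
  expect_equal(rk3$metric, rk$metric)
  expect_error(rank_by_pearson(ex, rep(2, 20)), "constant phenotype")
})

test_that("enrichment score reproduces the hand-walked 4-gene fixtures", {
  rk <- make_ranked(c("A", "B", "C", "D"), c(0.9, 0.5, -0.2, -0.8))
  top <- enrichment_score(rk, "A")
  expect_equal(top$ES, 1.0)            # hit increment 0.9/0.9 at position 1
  expect_equal(top$leading_edge, "A")
  bottom <- enrichment_score(rk, "D")
  expect_equal(bottom$ES, -1.0)        # trough -1 after three misses
  expect_equal(bottom$leading_edge, "D")
  expect_warning(enrichment_score(rk, "ZZZ"), "no member")
  expect_warning(enrichment_score(rk, c("A", "B", "C", "D")), "every ranked gene")
})

test_that("p_w = 0 equals the classical unweighted KS statistic", {
  set.seed(15)
  for (i in 1:100) {
    N <- sample(10:60, 1)
    genes <- sprintf("G%03d", 1:N)
    metric <- sort(rnorm(N), decreasing = TRUE)
    hits <- sort(sample(N, sample(1:(N - 1), 1)))
    es <- enrichment_score(make_ranked(genes, metric), genes[hits], p_w = 0)
    expect_equal(es$ES, ks_es_oracle(N, hits), tolerance = 1e-12)
  }
})

test_that("singleton sets match their closed-form extrema", {
  # one hit at position k: candidates are rs[k] = w - (k-1)/(N-1) and
  # rs[k-1] = -(k-1)/(N-1); with p_w = 1 the hit increment is exactly 1
  set.seed(16)
  for (i in 1:500) {
    N <- sample(5:40, 1)
    genes <- sprintf("G%03d", 1:N)
    metric <- sort(round(rnorm(N), 3), decreasing = TRUE)
    k <- sample(N, 1)
    if (metric[k] == 0) next
    es <- enrichment_score(make_ranked(genes, metric), genes[k], p_w = 1)
    up <- 1 - (k - 1) / (N - 1)
    down <- -(k - 1) / (N - 1)
    closed <- if (up >= -down) up else down
    expect_equal(es$ES, closed, tolerance = 1e-12)
  }
})

test_that("reversing the list with negated metrics flips the ES sign", {
  set.seed(17)
  for (i in 1:50) {
    N <- sample(8:40, 1)
    genes <- sprintf("G%03d", 1:N)
    metric <- sort(rnorm(N), decreasing = TRUE)
    hits <- sample(N, 3)
    fwd <- enrichment_score(make_ranked(genes, metric), genes[hits])
    rev_ <- enrichment_score(make_ranked(rev(genes), rev(-metric)), genes[hits])
    expect_equal(abs(rev_$ES), abs(fwd$ES), tolerance = 1e-12)
    # signs flip except at an exact max = -min tie, where the documented
    # tie-break makes both positive
    if (fwd$ES < 0 || rev_$ES < 0)
      expect_equal(rev_$ES, -fwd$ES, tolerance = 1e-12)
  }
})

test_that("weighted ES agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  set.seed(18)
  for (i in 1:50) {
    N <- sample(20:80, 1)
    metric <- sort(rnorm(N), decreasing = TRUE)
    genes <- sprintf("G%03d", 1:N)
    hits <- sort(sample(N, sample(2:10, 1)))
    ours <- enrichment_score(make_ranked(genes, metric), genes[hits], p_w = 1)
    ref <- fgsea::calcGseaStat(metric, hits, gseaParam = 1)
    expect_equal(ours$ES, ref, tolerance = 1e-9)
  }
})

test_that("permutation null is seeded, sized B and destroys real signal", {
  set.seed(19)
  vals <- matrix(rnorm(30 * 24), 30, 24,
                 dimnames = list(sprintf("G%03d", 1:30), sprintf("S%03d", 1:24)))
  ex <- expression_matrix(vals, dataset_name = "null")
  ph <- rnorm(24)
  sets <- gene_set_collection(list(S1 = sprintf("G%03d", 1:5),
                                   S2 = sprintf("G%03d", 10:18)))
  a <- permutation_null(ex, ph, sets, B = 100, seed = 5)
  b <- permutation_null(ex, ph, sets, B = 100, seed = 5)
  expect_identical(a, b)
  expect_equal(dim(a), c(2L, 100L))
  expect_true(all(is.finite(a)))
  expect_error(permutation_null(ex, ph, sets, B = 5), "B must be >= 10")
  # under a null cohort, observed ES and null ES are indistinguishable
  obs <- vapply(names(sets$sets), function(s)
    enrichment_score(rank_by_pearson(ex, ph), sets$sets[[s]])$ES, numeric(1))
  ks <- suppressWarnings(ks.test(obs, as.vector(a)))
  expect_gt(ks$p.value, 0.01)
})

test_that("NES, nominal p and the enriched flag follow the conventions", {
  nullES <- rbind(STRONG = abs(rnorm(100, 0.3, 0.05)),
                  ZERO = rnorm(100, 0, 0.2))
  obs <- c(STRONG = 0.9, ZERO = 0)
  tab <- normalize_and_fdr(obs, nullES)
  strong <- tab[tab$set_name == "STRONG", ]
  expect_equal(strong$p_nominal, 1 / 101, tolerance = 1e-12)
  expect_equal(strong$NES, 0.9 / mean(nullES["STRONG", ]), tolerance = 1e-12)
  zero <- tab[tab$set_name == "ZERO", ]
  expect_equal(zero$NES, 0); expect_false(zero$enriched)
  # enriched requires both thresholds
  expect_true(all(tab$p_nominal[tab$enriched] < 0.05))
  expect_true(all(tab$fdr_q[tab$enriched] < 0.25))
})

test_that("nominal permutation p-values are super-uniform under the null", {
  set.seed(20)
  vals <- matrix(rnorm(40 * 20), 40, 20,
                 dimnames = list(sprintf("G%03d", 1:40), sprintf("S%03d", 1:20)))
  ex <- expression_matrix(vals, dataset_name = "null")
  sets <- gene_set_collection(lapply(setNames(1:8, sprintf("SET%d", 1:8)),
                                     function(i) sprintf("G%03d", (4 * i - 3):(4 * i))))
  # correlate against a fresh random phenotype each replicate
  R <- 25
  pvals <- c()
  for (r in 1:R) {
    ph <- rnorm(20)
    ranked <- rank_by_pearson(ex, ph)
    obs <- vapply(names(sets$sets), function(s)
      enrichment_score(ranked, sets$sets[[s]])$ES, numeric(1))
    nullES <- permutation_null(ex, ph, sets, B = 40, seed = r)
    pvals <- c(pvals, normalize_and_fdr(obs, nullES)$p_nominal)
  }
  grid <- seq(0.05, 0.95, by = 0.05)
  ecdf_vals <- vapply(grid, function(g) mean(pvals <= g), numeric(1))
  expect_true(all(ecdf_vals <= grid + 2 / sqrt(length(pvals))))
})
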