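test_that("set prognostic percents and min-max normalization are exact", {
  sets <- gene_set_collection(list(
    S10 = sprintf("G%02d", 1:10),   # 3 prognostic of 10 -> 30%
    S0 = sprintf("G%02d", 11:15),   # 0%
    S60 = sprintf("G%02d", 16:20),  # 3 of 5 -> 60%
    TINY = c("G01", "G02")))        # low support
  labels <- setNames(rep("ns", 20), sprintf("G%02d", 1:20))
  labels[c("G01", "G02", "G03")] <- "unfavorable"
  labels[c("G16", "G17")] <- "favorable"; labels["G18"] <- "unfavorable"
  sc <- set_prognostic_value(sets, labels)
  sc_map <- setNames(sc$percent, sc$set_name)
  expect_equal(sc_map[["S10"]], 30)
  expect_equal(sc_map[["S0"]], 0)
  expect_equal(sc_map[["S60"]], 60)
  expect_equal(sc_map[["TINY"]], 100)  # both members prognostic
  nm <- setNames(sc$normalized, sc$set_name)
  expect_equal(nm[["S0"]], 0); expect_equal(nm[["S10"]], 0.3)
  expect_equal(nm[["S60"]], 0.6); expect_equal(nm[["TINY"]], 1)
  expect_true(sc$low_support[sc$set_name == "TINY"])
  # degenerate all-equal case: all normalized 0 with a warning
  expect_warning(
    sc0 <- set_prognostic_value(sets, setNames(rep("ns", 20), sprintf("G%02d", 1:20))),
    "identical")
  expect_true(all(sc0$normalized == 0))
  # sets outside the universe are skipped
  sets2 <- gene_set_collection(list(IN = c("G01", "G02"), OUT = c("ZZ1", "ZZ2")))
  expect_message(sc2 <- suppressWarnings(set_prognostic_value(sets2, labels)),
                 "skipped")
  expect_equal(sc2$set_name, "IN")
})

test_that("a set of planted prognostic genes outscores a null set", {
  wins <- vapply(1:5, function(s) {
    co <- generate_cohort(cohort_config(n_samples = 200, n_prognostic = 20,
                                        gamma = 1.5, beta_surv = 1,
                                        frac_de = 0, seed = s))
    planted <- names(co$truth$prognostic_genes)
    nulls <- setdiff(co$truth$genes, c(planted, "KIT"))[1:20]
    genes <- c(planted, nulls)
    sc <- kaplan_scan_all(co$expr, co$clinical, genes = genes)
    labels <- prognostic_classify(sc)
    sets <- gene_set_collection(list(PL = planted, NU = nulls))
    val <- set_prognostic_value(sets, labels, universe = genes)
    val$normalized[val$set_name == "PL"] > val$normalized[val$set_name == "NU"]
  }, logical(1))
  expect_true(all(wins))
})

test_that("cross-cohort overlap intersects by symbol, symmetrically", {
  rep_ <- cross_cohort_overlap(list(A = c("G1", "G2", "G3"),
                                    B = c("G2", "G3", "G4")))
  expect_equal(rep_$common_genes[["A vs B"]], c("G2", "G3"))
  expect_equal(rep_$comparisons$n_common, 2L)
  expect_equal(rep_$membership$A$common_flag, c(FALSE, TRUE, TRUE))
  swapped <- cross_cohort_overlap(list(B = c("G2", "G3", "G4"),
                                       A = c("G1", "G2", "G3")))
  expect_equal(swapped$common_genes[["B vs A"]], rep_$common_genes[["A vs B"]])
  none <- cross_cohort_overlap(list(A = "G1", B = "G9"))
  expect_length(none$common_genes[["A vs B"]], 0L)
  expect_warning(cross_cohort_overlap(list(A = "G1", B = character(0))),
                 "empty DEG list")
  expect_error(cross_cohort_overlap(list(A = "G1")), "two conditions")
})

test_that("prognosis distributions tally and conserve the DEG count", {
  labels <- c(G1 = "unfavorable", G2 = "unfavorable", G3 = "favorable",
              G4 = "ns", G5 = "ns")
  d <- prognosis_distribution(c("G1", "G2", "G3", "G4", "G5"), labels)
  expect_equal(d, c(unfavorable = 2L, favorable = 1L, ns = 2L))
  expect_equal(sum(d), 5L)
  expect_equal(prognosis_distribution(character(0), labels),
               c(unfavorable = 0L, favorable = 0L, ns = 0L))
  expect_warning(d2 <- prognosis_distribution(c("G1", "NEW"), labels),
                 "without a scan label")
  expect_equal(sum(d2), 2L)
})

test_that("DE genes with unfavorable loadings skew the DEG distribution", {
  skew_ok <- vapply(1:5, function(s) {
    # beta_de large enough that genes carrying the extra survival-loading
    # variance (gamma) still clear the q < 1e-4 DEG threshold
    co <- generate_cohort(cohort_config(n_samples = 200, frac_de = 0.10,
                                        n_prognostic = 30, gamma = 1.5,
                                        beta_surv = 1, prop_de_up = 1,
                                        beta_de = 2.5,
                                        prognostic_from_de = TRUE,
                                        n_genes = 500, seed = s))
    st <- make_strat(co$truth$high_samples,
                     setdiff(co$expr$sample_ids, co$truth$high_samples))
    deg <- run_deg(co$expr, st)
    degs <- deg$gene[deg$is_deg & deg$gene != "KIT"]
    sc <- kaplan_scan_all(co$expr, co$clinical, genes = degs)
    d <- prognosis_distribution(degs, prognostic_classify(sc))
    d[["unfavorable"]] > d[["favorable"]]
  }, logical(1))
  expect_gte(sum(skew_ok), 4)
})

test_that("Spearman association handles rank-preserving transforms and ties", {
  set.seed(50)
  x <- rnorm(12)
  vals <- rbind(A = x, MONO = exp(2 * x) + 5, REV = -x,
                CONST = rep(1, 12))
  colnames(vals) <- sprintf("S%02d", 1:12)
  ex <- expression_matrix(vals, dataset_name = "t")
  expect_equal(marker_association(ex, "A", "MONO")$rho, 1)
  expect_equal(marker_association(ex, "A", "REV")$rho, -1)
  expect_error(marker_association(ex, "A", "CONST"), "constant gene")
  expect_error(marker_association(ex, "A", "NOPE"), "unknown gene")
})

test_that("Spearman p at n = 6 equals full enumeration over 720 orderings", {
  set.seed(51)
  x <- rnorm(6); y <- rnorm(6)
  vals <- rbind(A = x, B = y); colnames(vals) <- sprintf("S%02d", 1:6)
  ex <- expression_matrix(vals, dataset_name = "t")
  got <- marker_association(ex, "A", "B")
  rhos <- vapply(all_perms(6L), function(p) cor(rank(x), p), numeric(1))
  p_enum <- mean(abs(rhos) >= abs(got$rho) - 1e-12)
  expect_equal(got$p, p_enum, tolerance = 1e-12)
})

test_that("Mann-Whitney subgroup comparison matches exact enumeration", {
  vals <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
                 dimnames = list("GENE", sprintf("S%d", 1:6)))
  ex <- expression_matrix(vals, dataset_name = "t")
  cl <- clinical_table(sprintf("S%d", 1:6), rep(100, 6), rep(1, 6),
                       rep(c("low", "high"), each = 3))
  res <- subgroup_compare(ex, cl, "GENE", "low", "high")
  expect_equal(unname(res$U), 0)
  expect_equal(res$p, 0.1)  # 2/20 label assignments as extreme
  sw <- subgroup_compare(ex, cl, "GENE", "high", "low")
  expect_equal(unname(sw$U), 9 - res$U)
  expect_equal(sw$p, res$p)
  # identical samples in both groups -> p = 1
  vals2 <- matrix(rep(c(1, 2, 3), 2), 1, 6,
                  dimnames = list("GENE", sprintf("S%d", 1:6)))
  ex2 <- expression_matrix(vals2, dataset_name = "t")
  expect_equal(subgroup_compare(ex2, cl, "GENE", "low", "high")$p, 1)
  expect_error(subgroup_compare(ex, cl, "GENE", "low", "nope"),
               "unknown subgroup")
})

test_that("exact and normal-approximation Mann-Whitney p agree at n = 8", {
  set.seed(52)
  ids <- sprintf("S%02d", 1:16)
  cl <- clinical_table(ids, rep(10, 16), rep(1, 16),
                       rep(c("a", "b"), each = 8))
  for (i in 1:100) {
    vals <- matrix(rnorm(16), 1, 16, dimnames = list("G", ids))
    ex <- expression_matrix(vals, dataset_name = "t")
    p_exact <- subgroup_compare(ex, cl, "G", "a", "b")$p
    w <- suppressWarnings(stats::wilcox.test(vals[1, 1:8], vals[1, 9:16],
                                             exact = FALSE, correct = TRUE))
    expect_lt(abs(p_exact - w$p.value), 0.02)
  }
})
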