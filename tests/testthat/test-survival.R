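test_that("product-limit estimate matches the hand-worked fixture", {
  km <- km_estimate(c(2, 3, 3, 5, 7, 8), c(1, 1, 1, 0, 1, 0))
  expect_equal(km$event_times, c(2, 3, 7))
  expect_equal(km_survival_at(km, 2), 5 / 6)
  expect_equal(km_survival_at(km, 3), 0.5)
  expect_equal(km_survival_at(km, 7), 0.25)
  expect_equal(km_survival_at(km, 1), 1)

  none <- km_estimate(c(4, 5), c(0, 0))
  expect_length(none$event_times, 0L)
  expect_equal(km_survival_at(none, 100), 1)

  one <- km_estimate(4, 1)
  expect_equal(km_survival_at(one, 4), 0)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "positive")
})

test_that("product-limit estimate equals independent oracles on random data", {
  set.seed(12)
  for (i in 1:200) {
    n <- sample(3:15, 1)
    times <- sample(1:10, n, replace = TRUE)
    events <- rbinom(n, 1, 0.7)
    if (sum(events) == 0) events[1] <- 1
    km <- km_estimate(times, events)
    ora <- km_oracle(times, events)
    expect_identical(km$event_times, ora$event_times)
    expect_equal(km$survival, ora$survival, tolerance = 1e-14)
    sf <- survival::survfit(survival::Surv(times, events) ~ 1)
    expect_equal(km_survival_at(km, km$event_times),
                 summary(sf, times = km$event_times)$surv, tolerance = 1e-12)
  }
})

test_that("log-rank is symmetric, shift-invariant and null on identical groups", {
  t1 <- c(2, 4, 6, 8); e1 <- c(1, 0, 1, 1)
  same <- logrank_test(t1, e1, t1, e1)
  expect_equal(same$chi2, 0); expect_equal(same$p, 1)
  set.seed(4)
  t2 <- c(1, 3, 5, 9); e2 <- c(1, 1, 0, 1)
  a <- logrank_test(t1, e1, t2, e2)
  b <- logrank_test(t2, e2, t1, e1)
  expect_equal(a$chi2, b$chi2); expect_equal(a$p, b$p)
  shifted <- logrank_test(t1 + 100, e1, t2 + 100, e2)
  expect_equal(a$chi2, shifted$chi2)
  expect_error(logrank_test(numeric(0), numeric(0), t1, e1), "non-empty")
})

test_that("log-rank agrees with survdiff and the permutation tail at small n", {
  # separated groups: all group-A deaths precede any group-B death
  tA <- c(1, 2, 3, 4, 5); eA <- c(1, 1, 1, 1, 0)
  tB <- c(6, 7, 8, 9, 10); eB <- c(1, 1, 0, 1, 0)
  obs <- logrank_test(tA, eA, tB, eB)
  sd <- survival::survdiff(
    survival::Surv(c(tA, tB), c(eA, eB)) ~ rep(1:2, each = 5))
  expect_equal(obs$chi2, unname(sd$chisq), tolerance = 1e-12)
  # permutation oracle: 1e4 random relabelings of the 10 subjects
  set.seed(77)
  times <- c(tA, tB); events <- c(eA, eB)
  chi_perm <- replicate(1e4, {
    idx <- sample(10, 5)
    g <- rep(FALSE, 10); g[idx] <- TRUE
    logrank_test(times[g], events[g], times[!g], events[!g])$chi2
  })
  p_perm <- mean(chi_perm >= obs$chi2 - 1e-12)
  # the 1-df chi-squared reference is asymptotic; at n = 10 it tracks the
  # exact relabeling tail to within a few hundredths
  expect_lt(abs(obs$p - p_perm), 0.03)
})

test_that("cutoff scan counts, Bonferroni and degeneracy follow the rules", {
  set.seed(31)
  n <- 88
  cl <- clinical_table(sprintf("S%03d", 1:n), rexp(n, 1 / 1000) + 1,
                       rbinom(n, 1, 0.6))
  x <- setNames(rnorm(n), cl$sample_id)  # all values distinct
  rec <- kaplan_scan(x, cl, min_group = 8)
  expect_equal(rec$k_tests, 88 - 2 * 8 + 1)  # 73 admissible cutoffs
  expect_equal(rec$p_bonf, min(1, rec$k_tests * rec$p_min))
  expect_true(rec$evaluable)

  const <- kaplan_scan(setNames(rep(1, n), cl$sample_id), cl, min_group = 8)
  expect_false(const$evaluable)
  expect_false(const$significant)

  expect_error(kaplan_scan(setNames(rnorm(5), paste0("X", 1:5)), cl),
               "misaligned")
})

test_that("the vectorized scan reproduces explicit per-cutoff log-rank tests", {
  set.seed(13)
  n <- 40
  cl <- clinical_table(sprintf("S%03d", 1:n), rexp(n, 1 / 500) + 1,
                       rbinom(n, 1, 0.7))
  x <- setNames(round(rnorm(n), 1), cl$sample_id)  # ties likely
  rec <- kaplan_scan(x, cl, min_group = 5)
  # brute force: every midpoint between consecutive distinct values
  v <- sort(unique(unname(x)))
  cuts <- (v[-1] + v[-length(v)]) / 2
  ps <- c()
  for (cut in cuts) {
    hi <- unname(x) > cut
    if (sum(hi) < 5 || sum(!hi) < 5) next
    ps <- c(ps, logrank_test(cl$os_time[hi], cl$os_event[hi],
                             cl$os_time[!hi], cl$os_event[!hi])$p)
  }
  expect_equal(rec$k_tests, length(ps))
  expect_equal(rec$p_min, min(ps), tolerance = 1e-12)
  # p_min can never exceed the median-split p of the same gene
  med <- unname(x) > median(x)
  p_med <- logrank_test(cl$os_time[med], cl$os_event[med],
                        cl$os_time[!med], cl$os_event[!med])$p
  expect_lte(rec$p_min, p_med + 1e-12)
})

test_that("classification labels follow threshold and direction", {
  recs <- data.frame(
    gene = c("A", "B", "C"),
    best_cutoff = 1, n_high = 10L, n_low = 10L, k_tests = 5L,
    p_min = c(0.0098, 0.0102, 0.2),
    p_bonf = c(0.049, 0.051, 1),
    significant = c(TRUE, FALSE, FALSE),
    direction = c("favorable", "unfavorable", "unfavorable"),
    evaluable = TRUE, stringsAsFactors = FALSE)
  lab <- prognostic_classify(recs, alpha = 0.05)
  expect_equal(as.vector(lab), c("favorable", "ns", "ns"))
  expect_equal(attr(lab, "counts"),
               c(unfavorable = 0L, favorable = 1L, ns = 2L))
})

test_that("scan sensitivity rises with the survival effect size", {
  sens <- vapply(c(0.3, 1, 2.5), function(bs) {
    co <- generate_cohort(cohort_config(n_samples = 150, n_genes = 50,
                                        n_prognostic = 15, frac_de = 0,
                                        gamma = 1.5, beta_surv = bs,
                                        seed = 60))
    sc <- kaplan_scan_all(co$expr, co$clinical,
                          genes = names(co$truth$prognostic_genes))
    mean(sc$significant)
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
  expect_gt(sens[3], sens[1])
})
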