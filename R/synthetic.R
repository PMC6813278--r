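#' Configuration for a synthetic tumor cohort
#'
#' The generator emulates a microarray-like cohort: log2 intensities with
#' Gaussian residual noise, one marker gene whose top-`q_true` fraction of
#' samples forms a latent "high" subpopulation, a block of differentially
#' expressed genes shifted in that subpopulation, a block of prognostic
#' genes loading on a standard-normal latent risk factor, exponential
#' survival with hazard proportional to `exp(beta_surv * u)`, and uniform
#' right censoring on `(0, c_max)`.
#'
#' Defaults describe an NB-like cohort of 88 patients (use
#' `n_samples = 237` for the AML-like cohort): 2000 genes, a 30\% marker-high
#' fraction, ~3\% of genes differentially expressed at one log2 unit and a
#' half, and 20 unfavorable prognostic genes. Baseline hazard 5e-4 per day
#' (median survival about 3.8 years) with a 10-year censoring window gives
#' a realistic ~55\% observed-event fraction.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param marker_name Symbol of the marker gene (first row).
#' @param q_true Fraction of samples in the true marker-high subpopulation.
#' @param frac_de Fraction of genes differentially expressed.
#' @param beta_de Log2 effect size of DE genes in the high group.
#' @param sigma Residual SD of log2 expression.
#' @param tau SD of the marker gene's own expression.
#' @param n_prognostic Number of survival-loaded genes.
#' @param gamma Loading of prognostic genes on the latent risk factor.
#' @param beta_surv Log hazard ratio per SD of latent risk.
#' @param lambda0 Baseline exponential hazard, per day.
#' @param c_max Censoring window upper bound, days.
#' @param subgroup_props Named proportions of clinical subgroups (sum 1).
#' @param prop_de_up Fraction of DE genes shifted up in the high group.
#' @param prop_prog_unfavorable Fraction of prognostic genes with positive
#'   loading (high expression = worse survival). Default 1: all planted
#'   prognostic genes are unfavorable.
#' @param prognostic_from_de If TRUE, prognostic genes are drawn from the
#'   DE genes (each carries both the DE shift and the survival loading,
#'   with the survival direction matching the DE direction).
#' @param marker_is_prognostic If TRUE the marker itself also loads on the
#'   latent risk with `+gamma` (mirrors a marker that is both stratifier
#'   and prognostic candidate).
#' @param mu_mean,mu_sd Per-gene baseline means are drawn
#'   Normal(`mu_mean`, `mu_sd`^2) — array-like spread of expression levels.
#' @param seed Integer seed; every generated object is a pure function of
#'   the config including this seed.
#' @return A list of class `CohortConfig`.
#' @export
cohort_config <- function(n_samples = 88, n_genes = 2000,
                          marker_name = "KIT", q_true = 0.30,
                          frac_de = 0.03, beta_de = 1.5, sigma = 1,
                          tau = 1, n_prognostic = 20, gamma = 1.5,
                          beta_surv = 1, lambda0 = 5e-4, c_max = 3650,
                          subgroup_props = c(A = 0.5, B = 0.5),
                          prop_de_up = 0.5, prop_prog_unfavorable = 1,
                          prognostic_from_de = FALSE,
                          marker_is_prognostic = FALSE,
                          mu_mean = 7, mu_sd = 1.5, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "CohortConfig"
  validate_cohort_config(cfg)
  cfg
}

#' Validate a cohort configuration
#' @param cfg A `CohortConfig`.
#' @return `cfg` invisibly; stops on the first violated invariant.
#' @export
validate_cohort_config <- function(cfg) {
  stopifnot_msg <- function(ok, msg) if (!ok) stop("config error: ", msg)
  stopifnot_msg(cfg$n_samples >= 4, "n_samples must be >= 4")
  stopifnot_msg(cfg$n_genes >= 2, "n_genes must be >= 2")
  stopifnot_msg(cfg$q_true > 0 && cfg$q_true < 1, "0 < q_true < 1 required")
  stopifnot_msg(cfg$frac_de >= 0 && cfg$frac_de < 1, "0 <= frac_de < 1 required")
  stopifnot_msg(cfg$sigma > 0, "sigma must be > 0")
  stopifnot_msg(cfg$lambda0 > 0, "lambda0 must be > 0")
  stopifnot_msg(cfg$c_max > 0, "c_max must be > 0")
  stopifnot_msg(abs(sum(cfg$subgroup_props) - 1) < 1e-8,
                "subgroup proportions must sum to 1")
  n_de <- round(cfg$frac_de * cfg$n_genes)
  extra_prog <- if (cfg$prognostic_from_de) 0 else cfg$n_prognostic
  stopifnot_msg(n_de + extra_prog + 1 <= cfg$n_genes,
                "n_prognostic + DE count (+ marker) exceeds n_genes")
  if (cfg$prognostic_from_de)
    stopifnot_msg(cfg$n_prognostic <= n_de,
                  "prognostic_from_de requires n_prognostic <= DE count")
  invisible(cfg)
}

#' Generate a synthetic cohort with planted structure
#'
#' @param config A [cohort_config()].
#' @return A list with elements `expr` ([expression_matrix()]),
#'   `clinical` ([clinical_table()]) and `truth` — a `GroundTruth` list
#'   holding `de_genes` (named direction vector, +1 up / -1 down in the
#'   high group), `prognostic_genes` (named direction vector, +1
#'   unfavorable / -1 favorable), `latent_risk`, `high_samples`,
#'   `enriched_sets` (filled by [generate_genesets()]), and `genes`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_samples; G <- cfg$n_genes
  sample_ids <- sprintf("S%03d", seq_len(n))
  genes <- c(toupper(cfg$marker_name), sprintf("G%04d", seq_len(G - 1)))

  n_de <- round(cfg$frac_de * G)
  pool <- genes[-1]
  de_genes <- if (n_de > 0) sample(pool, n_de) else character(0)
  n_up <- round(cfg$prop_de_up * n_de)
  de_dir <- setNames(c(rep(1, n_up), rep(-1, n_de - n_up)), de_genes)

  if (cfg$prognostic_from_de) {
    prog_genes <- if (cfg$n_prognostic > 0) sample(de_genes, cfg$n_prognostic)
                  else character(0)
    prog_dir <- de_dir[prog_genes]
  } else {
    rest <- setdiff(pool, de_genes)
    prog_genes <- if (cfg$n_prognostic > 0) sample(rest, cfg$n_prognostic)
                  else character(0)
    n_unf <- round(cfg$prop_prog_unfavorable * cfg$n_prognostic)
    prog_dir <- setNames(
      c(rep(1, n_unf), rep(-1, cfg$n_prognostic - n_unf)), prog_genes)
  }

  mu <- stats::rnorm(G, cfg$mu_mean, cfg$mu_sd)
  names(mu) <- genes

  marker_vals <- mu[1] + stats::rnorm(n, 0, cfg$tau)
  n_high <- max(1L, floor(cfg$q_true * n))
  high <- sample_ids[order(-marker_vals, sample_ids)][seq_len(n_high)]
  in_high <- as.numeric(sample_ids %in% high)

  u <- stats::rnorm(n)  # latent risk, one per sample

  x <- matrix(stats::rnorm(G * n, 0, cfg$sigma), G, n,
              dimnames = list(genes, sample_ids))
  x <- x + mu
  x[1, ] <- marker_vals
  if (n_de > 0)
    x[de_genes, ] <- x[de_genes, ] +
      outer(unname(de_dir) * cfg$beta_de, in_high)
  if (length(prog_genes) > 0)
    x[prog_genes, ] <- x[prog_genes, ] +
      outer(unname(prog_dir) * cfg$gamma, u)
  if (cfg$marker_is_prognostic)
    x[1, ] <- x[1, ] + cfg$gamma * u

  rate <- cfg$lambda0 * exp(cfg$beta_surv * u)
  T_ev <- stats::rexp(n, rate = rate)
  C <- stats::runif(n, 0, cfg$c_max)
  os_time <- pmin(T_ev, C)
  os_event <- as.integer(T_ev <= C)
  os_time <- pmax(os_time, 1e-6)  # guard: positive times

  props <- cfg$subgroup_props
  sub <- sample(rep(names(props),
                    times = .apportion(n, props)))

  truth <- list(de_genes = de_dir, prognostic_genes = prog_dir,
                prognostic_gamma = cfg$gamma, latent_risk = setNames(u, sample_ids),
                high_samples = high, enriched_sets = character(0),
                genes = genes)
  list(expr = expression_matrix(x, dataset_name = sprintf("synthetic_seed%d", cfg$seed)),
       clinical = clinical_table(sample_ids, os_time, os_event, sub),
       truth = truth)
}

# largest-remainder apportionment of n into proportions p (sums to n)
.apportion <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate gene sets with planted enrichment
#'
#' Half of the sets are "enriched": `purity * set_size` members are drawn
#' from the planted genes (up-regulated DE genes by default, mimicking a
#' coherently regulated pathway), the remainder at random; the other half
#' are fully random. Planted set names are recorded in
#' `truth$enriched_sets`.
#'
#' @param config The [cohort_config()] used for the cohort.
#' @param truth `GroundTruth` from [generate_cohort()].
#' @param n_sets Total number of sets (half enriched, half random).
#' @param set_size Members per set.
#' @param purity Fraction of an enriched set drawn from planted genes.
#' @param source `"de_up"`, `"de_down"`, `"de"` (either direction) or
#'   `"prognostic"` — which planted block enriched sets sample from.
#' @param seed Seed for the set draw (default `config$seed + 1`).
#' @return A list `(sets = GeneSetCollection, truth = updated truth)`.
#' @export
generate_genesets <- function(config, truth, n_sets = 10, set_size = 20,
                              purity = 0.8, source = c("de_up", "de_down",
                                                       "de", "prognostic"),
                              seed = NULL) {
  source <- match.arg(source)
  if (is.null(seed)) seed <- config$seed + 1L
  set.seed(seed)
  planted_pool <- switch(source,
    de_up = names(truth$de_genes)[truth$de_genes > 0],
    de_down = names(truth$de_genes)[truth$de_genes < 0],
    de = names(truth$de_genes),
    prognostic = names(truth$prognostic_genes))
  if (set_size > length(truth$genes))
    stop("config error: set_size exceeds n_genes")
  n_planted <- round(purity * set_size)
  if (n_planted > length(planted_pool))
    stop("config error: purity * set_size exceeds available planted genes")
  n_enr <- floor(n_sets / 2)
  sets <- list()
  for (i in seq_len(n_enr)) {
    core <- sample(planted_pool, n_planted)
    rest <- sample(setdiff(truth$genes, core), set_size - n_planted)
    sets[[sprintf("PLANTED_SET_%02d", i)]] <- c(core, rest)
  }
  for (i in seq_len(n_sets - n_enr))
    sets[[sprintf("RANDOM_SET_%02d", i)]] <- sample(truth$genes, set_size)
  truth$enriched_sets <- names(sets)[seq_len(n_enr)]
  desc <- setNames(ifelse(grepl("^PLANTED", names(sets)),
                          "planted enriched set", "random set"), names(sets))
  list(sets = gene_set_collection(sets, desc), truth = truth)
}

#' Generate a tree-shaped ontology with leaf annotations
#'
#' Builds a complete `branching`-ary rooted tree with `n_terms` terms
#' (node `i`'s parent is `ceiling((i-1)/branching)`), then annotates each
#' leaf with a random subset of the cohort's genes. Ancestor annotation
#' counts arise implicitly via descendant closure at information-content
#' time.
#'
#' @param n_terms Number of terms (>= 3).
#' @param branching Children per internal node.
#' @param truth `GroundTruth` supplying the gene universe.
#' @param seed Integer seed.
#' @param genes_per_leaf Genes annotated to each leaf.
#' @return An [ontology_annotations()] object (term ids `T001`, ...).
#' @export
generate_ontology <- function(n_terms, branching = 2, truth, seed = 1L,
                              genes_per_leaf = 5) {
  if (n_terms < 3) stop("config error: n_terms must be >= 3")
  set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n_terms))
  child <- ids[-1]
  parent <- ids[ceiling((seq_len(n_terms)[-1] - 1) / branching)]
  has_child <- ids %in% parent
  leaves <- ids[!has_child]
  annotations <- lapply(setNames(leaves, leaves), function(t)
    sample(truth$genes, min(genes_per_leaf, length(truth$genes))))
  ontology_annotations(data.frame(child = child, parent = parent,
                                  term_name = paste("term", child)),
                       annotations = annotations)
}
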