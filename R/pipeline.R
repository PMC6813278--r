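#' Assemble a pipeline configuration
#'
#' Either a `synthesis` block (a [cohort_config()] plus gene-set and
#' ontology settings) or an `inputs` block of file paths must be given.
#' Per-stage seeds are derived from the global seed by a fixed counter
#' scheme (`seed * 100 + stage index`), so stage-subset reruns stay
#' reproducible.
#'
#' @param synthesis NULL or a list with elements `cohort`
#'   (a [cohort_config()]), `genesets` (arguments for
#'   [generate_genesets()]) and `ontology` (arguments for
#'   [generate_ontology()]). The cohort config's own seed is overridden
#'   by a seed derived from the pipeline's global `seed`.
#' @param inputs NULL or a list of paths: `expression`, `clinical`,
#'   `sets` (GMT), `ontology_dag`, `ontology_annot`.
#' @param marker Marker gene symbol.
#' @param stratification List: `mode` ("fixed" or "adaptive") plus `q`
#'   (fixed) or `q0`, `step`, `m_min`, `q_max` (adaptive).
#' @param deg List: `variance_mode`, `q_threshold`.
#' @param scan List: `min_group` (NULL for the default floor), `alpha`.
#' @param gsea List: `B`, `p_w`, `p_cut`, `q_cut`.
#' @param seed Global integer seed (>= 0).
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(synthesis = list(cohort = cohort_config()),
                            inputs = NULL, marker = "KIT",
                            stratification = list(mode = "fixed", q = 0.30),
                            deg = list(variance_mode = "pooled",
                                       q_threshold = 1e-4),
                            scan = list(min_group = NULL, alpha = 0.05),
                            gsea = list(B = 100, p_w = 1, p_cut = 0.05,
                                        q_cut = 0.25),
                            seed = 1L) {
  cfg <- list(synthesis = synthesis, inputs = inputs, marker = marker,
              stratification = stratification, deg = deg, scan = scan,
              gsea = gsea, seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Validate a pipeline configuration
#'
#' Reporting operation: collects every violated invariant instead of
#' stopping at the first.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of violations (empty when valid), with
#'   attribute `valid`.
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (is.null(config$synthesis) && is.null(config$inputs))
    add("either a synthesis block or an inputs block is required")
  if (!is.null(config$inputs)) {
    need <- c("expression", "clinical")
    for (f in need)
      if (is.null(config$inputs[[f]]))
        add(sprintf("inputs block missing required path '%s'", f))
      else if (!file.exists(config$inputs[[f]]))
        add(sprintf("input path does not exist: %s", config$inputs[[f]]))
  }
  if (!is.null(config$synthesis)) {
    ok <- tryCatch({ validate_cohort_config(config$synthesis$cohort); TRUE },
                   error = function(e) { add(conditionMessage(e)); FALSE })
  }
  st <- config$stratification
  if (!st$mode %in% c("fixed", "adaptive"))
    add("stratification mode must be 'fixed' or 'adaptive'")
  if (st$mode == "fixed" && (is.null(st$q) || st$q <= 0 || st$q >= 1))
    add("fixed stratification needs 0 < q < 1")
  if (st$mode == "adaptive") {
    q0 <- if (is.null(st$q0)) 0.10 else st$q0
    q_max <- if (is.null(st$q_max)) 0.50 else st$q_max
    if (q0 >= q_max) add("adaptive stratification needs q0 < q_max")
    if (!is.null(st$m_min) && st$m_min < 1) add("m_min must be >= 1")
  }
  if (!is.null(config$deg$q_threshold) &&
      (config$deg$q_threshold <= 0 || config$deg$q_threshold >= 1))
    add("deg q_threshold must be in (0, 1)")
  if (!is.null(config$scan$alpha) &&
      (config$scan$alpha <= 0 || config$scan$alpha >= 1))
    add("scan alpha must be in (0, 1)")
  if (!is.null(config$gsea$B) && config$gsea$B < 10)
    add("gsea B must be >= 10")
  if (is.null(config$seed) || is.na(config$seed) || config$seed < 0)
    add("a non-negative integer seed is required")
  attr(v, "valid") <- length(v) == 0
  v
}

.stage_seed <- function(seed, index) (seed * 100L + index) %% .Machine$integer.max

#' Run the full analysis pipeline
#'
#' Stage order: (synthesize or load) -> stratify -> differential
#' expression -> Kaplan-Meier cutoff scan -> GSEA -> per-set prognostic
#' scores -> semantic landscape -> integration. Every stage writes a
#' deterministic report into `out_dir`; identical config + seed yields
#' byte-identical outputs. A stage failure aborts with the stage name;
#' reports written so far are kept and `manifest.json` marks the run
#' incomplete.
#'
#' @param config A [pipeline_config()]; must validate.
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of stages to run (default all); earlier stages a
#'   requested stage depends on are always run in-memory, but only the
#'   requested stages write reports.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("stratify", "deg", "kmscan", "gsea",
                                    "scores", "landscape", "integrate")) {
  viol <- validate_config(config)
  if (!attr(viol, "valid"))
    stop("invalid pipeline config:\n  - ", paste(viol, collapse = "\n  - "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, marker = config$marker,
                   stages_requested = stages, stages_completed = character(0),
                   complete = FALSE,
                   parameters = list(
                     q0 = 0.10, step = 0.05,
                     deg_q_threshold = config$deg$q_threshold,
                     scan_alpha = config$scan$alpha,
                     gsea_B = config$gsea$B,
                     gsea_p_cut = config$gsea$p_cut,
                     gsea_q_cut = config$gsea$q_cut))
  write_manifest <- function() {
    con <- file(file.path(out_dir, "manifest.json"), open = "wb")
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                                null = "null", digits = NA), con)
    close(con)
  }
  res <- list()
  run_stage <- function(name, fun) {
    out <- tryCatch(fun(), error = function(e) {
      write_manifest()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages_completed <<- c(manifest$stages_completed, name)
    out
  }

  # --- data stage -----------------------------------------------------
  res$data <- run_stage("data", function() {
    if (!is.null(config$synthesis)) {
      # the global pipeline seed drives synthesis via the counter scheme,
      # so --seed alone reproduces (or varies) the whole run
      cc <- config$synthesis$cohort
      cc$seed <- .stage_seed(config$seed, 1L)
      cohort <- generate_cohort(cc)
      gs_args <- config$synthesis$genesets
      if (is.null(gs_args)) gs_args <- list()
      gs <- do.call(generate_genesets,
                    c(list(config = cc, truth = cohort$truth), gs_args))
      cohort$truth <- gs$truth
      on_args <- config$synthesis$ontology
      if (is.null(on_args)) on_args <- list(n_terms = 15, branching = 2)
      onto <- do.call(generate_ontology,
                      c(on_args, list(truth = cohort$truth,
                                      seed = .stage_seed(config$seed, 2L))))
      # demo mapping: i-th gene set <-> i-th leaf term
      leaves <- onto$term_ids[lengths(onto$children[onto$term_ids]) == 0]
      term_map <- setNames(rep(leaves, length.out = length(gs$sets$sets)),
                           names(gs$sets$sets))
      list(expr = cohort$expr, clinical = cohort$clinical,
           truth = cohort$truth, sets = gs$sets, onto = onto,
           term_map = term_map)
    } else {
      inp <- config$inputs
      sets <- if (!is.null(inp$sets)) read_gmt(inp$sets) else NULL
      onto <- if (!is.null(inp$ontology_dag))
        read_ontology(inp$ontology_dag, inp$ontology_annot) else NULL
      list(expr = read_expression(inp$expression),
           clinical = read_clinical(inp$clinical),
           truth = NULL, sets = sets, onto = onto,
           term_map = inp$term_map)
    }
  })
  expr <- res$data$expr; clinical <- res$data$clinical

  # --- stratify -------------------------------------------------------
  res$strat <- run_stage("stratify", function() {
    st <- config$stratification
    if (st$mode == "fixed") {
      stratify_by_marker(expr, config$marker, st$q)
    } else {
      counter <- make_deg_counter(
        expr,
        q_threshold = if (is.null(config$deg$q_threshold)) 1e-4
                      else config$deg$q_threshold,
        variance_mode = if (is.null(config$deg$variance_mode)) "pooled"
                        else config$deg$variance_mode)
      adaptive_stratify(expr, config$marker, counter,
                        q0 = if (is.null(st$q0)) 0.10 else st$q0,
                        step = if (is.null(st$step)) 0.05 else st$step,
                        m_min = if (is.null(st$m_min)) 50 else st$m_min,
                        q_max = if (is.null(st$q_max)) 0.50 else st$q_max)
    }
  })
  if ("stratify" %in% stages) {
    s <- res$strat
    write_report(data.frame(field = c("marker", "q_strat", "n_high", "n_low",
                                      "converged"),
                            value = c(s$marker, s$q_strat, s$n_high, s$n_low,
                                      s$converged)),
                 file.path(out_dir, "stratification.tsv"))
    write_report(s$history, file.path(out_dir, "stratification_history.tsv"),
                 allow_empty = TRUE)
  }

  # --- differential expression ---------------------------------------
  res$deg <- run_stage("deg", function()
    run_deg(expr, res$strat,
            variance_mode = if (is.null(config$deg$variance_mode)) "pooled"
                            else config$deg$variance_mode,
            q_threshold = if (is.null(config$deg$q_threshold)) 1e-4
                          else config$deg$q_threshold))
  if ("deg" %in% stages) {
    write_report(res$deg, file.path(out_dir, "deg.tsv"))
    write_report(volcano_table(res$deg), file.path(out_dir, "volcano.tsv"))
  }

  # --- Kaplan-Meier cutoff scan --------------------------------------
  res$scan <- run_stage("kmscan", function()
    kaplan_scan_all(expr, clinical, min_group = config$scan$min_group,
                    alpha = if (is.null(config$scan$alpha)) 0.05
                            else config$scan$alpha))
  res$labels <- prognostic_classify(
    res$scan, alpha = if (is.null(config$scan$alpha)) 0.05
                      else config$scan$alpha)
  if ("kmscan" %in% stages) {
    write_report(res$scan, file.path(out_dir, "kaplan_scan.tsv"))
    write_report(data.frame(gene = names(res$labels),
                            label = unname(res$labels)),
                 file.path(out_dir, "prognostic_labels.tsv"))
  }

  # --- GSEA -----------------------------------------------------------
  if (!is.null(res$data$sets)) {
    res$gsea <- run_stage("gsea", function()
      run_gsea(expr, config$marker, res$data$sets,
               B = if (is.null(config$gsea$B)) 100 else config$gsea$B,
               seed = .stage_seed(config$seed, 5L),
               p_w = if (is.null(config$gsea$p_w)) 1 else config$gsea$p_w,
               p_cut = if (is.null(config$gsea$p_cut)) 0.05
                       else config$gsea$p_cut,
               q_cut = if (is.null(config$gsea$q_cut)) 0.25
                       else config$gsea$q_cut))
    if ("gsea" %in% stages)
      write_report(res$gsea, file.path(out_dir, "gsea.tsv"))

    # --- per-set prognostic scores -----------------------------------
    res$scores <- run_stage("scores", function()
      set_prognostic_value(res$data$sets, res$labels,
                           universe = expr$gene_ids))
    if ("scores" %in% stages)
      write_report(res$scores, file.path(out_dir, "set_scores.tsv"))

    # --- semantic landscape ------------------------------------------
    if (!is.null(res$data$onto)) {
      enriched_rows <- res$gsea[res$gsea$enriched, , drop = FALSE]
      res$landscape <- run_stage("landscape", function() {
        if (nrow(enriched_rows) == 0) return(NULL)
        build_landscape(res$gsea, res$data$onto, scores = res$scores,
                        term_map = res$data$term_map)
      })
      if ("landscape" %in% stages) {
        tab <- if (is.null(res$landscape))
          data.frame(set_name = character(0), term_id = character(0),
                     x = numeric(0), y = numeric(0), size = integer(0),
                     value = numeric(0))
        else
          data.frame(set_name = res$landscape$set_names,
                     term_id = res$landscape$term_ids,
                     x = res$landscape$coords[, 1],
                     y = res$landscape$coords[, 2],
                     size = res$landscape$size_channel,
                     value = res$landscape$value_channel)
        write_report(tab, file.path(out_dir, "landscape.tsv"),
                     allow_empty = TRUE)
      }
    }
  }

  # --- integration summaries -----------------------------------------
  res$distribution <- run_stage("integrate", function()
    prognosis_distribution(res$deg$gene[res$deg$is_deg], res$labels))
  if ("integrate" %in% stages)
    write_report(data.frame(label = names(res$distribution),
                            count = as.integer(res$distribution)),
                 file.path(out_dir, "deg_prognosis_distribution.tsv"))

  manifest$complete <- TRUE
  write_manifest()
  res$manifest <- manifest
  invisible(res)
}
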