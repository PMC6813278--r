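#' Construct an expression matrix object
#'
#' Wraps a genes x samples matrix of log2 expression intensities together
#' with a dataset label. Gene symbols are uppercased and must be unique;
#' use [collapse_duplicates()] first if the source has multi-probe genes.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene symbols) and colnames (sample ids).
#' @param dataset_name Label for the cohort (default "cohort").
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `dataset_name`.
#' @export
expression_matrix <- function(values, dataset_name = "cohort") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols; collapse duplicates before construction")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (!all(is.finite(values)))
    stop("expression values must all be finite (no NA/NaN/Inf)")
  structure(
    list(values = values,
         gene_ids = rownames(values),
         sample_ids = colnames(values),
         dataset_name = dataset_name),
    class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix '%s': %d genes x %d samples (log2)\n",
              x$dataset_name, length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Construct a clinical survival table
#'
#' @param sample_ids Unique sample labels.
#' @param os_time Overall survival time in days (> 0).
#' @param os_event Event flag: 1 = death observed, 0 = censored.
#' @param subgroup Optional categorical label per sample (karyotype,
#'   tumor type, ...); NA allowed.
#' @return A `data.frame` of class `ClinicalTable` with columns
#'   `sample_id`, `os_time`, `os_event`, `subgroup`.
#' @export
clinical_table <- function(sample_ids, os_time, os_event, subgroup = NULL) {
  n <- length(sample_ids)
  if (length(os_time) != n || length(os_event) != n)
    stop("sample_ids, os_time and os_event must have equal length")
  if (anyDuplicated(sample_ids))
    stop("sample ids must be unique")
  os_time <- as.numeric(os_time)
  if (any(!is.finite(os_time)) || any(os_time <= 0))
    stop("os_time must be finite and > 0 (days)")
  if (!all(os_event %in% c(0, 1)))
    stop("os_event must be 0 (censored) or 1 (death)")
  if (is.null(subgroup)) subgroup <- rep(NA_character_, n)
  out <- data.frame(sample_id = as.character(sample_ids),
                    os_time = os_time,
                    os_event = as.integer(os_event),
                    subgroup = as.character(subgroup),
                    stringsAsFactors = FALSE)
  class(out) <- c("ClinicalTable", "data.frame")
  out
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (member gene symbols).
#' @param descriptions Optional named character vector of descriptions.
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every set must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate set names")
  sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
  if (any(lengths(sets) == 0))
    stop("every set must be non-empty")
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, descriptions = descriptions[names(sets)]),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets, sizes %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Construct an ontology with term-gene annotations
#'
#' Holds a rooted acyclic `is_a` graph (child -> parent edges) plus direct
#' gene annotations per term. When the edge list has more than one root a
#' virtual root `"VROOT"` is inserted above all of them.
#'
#' @param edges Two-column data.frame or matrix of (child, parent) term ids.
#' @param term_names Optional named character vector of human-readable names.
#' @param annotations Named list: term id -> character vector of directly
#'   annotated gene symbols.
#' @return An object of class `OntologyAnnotations` with elements
#'   `term_ids`, `parents` (named list), `children` (named list),
#'   `term_names`, `annotations`, `root`.
#' @export
ontology_annotations <- function(edges, term_names = NULL, annotations = list()) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stop("edges must have (child, parent) columns")
  child <- as.character(edges[[1]]); parent <- as.character(edges[[2]])
  term_ids <- unique(c(child, parent))
  parents <- split(parent, factor(child, levels = term_ids))
  parents <- lapply(parents, unique)
  roots <- term_ids[lengths(parents[term_ids]) == 0]
  if (length(roots) == 0) {
    # every term has a parent: walk upward until a term repeats
    path <- term_ids[1]
    repeat {
      nxt <- parents[[path[length(path)]]][1]
      if (nxt %in% path) {
        cyc <- c(path[which(path == nxt):length(path)], nxt)
        stop("is_a graph contains a cycle: ", paste(cyc, collapse = " -> "))
      }
      path <- c(path, nxt)
    }
  }
  if (length(roots) > 1) {
    root <- "VROOT"
    term_ids <- c(term_ids, root)
    for (r in roots) parents[[r]] <- root
    parents[[root]] <- character(0)
  } else root <- roots
  cyc <- .find_cycle(term_ids, parents)
  if (!is.null(cyc))
    stop("is_a graph contains a cycle: ", paste(cyc, collapse = " -> "))
  annotations <- lapply(annotations, function(g) unique(toupper(as.character(g))))
  unknown <- setdiff(names(annotations), term_ids)
  if (length(unknown))
    stop("annotation to unknown term(s): ", paste(unknown, collapse = ", "))
  children <- lapply(setNames(term_ids, term_ids), function(t) character(0))
  for (t in term_ids) for (p in parents[[t]])
    children[[p]] <- c(children[[p]], t)
  if (is.null(term_names)) term_names <- setNames(term_ids, term_ids)
  structure(
    list(term_ids = term_ids, parents = parents, children = children,
         term_names = term_names, annotations = annotations, root = root),
    class = "OntologyAnnotations")
}

# Kahn-style check on child->parent edges; returns one cycle or NULL.
.find_cycle <- function(term_ids, parents) {
  state <- setNames(rep(0L, length(term_ids)), term_ids)  # 0 new, 1 open, 2 done
  for (start in term_ids) {
    if (state[start] != 0L) next
    stack <- list(list(node = start, path = start))
    # iterative DFS with explicit path for cycle reporting
    visit <- function(node, path) {
      state[node] <<- 1L
      for (p in parents[[node]]) {
        if (state[p] == 1L) return(c(path[which(path == p):length(path)], p))
        if (state[p] == 0L) {
          res <- visit(p, c(path, p))
          if (!is.null(res)) return(res)
        }
      }
      state[node] <<- 2L
      NULL
    }
    res <- visit(start, start)
    if (!is.null(res)) return(res)
  }
  NULL
}

#' @export
print.OntologyAnnotations <- function(x, ...) {
  cat(sprintf("OntologyAnnotations: %d terms, root '%s', %d annotated terms\n",
              length(x$term_ids), x$root, length(x$annotations)))
  invisible(x)
}
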