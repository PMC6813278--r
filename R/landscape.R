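#' Information content of every ontology term
#'
#' Annotation closure per term is the union of genes annotated to the term
#' or any descendant (each gene counted once); the information content is
#' `-ln(count / count(root))` in nats, so the root has IC 0. Terms with an
#' empty closure have undefined IC and are excluded (with a message).
#'
#' @param onto An [ontology_annotations()] object.
#' @return data.frame of class `TermInfo`: `term_id`, `annotation_count`,
#'   `ic`; only terms with a non-empty closure. The closures themselves
#'   are kept in the `closures` attribute (named list).
#' @export
information_content <- function(onto) {
  closures <- new.env(parent = emptyenv())
  closure_of <- function(t) {
    if (!is.null(closures[[t]])) return(closures[[t]])
    g <- onto$annotations[[t]]
    if (is.null(g)) g <- character(0)
    for (ch in onto$children[[t]]) g <- union(g, closure_of(ch))
    closures[[t]] <- g
    g
  }
  total <- length(closure_of(onto$root))
  if (total < 1) stop("no annotated genes anywhere in the ontology")
  counts <- vapply(onto$term_ids, function(t) length(closure_of(t)), numeric(1))
  empty <- counts == 0
  if (any(empty))
    message(sprintf("information_content: %d term(s) with empty closure excluded",
                    sum(empty)))
  out <- data.frame(term_id = onto$term_ids[!empty],
                    annotation_count = counts[!empty],
                    ic = -log(counts[!empty] / total),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "closures") <- mget(out$term_id, envir = closures)
  class(out) <- c("TermInfo", "data.frame")
  out
}

#' Ancestors of a term (the term itself included)
#' @param onto An [ontology_annotations()] object.
#' @param term A term id.
#' @return Character vector of ancestor term ids.
#' @export
term_ancestors <- function(onto, term) {
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(onto$parents[frontier])), seen)
  }
  seen
}

#' Resnik similarity between two terms
#'
#' The information content of the most informative common ancestor
#' (a term counts as its own ancestor); symmetric, in nats. Siblings whose
#' only common ancestor is the root score 0.
#'
#' @param t1,t2 Term ids.
#' @param info A [information_content()] table.
#' @param onto The [ontology_annotations()] object.
#' @return Similarity in nats (0 when no common ancestor has defined IC).
#' @export
resnik_similarity <- function(t1, t2, info, onto) {
  ic <- setNames(info$ic, info$term_id)
  if (is.na(ic[t1]) || is.na(ic[t2]))
    stop("both terms must have defined information content")
  common <- intersect(term_ancestors(onto, t1), term_ancestors(onto, t2))
  common <- common[common %in% names(ic)]
  if (length(common) == 0) return(0)
  max(ic[common])
}

#' Pairwise Resnik similarity matrix
#' @param terms Term ids.
#' @inheritParams resnik_similarity
#' @return Symmetric matrix of similarities; diagonal = per-term IC.
#' @export
resnik_matrix <- function(terms, info, onto) {
  anc <- lapply(setNames(terms, terms), function(t) term_ancestors(onto, t))
  ic <- setNames(info$ic, info$term_id)
  k <- length(terms)
  S <- matrix(0, k, k, dimnames = list(terms, terms))
  for (i in seq_len(k)) for (j in i:k) {
    common <- intersect(anc[[i]], anc[[j]])
    common <- common[common %in% names(ic)]
    S[i, j] <- S[j, i] <- if (length(common)) max(ic[common]) else 0
  }
  S
}

#' Convert a similarity matrix to a normalized distance matrix
#'
#' `d(i, j) = 1 - sim(i, j) / s_max` off the diagonal with `s_max` the
#' matrix maximum (self-similarities included), `d(i, i) = 0`. Bounded in
#' `[0, 1]`, scale-free (multiplying the similarities by a positive
#' constant leaves d unchanged). An all-zero similarity matrix yields all
#' distances 1 with a warning.
#'
#' @param sim_matrix Symmetric non-negative similarity matrix.
#' @return Distance matrix of the same dimension.
#' @export
similarity_to_distance <- function(sim_matrix) {
  if (!isSymmetric(unname(sim_matrix)))
    stop("similarity matrix must be symmetric")
  s_max <- max(sim_matrix)
  if (s_max <= 0) {
    warning("all similarities are zero; returning unit distances")
    D <- matrix(1, nrow(sim_matrix), ncol(sim_matrix),
                dimnames = dimnames(sim_matrix))
  } else {
    D <- 1 - sim_matrix / s_max
  }
  diag(D) <- 0
  D
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centering and eigendecomposition via `stats::cmdscale`, wrapped
#' with the conventions the landscape needs: fixed axis orientation (the
#' entry of largest magnitude on each axis is made positive), zero-filled
#' axes for negative eigenvalues among the top `k` (with a warning), a
#' normalized stress value, and well-defined output for 1- and 2-point
#' inputs.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param k Embedding dimension (default 2).
#' @return A list of class `SemanticCoordinates`: `term_ids`, `coords`
#'   (n x k), `eigenvalues` (descending, length min(k, n)), `stress`.
#' @export
classical_mds <- function(D, k = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n >= 3 && k > n) stop("k exceeds the number of points")
  if (n == 1) {
    return(structure(list(term_ids = ids,
                          coords = matrix(0, 1, k, dimnames = list(ids, NULL)),
                          eigenvalues = rep(0, k), stress = 0),
                     class = "SemanticCoordinates"))
  }
  if (n == 2) {
    d <- D[1, 2]
    coords <- matrix(0, 2, k, dimnames = list(ids, NULL))
    coords[, 1] <- c(d / 2, -d / 2)
    return(structure(list(term_ids = ids, coords = coords,
                          eigenvalues = c(d^2 / 2, rep(0, k - 1)),
                          stress = 0),
                     class = "SemanticCoordinates"))
  }
  fit <- stats::cmdscale(stats::as.dist(D), k = k, eig = TRUE)
  ev <- fit$eig[seq_len(k)]
  coords <- matrix(0, n, k, dimnames = list(ids, NULL))
  got <- ncol(fit$points)
  if (got > 0) coords[, seq_len(got)] <- fit$points
  if (any(ev < 0)) {
    warning("negative eigenvalue(s) among the top-k axes truncated to zero")
    coords[, ev < 0] <- 0
    ev[ev < 0] <- 0
  }
  # deterministic orientation: largest-|coordinate| entry positive per axis
  for (j in seq_len(k)) {
    i_star <- which.max(abs(coords[, j]))
    if (coords[i_star, j] < 0) coords[, j] <- -coords[, j]
  }
  Dhat <- as.matrix(stats::dist(coords))
  stress <- sqrt(sum((D - Dhat)^2) / sum(D^2))
  structure(list(term_ids = ids, coords = coords, eigenvalues = ev,
                 stress = stress),
            class = "SemanticCoordinates")
}

#' @export
print.SemanticCoordinates <- function(x, ...) {
  cat(sprintf("Semantic map: %d terms in %dD, stress = %.3g\n",
              length(x$term_ids), ncol(x$coords), x$stress))
  invisible(x)
}

#' @export
plot.SemanticCoordinates <- function(x, cex = NULL, col = NULL, ...) {
  size <- if (!is.null(x$size_channel)) sqrt(x$size_channel) else NULL
  if (is.null(cex) && !is.null(size)) cex <- 0.5 + 2 * size / max(size)
  if (is.null(col) && !is.null(x$value_channel)) {
    pal <- grDevices::colorRampPalette(c("cyan", "violet", "deeppink"))(101)
    col <- pal[1 + round(100 * x$value_channel)]
  }
  plot(x$coords[, 1], x$coords[, 2], cex = if (is.null(cex)) 1 else cex,
       col = if (is.null(col)) "black" else col, pch = 19,
       xlab = "MDS 1", ylab = "MDS 2", ...)
  invisible(x)
}

#' Semantic landscape of enriched ontology terms
#'
#' Restricted to the enriched sets, runs the full pipeline — information
#' content, pairwise Resnik similarity, normalized distance, classical MDS
#' — and attaches a size channel (measured set size) and a value channel
#' (normalized prognostic value per set). Enriched sets are mapped to
#' ontology terms by their set name (or via `term_map`); sets with no
#' matching term are excluded with a message. The first axis is oriented
#' so the largest set has non-negative x.
#'
#' @param enriched An `EnrichmentTable` (rows with `enriched == TRUE` are
#'   used; pass a pre-filtered table to override).
#' @param onto An [ontology_annotations()] object.
#' @param scores Optional `SetPrognosticScore` table from
#'   [set_prognostic_value()]; supplies the value channel.
#' @param term_map Optional named character vector set_name -> term_id.
#' @param only_enriched Use only rows flagged enriched (default TRUE).
#' @return A `SemanticCoordinates` object with `size_channel` and
#'   `value_channel` fields added.
#' @export
build_landscape <- function(enriched, onto, scores = NULL, term_map = NULL,
                            only_enriched = TRUE) {
  tab <- if (only_enriched) enriched[enriched$enriched, , drop = FALSE]
         else enriched
  if (nrow(tab) == 0) stop("no enriched sets to map")
  terms <- if (is.null(term_map)) tab$set_name
           else unname(term_map[tab$set_name])
  known <- terms %in% onto$term_ids
  if (any(!known))
    message(sprintf("build_landscape: %d set(s) with no ontology term excluded",
                    sum(!known)))
  tab <- tab[known, , drop = FALSE]; terms <- terms[known]
  if (nrow(tab) == 0) stop("no enriched set maps to an ontology term")
  info <- information_content(onto)
  S <- resnik_matrix(terms, info, onto)
  D <- similarity_to_distance(S)
  mds <- classical_mds(D, k = 2)
  # orientation anchored to the largest set
  i_big <- which.max(tab$size_measured)
  if (mds$coords[i_big, 1] < 0) mds$coords[, 1] <- -mds$coords[, 1]
  mds$term_ids <- terms
  mds$set_names <- tab$set_name
  mds$size_channel <- tab$size_measured
  val <- rep(NA_real_, nrow(tab))
  if (!is.null(scores)) {
    m <- match(tab$set_name, scores$set_name)
    val <- scores$normalized[m]
  }
  mds$value_channel <- val
  mds
}
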