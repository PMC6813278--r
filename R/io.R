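#' Read an expression matrix from TSV or GCT 1.2
#'
#' TSV layout: header row of sample ids, first column gene symbols.
#' GCT 1.2 layout: version line `#1.2`, a dims line `n_genes<TAB>n_samples`,
#' then a header with `Name` and `Description` columns. Duplicate gene
#' symbols are collapsed by keeping, per symbol, the row with the highest
#' mean expression; symbols are uppercased.
#'
#' @param path File path.
#' @param format `"tsv"` or `"gct"`; default guessed from the extension.
#' @param dataset_name Cohort label attached to the result.
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct"),
                            dataset_name = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  if (is.null(dataset_name))
    dataset_name <- sub("\\.[^.]*$", "", basename(path))
  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3 || trimws(lines[1]) != "#1.2")
      stop("GCT format error: first line must be '#1.2'")
    dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
    if (length(dims) < 2 || any(is.na(dims[1:2])))
      stop("GCT format error: malformed dims line")
    body <- utils::read.delim(textConnection(lines[-(1:2)]),
                              check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(body) != dims[1])
      stop(sprintf("GCT format error: dims line declares %d rows, found %d",
                   dims[1], nrow(body)))
    if (ncol(body) - 2L != dims[2])
      stop(sprintf("GCT format error: dims line declares %d samples, found %d",
                   dims[2], ncol(body) - 2L))
    genes <- as.character(body[[1]])
    vals <- body[, -(1:2), drop = FALSE]
  } else {
    body <- utils::read.delim(path, check.names = FALSE,
                              stringsAsFactors = FALSE)
    genes <- as.character(body[[1]])
    vals <- body[, -1, drop = FALSE]
  }
  m <- .as_numeric_matrix(vals, genes)
  m <- collapse_duplicates(m)
  expression_matrix(m, dataset_name = dataset_name)
}

.as_numeric_matrix <- function(df, genes) {
  m <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(genes, colnames(df)))
  for (j in seq_len(ncol(df))) {
    v <- df[[j]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & trimws(as.character(v)) != "")
    if (length(bad))
      stop(sprintf("parse error: non-numeric cell at row %d, column '%s'",
                   bad[1], colnames(df)[j]))
    m[, j] <- num
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing expression value at gene '%s', sample '%s'",
                 genes[idx[1]], colnames(df)[idx[2]]))
  }
  m
}

#' Collapse duplicate gene symbols to one row per symbol
#'
#' Keeps, for each (uppercased) symbol, the row with the highest mean
#' expression across samples — the usual deterministic multi-probe rule.
#' Idempotent: applying it to an already-unique matrix is a no-op.
#'
#' @param m Numeric matrix with gene-symbol rownames.
#' @return Matrix with unique uppercased rownames, original relative order
#'   of the kept rows preserved.
#' @export
collapse_duplicates <- function(m) {
  rownames(m) <- toupper(rownames(m))
  if (!anyDuplicated(rownames(m))) return(m)
  means <- rowMeans(m)
  keep <- rep(FALSE, nrow(m))
  for (sym in unique(rownames(m))) {
    idx <- which(rownames(m) == sym)
    keep[idx[which.max(means[idx])]] <- TRUE
  }
  m[keep, , drop = FALSE]
}

#' Read a clinical survival table from TSV
#'
#' Expects columns `sample_id`, `os_time` (days), `os_event` (0/1) and an
#' optional `subgroup`. Rows with a missing time or event are dropped; the
#' number dropped is reported via `message()` and in the `n_dropped`
#' attribute.
#'
#' @param path File path.
#' @return A [clinical_table()] with attribute `n_dropped`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "os_time", "os_event")
  if (!all(need %in% colnames(df)))
    stop("clinical TSV must have columns sample_id, os_time, os_event")
  time_num <- suppressWarnings(as.numeric(df$os_time))
  ev_raw <- df$os_event
  ev_num <- suppressWarnings(as.numeric(ev_raw))
  miss <- is.na(time_num) | is.na(ev_raw) | trimws(as.character(df$os_time)) == "" |
    trimws(as.character(ev_raw)) == ""
  # a present but invalid event code is an error, not a silent drop
  bad_ev <- which(!miss & !(ev_num %in% c(0, 1)))
  if (length(bad_ev))
    stop(sprintf("validation error: os_event outside {0,1} at row %d (sample '%s')",
                 bad_ev[1], df$sample_id[bad_ev[1]]))
  bad_t <- which(!miss & time_num <= 0)
  if (length(bad_t))
    stop(sprintf("validation error: non-positive os_time at row %d (sample '%s')",
                 bad_t[1], df$sample_id[bad_t[1]]))
  n_dropped <- sum(miss)
  if (n_dropped > 0)
    message(sprintf("read_clinical: dropped %d row(s) with missing time/event",
                    n_dropped))
  df <- df[!miss, , drop = FALSE]
  out <- clinical_table(df$sample_id, time_num[!miss], ev_num[!miss],
                        if ("subgroup" %in% colnames(df)) df$subgroup else NULL)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`. Trailing empty fields
#' are ignored and duplicate members within a set are deduplicated.
#'
#' @param path File path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[!(seq_along(f) > 2 & f == "")]
    if (length(f) < 3)
      stop(sprintf("GMT parse error at line %d: fewer than 3 fields", i))
    if (f[1] %in% names(sets))
      stop(sprintf("duplicate set name '%s' at line %d", f[1], i))
    sets[[f[1]]] <- f[-(1:2)]
    desc[f[1]] <- f[2]
  }
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection to GMT
#' @param gsc A [gene_set_collection()].
#' @param path Output path.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm)
    paste(c(nm, gsc$descriptions[[nm]], gsc$sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ontology DAG plus term-gene annotations from TSV
#'
#' @param dag_path TSV with columns child_term, parent_term and optionally
#'   term_name (name of the child term).
#' @param annot_path TSV with columns term, gene.
#' @return An [ontology_annotations()] object.
#' @export
read_ontology <- function(dag_path, annot_path) {
  dag <- utils::read.delim(dag_path, stringsAsFactors = FALSE)
  if (ncol(dag) < 2) stop("ontology DAG TSV needs (child, parent) columns")
  term_names <- NULL
  if (ncol(dag) >= 3)
    term_names <- setNames(as.character(dag[[3]]), as.character(dag[[1]]))
  ann <- utils::read.delim(annot_path, stringsAsFactors = FALSE)
  if (ncol(ann) < 2) stop("annotation TSV needs (term, gene) columns")
  annotations <- split(as.character(ann[[2]]), as.character(ann[[1]]))
  ontology_annotations(dag[, 1:2], term_names, annotations)
}

#' Write an ontology to the package's two-file TSV layout
#' @param onto An [ontology_annotations()] object.
#' @param dag_path,annot_path Output paths.
#' @export
write_ontology <- function(onto, dag_path, annot_path) {
  ch <- rep(names(onto$parents), lengths(onto$parents))
  pa <- unlist(onto$parents, use.names = FALSE)
  utils::write.table(
    data.frame(child_term = ch, parent_term = pa,
               term_name = unname(onto$term_names[ch])),
    dag_path, sep = "\t", quote = FALSE, row.names = FALSE)
  tm <- rep(names(onto$annotations), lengths(onto$annotations))
  utils::write.table(
    data.frame(term = tm, gene = unlist(onto$annotations, use.names = FALSE)),
    annot_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dag_path)
}

#' Write an expression matrix to TSV (or GCT 1.2)
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @param format `"tsv"` or `"gct"`.
#' @param digits Significant digits used for serialization (default 17,
#'   which round-trips doubles exactly through [read_expression()]).
#' @export
write_expression <- function(expr, path, format = c("tsv", "gct"), digits = 17) {
  format <- match.arg(format)
  v <- expr$values
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  rows <- vapply(seq_len(nrow(v)), function(i)
    paste(c(expr$gene_ids[i],
            if (format == "gct") "na" else NULL,
            fmt(v[i, ])), collapse = "\t"), character(1))
  header <- paste(c(if (format == "gct") c("Name", "Description") else "gene",
                    expr$sample_ids), collapse = "\t")
  lines <- c(if (format == "gct") c("#1.2", paste(nrow(v), ncol(v), sep = "\t")),
             header, rows)
  writeLines(lines, path)
  invisible(path)
}

#' Write a clinical table to TSV
#' @param clin A [clinical_table()].
#' @param path Output path.
#' @export
write_clinical <- function(clin, path) {
  utils::write.table(as.data.frame(clin), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a result table deterministically as TSV or JSON
#'
#' Rows are written in the order given (each producing operation documents
#' its ordering); floats are serialized at 6 significant digits so that a
#' write/read round trip preserves values to that precision and repeated
#' writes of the same input are byte-identical.
#'
#' @param records A data.frame of results.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param allow_empty Set TRUE to permit writing a zero-row table.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path, format = c("tsv", "json"),
                         allow_empty = FALSE) {
  format <- match.arg(format)
  records <- as.data.frame(records)
  if (nrow(records) == 0 && !allow_empty)
    stop("refusing to write an empty result table (set allow_empty = TRUE)")
  out <- records
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.6g", out[[j]])
  if (format == "tsv") {
    con <- file(path, open = "wb")  # binary connection: fixed \n line endings
    on.exit(close(con))
    writeLines(c(paste(colnames(out), collapse = "\t"),
                 if (nrow(out)) apply(out, 1, paste, collapse = "\t")),
               con)
  } else {
    # re-type numerics so JSON holds numbers, rounded identically to TSV
    for (j in seq_along(out))
      if (is.double(records[[j]])) out[[j]] <- as.numeric(out[[j]])
    json <- jsonlite::toJSON(out, dataframe = "rows", digits = NA,
                             na = "null", pretty = TRUE)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(json, con)
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#' @param path File path.
#' @param format `"tsv"` or `"json"`.
#' @return A data.frame.
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv")
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  else
    as.data.frame(jsonlite::fromJSON(path))
}
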