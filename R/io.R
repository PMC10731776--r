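#' Construct a labeled binary association matrix
#'
#' The central data object: a binary matrix `A` with microbes on the rows
#' and diseases on the columns, entry 1 where an association is recorded in
#' a database (or planted by the synthetic generator) and 0 otherwise.
#'
#' @param values Numeric matrix of 0/1 entries.
#' @param row_labels,col_labels Unique identifiers; default to existing
#'   dimnames.
#' @return A matrix of class `association_matrix` with dimnames set.
#' @export
association_matrix <- function(values,
                               row_labels = rownames(values),
                               col_labels = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(row_labels) || is.null(col_labels)) {
    abort("association_matrix needs row and column labels")
  }
  if (anyDuplicated(row_labels) || anyDuplicated(col_labels)) {
    abort("association_matrix labels must be unique")
  }
  if (nrow(values) < 2 || ncol(values) < 2) {
    abort("association_matrix needs at least 2 microbes and 2 diseases")
  }
  if (!all(values %in% c(0, 1))) {
    abort("association_matrix entries must be 0 or 1")
  }
  storage.mode(values) <- "double"
  dimnames(values) <- list(as.character(row_labels), as.character(col_labels))
  class(values) <- c("association_matrix", class(values))
  values
}

#' Read a microbe-disease association table
#'
#' Two layouts are accepted. `"pairs"` is the canonical exchange format used
#' by the curated databases: a TSV whose first two columns are microbe id
#' and disease id, one known association per row (a header line is detected
#' and skipped; duplicates are collapsed). `"matrix"` is a dense labeled 0/1
#' TSV as written by [write_matrix_tsv()], used mainly for fixtures.
#'
#' Labels are sorted lexicographically (C collation) so the matrix layout is
#' deterministic across runs and platforms.
#'
#' @param path Input file.
#' @param format `"pairs"` or `"matrix"`.
#' @return An [association_matrix()].
#' @export
read_association_table <- function(path, format = c("pairs", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "matrix") {
    m <- read_matrix_tsv(path)
    if (!all(m %in% c(0, 1))) abort("matrix-format association file has non-binary cells")
    return(association_matrix(m))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(paste0("empty association file: ", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2)
  if (length(bad)) {
    abort(sprintf("malformed row (need >= 2 tab-separated columns) at line %d of %s",
                  bad[1], path))
  }
  microbe <- vapply(parts, `[[`, "", 1L)
  disease <- vapply(parts, `[[`, "", 2L)
  # tolerate a header line
  if (tolower(microbe[1]) %in% c("microbe", "microbe_id", "m") &&
      tolower(disease[1]) %in% c("disease", "disease_id", "d")) {
    microbe <- microbe[-1]; disease <- disease[-1]
    if (!length(microbe)) abort(paste0("association file has only a header: ", path))
  }
  keep <- !duplicated(paste(microbe, disease, sep = "\r"))
  microbe <- microbe[keep]; disease <- disease[keep]
  rl <- sort_c(unique(microbe)); cl <- sort_c(unique(disease))
  A <- matrix(0, length(rl), length(cl), dimnames = list(rl, cl))
  A[cbind(match(microbe, rl), match(disease, cl))] <- 1
  association_matrix(A)
}

# locale-independent lexicographic sort for deterministic label order
sort_c <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(x)
}

#' Read per-disease ontology DAGs from an edge list
#'
#' The file is a 3-column TSV: disease id, child node, parent node. All rows
#' sharing a disease id describe that disease's ancestor graph, rooted at
#' the disease itself. Cycles and roots that never appear among the nodes
#' are rejected.
#'
#' @param path Input TSV.
#' @return A named list of [disease_dag()] objects, one per disease id.
#' @export
read_dag_edges <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("disease", "child", "parent"),
                   colClasses = "character")
  if (!nrow(df)) abort(paste0("empty DAG edge file: ", path))
  out <- lapply(split(df, df$disease), function(d) {
    disease_dag(root = d$disease[1],
                edges = data.frame(child = d$child, parent = d$parent,
                                   stringsAsFactors = FALSE))
  })
  out[sort_c(names(out))]
}

#' Write a labeled numeric matrix as TSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces doubles bit-exactly. The header row carries column
#' labels; the first column carries row labels.
#'
#' @param m Labeled numeric matrix (square similarity matrices, embeddings,
#'   score matrices and association matrices all qualify).
#' @param path Output file.
#' @export
write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("write_matrix_tsv requires a fully labeled matrix")
  }
  body <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  lines <- c(paste(c("id", colnames(m)), collapse = "\t"),
             paste(rownames(m), body, sep = "\t"))
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE)
  if (!ok) abort(paste0("cannot write matrix to: ", path))
  invisible(path)
}

#' Read a labeled numeric matrix written by [write_matrix_tsv()]
#'
#' @param path Input TSV with a header row and a leading label column.
#' @return A labeled numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   row.names = 1, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) abort(paste0("non-numeric cell in matrix file: ", path))
  storage.mode(m) <- "double"
  m
}
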