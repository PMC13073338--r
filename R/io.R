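#' Read an analyte-by-sample abundance matrix
#'
#' Reads a tab-separated abundance table: one header row of sample identifiers,
#' first column of analyte identifiers, remaining cells numeric abundances.
#' Blank cells become \code{NA} (missing is distinct from zero: zero is a valid
#' abundance on the raw scale only in pathological inputs, but blank always
#' means "not measured").
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix with analyte row names and sample column names.
#' @export
read_analyte_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("analyte matrix file needs a header and at least one row: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ID in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate analyte ID: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  n <- length(sample_ids)
  mat <- matrix(NA_real_, nrow = length(ids), ncol = n,
                dimnames = list(ids, sample_ids))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1L]
    length(cells) <- n                       # right-pad short rows (trailing blanks)
    blank <- is.na(cells) | cells == ""
    vals <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(vals) & !blank)
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' for analyte '%s', sample '%s'",
                   cells[bad[1L]], ids[i], sample_ids[bad[1L]]))
    }
    mat[i, ] <- vals
  }
  mat
}

#' Write an analyte matrix as tab-separated text
#'
#' Inverse of [read_analyte_matrix()]; missing values are written as blank
#' fields so that a round trip preserves values, ordering and missingness.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_analyte_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  header <- paste(c("analyte_id", colnames(mat)), collapse = "\t")
  fmt <- function(v) {
    out <- vapply(v, function(x) if (is.na(x)) "" else format(x, digits = 17L, scientific = FALSE),
                  character(1L))
    out
  }
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], fmt(mat[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read per-sample metadata
#'
#' @param path Tab-separated file with columns \code{sample_id, status, age,
#'   sex, stratum, batch, dataset} (header required).
#' @return A data frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  # read everything as character so identifier-like columns ("33", "F") are
  # not coerced to numbers or logicals, then restore the numeric columns
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "status", "age", "sex", "stratum", "batch", "dataset")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  bad <- setdiff(unique(df$status), c("AD", "CO"))
  if (length(bad)) stop("status must be AD or CO; found: ", paste(bad, collapse = ", "))
  df$age <- as.numeric(df$age)
  df$batch <- as.integer(df$batch)
  df
}

#' Write per-sample metadata
#' @param meta Data frame as returned by [read_sample_metadata()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line,
#' \code{name<TAB>description<TAB>member1<TAB>member2...}. Duplicate members
#' within a line are deduplicated; duplicate set names are an error; the order
#' of sets is preserved.
#'
#' @param path Path to a GMT file.
#' @return A list of class \code{gene_set_collection}: named list of character
#'   member vectors, with a \code{"description"} attribute per element.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) stop("GMT line ", short[1L], " has fewer than 3 fields")
  nms <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set name: ", paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- nms
  attr(sets, "description") <- stats::setNames(vapply(fields, `[[`, character(1L), 2L), nms)
  class(sets) <- "gene_set_collection"
  sets
}

#' Write a GMT gene-set collection
#' @param sets A \code{gene_set_collection} (named list of member vectors).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected edge list into a background interactome graph
#'
#' Two tab-separated columns, no header. Self-loops are dropped with a warning;
#' duplicate edges (in either orientation) are collapsed.
#'
#' @param path Path to the edge-list file.
#' @return An [igraph::graph] object, undirected and simple.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) stop("edge-list line ", bad[1L], " does not have exactly 2 fields")
  from <- vapply(fields, `[[`, character(1L), 1L)
  to <- vapply(fields, `[[`, character(1L), 2L)
  loops <- from == to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped from edge list")
    from <- from[!loops]; to <- to[!loops]
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a graph as a two-column edge list
#' @param graph An igraph object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Write an association/meta results table
#'
#' Fixed column order \code{analyte_id, stratum, stage, beta, se, p, fdr,
#' called, direction}; missing columns are filled with \code{NA} so tables from
#' different stages share one on-disk schema.
#'
#' @param df Results data frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_results_table <- function(df, path) {
  cols <- c("analyte_id", "stratum", "stage", "beta", "se", "p", "fdr", "called", "direction")
  for (cc in setdiff(cols, names(df))) df[[cc]] <- NA
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
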