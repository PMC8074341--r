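#' Expression set: matrix plus per-sample time/individual metadata
#'
#' A light container for a normalized gene-by-sample expression matrix and the
#' sample metadata the rhythm tests need: sampling time in decimal hours and an
#' individual/replicate identifier. Samples are aligned to metadata by sample
#' name, never by column order.
#'
#' @param x numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids).
#' @param meta data.frame with columns \code{sample}, \code{time} (hours) and
#'   \code{ind} (individual/replicate id).
#' @return an object of class \code{expression_set}: a list with elements
#'   \code{x} (matrix, columns reordered to metadata order), \code{time}
#'   (numeric) and \code{ind} (character).
#' @export
expression_set <- function(x, meta) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("x must have unique gene ids as rownames", call. = FALSE)
  if (is.null(colnames(x))) stop("x must have sample ids as colnames", call. = FALSE)
  if (!is.data.frame(meta)) stop("meta must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(c("sample", "time", "ind"), names(meta))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  meta$sample <- as.character(meta$sample)
  if (anyDuplicated(meta$sample)) stop("duplicate sample ids in metadata", call. = FALSE)
  if (ncol(x) != nrow(meta))
    stop("expression has ", ncol(x), " samples but metadata has ", nrow(meta),
         " rows", call. = FALSE)
  bad <- setdiff(colnames(x), meta$sample)
  if (length(bad))
    stop("sample name mismatch between expression and metadata: ",
         paste(bad, collapse = ", "), call. = FALSE)
  tm <- as.numeric(meta$time)
  if (any(!is.finite(tm))) stop("metadata times must be finite numbers", call. = FALSE)
  if (length(unique(tm)) < 2) stop("need at least 2 distinct sampling times", call. = FALSE)
  # align columns to metadata order by name
  x <- x[, meta$sample, drop = FALSE]
  structure(list(x = x, time = tm, ind = as.character(meta$ind)),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("<expression_set: %d genes x %d samples, %d time points, %d individuals>\n",
              nrow(x$x), ncol(x$x), length(unique(x$time)), length(unique(x$ind))))
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$x)

# canonical sample order (time, individual, name) so results do not depend on
# the order samples arrive in: fitting and rank statistics are mathematically
# order-invariant, and a fixed order makes them bitwise so
.canonicalize <- function(es) {
  ord <- order(es$time, es$ind, colnames(es$x))
  es$x <- es$x[, ord, drop = FALSE]
  es$time <- es$time[ord]
  es$ind <- es$ind[ord]
  es
}

#' Sample metadata of an expression set
#' @param es an \code{expression_set}.
#' @return data.frame with columns sample, time, ind.
#' @export
sample_meta <- function(es) {
  data.frame(sample = colnames(es$x), time = es$time, ind = es$ind,
             stringsAsFactors = FALSE)
}

# comma/tab sniffing on the header line
.sniff_sep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (lengths(regmatches(hdr, gregexpr("\t", hdr))) >=
      lengths(regmatches(hdr, gregexpr(",", hdr)))) "\t" else ","
}

#' Read an expression matrix and sample metadata from CSV/TSV
#'
#' The expression file carries gene ids in the first column; the metadata file
#' needs columns \code{sample}, \code{time}, \code{ind}. The delimiter (comma
#' or tab) is sniffed per file. Metadata row order is irrelevant: samples are
#' matched by name.
#'
#' @param expr_path path to the expression table.
#' @param meta_path path to the metadata table.
#' @return an \code{\link{expression_set}}.
#' @export
read_expression <- function(expr_path, meta_path) {
  for (p in c(expr_path, meta_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  ex <- utils::read.table(expr_path, header = TRUE, sep = .sniff_sep(expr_path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  gid <- as.character(ex[[1]])
  if (anyDuplicated(gid))
    stop("duplicate gene ids in ", expr_path, ": ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  m <- as.matrix(ex[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gid
  meta <- utils::read.table(meta_path, header = TRUE, sep = .sniff_sep(meta_path),
                            check.names = FALSE, stringsAsFactors = FALSE)
  expression_set(m, meta)
}

#' Write a results table to CSV
#'
#' Plain comma-separated output with a header, \code{NA} serialized as empty
#' fields, numbers at full double precision so a write/read round trip is
#' lossless to at least 12 significant digits.
#'
#' @param table a data.frame of results.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table)) stop("table must be a data.frame", call. = FALSE)
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a results table written by \code{write_results}
#' @param path path to the CSV.
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write an expression set to expression + metadata CSV files
#' @param es an \code{expression_set}.
#' @param expr_path,meta_path output paths.
#' @return invisibly, c(expr_path, meta_path).
#' @export
write_expression <- function(es, expr_path, meta_path) {
  df <- data.frame(gene = rownames(es$x), es$x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, expr_path, row.names = FALSE)
  utils::write.csv(sample_meta(es), meta_path, row.names = FALSE)
  invisible(c(expr_path, meta_path))
}
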