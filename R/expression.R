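#' Read an expression matrix from a delimited text file
#'
#' Reads a rectangular numeric table with a header row of gene names and
#' individuals (samples) as rows. An optional first column of non-numeric
#' sample identifiers is detected automatically and used as row names.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field delimiter, default tab.
#' @return A numeric matrix (individuals x genes) with gene names as column
#'   names, sample identifiers (if present) as row names, and attribute
#'   \code{standardized = FALSE}.
#' @seealso [standardize_expression()]
#' @export
read_expression <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  if (ncol(raw) < 1L || nrow(raw) < 1L) stop("empty expression table: ", path)
  sample_ids <- NULL
  first <- raw[[1L]]
  if (is.character(first) || is.factor(first)) {
    sample_ids <- as.character(first)
    raw <- raw[, -1L, drop = FALSE]
  }
  gene_names <- colnames(raw)
  if (anyDuplicated(gene_names)) {
    stop("duplicate gene names in header: ",
         paste(unique(gene_names[duplicated(gene_names)]), collapse = ", "))
  }
  for (j in seq_along(raw)) {
    if (!is.numeric(raw[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(raw[[j]])))))[1L]
      stop("non-numeric value in column '", gene_names[j], "', row ",
           if (is.na(bad)) "?" else bad)
    }
  }
  x <- as.matrix(raw)
  if (anyNA(x) || any(!is.finite(x))) stop("missing or non-finite entries in ", path)
  if (ncol(x) < 2L) stop("need at least 2 genes, got ", ncol(x))
  if (nrow(x) < 4L) stop("need at least 4 individuals, got ", nrow(x))
  if (!is.null(sample_ids)) {
    if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
    rownames(x) <- sample_ids
  }
  attr(x, "standardized") <- FALSE
  x
}

#' Column-standardize an expression matrix
#'
#' Z-scores every gene column on the full, non-truncated sample: subtracts the
#' column mean and divides by the sample standard deviation (n - 1
#' denominator). All network computations in this package assume full-sample
#' standardization performed before any phenotypic truncation; group subsets
#' are never re-standardized.
#'
#' @param x Numeric matrix, individuals x genes.
#' @return Matrix of the same shape with attribute \code{standardized = TRUE}.
#' @examples
#' x <- cbind(g1 = c(1, 2, 3), g2 = c(2, 4, 8))
#' standardize_expression(x)
#' @export
standardize_expression <- function(x) {
  x <- as_expression_matrix(x, min_n = 2L, min_p = 1L)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(x)[sds == 0]
    stop("constant column(s): ", paste(nm, collapse = ", "))
  }
  out <- scale(x, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  dimnames(out) <- dimnames(x)
  attr(out, "standardized") <- TRUE
  out
}

#' @keywords internal
is_standardized <- function(x) isTRUE(attr(x, "standardized"))

# Validate and coerce an individuals-x-genes matrix; assigns default gene
# names g1..gp when absent.
#' @keywords internal
as_expression_matrix <- function(x, min_n = 4L, min_p = 2L) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("expression matrix must be numeric")
  if (anyNA(x) || any(!is.finite(x))) stop("expression matrix has missing/non-finite entries")
  if (nrow(x) < min_n) stop("need at least ", min_n, " individuals")
  if (ncol(x) < min_p) stop("need at least ", min_p, " genes")
  if (is.null(colnames(x))) colnames(x) <- paste0("g", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x))) stop("duplicate gene names")
  x
}

#' Write a differential-network edge list as TSV
#'
#' Writes columns \code{gene_a}, \code{gene_b}, \code{q}, \code{q_signed},
#' \code{type} in a deterministic order: descending |q_signed|, ties broken by
#' the (gene_a, gene_b) name pair. Numeric values are written with 12
#' significant digits so that a read-back round-trip is lossless in practice.
#'
#' @param edges Data frame of edge records as produced by [top_edges()].
#' @param path Output file path.
#' @return Invisibly, the ordered data frame that was written.
#' @export
write_edge_list <- function(edges, path) {
  cols <- c("gene_a", "gene_b", "q", "q_signed", "type")
  if (!all(cols %in% names(edges))) {
    stop("edge list must have columns: ", paste(cols, collapse = ", "))
  }
  edges <- edges[, cols, drop = FALSE]
  if (nrow(edges) > 0L) {
    ord <- order(-abs(edges$q_signed), edges$gene_a, edges$gene_b)
    edges <- edges[ord, , drop = FALSE]
    rownames(edges) <- NULL
  }
  fmt <- edges
  fmt$q <- formatC(edges$q, digits = 12, format = "g")
  fmt$q_signed <- formatC(edges$q_signed, digits = 12, format = "g")
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edges)
}

#' Read back an edge list written by [write_edge_list()]
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns gene_a, gene_b, q, q_signed, type.
#' @export
read_edge_list <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "numeric", "character"))
  out
}

#' Write a group network matrix as a square TSV with gene-name header
#' @param net A matrix as returned by [group_correlation()] or
#'   [part_correlation()].
#' @param path Output file path.
#' @return Invisibly, \code{net}.
#' @export
write_network_tsv <- function(net, path) {
  m <- unclass(net)
  attr(m, "metric") <- NULL; attr(m, "group") <- NULL; attr(m, "a") <- NULL
  utils::write.table(format(m, digits = 12, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = TRUE, col.names = NA)
  invisible(net)
}
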