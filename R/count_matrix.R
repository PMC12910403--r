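#' Sparse single-cell count matrix with a modality tag
#'
#' A thin container around a \code{dgCMatrix} oriented cells x features, with
#' unique cell and feature identifiers in the dimnames, a modality tag and a
#' flag recording whether the values are raw counts or normalized.
#'
#' @param values matrix-like, cells in rows, features in columns. Coerced to
#'   \code{dgCMatrix}. Row and column names are required and must be unique.
#' @param modality one of \code{"RNA"}, \code{"ATAC_PEAK"}, \code{"ATAC_TSS"}.
#' @param normalized logical; \code{FALSE} for raw counts.
#'
#' @return an object of class \code{count_matrix}.
#' @export
count_matrix <- function(values, modality = c("RNA", "ATAC_PEAK", "ATAC_TSS"),
                         normalized = FALSE) {
  modality <- match.arg(modality)
  values <- as(as(as(values, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("count_matrix requires cell ids (rownames) and feature ids (colnames)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate cell ids in count matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids in count matrix")
  if (length(values@x) && min(values@x) < 0)
    stop("count matrix contains negative entries")
  structure(
    list(values = values, modality = modality, normalized = isTRUE(normalized)),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "<count_matrix> %s | %d cells x %d features | %s | %.2f%% nonzero\n",
    x$modality, nrow(x$values), ncol(x$values),
    if (x$normalized) "normalized" else "raw counts",
    100 * length(x$values@x) / max(1, prod(dim(x$values)))
  ))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Cell and feature identifiers of a count matrix
#' @param x a \code{count_matrix}.
#' @return character vector of ids.
#' @export
cell_ids <- function(x) rownames(x$values)

#' @rdname cell_ids
#' @export
feature_ids <- function(x) colnames(x$values)

#' Subset a count matrix by cells and/or features
#'
#' @param x a \code{count_matrix}.
#' @param cells,features index vectors (logical, integer or character);
#'   \code{NULL} keeps everything.
#' @return a \code{count_matrix} with the same modality and normalized flag.
#' @export
subset_count_matrix <- function(x, cells = NULL, features = NULL) {
  v <- x$values
  tot <- attr(x, "cell_totals")
  if (!is.null(cells)) {
    v <- v[cells, , drop = FALSE]
    if (!is.null(tot)) tot <- tot[rownames(v)]
  }
  if (!is.null(features)) v <- v[, features, drop = FALSE]
  out <- count_matrix(v, x$modality, x$normalized)
  attr(out, "cell_totals") <- tot
  out
}

# internal: stop unless the object is a count_matrix in the expected state
check_count_matrix <- function(x, normalized = NULL) {
  if (!inherits(x, "count_matrix")) stop("expected a count_matrix object")
  if (!is.null(normalized) && x$normalized != normalized) {
    stop(if (normalized) "expected normalized values, got raw counts"
         else "expected raw counts, got normalized values")
  }
  invisible(x)
}

#' Construct a cell metadata table
#'
#' One row per cell: identifier, broad class (\code{"Neurons"} or other),
#' neuron subtype and experimental condition. Conditions come from the closed
#' set used throughout the package.
#'
#' @param cell_id unique character ids.
#' @param cell_class character, e.g. \code{"Neurons"}.
#' @param subtype character subtype labels.
#' @param condition one of \code{"uninjured"}, \code{"7dpi"}, \code{"2mpi"}.
#' @return a \code{data.frame} with class \code{cell_table}.
#' @export
cell_table <- function(cell_id, cell_class, subtype, condition) {
  if (anyDuplicated(cell_id)) stop("cell ids must be unique")
  bad <- setdiff(unique(condition), c("uninjured", "7dpi", "2mpi"))
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  out <- data.frame(
    cell_id = as.character(cell_id),
    cell_class = as.character(cell_class),
    subtype = as.character(subtype),
    condition = as.character(condition),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cell_table", "data.frame")
  out
}

# internal: check matrix/table alignment
check_alignment <- function(matrix, cells) {
  if (!identical(cell_ids(matrix), cells$cell_id))
    stop("cell ids of the count matrix and the cell table do not align")
  invisible(TRUE)
}
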