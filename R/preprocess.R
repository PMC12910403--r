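#' Filter cells by total counts and detected features
#'
#' @param matrix a raw \code{\link{count_matrix}}.
#' @param cells the aligned \code{\link{cell_table}}.
#' @param min_counts,min_features inclusive lower thresholds; a cell is kept
#'   when its total count is >= \code{min_counts} and its number of nonzero
#'   features is >= \code{min_features}.
#' @return list with filtered \code{matrix} and \code{cells}, original order
#'   preserved.
#' @export
filter_cells <- function(matrix, cells, min_counts = 0, min_features = 0) {
  check_count_matrix(matrix)
  check_alignment(matrix, cells)
  if (min_counts < 0 || min_features < 0)
    stop("thresholds must be >= 0")
  totals <- Matrix::rowSums(matrix$values)
  nfeat <- Matrix::rowSums(matrix$values > 0)
  keep <- totals >= min_counts & nfeat >= min_features
  if (!any(keep))
    stop("cell filtering removed every cell (min_counts=", min_counts,
         ", min_features=", min_features, ")")
  list(matrix = subset_count_matrix(matrix, cells = keep),
       cells = cells[keep, , drop = FALSE])
}

#' Restrict a dataset to cells annotated as neurons
#'
#' @inheritParams filter_cells
#' @return list with \code{matrix} and \code{cells} restricted to
#'   \code{cell_class == "Neurons"}.
#' @export
subset_neurons <- function(matrix, cells) {
  check_count_matrix(matrix)
  check_alignment(matrix, cells)
  keep <- cells$cell_class == "Neurons"
  if (!any(keep)) stop("no cells labeled 'Neurons' in the cell table")
  list(matrix = subset_count_matrix(matrix, cells = keep),
       cells = cells[keep, , drop = FALSE])
}

#' Log-normalize RNA counts
#'
#' Per-cell depth normalization: each count is divided by the cell total,
#' multiplied by \code{scale_factor}, and log1p-transformed. Zeros stay zero,
#' so the sparsity pattern is preserved.
#'
#' @param matrix a raw RNA \code{\link{count_matrix}}.
#' @param scale_factor target per-cell total after depth scaling.
#' @return a normalized \code{count_matrix}; the original per-cell totals are
#'   kept in the \code{"cell_totals"} attribute for depth-confounding checks.
#' @export
lognormalize_rna <- function(matrix, scale_factor = 1e4) {
  check_count_matrix(matrix, normalized = FALSE)
  totals <- Matrix::rowSums(matrix$values)
  if (any(totals == 0))
    stop("cells with zero total counts: ",
         paste(cell_ids(matrix)[totals == 0], collapse = ", "))
  v <- Matrix::Diagonal(x = scale_factor / totals) %*% matrix$values
  v <- as(v, "CsparseMatrix")
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(matrix$values)
  out <- count_matrix(v, matrix$modality, normalized = TRUE)
  attr(out, "cell_totals") <- setNames(totals, cell_ids(matrix))
  out
}

#' TF-IDF normalize ATAC counts
#'
#' The standard scATAC term-frequency / inverse-document-frequency transform:
#' \code{tf = count / cell_total}, \code{idf = n_cells / n_cells_detecting},
#' value \code{= log1p(tf * idf * scale_factor)}. Features detected in zero
#' cells stay all-zero; the sparsity pattern is preserved.
#'
#' @param matrix a raw ATAC \code{\link{count_matrix}}.
#' @param scale_factor multiplicative constant inside the log1p.
#' @return a normalized \code{count_matrix} with per-cell totals in the
#'   \code{"cell_totals"} attribute.
#' @export
tfidf_normalize_atac <- function(matrix, scale_factor = 1e4) {
  check_count_matrix(matrix, normalized = FALSE)
  totals <- Matrix::rowSums(matrix$values)
  if (any(totals == 0))
    stop("cells with zero total counts: ",
         paste(cell_ids(matrix)[totals == 0], collapse = ", "))
  n_cells <- nrow(matrix$values)
  n_detect <- Matrix::colSums(matrix$values > 0)
  idf <- ifelse(n_detect > 0, n_cells / n_detect, 0)
  v <- Matrix::Diagonal(x = 1 / totals) %*% matrix$values %*%
    Matrix::Diagonal(x = idf)
  v <- as(v, "CsparseMatrix")
  v@x <- log1p(v@x * scale_factor)
  dimnames(v) <- dimnames(matrix$values)
  out <- count_matrix(v, matrix$modality, normalized = TRUE)
  attr(out, "cell_totals") <- setNames(totals, cell_ids(matrix))
  out
}

#' Latent semantic indexing (truncated SVD) of a TF-IDF matrix
#'
#' Computes the top \code{n_components} singular vectors of the normalized
#' matrix and returns cell embeddings \code{U \%*\% diag(d)}. Components whose
#' absolute Pearson correlation with per-cell sequencing depth (log1p of the
#' total count, since depth acts multiplicatively) exceeds
#' \code{depth_cor_max} are flagged in \code{components_dropped}; downstream
#' consumers exclude them.
#'
#' @param matrix a normalized \code{\link{count_matrix}} (TF-IDF for ATAC).
#' @param n_components number of components (< min(dim)).
#' @param depth_cor_max absolute depth-correlation above which a component is
#'   flagged as technical.
#' @return an \code{embedding}: list with \code{cell_ids},
#'   \code{coordinates} (cells x k), \code{method}, \code{singular_values}
#'   and \code{components_dropped}.
#' @export
run_lsi <- function(matrix, n_components = 30, depth_cor_max = 0.9) {
  check_count_matrix(matrix, normalized = TRUE)
  if (n_components >= min(dim(matrix$values)))
    stop("n_components must be < min(n_cells, n_features)")
  if (n_components < 2) stop("n_components must be >= 2")
  x <- as.matrix(matrix$values)
  sv <- svd(x, nu = n_components, nv = 0)
  coords <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(coords) <- cell_ids(matrix)
  colnames(coords) <- sprintf("LSI_%d", seq_len(n_components))
  dropped <- integer(0)
  totals <- attr(matrix, "cell_totals")
  if (!is.null(totals)) {
    dc <- apply(coords, 2, function(col) {
      if (sd(col) == 0) 0 else abs(cor(col, log1p(totals)))
    })
    dropped <- which(dc > depth_cor_max)
  }
  structure(list(cell_ids = cell_ids(matrix), coordinates = coords,
                 method = "LSI",
                 singular_values = sv$d[seq_len(n_components)],
                 components_dropped = as.integer(dropped)),
            class = "embedding")
}

#' Principal component analysis of a normalized matrix
#'
#' Centered, unit-variance PCA; constant features are excluded before
#' scaling.
#'
#' @inheritParams run_lsi
#' @return an \code{embedding} with method \code{"PCA"}.
#' @export
run_pca <- function(matrix, n_components = 30) {
  check_count_matrix(matrix, normalized = TRUE)
  if (n_components >= min(dim(matrix$values)))
    stop("n_components must be < min(n_cells, n_features)")
  x <- as.matrix(matrix$values)
  keep <- apply(x, 2, sd) > 0
  pc <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = TRUE,
               rank. = n_components)
  coords <- pc$x
  rownames(coords) <- cell_ids(matrix)
  structure(list(cell_ids = cell_ids(matrix), coordinates = coords,
                 method = "PCA",
                 singular_values = pc$sdev[seq_len(ncol(coords))],
                 components_dropped = integer(0)),
            class = "embedding")
}

# internal: embedding coordinates with flagged components removed
embedding_coords <- function(embedding) {
  co <- embedding$coordinates
  if (length(embedding$components_dropped))
    co <- co[, -embedding$components_dropped, drop = FALSE]
  co
}

#' Graph-based clustering of cells in an embedding
#'
#' Builds a shared-nearest-neighbor graph (k nearest Euclidean neighbors,
#' edges weighted by the Jaccard overlap of neighborhoods, weak edges
#' pruned) and partitions it with the Leiden algorithm under the modularity
#' objective. Components flagged in the embedding are excluded. Deterministic
#' given \code{seed}.
#'
#' @param embedding an \code{embedding} from \code{\link{run_lsi}} or
#'   \code{\link{run_pca}}.
#' @param resolution Leiden resolution parameter.
#' @param n_neighbors neighbors per cell for the SNN graph.
#' @param prune_jaccard SNN edges with Jaccard weight below this are removed.
#' @param seed RNG seed for the Leiden refinement.
#' @return integer cluster labels \code{0..C-1}, named by cell id.
#' @export
cluster_cells <- function(embedding, resolution = 1.0, n_neighbors = 15,
                          prune_jaccard = 1 / 15, seed = 0L) {
  co <- embedding_coords(embedding)
  n <- nrow(co)
  if (n <= n_neighbors)
    stop("need more cells (", n, ") than n_neighbors (", n_neighbors, ")")
  d <- as.matrix(dist(co))
  nn <- t(apply(d, 1, function(row) order(row)[2:(n_neighbors + 1)]))
  ## SNN: Jaccard overlap between neighbor sets (self included, as usual)
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), times = n_neighbors + 1),
    j = as.integer(cbind(seq_len(n), nn)),
    x = 1, dims = c(n, n)
  )
  shared <- as.matrix(adj %*% Matrix::t(adj))
  k1 <- n_neighbors + 1
  jac <- shared / (2 * k1 - shared)
  jac[jac < prune_jaccard] <- 0
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 10)
  labels <- igraph::membership(cl)
  labels <- match(labels, unique(labels)) - 1L  # relabel by first occurrence
  setNames(as.integer(labels), embedding$cell_ids)
}
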