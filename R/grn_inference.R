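#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of average-ranked values. The two-sided
#' p-value comes from \code{t = rho * sqrt((n - 2) / (1 - rho^2))} on
#' \code{n - 2} degrees of freedom; \code{rho = +/-1} gives \code{p = 0};
#' a constant input makes rho undefined and both values are returned as NA.
#'
#' @param x,y numeric vectors of equal length \code{n >= 3}, finite values.
#' @return list with \code{rho} and \code{p}.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = min(1, p))
}

#' Cross-modality TF-gene regulatory network
#'
#' For every (TF, gene) pair, computes the Spearman correlation between the
#' TF's per-cell normalized RNA expression and the gene's per-cell normalized
#' TSS-window accessibility across the same neurons, and retains pairs with
#' \code{|rho| > r_min} and \code{p < alpha}. The per-pair p is used raw (no
#' multiplicity adjustment) unless \code{adjust = TRUE}, in which case BH is
#' applied across all candidate pairs before thresholding. Pairs with
#' undefined rho (constant input) are dropped and counted. Genes detected in
#' fewer than \code{min_cells_detected} cells are excluded from the candidate
#' set.
#'
#' @param tfs TF gene ids (must be RNA features).
#' @param genes candidate target gene ids (must be TSS features); default all
#'   TSS features.
#' @param rna_norm normalized RNA \code{\link{count_matrix}}.
#' @param atac_tss_norm normalized TSS-window \code{\link{count_matrix}} over
#'   the same cells, in the same order.
#' @param r_min absolute-correlation threshold (exclusive).
#' @param alpha p-value threshold (exclusive).
#' @param min_cells_detected minimum nonzero cells for a candidate gene.
#' @param allow_self_loops keep TF-to-own-TSS edges (default off).
#' @param adjust apply BH across candidate pairs before thresholding.
#' @return a \code{regulatory_network}: list with \code{edges} (tf, target,
#'   rho, p, n_cells), \code{tf_nodes}, \code{target_nodes}, the thresholds,
#'   and \code{n_na_pairs}.
#' @export
build_tf_gene_network <- function(tfs, genes = NULL, rna_norm, atac_tss_norm,
                                  r_min = 0.3, alpha = 0.05,
                                  min_cells_detected = 3,
                                  allow_self_loops = FALSE, adjust = FALSE) {
  check_count_matrix(rna_norm, normalized = TRUE)
  check_count_matrix(atac_tss_norm, normalized = TRUE)
  if (!identical(cell_ids(rna_norm), cell_ids(atac_tss_norm)))
    stop("RNA and ATAC_TSS matrices must cover the same cells in the same order")
  missing_tf <- setdiff(tfs, feature_ids(rna_norm))
  if (length(missing_tf))
    stop("TF(s) absent from RNA features: ",
         paste(head(missing_tf, 5), collapse = ", "))
  if (is.null(genes)) genes <- feature_ids(atac_tss_norm)
  genes <- intersect(genes, feature_ids(atac_tss_norm))
  n <- nrow(rna_norm$values)
  if (n < 3) stop("need at least 3 cells")

  detected <- Matrix::colSums(atac_tss_norm$values[, genes, drop = FALSE] > 0)
  genes <- genes[detected >= min_cells_detected]

  edges <- data.frame(tf = character(), target = character(),
                      rho = numeric(), p = numeric(), n_cells = integer(),
                      stringsAsFactors = FALSE)
  n_na <- 0L
  if (length(tfs) && length(genes)) {
    rx <- apply(as.matrix(rna_norm$values[, tfs, drop = FALSE]), 2, rank)
    ry <- apply(as.matrix(atac_tss_norm$values[, genes, drop = FALSE]), 2, rank)
    const_x <- apply(rx, 2, sd) == 0
    const_y <- apply(ry, 2, sd) == 0
    rho <- suppressWarnings(cor(rx, ry))           # tfs x genes
    rho[const_x, ] <- NA
    rho[, const_y] <- NA
    tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
    p <- 2 * pt(-abs(tt), df = n - 2)
    p[abs(rho) >= 1] <- 0
    idx <- expand.grid(tf = tfs, target = genes, stringsAsFactors = FALSE)
    idx$rho <- as.vector(rho)
    idx$p <- pmin(1, as.vector(p))
    if (!allow_self_loops) idx <- idx[idx$tf != idx$target, , drop = FALSE]
    n_na <- sum(is.na(idx$rho))
    idx <- idx[!is.na(idx$rho), , drop = FALSE]
    if (adjust) idx$p <- bh_adjust(idx$p)
    keep <- abs(idx$rho) > r_min & idx$p < alpha
    edges <- idx[keep, , drop = FALSE]
    edges$n_cells <- n
    edges <- edges[order(-abs(edges$rho), edges$p, edges$tf, edges$target), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(
    edges = edges,
    tf_nodes = unique(edges$tf),
    target_nodes = unique(edges$target),
    r_min = r_min, alpha = alpha,
    n_na_pairs = n_na
  ), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %d edges | %d TFs -> %d targets | |rho| > %g, p < %g\n",
              nrow(x$edges), length(x$tf_nodes), length(x$target_nodes),
              x$r_min, x$alpha))
  invisible(x)
}

#' Top-k subnetwork around a focal TF
#'
#' Restricts the network to the focal TF's edges, ranked by descending
#' \code{|rho|} (ties: ascending p, then target id), keeping at most \code{k}.
#'
#' @param network a \code{regulatory_network}.
#' @param focal_tf TF id; must appear as a TF node.
#' @param k maximum number of targets.
#' @return a \code{regulatory_network} with at most \code{k} edges.
#' @export
focal_tf_subnetwork <- function(network, focal_tf, k = 20) {
  if (!(focal_tf %in% network$tf_nodes))
    stop("focal TF '", focal_tf, "' has no edges in the network")
  e <- network$edges[network$edges$tf == focal_tf, , drop = FALSE]
  e <- e[order(-abs(e$rho), e$p, e$target), , drop = FALSE]
  e <- head(e, k)
  rownames(e) <- NULL
  structure(list(edges = e, tf_nodes = focal_tf,
                 target_nodes = unique(e$target),
                 r_min = network$r_min, alpha = network$alpha,
                 n_na_pairs = 0L),
            class = "regulatory_network")
}

#' Node and edge tables for network visualization
#'
#' @param network a \code{regulatory_network}.
#' @return list with \code{nodes} (name, role) and \code{edges} (tf, target,
#'   rho, sign, magnitude), both deterministically ordered.
#' @export
export_network_plot_data <- function(network) {
  e <- network$edges
  nodes <- data.frame(
    name = c(sort(unique(e$tf)), sort(setdiff(unique(e$target), unique(e$tf)))),
    stringsAsFactors = FALSE
  )
  nodes$role <- ifelse(nodes$name %in% e$tf, "TF", "target")
  edges <- data.frame(
    tf = e$tf, target = e$target, rho = e$rho,
    sign = ifelse(e$rho >= 0, "positive", "negative"),
    magnitude = abs(e$rho),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}
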