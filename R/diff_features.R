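#' Two-sided Wilcoxon rank-sum test
#'
#' Computes the Mann-Whitney U statistic for the first group using average
#' ranks for ties. For small samples (n1 + n2 <= 12) without ties the
#' two-sided p-value is exact, by enumeration of all group assignments;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y numeric values of the two groups (both non-empty).
#' @return list with \code{U} (statistic of \code{x}) and \code{p}.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- anyDuplicated(pooled) > 0
  mu <- n1 * n2 / 2

  if (!ties && n <= 12) {
    ## exact: U is determined by which ranks go to group 1
    assignments <- combn(n, n1)
    ranks <- seq_len(n)
    U_all <- colSums(matrix(ranks[assignments], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(U_all - mu) >= abs(U - mu) - 1e-9)
  } else {
    tab <- table(pooled)
    tie_term <- sum(tab^3 - tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p = 1))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(U = U, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; monotone in the sorted order and
#' capped at 1.
#'
#' @param pvals numeric vector of p-values in \code{[0, 1]}.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Differential features between a condition and control
#'
#' Per-feature Wilcoxon rank-sum test of normalized values between cells of
#' \code{condition} and cells of \code{control}, with the detection-fraction
#' filter applied \emph{before} testing and BH adjustment computed across all
#' tested features: features detected (nonzero) in at most \code{min_pct} of
#' cells in both groups are excluded from testing, so they do not enter the
#' multiplicity correction.
#'
#' @param matrix a normalized \code{\link{count_matrix}}.
#' @param cells the aligned \code{\link{cell_table}}.
#' @param condition condition label of the test group.
#' @param control condition label of the reference group.
#' @param min_pct features whose detection fraction is <= this in both groups
#'   are excluded before testing.
#' @param alpha_adj adjusted-p cutoff for the returned list.
#' @param features optional feature ids to restrict testing to.
#' @param return_all return all tested features instead of only significant
#'   ones.
#' @return data.frame with feature_id, log2_fc (on expm1-ed group means with
#'   pseudocount 1), pct_group1, pct_group2, p, p_adj, direction.
#' @export
find_differential_features <- function(matrix, cells, condition,
                                       control = "uninjured",
                                       min_pct = 0.20, alpha_adj = 0.05,
                                       features = NULL, return_all = FALSE) {
  check_count_matrix(matrix, normalized = TRUE)
  check_alignment(matrix, cells)
  g1 <- cells$condition == condition
  g2 <- cells$condition == control
  if (!any(g1)) stop("no cells with condition '", condition, "'")
  if (!any(g2)) stop("no cells with condition '", control, "'")

  v <- matrix$values
  if (!is.null(features)) {
    missing <- setdiff(features, feature_ids(matrix))
    if (length(missing) == length(features))
      stop("none of the requested features are present in the matrix")
    v <- v[, intersect(features, feature_ids(matrix)), drop = FALSE]
  }

  pct1 <- Matrix::colMeans(v[g1, , drop = FALSE] > 0)
  pct2 <- Matrix::colMeans(v[g2, , drop = FALSE] > 0)
  tested <- which(pmax(pct1, pct2) > min_pct)
  if (!length(tested)) {
    out <- data.frame(feature_id = character(), log2_fc = numeric(),
                      pct_group1 = numeric(), pct_group2 = numeric(),
                      p = numeric(), p_adj = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
    return(out)
  }

  x1 <- as.matrix(v[g1, tested, drop = FALSE])
  x2 <- as.matrix(v[g2, tested, drop = FALSE])
  p <- vapply(seq_along(tested), function(j) {
    wilcoxon_rank_sum(x1[, j], x2[, j])$p
  }, numeric(1))
  m1 <- colMeans(expm1(x1))
  m2 <- colMeans(expm1(x2))
  log2_fc <- log2((m1 + 1) / (m2 + 1))
  p_adj <- bh_adjust(p)

  out <- data.frame(
    feature_id = colnames(v)[tested],
    log2_fc = log2_fc,
    pct_group1 = pct1[tested],
    pct_group2 = pct2[tested],
    p = p,
    p_adj = p_adj,
    direction = ifelse(log2_fc > 0, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(out$p_adj, out$p, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  if (return_all) out else out[out$p_adj < alpha_adj, , drop = FALSE]
}

#' Drop differential peaks lacking GC metadata
#'
#' GC correction by exclusion: differentially accessible peaks whose peak
#' record has a missing GC fraction are removed before motif enrichment.
#'
#' @param dap_list data.frame from \code{\link{find_differential_features}}
#'   on the peak modality (feature ids are peak ids).
#' @param peaks peak data.frame with peak_id and gc_fraction.
#' @return the filtered data.frame; the number of removals is reported via
#'   \code{message()}.
#' @export
exclude_missing_gc <- function(dap_list, peaks) {
  gc <- peaks$gc_fraction[match(dap_list$feature_id, peaks$peak_id)]
  drop <- is.na(gc)
  message(sum(drop), " of ", nrow(dap_list),
          " differential peaks excluded for missing GC metadata")
  out <- dap_list[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Differentially expressed transcription factors
#'
#' Runs the differential-feature test on the RNA modality restricted to a TF
#' gene set (typically the genes a motif library maps to), with BH adjustment
#' within that set. Gene symbols are matched case-insensitively.
#'
#' @param rna_matrix normalized RNA \code{\link{count_matrix}}.
#' @param cells aligned \code{\link{cell_table}}.
#' @param tf_name_set candidate TF gene symbols (non-empty).
#' @param condition test condition (vs \code{control}).
#' @inheritParams find_differential_features
#' @return data.frame of significant TFs (same columns as
#'   \code{\link{find_differential_features}}).
#' @export
find_differential_tfs <- function(rna_matrix, cells, tf_name_set, condition,
                                  control = "uninjured", min_pct = 0.20,
                                  alpha_adj = 0.05) {
  if (!length(tf_name_set)) stop("tf_name_set must be non-empty")
  feats <- feature_ids(rna_matrix)
  hit <- feats[toupper(feats) %in% toupper(tf_name_set)]
  if (!length(hit))
    stop("tf_name_set is disjoint from the RNA features")
  find_differential_features(rna_matrix, cells, condition, control,
                             min_pct = min_pct, alpha_adj = alpha_adj,
                             features = hit)
}
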