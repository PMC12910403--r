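#' Intersect motif-derived TFs with differentially expressed genes
#'
#' Maps enriched motif names to candidate TF gene symbols (heterodimers are
#' split) and intersects them, case-insensitively, with the DEG list — by
#' default only upregulated DEGs. Set sizes are reported for Venn output.
#'
#' @param enriched_motifs data.frame with a motif_name column (e.g. ranked
#'   enrichment records joined with motif names), or a character vector of
#'   motif names.
#' @param deg_list data.frame from \code{\link{find_differential_features}}
#'   on the RNA modality (feature_id, direction), or a character vector of
#'   gene ids.
#' @param up_only intersect with upregulated DEGs only.
#' @return list with \code{tfs} (gene ids on the DEG side), \code{n_motif_tfs},
#'   \code{n_degs}, \code{n_intersection}.
#' @export
intersect_motifs_degs <- function(enriched_motifs, deg_list, up_only = TRUE) {
  motif_names <- if (is.character(enriched_motifs)) enriched_motifs
                 else enriched_motifs$motif_name
  motif_genes <- motif_names_to_genes(motif_names)
  degs <- if (is.character(deg_list)) deg_list
          else if (up_only) deg_list$feature_id[deg_list$direction == "up"]
          else deg_list$feature_id
  degs <- unique(degs)
  hit <- degs[toupper(degs) %in% toupper(motif_genes)]
  list(tfs = sort(hit),
       n_motif_tfs = length(motif_genes),
       n_degs = length(degs),
       n_intersection = length(hit))
}

#' Prioritize candidate TFs across injury timepoints
#'
#' TFs supported at every supplied timepoint outrank TFs supported at a
#' subset; within a tier, candidates are ordered by descending mean motif
#' fold enrichment, with ties broken by TF id. With a single timepoint the
#' ranking reduces to descending fold enrichment.
#'
#' @param candidates_by_timepoint named list (names = timepoint labels), one
#'   data.frame per timepoint with columns \code{tf} and
#'   \code{fold_enrichment} (optionally \code{direction}).
#' @return data.frame with tf, timepoints_enriched (comma-joined),
#'   n_timepoints, mean_fold_enrichment, priority_rank.
#' @export
prioritize_across_timepoints <- function(candidates_by_timepoint) {
  if (!length(candidates_by_timepoint))
    stop("at least one timepoint must be supplied")
  if (is.null(names(candidates_by_timepoint)) ||
      any(!nzchar(names(candidates_by_timepoint))))
    stop("candidates_by_timepoint must be a named list of timepoints")
  rows <- do.call(rbind, lapply(names(candidates_by_timepoint), function(tp) {
    d <- candidates_by_timepoint[[tp]]
    if (!nrow(d)) return(NULL)
    data.frame(tf = d$tf, timepoint = tp,
               fold_enrichment = d$fold_enrichment,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows) || !nrow(rows)) {
    return(data.frame(tf = character(), timepoints_enriched = character(),
                      n_timepoints = integer(),
                      mean_fold_enrichment = numeric(),
                      priority_rank = integer(), stringsAsFactors = FALSE))
  }
  agg <- split(rows, rows$tf)
  out <- do.call(rbind, lapply(agg, function(d) {
    data.frame(tf = d$tf[1],
               timepoints_enriched = paste(sort(unique(d$timepoint)),
                                           collapse = ","),
               n_timepoints = length(unique(d$timepoint)),
               mean_fold_enrichment = mean(d$fold_enrichment),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n_timepoints, -out$mean_fold_enrichment, out$tf), ,
             drop = FALSE]
  out$priority_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
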