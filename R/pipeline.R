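#' Assemble a pipeline configuration
#'
#' One object drives the whole workflow: the synthetic-data design, every
#' analysis threshold, and a single master seed from which all stage
#' sub-streams are derived.
#'
#' @param sim named list of \code{\link{sim_config}} overrides (the seed is
#'   taken from \code{seed} below).
#' @param min_pct detection-fraction filter for differential testing.
#' @param alpha_adj adjusted-p cutoff for DAPs/DEGs.
#' @param fold_min,alpha_motif motif-enrichment thresholds.
#' @param r_min,alpha_edge network edge-retention thresholds.
#' @param top_k focal-TF subnetwork size.
#' @param n_background_per_query GC-matched background peaks drawn per query
#'   peak (capped by the available pool).
#' @param focal_tf TF whose subnetwork is extracted; \code{NULL} = the top
#'   prioritized candidate.
#' @param seed master seed.
#' @return a list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = list(), min_pct = 0.20, alpha_adj = 0.05,
                            fold_min = 0.5, alpha_motif = 0.05,
                            r_min = 0.3, alpha_edge = 0.05, top_k = 20,
                            n_background_per_query = 5,
                            focal_tf = NULL, seed = 1L) {
  stopifnot(min_pct >= 0, min_pct < 1,
            alpha_adj > 0, alpha_adj <= 1,
            alpha_motif > 0, alpha_motif <= 1,
            alpha_edge > 0, alpha_edge <= 1,
            r_min >= 0, r_min < 1,
            top_k >= 1, n_background_per_query >= 1)
  structure(list(sim = sim, min_pct = min_pct, alpha_adj = alpha_adj,
                 fold_min = fold_min, alpha_motif = alpha_motif,
                 r_min = r_min, alpha_edge = alpha_edge, top_k = top_k,
                 n_background_per_query = n_background_per_query,
                 focal_tf = focal_tf, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of \code{\link{pipeline_config}}, with a
#' \code{sim:} block for the generator overrides.
#'
#' @param path YAML file.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> preprocess -> differential features -> motif
#' enrichment -> intersection/prioritization -> TF-gene network -> focal
#' subnetwork, writing stage outputs and a JSON summary into \code{outdir}.
#' Every stage is reproducible from (config, seed); the summary JSON is
#' byte-identical across re-runs of the same config.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param outdir output directory (created if needed); \code{NULL} skips all
#'   file output.
#' @return (invisibly) a list with the stage results and the \code{summary}
#'   list that is serialized to JSON.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    message("[multigrn] ", msg)
  }

  ## --- simulate -----------------------------------------------------------
  cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
  sim <- simulate_multiome(cfg)
  injured <- setdiff(cfg$conditions, cfg$conditions[1])
  control <- cfg$conditions[1]
  note("simulated ", nrow(sim$cells), " cells, ", cfg$n_genes, " genes, ",
       cfg$n_peaks, " peaks")

  ## --- preprocess ---------------------------------------------------------
  neur_rna <- subset_neurons(sim$rna, sim$cells)
  neur_pk <- subset_count_matrix(sim$atac_peaks, cells = neur_rna$cells$cell_id)
  neur_tss <- subset_count_matrix(sim$atac_tss, cells = neur_rna$cells$cell_id)
  rna_norm <- lognormalize_rna(neur_rna$matrix)
  pk_norm <- tfidf_normalize_atac(neur_pk)
  tss_norm <- tfidf_normalize_atac(neur_tss)
  cells <- neur_rna$cells
  note("retained ", nrow(cells), " neurons")

  ## --- differential features + motif enrichment per timepoint -------------
  tf_gene_set <- motif_names_to_genes(sim$pfm$motif_name)
  daps <- list(); motifs <- list(); degs <- list(); candidates <- list()
  for (i in seq_along(injured)) {
    cond <- injured[i]
    dap <- find_differential_features(pk_norm, cells, cond, control,
                                      min_pct = config$min_pct,
                                      alpha_adj = config$alpha_adj)
    dap <- suppressMessages(exclude_missing_gc(dap, sim$peaks))
    daps[[cond]] <- dap
    deg <- find_differential_features(rna_norm, cells, cond, control,
                                      min_pct = config$min_pct,
                                      alpha_adj = config$alpha_adj)
    degs[[cond]] <- deg
    note(cond, ": ", nrow(dap), " DAPs (GC-complete), ", nrow(deg), " DEGs")

    ## motif enrichment runs on peaks that GAIN accessibility after injury
    up_dap <- dap$feature_id[dap$direction == "up"]
    enr <- data.frame()
    if (length(up_dap) > 0) {
      query <- sim$peaks[sim$peaks$peak_id %in% up_dap, , drop = FALSE]
      pool <- sim$peaks[!(sim$peaks$peak_id %in% dap$feature_id) &
                          !is.na(sim$peaks$gc_fraction), , drop = FALSE]
      ## ~10 query peaks per GC bin; coarsen further if the pool cannot
      ## supply a background at least as large as the query (the
      ## hypergeometric test needs n_bg >= n_query)
      n_bins <- max(1L, min(10L, nrow(query) %/% 10L))
      repeat {
        n_bg <- min(nrow(pool),
                    config$n_background_per_query * nrow(query),
                    feasible_background_size(query, pool, n_bins = n_bins))
        if (n_bg >= nrow(query) || n_bins == 1L) break
        n_bins <- n_bins - 1L
      }
      bg <- match_background_by_gc(query, pool, n_bg, n_bins = n_bins,
                                   seed = sub_seed(config$seed, 400L + i))
      occ <- motif_occurrence_matrix(rbind(query, bg), list(sim$pfm))
      rec <- test_motif_enrichment(query, bg, occ)
      rec$motif_name <- sim$pfm$motif_name
      enr <- rank_motifs(rec, fold_min = config$fold_min,
                         alpha = config$alpha_motif)
    }
    motifs[[cond]] <- enr
    inter <- intersect_motifs_degs(
      if (nrow(enr)) enr else character(0), deg, up_only = TRUE)
    fe <- vapply(inter$tfs, function(tf) {
      maps <- vapply(enr$motif_name, function(nm) {
        toupper(tf) %in% toupper(motif_names_to_genes(nm))
      }, logical(1))
      mean(enr$fold_enrichment[maps])
    }, numeric(1))
    candidates[[cond]] <- data.frame(tf = inter$tfs, fold_enrichment = fe,
                                     stringsAsFactors = FALSE)
    note(cond, ": ", nrow(enr), " enriched motifs, ",
         inter$n_intersection, " motif+DEG TFs")
  }

  ## --- cross-phase prioritization -----------------------------------------
  prioritized <- prioritize_across_timepoints(candidates)

  ## --- network on differentially expressed TFs ----------------------------
  diff_tfs <- tryCatch(
    find_differential_tfs(rna_norm, cells, tf_gene_set, injured[1],
                          control = control, min_pct = config$min_pct,
                          alpha_adj = config$alpha_adj),
    error = function(e) data.frame(feature_id = character())
  )
  network_tfs <- unique(c(diff_tfs$feature_id, prioritized$tf))
  network <- if (length(network_tfs)) {
    build_tf_gene_network(network_tfs, NULL, rna_norm, tss_norm,
                          r_min = config$r_min, alpha = config$alpha_edge)
  } else {
    structure(list(edges = data.frame(tf = character(), target = character(),
                                      rho = numeric(), p = numeric(),
                                      n_cells = integer()),
                   tf_nodes = character(), target_nodes = character(),
                   r_min = config$r_min, alpha = config$alpha_edge,
                   n_na_pairs = 0L), class = "regulatory_network")
  }
  note("network: ", nrow(network$edges), " edges over ",
       length(network$tf_nodes), " TFs")

  focal <- config$focal_tf
  if (is.null(focal))
    focal <- if (nrow(prioritized)) prioritized$tf[1] else NA_character_
  subnet <- if (!is.na(focal) && focal %in% network$tf_nodes)
    focal_tf_subnetwork(network, focal, k = config$top_k) else NULL
  note("focal TF: ", focal, " (",
       if (is.null(subnet)) 0 else nrow(subnet$edges), " subnetwork edges)")

  summary <- list(
    seed = config$seed,
    n_cells = nrow(sim$cells),
    n_neurons = nrow(cells),
    n_genes = cfg$n_genes,
    n_peaks = cfg$n_peaks,
    n_daps = lapply(daps, nrow),
    n_degs = lapply(degs, nrow),
    n_enriched_motifs = lapply(motifs, nrow),
    n_candidate_tfs = nrow(prioritized),
    top_prioritized_tf = if (nrow(prioritized)) prioritized$tf[1] else NA,
    n_network_edges = nrow(network$edges),
    focal_tf = focal,
    focal_subnetwork_size = if (is.null(subnet)) 0L else nrow(subnet$edges)
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (cond in injured) {
      write.table(daps[[cond]], file.path(outdir, paste0("daps_", cond, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(degs[[cond]], file.path(outdir, paste0("degs_", cond, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(motifs[[cond]],
                  file.path(outdir, paste0("motifs_", cond, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(prioritized, file.path(outdir, "prioritized_tfs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_network(network, file.path(outdir, "network_edges.tsv"), "edge_tsv")
    write_network(network, file.path(outdir, "network.graphml"), "graphml")
    if (!is.null(subnet))
      write_network(subnet, file.path(outdir, "focal_subnetwork.tsv"),
                    "edge_tsv")
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         na = "null")
    writeLines(log_lines, file.path(outdir, "pipeline.log"))
  }

  invisible(list(sim = sim, cells = cells, daps = daps, degs = degs,
                 motifs = motifs, candidates = candidates,
                 prioritized = prioritized, network = network,
                 focal_tf = focal, subnetwork = subnet, summary = summary))
}
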