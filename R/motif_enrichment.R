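#' GC fraction of a DNA sequence
#'
#' (#G + #C) / length. The ambiguous base N contributes to the denominator
#' only, so sequences containing N are pulled toward lower GC.
#'
#' @param sequence DNA string over A/C/G/T/N, length >= 1.
#' @return numeric in \code{[0, 1]}.
#' @export
gc_fraction <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  if (grepl("[^ACGTNacgtn]", sequence))
    stop("sequence contains characters outside A/C/G/T/N")
  chars <- strsplit(toupper(sequence), "")[[1]]
  sum(chars %in% c("G", "C")) / length(chars)
}

#' Convert a PFM to a position weight (log-odds) matrix
#'
#' Each cell becomes \code{log2(((count + pc * bg) / (colsum + pc)) / bg)}
#' with total pseudocount \code{pc} split across bases by the background
#' frequencies \code{bg}.
#'
#' @param x a \code{\link{pfm}}.
#' @param background base frequencies (A, C, G, T), summing to 1.
#' @param pseudocount total pseudocount added per column.
#' @return 4 x L numeric matrix of log2-odds scores.
#' @export
pfm_to_pwm <- function(x, background = rep(0.25, 4), pseudocount = 0.8) {
  if (length(background) != 4 || any(background <= 0))
    stop("background must be four positive frequencies")
  background <- background / sum(background)
  counts <- x$counts
  colsum <- rep(colSums(counts), each = 4)
  prob <- (counts + pseudocount * background) / (colsum + pseudocount)
  log2(prob / background)
}

#' Scan a sequence for motif hits on both strands
#'
#' Slides the PWM over the sequence and over its reverse complement and
#' reports windows whose log-odds score reaches \code{threshold_bits}.
#' Reverse-strand hits are reported in forward coordinates (1-based start of
#' the window on the given sequence). Windows containing N never match.
#'
#' @param sequence DNA string.
#' @param pfm a \code{\link{pfm}}.
#' @param background base frequencies for the log-odds (default uniform).
#' @param threshold_bits minimum score; default 80\% of the motif's maximum
#'   achievable score.
#' @param pseudocount total pseudocount per PFM column.
#' @return data.frame with start, strand, score; zero rows when the sequence
#'   is shorter than the motif or nothing matches.
#' @export
scan_motif <- function(sequence, pfm, background = rep(0.25, 4),
                       threshold_bits = NULL, pseudocount = 0.8) {
  pwm <- pfm_to_pwm(pfm, background, pseudocount)
  if (is.null(threshold_bits))
    threshold_bits <- 0.8 * sum(apply(pwm, 2, max))
  L <- ncol(pwm)
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  empty <- data.frame(start = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (n < L) return(empty)
  code <- match(chars, c("A", "C", "G", "T"))  # N -> NA
  W <- n - L + 1L
  fwd <- numeric(W); rev <- numeric(W)
  ## reverse-complement scan in forward coordinates: complement base,
  ## reversed column order
  for (j in seq_len(L)) {
    b <- code[j:(j + W - 1L)]
    fwd <- fwd + pwm[cbind(b, j)]
    rev <- rev + pwm[cbind(5L - b, L - j + 1L)]
  }
  fwd[is.na(fwd)] <- -Inf
  rev[is.na(rev)] <- -Inf
  fi <- which(fwd >= threshold_bits)
  ri <- which(rev >= threshold_bits)
  hits <- rbind(
    data.frame(start = fi, strand = rep("+", length(fi)),
               score = fwd[fi], stringsAsFactors = FALSE),
    data.frame(start = ri, strand = rep("-", length(ri)),
               score = rev[ri], stringsAsFactors = FALSE)
  )
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

#' Binary motif-occurrence matrix over peaks
#'
#' Scans every peak sequence with every motif and records presence/absence.
#'
#' @param peaks peak data.frame with peak_id and sequence columns.
#' @param pfms list of \code{\link{pfm}} objects.
#' @inheritParams scan_motif
#' @return list with \code{occurrence} (binary peaks x motifs matrix) and
#'   \code{scan_threshold_bits} (named per motif).
#' @export
motif_occurrence_matrix <- function(peaks, pfms, background = rep(0.25, 4),
                                    threshold_bits = NULL, pseudocount = 0.8) {
  if (is.null(peaks$sequence) || any(is.na(peaks$sequence)))
    stop("every peak needs a sequence to be scanned")
  ids <- vapply(pfms, function(m) m$motif_id, character(1))
  occ <- matrix(0L, nrow(peaks), length(pfms),
                dimnames = list(peaks$peak_id, ids))
  thr <- setNames(numeric(length(pfms)), ids)
  for (k in seq_along(pfms)) {
    pwm <- pfm_to_pwm(pfms[[k]], background, pseudocount)
    thr[k] <- if (is.null(threshold_bits)) 0.8 * sum(apply(pwm, 2, max))
              else threshold_bits
    for (i in seq_len(nrow(peaks))) {
      h <- scan_motif(peaks$sequence[i], pfms[[k]], background,
                      threshold_bits = thr[k], pseudocount = pseudocount)
      occ[i, k] <- as.integer(nrow(h) > 0)
    }
  }
  list(occurrence = occ, scan_threshold_bits = thr)
}

#' GC-matched background peak selection
#'
#' Bins the query peaks' GC fractions into \code{n_bins} quantile bins and
#' samples background peaks from the pool, without replacement, so that the
#' background's bin proportions match the query's (largest-remainder
#' rounding). All peaks must carry GC metadata.
#'
#' @param query_peaks,pool_peaks peak data.frames (pool disjoint from query).
#' @param n_background number of background peaks to draw.
#' @param n_bins number of GC quantile bins.
#' @param seed RNG seed for the sampling.
#' @return the sampled background peak data.frame.
#' @export
match_background_by_gc <- function(query_peaks, pool_peaks, n_background,
                                   n_bins = 10, seed = 0L) {
  if (any(is.na(query_peaks$gc_fraction)) || any(is.na(pool_peaks$gc_fraction)))
    stop("all query and pool peaks must have non-missing GC fractions")
  if (length(intersect(query_peaks$peak_id, pool_peaks$peak_id)))
    stop("pool peaks must be disjoint from query peaks")
  if (n_background > nrow(pool_peaks))
    stop("pool smaller than requested background size")
  breaks <- gc_quantile_breaks(query_peaks$gc_fraction, n_bins)
  qbin <- cut(query_peaks$gc_fraction, breaks, include.lowest = TRUE)
  pbin <- cut(pool_peaks$gc_fraction, breaks, include.lowest = TRUE)
  prop <- tabulate(qbin, nbins = nlevels(qbin)) / nrow(query_peaks)
  take <- lr_apportion(n_background, prop)
  set.seed(seed)
  sel <- integer(0)
  for (b in seq_len(nlevels(qbin))) {
    if (take[b] == 0) next
    cand <- which(as.integer(pbin) == b)
    if (length(cand) < take[b])
      stop("background pool too small in GC bin ", levels(qbin)[b],
           " (need ", take[b], ", have ", length(cand), ")")
    sel <- c(sel, if (length(cand) == 1) cand else sample(cand, take[b]))
  }
  out <- pool_peaks[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Largest GC-matched background drawable from a pool
#'
#' Given the query's GC quantile bins, returns the largest background size
#' for which \code{\link{match_background_by_gc}} can fill every bin from
#' the pool in the query's proportions.
#'
#' @inheritParams match_background_by_gc
#' @return integer, the maximal feasible \code{n_background}.
#' @export
feasible_background_size <- function(query_peaks, pool_peaks, n_bins = 10) {
  breaks <- gc_quantile_breaks(query_peaks$gc_fraction, n_bins)
  qbin <- cut(query_peaks$gc_fraction, breaks, include.lowest = TRUE)
  pbin <- cut(pool_peaks$gc_fraction, breaks, include.lowest = TRUE)
  prop <- tabulate(qbin, nbins = nlevels(qbin)) / nrow(query_peaks)
  avail <- tabulate(pbin, nbins = nlevels(qbin))
  used <- prop > 0
  n <- as.integer(floor(min(avail[used] / prop[used])))
  # largest-remainder rounding may push a bin one above n * prop; back off
  while (n > 0 && any(lr_apportion(n, prop) > avail)) n <- n - 1L
  n
}

# internal: GC quantile breaks over the query, clamped to the query range
# (pool peaks outside it are never drawn); degenerate single-value queries
# get one narrow bin around that value
gc_quantile_breaks <- function(gc, n_bins) {
  br <- unique(quantile(gc, probs = seq(0, 1, length.out = n_bins + 1)))
  eps <- 1e-8
  if (length(br) == 1) return(c(br - eps, br + eps))
  br[1] <- br[1] - eps
  br[length(br)] <- br[length(br)] + eps
  br
}

# internal: largest-remainder apportionment of n over bin proportions
lr_apportion <- function(n, prop) {
  raw <- prop * n
  take <- floor(raw)
  rem <- n - sum(take)
  if (rem > 0) {
    extra <- order(raw - take, decreasing = TRUE)[seq_len(rem)]
    take[extra] <- take[extra] + 1L
  }
  take
}

#' Hypergeometric motif over-representation in query peaks
#'
#' For each motif, tests whether the motif-positive fraction among the query
#' peaks exceeds the background's, with the background as the sampled
#' population: \code{P(X >= n_query_pos)} for
#' \code{X ~ Hypergeom(N = n_bg, K = n_bg_pos, draws = n_query)}. Fold
#' enrichment is the ratio of observed to background positive fractions.
#' A motif absent from the background but present in the query gets
#' \code{fold_enrichment = Inf} and \code{p = NA} with \code{flagged = TRUE}.
#'
#' @param query_peaks,background_peaks peak data.frames (peak_id used).
#' @param occ result of \code{\link{motif_occurrence_matrix}} (or its
#'   \code{occurrence} matrix) covering both peak sets.
#' @return data.frame of enrichment records: motif_id, motif_name (when
#'   available), counts, fractions, fold_enrichment, p, flagged.
#' @export
test_motif_enrichment <- function(query_peaks, background_peaks, occ) {
  if (is.list(occ) && !is.matrix(occ)) occ <- occ$occurrence
  qid <- query_peaks$peak_id; bid <- background_peaks$peak_id
  missing <- setdiff(c(qid, bid), rownames(occ))
  if (length(missing))
    stop("occurrence matrix does not cover peaks: ",
         paste(head(missing, 3), collapse = ", "))
  n_query <- length(qid); n_bg <- length(bid)
  qpos <- colSums(occ[qid, , drop = FALSE])
  bpos <- colSums(occ[bid, , drop = FALSE])
  pct_obs <- qpos / n_query
  pct_bg <- bpos / n_bg
  fold <- ifelse(bpos == 0, ifelse(qpos == 0, NA_real_, Inf),
                 pct_obs / pct_bg)
  p <- ifelse(bpos == 0, NA_real_,
              phyper(qpos - 1, bpos, n_bg - bpos, n_query,
                     lower.tail = FALSE))
  data.frame(
    motif_id = colnames(occ),
    n_query_pos = as.integer(qpos), n_query = n_query,
    n_bg_pos = as.integer(bpos), n_bg = n_bg,
    pct_observed = pct_obs, pct_background = pct_bg,
    fold_enrichment = fold, p = p,
    flagged = bpos == 0 & qpos > 0,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Filter and rank motif enrichment records
#'
#' Keeps records with \code{fold_enrichment > fold_min} and \code{p < alpha},
#' sorted by descending fold enrichment; ties are broken by ascending p,
#' then motif id.
#'
#' @param records data.frame from \code{\link{test_motif_enrichment}}.
#' @param fold_min fold-enrichment threshold (exclusive).
#' @param alpha p-value threshold (exclusive).
#' @return the filtered, ordered data.frame.
#' @export
rank_motifs <- function(records, fold_min = 0.5, alpha = 0.05) {
  keep <- !is.na(records$p) & !is.na(records$fold_enrichment) &
    records$fold_enrichment > fold_min & records$p < alpha
  out <- records[keep, , drop = FALSE]
  out <- out[order(-out$fold_enrichment, out$p, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map motif names to candidate TF gene symbols
#'
#' Heterodimer names (\code{"TFA::TFB"}) split into both constituents;
#' matching downstream is case-insensitive.
#'
#' @param motif_names character vector of motif names.
#' @return character vector of unique candidate gene symbols.
#' @export
motif_names_to_genes <- function(motif_names) {
  unique(unlist(strsplit(motif_names, "::", fixed = TRUE), use.names = FALSE))
}
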