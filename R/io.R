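#' Position frequency matrix
#'
#' Nucleotide counts per motif column, rows A, C, G, T.
#'
#' @param motif_id motif identifier (e.g. a JASPAR accession).
#' @param motif_name motif name; for TF motifs usually the TF gene symbol,
#'   with heterodimers written \code{"TFA::TFB"}.
#' @param counts numeric matrix, 4 rows x L columns, non-negative, every
#'   column summing to a positive value.
#' @return an object of class \code{pfm}.
#' @export
pfm <- function(motif_id, motif_name, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4)
    stop("PFM must have exactly 4 rows (A, C, G, T)")
  if (ncol(counts) < 1) stop("PFM must have at least one column")
  if (any(counts < 0)) stop("PFM counts must be non-negative")
  if (any(colSums(counts) <= 0)) stop("every PFM column sum must be > 0")
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(motif_id = as.character(motif_id),
                 motif_name = as.character(motif_name),
                 counts = counts),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %s (%s), length %d, consensus %s\n",
              x$motif_id, x$motif_name, ncol(x$counts), pfm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PFM (highest count per column, ties to the
#' alphabetically first base)
#' @param x a \code{pfm}.
#' @return character scalar.
#' @export
pfm_consensus <- function(x) {
  paste(rownames(x$counts)[apply(x$counts, 2, which.max)], collapse = "")
}

#' Read a MatrixMarket count matrix with feature/barcode sidecars
#'
#' Files on disk follow the cellranger-style layout: the MTX holds features
#' in rows and cells in columns with 1-based coordinates; internally the
#' matrix is transposed to cells x features.
#'
#' @param mtx_path MatrixMarket coordinate file.
#' @param features_path,barcodes_path one-id-per-line TSVs (first column used).
#' @param modality modality tag for the result.
#' @return a \code{\link{count_matrix}}.
#' @export
read_count_matrix <- function(mtx_path, features_path, barcodes_path,
                              modality = c("RNA", "ATAC_PEAK", "ATAC_TSS")) {
  modality <- match.arg(modality)
  m <- Matrix::readMM(mtx_path)
  # readMM may return symmetric/pattern classes; force a general numeric
  # matrix so asymmetric dimnames can be attached
  m <- as(as(m, "dMatrix"), "generalMatrix")
  features <- read.table(features_path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)[[1]]
  barcodes <- read.table(barcodes_path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(features))
    stop("feature count mismatch between ", mtx_path, " and ", features_path)
  if (ncol(m) != length(barcodes))
    stop("barcode count mismatch between ", mtx_path, " and ", barcodes_path)
  if (anyDuplicated(features))
    stop("duplicate feature ids in ", features_path)
  if (anyDuplicated(barcodes))
    stop("duplicate barcode ids in ", barcodes_path)
  m <- Matrix::t(m)
  dimnames(m) <- list(barcodes, features)
  count_matrix(m, modality)
}

#' Write a count matrix as MatrixMarket plus sidecars
#'
#' Inverse of \code{\link{read_count_matrix}}: the matrix is written
#' features x cells.
#'
#' @param x a \code{\link{count_matrix}}.
#' @param mtx_path,features_path,barcodes_path output paths.
#' @return invisibly, the three paths.
#' @export
write_count_matrix <- function(x, mtx_path, features_path, barcodes_path) {
  check_count_matrix(x)
  Matrix::writeMM(Matrix::t(x$values), mtx_path)
  writeLines(feature_ids(x), features_path)
  writeLines(cell_ids(x), barcodes_path)
  invisible(c(mtx_path, features_path, barcodes_path))
}

#' Read peaks from a BED file
#'
#' BED is 0-based half-open; coordinates are kept unchanged. Column 4 is the
#' peak id (generated as \code{chrom:start-end} when absent), column 5 (score)
#' carries the GC fraction when present (\code{"."} = missing).
#'
#' @param path BED file (3-6 columns, tab-separated).
#' @return data.frame with chrom, start, end, peak_id, gc_fraction.
#' @export
read_peaks_bed <- function(path) {
  b <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (ncol(b) < 3) stop("BED file ", path, " has fewer than 3 columns")
  start <- as.integer(b[[2]]); end <- as.integer(b[[3]])
  if (any(is.na(start)) || any(is.na(end)))
    stop("non-numeric coordinates in ", path)
  if (any(start >= end))
    stop("BED intervals with start >= end in ", path)
  peak_id <- if (ncol(b) >= 4) b[[4]] else sprintf("%s:%d-%d", b[[1]], start, end)
  gc <- rep(NA_real_, nrow(b))
  if (ncol(b) >= 5) {
    ok <- b[[5]] != "."
    gc[ok] <- as.numeric(b[[5]][ok])
  }
  data.frame(chrom = b[[1]], start = start, end = end, peak_id = peak_id,
             gc_fraction = gc, stringsAsFactors = FALSE)
}

#' Write peaks as BED6
#'
#' @param peaks data.frame with chrom, start, end, peak_id and optionally
#'   gc_fraction (written into the score column, \code{"."} when missing).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_peaks_bed <- function(peaks, path) {
  gc <- if ("gc_fraction" %in% names(peaks)) peaks$gc_fraction else NA_real_
  score <- ifelse(is.na(gc), ".", format(gc, digits = 10, trim = TRUE))
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                    score, ".", stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a FASTA file into a named vector of sequences
#'
#' Multi-line records are joined; sequences must be over the A/C/G/T/N
#' alphabet (case-insensitive, returned upper-case).
#'
#' @param path FASTA file.
#' @return named character vector, names = record ids (first word of header).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (any(grepl("[^ACGTN]", seqs)))
    stop("non-ACGTN characters in sequences of ", path)
  seqs
}

#' Write named sequences as FASTA
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read motifs from a JASPAR-format text file
#'
#' Parses the standard JASPAR layout: a \code{">id name"} header followed by
#' four rows, one per base, e.g. \code{A  [ 4  0 12 ]}. Bare whitespace-
#' separated numbers without base letter or brackets are also accepted.
#'
#' @param path JASPAR text file.
#' @return list of \code{\link{pfm}} objects.
#' @export
read_jaspar_pfms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR motif headers ('>') found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[i]])
    parts <- strsplit(trimws(header), "\\s+")[[1]]
    motif_id <- parts[1]
    motif_name <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else parts[1]
    body <- lines[(starts[i] + 1L):ends[i]]
    if (length(body) != 4)
      stop("motif ", motif_id, " in ", path, " does not have 4 count rows")
    rows <- lapply(body, function(l) {
      l <- sub("^\\s*[ACGTacgt]\\s*", "", l)
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    L <- unique(vapply(rows, length, integer(1)))
    if (length(L) != 1)
      stop("ragged count rows for motif ", motif_id, " in ", path)
    out[[i]] <- pfm(motif_id, motif_name, do.call(rbind, rows))
  }
  out
}

#' Write motifs in JASPAR text format
#' @param pfms list of \code{\link{pfm}} objects.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_jaspar_pfms <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in pfms) {
    writeLines(sprintf(">%s %s", m$motif_id, m$motif_name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(m$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Write a regulatory network to disk
#'
#' @param network a \code{regulatory_network}
#'   (see \code{\link{build_tf_gene_network}}).
#' @param path output path.
#' @param format \code{"edge_tsv"} (one row per edge: tf, target, rho, p) or
#'   \code{"graphml"}.
#' @return invisibly, the path.
#' @export
write_network <- function(network, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  edges <- network$edges[, c("tf", "target", "rho", "p"), drop = FALSE]
  if (format == "edge_tsv") {
    write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    nodes <- data.frame(
      name = c(unique(edges$tf), setdiff(unique(edges$target), unique(edges$tf))),
      stringsAsFactors = FALSE
    )
    g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
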