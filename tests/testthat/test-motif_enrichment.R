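test_that("GC fraction counts G+C over the full length, N in denominator", {
  expect_equal(gc_fraction("ACGT"), 0.5)
  expect_equal(gc_fraction("AAAA"), 0)
  expect_equal(gc_fraction("GCGC"), 1)
  expect_equal(gc_fraction("GCNN"), 0.5)
  expect_equal(gc_fraction("acgt"), 0.5)
  expect_error(gc_fraction("ACGU"), "A/C/G/T/N")
  expect_error(gc_fraction(""), "non-empty")
})

test_that("a uniform PFM scores every window at zero bits", {
  u <- pfm("U", "U", matrix(5, 4, 3))
  pwm <- pfm_to_pwm(u)
  expect_equal(max(abs(pwm)), 0, tolerance = 1e-12)
  hits <- scan_motif("ACGTACGTAC", u, threshold_bits = 0)
  expect_equal(nrow(hits), 2 * (10 - 3 + 1))  # every window, both strands
  expect_true(all(abs(hits$score) < 1e-12))
})

test_that("sequences shorter than the motif return an empty hit table", {
  m <- pfm("M", "M", matrix(c(9, 1, 1, 1), 4, 5))
  hits <- scan_motif("ACG", m)
  expect_equal(nrow(hits), 0)
})

test_that("planted consensus sites are detected at the default threshold", {
  cfg <- small_config(seed = 10, motif_planting_rate_dap = 1,
                      motif_planting_rate_background = 0,
                      missing_gc_fraction = 0)
  r <- generate_rna_counts(cfg)
  s <- generate_peak_sequences(cfg, r$truth)
  planted <- s$peaks$peak_id %in% s$truth$motif$positive_peak_ids
  n_hits <- vapply(s$peaks$sequence, function(sq) {
    nrow(scan_motif(sq, s$pfm))
  }, numeric(1), USE.NAMES = FALSE)
  expect_true(all(n_hits[planted] >= 1))
})

test_that("scanning is strand-symmetric", {
  set.seed(11)
  counts <- matrix(rpois(4 * 6, 3) + 1, 4, 6)
  m <- pfm("M", "M", counts)
  # reverse-complement PFM: rows A<->T, C<->G, columns reversed
  rc <- pfm("MRC", "MRC", counts[4:1, 6:1])
  for (rep in 1:5) {
    sq <- random_dna(60)
    h1 <- scan_motif(sq, m, threshold_bits = 2)
    h2 <- scan_motif(sq, rc, threshold_bits = 2)
    # same windows, opposite strands
    expect_setequal(paste(h1$start, h1$strand),
                    paste(h2$start, chartr("+-", "-+", h2$strand)))
    expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-12)
  }
  # scanning the reverse-complemented sequence mirrors coordinates
  sq <- random_dna(50)
  h <- scan_motif(sq, m, threshold_bits = 2)
  hr <- scan_motif(revcomp(sq), m, threshold_bits = 2)
  L <- ncol(m$counts)
  expect_setequal(paste(h$start, h$strand),
                  paste(50 - L + 2 - hr$start, chartr("+-", "-+", hr$strand)))
})

test_that("GC-matched background reproduces the query's GC composition", {
  set.seed(12)
  mkpeaks <- function(gc, prefix) {
    data.frame(chrom = "chr1", start = seq_along(gc) * 100,
               end = seq_along(gc) * 100 + 50,
               peak_id = sprintf("%s%04d", prefix, seq_along(gc)),
               gc_fraction = gc, stringsAsFactors = FALSE)
  }
  gc <- rbeta(200, 5, 5)
  query <- mkpeaks(gc, "q")
  pool <- mkpeaks(rep(gc, 3), "b")  # identical GC composition, 3x size
  bg <- match_background_by_gc(query, pool, 200, n_bins = 10, seed = 1)
  brk <- quantile(query$gc_fraction, seq(0, 1, 0.1))
  brk[1] <- -Inf; brk[11] <- Inf
  hq <- table(cut(query$gc_fraction, brk))
  hb <- table(cut(bg$gc_fraction, brk))
  expect_true(all(abs(hq - hb) <= 1))

  # two-block pool: query all high-GC -> background drawn from the
  # high-GC half only
  q2 <- mkpeaks(rep(0.7, 50), "q")
  p2 <- mkpeaks(c(rep(0.3, 100), rep(0.7, 100)), "b")
  bg2 <- match_background_by_gc(q2, p2, 80, seed = 2)
  expect_true(all(bg2$gc_fraction == 0.7))

  expect_error(match_background_by_gc(q2, p2, 150, seed = 2), "GC bin")
  expect_error(match_background_by_gc(q2, p2[1:10, ], 50, seed = 2),
               "smaller")
  expect_error(match_background_by_gc(query, query, 10, seed = 1), "disjoint")
})

test_that("GC matching beats random background sampling", {
  ks <- function(a, b) suppressWarnings(ks.test(a, b)$statistic)
  wins <- 0L; attempts <- 0L
  for (seed in 1:20) {
    set.seed(seed + 100)
    qgc <- rbeta(80, 7, 5)        # GC-rich query
    pgc <- rbeta(1500, 5, 7)      # GC-poorer pool
    query <- data.frame(chrom = "c", start = 1:80, end = 2:81,
                        peak_id = sprintf("q%d", 1:80), gc_fraction = qgc,
                        stringsAsFactors = FALSE)
    pool <- data.frame(chrom = "c", start = 1:1500, end = 2:1501,
                       peak_id = sprintf("b%d", 1:1500), gc_fraction = pgc,
                       stringsAsFactors = FALSE)
    n_bg <- min(150, feasible_background_size(query, pool))
    if (n_bg < 20) next  # top query GC bin unrepresented in the pool
    attempts <- attempts + 1L
    bg <- match_background_by_gc(query, pool, n_bg, seed = seed)
    set.seed(seed)
    rnd <- pool[sample(1500, n_bg), ]
    if (ks(qgc, bg$gc_fraction) <= ks(qgc, rnd$gc_fraction)) wins <- wins + 1L
  }
  expect_gte(attempts, 12)
  expect_gte(wins, attempts - 1L)
})

test_that("hypergeometric enrichment matches the closed-form example", {
  query <- data.frame(peak_id = sprintf("q%d", 1:10), stringsAsFactors = FALSE)
  bg <- data.frame(peak_id = sprintf("b%d", 1:100), stringsAsFactors = FALSE)
  occ <- matrix(0L, 110, 1,
                dimnames = list(c(query$peak_id, bg$peak_id), "M1"))
  occ[c(sprintf("q%d", 1:4), sprintf("b%d", 1:10)), 1] <- 1L
  rec <- test_motif_enrichment(query, bg, occ)
  expect_equal(rec$fold_enrichment, 4.0)
  expect_equal(rec$p, hyper_tail_bruteforce(4, 10, 100, 10), tolerance = 1e-12)
  expect_equal(rec$p, 0.0082, tolerance = 1e-2)

  # same composition as background -> fold 1
  occ2 <- occ; occ2[, 1] <- 0L
  occ2[c(sprintf("q%d", 1:2), sprintf("b%d", 1:20)), 1] <- 1L
  expect_equal(test_motif_enrichment(query, bg, occ2)$fold_enrichment, 1.0)

  # motif absent from background but present in query
  occ3 <- occ; occ3[, 1] <- 0L; occ3["q1", 1] <- 1L
  rec3 <- test_motif_enrichment(query, bg, occ3)
  expect_true(is.infinite(rec3$fold_enrichment))
  expect_true(is.na(rec3$p))
  expect_true(rec3$flagged)
})

test_that("hypergeometric tail equals brute-force enumeration (N <= 30)", {
  set.seed(14)
  for (rep in 1:100) {
    N <- sample(5:30, 1)
    K <- sample(0:N, 1)
    draws <- sample(1:N, 1)
    q <- sample(0:min(K, draws), 1)
    ours <- phyper(q - 1, K, N - K, draws, lower.tail = FALSE)
    expect_equal(ours, hyper_tail_bruteforce(q, K, N, draws),
                 tolerance = 1e-12)
  }
})

test_that("enrichment is invariant to peak and motif order", {
  set.seed(15)
  peaks <- data.frame(peak_id = sprintf("p%d", 1:60), stringsAsFactors = FALSE)
  occ <- matrix(rbinom(60 * 3, 1, 0.3), 60, 3,
                dimnames = list(peaks$peak_id, c("M1", "M2", "M3")))
  q <- peaks[1:20, , drop = FALSE]; b <- peaks[21:60, , drop = FALSE]
  r1 <- test_motif_enrichment(q, b, occ)
  perm <- sample(60); mperm <- sample(3)
  r2 <- test_motif_enrichment(q[sample(20), , drop = FALSE],
                              b[sample(40), , drop = FALSE],
                              occ[perm, mperm])
  r2 <- r2[match(r1$motif_id, r2$motif_id), ]
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$fold_enrichment, r2$fold_enrichment, tolerance = 1e-12)
})

test_that("motif ranking applies both thresholds and the tie rules", {
  rec <- data.frame(
    motif_id = c("A", "B", "C"),
    fold_enrichment = c(3.0, 0.4, 2.0),
    p = c(0.01, 0.001, 0.2),
    stringsAsFactors = FALSE
  )
  out <- rank_motifs(rec, fold_min = 0.5, alpha = 0.05)
  expect_equal(out$motif_id, "A")
  expect_equal(nrow(rank_motifs(rec[0, ])), 0)

  tie <- data.frame(motif_id = c("M2", "M1"),
                    fold_enrichment = c(2, 2), p = c(0.01, 0.001),
                    stringsAsFactors = FALSE)
  expect_equal(rank_motifs(tie)$motif_id, c("M1", "M2"))
  # fold in (0.5, 1]: depleted-but-passing motifs are kept, as configured
  dep <- data.frame(motif_id = "D", fold_enrichment = 0.8, p = 0.01,
                    stringsAsFactors = FALSE)
  expect_equal(nrow(rank_motifs(dep)), 1)
  expect_equal(nrow(rank_motifs(dep, fold_min = 1)), 0)
})

test_that("motif names map to TF genes with heterodimer splitting", {
  expect_setequal(motif_names_to_genes(c("Creb5", "Tfa::Tfb", "Creb5")),
                  c("Creb5", "Tfa", "Tfb"))
})
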