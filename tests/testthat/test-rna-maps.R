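test_that("junction map formula matches hand arithmetic", {
  ## one internal junction, one mRNA of length 600, all 20 starts at -24:
  ## raw[-24] = (20/20) * 600 / 1 = 600, 0 elsewhere
  cd <- make_cdnas("tx1", start = rep(300L - 24L, 20), end = rep(305L, 20))
  jx <- data.table::data.table(ref = "tx1", pos = 300L, internal = TRUE)
  data.table::setattr(jx, "seqlens", c(tx1 = 600L))
  jm <- junction_map(cd, jx, "starts", window = 30, smooth = 0)
  expect_equal(jm$raw[jm$offset == -24], 600)
  expect_equal(sum(jm$raw), 600)
  expect_error(junction_map(cd[0], jx), "zero cDNAs")
})

test_that("a uniform library normalises to 1 everywhere", {
  L <- 3000L
  truncmap:::with_seed(55, {
    st <- sample.int(L - 40L, 30000L, replace = TRUE) - 1L
  })
  cd <- make_cdnas("tx1", start = st, end = st + 29L)
  jx <- data.table::data.table(ref = "tx1", pos = c(1000L, 2000L),
                               internal = TRUE)
  data.table::setattr(jx, "seqlens", c(tx1 = L))
  jm <- junction_map(cd, jx, "starts", window = 100, smooth = 0)
  ## expected value 1 with binomial noise: 3 sigma per-offset tolerance
  p <- 2 / (L - 40)
  sigma <- sqrt(30000 * p * (1 - p)) / (30000 * p)
  expect_true(all(abs(jm$raw - 1) < 3.5 * sigma + 0.2))
  expect_lt(abs(mean(jm$raw) - 1), 0.05)
})

test_that("EJC-like truncation geometry enriches starts just downstream
           of the deposition site", {
  ## crosslinks planted at junction offsets -25..-21 (one nt upstream of
  ## the canonical deposition region), truncated starts land at -24..-20
  cfg <- sim_config(seed = 121, n_transcripts = 4,
                    transcript_length = 3000, exon_length = 300,
                    site_model = list(list(kind = "junction",
                                           offsets = c(-25, -21))),
                    truncation_rate = 1, n_molecules = 4000)
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_reads(tx$sequences, tx$annotation, cfg)
  jx <- tx$annotation$junctions
  data.table::setattr(jx, "seqlens", tx$annotation$seqlens)
  jm <- junction_map(collapse_umis(sim$reads), jx, "starts",
                     window = 60, smooth = 0)
  expect_true(jm$offset[which.max(jm$raw)] %in% -24:-20)
  inside <- sum(jm$raw[jm$offset %in% -24:-20])
  expect_gt(inside / sum(jm$raw), 0.9)
})

test_that("gaussian smoothing preserves mass to 1e-9", {
  truncmap:::with_seed(2, {
    x <- c(rep(0, 20), runif(60) * 5, rep(0, 20))
  })
  for (w in c(5, 10)) {
    sm <- gauss_smooth(x, w)
    expect_lt(abs(sum(sm) - sum(x)), 1e-9)
  }
  ## a point mass spreads but keeps its total
  pt <- c(rep(0, 50), 7, rep(0, 50))
  expect_lt(abs(sum(gauss_smooth(pt, 5)) - 7), 1e-9)
})

test_that("ytract map is exactly 1 for constant counts and scale-free", {
  yt <- data.table::data.table(ref = "tx1", start = 300L, end = 340L)
  ## constant coverage everywhere: every position has one end
  pos <- 0:999
  cd <- make_cdnas("tx1", start = pmax(0L, pos - 29L), end = pos)
  ym <- ytract_map(cd, yt, "ends", search_flank = 100, smooth = 0)
  expect_true(all(abs(ym$raw - 1) < 1e-12))

  ## multiplying one site's counts by a constant changes nothing
  yt2 <- data.table::data.table(ref = c("tx1", "tx2"),
                                start = c(300L, 300L), end = c(340L, 340L))
  truncmap:::with_seed(8, {
    st1 <- sample(100:900, 500, TRUE)
    st2 <- sample(100:900, 500, TRUE)
  })
  cd1 <- make_cdnas("tx1", start = st1, end = st1 + 29L)
  cd2 <- make_cdnas("tx2", start = st2, end = st2 + 29L)
  both <- as_cdna_tbl(data.table::rbindlist(list(cd1, cd2)))
  scaled <- data.table::copy(both)
  scaled[scaled$ref == "tx2", "count"] <- 5L
  m1 <- ytract_map(both, yt2, "ends", smooth = 0)
  m2 <- ytract_map(scaled, yt2, "ends", smooth = 0)
  expect_equal(m1$raw, m2$raw, tolerance = 1e-12)
})

test_that("ytract geometry: short cDNAs map the 3' region, long the 5'", {
  ## crosslinks across a 40-nt tract, cleavage only downstream of it
  cfg <- sim_config(seed = 81, n_transcripts = 2, transcript_length = 2000,
                    site_model = list(list(kind = "ytract", length = 40,
                                           n = 4)),
                    cleavage_model = list(kind = "positional",
                                          positions = NULL),
                    cdna_length_dist = list(values = 17:60),
                    truncation_rate = 1, n_molecules = 6000)
  tx <- simulate_transcriptome(cfg)
  yt <- tx$annotation$ytracts
  cfg$cleavage_model$positions <- lapply(split(yt, yt$ref), function(d)
    sort(as.integer(d$end + 10L)))
  sim <- simulate_reads(tx$sequences, tx$annotation, cfg)
  col <- collapse_umis(sim$reads)
  dt <- data.table::as.data.table(col)
  dt$category <- length_category(dt$length)
  yt_i <- yt[1]
  short_starts <- dt[ref == yt_i$ref & category == "17-29" &
                     start >= yt_i$start & start < yt_i$end, start]
  long_starts <- dt[ref == yt_i$ref & category == ">39" &
                    start >= yt_i$start & start < yt_i$end, start]
  expect_gt(length(short_starts), 0)
  expect_gt(length(long_starts), 0)
  expect_gt(mean(short_starts), mean(long_starts))
})

test_that("end-peak grouped heatmap normalises to a global max of 1", {
  cfg <- sim_config(seed = 91, n_transcripts = 3, transcript_length = 3000,
                    exon_length = 300,
                    site_model = list(list(kind = "junction",
                                           offsets = c(-25, -21))),
                    truncation_rate = 1, n_molecules = 3000)
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_reads(tx$sequences, tx$annotation, cfg)
  col <- collapse_umis(sim$reads)
  jx <- tx$annotation$junctions[tx$annotation$junctions$internal == TRUE]
  ep <- junction_end_peak(col, jx, coverage_quantile = 0)
  hm <- endpeak_grouped_heatmap(col, jx, ep, n_top = 50)
  expect_equal(max(hm), 1)
  expect_equal(nrow(hm), length(unique(ep$peak_offset)))
  ## all end peaks identical -> one row
  ep1 <- data.table::copy(ep)
  ep1$peak_offset <- 5L
  hm1 <- endpeak_grouped_heatmap(col, jx, ep1, n_top = 50)
  expect_equal(nrow(hm1), 1L)
})

test_that("reachability follows the 17-nt rule", {
  ep <- data.table::data.table(ref = "tx1", junction_pos = 1000L,
                               peak_offset = c(-30L, -3L, 20L, -20L))
  fl <- reachability_flags(ep)
  ## peak upstream of the region flagged separately
  expect_equal(fl$peak_upstream, c(TRUE, FALSE, FALSE, FALSE))
  ## -3 - (-20) = 17 -> exactly reachable; 20 nt downstream -> reachable;
  ## peak at the region 3' edge -> not reachable
  expect_equal(fl$reachable, c(FALSE, TRUE, TRUE, FALSE))

  ## uniform end-peak offsets: flagged fraction matches the analytic rule
  offs <- -30:30
  epu <- data.table::data.table(ref = "x", junction_pos = 0L,
                                peak_offset = offs)
  flu <- reachability_flags(epu)
  expect_equal(mean(flu$reachable),
               mean(offs >= -20L + 17L))
})

test_that("end nucleotide composition sums to 1 and sees cut-after-A", {
  cfg <- sim_config(seed = 101, n_transcripts = 2,
                    transcript_length = 2000,
                    site_model = list(list(kind = "motif", motif = "TTGG",
                                           n = 20)),
                    cleavage_model = list(kind = "sequence", base = "A"),
                    truncation_rate = 1, n_molecules = 2000)
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_reads(tx$sequences, tx$annotation, cfg)
  col <- collapse_umis(sim$reads)
  comp <- end_nucleotide_composition(col, tx$sequences)
  expect_true(all(abs(rowSums(as.matrix(comp[, -1])) - 1) < 1e-12))
  expect_equal(comp$A[comp$offset == 0], 1)

  ## null: uniform ends on i.i.d. sequence -> all fractions ~ 0.25
  truncmap:::with_seed(9, {
    seqs0 <- c(tx1 = random_seq(5000))
    en <- sample(100:4900, 4000, replace = TRUE)
  })
  cd0 <- make_cdnas("tx1", start = en - 29L, end = en)
  comp0 <- end_nucleotide_composition(cd0, seqs0)
  expect_true(all(abs(as.matrix(comp0[, -1]) - 0.25) < 0.05))
})

test_that("intron end fraction matches the analytic expectation", {
  introns <- data.table::data.table(ref = "tx1", start = 0L, end = 1000L)
  ## all ends on the last intronic nucleotide
  cd <- make_cdnas("tx1", start = rep(970L, 10), end = rep(999L, 10))
  expect_equal(intron_end_fraction(cd, introns)$fraction, 1)
  ## uniform ends over the intron ~ 2/1000
  truncmap:::with_seed(6, {
    en <- sample.int(1000L, 50000L, replace = TRUE) - 1L
  })
  cdu <- make_cdnas("tx1", start = pmax(0L, en - 29L), end = en)
  f <- intron_end_fraction(cdu, introns)
  expect_equal(f$fraction, 2 / 1000, tolerance = 0.35)
  ## PCR duplication invariance after collapse
  dup <- data.table::copy(cdu)
  dup$count <- 4L
  expect_equal(intron_end_fraction(dup, introns)$fraction, f$fraction)
  ## no intronic cDNAs -> flagged
  far <- make_cdnas("tx2", start = 1L, end = 30L)
  expect_true(intron_end_fraction(far, introns)$flagged)
})

test_that("pentamer discovery recovers a planted motif and stays quiet
           on nulls", {
  truncmap:::with_seed(17, {
    seqs <- c(tx1 = random_seq(30000))
  })
  ## plant TCTTT at every peak
  sch <- strsplit(seqs[["tx1"]], "")[[1]]
  peaks <- seq(500L, 29000L, by = 250L)
  for (p in peaks) sch[(p + 1):(p + 5)] <- c("T", "C", "T", "T", "T")
  seqs_planted <- c(tx1 = paste0(sch, collapse = ""))
  sp <- data.table::data.table(ref = "tx1", pos = as.integer(peaks + 2L))
  tab <- discover_pentamers(sp, seqs_planted, n_shuffles = 30, seed = 4)
  expect_equal(tab$kmer[1], "TCTTT")
  expect_gt(tab$z[1], 10)

  ## null: random peaks on random sequence
  truncmap:::with_seed(18, {
    sp0 <- data.table::data.table(
      ref = "tx1", pos = sample(500:29000, 100))
  })
  tab0 <- discover_pentamers(sp0, seqs, n_shuffles = 30, seed = 5)
  expect_lt(max(tab0$z, na.rm = TRUE), 10)
})

test_that("cluster motif heatmap has the advertised shape", {
  truncmap:::with_seed(19, {
    seqs <- c(tx1 = random_seq(20000))
  })
  ## clusters made of pure TTGG repeats -> coverage 1 inside the span
  sch <- strsplit(seqs[["tx1"]], "")[[1]]
  cl_start <- seq(200L, 19000L, by = 400L)
  cl_len <- rep(c(20L, 40L, 60L), length.out = length(cl_start))
  for (i in seq_along(cl_start)) {
    idx <- (cl_start[i] + 1):(cl_start[i] + cl_len[i])
    sch[idx] <- rep(c("T", "T", "G", "G"), length.out = length(idx))
  }
  seqs2 <- c(tx1 = paste0(sch, collapse = ""))
  cl <- data.table::data.table(ref = "tx1", start = cl_start,
                               end = cl_start + cl_len,
                               count = 10L)
  hm <- cluster_motif_heatmap(cl, c("TTGG"), seqs2, row_size = 20,
                              flank = 10)
  expect_equal(nrow(hm), ceiling(nrow(cl) / 20))
  expect_true(attr(hm, "flagged_single_row") == FALSE)
  ## rows of planted motif-defined clusters: high coverage inside,
  ## falling off at the boundary
  inside <- hm[, colnames(hm) == "5"]
  outside <- hm[, colnames(hm) == "-10"]
  expect_true(all(inside > 0.9, na.rm = TRUE))
  expect_true(all(outside < 0.5, na.rm = TRUE))
  ## fewer clusters than row_size -> one flagged row
  hm1 <- cluster_motif_heatmap(cl[1:5], c("TTGG"), seqs2, row_size = 300)
  expect_equal(nrow(hm1), 1L)
  expect_true(attr(hm1, "flagged_single_row"))
})
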