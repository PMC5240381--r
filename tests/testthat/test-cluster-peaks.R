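regions1 <- function(len = 10000L) data.table::data.table(
  ref = "tx1", start = 0L, end = len)

test_that("an extreme pile of starts yields exactly one cluster", {
  st <- data.table::data.table(ref = "tx1", pos = 5000L, count = 100L)
  cl <- call_clusters(st, regions1(), n_permutations = 20, seed = 1)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$peak, 5000L)
  expect_lte(cl$fdr, 0.05)
  expect_error(call_clusters(st, regions1(), n_permutations = 0),
               "n_permutations")
})

test_that("the merge rule is 'less than 21 nt apart'", {
  mk <- function(gap) data.table::data.table(
    ref = "tx1", pos = c(1000L, 1000L + gap), count = c(50L, 50L))
  cl20 <- call_clusters(mk(20L), regions1(), n_permutations = 20, seed = 2)
  expect_equal(nrow(cl20), 1L)
  expect_equal(cl20$end - cl20$start, 21L)
  cl22 <- call_clusters(mk(22L), regions1(), n_permutations = 20, seed = 2)
  expect_equal(nrow(cl22), 2L)
})

test_that("FDR calibration: uniform nulls rarely enter clusters", {
  fracs <- vapply(1:12, function(sd) {
    truncmap:::with_seed(200 + sd, {
      pos <- sample.int(2000L, 150L, replace = TRUE) - 1L
    })
    st <- data.table::data.table(ref = "tx1", pos = pos)
    st <- st[, .(count = .N), by = .(ref, pos)]
    cl <- call_clusters(st, regions1(2000L), n_permutations = 40,
                        seed = 300 + sd)
    if (!nrow(cl)) return(0)
    inside <- sum(vapply(seq_len(nrow(cl)), function(i)
      sum(st$pos >= cl$start[i] & st$pos < cl$end[i]), numeric(1)))
    inside / nrow(st)
  }, numeric(1))
  expect_lte(mean(fracs), 0.05 + 3 * stats::sd(fracs) / sqrt(length(fracs)))
})

test_that("retained start positions grow monotonically with the threshold", {
  truncmap:::with_seed(7, {
    pos <- c(sample.int(3000L, 200L, replace = TRUE) - 1L,
             rep(1500L, 30L), rep(1540L, 25L))
  })
  st <- data.table::data.table(ref = "tx1", pos = pos)
  st <- st[, .(count = .N), by = .(ref, pos)]
  spans <- vapply(c(0.01, 0.05, 0.2, 0.5), function(a) {
    cl <- call_clusters(st, regions1(3000L), fdr_threshold = a,
                        n_permutations = 40, seed = 5)
    if (!nrow(cl)) 0L else sum(cl$end - cl$start)
  }, numeric(1))
  expect_true(all(diff(spans) >= 0))
})

test_that("permutation determinism: same seed, same clusters", {
  s <- small_sim(seed = 19, n_molecules = 2000)
  st <- start_counts(collapse_umis(s$reads))
  regs <- data.table::data.table(ref = names(s$annotation$seqlens),
                                 start = 0L,
                                 end = as.integer(s$annotation$seqlens))
  a <- call_clusters(st, regs, n_permutations = 25, seed = 99)
  b <- call_clusters(st, regs, n_permutations = 25, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("planted clusters are recovered over uniform background", {
  hits <- 0L; tot <- 0L
  for (sd in 1:8) {
    truncmap:::with_seed(400 + sd, {
      bg <- sample.int(2000L, 100L, replace = TRUE) - 1L
      planted <- sample(200:1800, 3)
    })
    pos <- c(bg, rep(planted, each = 20L))
    st <- data.table::data.table(ref = "tx1", pos = as.integer(pos))
    st <- st[, .(count = .N), by = .(ref, pos)]
    cl <- call_clusters(st, regions1(2000L), n_permutations = 40,
                        seed = 500 + sd)
    for (p in planted) {
      tot <- tot + 1L
      if (nrow(cl) && any(cl$start <= p & p < cl$end)) hits <- hits + 1L
    }
  }
  expect_gte(hits / tot, 0.95)
})

test_that("find_peak ties resolve toward the region 5' boundary", {
  pos <- data.table::data.table(ref = "tx1", pos = c(10L, 12L),
                                count = c(5L, 5L))
  pk <- find_peak(list(ref = "tx1", start = 0L, end = 100L), pos)
  expect_equal(pk$peak, 10L)
  ## minus-strand region: 5' boundary is the high coordinate
  pk_m <- find_peak(list(ref = "tx1", start = 0L, end = 100L,
                         strand = "-"), pos)
  expect_equal(pk_m$peak, 12L)
  ## single position and empty region
  expect_equal(find_peak(list(ref = "tx1", start = 0L, end = 11L),
                         pos)$peak, 10L)
  expect_true(find_peak(list(ref = "tx1", start = 50L, end = 60L),
                        pos)$empty)
})

test_that("find_peak equals the brute-force oracle on random fixtures", {
  truncmap:::with_seed(12, {
    for (i in 1:200) {
      n <- sample(1:8, 1)
      pos <- data.table::data.table(
        ref = "r", pos = sample.int(50L, n), count = sample.int(5L, n,
                                                              replace = TRUE))
      pos <- pos[, .(count = sum(count)), by = .(ref, pos)]
      region <- list(ref = "r", start = 0L, end = 51L)
      expect_identical(find_peak(region, pos)$peak,
                       oracle_find_peak(region, pos)$peak)
    }
  })
})

test_that("median filter keeps peaks at or above the median", {
  pk <- data.table::data.table(region = 1:5, count = c(1L, 2L, 3L, 4L, 5L))
  out <- apply_median_filter(pk)
  expect_equal(out$passed, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(attr(out, "median_count"), 3L)
  ## all equal -> all pass
  pk2 <- data.table::data.table(count = rep(7L, 4))
  expect_true(all(apply_median_filter(pk2)$passed))
  ## pass fraction always in [0.5, 1]
  truncmap:::with_seed(4, {
    for (i in 1:50) {
      cnt <- sample.int(20L, sample(2:30, 1), replace = TRUE)
      f <- mean(apply_median_filter(data.table::data.table(count = cnt))$passed)
      expect_gte(f, 0.5)
      expect_lte(f, 1)
    }
  })
})

test_that("top-cluster selection honours the length boundary and oracle", {
  cl <- data.table::data.table(
    ref = "tx1", start = c(0L, 100L, 200L, 300L, 400L),
    end = c(31L, 130L, 245L, 340L, 460L),   # lengths 31,30,45,40,60
    count = c(10L, 99L, 50L, 20L, 5L))
  top3 <- select_top_clusters(cl, n = 3, min_length = 31L)
  ## length-30 cluster is excluded despite its high count
  expect_false(100L %in% top3$start)
  expect_setequal(top3$start, c(0L, 200L, 300L))
  ## random fixtures against the oracle
  truncmap:::with_seed(31, {
    for (i in 1:100) {
      m <- sample(1:30, 1)
      st <- cumsum(sample.int(100L, m, replace = TRUE))
      cl2 <- data.table::data.table(
        ref = "x", start = st,
        end = st + sample.int(60L, m, replace = TRUE),
        count = sample.int(1000L, m, replace = TRUE))
      got <- select_top_clusters(cl2, n = 5, min_length = 31L)
      want <- oracle_top(cl2, 5, 31L)
      expect_setequal(got$start, want$start)
    }
  })
})

test_that("junction end peaks recover forced cleavage sites", {
  cfg <- sim_config(seed = 61, n_transcripts = 3, transcript_length = 3000,
                    exon_length = 300,
                    site_model = list(list(kind = "junction",
                                           offsets = c(-25, -21))),
                    cleavage_model = list(
                      kind = "positional",
                      positions = list(tx001 = seq(290L, 2990L, 300L),
                                       tx002 = seq(290L, 2990L, 300L),
                                       tx003 = seq(290L, 2990L, 300L))),
                    truncation_rate = 1, n_molecules = 4000)
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_reads(tx$sequences, tx$annotation, cfg)
  col <- collapse_umis(sim$reads)
  jx <- tx$annotation$junctions[tx$annotation$junctions$internal == TRUE]
  ep <- junction_end_peak(col, jx, exon_min_length = 100,
                          coverage_quantile = 0)
  ## all cleavage happens at junction - 10 (grid position 290 per exon)
  expect_true(all(ep$peak_offset == -10L))
})

test_that("junction filtering excludes short exons", {
  cd <- make_cdnas("tx1", start = c(80L, 85L), end = c(110L, 115L))
  jx <- data.table::data.table(ref = "tx1", pos = 100L,
                               exon_up_len = 100L)   # not > 100 -> excluded
  ep <- junction_end_peak(cd, jx)
  expect_equal(nrow(ep), 0L)
  jx2 <- data.table::data.table(ref = "tx1", pos = 100L,
                                exon_up_len = 101L)
  ep2 <- junction_end_peak(cd, jx2, coverage_quantile = 0)
  expect_equal(nrow(ep2), 1L)
  expect_equal(ep2$peak_offset, 10L)
})
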