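## shared fixture builders and brute-force oracles

## a minimal cdna table from parallel vectors
make_cdnas <- function(ref, start, end, umi = NULL, del = NULL, trans = NULL,
                       strand = "+", count = 1L) {
  n <- length(start)
  as_cdna_tbl(data.table::data.table(
    read_id = sprintf("r%04d", seq_len(n)),
    ref = rep_len(ref, n), strand = rep_len(strand, n),
    start = as.integer(start), end = as.integer(end),
    umi = if (is.null(umi)) sprintf("u%04d", seq_len(n)) else rep_len(umi, n),
    del_offsets = if (is.null(del)) rep(list(integer(0)), n) else del,
    trans_offsets = if (is.null(trans)) rep(list(integer(0)), n) else trans,
    count = rep_len(as.integer(count), n)))
}

random_seq <- function(n, seed = NULL) {
  gen <- function() paste0(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  if (is.null(seed)) gen() else truncmap:::with_seed(seed, gen())
}

## default small simulation used by several tests
small_sim <- function(seed = 1, n_molecules = 3000, ...) {
  cfg <- sim_config(seed = seed, n_transcripts = 4,
                    transcript_length = 2500,
                    site_model = list(list(kind = "motif", motif = "TTGG",
                                           n = 30)),
                    n_molecules = n_molecules, ...)
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_reads(tx$sequences, tx$annotation, cfg)
  c(tx, sim, list(config = cfg))
}

## ---- independent oracles (kept deliberately naive) -------------------

## peak: scan all positions, max count, tie -> closest to region 5' end
oracle_find_peak <- function(region, positions) {
  best <- NULL
  strand <- if (is.null(region$strand)) "+" else region$strand
  rng <- region$start:(region$end - 1L)
  if (identical(strand, "-")) rng <- rev(rng)
  for (p in rng) {
    ct <- sum(positions$count[positions$ref == region$ref &
                              positions$pos == p])
    if (ct > 0 && (is.null(best) || ct > best$count))
      best <- list(peak = p, count = ct)
  }
  best
}

## UMI collapse: group by the full key, count rows, longest representative
oracle_collapse <- function(cdnas) {
  key <- paste(cdnas$ref, cdnas$strand, cdnas$start, cdnas$umi, sep = "|")
  split_idx <- split(seq_len(nrow(cdnas)), key)
  out <- lapply(split_idx, function(ix) {
    rep_i <- ix[which.max(cdnas$length[ix])]
    list(key = key[rep_i], count = sum(cdnas$count[ix]),
         end = cdnas$end[rep_i])
  })
  out[order(names(out))]
}

## motif coverage of one read window by naive string scanning
oracle_motif_cover <- function(seq_chr, motifs, pos) {
  k <- nchar(motifs[1])
  for (s0 in max(0L, pos - k + 1L):pos) {
    if (s0 + k > nchar(seq_chr)) next
    if (substring(seq_chr, s0 + 1L, s0 + k) %in% motifs) return(TRUE)
  }
  FALSE
}

## top clusters: filter + full sort
oracle_top <- function(clusters, n, min_length) {
  cl <- as.data.frame(clusters)
  cl <- cl[cl$end - cl$start >= min_length, ]
  cl <- cl[order(-cl$count), ]
  head(cl, n)
}
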