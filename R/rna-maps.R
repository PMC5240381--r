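#' Mass-preserving Gaussian smoothing
#'
#' Each input value's mass is redistributed over neighbouring offsets with
#' Gaussian weights (sd = `window / 2`, truncated at 3 sd) renormalised
#' within the vector's range, so the total is preserved exactly (up to
#' floating point). The kernel is recorded so output provenance is
#' explicit.
#'
#' @param x numeric vector.
#' @param window smoothing window in nt (5 for junction maps, 10 for
#'   Y-tract maps).
#' @return smoothed numeric vector with attribute `kernel`.
#' @export
gauss_smooth <- function(x, window) {
  n <- length(x)
  sdv <- window / 2
  h <- ceiling(3 * sdv)
  k <- stats::dnorm(-h:h, sd = sdv)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - h):min(n, i + h)
    w <- k[j - i + h + 1L]
    out[j] <- out[j] + x[i] * w / sum(w)
  }
  attr(out, "kernel") <- sprintf("gaussian(sd=%.2f, trunc=3sd)", sdv)
  out
}

#' Metagene RNA map around exon-exon junctions
#'
#' Counts cDNA-starts or -ends at each offset from internal exon-exon
#' junctions (offset 0 = first nucleotide of the downstream exon; first
#' and last junctions of each transcript are excluded to avoid border
#' effects) and normalises to the uniform expectation:
#' `RNAmap[n] = (cDNAs[n] / sum(cDNAs)) * length(mRNAs) /
#' count(junctions)`, where `sum(cDNAs)` is the total number of cDNAs on
#' the examined mRNAs and `length(mRNAs)` their summed length. A uniform
#' library therefore converges to 1 at every offset. The raw map is
#' returned alongside a Gaussian-smoothed copy (window 5 nt).
#'
#' @param cdnas a collapsed [as_cdna_tbl()] table.
#' @param junctions junction table (`ref`, `pos`, optional `internal`).
#' @param what `"starts"` or `"ends"`.
#' @param window half-width in nt of the map.
#' @param smooth smoothing window (nt); `0` skips smoothing.
#' @return object of class `rna_map`: `data.table(offset, raw, smoothed)`
#'   with attributes `anchor`, `n_junctions`, `total_cdnas`,
#'   `total_length` and `formula`.
#' @export
junction_map <- function(cdnas, junctions, what = c("starts", "ends"),
                         window = 150L, smooth = 5L) {
  what <- match.arg(what)
  jx <- as.data.table(junctions)
  if ("internal" %in% names(jx)) jx <- jx[internal == TRUE]
  if (!nrow(jx)) stop("no internal junctions")
  dt <- as.data.table(cdnas)
  mrefs <- unique(jx$ref)
  dt <- dt[ref %in% mrefs]
  total <- sum(dt$count)
  if (total == 0L) stop("zero cDNAs on junction-bearing transcripts")
  cnts <- dt[, .(count = sum(count)),
             by = .(ref, pos = if (what == "starts") start else end)]
  setkey(cnts, ref, pos)
  offs <- (-window):window
  raw_counts <- numeric(length(offs))
  for (i in seq_len(nrow(jx))) {
    hit <- cnts[.(jx$ref[i], jx$pos[i] + offs), count]
    hit[is.na(hit)] <- 0L
    raw_counts <- raw_counts + hit
  }
  tot_len <- sum(attr_seqlens(cdnas, jx, mrefs))
  raw <- (raw_counts / total) * tot_len / nrow(jx)
  sm <- if (smooth > 0) gauss_smooth(raw, smooth) else raw
  out <- data.table(offset = offs, raw = raw, smoothed = as.numeric(sm))
  setattr(out, "class", c("rna_map", class(data.table())))
  setattr(out, "anchor", "exon_exon_junction")
  setattr(out, "n_junctions", nrow(jx))
  setattr(out, "total_cdnas", total)
  setattr(out, "total_length", tot_len)
  setattr(out, "formula",
          "RNAmap[n] = (cDNAs[n]/sum(cDNAs)) * length(mRNAs)/count(junctions)")
  out[]
}

## mRNA lengths: prefer an explicit seqlens attribute on the junction
## table, else infer from the largest coordinate seen
attr_seqlens <- function(cdnas, jx, mrefs) {
  sl <- attr(jx, "seqlens", exact = TRUE)
  if (!is.null(sl)) return(sl[mrefs])
  dt <- as.data.table(cdnas)
  mx <- dt[ref %in% mrefs, .(len = max(end) + 1L), by = ref]
  jmx <- jx[, .(len = max(pos) + 1L), by = ref]
  m <- merge(mx, jmx, by = "ref", all = TRUE)
  pmax(m$len.x, m$len.y, na.rm = TRUE)
}

#' RNA map around pyrimidine-tract binding sites
#'
#' Per-site counts are first MaxCount-normalised: within the site plus
#' `search_flank` nt on both sides, the largest per-position count
#' defines MaxCount and all counts at the site are divided by it,
#' removing per-site abundance differences exactly. The normalised counts
#' are averaged across sites (anchored at the tract 3' end, offset 0 =
#' first nt downstream of the tract), divided by the average over the
#' `norm_flank` region downstream (default 50-100 nt, i.e. outside the
#' binding site), and Gaussian-smoothed (window 10 nt). Sites with
#' MaxCount 0 are excluded and counted; a zero downstream average flags
#' the map instead of producing infinities.
#'
#' @param cdnas a collapsed [as_cdna_tbl()] table.
#' @param ytracts `data.table(ref, start, end)` of Y-tract intervals.
#' @param what `"starts"` or `"ends"`.
#' @param search_flank nt examined on both sides of the site for MaxCount.
#' @param norm_flank inclusive downstream offset range for the final
#'   normalisation.
#' @param smooth smoothing window in nt; `0` skips smoothing.
#' @return `rna_map` table (`offset`, `raw`, `smoothed`) with attributes
#'   `n_sites`, `n_excluded` (MaxCount 0) and `flagged` (zero downstream
#'   average).
#' @export
ytract_map <- function(cdnas, ytracts, what = c("starts", "ends"),
                       search_flank = 120L, norm_flank = c(50L, 100L),
                       smooth = 10L) {
  what <- match.arg(what)
  yt <- as.data.table(ytracts)
  if (!nrow(yt)) stop("no ytracts")
  cnts <- start_counts(cdnas, sub("s$", "", what))
  max_len <- max(yt$end - yt$start)
  offs <- (-(max_len + search_flank)):(search_flank)  # rel. tract 3' end
  acc <- numeric(length(offs))
  nused <- 0L; nexcl <- 0L
  for (i in seq_len(nrow(yt))) {
    anchor <- yt$end[i]                       # first nt downstream = offset 0
    site_lo <- yt$start[i] - search_flank
    site_hi <- yt$end[i] - 1L + search_flank
    v <- cnts[.(yt$ref[i], site_lo:site_hi), count]
    v[is.na(v)] <- 0L
    mx <- max(v)
    if (mx == 0) { nexcl <- nexcl + 1L; next }
    hit <- cnts[.(yt$ref[i], anchor + offs), count]
    hit[is.na(hit)] <- 0L
    acc <- acc + hit / mx
    nused <- nused + 1L
  }
  if (!nused) stop("all sites have MaxCount 0")
  avg <- acc / nused
  dn <- avg[offs >= norm_flank[1] & offs <= norm_flank[2]]
  dmean <- mean(dn)
  flagged <- !(dmean > 0)
  raw <- if (flagged) avg else avg / dmean
  sm <- if (smooth > 0) gauss_smooth(raw, smooth) else raw
  out <- data.table(offset = offs, raw = raw, smoothed = as.numeric(sm))
  setattr(out, "class", c("rna_map", class(data.table())))
  setattr(out, "anchor", "ytract_3prime_end")
  setattr(out, "n_sites", nused)
  setattr(out, "n_excluded", nexcl)
  setattr(out, "flagged", flagged)
  out[]
}

#' Heatmap of cDNA-starts grouped by cDNA-end peak position
#'
#' Junctions (the `n_top` with the highest cDNA count) are grouped by the
#' offset of their cDNA-end peak; each row is the average per-offset
#' cDNA-start count over the junctions in that group, and all cells are
#' divided by the global maximum. With a narrow cDNA length range, row
#' maxima track the end-peak offset shifted by the typical cDNA length;
#' with broad lengths the rows share a common start region.
#'
#' @param cdnas a collapsed [as_cdna_tbl()] table.
#' @param junctions junction table (`ref`, `pos`).
#' @param end_peaks [junction_end_peak()] output.
#' @param n_top number of junctions kept, ranked by cDNA count.
#' @param window half-width of the offset axis.
#' @return object of class `grouped_heatmap`: matrix (rows = end-peak
#'   offsets, ascending; columns = offsets) with global maximum 1, plus
#'   attribute `row_n` (junctions per row).
#' @export
endpeak_grouped_heatmap <- function(cdnas, junctions, end_peaks,
                                    n_top = 1000L, window = 60L) {
  jx <- as.data.table(junctions)
  ep <- as.data.table(end_peaks)
  dt <- as.data.table(cdnas)
  ## rank junctions by cDNA count in a window around them
  jx_cnt <- vapply(seq_len(nrow(ep)), function(i)
    sum(dt[ref == ep$ref[i] &
           start >= ep$junction_pos[i] - window &
           start <= ep$junction_pos[i] + window, count]), numeric(1))
  ep <- ep[order(-jx_cnt)][seq_len(min(n_top, nrow(ep)))]
  cnts <- start_counts(dt, "start")
  offs <- (-window):window
  groups <- sort(unique(ep$peak_offset))
  mat <- matrix(0, nrow = length(groups), ncol = length(offs),
                dimnames = list(groups, offs))
  row_n <- integer(length(groups))
  for (gi in seq_along(groups)) {
    sel <- ep[peak_offset == groups[gi]]
    prof <- numeric(length(offs))
    for (i in seq_len(nrow(sel))) {
      hit <- cnts[.(sel$ref[i], sel$junction_pos[i] + offs), count]
      hit[is.na(hit)] <- 0L
      prof <- prof + hit
    }
    mat[gi, ] <- prof / nrow(sel)
    row_n[gi] <- nrow(sel)
  }
  keep <- row_n > 0L
  mat <- mat[keep, , drop = FALSE]
  gmax <- max(mat)
  if (gmax > 0) mat <- mat / gmax
  attr(mat, "row_n") <- row_n[keep]
  class(mat) <- c("grouped_heatmap", class(mat))
  mat
}

#' Flag junctions whose binding region is unreachable by cDNA-starts
#'
#' A crosslink inside the expected binding region can only be captured by
#' a cDNA of >= `min_cdna` nt ending at the cDNA-end peak, so end peaks
#' closer than `min_cdna` nt to the 3' edge of the target region leave
#' part of the region invisible. End peaks upstream of the region are
#' flagged separately (`peak_upstream`).
#'
#' @param end_peaks [junction_end_peak()] output (`peak_offset` relative
#'   to the junction).
#' @param target_region inclusive offset range of the expected binding
#'   region, default `c(-24, -20)` (the canonical EJC region).
#' @param min_cdna minimal isolable cDNA length (17 nt).
#' @return the input with logical columns `reachable` and
#'   `peak_upstream`.
#' @export
reachability_flags <- function(end_peaks, target_region = c(-24L, -20L),
                               min_cdna = 17L) {
  ep <- copy(as.data.table(end_peaks))
  edge3 <- target_region[2]
  ep[, peak_upstream := peak_offset < target_region[1]]
  ep[, reachable := !peak_upstream & (peak_offset - edge3) >= min_cdna]
  ep[]
}

#' Nucleotide composition around cDNA-ends
#'
#' Per offset from the cDNA-end nucleotide (offset 0 = the end itself),
#' the A/C/G/T fractions over all cDNAs; unbiased RNase I fragmentation
#' gives flat composition, while e.g. A-enrichment at the end indicates
#' RNase-I-independent fragmentation. Windows truncated by a reference
#' edge are skipped and counted in attribute `n_skipped`.
#'
#' @param cdnas a collapsed [as_cdna_tbl()] table.
#' @param sequences reference sequences.
#' @param window inclusive offset range, default `c(-10, 10)`.
#' @return `data.table(offset, A, C, G, T)`; fractions sum to 1 at every
#'   offset.
#' @export
end_nucleotide_composition <- function(cdnas, sequences,
                                       window = c(-10L, 10L)) {
  seq_chr <- as_seq_chr(sequences)
  lens <- nchar(seq_chr)
  offs <- window[1]:window[2]
  ok <- cdnas$end + window[1] >= 0L &
        cdnas$end + window[2] < lens[cdnas$ref]
  n_skipped <- sum(!ok)
  sub <- cdnas[ok]
  counts <- matrix(0L, nrow = length(offs), ncol = 4,
                   dimnames = list(offs, c("A", "C", "G", "T")))
  for (i in seq_len(nrow(sub))) {
    b <- substring(seq_chr[[sub$ref[i]]],
                   sub$end[i] + window[1] + 1L, sub$end[i] + window[2] + 1L)
    b <- strsplit(b, "")[[1]]
    for (j in seq_along(offs))
      counts[j, b[j]] <- counts[j, b[j]] + sub$count[i]
  }
  tot <- rowSums(counts)
  out <- data.table(offset = offs,
                    A = counts[, "A"] / tot, C = counts[, "C"] / tot,
                    G = counts[, "G"] / tot, T = counts[, "T"] / tot)
  setattr(out, "n_skipped", n_skipped)
  out[]
}

#' Fraction of intron-mapping cDNAs ending at the intron 3' end
#'
#' Among cDNAs overlapping introns, the fraction whose end falls on the
#' last or second-to-last intronic nucleotide -- the signature of
#' spliceosomal 3' splice-site cleavage (intron lariat ends) rather than
#' RNase fragmentation. Invariant to PCR duplication after
#' [collapse_umis()].
#'
#' @param cdnas a collapsed [as_cdna_tbl()] table.
#' @param introns `data.table(ref, start, end)`, half-open.
#' @return `list(fraction, n_intronic, n_at_end, flagged)`; `flagged`
#'   when no intronic cDNAs exist.
#' @export
intron_end_fraction <- function(cdnas, introns) {
  intr <- as.data.table(introns)
  dt <- as.data.table(cdnas)
  n_intronic <- 0L
  n_at_end <- 0L
  for (i in seq_len(nrow(intr))) {
    ov <- dt[ref == intr$ref[i] & start < intr$end[i] & end >= intr$start[i]]
    if (!nrow(ov)) next
    n_intronic <- n_intronic + sum(ov$count)
    n_at_end <- n_at_end +
      sum(ov[end %in% c(intr$end[i] - 1L, intr$end[i] - 2L), count])
  }
  if (n_intronic == 0L)
    return(list(fraction = NA_real_, n_intronic = 0L, n_at_end = 0L,
                flagged = TRUE))
  list(fraction = n_at_end / n_intronic, n_intronic = n_intronic,
       n_at_end = n_at_end, flagged = FALSE)
}

#' Discover binding-site pentamers around cDNA-start peaks
#'
#' Counts k-mer occurrences in the `region` window around each cDNA-start
#' peak and compares them with `n_shuffles` mononucleotide-shuffled
#' versions of the same window sequences: `z = (obs - mean_bg) / sd_bg`.
#' k-mers with `sd_bg = 0` are reported separately (`z = NA`,
#' `degenerate = TRUE`) rather than given infinite scores. The z-score
#' construction (background model and counting unit) is a pinned choice
#' of this package, so the threshold is a parameter rather than a
#' hard-coded constant.
#'
#' @param start_peaks `data.table(ref, pos)` of cDNA-start peaks (e.g.
#'   cluster peaks).
#' @param sequences reference sequences.
#' @param region inclusive offset window around each peak, default
#'   `c(-10, 10)`.
#' @param k k-mer length (default 5).
#' @param z_threshold retain k-mers with `z > z_threshold` (`NULL` keeps
#'   all).
#' @param n_shuffles shuffled backgrounds.
#' @param seed RNG seed for the shuffles.
#' @return `data.table(kmer, obs, mean_bg, sd_bg, z, degenerate)` sorted
#'   by decreasing z.
#' @export
discover_pentamers <- function(start_peaks, sequences,
                               region = c(-10L, 10L), k = 5L,
                               z_threshold = NULL, n_shuffles = 100L,
                               seed = NULL) {
  if (n_shuffles < 2L) stop("n_shuffles must be >= 2")
  seq_chr <- as_seq_chr(sequences)
  sp <- as.data.table(start_peaks)
  lens <- nchar(seq_chr)
  wins <- character(0)
  for (i in seq_len(nrow(sp))) {
    lo <- sp$pos[i] + region[1]
    hi <- sp$pos[i] + region[2]
    if (lo < 0L || hi >= lens[[sp$ref[i]]]) next
    wins <- c(wins, substring(seq_chr[[sp$ref[i]]], lo + 1L, hi + 1L))
  }
  if (!length(wins)) stop("no usable peak windows")
  count_kmers <- function(strs) {
    tab <- new.env(parent = emptyenv())
    for (s in strs) {
      n <- nchar(s)
      if (n < k) next
      km <- substring(s, 1:(n - k + 1L), k:n)
      for (m in km) assign(m, (get0(m, envir = tab) %||% 0L) + 1L,
                           envir = tab)
    }
    tab
  }
  obs_tab <- count_kmers(wins)
  wins_split <- strsplit(wins, "")
  with_seed(seed, {
    bg <- matrix(0L, nrow = n_shuffles, ncol = 0)
    bg_counts <- list()
    for (s in seq_len(n_shuffles)) {
      shuf <- vapply(wins_split, function(ch)
        paste0(sample(ch), collapse = ""), character(1))
      bg_counts[[s]] <- count_kmers(shuf)
    }
    all_k <- unique(c(ls(obs_tab), unlist(lapply(bg_counts, ls))))
    getn <- function(tab, m) get0(m, envir = tab) %||% 0L
    res <- data.table(kmer = all_k,
                      obs = vapply(all_k, getn, integer(1), tab = obs_tab))
    bgm <- vapply(all_k, function(m)
      vapply(bg_counts, getn, integer(1), m = m), numeric(n_shuffles))
    res[, mean_bg := colMeans(bgm)]
    res[, sd_bg := apply(bgm, 2, sd)]
    res[, z := ifelse(sd_bg > 0, (obs - mean_bg) / sd_bg, NA_real_)]
    res[, degenerate := sd_bg == 0]
    setorder(res, -z, na.last = TRUE)
    if (!is.null(z_threshold)) res <- res[degenerate | z > z_threshold]
    res[]
  })
}

#' Motif-coverage heatmap over length-sorted crosslink clusters
#'
#' Clusters (typically from the 3-nt clustering variant) are sorted by
#' length and chunked into rows of `row_size`. Each row's coordinate is
#' anchored two-sidedly: positions up to half the row's median length are
#' taken relative to the cluster start, the remainder relative to the
#' cluster end, with `flank` nt added on both sides, so motif coverage
#' falling off at both boundaries stays visible across all row lengths.
#' Cell values are the average per-nucleotide motif coverage (0..1).
#'
#' @param clusters a [call_clusters()] result.
#' @param motif_set `motif_set` or character vector of k-mers (e.g.
#'   discovered pentamers).
#' @param sequences reference sequences.
#' @param row_size clusters per row (default 300); fewer clusters than
#'   `row_size` produce a single flagged row.
#' @param flank nt shown beyond the cluster boundaries.
#' @return `grouped_heatmap` matrix (rows shortest to longest) with
#'   attributes `row_median_len` and `flagged_single_row`.
#' @export
cluster_motif_heatmap <- function(clusters, motif_set, sequences,
                                  row_size = 300L, flank = 20L) {
  cl <- as.data.table(clusters)
  if (!nrow(cl)) stop("no clusters")
  masks <- motif_coverage_masks(sequences, motif_set)
  cl <- cl[order(end - start)]
  n <- nrow(cl)
  n_rows <- max(1L, ceiling(n / row_size))
  flagged <- n < row_size
  row_of <- rep(seq_len(n_rows), each = row_size, length.out = n)
  med_len <- integer(n_rows)
  rows <- list()
  for (r in seq_len(n_rows)) {
    sub <- cl[row_of == r]
    m <- as.integer(round(median(sub$end - sub$start)))
    med_len[r] <- m
    half <- m %/% 2L
    offs <- (-flank):(m - 1L + flank)    # row coordinate, 0 = cluster start
    acc <- numeric(length(offs)); cnt <- numeric(length(offs))
    for (i in seq_len(nrow(sub))) {
      mask <- masks[[sub$ref[i]]]
      for (j in seq_along(offs)) {
        o <- offs[j]
        p <- if (o < half) sub$start[i] + o
             else sub$end[i] - 1L - (m - 1L - o)   # end-anchored half
        if (p >= 0L && p < length(mask)) {
          acc[j] <- acc[j] + mask[p + 1L]
          cnt[j] <- cnt[j] + 1L
        }
      }
    }
    rows[[r]] <- ifelse(cnt > 0, acc / cnt, NA_real_)
  }
  ncol_max <- max(lengths(rows))
  mat <- t(vapply(rows, function(v) c(v, rep(NA_real_, ncol_max - length(v))),
                  numeric(ncol_max)))
  colnames(mat) <- seq(-flank, length.out = ncol_max)
  rownames(mat) <- sprintf("row%02d", seq_len(n_rows))
  attr(mat, "row_median_len") <- med_len
  attr(mat, "flagged_single_row") <- flagged
  class(mat) <- c("grouped_heatmap", class(mat))
  mat
}
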