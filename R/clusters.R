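#' Per-position cDNA start or end counts
#'
#' Sums collapsed multiplicities per `(ref, pos)`.
#'
#' @param cdnas a [as_cdna_tbl()] table.
#' @param what `"start"` or `"end"`.
#' @return `data.table(ref, pos, count)` keyed by `(ref, pos)`.
#' @export
start_counts <- function(cdnas, what = c("start", "end")) {
  what <- match.arg(what)
  dt <- as.data.table(cdnas)[, .(ref = ref,
                                 pos = if (what == "start") start else end,
                                 count)]
  out <- dt[, .(count = sum(count)), by = .(ref, pos)]
  setkey(out, ref, pos)
  out[]
}

#' Call FDR-significant crosslink clusters from cDNA-start counts
#'
#' For every position in a region the cDNA-start counts within a symmetric
#' window of `spacing` nt on each side are summed. The null is generated
#' by repositioning the region's starts uniformly at random within the
#' region (count-preserving), `n_permutations` times. The empirical FDR of
#' a window height h is mean(shuffled positions with height >= h) /
#' (observed positions with height >= h), forced non-increasing in h.
#' Observed start positions whose height passes `fdr_threshold` are
#' retained; retained positions closer than `merge_gap` nt are merged into
#' one cluster spanning the extremal retained starts (boundaries are the
#' start span, not extended by the window, so cluster length reflects
#' start dispersion). The 3-nt clustering variant is the same code path
#' with `spacing = 3, merge_gap = 3`.
#'
#' @param starts a `(ref, pos, count)` table from [start_counts()].
#' @param regions `data.table(ref, start, end)`, 0-based half-open; every
#'   start must lie inside a region. This is also the shuffling domain.
#' @param spacing half-width of the clustering window in nt.
#' @param fdr_threshold empirical FDR cutoff.
#' @param merge_gap merge retained positions `< merge_gap` nt apart.
#' @param n_permutations number of shuffles (> 0).
#' @param seed RNG seed for the permutations.
#' @return `data.table` of class `crosslink_clusters`: `ref`, `start`,
#'   `end` (half-open span of retained starts), `count` (total cDNA count
#'   in the span), `peak`, `peak_height` (window height at peak), `fdr`
#'   (at the peak height), `window` (the spacing used) and `flagged_short`
#'   for regions shorter than `2 * spacing + 1`.
#' @export
call_clusters <- function(starts, regions, spacing = 15L,
                          fdr_threshold = 0.05, merge_gap = 21L,
                          n_permutations = 100L, seed = NULL) {
  if (n_permutations < 1L) stop("n_permutations must be > 0")
  regions <- as.data.table(regions)
  starts <- as.data.table(starts)
  out <- with_seed(seed, {
    res <- list()
    for (i in seq_len(nrow(regions))) {
      rg <- regions[i]
      W <- rg$end - rg$start
      flag_short <- W < 2L * spacing + 1L
      sv <- starts[ref == rg$ref & pos >= rg$start & pos < rg$end]
      if (!nrow(sv)) next
      v <- integer(W)
      v[sv$pos - rg$start + 1L] <- sv$count
      h <- window_sums(v, spacing)
      hmax <- max(h)
      ## null: tally of window heights across permutations
      null_tab <- numeric(hmax + 1L)
      ntot <- sum(v)
      for (p in seq_len(n_permutations)) {
        pv <- tabulate(sample.int(W, ntot, replace = TRUE), W)
        ph <- window_sums(pv, spacing)
        pt <- tabulate(pmin(ph, hmax) + 1L, hmax + 1L)
        null_tab <- null_tab + pt
      }
      ## survival counts for heights 0..hmax
      obs_ge <- rev(cumsum(rev(tabulate(h + 1L, hmax + 1L))))
      exp_ge <- rev(cumsum(rev(null_tab))) / n_permutations
      fdr_h <- pmin(1, exp_ge / pmax(obs_ge, 1L))
      fdr_h <- rev(cummin(rev(fdr_h)))       # monotone in height
      pass_h <- which(fdr_h <= fdr_threshold) - 1L  # heights passing
      if (!length(pass_h)) next
      hmin_pass <- min(pass_h)
      keep_pos <- which(v > 0L & h >= hmin_pass)
      if (!length(keep_pos)) next
      ## merge retained positions < merge_gap apart
      grp <- cumsum(c(1L, diff(keep_pos) >= merge_gap))
      for (gidx in unique(grp)) {
        pp <- keep_pos[grp == gidx]
        span <- range(pp)
        cl_start <- rg$start + span[1] - 1L
        cl_end <- rg$start + span[2]          # half-open
        cnt <- sum(v[span[1]:span[2]])
        pk <- find_peak(list(ref = rg$ref, start = cl_start, end = cl_end,
                             strand = "+"),
                        data.table(ref = rg$ref,
                                   pos = rg$start + which(v > 0L) - 1L,
                                   count = v[v > 0L]))
        res[[length(res) + 1L]] <- data.table(
          ref = rg$ref, start = cl_start, end = cl_end, count = cnt,
          peak = pk$peak, peak_height = h[pk$peak - rg$start + 1L],
          fdr = fdr_h[min(h[pk$peak - rg$start + 1L], hmax) + 1L],
          window = spacing, flagged_short = flag_short)
      }
    }
    if (length(res)) rbindlist(res)
    else data.table(ref = character(), start = integer(), end = integer(),
                    count = integer(), peak = integer(),
                    peak_height = integer(), fdr = numeric(),
                    window = integer(), flagged_short = logical())
  })
  setattr(out, "class", c("crosslink_clusters", class(data.table())))
  out[]
}

## windowed sum of a count vector with half-width s (edges use partial
## windows)
window_sums <- function(v, s) {
  W <- length(v)
  cs <- cumsum(c(0L, v))
  i <- seq_len(W)
  cs[pmin(W, i + s) + 1L] - cs[pmax(1L, i - s)]
}

#' Find the peak position within a region
#'
#' Returns the position with the maximum count; ties are resolved to the
#' position closest to the region's 5' boundary (the lowest coordinate on
#' the plus strand, the highest on the minus strand).
#'
#' @param region list or one-row table with `ref`, `start`, `end`
#'   (half-open) and optionally `strand`.
#' @param positions `data.table(ref, pos, count)` (e.g. [start_counts()]).
#' @param tie_rule only `"closest_to_region_start"` is implemented.
#' @return `list(peak, count, n, empty)`; `empty = TRUE` (with `peak =
#'   NA`) when no position falls inside the region.
#' @export
find_peak <- function(region, positions,
                      tie_rule = "closest_to_region_start") {
  stopifnot(tie_rule == "closest_to_region_start")
  positions <- as.data.table(positions)
  inr <- positions[ref == region$ref & pos >= region$start &
                   pos < region$end]
  if (!nrow(inr))
    return(list(peak = NA_integer_, count = 0L, n = 0L, empty = TRUE))
  strand <- region$strand %||% "+"
  mx <- max(inr$count)
  cand <- inr$pos[inr$count == mx]
  pk <- if (identical(strand, "-")) max(cand) else min(cand)
  list(peak = pk, count = mx, n = nrow(inr), empty = FALSE)
}

#' Median filter on peak calls
#'
#' Computes the median of peak counts over the collection and marks peaks
#' with a count below the median as failed; failed peaks are excluded
#' from downstream analyses.
#'
#' @param peaks `data.table` with a `count` column (or `peak_count`).
#' @return the input with a logical `passed` column and attribute
#'   `median_count`; rows failing the filter have `passed = FALSE`.
#' @export
apply_median_filter <- function(peaks) {
  dt <- copy(as.data.table(peaks))
  cnt <- if ("count" %in% names(dt)) dt$count else dt$peak_count
  if (!length(cnt)) stop("no peaks")
  med <- median(cnt)
  dt[, passed := cnt >= med]
  setattr(dt, "median_count", med)
  dt[]
}

#' Select the top clusters by total cDNA count
#'
#' Filters clusters to a minimum length (default > 30 nt, i.e. length >=
#' 31) and keeps the `n` with the highest total cDNA count, in stable
#' order of the input.
#'
#' @param clusters a [call_clusters()] result.
#' @param n number of clusters to keep.
#' @param min_length minimum cluster length in nt (inclusive).
#' @return the selected subset.
#' @export
select_top_clusters <- function(clusters, n = 1000L, min_length = 31L) {
  dt <- as.data.table(clusters)
  dt <- dt[end - start >= min_length]
  if (!nrow(dt)) return(dt[])
  ord <- order(-dt$count)            # stable for ties
  dt[sort(head(ord, n))][]
}

#' Call the cDNA-end peak around each exon-exon junction
#'
#' Junctions are filtered to those whose upstream exon is longer than
#' `exon_min_length` nt and lies in the top `1 - coverage_quantile`
#' fraction of exons by collapsed cDNA coverage, ensuring enough cDNAs to
#' place the peak. Within `search_window` (offsets relative to the first
#' nucleotide of the downstream exon) the position with the maximum
#' cDNA-end count becomes the cDNA-end peak; ties resolve to the most
#' upstream position, as in [find_peak()]. Junctions with no ends in the
#' window are skipped and counted in attribute `n_no_ends`.
#'
#' @param cdnas a collapsed [as_cdna_tbl()] table.
#' @param junctions `data.table(ref, pos, exon_up_len, ...)` (e.g.
#'   `annotation$junctions`).
#' @param search_window inclusive offset range searched, default
#'   `c(-20, 25)`.
#' @param exon_min_length strict lower bound on upstream exon length.
#' @param coverage_quantile coverage quantile cutoff (0.5 = top half).
#' @return `data.table(ref, junction_pos, peak_offset, peak_count,
#'   n_ends)`, one row per retained junction.
#' @export
junction_end_peak <- function(cdnas, junctions, search_window = c(-20L, 25L),
                              exon_min_length = 100L,
                              coverage_quantile = 0.5) {
  jx <- copy(as.data.table(junctions))
  if (!nrow(jx)) stop("no junctions")
  if (!"exon_up_len" %in% names(jx)) jx[, exon_up_len := NA_integer_]
  ends <- start_counts(cdnas, "end")
  dt <- as.data.table(cdnas)
  ## coverage = collapsed cDNAs overlapping the upstream exon
  cov <- vapply(seq_len(nrow(jx)), function(i) {
    ex_start <- jx$pos[i] - (jx$exon_up_len[i] %||% NA_integer_)
    if (is.na(ex_start)) return(NA_real_)
    sum(dt[ref == jx$ref[i] & end >= ex_start & start < jx$pos[i], count])
  }, numeric(1))
  jx[, coverage := cov]
  keep <- rep(TRUE, nrow(jx))
  if (!all(is.na(jx$exon_up_len)))
    keep <- keep & !is.na(jx$exon_up_len) & jx$exon_up_len > exon_min_length
  if (!all(is.na(jx$coverage))) {
    thr <- quantile(jx$coverage[keep], coverage_quantile, na.rm = TRUE,
                    names = FALSE)
    keep <- keep & jx$coverage >= thr
  }
  jx <- jx[keep]
  res <- list()
  n_no_ends <- 0L
  for (i in seq_len(nrow(jx))) {
    pk <- find_peak(list(ref = jx$ref[i],
                         start = jx$pos[i] + search_window[1],
                         end = jx$pos[i] + search_window[2] + 1L,
                         strand = "+"),
                    ends)
    if (pk$empty) { n_no_ends <- n_no_ends + 1L; next }
    res[[length(res) + 1L]] <- data.table(
      ref = jx$ref[i], junction_pos = jx$pos[i],
      peak_offset = pk$peak - jx$pos[i], peak_count = pk$count,
      n_ends = pk$n)
  }
  out <- if (length(res)) rbindlist(res)
         else data.table(ref = character(), junction_pos = integer(),
                         peak_offset = integer(), peak_count = integer(),
                         n_ends = integer())
  setattr(out, "n_no_ends", n_no_ends)
  out[]
}
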