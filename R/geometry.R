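#' Offset heatmap of short-category versus long-category cDNA-starts
#'
#' For every position bearing at least one start from the reference length
#' bin (default cDNAs longer than 39 nt), accumulates comparison-bin start
#' counts at offsets delta in `[-window, window]`, weighted by the
#' reference count at that position. Each row (comparison bin) is
#' normalised to sum to 1, so the value at delta = 0 is that bin's
#' coinciding-start fraction: libraries with unconstrained cDNA-ends put
#' the modal mass at 0, while constrained ends shift the mode off zero.
#'
#' @param cdnas a collapsed [as_cdna_tbl()] table.
#' @param reference_bin length category used as reference (default
#'   `">39"`).
#' @param comparison_bins length categories compared against it.
#' @param window maximum |offset| in nt.
#' @return matrix with one row per comparison bin and one column per
#'   offset `-window..window`; empty bins give all-NA rows. Attribute
#'   `coinciding` holds the per-row mass at delta = 0.
#' @export
start_offset_matrix <- function(cdnas, reference_bin = ">39",
                                comparison_bins = c("17-29", "30-34",
                                                    "35-39"),
                                window = 40L) {
  dt <- copy(as.data.table(cdnas))
  dt[, category := as.character(length_category(length))]
  refc <- dt[category == reference_bin,
             .(rcount = sum(count)), by = .(ref, pos = start)]
  if (!nrow(refc)) stop("reference bin is empty")
  offs <- (-window):window
  mat <- matrix(0, nrow = length(comparison_bins), ncol = length(offs),
                dimnames = list(comparison_bins, offs))
  for (b in comparison_bins) {
    cmp <- dt[category == b, .(ccount = sum(count)), by = .(ref, pos = start)]
    if (!nrow(cmp)) { mat[b, ] <- NA_real_; next }
    setkey(cmp, ref, pos)
    for (j in seq_along(offs)) {
      m <- cmp[refc[, .(ref, pos = pos + offs[j], rcount)],
               on = c("ref", "pos"), nomatch = NULL]
      mat[b, j] <- sum(as.numeric(m$ccount) * m$rcount)
    }
    s <- sum(mat[b, ])
    if (s > 0) mat[b, ] <- mat[b, ] / s
  }
  attr(mat, "coinciding") <- mat[, as.character(0)]
  attr(mat, "window") <- window
  mat
}

#' cDNA-end constraint score (log2 peak-to-flank ratio)
#'
#' For each called cDNA-end peak, log2 of the end count at the peak over
#' the mean end count in the flank 5-25 nt downstream. Zero-count flank
#' positions are included in the mean (denominator = 21 positions), so
#' the score is exactly invariant to multiplying all counts by a
#' constant. A flank with zero total count leaves the score undefined
#' (`NA`, `flagged = TRUE`), never infinite.
#'
#' @param peaks `data.table(ref, peak)` of end-peak positions (absolute
#'   coordinates); [junction_end_peak()] output is accepted (offsets are
#'   resolved against `junction_pos`).
#' @param ends `(ref, pos, count)` table of cDNA-end counts
#'   ([start_counts()] with `what = "end"`).
#' @param flank inclusive downstream offset range, default `c(5, 25)`.
#' @return `data.table(ref, peak, peak_count, flank_mean, score, flagged)`.
#' @export
end_constraint_score <- function(peaks, ends, flank = c(5L, 25L)) {
  pk <- as.data.table(peaks)
  if (!"peak" %in% names(pk) && all(c("junction_pos", "peak_offset") %in%
                                    names(pk)))
    pk[, peak := junction_pos + peak_offset]
  ends <- as.data.table(ends)
  setkey(ends, ref, pos)
  nfl <- flank[2] - flank[1] + 1L
  res <- lapply(seq_len(nrow(pk)), function(i) {
    pc <- ends[.(pk$ref[i], pk$peak[i]), count]
    pc <- if (is.na(pc)) 0L else pc
    fl <- ends[.(pk$ref[i], (pk$peak[i] + flank[1]):(pk$peak[i] + flank[2])),
               count]
    fl[is.na(fl)] <- 0L
    fm <- sum(fl) / nfl
    data.table(ref = pk$ref[i], peak = pk$peak[i], peak_count = pc,
               flank_mean = fm,
               score = if (fm > 0 && pc > 0) log2(pc / fm) else NA_real_,
               flagged = !(fm > 0 && pc > 0))
  })
  rbindlist(res)[]
}

#' Length-stratified start/end profiles around anchors
#'
#' Counts cDNA starts (or ends) at each offset from a set of anchor
#' positions (e.g. cDNA-start peaks from the top crosslink clusters), one
#' profile per cDNA length category. Profiles are raw counts; total
#' counts are conserved for reads within the window of exactly one
#' anchor.
#'
#' @param cdnas a collapsed [as_cdna_tbl()] table.
#' @param anchors `data.table(ref, pos)` of anchor positions.
#' @param what `"starts"` or `"ends"`.
#' @param categories length categories to report.
#' @param window half-width in nt.
#' @return named list of `positional_profile`s, one per category.
#' @export
anchored_length_profiles <- function(cdnas, anchors,
                                     what = c("starts", "ends"),
                                     categories = c("17-29", "30-34",
                                                    "35-39", ">39"),
                                     window = 60L) {
  what <- match.arg(what)
  dt <- copy(as.data.table(cdnas))
  dt[, category := as.character(length_category(length))]
  dt[, pos := if (what == "starts") start else end]
  anchors <- as.data.table(anchors)
  offs <- (-window):window
  out <- list()
  for (cat in categories) {
    cnts <- dt[category == cat, .(count = sum(count)), by = .(ref, pos)]
    setkey(cnts, ref, pos)
    prof <- numeric(length(offs))
    for (i in seq_len(nrow(anchors))) {
      hit <- cnts[.(anchors$ref[i], anchors$pos[i] + offs), count]
      hit[is.na(hit)] <- 0L
      prof <- prof + hit
    }
    out[[cat]] <- positional_profile(offs, prof, rep(nrow(anchors),
                                                     length(offs)),
                                     anchor = paste0("anchor_", what),
                                     denominator = sum(cnts$count))
  }
  out
}

#' Empirical cumulative distribution of cDNA-starts around start peaks
#'
#' Pools start offsets within `half_window` nt of the supplied cDNA-start
#' peaks and returns one ECDF per length category. In libraries with
#' constrained cDNA-ends the curves of different length categories
#' separate; with unconstrained ends they overlap.
#'
#' @param cdnas a collapsed [as_cdna_tbl()] table.
#' @param start_peaks `data.table(ref, pos)` of cDNA-start peaks.
#' @param half_window window half-width (default 25 nt).
#' @param categories length categories to report.
#' @return `data.table(category, offset, cum_frac)`; curves are
#'   nondecreasing and end at 1.
#' @export
start_ecdf <- function(cdnas, start_peaks, half_window = 25L,
                       categories = c("17-29", "30-34", "35-39", ">39")) {
  dt <- copy(as.data.table(cdnas))
  dt[, category := as.character(length_category(length))]
  sp <- as.data.table(start_peaks)
  res <- list()
  for (cat in categories) {
    sub <- dt[category == cat]
    if (!nrow(sub)) next
    offs <- integer(0)
    wts <- integer(0)
    for (i in seq_len(nrow(sp))) {
      d <- sub[ref == sp$ref[i] &
               abs(start - sp$pos[i]) <= half_window]
      if (nrow(d)) {
        offs <- c(offs, d$start - sp$pos[i])
        wts <- c(wts, d$count)
      }
    }
    if (!length(offs)) next
    grid <- (-half_window):half_window
    cum <- cumsum(vapply(grid, function(g) sum(wts[offs == g]),
                         numeric(1)))
    res[[cat]] <- data.table(category = cat, offset = grid,
                             cum_frac = cum / cum[length(cum)])
  }
  rbindlist(res)[]
}
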