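#' Positional profiles
#'
#' A `positional_profile` is a `data.table(offset, value, n)` with
#' attributes `anchor` (what offset 0 means) and `denominator` (number of
#' cDNAs the proportions are computed over). Proportions are unsmoothed;
#' smoothing is a plotting concern handled by [gauss_smooth()].
#'
#' @param offset integer offsets.
#' @param value per-offset value (count or proportion).
#' @param n per-offset denominator.
#' @param anchor description of the anchor.
#' @param denominator overall denominator.
#' @return a `positional_profile`.
#' @keywords internal
positional_profile <- function(offset, value, n, anchor, denominator) {
  out <- data.table(offset = as.integer(offset), value = value, n = n)
  setattr(out, "class", c("positional_profile", class(data.table())))
  setattr(out, "anchor", anchor)
  setattr(out, "denominator", denominator)
  out
}

## k-mers (one per register, possibly repeated) whose occurrence covers
## 0-based position `pos` of `seq_chr`; out-of-range registers are dropped
## so callers can detect edge-truncated register sets (length < k)
kmers_covering <- function(seq_chr, pos, k) {
  lo <- pos - k + 1L
  starts <- lo:pos
  starts <- starts[starts >= 0L & starts + k <= nchar(seq_chr)]
  if (!length(starts)) return(character(0))
  substring(seq_chr, starts + 1L, starts + k)
}

#' Define crosslink-associated (CL) motifs
#'
#' Scores every k-mer by the number of cDNAs with an occurrence covering
#' the nucleotide just upstream of the cDNA-start (`near_offset`, default
#' -1: the crosslink site of a truncated cDNA) versus covering the
#' nucleotide at `far_offset` (default -10), and keeps k-mers whose
#' near/far ratio exceeds `min_fold`. The homopolymeric `TTTT` tetramer is
#' excluded by default: it is usually part of longer T-tracts and blurs
#' the positional resolution. On the mock eCLIP input data this procedure
#' yields ten U-rich tetramers (TTTG, TTTC, TTGG, TTTA, ATTG, ATTT, TCGT,
#' TTGA, TTCT, CTTT); that list is documentation, not a bundled result.
#'
#' @param cdnas a [as_cdna_tbl()] table (each record counted once; the
#'   result is invariant to PCR duplicates after [collapse_umis()]).
#' @param sequences reference sequences.
#' @param k motif length (default 4).
#' @param near_offset,far_offset offsets from the cDNA-start that are
#'   compared.
#' @param min_fold enrichment threshold (ratio > `min_fold` is kept).
#' @param exclude k-mers removed from the result.
#' @return an object of class `motif_set`: list with `k`, `motifs`
#'   (character), `scores` (`data.table(kmer, near, far, fold)`),
#'   `excluded`, and `n_skipped` cDNAs too close to a reference edge.
#' @export
define_cl_motifs <- function(cdnas, sequences, k = 4L, near_offset = -1L,
                             far_offset = -10L, min_fold = 1.5,
                             exclude = "TTTT") {
  seq_chr <- as_seq_chr(sequences)
  near_ct <- new.env(parent = emptyenv())
  far_ct <- new.env(parent = emptyenv())
  bump <- function(envir, kmers) for (m in kmers)
    assign(m, (get0(m, envir = envir) %||% 0L) + 1L, envir = envir)
  n_skipped <- 0L
  for (i in seq_len(nrow(cdnas))) {
    s <- seq_chr[[cdnas$ref[i]]]
    near <- kmers_covering(s, cdnas$start[i] + near_offset, k)
    far <- kmers_covering(s, cdnas$start[i] + far_offset, k)
    if (length(near) < k || length(far) < k) {  # truncated register set
      n_skipped <- n_skipped + 1L
      next
    }
    bump(near_ct, unique(near))
    bump(far_ct, unique(far))
  }
  all_k <- union(ls(near_ct), ls(far_ct))
  scores <- data.table(
    kmer = all_k,
    near = vapply(all_k, function(m) get0(m, envir = near_ct) %||% 0L,
                  integer(1)),
    far = vapply(all_k, function(m) get0(m, envir = far_ct) %||% 0L,
                 integer(1)))
  scores[, fold := ifelse(far > 0L, near / far,
                          ifelse(near > 0L, Inf, NA_real_))]
  setorder(scores, -fold, kmer)
  motifs <- setdiff(scores[fold > min_fold & near > 0L, kmer], exclude)
  structure(list(k = as.integer(k), motifs = motifs, scores = scores[],
                 excluded = exclude, min_fold = min_fold,
                 n_skipped = n_skipped),
            class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  cat("motif_set: ", length(x$motifs), " ", x$k, "-mers (fold > ",
      x$min_fold, "): ", paste(head(x$motifs, 12), collapse = " "),
      if (length(x$motifs) > 12) " ...", "\n", sep = "")
  invisible(x)
}

## per-reference logical vector: TRUE where any motif occurrence covers
## the position
motif_coverage_masks <- function(sequences, motifs) {
  seq_chr <- as_seq_chr(sequences)
  if (is.character(motifs)) motifs <- list(motifs = motifs)
  mot <- if (inherits(motifs, "motif_set")) motifs$motifs else motifs$motifs
  lapply(seq_chr, function(s) {
    mask <- logical(nchar(s))
    subj <- Biostrings::DNAString(s)
    for (m in mot) {
      hits <- Biostrings::matchPattern(m, subj)
      if (length(hits))
        for (j in seq_along(hits))
          mask[IRanges::start(hits)[j]:IRanges::end(hits)[j]] <- TRUE
    }
    mask
  })
}

#' Motif coverage relative to cDNA-starts
#'
#' Value at offset `d` = fraction of cDNAs for which any motif occurrence
#' covers the nucleotide at `cDNA-start + d`. In a truncated library the
#' profile peaks at offsets -1/0 (the crosslink and the first cDNA
#' nucleotide); in a readthrough library it peaks inside the read body at
#' the position of the crosslink.
#'
#' @param cdnas a [as_cdna_tbl()] table.
#' @param motifs a `motif_set` (or character vector of k-mers).
#' @param sequences reference sequences.
#' @param window integer `c(lo, hi)` of offsets from the cDNA-start.
#' @return a `positional_profile` of proportions.
#' @export
motif_coverage_profile <- function(cdnas, motifs, sequences,
                                   window = c(-20L, 40L)) {
  if (is.character(motifs)) motifs <- list(motifs = motifs)
  if (!length(if (inherits(motifs, "motif_set")) motifs$motifs
              else motifs$motifs))
    stop("empty motif set")
  masks <- motif_coverage_masks(sequences, motifs)
  offs <- window[1]:window[2]
  lens <- vapply(masks, base::length, integer(1))
  refi <- match(cdnas$ref, names(masks))
  val <- numeric(length(offs))
  nn <- integer(length(offs))
  for (j in seq_along(offs)) {
    p <- cdnas$start + offs[j]
    ok <- p >= 0L & p < lens[refi]
    hit <- mapply(function(ri, pp) masks[[ri]][pp + 1L],
                  refi[ok], p[ok])
    nn[j] <- sum(ok)
    val[j] <- if (nn[j]) mean(hit) else 0
  }
  positional_profile(offs, val, nn, anchor = "cdna_start",
                     denominator = nrow(cdnas))
}

#' Positional density of deletions or transitions within cDNAs
#'
#' Value at 1-based position `p` = fraction of cDNAs carrying the mutation
#' at their p-th nucleotide (reference space from the cDNA-start). Input
#' should be pre-filtered to cDNAs shorter than 40 nt ([filter_short()]).
#'
#' @param cdnas a [as_cdna_tbl()] table.
#' @param kind `"deletion"` or `"transition"`.
#' @param max_position largest 1-based position reported.
#' @return a `positional_profile` (anchor `"cdna_start_1based"`); an empty
#'   input yields an all-zero profile with attribute `denominator = 0`.
#' @export
mutation_density_profile <- function(cdnas, kind = c("deletion", "transition"),
                                     max_position = 39L) {
  kind <- match.arg(kind)
  col <- if (kind == "deletion") "del_offsets" else "trans_offsets"
  pos <- 1:max_position
  N <- nrow(cdnas)
  if (N == 0L)
    return(positional_profile(pos, numeric(length(pos)),
                              integer(length(pos)),
                              anchor = "cdna_start_1based", denominator = 0L))
  offs <- unlist(lapply(cdnas[[col]], unique)) + 1L   # 1-based positions
  tab <- tabulate(offs[offs >= 1L & offs <= max_position], max_position)
  positional_profile(pos, tab / N, rep(N, length(pos)),
                     anchor = "cdna_start_1based", denominator = N)
}

#' Classify cDNAs by mutation position
#'
#' Three classes: `first7` (a deletion/transition within the first 7 nt of
#' the cDNA, 1-based), `elsewhere` (mutations only beyond position 7) and
#' `none`. cDNAs with mutations in both zones go to `first7` (the most-5'
#' mutation decides, matching the truncation logic).
#'
#' @inheritParams mutation_density_profile
#' @return factor of length `nrow(cdnas)` with levels
#'   `c("first7", "elsewhere", "none")`.
#' @export
classify_by_mutation <- function(cdnas, kind = c("deletion", "transition")) {
  kind <- match.arg(kind)
  col <- if (kind == "deletion") "del_offsets" else "trans_offsets"
  cls <- vapply(cdnas[[col]], function(o) {
    if (!length(o)) return("none")
    if (min(o) + 1L <= 7L) "first7" else "elsewhere"
  }, character(1))
  factor(cls, levels = c("first7", "elsewhere", "none"))
}

#' Subdivide first-7-nt mutation cDNAs by motif placement
#'
#' For cDNAs whose mutation lies in the first 7 nt, separates those whose
#' motif sits at the mutation zone (an occurrence fully within the 1st to
#' 10th nucleotide of the cDNA, offsets 0..9) from those whose motif
#' overlaps position 0 (an occurrence covering the cDNA-start nucleotide,
#' typically extending upstream over the crosslink) and from cDNAs with a
#' motif at neither position. A cDNA can satisfy both tests;
#' `precedence` decides which class wins, reproducing the two opposite
#' orderings used for deletion-based and transition-based subdivision.
#'
#' @param cdnas_first7 a [as_cdna_tbl()] table restricted to the `first7`
#'   class of [classify_by_mutation()].
#' @param motifs a `motif_set` or character vector.
#' @param sequences reference sequences.
#' @param precedence `"mutation_first"` (zone test wins) or
#'   `"start_first"` (start test wins).
#' @return factor with levels `c("mutation_zone", "start", "neither")`.
#' @export
subdivide_first7 <- function(cdnas_first7, motifs, sequences,
                             precedence = c("mutation_first",
                                            "start_first")) {
  precedence <- match.arg(precedence)
  mot <- if (inherits(motifs, "motif_set")) motifs$motifs else motifs
  k <- unique(nchar(mot))
  if (length(k) != 1L) stop("motifs must share one length")
  seq_chr <- as_seq_chr(sequences)
  ## per reference: occurrence start positions (0-based)
  occ <- lapply(seq_chr, function(s) {
    subj <- Biostrings::DNAString(s)
    sort(unique(unlist(lapply(mot, function(m)
      IRanges::start(Biostrings::matchPattern(m, subj)) - 1L))))
  })
  cls <- character(nrow(cdnas_first7))
  for (i in seq_len(nrow(cdnas_first7))) {
    st <- cdnas_first7$start[i]
    os <- occ[[cdnas_first7$ref[i]]]
    in_zone <- any(os >= st & os + k - 1L <= st + 9L)
    at_start <- any(os <= st & os + k - 1L >= st)
    cls[i] <- if (precedence == "mutation_first") {
      if (in_zone) "mutation_zone" else if (at_start) "start" else "neither"
    } else {
      if (at_start) "start" else if (in_zone) "mutation_zone" else "neither"
    }
  }
  factor(cls, levels = c("mutation_zone", "start", "neither"))
}
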