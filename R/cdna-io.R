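#' Aligned cDNA tables
#'
#' The central container is a `data.table` of class `cdna_tbl` with one row
#' per aligned cDNA: `read_id`, `ref`, `strand`, `start` and `end` (0-based
#' positions of the first and last transcribed nucleotide in transcript
#' orientation; on minus-strand genomic alignments `start` maps to the
#' highest genomic coordinate), `length` (reference-space span), `umi`,
#' `del_offsets` / `trans_offsets` (list columns of 0-based offsets from
#' the cDNA-start, in reference space / transcript orientation) and
#' `count` (multiplicity, >1 after UMI collapse).
#'
#' @param x a data.frame/data.table with the columns above (`length` and
#'   `count` are filled in when missing).
#' @return a `cdna_tbl`.
#' @export
as_cdna_tbl <- function(x) {
  dt <- as.data.table(x)
  if (!"length" %in% names(dt))
    dt[, length := abs(end - start) + 1L]
  if (!"count" %in% names(dt)) dt[, count := 1L]
  if (!"strand" %in% names(dt)) dt[, strand := "+"]
  if (!"del_offsets" %in% names(dt))
    dt[, del_offsets := rep(list(integer(0)), .N)]
  if (!"trans_offsets" %in% names(dt))
    dt[, trans_offsets := rep(list(integer(0)), .N)]
  need <- c("read_id", "ref", "strand", "start", "end", "length", "umi",
            "del_offsets", "trans_offsets", "count")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("missing cdna columns: ", paste(miss, collapse = ", "))
  setcolorder(dt, need)
  setattr(dt, "class", c("cdna_tbl", class(data.table())))
  dt[]
}

#' Write aligned cDNAs in the package TSV dialect
#'
#' Columns: `read_id`, `ref`, `start`, `end`, `strand`, `umi`,
#' `del_offsets`, `trans_offsets`, `count`; offset lists are comma-joined
#' 0-based offsets from the cDNA-start, `.` when empty.
#'
#' @param cdnas a [as_cdna_tbl()] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cdna_tsv <- function(cdnas, path) {
  out <- data.table(read_id = cdnas$read_id, ref = cdnas$ref,
                    start = cdnas$start, end = cdnas$end,
                    strand = cdnas$strand, umi = cdnas$umi,
                    del_offsets = offsets_to_chr(cdnas$del_offsets),
                    trans_offsets = offsets_to_chr(cdnas$trans_offsets),
                    count = cdnas$count)
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Load aligned cDNAs from TSV or BAM
#'
#' For BAM input (via Rsamtools) deletions are taken from `D` operations in
#' the CIGAR and T-to-C transitions are computed natively by comparing the
#' read sequence with the reference, restricted to reference-T / read-C in
#' transcript orientation (on minus-strand alignments this is a plus-strand
#' A-to-G mismatch). Soft-clipped bases are excluded from all offsets.
#' Unmapped records are skipped and counted in attribute `n_unmapped`.
#'
#' @param path input file.
#' @param format `"tsv"` (the package dialect) or `"bam"`.
#' @param reference named character vector or `DNAStringSet` of reference
#'   sequences; required for transition extraction from BAM.
#' @param missing_umi `"error"` or `"surrogate"`: records without a UMI tag
#'   either abort loading or receive a unique surrogate UMI (logged via
#'   attribute `n_surrogate_umi`).
#' @param umi_tag BAM tag holding the UMI (default `"RX"`).
#' @return a [as_cdna_tbl()] table.
#' @export
load_alignments <- function(path, format = c("tsv", "bam"), reference = NULL,
                            missing_umi = c("error", "surrogate"),
                            umi_tag = "RX") {
  format <- match.arg(format)
  missing_umi <- match.arg(missing_umi)
  if (format == "tsv") {
    dt <- fread(path, sep = "\t",
                colClasses = list(character = c("del_offsets",
                                                "trans_offsets")))
    dt[, del_offsets := chr_to_offsets(del_offsets)]
    dt[, trans_offsets := chr_to_offsets(trans_offsets)]
    return(as_cdna_tbl(dt))
  }
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("BAM input requires the Rsamtools package")
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = umi_tag)
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  unmapped <- bitwAnd(b$flag, 4L) > 0L
  n_unmapped <- sum(unmapped)
  keep <- which(!unmapped)
  umis <- b$tag[[umi_tag]]
  if (is.null(umis)) umis <- rep(NA_character_, length(b$qname))
  n_surrogate <- 0L
  rows <- vector("list", length(keep))
  seq_chr <- if (!is.null(reference)) as_seq_chr(reference) else NULL
  for (j in seq_along(keep)) {
    i <- keep[j]
    al <- parse_alignment(pos0 = b$pos[i] - 1L, cigar = b$cigar[i],
                          read_seq = as.character(b$seq[i]),
                          ref_seq = if (is.null(seq_chr)) NULL
                                    else seq_chr[[as.character(b$rname[i])]],
                          minus = bitwAnd(b$flag[i], 16L) > 0L)
    u <- umis[i]
    if (is.na(u) || !nzchar(u)) {
      if (missing_umi == "error") stop("missing UMI tag in record ",
                                       b$qname[i])
      n_surrogate <- n_surrogate + 1L
      u <- sprintf("surrogate%07d", n_surrogate)
    }
    rows[[j]] <- data.table(
      read_id = b$qname[i], ref = as.character(b$rname[i]),
      strand = al$strand, start = al$start, end = al$end,
      length = al$length, umi = u,
      del_offsets = list(al$del), trans_offsets = list(al$trans),
      count = 1L)
  }
  out <- as_cdna_tbl(rbindlist(rows))
  setattr(out, "n_unmapped", n_unmapped)
  setattr(out, "n_surrogate_umi", n_surrogate)
  out
}

## walk one CIGAR; genomic coordinates are 0-based, pos0 = leftmost aligned
parse_alignment <- function(pos0, cigar, read_seq, ref_seq, minus) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n_op <- as.integer(sub("[A-Z=]$", "", ops))
  t_op <- sub("^\\d+", "", ops)
  gpos <- pos0          # next reference position
  rpos <- 0L            # next read position (0-based, after clip handling)
  read <- strsplit(read_seq, "")[[1]]
  del_g <- integer(0)   # genomic positions of deleted reference bases
  mm_g <- integer(0)    # genomic positions of T->C (transcript sense)
  for (k in seq_along(n_op)) {
    w <- n_op[k]
    op <- t_op[k]
    if (op %in% c("M", "=", "X")) {
      if (!is.null(ref_seq)) {
        rb <- substring(ref_seq, gpos + 1L, gpos + w)
        rb <- strsplit(rb, "")[[1]]
        qb <- read[(rpos + 1L):(rpos + w)]
        hit <- if (minus) which(rb == "A" & qb == "G")
               else which(rb == "T" & qb == "C")
        if (length(hit)) mm_g <- c(mm_g, gpos + hit - 1L)
      }
      gpos <- gpos + w; rpos <- rpos + w
    } else if (op == "D" || op == "N") {
      if (op == "D") del_g <- c(del_g, gpos:(gpos + w - 1L))
      gpos <- gpos + w
    } else if (op == "I" || op == "S") {
      rpos <- rpos + w
    } # H, P consume nothing we track
  }
  gstart <- pos0
  gend <- gpos - 1L
  if (minus) {
    list(strand = "-", start = gend, end = gstart,
         length = gend - gstart + 1L,
         del = sort(gend - del_g), trans = sort(gend - mm_g))
  } else {
    list(strand = "+", start = gstart, end = gend,
         length = gend - gstart + 1L,
         del = sort(del_g - gstart), trans = sort(mm_g - gstart))
  }
}

#' Write aligned cDNAs as SAM
#'
#' Reconstructs each read sequence from the reference by removing deleted
#' bases and applying T-to-C transitions, encodes deletions in the CIGAR,
#' and stores the UMI in a tag (default `RX`). Convert to BAM with
#' `Rsamtools::asBam()` or `samtools` when needed.
#'
#' @inheritParams write_cdna_tsv
#' @param sequences reference sequences (named).
#' @param umi_tag tag name for the UMI.
#' @return `path`, invisibly.
#' @export
write_sam <- function(cdnas, sequences, path, umi_tag = "RX") {
  seq_chr <- as_seq_chr(sequences)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", names(seq_chr),
                       nchar(seq_chr))), con)
  o <- order(cdnas$ref, pmin(cdnas$start, cdnas$end))
  for (i in o) {
    g1 <- min(cdnas$start[i], cdnas$end[i])         # leftmost genomic
    g2 <- max(cdnas$start[i], cdnas$end[i])
    minus <- cdnas$strand[i] == "-"
    dg <- if (minus) cdnas$start[i] - cdnas$del_offsets[[i]]
          else cdnas$start[i] + cdnas$del_offsets[[i]]
    tg <- if (minus) cdnas$start[i] - cdnas$trans_offsets[[i]]
          else cdnas$start[i] + cdnas$trans_offsets[[i]]
    span <- g1:g2
    base <- strsplit(substring(seq_chr[[cdnas$ref[i]]], g1 + 1L, g2 + 1L),
                     "")[[1]]
    names(base) <- span
    if (length(tg)) base[as.character(tg)] <- "C"  # transcript-sense T->C
    keep <- !span %in% dg
    read_plus <- base[keep]
    if (minus) {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      ## stored plus-strand: transitions become A->G on the plus strand
      read_plus <- base
      if (length(tg)) read_plus[as.character(tg)] <- "G"
      read_plus <- read_plus[keep]
    }
    ## CIGAR from the kept/deleted mask
    r <- rle(keep)
    cig <- paste0(r$lengths, ifelse(r$values, "M", "D"), collapse = "")
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\t%s:Z:%s",
                       cdnas$read_id[i], if (minus) 16L else 0L,
                       cdnas$ref[i], g1 + 1L, cig,
                       paste0(read_plus, collapse = ""),
                       umi_tag, cdnas$umi[i]), con)
  }
  invisible(path)
}

#' Collapse PCR duplicates by UMI
#'
#' Records identical in `(ref, strand, start, umi)` become a single record
#' whose `count` is the number of collapsed reads; among same-key records
#' the one with the longest end is retained as representative (the key is
#' the start position only, mirroring standard iCLIP deduplication, which
#' collapses cDNAs with the same UMI mapped to the same starting
#' position). Collapse is idempotent.
#'
#' @param cdnas a [as_cdna_tbl()] table.
#' @return a collapsed `cdna_tbl`.
#' @export
collapse_umis <- function(cdnas) {
  dt <- copy(as.data.table(cdnas))
  ## representative = longest record in each (ref, strand, start, umi) key
  setorder(dt, ref, strand, start, umi, -length)
  out <- dt[, c(.SD[1L], .(count = sum(count))),
            by = .(ref, strand, start, umi),
            .SDcols = c("read_id", "end", "length", "del_offsets",
                        "trans_offsets")]
  setcolorder(out, c("read_id", "ref", "strand", "start", "end", "length",
                     "umi", "del_offsets", "trans_offsets", "count"))
  as_cdna_tbl(out)
}

#' Keep cDNAs shorter than a length threshold
#'
#' Mutation-density and motif analyses are restricted to cDNAs shorter
#' than 40 nt because sequencing-error rates rise with cDNA length.
#'
#' @param cdnas a [as_cdna_tbl()] table.
#' @param max_length_exclusive keep `length < max_length_exclusive`.
#' @return the subset, still a `cdna_tbl`.
#' @export
filter_short <- function(cdnas, max_length_exclusive = 40L) {
  as_cdna_tbl(cdnas[cdnas$length < max_length_exclusive])
}

#' cDNA length categories
#'
#' The four categories used for length-stratified start/end profiles:
#' 17-29, 30-34, 35-39 and >39 nt.
#'
#' @param cdna a `cdna_tbl` or an integer vector of lengths (all >= 17).
#' @return a factor with levels `"17-29"`, `"30-34"`, `"35-39"`, `">39"`.
#' @export
length_category <- function(cdna) {
  len <- if (is.numeric(cdna)) as.integer(cdna) else cdna$length
  if (any(len < 17L)) stop("cDNA length < 17 nt")
  cut(len, breaks = c(16L, 29L, 34L, 39L, Inf),
      labels = c("17-29", "30-34", "35-39", ">39"), right = TRUE)
}
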