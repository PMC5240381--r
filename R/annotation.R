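#' Region annotations used throughout the package
#'
#' A light container for the features the analyses anchor on: transcript
#' lengths, planted/annotated binding sites, exon-exon junctions (position
#' = 0-based coordinate of the first nucleotide of the downstream exon),
#' pyrimidine (Y-)tract intervals and optional intron intervals. All
#' intervals are 0-based half-open `[start, end)` on the sense strand.
#'
#' @param seqlens named integer vector of reference lengths.
#' @param sites `data.table(ref, start, end, type, name)` of crosslinkable
#'   sites (may be empty).
#' @param junctions `data.table(ref, pos, internal, exon_up_len,
#'   exon_down_len)`; `internal` marks junctions that are neither first nor
#'   last in their transcript.
#' @param ytracts `data.table(ref, start, end)` of Y-tract intervals.
#' @param introns optional `data.table(ref, start, end)` of intron
#'   intervals (pre-mRNA-space analyses).
#' @return an object of class `region_annotation`.
#' @export
region_annotation <- function(seqlens,
                              sites = NULL,
                              junctions = NULL,
                              ytracts = NULL,
                              introns = NULL) {
  empty_iv <- function() data.table(ref = character(), start = integer(),
                                    end = integer())
  if (is.null(sites))
    sites <- data.table(ref = character(), start = integer(),
                        end = integer(), type = character(),
                        name = character())
  if (is.null(junctions))
    junctions <- data.table(ref = character(), pos = integer(),
                            internal = logical(), exon_up_len = integer(),
                            exon_down_len = integer())
  if (is.null(ytracts)) ytracts <- empty_iv()
  setDT(sites); setDT(junctions); setDT(ytracts)
  if (!is.null(introns)) setDT(introns)
  bad <- function(iv) nrow(iv) &&
    (any(!iv$ref %in% names(seqlens)) ||
     any(iv$start < 0L) || any(iv$end > seqlens[iv$ref]))
  if (bad(sites)) stop("site interval outside its reference")
  if (bad(ytracts)) stop("ytract interval outside its reference")
  if (!is.null(introns) && bad(introns))
    stop("intron interval outside its reference")
  if (nrow(junctions) &&
      (any(junctions$pos < 0L) ||
       any(junctions$pos > seqlens[junctions$ref])))
    stop("junction outside its reference")
  structure(list(seqlens = seqlens, sites = sites, junctions = junctions,
                 ytracts = ytracts, introns = introns),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat("region_annotation:", length(x$seqlens), "references,",
      nrow(x$sites), "sites,", nrow(x$junctions), "junctions,",
      nrow(x$ytracts), "ytracts",
      if (!is.null(x$introns)) paste0(", ", nrow(x$introns), " introns"),
      "\n")
  invisible(x)
}

#' Write annotation features as BED6
#'
#' Intervals are written 0-based half-open, junctions as single-base
#' intervals at the first nucleotide of the downstream exon, all on the
#' plus strand (the simulator works in transcript space).
#'
#' @param annotation a [region_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(annotation, path) {
  rows <- list()
  if (nrow(annotation$sites))
    rows$sites <- annotation$sites[, .(ref, start, end,
                                       name = paste0("site:", name),
                                       score = 0L, strand = "+")]
  if (nrow(annotation$junctions))
    rows$junctions <- annotation$junctions[, .(ref, start = pos,
                                               end = pos + 1L,
                                               name = "junction",
                                               score = 0L, strand = "+")]
  if (nrow(annotation$ytracts))
    rows$ytracts <- annotation$ytracts[, .(ref, start, end,
                                           name = "ytract",
                                           score = 0L, strand = "+")]
  bed <- rbindlist(rows)
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
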