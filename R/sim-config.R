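#' Configuration for the iCLIP read simulator
#'
#' Bundles and validates every knob of the mechanistic model: crosslink
#' placement on planted sites, truncation versus readthrough during reverse
#' transcription, deletions and 4SU-induced T-to-C transitions at
#' crosslinks, RNase cleavage that is unconstrained or restricted to
#' specific positions/sequence contexts, the cDNA length distribution
#' (support must start at >= 17 nt, the practical lower bound for library
#' isolation and unique mapping), and PCR duplication resolved by UMIs.
#'
#' @param seed integer; drives all randomness, identical configs give
#'   byte-identical output.
#' @param n_transcripts number of background transcripts to simulate.
#' @param transcript_length length in nt; a scalar or a vector of length
#'   `n_transcripts`.
#' @param site_model list of site specifications. Each element is a list
#'   with `kind` one of:
#'   * `"motif"`: plant `motif` (a DNA string) at `density` expected
#'     occurrences per nt (Poisson), or exactly `n` occurrences;
#'   * `"ytract"`: plant pyrimidine tracts of `length` nt (`n` per
#'     transcript set, default 1 per transcript), drawn from T/C with
#'     C fraction `c_frac` (default [sim_config()]`$ytract_c_frac`);
#'   * `"junction"`: one site per internal exon-exon junction spanning
#'     `offsets` (inclusive, relative to the first nucleotide of the
#'     downstream exon), e.g. `c(-24, -20)` for the canonical EJC region.
#' @param crosslink_offset_dist `"uniform"` (uniform over the site) or
#'   `list(kind = "fixed", offset = k)` (0-based offset from site start).
#' @param truncation_rate probability that reverse transcription truncates
#'   at the crosslinked peptide. Default 0.85: comparative analyses place
#'   truncation above 80% of iCLIP cDNAs.
#' @param readthrough_deletion_rate probability that a readthrough cDNA
#'   carries a deletion at the crosslink.
#' @param readthrough_tail_mean mean of the geometric tail by which a
#'   readthrough cDNA extends upstream of the crosslink (>= 1 nt).
#' @param four_su logical; enable 4SU crosslinking mode (T-to-C
#'   transitions).
#' @param true_transition_rate probability that a readthrough cDNA whose
#'   crosslink is on a reference T carries a T-to-C transition there.
#' @param background_transition_rate per-reference-T probability of a
#'   spurious T-to-C transition anywhere in a read.
#' @param cleavage_model `list(kind = "uniform")`,
#'   `list(kind = "positional", positions = <named list of 0-based
#'   integer vectors per transcript>)` (cleavage only at those inclusive
#'   end positions), or `list(kind = "sequence", base = "A")` (cleavage
#'   only immediately after the given base).
#' @param cdna_length_dist `list(values = <integer support>, probs =
#'   <weights or NULL for uniform>)`; the support minimum must be >= 17 nt.
#' @param pcr_duplication mean number of extra PCR copies per molecule
#'   (Poisson); 0 disables duplication.
#' @param n_molecules number of cDNA molecules to simulate.
#' @param exon_length if not `NULL`, transcripts are partitioned into exons
#'   of this length and exon-exon junction coordinates are annotated.
#' @param umi_length UMI length in nt (library barcodes carry the unique
#'   molecular identifier used to collapse PCR duplicates).
#' @param ytract_c_frac default C fraction inside planted Y-tracts.
#'
#' @return a validated list of class `sim_config`.
#' @seealso [simulate_transcriptome()], [simulate_reads()]
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 20L,
                       transcript_length = 2000L,
                       site_model = list(list(kind = "motif",
                                              motif = "TTTG",
                                              density = 0.002)),
                       crosslink_offset_dist = "uniform",
                       truncation_rate = 0.85,
                       readthrough_deletion_rate = 0.8,
                       readthrough_tail_mean = 10,
                       four_su = FALSE,
                       true_transition_rate = 0.5,
                       background_transition_rate = 0.05,
                       cleavage_model = list(kind = "uniform"),
                       cdna_length_dist = list(values = 17:60, probs = NULL),
                       pcr_duplication = 1,
                       n_molecules = 10000L,
                       exon_length = NULL,
                       umi_length = 9L,
                       ytract_c_frac = 0.25) {
  cfg <- list(seed = as.integer(seed),
              n_transcripts = as.integer(n_transcripts),
              transcript_length = as.integer(transcript_length),
              site_model = site_model,
              crosslink_offset_dist = crosslink_offset_dist,
              truncation_rate = truncation_rate,
              readthrough_deletion_rate = readthrough_deletion_rate,
              readthrough_tail_mean = readthrough_tail_mean,
              four_su = isTRUE(four_su),
              true_transition_rate = true_transition_rate,
              background_transition_rate = background_transition_rate,
              cleavage_model = cleavage_model,
              cdna_length_dist = cdna_length_dist,
              pcr_duplication = pcr_duplication,
              n_molecules = as.integer(n_molecules),
              exon_length = if (is.null(exon_length)) NULL
                            else as.integer(exon_length),
              umi_length = as.integer(umi_length),
              ytract_c_frac = ytract_c_frac)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config a `sim_config` object.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.na(config$n_transcripts) || config$n_transcripts < 1L)
    stop("n_transcripts must be >= 1")
  if (!length(config$transcript_length) %in% c(1L, config$n_transcripts))
    stop("transcript_length must be a scalar or one value per transcript")
  if (any(config$transcript_length < 1L))
    stop("transcript lengths must be positive")
  stopifnot_prob(config$truncation_rate, "truncation_rate")
  stopifnot_prob(config$readthrough_deletion_rate, "readthrough_deletion_rate")
  stopifnot_prob(config$true_transition_rate, "true_transition_rate")
  stopifnot_prob(config$background_transition_rate,
                 "background_transition_rate")
  if (config$readthrough_tail_mean < 1)
    stop("readthrough_tail_mean must be >= 1")
  ld <- config$cdna_length_dist
  if (is.null(ld$values) || any(ld$values != as.integer(ld$values)))
    stop("cdna_length_dist$values must be integer lengths")
  if (min(ld$values) < 17L)
    stop("cdna_length_dist support must be >= 17 nt: ",
         "shorter cDNAs are not isolated or uniquely mapped")
  if (!is.null(ld$probs) && length(ld$probs) != length(ld$values))
    stop("cdna_length_dist$probs must match values in length")
  if (!config$cleavage_model$kind %in% c("uniform", "positional", "sequence"))
    stop("cleavage_model$kind must be uniform, positional or sequence")
  if (config$cleavage_model$kind == "sequence" &&
      !config$cleavage_model$base %in% c("A", "C", "G", "T"))
    stop("cleavage_model$base must be one of A, C, G, T")
  if (config$pcr_duplication < 0) stop("pcr_duplication must be >= 0")
  if (config$umi_length < 1L || 4^config$umi_length < config$n_molecules)
    stop("umi_length too short to give each molecule a unique UMI")
  invisible(config)
}
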