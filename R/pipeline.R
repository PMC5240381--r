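#' Run the full analysis pipeline on simulated or loaded data
#'
#' Orchestrates simulate -> load -> collapse -> motifs -> clusters ->
#' geometry -> maps -> QC with one configuration, writing every stage's
#' tables (TSV with `#`-comment headers recording module and parameters)
#' plus a resolved copy of the configuration and a log to `out_dir`.
#' Deterministic under a fixed seed: a rerun with the same config writes
#' byte-identical tables.
#'
#' @param config a named list, or path to a JSON file, with elements
#'   `seed`, `out_dir`, optional `input` (`list(reads, format,
#'   reference)`; when absent the simulator runs with `sim` parameters
#'   passed to [sim_config()]), and optional parameter blocks `motifs`
#'   (`k`, `min_fold`), `clusters` (`spacing`, `merge_gap`, `fdr`,
#'   `n_permutations`), `geometry` (`window`) and `maps` (`smooth`).
#'   Unknown top-level keys are rejected.
#' @param out_dir overrides `config$out_dir`.
#' @return invisibly, a named list of output paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config))
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  known <- c("seed", "out_dir", "input", "sim", "motifs", "clusters",
             "geometry", "maps")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("config requires out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  logf <- file.path(out_dir, "pipeline.log")
  cat("", file = logf)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    message(msg)
    cat(msg, "\n", file = logf, append = TRUE)
  }
  stage <- function(name, expr) {
    say("stage ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  paths <- list()
  emit <- function(name, dt, params = "") {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    hdr <- sprintf("# truncmap %s | %s | seed=%d", name, params, seed)
    writeLines(hdr, p)
    fwrite(as.data.table(dt), p, sep = "\t", append = TRUE,
           col.names = TRUE)
    paths[[name]] <<- p
    p
  }

  ## ---- inputs -------------------------------------------------------
  if (!is.null(config$input)) {
    inp <- config$input
    if (!file.exists(inp$reads)) stop("pipeline stage 'load' failed: ",
                                      "missing input: ", inp$reads)
    sequences <- NULL
    if (!is.null(inp$reference)) {
      fa <- Biostrings::readDNAStringSet(inp$reference)
      names(fa) <- sub("\\s.*", "", names(fa))
      sequences <- fa
    }
    reads <- stage("load", load_alignments(inp$reads,
                                           format = inp$format %||% "tsv",
                                           reference = sequences))
    annotation <- NULL
    truth <- NULL
  } else {
    simargs <- config$sim %||% list()
    simargs$seed <- seed
    cfg <- stage("simulate", do.call(sim_config, simargs))
    tx <- stage("simulate", simulate_transcriptome(cfg))
    sim <- stage("simulate", simulate_reads(tx$sequences, tx$annotation,
                                            cfg))
    sequences <- tx$sequences
    annotation <- tx$annotation
    reads <- sim$reads
    truth <- sim$truth
    Biostrings::writeXStringSet(sequences,
                                file.path(out_dir, "transcripts.fa"))
    write_annotation_bed(annotation, file.path(out_dir, "annotation.bed"))
    emit("truth", truth[, .(molecule, ref, crosslink, truncated, cleavage,
                            start, end, status, n_copies)],
         "simulator ground truth")
    paths$reads_tsv <- write_cdna_tsv(reads,
                                      file.path(out_dir, "reads.tsv"))
  }

  ## ---- collapse -----------------------------------------------------
  collapsed <- stage("collapse", collapse_umis(reads))
  emit("collapsed", data.table(ref = collapsed$ref,
                               start = collapsed$start,
                               end = collapsed$end, umi = collapsed$umi,
                               count = collapsed$count),
       "umi collapse (key: ref,strand,start,umi)")

  ## ---- motifs -------------------------------------------------------
  mp <- config$motifs %||% list()
  short <- filter_short(collapsed)
  motifs <- NULL
  if (!is.null(sequences)) {
    motifs <- stage("motifs",
                    define_cl_motifs(short, sequences,
                                     k = mp$k %||% 4L,
                                     min_fold = mp$min_fold %||% 1.5))
    emit("cl_motifs", motifs$scores,
         sprintf("k=%d min_fold=%.2f", mp$k %||% 4L, mp$min_fold %||% 1.5))
    if (length(motifs$motifs)) {
      prof <- stage("motifs", motif_coverage_profile(short, motifs,
                                                     sequences))
      emit("motif_coverage", prof, "window=[-20,40]")
    }
    dele <- stage("motifs", mutation_density_profile(short, "deletion"))
    emit("deletion_profile", dele, "cdnas < 40 nt")
  }

  ## ---- clusters -----------------------------------------------------
  cp <- config$clusters %||% list()
  regions <- if (!is.null(annotation))
    data.table(ref = names(annotation$seqlens), start = 0L,
               end = as.integer(annotation$seqlens))
  else collapsed[, .(start = 0L, end = max(end) + 1L), by = ref][,
                 .(ref, start, end)]
  clusters <- stage("clusters",
                    call_clusters(start_counts(collapsed), regions,
                                  spacing = cp$spacing %||% 15L,
                                  merge_gap = cp$merge_gap %||% 21L,
                                  fdr_threshold = cp$fdr %||% 0.05,
                                  n_permutations = cp$n_permutations %||%
                                    100L,
                                  seed = seed + 2L))
  emit("clusters", clusters,
       sprintf("spacing=%d merge_gap=%d fdr=%.2f perms=%d",
               cp$spacing %||% 15L, cp$merge_gap %||% 21L,
               cp$fdr %||% 0.05, cp$n_permutations %||% 100L))

  ## ---- geometry -----------------------------------------------------
  gp <- config$geometry %||% list()
  geom <- NULL
  if (nrow(clusters)) {
    cats <- table(length_category(collapsed))
    if (cats[">39"] > 0L && sum(cats[c("17-29", "30-34", "35-39")]) > 0L) {
      offmat <- stage("geometry",
                      start_offset_matrix(collapsed,
                                          window = gp$window %||% 40L))
      geom <- offmat
      emit("offset_matrix",
           data.table(category = rownames(offmat), offmat),
           sprintf("window=%d row-normalised", gp$window %||% 40L))
    }
    scores <- stage("geometry",
                    end_constraint_score(
                      data.table(ref = clusters$ref, peak = clusters$peak),
                      start_counts(collapsed, "end")))
    emit("end_constraint", scores, "flank=[+5,+25]")
  } else scores <- NULL

  ## ---- maps ---------------------------------------------------------
  mapp <- config$maps %||% list()
  if (!is.null(annotation) && nrow(annotation$junctions)) {
    jx <- annotation$junctions
    setattr(jx, "seqlens", annotation$seqlens)
    jmap <- stage("maps", junction_map(collapsed, jx, "starts",
                                       smooth = mapp$smooth %||% 5L))
    emit("junction_map_starts", jmap,
         sprintf("smooth=%d; %s", mapp$smooth %||% 5L,
                 attr(jmap, "formula")))
  }
  if (!is.null(sequences)) {
    comp <- stage("maps", end_nucleotide_composition(collapsed, sequences))
    emit("end_composition", comp, "window=[-10,10]")
  }

  ## ---- qc -----------------------------------------------------------
  qc <- stage("qc", qc_report(reads, collapsed, scores = scores,
                              offset_matrix = geom))
  qcdt <- data.table(metric = names(unlist(qc)), value = unlist(qc))
  emit("qc", qcdt, "library QC")

  resolved <- config
  resolved$seed <- seed
  resolved$out_dir <- out_dir
  jsonlite::write_json(resolved, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths$resolved_config <- file.path(out_dir, "resolved_config.json")
  say("done")
  invisible(paths)
}

#' Library QC summary
#'
#' Summarises the technical health of a truncation-based CLIP library:
#' size before/after UMI collapse, the length histogram and the fraction
#' of cDNAs shorter than 39 nt (a narrow, short-dominated library is the
#' risk signature), deletion and transition rates, the cDNA-end
#' constraint score distribution and the coinciding-start mass at
#' delta = 0 when available.
#'
#' @param reads pre-collapse [as_cdna_tbl()] table.
#' @param collapsed post-collapse table.
#' @param scores optional [end_constraint_score()] table.
#' @param offset_matrix optional [start_offset_matrix()] result.
#' @param intron_fraction optional [intron_end_fraction()] result.
#' @return list of class `qc_report`; all fraction fields lie in [0, 1].
#' @export
qc_report <- function(reads, collapsed, scores = NULL, offset_matrix = NULL,
                      intron_fraction = NULL) {
  lens <- rep(collapsed$length, collapsed$count)
  out <- list(
    n_reads = nrow(reads),
    n_collapsed = nrow(collapsed),
    duplication_rate = 1 - nrow(collapsed) / max(1L, nrow(reads)),
    frac_below_39 = mean(lens < 39L),
    median_length = median(lens),
    deletion_rate = mean(lengths(collapsed$del_offsets) > 0L),
    transition_rate = mean(lengths(collapsed$trans_offsets) > 0L))
  if (!is.null(scores))
    out$end_constraint_median <- median(scores$score, na.rm = TRUE)
  if (!is.null(offset_matrix)) {
    coin <- attr(offset_matrix, "coinciding")
    out$coinciding_mass <- mean(coin, na.rm = TRUE)
  }
  if (!is.null(intron_fraction))
    out$lariat_end_fraction <- intron_fraction$fraction
  structure(out, class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("truncmap QC report\n")
  for (nm in names(x))
    cat(sprintf("  %-24s %s\n", nm, format(x[[nm]], digits = 4)))
  invisible(x)
}

#' Minimal command-line entry point
#'
#' `truncmap run --config run.json [--out DIR] [--seed N]` executes
#' [run_pipeline()]. Used by the `exec/truncmap` script.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly.
#' @export
truncmap_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: truncmap run --config run.json [--out DIR] [--seed N]"
  if (!length(args) || args[1] != "run") { message(usage); return(invisible(1L)) }
  getopt <- function(flag) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else NULL
  }
  cfg_path <- getopt("--config")
  if (is.null(cfg_path)) { message(usage); return(invisible(1L)) }
  cfg <- jsonlite::fromJSON(cfg_path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  sd <- getopt("--seed")
  if (!is.null(sd)) cfg$seed <- as.integer(sd)
  run_pipeline(cfg, out_dir = getopt("--out"))
  invisible(0L)
}
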