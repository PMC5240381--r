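#' Simulate a transcriptome with planted crosslinkable features
#'
#' Generates i.i.d. uniform background sequences and plants the features
#' requested by `config$site_model`: exact motif occurrences, pyrimidine
#' (Y-)tracts, and per-junction sites (e.g. the expected EJC region at
#' nucleotides -24..-20 upstream of exon-exon junctions). Planted features
#' never overlap each other. If `config$exon_length` is set, transcripts
#' are partitioned into exons and junction coordinates are annotated;
#' junctions that are first or last in their transcript are flagged
#' non-internal so metagene maps can exclude them.
#'
#' @param config a [sim_config()].
#' @return `list(sequences = DNAStringSet, annotation = region_annotation)`.
#'   Every planted feature is recorded in `annotation$sites`; Y-tracts are
#'   additionally listed in `annotation$ytracts`.
#' @export
simulate_transcriptome <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    n <- config$n_transcripts
    lens <- rep(config$transcript_length, length.out = n)
    refs <- sprintf("tx%03d", seq_len(n))
    names(lens) <- refs
    chars <- lapply(lens, function(L)
      sample(c("A", "C", "G", "T"), L, replace = TRUE))
    names(chars) <- refs

    ## exon structure first, so junction-anchored sites can be planted
    junctions <- NULL
    if (!is.null(config$exon_length)) {
      el <- config$exon_length
      jl <- lapply(refs, function(r) {
        L <- lens[[r]]
        bnd <- seq(el, L - 1L, by = el)   # first nt of each downstream exon
        if (!length(bnd)) return(NULL)
        data.table(ref = r, pos = as.integer(bnd),
                   internal = seq_along(bnd) > 1L &
                              seq_along(bnd) < length(bnd),
                   exon_up_len = as.integer(c(bnd[1], diff(bnd))),
                   exon_down_len = as.integer(c(diff(bnd), L - bnd[length(bnd)])))
      })
      junctions <- rbindlist(jl)
    }

    occupied <- lapply(lens, function(L) logical(L))
    sites <- list()
    plant <- function(r, s0, letters, type, nm) {
      w <- length(letters)
      idx <- (s0 + 1L):(s0 + w)
      chars[[r]][idx] <<- letters
      occupied[[r]][idx] <<- TRUE
      sites[[length(sites) + 1L]] <<- data.table(
        ref = r, start = as.integer(s0), end = as.integer(s0 + w),
        type = type, name = nm)
    }
    free_slot <- function(r, s0, w) {
      if (s0 < 0L || s0 + w > lens[[r]]) return(FALSE)
      !any(occupied[[r]][(s0 + 1L):(s0 + w)])
    }

    for (spec in config$site_model) {
      kind <- spec$kind %||% "motif"
      if (kind == "motif") {
        motif <- strsplit(spec$motif, "")[[1]]
        w <- length(motif)
        if (any(w > lens))
          stop("site of length ", w, " longer than shortest transcript")
        n_occ <- if (!is.null(spec$n)) spec$n
                 else rpois(1L, spec$density * sum(lens))
        placed <- 0L; tries <- 0L
        while (placed < n_occ && tries < 50L * n_occ + 100L) {
          tries <- tries + 1L
          r <- sample(refs, 1L, prob = lens)
          s0 <- sample.int(lens[[r]] - w + 1L, 1L) - 1L
          if (free_slot(r, s0, w)) {
            plant(r, s0, motif, "motif", spec$motif)
            placed <- placed + 1L
          }
        }
      } else if (kind == "ytract") {
        w <- as.integer(spec$length)
        if (any(w > lens))
          stop("site of length ", w, " longer than shortest transcript")
        n_occ <- spec$n %||% config$n_transcripts
        c_frac <- spec$c_frac %||% config$ytract_c_frac
        placed <- 0L; tries <- 0L
        while (placed < n_occ && tries < 50L * n_occ + 100L) {
          tries <- tries + 1L
          r <- sample(refs, 1L, prob = lens)
          s0 <- sample.int(lens[[r]] - w + 1L, 1L) - 1L
          if (free_slot(r, s0, w)) {
            letters <- sample(c("T", "C"), w, replace = TRUE,
                              prob = c(1 - c_frac, c_frac))
            plant(r, s0, letters, "ytract", sprintf("ytract%02d", placed + 1L))
            placed <- placed + 1L
          }
        }
      } else if (kind == "junction") {
        if (is.null(junctions) || !nrow(junctions))
          stop("junction site model requires exon_length")
        off <- spec$offsets %||% c(-24L, -20L)
        jj <- junctions[internal == TRUE]
        for (i in seq_len(nrow(jj))) {
          s0 <- jj$pos[i] + off[1]
          w <- off[2] - off[1] + 1L
          if (free_slot(jj$ref[i], s0, w))
            plant(jj$ref[i], s0,
                  chars[[jj$ref[i]]][(s0 + 1L):(s0 + w)],  # keep sequence
                  "junction_site", sprintf("jxn:%s:%d", jj$ref[i], jj$pos[i]))
        }
      } else stop("unknown site kind: ", kind)
    }

    seqs <- Biostrings::DNAStringSet(vapply(chars, paste0, character(1),
                                            collapse = ""))
    sites_dt <- if (length(sites)) rbindlist(sites) else NULL
    ytr <- if (!is.null(sites_dt))
      sites_dt[type == "ytract", .(ref, start, end)] else NULL
    ann <- region_annotation(lens, sites = sites_dt, junctions = junctions,
                             ytracts = ytr)
    list(sequences = seqs, annotation = ann)
  })
}

#' Simulate iCLIP-like aligned cDNAs with ground truth
#'
#' Each molecule draws a crosslink from the planted sites, a desired cDNA
#' length `L` from `cdna_length_dist`, and a cleavage site downstream of
#' the crosslink. With probability `truncation_rate` reverse transcription
#' truncates at the crosslinked peptide, so the cDNA starts at
#' `crosslink + 1` and ends at the cleavage site; otherwise the cDNA reads
#' through, extending a geometric tail upstream of the crosslink, and
#' carries a deletion at the crosslink with `readthrough_deletion_rate`.
#' Under constrained cleavage models the cleavage site snaps to the
#' nearest legal position whose distance from the crosslink lies within
#' the support range of the length distribution; molecules with no legal
#' cut are dropped (and counted), never silently mis-placed. Reads shorter
#' than 17 nt are dropped and counted. In 4SU mode T-to-C transitions are
#' injected at crosslinks on reference Ts (readthrough molecules only; a
#' truncated cDNA does not contain its crosslink) plus background
#' transitions at any reference T. Every molecule receives a unique UMI
#' and `1 + Poisson(pcr_duplication)` PCR copies.
#'
#' @param sequences transcript sequences from [simulate_transcriptome()].
#' @param annotation matching [region_annotation()] with at least one site.
#' @param config the same [sim_config()].
#' @return `list(reads, truth, dropped)`: `reads` is a [cdna_tbl()] with
#'   one row per sequenced read (PCR duplicates included), `truth` one row
#'   per molecule with its crosslink, truncation flag, cleavage site,
#'   injected mutation offsets and status
#'   (`emitted`/`dropped_short`/`dropped_no_cut`), and `dropped` the two
#'   drop counts. Molecule conservation holds exactly:
#'   `n_molecules = collapsed reads + dropped_short + dropped_no_cut`.
#' @export
simulate_reads <- function(sequences, annotation, config) {
  validate_sim_config(config)
  sites <- annotation$sites  # every planted site type is crosslinkable
  if (is.null(sites) || nrow(sites) == 0L)
    stop("no crosslink sites in annotation")
  seq_chr <- as_seq_chr(sequences)
  seq_split <- lapply(seq_chr, function(s) strsplit(s, "")[[1]])
  lens <- annotation$seqlens

  with_seed(config$seed + 1L, {
    n <- config$n_molecules
    si <- sample.int(nrow(sites), n, replace = TRUE)
    ref <- sites$ref[si]
    sw <- sites$end[si] - sites$start[si]
    xod <- config$crosslink_offset_dist
    X <- if (identical(xod, "uniform")) {
      sites$start[si] + floor(runif(n) * sw)
    } else if (is.list(xod) && identical(xod$kind, "fixed")) {
      sites$start[si] + as.integer(xod$offset)
    } else stop("unknown crosslink_offset_dist")
    X <- as.integer(X)

    ld <- config$cdna_length_dist
    L <- as.integer(sample(length(ld$values), n, replace = TRUE,
                           prob = ld$probs))
    L <- ld$values[L]
    lmin <- min(ld$values); lmax <- max(ld$values)

    ## cleavage: inclusive end position E of the RNA fragment
    cm <- config$cleavage_model
    E0 <- X + L
    if (cm$kind == "uniform") {
      E <- pmin(E0, lens[ref] - 1L)
    } else {
      allowed <- if (cm$kind == "positional") {
        lapply(cm$positions, as.integer)
      } else {
        lapply(seq_split, function(s) which(s == cm$base) - 1L)
      }
      E <- rep(NA_integer_, n)
      for (i in seq_len(n)) {
        a <- allowed[[ref[i]]]
        a <- a[a - X[i] >= lmin & a - X[i] <= lmax & a <= lens[[ref[i]]] - 1L]
        if (length(a)) E[i] <- a[which.min(abs(a - E0[i]))]
      }
    }
    no_cut <- is.na(E)

    truncated <- runif(n) < config$truncation_rate
    g <- integer(n)
    if (any(!truncated))
      g[!truncated] <- 1L + rgeom(sum(!truncated),
                                  prob = 1 / config$readthrough_tail_mean)
    start <- ifelse(truncated, X + 1L, pmax(0L, X - g))
    start <- as.integer(start)
    rlen <- E - start + 1L
    short <- !no_cut & rlen < 17L
    emitted <- !no_cut & !short

    ## mutations (only meaningful for emitted molecules)
    del <- rep(list(integer(0)), n)
    trs <- rep(list(integer(0)), n)
    refbase_X <- vapply(seq_len(n), function(i) seq_split[[ref[i]]][X[i] + 1L],
                        character(1))
    has_del <- emitted & !truncated &
      runif(n) < config$readthrough_deletion_rate
    del[has_del] <- as.list(X[has_del] - start[has_del])
    if (config$four_su) {
      true_tr <- emitted & !truncated & !has_del & refbase_X == "T" &
        runif(n) < config$true_transition_rate
      trs[true_tr] <- as.list(X[true_tr] - start[true_tr])
      if (config$background_transition_rate > 0) {
        p <- config$background_transition_rate
        for (i in which(emitted)) {
          span <- (start[i] + 1L):(E[i] + 1L)
          tpos <- span[seq_split[[ref[i]]][span] == "T"] - 1L
          tpos <- setdiff(tpos, c(del[[i]] + start[i], trs[[i]] + start[i]))
          if (length(tpos)) {
            hit <- tpos[runif(length(tpos)) < p]
            if (length(hit))
              trs[[i]] <- sort(unique(c(trs[[i]], hit - start[i])))
          }
        }
      }
    }

    ## unique UMIs (index-coded base-4 words drawn without replacement)
    codes <- sample.int(4^config$umi_length, n)
    umi <- encode_umi(codes - 1L, config$umi_length)

    status <- rep("emitted", n)
    status[short] <- "dropped_short"
    status[no_cut] <- "dropped_no_cut"
    truth <- data.table(
      molecule = sprintf("m%07d", seq_len(n)),
      ref = ref, crosslink = X, truncated = truncated,
      cleavage = E, start = start, end = E,
      del_offsets = del, trans_offsets = trs,
      umi = umi, status = status)

    keep <- which(emitted)
    n_copies <- integer(n)
    n_copies[keep] <- 1L + rpois(length(keep), config$pcr_duplication)
    truth[, n_copies := n_copies]

    idx <- rep(keep, n_copies[keep])
    dup <- sequence(n_copies[keep])
    reads <- data.table(
      read_id = sprintf("%s.%d", truth$molecule[idx], dup),
      ref = ref[idx], strand = "+",
      start = start[idx], end = E[idx],
      length = E[idx] - start[idx] + 1L,
      umi = umi[idx],
      del_offsets = del[idx], trans_offsets = trs[idx],
      count = 1L)
    reads <- as_cdna_tbl(reads)

    list(reads = reads, truth = truth,
         dropped = c(short = sum(short), no_cut = sum(no_cut)))
  })
}

## integer codes (0-based) -> ACGT words
encode_umi <- function(codes, width) {
  base <- c("A", "C", "G", "T")
  out <- matrix("A", nrow = length(codes), ncol = width)
  x <- codes
  for (j in seq_len(width)) {
    out[, width - j + 1L] <- base[x %% 4L + 1L]
    x <- x %/% 4L
  }
  apply(out, 1L, paste0, collapse = "")
}
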