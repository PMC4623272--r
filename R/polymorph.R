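# Empty-allele (uninserted) detection from trace reads: locus windows,
# trace-to-window gapped alignment, evidence filtering, locus uniqueness
# and heterozygous-locus calls.

#' Extract the locus window (element plus flanks)
#'
#' Returns the ~2.2 kb window used as the query against trace reads: the
#' element and up to `flank` bp on each side, truncated (and flagged) at
#' chromosome ends.
#'
#' @param genome Named character or DNAStringSet keyed by chromosome.
#' @param locus One-row locus data.frame (`locus_id`, `chrom`, `start`,
#'   `end`; 0-based half-open).
#' @param flank Flank length in bp.
#' @return List: `locus_id`, `chrom`, `window_start`, `window_end`,
#'   `sequence`, `elt_offset` (element start within the window),
#'   `elt_length`, `truncated_left`, `truncated_right`.
#' @export
extract_window <- function(genome, locus, flank = 1000L) {
  genome <- .as_seq_chr(genome)
  chrom <- locus$chrom
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  L <- nchar(genome[[chrom]])
  if (locus$start < 0 || locus$end > L) {
    stop("locus ", locus$locus_id, " outside genome bounds")
  }
  ws <- max(0L, locus$start - flank)
  we <- min(L, locus$end + flank)
  list(locus_id = locus$locus_id, chrom = chrom,
       window_start = ws, window_end = we,
       sequence = substr(genome[[chrom]], ws + 1L, we),
       elt_offset = locus$start - ws,
       elt_length = locus$end - locus$start,
       truncated_left = ws > locus$start - flank,
       truncated_right = we < locus$end + flank)
}

# Parse one pairwise alignment into segment/gap summaries.
# Returns NULL or a list with overall stats and a data.frame of large
# deletions (gaps in the trace relative to the window).
.summarize_alignment <- function(aln, window_offset0, min_gap) {
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ncol_aln <- length(pat)
  sub_start0 <- window_offset0 + IRanges::start(Biostrings::subject(aln)) - 1L
  is_del <- pat == "-"          # window bases absent from the trace
  r <- rle(is_del)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  del <- data.frame(col_start = starts[r$values & r$lengths >= min_gap],
                    col_end = ends[r$values & r$lengths >= min_gap])
  # window coordinate of each column (0-based; gaps in subject don't advance)
  sub_adv <- cumsum(sub != "-")
  col_w0 <- sub_start0 + sub_adv - 1L
  matches <- pat == sub & pat != "-"
  out_del <- NULL
  if (nrow(del) > 0) {
    out_del <- data.frame(
      gap_start = col_w0[del$col_start],          # 0-based window coords
      gap_end = col_w0[del$col_end] + 1L,
      gap_len = del$col_end - del$col_start + 1L,
      left_identity = NA_real_, right_identity = NA_real_,
      left_anchor = NA_integer_, right_anchor = NA_integer_
    )
    for (i in seq_len(nrow(del))) {
      lcols <- seq_len(del$col_start[i] - 1L)
      rcols <- if (del$col_end[i] < ncol_aln)
        seq(del$col_end[i] + 1L, ncol_aln) else integer(0)
      # identity of each flanking aligned segment, excluding other large gaps
      lk <- lcols[!is_del[lcols] | TRUE]
      out_del$left_identity[i] <- if (length(lcols))
        100 * sum(matches[lcols]) / length(lcols) else 0
      out_del$right_identity[i] <- if (length(rcols))
        100 * sum(matches[rcols]) / length(rcols) else 0
      out_del$left_anchor[i] <- sum(pat[lcols] != "-")
      out_del$right_anchor[i] <- sum(pat[rcols] != "-")
    }
  }
  list(score = Biostrings::score(aln),
       matches = sum(matches), columns = ncol_aln,
       identity = 100 * sum(matches) / ncol_aln,
       window_start = sub_start0,
       window_end = col_w0[ncol_aln] + 1L,
       deletions = out_del)
}

# Sampled k-mers of the two flanks of a window (element masked out: element
# words are shared between loci and would make every filled read from every
# locus a candidate everywhere).
.window_flank_kmers <- function(window, k = 16L, step = 25L) {
  sides <- list(
    L = substr(window$sequence, 1, window$elt_offset),
    R = substr(window$sequence,
               window$elt_offset + window$elt_length + 1L,
               nchar(window$sequence))
  )
  out <- lapply(names(sides), function(s) {
    if (nchar(sides[[s]]) < k) return(NULL)
    kq <- .query_kmers(sides[[s]], k, step = step)
    if (length(kq$kmers) == 0) return(NULL)
    data.frame(kmer = kq$kmers, side = s)
  })
  do.call(rbind, out)
}

# Batch k-mer prescreen: for each window, the trace indices sharing at
# least one exact flank word on each side of the element (on either
# strand). One PDict scan over the whole trace set serves every window.
.prescreen_trace_candidates <- function(windows, traces_fwd, traces_rev,
                                        k = 16L, step = 25L) {
  km <- lapply(windows, .window_flank_kmers, k = k, step = step)
  tab <- do.call(rbind, lapply(seq_along(km), function(i) {
    if (is.null(km[[i]])) return(NULL)
    cbind(km[[i]], win = i)
  }))
  out <- vector("list", length(windows))
  if (is.null(tab) || nrow(tab) == 0) return(out)
  pd <- Biostrings::PDict(tab$kmer)
  hf <- Biostrings::vcountPDict(pd, traces_fwd) > 0
  hr <- Biostrings::vcountPDict(pd, traces_rev) > 0
  for (i in seq_along(windows)) {
    li <- which(tab$win == i & tab$side == "L")
    ri <- which(tab$win == i & tab$side == "R")
    if (length(li) == 0 || length(ri) == 0) {
      out[[i]] <- integer(0)
      next
    }
    fwd_ok <- (colSums(hf[li, , drop = FALSE]) > 0) &
      (colSums(hf[ri, , drop = FALSE]) > 0)
    rev_ok <- (colSums(hr[li, , drop = FALSE]) > 0) &
      (colSums(hr[ri, , drop = FALSE]) > 0)
    out[[i]] <- which(fwd_ok | rev_ok)
  }
  out
}

# Trim a deletion by its target-site-duplication overlap: an empty-allele
# read aligned to the filled reference shows a deletion of element plus one
# TSD copy, and the aligner may place the duplicated bases at either end of
# the gap. The longest common suffix (prefix) between the gap sequence and
# the retained sequence immediately left (right) of it measures the
# duplication; the corrected length estimates the inserted element alone.
.tsd_trim <- function(window_seq, gap_start0, gap_end0, cap = 30L) {
  gap_seq <- substr(window_seq, gap_start0 + 1L, gap_end0)
  left_ret <- substr(window_seq, max(1L, gap_start0 - cap + 1L), gap_start0)
  right_ret <- substr(window_seq, gap_end0 + 1L,
                      min(nchar(window_seq), gap_end0 + cap))
  t_left <- .lcs_len(gap_seq, left_ret, cap = cap)
  t_right <- .lcp_len(gap_seq, right_ret, cap = cap)
  max(t_left, t_right)
}

#' Align a trace read to a locus window
#'
#' Semi-global alignment (whole trace, local on the window) on both strands
#' with an affine gap model whose high opening and low extension penalty
#' make one large deletion affordable while discouraging scattered small
#' gaps; reports every deletion of
#' at least `min_gap` bp in the trace relative to the window, together with
#' the identity and anchor length of the aligned segments flanking it, the
#' raw gap length and the TSD-corrected gap length.
#'
#' @param window Result of [extract_window()] (or a list with `sequence`).
#' @param trace Character string or one-row data.frame with `sequence`.
#' @param min_gap Minimum deletion length reported (bp).
#' @param min_score Minimum alignment score to report an alignment; poorer
#'   alignments return the "no alignment" result.
#' @param gap_opening,gap_extension Gap penalties of the alignment.
#' @return List: `aligned` (logical), `strand`, `score`, `identity`,
#'   `window_start`, `window_end` and `deletions` (NULL or a data.frame with
#'   `gap_start`, `gap_end`, `gap_len`, `tsd_overlap`, `gap_len_corrected`,
#'   flank identities and anchors).
#' @export
match_trace <- function(window, trace, min_gap = 50L, min_score = 60,
                        gap_opening = 40, gap_extension = 0.1) {
  trace_seq <- if (is.character(trace)) trace else trace$sequence
  wseq <- window$sequence
  if (nchar(trace_seq) < 2 * min_gap) {
    # too short to anchor a large deletion on both sides; still alignable
  }
  submat <- .scan_submat()
  best <- NULL
  for (strand in c("+", "-")) {
    ts <- if (strand == "-") .revcomp(trace_seq) else trace_seq
    aln <- try(Biostrings::pairwiseAlignment(
      pattern = ts, subject = wseq, type = "global-local",
      substitutionMatrix = submat,
      gapOpening = gap_opening, gapExtension = gap_extension), silent = TRUE)
    if (inherits(aln, "try-error")) next
    if (is.null(best) || Biostrings::score(aln) > best$score_raw) {
      best <- list(aln = aln, strand = strand,
                   score_raw = Biostrings::score(aln))
    }
  }
  if (is.null(best) || best$score_raw < min_score) {
    return(list(aligned = FALSE, strand = NA_character_, score = NA_real_,
                identity = NA_real_, deletions = NULL))
  }
  s <- .summarize_alignment(best$aln, window_offset0 = 0L, min_gap = min_gap)
  if (!is.null(s$deletions)) {
    s$deletions$tsd_overlap <- vapply(seq_len(nrow(s$deletions)), function(i)
      .tsd_trim(wseq, s$deletions$gap_start[i], s$deletions$gap_end[i]),
      integer(1))
    s$deletions$gap_len_corrected <-
      s$deletions$gap_len - s$deletions$tsd_overlap
  }
  list(aligned = TRUE, strand = best$strand, score = s$score,
       identity = s$identity, window_start = s$window_start,
       window_end = s$window_end, deletions = s$deletions)
}

#' Detect empty-allele evidence at a locus
#'
#' Aligns every trace from the reference project to the locus window and
#' emits one evidence row per read showing a large deletion whose
#' TSD-corrected length is within `gap_tol` of the element length, whose
#' aligned flanking segments are both at least `min_flank_identity`
#' identical, whose anchors are at least `min_anchor` bp, and which overlaps
#' the element interval.
#'
#' @param window Result of [extract_window()].
#' @param traces data.frame(trace_id, project, sequence).
#' @param project Reference project identifier; reads from other projects
#'   are never counted.
#' @param gap_tol Allowed deviation of the corrected gap length from the
#'   element length (bp; the classic rule is element 225 +/- 10).
#' @param min_flank_identity Minimum percent identity of each flanking
#'   segment.
#' @param min_anchor Minimum aligned trace bases on each side of the gap.
#' @param candidate_ids Optional trace ids to restrict the alignment to
#'   (precomputed k-mer prescreen); by default a prescreen on the window's
#'   flank words is applied when the trace set is large.
#' @param ... Passed to [match_trace()].
#' @return data.frame(locus_id, trace_id, gap_length, gap_raw, tsd_overlap,
#'   left_flank_identity, right_flank_identity, left_anchor, right_anchor).
#' @export
detect_empty_allele <- function(window, traces, project = "G836",
                                gap_tol = 10L, min_flank_identity = 98,
                                min_anchor = 50L, candidate_ids = NULL,
                                ...) {
  traces <- traces[!is.na(traces$project) & traces$project == project, ,
                   drop = FALSE]
  if (!is.null(candidate_ids)) {
    traces <- traces[traces$trace_id %in% candidate_ids, , drop = FALSE]
  } else if (nrow(traces) > 20) {
    dss <- Biostrings::DNAStringSet(traces$sequence)
    cand <- .prescreen_trace_candidates(
      list(window), dss, Biostrings::reverseComplement(dss))[[1]]
    traces <- traces[cand, , drop = FALSE]
  }
  elt_lo <- window$elt_offset
  elt_hi <- window$elt_offset + window$elt_length
  rows <- list()
  for (i in seq_len(nrow(traces))) {
    m <- match_trace(window, traces$sequence[i], ...)
    if (!isTRUE(m$aligned) || is.null(m$deletions)) next
    d <- m$deletions
    ok <- abs(d$gap_len_corrected - window$elt_length) <= gap_tol &
      d$left_identity >= min_flank_identity &
      d$right_identity >= min_flank_identity &
      d$left_anchor >= min_anchor & d$right_anchor >= min_anchor &
      d$gap_start < elt_hi & d$gap_end > elt_lo
    if (any(ok)) {
      k <- which(ok)[1]
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = window$locus_id, trace_id = traces$trace_id[i],
        gap_length = d$gap_len_corrected[k], gap_raw = d$gap_len[k],
        tsd_overlap = d$tsd_overlap[k],
        left_flank_identity = d$left_identity[k],
        right_flank_identity = d$right_identity[k],
        left_anchor = d$left_anchor[k], right_anchor = d$right_anchor[k]
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(locus_id = character(), trace_id = character(),
                      gap_length = integer(), gap_raw = integer(),
                      tsd_overlap = integer(),
                      left_flank_identity = numeric(),
                      right_flank_identity = numeric(),
                      left_anchor = integer(), right_anchor = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Check whether a locus lies in single-copy sequence
#'
#' Realigns each flank (the element itself is masked out) against the whole
#' genome; if either flank matches a second location at `dup_identity`
#' percent identity over at least `dup_coverage` of its length, the locus
#' is flagged multicopy (segmental-duplication analogue).
#'
#' @param window Result of [extract_window()].
#' @param genome Named character or DNAStringSet.
#' @param dup_identity Percent identity threshold for a duplicate flank.
#' @param dup_coverage Minimum fraction of the flank length matched.
#' @param word_size,step Seeding parameters of the similarity search.
#' @return "unique" or "multicopy".
#' @export
check_locus_uniqueness <- function(window, genome, dup_identity = 95,
                                   dup_coverage = 0.8, word_size = 16L,
                                   step = 50L) {
  res <- .batch_uniqueness(list(window), genome,
                           dup_identity = dup_identity,
                           dup_coverage = dup_coverage,
                           word_size = word_size, step = step)
  unname(res[[1]])
}

# Batched uniqueness screen: one PDict scan of all flank words over the
# genome (both orientations); seed clusters not overlapping a flank's own
# location are realigned and scored. Returns a character vector (unique /
# multicopy) named by locus id.
.batch_uniqueness <- function(windows, genome, dup_identity = 95,
                              dup_coverage = 0.8, word_size = 16L,
                              step = 50L, min_seeds = 3L, slack = 30L) {
  genome <- .as_dss(genome)
  out <- setNames(rep("unique", length(windows)),
                  vapply(windows, `[[`, "", "locus_id"))
  flanks <- list()
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    defs <- list(
      L = c(1L, w$elt_offset),
      R = c(w$elt_offset + w$elt_length + 1L, nchar(w$sequence))
    )
    for (s in names(defs)) {
      seqs <- substr(w$sequence, defs[[s]][1], defs[[s]][2])
      if (nchar(seqs) < 100) next
      flanks[[length(flanks) + 1L]] <- list(
        win = i, seq = seqs, chrom = w$chrom,
        start = w$window_start + defs[[s]][1] - 1L,
        end = w$window_start + defs[[s]][2])
    }
  }
  if (length(flanks) == 0) return(out)
  tab <- do.call(rbind, lapply(seq_along(flanks), function(fi) {
    kq <- .query_kmers(flanks[[fi]]$seq, word_size, step = step)
    if (length(kq$kmers) == 0) return(NULL)
    data.frame(kmer = kq$kmers, qpos = kq$qpos, flank = fi)
  }))
  if (is.null(tab) || nrow(tab) == 0) return(out)
  pd <- Biostrings::PDict(tab$kmer)
  for (ci in seq_along(genome)) {
    contig <- names(genome)[ci]
    clen <- length(genome[[ci]])
    for (orient in c("+", "-")) {
      subject_dna <- if (orient == "+") genome[[ci]] else
        Biostrings::reverseComplement(genome[[ci]])
      m <- Biostrings::matchPDict(pd, subject_dna)
      counts <- S4Vectors::elementNROWS(m)
      if (sum(counts) == 0) next
      seeds_all <- data.frame(
        spos = unlist(IRanges::start(m), use.names = FALSE),
        qpos = rep(tab$qpos, counts),
        flank = rep(tab$flank, counts))
      seeds_all$diag <- seeds_all$spos - seeds_all$qpos
      for (fi in unique(seeds_all$flank)) {
        f <- flanks[[fi]]
        if (out[f$win] == "multicopy") next
        seeds <- seeds_all[seeds_all$flank == fi, , drop = FALSE]
        qlen <- nchar(f$seq)
        clusters <- .cluster_seeds(seeds, min_seeds = min_seeds,
                                   max_gap = qlen)
        for (cl in clusters) {
          # implied region, in forward-genome coordinates (0-based)
          r0 <- max(0L, min(cl$spos - cl$qpos + 1L) - slack - 1L)
          r1 <- min(clen, max(cl$spos + (qlen - cl$qpos)) + slack)
          if (orient == "-") {
            tmp <- clen - r1
            r1 <- clen - r0
            r0 <- tmp
          }
          own <- contig == f$chrom && r0 < f$end && r1 > f$start
          if (own) next
          hit <- .align_candidate(Biostrings::DNAString(f$seq), subject_dna,
                                  cl, qlen, slack = slack)
          if (is.null(hit)) next
          if (hit$identity >= dup_identity &&
              (hit$end - hit$start) / qlen >= dup_coverage) {
            out[f$win] <- "multicopy"
            break
          }
        }
      }
    }
  }
  out
}

#' Call heterozygous loci from evidence and uniqueness
#'
#' A locus is called heterozygous (one filled, one empty allele in the
#' reference individual) when it lies in single-copy sequence and at least
#' `min_traces` empty-allele evidence rows support it.
#'
#' @param loci Locus data.frame (kept loci).
#' @param evidence data.frame from [detect_empty_allele()], all loci pooled.
#' @param uniqueness Named character vector (locus_id -> "unique" /
#'   "multicopy").
#' @param min_traces Minimum supporting traces.
#' @return data.frame(locus_id, chrom, start, end, identity,
#'   n_supporting_traces, trace_ids) for called loci.
#' @export
call_polymorphic_loci <- function(loci, evidence, uniqueness,
                                  min_traces = 1L) {
  counts <- table(evidence$locus_id)
  out <- list()
  for (i in seq_len(nrow(loci))) {
    id <- loci$locus_id[i]
    n <- if (id %in% names(counts)) as.integer(counts[[id]]) else 0L
    uniq <- !is.na(uniqueness[id]) && uniqueness[id] == "unique"
    if (uniq && n >= min_traces) {
      tr <- evidence$trace_id[evidence$locus_id == id]
      out[[length(out) + 1L]] <- data.frame(
        locus_id = id, chrom = loci$chrom[i], start = loci$start[i],
        end = loci$end[i], identity = loci$identity[i],
        n_supporting_traces = n,
        trace_ids = paste(sort(tr), collapse = ";")
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(locus_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      identity = numeric(), n_supporting_traces = integer(),
                      trace_ids = character()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full polymorphism stage over kept loci
#'
#' Extracts the window of every kept locus, screens the reference-project
#' traces for empty-allele evidence, checks locus uniqueness, and calls
#' heterozygous loci.
#'
#' @param loci Locus table; only `filter_status == "kept"` rows are used.
#' @param genome Named character or DNAStringSet keyed by chromosome.
#' @param traces data.frame(trace_id, project, sequence).
#' @param project Reference project id.
#' @param flank Window flank (bp).
#' @param min_traces Minimum supporting traces per call.
#' @param ... Passed to [detect_empty_allele()].
#' @return List: `calls` (called heterozygous loci), `evidence`,
#'   `uniqueness`.
#' @export
find_heterozygous_loci <- function(loci, genome, traces, project = "G836",
                                   flank = 1000L, min_traces = 1L, ...) {
  kept <- loci[loci$filter_status == "kept", , drop = FALSE]
  genome <- .as_dss(genome)
  proj <- traces[!is.na(traces$project) & traces$project == project, ,
                 drop = FALSE]
  dss <- Biostrings::DNAStringSet(proj$sequence)
  rev <- Biostrings::reverseComplement(dss)
  windows <- lapply(seq_len(nrow(kept)), function(i)
    extract_window(genome, kept[i, ], flank = flank))
  cands <- .prescreen_trace_candidates(windows, dss, rev)
  evidence <- list()
  with_evidence <- logical(nrow(kept))
  for (i in seq_len(nrow(kept))) {
    if (length(cands[[i]]) == 0) next
    ev <- detect_empty_allele(windows[[i]], traces, project = project,
                              candidate_ids = proj$trace_id[cands[[i]]], ...)
    if (nrow(ev) > 0) {
      evidence[[length(evidence) + 1L]] <- ev
      with_evidence[i] <- TRUE
    }
  }
  # the uniqueness screen is only needed for loci with evidence
  uniqueness <- setNames(rep("unique", nrow(kept)), kept$locus_id)
  if (any(with_evidence)) {
    uniqueness[with_evidence] <-
      .batch_uniqueness(windows[with_evidence], genome)
  }
  evidence <- if (length(evidence)) do.call(rbind, evidence) else
    data.frame(locus_id = character(), trace_id = character())
  calls <- call_polymorphic_loci(kept, evidence, uniqueness,
                                 min_traces = min_traces)
  list(calls = calls, evidence = evidence, uniqueness = uniqueness)
}

#' Write the heterozygous-locus table
#'
#' 1-based inclusive coordinates, identity to one decimal, supporting trace
#' ids semicolon-joined.
#'
#' @param calls data.frame from [call_polymorphic_loci()].
#' @param path File path.
#' @export
write_polymorphic_table <- function(calls, path) {
  out <- calls
  out$start <- out$start + 1L
  out$identity <- sprintf("%.1f", out$identity)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
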