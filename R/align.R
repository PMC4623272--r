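# Internal alignment machinery: k-mer seeding, diagonal clustering and
# candidate-window alignment. Used by the genome scanner, the locus
# uniqueness check and trace matching.

# Default scoring for consensus-vs-genome scans: substitutions cheap relative
# to gaps so that substitution-diverged copies align gaplessly.
.scan_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

# All w-mers of `seq` with their 1-based query offsets. Ambiguous letters are
# skipped (PDict requires plain ACGT).
.query_kmers <- function(seq, w, step = 1L) {
  L <- nchar(seq)
  if (L < w) stop("query shorter than word size (", L, " < ", w, ")")
  starts <- seq.int(1L, L - w + 1L, by = step)
  kmers <- substring(seq, starts, starts + w - 1L)
  keep <- !grepl("[^ACGT]", kmers)
  list(kmers = kmers[keep], qpos = starts[keep])
}

# Exact seed matches of query k-mers on one subject sequence.
# Returns data.frame(qpos, spos, diag) with 1-based positions.
.seed_hits <- function(kq, subject_dna) {
  if (length(kq$kmers) == 0) {
    return(data.frame(qpos = integer(), spos = integer(), diag = integer()))
  }
  pd <- Biostrings::PDict(kq$kmers)
  m <- Biostrings::matchPDict(pd, subject_dna)
  counts <- S4Vectors::elementNROWS(m)
  if (sum(counts) == 0) {
    return(data.frame(qpos = integer(), spos = integer(), diag = integer()))
  }
  spos <- unlist(IRanges::start(m), use.names = FALSE)
  qpos <- rep(kq$qpos, counts)
  data.frame(qpos = qpos, spos = spos, diag = spos - qpos)
}

# Greedy single-linkage clustering of seeds into candidate bands.
# Seeds are on a common diagonal (+/- band) and within `max_span` of each
# other along the subject.
.cluster_seeds <- function(seeds, band = 25L, max_gap = 400L,
                           min_seeds = 2L) {
  if (nrow(seeds) == 0) return(list())
  seeds <- seeds[order(seeds$diag, seeds$spos), , drop = FALSE]
  brk <- c(TRUE, diff(seeds$diag) > band | diff(seeds$spos) > max_gap)
  grp <- cumsum(brk)
  out <- split(seeds, grp)
  out[vapply(out, nrow, 1L) >= min_seeds]
}

# Globally align `query` against a candidate slice of the subject around a
# seed cluster; returns hit coordinates (0-based half-open, on the subject),
# match counts and score. `query` must be fully consumed (type global-local).
.align_candidate <- function(query_dna, subject_dna, cluster, qlen,
                             slack = 30L, gap_opening = 5, gap_extension = 2) {
  slen <- length(subject_dna)
  wstart <- max(1L, min(cluster$spos - cluster$qpos + 1L) - slack)
  wend <- min(slen, max(cluster$spos + (qlen - cluster$qpos)) + slack)
  if (wend - wstart + 1L < qlen * 0.5) return(NULL)
  window <- Biostrings::subseq(subject_dna, wstart, wend)
  aln <- Biostrings::pairwiseAlignment(
    pattern = query_dna, subject = window, type = "global-local",
    substitutionMatrix = .scan_submat(),
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  s0 <- wstart + IRanges::start(Biostrings::subject(aln)) - 2L  # 0-based
  e0 <- wstart + IRanges::end(Biostrings::subject(aln)) - 1L    # half-open
  list(start = s0, end = e0,
       matches = Biostrings::nmatch(aln), aligned_columns = cols,
       identity = 100 * Biostrings::nmatch(aln) / cols,
       score = Biostrings::score(aln))
}

# Find all regions of `genome` similar to `query` (both strands).
# Returns data.frame(contig, start, end, strand, identity, coverage, score)
# with 0-based half-open coordinates. Used by the scanner (full sensitivity,
# step = 1) and the duplication check (sparser seeding).
.find_similar_regions <- function(query, genome, word_size = 11L,
                                  step = 1L, min_seeds = 2L,
                                  band = 25L, slack = 30L) {
  query <- .as_seq_chr(query)[[1]]
  genome <- .as_dss(genome)
  qlen <- nchar(query)
  queries <- c(`+` = query, `-` = .revcomp(query))
  res <- list()
  for (ci in seq_along(genome)) {
    contig <- names(genome)[ci]
    subject_dna <- genome[[ci]]
    for (strand in names(queries)) {
      kq <- .query_kmers(queries[[strand]], word_size, step = step)
      seeds <- .seed_hits(kq, subject_dna)
      clusters <- .cluster_seeds(seeds, band = band, min_seeds = min_seeds,
                                 max_gap = max(400L, qlen))
      for (cl in clusters) {
        qdna <- Biostrings::DNAString(queries[[strand]])
        hit <- .align_candidate(qdna, subject_dna, cl, qlen, slack = slack)
        if (is.null(hit)) next
        res[[length(res) + 1L]] <- data.frame(
          contig = contig, start = hit$start, end = hit$end, strand = strand,
          matches = hit$matches, aligned_columns = hit$aligned_columns,
          identity = hit$identity,
          coverage = (hit$end - hit$start) / qlen,
          score = hit$score
        )
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      matches = integer(), aligned_columns = integer(),
                      identity = numeric(), coverage = numeric(),
                      score = numeric()))
  }
  do.call(rbind, res)
}

# Resolve overlapping hits on the same contig: keep highest score, ties to
# the leftmost start.
.resolve_overlaps <- function(hits) {
  if (nrow(hits) <= 1) return(hits)
  hits <- hits[order(hits$contig, -hits$score, hits$start), , drop = FALSE]
  keep <- logical(nrow(hits))
  for (contig in unique(hits$contig)) {
    idx <- which(hits$contig == contig)
    taken <- IRanges::IRanges()
    for (i in idx) {
      ir <- IRanges::IRanges(hits$start[i] + 1L, hits$end[i])
      if (length(taken) == 0 ||
          sum(IRanges::countOverlaps(ir, taken)) == 0) {
        keep[i] <- TRUE
        taken <- c(taken, ir)
      }
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits[order(hits$contig, hits$start), , drop = FALSE]
}
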