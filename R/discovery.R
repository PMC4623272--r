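# Discovery of consensus-matching loci: k-mer seeded scan, filters
# (length, identity, placement, repeat embedding) and identity classes.

#' Scan a genome for consensus-matching loci
#'
#' k-mer seeded, banded scan of both strands: exact word matches between the
#' consensus and the genome are clustered on diagonals, each cluster is
#' realigned (global on the consensus, local on the genome) and overlapping
#' hits are resolved keeping the highest-scoring, then leftmost. Identity is
#' matches over alignment columns, gap columns counting as mismatch
#' (BLAST hit-table semantics).
#'
#' @param consensus Consensus element (character, DNAString(Set), or list
#'   with `id`/`sequence`).
#' @param genome Genome (named character or DNAStringSet).
#' @param word_size Seed word size (>= 8).
#' @param min_report Minimum percent identity reported (default 80, leaving
#'   headroom below the 84\% filter).
#' @param min_seeds Minimum co-diagonal seeds to trigger extension.
#' @return data.frame(contig, start, end, strand, matches, aligned_columns,
#'   identity, score); 0-based half-open coordinates on the forward strand.
#' @export
scan_genome <- function(consensus, genome, word_size = 11L, min_report = 80,
                        min_seeds = 2L) {
  if (is.list(consensus) && !is.null(consensus$sequence)) {
    consensus <- consensus$sequence
  }
  consensus <- .as_seq_chr(consensus)[[1]]
  if (word_size < 8) stop("word_size must be >= 8")
  if (nchar(consensus) < word_size) {
    stop("consensus shorter than word size")
  }
  genome <- .as_dss(genome)
  if (length(genome) == 0 || all(Biostrings::width(genome) == 0)) {
    stop("genome is empty")
  }
  hits <- .find_similar_regions(consensus, genome, word_size = word_size,
                                min_seeds = min_seeds)
  hits <- hits[hits$identity >= min_report, , drop = FALSE]
  hits <- .resolve_overlaps(hits)
  hits$coverage <- NULL
  rownames(hits) <- NULL
  hits
}

#' Apply the length and identity filters to scan hits
#'
#' Keeps hits whose aligned length is within `length_tol` of the consensus
#' length and whose identity reaches `min_identity`. All hits are retained
#' with a `filter_status` so that filter counts are auditable
#' (kept + dropped = total). The identity threshold is inclusive by default
#' (`strict_gt = TRUE` switches to a strict > comparison).
#'
#' @param hits data.frame from [scan_genome()].
#' @param element_length Reference element length (default 225).
#' @param length_tol Allowed deviation in bp (default 10).
#' @param min_identity Identity threshold in percent (default 84).
#' @param strict_gt Require identity strictly greater than the threshold.
#' @return The hits with `locus_id`, `length` and `filter_status` columns.
#' @export
filter_hits <- function(hits, element_length = 225L, length_tol = 10L,
                        min_identity = 84, strict_gt = FALSE) {
  hits$length <- hits$aligned_columns
  pass_len <- hits$length >= element_length - length_tol &
    hits$length <= element_length + length_tol
  pass_id <- if (strict_gt) hits$identity > min_identity else
    hits$identity >= min_identity
  hits$filter_status <- ifelse(!pass_len, "dropped_length",
                               ifelse(!pass_id, "dropped_identity", "kept"))
  hits$locus_id <- sprintf("ERE1_%05d", seq_len(nrow(hits)))
  hits
}

#' Lift hits from contig to chromosome coordinates
#'
#' Placed contigs get offset-shifted (and, for reverse-oriented contigs,
#' reflected and strand-flipped) coordinates; hits on contigs absent from
#' the placement table are marked `dropped_unplaced`.
#'
#' @param hits data.frame with `contig`, `start`, `end`, `strand` (0-based
#'   half-open).
#' @param placement data.frame from [read_placement()]; reverse-oriented
#'   rows need a `length` column (or supply `contig_lengths`).
#' @param contig_lengths Optional named vector of contig lengths.
#' @return The hits with `chrom` plus lifted `start`/`end`/`strand`;
#'   original contig coordinates kept as `contig_start`/`contig_end`.
#' @export
lift_to_genome <- function(hits, placement, contig_lengths = NULL) {
  hits$contig_start <- hits$start
  hits$contig_end <- hits$end
  hits$contig_strand <- hits$strand
  m <- match(hits$contig, placement$contig)
  placed <- !is.na(m)
  hits$chrom <- ifelse(placed, placement$chrom[m], NA_character_)
  if (is.null(hits$filter_status)) hits$filter_status <- "kept"
  hits$filter_status[!placed & hits$filter_status == "kept"] <-
    "dropped_unplaced"

  off <- placement$offset[m]
  orient <- placement$orientation[m]
  len <- placement$length[m]
  if (is.null(len)) len <- rep(NA_real_, length(m))
  if (!is.null(contig_lengths)) {
    len <- ifelse(is.na(len), contig_lengths[hits$contig], len)
  }
  rev_rows <- placed & orient == "-"
  if (any(rev_rows & is.na(len))) {
    stop("contig length required to lift reverse-oriented contig(s): ",
         paste(unique(hits$contig[rev_rows & is.na(len)]), collapse = ", "))
  }
  new_start <- ifelse(rev_rows, off + len - hits$end, off + hits$start)
  new_end <- ifelse(rev_rows, off + len - hits$start, off + hits$end)
  flip <- function(s) ifelse(s == "+", "-", "+")
  hits$start <- ifelse(placed, new_start, hits$start)
  hits$end <- ifelse(placed, new_end, hits$end)
  hits$strand <- ifelse(rev_rows, flip(hits$strand), hits$strand)
  hits
}

#' Drop loci embedded in other repeats
#'
#' A locus overlapping any non-self repeat interval by at least
#' `min_overlap` bp (default 1: any overlap counts as an interruption) is
#' marked `dropped_repeat`.
#'
#' @param loci Locus data.frame with `chrom`, `start`, `end`,
#'   `filter_status`.
#' @param repeats data.frame(chrom, start, end, name), 0-based half-open;
#'   may contain nested intervals.
#' @param min_overlap Minimum overlap in bp to trigger the drop.
#' @param self_names Repeat names to ignore (annotations of the scanned
#'   element family itself).
#' @return The loci with updated `filter_status`.
#' @export
exclude_repeat_embedded <- function(loci, repeats, min_overlap = 1L,
                                    self_names = "ERE1") {
  if (is.null(loci$filter_status)) loci$filter_status <- "kept"
  if (nrow(repeats) == 0 || nrow(loci) == 0) return(loci)
  repeats <- repeats[!(repeats$name %in% self_names), , drop = FALSE]
  if (nrow(repeats) == 0) return(loci)
  active <- which(loci$filter_status == "kept")
  if (length(active) == 0) return(loci)
  q <- GenomicRanges::GRanges(loci$chrom[active],
                              IRanges::IRanges(loci$start[active] + 1L,
                                               loci$end[active]))
  s <- GenomicRanges::GRanges(repeats$chrom,
                              IRanges::IRanges(repeats$start + 1L,
                                               repeats$end))
  ov <- GenomicRanges::findOverlaps(q, s, minoverlap = min_overlap)
  hit <- unique(S4Vectors::queryHits(ov))
  loci$filter_status[active[hit]] <- "dropped_repeat"
  loci
}

#' Assign the identity class of a locus
#'
#' Eight 2-point bins over 84-100\% identity: [84,86), [86,88), ...,
#' [96,98) and the closed top bin [98,100]. Labels are "84-86" ... "98-100".
#'
#' @param identity Numeric vector of percent identities (>= 84).
#' @return Character vector of class labels.
#' @export
assign_identity_class <- function(identity) {
  if (any(identity < 84 | identity > 100)) {
    stop("identity outside [84, 100]: such loci should have been filtered")
  }
  idx <- pmin(floor((identity - 84) / 2), 7)
  lower <- 84 + 2 * idx
  upper <- ifelse(idx == 7, 100, lower + 2)
  paste0(lower, "-", upper)
}

#' Identity-class labels in increasing order
#' @return Character vector of the eight class labels.
#' @export
identity_class_levels <- function() {
  lower <- seq(84, 98, by = 2)
  paste0(lower, "-", c(head(lower, -1) + 2, 100))
}

#' Run the full discovery stage
#'
#' Scan, filter by length/identity, lift to chromosome coordinates (if a
#' placement table is given), drop repeat-embedded loci, and label identity
#' classes of kept loci.
#'
#' @inheritParams scan_genome
#' @inheritParams filter_hits
#' @param repeats Optional repeat annotation (see
#'   [exclude_repeat_embedded()]).
#' @param placement Optional placement table (see [lift_to_genome()]).
#' @param min_repeat_overlap Minimum repeat overlap in bp.
#' @return Locus table with `filter_status` and, for kept loci,
#'   `identity_class`.
#' @export
discover_loci <- function(consensus, genome, repeats = NULL,
                          placement = NULL, word_size = 11L,
                          min_report = 80, element_length = NULL,
                          length_tol = 10L, min_identity = 84,
                          strict_gt = FALSE, min_repeat_overlap = 1L) {
  if (is.list(consensus) && !is.null(consensus$sequence)) {
    consensus <- consensus$sequence
  }
  consensus <- .as_seq_chr(consensus)[[1]]
  if (is.null(element_length)) element_length <- nchar(consensus)
  hits <- scan_genome(consensus, genome, word_size = word_size,
                      min_report = min_report)
  loci <- filter_hits(hits, element_length = element_length,
                      length_tol = length_tol, min_identity = min_identity,
                      strict_gt = strict_gt)
  if (!is.null(placement)) {
    loci <- lift_to_genome(loci, placement)
  } else {
    loci$chrom <- loci$contig
  }
  if (!is.null(repeats)) {
    loci <- exclude_repeat_embedded(loci, repeats,
                                    min_overlap = min_repeat_overlap)
  }
  loci$identity_class <- NA_character_
  kept <- loci$filter_status == "kept"
  loci$identity_class[kept] <- assign_identity_class(loci$identity[kept])
  loci
}
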