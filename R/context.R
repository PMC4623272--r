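# Position of loci relative to gene models, and annotation of insertion
# alleles under the target-primed reverse transcription (TPRT) model:
# target-site duplication detection and integration microhomology.

.parse_exons <- function(gene) {
  starts <- as.integer(strsplit(gene$exon_starts, ",")[[1]])
  ends <- as.integer(strsplit(gene$exon_ends, ",")[[1]])
  if (length(starts) != length(ends) || any(ends <= starts)) {
    stop("malformed exon list for gene ", gene$gene_id)
  }
  data.frame(start = starts, end = ends)
}

.gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
}

#' Classify loci relative to gene models
#'
#' Category precedence: overlap with any exon -> `exon`; full containment
#' in an intron of any gene -> `intron`; otherwise the locus is binned by
#' the gap distance (bases separating the locus from the strand-aware 5'
#' end, i.e. the transcription start site, of the nearest gene; 0 when the
#' locus covers it): `le_1kb` (<= 1 kb),
#' `kb_1_5` (1-5 kb), `kb_5_10` (5-10 kb), `gt_10kb` (> 10 kb). A
#' chromosome without genes yields `gt_10kb` with no nearest gene. Distance
#' ties are broken by the lexicographically smaller gene id.
#'
#' @param loci Locus data.frame (`locus_id`, `chrom`, `start`, `end`;
#'   0-based half-open).
#' @param genes Gene models in refGene-style layout (see
#'   [read_gene_models()]).
#' @return data.frame(locus_id, category, nearest_gene_id, distance_to_5p).
#' @export
classify_relative_to_genes <- function(loci, genes) {
  n <- nrow(loci)
  out <- data.frame(locus_id = loci$locus_id,
                    category = rep("gt_10kb", n),
                    nearest_gene_id = NA_character_,
                    distance_to_5p = NA_real_)
  if (nrow(genes) == 0 || n == 0) return(out)

  exon_list <- lapply(seq_len(nrow(genes)), function(i)
    .parse_exons(genes[i, ]))
  exon_gr <- GenomicRanges::GRanges(
    rep(genes$chrom, vapply(exon_list, nrow, 1L)),
    IRanges::IRanges(
      unlist(lapply(exon_list, `[[`, "start")) + 1L,
      unlist(lapply(exon_list, `[[`, "end"))))
  intron_rows <- lapply(seq_len(nrow(genes)), function(i) {
    ex <- exon_list[[i]][order(exon_list[[i]]$start), , drop = FALSE]
    if (nrow(ex) < 2) return(NULL)
    data.frame(chrom = genes$chrom[i],
               start = ex$end[-nrow(ex)], end = ex$start[-1])
  })
  intron_rows <- do.call(rbind, intron_rows)
  intron_gr <- if (!is.null(intron_rows) && nrow(intron_rows) > 0)
    GenomicRanges::GRanges(intron_rows$chrom,
                           IRanges::IRanges(intron_rows$start + 1L,
                                            intron_rows$end))
  else GenomicRanges::GRanges()

  loci_gr <- GenomicRanges::GRanges(loci$chrom,
                                    IRanges::IRanges(loci$start + 1L,
                                                     loci$end))
  in_exon <- unique(S4Vectors::queryHits(suppressWarnings(
    GenomicRanges::findOverlaps(loci_gr, exon_gr))))
  in_intron <- unique(S4Vectors::queryHits(suppressWarnings(
    GenomicRanges::findOverlaps(loci_gr, intron_gr, type = "within"))))
  out$category[in_intron] <- "intron"
  out$category[in_exon] <- "exon"    # exon takes precedence

  tss <- .gene_tss(genes)
  rest <- setdiff(seq_len(n), union(in_exon, in_intron))
  for (i in rest) {
    same <- which(genes$chrom == loci$chrom[i])
    if (length(same) == 0) next   # gt_10kb, nearest gene absent
    # gap distance (bases separating the locus from the TSS; 0 on overlap)
    d <- ifelse(loci$end[i] <= tss[same], tss[same] - loci$end[i],
                ifelse(loci$start[i] > tss[same],
                       loci$start[i] - tss[same] - 1L, 0L))
    ord <- order(d, genes$gene_id[same])
    best <- same[ord[1]]
    dist <- d[ord[1]]
    out$nearest_gene_id[i] <- genes$gene_id[best]
    out$distance_to_5p[i] <- dist
    out$category[i] <- if (dist <= 1000) "le_1kb" else
      if (dist <= 5000) "kb_1_5" else
        if (dist <= 10000) "kb_5_10" else "gt_10kb"
  }
  out
}

#' Summarize position classes
#'
#' @param classes data.frame from [classify_relative_to_genes()].
#' @return data.frame(category, n, fraction); fractions sum to 1.
#' @export
summarize_position_classes <- function(classes) {
  if (nrow(classes) == 0) stop("no loci to summarize")
  levels <- c("exon", "intron", "le_1kb", "kb_1_5", "kb_5_10", "gt_10kb")
  counts <- table(factor(classes$category, levels = levels))
  data.frame(category = levels, n = as.integer(counts),
             fraction = as.numeric(counts) / nrow(classes))
}

#' Detect the target-site duplication of an insertion allele
#'
#' Decomposes a filled/empty allele pair as `filled = L r X r R`,
#' `empty = L r R`, where `X` is the inserted element and `r` the
#' target-site duplication: among all decompositions consistent with the
#' two sequences, the one with the longest exact repeat `r` is reported
#' (ties broken by the leftmost nick position). Identical alleles yield an
#' empty element interval and TSD length 0. Length conservation
#' `len(filled) - len(empty) = element + TSD` holds by construction and is
#' checked against the supplied element.
#'
#' @param filled_allele,empty_allele Character strings.
#' @param element Element sequence (character) or its length; used to
#'   validate the recovered inserted segment.
#' @param max_tsd Maximum repeat length searched (bp).
#' @param min_anchor Minimum shared flank (bp) required between the two
#'   alleles.
#' @return List (class `tsd_report`): `tsd_length`, `tsd_sequence`,
#'   `nick_position` (0-based offset of the gap in the empty allele),
#'   `element_start`, `element_end` (0-based half-open in the filled
#'   allele), `inserted_length`, `element_matches` (logical), `empty_seq`.
#' @export
detect_tsd <- function(filled_allele, empty_allele, element, max_tsd = 30L,
                       min_anchor = 10L) {
  f <- .as_seq_chr(filled_allele)[[1]]
  e <- .as_seq_chr(empty_allele)[[1]]
  D <- nchar(f) - nchar(e)
  if (D < 0) stop("filled allele shorter than empty allele")
  elt_len <- if (is.character(element)) nchar(element) else as.integer(element)
  if (D == 0) {
    if (f != e) stop("alleles of equal length but different sequence")
    return(structure(list(tsd_length = 0L, tsd_sequence = "",
                          nick_position = NA_integer_,
                          element_start = NA_integer_,
                          element_end = NA_integer_,
                          inserted_length = 0L, element_matches = FALSE,
                          empty_seq = e), class = "tsd_report"))
  }
  p <- .lcp_len(f, e)
  s <- .lcs_len(f, e)
  if (p < min_anchor || s < min_anchor) {
    stop("alleles share less than ", min_anchor, " bp of identical flank")
  }
  lo <- max(0L, nchar(e) - s)   # candidate nick positions (0-based)
  hi <- p
  if (lo > hi) stop("no consistent gap placement for the allele pair")
  fv <- strsplit(f, "")[[1]]
  best_t <- -1L
  best_i <- NA_integer_
  for (i in lo:hi) {
    # longest j <= min(i, max_tsd, D) with
    # filled[i-j+1 .. i] == filled[i+D-j+1 .. i+D] (1-based)
    jmax <- min(i, max_tsd, D)
    t <- 0L
    while (t < jmax && fv[i - t] == fv[i + D - t]) t <- t + 1L
    if (t > best_t) {
      best_t <- t
      best_i <- i
    }
  }
  t <- best_t
  i <- best_i
  ins_len <- D - t
  elt_seq <- substr(f, i + 1L, i + ins_len)
  matches <- if (is.character(element)) {
    # substitution-tolerant comparison of the recovered inserted segment
    nchar(element) == ins_len &&
      sum(strsplit(element, "")[[1]] != strsplit(elt_seq, "")[[1]]) <=
        ceiling(0.2 * ins_len)
  } else {
    ins_len == elt_len
  }
  structure(list(
    tsd_length = t,
    tsd_sequence = if (t > 0) substr(f, i - t + 1L, i) else "",
    nick_position = i - t,   # offset of the duplicated target in the empty allele
    element_start = i, element_end = i + ins_len,
    inserted_length = ins_len,
    element_matches = matches,
    empty_seq = e
  ), class = "tsd_report")
}

#' Integration microhomology at the nick site
#'
#' Under TPRT, the genomic nick frees a 3'-OH whose strand presents a
#' single-stranded T-run (the minus strand of an A-run on the plus strand
#' starting at the left nick); the poly-A tail of the element RNA anneals
#' to it. This reports the longest suffix of the element's poly-A tail that
#' is complementary to the minus strand immediately 3' of the nick, i.e.
#' the length of the shared A-run between the element tail and the empty
#' allele at the nick.
#'
#' @param tsd_report A `tsd_report` from [detect_tsd()].
#' @param element Element sequence (character).
#' @param empty_allele Optional empty-allele sequence; defaults to the one
#'   stored in the report.
#' @return List: `length`, `sequence` (the T-run on the minus strand, e.g.
#'   "TTTTT" for length 5).
#' @export
find_integration_microhomology <- function(tsd_report, element,
                                           empty_allele = NULL) {
  e <- if (is.null(empty_allele)) tsd_report$empty_seq else
    .as_seq_chr(empty_allele)[[1]]
  elt <- .as_seq_chr(element)[[1]]
  if (is.na(tsd_report$nick_position)) {
    return(list(length = 0L, sequence = ""))
  }
  # poly-A tail length of the element
  ev <- rev(strsplit(elt, "")[[1]])
  tail_a <- 0L
  while (tail_a < length(ev) && ev[tail_a + 1L] == "A") tail_a <- tail_a + 1L
  # left nick = start of the target-site duplication in the empty allele
  left_nick <- tsd_report$nick_position
  after <- substr(e, left_nick + 1L, nchar(e))
  av <- strsplit(after, "")[[1]]
  run <- 0L
  while (run < length(av) && av[run + 1L] == "A") run <- run + 1L
  k <- min(tail_a, run)
  list(length = k, sequence = strrep("T", k))
}
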