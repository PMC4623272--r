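# Fixture builders and independent oracles used across the suite.

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Global identity (matches / alignment columns) via an independent
# Needleman-Wunsch alignment.
oracle_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 5, gapExtension = 2)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / cols
}

# Construct a filled/empty allele pair with a planted TSD whose maximal
# decomposition is provably unique: the flank base left of the duplicated
# target differs from the element's last base, and the element's first
# base differs from the right flank's first base (otherwise the repeat
# could extend by coincidence).
make_tsd_pair <- function(seed, tsd_len, elt_len = 60, flank = 120,
                          elt = NULL) {
  set.seed(seed)
  if (is.null(elt)) elt <- rand_seq(elt_len)
  elt_len <- nchar(elt)
  repeat {
    L <- rand_seq(flank)
    r <- if (tsd_len > 0) rand_seq(tsd_len) else ""
    R <- rand_seq(flank)
    e_last <- substr(elt, elt_len, elt_len)
    e_first <- substr(elt, 1, 1)
    ok <- substr(L, flank, flank) != e_last &&
      substr(R, 1, 1) != e_first &&
      (tsd_len == 0 || substr(r, tsd_len, tsd_len) != e_last)
    if (ok) break
  }
  list(filled = paste0(L, r, elt, r, R),
       empty = paste0(L, r, R),
       element = elt, tsd_len = tsd_len, tsd_seq = r,
       nick = nchar(L))  # 0-based offset of r in the empty allele
}

# Brute-force TSD oracle: enumerate every decomposition
# filled = L r X r R / empty = L r R by direct substring comparison,
# return the maximal repeat length (ties: leftmost nick).
oracle_tsd <- function(filled, empty, max_tsd = 30) {
  D <- nchar(filled) - nchar(empty)
  best <- NULL
  for (i in 0:nchar(empty)) {       # gap opens after i bases of the empty
    pre_ok <- i == 0 ||
      substr(filled, 1, i) == substr(empty, 1, i)
    suf_ok <- substr(filled, i + D + 1, nchar(filled)) ==
      substr(empty, i + 1, nchar(empty))
    if (!pre_ok || !suf_ok) next
    for (t in min(i, max_tsd, D):0) {
      r1 <- substr(filled, i - t + 1, i)
      r2 <- substr(filled, i + D - t + 1, i + D)
      if (t == 0 || r1 == r2) {
        cand <- list(nick = i - t, tsd_len = t, gap_open = i)
        if (is.null(best) || cand$tsd_len > best$tsd_len) best <- cand
        break
      }
    }
  }
  best
}

# Tiny planted-locus genome used by several discovery/polymorph tests.
make_planted_genome <- function(seed, n_loci = 3, chrom_len = 30000,
                                identities = NULL, tsd = NULL,
                                strand = NULL, consensus = NULL) {
  set.seed(seed)
  if (is.null(consensus)) consensus <- generate_consensus(seed, 225)
  if (is.null(identities)) identities <- rep(100, n_loci)
  if (is.null(tsd)) tsd <- rep(10L, n_loci)
  if (is.null(strand)) strand <- rep("+", n_loci)
  bg <- c(chrA = rand_seq(chrom_len))
  pos <- floor(seq(4000, chrom_len - 4000, length.out = n_loci))
  specs <- data.frame(
    locus_id = sprintf("L%02d", seq_len(n_loci)), chrom = "chrA",
    insert_pos = pos,
    element_seq = vapply(seq_len(n_loci), function(i)
      diverge_element(consensus, identities[i], seed = seed * 100 + i),
      character(1)),
    tsd_len = tsd, strand = strand)
  pl <- plant_insertions(bg, specs)
  pl$consensus <- consensus
  pl
}

# Empty-allele read spanning the insertion point of a planted locus.
make_empty_read <- function(genome, truth_row, left_anchor = 300,
                            right_anchor = 300) {
  g <- as.character(genome)
  chrom <- truth_row$chrom
  s <- truth_row$start; e <- truth_row$end; t <- truth_row$tsd_len
  left <- substr(g[[chrom]], s - left_anchor + 1, s)
  right <- substr(g[[chrom]], e + t + 1, e + t + right_anchor)
  paste0(left, right)
}
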