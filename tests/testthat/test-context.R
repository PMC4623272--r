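# Gene-context classification and TPRT annotation (target-site duplication,
# integration microhomology).

two_exon_gene <- function(id, chrom, strand, tx_start, tx_end,
                          exon1_end, exon2_start, source = "validated") {
  data.frame(gene_id = id, chrom = chrom, strand = strand,
             tx_start = tx_start, tx_end = tx_end,
             exon_starts = paste(c(tx_start, exon2_start), collapse = ","),
             exon_ends = paste(c(exon1_end, tx_end), collapse = ","),
             source = source)
}

test_that("intron containment, exon overlap and distance bins", {
  genes <- two_exon_gene("G1", "chr1", "+", 10000, 20000, 11000, 19000)
  # fully inside the single intron
  loci <- data.frame(locus_id = "a", chrom = "chr1",
                     start = 15000, end = 15225)
  expect_equal(classify_relative_to_genes(loci, genes)$category, "intron")
  # overlapping an exon wins over intron
  le <- data.frame(locus_id = "b", chrom = "chr1",
                   start = 10900, end = 11125)
  expect_equal(classify_relative_to_genes(le, genes)$category, "exon")
  # 800 bp upstream of a + strand TSS
  up <- data.frame(locus_id = "c", chrom = "chr1", start = 8975, end = 9200)
  res <- classify_relative_to_genes(up, genes)
  expect_equal(res$category, "le_1kb")
  expect_equal(res$distance_to_5p, 800)
  # bins at increasing distance
  far <- data.frame(locus_id = c("d", "e"), chrom = "chr1",
                    start = c(6800, 2000), end = c(7025, 2225))
  cats <- classify_relative_to_genes(far, genes)$category
  expect_equal(cats, c("kb_1_5", "kb_5_10"))
})

test_that("minus-strand genes measure distance from their 3' coordinate end", {
  genes <- two_exon_gene("G1", "chr1", "-", 10000, 20000, 11000, 19000)
  # 5' end of a minus-strand gene is tx_end - 1 = 19999; 500 bases separate
  # it from a locus starting at 20500
  right <- data.frame(locus_id = "a", chrom = "chr1",
                      start = 20500, end = 20725)
  res <- classify_relative_to_genes(right, genes)
  expect_equal(res$category, "le_1kb")
  expect_equal(res$distance_to_5p, 500)
})

test_that("distance ties go to the lexicographically smaller gene id", {
  g1 <- two_exon_gene("G2", "chr1", "+", 23225, 30000, 24000, 29000)
  g2 <- two_exon_gene("G1", "chr1", "-", 10000, 17000, 11000, 16000)
  genes <- rbind(g1, g2)
  # locus [20000, 20225): gap of 3000 to G2's TSS (23225) and to G1's TSS
  # (16999)
  locus <- data.frame(locus_id = "t", chrom = "chr1",
                      start = 20000, end = 20225)
  res <- classify_relative_to_genes(locus, genes)
  expect_equal(res$category, "kb_1_5")
  expect_equal(res$nearest_gene_id, "G1")
})

test_that("chromosomes without genes default to the far bin", {
  genes <- two_exon_gene("G1", "chr1", "+", 0, 5000, 1000, 4000)
  locus <- data.frame(locus_id = "a", chrom = "chr9",
                      start = 100, end = 325)
  res <- classify_relative_to_genes(locus, genes)
  expect_equal(res$category, "gt_10kb")
  expect_true(is.na(res$nearest_gene_id))
})

test_that("classification is invariant under coordinate translation", {
  set.seed(61)
  genes <- rbind(
    two_exon_gene("G1", "chr1", "+", 10000, 20000, 11000, 19000),
    two_exon_gene("G2", "chr1", "-", 40000, 52000, 41000, 51000))
  loci <- data.frame(locus_id = sprintf("l%02d", 1:20), chrom = "chr1",
                     start = sort(sample.int(60000, 20)))
  loci$end <- loci$start + 225
  base <- classify_relative_to_genes(loci, genes)
  shift <- 5000
  genes2 <- genes
  genes2$tx_start <- genes2$tx_start + shift
  genes2$tx_end <- genes2$tx_end + shift
  genes2$exon_starts <- vapply(strsplit(genes$exon_starts, ","), function(x)
    paste(as.integer(x) + shift, collapse = ","), character(1))
  genes2$exon_ends <- vapply(strsplit(genes$exon_ends, ","), function(x)
    paste(as.integer(x) + shift, collapse = ","), character(1))
  loci2 <- loci
  loci2$start <- loci2$start + shift
  loci2$end <- loci2$end + shift
  moved <- classify_relative_to_genes(loci2, genes2)
  expect_equal(base$category, moved$category)
  expect_equal(base$distance_to_5p, moved$distance_to_5p)
})

test_that("position-class summary conserves counts and fractions", {
  classes <- data.frame(locus_id = letters[1:10],
                        category = rep("intron", 10))
  s <- summarize_position_classes(classes)
  expect_equal(s$fraction[s$category == "intron"], 1)
  expect_equal(sum(s$n), 10)
  expect_equal(sum(s$fraction), 1)
  expect_error(summarize_position_classes(classes[0, ]), "no loci")
})

test_that("pipeline classification agrees with a brute-force oracle", {
  cfg <- simulation_config(seed = 62, n_loci = 40, genome_length = 450000,
                           n_het_loci = 0, n_repeat_embedded = 0,
                           n_duplicated = 0)
  truth <- simulate_insertion_history(cfg)[1:40, ]
  set.seed(62)
  truth$chrom <- "chr1"
  truth$start <- sort(sample(seq(5000, 440000, by = 11000))) +
    sample(-400:400, 40, replace = TRUE)
  truth$end <- truth$start + 225
  genes <- simulate_gene_models(truth, cfg)
  got <- classify_relative_to_genes(truth, genes)
  # independent O(n*m) reimplementation of the definition
  oracle <- vapply(seq_len(nrow(truth)), function(i) {
    s <- truth$start[i]; e <- truth$end[i]
    cat_i <- NA_character_
    in_exon <- FALSE; in_intron <- FALSE
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != truth$chrom[i]) next
      ex_s <- as.integer(strsplit(genes$exon_starts[j], ",")[[1]])
      ex_e <- as.integer(strsplit(genes$exon_ends[j], ",")[[1]])
      if (any(s < ex_e & e > ex_s)) in_exon <- TRUE
      if (length(ex_s) > 1) {
        for (k in seq_len(length(ex_s) - 1)) {
          if (s >= ex_e[k] && e <= ex_s[k + 1]) in_intron <- TRUE
        }
      }
    }
    if (in_exon) return("exon")
    if (in_intron) return("intron")
    tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
    d <- ifelse(e <= tss, tss - e, ifelse(s > tss, s - tss - 1L, 0L))
    d <- d[genes$chrom == truth$chrom[i]]
    if (length(d) == 0) return("gt_10kb")
    dm <- min(d)
    if (dm <= 1000) "le_1kb" else if (dm <= 5000) "kb_1_5"
    else if (dm <= 10000) "kb_5_10" else "gt_10kb"
  }, character(1))
  expect_equal(got$category, oracle)
  expect_equal(summarize_position_classes(got)$n,
               summarize_position_classes(
                 data.frame(locus_id = truth$locus_id,
                            category = oracle))$n)
})

test_that("TSD detection recovers planted repeats of every length", {
  for (t in 0:20) {
    fx <- make_tsd_pair(seed = 100 + t, tsd_len = t)
    rep <- detect_tsd(fx$filled, fx$empty, fx$element)
    expect_equal(rep$tsd_length, t)
    expect_equal(rep$tsd_sequence, fx$tsd_seq)
    expect_equal(rep$nick_position, fx$nick)
    expect_equal(rep$element_start, fx$nick + t)
    expect_equal(rep$element_end, fx$nick + t + nchar(fx$element))
    expect_true(rep$element_matches)
    # length conservation on every report
    expect_equal(nchar(fx$filled) - nchar(fx$empty),
                 rep$inserted_length + rep$tsd_length)
  }
})

test_that("TSD detection matches the exhaustive decomposition oracle", {
  set.seed(63)
  for (k in 1:100) {
    t <- sample(0:20, 1)
    fx <- make_tsd_pair(seed = 2000 + k, tsd_len = t,
                        elt_len = sample(40:80, 1),
                        flank = sample(80:150, 1))
    rep <- detect_tsd(fx$filled, fx$empty, fx$element)
    orc <- oracle_tsd(fx$filled, fx$empty)
    expect_equal(rep$tsd_length, orc$tsd_len)
    expect_equal(rep$nick_position, orc$nick)
    expect_equal(nchar(fx$filled) - nchar(fx$empty),
                 rep$inserted_length + rep$tsd_length)
  }
})

test_that("a 14 bp TSD pair mirroring the myostatin geometry is exact", {
  fx <- make_tsd_pair(seed = 7, tsd_len = 14, elt_len = 225, flank = 200)
  rep <- detect_tsd(fx$filled, fx$empty, fx$element)
  expect_equal(rep$tsd_length, 14)
  expect_equal(rep$inserted_length, 225)
  expect_identical(rep$tsd_sequence, fx$tsd_seq)
})

test_that("identical alleles signal no insertion", {
  s <- rand_seq(300, seed = 64)
  rep <- detect_tsd(s, s, 225)
  expect_equal(rep$tsd_length, 0)
  expect_equal(rep$inserted_length, 0)
  expect_true(is.na(rep$element_start))
})

test_that("microhomology reports the shared A-run at the nick", {
  set.seed(65)
  for (k in 0:5) {
    # element ends in a poly-A tail of >= k; the empty allele continues
    # with exactly k A's at the left nick
    elt <- paste0(rand_seq(54), strrep("A", 6))
    repeat {
      L <- rand_seq(100)
      post <- paste0(strrep("A", k), "C", rand_seq(99 - k))
      r <- paste0(substr(post, 1, 10))
      # target-site duplication = first 10 bases after the nick
      ok <- substr(L, 100, 100) != "A" && substr(r, 10, 10) != "A"
      if (k < 10 && ok) break
    }
    filled <- paste0(L, r, elt, r, substr(post, 11, nchar(post)))
    empty <- paste0(L, post)
    rep <- detect_tsd(filled, empty, elt)
    mh <- find_integration_microhomology(rep, elt)
    expect_equal(mh$length, k)
    expect_equal(mh$sequence, strrep("T", k))
  }
})
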