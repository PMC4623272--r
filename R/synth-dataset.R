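# End-to-end synthetic dataset assembly: a genome with planted SINE copies,
# matched annotations (repeats, genes, placement), trace reads and a
# population genotype panel, plus the complete ground-truth table.

#' Simulate a gene-model annotation around planted loci
#'
#' Draws a position category per locus (intronic, or a distance bin from the
#' nearest transcription start site) and constructs a two-exon gene model
#' realising it: intronic loci get a gene whose single intron contains the
#' element; distance-bin loci get a gene whose strand-aware 5' end lies at a
#' distance drawn inside the bin, on a random side of the locus. Loci in the
#' ">10 kb" category receive no gene of their own. Because neighbouring
#' genes can end up closer than a locus' own gene, the realised category is
#' defined by [classify_relative_to_genes()]; the intent is only a sampling
#' device.
#'
#' @param truth Truth table with `locus_id`, `chrom`, `start`, `end`.
#' @param config A `sim_config`.
#' @param category_probs Named sampling probabilities for categories
#'   `intron`, `le_1kb`, `kb_1_5`, `kb_5_10`, `gt_10kb`.
#' @return data.frame in refGene-style layout (`gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `exon_starts`, `exon_ends`, `source`), 0-based
#'   half-open.
#' @export
simulate_gene_models <- function(truth, config,
                                 category_probs = c(intron = 0.454,
                                                    le_1kb = 0.02,
                                                    kb_1_5 = 0.10,
                                                    kb_5_10 = 0.12,
                                                    gt_10kb = 0.306)) {
  cfg <- validate_sim_config(config)
  set.seed(.stage_seed(cfg$seed, "genes"))
  category_probs <- category_probs / sum(category_probs)
  cats <- sample(names(category_probs), nrow(truth), replace = TRUE,
                 prob = category_probs)
  rows <- list()
  gid <- 0L
  add_gene <- function(chrom, strand, tx_start, tx_end, exons) {
    gid <<- gid + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = sprintf("G%04d", gid), chrom = chrom, strand = strand,
      tx_start = tx_start, tx_end = tx_end,
      exon_starts = paste(vapply(exons, `[[`, 0, 1), collapse = ","),
      exon_ends = paste(vapply(exons, `[[`, 0, 2), collapse = ","),
      source = sample(c("validated", "putative"), 1)
    )
  }
  for (i in seq_len(nrow(truth))) {
    cat_i <- cats[i]
    s <- truth$start[i]; e <- truth$end[i]; chrom <- truth$chrom[i]
    if (cat_i == "intron") {
      tx_start <- s - 1500L; tx_end <- e + 1500L
      add_gene(chrom, sample(c("+", "-"), 1), tx_start, tx_end,
               list(c(tx_start, tx_start + 300L), c(tx_end - 300L, tx_end)))
    } else if (cat_i != "gt_10kb") {
      d <- switch(cat_i,
                  le_1kb = floor(runif(1, 200, 900)),
                  kb_1_5 = floor(runif(1, 1500, 4500)),
                  kb_5_10 = floor(runif(1, 5500, 9000)))
      glen <- 2000L
      if (runif(1) < 0.5) {
        # gene to the right, + strand, TSS facing the locus
        tx_start <- e + d; tx_end <- tx_start + glen
        add_gene(chrom, "+", tx_start, tx_end,
                 list(c(tx_start, tx_start + 300L), c(tx_end - 300L, tx_end)))
      } else {
        # gene to the left, - strand, TSS (tx_end - 1) facing the locus
        tss <- s - d
        tx_end <- tss + 1L; tx_start <- tx_end - glen
        add_gene(chrom, "-", tx_start, tx_end,
                 list(c(tx_start, tx_start + 300L), c(tx_end - 300L, tx_end)))
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), tx_start = integer(),
                      tx_end = integer(), exon_starts = character(),
                      exon_ends = character(), source = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a complete ERE1-style dataset with ground truth
#'
#' Assembles every input the analysis pipeline consumes: a multi-contig
#' genome carrying `n_loci` planted element copies diverged to clock-drawn
#' identities and flanked by target-site duplications; a contig placement
#' table; a repeat annotation in which `n_repeat_embedded` loci are nested
#' inside a simulated older repeat (plus decoy intervals away from loci);
#' `n_duplicated` loci whose whole window is copied elsewhere in the genome
#' (segmental-duplication analogues); gene models; trace reads for a
#' reference individual heterozygous at `n_het_loci` loci; and a
#' multi-species genotype panel. The returned truth table records planted
#' coordinates, identities, TSDs and all flags.
#'
#' @param config A `sim_config`.
#' @return A list with elements `config`, `consensus`, `contigs`,
#'   `placement`, `genome` (chromosome-named copy of the contigs), `truth`,
#'   `repeats`, `genes`, `traces`, `genotypes`.
#' @export
simulate_ere1_dataset <- function(config = simulation_config()) {
  cfg <- validate_sim_config(config)
  history <- simulate_insertion_history(cfg)
  n <- nrow(history)

  # designate disjoint special locus sets
  set.seed(.stage_seed(cfg$seed, "plant"))
  shuffled <- sample(history$locus_id)
  embedded_ids <- shuffled[seq_len(cfg$n_repeat_embedded)]
  dup_ids <- shuffled[cfg$n_repeat_embedded + seq_len(cfg$n_duplicated)]
  het_ids <- shuffled[cfg$n_repeat_embedded + cfg$n_duplicated +
                        seq_len(cfg$n_het_loci)]
  # duplicated loci are also made heterozygous so that the uniqueness veto
  # (not the absence of evidence) is what excludes them from the calls
  het_like <- c(het_ids, dup_ids)
  history$ref_genotype <- ifelse(history$locus_id %in% het_like, "+/-", "+/+")
  need_freq <- history$locus_id %in% het_like & !history$polymorphic
  history$polymorphic <- history$polymorphic | history$locus_id %in% het_like
  history$allele_freq_plus[need_freq] <- runif(sum(need_freq), 0.05, 0.95)

  # diverged element per locus
  consensus <- generate_consensus(cfg$seed, cfg$consensus_length,
                                  cfg$tail_length)
  elements <- vapply(seq_len(n), function(i) {
    diverge_element(consensus, history$identity[i], seed = cfg$seed + i)
  }, character(1))

  # background contigs and insertion positions
  set.seed(.stage_seed(cfg$seed, "background"))
  clen <- floor(cfg$genome_length / cfg$n_contigs)
  contigs <- setNames(
    vapply(seq_len(cfg$n_contigs), function(i) .random_dna(clen),
           character(1)),
    paste0("ctg", seq_len(cfg$n_contigs)))
  per_contig <- diff(floor(seq(0, n, length.out = cfg$n_contigs + 1)))
  margin <- cfg$flank_length + 500L
  specs <- list()
  idx <- 0L
  for (ci in seq_len(cfg$n_contigs)) {
    k <- per_contig[ci]
    if (k == 0) next
    slots <- floor(seq(margin, clen - margin, length.out = k))
    jitter <- floor(runif(k, -400, 400))
    pos <- pmin(clen - margin, pmax(margin, slots + jitter))
    specs[[ci]] <- data.frame(
      locus_id = history$locus_id[idx + seq_len(k)],
      chrom = names(contigs)[ci],
      insert_pos = sort(pos),
      element_seq = elements[idx + seq_len(k)],
      tsd_len = sample(seq(cfg$tsd_length_range[1], cfg$tsd_length_range[2]),
                       k, replace = TRUE),
      strand = sample(c("+", "-"), k, replace = TRUE),
      inside_repeat = history$locus_id[idx + seq_len(k)] %in% embedded_ids
    )
    idx <- idx + k
  }
  specs <- do.call(rbind, specs)
  planted <- plant_insertions(contigs, specs)
  genome_chr <- .as_seq_chr(planted$genome)
  truth <- merge(planted$truth, history, by = "locus_id", sort = FALSE)
  truth$multicopy <- truth$locus_id %in% dup_ids
  truth$is_duplicate_copy <- FALSE

  # duplicate whole windows of the designated loci onto the last contig
  fl <- cfg$flank_length
  last <- names(genome_chr)[length(genome_chr)]
  dup_rows <- list()
  for (id in dup_ids) {
    r <- truth[truth$locus_id == id, ]
    src <- genome_chr[[r$chrom]]
    w0 <- r$start - fl
    w1 <- r$end + r$tsd_len + fl
    window <- substr(src, w0 + 1L, w1)
    spacer <- .random_dna(500L)
    base <- nchar(genome_chr[[last]]) + nchar(spacer)
    genome_chr[[last]] <- paste0(genome_chr[[last]], spacer, window)
    dup_rows[[length(dup_rows) + 1L]] <- within(r, {
      locus_id <- paste0(locus_id, "_dup")
      chrom <- last
      start <- base + fl
      end <- start + element_length
      ref_genotype <- "+/+"
      polymorphic <- FALSE
      is_duplicate_copy <- TRUE
    })
  }
  if (length(dup_rows)) truth <- rbind(truth, do.call(rbind, dup_rows))
  rownames(truth) <- NULL

  # repeat annotation: embedding repeats plus decoys between loci
  repeats <- planted$repeats
  if (cfg$n_decoy_repeats > 0) {
    ord <- truth[!truth$is_duplicate_copy, ]
    ord <- ord[order(ord$chrom, ord$start), ]
    gaps <- list()
    for (i in seq_len(nrow(ord) - 1L)) {
      if (ord$chrom[i] != ord$chrom[i + 1L]) next
      mid <- floor((ord$end[i] + ord$start[i + 1L]) / 2)
      if (mid - ord$end[i] > 2500 && ord$start[i + 1L] - mid > 2500) {
        gaps[[length(gaps) + 1L]] <- data.frame(
          chrom = ord$chrom[i], start = mid - 200L, end = mid + 200L,
          name = "SimLTR")
      }
    }
    if (length(gaps)) {
      gaps <- do.call(rbind, gaps)
      take <- seq_len(min(cfg$n_decoy_repeats, nrow(gaps)))
      repeats <- rbind(repeats, gaps[sample(nrow(gaps), length(take)), ])
    }
  }
  rownames(repeats) <- NULL

  # contig -> chromosome placement (identity layout; lift is exercised with
  # offsets and orientation flips in dedicated fixtures)
  chrom_names <- sub("^ctg", "chr", names(genome_chr))
  placement <- data.frame(
    contig = names(genome_chr), chrom = chrom_names, offset = 0L,
    orientation = "+", length = nchar(genome_chr)
  )
  truth$chrom <- sub("^ctg", "chr", truth$chrom)
  repeats$chrom <- sub("^ctg", "chr", repeats$chrom)
  genome <- setNames(genome_chr, chrom_names)

  genes <- simulate_gene_models(truth[!truth$is_duplicate_copy, ], cfg)
  traces <- simulate_traces(genome, truth, cfg)
  genotypes <- simulate_population_genotypes(
    truth[!truth$is_duplicate_copy, ], cfg)

  list(config = cfg, consensus = consensus,
       contigs = .as_dss(genome_chr), placement = placement,
       genome = .as_dss(genome), truth = truth, repeats = repeats,
       genes = genes, traces = traces, genotypes = genotypes)
}

#' Write a simulated dataset to disk
#'
#' Emits the standard plain-text formats the pipeline reads back: contig
#' FASTA, assembled chromosome FASTA (used by the trace stage, which works
#' in chromosome coordinates), placement TSV, truth TSV, repeats BED
#' (0-based half-open), gene models TSV, traces FASTA with `project=`
#' header tokens, genotype TSV and the species tree in Newick format.
#'
#' @param dataset Result of [simulate_ere1_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_simulation <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    chromosomes = file.path(dir, "chromosomes.fa"),
    consensus = file.path(dir, "consensus.fa"),
    placement = file.path(dir, "placement.tsv"),
    truth = file.path(dir, "truth.tsv"),
    repeats = file.path(dir, "repeats.bed"),
    genes = file.path(dir, "genes.tsv"),
    traces = file.path(dir, "traces.fa"),
    genotypes = file.path(dir, "genotypes.tsv"),
    tree = file.path(dir, "tree.nwk")
  )
  Biostrings::writeXStringSet(dataset$contigs, paths["genome"])
  Biostrings::writeXStringSet(dataset$genome, paths["chromosomes"])
  cons <- Biostrings::DNAStringSet(setNames(dataset$consensus, "consensus"))
  Biostrings::writeXStringSet(cons, paths["consensus"])
  write.table(dataset$placement, paths["placement"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  bed <- dataset$repeats[, c("chrom", "start", "end", "name")]
  write.table(bed, paths["repeats"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(dataset$genes, paths["genes"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_traces_fasta(dataset$traces, paths["traces"])
  write.table(dataset$genotypes, paths["genotypes"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(dataset$config$species_tree, paths["tree"])
  invisible(paths)
}
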