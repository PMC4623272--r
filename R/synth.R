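# Synthetic-data generator: consensus, diverged copies, planted insertions
# with target-site duplications, insertion histories, trace reads and
# population genotype panels, all with ground truth.

#' Generate a synthetic SINE consensus sequence
#'
#' Draws a deterministic uppercase ACGT sequence of the requested length
#' ending in a poly-A tail, the hallmark of retrotransposed SINEs required
#' for microhomology-mediated target-primed reverse transcription.
#'
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @param length Element length in bp (>= 50).
#' @param tail_length Poly-A tail length in bp (>= 5).
#' @return A single character string.
#' @export
generate_consensus <- function(seed, length = 225L, tail_length = 8L) {
  if (!is.numeric(length) || length(length) != 1 || length <= 0) {
    stop("length must be a positive number")
  }
  if (length < 50) stop("length must be >= 50 bp")
  if (tail_length < 5) stop("tail_length must be >= 5 bp")
  set.seed(.stage_seed(seed, "consensus"))
  body <- .random_dna(length - tail_length)
  paste0(body, strrep("A", tail_length))
}

#' Diverge an element by random substitutions to a target identity
#'
#' Applies exactly `round(L * (100 - target_identity) / 100)` substitutions
#' at uniformly chosen positions (no indels), so the global identity to the
#' input, computed as matches over alignment columns, is within 0.5
#' percentage points of the target.
#'
#' @param element Character string (ACGT).
#' @param target_identity Target percent identity in (50, 100].
#' @param seed Integer seed.
#' @return The diverged sequence.
#' @export
diverge_element <- function(element, target_identity, seed) {
  element <- .as_seq_chr(element)[[1]]
  if (!is.numeric(target_identity) || target_identity <= 0 ||
      target_identity > 100) {
    stop("target_identity must be in (0, 100]")
  }
  if (target_identity < 50) {
    stop("target_identity below 50% is outside the modelled regime")
  }
  L <- nchar(element)
  n_sub <- round(L * (100 - target_identity) / 100)
  if (n_sub == 0) return(element)
  set.seed(.stage_seed(seed, "diverge"))
  pos <- sample.int(L, n_sub)
  chars <- strsplit(element, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Plant SINE insertions with target-site duplications into a genome
#'
#' At each insertion site the `tsd_len` bases 5' of the cut are duplicated so
#' the inserted element ends up flanked by identical direct repeats, the
#' signature of target-primed reverse transcription. Loci flagged
#' `inside_repeat` additionally receive a covering interval in the returned
#' repeat annotation, emulating nesting inside an older transposon.
#'
#' @param background Named character vector or `DNAStringSet`: the empty
#'   genome.
#' @param specs data.frame with columns `locus_id`, `chrom`, `insert_pos`
#'   (0-based cut position in background coordinates), `element_seq`,
#'   `tsd_len`; optional `strand` (default "+") and `inside_repeat`
#'   (default FALSE).
#' @param repeat_pad Padding (bp) of the simulated embedding repeat around
#'   an `inside_repeat` locus.
#' @return List with `genome` (DNAStringSet), `truth` (data.frame with final
#'   0-based half-open element coordinates, TSD sequence and flags) and
#'   `repeats` (data.frame of simulated embedding-repeat intervals).
#' @export
plant_insertions <- function(background, specs, repeat_pad = 150L) {
  background <- .as_seq_chr(background)
  stopifnot(all(c("locus_id", "chrom", "insert_pos", "element_seq",
                  "tsd_len") %in% names(specs)))
  if (is.null(specs$strand)) specs$strand <- "+"
  if (is.null(specs$inside_repeat)) specs$inside_repeat <- FALSE
  if (!all(specs$chrom %in% names(background))) {
    bad <- setdiff(unique(specs$chrom), names(background))
    stop("unknown chromosome(s) in specs: ", paste(bad, collapse = ", "))
  }
  # overlap check: the cut site plus the duplicated target bases must not
  # collide between insertions on the same chromosome
  ov <- unlist(lapply(split(specs, specs$chrom), function(s) {
    s <- s[order(s$insert_pos), , drop = FALSE]
    if (nrow(s) < 2) return(character())
    lo <- s$insert_pos - s$tsd_len
    hi <- s$insert_pos
    clash <- which(lo[-1] < hi[-nrow(s)])
    unique(c(s$locus_id[clash], s$locus_id[clash + 1L]))
  }))
  if (length(ov) > 0) {
    stop("overlapping insertion specs for loci: ",
         paste(sort(unique(ov)), collapse = ", "))
  }

  truth <- list()
  repeats <- list()
  for (chrom in names(background)) {
    s <- specs[specs$chrom == chrom, , drop = FALSE]
    if (nrow(s) == 0) next
    s <- s[order(s$insert_pos), , drop = FALSE]
    seqc <- background[[chrom]]
    pieces <- character(0)
    prev <- 0L  # 0-based: bases [0, prev) already emitted
    shift <- 0L
    for (i in seq_len(nrow(s))) {
      p <- s$insert_pos[i]
      t <- s$tsd_len[i]
      if (t > p) stop("tsd_len exceeds available 5' sequence at locus ",
                      s$locus_id[i])
      elt <- if (s$strand[i] == "-") .revcomp(s$element_seq[i]) else
        s$element_seq[i]
      tsd_seq <- if (t > 0) substr(seqc, p - t + 1L, p) else ""
      pieces <- c(pieces, substr(seqc, prev + 1L, p), elt, tsd_seq)
      start <- p + shift
      truth[[length(truth) + 1L]] <- data.frame(
        locus_id = s$locus_id[i], chrom = chrom,
        start = start, end = start + nchar(elt),
        strand = s$strand[i], element_length = nchar(elt),
        tsd_len = t, tsd_seq = tsd_seq,
        inside_repeat = isTRUE(s$inside_repeat[i])
      )
      if (isTRUE(s$inside_repeat[i])) {
        repeats[[length(repeats) + 1L]] <- data.frame(
          chrom = chrom,
          start = max(0L, start - repeat_pad),
          end = start + nchar(elt) + t + repeat_pad,
          name = "SimLINE"
        )
      }
      shift <- shift + nchar(elt) + t
      prev <- p
    }
    pieces <- c(pieces, substr(seqc, prev + 1L, nchar(seqc)))
    background[[chrom]] <- paste(pieces, collapse = "")
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(locus_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               element_length = integer(), tsd_len = integer(),
               tsd_seq = character(), inside_repeat = logical())
  repeats <- if (length(repeats)) do.call(rbind, repeats) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character())
  # clip repeat intervals to chromosome ends
  if (nrow(repeats) > 0) {
    lens <- setNames(nchar(background), names(background))
    repeats$end <- pmin(repeats$end, lens[repeats$chrom])
    rownames(repeats) <- NULL
  }
  rownames(truth) <- NULL
  list(genome = .as_dss(background), truth = truth, repeats = repeats)
}

#' Simulate an insertion history under the identity clock
#'
#' Draws per-locus insertion ages and derives: percent identity to the
#' consensus under a linear substitution clock (clamped to [84, 100]); the
#' probability that the locus is still polymorphic, decaying exponentially
#' with age; the allele frequency of the inserted allele for polymorphic
#' loci; the lineage distribution on the species tree (older than the
#' radiation: present in all species; between radiation and horse split:
#' horse lineage only; younger: domestic horse only); and the genotype of
#' the reference individual drawn under Hardy-Weinberg.
#'
#' @param config A `sim_config`.
#' @param n_loci Optional override of `config$n_loci`.
#' @return data.frame, one row per locus (the truth-table stub).
#' @export
simulate_insertion_history <- function(config, n_loci = NULL) {
  cfg <- validate_sim_config(config)
  n <- if (is.null(n_loci)) cfg$n_loci else n_loci
  set.seed(.stage_seed(cfg$seed, "history"))
  age <- runif(n, cfg$age_range[1], cfg$age_range[2])
  identity <- pmin(100, pmax(84, 100 * (1 - cfg$mutation_rate_per_site_per_My * age)))
  p_poly <- pmin(1, cfg$polymorphism_p0 * exp(-age / cfg$polymorphism_decay_tau))
  polymorphic <- runif(n) < p_poly
  freq <- ifelse(polymorphic, runif(n, 0.05, 0.95), 1)
  lineage <- ifelse(age > cfg$radiation_age, "all_equus",
                    ifelse(age > cfg$horse_split_age, "horse_lineage",
                           "caballus_only"))
  ref_draw <- runif(n)
  ref_genotype <- ifelse(!polymorphic, "+/+",
                         ifelse(ref_draw < freq^2, "+/+",
                                ifelse(ref_draw < freq^2 + 2 * freq * (1 - freq),
                                       "+/-", "-/-")))
  data.frame(
    locus_id = sprintf("L%04d", seq_len(n)),
    age = age, identity = identity, polymorphic = polymorphic,
    allele_freq_plus = freq, lineage = lineage,
    ref_genotype = ref_genotype
  )
}

#' Simulate trace reads for the reference individual
#'
#' For every requested locus, emits `trace_depth` reads per haplotype of the
#' reference individual: filled-haplotype reads are substrings of the
#' reference genome around the locus; empty-haplotype reads (heterozygous
#' loci only) are substrings of the empty allele (element plus one TSD copy
#' excised) spanning the insertion point with at least `trace_anchor` bases
#' on each side. Roughly half the reads are reverse-complemented. Decoy
#' reads carrying a different project tag are emitted for a subset of loci.
#'
#' @param genome DNAStringSet / named character: the reference (filled)
#'   genome, keyed by the chromosome names used in `truth`.
#' @param truth Truth table from [plant_insertions()] merged with
#'   `ref_genotype` (see [simulate_ere1_dataset()]).
#' @param config A `sim_config`.
#' @param het_loci Character vector of locus ids at which the reference
#'   individual is heterozygous. Defaults to `truth$ref_genotype == "+/-"`.
#' @return data.frame(trace_id, project, sequence, locus_id, haplotype).
#' @export
simulate_traces <- function(genome, truth, config, het_loci = NULL) {
  cfg <- validate_sim_config(config)
  genome <- .as_seq_chr(genome)
  if (is.null(het_loci)) {
    het_loci <- truth$locus_id[truth$ref_genotype == "+/-"]
  }
  if (!all(het_loci %in% truth$locus_id)) {
    stop("het_loci must be a subset of truth$locus_id")
  }
  set.seed(.stage_seed(cfg$seed, "traces"))
  rl <- cfg$trace_length
  anc <- cfg$trace_anchor
  fl <- cfg$flank_length
  reads <- list()
  emit <- function(seq, project, locus_id, hap) {
    if (runif(1) < 0.5) seq <- .revcomp(seq)
    reads[[length(reads) + 1L]] <<- data.frame(
      trace_id = sprintf("TR%06d", length(reads) + 1L),
      project = project, sequence = seq,
      locus_id = locus_id, haplotype = hap
    )
  }
  for (i in seq_len(nrow(truth))) {
    chrom <- truth$chrom[i]
    L <- nchar(genome[[chrom]])
    start <- truth$start[i]; end <- truth$end[i]
    tsd <- truth$tsd_len[i]
    het <- truth$locus_id[i] %in% het_loci
    # filled haplotype reads (both haplotypes if homozygous present)
    n_filled <- cfg$trace_depth * (2L - as.integer(het))
    lo <- max(0L, start - fl)
    hi <- min(L - rl, end + fl - rl)
    if (hi >= lo) {
      for (k in seq_len(n_filled)) {
        off <- floor(runif(1, lo, hi + 1))
        emit(substr(genome[[chrom]], off + 1L, off + rl),
             cfg$trace_project, truth$locus_id[i], "filled")
      }
    }
    if (het) {
      # empty allele: excise element plus the downstream TSD copy
      left <- substr(genome[[chrom]], max(1L, start - fl + 1L), start)
      right <- substr(genome[[chrom]], end + tsd + 1L,
                      min(L, end + tsd + fl))
      empty_seq <- paste0(left, right)
      junction <- nchar(left)
      off_lo <- max(0L, junction - rl + anc)
      off_hi <- min(nchar(empty_seq) - rl, junction - anc)
      if (off_hi < off_lo) {
        stop("flanks too short to emit junction-spanning reads at locus ",
             truth$locus_id[i])
      }
      for (k in seq_len(cfg$trace_depth)) {
        off <- floor(runif(1, off_lo, off_hi + 1))
        emit(substr(empty_seq, off + 1L, off + rl),
             cfg$trace_project, truth$locus_id[i], "empty")
        # decoy: same evidence, wrong project - must never be counted
        if (k == 1L) {
          emit(substr(empty_seq, off + 1L, off + rl),
               cfg$decoy_project, truth$locus_id[i], "empty_decoy")
        }
      }
    }
  }
  out <- do.call(rbind, reads)
  rownames(out) <- NULL
  out
}

#' Simulate a population genotype panel
#'
#' Per individual and locus, genotypes are drawn under Hardy-Weinberg from
#' the group's allele frequency: species outside the locus' lineage are
#' homozygous empty; fixed loci are homozygous inserted in species carrying
#' them; polymorphic loci segregate (same insertion frequency in the horse
#' species that carry them). An optional missing-data rate blanks cells.
#'
#' @param truth data.frame with `locus_id`, `lineage`, `polymorphic`,
#'   `allele_freq_plus` (from [simulate_insertion_history()]).
#' @param config A `sim_config`; `n_individuals_per_group` names the species
#'   groups.
#' @return Long data.frame(locus_id, individual, species, group, genotype).
#' @export
simulate_population_genotypes <- function(truth, config) {
  cfg <- validate_sim_config(config)
  set.seed(.stage_seed(cfg$seed, "genotypes"))
  groups <- cfg$n_individuals_per_group
  horse_species <- c("caballus", "przewalskii")
  present_in <- function(lineage) switch(
    lineage,
    all_equus = names(groups),
    horse_lineage = intersect(horse_species, names(groups)),
    caballus_only = intersect("caballus", names(groups)),
    stop("unknown lineage: ", lineage)
  )
  rows <- list()
  for (g in names(groups)) {
    inds <- sprintf("%s_%02d", g, seq_len(groups[[g]]))
    for (i in seq_len(nrow(truth))) {
      pres <- g %in% present_in(truth$lineage[i])
      if (!pres) {
        geno <- rep("-/-", length(inds))
      } else if (!truth$polymorphic[i] || !(g %in% horse_species)) {
        geno <- rep("+/+", length(inds))
      } else {
        f <- truth$allele_freq_plus[i]
        n_plus <- rbinom(length(inds), 2, f)
        geno <- c("-/-", "+/-", "+/+")[n_plus + 1L]
      }
      if (cfg$missing_rate > 0) {
        geno[runif(length(geno)) < cfg$missing_rate] <- "missing"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = truth$locus_id[i], individual = inds,
        species = g, group = g, genotype = geno
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
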