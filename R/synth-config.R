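#' Simulation configuration
#'
#' Collects and validates the parameters of the synthetic-data generator.
#' The defaults encode the study conditions the pipeline is designed for:
#' a ~225 bp SINE consensus, eight 2-point identity classes spanning
#' 84-100\% identity generated by a linear divergence clock, an exponential
#' decay of insertion polymorphism with age calibrated so that ~4.6\% of the
#' youngest class and ~0.1\% of the oldest class are polymorphic, a 3.8 My
#' radiation of the genus separating the horse lineage from the other
#' equids, and short (<1 kb) trace reads from a designated reference
#' individual tagged with a sequencing-project identifier.
#'
#' @param seed Integer global seed. Per-stage substreams are derived from it
#'   by fixed offsets, so a config is fully reproducible.
#' @param genome_length Total background genome length in bp (split over
#'   `n_contigs` contigs).
#' @param n_contigs Number of contigs/chromosomes.
#' @param n_loci Number of SINE copies planted in the genome.
#' @param consensus_length Length of the consensus element in bp.
#' @param tail_length Length of the consensus poly-A tail in bp (>= 5).
#' @param age_range Two-element numeric, insertion-age range in My. With the
#'   default clock the range 0-16 My maps onto identities 100-84\%.
#' @param mutation_rate_per_site_per_My Fraction of sites substituted per My;
#'   identity = 100 * (1 - rate * age), clamped to [84, 100].
#' @param polymorphism_decay_tau Decay time (My) of the probability that a
#'   locus is still polymorphic: P = p0 * exp(-age / tau).
#' @param polymorphism_p0 Prefactor of the polymorphism law (probability that
#'   a brand-new insertion is observed as polymorphic).
#' @param radiation_age Age (My) of the radiation of the genus: older loci
#'   are present in all species.
#' @param horse_split_age Age (My) of the split between the two horse
#'   species; younger loci are private to the domestic horse.
#' @param tsd_length_range Two-element integer, target-site-duplication
#'   length range in bp.
#' @param flank_length Flank length (bp) used for locus windows and
#'   minimum spacing between planted loci.
#' @param trace_length Trace read length in bp; must be < 1000 (traces are
#'   short unassembled reads) and > 2 * trace_anchor.
#' @param trace_depth Reads per locus per haplotype of the reference
#'   individual.
#' @param trace_anchor Minimum flank anchor (bp) a junction-spanning read
#'   keeps on each side of the insertion point.
#' @param trace_project Project tag of the reference individual's reads.
#' @param decoy_project Project tag used for decoy reads.
#' @param n_het_loci Number of loci at which the reference individual is
#'   heterozygous (carries one filled and one empty allele).
#' @param n_repeat_embedded Number of loci nested inside another simulated
#'   repeat (to be discarded by the repeat filter).
#' @param n_duplicated Number of loci whose whole window is duplicated
#'   elsewhere in the genome (to be discarded by the uniqueness check).
#' @param n_decoy_repeats Number of repeat intervals placed away from any
#'   locus.
#' @param missing_rate Per-cell missing-genotype probability in the
#'   population panel.
#' @param n_individuals_per_group Named integer vector, individuals genotyped
#'   per species group. Defaults mirror a 7-species equid panel.
#' @param species_tree Newick string for the species tree. The default tree
#'   has the two horse species splitting `horse_split_age` My ago and the
#'   remaining species radiating `radiation_age` My ago.
#'
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 2e6,
                              n_contigs = 2L,
                              n_loci = 200L,
                              consensus_length = 225L,
                              tail_length = 8L,
                              age_range = c(0, 16),
                              mutation_rate_per_site_per_My = 0.01,
                              polymorphism_decay_tau = 3.656,
                              polymorphism_p0 = 0.166,
                              radiation_age = 3.8,
                              horse_split_age = 0.72,
                              tsd_length_range = c(5L, 20L),
                              flank_length = 1000L,
                              trace_length = 700L,
                              trace_depth = 3L,
                              trace_anchor = 60L,
                              trace_project = "G836",
                              decoy_project = "G900",
                              n_het_loci = 30L,
                              n_repeat_embedded = 10L,
                              n_duplicated = 5L,
                              n_decoy_repeats = 10L,
                              missing_rate = 0,
                              n_individuals_per_group = c(
                                caballus = 30L, przewalskii = 20L,
                                asinus = 3L, kiang = 1L, hemionus = 1L,
                                grevyi = 1L, zebra = 1L),
                              species_tree = NULL) {
  cfg <- as.list(environment())
  if (is.null(cfg$species_tree)) {
    cfg$species_tree <- .default_species_tree(radiation_age, horse_split_age)
  }
  validate_sim_config(cfg)
}

.default_species_tree <- function(radiation_age, horse_split_age) {
  r <- radiation_age
  s <- horse_split_age
  sprintf(paste0(
    "((caballus:%.3f,przewalskii:%.3f):%.3f,",
    "(((asinus:1.0,kiang:1.0):0.5,hemionus:1.5):%.3f,",
    "(grevyi:1.4,zebra:1.4):%.3f):0.5);"),
    s, s, r - s, r - 0.5 - 1.5, r - 0.5 - 1.4)
}

#' @rdname simulation_config
#' @param cfg A `sim_config` list.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  if (cfg$consensus_length < 50) stop("consensus_length must be >= 50")
  if (cfg$trace_length >= 1000) {
    stop("trace_length must be < 1000 bp: traces model short unassembled reads")
  }
  if (cfg$trace_length <= 2 * cfg$trace_anchor) {
    stop("trace_length must exceed 2 * trace_anchor (",
         2 * cfg$trace_anchor, " bp)")
  }
  footprint <- cfg$n_loci * (cfg$consensus_length + 2 * cfg$flank_length)
  if (cfg$genome_length <= footprint) {
    stop("genome_length (", cfg$genome_length, ") must exceed n_loci * ",
         "(consensus_length + 2*flank_length) = ", footprint)
  }
  if (length(cfg$tsd_length_range) != 2 ||
      any(cfg$tsd_length_range < 0)) {
    stop("tsd_length_range must be two non-negative lengths")
  }
  max_ident_loss <- 100 * cfg$mutation_rate_per_site_per_My * max(cfg$age_range)
  if (max_ident_loss > 16 + 1e-9) {
    # identities are clamped at 84; warn-free by construction otherwise
  }
  if (cfg$n_het_loci + cfg$n_repeat_embedded + cfg$n_duplicated > cfg$n_loci) {
    stop("special locus counts exceed n_loci")
  }
  structure(cfg, class = "sim_config")
}
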