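# Population and evolutionary statistics: PCR-size genotyping, allele and
# genotype frequencies, chi-square tests, identity-class/polymorphism
# correlation, insertion-age classification on the species tree, two-locus
# concordance and linkage disequilibrium, and delta-delta-Cq fold changes.
#
# The chi-square and correlation statistics are computed from their defining
# formulas (no continuity correction anywhere); base-R chisq.test/cor.test
# serve only as independent cross-checks in the test suite.

#' Call a genotype from PCR band sizes
#'
#' The insertion allele amplifies a long product, the empty allele a short
#' one (defaults 441 and 214 bp for the myostatin-promoter assay); bands
#' are matched to alleles within `tolerance` bp.
#'
#' @param bands Numeric vector of observed band sizes (1 or 2 bands).
#' @param plus_size,minus_size Expected product sizes (bp) of the inserted
#'   (+) and empty (-) allele.
#' @param tolerance Matching tolerance in bp.
#' @return One of "+/+", "+/-", "-/-" or "missing" (with a warning for
#'   unmatched or excess bands).
#' @export
genotype_from_pcr <- function(bands, plus_size = 441, minus_size = 214,
                              tolerance = 5) {
  if (abs(plus_size - minus_size) <= 2 * tolerance) {
    stop("allele product sizes must differ by more than 2 * tolerance")
  }
  if (length(bands) < 1 || length(bands) > 2) {
    warning("expected 1-2 bands, got ", length(bands))
    return("missing")
  }
  has_plus <- any(abs(bands - plus_size) <= tolerance)
  has_minus <- any(abs(bands - minus_size) <= tolerance)
  unmatched <- !(abs(bands - plus_size) <= tolerance |
                   abs(bands - minus_size) <= tolerance)
  if (any(unmatched)) {
    warning("band(s) matching neither allele: ",
            paste(bands[unmatched], collapse = ", "))
    return("missing")
  }
  if (has_plus && has_minus) "+/-" else if (has_plus) "+/+" else "-/-"
}

#' Allele and genotype frequencies per group
#'
#' From genotype counts per group computes the allele counts
#' (`n+ = 2 n(+/+) + n(+/-)`) and the genotype counts, with percentages on
#' non-missing individuals rounded half-up to one decimal (printed-table
#' convention).
#'
#' @param genotypes Either a long data.frame with columns `group` and
#'   `genotype` (one row per individual, genotypes "+/+", "+/-", "-/-",
#'   "missing"), or a counts data.frame with columns `group`, `n_pp`,
#'   `n_pm`, `n_mm`.
#' @param digits Decimals for the printed percentages.
#' @return data.frame, one row per group: individuals, allele counts and
#'   percentages, homozygous/heterozygous counts and percentages.
#' @export
allele_genotype_frequencies <- function(genotypes, digits = 1) {
  if (all(c("n_pp", "n_pm", "n_mm") %in% names(genotypes))) {
    counts <- genotypes
  } else {
    .assert_genotype(genotypes$genotype)
    keep <- genotypes$genotype %in% c("+/+", "+/-", "-/-")
    g <- genotypes[keep, , drop = FALSE]
    if (nrow(g) == 0) stop("no non-missing genotypes")
    tab <- table(g$group, factor(g$genotype,
                                 levels = c("+/+", "+/-", "-/-")))
    counts <- data.frame(group = rownames(tab),
                         n_pp = as.integer(tab[, "+/+"]),
                         n_pm = as.integer(tab[, "+/-"]),
                         n_mm = as.integer(tab[, "-/-"]))
  }
  n_ind <- counts$n_pp + counts$n_pm + counts$n_mm
  if (any(n_ind == 0)) {
    stop("group(s) without genotyped individuals: ",
         paste(counts$group[n_ind == 0], collapse = ", "))
  }
  allele_plus <- 2L * counts$n_pp + counts$n_pm
  allele_minus <- 2L * counts$n_mm + counts$n_pm
  total_alleles <- 2L * n_ind
  data.frame(
    group = counts$group,
    n_individuals = n_ind,
    allele_plus = allele_plus,
    allele_minus = allele_minus,
    pct_allele_plus = round_half_up(100 * allele_plus / total_alleles, digits),
    pct_allele_minus = round_half_up(100 * allele_minus / total_alleles, digits),
    n_pp = counts$n_pp, n_mm = counts$n_mm, n_pm = counts$n_pm,
    pct_pp = round_half_up(100 * counts$n_pp / n_ind, digits),
    pct_mm = round_half_up(100 * counts$n_mm / n_ind, digits),
    pct_pm = round_half_up(100 * counts$n_pm / n_ind, digits)
  )
}

#' Myostatin-promoter genotype counts
#'
#' The packaged genotype counts of the insertion assay at the myostatin
#' promoter: five domestic breeds plus Przewalski's horse (panel A) and
#' four sport-aptitude groups (panel B).
#'
#' @return data.frame(group, panel, n_pp, n_pm, n_mm).
#' @export
myostatin_genotype_counts <- function() {
  path <- system.file("extdata", "myostatin_genotype_counts.tsv",
                      package = "ereScout", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Chi-square goodness-of-fit test
#'
#' `chi2 = sum (O - E)^2 / E` with `E = N * expected_fractions`,
#' `df = k - 1`, no continuity correction; p from the upper tail of the
#' chi-square distribution.
#'
#' @param observed Integer vector of observed counts.
#' @param expected_fractions Numeric vector of expected fractions (sums
#'   to 1).
#' @return List (class `contingency_result`): `observed`, `expected`,
#'   `statistic`, `df`, `p_value`.
#' @export
chisq_goodness_of_fit <- function(observed, expected_fractions) {
  if (length(observed) != length(expected_fractions)) {
    stop("observed and expected_fractions must have equal length")
  }
  if (abs(sum(expected_fractions) - 1) > 1e-8) {
    stop("expected_fractions must sum to 1")
  }
  expected <- sum(observed) * expected_fractions
  if (any(expected <= 0)) stop("expected counts must be positive")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(observed = observed, expected = expected,
                 statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE)),
            class = "contingency_result")
}

#' Chi-square test of independence
#'
#' Expected cells are `row total * column total / grand total`; the
#' statistic is summed over all cells with `df = (r-1)(c-1)`, no continuity
#' correction.
#'
#' @param tab Numeric matrix (r x c contingency table).
#' @return List (class `contingency_result`).
#' @export
chisq_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2x2")
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("degenerate table: zero row or column marginal")
  }
  expected <- outer(rs, cs) / N
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  structure(list(observed = tab, expected = expected, statistic = stat,
                 df = df, p_value = pchisq(stat, df, lower.tail = FALSE)),
            class = "contingency_result")
}

#' Identity-class summary of polymorphic loci
#'
#' Cross-tabulates kept loci by identity class and flags the polymorphic
#' ones, yielding per-class locus counts, polymorphic counts and fractions.
#'
#' @param loci Locus data.frame with `locus_id` and `identity` (kept loci),
#'   or with a precomputed `identity_class` column.
#' @param polymorphic_ids Character vector of locus ids called polymorphic.
#' @return data.frame(identity_class, n_loci, n_polymorphic, fraction).
#' @export
identity_class_summary <- function(loci, polymorphic_ids) {
  cls <- if (!is.null(loci$identity_class) &&
             !all(is.na(loci$identity_class))) loci$identity_class
  else assign_identity_class(loci$identity)
  levels <- identity_class_levels()
  f <- factor(cls, levels = levels)
  n <- table(f)
  np <- table(f[loci$locus_id %in% polymorphic_ids])
  data.frame(identity_class = levels,
             n_loci = as.integer(n),
             n_polymorphic = as.integer(np),
             fraction = ifelse(as.integer(n) > 0,
                               as.integer(np) / as.integer(n), NA_real_))
}

#' Correlation between class identity and log polymorphic fraction
#'
#' Pearson product-moment correlation between the identity of each class
#' (midpoint by default) and the natural logarithm of its polymorphic
#' fraction; classes with zero polymorphic loci are excluded (ln 0 is
#' undefined). Significance via the t transform
#' `t = r sqrt((n-2)/(1-r^2))` with `df = n - 2`, two-sided.
#'
#' @param summary data.frame from [identity_class_summary()].
#' @param covariate "midpoint" (default) or "lower" bound of each class.
#' @return List (class `correlation_result`): `r`, `n`, `t`, `df`,
#'   `p_value`.
#' @export
pearson_identity_logfreq <- function(summary,
                                     covariate = c("midpoint", "lower")) {
  covariate <- match.arg(covariate)
  lower <- as.numeric(sub("-.*", "", summary$identity_class))
  upper <- as.numeric(sub(".*-", "", summary$identity_class))
  x_all <- if (covariate == "midpoint") (lower + upper) / 2 else lower
  use <- !is.na(summary$fraction) & summary$fraction > 0
  if (sum(use) < 3) {
    stop("need at least 3 classes with a non-zero polymorphic fraction")
  }
  x <- x_all[use]
  y <- log(summary$fraction[use])
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  pearson_p_from_r(r, length(x))
}

#' Significance of a Pearson correlation via the t transform
#'
#' @param r Correlation coefficient.
#' @param n Number of pairs.
#' @return List (class `correlation_result`): `r`, `n`, `t`, `df`,
#'   `p_value` (two-sided).
#' @export
pearson_p_from_r <- function(r, n) {
  if (n < 3) stop("need at least 3 pairs")
  df <- n - 2L
  t <- if (abs(r) >= 1) Inf else r * sqrt(df / (1 - r^2))
  structure(list(r = r, n = n, t = t, df = df,
                 p_value = 2 * pt(-abs(t), df)),
            class = "correlation_result")
}

#' Species-level presence states from a genotype panel
#'
#' @param genotypes Long data.frame(locus_id, species, genotype).
#' @return data.frame(locus_id, species, state) with state in
#'   present / polymorphic / absent / missing.
#' @export
species_presence <- function(genotypes) {
  .assert_genotype(genotypes$genotype)
  key <- interaction(genotypes$locus_id, genotypes$species, drop = TRUE)
  rows <- lapply(split(genotypes, key), function(g) {
    gt <- g$genotype[g$genotype %in% c("+/+", "+/-", "-/-")]
    state <- if (length(gt) == 0) "missing"
    else if (any(gt %in% c("+/-")) ||
             (any(gt == "+/+") && any(gt == "-/-"))) "polymorphic"
    else if (any(gt == "+/+")) "present"
    else "absent"
    data.frame(locus_id = g$locus_id[1], species = g$species[1],
               state = state)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify insertion age from presence/absence across species
#'
#' On the equid tree the horse lineage (domestic and Przewalski's horse)
#' split from the other species at the radiation of the genus; loci present
#' in every species predate the radiation (`all_equus`), loci confined to
#' the two horse species postdate it (`horse_lineage`), loci private to the
#' domestic horse are the youngest (`caballus_only`), and patterns that
#' violate the tree are `unresolved`. The classification is a pure function
#' of the presence/absence pattern; per-species polymorphism flags are
#' carried alongside.
#'
#' @param presence data.frame(locus_id, species, state) from
#'   [species_presence()], or a genotype panel (long format), in which case
#'   presence is derived first.
#' @param horse_species Names of the two horse species.
#' @param caballus Name of the domestic horse.
#' @param tree Optional `phylo` or Newick string; when given, its tip
#'   labels must contain every species in `presence`.
#' @return data.frame(locus_id, age_class, polymorphic_in) where
#'   `polymorphic_in` is a comma-joined list of species.
#' @export
classify_insertion_age <- function(presence,
                                   horse_species = c("caballus",
                                                     "przewalskii"),
                                   caballus = "caballus", tree = NULL) {
  if ("genotype" %in% names(presence)) {
    presence <- species_presence(presence)
  }
  species <- unique(presence$species)
  need <- c(horse_species)
  if (!all(need %in% species)) {
    stop("missing species group(s): ",
         paste(setdiff(need, species), collapse = ", "))
  }
  if (length(setdiff(species, horse_species)) == 0) {
    stop("need at least one non-horse species group")
  }
  if (!is.null(tree)) {
    if (is.character(tree)) tree <- ape::read.tree(text = tree)
    if (!all(species %in% tree$tip.label)) {
      stop("species absent from tree: ",
           paste(setdiff(species, tree$tip.label), collapse = ", "))
    }
  }
  others <- setdiff(species, horse_species)
  rows <- lapply(split(presence, presence$locus_id), function(p) {
    st <- setNames(p$state, p$species)
    has <- function(sp) st[sp] %in% c("present", "polymorphic")
    known <- function(sp) !st[sp] %in% "missing"
    in_horses <- vapply(horse_species, has, TRUE)
    in_others <- vapply(others, has, TRUE)
    cls <- if (all(in_horses) && all(in_others)) "all_equus"
    else if (all(in_horses) && !any(in_others)) "horse_lineage"
    else if (has(caballus) &&
             !any(vapply(setdiff(species, caballus), has, TRUE)))
      "caballus_only"
    else "unresolved"
    data.frame(locus_id = p$locus_id[1], age_class = cls,
               polymorphic_in = paste(
                 p$species[p$state == "polymorphic"], collapse = ","))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Conservation across the genus by identity class
#'
#' Cross-tabulates loci by identity class and insertion-age class and
#' reports, per identity class, the fraction conserved in all species.
#'
#' @param age data.frame from [classify_insertion_age()].
#' @param classes data.frame(locus_id, identity_class).
#' @return data.frame(identity_class, n_loci, n_all_equus,
#'   fraction_all_equus).
#' @export
conservation_by_identity_class <- function(age, classes) {
  m <- merge(classes, age, by = "locus_id")
  levels <- identity_class_levels()
  f <- factor(m$identity_class, levels = levels)
  n <- table(f)
  ncons <- table(f[m$age_class == "all_equus"])
  data.frame(identity_class = levels,
             n_loci = as.integer(n),
             n_all_equus = as.integer(ncons),
             fraction_all_equus = ifelse(as.integer(n) > 0,
                                         as.integer(ncons) / as.integer(n),
                                         NA_real_))
}

# EM estimate of two-locus haplotype frequencies from unphased genotype
# counts. g1, g2 are allele-dosage vectors (0/1/2 copies of allele A and B).
.em_haplotypes <- function(g1, g2, max_iter = 200, tol = 1e-12) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  n <- length(g1)
  pA <- mean(g1) / 2
  pB <- mean(g2) / 2
  # haplotypes: AB, Ab, aB, ab
  h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  dh <- sum(g1 == 1 & g2 == 1)   # double heterozygotes
  # counts of unambiguous haplotypes
  base <- c(
    AB = sum((g1 == 2) * g2 + (g1 == 1) * (g2 == 2)),
    Ab = sum((g1 == 2) * (2 - g2) + (g1 == 1) * (g2 == 0)),
    aB = sum((g1 == 0) * g2 + (g1 == 1 & g2 == 2)),
    ab = sum((g1 == 0) * (2 - g2) + (g1 == 1 & g2 == 0))
  )
  for (it in seq_len(max_iter)) {
    cis <- h[1] * h[4]
    trans <- h[2] * h[3]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    cnt <- base + dh * c(w, 1 - w, 1 - w, w)
    h_new <- cnt / (2 * n)
    if (max(abs(h_new - h)) < tol) {
      h <- h_new
      break
    }
    h <- h_new
  }
  h
}

#' Two-locus genotype concordance and linkage disequilibrium
#'
#' Counts individuals whose genotype pair is in the declared concordance
#' map (by default the insertion + allele travels with the C SNP allele:
#' (+/+, C/C), (+/-, C/T), (-/-, T/T)), and estimates r-squared from
#' maximum-likelihood haplotype frequencies obtained by
#' expectation-maximisation on the unphased two-locus genotypes:
#' `r2 = D^2 / (pA pa pB pb)` with `D = h(AB) - pA pB`.
#'
#' @param geno_a Genotypes at the first locus ("+/+", "+/-", "-/-").
#' @param geno_b Genotypes at the second locus (e.g. "C/C", "C/T", "T/T").
#' @param concordance_map Named character vector mapping first-locus
#'   genotypes to the concordant second-locus genotype.
#' @return List: `n_concordant`, `n_total` (complete pairs),
#'   `concordance`, `r2` (NA with a message for monomorphic loci),
#'   `haplotype_freqs`, `D`.
#' @export
two_locus_concordance_and_r2 <- function(geno_a, geno_b,
                                         concordance_map = c(
                                           "+/+" = "C/C", "+/-" = "C/T",
                                           "-/-" = "T/T")) {
  ok_a <- geno_a %in% names(concordance_map)
  alleles_b <- sort(unique(unlist(strsplit(
    unname(concordance_map), "/"))))
  complete <- ok_a & !is.na(geno_b) & geno_b != "missing"
  n_total <- sum(complete)
  n_conc <- sum(complete & concordance_map[geno_a] == geno_b)
  dosage_a <- c("+/+" = 2, "+/-" = 1, "-/-" = 0)[geno_a[complete]]
  # dosage of the allele concordant with "+" (first allele of map["+/+"])
  ref_b <- strsplit(unname(concordance_map[["+/+"]]), "/")[[1]][1]
  dosage_b <- vapply(strsplit(geno_b[complete], "/"), function(a)
    sum(a == ref_b), 0)
  pA <- mean(dosage_a) / 2
  pB <- mean(dosage_b) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    return(list(n_concordant = n_conc, n_total = n_total,
                concordance = if (n_total > 0) n_conc / n_total else NA_real_,
                r2 = NA_real_, haplotype_freqs = NULL, D = NA_real_,
                note = "monomorphic locus: r2 undefined"))
  }
  h <- .em_haplotypes(dosage_a, dosage_b)
  D <- unname(h[1]) - pA * pB
  r2 <- unname(D^2 / (pA * (1 - pA) * pB * (1 - pB)))
  list(n_concordant = n_conc, n_total = n_total,
       concordance = n_conc / n_total, r2 = r2,
       haplotype_freqs = setNames(h, c("AB", "Ab", "aB", "ab")), D = D)
}

#' Relative expression by the delta-delta-Cq method
#'
#' `dCq = mean Cq(target) - mean Cq(control)` per condition;
#' `ddCq = dCq(condition) - dCq(reference)`; fold change `2^(-ddCq)`.
#'
#' @param cq data.frame(condition, gene, cq), one row per replicate.
#' @param target_gene,control_gene Gene names.
#' @param reference Reference condition (fold change 1 by definition).
#' @return data.frame(condition, dcq, ddcq, fold_change).
#' @export
fold_change_ddcq <- function(cq, target_gene, control_gene, reference) {
  conds <- unique(cq$condition)
  if (!reference %in% conds) stop("reference condition not in data")
  dcq <- vapply(conds, function(cond) {
    tg <- cq$cq[cq$condition == cond & cq$gene == target_gene]
    cg <- cq$cq[cq$condition == cond & cq$gene == control_gene]
    if (length(tg) == 0) stop("no target-gene Cq for condition ", cond)
    if (length(cg) == 0) stop("no control-gene Cq for condition ", cond)
    mean(tg) - mean(cg)
  }, numeric(1))
  ddcq <- dcq - dcq[[reference]]
  data.frame(condition = conds, dcq = unname(dcq), ddcq = unname(ddcq),
             fold_change = 2^(-unname(ddcq)))
}
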