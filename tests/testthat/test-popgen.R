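# Population statistics: PCR genotyping, frequency tables, chi-square
# tests, identity/polymorphism correlation, insertion-age classes,
# two-locus LD and delta-delta-Cq.

test_that("PCR band sizes map to genotypes within tolerance", {
  expect_equal(genotype_from_pcr(441), "+/+")
  expect_equal(genotype_from_pcr(c(214, 441)), "+/-")
  expect_equal(genotype_from_pcr(214), "-/-")
  expect_equal(genotype_from_pcr(c(443, 212)), "+/-")
  expect_warning(g <- genotype_from_pcr(350), "neither")
  expect_equal(g, "missing")
  expect_warning(g3 <- genotype_from_pcr(c(214, 300, 441)), "bands")
  expect_equal(g3, "missing")
  expect_error(genotype_from_pcr(441, plus_size = 220, minus_size = 214),
               "differ")
})

test_that("the myostatin genotype table reproduces every printed cell", {
  counts <- myostatin_genotype_counts()
  freq <- allele_genotype_frequencies(counts)
  row <- function(g) freq[freq$group == g, ]
  qh <- row("Quarter Horse")
  expect_equal(qh$allele_plus, 23)
  expect_equal(qh$allele_minus, 17)
  expect_equal(qh$pct_allele_plus, 57.5)
  expect_equal(qh$pct_allele_minus, 42.5)
  expect_equal(qh$pct_pp, 45)
  expect_equal(qh$pct_mm, 30)
  expect_equal(qh$pct_pm, 25)
  an <- row("Andalusian")
  expect_equal(c(an$pct_allele_plus, an$pct_allele_minus), c(7.5, 92.5))
  expect_equal(c(an$pct_mm, an$pct_pm), c(85, 15))
  li <- row("Lipizzaner")
  expect_equal(li$allele_minus, 46)
  expect_equal(li$pct_allele_minus, 100)
  sj <- row("Show Jumpers")
  expect_equal(c(sj$pct_allele_plus, sj$pct_allele_minus), c(1.7, 98.3))
  expect_equal(c(sj$pct_mm, sj$pct_pm), c(96.7, 3.3))
  ut <- row("Unselected Thoroughbreds")
  expect_equal(c(ut$allele_plus, ut$allele_minus), c(65, 85))
  expect_equal(c(ut$pct_allele_plus, ut$pct_allele_minus), c(43.3, 56.7))
  expect_equal(c(ut$pct_pp, ut$pct_pm, ut$pct_mm), c(24.0, 38.7, 37.3))
  et <- row("Elite Thoroughbreds")
  expect_equal(c(et$allele_plus, et$allele_minus), c(135, 99))
  expect_equal(c(et$pct_allele_plus, et$pct_allele_minus), c(57.7, 42.3))
  expect_equal(c(et$pct_pp, et$pct_mm, et$pct_pm), c(28.2, 12.8, 59.0))
})

test_that("allele counts conserve on long-format genotype input", {
  set.seed(71)
  g <- data.frame(group = "x",
                  genotype = sample(c("+/+", "+/-", "-/-"), 50, TRUE))
  f <- allele_genotype_frequencies(g)
  expect_equal(f$allele_plus + f$allele_minus, 2 * 50)
  expect_error(allele_genotype_frequencies(
    data.frame(group = "x", genotype = "missing")), "non-missing")
})

test_that("goodness of fit matches the hand formula and the printed p", {
  res <- chisq_goodness_of_fit(c(135, 99), c(65 / 150, 85 / 150))
  # hand oracle: E = (101.4, 132.6); chi2 = 33.6^2/101.4 + 33.6^2/132.6
  expect_equal(res$statistic, 33.6^2 / 101.4 + 33.6^2 / 132.6,
               tolerance = 1e-12)
  expect_equal(res$statistic, 19.65, tolerance = 1e-3)
  expect_equal(signif(res$p_value, 2), 9.3e-6)
  # exactly proportional observations
  res0 <- chisq_goodness_of_fit(c(65, 85) * 2, c(65 / 150, 85 / 150))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(chisq_goodness_of_fit(c(1, 2), c(1, 0)), "positive")
  expect_error(chisq_goodness_of_fit(c(1, 2), c(0.6, 0.6)), "sum to 1")
})

test_that("independence test: closed form and uniform table", {
  res <- chisq_independence(matrix(c(10, 0, 0, 10), 2))
  # 2x2 closed form N(ad-bc)^2 / (r1 r2 c1 c2)
  expect_equal(res$statistic, 20 * (10 * 10)^2 / (10 * 10 * 10 * 10))
  expect_lt(res$p_value, 1e-4)
  expect_equal(chisq_independence(matrix(5, 2, 2))$statistic, 0)
  expect_error(chisq_independence(matrix(c(0, 0, 1, 2), 2)), "degenerate")
})

test_that("chi-square implementations agree with stats:: to 1e-10", {
  set.seed(72)
  for (k in 1:100) {
    tab <- matrix(rpois(6, 20) + 1, 2, 3)
    mine <- chisq_independence(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    obs <- rpois(4, 30) + 1
    ef <- (function(x) x / sum(x))(runif(4) + 0.1)
    mg <- chisq_goodness_of_fit(obs, ef)
    rg <- suppressWarnings(chisq.test(obs, p = ef))
    expect_equal(mg$statistic, unname(rg$statistic), tolerance = 1e-10)
    expect_equal(mg$p_value, rg$p.value, tolerance = 1e-10)
  }
})

test_that("Pearson correlation and its t-transform p-value", {
  # perfectly linear relation
  sm <- data.frame(identity_class = identity_class_levels(),
                   n_loci = rep(100, 8), n_polymorphic = 1,
                   fraction = exp(seq(-8, -1)))
  res <- pearson_identity_logfreq(sm)
  expect_equal(res$r, 1, tolerance = 1e-12)
  # the printed summary statistic: r = 0.93 with n = 8
  p93 <- pearson_p_from_r(0.93, 8)
  expect_equal(p93$t, 0.93 * sqrt(6 / (1 - 0.93^2)), tolerance = 1e-12)
  expect_equal(p93$p_value, 2 * pt(-p93$t, 6), tolerance = 1e-15)
  # cross-check the transform against cor.test on data with that exact r
  set.seed(73)
  x <- 1:8
  y <- 0.93 * scale(x) + sqrt(1 - 0.93^2) * scale(resid(lm(rnorm(8) ~ x)))
  ct <- cor.test(x, as.numeric(y))
  expect_equal(unname(ct$estimate), 0.93, tolerance = 1e-9)
  expect_equal(pearson_p_from_r(unname(ct$estimate), 8)$p_value,
               ct$p.value, tolerance = 1e-9)
  # fewer than 3 usable classes
  sm$fraction <- c(0.1, 0.05, rep(0, 6))
  expect_error(pearson_identity_logfreq(sm), "at least 3")
})

test_that("insertion-age classes follow the tree", {
  species <- c("caballus", "przewalskii", "asinus", "kiang", "hemionus",
               "grevyi", "zebra")
  mk <- function(states) data.frame(locus_id = "L", species = species,
                                    state = states)
  all_p <- classify_insertion_age(mk(rep("present", 7)))
  expect_equal(all_p$age_class, "all_equus")
  horses <- classify_insertion_age(
    mk(c("present", "present", rep("absent", 5))))
  expect_equal(horses$age_class, "horse_lineage")
  cab <- classify_insertion_age(
    mk(c("polymorphic", rep("absent", 6))))
  expect_equal(cab$age_class, "caballus_only")
  expect_equal(cab$polymorphic_in, "caballus")
  # pattern violating the tree: present in zebra, absent in horses
  odd <- classify_insertion_age(
    mk(c("absent", "absent", rep("absent", 4), "present")))
  expect_equal(odd$age_class, "unresolved")
  # a missing horse group is an error
  expect_error(classify_insertion_age(
    data.frame(locus_id = "L", species = "caballus", state = "present")),
    "missing species|non-horse")
})

test_that("age classes are invariant to permuting individuals in groups", {
  cfg <- simulation_config(seed = 74, n_loci = 50, genome_length = 1e6,
                           n_het_loci = 5, n_repeat_embedded = 0,
                           n_duplicated = 0)
  h <- simulate_insertion_history(cfg)
  g <- simulate_population_genotypes(h, cfg)
  base <- classify_insertion_age(g, tree = cfg$species_tree)
  set.seed(1)
  perm <- g[sample(nrow(g)), ]
  expect_equal(classify_insertion_age(perm), base)
})

test_that("conservation fraction is non-increasing with identity", {
  cfg <- simulation_config(seed = 75, n_loci = 300, genome_length = 2e6,
                           n_het_loci = 0, n_repeat_embedded = 0,
                           n_duplicated = 0)
  h <- simulate_insertion_history(cfg)
  g <- simulate_population_genotypes(h, cfg)
  age <- classify_insertion_age(g)
  cons <- conservation_by_identity_class(
    age, data.frame(locus_id = h$locus_id,
                    identity_class = assign_identity_class(h$identity)))
  fr <- cons$fraction_all_equus[!is.na(cons$fraction_all_equus)]
  expect_true(all(diff(fr) <= 0))
  expect_equal(sum(cons$n_loci), nrow(h))
  # degenerate: everything ancient
  age2 <- age
  age2$age_class <- "all_equus"
  cons2 <- conservation_by_identity_class(
    age2, data.frame(locus_id = h$locus_id,
                     identity_class = assign_identity_class(h$identity)))
  ok <- cons2$n_loci > 0
  expect_true(all(cons2$fraction_all_equus[ok] == 1))
})

test_that("two-locus concordance and EM r2", {
  # perfect linkage
  ga <- c(rep("+/+", 5), rep("+/-", 5), rep("-/-", 5))
  gb <- c(rep("C/C", 5), rep("C/T", 5), rep("T/T", 5))
  res <- two_locus_concordance_and_r2(ga, gb)
  expect_equal(res$concordance, 1)
  expect_equal(res$r2, 1, tolerance = 1e-9)
  # a single heterozygote pair is concordant
  one <- two_locus_concordance_and_r2("+/-", "C/T")
  expect_equal(one$n_concordant, 1)
  # EM equals the closed form when no double heterozygotes exist
  ga2 <- c(rep("+/+", 8), rep("-/-", 12), rep("+/-", 0))
  gb2 <- c(rep("C/C", 6), rep("C/T", 2), rep("T/T", 12))
  res2 <- two_locus_concordance_and_r2(ga2, gb2)
  d1 <- c(rep(2, 8), rep(0, 12))
  d2 <- c(rep(2, 6), rep(1, 2), rep(0, 12))
  hAB <- sum((d1 == 2) * d2) / (2 * 20)
  pA <- mean(d1) / 2; pB <- mean(d2) / 2
  D <- hAB - pA * pB
  expect_equal(res2$r2, D^2 / (pA * (1 - pA) * pB * (1 - pB)),
               tolerance = 1e-9)
  # monomorphic locus: r2 undefined
  mono <- two_locus_concordance_and_r2(rep("+/+", 5), rep("C/C", 5))
  expect_true(is.na(mono$r2))
})

test_that("EM r2 recovers the phased-sample value at n = 200", {
  set.seed(1)
  hap <- c(AB = 0.6, Ab = 0.1, aB = 0.05, ab = 0.25)
  n <- 200
  h1 <- sample(names(hap), n, TRUE, hap)
  h2 <- sample(names(hap), n, TRUE, hap)
  d1 <- (substr(h1, 1, 1) == "A") + (substr(h2, 1, 1) == "A")
  d2 <- (substr(h1, 2, 2) == "B") + (substr(h2, 2, 2) == "B")
  geno_a <- c("-/-", "+/-", "+/+")[d1 + 1]
  geno_b <- c("T/T", "C/T", "C/C")[d2 + 1]
  est <- two_locus_concordance_and_r2(geno_a, geno_b)$r2
  ph <- table(factor(c(h1, h2), levels = names(hap))) / (2 * n)
  pA <- ph[[1]] + ph[[2]]; pB <- ph[[1]] + ph[[3]]
  D <- ph[[1]] - pA * pB
  truth <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  expect_lt(abs(est - truth), 0.05)
})

test_that("delta-delta-Cq fold changes", {
  cq <- data.frame(
    condition = rep(c("wild_type", "insertion"), each = 4),
    gene = rep(c("eGFP", "eGFP", "GAPDH", "GAPDH"), 2),
    cq = c(20, 20.2, 18, 18.2, 22.7, 22.9, 18.05, 18.15))
  res <- fold_change_ddcq(cq, "eGFP", "GAPDH", "wild_type")
  expect_equal(res$fold_change[res$condition == "wild_type"], 1)
  # ddCq of +2.68 is a ~6.4-fold reduction
  expect_equal(2^-2.68, 0.156, tolerance = 1e-3)
  ins <- res[res$condition == "insertion", ]
  expect_equal(ins$ddcq, (22.8 - 18.1) - (20.1 - 18.1), tolerance = 1e-9)
  expect_equal(ins$fold_change, 2^-ins$ddcq)
  # doubling
  cq2 <- data.frame(condition = rep(c("a", "b"), each = 2),
                    gene = rep(c("t", "c"), 2), cq = c(10, 10, 9, 10))
  r2 <- fold_change_ddcq(cq2, "t", "c", "a")
  expect_equal(r2$fold_change[r2$condition == "b"], 2)
  expect_error(fold_change_ddcq(cq2[cq2$gene == "t", ], "t", "c", "a"),
               "control")
})
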