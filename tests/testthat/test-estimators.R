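# Linkage, Cre bias, insert number, viability and ratio tests.

test_that("recombinant gamete counting follows maximum parsimony", {
  f9 <- agoc_acos_cross(linked_setup, "F9")  # cis [mO,mCe]/[mC,mVe] parents
  # both gametes parental
  r0 <- count_recombinant_gametes("AGOC(mO/mO); ACOS(mCe/mCe)", f9)
  expect_equal(r0$count, 0)
  expect_false(r0$ambiguous)
  # one recombinant gamete required
  r1 <- count_recombinant_gametes("AGOC(mO/mO); ACOS(mCe/mVe)", f9)
  expect_equal(r1$count, 1)
  expect_false(r1$ambiguous)
  # two recombinant gametes required
  r2 <- count_recombinant_gametes("AGOC(mO/mO); ACOS(mVe/mVe)", f9)
  expect_equal(r2$count, 2)
  expect_false(r2$ambiguous)
  # the double-heterozygote class: parental x parental or double recombinant
  ra <- count_recombinant_gametes("AGOC(mC/mO); ACOS(mCe/mVe)", f9)
  expect_equal(ra$count, 0)
  expect_true(ra$ambiguous)
  expect_equal(ra$counts, c(0, 2))
  # impossible class
  expect_error(count_recombinant_gametes("AGOC(mO/mO)", f9), "impossible")
})

test_that("parsimony counts agree with brute-force gamete-pair enumeration", {
  # independent oracle: enumerate the 4 x 4 origin-labelled gamete pairs of
  # cis [1,1]/[2,2] parents directly, minimizing recombinants per progeny
  # flavor
  f9 <- agoc_acos_cross(linked_setup, "F9")
  gam <- list(list(a = "mO", c = "mCe", rec = 0),  # parental homolog 1
              list(a = "mC", c = "mVe", rec = 0),  # parental homolog 2
              list(a = "mO", c = "mVe", rec = 1),
              list(a = "mC", c = "mCe", rec = 1))
  best <- list()
  for (g1 in gam) for (g2 in gam) {
    key <- paste(paste(sort(c(g1$a, g2$a)), collapse = "/"),
                 paste(sort(c(g1$c, g2$c)), collapse = "/"), sep = "; ")
    rec <- g1$rec + g2$rec
    prev <- best[[key]]
    best[[key]] <- if (is.null(prev)) rec else min(prev, rec)
  }
  for (key in names(best)) {
    parts <- strsplit(key, "; ", fixed = TRUE)[[1]]
    flav <- paste0("AGOC(", parts[1], "); ACOS(", parts[2], ")")
    expect_equal(count_recombinant_gametes(flav, f9)$count, best[[key]],
                 label = flav)
  }
})

test_that("the printed three-repetition worked example reproduces", {
  est <- estimate_linkage(data.frame(recombinant = c(98, 96, 147),
                                     total = c(1248, 1171, 1651)))
  # independent arithmetic on the fractions
  frac <- c(98 / 1248, 96 / 1171, 147 / 1651)
  expect_equal(est$mean_cM, 100 * mean(frac), tolerance = 1e-12)
  expect_equal(est$sd_cM, 100 * sqrt(sum((frac - mean(frac))^2) / 2),
               tolerance = 1e-12)
  expect_equal(round(est$mean_cM, 2), 8.32)
  expect_equal(round(est$sd_cM, 2), 0.54)
})

test_that("degenerate linkage inputs are handled explicitly", {
  one <- estimate_linkage(data.frame(recombinant = 0, total = 1000))
  expect_equal(one$mean_cM, 0)
  expect_true(is.na(one$sd_cM))
  expect_error(estimate_linkage(data.frame(recombinant = numeric(0),
                                           total = numeric(0))),
               "at least one")
  expect_error(estimate_linkage(data.frame(recombinant = 5, total = 0)),
               "> 0")
  expect_error(estimate_linkage(data.frame(recombinant = 11, total = 10)),
               "\\[0, total\\]")
})

test_that("simulated score tables recover the true linkage", {
  for (r_true in c(0.10)) {
    ex <- generate_linkage_experiment(r_true, n_progeny_per_rep = 1000,
                                      repetitions = 3, seed = 5)
    reps <- t(vapply(ex$tables, score_recombination, numeric(2),
                     cross = ex$cross))
    est <- estimate_linkage(as.data.frame(reps))
    # binomial Monte-Carlo SD of the mean plus the parsimony bias bound
    se_cM <- 100 * sqrt(r_true * (1 - r_true) / (2 * 1000)) / sqrt(3)
    bound <- 3 * se_cM + 100 * r_true^2 / 2
    expect_lt(abs(est$mean_cM - 100 * r_true), bound)
    # parsimony never overcounts: estimate cannot exceed truth by more
    # than sampling noise
    expect_lt(est$mean_cM, 100 * r_true + 3 * se_cM)
  }
})

test_that("linkage recovery holds across seeds (parsimony bias bounded)", {
  r_true <- 0.0831
  n <- 700
  for (seed in 0:9) {
    ex <- generate_linkage_experiment(r_true, n, repetitions = 3, seed = seed)
    reps <- t(vapply(ex$tables, score_recombination, numeric(2),
                     cross = ex$cross))
    est <- estimate_linkage(as.data.frame(reps))
    se_cM <- 100 * sqrt(r_true * (1 - r_true) / (2 * n)) / sqrt(3)
    expect_lt(abs(est$mean_cM - 100 * r_true),
              3 * se_cM + 100 * r_true^2 / 2)
  }
})

test_that("Cre bias estimation recovers ratio and beta", {
  cb <- estimate_cre_bias(500, 100)
  expect_equal(cb$ratio, 5)
  expect_equal(cb$beta_hat, 5 / 6, tolerance = 1e-12)
  expect_equal(estimate_cre_bias(100, 100)$beta_hat, 0.5)
  expect_equal(estimate_cre_bias(10, 0)$ratio, Inf)
  expect_error(estimate_cre_bias(0, 0), "positive")

  # recovery from a simulated F4 cross at biased excision
  f4 <- acos_cross(acos_setup, "F4", lx_params(beta = 5 / 6))
  tab <- sample_progeny(f4, 1e4, seed = 9)
  cnt <- function(ph) sum(tab$count[tab$phenotype %in% ph])
  est <- estimate_cre_bias(cnt(c("mCe", "mC,mCe")), cnt(c("mVe", "mC,mVe")))
  expect_equal(est$beta_hat, 5 / 6, tolerance = 0.02)
  expect_equal(est$ratio, 5, tolerance = 0.5)
})

test_that("insert-number classification applies the 60% rule", {
  expect_equal(classify_insert_number(110, 200)$classification, "single")
  expect_equal(classify_insert_number(120, 200)$classification, "single")
  expect_equal(classify_insert_number(121, 200)$classification, "multiple")
  expect_equal(classify_insert_number(200, 200)$classification, "multiple")
  expect_error(classify_insert_number(1, 0), "> 0")
  # expected fractions for k unlinked inserts, cross-checked by enumeration
  expect_equal(expected_marker_fraction(1), 0.5)
  expect_equal(expected_marker_fraction(2), 0.75)
  g <- lx_genome(
    list(lx_chromosome("A"), lx_chromosome("B")),
    list(lx_construct("I1", "A", 10, c("mCe", "mVe")),
         lx_construct("I2", "B", 10, c("mCe", "mVe"))))
  two <- lx_cross(g,
                  lx_genotype(g, "XX", list(al("I1", "DUAL_PRE", 1),
                                            al("I2", "DUAL_PRE", 1))),
                  lx_genotype(g, "XY"))
  p <- class_probability(two, function(gt)
    length(phenotype_of(gt, g)$visible) > 0)
  expect_equal(p, expected_marker_fraction(2), tolerance = 1e-12)
})

test_that("viability classification uses the 0.7085 midpoint threshold", {
  expect_equal(lx_thresholds$viability_min_fraction, 0.7085)
  expect_equal(classify_viability(150, 200)$classification, "viable")   # 75%
  expect_equal(classify_viability(100, 150)$classification, "lethal")   # 66.7%
  expect_equal(classify_viability(141, 200)$classification, "lethal")   # 70.5%
  expect_equal(classify_viability(142, 200)$classification, "viable")   # 71%
  expect_error(classify_viability(1, 0), "> 0")
})

test_that("one-sample t-test matches a textbook closed form", {
  # mean equal to the theoretical ratio: t = 0, p = 1
  r0 <- t_test_vs_theoretical(c(0.24, 0.25, 0.26), 0.25)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_equal(r0$df, 2)
  expect_equal(r0$stars, "ns")

  # df = 2 closed form: P(T > t) = (1 - t / sqrt(t^2 + 2)) / 2
  obs <- c(0.0785256, 0.0819812, 0.0890369)
  rt <- t_test_vs_theoretical(obs, 0.102)
  t_manual <- (mean(obs) - 0.102) / (stats::sd(obs) / sqrt(3))
  p_manual <- 2 * (1 - abs(t_manual) / sqrt(t_manual^2 + 2)) / 2
  expect_equal(rt$t, t_manual, tolerance = 1e-9)
  expect_equal(rt$p, p_manual, tolerance = 1e-6)
  expect_equal(rt$t, -6.08, tolerance = 0.01)
  expect_equal(rt$p, 0.026, tolerance = 0.01)
  expect_equal(rt$stars, "*")

  expect_error(t_test_vs_theoretical(0.25, 0.25), "at least 2")
  expect_error(t_test_vs_theoretical(c(0.3, 0.3), 0.25), "zero variance")
})

test_that("t statistic and p agree with the closed form for df up to 30", {
  set.seed(1)
  for (n in c(3, 5, 10, 31)) {
    obs <- stats::runif(n, 0.2, 0.3)
    rt <- t_test_vs_theoretical(obs, 0.25)
    t_manual <- (mean(obs) - 0.25) / (stats::sd(obs) / sqrt(n))
    p_manual <- 2 * stats::pt(-abs(t_manual), n - 1)
    expect_equal(rt$t, t_manual, tolerance = 1e-9)
    expect_equal(rt$p, p_manual, tolerance = 1e-6)
    expect_equal(rt$df, n - 1)
  }
})

test_that("linked enumeration shifts every class in the parsimony direction", {
  su <- linked_setup
  f9_linked <- agoc_acos_cross(su, "F9")
  f9_free <- agoc_acos_cross(su, "F9",
                             params = lx_params(linkage = list(ChLG9 = 0.5)))
  dl <- progeny_distribution(f9_linked)
  df <- progeny_distribution(f9_free)
  flavors <- unique(df$flavor)
  expect_equal(length(flavors), 9)
  for (fl in flavors) {
    need <- count_recombinant_gametes(fl, f9_linked)$count
    pl <- flavor_prob(dl, fl)
    pf <- flavor_prob(df, fl)
    if (need == 0) expect_gt(pl, pf) else expect_lt(pl, pf)
  }
})
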