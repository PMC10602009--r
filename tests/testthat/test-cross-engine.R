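# Exact progeny enumeration: the oracle for every theoretical ratio.

test_that("heterozygous sibling cross segregates 25/50/25", {
  d <- progeny_distribution(acos_cross(acos_setup, "F6"))
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  expect_equal(flavor_prob(d, "ACOS(mCe/mCe)"), 0.25)
  expect_equal(flavor_prob(d, "ACOS(mCe/mVe)"), 0.50)
  expect_equal(flavor_prob(d, "ACOS(mVe/mVe)"), 0.25)
})

test_that("wild-type cross yields a single certain class", {
  g <- acos_setup$genome
  wt <- lx_cross(g, lx_genotype(g, "XX"), lx_genotype(g, "XY"))
  d <- progeny_distribution(wt)
  expect_equal(unique(d$flavor), "wildtype")
  expect_equal(sum(d$prob), 1)
  expect_equal(distinct_genotype_count(wt), 1)
  ph <- phenotype_distribution(wt)
  expect_equal(ph$phenotype, "-")
  expect_equal(ph$prob, 1)
})

test_that("F4 cross splits the construct evenly into its flavors at beta 0.5", {
  ph <- phenotype_distribution(acos_cross(acos_setup, "F4"))
  expect_equal(ph$prob[ph$phenotype == "mCe"], 0.125)
  expect_equal(ph$prob[ph$phenotype == "mVe"], 0.125)
  expect_equal(ph$prob[ph$phenotype == "mC,mCe"], 0.125)
  expect_equal(ph$prob[ph$phenotype == "mC,mVe"], 0.125)
  expect_equal(sum(ph$prob), 1, tolerance = 1e-12)
})

test_that("unlinked double-hemizygote cross yields 16 classes at 6.25%", {
  f8 <- agoc_acos_cross(unlinked_setup, "F8")
  expect_equal(distinct_genotype_count(f8), 16)
  d <- progeny_distribution(f8)
  fl <- tapply(d$prob, d$flavor, sum)
  expect_equal(as.numeric(fl), rep(0.0625, 16), tolerance = 1e-12)
  # the (mC; mCe) double-hemizygote class specifically
  p <- class_probability(f8, function(g) {
    ph <- phenotype_of(g, unlinked_setup$genome)
    identical(ph$visible, c("mC", "mCe"))
  })
  expect_equal(p, 0.0625)
})

test_that("double-heterozygous sibling cross gives 6.25% per double homozygote", {
  f9 <- agoc_acos_cross(unlinked_setup, "F9")
  g <- unlinked_setup$genome
  p <- class_probability(f9, function(gt) {
    za <- zygosity(gt, "AGOC", g)
    zc <- zygosity(gt, "ACOS", g)
    za$class == "homozygous" && za$states[1] == "FIRST_ONLY" &&
      zc$class == "homozygous" && zc$states[1] == "FIRST_ONLY"
  })
  expect_equal(p, 0.0625)
  # all four double-homozygous flavors arise
  d <- progeny_distribution(f9)
  dh <- unique(d$flavor[grepl("AGOC\\((mO/mO|mC/mC)\\)", d$flavor) &
                          grepl("ACOS\\((mCe/mCe|mVe/mVe)\\)", d$flavor)])
  expect_equal(length(dh), 4)
  expect_equal(class_probability(f9, function(gt) TRUE), 1)
})

test_that("linked F8 double-heterozygote class needs two recombinant gametes", {
  f8 <- agoc_acos_cross(linked_setup, "F8")
  r <- 0.0831
  d <- progeny_distribution(f8)
  p_dbl <- sum(d$prob[d$phenotype == "mC,mCe,mO,mVe"])
  expect_equal(p_dbl, (r / 2)^2, tolerance = 1e-12)
  # only the cis arrangement arises
  expect_equal(unique(d$genotype[d$phenotype == "mC,mCe,mO,mVe"]),
               "ChLG9[mC+mVe/mO+mCe]")

  # independent oracle: brute-force enumeration of the 4 x 4 gamete pairings
  # of trans parents [mO]/[mCe] x [mC]/[mVe] with plain arithmetic
  gametes <- function() list(
    list(set = c("mO"), p = (1 - r) / 2),
    list(set = c("mCe"), p = (1 - r) / 2),
    list(set = c("mO", "mCe"), p = r / 2),
    list(set = character(0), p = r / 2))
  gametes_f <- function() list(
    list(set = c("mC"), p = (1 - r) / 2),
    list(set = c("mVe"), p = (1 - r) / 2),
    list(set = c("mC", "mVe"), p = r / 2),
    list(set = character(0), p = r / 2))
  p_brute <- 0
  for (gm in gametes()) for (gf in gametes_f()) {
    if (setequal(c(gm$set, gf$set), c("mO", "mC", "mCe", "mVe")))
      p_brute <- p_brute + gm$p * gf$p
  }
  expect_equal(p_dbl, p_brute, tolerance = 1e-12)
})

test_that("lethality zeroes homozygous classes and renormalizes the rest", {
  hs <- hemizygote_sibling_cross(acos_lethal_setup$genome, "ACOS")
  raw <- progeny_distribution(hs, apply_lethality = FALSE)
  flt <- progeny_distribution(hs, apply_lethality = TRUE)
  expect_equal(sum(raw$prob), 1, tolerance = 1e-12)
  expect_equal(sum(flt$prob), 1, tolerance = 1e-12)
  expect_false(any(grepl("ACOS\\(mCe-mVe/mCe-mVe\\)", flt$flavor)))
  # survivors scale by 1 / total surviving mass (3/4)
  surv_mass <- sum(raw$prob[raw$flavor %in% flt$flavor])
  for (fl in unique(flt$flavor))
    expect_equal(flavor_prob(flt, fl), flavor_prob(raw, fl) / surv_mass,
                 tolerance = 1e-12)
  # marker-positive fraction among survivors is 2/3
  ph <- phenotype_distribution(hs, apply_lethality = TRUE)
  expect_equal(ph$prob[ph$phenotype == "mCe,mVe"], 2 / 3, tolerance = 1e-12)
})

test_that("viable hemizygote sibling cross shows 75% marker-positive", {
  hs <- hemizygote_sibling_cross(acos_setup$genome, "ACOS")
  ph <- phenotype_distribution(hs)
  expect_equal(ph$prob[ph$phenotype == "mCe,mVe"], 0.75)
})

test_that("swapping parents leaves autosomal progeny unchanged; X obeys sex linkage", {
  su <- unlinked_setup
  g <- su$genome
  f8 <- agoc_acos_cross(su, "F8")
  rev8 <- lx_cross(g,
                   lx_genotype(g, "XX", list(al("AGOC", "SECOND_ONLY", 1),
                                             al("ACOS", "SECOND_ONLY", 2))),
                   lx_genotype(g, "XY", list(al("AGOC", "FIRST_ONLY", 1),
                                             al("ACOS", "FIRST_ONLY", 2))))
  d1 <- progeny_distribution(f8)
  d2 <- progeny_distribution(rev8)
  agg <- function(d) {
    x <- tapply(d$prob, d$flavor, sum)
    x[order(names(x))]
  }
  expect_equal(agg(d1), agg(d2), tolerance = 1e-12)

  # X-linked helper passes from father to daughters only
  f3 <- acos_cross(acos_setup, "F3")
  d3 <- progeny_distribution(f3)
  expect_true(all(d3$sex[grepl("FIRE", d3$flavor)] == "XX"))
  expect_equal(sum(d3$prob[grepl("FIRE", d3$flavor)]), 0.5, tolerance = 1e-12)
})

test_that("expected ratio table is consistent, sorted and sums to 100", {
  tab <- expected_ratio_table(acos_cross(acos_setup, "F6"))
  expect_equal(sum(tab$theoretical_percent), 100)
  expect_equal(tab$theoretical_percent, c(50, 25, 25))
  tab8 <- expected_ratio_table(agoc_acos_cross(unlinked_setup, "F8"),
                               level = "genotype")
  expect_equal(nrow(tab8), 16)
  expect_equal(unique(tab8$theoretical_percent), 6.25)
})
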