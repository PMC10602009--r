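# Stochastic sampling and the two mating procedures.

test_that("sample_progeny is reproducible and respects lethality", {
  f6 <- acos_cross(acos_setup, "F6")
  t1 <- sample_progeny(f6, 500, seed = 11)
  t2 <- sample_progeny(f6, 500, seed = 11)
  expect_identical(t1, t2)
  expect_equal(sum(t1$count), 500)

  expect_equal(nrow(sample_progeny(f6, 0, seed = 1)), 0)

  # lethal construct: homozygotes are conceived but never scored
  hs <- hemizygote_sibling_cross(acos_lethal_setup$genome, "ACOS")
  tl <- sample_progeny(hs, 3000, seed = 4)
  expect_lt(sum(tl$count), 3000)
  gc <- attr(tl, "genotype_counts")
  expect_false(any(grepl("mCe-mVe/mCe-mVe", gc$flavor)))
  frac <- sum(tl$count[tl$phenotype == "mCe,mVe"]) / sum(tl$count)
  expect_equal(frac, 2 / 3, tolerance = 0.05)
})

test_that("large samples concentrate on the enumerated phenotype ratios", {
  f6 <- acos_cross(acos_setup, "F6")
  tab <- sample_progeny(f6, 1e6, seed = 2)
  frac <- tab$count / sum(tab$count)
  names(frac) <- tab$phenotype
  expect_equal(unname(frac["mCe"]), 0.25, tolerance = 0.005)
  expect_equal(unname(frac["mCe,mVe"]), 0.50, tolerance = 0.005)
  expect_equal(unname(frac["mVe"]), 0.25, tolerance = 0.005)
})

test_that("10^6-draw samples stay within 0.005 total variation of enumeration", {
  for (cross in canonical_crosses()) {
    expected <- phenotype_distribution(cross, apply_lethality = TRUE)
    tab <- sample_progeny(cross, 1e6, seed = 1)
    counts <- numeric(nrow(expected))
    counts[match(tab$phenotype, expected$phenotype)] <- tab$count
    tv <- sum(abs(counts / sum(counts) - expected$prob)) / 2
    expect_lt(tv, 0.005)
  }
})

test_that("sampled frequencies fit the enumeration (chi-square, seeds 0-9)", {
  crosses <- canonical_crosses()[c("F4", "F9_linked")]
  for (cross in crosses) {
    expected <- phenotype_distribution(cross, apply_lethality = TRUE)
    for (seed in 0:9) {
      tab <- sample_progeny(cross, 1e5, seed = seed)
      counts <- expected$prob * 0
      m <- match(tab$phenotype, expected$phenotype)
      counts[m] <- tab$count
      gof <- suppressWarnings(stats::chisq.test(counts, p = expected$prob))
      expect_gt(gof$p.value, 0.001)
    }
  }
})

test_that("viable single-transgene procedure completes with both flavors", {
  su <- acos_setup
  res <- run_acos_procedure(su$genome, su$acos, su$helper, lx_params(),
                            n_per_cross = 200, seed = 3)
  expect_equal(res$status, "completed")
  expect_equal(sort(unname(unlist(res$cultures))),
               c("ACOS(mCe/mCe)", "ACOS(mVe/mVe)"))
  expect_equal(names(res$steps), c("F3", "F4", "F5", "F6"))
  # determinism contract
  res2 <- run_acos_procedure(su$genome, su$acos, su$helper, lx_params(),
                             n_per_cross = 200, seed = 3)
  expect_identical(res, res2)
})

test_that("homozygous-lethal construct aborts at the homozygote selection", {
  su <- acos_lethal_setup
  res <- run_acos_procedure(su$genome, su$acos, su$helper, lx_params(),
                            n_per_cross = 200, seed = 3)
  expect_equal(res$status, "aborted")
  expect_equal(res$aborted_step, "F7")
  expect_match(res$reason, "lack of suitable progeny")
})

test_that("misconfigured single-transgene scheme raises configuration errors", {
  su <- acos_setup
  expect_error(run_acos_procedure(su$genome, "FIRE", "FIRE"),
               "configuration error")
  expect_error(run_acos_procedure(su$genome, "ACOS", "ACOS"),
               "configuration error")
})

test_that("unlinked double-transgene procedure yields all four F10 flavors", {
  su <- unlinked_setup
  res <- run_agoc_acos_procedure(su$genome, su$agoc, su$acos, su$params,
                                 n_per_cross = 400, seed = 8)
  expect_equal(res$status, "completed")
  expect_equal(length(res$cultures), 4)
  expect_setequal(unname(unlist(res$cultures)),
                  c("AGOC(mO/mO); ACOS(mCe/mCe)",
                    "AGOC(mO/mO); ACOS(mVe/mVe)",
                    "AGOC(mC/mC); ACOS(mCe/mCe)",
                    "AGOC(mC/mC); ACOS(mVe/mVe)"))
})

test_that("X-linked variant completes with double-homozygous females", {
  su <- xlinked_setup
  res <- run_agoc_acos_procedure(su$genome, su$agoc, su$acos, su$params,
                                 n_per_cross = 400, seed = 8)
  expect_equal(res$status, "completed")
  expect_equal(names(res$steps), c("F7a", "F7b", "F8a", "F8b", "F9a", "F9b"))
  expect_equal(length(res$cultures), 4)
})

test_that("tight linkage with modest broods aborts at the F9 selection", {
  su <- linked_setup  # 8.31 cM: expected double-het count 100*(r/2)^2 < 1
  res <- run_agoc_acos_procedure(su$genome, su$agoc, su$acos, su$params,
                                 n_per_cross = 100, seed = 8)
  expect_equal(res$status, "aborted")
  expect_equal(res$aborted_step, "F9")
})

test_that("procedure selections rely on phenotype-resolvable classes only", {
  # every selection target of a completed run resolves uniquely from
  # phenotype + sex + cross context alone
  su <- acos_setup
  res <- run_acos_procedure(su$genome, su$acos, su$helper, lx_params(),
                            n_per_cross = 300, seed = 12)
  expect_equal(res$status, "completed")
  checks <- list(
    list(cross = acos_cross(su, "F3"), ph = c("mC", "mCe", "mVe"), sex = "XX"),
    list(cross = acos_cross(su, "F4"), ph = "mCe", sex = "XX"),
    list(cross = acos_cross(su, "F4"), ph = "mVe", sex = "XY"),
    list(cross = acos_cross(su, "F5"), ph = c("mCe", "mVe"), sex = "XX"),
    list(cross = acos_cross(su, "F6"), ph = "mCe", sex = "XX"),
    list(cross = acos_cross(su, "F6"), ph = "mVe", sex = "XY"))
  for (ck in checks) {
    r <- resolve_genotypes(ck$ph, ck$cross, sex = ck$sex)
    expect_true(r$unique, label = paste(ck$cross$id, phenotype_string(ck$ph)))
  }
})

test_that("score tables from procedures bind into one well-formed table", {
  su <- acos_setup
  res <- run_acos_procedure(su$genome, su$acos, su$helper, lx_params(),
                            n_per_cross = 150, seed = 1)
  tab <- procedure_score_tables(res)
  expect_true(all(c("cross_id", "generation", "phenotype", "count") %in%
                    names(tab)))
  expect_setequal(unique(tab$cross_id), c("F3", "F4", "F5", "F6"))
  expect_true(all(tab$count >= 0))
})
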