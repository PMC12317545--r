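test_that("trait derivation follows the printed definitions", {
  rec <- data.frame(
    genotype_id = "G1", treatment = "HP", replicate = 1,
    trait = c("P_conc", "SDW", "RDW", "SFW", "RFW", "TFW", "TDW"),
    value = c(200, 1.5, 0.6, 10, 4, 2, 0.3)
  )
  out <- phenoRecords(deriveTraits(PhenotypeTable(rec)))
  val <- function(tr) out$value[out$trait == tr]
  expect_equal(val("Pupt"), 200 * 1.5 / 100)    # 3 mg per plant
  expect_equal(val("PUE"), 1.5 / 3)             # 0.5 g per mg
  expect_equal(val("RS_ratio"), 0.6 / 1.5)
  expect_equal(val("TotalFW"), 10 + 4 + 2)
  expect_equal(val("TotalDW"), 1.5 + 0.6 + 0.3)
})

test_that("division guards flag records missing instead of infinite", {
  rec <- data.frame(
    genotype_id = c("G1", "G1", "G2", "G2", "G2"),
    treatment = "HP", replicate = 1,
    trait = c("P_conc", "SDW", "P_conc", "SDW", "RDW"),
    value = c(0, 1.5, 250, 0, 0.4)
  )
  out <- phenoRecords(deriveTraits(PhenotypeTable(rec)))
  expect_equal(out$value[out$trait == "Pupt" & out$genotype_id == "G1"], 0)
  expect_true(is.na(out$value[out$trait == "PUE" & out$genotype_id == "G1"]))
  expect_true(is.na(out$value[out$trait == "RS_ratio" &
                                out$genotype_id == "G2"]))
  expect_warning(deriveTraits(PhenotypeTable(rbind(
    rec, data.frame(genotype_id = "G1", treatment = "HP", replicate = 1,
                    trait = "Pupt", value = 9)))), "overwriting")
})

test_that("PUE times P_conc is 100 wherever both are defined", {
  sim <- simulatePhenotypes(phenoSimConfig(n_genotypes = 40, seed = 21))
  out <- phenoRecords(deriveTraits(sim$phenotypes))
  keys <- c("genotype_id", "treatment", "replicate")
  both <- merge(out[out$trait == "PUE", c(keys, "value")],
                out[out$trait == "P_conc", c(keys, "value")], by = keys,
                suffixes = c("_pue", "_pconc"))
  ok <- !is.na(both$value_pue) & !is.na(both$value_pconc)
  expect_gt(sum(ok), 0)
  expect_equal(both$value_pue[ok] * both$value_pconc[ok],
               rep(100, sum(ok)))
})

test_that("genotype means average the non-missing replicates", {
  rec <- data.frame(
    genotype_id = c("G1", "G1", "G2", "G2", "G3", "G3"),
    treatment = "HP", replicate = rep(1:2, 3), trait = "SDW",
    value = c(1, 3, 2, NA, NA, NA)
  )
  m <- genotypeMeans(PhenotypeTable(rec))
  expect_equal(m$mean[m$genotype_id == "G1"], 2)
  expect_equal(m$n_reps[m$genotype_id == "G1"], 2L)
  expect_equal(m$mean[m$genotype_id == "G2"], 2)
  expect_equal(m$n_reps[m$genotype_id == "G2"], 1L)
  expect_false("G3" %in% m$genotype_id)   # no non-missing replicate

  sim <- simulatePhenotypes(phenoSimConfig(n_genotypes = 30, seed = 3))
  mm <- genotypeMeans(sim$phenotypes)
  expect_true(all(table(mm$trait) == 30 * 2))
})

test_that("descriptive statistics summarize genotype means", {
  m <- data.frame(genotype_id = c("G1", "G2", "G3"), treatment = "HP",
                  trait = "SDW", mean = c(1, 2, 3), n_reps = 2L)
  d <- descriptiveStats(m)
  expect_equal(unlist(d[c("min", "mean", "max", "sd")], use.names = FALSE),
               c(1, 2, 3, 1))
  m$mean <- 5
  expect_equal(descriptiveStats(m)$sd, 0)
  expect_error(descriptiveStats(m[1, ]), "fewer than 2")
})

test_that("two-way ANOVA reproduces the hand-enumerated partition", {
  a <- anovaTwoWay(anovaExampleTable(), "SDW")
  expect_equal(a$msq_re, 0)
  expect_equal(a$terms$ss[a$terms$term == "GxT"], 0)
  expect_equal(a$msq_g, 2)
  expect_equal(a$terms$df[a$terms$term == "G"], 1)
  expect_equal(a$terms$ss[a$terms$term == "T"], 8)

  # against the explicit enumeration oracle on random balanced fixtures
  for (s in 1:5) {
    tab <- randomBalancedTable(n_g = 5, n_r = 3, seed = s)
    a <- anovaTwoWay(tab, "SDW")
    o <- anovaOracle(phenoRecords(tab))
    expect_equal(a$terms$ss[a$terms$term == "G"], o$ss_g)
    expect_equal(a$terms$ss[a$terms$term == "T"], o$ss_t)
    expect_equal(a$terms$ss[a$terms$term == "E"], o$ss_e)
    expect_equal(a$terms$ss[a$terms$term == "GxT"], o$ss_gt)
    expect_equal(a$terms$ss[a$terms$term == "Residual"], o$ss_res)
    expect_equal(sum(a$terms$ss), o$ss_tot)
  }
})

test_that("degenerate and unbalanced ANOVA inputs are handled", {
  tab <- anovaExampleTable()
  rec <- phenoRecords(tab)
  rec$value <- 1
  a <- anovaTwoWay(PhenotypeTable(rec), "SDW")
  expect_true(all(a$terms$ss == 0))
  expect_true(all(is.na(a$terms$f[a$terms$term != "Residual"])))

  unbal <- PhenotypeTable(rec[-1, ])
  expect_error(anovaTwoWay(unbal, "SDW"), "balanced")
})

test_that("variance components and heritability follow the printed formulas", {
  a <- structure(list(trait = "x", msq_g = 1.0, msq_gt = 0.4, msq_re = 0.2,
                      n_treatments = 2L, n_replicates = 2L),
                 class = "AnovaResult")
  v <- varianceComponents(a)
  expect_equal(v$sigma2_g, 0.15)
  expect_equal(v$sigma2_gt, 0.10)
  expect_equal(v$sigma2_re, 0.20)
  expect_equal(v$sigma2_p, 0.25)
  expect_equal(v$h2_bs, 0.60)

  a$msq_g <- a$msq_gt   # boundary: no genotypic variance
  v <- varianceComponents(a)
  expect_equal(v$sigma2_g, 0)
  expect_equal(v$h2_bs, 0)

  a$msq_gt <- 0.05      # negative raw interaction component is clamped
  v <- varianceComponents(a)
  expect_equal(v$sigma2_gt, 0)
  expect_lt(v$raw$sigma2_gt, 0)
  expect_true(v$h2_bs >= 0 && v$h2_bs <= 1)

  expect_error(varianceComponents(a, T = 1, R = 2), "T >= 2")
})

test_that("heritability estimates recover the simulated truth", {
  # single-trait panels at true H2 = 0.6
  tt <- data.frame(trait = "SDW", mean_HP = 1.5, mean_LP = 0.5,
                   sd_g = sqrt(0.6 / 0.4 * (0.25^2 / 2 + 0.5^2 / 4)),
                   sd_gt = 0.25, sd_re = 0.5)
  h2 <- vapply(1:40, function(s) {
    sim <- simulatePhenotypes(phenoSimConfig(n_genotypes = 100, traits = tt,
                                             seed = s))
    varianceComponents(anovaTwoWay(sim$phenotypes, "SDW"))$h2_bs
  }, numeric(1))
  expect_lt(abs(mean(h2) - 0.6), 0.05)
})

test_that("HP-to-LP change metrics use the stated sign convention", {
  m <- data.frame(genotype_id = rep(c("G1", "G2", "G3"), each = 2),
                  treatment = rep(c("HP", "LP"), 3), trait = "SDW",
                  mean = c(2, 1, 1, 1.2, 0, 0.5), n_reps = 2L)
  cm <- changeMetrics(m, "SDW")
  per <- cm$per_genotype
  expect_equal(per$delta[per$genotype_id == "G1"], 1)
  expect_equal(per$pct_reduction[per$genotype_id == "G1"], 50)
  expect_equal(per$pct_reduction[per$genotype_id == "G2"], -20)
  expect_true(is.na(per$pct_reduction[per$genotype_id == "G3"]))
  expect_equal(cm$summary$n_increased_lp, 2L)
  expect_equal(cm$summary$mean_pct_reduction, mean(c(50, -20)))
  rm <- changeMetrics(m, "SDW", summary_method = "ratio_of_means")
  expect_equal(rm$summary$mean_pct_reduction, 100 * (3 - 2.7) / 3)
})
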