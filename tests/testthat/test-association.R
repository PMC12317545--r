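test_that("marker QC applies strict call-rate-then-MAF filtering", {
  # 20 samples x 6 markers, hand-enumerated:
  #  m1: call rate 16/20 = 0.80  -> removed (call rate)
  #  m2: call rate 17/20 = 0.85  -> kept (boundary is strict 'lower than')
  #  m3: monomorphic, MAF 0      -> removed (MAF)
  #  m4: 2 alt alleles / 40, MAF 0.05 -> kept (boundary)
  #  m5: 1 alt allele / 40, MAF 0.025 -> removed (MAF)
  #  m6: common, MAF 0.5         -> kept
  d <- cbind(
    m1 = c(rep(NA, 4), rep(1, 16)),
    m2 = c(rep(NA, 3), rep(c(0, 1), length.out = 17)),
    m3 = rep(0, 20),
    m4 = c(2, rep(0, 19)),
    m5 = c(1, rep(0, 19)),
    m6 = rep(c(0, 2), 10)
  )
  g <- tinyGenotypes(unname(d))
  qc <- markerQC(g)
  r <- qc$report
  expect_equal(r$removed_call_rate, 1)
  expect_equal(r$removed_maf, 2)
  expect_equal(r$markers_out, 3)
  expect_equal(r$markers_in, r$markers_out + r$removed_call_rate +
                 r$removed_maf)
  expect_setequal(markerInfo(qc$genotypes)$marker_id,
                  c("m02", "m04", "m06"))
})

test_that("QC bookkeeping reconciles on random panels", {
  for (s in 1:5) {
    sim <- simulateGenotypes(genoSimConfig(n_samples = 40, n_markers = 150,
                                           missing_rate = 0.2, seed = s))
    r <- markerQC(sim$genotypes)$report
    expect_equal(r$markers_in,
                 r$markers_out + r$removed_call_rate + r$removed_maf)
  }
})

test_that("mean imputation preserves the observed column means", {
  g <- tinyGenotypes(matrix(c(0, 2, NA, 1, 1, 1), ncol = 2))
  gi <- imputeMean(g)
  expect_equal(unname(dosage(gi)[, 1]), c(0, 2, 1))
  expect_equal(unname(dosage(gi)[, 2]), c(1, 1, 1))   # untouched

  sim <- simulateGenotypes(genoSimConfig(n_samples = 100, n_markers = 200,
                                         missing_rate = 0.05, seed = 3))
  pre <- colMeans(dosage(sim$genotypes), na.rm = TRUE)
  post <- colMeans(dosage(imputeMean(sim$genotypes)))
  expect_equal(unname(post), unname(pre))

  all_missing <- tinyGenotypes(matrix(c(NA, NA, 0, 1), ncol = 2))
  expect_error(imputeMean(all_missing), "no observed calls")
})

test_that("PC covariates capture simulated structure", {
  sim <- simulateGenotypes(genoSimConfig(n_samples = 60, n_markers = 500,
                                         n_subpop = 2, fst = 0.4,
                                         missing_rate = 0, seed = 2))
  pc <- pcaCovariates(sim$genotypes, n_pc = 3)
  split_sign <- tapply(pc[, 1], sim$truth$subpop$subpop, median)
  expect_true(prod(sign(split_sign)) < 0)
  ev <- attr(pc, "explained_variance")
  expect_true(all(diff(ev) <= 0))
  expect_lte(sum(ev), 1)

  rank1 <- tinyGenotypes(outer(c(0, 1, 2, 1, 0, 2), rep(1, 5)))
  p1 <- pcaCovariates(rank1, n_pc = 1)
  expect_equal(attr(p1, "explained_variance")[1], 1)
  const <- tinyGenotypes(matrix(1, nrow = 6, ncol = 4))
  expect_error(pcaCovariates(const, n_pc = 1), "constant")
})

test_that("the scan reproduces full OLS for the marker coefficient", {
  # 10-sample hand dataset, no covariates: closed-form simple regression
  x <- c(0, 1, 2, 0, 1, 2, 0, 1, 1, 2)
  y <- c(1.0, 1.5, 2.1, 0.9, 1.6, 2.3, 1.2, 1.4, 1.7, 2.0)
  g <- tinyGenotypes(cbind(x))
  rec <- glmScan(g, setNames(y, sampleIds(g)))
  beta_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  res <- y - mean(y) - beta_hat * (x - mean(x))
  se_hat <- sqrt(sum(res^2) / 8 / sum((x - mean(x))^2))
  expect_equal(rec$beta, beta_hat)
  expect_equal(rec$se, se_hat)
  expect_equal(rec$p, 2 * pt(-abs(beta_hat / se_hat), 8))

  # with covariates: must equal lm() on the full model, marker by marker
  set.seed(17)
  d <- matrix(rbinom(30 * 8, 2, 0.4), nrow = 30)
  g <- tinyGenotypes(d)
  covs <- matrix(rnorm(60), ncol = 2)
  yy <- rnorm(30) + 0.5 * d[, 3] + covs %*% c(1, -1)
  rec <- glmScan(g, setNames(as.vector(yy), sampleIds(g)), covariates = covs)
  for (j in c(1, 3, 8)) {
    fit <- summary(lm(yy ~ covs + d[, j]))$coefficients
    expect_equal(rec$beta[j], fit[4, 1])
    expect_equal(rec$se[j], fit[4, 2])
    expect_equal(rec$p[j], fit[4, 4])
  }
})

test_that("scan handles degenerate phenotypes and markers", {
  d <- cbind(c(0, 1, 2, 1, 0, 2, 1, 1), rep(1, 8))
  g <- tinyGenotypes(d)
  rec <- glmScan(g, setNames(rep(3, 8), sampleIds(g)))
  expect_equal(rec$beta[1], 0)
  expect_equal(rec$flag[2], "constant_marker")
  expect_true(is.na(rec$p[2]))
})

test_that("scan statistics are invariant under joint sample permutation", {
  sim <- simulateGenotypes(genoSimConfig(n_samples = 40, n_markers = 100,
                                         missing_rate = 0, seed = 23))
  g <- sim$genotypes
  set.seed(1)
  y <- setNames(rnorm(40) + dosage(g)[, 5], sampleIds(g))
  base <- glmScan(g, y)
  perm <- sample(40)
  gp <- GenotypeMatrix(dosage(g)[perm, ], markerInfo(g),
                       sampleIds = sampleIds(g)[perm])
  permuted <- glmScan(gp, y)
  expect_equal(permuted$beta, base$beta)
  expect_equal(permuted$p, base$p)
})

test_that("Bonferroni control follows the printed threshold rule", {
  expect_equal(bonferroniThreshold(4796), -log10(0.05 / 4796))
  expect_equal(bonferroniThreshold(4796), 4.9819, tolerance = 1e-4)

  rec <- data.frame(p = c(0.05 / 2, 0.01, NA))
  out <- applyBonferroni(rec, alpha = 0.05)
  expect_equal(out$rule$m, 2)
  expect_false(out$records$significant[1])  # p == alpha/M is not significant
  expect_true(out$records$significant[2])
  expect_false(out$records$significant[3])

  # doubling M never turns a non-significant marker significant
  set.seed(2)
  p <- runif(50, 1e-8, 1)
  r1 <- applyBonferroni(data.frame(p = p))$records$significant
  r2 <- applyBonferroni(data.frame(p = rep(p, 2)))$records$significant[1:50]
  expect_true(all(r2 <= r1))
})

test_that("PVE variants match hand arithmetic and the algebraic identity", {
  expect_equal(computePVE(1, 0.1, 0.5, 200, "shim"), 1 / 3)
  expect_equal(computePVE(1, 0.1, 0.5, 200, "as_printed"), 0.25)
  expect_equal(computePVE(0, 0.1, 0.3, 200, "shim"), 0)
  expect_equal(computePVE(0, 0.1, 0.3, 200, "as_printed"), 0)

  # shim variant: the maf factor cancels to beta^2 / (beta^2 + N SE^2)
  set.seed(3)
  beta <- rnorm(20)
  se <- runif(20, 0.01, 1)
  maf <- runif(20, 0.01, 0.5)
  n <- sample(50:500, 20)
  expect_equal(computePVE(beta, se, maf, n, "shim"),
               beta^2 / (beta^2 + n * se^2))

  # strictly increasing in |beta| at fixed SE, maf, N
  pve <- computePVE(seq(0, 3, by = 0.5), 0.2, 0.25, 100)
  expect_true(all(diff(pve) > 0))
  expect_true(all(pve >= 0 & pve <= 1))
  expect_error(computePVE(1, 0.1, 0.6, 100), "maf")
  expect_error(computePVE(1, 0, 0.4, 100), "se_beta")
})

test_that("candidate-gene windows use inclusive 1 Mb interval overlap", {
  genes <- GenomicRanges::GRanges(
    c("1", "1", "2", "1"),
    IRanges::IRanges(start = c(900000, 1050000, 1500000, 1999000),
                     end = c(950000, 1060000, 1600000, 2002000)))
  S4Vectors::mcols(genes)$gene_id <- c("far", "near", "wrongchr", "span")
  S4Vectors::mcols(genes)$description <- ""
  hits <- candidateGenes(list(chrom = "1", pos = 2000000), genes)
  expect_equal(hits$gene_id, c("span", "near"))
  expect_equal(hits$distance_bp[1], 0)    # marker inside the gene
  expect_false("far" %in% hits$gene_id)   # ends 50 kb outside the window
  expect_false("wrongchr" %in% hits$gene_id)
})

test_that("indexed window query agrees with a brute-force scan", {
  set.seed(11)
  n <- 300
  chrom <- sample(c("1", "2", "3"), n, replace = TRUE)
  start <- sample.int(5e6, n)
  genes <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start, start + sample.int(50000, n)))
  S4Vectors::mcols(genes)$gene_id <- sprintf("gene%03d", 1:n)
  S4Vectors::mcols(genes)$description <- ""
  marker <- list(chrom = "2", pos = 2500000)
  got <- candidateGenes(marker, genes, window_bp = 1e6)
  lo <- marker$pos - 1e6
  hi <- marker$pos + 1e6
  brute <- sprintf("gene%03d", which(
    chrom == "2" & start <= hi & GenomicRanges::end(genes) >= lo))
  expect_setequal(got$gene_id, brute)
})
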