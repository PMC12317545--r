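clusterMeansFixture <- function(values, trait = "SDW", treatment = "HP") {
  data.frame(genotype_id = sprintf("G%02d", seq_along(values)),
             treatment = treatment, trait = trait, mean = values,
             n_reps = 2L)
}

test_that("z-standardization centers and scales each column", {
  m <- clusterMeansFixture(c(1, 2, 3))
  z <- standardizeTraits(m, traits = "SDW", treatments = "HP")
  expect_equal(unname(z[, "SDW_HP"]), c(-1, 0, 1))

  expect_warning(
    zc <- standardizeTraits(clusterMeansFixture(c(5, 5, 5)),
                            traits = "SDW", treatments = "HP"),
    "constant")
  expect_equal(unname(zc[, 1]), c(0, 0, 0))

  sim <- simulatePhenotypes(phenoSimConfig(n_genotypes = 25, seed = 14))
  mm <- genotypeMeans(deriveTraits(sim$phenotypes))
  z <- standardizeTraits(mm)
  expect_equal(unname(colMeans(z)), rep(0, ncol(z)), tolerance = 1e-9)
  expect_equal(unname(apply(z, 2, sd)), rep(1, ncol(z)), tolerance = 1e-9)
})

test_that("missing cells are mean-imputed before scaling, with a count", {
  m <- clusterMeansFixture(c(1, 2, 3))
  m <- rbind(m, clusterMeansFixture(c(4, NA, 6), treatment = "LP"))
  z <- suppressWarnings(standardizeTraits(m, traits = "SDW"))
  expect_equal(attr(z, "n_imputed"), 1L)
  expect_equal(unname(z["G02", "SDW_LP"]), 0)  # imputed to the column mean
})

test_that("well-separated groups are recovered at the main cut", {
  z <- rbind(matrix(rnorm(8, 0, 0.01), 4), matrix(rnorm(8, 10, 0.01), 4))
  rownames(z) <- sprintf("G%d", 1:8)
  cl <- clusterGenotypes(z, k_main = 2, k_sub = 2)$assignments
  expect_equal(length(unique(cl$main_cluster[1:4])), 1)
  expect_equal(length(unique(cl$main_cluster[5:8])), 1)
  expect_false(cl$main_cluster[1] == cl$main_cluster[5])

  # duplicate rows always co-cluster
  zdup <- z[c(1, 1, 2, 5, 6, 5), ]
  rownames(zdup) <- sprintf("G%d", 1:6)
  a <- clusterGenotypes(zdup, k_main = 2, k_sub = 2)$assignments
  expect_equal(a$sub_cluster[1], a$sub_cluster[2])
  expect_equal(a$sub_cluster[4], a$sub_cluster[6])
})

test_that("merge heights match a naive agglomeration oracle", {
  set.seed(31)
  z <- matrix(rnorm(20 * 3), nrow = 20)
  rownames(z) <- sprintf("G%02d", 1:20)
  hc <- clusterGenotypes(z, k_main = 2, k_sub = 4)$tree
  expect_equal(sort(hc$height), sort(naiveCompleteLinkageHeights(z)))
})

test_that("the main cut coarsens the sub-cluster partition", {
  set.seed(5)
  z <- matrix(rnorm(40 * 4), nrow = 40)
  rownames(z) <- sprintf("G%02d", 1:40)
  cl <- clusterGenotypes(z, k_main = 2, k_sub = 9)$assignments
  nesting <- table(cl$sub_cluster, cl$main_cluster)
  expect_true(all(rowSums(nesting > 0) == 1))
  expect_equal(length(unique(cl$sub_cluster)), 9)
})

test_that("clustering is order-invariant up to label renaming", {
  set.seed(6)
  z <- matrix(rnorm(30 * 4), nrow = 30)
  rownames(z) <- sprintf("G%02d", 1:30)
  a <- clusterGenotypes(z, k_sub = 5)$assignments
  perm <- sample(nrow(z))
  b <- clusterGenotypes(z[perm, ], k_sub = 5)$assignments
  b <- b[match(a$genotype_id, b$genotype_id), ]
  # same partition: co-membership matrices agree
  expect_identical(outer(a$sub_cluster, a$sub_cluster, "=="),
                   outer(b$sub_cluster, b$sub_cluster, "=="))
})

test_that("cluster mean profiles and performance classes are reproducible", {
  m <- clusterMeansFixture(c(1, 1, 3, 3))
  assign <- data.frame(genotype_id = sprintf("G%02d", 1:4),
                       main_cluster = "A", sub_cluster = c(1, 1, 2, 2))
  cm <- clusterMeans(assign, m, traits = "SDW", treatments = "HP")$cluster_means
  expect_equal(cm$SDW_HP, c(1, 3))
  expect_equal(cm$performance_class, c("worst", "best"))
  expect_equal(cm$n_genotypes, c(2L, 2L))

  single <- clusterMeans(data.frame(genotype_id = sprintf("G%02d", 1:4),
                                    main_cluster = "A", sub_cluster = 1),
                         m, traits = "SDW", treatments = "HP")$cluster_means
  expect_equal(single$performance_class, "intermediate")

  # conservation: size-weighted cluster means reproduce the grand mean
  set.seed(9)
  m2 <- clusterMeansFixture(runif(12, 0, 5))
  assign2 <- data.frame(genotype_id = sprintf("G%02d", 1:12),
                        main_cluster = "A",
                        sub_cluster = rep(1:3, times = c(3, 4, 5)))
  cm2 <- clusterMeans(assign2, m2, traits = "SDW",
                      treatments = "HP")$cluster_means
  expect_equal(sum(cm2$SDW_HP * cm2$n_genotypes) / sum(cm2$n_genotypes),
               mean(m2$mean))
})

test_that("planted performance tiers are recovered by the sub-clusters", {
  hits <- vapply(1:5, function(s) {
    set.seed(s)
    tiers <- rep(1:3, each = 20)
    base <- c(1, 3, 5)[tiers]
    m <- do.call(rbind, lapply(c("SDW", "RDW"), function(tr) {
      do.call(rbind, lapply(c("HP", "LP"), function(tm) {
        data.frame(genotype_id = sprintf("G%02d", 1:60), treatment = tm,
                   trait = tr, mean = base + rnorm(60, 0, 0.3), n_reps = 2L)
      }))
    }))
    z <- standardizeTraits(m, traits = c("SDW", "RDW"))
    cl <- clusterGenotypes(z, k_main = 2, k_sub = 3)
    cm <- clusterMeans(cl, m, traits = c("SDW", "RDW"))$cluster_means
    class_of <- setNames(cm$performance_class, cm$sub_cluster)
    got <- class_of[as.character(cl$assignments$sub_cluster)]
    want <- c("worst", "intermediate", "best")[tiers[
      match(cl$assignments$genotype_id, sprintf("G%02d", 1:60))]]
    mean(got == want)
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})
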