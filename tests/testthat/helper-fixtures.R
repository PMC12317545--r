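# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# minimal long phenotype data.frame: one genotype, both treatments, 2 reps
tinyPhenoRecords <- function() {
  data.frame(
    genotype_id = "G1",
    treatment = rep(c("HP", "LP"), each = 2),
    replicate = rep(1:2, 2),
    trait = "SDW",
    value = c(1.2, 1.4, 0.5, 0.6),
    stringsAsFactors = FALSE
  )
}

# balanced two-genotype fixture from the worked ANOVA example:
# G1: HP {1,1}, LP {3,3}; G2: HP {2,2}, LP {4,4}
anovaExampleTable <- function() {
  PhenotypeTable(data.frame(
    genotype_id = rep(c("G1", "G2"), each = 4),
    treatment = rep(rep(c("HP", "LP"), each = 2), 2),
    replicate = rep(1:2, 4),
    trait = "SDW",
    value = c(1, 1, 3, 3, 2, 2, 4, 4)
  ))
}

# independent sum-of-squares enumeration oracle for the balanced two-way
# design with replicate blocks (never calls aov)
anovaOracle <- function(rec) {
  y <- rec$value
  gbar <- tapply(y, rec$genotype_id, mean)
  tbar <- tapply(y, rec$treatment, mean)
  rbar <- tapply(y, rec$replicate, mean)
  ybar <- mean(y)
  G <- length(gbar); T_ <- length(tbar); R_ <- length(rbar)
  cell <- tapply(y, list(rec$genotype_id, rec$treatment), mean)
  ss_g <- T_ * R_ * sum((gbar - ybar)^2)
  ss_t <- G * R_ * sum((tbar - ybar)^2)
  ss_e <- G * T_ * sum((rbar - ybar)^2)
  ss_gt <- R_ * sum((sweep(sweep(cell, 1, gbar), 2, tbar) + ybar)^2)
  ss_tot <- sum((y - ybar)^2)
  list(ss_g = ss_g, ss_t = ss_t, ss_e = ss_e, ss_gt = ss_gt,
       ss_res = ss_tot - ss_g - ss_t - ss_e - ss_gt, ss_tot = ss_tot)
}

# random balanced phenotype table
randomBalancedTable <- function(n_g = 4, n_r = 2, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(genotype_id = sprintf("G%d", seq_len(n_g)),
                      treatment = c("HP", "LP"), replicate = seq_len(n_r),
                      stringsAsFactors = FALSE)
  grid$trait <- "SDW"
  grid$value <- abs(rnorm(nrow(grid), 2, 1))
  PhenotypeTable(grid)
}

# small genotype matrix from an explicit dosage matrix (samples x markers)
tinyGenotypes <- function(d, chrom = NULL, pos = NULL, ploidy = 2) {
  M <- ncol(d)
  if (is.null(chrom)) chrom <- rep("1", M)
  if (is.null(pos)) pos <- seq_len(M) * 100L
  GenotypeMatrix(
    d,
    data.frame(marker_id = sprintf("m%02d", seq_len(M)), chrom = chrom,
               pos = pos, ref = "A", alt = "C"),
    sampleIds = sprintf("S%02d", seq_len(nrow(d))),
    ploidy = ploidy
  )
}

# hand-written VCF text fixture
writeVcfFixture <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t")
  )
  writeLines(c(header, lines), path)
  path
}

# hand-written GFF3 text fixture
writeGffFixture <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

# naive O(n^3) agglomerative clustering oracle (complete linkage) returning
# the sorted merge heights; independent of stats::hclust
naiveCompleteLinkageHeights <- function(x) {
  d <- as.matrix(dist(x))
  groups <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(groups)) {
      for (j in seq_len(i - 1)) {
        h <- max(d[groups[[i]], groups[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(j, i)
        }
      }
    }
    heights <- c(heights, best_h)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  heights
}
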