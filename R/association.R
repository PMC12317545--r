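#' Marker quality control
#'
#' Filters a dosage panel in two ordered steps: (1) markers with a call rate
#' (fraction of non-missing calls) *lower than* `call_rate_min` are
#' discarded; (2) among the survivors, markers with a folded minor allele
#' frequency *lower than* `maf_min` are discarded. Both thresholds are
#' strict — a marker exactly at the threshold is kept — and each marker is
#' counted in at most one removal bin, so the report always reconciles:
#' `markers_in = markers_out + removed_call_rate + removed_maf`.
#'
#' @param g a [GenotypeMatrix].
#' @param call_rate_min minimum call rate (default 0.85).
#' @param maf_min minimum MAF over non-missing calls (default 0.05).
#' @return list with `genotypes` (filtered [GenotypeMatrix]) and `report`
#'   (list `markers_in`, `removed_call_rate`, `removed_maf`, `markers_out`,
#'   `call_rate_min`, `maf_min`).
#' @export
markerQC <- function(g, call_rate_min = 0.85, maf_min = 0.05) {
  stopifnot(is(g, "GenotypeMatrix"))
  d <- dosage(g)
  call_rate <- colMeans(!is.na(d))
  low_cr <- call_rate < call_rate_min
  maf <- .foldedMaf(d, ploidy(g))
  low_maf <- !low_cr & (is.na(maf) | maf < maf_min)
  keep <- !low_cr & !low_maf
  if (!any(keep)) .stopf("no markers retained after QC")
  out <- g[keep, ]
  report <- list(markers_in = ncol(d),
                 removed_call_rate = sum(low_cr),
                 removed_maf = sum(low_maf),
                 markers_out = sum(keep),
                 call_rate_min = call_rate_min, maf_min = maf_min)
  list(genotypes = out, report = report)
}

#' Mean-dosage imputation
#'
#' Replaces every missing call by the marker's mean dosage over non-missing
#' samples, leaving the non-missing column means unchanged. Intended for the
#' post-QC matrix; a marker with no observed call at all cannot be imputed
#' and raises an error.
#'
#' @param g a [GenotypeMatrix].
#' @return a [GenotypeMatrix] without missing cells (dosages may be
#'   fractional).
#' @export
imputeMean <- function(g) {
  stopifnot(is(g, "GenotypeMatrix"))
  d <- dosage(g)
  n_ok <- colSums(!is.na(d))
  if (any(n_ok == 0)) {
    .stopf("%d marker(s) have no observed calls; run markerQC first",
           sum(n_ok == 0))
  }
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- mu[idx[, 2]]
  GenotypeMatrix(d, markerInfo(g), sampleIds = sampleIds(g),
                 ploidy = ploidy(g))
}

#' Principal-component covariates for structure control
#'
#' PCA of the centered (optionally scaled) imputed dosage matrix. The
#' leading component scores serve as covariates in the association scan to
#' absorb population stratification.
#'
#' @param g an imputed [GenotypeMatrix].
#' @param n_pc number of components to return (default 3).
#' @param scale also scale markers to unit variance (default FALSE).
#' @return samples x `n_pc` score matrix with attribute
#'   `explained_variance` (fractions, non-increasing).
#' @export
pcaCovariates <- function(g, n_pc = 3, scale = FALSE) {
  stopifnot(is(g, "GenotypeMatrix"))
  d <- dosage(g)
  if (anyNA(d)) .stopf("impute the matrix before PCA (see imputeMean)")
  if (n_pc >= min(dim(d))) .stopf("n_pc must be < min(samples, markers)")
  v <- apply(d, 2, sd)
  if (all(v == 0)) .stopf("constant dosage matrix; PCA undefined")
  if (scale) d <- d[, v > 0, drop = FALSE]
  pc <- prcomp(d, center = TRUE, scale. = scale)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  rownames(scores) <- sampleIds(g)
  attr(scores, "explained_variance") <- ev[seq_len(n_pc)]
  scores
}

#' Single-marker least-squares association scan
#'
#' Per marker, ordinary least squares of the phenotype on (intercept,
#' covariates, dosage); the dosage coefficient's estimate, standard error
#' and two-sided t-test p-value are reported. Computation uses
#' Frisch–Waugh residualization on the covariate block, which reproduces
#' the full-model OLS marker coefficient exactly and keeps the scan
#' vectorized over markers. Samples with missing phenotype are dropped;
#' markers that are constant after imputation get a missing p-value and a
#' `"constant_marker"` flag. The per-marker MAF (folded, over the samples
#' scanned) and sample size are recorded for downstream PVE estimation.
#'
#' @param g an imputed [GenotypeMatrix].
#' @param y named numeric vector of per-sample trait values (names matched
#'   against `sampleIds(g)`; an unnamed vector must align with the sample
#'   order).
#' @param covariates optional samples x q covariate matrix (e.g. from
#'   [pcaCovariates()]).
#' @return data.frame of association records: `marker_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `beta`, `se`, `p`, `maf`, `n`, `flag`.
#' @export
glmScan <- function(g, y, covariates = NULL) {
  stopifnot(is(g, "GenotypeMatrix"))
  d <- dosage(g)
  if (anyNA(d)) .stopf("impute the genotype matrix before scanning")
  if (!is.null(names(y))) {
    y <- y[sampleIds(g)]
  } else if (length(y) != nSamples(g)) {
    .stopf("y has %d values for %d samples", length(y), nSamples(g))
  }
  ok <- !is.na(y)
  y <- as.numeric(y[ok])
  d <- d[ok, , drop = FALSE]
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)[ok, , drop = FALSE]
  }
  n <- length(y)
  q <- 1L + if (is.null(covariates)) 0L else ncol(covariates)
  if (n < q + 3L) .stopf("too few samples (%d) for %d covariates", n, q - 1L)
  Z <- cbind(rep(1, n), covariates)
  Q <- qr.Q(qr(Z))
  ry <- y - Q %*% crossprod(Q, y)
  rX <- d - Q %*% crossprod(Q, d)
  rxx <- colSums(rX^2)
  rxy <- as.vector(crossprod(rX, ry))
  ryy <- sum(ry^2)
  df <- n - q - 1L
  # markers constant across the scanned samples (or numerically collinear
  # with the covariates) carry no contrast
  xconst <- apply(d, 2, function(v) max(v) == min(v)) |
    rxx < sqrt(.Machine$double.eps)
  beta <- ifelse(!xconst, rxy / rxx, NA_real_)
  rss <- ryy - ifelse(!xconst, rxy^2 / rxx, 0)
  sigma2 <- pmax(rss, 0) / df
  se <- ifelse(!xconst, sqrt(sigma2 / rxx), NA_real_)
  tstat <- ifelse(!is.na(se) & se > 0, beta / se, NA_real_)
  p <- 2 * pt(-abs(tstat), df)
  # a constant phenotype carries no signal: report zero effects, not NA
  if (ryy < sqrt(.Machine$double.eps) * max(1, mean(y)^2)) {
    beta[!xconst] <- 0
    p[!xconst] <- NA_real_
  }
  mi <- markerInfo(g)
  data.frame(marker_id = mi$marker_id, chrom = mi$chrom, pos = mi$pos,
             ref = mi$ref, alt = mi$alt, beta = beta, se = se, p = p,
             maf = .foldedMaf(d, ploidy(g)), n = n,
             flag = ifelse(!xconst, "", "constant_marker"),
             stringsAsFactors = FALSE)
}

#' Bonferroni significance threshold
#'
#' `-log10(alpha / M)` for `M` tested markers: the genome-wide threshold on
#' the `-log10(p)` scale (e.g. `M = 4796`, `alpha = 0.05` gives 4.98).
#'
#' @param m number of tested markers.
#' @param alpha family-wise error rate (default 0.05).
#' @return threshold on the `-log10(p)` scale.
#' @export
bonferroniThreshold <- function(m, alpha = 0.05) {
  if (m < 1) .stopf("m must be positive")
  -log10(alpha / m)
}

#' Apply the Bonferroni rule to scan records
#'
#' Flags records with `-log10(p)` strictly above the Bonferroni threshold
#' computed from the number of records with a valid p-value (a marker at
#' exactly `p = alpha / M` is *not* significant).
#'
#' @param records association records from [glmScan()].
#' @param alpha family-wise error rate (default 0.05).
#' @return list with `records` (input plus `significant` column) and `rule`
#'   (list `alpha`, `m`, `threshold_neglog10p`).
#' @export
applyBonferroni <- function(records, alpha = 0.05) {
  m <- sum(!is.na(records$p))
  if (m == 0) .stopf("no valid p-values to threshold")
  thr <- bonferroniThreshold(m, alpha)
  records$significant <- !is.na(records$p) & -log10(records$p) > thr
  list(records = records,
       rule = list(alpha = alpha, m = m, threshold_neglog10p = thr))
}

#' Phenotypic variance explained by a SNP
#'
#' Estimates the fraction of phenotypic variance explained by a marker from
#' its effect estimate `beta`, standard error, folded MAF `f` and sample
#' size `N`. Two variants are provided:
#'
#' * `"shim"` (default): `2 beta^2 f (1-f) / (2 beta^2 f (1-f) +
#'   SE^2 2 N f (1-f))`, the algebraically consistent form in which the
#'   `f(1-f)` factor cancels to `beta^2 / (beta^2 + N SE^2)`;
#' * `"as_printed"`: identical except that the first denominator term is
#'   `2 beta^2 (1-f)` (one MAF factor fewer), kept because that is how the
#'   source formula is commonly typeset.
#'
#' Both return values in `[0, 1]` and 0 when `beta = 0`.
#'
#' @param beta marker effect per alternate-allele copy (trait units).
#' @param se_beta standard error of `beta` (> 0).
#' @param maf folded minor allele frequency in (0, 0.5].
#' @param n sample size (>= 2).
#' @param variant `"shim"` or `"as_printed"`.
#' @return PVE fraction(s) in `[0, 1]` (vectorized over the inputs).
#' @export
computePVE <- function(beta, se_beta, maf, n,
                       variant = c("shim", "as_printed")) {
  variant <- match.arg(variant)
  if (any(maf <= 0 | maf > 0.5, na.rm = TRUE)) {
    .stopf("maf must lie in (0, 0.5]")
  }
  if (any(se_beta <= 0, na.rm = TRUE)) .stopf("se_beta must be > 0")
  if (any(n < 2, na.rm = TRUE)) .stopf("n must be >= 2")
  num <- 2 * beta^2 * maf * (1 - maf)
  first <- if (variant == "shim") 2 * beta^2 * maf * (1 - maf) else
    2 * beta^2 * (1 - maf)
  num / (first + se_beta^2 * 2 * n * maf * (1 - maf))
}

#' Candidate genes around a marker
#'
#' Returns the genes on the marker's chromosome whose span overlaps the
#' inclusive window `[pos - window_bp, pos + window_bp]`, sorted by distance
#' from the marker (0 when the marker lies inside the gene, ties by start
#' coordinate). An empty result is allowed.
#'
#' @param marker one-row data.frame (or list) with `chrom` and `pos`, e.g. a
#'   row of [markerInfo()] or of a scan result.
#' @param genes gene annotation `GRanges` from [readGeneAnnotation()].
#' @param window_bp half-window in bp (default 1e6: 1 Mb up- and
#'   downstream).
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `distance_bp`,
#'   `description`.
#' @export
candidateGenes <- function(marker, genes, window_bp = 1e6) {
  chrom <- as.character(marker$chrom)
  pos <- as.numeric(marker$pos)
  win <- GRanges(chrom, IRanges(max(1, pos - window_bp), pos + window_bp))
  hits <- suppressWarnings(findOverlaps(win, genes))
  g <- genes[S4Vectors::subjectHits(hits)]
  if (!length(g)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      distance_bp = numeric(), description = character(),
                      stringsAsFactors = FALSE))
  }
  snp <- GRanges(chrom, IRanges(pos, pos))
  dist <- suppressWarnings(distance(snp, g))
  out <- data.frame(gene_id = mcols(g)$gene_id,
                    chrom = as.character(seqnames(g)),
                    start = start(g), end = end(g),
                    distance_bp = as.numeric(dist),
                    description = mcols(g)$description,
                    stringsAsFactors = FALSE)
  out <- out[order(out$distance_bp, out$start), ]
  rownames(out) <- NULL
  out
}
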