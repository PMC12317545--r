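#' Default per-trait simulation parameters
#'
#' One row per simulated primary trait with the per-treatment grand means
#' and the genotypic (`sd_g`), genotype-by-treatment (`sd_gt`) and residual
#' (`sd_re`) standard deviations, all in trait units. The defaults emulate a
#' greenhouse pot screen of a potato diversity panel under high-P control
#' (HP) and low-P stress (LP): biomass, height and P-concentration means are
#' markedly lower under LP, and the SDs are sized to give moderate-to-high
#' broad-sense heritabilities (roughly 0.5--0.8). Derived traits (Pupt, PUE,
#' RS_ratio, TotalFW, TotalDW) are never simulated directly; they are
#' computed downstream by [deriveTraits()] so the derivation identities hold
#' exactly.
#'
#' @return data.frame with columns `trait`, `mean_HP`, `mean_LP`, `sd_g`,
#'   `sd_gt`, `sd_re`.
#' @export
defaultTraitParams <- function() {
  data.frame(
    trait   = c("SFW", "SDW", "RFW", "RDW", "TFW", "TDW", "PH1", "PH2",
                "RL", "P_conc"),
    mean_HP = c(14.28, 1.53, 5.76, 0.64, 4.41, 0.52, 4.98, 16.35,
                22.97, 321),
    mean_LP = c(3.66, 0.50, 3.14, 0.38, 2.25, 0.43, 4.93, 11.08,
                19.53, 172),
    sd_g    = c(2.2, 0.26, 1.30, 0.16, 1.30, 0.17, 1.30, 2.80, 2.40, 35),
    sd_gt   = c(1.5, 0.15, 0.90, 0.09, 0.90, 0.12, 0.50, 1.00, 1.40, 20),
    sd_re   = c(1.5, 0.15, 0.90, 0.09, 0.90, 0.12, 0.60, 1.00, 1.50, 18),
    stringsAsFactors = FALSE
  )
}

#' Phenotype simulation configuration
#'
#' @param n_genotypes panel size (default 200).
#' @param n_replicates replicates per genotype x treatment cell (default 2;
#'   at least 2, as the variance-component formulas require).
#' @param traits per-trait parameter table as in [defaultTraitParams()].
#' @param missing_rate fraction of cells randomly deleted to exercise
#'   missing-data handling (default 0 = balanced design).
#' @param seed integer seed; the phenotype noise stream is independent of
#'   the genotype stream.
#' @return a `phenoSimConfig` list.
#' @export
phenoSimConfig <- function(n_genotypes = 200, n_replicates = 2,
                           traits = defaultTraitParams(),
                           missing_rate = 0, seed = 1) {
  traits <- as.data.frame(traits)
  needed <- c("trait", "mean_HP", "mean_LP", "sd_g", "sd_gt", "sd_re")
  miss <- setdiff(needed, names(traits))
  if (length(miss)) .stopf("trait table lacks column(s): %s",
                           paste(miss, collapse = ", "))
  if (n_replicates < 2) .stopf("n_replicates must be >= 2")
  if (any(traits$sd_g < 0 | traits$sd_gt < 0 | traits$sd_re < 0)) {
    .stopf("all simulation SDs must be >= 0")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    .stopf("missing_rate must lie in [0, 1)")
  }
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_replicates = as.integer(n_replicates),
                 treatments = TREATMENTS, traits = traits,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "phenoSimConfig")
}

#' Broad-sense heritability implied by a simulation configuration
#'
#' Closed form for the balanced design: with T treatments and R replicates,
#' `H2 = sd_g^2 / (sd_g^2 + sd_gt^2 / T + sd_re^2 / (T * R))`.
#'
#' @param cfg a [phenoSimConfig()].
#' @return named numeric vector of per-trait true heritabilities.
#' @export
impliedH2 <- function(cfg) {
  tt <- cfg$traits
  T_ <- length(cfg$treatments)
  R_ <- cfg$n_replicates
  h2 <- tt$sd_g^2 / (tt$sd_g^2 + tt$sd_gt^2 / T_ + tt$sd_re^2 / (T_ * R_))
  setNames(h2, tt$trait)
}

#' Genotype simulation configuration
#'
#' Structured SNP panel generator settings. Population structure follows a
#' star-shaped island model: per marker an ancestral frequency
#' `p ~ Uniform(0.05, 0.95)`, subpopulation frequencies
#' `~ Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` (so F acts as a divergence /
#' Fst-like parameter), and dosages `~ Binomial(ploidy, p_subpop)`.
#'
#' @param n_samples samples in the panel (default 200).
#' @param n_markers markers before QC (default 4800).
#' @param n_chromosomes chromosomes the markers are spread over (default 12).
#' @param chrom_length_bp chromosome length in bp (default 7e7).
#' @param n_subpop number of subpopulations K (default 3).
#' @param fst divergence parameter F in (0, 1) (default 0.1).
#' @param missing_rate per-cell missing-call probability (default 0.03).
#' @param ploidy dosage ceiling (default 2, diploidized calls).
#' @param planted_effects optional data.frame of planted marker effects with
#'   columns `marker` (column index into the simulated matrix) or
#'   `marker_id`, `trait`, `beta` (trait units per alternate-allele copy)
#'   and optionally `treatment` (`"HP"`, `"LP"` or `"both"`, the default).
#' @param seed integer seed.
#' @return a `genoSimConfig` list.
#' @export
genoSimConfig <- function(n_samples = 200, n_markers = 4800,
                          n_chromosomes = 12, chrom_length_bp = 7e7,
                          n_subpop = 3, fst = 0.1, missing_rate = 0.03,
                          ploidy = 2, planted_effects = NULL, seed = 1) {
  if (fst <= 0 || fst >= 1) .stopf("fst must lie in (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) {
    .stopf("missing_rate must lie in [0, 1)")
  }
  if (!is.null(planted_effects)) {
    planted_effects <- as.data.frame(planted_effects)
    if (!"trait" %in% names(planted_effects) ||
        !"beta" %in% names(planted_effects)) {
      .stopf("planted_effects needs 'trait' and 'beta' columns")
    }
    if (is.null(planted_effects$treatment)) planted_effects$treatment <- "both"
    if ("marker" %in% names(planted_effects) &&
        any(planted_effects$marker > n_markers | planted_effects$marker < 1)) {
      .stopf("planted marker index outside 1..n_markers")
    }
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_markers = as.integer(n_markers),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = as.numeric(chrom_length_bp),
                 n_subpop = as.integer(n_subpop), fst = fst,
                 missing_rate = missing_rate, ploidy = as.integer(ploidy),
                 planted_effects = planted_effects, seed = as.integer(seed)),
            class = "genoSimConfig")
}

#' Simulate a structured SNP panel
#'
#' Draws a [GenotypeMatrix] under the island model described in
#' [genoSimConfig()], masks calls at the configured missing rate, and
#' returns the full ground truth (subpopulation labels, ancestral and
#' subpopulation allele frequencies, realized minor-allele frequencies).
#' Fully deterministic given `(cfg, cfg$seed)`.
#'
#' @param cfg a [genoSimConfig()].
#' @return `list(genotypes = GenotypeMatrix, truth = list(...))`.
#' @export
simulateGenotypes <- function(cfg) {
  stopifnot(inherits(cfg, "genoSimConfig"))
  set.seed(.childSeed(cfg$seed, 2L))
  M <- cfg$n_markers
  n <- cfg$n_samples
  K <- cfg$n_subpop
  chrom <- sort(rep_len(seq_len(cfg$n_chromosomes), M))
  pos <- unlist(lapply(split(seq_len(M), chrom), function(idx) {
    sort(sample.int(cfg$chrom_length_bp, length(idx)))
  }), use.names = FALSE)
  p_anc <- runif(M, 0.05, 0.95)
  f <- cfg$fst
  sub_freq <- matrix(rbeta(K * M, rep(p_anc, each = K) * (1 - f) / f,
                           rep(1 - p_anc, each = K) * (1 - f) / f),
                     nrow = K)
  subpop <- rep_len(seq_len(K), n)
  P <- sub_freq[subpop, , drop = FALSE]              # n x M success probs
  d <- matrix(rbinom(n * M, cfg$ploidy, as.vector(P)), nrow = n)
  if (cfg$missing_rate > 0) {
    d[runif(n * M) < cfg$missing_rate] <- NA
  }
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, M, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
  markers <- data.frame(
    marker_id = sprintf("loc%d_pos%d", seq_len(M), (pos %% 97L) + 1L),
    chrom = as.character(chrom), pos = pos, ref = ref, alt = unname(alt),
    stringsAsFactors = FALSE
  )
  sample_ids <- sprintf("G%03d", seq_len(n))
  g <- GenotypeMatrix(d, markers, sampleIds = sample_ids,
                      ploidy = cfg$ploidy)
  # realized folded MAF in the sorted marker order
  maf <- .foldedMaf(dosage(g), ploidy(g))
  truth <- list(
    subpop = data.frame(sample_id = sample_ids, subpop = subpop),
    ancestral_freq = setNames(p_anc, markers$marker_id)[markerInfo(g)$marker_id],
    maf_realized = maf,
    seed = cfg$seed
  )
  list(genotypes = g, truth = truth)
}

# Folded minor-allele frequency per marker over non-missing calls.
#' @noRd
.foldedMaf <- function(d, ploidy) {
  n_ok <- colSums(!is.na(d))
  f <- colSums(d, na.rm = TRUE) / (ploidy * pmax(n_ok, 1))
  f[n_ok == 0] <- NA
  pmin(f, 1 - f)
}

#' Simulate a phenotype panel with known ground truth
#'
#' Draws a balanced phenotype table under the two-way model
#' `value = mu_t + g_i + (gt)_it + sum_m beta_m x_im [t targeted] + eps`
#' with `g ~ N(0, sd_g^2)`, `(gt) ~ N(0, sd_gt^2)` and
#' `eps ~ N(0, sd_re^2)`, per trait. Planted marker effects (supplied
#' directly or via `genoCfg$planted_effects`) add `beta` trait units per
#' alternate-allele copy to the targeted treatment(s); they require a
#' genotype matrix whose sample ids name the genotypes. Negative draws for
#' non-negative traits are truncated at 0 and counted in the truth record.
#'
#' @param cfg a [phenoSimConfig()].
#' @param genotypes optional [GenotypeMatrix] aligned by sample id.
#' @param plantedEffects optional planted-effect table (see
#'   [genoSimConfig()]).
#' @param genoCfg optional [genoSimConfig()]; its `planted_effects` are used
#'   when `plantedEffects` is not given.
#' @return `list(phenotypes = PhenotypeTable, truth = list(...))` where the
#'   truth holds realized genotype effects, planted betas with realized MAF,
#'   the implied per-trait heritabilities and truncation counts.
#' @export
simulatePhenotypes <- function(cfg, genotypes = NULL, plantedEffects = NULL,
                               genoCfg = NULL) {
  stopifnot(inherits(cfg, "phenoSimConfig"))
  if (is.null(plantedEffects) && !is.null(genoCfg)) {
    plantedEffects <- genoCfg$planted_effects
  }
  if (!is.null(plantedEffects)) {
    plantedEffects <- as.data.frame(plantedEffects)
    if (is.null(genotypes)) {
      .stopf("planted effects require a genotype matrix")
    }
    bad <- setdiff(plantedEffects$trait, cfg$traits$trait)
    if (length(bad)) {
      .stopf("planted trait(s) not in the simulated trait list: %s",
             paste(bad, collapse = ", "))
    }
    if (is.null(plantedEffects$treatment)) plantedEffects$treatment <- "both"
    if (!"marker_id" %in% names(plantedEffects)) {
      plantedEffects$marker_id <- markerInfo(genotypes)$marker_id[plantedEffects$marker]
    }
    miss <- setdiff(plantedEffects$marker_id, markerInfo(genotypes)$marker_id)
    if (length(miss)) .stopf("planted marker(s) not in the genotype matrix: %s",
                             paste(miss, collapse = ", "))
  }
  ids <- if (!is.null(genotypes)) sampleIds(genotypes) else
    sprintf("G%03d", seq_len(cfg$n_genotypes))
  n <- length(ids)
  T_ <- length(cfg$treatments)
  R_ <- cfg$n_replicates

  set.seed(.childSeed(cfg$seed, 1L))
  rec_list <- vector("list", nrow(cfg$traits))
  g_truth <- vector("list", nrow(cfg$traits))
  trunc_count <- setNames(integer(nrow(cfg$traits)), cfg$traits$trait)
  for (k in seq_len(nrow(cfg$traits))) {
    tp <- cfg$traits[k, ]
    mu <- setNames(c(tp$mean_HP, tp$mean_LP), TREATMENTS)[cfg$treatments]
    g_i <- rnorm(n, 0, tp$sd_g)
    gt_it <- matrix(rnorm(n * T_, 0, tp$sd_gt), nrow = n)
    planted_it <- matrix(0, nrow = n, ncol = T_)
    if (!is.null(plantedEffects)) {
      pk <- plantedEffects[plantedEffects$trait == tp$trait, , drop = FALSE]
      if (nrow(pk)) {
        dmat <- dosage(genotypes)
        for (j in seq_len(nrow(pk))) {
          x <- dmat[, pk$marker_id[j]]
          x[is.na(x)] <- mean(x, na.rm = TRUE)
          cols <- if (pk$treatment[j] == "both") seq_len(T_) else
            which(cfg$treatments == pk$treatment[j])
          planted_it[, cols] <- planted_it[, cols] + pk$beta[j] * x
        }
      }
    }
    vals <- array(NA_real_, dim = c(n, T_, R_))
    for (t in seq_len(T_)) {
      for (r in seq_len(R_)) {
        vals[, t, r] <- mu[t] + g_i + gt_it[, t] + planted_it[, t] +
          rnorm(n, 0, tp$sd_re)
      }
    }
    if (tp$trait %in% NONNEG_TRAITS) {
      nneg <- sum(vals < 0)
      if (nneg > 0) vals[vals < 0] <- 0
      trunc_count[tp$trait] <- nneg
    }
    rec_list[[k]] <- data.frame(
      genotype_id = rep(ids, times = T_ * R_),
      treatment = rep(rep(cfg$treatments, each = n), times = R_),
      replicate = rep(seq_len(R_), each = n * T_),
      trait = tp$trait,
      value = as.vector(vals),
      stringsAsFactors = FALSE
    )
    g_truth[[k]] <- data.frame(trait = tp$trait, genotype_id = ids, g = g_i,
                               stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rec_list)
  if (cfg$missing_rate > 0) {
    rec$value[runif(nrow(rec)) < cfg$missing_rate] <- NA
  }
  planted_truth <- NULL
  if (!is.null(plantedEffects)) {
    maf <- .foldedMaf(dosage(genotypes), ploidy(genotypes))
    planted_truth <- plantedEffects
    planted_truth$maf <- maf[planted_truth$marker_id]
  }
  truth <- list(genotype_effects = do.call(rbind, g_truth),
                planted = planted_truth,
                h2_implied = impliedH2(cfg),
                truncated = trunc_count,
                seed = cfg$seed)
  list(phenotypes = PhenotypeTable(rec), truth = truth)
}
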