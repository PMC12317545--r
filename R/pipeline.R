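#' Pipeline configuration
#'
#' Single configuration object for [runPipeline()]. Inputs are either file
#' paths (phenotype CSV, genotype VCF/dosage CSV, GFF3 annotation) or
#' simulation configs; every analysis threshold is recorded here so each
#' run's output is fully traceable.
#'
#' @param phenotypes path to a phenotype CSV, or `NULL` to simulate.
#' @param genotypes path to a VCF (`.vcf`) or dosage CSV, or `NULL` to
#'   simulate.
#' @param annotation optional path to a GFF3 file for candidate-gene
#'   queries.
#' @param pheno_sim,geno_sim simulation configs used when the respective
#'   input path is `NULL` (defaults: [phenoSimConfig()] / [genoSimConfig()]
#'   reseeded from `seed`).
#' @param anova_traits traits for ANOVA/heritability (default: all traits
#'   present after derivation).
#' @param tolerance_traits traits entering STI and MFVP (default SDW, RDW,
#'   TotalDW, Pupt).
#' @param gwas_traits traits scanned per context (default the tolerance
#'   set); each is scanned under HP, LP, their difference (delta) and STI.
#' @param stages character vector of enabled stages, any of
#'   `"phenostats"`, `"tolerance"`, `"cluster"`, `"gwas"`.
#' @param call_rate_min,maf_min,n_pc,alpha,window_bp,pve_variant GWAS
#'   settings (see [markerQC()], [pcaCovariates()], [applyBonferroni()],
#'   [candidateGenes()], [computePVE()]).
#' @param k_main,k_sub,top_k clustering cut sizes and tolerance list length.
#' @param out_dir optional output directory; when set, every stage writes
#'   its result tables as TSV.
#' @param seed integer seed driving all simulation randomness.
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(phenotypes = NULL, genotypes = NULL,
                           annotation = NULL, pheno_sim = NULL,
                           geno_sim = NULL, anova_traits = NULL,
                           tolerance_traits = TOLERANCE_TRAITS,
                           gwas_traits = TOLERANCE_TRAITS,
                           stages = c("phenostats", "tolerance", "cluster",
                                      "gwas"),
                           call_rate_min = 0.85, maf_min = 0.05, n_pc = 3,
                           alpha = 0.05, window_bp = 1e6,
                           pve_variant = "shim", k_main = 2, k_sub = 9,
                           top_k = 20, out_dir = NULL, seed = 1) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(call_rate_min >= 0, call_rate_min <= 1,
            maf_min >= 0, maf_min <= 0.5, alpha > 0, alpha < 1,
            window_bp >= 0, n_pc >= 0, k_main >= 1, k_sub >= k_main,
            top_k >= 1)
  structure(list(phenotypes = phenotypes, genotypes = genotypes,
                 annotation = annotation, pheno_sim = pheno_sim,
                 geno_sim = geno_sim, anova_traits = anova_traits,
                 tolerance_traits = tolerance_traits,
                 gwas_traits = gwas_traits, stages = stages,
                 call_rate_min = call_rate_min, maf_min = maf_min,
                 n_pc = n_pc, alpha = alpha, window_bp = window_bp,
                 pve_variant = pve_variant, k_main = k_main, k_sub = k_sub,
                 top_k = top_k, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Run the full screening-and-association pipeline
#'
#' Executes the enabled stages in order: trait derivation and genotype
#' means, descriptive statistics + ANOVA + variance components and
#' heritability ("phenostats"); STI/MFVP scoring with top/bottom-k
#' selection ("tolerance"); z-standardization and hierarchical clustering
#' with sub-cluster mean profiles ("cluster"); marker QC, mean imputation,
#' PC covariates, per-context association scans with Bonferroni control and
#' PVE, plus candidate-gene windows when annotation is available ("gwas").
#' Inputs missing for an enabled stage fail before any computation starts.
#' With a fixed `(config, seed)` the run — including any simulated inputs —
#' is fully deterministic.
#'
#' @param cfg a [pipelineConfig()].
#' @return list with one element per executed stage plus `report` (stage
#'   record counts, parameter echo, seed) and, when inputs were simulated,
#'   `truth`.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipelineConfig"))
  # --- fail-fast validation -------------------------------------------------
  for (p in c(cfg$phenotypes, cfg$genotypes, cfg$annotation)) {
    if (!is.null(p) && !file.exists(p)) .stopf("input not found: %s", p)
  }
  need_geno <- "gwas" %in% cfg$stages
  report <- list(parameters = cfg[!(names(cfg) %in%
                                      c("pheno_sim", "geno_sim"))],
                 seed = cfg$seed, stages = list(),
                 version = as.character(utils::packageVersion("phosGWAS")))
  out <- list(report = report)

  # --- inputs ---------------------------------------------------------------
  truth <- list()
  geno <- NULL
  if (!is.null(cfg$genotypes)) {
    geno <- if (grepl("\\.vcf(\\.gz)?$", cfg$genotypes)) {
      readGenotypesVcf(cfg$genotypes)
    } else {
      readDosageCsv(cfg$genotypes)
    }
  } else if (need_geno) {
    gcfg <- cfg$geno_sim
    if (is.null(gcfg)) gcfg <- genoSimConfig(seed = cfg$seed)
    sim <- simulateGenotypes(gcfg)
    geno <- sim$genotypes
    truth$genotypes <- sim$truth
  }
  if (!is.null(cfg$phenotypes)) {
    pheno <- readPhenotypeTable(cfg$phenotypes)
  } else {
    pcfg <- cfg$pheno_sim
    if (is.null(pcfg)) pcfg <- phenoSimConfig(seed = cfg$seed)
    gcfg <- cfg$geno_sim
    # planted effects only apply when a genotype panel is in play
    sim <- simulatePhenotypes(pcfg, genotypes = geno,
                              genoCfg = if (!is.null(geno)) gcfg)
    pheno <- sim$phenotypes
    truth$phenotypes <- sim$truth
  }
  annot <- if (!is.null(cfg$annotation)) readGeneAnnotation(cfg$annotation)

  # --- derivation and means (always run) ------------------------------------
  pheno <- deriveTraits(pheno)
  means <- genotypeMeans(pheno)
  out$phenotypes <- pheno
  out$means <- means
  out$report$stages$derive <- list(n_records = nrow(phenoRecords(pheno)),
                                   n_means = nrow(means))

  if ("phenostats" %in% cfg$stages) {
    traits <- cfg$anova_traits
    if (is.null(traits)) traits <- unique(phenoRecords(pheno)$trait)
    desc <- descriptiveStats(means[means$trait %in% traits, ])
    vc <- lapply(traits, function(tr) {
      a <- tryCatch(anovaTwoWay(pheno, tr), error = function(e) NULL)
      if (is.null(a)) return(NULL)
      v <- varianceComponents(a)
      data.frame(trait = tr, msq_g = a$msq_g, msq_gt = a$msq_gt,
                 msq_re = a$msq_re,
                 p_g = a$terms$p[a$terms$term == "G"],
                 p_t = a$terms$p[a$terms$term == "T"],
                 p_e = a$terms$p[a$terms$term == "E"],
                 p_gxt = a$terms$p[a$terms$term == "GxT"],
                 sigma2_g = v$sigma2_g, sigma2_gt = v$sigma2_gt,
                 sigma2_re = v$sigma2_re, sigma2_p = v$sigma2_p,
                 h2_bs = v$h2_bs, stringsAsFactors = FALSE)
    })
    herit <- do.call(rbind, vc)
    chg <- lapply(setNames(nm = intersect(c("SDW", "RDW", "RS_ratio", "RL"),
                                          unique(means$trait))),
                  function(tr) changeMetrics(means, tr))
    out$phenostats <- list(descriptive = desc, heritability = herit,
                           change = chg)
    out$report$stages$phenostats <- list(n_traits = length(traits))
  }

  if ("tolerance" %in% cfg$stages) {
    sti <- lapply(setNames(nm = cfg$tolerance_traits), computeSTI,
                  means = means)
    mfvp <- computeMFVP(sti)
    sel <- rankSelect(mfvp, min(cfg$top_k, nrow(mfvp)))
    out$tolerance <- list(sti = sti, mfvp = mfvp, selection = sel)
    out$report$stages$tolerance <- list(n_genotypes = nrow(mfvp),
                                        n_traits = length(sti))
  }

  if ("cluster" %in% cfg$stages) {
    z <- standardizeTraits(means, traits = cfg$tolerance_traits)
    cl <- clusterGenotypes(z, k_main = cfg$k_main,
                           k_sub = min(cfg$k_sub, nrow(z)))
    cm <- clusterMeans(cl, means, traits = cfg$tolerance_traits)
    out$cluster <- list(z = z, assignments = cl$assignments, tree = cl$tree,
                        cluster_means = cm$cluster_means)
    out$report$stages$cluster <- list(n_genotypes = nrow(z),
                                      k_sub = length(unique(
                                        cl$assignments$sub_cluster)))
  }

  if (need_geno) {
    qc <- markerQC(geno, cfg$call_rate_min, cfg$maf_min)
    gi <- imputeMean(qc$genotypes)
    covs <- if (cfg$n_pc > 0) pcaCovariates(gi, n_pc = cfg$n_pc)
    scans <- list()
    for (tr in cfg$gwas_traits) {
      ys <- .traitContexts(means, tr,
                           sti = if (!is.null(out$tolerance))
                             out$tolerance$sti[[tr]])
      for (ctx in names(ys)) {
        rec <- glmScan(gi, ys[[ctx]], covariates = covs)
        rec <- applyBonferroni(rec, cfg$alpha)
        r <- rec$records
        okm <- !is.na(r$p) & r$maf > 0
        r$pve <- NA_real_
        r$pve[okm] <- computePVE(r$beta[okm], r$se[okm], r$maf[okm],
                                 r$n[okm], variant = cfg$pve_variant)
        r$trait <- tr
        r$context <- ctx
        scans[[paste(tr, ctx, sep = "_")]] <-
          list(records = r, rule = rec$rule)
      }
    }
    records <- do.call(rbind, lapply(scans, `[[`, "records"))
    rownames(records) <- NULL
    hits <- records[records$significant & !is.na(records$significant), ,
                    drop = FALSE]
    cand <- NULL
    if (!is.null(annot) && nrow(hits)) {
      cand <- do.call(rbind, lapply(seq_len(nrow(hits)), function(i) {
        cg <- candidateGenes(hits[i, ], annot, window_bp = cfg$window_bp)
        if (!nrow(cg)) return(NULL)
        cbind(marker_id = hits$marker_id[i], trait = hits$trait[i],
              context = hits$context[i], cg)
      }))
    }
    out$gwas <- list(qc = qc$report, records = records, hits = hits,
                     candidate_genes = cand,
                     rule = scans[[1]]$rule,
                     explained_variance =
                       if (!is.null(covs)) attr(covs, "explained_variance"))
    out$report$stages$gwas <- list(markers_in = qc$report$markers_in,
                                   markers_out = qc$report$markers_out,
                                   n_scans = length(scans),
                                   n_hits = nrow(hits))
  }
  if (length(truth)) out$truth <- truth

  if (!is.null(cfg$out_dir)) .writePipelineOutputs(out, cfg$out_dir)
  out
}

# Phenotype vectors per scan context for one trait: genotype means under HP
# and LP, their HP-LP difference, and the trait's STI when available.
#' @noRd
.traitContexts <- function(means, trait, sti = NULL) {
  s <- means[means$trait == trait, ]
  ys <- list()
  for (tm in TREATMENTS) {
    sub <- s[s$treatment == tm, ]
    if (nrow(sub)) ys[[tm]] <- setNames(sub$mean, sub$genotype_id)
  }
  if (all(TREATMENTS %in% names(ys))) {
    shared <- intersect(names(ys$HP), names(ys$LP))
    ys$delta <- ys$HP[shared] - ys$LP[shared]
  }
  if (!is.null(sti)) ys$STI <- setNames(sti$sti, sti$genotype_id)
  ys
}

#' @noRd
.writeTsv <- function(x, dir, name) {
  write.table(x, file.path(dir, paste0(name, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' @noRd
.writePipelineOutputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .writeTsv(phenoRecords(out$phenotypes), dir, "phenotypes_derived")
  .writeTsv(out$means, dir, "genotype_means")
  if (!is.null(out$phenostats)) {
    .writeTsv(out$phenostats$descriptive, dir, "descriptive_stats")
    if (!is.null(out$phenostats$heritability)) {
      .writeTsv(out$phenostats$heritability, dir, "heritability")
    }
  }
  if (!is.null(out$tolerance)) {
    .writeTsv(out$tolerance$mfvp, dir, "mfvp")
    .writeTsv(out$tolerance$selection$top, dir, "mfvp_top")
    .writeTsv(out$tolerance$selection$bottom, dir, "mfvp_bottom")
  }
  if (!is.null(out$cluster)) {
    .writeTsv(out$cluster$assignments, dir, "cluster_assignments")
    .writeTsv(out$cluster$cluster_means, dir, "cluster_means")
  }
  if (!is.null(out$gwas)) {
    .writeTsv(out$gwas$records, dir, "association_records")
    .writeTsv(out$gwas$hits, dir, "association_hits")
    if (!is.null(out$gwas$candidate_genes)) {
      .writeTsv(out$gwas$candidate_genes, dir, "candidate_genes")
    }
    .writeTsv(data.frame(out$gwas$qc), dir, "qc_report")
  }
  invisible(dir)
}

#' Write a ready-to-read synthetic fixture to disk
#'
#' Generates a small synthetic data set with [simulateGenotypes()] /
#' [simulatePhenotypes()] and writes it in the interchange formats the
#' readers consume, plus a JSON ground-truth file: `kind = "phenotypes"`
#' writes `phenotypes.csv` + `truth.json`; `"genotypes"` writes
#' `genotypes.vcf`, `dosage.csv` + `truth.json`; `"panel"` writes all of
#' them with planted marker effects linking the two. Identical
#' `(kind, seed)` always produce identical files.
#'
#' @param kind `"phenotypes"`, `"genotypes"` or `"panel"`.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @param pheno_cfg,geno_cfg optional simulation configs (reseeded from
#'   `seed`).
#' @return named character vector of the files written, invisibly.
#' @export
makeFixture <- function(kind = c("panel", "phenotypes", "genotypes"),
                        seed = 1, dir = tempdir(), pheno_cfg = NULL,
                        geno_cfg = NULL) {
  kind <- match.arg(kind)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  truth <- list(seed = seed, kind = kind)
  geno <- NULL
  if (kind %in% c("genotypes", "panel")) {
    if (is.null(geno_cfg)) {
      geno_cfg <- genoSimConfig(
        n_samples = 50, n_markers = 300, n_chromosomes = 4,
        missing_rate = 0.05, seed = seed,
        planted_effects = if (kind == "panel") {
          data.frame(marker = 10, trait = "SDW", beta = 0.3,
                     treatment = "both")
        }
      )
    }
    sim <- simulateGenotypes(geno_cfg)
    geno <- sim$genotypes
    files["vcf"] <- writeGenotypesVcf(geno, file.path(dir, "genotypes.vcf"))
    files["dosage"] <- writeDosageCsv(geno, file.path(dir, "dosage.csv"))
    truth$genotypes <- list(subpop = sim$truth$subpop,
                            maf_realized = sim$truth$maf_realized)
  }
  if (kind %in% c("phenotypes", "panel")) {
    if (is.null(pheno_cfg)) {
      pheno_cfg <- phenoSimConfig(
        n_genotypes = if (is.null(geno)) 50 else nSamples(geno), seed = seed)
    }
    sim <- simulatePhenotypes(pheno_cfg, genotypes = geno,
                              genoCfg = geno_cfg)
    files["phenotypes"] <- writePhenotypeTable(
      sim$phenotypes, file.path(dir, "phenotypes.csv"))
    truth$phenotypes <- list(h2_implied = as.list(sim$truth$h2_implied),
                             planted = sim$truth$planted,
                             truncated = as.list(sim$truth$truncated))
  }
  truth_path <- file.path(dir, "truth.json")
  write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
             dataframe = "columns", pretty = TRUE)
  files["truth"] <- truth_path
  invisible(files)
}
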