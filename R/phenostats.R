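#' Derive phosphorus-efficiency traits
#'
#' Adds the derived traits to a phenotype table wherever their source traits
#' are present for a (genotype, treatment, replicate) cell:
#'
#' * `Pupt = P_conc * SDW / 100` — P uptake in mg per plant (P_conc is in
#'   mg per 100 g dry matter, SDW in g);
#' * `PUE = SDW / Pupt` — P utilization efficiency in g biomass per mg P
#'   (algebraically `100 / P_conc`, so `PUE * P_conc = 100` wherever both
#'   are defined);
#' * `RS_ratio = RDW / SDW`;
#' * `TotalFW = SFW + RFW + TFW` and `TotalDW = SDW + RDW + TDW`.
#'
#' Division guards: when `Pupt` is 0 the PUE record is set missing (never
#' infinite), likewise `RS_ratio` when `SDW` is 0. Existing records of a
#' derived trait are overwritten with a warning.
#'
#' @param table a [PhenotypeTable].
#' @return a [PhenotypeTable] including the derivable traits.
#' @export
deriveTraits <- function(table) {
  stopifnot(is(table, "PhenotypeTable"))
  rec <- phenoRecords(table)
  derived <- c("Pupt", "PUE", "RS_ratio", "TotalFW", "TotalDW")
  old <- intersect(unique(rec$trait), derived)
  if (length(old)) {
    .warnf("overwriting existing derived trait(s): %s",
           paste(old, collapse = ", "))
    rec <- rec[!rec$trait %in% old, , drop = FALSE]
  }
  # wide view per (genotype, treatment, replicate) cell
  key <- paste(rec$genotype_id, rec$treatment, rec$replicate, sep = "\r")
  cells <- rec[!duplicated(key), c("genotype_id", "treatment", "replicate")]
  ck <- key[!duplicated(key)]
  wide <- list()
  for (tr in unique(rec$trait)) {
    sub <- rec[rec$trait == tr, ]
    v <- rep(NA_real_, nrow(cells))
    v[match(paste(sub$genotype_id, sub$treatment, sub$replicate, sep = "\r"),
            ck)] <- sub$value
    wide[[tr]] <- v
  }
  # derived records are kept for every cell; underivable cells carry an
  # explicit NA (flagged missing, never infinite)
  add <- function(trait, value) {
    data.frame(genotype_id = cells$genotype_id, treatment = cells$treatment,
               replicate = cells$replicate, trait = trait, value = value,
               stringsAsFactors = FALSE)
  }
  out <- list(rec)
  if (all(c("P_conc", "SDW") %in% names(wide))) {
    pupt <- wide$P_conc * wide$SDW / 100
    out <- c(out, list(add("Pupt", pupt)))
    pue <- ifelse(!is.na(pupt) & pupt > 0, wide$SDW / pupt, NA_real_)
    out <- c(out, list(add("PUE", pue)))
  }
  if (all(c("RDW", "SDW") %in% names(wide))) {
    rs <- ifelse(!is.na(wide$SDW) & wide$SDW > 0, wide$RDW / wide$SDW,
                 NA_real_)
    out <- c(out, list(add("RS_ratio", rs)))
  }
  if (all(c("SFW", "RFW", "TFW") %in% names(wide))) {
    out <- c(out, list(add("TotalFW", wide$SFW + wide$RFW + wide$TFW)))
  }
  if (all(c("SDW", "RDW", "TDW") %in% names(wide))) {
    out <- c(out, list(add("TotalDW", wide$SDW + wide$RDW + wide$TDW)))
  }
  PhenotypeTable(do.call(rbind, out))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genotype means per treatment
#'
#' Arithmetic mean over replicates for every (genotype, treatment, trait),
#' excluding missing replicates; the number of replicates entering each mean
#' is recorded. Cells with no non-missing replicate are absent from the
#' result.
#'
#' @param table a [PhenotypeTable].
#' @return data.frame with columns `genotype_id`, `treatment`, `trait`,
#'   `mean`, `n_reps` (the "trait means by treatment" table used by all
#'   downstream statistics).
#' @export
genotypeMeans <- function(table) {
  stopifnot(is(table, "PhenotypeTable"))
  rec <- phenoRecords(table)
  rec <- rec[!is.na(rec$value), , drop = FALSE]
  if (!nrow(rec)) .stopf("no non-missing phenotype values")
  key <- interaction(rec$genotype_id, rec$treatment, rec$trait, drop = TRUE,
                     sep = "\r")
  mean_v <- tapply(rec$value, key, mean)
  n_v <- tapply(rec$value, key, length)
  parts <- do.call(rbind, strsplit(names(mean_v), "\r", fixed = TRUE))
  out <- data.frame(genotype_id = parts[, 1], treatment = parts[, 2],
                    trait = parts[, 3], mean = as.numeric(mean_v),
                    n_reps = as.integer(n_v), stringsAsFactors = FALSE)
  out <- out[order(out$trait, out$treatment, out$genotype_id), ]
  rownames(out) <- NULL
  out
}

#' Descriptive statistics over genotype means
#'
#' Min, mean, max and sample SD of the genotype means, per trait and
#' treatment — the descriptive panel summary reported alongside ANOVA
#' significance and heritability.
#'
#' @param means genotype-mean table from [genotypeMeans()].
#' @return data.frame with columns `trait`, `treatment`, `min`, `mean`,
#'   `max`, `sd`, `n_genotypes`.
#' @export
descriptiveStats <- function(means) {
  out <- do.call(rbind, lapply(split(means, means[c("trait", "treatment")],
                                     drop = TRUE), function(s) {
    if (nrow(s) < 2) {
      .stopf("fewer than 2 genotypes for %s under %s: SD undefined",
             s$trait[1], s$treatment[1])
    }
    data.frame(trait = s$trait[1], treatment = s$treatment[1],
               min = min(s$mean), mean = mean(s$mean), max = max(s$mean),
               sd = sd(s$mean), n_genotypes = nrow(s),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$trait, out$treatment), ]
  rownames(out) <- NULL
  out
}

#' Two-way ANOVA of a trait
#'
#' Fits `value ~ replicate + genotype * treatment` with [stats::aov()] on a
#' balanced complete design (every genotype x treatment cell observed in
#' every replicate): genotype (G), treatment (T) and their interaction
#' (G x T) as fixed effects plus the replication block (E). Mean squares,
#' F statistics against the residual and p-values are returned per term.
#' Unbalanced data are rejected (the downstream variance-component formulas
#' assume balance); subset to a balanced core first.
#'
#' @param table a [PhenotypeTable].
#' @param trait trait code to analyse.
#' @return an `AnovaResult` list with elements `trait`, `terms` (data.frame
#'   of df/ss/ms/F/p for E, G, T, GxT and residual), `msq_g`, `msq_gt`,
#'   `msq_re`, `n_genotypes`, `n_treatments`, `n_replicates`.
#' @export
anovaTwoWay <- function(table, trait) {
  stopifnot(is(table, "PhenotypeTable"))
  rec <- phenoRecords(table)
  rec <- rec[rec$trait == trait & !is.na(rec$value), , drop = FALSE]
  if (!nrow(rec)) .stopf("no observations for trait %s", trait)
  tab <- table(rec$genotype_id, rec$treatment)
  R_ <- unique(as.vector(tab))
  if (length(R_) != 1 || R_ < 2) {
    .stopf(paste("trait %s is not a balanced complete design (replicate",
                 "counts per genotype x treatment cell: %s); subset to a",
                 "balanced core before calling anovaTwoWay"),
           trait, paste(sort(unique(as.vector(tab))), collapse = ","))
  }
  df <- data.frame(value = rec$value,
                   genotype = factor(rec$genotype_id),
                   treatment = factor(rec$treatment),
                   replicate = factor(rec$replicate))
  fit <- aov(value ~ replicate + genotype + treatment + genotype:treatment,
             data = df)
  s <- summary(fit)[[1]]
  rn <- trimws(rownames(s))
  pick <- function(term, col) {
    i <- match(term, rn)
    if (is.na(i)) NA_real_ else s[i, col]
  }
  term_names <- c("replicate", "genotype", "treatment", "genotype:treatment",
                  "Residuals")
  labels <- c("E", "G", "T", "GxT", "Residual")
  terms <- data.frame(
    term = labels,
    df = vapply(term_names, pick, numeric(1), col = "Df"),
    ss = vapply(term_names, pick, numeric(1), col = "Sum Sq"),
    ms = vapply(term_names, pick, numeric(1), col = "Mean Sq"),
    f = vapply(term_names, pick, numeric(1), col = "F value"),
    p = vapply(term_names, pick, numeric(1), col = "Pr(>F)"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  # all-identical input: every partition is exactly zero and no F test exists
  tot <- sum((df$value - mean(df$value))^2)
  if (tot < sqrt(.Machine$double.eps) * max(1, mean(df$value)^2)) {
    terms$ss <- 0
    terms$ms <- 0
    terms$f <- NA_real_
    terms$p <- NA_real_
  }
  terms$f[!is.finite(terms$f)] <- NA_real_
  terms$p[is.nan(terms$p)] <- NA_real_
  structure(list(
    trait = trait, terms = terms,
    msq_g = terms$ms[terms$term == "G"],
    msq_gt = terms$ms[terms$term == "GxT"],
    msq_re = terms$ms[terms$term == "Residual"],
    n_genotypes = nlevels(df$genotype),
    n_treatments = nlevels(df$treatment),
    n_replicates = as.integer(R_)
  ), class = "AnovaResult")
}

#' @export
print.AnovaResult <- function(x, ...) {
  cat("Two-way ANOVA for", x$trait, "-", x$n_genotypes, "genotypes x",
      x$n_treatments, "treatments x", x$n_replicates, "replicates\n")
  print(x$terms, digits = 4)
  invisible(x)
}

#' Variance components and broad-sense heritability
#'
#' Moment estimators from the balanced-design mean squares:
#' `sigma2_G = (MSQ_G - MSQ_GT) / (T R)`,
#' `sigma2_GT = (MSQ_GT - MSQ_Re) / R`, `sigma2_Re = MSQ_Re`, phenotypic
#' variance `sigma2_P = sigma2_G + sigma2_GT / T + sigma2_Re / (T R)` and
#' `H2_bs = sigma2_G / sigma2_P`. Negative raw component estimates are
#' clamped to zero for reporting (raw values are retained in `$raw`), which
#' keeps the reported heritability inside `[0, 1]`; `H2_bs` is missing when
#' `sigma2_P` is 0.
#'
#' @param a an `AnovaResult` from [anovaTwoWay()].
#' @param T number of treatments (default taken from `a`).
#' @param R number of replicates (default taken from `a`).
#' @return a `VarianceComponents` list with `sigma2_g`, `sigma2_gt`,
#'   `sigma2_re`, `sigma2_p`, `h2_bs` and `raw`.
#' @export
varianceComponents <- function(a, T = a$n_treatments, R = a$n_replicates) {
  stopifnot(inherits(a, "AnovaResult"))
  if (T < 2 || R < 2) .stopf("variance components require T >= 2 and R >= 2")
  raw_g <- (a$msq_g - a$msq_gt) / (T * R)
  raw_gt <- (a$msq_gt - a$msq_re) / R
  raw_re <- a$msq_re
  s2_g <- max(raw_g, 0)
  s2_gt <- max(raw_gt, 0)
  s2_re <- max(raw_re, 0)
  s2_p <- s2_g + s2_gt / T + s2_re / (T * R)
  h2 <- if (s2_p > 0) s2_g / s2_p else NA_real_
  structure(list(trait = a$trait, sigma2_g = s2_g, sigma2_gt = s2_gt,
                 sigma2_re = s2_re, sigma2_p = s2_p, h2_bs = h2,
                 raw = list(sigma2_g = raw_g, sigma2_gt = raw_gt,
                            sigma2_re = raw_re)),
            class = "VarianceComponents")
}

#' @export
print.VarianceComponents <- function(x, ...) {
  cat(sprintf(paste0("Variance components for %s: sigma2_G = %.4g, ",
                     "sigma2_GT = %.4g, sigma2_Re = %.4g, sigma2_P = %.4g, ",
                     "H2_bs = %.3f\n"),
              x$trait, x$sigma2_g, x$sigma2_gt, x$sigma2_re, x$sigma2_p,
              x$h2_bs))
  invisible(x)
}

#' HP-to-LP change metrics
#'
#' Per genotype: the absolute change `delta = HP - LP` (trait units) and the
#' percent reduction `100 (HP - LP) / HP` under low-P stress. The panel
#' summary averages the per-genotype percent reductions (an option switches
#' to the ratio of panel means) and counts genotypes whose value increased
#' under LP (negative reduction). Genotypes lacking either treatment mean
#' are dropped; a genotype with HP mean 0 gets a missing percent reduction.
#'
#' @param means genotype-mean table from [genotypeMeans()].
#' @param trait trait code.
#' @param summary_method `"per_genotype"` (mean of per-genotype ratios,
#'   default) or `"ratio_of_means"`.
#' @return list with `per_genotype` (data.frame `genotype_id`, `hp`, `lp`,
#'   `delta`, `pct_reduction`) and `summary` (list with
#'   `mean_pct_reduction`, `n_increased_lp`, `n_genotypes`, `n_missing_pct`).
#' @export
changeMetrics <- function(means, trait,
                          summary_method = c("per_genotype",
                                             "ratio_of_means")) {
  summary_method <- match.arg(summary_method)
  s <- means[means$trait == trait, , drop = FALSE]
  hp <- s[s$treatment == "HP", c("genotype_id", "mean")]
  lp <- s[s$treatment == "LP", c("genotype_id", "mean")]
  m <- merge(hp, lp, by = "genotype_id", suffixes = c("_hp", "_lp"))
  if (!nrow(m)) .stopf("no genotype has both HP and LP means for %s", trait)
  delta <- m$mean_hp - m$mean_lp
  pct <- ifelse(m$mean_hp != 0, 100 * delta / m$mean_hp, NA_real_)
  per <- data.frame(genotype_id = m$genotype_id, hp = m$mean_hp,
                    lp = m$mean_lp, delta = delta, pct_reduction = pct,
                    stringsAsFactors = FALSE)
  mean_pct <- if (summary_method == "per_genotype") {
    mean(pct, na.rm = TRUE)
  } else {
    100 * (mean(m$mean_hp) - mean(m$mean_lp)) / mean(m$mean_hp)
  }
  list(per_genotype = per,
       summary = list(mean_pct_reduction = mean_pct,
                      n_increased_lp = sum(m$mean_lp > m$mean_hp),
                      n_genotypes = nrow(m),
                      n_missing_pct = sum(is.na(pct))))
}
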