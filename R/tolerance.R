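#' Stress tolerance index (STI) per trait
#'
#' For genotype i with trait mean `Y_pi` under the high-P control and `Y_si`
#' under low-P stress, `STI_i = Y_pi * Y_si / mean(Y_p)^2`, where `mean(Y_p)`
#' is the mean control performance of *all* genotypes with an HP value for
#' the trait (not only those with complete HP+LP data). High STI marks
#' genotypes performing well under both regimes; a genotype at the panel
#' mean under both regimes scores exactly 1. Genotypes lacking either
#' treatment mean are excluded and listed in the `"excluded"` attribute.
#'
#' @param means genotype-mean table from [genotypeMeans()].
#' @param trait trait code.
#' @return data.frame `genotype_id`, `y_p`, `y_s`, `sti`, with attributes
#'   `mean_yp` and `excluded`.
#' @export
computeSTI <- function(means, trait) {
  s <- means[means$trait == trait, , drop = FALSE]
  if (!nrow(s)) .stopf("no means for trait %s", trait)
  hp <- s[s$treatment == "HP", c("genotype_id", "mean")]
  lp <- s[s$treatment == "LP", c("genotype_id", "mean")]
  mean_yp <- mean(hp$mean)
  if (!is.finite(mean_yp) || mean_yp == 0) {
    .stopf("mean HP performance for %s is zero; STI undefined", trait)
  }
  m <- merge(hp, lp, by = "genotype_id", suffixes = c("_p", "_s"))
  excluded <- setdiff(union(hp$genotype_id, lp$genotype_id), m$genotype_id)
  out <- data.frame(genotype_id = m$genotype_id, y_p = m$mean_p,
                    y_s = m$mean_s, sti = m$mean_p * m$mean_s / mean_yp^2,
                    stringsAsFactors = FALSE)
  out <- out[order(out$genotype_id), ]
  rownames(out) <- NULL
  attr(out, "mean_yp") <- mean_yp
  attr(out, "trait") <- trait
  attr(out, "excluded") <- excluded
  out
}

#' Membership-function value for P-stress tolerance (MFVP)
#'
#' Combines per-trait STI scores into one tolerance score per genotype:
#' each trait's STI is min-max rescaled over the genotype set,
#' `U_ij = (STI_ij - STI_jmin) / (STI_jmax - STI_jmin)`, and the composite
#' is the unweighted mean `U_i = (1/n) sum_j U_ij`. Only genotypes present
#' in every trait's STI table enter (the intersection; exclusions are
#' recorded). Traits whose STI is constant across the panel carry no
#' ranking information and are dropped from the average with a warning
#' (`n` reduced accordingly).
#'
#' @param sti_tables named list of [computeSTI()] results, one per trait.
#' @return data.frame with `genotype_id`, one `U_<trait>` column per
#'   retained trait, `mfvp` and `n_traits`; attributes `sti_range` (per-
#'   trait min/max), `dropped_traits`, `excluded_genotypes`.
#' @export
computeMFVP <- function(sti_tables) {
  if (!length(sti_tables)) .stopf("at least one STI table is required")
  if (is.null(names(sti_tables)) || any(names(sti_tables) == "")) {
    names(sti_tables) <- vapply(sti_tables, attr, character(1),
                                which = "trait")
  }
  ids <- Reduce(intersect, lapply(sti_tables, `[[`, "genotype_id"))
  if (!length(ids)) .stopf("no genotype is shared by all STI tables")
  excluded <- setdiff(unique(unlist(lapply(sti_tables, `[[`,
                                           "genotype_id"))), ids)
  ids <- sort(ids)
  u <- list()
  rng <- list()
  dropped <- character()
  for (tr in names(sti_tables)) {
    s <- sti_tables[[tr]]
    sti <- s$sti[match(ids, s$genotype_id)]
    lo <- min(sti)
    hi <- max(sti)
    rng[[tr]] <- c(min = lo, max = hi)
    if (hi == lo) {
      dropped <- c(dropped, tr)
      .warnf("trait %s has constant STI; dropped from the MFVP average", tr)
      next
    }
    u[[tr]] <- (sti - lo) / (hi - lo)
  }
  if (!length(u)) .stopf("all traits have constant STI; MFVP undefined")
  um <- do.call(cbind, u)
  out <- data.frame(genotype_id = ids, stringsAsFactors = FALSE)
  for (tr in colnames(um)) out[[paste0("U_", tr)]] <- um[, tr]
  out$mfvp <- rowMeans(um)
  out$n_traits <- ncol(um)
  attr(out, "sti_range") <- rng
  attr(out, "dropped_traits") <- dropped
  attr(out, "excluded_genotypes") <- excluded
  out
}

#' Select the most and least tolerant genotypes
#'
#' Sorts genotypes by MFVP (descending) with ties broken lexicographically
#' by genotype id, and returns the top-k and bottom-k with their scores.
#'
#' @param mfvp result of [computeMFVP()].
#' @param k number of genotypes per list.
#' @return list of data.frames `top` and `bottom` (columns `rank`,
#'   `genotype_id`, `mfvp`).
#' @export
rankSelect <- function(mfvp, k) {
  if (k <= 0) .stopf("k must be positive")
  if (k > nrow(mfvp)) .stopf("k = %d exceeds the %d ranked genotypes",
                             k, nrow(mfvp))
  ord <- order(-mfvp$mfvp, mfvp$genotype_id)
  ranked <- data.frame(rank = seq_len(nrow(mfvp)),
                       genotype_id = mfvp$genotype_id[ord],
                       mfvp = mfvp$mfvp[ord], stringsAsFactors = FALSE)
  list(top = head(ranked, k),
       bottom = ranked[seq(nrow(ranked), nrow(ranked) - k + 1), ])
}
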