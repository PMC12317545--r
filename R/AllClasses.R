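#' PhenotypeTable: long-format phenotype records
#'
#' Validated container for greenhouse phenotype measurements in long format:
#' one row per (genotype, treatment, replicate, trait). Treatments are the
#' two phosphorus regimes `HP` (high-P control) and `LP` (low-P stress).
#' Trait codes follow the field's conventions (SFW, SDW, RFW, RDW, TFW, TDW,
#' TotalFW, TotalDW, PH1, PH2, RL, P_conc, Pupt, PUE, RS_ratio); additional
#' codes are accepted. Values of weight/length/concentration traits must be
#' non-negative; missing values are carried as `NA` and never imputed at
#' construction time.
#'
#' @slot records a `data.frame` with columns `genotype_id`, `treatment`,
#'   `replicate`, `trait`, `value`.
#' @export
setClass("PhenotypeTable", slots = c(records = "data.frame"))

# Validate long phenotype records; returns data.frame(row, problem) with one
# entry per offending record (empty when valid).
#' @noRd
.phenoProblems <- function(rec) {
  probs <- data.frame(row = integer(), problem = character())
  bad <- !(rec$treatment %in% TREATMENTS)
  if (any(bad)) {
    probs <- rbind(probs, data.frame(
      row = which(bad),
      problem = sprintf("unknown treatment '%s' (expected HP or LP)",
                        rec$treatment[bad])
    ))
  }
  badrep <- !is.finite(rec$replicate) | rec$replicate < 1 |
    rec$replicate != round(rec$replicate)
  if (any(badrep)) {
    probs <- rbind(probs, data.frame(
      row = which(badrep),
      problem = "replicate must be a positive integer"
    ))
  }
  key <- paste(rec$genotype_id, rec$treatment, rec$replicate, rec$trait,
               sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    probs <- rbind(probs, data.frame(
      row = which(dup),
      problem = sprintf("duplicate key (%s, %s, %s, %s)",
                        rec$genotype_id[dup], rec$treatment[dup],
                        rec$replicate[dup], rec$trait[dup])
    ))
  }
  neg <- rec$trait %in% NONNEG_TRAITS & !is.na(rec$value) & rec$value < 0
  if (any(neg)) {
    probs <- rbind(probs, data.frame(
      row = which(neg),
      problem = sprintf("negative value %g for non-negative trait %s",
                        rec$value[neg], rec$trait[neg])
    ))
  }
  probs
}

setValidity("PhenotypeTable", function(object) {
  rec <- object@records
  needed <- c("genotype_id", "treatment", "replicate", "trait", "value")
  miss <- setdiff(needed, names(rec))
  if (length(miss)) {
    return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }
  probs <- .phenoProblems(rec)
  if (nrow(probs)) {
    return(sprintf("invalid records: %s",
                   paste(sprintf("row %d: %s", head(probs$row, 5),
                                 head(probs$problem, 5)), collapse = "; ")))
  }
  TRUE
})

#' Construct a PhenotypeTable
#'
#' @param records data.frame with columns `genotype_id`, `treatment`,
#'   `replicate`, `trait`, `value`.
#' @return a validated [PhenotypeTable-class] object.
#' @examples
#' rec <- data.frame(genotype_id = "G1", treatment = c("HP", "HP", "LP", "LP"),
#'                   replicate = c(1, 2, 1, 2), trait = "SDW",
#'                   value = c(1.2, 1.4, 0.5, 0.6))
#' PhenotypeTable(rec)
#' @export
PhenotypeTable <- function(records) {
  records <- as.data.frame(records)
  records$genotype_id <- as.character(records$genotype_id)
  records$treatment <- as.character(records$treatment)
  records$replicate <- as.numeric(records$replicate)
  records$trait <- as.character(records$trait)
  records$value <- as.numeric(records$value)
  rownames(records) <- NULL
  new("PhenotypeTable", records = records)
}

#' @rdname accessors
#' @export
setMethod("phenoRecords", "PhenotypeTable", function(x) x@records)

setMethod("show", "PhenotypeTable", function(object) {
  rec <- object@records
  cat("PhenotypeTable:", nrow(rec), "records |",
      length(unique(rec$genotype_id)), "genotypes |",
      length(unique(rec$trait)), "traits |",
      "treatments:", paste(sort(unique(rec$treatment)), collapse = "/"), "\n")
})

#' GenotypeMatrix: SNP dosage panel with marker map
#'
#' Biallelic SNP dosages for a sample panel, stored as a
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with markers as rows and samples as columns. The single assay `"dosage"`
#' holds alternate-allele counts in `[0, ploidy]` (`NA` = missing call; raw
#' calls are integers, mean-imputed matrices may hold fractional dosages).
#' The marker map (`marker_id`, `chrom`, `pos`, `ref`, `alt`) lives in
#' `rowData` and is kept sorted by (chromosome, position); positions are
#' 1-based, as in VCF.
#'
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'dosage' is required")
  }
  rd <- rowData(object)
  needed <- c("marker_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(needed, colnames(rd))
  if (length(miss)) {
    return(sprintf("rowData lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (nrow(rd)) {
    if (any(rd$pos < 1)) return("marker positions must be >= 1")
    if (any(rd$ref == rd$alt)) return("ref and alt alleles must differ")
    if (anyDuplicated(rd$marker_id)) return("duplicate marker_id")
    ord <- .markerOrder(rd$chrom, rd$pos)
    if (!identical(ord, seq_len(nrow(rd)))) {
      return("markers must be sorted by (chromosome, position)")
    }
  }
  pl <- metadata(object)$ploidy
  if (is.null(pl) || pl < 1) return("metadata()$ploidy must be a positive integer")
  d <- assay(object, "dosage")
  if (any(d < 0 | d > pl, na.rm = TRUE)) {
    return(sprintf("dosages must lie in [0, %d]", pl))
  }
  TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosage numeric matrix of alternate-allele counts, samples in rows
#'   and markers in columns (`NA` = missing call).
#' @param markers data.frame with one row per marker and columns
#'   `marker_id`, `chrom`, `pos`, `ref`, `alt`. Rows are re-sorted by
#'   (chromosome, position) together with the dosage columns.
#' @param sampleIds character vector of sample identifiers; defaults to
#'   `rownames(dosage)`.
#' @param ploidy maximum dosage (2 for diploidized calls, 4 for tetraploid
#'   dosages).
#' @return a [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(dosage, markers, sampleIds = rownames(dosage),
                           ploidy = 2L) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  markers <- as.data.frame(markers)
  if (ncol(dosage) != nrow(markers)) {
    .stopf("dosage has %d marker columns but the map describes %d markers",
           ncol(dosage), nrow(markers))
  }
  if (is.null(sampleIds)) {
    sampleIds <- sprintf("S%03d", seq_len(nrow(dosage)))
  }
  if (length(sampleIds) != nrow(dosage)) {
    .stopf("got %d sample ids for %d dosage rows", length(sampleIds),
           nrow(dosage))
  }
  markers$marker_id <- as.character(markers$marker_id)
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  markers$ref <- as.character(markers$ref)
  markers$alt <- as.character(markers$alt)
  ord <- .markerOrder(markers$chrom, markers$pos)
  markers <- markers[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  m <- t(dosage)
  dimnames(m) <- list(markers$marker_id, as.character(sampleIds))
  se <- SummarizedExperiment(
    assays = list(dosage = m),
    rowData = DataFrame(markers, row.names = markers$marker_id),
    colData = DataFrame(sample_id = as.character(sampleIds),
                        row.names = as.character(sampleIds)),
    metadata = list(ploidy = as.integer(ploidy))
  )
  new("GenotypeMatrix", se)
}

#' @rdname accessors
#' @export
setMethod("dosage", "GenotypeMatrix", function(x) t(assay(x, "dosage")))

#' @rdname accessors
#' @export
setMethod("markerInfo", "GenotypeMatrix", function(x) {
  as.data.frame(rowData(x))
})

#' @rdname accessors
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) {
  as.character(colData(x)$sample_id)
})

#' @rdname accessors
#' @export
setMethod("ploidy", "GenotypeMatrix", function(x) metadata(x)$ploidy)

#' @rdname accessors
#' @export
setMethod("nMarkers", "GenotypeMatrix", function(x) nrow(x))

#' @rdname accessors
#' @export
setMethod("nSamples", "GenotypeMatrix", function(x) ncol(x))

setMethod("show", "GenotypeMatrix", function(object) {
  d <- assay(object, "dosage")
  miss <- mean(is.na(d))
  cat("GenotypeMatrix:", nrow(object), "markers x", ncol(object), "samples",
      sprintf("| ploidy %d | %.1f%% missing\n",
              metadata(object)$ploidy, 100 * miss))
  chroms <- unique(rowData(object)$chrom)
  cat("  chromosomes:", paste(head(chroms, 15), collapse = " "),
      if (length(chroms) > 15) "..." else "", "\n")
})
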