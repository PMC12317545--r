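#' Read a phenotype table from CSV
#'
#' Reads greenhouse phenotype measurements into a [PhenotypeTable]. Two
#' dialects are supported: `"long"` (columns `genotype_id`, `treatment`,
#' `replicate`, `trait`, `value`) and `"wide"` (columns `genotype_id`,
#' `treatment`, `replicate` plus one column per trait code). Internally the
#' table is always long. Validation failures are reported with the file line
#' numbers of the offending rows; missing values are kept as `NA`.
#'
#' @param path path to a CSV file.
#' @param format `"long"` or `"wide"`.
#' @param sep field separator (default `","`).
#' @return a [PhenotypeTable].
#' @export
readPhenotypeTable <- function(path, format = c("long", "wide"), sep = ",") {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("phenotype file not found: %s", path)
  raw <- read.csv(path, sep = sep, check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (!nrow(raw)) .stopf("phenotype file is empty: %s", path)
  if (format == "long") {
    needed <- c("genotype_id", "treatment", "replicate", "trait", "value")
    miss <- setdiff(needed, names(raw))
    if (length(miss)) {
      .stopf("long-format phenotype CSV lacks column(s): %s",
             paste(miss, collapse = ", "))
    }
    rec <- raw[needed]
    # file line = data row + header line
    line_of_row <- seq_len(nrow(rec)) + 1L
  } else {
    keys <- c("genotype_id", "treatment", "replicate")
    miss <- setdiff(keys, names(raw))
    if (length(miss)) {
      .stopf("wide-format phenotype CSV lacks column(s): %s",
             paste(miss, collapse = ", "))
    }
    traits <- setdiff(names(raw), keys)
    if (!length(traits)) .stopf("wide-format phenotype CSV has no trait columns")
    rec <- do.call(rbind, lapply(traits, function(tr) {
      data.frame(genotype_id = raw$genotype_id, treatment = raw$treatment,
                 replicate = raw$replicate, trait = tr,
                 value = as.numeric(raw[[tr]]),
                 src_row = seq_len(nrow(raw)), stringsAsFactors = FALSE)
    }))
    line_of_row <- rec$src_row + 1L
    rec$src_row <- NULL
  }
  rec$genotype_id <- as.character(rec$genotype_id)
  rec$treatment <- as.character(rec$treatment)
  rec$replicate <- as.numeric(rec$replicate)
  rec$trait <- as.character(rec$trait)
  rec$value <- as.numeric(rec$value)
  probs <- .phenoProblems(rec)
  if (nrow(probs)) {
    msg <- paste(sprintf("line %d: %s", line_of_row[probs$row], probs$problem),
                 collapse = "\n  ")
    .stopf("invalid phenotype records in %s:\n  %s", path, msg)
  }
  PhenotypeTable(rec)
}

#' Write a phenotype table to CSV
#'
#' @param x a [PhenotypeTable].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePhenotypeTable <- function(x, path) {
  stopifnot(is(x, "PhenotypeTable"))
  write.csv(phenoRecords(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
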