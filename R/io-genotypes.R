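#' Read biallelic SNP genotypes from VCF
#'
#' Parses a VCF (v4.x) with a `GT` FORMAT field into a [GenotypeMatrix] of
#' alternate-allele counts: for diploid calls `0/0 -> 0`, `0/1 -> 1`,
#' `1/1 -> 2`, `./. -> NA` (and analogously for higher ploidy, counting `1`
#' alleles among the called copies). Records with more than one ALT allele
#' are skipped and their count reported via `message()`. Phased separators
#' (`|`) are accepted.
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @param ploidy expected ploidy of the GT calls (default 2, matching
#'   diploidized GBS consensus calls; use 4 for tetraploid dosages).
#' @return a [GenotypeMatrix].
#' @export
readGenotypesVcf <- function(path, ploidy = 2L) {
  if (!file.exists(path)) .stopf("VCF not found: %s", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)      # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) .stopf("VCF contains no variant records: %s", path)
  if (ncol(vcf@gt) < 2L) .stopf("VCF has no sample genotype columns: %s", path)
  fmt <- vcf@gt[, "FORMAT"]
  if (!all(vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, logical(1)))) {
    .stopf("VCF records lack a GT FORMAT field: %s", path)
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    message(sprintf("readGenotypesVcf: skipped %d multiallelic record(s)",
                    sum(multi)))
  }
  keep <- !multi
  if (!any(keep)) .stopf("no biallelic records left in %s", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  # translate the small set of distinct GT strings once
  lv <- unique(as.vector(gt))
  dose_of <- vapply(lv, function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al == "1")
  }, numeric(1))
  d <- matrix(dose_of[match(as.vector(gt), lv)], nrow = nrow(gt))
  colnames(d) <- colnames(gt)

  id <- fix$ID
  id[is.na(id) | id == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(id) | id == "."]
  markers <- data.frame(marker_id = id, chrom = fix$CHROM,
                        pos = as.integer(fix$POS), ref = fix$REF,
                        alt = fix$ALT, stringsAsFactors = FALSE)
  GenotypeMatrix(t(d), markers, sampleIds = colnames(gt),
                 ploidy = as.integer(ploidy))
}

#' Write a GenotypeMatrix as plain-text VCF
#'
#' Emits an uncompressed VCFv4.2 file with a GT field reconstructed from
#' integer dosages (diploid: `0 -> 0/0`, `1 -> 0/1`, `2 -> 1/1`,
#' `NA -> ./.`; for higher ploidy the alternate copies are listed last).
#' Fractional (imputed) dosages cannot be represented and raise an error.
#'
#' @param x a [GenotypeMatrix] with integer dosages.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypesVcf <- function(x, path) {
  stopifnot(is(x, "GenotypeMatrix"))
  d <- assay(x, "dosage")           # markers x samples
  if (any(d != round(d), na.rm = TRUE)) {
    .stopf("cannot write fractional (imputed) dosages as GT calls")
  }
  pl <- ploidy(x)
  gt_of <- vapply(0:pl, function(k) {
    paste(c(rep("0", pl - k), rep("1", k)), collapse = "/")
  }, character(1))
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  if (pl != 2L) gt[] <- paste(rep(".", pl), collapse = "/")
  ok <- !is.na(d)
  gt[ok] <- gt_of[d[ok] + 1L]
  mi <- markerInfo(x)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=phosGWAS",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleIds(x)), collapse = "\t")
  )
  body <- paste(mi$chrom, mi$pos, mi$marker_id, mi$ref, mi$alt, ".", "PASS",
                ".", "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write dosage CSV
#'
#' Dosage CSV interchange format: one row per marker with columns
#' `marker_id`, `chrom`, `pos`, `ref`, `alt` followed by one column per
#' sample holding the alternate-allele dosage (empty = missing). A round
#' trip through [writeDosageCsv()] and [readDosageCsv()] reproduces the
#' dosage matrix, sample order and marker map exactly.
#'
#' @param path CSV path.
#' @param ploidy maximum dosage (default 2).
#' @return [readDosageCsv()] returns a [GenotypeMatrix];
#'   [writeDosageCsv()] returns `path` invisibly.
#' @export
readDosageCsv <- function(path, ploidy = 2L) {
  if (!file.exists(path)) .stopf("dosage CSV not found: %s", path)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("marker_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(needed, names(raw))
  if (length(miss)) {
    .stopf("dosage CSV lacks column(s): %s", paste(miss, collapse = ", "))
  }
  samples <- setdiff(names(raw), needed)
  if (!length(samples)) .stopf("dosage CSV has no sample columns")
  d <- t(as.matrix(raw[samples]))           # samples x markers
  storage.mode(d) <- "double"
  GenotypeMatrix(d, raw[needed], sampleIds = samples,
                 ploidy = as.integer(ploidy))
}

#' @rdname readDosageCsv
#' @param x a [GenotypeMatrix].
#' @export
writeDosageCsv <- function(x, path) {
  stopifnot(is(x, "GenotypeMatrix"))
  out <- cbind(markerInfo(x)[c("marker_id", "chrom", "pos", "ref", "alt")],
               as.data.frame(assay(x, "dosage"), check.names = FALSE))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
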