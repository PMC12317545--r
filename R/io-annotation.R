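#' Read gene annotation from GFF3
#'
#' Imports features of one type (default `"gene"`) from a GFF3 file into a
#' `GRanges` with metadata columns `gene_id` (from the `ID` attribute) and
#' `description` (from `description` or `Note`, empty when absent).
#' Coordinates stay 1-based inclusive per the GFF3 convention, matching the
#' 1-based SNP positions used throughout the package. Features are sorted
#' by (chromosome, start) and `gene_id` must be unique.
#'
#' @param path path to a GFF3 file.
#' @param featureType feature type to keep (column 3 of the GFF3).
#' @return a `GRanges` of gene records.
#' @export
readGeneAnnotation <- function(path, featureType = "gene") {
  if (!file.exists(path)) .stopf("GFF3 not found: %s", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) .stopf("malformed GFF3 %s: %s", path, conditionMessage(e))
  )
  gr <- gr[!is.na(mcols(gr)$type) & as.character(mcols(gr)$type) == featureType]
  if (!length(gr)) {
    .stopf("no '%s' features found in %s", featureType, path)
  }
  id <- as.character(mcols(gr)$ID)
  if (any(is.na(id) | id == "")) {
    .stopf("GFF3 '%s' features without an ID attribute in %s", featureType, path)
  }
  if (anyDuplicated(id)) .stopf("duplicate gene IDs in %s", path)
  desc <- mcols(gr)$description
  if (is.null(desc)) desc <- mcols(gr)$Note
  if (is.null(desc)) desc <- rep("", length(gr))
  desc <- vapply(desc, function(x) paste(as.character(x), collapse = "; "),
                 character(1))
  desc[is.na(desc)] <- ""
  out <- GRanges(seqnames = as.character(seqnames(gr)),
                 ranges = IRanges(start(gr), end(gr)))
  mcols(out)$gene_id <- unname(id)
  mcols(out)$description <- unname(desc)
  ord <- .markerOrder(as.character(seqnames(out)), start(out))
  out[ord]
}
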