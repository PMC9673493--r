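# Feature annotations: rRNA / tRNA / CDS features with full-length and
# partial flags, carried as a plain data.frame with columns
#   contig_id, start, end, strand, feature_type, full_length, isotype,
#   partial_flags
# Coordinates are 1-based inclusive (GFF convention) throughout.

FEATURE_TYPES <- c("rRNA_5S", "rRNA_16S", "rRNA_23S", "tRNA", "CDS")

empty_annotations <- function() {
  data.frame(contig_id = character(), start = integer(), end = integer(),
             strand = character(), feature_type = character(),
             full_length = logical(), isotype = character(),
             partial_flags = character())
}

validate_annotations <- function(ann) {
  need <- c("contig_id", "start", "end", "strand", "feature_type",
            "full_length")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotations missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(ann$start > ann$end)) {
    bad <- which(ann$start > ann$end)[1]
    stop(sprintf("feature on %s has start %d > end %d",
                 ann$contig_id[bad], ann$start[bad], ann$end[bad]))
  }
  if (!all(ann$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(ann$feature_type %in% FEATURE_TYPES)) {
    stop("unknown feature_type: ",
         setdiff(ann$feature_type, FEATURE_TYPES)[1])
  }
  if (!"isotype" %in% names(ann)) ann$isotype <- NA_character_
  if (!"partial_flags" %in% names(ann)) ann$partial_flags <- NA_character_
  ann
}

#' Read rRNA/tRNA/CDS feature annotations from GFF3
#'
#' Expects the attributes `full_length=true|false`, `isotype=<aa>` (tRNA)
#' and `partial=<2-digit code>` (CDS; `"00"` means both gene edges
#' present). Rows whose type is not one of `rRNA_5S`, `rRNA_16S`,
#' `rRNA_23S`, `tRNA`, `CDS` are skipped with a warning. Coordinates stay
#' 1-based inclusive.
#'
#' @param path Path to a GFF3 file.
#' @return Annotation data.frame (one row per feature).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gff <- rtracklayer::readGFF(path)
  gff <- as.data.frame(gff, stringsAsFactors = FALSE)
  known <- gff$type %in% FEATURE_TYPES
  if (any(!known)) {
    warning("skipping ", sum(!known), " feature(s) of unknown type: ",
            paste(unique(gff$type[!known]), collapse = ", "))
    gff <- gff[known, , drop = FALSE]
  }
  ann <- data.frame(
    contig_id = as.character(gff$seqid),
    start = as.integer(gff$start),
    end = as.integer(gff$end),
    strand = as.character(gff$strand),
    feature_type = as.character(gff$type),
    full_length = tolower(gff$full_length %||% "true") == "true",
    isotype = as.character(gff$isotype %||% NA_character_),
    partial_flags = as.character(gff$partial %||% NA_character_)
  )
  validate_annotations(ann)
}

#' Write feature annotations as GFF3
#'
#' @param ann Annotation data.frame as produced by [read_annotations()] or
#'   [simulate_annotations()].
#' @param path Output path.
#' @param source Value for the GFF source column.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(ann, path, source = "magcurate") {
  ann <- validate_annotations(ann)
  attrs <- sprintf("ID=feat%d;full_length=%s", seq_len(nrow(ann)),
                   tolower(as.character(ann$full_length)))
  has_iso <- !is.na(ann$isotype)
  attrs[has_iso] <- paste0(attrs[has_iso], ";isotype=", ann$isotype[has_iso])
  has_part <- !is.na(ann$partial_flags)
  attrs[has_part] <- paste0(attrs[has_part], ";partial=",
                            ann$partial_flags[has_part])
  rows <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                  ann$contig_id, source, ann$feature_type,
                  ann$start, ann$end, ann$strand, attrs)
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Read a genome metadata table
#'
#' Tab-separated with header columns `genome_id`, `is_circular`,
#' `assembly_size`, `n_contigs`, `completeness`, `contamination` and
#' optionally `compartment`.
#'
#' @param path Path to the TSV.
#' @return Metadata data.frame.
#' @export
read_genome_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  md <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_metadata(md)
}

validate_metadata <- function(md) {
  need <- c("genome_id", "is_circular", "assembly_size", "n_contigs",
            "completeness", "contamination")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"compartment" %in% names(md)) md$compartment <- NA_character_
  md$is_circular <- as.logical(md$is_circular)
  if (anyDuplicated(md$genome_id)) stop("duplicate genome_id in metadata")
  if (any(md$completeness < 0 | md$completeness > 100)) {
    stop("completeness must lie in [0, 100]")
  }
  if (any(md$contamination < 0)) stop("contamination must be >= 0")
  if (any(md$is_circular & md$n_contigs != 1L)) {
    stop("a circular genome must consist of exactly 1 contig")
  }
  md
}

#' Write a genome metadata table (TSV)
#' @param md Metadata data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome_metadata <- function(md, path) {
  md <- validate_metadata(md)
  write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
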