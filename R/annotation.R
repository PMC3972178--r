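# Genomic annotation: promoter regions around the TSS and the probes tiling
# them. Coordinates are 0-based half-open (BED convention) throughout the
# package; human-facing reports convert to 1-based inclusive.

PROMOTER_UPSTREAM <- 1000L   # bp upstream of the TSS (transcription sense)
PROMOTER_DOWNSTREAM <- 250L  # bp downstream of the TSS

#' Construct a genomic annotation
#'
#' Cross-links probes to the promoters they tile and validates coordinates.
#' Promoter regions are derived from TSS and strand: the region spans
#' 1000 bp upstream to 250 bp downstream of the TSS in transcription
#' orientation, so minus-strand promoters extend to higher genomic
#' coordinates on the upstream side.
#'
#' @param chromosome_lengths Named integer vector, chromosome name to length
#'   in bp.
#' @param probes data.frame with columns `probe_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `promoter_id`.
#' @param promoters data.frame with columns `promoter_id`, `gene_symbol`,
#'   `chrom`, `tss`, `strand` (`+`/`-`), `cpg_count`, `c_count`, `g_count`,
#'   `length_bp`.
#' @return A list of class `medip_annotation` with elements
#'   `chromosome_lengths`, `probes`, `promoters`; the promoter table gains
#'   derived `region_start`/`region_end` columns.
#' @export
medip_annotation <- function(chromosome_lengths, probes, promoters) {
  stopifnot(is.data.frame(probes), is.data.frame(promoters))
  need_probe <- c("probe_id", "chrom", "start", "end", "promoter_id")
  need_prom <- c("promoter_id", "gene_symbol", "chrom", "tss", "strand",
                 "cpg_count", "c_count", "g_count", "length_bp")
  miss <- setdiff(need_probe, names(probes))
  if (length(miss)) stop("probe table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(need_prom, names(promoters))
  if (length(miss)) stop("promoter table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(names(chromosome_lengths)) || any(chromosome_lengths <= 0)) {
    stop("'chromosome_lengths' must be a named vector of positive lengths",
         call. = FALSE)
  }
  probes <- probes[, need_probe]
  promoters <- promoters[, need_prom]
  probes$probe_id <- as.character(probes$probe_id)
  probes$promoter_id <- as.character(probes$promoter_id)
  promoters$promoter_id <- as.character(promoters$promoter_id)

  promoters$region_start <- ifelse(
    promoters$strand == "+",
    promoters$tss - PROMOTER_UPSTREAM,
    promoters$tss - PROMOTER_DOWNSTREAM
  )
  promoters$region_end <- promoters$region_start +
    PROMOTER_UPSTREAM + PROMOTER_DOWNSTREAM

  ann <- structure(
    list(chromosome_lengths = chromosome_lengths,
         probes = probes, promoters = promoters),
    class = "medip_annotation"
  )
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  probes <- ann$probes
  promoters <- ann$promoters
  lens <- ann$chromosome_lengths

  if (anyDuplicated(promoters$promoter_id)) {
    stop("duplicated promoter_id in promoter table", call. = FALSE)
  }
  if (anyDuplicated(probes$probe_id)) {
    stop("duplicated probe_id in probe table", call. = FALSE)
  }
  if (!all(promoters$strand %in% c("+", "-"))) {
    stop("promoter strand must be '+' or '-'", call. = FALSE)
  }
  bad_chrom <- setdiff(unique(c(probes$chrom, promoters$chrom)), names(lens))
  if (length(bad_chrom)) {
    stop("chromosome(s) without a declared length: ",
         paste(bad_chrom, collapse = ", "), call. = FALSE)
  }

  if (nrow(probes) > 0) {
    bad <- which(!(probes$start >= 0 & probes$start < probes$end &
                     probes$end <= lens[probes$chrom]))
    if (length(bad)) {
      stop("probe interval out of bounds or start >= end at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    idx <- match(probes$promoter_id, promoters$promoter_id)
    if (anyNA(idx)) {
      bad <- which(is.na(idx))
      stop("probe(s) reference unknown promoter_id: ",
           paste(utils::head(probes$probe_id[bad], 5), collapse = ", "),
           call. = FALSE)
    }
    inside <- probes$chrom == promoters$chrom[idx] &
      probes$start >= promoters$region_start[idx] &
      probes$end <= promoters$region_end[idx]
    if (!all(inside)) {
      bad <- which(!inside)
      stop("probe(s) outside their promoter region: ",
           paste(utils::head(probes$probe_id[bad], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  if (nrow(promoters) > 0) {
    bad <- which(!(promoters$region_start >= 0 &
                     promoters$region_end <= lens[promoters$chrom]))
    if (length(bad)) {
      stop("promoter region out of chromosome bounds for: ",
           paste(utils::head(promoters$promoter_id[bad], 5), collapse = ", "),
           call. = FALSE)
    }
    with_counts <- !is.na(promoters$cpg_count)
    if (any(promoters$cpg_count[with_counts] >
              pmin(promoters$c_count[with_counts],
                   promoters$g_count[with_counts]))) {
      stop("cpg_count exceeds min(c_count, g_count) for some promoter",
           call. = FALSE)
    }
  }
  ann
}

#' Read a genomic annotation from disk
#'
#' @param probe_bed Path to a BED6-compatible probe file (chrom, start, end,
#'   probe_id, score, strand) with an extra seventh column `promoter_id`.
#' @param promoter_table Path to a TSV with columns `promoter_id`,
#'   `gene_symbol`, `chrom`, `tss`, `strand`, `cpg_count`, `c_count`,
#'   `g_count`, `length_bp`.
#' @param chrom_sizes Optional path to a two-column TSV (chrom, length). When
#'   omitted, each chromosome's length is taken as the largest end coordinate
#'   seen on it.
#' @return A `medip_annotation`.
#' @export
read_annotation <- function(probe_bed, promoter_table, chrom_sizes = NULL) {
  for (p in c(probe_bed, promoter_table, chrom_sizes)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  bed <- utils::read.delim(probe_bed, header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "character", "integer", "character",
                                          "character"))
  if (ncol(bed) != 7) {
    stop("probe BED must have 7 columns (BED6 + promoter_id), found ",
         ncol(bed), call. = FALSE)
  }
  names(bed) <- c("chrom", "start", "end", "probe_id", "score", "strand",
                  "promoter_id")
  probes <- bed[, c("probe_id", "chrom", "start", "end", "promoter_id")]

  promoters <- utils::read.delim(promoter_table, header = TRUE,
                                 stringsAsFactors = FALSE)
  need <- c("promoter_id", "gene_symbol", "chrom", "tss", "strand",
            "cpg_count", "c_count", "g_count", "length_bp")
  miss <- setdiff(need, names(promoters))
  if (length(miss)) {
    stop("promoter table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  if (is.null(chrom_sizes)) {
    ends <- c(tapply(probes$end, probes$chrom, max),
              tapply(promoters$tss + PROMOTER_UPSTREAM, promoters$chrom, max))
    lens <- tapply(ends, names(ends), max)
    lens <- stats::setNames(as.numeric(lens), names(lens))
  } else {
    cs <- utils::read.delim(chrom_sizes, header = FALSE,
                            stringsAsFactors = FALSE)
    lens <- stats::setNames(as.numeric(cs[[2]]), as.character(cs[[1]]))
  }
  medip_annotation(lens, probes, promoters)
}

#' Write a genomic annotation to disk
#'
#' Writes three files into `dir`: `probes.bed` (BED6 + promoter_id),
#' `promoters.tsv`, and `chrom.sizes`. The on-disk representation
#' round-trips through [read_annotation()] byte-identically.
#'
#' @param annotation A `medip_annotation`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written (named character vector).
#' @export
write_annotation <- function(annotation, dir) {
  stopifnot(inherits(annotation, "medip_annotation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(probes = file.path(dir, "probes.bed"),
             promoters = file.path(dir, "promoters.tsv"),
             chrom_sizes = file.path(dir, "chrom.sizes"))

  pr <- annotation$probes
  bed <- data.frame(chrom = pr$chrom, start = pr$start, end = pr$end,
                    probe_id = pr$probe_id, score = 0L, strand = ".",
                    promoter_id = pr$promoter_id)
  utils::write.table(bed, paths["probes"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  pm <- annotation$promoters
  pm <- pm[, c("promoter_id", "gene_symbol", "chrom", "tss", "strand",
               "cpg_count", "c_count", "g_count", "length_bp")]
  utils::write.table(pm, paths["promoters"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  cs <- data.frame(chrom = names(annotation$chromosome_lengths),
                   length = as.numeric(annotation$chromosome_lengths))
  utils::write.table(cs, paths["chrom_sizes"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

# probe -> promoter row index lookup
probe_promoter_index <- function(annotation) {
  match(annotation$probes$promoter_id, annotation$promoters$promoter_id)
}

# interval midpoints of probes, used for window assignment and distances
probe_midpoints <- function(annotation) {
  (annotation$probes$start + annotation$probes$end) / 2
}
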