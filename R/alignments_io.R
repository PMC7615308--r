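#' Write aligned read records to SAM or TSV
#'
#' Two on-disk dialects carry the same records:
#'
#' * **TSV**: 8 columns `read_id, cell, umi, chrom, strand, start, cigar,
#'   mapq` with a header line; `start` is 0-based; missing UMIs are written
#'   as `NA`. The TSV dialect round-trips losslessly and in order through
#'   [load_alignments()].
#' * **SAM**: one `@SQ` line per chromosome (length padded past the last
#'   aligned base), reads carry the cell barcode in the `CB` tag and the UMI
#'   in the `UB` tag, strand is encoded in FLAG bit 0x10, and `POS` is
#'   1-based per the SAM convention. Sequences are written as `*` (the
#'   simulator generates alignments, not bases). Reading SAM goes through
#'   BAM conversion, which coordinate-sorts, so SAM round-trips preserve the
#'   record set but not row order.
#'
#' @param records data.frame with columns read_id, cell, umi, chrom, strand,
#'   start (0-based), cigar, mapq
#' @param path output file
#' @param dialect `"TSV"` or `"SAM"`
#' @return `path`, invisibly
#' @export
write_alignments <- function(records, path, dialect = c("TSV", "SAM")) {
  dialect <- match.arg(dialect)
  req <- c("read_id", "cell", "umi", "chrom", "strand", "start", "cigar",
           "mapq")
  if (!all(req %in% names(records)))
    stop("'records' must have columns: ", paste(req, collapse = ", "))
  records <- records[, req]
  if (dialect == "TSV") {
    write_tsv(records, path)
    return(invisible(path))
  }
  # SAM
  widths <- if (nrow(records) > 0L)
    GenomicAlignments::cigarWidthAlongReferenceSpace(records$cigar)
  else integer(0)
  chroms <- unique(records$chrom)
  if (length(chroms) == 0L) chroms <- "unknown"
  sq_len <- vapply(chroms, function(ch) {
    i <- which(records$chrom == ch)
    if (length(i) == 0L) 1000L
    else as.integer(max(records$start[i] + widths[i]) + 1000L)
  }, integer(1))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms, sq_len))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(records) > 0L) {
    flag <- ifelse(records$strand == "-", 16L, 0L)
    tags <- sprintf("CB:Z:%s", records$cell)
    has_umi <- !is.na(records$umi)
    tags[has_umi] <- paste0(tags[has_umi],
                            sprintf("\tUB:Z:%s", records$umi[has_umi]))
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*\t%s",
                       records$read_id, flag, records$chrom,
                       records$start + 1L, records$mapq, records$cigar,
                       tags), con)
  }
  invisible(path)
}

#' Load aligned read records from SAM or TSV
#'
#' Validates CIGAR strings (operation lengths must be positive integers) and
#' basic field sanity; a malformed record is reported with its line number.
#' Reads on chromosomes other than the junction's are retained - they are
#' classified NON_JUNCTION downstream, which keeps the read partition
#' accounting exact.
#'
#' @param path input file
#' @param dialect `"TSV"` or `"SAM"`
#' @return data.frame of records (see [write_alignments()] for columns)
#' @export
load_alignments <- function(path, dialect = c("TSV", "SAM")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "TSV") {
    df <- read_tsv(path, colClasses = c(
      read_id = "character", cell = "character", umi = "character",
      chrom = "character", strand = "character", start = "integer",
      cigar = "character", mapq = "integer"))
    validate_records(df, line_offset = 1L)  # header is line 1
    return(df)
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = c("CB", "UB"))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  n <- length(x$qname)
  umi <- x$tag$UB
  if (is.null(umi)) umi <- rep(NA_character_, n)
  df <- data.frame(read_id = x$qname,
                   cell = x$tag$CB %||% rep(NA_character_, n),
                   umi = umi,
                   chrom = as.character(x$rname),
                   strand = ifelse(bitwAnd(x$flag, 16L) > 0L, "-", "+"),
                   start = x$pos - 1L,
                   cigar = x$cigar,
                   mapq = x$mapq,
                   stringsAsFactors = FALSE)
  validate_records(df)
  df
}

#' @noRd
validate_records <- function(df, line_offset = 0L) {
  req <- c("read_id", "cell", "umi", "chrom", "strand", "start", "cigar",
           "mapq")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("alignment table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(invisible(df))
  bad_strand <- which(!df$strand %in% c("+", "-"))
  bad_start <- which(is.na(df$start) | df$start < 0L)
  bad_cigar <- which(!grepl("^([1-9][0-9]*[MIDNSHP=X])+$", df$cigar))
  bad <- c(bad_strand, bad_start, bad_cigar)
  if (length(bad) > 0L) {
    ln <- min(bad) + line_offset
    stop(sprintf("malformed alignment record at line %d (%s)", ln,
                 if (min(bad) %in% bad_cigar) "invalid CIGAR"
                 else if (min(bad) %in% bad_start) "invalid start"
                 else "invalid strand"))
  }
  invisible(df)
}
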