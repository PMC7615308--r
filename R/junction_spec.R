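#' Define the Wt1 exon-9 alternative donor junction
#'
#' A `junction_spec` pins down the genomic geometry of the two competing 5'
#' splice donors at the end of Wt1 exon 9: the canonical donor used by -KTS
#' transcripts and the alternative donor 9 nt further downstream (in
#' transcription direction) whose use appends the KTS codons, plus the shared
#' exon-10 acceptor. All coordinates are 0-based; a splice gap is the
#' half-open genomic interval `[first intronic base, first exonic base)`.
#' Conversion to SAM's 1-based coordinates happens only at the SAM boundary.
#'
#' On the `-` strand "downstream" means decreasing genomic coordinate:
#' `donor_minus` is still the first intronic base in transcription direction
#' (the genomically highest intronic base) and the +KTS donor sits at
#' `donor_minus - alt_offset`.
#'
#' Exact genome coordinates of the mouse Wt1 donors are configuration, not
#' code; the defaults are placeholder coordinates with the correct geometry.
#'
#' @param gene_id gene symbol, informational only
#' @param chrom chromosome name reads must match to be junction candidates
#' @param strand `"+"` or `"-"`; transcription direction
#' @param donor_minus 0-based coordinate of the first intronic base of the
#'   canonical (-KTS) junction
#' @param alt_offset nt extension of the +KTS donor relative to the canonical
#'   donor (9 for the three KTS codons)
#' @param acceptor 0-based coordinate of the first base of exon 10
#'   (transcription direction)
#' @param min_anchor minimum aligned bases required on each side of the splice
#'   gap for a confident isoform call
#' @param min_mapq minimum mapping quality for a confident isoform call
#' @return an object of class `junction_spec`
#' @examples
#' spec <- junction_spec(donor_minus = 1000, acceptor = 2000)
#' spec
#' @export
junction_spec <- function(gene_id = "Wt1", chrom = "2", strand = c("+", "-"),
                          donor_minus = 1000000L, alt_offset = 9L,
                          acceptor = 1001500L, min_anchor = 6L,
                          min_mapq = 20L) {
  strand <- match.arg(strand)
  alt_offset <- assert_count(alt_offset, "alt_offset")
  min_anchor <- assert_count(min_anchor, "min_anchor")
  min_mapq <- assert_count(min_mapq, "min_mapq", min = 0L)
  donor_minus <- as.integer(donor_minus)
  acceptor <- as.integer(acceptor)
  if (strand == "+" && donor_minus + alt_offset >= acceptor)
    stop("on the + strand 'donor_minus + alt_offset' must be < 'acceptor'")
  if (strand == "-" && donor_minus - alt_offset <= acceptor)
    stop("on the - strand 'donor_minus - alt_offset' must be > 'acceptor'")
  structure(list(gene_id = gene_id, chrom = as.character(chrom),
                 strand = strand, donor_minus = donor_minus,
                 alt_offset = alt_offset, acceptor = acceptor,
                 min_anchor = min_anchor, min_mapq = min_mapq),
            class = "junction_spec")
}

#' @export
print.junction_spec <- function(x, ...) {
  cat(sprintf("junction_spec for %s (%s%s)\n", x$gene_id, x$chrom, x$strand))
  cat(sprintf("  -KTS donor (first intronic base): %d\n", x$donor_minus))
  cat(sprintf("  +KTS donor offset: +%d nt downstream\n", x$alt_offset))
  cat(sprintf("  exon-10 acceptor: %d\n", x$acceptor))
  cat(sprintf("  filters: min_anchor=%d, min_mapq=%d\n",
              x$min_anchor, x$min_mapq))
  invisible(x)
}

#' Genomic splice-gap intervals implied by a junction spec
#'
#' Returns the 0-based half-open genomic intervals that a read's splice gap
#' must match exactly to support each isoform.
#'
#' @param spec a [junction_spec()]
#' @return list with elements `minus` and `plus`, each `c(start, end)`
#'   half-open, and `acceptor_side`: `"end"` if the acceptor-adjacent gap
#'   boundary is the genomic end of the gap (+ strand) or `"start"`
#'   (- strand)
#' @export
junction_gaps <- function(spec) {
  stopifnot(inherits(spec, "junction_spec"))
  if (spec$strand == "+") {
    list(minus = c(spec$donor_minus, spec$acceptor),
         plus = c(spec$donor_minus + spec$alt_offset, spec$acceptor),
         acceptor_side = "end")
  } else {
    list(minus = c(spec$acceptor + 1L, spec$donor_minus + 1L),
         plus = c(spec$acceptor + 1L, spec$donor_minus - spec$alt_offset + 1L),
         acceptor_side = "start")
  }
}

#' Read or write a junction spec as JSON
#'
#' @param path JSON file path
#' @return `read_junction_spec()` returns a [junction_spec()];
#'   `write_junction_spec()` returns `path` invisibly.
#' @export
read_junction_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  junction_spec(gene_id = j$gene_id %||% "Wt1",
                chrom = j$chrom %||% "2",
                strand = j$strand %||% "+",
                donor_minus = j$donor_minus,
                alt_offset = j$alt_offset %||% 9L,
                acceptor = j$acceptor,
                min_anchor = j$min_anchor %||% 6L,
                min_mapq = j$min_mapq %||% 20L)
}

#' @rdname read_junction_spec
#' @param spec a [junction_spec()]
#' @export
write_junction_spec <- function(spec, path) {
  stopifnot(inherits(spec, "junction_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
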