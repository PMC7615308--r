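#' Classify junction-spanning reads into +KTS / -KTS calls
#'
#' A read supports an isoform when it contains exactly one splice gap whose
#' genomic interval equals that isoform's junction gap (canonical donor to
#' acceptor for -KTS; the donor `alt_offset` nt downstream in transcription
#' direction for +KTS), its two aligned anchors flanking the gap are at least
#' `spec$min_anchor` bases, and its mapping quality is at least
#' `spec$min_mapq`. The full decision rule, applied per read:
#'
#' * `MINUS_KTS` / `PLUS_KTS` - one evaluable gap matching the respective
#'   isoform gap exactly, anchors and mapq pass;
#' * `AMBIGUOUS` - the gap reaches the acceptor but starts at neither donor
#'   (e.g. perturbed alignments), or it matches a donor but anchors/mapq
#'   fail;
#' * `NON_JUNCTION` - everything else: wrong chromosome or strand, no gap,
#'   a gap not reaching the acceptor, or several gaps reaching it.
#'
#' Reads with more than one gap are evaluated only on the single gap that
#' reaches the acceptor, if exactly one does. Contiguous (ungapped) reads
#' overlapping the 9-nt extension are not +KTS evidence by default since
#' they cannot exclude an unspliced (intronic) origin; set
#' `contiguous_plus = TRUE` to count an ungapped read that spans the
#' canonical donor boundary with `min_anchor` bases on both sides as
#' `PLUS_KTS` support.
#'
#' Coordinates are 0-based half-open throughout; gap = `[first intronic
#' base, first exonic base)` in genomic orientation.
#'
#' @param records alignment data.frame (see [load_alignments()])
#' @param spec a [junction_spec()]
#' @param contiguous_plus count ungapped reads spanning the canonical donor
#'   boundary as +KTS evidence
#' @return data.frame with columns read_id, cell, umi, call; `call` is one
#'   of `"PLUS_KTS"`, `"MINUS_KTS"`, `"AMBIGUOUS"`, `"NON_JUNCTION"` -
#'   exactly one call per read, so calls partition the input.
#' @examples
#' spec <- junction_spec(donor_minus = 1000, acceptor = 2000)
#' r <- data.frame(read_id = "r1", cell = "c1", umi = NA, chrom = "2",
#'                 strand = "+", start = 980, cigar = "20M1000N20M",
#'                 mapq = 60)
#' classify_reads(r, spec)$call  # MINUS_KTS
#' @export
classify_reads <- function(records, spec, contiguous_plus = FALSE) {
  stopifnot(inherits(spec, "junction_spec"))
  n <- nrow(records)
  out <- data.frame(read_id = records$read_id, cell = records$cell,
                    umi = if ("umi" %in% names(records)) records$umi
                          else NA_character_,
                    call = rep("NON_JUNCTION", n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)

  gp <- junction_gaps(spec)
  on_target <- records$chrom == spec$chrom & records$strand == spec$strand
  blocks <- GenomicAlignments::extractAlignmentRangesOnReference(
    records$cigar, pos = records$start + 1L, drop.D.ranges = FALSE)
  bdf <- as.data.frame(IRanges::gaps(blocks))
  # 0-based half-open gap coordinates with their read index
  ridx <- bdf$group
  gs <- bdf$start - 1L
  ge <- bdf$end
  ngap <- tabulate(ridx, nbins = n)

  at_acceptor <- if (gp$acceptor_side == "end") ge == gp$minus[2L]
                 else gs == gp$minus[1L]
  n_at_acc <- tabulate(ridx[at_acceptor], nbins = n)

  # evaluable: exactly one acceptor-reaching gap on an on-target read
  eval_gap <- at_acceptor & n_at_acc[ridx] == 1L & on_target[ridx]
  if (any(eval_gap)) {
    ri <- ridx[eval_gap]
    egs <- gs[eval_gap]
    ege <- ge[eval_gap]
    # anchors: widths of the aligned blocks flanking the evaluated gap
    blk <- as.data.frame(blocks)
    nblk <- tabulate(blk$group, nbins = n)
    boff <- cumsum(c(0L, nblk))[ri]
    gpos <- (seq_along(ridx) -
               cumsum(c(0L, ngap))[ridx])[eval_gap]  # gap rank within read
    left_anchor <- blk$width[boff + gpos]
    right_anchor <- blk$width[boff + gpos + 1L]
    pass <- left_anchor >= spec$min_anchor &
      right_anchor >= spec$min_anchor &
      !is.na(records$mapq[ri]) & records$mapq[ri] >= spec$min_mapq
    is_minus <- egs == gp$minus[1L] & ege == gp$minus[2L]
    is_plus <- egs == gp$plus[1L] & ege == gp$plus[2L]
    call <- rep("AMBIGUOUS", length(ri))
    call[is_minus & pass] <- "MINUS_KTS"
    call[is_plus & pass] <- "PLUS_KTS"
    out$call[ri] <- call
  }

  if (contiguous_plus) {
    # ungapped read covering the canonical donor boundary with min_anchor
    # aligned bases on each side: the alignment continues past the donor
    # into the 9-nt extension, which a spliced -KTS mRNA cannot produce
    blk <- as.data.frame(blocks)
    nblk <- tabulate(blk$group, nbins = n)
    cand <- which(ngap == 0L & nblk == 1L & on_target)
    if (length(cand) > 0L) {
      row1 <- match(cand, blk$group)
      fs <- blk$start[row1] - 1L
      fe <- blk$end[row1]
      a <- spec$min_anchor
      bound <- if (spec$strand == "+") spec$donor_minus
               else spec$donor_minus + 1L
      spans <- fs <= bound - a & fe >= bound + a
      out$call[cand[spans]] <- "PLUS_KTS"
    }
  }
  out
}

#' @rdname classify_reads
#' @param r a single-row alignment data.frame
#' @return `classify_read()` returns the call string for one record.
#' @export
classify_read <- function(r, spec, contiguous_plus = FALSE) {
  classify_reads(r[1L, , drop = FALSE], spec,
                 contiguous_plus = contiguous_plus)$call
}
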