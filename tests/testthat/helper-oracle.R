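# Brute-force reference classifier, independent of the package's CIGAR-walk
# route: it reconstructs the read's genomic footprint base by base and
# string-matches the local footprint around the acceptor-reaching gap
# against the two isoform junction footprints.

oracle_footprint <- function(start, cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", toks))
  ops <- sub("^[0-9]+", "", toks)
  pos <- start
  covered <- integer(0)
  for (t in seq_along(ops)) {
    if (ops[t] %in% c("M", "=", "X", "D")) {
      covered <- c(covered, seq.int(pos, length.out = lens[t]))
      pos <- pos + lens[t]
    } else if (ops[t] == "N") {
      pos <- pos + lens[t]
    }
    # I, S, H, P consume no reference
  }
  covered
}

oracle_classify <- function(rec, spec) {
  if (rec$chrom != spec$chrom || rec$strand != spec$strand)
    return("NON_JUNCTION")
  covered <- oracle_footprint(rec$start, rec$cigar)
  if (length(covered) == 0L) return("NON_JUNCTION")
  # runs of consecutive covered positions
  run_id <- cumsum(c(1L, diff(covered) != 1L))
  runs <- split(covered, run_id)
  if (length(runs) == 1L) return("NON_JUNCTION")
  # gap g sits between runs[[g]] and runs[[g+1]]
  gap_start <- vapply(seq_len(length(runs) - 1L),
                      function(g) runs[[g]][length(runs[[g]])] + 1L,
                      integer(1))
  gap_end <- vapply(seq_len(length(runs) - 1L),
                    function(g) runs[[g + 1L]][1L], integer(1))
  reaches_acceptor <- if (spec$strand == "+") gap_end == spec$acceptor
                      else gap_start == spec$acceptor + 1L
  if (sum(reaches_acceptor) != 1L) return("NON_JUNCTION")
  g <- which(reaches_acceptor)
  local <- c(runs[[g]], runs[[g + 1L]])

  # isoform junction footprints: exonic positions flanking each junction,
  # written out base by base with a window wider than any anchor
  w <- length(covered) + 10L
  if (spec$strand == "+") {
    donor_plus <- spec$donor_minus + spec$alt_offset
    fp_minus <- c(seq(spec$donor_minus - w, spec$donor_minus - 1L),
                  seq(spec$acceptor, spec$acceptor + w))
    fp_plus <- c(seq(donor_plus - w, donor_plus - 1L),
                 seq(spec$acceptor, spec$acceptor + w))
    junction_left <- c(spec$donor_minus - 1L, donor_plus - 1L)
  } else {
    donor_plus <- spec$donor_minus - spec$alt_offset
    fp_minus <- c(seq(spec$acceptor - w, spec$acceptor),
                  seq(spec$donor_minus + 1L, spec$donor_minus + w))
    fp_plus <- c(seq(spec$acceptor - w, spec$acceptor),
                 seq(donor_plus + 1L, donor_plus + w))
    junction_left <- c(spec$acceptor, spec$acceptor)
  }
  matches_fp <- function(fp, jleft) {
    hit <- match(local, fp)
    if (anyNA(hit) || any(diff(hit) != 1L)) return(FALSE)
    jleft %in% local  # slice must straddle the junction
  }
  is_minus <- matches_fp(fp_minus, junction_left[1L])
  is_plus <- matches_fp(fp_plus, junction_left[2L])
  if (!is_minus && !is_plus) return("AMBIGUOUS")
  anchors_ok <- length(runs[[g]]) >= spec$min_anchor &&
    length(runs[[g + 1L]]) >= spec$min_anchor
  if (!anchors_ok || is.na(rec$mapq) || rec$mapq < spec$min_mapq)
    return("AMBIGUOUS")
  if (is_minus) "MINUS_KTS" else "PLUS_KTS"
}

oracle_classify_all <- function(records, spec) {
  vapply(seq_len(nrow(records)),
         function(i) oracle_classify(records[i, ], spec), character(1))
}

# small fixture builders -----------------------------------------------------

test_spec <- function(strand = "+", ...) {
  if (strand == "+")
    junction_spec(donor_minus = 1000L, acceptor = 2000L, strand = "+", ...)
  else
    junction_spec(donor_minus = 2000L, acceptor = 1000L, strand = "-", ...)
}

make_read <- function(start, cigar, read_id = "r1", cell = "c1",
                      umi = NA_character_, chrom = "2", strand = "+",
                      mapq = 60L) {
  data.frame(read_id = read_id, cell = cell, umi = umi, chrom = chrom,
             strand = strand, start = as.integer(start), cigar = cigar,
             mapq = as.integer(mapq), stringsAsFactors = FALSE)
}

# scene with nuclei on a fixed grid and optional explicit dots
grid_scene <- function(n_nuclei = 3L, dots = NULL, width = 200L,
                       height = 200L, pixel_size = 0.5, noise_sd = 0,
                       marker_positive = NULL, seed = 1L) {
  cx <- c(40, 120, 160, 60, 150, 100, 30, 170, 100, 40)[seq_len(n_nuclei)]
  cy <- c(40, 60, 150, 140, 110, 30, 100, 40, 170, 170)[seq_len(n_nuclei)]
  nuclei <- data.frame(cx = cx, cy = cy, ax = 12, ay = 9, intensity = 0.8)
  if (!is.null(marker_positive)) nuclei$marker_positive <- marker_positive
  image_scene_config(width, height, pixel_size, nuclei = nuclei,
                     dots = dots, noise_sd = noise_sd, seed = seed)
}
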