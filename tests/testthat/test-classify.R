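# spec geometry used throughout: + strand, -KTS gap [1000, 2000),
# +KTS gap [1009, 2000)

test_that("exact junction gaps give isoform calls, shifted gaps ambiguity", {
  spec <- test_spec()
  expect_equal(classify_read(make_read(980, "20M1000N20M"), spec),
               "MINUS_KTS")
  expect_equal(classify_read(make_read(989, "20M991N20M"), spec),
               "PLUS_KTS")
  # gap [1005, 2000): reaches the acceptor, starts at neither donor
  expect_equal(classify_read(make_read(985, "20M995N20M"), spec),
               "AMBIGUOUS")
  # gap [1000, 1990): right gap start, wrong end
  expect_equal(classify_read(make_read(980, "20M990N20M"), spec),
               "NON_JUNCTION")
})

test_that("anchor and mapq filters demote otherwise matching reads", {
  spec <- test_spec()  # min_anchor 6, min_mapq 20
  expect_equal(classify_read(make_read(995, "5M1000N20M"), spec),
               "AMBIGUOUS")
  expect_equal(classify_read(make_read(980, "20M1000N5M"), spec),
               "AMBIGUOUS")
  expect_equal(classify_read(make_read(994, "6M1000N6M"), spec),
               "MINUS_KTS")
  expect_equal(classify_read(make_read(980, "20M1000N20M", mapq = 10),
                             spec), "AMBIGUOUS")
})

test_that("off-target, ungapped and multi-gap reads are handled", {
  spec <- test_spec()
  expect_equal(classify_read(make_read(980, "20M1000N20M", chrom = "3"),
                             spec), "NON_JUNCTION")
  expect_equal(classify_read(make_read(980, "20M1000N20M", strand = "-"),
                             spec), "NON_JUNCTION")
  expect_equal(classify_read(make_read(500, "40M"), spec), "NON_JUNCTION")
  # two gaps, only the second reaches the acceptor -> evaluate it
  expect_equal(classify_read(make_read(880, "20M80N20M1000N20M"), spec),
               "MINUS_KTS")
  # two gaps both reaching the acceptor is impossible; two gaps neither
  # reaching it -> NON_JUNCTION
  expect_equal(classify_read(make_read(500, "20M50N20M50N20M"), spec),
               "NON_JUNCTION")
  # deletions do not split the anchor
  expect_equal(classify_read(make_read(977, "10M3D10M1000N20M"), spec),
               "MINUS_KTS")
})

test_that("contiguous reads over the extension need the opt-in flag", {
  spec <- test_spec()
  r <- make_read(990, "30M")  # covers [990, 1020): spans the -KTS donor
  expect_equal(classify_read(r, spec), "NON_JUNCTION")
  expect_equal(classify_read(r, spec, contiguous_plus = TRUE), "PLUS_KTS")
  # too short on the extension side of the donor boundary
  r2 <- make_read(990, "13M")
  expect_equal(classify_read(r2, spec, contiguous_plus = TRUE),
               "NON_JUNCTION")
})

test_that("calls partition any simulated read set", {
  spec <- test_spec()
  sim <- simulate_experiment(list(genotype_wt(), genotype_plus_ko()),
                             n_cells = 50, depth = 20, error_rate = 0.3,
                             seed = 21, spec = spec)
  calls <- classify_reads(sim$alignments, spec)
  expect_equal(nrow(calls), nrow(sim$alignments))
  expect_true(all(calls$call %in% c("PLUS_KTS", "MINUS_KTS", "AMBIGUOUS",
                                    "NON_JUNCTION")))
})

test_that("classification agrees with the footprint-matching oracle", {
  for (strand in c("+", "-")) {
    spec <- test_spec(strand)
    sim <- simulate_cells(genotype_wt(), 40, 25, error_rate = 0.25,
                          seed = 31, spec = spec, anchor_range = c(4L, 30L))
    rec <- sim$alignments
    # salt in structured edge cases
    extra <- do.call(rbind, list(
      make_read(980, "20M1000N20M", read_id = "e1"),
      make_read(980, "20M1000N20M", read_id = "e2", mapq = 5),
      make_read(500, "40M", read_id = "e3"),
      make_read(880, "20M80N20M1000N20M", read_id = "e4"),
      make_read(880, "20M80N20M980N20M", read_id = "e6"),
      make_read(995, "5M1000N20M", read_id = "e5")))
    extra$strand <- spec$strand
    if (strand == "-") extra <- extra[extra$read_id == "e3", , drop = FALSE]
    rec <- rbind(rec, extra)
    got <- classify_reads(rec, spec)$call
    want <- oracle_classify_all(rec, spec)
    expect_identical(got, want)
  }
})

test_that("mirroring a + strand scenario onto the - strand preserves calls", {
  spec_p <- test_spec("+")
  sim <- simulate_cells(genotype_wt(), 40, 25, error_rate = 0.25,
                        seed = 41, spec = spec_p)
  rec <- sim$alignments
  calls_p <- classify_reads(rec, spec_p)$call

  M <- 5000L  # reflect genomic coordinate p -> M - p
  spec_m <- junction_spec(donor_minus = M - spec_p$donor_minus,
                          acceptor = M - spec_p$acceptor, strand = "-",
                          alt_offset = spec_p$alt_offset,
                          min_anchor = spec_p$min_anchor,
                          min_mapq = spec_p$min_mapq)
  widths <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar)
  mirror <- rec
  mirror$strand <- "-"
  mirror$start <- M - (rec$start + widths) + 1L
  mirror$cigar <- vapply(rec$cigar, function(cg) {
    toks <- regmatches(cg, gregexpr("[0-9]+[A-Z=]", cg))[[1]]
    paste(rev(toks), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  calls_m <- classify_reads(mirror, spec_m)$call
  expect_identical(calls_m, calls_p)
})
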