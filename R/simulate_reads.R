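#' Simulate junction-spanning single-cell reads for a genotype
#'
#' Draws per-cell junction read counts from a Poisson distribution whose rate
#' is the genotype-adjusted depth (see [expected_isoform_rates()]), assigns
#' each read an isoform by the genotype's -KTS fraction, and emits one
#' junction-spanning gapped alignment per read: the splice gap runs from the
#' isoform's donor to the shared acceptor, flanked by aligned anchors whose
#' lengths are drawn uniformly from `anchor_range`. With probability
#' `error_rate` a read's donor-side gap boundary is perturbed by 1-3 nt
#' (both directions, uniform), which downstream classification reports as
#' AMBIGUOUS; this exercises classifier robustness without simulating
#' base-level sequencing errors.
#'
#' The returned truth table records, per cell, the expected -KTS fraction of
#' the genotype and the realised pre-error isoform counts.
#'
#' @param model a [genotype_model()]
#' @param n_cells number of cells to simulate
#' @param depth expected junction reads per cell of the WT/WT reference
#'   genotype
#' @param error_rate per-read probability of a donor-boundary perturbation,
#'   in `[0, 0.5)`
#' @param seed integer seed, or NULL to use the current RNG state; one seed
#'   drives a single sequential stream across cells (cells are generated in
#'   order, reads within cells in order)
#' @param spec [junction_spec()] defining the junction geometry
#' @param anchor_range integer range the two anchor lengths are drawn from
#' @param with_umi attach 8-nt UMIs to reads
#' @param mapq mapping quality written on every simulated read
#' @return list with `alignments` (data.frame: read_id, cell, umi, chrom,
#'   strand, start, cigar, mapq; 0-based starts) and `truth` (data.frame:
#'   cell_id, genotype, true_minus_fraction, n_minus_true, n_plus_true,
#'   n_total_true)
#' @examples
#' sim <- simulate_cells(genotype_plus_ko(), n_cells = 5, depth = 20,
#'                       seed = 1)
#' head(sim$truth)
#' @export
simulate_cells <- function(model, n_cells, depth, error_rate = 0,
                           seed = NULL, spec = junction_spec(),
                           anchor_range = c(20L, 40L), with_umi = TRUE,
                           mapq = 60L) {
  stopifnot(inherits(model, "genotype_model"),
            inherits(spec, "junction_spec"))
  n_cells <- assert_count(n_cells, "n_cells")
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0)
    stop("'depth' must be a single positive number")
  if (!is.numeric(error_rate) || length(error_rate) != 1L ||
      error_rate < 0 || error_rate >= 0.5)
    stop("'error_rate' must be in [0, 0.5)")
  set_seed_if(seed)

  rates <- expected_isoform_rates(model, depth)
  if (rates$lambda_total == 0)
    warning("genotype '", model$label,
            "' has no expressed alleles; simulating zero reads")
  bc <- random_barcodes(n_cells)
  n_tot <- rpois(n_cells, rates$lambda_total)
  mf <- if (rates$lambda_total > 0) rates$minus_fraction else 0
  n_minus <- rbinom(n_cells, n_tot, mf)

  truth <- data.frame(cell_id = bc, genotype = model$label,
                      true_minus_fraction = if (rates$lambda_total > 0)
                        rates$minus_fraction else NA_real_,
                      n_minus_true = n_minus,
                      n_plus_true = n_tot - n_minus,
                      n_total_true = n_tot,
                      stringsAsFactors = FALSE)

  total_reads <- sum(n_tot)
  if (total_reads == 0L) {
    aln <- data.frame(read_id = character(0), cell = character(0),
                      umi = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      cigar = character(0), mapq = integer(0),
                      stringsAsFactors = FALSE)
    return(list(alignments = aln, truth = truth))
  }

  cell_of <- rep(bc, n_tot)
  # per read: isoform (TRUE = -KTS); -KTS reads listed first within a cell
  is_minus <- unlist(lapply(seq_len(n_cells), function(i)
    rep(c(TRUE, FALSE), c(n_minus[i], n_tot[i] - n_minus[i]))))

  gp <- junction_gaps(spec)
  gs <- ifelse(is_minus, gp$minus[1L], gp$plus[1L])
  ge <- ifelse(is_minus, gp$minus[2L], gp$plus[2L])

  # donor-boundary perturbation: the donor side is the gap end that differs
  # between the two isoforms (genomic start on +, genomic end on -)
  err <- runif(total_reads) < error_rate
  if (any(err)) {
    delta <- sample(c(-3L, -2L, -1L, 1L, 2L, 3L), sum(err), replace = TRUE)
    if (gp$acceptor_side == "end") gs[err] <- gs[err] + delta
    else ge[err] <- ge[err] + delta
  }

  left <- sample(seq.int(anchor_range[1L], anchor_range[2L]),
                 total_reads, replace = TRUE)
  right <- sample(seq.int(anchor_range[1L], anchor_range[2L]),
                  total_reads, replace = TRUE)
  aln <- data.frame(
    read_id = sprintf("read%07d", seq_len(total_reads)),
    cell = cell_of,
    umi = if (with_umi) random_barcodes(total_reads, width = 8L,
                                        unique = FALSE)
          else NA_character_,
    chrom = spec$chrom,
    strand = spec$strand,
    start = as.integer(gs - left),
    cigar = sprintf("%dM%dN%dM", left, ge - gs, right),
    mapq = as.integer(mapq),
    stringsAsFactors = FALSE)
  list(alignments = aln, truth = truth)
}

#' Simulate a multi-genotype experiment
#'
#' Runs [simulate_cells()] once per genotype and row-binds alignments and
#' truth tables. Each genotype consumes its own block of the sequential RNG
#' stream started by `seed`.
#'
#' @param models list of [genotype_model()] objects
#' @param n_cells cells per genotype (recycled)
#' @param depth,error_rate,seed,spec,... passed to [simulate_cells()]
#' @return list with combined `alignments` and `truth`
#' @export
simulate_experiment <- function(models, n_cells, depth, error_rate = 0,
                                seed = NULL, spec = junction_spec(), ...) {
  stopifnot(is.list(models), length(models) >= 1L)
  n_cells <- rep_len(n_cells, length(models))
  set_seed_if(seed)
  sims <- lapply(seq_along(models), function(i)
    simulate_cells(models[[i]], n_cells[i], depth, error_rate,
                   seed = NULL, spec = spec, ...))
  aln <- do.call(rbind, lapply(sims, `[[`, "alignments"))
  if (nrow(aln) > 0L)
    aln$read_id <- sprintf("read%07d", seq_len(nrow(aln)))
  list(alignments = aln,
       truth = do.call(rbind, lapply(sims, `[[`, "truth")))
}
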