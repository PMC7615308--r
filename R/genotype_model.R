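#' Alleles and genotype models for isoform simulation
#'
#' An allele is characterised by what it can splice: a `WT` allele produces
#' both isoforms (+KTS with probability `wt_plus_fraction`), a `FRASIER`
#' allele carries an intron-9 donor mutation that abolishes the +KTS donor
#' and therefore emits -KTS transcripts only, and a `NULL` allele (whole-gene
#' knockout) emits nothing. `expression_budget` is a relative transcriptional
#' weight (default 1 per allele, so a two-WT genotype has total weight 2).
#'
#' @param kind `"WT"`, `"FRASIER"` or `"NULL"`
#' @param expression_budget non-negative relative expression weight
#' @return an object of class `allele`
#' @export
allele <- function(kind = c("WT", "FRASIER", "NULL"), expression_budget = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(expression_budget) || length(expression_budget) != 1L ||
      is.na(expression_budget) || expression_budget < 0)
    stop("'expression_budget' must be a single non-negative number")
  structure(list(kind = kind, expression_budget = expression_budget),
            class = "allele")
}

#' @description
#' `genotype_model()` pairs two alleles and fixes the splice behaviour of WT
#' alleles and whether transcriptional compensation applies. With
#' `compensation = TRUE` the total expected output of the non-NULL alleles is
#' held equal to the two-WT-allele total, reflecting the observation that
#' total WT1 output is unchanged when the +KTS donor is lost: a
#' FRASIER/FRASIER genotype then produces as many junction reads as WT/WT,
#' all of them -KTS, i.e. twice the WT/WT -KTS output when
#' `wt_plus_fraction = 0.5`.
#'
#' @param alleles list of exactly two [allele()] objects
#' @param wt_plus_fraction probability that a read from a WT allele is +KTS
#' @param compensation logical; hold the total expected output of non-NULL
#'   alleles equal to the two-WT total
#' @param label genotype label carried into truth tables (default built from
#'   the allele kinds, e.g. `"WT/FRASIER"`)
#' @rdname allele
#' @examples
#' wt <- genotype_model(list(allele("WT"), allele("WT")))
#' ko <- genotype_model(list(allele("FRASIER"), allele("FRASIER")))
#' expected_isoform_rates(wt, depth = 100)
#' expected_isoform_rates(ko, depth = 100)
#' @export
genotype_model <- function(alleles, wt_plus_fraction = 0.5,
                           compensation = TRUE, label = NULL) {
  if (!is.list(alleles) || length(alleles) != 2L ||
      !all(vapply(alleles, inherits, logical(1), "allele")))
    stop("'alleles' must be a list of exactly two allele() objects")
  assert_prob(wt_plus_fraction, "wt_plus_fraction")
  stopifnot(is.logical(compensation), length(compensation) == 1L)
  kinds <- vapply(alleles, `[[`, character(1), "kind")
  structure(list(alleles = alleles,
                 wt_plus_fraction = wt_plus_fraction,
                 compensation = compensation,
                 label = label %||% paste(kinds, collapse = "/")),
            class = "genotype_model")
}

#' @export
print.genotype_model <- function(x, ...) {
  cat(sprintf("genotype_model %s (wt_plus_fraction=%.3g, compensation=%s)\n",
              x$label, x$wt_plus_fraction, x$compensation))
  invisible(x)
}

#' Expected per-cell isoform output of a genotype
#'
#' Computes the expected junction-read rates implied by a genotype model at a
#' given sequencing depth. `depth` is the expected junction reads per cell of
#' the two-WT-allele reference genotype; without compensation each allele
#' contributes `depth * budget / 2`, with compensation the non-NULL alleles
#' share the full `depth` in proportion to their budgets.
#'
#' @param model a [genotype_model()]
#' @param depth expected junction reads per cell for the WT/WT reference
#' @return list with `lambda_total`, `lambda_minus`, `lambda_plus` (expected
#'   reads per cell) and `minus_fraction` (NaN for a genotype with no output)
#' @export
expected_isoform_rates <- function(model, depth) {
  stopifnot(inherits(model, "genotype_model"), is.numeric(depth), depth > 0)
  kinds <- vapply(model$alleles, `[[`, character(1), "kind")
  budgets <- vapply(model$alleles, `[[`, numeric(1), "expression_budget")
  active <- kinds != "NULL" & budgets > 0
  lam <- depth * budgets / 2
  if (model$compensation && any(active)) {
    lam[active] <- depth * budgets[active] / sum(budgets[active])
    lam[!active] <- 0
  } else {
    lam[!active] <- 0
  }
  mf_allele <- ifelse(kinds == "FRASIER", 1,
                      ifelse(kinds == "WT", 1 - model$wt_plus_fraction, 0))
  lambda_total <- sum(lam)
  lambda_minus <- sum(lam * mf_allele)
  list(lambda_total = lambda_total,
       lambda_minus = lambda_minus,
       lambda_plus = lambda_total - lambda_minus,
       minus_fraction = if (lambda_total > 0) lambda_minus / lambda_total
                        else NaN)
}

#' Convenience genotype constructors
#'
#' Shorthands for the genotypes of the -KTS allelic series: wildtype
#' (`WT/WT`), the +KTS knockout that carries two -KTS-only alleles
#' (`FRASIER/FRASIER`), and the compound with one -KTS-only and one null
#' allele (`FRASIER/NULL`).
#'
#' @param wt_plus_fraction,compensation passed to [genotype_model()]
#' @return a [genotype_model()]
#' @export
genotype_wt <- function(wt_plus_fraction = 0.5, compensation = TRUE) {
  genotype_model(list(allele("WT"), allele("WT")),
                 wt_plus_fraction = wt_plus_fraction,
                 compensation = compensation, label = "WT/WT")
}

#' @rdname genotype_wt
#' @export
genotype_plus_ko <- function(wt_plus_fraction = 0.5, compensation = TRUE) {
  genotype_model(list(allele("FRASIER"), allele("FRASIER")),
                 wt_plus_fraction = wt_plus_fraction,
                 compensation = compensation, label = "FRASIER/FRASIER")
}

#' @rdname genotype_wt
#' @export
genotype_plus_ko_null <- function(wt_plus_fraction = 0.5,
                                  compensation = FALSE) {
  genotype_model(list(allele("FRASIER"), allele("NULL")),
                 wt_plus_fraction = wt_plus_fraction,
                 compensation = compensation, label = "FRASIER/NULL")
}
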