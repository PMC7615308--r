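#' Run the full quantification pipeline from a config
#'
#' Executes both quantification arms from a single declarative config and
#' writes all tables, a JSON run manifest (package version, seed,
#' parameters) and a plain-text summary into `out_dir`. The run is
#' deterministic given the config: re-running with the same config produces
#' identical tables.
#'
#' The config is a named list (or a path to a JSON/YAML file with the same
#' structure):
#'
#' * `seed` - integer master seed.
#' * `junctions` - optional; either `simulate` (list of genotype blocks,
#'   each with `label`, `alleles` (list of `{kind, expression_budget}`),
#'   `wt_plus_fraction`, `compensation`, `n_cells`, `depth`, `error_rate`)
#'   or `alignments` (`{path, dialect}`); plus optional `spec` (inline
#'   [junction_spec()] fields or a JSON path), `dedup_umi`, `ci_method`,
#'   `group_by` (label columns for [aggregate_groups()]).
#' * `image` - optional; either `simulate` (fields of
#'   [image_scene_config()], with `nuclei`/`dots` as data.frame-like lists,
#'   or `random` with [random_scene()] arguments) or `tiff`
#'   (`{path, channels, pixel_size}`); plus optional `segment_params`,
#'   `spot_params`, `max_dist_um`, `marker_rule`.
#' * `comparisons` - optional list; each element has `type`
#'   (`"fold_change"`, `"permutation_test"` or `"dose_trend"`), `label`
#'   (the cell label column to group on) and `groups` (for fold_change:
#'   reference then comparison; for dose_trend: dose-ordered level names),
#'   plus optional `n_boot`/`n_perm`.
#'
#' All referenced input files are checked before any stage runs; a missing
#' input aborts with a config error and writes nothing.
#'
#' @param config named list or path to a JSON/YAML config file
#' @param out_dir output directory (created if needed)
#' @return invisible list with the in-memory stage results
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(is.list(config))
  validate_config(config)

  seed <- as.integer(config$seed %||% 1L)
  results <- list()
  tables <- list()

  jc <- config$junctions
  if (!is.null(jc)) {
    spec <- parse_spec_config(jc$spec)
    if (!is.null(jc$simulate)) {
      models <- lapply(jc$simulate, function(g)
        genotype_model(lapply(g$alleles, function(a)
          allele(a$kind, a$expression_budget %||% 1)),
          wt_plus_fraction = g$wt_plus_fraction %||% 0.5,
          compensation = g$compensation %||% TRUE,
          label = g$label))
      set.seed(seed)
      sims <- lapply(seq_along(jc$simulate), function(i) {
        g <- jc$simulate[[i]]
        simulate_cells(models[[i]], g$n_cells, g$depth,
                       g$error_rate %||% 0, seed = NULL, spec = spec)
      })
      aln <- do.call(rbind, lapply(sims, `[[`, "alignments"))
      truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
      labels <- truth[, c("cell_id", "genotype")]
    } else {
      aln <- load_alignments(jc$alignments$path,
                             jc$alignments$dialect %||% "TSV")
      truth <- NULL
      labels <- NULL
    }
    calls <- classify_reads(aln, spec)
    counts <- count_cells(calls, dedup_umi = jc$dedup_umi, labels = labels)
    counts <- estimate_ratio(counts, ci_method = jc$ci_method %||% "wilson")
    tables$per_cell_counts <- counts
    if (!is.null(jc$group_by))
      tables$group_summary <- aggregate_groups(counts,
                                               unlist(jc$group_by))
    results$junctions <- list(spec = spec, alignments = aln,
                              truth = truth, counts = counts)
  }

  ic <- config$image
  if (!is.null(ic)) {
    if (!is.null(ic$simulate)) {
      scene <- parse_scene_config(ic$simulate, seed)
      sim <- simulate_basescope_image(scene)
      stack <- sim$stack
      results$image_truth <- sim[c("nuclei", "dots")]
    } else {
      stack <- read_image_stack(ic$tiff$path,
                                unlist(ic$tiff$channels),
                                ic$tiff$pixel_size)
    }
    q <- quantify_image_stack(stack,
                              segment_params = ic$segment_params %||% list(),
                              spot_params = ic$spot_params %||% list(),
                              max_dist_um = ic$max_dist_um %||% 10,
                              marker_rule = ic$marker_rule %||% "otsu")
    tables$spots <- q$spots
    tables$per_nucleus_area <- q$signal$per_nucleus
    tables$unassigned_area <- q$signal$unassigned
    if (!is.null(q$marker)) tables$marker_calls <- q$marker$table
    results$image <- q
  }

  comps <- lapply(config$comparisons %||% list(), function(cm) {
    counts <- tables$per_cell_counts
    if (is.null(counts))
      stop("config error: comparisons require a junctions stage")
    lab <- counts[[cm$label]]
    run_one_comparison(cm, counts, lab, seed)
  })
  if (length(comps) > 0L)
    tables$comparisons <- do.call(rbind, comps)
  results$comparisons <- comps

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables))
    write_tsv(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  manifest <- list(package = "wt1kts",
                   version = as.character(packageVersion("wt1kts")),
                   r_version = R.version.string,
                   seed = seed, config = config,
                   outputs = paste0(names(tables), ".tsv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(summarise_run(tables), file.path(out_dir, "summary.txt"))
  invisible(c(results, list(tables = tables, out_dir = out_dir)))
}

#' @noRd
read_config <- function(path) {
  if (!file.exists(path)) stop("config error: no such config file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
}

#' @noRd
validate_config <- function(config) {
  jc <- config$junctions
  if (!is.null(jc) && is.null(jc$simulate)) {
    if (is.null(jc$alignments$path))
      stop("config error: junctions stage needs 'simulate' or 'alignments'")
    if (!file.exists(jc$alignments$path))
      stop("config error: alignments file not found: ", jc$alignments$path)
  }
  if (!is.null(jc) && is.character(jc$spec) && !file.exists(jc$spec))
    stop("config error: junction spec file not found: ", jc$spec)
  ic <- config$image
  if (!is.null(ic) && is.null(ic$simulate)) {
    if (is.null(ic$tiff$path))
      stop("config error: image stage needs 'simulate' or 'tiff'")
    if (!file.exists(ic$tiff$path))
      stop("config error: TIFF file not found: ", ic$tiff$path)
  }
  invisible(config)
}

#' @noRd
parse_spec_config <- function(sp) {
  if (is.null(sp)) return(junction_spec())
  if (inherits(sp, "junction_spec")) return(sp)
  if (is.character(sp)) return(read_junction_spec(sp))
  do.call(junction_spec, sp)
}

#' @noRd
parse_scene_config <- function(sc, seed) {
  if (inherits(sc, "image_scene_config")) return(sc)
  if (!is.null(sc$random)) {
    args <- sc$random
    args$seed <- args$seed %||% seed
    return(do.call(random_scene, args))
  }
  as_df <- function(x) if (is.data.frame(x) || is.null(x)) x else
    do.call(rbind, lapply(x, function(r) as.data.frame(r)))
  image_scene_config(width = sc$width, height = sc$height,
                     pixel_size = sc$pixel_size,
                     nuclei = as_df(sc$nuclei), dots = as_df(sc$dots),
                     noise_sd = sc$noise_sd %||% 0,
                     marker_intensity = sc$marker_intensity %||% 0.6,
                     seed = sc$seed %||% seed)
}

#' @noRd
run_one_comparison <- function(cm, counts, lab, seed) {
  if (cm$type == "fold_change") {
    a <- counts[lab == cm$groups[[1L]], , drop = FALSE]
    b <- counts[lab == cm$groups[[2L]], , drop = FALSE]
    r <- fold_change(a, b, n_boot = cm$n_boot %||% 2000L,
                     n_perm = cm$n_perm %||% 999L, seed = seed)
    data.frame(type = "fold_change",
               groups = paste(unlist(cm$groups), collapse = " vs "),
               estimate = r$fold_change, ci_low = r$ci_low,
               ci_high = r$ci_high, p_value = r$p_value)
  } else if (cm$type == "permutation_test") {
    keep <- lab %in% unlist(cm$groups)
    r <- permutation_test(counts$n_minus[keep], lab[keep],
                          n_perm = cm$n_perm %||% 999L, seed = seed)
    data.frame(type = "permutation_test",
               groups = paste(unlist(cm$groups), collapse = " vs "),
               estimate = r$statistic, ci_low = NA_real_,
               ci_high = NA_real_, p_value = r$p_value)
  } else if (cm$type == "dose_trend") {
    keep <- lab %in% unlist(cm$groups)
    r <- dose_trend(counts$n_minus[keep],
                    factor(lab[keep], levels = unlist(cm$groups)),
                    n_perm = cm$n_perm %||% 999L, seed = seed)
    data.frame(type = "dose_trend",
               groups = paste(unlist(cm$groups), collapse = " < "),
               estimate = r$statistic, ci_low = NA_real_,
               ci_high = NA_real_, p_value = r$p_value)
  } else stop("config error: unknown comparison type: ", cm$type)
}

#' @noRd
summarise_run <- function(tables) {
  out <- c("wt1kts pipeline summary", "=======================")
  if (!is.null(tables$per_cell_counts)) {
    pc <- tables$per_cell_counts
    out <- c(out, sprintf("cells quantified: %d", nrow(pc)),
             sprintf("mean -KTS fraction (defined cells): %.3f",
                     mean(pc$minus_fraction, na.rm = TRUE)))
  }
  if (!is.null(tables$per_nucleus_area)) {
    pn <- tables$per_nucleus_area
    for (ch in unique(pn$channel))
      out <- c(out, sprintf("channel %s: %.2f um^2 total over %d nuclei",
                            ch, sum(pn$area_um2[pn$channel == ch]),
                            length(unique(pn$nucleus))))
  }
  if (!is.null(tables$marker_calls))
    out <- c(out, sprintf("marker-positive nuclei: %d / %d",
                          sum(tables$marker_calls$positive),
                          nrow(tables$marker_calls)))
  if (!is.null(tables$comparisons)) {
    cmp <- tables$comparisons
    out <- c(out, apply(cmp, 1L, function(r)
      sprintf("%s %s: estimate %s, p %s", r[["type"]], r[["groups"]],
              r[["estimate"]], r[["p_value"]])))
  }
  out
}
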