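`%||%` <- function(x, y) if (is.null(x)) y else x

#' Set the RNG seed if one is given
#'
#' Deterministic entry points accept `seed = NULL` (use the current RNG
#' state) or an integer seed. All draws inside one call then come from the
#' single sequential stream started here.
#' @noRd
set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  invisible(as.integer(x))
}

#' Otsu threshold of a numeric vector
#'
#' Exhaustive between-class-variance maximisation over midpoints of sorted
#' unique values. Used for small vectors (e.g. per-nucleus mean intensities);
#' whole-image thresholds go through [EBImage::otsu()].
#' @return threshold value; values strictly above it are "foreground"
#' @noRd
otsu_vector <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2L) return(Inf)
  cand <- (u[-1L] + u[-length(u)]) / 2
  bcv <- vapply(cand, function(t) {
    w1 <- mean(x <= t)
    w2 <- 1 - w1
    if (w1 == 0 || w2 == 0) return(0)
    w1 * w2 * (mean(x[x > t]) - mean(x[x <= t]))^2
  }, numeric(1))
  cand[which.max(bcv)]
}

#' Label connected components of a binary mask
#'
#' Components are computed on the pixel adjacency graph with 4- or
#' 8-connectivity. Labels are 1..K in order of first (column-major) pixel.
#'
#' @param mask logical or 0/1 matrix
#' @param connectivity 4 or 8
#' @return integer matrix of the same shape, 0 = background
#' @noRd
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  mask <- mask > 0
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  nr <- nrow(mask)
  nc <- ncol(mask)
  i <- ((idx - 1L) %% nr) + 1L
  j <- ((idx - 1L) %/% nr) + 1L
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  node <- match(idx, idx)  # 1..n
  edges <- lapply(shifts, function(s) {
    ii <- i + s[1L]
    jj <- j + s[2L]
    ok <- ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
    nb <- (jj[ok] - 1L) * nr + ii[ok]
    hit <- match(nb, idx)
    keep <- !is.na(hit)
    cbind(node[ok][keep], hit[keep])
  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # relabel in order of first appearance (column-major scan)
  first <- match(unique(memb), memb)
  relab <- integer(max(memb))
  relab[memb[sort(first)]] <- seq_along(first)
  lab[idx] <- relab[memb]
  lab
}

#' Wilson score interval for a binomial proportion (no continuity correction)
#'
#' Vectorised closed form; agrees with `prop.test(correct = FALSE)`.
#' @noRd
wilson_ci <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  cbind(low = pmax(0, ctr - hw), high = pmin(1, ctr + hw))
}

#' Clopper-Pearson exact interval via beta quantiles
#'
#' Vectorised; agrees with `binom.test()$conf.int`.
#' @noRd
clopper_pearson_ci <- function(k, n, conf = 0.95) {
  a <- (1 - conf) / 2
  low <- ifelse(k == 0, 0, qbeta(a, k, n - k + 1))
  high <- ifelse(k == n, 1, qbeta(1 - a, k + 1, n - k))
  cbind(low = low, high = high)
}

#' Write a data.frame as TSV (no quoting, no row names)
#' @noRd
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

# unique = TRUE is meant for cell barcodes; UMIs are drawn with
# unique = FALSE (collisions across cells are real and harmless)
random_barcodes <- function(n, width = 12L, unique = TRUE) {
  draw <- function(m) {
    chars <- sample(c("A", "C", "G", "T"), m * width, replace = TRUE)
    apply(matrix(chars, nrow = width), 2L, paste, collapse = "")
  }
  bc <- draw(n)
  if (unique) {
    for (tries in 1:100) {
      dup <- which(duplicated(bc))
      if (length(dup) == 0L) break
      bc[dup] <- draw(length(dup))
    }
    if (anyDuplicated(bc))
      stop("cannot draw ", n, " distinct barcodes of width ", width)
  }
  bc
}
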