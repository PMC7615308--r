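call_df <- function(calls, cell = "c1", umi = NA_character_) {
  data.frame(read_id = sprintf("r%d", seq_along(calls)), cell = cell,
             umi = umi, call = calls, stringsAsFactors = FALSE)
}

test_that("per-cell tallies count informative and ambiguous units", {
  calls <- call_df(rep(c("PLUS_KTS", "MINUS_KTS"), each = 5))
  counts <- count_cells(calls)
  expect_equal(counts$n_plus, 5L)
  expect_equal(counts$n_minus, 5L)
  expect_equal(counts$n_ambiguous, 0L)
  # NON_JUNCTION reads never enter the counts
  counts2 <- count_cells(rbind(calls, call_df("NON_JUNCTION")))
  expect_equal(counts2[, c("n_plus", "n_minus", "n_ambiguous")],
               counts[, c("n_plus", "n_minus", "n_ambiguous")])
})

test_that("UMI deduplication collapses to majority calls with ties ambiguous", {
  two <- call_df(c("PLUS_KTS", "MINUS_KTS"), umi = "AAAAAAAA")
  on <- count_cells(two, dedup_umi = TRUE)
  expect_equal(on[, c("n_plus", "n_minus", "n_ambiguous")],
               data.frame(n_plus = 0L, n_minus = 0L, n_ambiguous = 1L))
  off <- count_cells(two, dedup_umi = FALSE)
  expect_equal(off[, c("n_plus", "n_minus")],
               data.frame(n_plus = 1L, n_minus = 1L))
  # clear majority wins; reads without UMI stay separate units
  maj <- rbind(call_df(c("MINUS_KTS", "MINUS_KTS", "PLUS_KTS"),
                       umi = "CCCCCCCC"),
               call_df("PLUS_KTS"))
  m <- count_cells(maj)  # auto: UMIs present -> dedup on
  expect_equal(m[, c("n_plus", "n_minus")],
               data.frame(n_plus = 1L, n_minus = 1L))
})

test_that("labelled cells with no junction reads appear with zero counts", {
  calls <- call_df("MINUS_KTS", cell = "cellA")
  labels <- data.frame(cell_id = c("cellA", "cellB"),
                       genotype = c("WT/WT", "WT/WT"))
  counts <- count_cells(calls, labels = labels)
  expect_equal(nrow(counts), 2L)
  expect_equal(counts$n_minus[counts$cell_id == "cellB"], 0L)
})

test_that("minus fraction and undefined flagging behave", {
  counts <- data.frame(cell_id = c("a", "b"), n_plus = c(5L, 0L),
                       n_minus = c(5L, 0L), n_ambiguous = c(2L, 1L))
  est <- estimate_ratio(counts)
  expect_equal(est$minus_fraction[1], 0.5)
  expect_true(est$defined[1])
  expect_false(est$defined[2])
  expect_true(is.na(est$minus_fraction[2]))
  expect_true(all(est$ci_low[1] <= 0.5 & 0.5 <= est$ci_high[1]))
})

test_that("Clopper-Pearson CI matches a direct tail-probability search", {
  # oracle: solve sum_{k>=x} dbinom(k,n,p) = alpha/2 (lower) and
  # sum_{k<=x} dbinom(k,n,p) = alpha/2 (upper) by root search
  cp_oracle <- function(x, n, conf = 0.95) {
    a <- (1 - conf) / 2
    lo <- if (x == 0) 0 else
      uniroot(function(p) sum(dbinom(x:n, n, p)) - a, c(1e-12, 1 - 1e-12),
              tol = 1e-12)$root
    hi <- if (x == n) 1 else
      uniroot(function(p) sum(dbinom(0:x, n, p)) - a, c(1e-12, 1 - 1e-12),
              tol = 1e-12)$root
    c(lo, hi)
  }
  cases <- rbind(c(8, 2), c(1, 9), c(0, 7), c(12, 0), c(3, 3))
  for (i in seq_len(nrow(cases))) {
    n_minus <- cases[i, 1]
    n_plus <- cases[i, 2]
    est <- estimate_ratio(data.frame(n_plus = n_plus, n_minus = n_minus),
                          ci_method = "clopper_pearson")
    want <- cp_oracle(n_minus, n_minus + n_plus)
    expect_equal(c(est$ci_low, est$ci_high), want, tolerance = 1e-8)
  }
})

test_that("Wilson CI matches prop.test without continuity correction", {
  for (kn in list(c(5, 10), c(0, 12), c(12, 12), c(30, 55))) {
    est <- estimate_ratio(data.frame(n_plus = kn[2] - kn[1],
                                     n_minus = kn[1]))
    ref <- prop.test(kn[1], kn[2], correct = FALSE)$conf.int
    expect_equal(c(est$ci_low, est$ci_high), as.numeric(ref),
                 tolerance = 1e-10)
  }
})

test_that("group aggregation pools counts correctly", {
  counts <- data.frame(cell_id = c("a", "b"), n_plus = c(0L, 2L),
                       n_minus = c(2L, 0L), n_ambiguous = 0L,
                       genotype = "WT/WT")
  g <- aggregate_groups(counts, "genotype")
  expect_equal(g$mean_minus_units, 1)
  expect_equal(g$pooled_minus_fraction, 0.5)
  expect_error(aggregate_groups(counts, "nope"), "unknown grouping key")

  # 2x2 label grid -> 4 rows
  counts4 <- data.frame(cell_id = letters[1:8], n_plus = 1L, n_minus = 1L,
                        n_ambiguous = 0L,
                        sex = rep(c("XX", "XY"), each = 4),
                        stage = rep(c("E11.5", "E12.5"), 4))
  expect_equal(nrow(aggregate_groups(counts4, c("sex", "stage"))), 4L)
})

test_that("pooled fraction is the informative-count-weighted mean", {
  set.seed(5)
  counts <- data.frame(cell_id = sprintf("c%d", 1:50),
                       n_plus = rpois(50, 4), n_minus = rpois(50, 7),
                       n_ambiguous = 0L, genotype = "g")
  counts <- counts[counts$n_plus + counts$n_minus > 0, ]
  g <- aggregate_groups(counts, "genotype")
  ninf <- counts$n_plus + counts$n_minus
  want <- sum(ninf * (counts$n_minus / ninf)) / sum(ninf)
  expect_equal(g$pooled_minus_fraction, want)
})
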