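make_stats <- function(n, seed = 1) {
  # minimal ranked probe_stats-like table with three treatment pairs
  set.seed(seed)
  pairs <- c("A_vs_B", "A_vs_C", "B_vs_C")
  out <- data.frame(probe_id = sprintf("g%04d", seq_len(n)))
  for (nm in pairs) out[[paste0("p_", nm)]] <- runif(n)
  out$min_p <- do.call(pmin, out[paste0("p_", pairs)])
  out <- out[order(out$min_p, out$probe_id), ]
  out$rank <- seq_len(n)
  rownames(out) <- NULL
  structure(out, pairs = pairs, treatments = c("A", "B", "C"),
            class = c("probe_stats", "data.frame"))
}

test_that("top-k selection returns contiguous best ranks and warns when short", {
  stats <- make_stats(2000)
  top <- select_top_k(stats, 500)
  expect_equal(nrow(top), 500)
  expect_equal(top$rank, 1:500)
  expect_identical(attr(top, "pairs"), attr(stats, "pairs"))
  expect_warning(all_of_them <- select_top_k(make_stats(5), 10), "only 5")
  expect_equal(nrow(all_of_them), 5)
  expect_error(select_top_k(stats, 0), "positive integer")
})

test_that("direction calls reproduce the printed worked example and its oracle", {
  tab1 <- read_relative_expression(fixture_path("table1.tsv"))
  calls <- direction_calls(tab1, "control")
  r <- calls[calls$probe_id == "MZ00042168", ]
  expect_identical(r$wcr_untreated, "DOWN")
  expect_identical(r$wcr_treated, "UP")
  expect_identical(unique(calls$control), "UNCHANGED")
  # independent oracle: linear scan of the printed columns
  n_down_oracle <- sum(tab1$wcr_untreated < tab1$control)
  expect_equal(sum(calls$wcr_untreated == "DOWN"), n_down_oracle)
  expect_equal(n_down_oracle, 31)
})

test_that("direction calls honour the tolerance and shift invariance", {
  expr <- structure(
    data.frame(probe_id = c("p1", "p2"), ctl = c(1, 2), trt = c(1.05, 1.2)),
    treatments = c("ctl", "trt"), class = c("expression_table", "data.frame"))
  expect_identical(direction_calls(expr, "ctl")$trt, c("UP", "DOWN"))
  expect_identical(direction_calls(expr, "ctl", tolerance = 0.1)$trt,
                   c("UNCHANGED", "DOWN"))
  shifted <- expr
  shifted$ctl <- shifted$ctl + 5
  shifted$trt <- shifted$trt + 5
  expect_equal(direction_calls(shifted, "ctl"), direction_calls(expr, "ctl"),
               ignore_attr = TRUE)
  expect_error(direction_calls(expr, "nope"), "unknown control label")
})

test_that("similarity partition follows the p > alpha rule and conserves k", {
  pairs <- c("A_vs_B", "A_vs_C", "B_vs_C")
  stats <- structure(data.frame(
    probe_id = c("g1", "g2", "g3"),
    p_A_vs_B = c(0.9, 0.01, 0.01),
    p_A_vs_C = c(0.01, 0.9, 0.01),
    p_B_vs_C = c(0.01, 0.01, 0.01)
  ), pairs = pairs, class = c("probe_stats", "data.frame"))
  part <- similarity_partition(stats, 0.05)
  cells <- setNames(part$cells$count, part$cells$cell)
  expect_equal(cells[["A_vs_B"]], 1)
  expect_equal(cells[["A_vs_C"]], 1)
  expect_equal(cells[["none"]], 1)
  expect_equal(sum(part$cells$count), 3)

  # boundaries: p > 0 always (all similar); p > 1 never
  part0 <- similarity_partition(stats, 0)
  expect_equal(part0$all_similar, 3)
  part1 <- similarity_partition(stats, 1)
  expect_equal(part1$none_similar, 3)

  # conservation under random p-values, across alphas
  big <- make_stats(400, seed = 5)
  for (alpha in c(0, 0.01, 0.05, 0.5, 1))
    expect_equal(sum(similarity_partition(big, alpha)$cells$count), 400)
})

test_that("category summaries reproduce the published split and conserve k", {
  # the published category split (its printed counts total 498)
  split <- c(defense = 225, metabolic = 126, unknown = 73,
             architecture = 30, replication = 44)
  ids <- sprintf("g%03d", seq_len(sum(split)))
  ann <- setNames(rep(names(split), split), ids)
  counts <- category_summary(ids, ann)
  expect_equal(sum(counts), sum(split))
  expect_equal(as.integer(counts[names(split)]), unname(split))
  # missing annotations fall into "unknown"
  expect_equal(unname(category_summary(ids, NULL)[["unknown"]]), length(ids))
  expect_equal(sum(category_summary(ids, ann[1:100])), length(ids))
})

test_that("heat-map matrices export deterministically and round-trip", {
  stats <- data.frame(probe_id = c("p2", "p1"),
                      mean_A = c(1.234567, -0.5),
                      mean_B = c(2.5, 0.25),
                      mean_C = c(-1, 3),
                      rank = c(2, 1))
  M <- export_heatmap_matrix(stats)
  expect_equal(dim(M), c(2, 3))
  expect_equal(rownames(M), c("p1", "p2"))  # rank order
  ann <- c(p1 = "z_late", p2 = "a_early")
  Mc <- export_heatmap_matrix(stats, order_by = "category", annotation = ann)
  expect_equal(rownames(Mc), c("p2", "p1"))  # grouped by category label
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  export_heatmap_matrix(stats, path = path)
  back <- utils::read.delim(path)
  expect_equal(as.matrix(back[-1]), signif(M, 6),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("cross-platform direction concordance compares signs, not scales", {
  tab1 <- read_relative_expression(fixture_path("table1.tsv"))
  tab2 <- read_relative_expression(fixture_path("table2.tsv"))
  conc <- direction_concordance(tab1, tab2, "control")
  expect_equal(conc$n_shared, 3)     # MZ00044023, MZ00035455, MZ00039775
  expect_equal(conc$n_concordant, 3) # the QRT-PCR signs mirror the array
  # identical tables are fully concordant; flipped signs are not
  expect_equal(direction_concordance(tab1, tab1, "control")$n_concordant, 36)
  flipped <- tab2
  for (tr in c("wcr_untreated", "wcr_treated"))
    flipped[[tr]] <- 2 * flipped$control - flipped[[tr]]
  expect_equal(direction_concordance(tab1, flipped, "control")$n_concordant, 0)
  # no shared ids -> empty result with a warning
  lonely <- tab2
  lonely$probe_id <- paste0("x", lonely$probe_id)
  expect_warning(none <- direction_concordance(tab1, lonely, "control"),
                 "share no probe ids")
  expect_equal(none$n_shared, 0)
})
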