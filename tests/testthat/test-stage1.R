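test_that("log transform maps known values and guards its state", {
  d <- build_loop_design(c("A", "B"), 1, dye_swap = FALSE)
  cfg <- sim_config(n_probes = 3, n_panels = 1, baseline = 3, dye_effect = 0,
                    panel_sd = 0, array_sd = 0, dye_in_array_sd = 0,
                    residual_sd = 0, de_fraction = 0)
  raw <- simulate_experiment(cfg, d)$intensities  # every intensity is 2^3
  lg <- log_transform(raw, base = 2)
  expect_true(all(lg$intensity == 3))
  expect_true(attr(lg, "log_scale"))
  expect_error(log_transform(lg), "already on the log scale")
  raw$intensity[1] <- -1
  expect_error(log_transform(raw), "non-positive")
  one <- raw; one$intensity <- 1
  expect_true(all(log_transform(one, base = 10)$intensity == 0))
})

test_that("a constant table fits to a pure intercept with zero components", {
  d <- paper_design()
  cfg <- sim_config(n_probes = 12, n_panels = 3, baseline = 5, dye_effect = 0,
                    panel_sd = 0, array_sd = 0, dye_in_array_sd = 0,
                    residual_sd = 0, de_fraction = 0)
  fit <- fit_stage1(log_transform(simulate_experiment(cfg, d)$intensities), d)
  expect_equal(fit$fixed_effects$intercept, 5)
  expect_equal(unname(fit$fixed_effects$dye), c(0, 0))
  expect_true(all(abs(fit$fixed_effects$treatment) < 1e-12))
  expect_true(all(abs(fit$fixed_effects$panel) < 1e-12))
  expect_equal(fit$variance_components$array, 0)
  expect_equal(fit$variance_components$dye_in_array, 0)
  expect_equal(fit$variance_components$residual, 0)
  expect_true(all(abs(fit$residuals) < 1e-12))
})

test_that("variance components and the dye effect are recovered across seeds", {
  d <- paper_design()
  truth <- c(array = 0.25, dye_in_array = 0.09, residual = 0.16)
  est <- vapply(1:24, function(s) {
    cfg <- sim_config(n_probes = 1000, array_sd = 0.5, dye_in_array_sd = 0.3,
                      residual_sd = 0.4, de_fraction = 0, seed = 400 + s)
    fit <- fit_stage1(log_transform(simulate_experiment(cfg, d)$intensities), d)
    c(unlist(fit$variance_components),
      dye = unname(fit$fixed_effects$dye[["CY5"]] - fit$fixed_effects$dye[["CY3"]]))
  }, numeric(4))
  med <- apply(est[1:3, ], 1, median)
  expect_true(all(abs(med - truth) / truth < 0.2))
  # residual component is estimated from ~36k df: tight per-seed accuracy
  expect_lt(median(abs(est["residual", ] - 0.16) / 0.16), 0.02)
  expect_lt(abs(mean(est["dye", ]) - 0.1), 0.02)
})

test_that("method-of-moments components agree with the REML cross-check", {
  skip_if_not_installed("lme4")
  d <- paper_design()
  cfg <- sim_config(n_probes = 500, de_fraction = 0, seed = 42)
  lt <- log_transform(simulate_experiment(cfg, d)$intensities)
  mom <- fit_stage1(lt, d, method = "mom")$variance_components
  reml <- fit_stage1(lt, d, method = "reml")$variance_components
  # exact balance: the two estimators coincide up to optimizer tolerance
  expect_equal(mom$array, reml$array, tolerance = 0.01)
  expect_equal(mom$dye_in_array, reml$dye_in_array, tolerance = 0.01)
  expect_equal(mom$residual, reml$residual, tolerance = 1e-8)
})

test_that("a zero array component is clamped near zero, never negative", {
  d <- paper_design()
  cfg <- sim_config(n_probes = 500, array_sd = 0, de_fraction = 0, seed = 17)
  fit <- fit_stage1(log_transform(simulate_experiment(cfg, d)$intensities), d)
  expect_gte(fit$variance_components$array, 0)
  expect_lt(fit$variance_components$array, 0.02)
})

test_that("unshrunken projection residuals are exactly orthogonal to the design", {
  d <- paper_design()
  cfg <- sim_config(n_probes = 200, n_panels = 8, seed = 9)
  lt <- log_transform(simulate_experiment(cfg, d)$intensities)
  fit <- fit_stage1(lt, d, shrink_blups = FALSE)
  r <- extract_residuals(fit)
  des <- attr(r, "design")
  n <- length(r)
  # sums vanish within every channel-sample, hence every array/dye/treatment
  expect_lt(max(abs(colSums(r))), 1e-8 * n)
  for (fac in list(des$array_id, des$dye, des$treatment))
    expect_lt(max(abs(tapply(colSums(r), fac, sum))), 1e-8 * n)
  # and within every panel
  pan <- fit$probe_panel
  expect_lt(max(abs(tapply(rowSums(r), pan, sum))), 1e-8 * n)
})

test_that("default (shrunken-BLUP) residuals are centred and near-orthogonal", {
  d <- paper_design()
  cfg <- sim_config(n_probes = 300, n_panels = 8, seed = 10, de_fraction = 0)
  r <- pipeline_residuals(cfg, d)
  expect_lt(abs(mean(r)), 1e-10)
  # residual correlation with fixed-effect columns is negligible at n ~ 1e4
  des <- attr(r, "design")
  v <- as.vector(r)
  dye_col <- rep(as.numeric(des$dye == "CY5"), each = nrow(r))
  expect_lt(abs(cor(v, dye_col)), 0.01)
  for (tr in paper_treatments) {
    trt_col <- rep(as.numeric(des$treatment == tr), each = nrow(r))
    expect_lt(abs(cor(v, trt_col)), 0.01)
  }
})

test_that("misaligned data and invalid inputs are rejected", {
  d <- paper_design()
  cfg <- sim_config(n_probes = 10, n_panels = 2, seed = 1)
  sim <- simulate_experiment(cfg, d)
  expect_error(fit_stage1(sim$intensities, d), "log-scale")
  lt <- log_transform(sim$intensities)
  expect_error(fit_stage1(lt, build_loop_design(c("A", "B"), 1)),
               "do not match the design")
  short <- lt[lt$array_id != "A_r1_fwd_01", ]
  attributes(short)[c("log_scale", "log_base", "class")] <-
    attributes(lt)[c("log_scale", "log_base", "class")]
  expect_error(fit_stage1(short, d), "do not match the design")
})
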