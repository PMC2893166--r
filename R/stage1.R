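#' Log-transform an intensity table
#'
#' @param x An `intensity_table` on the raw scale.
#' @param base Logarithm base; 2 by default (the convention for expression
#'   ratios).
#' @return The table with `intensity` replaced by `log_base(intensity)` and
#'   its metadata marked log-scale.  Transforming an already log-scale table
#'   is an error.
#' @export
log_transform <- function(x, base = 2) {
  if (!inherits(x, "intensity_table"))
    stop("`x` must be an intensity_table", call. = FALSE)
  if (isTRUE(attr(x, "log_scale")))
    stop("table is already on the log scale", call. = FALSE)
  if (any(x$intensity <= 0))
    stop("non-positive intensities cannot be log transformed", call. = FALSE)
  x$intensity <- log(x$intensity, base = base)
  attr(x, "log_scale") <- TRUE
  attr(x, "log_base") <- base
  x
}

#' Fit stage 1 of the two-stage mixed linear model
#'
#' Stage 1 is the global normalisation fit across all probes.  Fixed effects
#' -- intercept, panel (print-tip block), dye and treatment -- are estimated
#' by least squares under sum-to-zero constraints (the design is balanced, so
#' the channel-level and probe-level effect families are orthogonal and the
#' estimates are simple contrasts of cell means).  The random array and
#' dye-within-array effects are estimated as variance components by the
#' balanced-design method of moments (Henderson III applied to the
#' channel-sample means), with negative moment estimates clamped to zero;
#' `method = "reml"` instead refines the channel-level components by
#' restricted maximum likelihood (via \pkg{lme4}), which is preferable when
#' the design has been subsetted and is no longer exactly balanced.
#'
#' Residuals passed on to stage 2 are
#' `observation - intercept - panel - dye - treatment - predicted array
#' effect - predicted dye-within-array effect`.  With
#' `shrink_blups = TRUE` (default) the random-effect predictions are the
#' usual shrunken BLUPs; with `shrink_blups = FALSE` they are the unshrunken
#' channel effects, in which case residuals are an exact least-squares
#' projection and sum to zero within every array, dye, treatment and panel.
#' `subtract_blups = FALSE` skips the random-effect subtraction entirely.
#'
#' @param data A log-scale `intensity_table` covering every channel-sample
#'   of `design` (one record per probe x channel-sample).
#' @param design A valid `loop_design`.
#' @param subtract_blups Subtract predicted random effects from the
#'   residuals?  Default `TRUE`, the standard two-stage practice.
#' @param shrink_blups Shrink the random-effect predictions by their BLUP
#'   factors?  Default `TRUE`.
#' @param method Variance-component estimator: `"mom"` (Henderson III
#'   method of moments, default) or `"reml"`.
#' @return A `stage1_fit` object: a list with `fixed_effects` (intercept and
#'   named panel/dye/treatment effect vectors), `variance_components`
#'   (`array`, `dye_in_array`, `residual`), `random_predictions` (per-array
#'   and per-channel), `residuals` (probe x channel-sample matrix), the
#'   `design`, and the per-probe panel assignment.
#' @seealso [extract_residuals()], [run_probe_inference()]
#' @export
fit_stage1 <- function(data, design, subtract_blups = TRUE,
                       shrink_blups = TRUE, method = c("mom", "reml")) {
  method <- match.arg(method)
  if (!inherits(data, "intensity_table"))
    stop("`data` must be an intensity_table", call. = FALSE)
  if (!isTRUE(attr(data, "log_scale")))
    stop("fit_stage1() expects log-scale intensities; call log_transform() first",
         call. = FALSE)
  v <- validate_design(design)
  if (length(v)) stop("invalid design: ", v[1], call. = FALSE)

  chan_design <- channel_key(design$array_id, design$dye)
  chan_data <- channel_key(data$array_id, data$dye)
  if (!setequal(unique(chan_data), chan_design))
    stop("channel-samples in the data do not match the design", call. = FALSE)

  probes <- unique(data$probe_id)
  G <- length(probes)
  C <- nrow(design)
  if (nrow(data) != G * C)
    stop("intensity table is incomplete: expected one record per probe x channel-sample",
         call. = FALSE)
  gi <- match(data$probe_id, probes)
  ci <- match(chan_data, chan_design)
  Y <- matrix(NA_real_, G, C, dimnames = list(probes, chan_design))
  Y[cbind(gi, ci)] <- data$intensity
  if (anyNA(Y))
    stop("intensity table is incomplete: missing probe x channel-sample records",
         call. = FALSE)
  panel <- data$panel[match(probes, data$probe_id)]
  if (any(tapply(data$panel, gi, function(p) length(unique(p))) != 1L))
    stop("panel assignment differs across channels for some probe",
         call. = FALSE)
  P <- length(unique(panel))
  if (G * C <= C + (P - 1) + 3)
    stop("fewer observations than fixed-effect parameters", call. = FALSE)

  ## --- fixed effects (balanced design: effects are cell-mean contrasts) ---
  mu <- mean(Y)
  row_mean <- rowMeans(Y)
  panel_eff <- c(tapply(row_mean, panel, mean)) - mu

  m <- colMeans(Y)  # channel-sample means
  dyef <- factor(design$dye, levels = .dyes)
  trtf <- factor(design$treatment,
                 levels = attr(design, "treatments") %||% unique(design$treatment))
  Xc <- stats::model.matrix(~ dyef + trtf,
                            contrasts.arg = list(dyef = "contr.sum",
                                                 trtf = "contr.sum"))
  if (nrow(Xc) <= ncol(Xc))
    stop("fewer channel-samples than channel-level fixed-effect parameters",
         call. = FALSE)
  qr_r <- qr(Xc)
  co <- qr.coef(qr_r, m)
  nt <- nlevels(trtf)
  dye_eff <- c(co[2], -co[2])
  names(dye_eff) <- levels(dyef)
  trt_co <- co[2 + seq_len(nt - 1)]
  trt_eff <- c(trt_co, -sum(trt_co))
  names(trt_eff) <- levels(trtf)

  chan_fix <- dye_eff[as.character(design$dye)] +
    trt_eff[as.character(design$treatment)]
  R0 <- sweep(Y - mu - panel_eff[as.character(panel)], 2, chan_fix)

  ## --- residual variance component (within channel, panel removed) ---
  u_full <- colMeans(R0)
  Rw <- sweep(R0, 2, u_full)
  df_e <- G * C - C - (P - 1)
  sigma2_e <- sum(Rw^2) / df_e

  ## --- array / dye-within-array components, Henderson III on channel means ---
  arrf <- factor(design$array_id)
  Xf <- stats::model.matrix(~ dyef + trtf + arrf,
                            contrasts.arg = list(dyef = "contr.sum",
                                                 trtf = "contr.sum",
                                                 arrf = "contr.sum"))
  qr_f <- qr(Xf)
  ss_red  <- sum(qr.resid(qr_r, m)^2)
  ss_full <- sum(qr.resid(qr_f, m)^2)
  df_full <- C - qr_f$rank
  rd <- qr_f$rank - qr_r$rank
  if (df_full < 1)
    stop("not enough channel-samples to separate array and residual variation",
         call. = FALSE)
  sigma2_w <- ss_full / df_full  # dye-in-array + residual noise on a channel mean
  Z <- stats::model.matrix(~ 0 + arrf)
  c_tr <- sum(Z * qr.fitted(qr_f, Z)) - sum(Z * qr.fitted(qr_r, Z))
  sigma2_A <- max(0, (ss_red - ss_full - rd * sigma2_w) / c_tr)
  sigma2_D <- max(0, sigma2_w - sigma2_e / G)

  if (method == "reml") {
    if (!requireNamespace("lme4", quietly = TRUE))
      stop("method = \"reml\" requires the lme4 package", call. = FALSE)
    dd <- data.frame(m = m, dye = dyef, trt = trtf, array = arrf)
    lf <- suppressMessages(suppressWarnings(
      lme4::lmer(m ~ dye + trt + (1 | array), data = dd, REML = TRUE)))
    vc <- lme4::VarCorr(lf)
    sigma2_A <- as.numeric(vc$array)
    sigma2_w <- stats::sigma(lf)^2
    sigma2_D <- max(0, sigma2_w - sigma2_e / G)
  }

  ## --- random-effect predictions ---
  u <- qr.resid(qr_r, m)  # channel deviations: array + dye-in-array + noise
  ubar_a <- c(tapply(u, arrf, mean))
  chan_noise <- sigma2_D + sigma2_e / G
  var_ubar <- sigma2_A + chan_noise / 2
  kA <- if (!shrink_blups) 1 else if (var_ubar > 0) sigma2_A / var_ubar else 0
  kD <- if (!shrink_blups) 1 else if (chan_noise > 0) sigma2_D / chan_noise else 0
  A_hat <- kA * ubar_a
  D_hat <- kD * (u - A_hat[as.character(arrf)])
  names(D_hat) <- chan_design

  R <- if (isTRUE(subtract_blups))
    sweep(R0, 2, A_hat[as.character(arrf)] + D_hat)
  else R0

  structure(list(
    fixed_effects = list(intercept = unname(mu),
                         panel = panel_eff,
                         dye = dye_eff,
                         treatment = trt_eff),
    variance_components = list(array = sigma2_A,
                               dye_in_array = sigma2_D,
                               residual = sigma2_e),
    random_predictions = list(array = A_hat, dye_in_array = D_hat),
    residuals = R,
    design = design,
    probe_panel = stats::setNames(panel, probes),
    method = method,
    subtract_blups = isTRUE(subtract_blups),
    shrink_blups = isTRUE(shrink_blups),
    log_base = attr(data, "log_base")
  ), class = "stage1_fit")
}

#' Extract the stage-1 residual table
#'
#' @param fit A `stage1_fit`.
#' @return A `stage1_residuals` matrix (probe x channel-sample) whose
#'   `design` attribute carries the treatment and dye of every column, as
#'   needed by the per-probe stage-2 models.
#' @export
extract_residuals <- function(fit) {
  if (!inherits(fit, "stage1_fit"))
    stop("`fit` must be a stage1_fit", call. = FALSE)
  r <- fit$residuals
  attr(r, "design") <- fit$design
  class(r) <- c("stage1_residuals", class(r))
  r
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat("Stage-1 mixed-model fit (", x$method, ")\n", sep = "")
  cat(sprintf("  %d probes x %d channel-samples; intercept %.4f\n",
              nrow(x$residuals), ncol(x$residuals),
              x$fixed_effects$intercept))
  vc <- x$variance_components
  cat(sprintf("  variance components: array %.5f, dye-in-array %.5f, residual %.5f\n",
              vc$array, vc$dye_in_array, vc$residual))
  cat(sprintf("  dye effect (CY5 - CY3): %.4f\n",
              x$fixed_effects$dye[["CY5"]] - x$fixed_effects$dye[["CY3"]]))
  invisible(x)
}
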