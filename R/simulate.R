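#' Simulation configuration for two-channel intensity data
#'
#' Bundles the generative parameters of the synthetic-data module.  Log-scale
#' intensities are composed exactly as the stage-1 model assumes:
#' `baseline + panel + dye + treatment shift + array + dye-within-array +
#' noise`, with the array and dye-within-array terms drawn as Normal random
#' effects and probe-level Normal noise on top.
#'
#' Default magnitudes are package choices on the log2 scale, picked to look
#' like a routine two-colour spotted-array experiment: array-to-array
#' standard deviation 0.3, dye-within-array 0.2, probe-level residual 0.4,
#' and a global CY5-CY3 dye offset of 0.1.  The differential-expression
#' defaults (5\% of probes shifted by two residual standard deviations, 74\%
#' of them downward) emulate a treatment that suppresses most of the genes it
#' touches.
#'
#' @param n_probes Number of probes on the array.
#' @param n_panels Number of printed panels (print-tip blocks); probes are
#'   assigned to panels cyclically.
#' @param baseline Grand mean log2 intensity.
#' @param dye_effect Additive CY5 minus CY3 offset on the log scale.
#' @param panel_sd Standard deviation of the fixed panel effects (one draw
#'   per panel per simulation).
#' @param array_sd Standard deviation of the random array effect.
#' @param dye_in_array_sd Standard deviation of the random dye-within-array
#'   effect.
#' @param residual_sd Probe-level residual standard deviation.
#' @param de_fraction Fraction of probes that are truly differentially
#'   expressed.
#' @param effect_size Absolute log-scale shift of a DE probe in its shifted
#'   treatment.
#' @param down_fraction Fraction of DE probes shifted downward (the rest are
#'   shifted up).
#' @param seed Integer seed; identical `(config, design, seed)` give
#'   bit-identical output.
#' @return A validated `sim_config` list.
#' @seealso [simulate_experiment()]
#' @export
sim_config <- function(n_probes = 2000, n_panels = 48, baseline = 10,
                       dye_effect = 0.1, panel_sd = 0.25, array_sd = 0.3,
                       dye_in_array_sd = 0.2, residual_sd = 0.4,
                       de_fraction = 0.05, effect_size = 0.8,
                       down_fraction = 0.74, seed = 1L) {
  cfg <- list(n_probes = n_probes, n_panels = n_panels, baseline = baseline,
              dye_effect = dye_effect, panel_sd = panel_sd,
              array_sd = array_sd, dye_in_array_sd = dye_in_array_sd,
              residual_sd = residual_sd, de_fraction = de_fraction,
              effect_size = effect_size, down_fraction = down_fraction,
              seed = as.integer(seed))
  num1 <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x)
  for (nm in names(cfg))
    if (!num1(cfg[[nm]]))
      stop(sprintf("`%s` must be a single non-missing number", nm),
           call. = FALSE)
  if (cfg$n_probes < 1 || cfg$n_probes %% 1 != 0)
    stop("`n_probes` must be a positive integer", call. = FALSE)
  if (cfg$n_panels < 1 || cfg$n_panels %% 1 != 0)
    stop("`n_panels` must be a positive integer", call. = FALSE)
  for (nm in c("panel_sd", "array_sd", "dye_in_array_sd", "residual_sd"))
    if (cfg[[nm]] < 0)
      stop(sprintf("`%s` must be non-negative", nm), call. = FALSE)
  for (nm in c("de_fraction", "down_fraction"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop(sprintf("`%s` must lie in [0, 1]", nm), call. = FALSE)
  if (cfg$effect_size < 0)
    stop("`effect_size` must be non-negative", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Simulate a two-channel loop-design experiment with ground truth
#'
#' Generates raw-scale probe intensities for every channel-sample of a loop
#' design, mirroring the effect structure fitted by [fit_stage1()]: the log
#' intensity of probe g in channel `(array, dye)` carrying treatment `trt` is
#' `baseline + panel(g) + dye + shift_g(trt) + A_array + D_(array,dye) +
#' noise`, with `A ~ N(0, array_sd^2)`, `D ~ N(0, dye_in_array_sd^2)` and
#' `noise ~ N(0, residual_sd^2)`.  Intensities are exponentiated to the raw
#' scale (base `log_base`) so the emitted table is strictly positive.
#'
#' A fraction `de_fraction` of probes receives a true treatment shift of
#' `effect_size` in `shift_treatment` (downward for `down_fraction` of them),
#' recorded in the returned ground truth for recovery testing.
#'
#' @param config A [sim_config()].
#' @param design A valid [build_loop_design()] design.
#' @param shift_treatment Treatment receiving the true DE shifts; defaults to
#'   the design's second treatment label.
#' @param log_base Base used when exponentiating to the raw scale.
#' @return A list with `intensities` (an `intensity_table`: long data frame
#'   `probe_id`, `panel`, `array_id`, `dye`, `intensity`) and `truth`
#'   (a `ground_truth` data frame `probe_id`, `is_de`, `treatment`, `shift`).
#' @examples
#' d <- build_loop_design(c("A", "B"), 1, dye_swap = FALSE)
#' sim <- simulate_experiment(sim_config(n_probes = 10, n_panels = 2), d)
#' head(sim$intensities)
#' @export
simulate_experiment <- function(config, design, shift_treatment = NULL,
                                log_base = 2) {
  if (!inherits(config, "sim_config"))
    stop("`config` must be built with sim_config()", call. = FALSE)
  v <- validate_design(design)
  if (length(v))
    stop("invalid design: ", v[1], call. = FALSE)
  trts <- attr(design, "treatments") %||% unique(design$treatment)
  if (is.null(shift_treatment))
    shift_treatment <- trts[min(2L, length(trts))]
  if (!shift_treatment %in% trts)
    stop("`shift_treatment` is not a design treatment", call. = FALSE)

  G <- config$n_probes
  C <- nrow(design)
  P <- config$n_panels
  set.seed(config$seed)

  probe_id  <- sprintf("probe_%05d", seq_len(G))
  panel     <- ((seq_len(G) - 1L) %% P) + 1L
  panel_eff <- stats::rnorm(P, 0, config$panel_sd)
  arrays    <- unique(design$array_id)
  A <- stats::rnorm(length(arrays), 0, config$array_sd)
  names(A) <- arrays
  D <- stats::rnorm(C, 0, config$dye_in_array_sd)

  n_de  <- round(config$de_fraction * G)
  shift <- numeric(G)
  if (n_de > 0) {
    de_idx <- sample.int(G, n_de)
    sgn <- rep(1, n_de)
    n_down <- round(config$down_fraction * n_de)
    if (n_down > 0) sgn[seq_len(n_down)] <- -1
    shift[de_idx] <- sgn * config$effect_size
  }

  chan_fixed <- ifelse(design$dye == "CY5", config$dye_effect, 0) +
    A[design$array_id] + D
  trt_hit <- as.numeric(design$treatment == shift_treatment)

  M <- matrix(stats::rnorm(G * C, 0, config$residual_sd), G, C)
  M <- M + config$baseline + panel_eff[panel] + outer(shift, trt_hit)
  M <- sweep(M, 2, chan_fixed, "+")

  intensities <- data.frame(
    probe_id  = rep(probe_id, times = C),
    panel     = rep(panel, times = C),
    array_id  = rep(design$array_id, each = G),
    dye       = rep(design$dye, each = G),
    intensity = as.vector(log_base^M),
    stringsAsFactors = FALSE
  )
  intensities <- structure(intensities, log_scale = FALSE,
                           log_base = NA_real_,
                           class = c("intensity_table", "data.frame"))
  truth <- structure(data.frame(
    probe_id  = probe_id,
    is_de     = shift != 0,
    treatment = ifelse(shift != 0, shift_treatment, NA_character_),
    shift     = shift,
    stringsAsFactors = FALSE
  ), shift_treatment = shift_treatment,
     class = c("ground_truth", "data.frame"))
  list(intensities = intensities, truth = truth)
}

#' Simulate an egg-hatch assay
#'
#' Each egg hatches independently with probability `hatch_prob`; the hatch
#' day of a hatched egg is a discretised Normal(`mean_day`, `sd_day`)
#' truncated at day 1, producing the bell-shaped hatch curve typical of
#' insect egg batches.
#'
#' @param n_replicates Number of biological replicates (dishes).
#' @param n_eggs Eggs per replicate.
#' @param hatch_prob Per-egg hatch probability.
#' @param mean_day,sd_day Mean and standard deviation of the hatch-day
#'   distribution (`sd_day > 0`).
#' @param seed Integer seed.
#' @return A `hatch_data` data frame with columns `replicate`, `day`,
#'   `hatched` (counts for every day `1..max`), carrying attribute `n_eggs`
#'   (per-replicate egg counts).
#' @export
simulate_hatch_assay <- function(n_replicates = 10, n_eggs = 100,
                                 hatch_prob = 0.885, mean_day = 6,
                                 sd_day = 1.5, seed = 1L) {
  if (n_replicates < 1 || n_eggs < 1)
    stop("`n_replicates` and `n_eggs` must be positive", call. = FALSE)
  if (!is.numeric(hatch_prob) || hatch_prob < 0 || hatch_prob > 1)
    stop("`hatch_prob` must lie in [0, 1]", call. = FALSE)
  if (sd_day <= 0) stop("`sd_day` must be positive", call. = FALSE)
  set.seed(seed)
  days_by_rep <- lapply(seq_len(n_replicates), function(r) {
    hatched <- stats::rbinom(1, n_eggs, hatch_prob)
    if (hatched == 0) return(integer())
    pmax(1L, as.integer(round(stats::rnorm(hatched, mean_day, sd_day))))
  })
  max_day <- max(1L, unlist(c(1L, days_by_rep)))
  df <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    data.frame(replicate = r, day = seq_len(max_day),
               hatched = tabulate(days_by_rep[[r]], nbins = max_day))
  }))
  rownames(df) <- NULL
  structure(df, n_eggs = rep(n_eggs, n_replicates),
            class = c("hatch_data", "data.frame"))
}

#' Simulate a host-location assay
#'
#' Each larva locates the host with probability `locate_prob`; location times
#' are drawn from a geometric distribution over `interval`-minute observation
#' bins whose median equals `median_minutes`, and larvae whose drawn time
#' exceeds the observation `window` are censored along with the
#' never-locators.
#'
#' @param n_replicates Number of replicate dishes.
#' @param n_larvae Larvae per dish.
#' @param locate_prob Probability that a larva locates the host at all.
#' @param median_minutes Median location time of the locating larvae.
#' @param seed Integer seed.
#' @param window Observation window in minutes.
#' @param interval Count interval in minutes.
#' @return A `location_data` data frame with columns `replicate`, `larva`,
#'   `minutes` (`NA` when censored) and `censored`, carrying attributes
#'   `window` and `interval`.
#' @export
simulate_host_location <- function(n_replicates = 10, n_larvae = 10,
                                   locate_prob = 0.95, median_minutes = 20,
                                   seed = 1L, window = 60, interval = 5) {
  if (n_replicates < 1 || n_larvae < 1)
    stop("`n_replicates` and `n_larvae` must be positive", call. = FALSE)
  if (!is.numeric(locate_prob) || locate_prob < 0 || locate_prob > 1)
    stop("`locate_prob` must lie in [0, 1]", call. = FALSE)
  if (median_minutes <= 0)
    stop("`median_minutes` must be positive", call. = FALSE)
  set.seed(seed)
  p_bin <- 1 - 0.5^(interval / median_minutes)
  n <- n_replicates * n_larvae
  locates <- stats::runif(n) < locate_prob
  minutes <- (stats::rgeom(n, p_bin) + 1L) * interval
  censored <- !locates | minutes > window
  minutes[censored] <- NA_real_
  df <- data.frame(
    replicate = rep(seq_len(n_replicates), each = n_larvae),
    larva     = rep(seq_len(n_larvae), times = n_replicates),
    minutes   = minutes,
    censored  = censored
  )
  structure(df, window = window, interval = interval,
            class = c("location_data", "data.frame"))
}
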