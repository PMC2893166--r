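#' Percent hatch of an egg batch
#'
#' @param data A `hatch_data` table (see [simulate_hatch_assay()]): columns
#'   `replicate`, `day`, `hatched`, with per-replicate egg totals either in
#'   the `n_eggs` attribute or an `n_eggs` column.
#' @return A list with `per_replicate` (percent hatch per replicate, the
#'   vector fed to [two_sample_t()]) and `total` (colony percent hatch,
#'   `100 * total hatched / total eggs`).
#' @examples
#' h <- simulate_hatch_assay(hatch_prob = 0.89, seed = 7)
#' percent_hatch(h)$total
#' @export
percent_hatch <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("replicate", "day", "hatched") %in% names(data)))
  reps <- unique(data$replicate)
  eggs <- attr(data, "n_eggs")
  if (is.null(eggs) && "n_eggs" %in% names(data))
    eggs <- vapply(reps, function(r) data$n_eggs[data$replicate == r][1], 0)
  if (is.null(eggs))
    stop("egg totals missing: provide an `n_eggs` attribute or column",
         call. = FALSE)
  if (any(eggs <= 0))
    stop("every replicate needs a positive egg count", call. = FALSE)
  hatched <- vapply(reps, function(r) sum(data$hatched[data$replicate == r]), 0)
  per <- 100 * hatched / eggs
  names(per) <- as.character(reps)
  list(per_replicate = per, total = 100 * sum(hatched) / sum(eggs))
}

#' Mean hatch curve across replicates
#'
#' Per-day hatch counts averaged over replicates; days without hatch report
#' zero.  The series is truncated `stop_after` days after the last day with
#' any hatch (the assay's stop rule), which never alters totals.
#'
#' @param data A `hatch_data` table.
#' @param stop_after Days without hatch after which the series ends.
#' @return A data frame with `day` and `mean_hatched`.
#' @export
hatch_curve <- function(data, stop_after = 7) {
  stopifnot(is.data.frame(data),
            all(c("replicate", "day", "hatched") %in% names(data)))
  n_rep <- length(unique(data$replicate))
  if (n_rep < 1) stop("at least one replicate required", call. = FALSE)
  max_day <- max(data$day)
  tot <- vapply(seq_len(max_day),
                function(d) sum(data$hatched[data$day == d]), 0)
  last <- if (any(tot > 0)) max(which(tot > 0)) else 1L
  keep <- seq_len(min(max_day, last + stop_after))
  data.frame(day = keep, mean_hatched = tot[keep] / n_rep)
}

#' Pooled-variance two-sample Student's t test
#'
#' Two-sided Student's t with pooled variance on `n_a + n_b - 2` degrees of
#' freedom, as used to compare per-replicate assay summaries between
#' colonies.
#'
#' @param a,b Numeric vectors of length at least 2.
#' @return An `assay_comparison` list: `statistic`, `p_value`, `n_a`, `n_b`,
#'   `df`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, p ~ 0.288
#' @export
two_sample_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations", call. = FALSE)
  if (anyNA(a) || anyNA(b))
    stop("missing values are not allowed", call. = FALSE)
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  d <- mean(a) - mean(b)
  if (sp2 <= 0) {
    tval <- if (abs(d) <= 1e-12) 0 else sign(d) * Inf
    p <- if (tval == 0) 1 else 0
  } else {
    tval <- d / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * stats::pt(-abs(tval), df)
  }
  structure(list(statistic = tval, p_value = p, n_a = na, n_b = nb, df = df),
            class = "assay_comparison")
}

#' @export
print.assay_comparison <- function(x, ...) {
  cat(sprintf("Two-sample t: t = %.4f, p = %.4f (df = %d; n = %d vs %d)\n",
              x$statistic, x$p_value, x$df, x$n_a, x$n_b))
  invisible(x)
}

#' Fraction of larvae locating the host within a time limit
#'
#' Censored larvae (never located, or located after the observation window)
#' count in the denominator.
#'
#' @param data A `location_data` table (see [simulate_host_location()]).
#' @param minutes Time limit in minutes; must be positive.
#' @return A list with `per_replicate` fractions and the `overall` fraction.
#' @export
location_fraction_within <- function(data, minutes = 60) {
  stopifnot(is.data.frame(data),
            all(c("replicate", "minutes", "censored") %in% names(data)))
  if (!is.numeric(minutes) || minutes <= 0)
    stop("`minutes` must be positive", call. = FALSE)
  located <- !data$censored & !is.na(data$minutes) & data$minutes <= minutes
  per <- tapply(located, data$replicate, mean)
  list(per_replicate = per, overall = mean(located))
}
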