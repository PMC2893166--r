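#' Fit the stage-2 fixed-effect model for one probe
#'
#' Least-squares fit of `residual = mean + dye + treatment + error` for a
#' single probe, under sum-to-zero coding.  The returned LS means are the
#' fitted treatment means adjusted for dye; `mse` is the residual sum of
#' squares over the error degrees of freedom
#' `n - 1 - (n_dyes - 1) - (n_treatments - 1)`.
#'
#' @param values Numeric vector of stage-1 residuals for the probe, one per
#'   channel-sample.
#' @param treatment Treatment label of each value.
#' @param dye Optional dye label of each value; omit (or pass a single-level
#'   vector) for a dye-free one-way fit.
#' @return A `probe_fit` list: `ls_means`, `dye_effect` (second dye level
#'   minus first), `mse`, `df_error`, `ss_treatment`, `n_per_treatment`.
#' @examples
#' fit <- fit_probe_model(c(1, 2, 3, 2, 3, 4), rep(c("A", "B"), each = 3))
#' f_test(fit)
#' @export
fit_probe_model <- function(values, treatment, dye = NULL) {
  values <- as.numeric(values)
  if (anyNA(values))
    stop("missing residual values: stage-2 fits need one residual per channel-sample",
         call. = FALSE)
  trtf <- factor(treatment)
  if (length(values) != length(trtf))
    stop("`values` and `treatment` lengths differ", call. = FALSE)
  if (nlevels(trtf) < 2)
    stop("need at least two treatments", call. = FALSE)
  dyef <- NULL
  if (!is.null(dye)) {
    dyef <- factor(dye)
    if (length(dyef) != length(values))
      stop("`values` and `dye` lengths differ", call. = FALSE)
    if (nlevels(dyef) < 2) dyef <- NULL
  }
  X <- if (is.null(dyef))
    stats::model.matrix(~ trtf, contrasts.arg = list(trtf = "contr.sum"))
  else
    stats::model.matrix(~ dyef + trtf,
                        contrasts.arg = list(dyef = "contr.sum",
                                             trtf = "contr.sum"))
  df_error <- length(values) - ncol(X)
  if (df_error < 1)
    stop("insufficient data: no error degrees of freedom", call. = FALSE)
  qx <- qr(X)
  co <- qr.coef(qx, values)
  rss <- sum(qr.resid(qx, values)^2)
  X0 <- X[, !grepl("^trtf", colnames(X)), drop = FALSE]
  ss_trt <- max(0, sum(qr.resid(qr(X0), values)^2) - rss)
  nt <- nlevels(trtf)
  trt_co <- co[grep("^trtf", names(co))]
  trt_eff <- c(trt_co, -sum(trt_co))
  names(trt_eff) <- levels(trtf)
  dye_effect <- if (is.null(dyef)) 0 else -2 * co[grep("^dyef", names(co))]
  structure(list(
    ls_means = co[[1]] + trt_eff,
    dye_effect = unname(dye_effect),
    mse = rss / df_error,
    df_error = df_error,
    ss_treatment = ss_trt,
    n_treatments = nt,
    n_per_treatment = table(trtf)
  ), class = "probe_fit")
}

#' F test for a treatment effect within one probe
#'
#' `F = (treatment SS / (t - 1)) / MSE` on `(t - 1, df_error)` degrees of
#' freedom, upper-tail p.  Exact fits (`mse == 0`) are flagged: p is 0 when
#' the treatment sum of squares is non-zero and 1 otherwise.
#'
#' @param fit A `probe_fit`.
#' @return A list with `f_stat`, `f_p` and `exact_fit`.
#' @export
f_test <- function(fit) {
  stopifnot(inherits(fit, "probe_fit"))
  df1 <- fit$n_treatments - 1
  if (fit$mse <= 0) {
    if (fit$ss_treatment > 1e-12)
      return(list(f_stat = Inf, f_p = 0, exact_fit = TRUE))
    return(list(f_stat = NaN, f_p = 1, exact_fit = TRUE))
  }
  f <- (fit$ss_treatment / df1) / fit$mse
  list(f_stat = f,
       f_p = stats::pf(f, df1, fit$df_error, lower.tail = FALSE),
       exact_fit = FALSE)
}

#' Pairwise t tests between treatments within one probe
#'
#' For every treatment pair, `t = (lsmean_i - lsmean_j) /
#' sqrt(mse * (1/n_i + 1/n_j))` on `df_error` degrees of freedom, two-sided.
#'
#' @param fit A `probe_fit`.
#' @return A data frame with one row per pair: `treatment_a`, `treatment_b`,
#'   `t`, `p`.
#' @export
pairwise_t_tests <- function(fit) {
  stopifnot(inherits(fit, "probe_fit"))
  trts <- names(fit$ls_means)
  pairs <- utils::combn(trts, 2)
  n <- fit$n_per_treatment
  res <- apply(pairs, 2, function(pr) {
    d <- fit$ls_means[[pr[1]]] - fit$ls_means[[pr[2]]]
    se <- sqrt(fit$mse * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    if (se <= 0) {
      if (abs(d) <= 1e-12) c(t = 0, p = 1) else c(t = sign(d) * Inf, p = 0)
    } else {
      tval <- d / se
      c(t = tval, p = 2 * stats::pt(-abs(tval), fit$df_error))
    }
  })
  data.frame(treatment_a = pairs[1, ], treatment_b = pairs[2, ],
             t = res["t", ], p = res["p", ], stringsAsFactors = FALSE)
}

# counts of k-subsets of ranks 1..N by rank sum (index = sum + 1)
ranksum_null_counts <- function(k, N) {
  maxs <- sum(seq(N - k + 1, N))
  f <- matrix(0, k + 1, maxs + 1)
  f[1, 1] <- 1
  for (i in seq_len(N)) {
    for (j in seq(min(i, k), 1)) {
      idx <- seq_len(maxs + 1 - i)
      f[j + 1, idx + i] <- f[j + 1, idx + i] + f[j, idx]
    }
  }
  f[k + 1, ]
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test reporting the rank sum of the first sample.
#' When the combined sample size is at most 14 and there are no ties, the
#' two-sided p-value is exact: the null distribution of the rank sum is
#' enumerated by counting rank subsets, and both tails at least as extreme
#' as the observed sum (and its reflection about the null mean) are summed.
#' Otherwise a Normal approximation with tie and continuity corrections is
#' used.
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact enumeration;
#'   `NULL` (default) selects it automatically.  Exact p-values require
#'   tie-free data; with ties the approximation is used with a warning.
#' @return A list with `rank_sum`, `p` and `exact`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p  # 0.1
#' @export
wilcoxon_rank_sum <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b))
    stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(a) || anyNA(b))
    stop("missing values are not allowed", call. = FALSE)
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])
  ties <- anyDuplicated(c(a, b)) > 0
  if (is.null(exact)) exact <- N <= 14 && !ties
  if (exact && ties) {
    warning("ties present; falling back to the Normal approximation")
    exact <- FALSE
  }
  if (exact) {
    counts <- ranksum_null_counts(na, N)
    total <- choose(N, na)
    refl <- na * (N + 1) - w       # reflection of w about 2 * E[W]
    lo <- min(w, refl); hi <- max(w, refl)
    sums <- seq_along(counts) - 1
    p <- (sum(counts[sums <= lo]) + sum(counts[sums >= hi])) / total
    p <- min(1, p)
  } else {
    mu <- na * (N + 1) / 2
    tj <- table(c(a, b))
    sig2 <- na * nb * (N + 1) / 12 -
      na * nb * sum(tj^3 - tj) / (12 * N * (N - 1))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu - 0.5 * sign(w - mu)) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(rank_sum = w, p = p, exact = exact)
}

#' Run the per-probe test battery and rank the probes
#'
#' For every probe of a stage-1 residual table: fits the stage-2 fixed
#' dye + treatment model, computes the treatment F test, all pairwise t
#' tests and (optionally) Wilcoxon rank-sum tests on the residuals grouped
#' by treatment (dyes pooled).  Probes are ordered by their smallest
#' pairwise t p-value (`order_by = "min_t"`, the default ranking statistic)
#' or by the F p-value, with ties broken lexicographically by probe id, and
#' assigned ranks `1..n`.  A probe is flagged significant when its smallest
#' pairwise p-value is at most `alpha`.
#'
#' The per-probe fits share one design matrix, so the battery is evaluated
#' for all probes in a handful of matrix operations.
#'
#' @param residuals A `stage1_residuals` matrix (see [extract_residuals()])
#'   or a probe x channel-sample matrix whose columns follow `design`.
#' @param design The `loop_design`; taken from `residuals` when present.
#' @param alpha Significance threshold applied to the smallest pairwise
#'   p-value.  Default 0.05.
#' @param order_by Ranking statistic, `"min_t"` or `"f"`.
#' @param wilcoxon Compute Wilcoxon rank-sum p-values?  Default `TRUE`.
#' @return A `probe_stats` data frame in rank order: `probe_id`, `f_stat`,
#'   `f_p`, per-pair `t_*`, `p_*` (and `wp_*`) columns, `min_p`,
#'   per-treatment `mean_*` columns, `rank`, `significant`; attributes
#'   `pairs`, `treatments`, `alpha`, `order_by`.
#' @export
run_probe_inference <- function(residuals, design = NULL, alpha = 0.05,
                                order_by = c("min_t", "f"), wilcoxon = TRUE) {
  order_by <- match.arg(order_by)
  if (is.null(design)) design <- attr(residuals, "design")
  if (is.null(design))
    stop("a design is required (pass `design` or use extract_residuals())",
         call. = FALSE)
  v <- validate_design(design)
  if (length(v)) stop("invalid design: ", v[1], call. = FALSE)
  M <- residuals
  attr(M, "design") <- NULL
  class(M) <- NULL
  M <- as.matrix(M)
  C <- nrow(design)
  if (ncol(M) != C)
    stop("residual table and design disagree on the number of channel-samples",
         call. = FALSE)
  key <- channel_key(design$array_id, design$dye)
  if (!is.null(colnames(M))) {
    if (!setequal(colnames(M), key))
      stop("residual columns do not match the design channel-samples",
           call. = FALSE)
    M <- M[, key, drop = FALSE]
  }
  probes <- rownames(M) %||% sprintf("probe_%05d", seq_len(nrow(M)))
  G <- nrow(M)

  trtf <- factor(design$treatment,
                 levels = attr(design, "treatments") %||% unique(design$treatment))
  dyef <- factor(design$dye, levels = .dyes)
  X <- stats::model.matrix(~ dyef + trtf,
                           contrasts.arg = list(dyef = "contr.sum",
                                                trtf = "contr.sum"))
  X0 <- stats::model.matrix(~ dyef,
                            contrasts.arg = list(dyef = "contr.sum"))
  df_error <- C - ncol(X)
  if (df_error < 1)
    stop("insufficient data: no error degrees of freedom", call. = FALSE)
  qrX <- qr(X); qrX0 <- qr(X0)
  TM <- t(M)
  rss_full <- colSums(qr.resid(qrX, TM)^2)
  rss_red  <- colSums(qr.resid(qrX0, TM)^2)
  mse <- rss_full / df_error
  coefs <- qr.coef(qrX, TM)
  nt <- nlevels(trtf)
  trt_rows <- grep("^trtf", rownames(coefs))
  trt_eff <- rbind(coefs[trt_rows, , drop = FALSE],
                   -colSums(coefs[trt_rows, , drop = FALSE]))
  lsm <- sweep(trt_eff, 2, coefs[1, ], "+")
  rownames(lsm) <- levels(trtf)
  n_per <- table(trtf)

  ss_trt <- pmax(0, rss_red - rss_full)
  f_stat <- (ss_trt / (nt - 1)) / mse
  f_p <- stats::pf(f_stat, nt - 1, df_error, lower.tail = FALSE)
  z <- mse <= 0
  if (any(z)) {
    hit <- ss_trt[z] > 1e-12
    f_stat[z] <- ifelse(hit, Inf, NaN)
    f_p[z] <- ifelse(hit, 0, 1)
  }

  out <- data.frame(probe_id = probes, f_stat = f_stat, f_p = f_p,
                    stringsAsFactors = FALSE)
  pairs <- utils::combn(levels(trtf), 2)
  pair_names <- character(ncol(pairs))
  min_p <- rep(Inf, G)
  for (j in seq_len(ncol(pairs))) {
    t1 <- pairs[1, j]; t2 <- pairs[2, j]
    d <- lsm[t1, ] - lsm[t2, ]
    se <- sqrt(mse * (1 / n_per[[t1]] + 1 / n_per[[t2]]))
    tval <- ifelse(se > 0, d / se,
                   ifelse(abs(d) > 1e-12, sign(d) * Inf, 0))
    pval <- ifelse(se > 0, 2 * stats::pt(-abs(tval), df_error),
                   ifelse(abs(d) > 1e-12, 0, 1))
    nm <- paste(t1, t2, sep = "_vs_")
    pair_names[j] <- nm
    out[[paste0("t_", nm)]] <- tval
    out[[paste0("p_", nm)]] <- pval
    if (wilcoxon) {
      ia <- which(design$treatment == t1)
      ib <- which(design$treatment == t2)
      out[[paste0("wp_", nm)]] <- vapply(seq_len(G), function(g)
        wilcoxon_rank_sum(M[g, ia], M[g, ib])$p, 0)
    }
    min_p <- pmin(min_p, pval)
  }
  out$min_p <- min_p
  for (tr in levels(trtf)) out[[paste0("mean_", tr)]] <- lsm[tr, ]

  ord_stat <- if (order_by == "min_t") out$min_p else out$f_p
  ord <- order(ord_stat, out$probe_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$significant <- out$min_p <= alpha
  rownames(out) <- NULL
  structure(out, pairs = pair_names, treatments = levels(trtf),
            alpha = alpha, order_by = order_by,
            class = c("probe_stats", "data.frame"))
}
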