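#' Build a dye-swapped loop design
#'
#' Constructs the hybridisation layout of a two-colour loop design.
#' Treatments are arranged in a single cycle `T1 -> T2 -> ... -> Tt -> T1`;
#' every arrow becomes one array, with the source sample labelled CY3 and the
#' target CY5.  The cycle is repeated once per biological replicate, and with
#' `dye_swap = TRUE` every loop is duplicated with the dye assignment
#' reversed, so that each ordered treatment adjacency is hybridised equally
#' often in both dye orientations and dye-specific bias cancels.
#'
#' Array identifiers are generated deterministically from the replicate,
#' orientation and cycle position, so the same call always yields a
#' byte-identical design.
#'
#' @param treatments Character vector of at least two distinct treatment
#'   labels, in cycle order.
#' @param n_replicates Number of biological replicates (loops per dye
#'   orientation).
#' @param dye_swap Duplicate every loop with dyes reversed?  Default `TRUE`.
#'
#' @return A `loop_design`: a data frame with one row per channel-sample
#'   (two per array) and columns `array_id`, `dye` (`"CY3"`/`"CY5"`),
#'   `treatment` and `replicate`, carrying attributes `treatments` (the
#'   ordered label set) and `dye_swap`.
#'
#' @examples
#' d <- build_loop_design(c("control", "wcr_untreated", "wcr_treated"), 3)
#' summarize_design(d)   # 18 arrays, 36 channel-samples, 18 comparisons
#' @export
build_loop_design <- function(treatments, n_replicates, dye_swap = TRUE) {
  treatments <- as.character(treatments)
  if (length(treatments) < 2 || anyDuplicated(treatments) || anyNA(treatments))
    stop("a loop design needs at least 2 distinct treatment labels",
         call. = FALSE)
  if (!is.numeric(n_replicates) || length(n_replicates) != 1 ||
      is.na(n_replicates) || n_replicates < 1 || n_replicates %% 1 != 0)
    stop("`n_replicates` must be a positive integer", call. = FALSE)
  t <- length(treatments)
  orientations <- if (isTRUE(dye_swap)) c("fwd", "rev") else "fwd"
  rows <- vector("list", n_replicates * length(orientations) * t)
  i <- 0L
  for (r in seq_len(n_replicates)) {
    for (orient in orientations) {
      for (pos in seq_len(t)) {
        src <- treatments[pos]
        tgt <- treatments[pos %% t + 1L]
        i <- i + 1L
        rows[[i]] <- data.frame(
          array_id  = sprintf("A_r%d_%s_%02d", r, orient, pos),
          dye       = if (orient == "fwd") .dyes else rev(.dyes),
          treatment = c(src, tgt),
          replicate = as.integer(r),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  design <- do.call(rbind, rows)
  rownames(design) <- NULL
  structure(design,
            treatments = treatments,
            dye_swap   = isTRUE(dye_swap),
            class      = c("loop_design", "data.frame"))
}

#' Summarise a loop design
#'
#' Counts arrays, channel-samples and direct within-array comparisons.  Each
#' two-channel array yields exactly one direct comparison, so
#' `n_comparisons == n_arrays`; the three-treatment, three-replicate
#' dye-swapped design yields 18.
#'
#' @param design A `loop_design` (or equivalent data frame).
#' @return A list with `n_arrays`, `n_samples` and `n_comparisons`.
#' @export
summarize_design <- function(design) {
  v <- validate_design(design)
  if (length(v))
    stop("invalid design:\n", paste("-", v, collapse = "\n"), call. = FALSE)
  n_arrays <- length(unique(design$array_id))
  list(n_arrays      = n_arrays,
       n_samples     = nrow(design),
       n_comparisons = n_arrays)
}

#' Validate a loop design
#'
#' Checks the structural invariants of a two-colour loop design: every array
#' carries exactly two channel-samples with distinct dyes, no array
#' hybridises the same treatment in both channels, `(treatment, replicate)`
#' channel counts are balanced, and -- for dye-swapped designs -- every
#' treatment pair is hybridised equally often in both dye orientations.
#'
#' Violations are returned as data, not raised as errors, so the function can
#' be used to triage externally supplied design tables.
#'
#' @param design A `loop_design` or a data frame with columns `array_id`,
#'   `dye`, `treatment`, `replicate`.
#' @return A character vector of violation messages; empty if the design is
#'   valid.
#' @export
validate_design <- function(design) {
  req <- c("array_id", "dye", "treatment", "replicate")
  if (!is.data.frame(design) || !all(req %in% names(design)))
    return(sprintf("design must be a data frame with columns %s",
                   paste(req, collapse = ", ")))
  out <- character()
  trts <- attr(design, "treatments") %||% unique(design$treatment)
  bad_dye <- setdiff(unique(design$dye), .dyes)
  if (length(bad_dye))
    out <- c(out, sprintf("unknown dye label(s): %s",
                          paste(bad_dye, collapse = ", ")))
  bad_trt <- setdiff(unique(design$treatment), trts)
  if (length(bad_trt))
    out <- c(out, sprintf("treatment label(s) outside the design set: %s",
                          paste(bad_trt, collapse = ", ")))
  by_array <- split(design, design$array_id)
  for (aid in names(by_array)) {
    a <- by_array[[aid]]
    if (nrow(a) != 2) {
      out <- c(out, sprintf("array %s has %d channel-samples (expected 2)",
                            aid, nrow(a)))
      next
    }
    if (length(unique(a$dye)) != 2)
      out <- c(out, sprintf("array %s does not use both dyes", aid))
    if (a$treatment[1] == a$treatment[2])
      out <- c(out, sprintf(
        "array %s hybridizes treatment '%s' in both channels",
        aid, a$treatment[1]))
  }
  tab <- table(design$treatment, design$replicate)
  if (length(unique(as.vector(tab))) > 1)
    out <- c(out, "unbalanced (treatment, replicate) channel-sample counts")
  if (isTRUE(attr(design, "dye_swap"))) {
    ok <- vapply(by_array, function(a)
      nrow(a) == 2 && length(unique(a$dye)) == 2 &&
        a$treatment[1] != a$treatment[2], TRUE)
    ori <- orientation_table(by_array[ok])
    for (k in unique(ori$pair)) {
      n_f <- sum(ori$pair == k & ori$forward)
      n_r <- sum(ori$pair == k & !ori$forward)
      if (n_f != n_r)
        out <- c(out, sprintf(
          "treatment pair %s is dye-unbalanced (%d vs %d orientations)",
          k, n_f, n_r))
    }
  }
  out
}

# per valid array: the unordered treatment pair and whether the
# lexicographically first treatment sits in the CY3 channel
orientation_table <- function(arrays) {
  pair <- vapply(arrays, function(a) {
    p <- sort(a$treatment)
    paste(p[1], p[2], sep = "|")
  }, "")
  forward <- vapply(arrays, function(a) {
    p <- sort(a$treatment)
    a$treatment[a$dye == "CY3"] == p[1]
  }, TRUE)
  data.frame(pair = pair, forward = forward, stringsAsFactors = FALSE)
}

#' @export
print.loop_design <- function(x, ...) {
  s <- tryCatch(summarize_design(x), error = function(e) NULL)
  cat("Loop design:",
      paste(attr(x, "treatments") %||% unique(x$treatment), collapse = " -> "),
      if (isTRUE(attr(x, "dye_swap"))) "(dye swap)" else "(no dye swap)", "\n")
  if (!is.null(s))
    cat(sprintf("  %d arrays, %d channel-samples, %d within-array comparisons\n",
                s$n_arrays, s$n_samples, s$n_comparisons))
  invisible(x)
}
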