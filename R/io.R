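#' Read a channel-intensity table
#'
#' Reads the pipeline's GPR-like tab-delimited intensity format: one record
#' per probe x channel-sample with columns `probe_id`, `panel`, `array_id`,
#' `dye`, `intensity`.  Intensities must be positive on the raw scale;
#' offending rows are reported by line number.  Unicode minus signs (U+2212)
#' are normalised before numeric parsing.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @return An `intensity_table` data frame (raw scale).
#' @export
read_intensity_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, encoding = "UTF-8")
  req <- c("probe_id", "panel", "array_id", "dye", "intensity")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("intensity table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  val <- suppressWarnings(as.numeric(normalize_minus(as.character(tab$intensity))))
  bad <- which(is.na(val) | val <= 0)
  if (length(bad))
    stop("non-positive or unparseable intensity at line(s): ",
         paste(utils::head(bad + 1L, 20), collapse = ", "), call. = FALSE)
  tab$intensity <- val
  dup <- which(duplicated(tab[c("probe_id", "array_id", "dye")]))
  if (length(dup))
    stop("duplicate (probe_id, array_id, dye) record at line(s): ",
         paste(utils::head(dup + 1L, 20), collapse = ", "), call. = FALSE)
  structure(tab, log_scale = FALSE, log_base = NA_real_,
            class = c("intensity_table", "data.frame"))
}

#' Write a channel-intensity table
#'
#' @param tab An `intensity_table`.
#' @param path Output path (tab-delimited, UTF-8, LF line endings).
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(tab, path) {
  req <- c("probe_id", "panel", "array_id", "dye", "intensity")
  stopifnot(is.data.frame(tab), all(req %in% names(tab)))
  utils::write.table(tab[req], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a design table
#'
#' The design TSV has columns `array_id`, `dye`, `treatment`, `replicate`.
#' On reading, the treatment set is taken in order of first appearance and
#' the dye-swap flag, if not given, is inferred from whether every treatment
#' pair is hybridised in both dye orientations.
#'
#' @param design A `loop_design`.
#' @param path File path.
#' @param dye_swap Optional logical overriding the inferred dye-swap flag.
#' @return `write_design_table()` returns `path` invisibly;
#'   `read_design_table()` returns a `loop_design`.
#' @export
write_design_table <- function(design, path) {
  req <- c("array_id", "dye", "treatment", "replicate")
  stopifnot(is.data.frame(design), all(req %in% names(design)))
  utils::write.table(design[req], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_table
#' @export
read_design_table <- function(path, dye_swap = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, encoding = "UTF-8")
  req <- c("array_id", "dye", "treatment", "replicate")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("design table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(dye_swap)) {
    by_array <- split(tab, tab$array_id)
    ok <- vapply(by_array, function(a)
      nrow(a) == 2 && length(unique(a$dye)) == 2 &&
        a$treatment[1] != a$treatment[2], TRUE)
    ori <- orientation_table(by_array[ok])
    dye_swap <- length(ori$pair) > 0 &&
      all(vapply(unique(ori$pair), function(k) {
        sum(ori$pair == k & ori$forward) == sum(ori$pair == k & !ori$forward)
      }, TRUE))
  }
  structure(tab,
            treatments = unique(tab$treatment),
            dye_swap   = isTRUE(dye_swap),
            class      = c("loop_design", "data.frame"))
}

#' Read a relative-expression table
#'
#' Parses a tab-delimited table of per-treatment mean relative expression
#' (one row per probe), the layout used for the packaged worked-example
#' fixtures.  All columns other than `probe_id` and `annotation` are treated
#' as treatment means unless `treatments` names them explicitly.  Unicode
#' minus signs (U+2212), as printed in publication tables, are normalised
#' before numeric parsing; row order is preserved.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param treatments Optional character vector naming the treatment columns.
#' @return An `expression_table` data frame with attribute `treatments`.
#' @examples
#' tab1 <- read_relative_expression(
#'   system.file("extdata", "table1.tsv", package = "loopmaa"))
#' nrow(tab1)  # 36
#' @export
read_relative_expression <- function(path, treatments = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, encoding = "UTF-8")
  if (!"probe_id" %in% names(tab))
    stop("expression table must have a `probe_id` column", call. = FALSE)
  if (anyDuplicated(tab$probe_id))
    stop("duplicate probe_id in expression table: ",
         tab$probe_id[duplicated(tab$probe_id)][1], call. = FALSE)
  if (is.null(treatments))
    treatments <- setdiff(names(tab), c("probe_id", "annotation"))
  miss <- setdiff(treatments, names(tab))
  if (length(miss))
    stop("declared treatment column(s) not found: ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (tr in treatments) {
    val <- suppressWarnings(as.numeric(normalize_minus(as.character(tab[[tr]]))))
    bad <- which(is.na(val) & !is.na(tab[[tr]]))
    if (length(bad))
      stop(sprintf("unparseable value in column '%s' at line(s): %s",
                   tr, paste(bad + 1L, collapse = ", ")), call. = FALSE)
    tab[[tr]] <- val
  }
  structure(tab, treatments = treatments,
            class = c("expression_table", "data.frame"))
}

# fixed serialisation order for probe-level statistics
probe_result_columns <- function(stats) {
  pairs <- attr(stats, "pairs") %||%
    sub("^p_", "", grep("^p_", names(stats), value = TRUE))
  pair_cols <- as.vector(t(cbind(paste0("t_", pairs), paste0("p_", pairs),
                                 if (all(paste0("wp_", pairs) %in% names(stats)))
                                   paste0("wp_", pairs))))
  mean_cols <- grep("^mean_", names(stats), value = TRUE)
  c("probe_id", "rank", "f_stat", "f_p", pair_cols, "min_p", mean_cols,
    "significant")
}

#' Write / read per-probe test results
#'
#' Serialises a `probe_stats` table (see [run_probe_inference()]) with a
#' fixed column order -- probe id, rank, F statistic and p-value, pairwise t
#' and Wilcoxon p-values, the ranking statistic `min_p`, per-treatment means
#' and the significance flag -- in rank order with ties broken by probe id,
#' numeric values at 6 significant digits.
#'
#' @param stats A non-empty `probe_stats` data frame.
#' @param path File path.
#' @return `write_probe_results()` returns `path` invisibly;
#'   `read_probe_results()` returns a `probe_stats` data frame.
#' @export
write_probe_results <- function(stats, path) {
  if (!is.data.frame(stats) || nrow(stats) == 0)
    stop("`stats` must be a non-empty probe-statistics table", call. = FALSE)
  cols <- probe_result_columns(stats)
  miss <- setdiff(cols, names(stats))
  if (length(miss))
    stop("probe-statistics table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- stats[order(stats$rank, stats$probe_id), cols, drop = FALSE]
  for (nm in cols)
    if (is.numeric(out[[nm]]) && nm != "rank")
      out[[nm]] <- signif(out[[nm]], 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_results
#' @export
read_probe_results <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, encoding = "UTF-8")
  req <- c("probe_id", "rank", "f_stat", "f_p", "min_p", "significant")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("probe-results file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tab$significant <- as.logical(tab$significant)
  pairs <- sub("^p_", "", grep("^p_", names(tab), value = TRUE))
  structure(tab, pairs = pairs,
            class = c("probe_stats", "data.frame"))
}
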