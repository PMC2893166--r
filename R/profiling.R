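#' Select the top-k probes by rank
#'
#' Returns the `k` best-ranked probes in rank order (ranks `1..k`
#' contiguous).  If fewer than `k` probes are available all are returned
#' with a warning.
#'
#' @param stats A `probe_stats` table (see [run_probe_inference()]).
#' @param k Number of probes to keep.
#' @return A `probe_stats` table of at most `k` rows.
#' @export
select_top_k <- function(stats, k) {
  if (!is.data.frame(stats) || !"rank" %in% names(stats))
    stop("`stats` must be a ranked probe-statistics table", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1 || k %% 1 != 0)
    stop("`k` must be a positive integer", call. = FALSE)
  at <- attributes(stats)
  ord <- order(stats$rank)
  if (k > nrow(stats)) {
    warning(sprintf("only %d probes available; returning all of them",
                    nrow(stats)))
    k <- nrow(stats)
  }
  out <- stats[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  for (nm in c("pairs", "treatments", "alpha", "order_by"))
    attr(out, nm) <- at[[nm]]
  class(out) <- class(stats)
  out
}

#' Direction-of-regulation calls against a control treatment
#'
#' For every probe and every non-control treatment: `UP` if the treatment
#' mean exceeds the control mean by more than `tolerance`, `DOWN` if it
#' falls short by more than `tolerance`, `UNCHANGED` otherwise.  The control
#' column itself is `UNCHANGED` by definition.  Calls are invariant to
#' adding a constant to all treatment columns of a probe.
#'
#' @param expr An `expression_table` (see [read_relative_expression()]) or a
#'   data frame with `probe_id` and one numeric column per treatment.
#' @param control_label The control treatment column.
#' @param tolerance Dead band around zero; default 0 (any non-zero
#'   difference is a call).
#' @return A `direction_calls` data frame: `probe_id` plus one call column
#'   per treatment.
#' @export
direction_calls <- function(expr, control_label, tolerance = 0) {
  trts <- attr(expr, "treatments") %||%
    setdiff(names(expr), c("probe_id", "annotation"))
  if (!control_label %in% trts)
    stop(sprintf("unknown control label '%s'", control_label), call. = FALSE)
  if (tolerance < 0) stop("`tolerance` must be non-negative", call. = FALSE)
  out <- data.frame(probe_id = expr$probe_id, stringsAsFactors = FALSE)
  out[[control_label]] <- rep("UNCHANGED", nrow(expr))
  for (tr in setdiff(trts, control_label)) {
    d <- expr[[tr]] - expr[[control_label]]
    out[[tr]] <- ifelse(d > tolerance, "UP",
                        ifelse(d < -tolerance, "DOWN", "UNCHANGED"))
  }
  structure(out, control = control_label, tolerance = tolerance,
            treatments = trts,
            class = c("direction_calls", "data.frame"))
}

#' Treatment-similarity (Venn) partition of a top-k probe set
#'
#' A probe is "similar" for a treatment pair when its pairwise t-test
#' p-value exceeds `alpha` (failure to reject equality of that pair's
#' means).  Probes are partitioned into the disjoint Venn cells defined by
#' the set of pairs for which they are similar; cell counts always sum to
#' the number of probes.
#'
#' @param stats A `probe_stats` table (typically the [select_top_k()]
#'   output) with `p_*` columns for every treatment pair.
#' @param alpha Similarity threshold: similar iff `p > alpha`.
#' @return A `similarity_partition` list: `k`, `alpha`, `pair_counts`
#'   (marginal similar counts per pair), `cells` (a data frame of all
#'   `2^n_pairs` disjoint cells and their counts), `all_similar`,
#'   `none_similar`.
#' @export
similarity_partition <- function(stats, alpha) {
  pairs <- attr(stats, "pairs") %||%
    sub("^p_", "", grep("^p_", names(stats), value = TRUE))
  if (!length(pairs))
    stop("no pairwise p-value columns found", call. = FALSE)
  pcols <- paste0("p_", pairs)
  miss <- setdiff(pcols, names(stats))
  if (length(miss))
    stop("missing pairwise p-values: ", paste(miss, collapse = ", "),
         call. = FALSE)
  k <- nrow(stats)
  sim <- matrix(FALSE, k, length(pairs), dimnames = list(NULL, pairs))
  for (j in seq_along(pairs)) sim[, j] <- stats[[pcols[j]]] > alpha
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(pairs)))
  names(combos) <- pairs
  cell_of <- function(s) if (!any(s)) "none" else paste(pairs[s], collapse = "+")
  cell_labels <- apply(as.matrix(combos), 1, cell_of)
  probe_cells <- if (k > 0) apply(sim, 1, cell_of) else character()
  counts <- table(factor(probe_cells, levels = cell_labels))
  cells <- data.frame(cell = cell_labels, count = as.integer(counts),
                      stringsAsFactors = FALSE)
  structure(list(
    k = k,
    alpha = alpha,
    pair_counts = colSums(sim),
    cells = cells,
    all_similar = sum(rowSums(sim) == length(pairs)),
    none_similar = sum(rowSums(sim) == 0)
  ), class = "similarity_partition")
}

#' @export
print.similarity_partition <- function(x, ...) {
  cat(sprintf("Similarity partition of %d probes (similar iff p > %g)\n",
              x$k, x$alpha))
  cat("  per-pair similar counts:\n")
  for (nm in names(x$pair_counts))
    cat(sprintf("    %-40s %d\n", nm, x$pair_counts[[nm]]))
  cat(sprintf("  similar for all pairs: %d; for none: %d\n",
              x$all_similar, x$none_similar))
  invisible(x)
}

#' Functional-category counts for a probe set
#'
#' Tallies the annotation categories of a set of probe ids.  Probes without
#' an annotation fall into the `"unknown"` category; counts always sum to
#' the number of ids.
#'
#' @param ids Character vector of probe ids.
#' @param annotation A named character vector (`probe_id -> category`) or a
#'   data frame with columns `probe_id` and `category`; `NULL` sends
#'   everything to `"unknown"`.
#' @return A named integer vector of counts, in decreasing order.
#' @export
category_summary <- function(ids, annotation = NULL) {
  if (is.data.frame(annotation)) {
    stopifnot(all(c("probe_id", "category") %in% names(annotation)))
    annotation <- stats::setNames(as.character(annotation$category),
                                  annotation$probe_id)
  }
  cat <- if (is.null(annotation)) rep(NA_character_, length(ids))
         else unname(annotation[ids])
  cat[is.na(cat) | !nzchar(cat)] <- "unknown"
  sort(table(cat), decreasing = TRUE)
}

#' Export a heat-map matrix of per-treatment means
#'
#' Builds (and optionally writes) the tab-delimited matrix behind an
#' expression heat map: rows are probes in a deterministic order, columns
#' are the per-treatment means.  Rendering the image itself is left to
#' dedicated tools.
#'
#' @param stats A data frame with `probe_id` and per-treatment `mean_*`
#'   columns (e.g. a `probe_stats` table).
#' @param path Optional output path; values are written at 6 significant
#'   digits.
#' @param order_by Row order: `"rank"` (by the `rank` column when present,
#'   otherwise input order) or `"category"` (grouped by annotation, then
#'   probe id).
#' @param annotation Category map used when `order_by = "category"`; as in
#'   [category_summary()].
#' @return The probe x treatment matrix, invisibly when written.
#' @export
export_heatmap_matrix <- function(stats, path = NULL,
                                  order_by = c("rank", "category"),
                                  annotation = NULL) {
  order_by <- match.arg(order_by)
  mcols <- grep("^mean_", names(stats), value = TRUE)
  if (!length(mcols))
    stop("no per-treatment `mean_*` columns present", call. = FALSE)
  M <- as.matrix(stats[mcols])
  rownames(M) <- stats$probe_id
  colnames(M) <- sub("^mean_", "", mcols)
  if (order_by == "rank") {
    if ("rank" %in% names(stats)) M <- M[order(stats$rank), , drop = FALSE]
  } else {
    if (is.data.frame(annotation))
      annotation <- stats::setNames(as.character(annotation$category),
                                    annotation$probe_id)
    cat <- if (is.null(annotation)) rep(NA_character_, nrow(M))
           else unname(annotation[rownames(M)])
    cat[is.na(cat) | !nzchar(cat)] <- "unknown"
    M <- M[order(cat, rownames(M)), , drop = FALSE]
  }
  if (!is.null(path)) {
    df <- data.frame(probe_id = rownames(M), signif(M, 6),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(M))
  }
  M
}

#' Cross-platform direction concordance
#'
#' For every probe shared by two expression tables, compares the sign of
#' `(treatment mean - control mean)` between the tables for every
#' non-control treatment; a probe is concordant when all signs match (zero
#' matches zero only).  Signs rather than magnitudes are compared because
#' the two platforms' scales generally differ (e.g. log array means versus
#' ng RNA from QRT-PCR).
#'
#' @param expr_a,expr_b `expression_table`s sharing treatment labels and at
#'   least one probe id.
#' @param control_label The common control treatment column.
#' @return A list with `n_shared`, `n_concordant` and a named logical
#'   vector `concordant`.
#' @export
direction_concordance <- function(expr_a, expr_b, control_label) {
  trts_a <- attr(expr_a, "treatments") %||%
    setdiff(names(expr_a), c("probe_id", "annotation"))
  trts_b <- attr(expr_b, "treatments") %||%
    setdiff(names(expr_b), c("probe_id", "annotation"))
  trts <- intersect(trts_a, trts_b)
  if (!control_label %in% trts)
    stop(sprintf("control label '%s' must be a treatment column of both tables",
                 control_label), call. = FALSE)
  others <- setdiff(trts, control_label)
  if (!length(others))
    stop("tables share no non-control treatment columns", call. = FALSE)
  shared <- intersect(expr_a$probe_id, expr_b$probe_id)
  if (!length(shared)) {
    warning("the two tables share no probe ids")
    return(list(n_shared = 0L, n_concordant = 0L,
                concordant = stats::setNames(logical(), character())))
  }
  ia <- match(shared, expr_a$probe_id)
  ib <- match(shared, expr_b$probe_id)
  conc <- rep(TRUE, length(shared))
  for (tr in others) {
    sa <- sign(expr_a[[tr]][ia] - expr_a[[control_label]][ia])
    sb <- sign(expr_b[[tr]][ib] - expr_b[[control_label]][ib])
    conc <- conc & (sa == sb)
  }
  list(n_shared = length(shared),
       n_concordant = sum(conc),
       concordant = stats::setNames(conc, shared))
}
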