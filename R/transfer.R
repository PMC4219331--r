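#' Default normalized E-value threshold grid
#'
#' The five-point grid `1e-20, 1e-16, 1e-12, 1e-8, 1e-4` over which the
#' benchmark sweeps; thresholds apply to normalized E-values with the
#' convention "passes iff normalized E <= threshold".
#'
#' @return Numeric vector of thresholds, strictly increasing.
#' @export
default_threshold_grid <- function() {
  c(1e-20, 1e-16, 1e-12, 1e-8, 1e-4)
}

#' Classify queries by their best passing hit
#'
#' For each query, among hits whose normalized E-value passes the threshold,
#' the best hit is selected under the global tie-break (normalized E
#' ascending, raw score descending, target id, then label lexicographic when
#' a target carries several labels), and its target's family label becomes
#' the prediction. Queries with no passing hit are `UNCLASSIFIED`.
#'
#' @param hits A hits tibble (see [search_all_vs_all()]).
#' @param query_ids Character vector of all query ids (queries without hits
#'   are still reported, as `UNCLASSIFIED`).
#' @param target_labels A data frame with `id`, `label` covering every hit
#'   target (targets may carry several labels, one row each).
#' @param threshold Normalized E-value threshold.
#' @return A tibble with one row per query: `query_id`, `predicted`
#'   (`"UNCLASSIFIED"` when nothing passes), `best_target`,
#'   `best_normalized_evalue` (`NA` when unclassified), `threshold`.
#' @export
classify_queries <- function(hits, query_ids, target_labels, threshold) {
  lab <- dplyr::distinct(as_tibble(target_labels)[, c("id", "label")])
  pass <- dplyr::filter(as_tibble(hits), .data$normalized_evalue <= threshold)
  unmatched <- setdiff(unique(pass$target_id), lab$id)
  if (length(unmatched) > 0) {
    abort(paste0("hit target(s) without a reference label: ",
                 paste(utils::head(unmatched, 3), collapse = ", ")))
  }
  pass <- dplyr::inner_join(pass, lab, by = c(target_id = "id"),
                            relationship = "many-to-many")
  best <- dplyr::slice_head(
    dplyr::group_by(
      dplyr::arrange(pass, .data$normalized_evalue, dplyr::desc(.data$raw_score),
                     .data$target_id, .data$label),
      .data$query_id),
    n = 1)
  best <- dplyr::ungroup(best)
  out <- tibble(query_id = query_ids)
  out <- dplyr::left_join(out, best[, c("query_id", "label", "target_id",
                                        "normalized_evalue")], by = "query_id")
  tibble(query_id = out$query_id,
         predicted = ifelse(is.na(out$label), "UNCLASSIFIED", out$label),
         best_target = out$target_id,
         best_normalized_evalue = out$normalized_evalue,
         threshold = threshold)
}

#' Per-family one-vs-rest confusion cells
#'
#' Builds, for each shared family, the one-vs-rest confusion counts over all
#' classified evaluation instances (an instance is a query under one of its
#' true labels; queries carrying several substrate labels contribute one
#' instance per label). `UNCLASSIFIED` queries are excluded from every cell:
#' for family f, `tp` counts instances with true = predicted = f, `fn` those
#' with true = f predicted elsewhere, `fp` those predicted f but truly
#' elsewhere, and `tn` is the remainder of the classified instances.
#'
#' @param results An instance-level tibble with columns `true` and
#'   `predicted` (one threshold's classifications joined to true labels).
#' @param shared Character vector of family labels to tabulate.
#' @return A tibble with `label`, `tp`, `fp`, `fn`, `tn`, `size` (instances
#'   truly in the family, classified or not).
#' @export
confusion_by_family <- function(results, shared) {
  res <- as_tibble(results)
  cls <- dplyr::filter(res, .data$predicted != "UNCLASSIFIED")
  n_cls <- nrow(cls)
  purrr::map_dfr(shared, function(f) {
    tp <- sum(cls$true == f & cls$predicted == f)
    fn <- sum(cls$true == f & cls$predicted != f)
    fp <- sum(cls$true != f & cls$predicted == f)
    tibble(label = f, tp = tp, fp = fp, fn = fn, tn = n_cls - tp - fp - fn,
           size = sum(res$true == f))
  })
}

#' Precision, recall and F-measure in percent
#'
#' `precision = 100 * tp / (tp + fp)`, `recall = 100 * tp / (tp + fn)`,
#' `f_measure = 2 p r / (p + r)`; each defined as 0 when its denominator
#' is 0.
#'
#' @param tp,fp,fn Non-negative counts (vectorized).
#' @param p,r Precision and recall percentages in `[0, 100]`.
#' @return Percentage(s) in `[0, 100]`.
#' @export
precision_pct <- function(tp, fp) {
  ifelse(tp + fp == 0, 0, 100 * tp / (tp + fp))
}

#' @rdname precision_pct
#' @export
recall_pct <- function(tp, fn) {
  ifelse(tp + fn == 0, 0, 100 * tp / (tp + fn))
}

#' @rdname precision_pct
#' @export
f_measure_pct <- function(p, r) {
  stopifnot(all(p >= 0 & p <= 100), all(r >= 0 & r <= 100))
  ifelse(p + r == 0, 0, 2 * p * r / (p + r))
}

#' Family-size weighted average
#'
#' Averages per-family metric values with weights equal to family member
#' counts, the benchmark's macro-averaging rule: multiply each family's value
#' by its member count, then divide by the total member count.
#'
#' @param values Per-family values.
#' @param sizes Matching non-negative family sizes.
#' @return The weighted average.
#' @export
weighted_average <- function(values, sizes) {
  stopifnot(length(values) == length(sizes), all(sizes >= 0))
  if (sum(sizes) == 0) abort("total family size is zero")
  sum(values * sizes) / sum(sizes)
}

#' Percentage of queries left unclassified
#'
#' @param results A per-query classification tibble (see
#'   [classify_queries()]).
#' @return Percentage of queries with prediction `UNCLASSIFIED`.
#' @export
unclassified_fraction <- function(results) {
  if (nrow(results) == 0) abort("no classification results")
  100 * mean(results$predicted == "UNCLASSIFIED")
}

#' Sweep classification thresholds and evaluate annotation transfer
#'
#' Runs the whole evaluation for one hit table: at each threshold of the
#' grid, queries are classified by best passing hit, per-family one-vs-rest
#' confusion cells are tabulated over the classified instances, per-family
#' precision/recall/F are computed and averaged with family-size weights
#' (query-side test-set sizes by default), and the unclassified percentage is
#' recorded. F is computed per family from that family's precision and
#' recall, then weighted -- not from the aggregated precision and recall.
#' A family with no classified member and no prediction into it at a given
#' threshold contributes nothing to the averages at that threshold: its
#' members show up in the unclassified fraction instead (this is what allows
#' strict thresholds to combine a high unclassified percentage with high
#' precision and recall among the sequences that do classify).
#'
#' @param hits A hits tibble (one search pass; see [search_all_vs_all()]).
#' @param query_labels Instance table for the query side: `id`, `label` (one
#'   row per true label of each query).
#' @param target_labels Label table for the reference side: `id`, `label`.
#' @param grid Strictly increasing threshold vector,
#'   default [default_threshold_grid()].
#' @param weight_side `"query"` (default) to weight families by query-side
#'   instance counts, `"reference"` for reference-side member counts.
#' @return A `benchmark_report` object: list with `report` (tibble:
#'   `threshold`, `precision`, `recall`, `f_measure`, `unclassified`),
#'   `cells` (per-threshold per-family confusion cells),
#'   `classifications` (per-threshold per-query predictions), and `grid`.
#' @export
threshold_sweep <- function(hits, query_labels, target_labels,
                            grid = default_threshold_grid(),
                            weight_side = c("query", "reference")) {
  weight_side <- match.arg(weight_side)
  if (is.unsorted(grid, strictly = TRUE)) abort("grid must be strictly increasing")
  ql <- dplyr::distinct(as_tibble(query_labels)[, c("id", "label")])
  tl <- dplyr::distinct(as_tibble(target_labels)[, c("id", "label")])
  shared <- sort(unique(ql$label))
  sizes <- if (weight_side == "query") {
    dplyr::count(ql, .data$label, name = "size")
  } else {
    dplyr::count(tl, .data$label, name = "size")
  }

  rows <- list(); cells_all <- list(); class_all <- list()
  for (th in grid) {
    cl <- classify_queries(hits, unique(ql$id), tl, th)
    inst <- dplyr::left_join(ql, cl, by = c(id = "query_id"))
    inst <- tibble(id = inst$id, true = inst$label, predicted = inst$predicted)
    cells <- confusion_by_family(inst, shared)
    cells <- dplyr::left_join(dplyr::select(cells, -"size"), sizes, by = "label")
    cells$size[is.na(cells$size)] <- 0L
    p <- precision_pct(cells$tp, cells$fp)
    r <- recall_pct(cells$tp, cells$fn)
    f <- f_measure_pct(p, r)
    # families with no classified member and no prediction into them carry
    # no information at this threshold and are excluded from the averages
    # (their queries are already accounted for by the unclassified fraction)
    act <- cells$tp + cells$fp + cells$fn > 0
    wavg <- function(v) {
      if (!any(act) || sum(cells$size[act]) == 0) 0 else
        weighted_average(v[act], cells$size[act])
    }
    rows[[length(rows) + 1L]] <- tibble(
      threshold = th,
      precision = wavg(p),
      recall = wavg(r),
      f_measure = wavg(f),
      unclassified = unclassified_fraction(cl))
    cells$threshold <- th
    cells_all[[length(cells_all) + 1L]] <- cells
    class_all[[length(class_all) + 1L]] <- cl
  }
  structure(list(report = dplyr::bind_rows(rows),
                 cells = dplyr::bind_rows(cells_all),
                 classifications = dplyr::bind_rows(class_all),
                 grid = grid, weight_side = weight_side,
                 n_queries = length(unique(ql$id)),
                 n_families = length(shared)),
            class = "benchmark_report")
}

#' Cross-tabulate substrate_TC family match strength
#'
#' For every pair of a query-side and a reference-side family, takes the best
#' (smallest) normalized E-value over all member pairs and bins it on the
#' threshold grid: with the default grid, best E <= 1e-20 gives bin 4 (black
#' in the grayscale rendering), (1e-20, 1e-16] bin 3, (1e-16, 1e-12] bin 2,
#' (1e-12, 1e-8] bin 1 and anything worse bin 0 (white). Family pairs with no
#' reported hit at all are `NA` (missing), not 0.
#'
#' @inheritParams threshold_sweep
#' @return A `substrate_crosstab` object: list with `table` (tibble:
#'   `query_family`, `target_family`, `best_evalue`, `bin`) and `grid`.
#' @export
substrate_tc_crosstab <- function(hits, query_labels, target_labels,
                                  grid = default_threshold_grid()) {
  ql <- dplyr::distinct(as_tibble(query_labels)[, c("id", "label")])
  tl <- dplyr::distinct(as_tibble(target_labels)[, c("id", "label")])
  h <- dplyr::inner_join(as_tibble(hits), ql, by = c(query_id = "id"),
                         relationship = "many-to-many")
  h <- dplyr::rename(h, query_family = "label")
  h <- dplyr::inner_join(h, tl, by = c(target_id = "id"),
                         relationship = "many-to-many")
  h <- dplyr::rename(h, target_family = "label")
  best <- dplyr::summarise(
    dplyr::group_by(h, .data$query_family, .data$target_family),
    best_evalue = min(.data$normalized_evalue), .groups = "drop")
  full <- tidyr::expand_grid(query_family = sort(unique(ql$label)),
                             target_family = sort(unique(tl$label)))
  full <- dplyr::left_join(full, best, by = c("query_family", "target_family"))
  full$bin <- evalue_bin(full$best_evalue, grid)
  structure(list(table = full, grid = grid), class = "substrate_crosstab")
}

# bin = number of grid thresholds passed minus one, floored at 0; NA stays NA
evalue_bin <- function(e, grid = default_threshold_grid()) {
  passes <- vapply(e, function(x) {
    if (is.na(x)) NA_integer_ else sum(x <= grid)
  }, integer(1))
  pmax(passes - 1L, 0L)
}

#' Write / read a benchmark report TSV
#'
#' The TSV mirrors the benchmark's standard table layout: one row each for
#' Precision, Recall, F-measure and Unclassified (percent), one column per
#' threshold. The round trip `read_report(write_report(x))` is lossless for
#' the report table.
#'
#' @param report A `benchmark_report`.
#' @param path Output path.
#' @return `path` invisibly (`write_report`); a report-shaped tibble with a
#'   `metric` column (`read_report`).
#' @export
write_report <- function(report, path) {
  rep <- report$report
  m <- t(as.matrix(rep[, c("precision", "recall", "f_measure", "unclassified")]))
  out <- as_tibble(m, .name_repair = "minimal")
  names(out) <- format(rep$threshold, scientific = TRUE)
  out <- dplyr::bind_cols(tibble(metric = c("Precision [%]", "Recall [%]",
                                            "F-measure [%]", "Unclassified [%]")),
                          out)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  readr::read_tsv(path, col_types = readr::cols("metric" = readr::col_character(),
                                                .default = readr::col_double()),
                  progress = FALSE)
}
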