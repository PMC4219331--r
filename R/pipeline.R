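# Orchestration: the stages wired into the benchmark's standard experiments,
# with per-run output directories that allow bit-for-bit reruns.

#' Simulate a benchmark and write it to disk
#'
#' Wraps [generate_benchmark()] and writes, per organism, a FASTA file and an
#' annotation TSV, plus the ground-truth TSV and the resolved configuration
#' (YAML) for reproducibility.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if missing).
#' @return The [generate_benchmark()] result, invisibly.
#' @export
run_simulation <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bench <- generate_benchmark(config)
  for (ds in list(bench$dataset_a, bench$dataset_b)) {
    org <- attr(ds, "organism")
    write_fasta(ds, file.path(out_dir, paste0(org, ".fasta")))
    readr::write_tsv(ds[, c("id", "organism", "tc_family", "substrates")],
                     file.path(out_dir, paste0(org, "_annotations.tsv")))
  }
  readr::write_tsv(bench$truth, file.path(out_dir, "ground_truth.tsv"))
  cfg <- unclass(config)
  cfg$background <- as.list(cfg$background)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(bench)
}

#' Read a simulation configuration from YAML
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [simulation_config()].
#' @return A validated `sim_config`.
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$background)) raw$background <- unlist(raw$background)
  known <- names(formals(simulation_config))
  do.call(simulation_config, raw[intersect(names(raw), known)])
}

#' Run the annotation-transfer benchmark between two datasets
#'
#' The full pipeline for one (organism pair, family kind, engine)
#' combination: restrict both datasets to their shared families, search all
#' queries (dataset A) against the reference (dataset B), sweep the threshold
#' grid, and optionally write the report TSV, hits TSV, per-family cells TSV
#' and a stage-level log to `out_dir`. For the `substrate_tc` kind the
#' cross-tabulation is emitted as well.
#'
#' @param dataset_a,dataset_b Annotated dataset tibbles; A supplies the
#'   queries, B the reference annotations.
#' @param kind Family labeling kind (see [family_labels()]).
#' @param engine Search engine (see [search_all_vs_all()]).
#' @param scheme A [scoring_scheme()].
#' @param grid Threshold grid.
#' @param min_members Minimum family size within each dataset.
#' @param out_dir Optional output directory.
#' @param ... Passed on to [search_all_vs_all()].
#' @return A list with `report` (a `benchmark_report`), `hits`, `shared`,
#'   and (for `substrate_tc`) `crosstab`.
#' @export
run_benchmark <- function(dataset_a, dataset_b,
                          kind = c("tc", "substrate", "substrate_tc"),
                          engine = c("builtin_local", "builtin_global"),
                          scheme = scoring_scheme(),
                          grid = default_threshold_grid(),
                          min_members = 2, out_dir = NULL, ...) {
  kind <- match.arg(kind)
  engine <- match.arg(engine)
  shared <- build_shared_dataset(dataset_a, dataset_b, kind, min_members)
  log_lines <- c(
    paste0("kind=", kind, " engine=", engine),
    paste0("shared families: ", length(shared$shared)),
    paste0("query records kept: ", length(unique(shared$ref_a$id)),
           " of ", length(unique(dataset_a$id))),
    paste0("reference records kept: ", length(unique(shared$ref_b$id)),
           " of ", length(unique(dataset_b$id))))
  hits <- search_all_vs_all(shared$ref_a, shared$ref_b, engine, scheme, ...)
  log_lines <- c(log_lines, paste0("hits reported: ", nrow(hits)))
  report <- threshold_sweep(hits, shared$ref_a[, c("id", "label")],
                            shared$ref_b[, c("id", "label")], grid)
  log_lines <- c(log_lines,
                 sprintf("threshold %.0e: unclassified %.1f%%",
                         report$report$threshold, report$report$unclassified))
  out <- list(report = report, hits = hits, shared = shared)
  if (kind == "substrate_tc") {
    out$crosstab <- substrate_tc_crosstab(hits, shared$ref_a[, c("id", "label")],
                                          shared$ref_b[, c("id", "label")], grid)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(out_dir, "report.tsv"))
    write_hits(hits, file.path(out_dir, "hits.tsv"))
    readr::write_tsv(report$cells, file.path(out_dir, "cells.tsv"))
    write_shared_manifest(shared, file.path(out_dir, "shared_manifest.tsv"))
    if (!is.null(out$crosstab)) {
      write_crosstab(out$crosstab, file.path(out_dir, "crosstab.tsv"))
    }
    writeLines(log_lines, file.path(out_dir, "log.txt"))
  }
  out
}

#' Run the motif-based transfer benchmark
#'
#' For every shared family (minimum `min_members` members on each side,
#' default 3), discovers up to `n_motifs` motifs in dataset A's members with
#' [em_discover()], scans dataset B's shared-family sequences with
#' [scan_motifs()], converts per-sequence combined E-values into a hits
#' table (`backend = "motif_scan"`, target = source family label) and sweeps
#' the threshold grid. Per-hit E-value normalization is off by default for
#' this backend (`normalize = FALSE`).
#'
#' @inheritParams run_benchmark
#' @param width,n_motifs Motif discovery controls (see [em_discover()]).
#' @param normalize Apply per-hit normalization to combined E-values.
#' @param seed Seed forwarded to [em_discover()].
#' @return A list with `report`, `hits`, `motifs` (named list per family),
#'   `shared`.
#' @export
run_motif_benchmark <- function(dataset_a, dataset_b,
                                kind = c("tc", "substrate", "substrate_tc"),
                                width = 15L, n_motifs = 3L,
                                grid = default_threshold_grid(),
                                min_members = 3, normalize = FALSE,
                                seed = 1L, out_dir = NULL) {
  kind <- match.arg(kind)
  shared <- build_shared_dataset(dataset_a, dataset_b, kind, min_members)
  fams <- shared$shared
  test_seqs <- dplyr::distinct(shared$ref_b[, c("id", "sequence")])
  motifs_by_family <- list()
  hit_rows <- list()
  for (f in fams) {
    train <- dplyr::distinct(
      dplyr::filter(shared$ref_a, .data$label == f)[, c("id", "sequence")])
    motifs <- em_discover(train, width = width, n_motifs = n_motifs,
                          min_sequences = min_members, seed = seed,
                          source_family = f)
    if (length(motifs) == 0) next
    motifs_by_family[[f]] <- motifs
    sc <- scan_motifs(motifs, test_seqs)
    per_seq <- dplyr::distinct(sc[, c("sequence_id", "combined_pvalue",
                                      "combined_evalue")])
    hit_rows[[f]] <- tibble(query_id = per_seq$sequence_id,
                            target_id = f,
                            raw_score = -log10(pmax(per_seq$combined_pvalue,
                                                    .Machine$double.xmin)),
                            raw_evalue = pmax(per_seq$combined_evalue,
                                              .Machine$double.xmin),
                            backend = "motif_scan")
  }
  if (length(hit_rows) == 0) abort("no eligible family for motif discovery")
  hits <- dplyr::bind_rows(hit_rows)
  if (normalize) {
    hits <- dplyr::ungroup(
      dplyr::mutate(dplyr::group_by(hits, .data$query_id),
                    normalized_evalue = normalize_per_hit(.data$raw_evalue, dplyr::n())))
  } else {
    hits$normalized_evalue <- hits$raw_evalue
  }
  hits <- sort_hits(hits)[, c("query_id", "target_id", "raw_score",
                              "raw_evalue", "normalized_evalue", "backend")]
  target_labels <- tibble(id = fams, label = fams)
  report <- threshold_sweep(hits, shared$ref_b[, c("id", "label")],
                            target_labels, grid)
  out <- list(report = report, hits = hits, motifs = motifs_by_family,
              shared = shared)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(out_dir, "report.tsv"))
    write_hits(hits, file.path(out_dir, "hits.tsv"))
    all_motifs <- unlist(motifs_by_family, recursive = FALSE)
    write_meme(all_motifs, file.path(out_dir, "motifs.meme"))
    writeLines(vapply(all_motifs, pwm_to_regex, character(1)),
               file.path(out_dir, "motifs_regex.txt"))
  }
  out
}
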