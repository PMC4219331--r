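#' All-vs-all homology search between two datasets
#'
#' Compares every query against every reference sequence with one of the
#' built-in engines and returns one hit row per pair whose raw E-value passes
#' the report ceiling. The local engine derives raw E-values from
#' Karlin-Altschul statistics (and normalizes per database residue); the
#' global engine derives them from a shuffle null as `p * db_sequences` (a
#' per-sequence statistic, hence normalized per reported hit, per query).
#' Comparisons of identical ids are skipped.
#'
#' @param queries,reference Data frames with `id` and `sequence` columns
#'   (label-expanded tables are de-duplicated on `id` first); queries and
#'   reference are expected to come from different organisms.
#' @param engine `"builtin_local"` or `"builtin_global"`.
#' @param scheme A [scoring_scheme()].
#' @param report_ceiling Raw E-value ceiling for reporting a hit (default 10).
#' @param n_shuffles,seed Shuffle-null parameters for the global engine.
#' @return A tibble with columns `query_id`, `target_id`, `raw_score`,
#'   `raw_evalue`, `normalized_evalue`, `backend`, sorted by query then by
#'   (normalized E ascending, raw score descending, target id).
#' @export
search_all_vs_all <- function(queries, reference,
                              engine = c("builtin_local", "builtin_global"),
                              scheme = scoring_scheme(),
                              report_ceiling = 10,
                              n_shuffles = 60, seed = 1L) {
  engine <- match.arg(engine)
  q <- dplyr::distinct(as_tibble(queries)[, c("id", "sequence")])
  r <- dplyr::distinct(as_tibble(reference)[, c("id", "sequence")])
  if (nrow(r) == 0) abort("empty reference dataset")
  if (nrow(q) == 0) abort("empty query dataset")
  db_res <- sum(nchar(r$sequence))
  db_seq <- nrow(r)
  r <- dplyr::arrange(r, .data$id)

  rows <- vector("list", nrow(q))
  for (qi in seq_len(nrow(q))) {
    qid <- q$id[qi]; qseq <- q$sequence[qi]
    tgt <- r[r$id != qid, , drop = FALSE]
    if (nrow(tgt) == 0) next
    if (engine == "builtin_local") {
      ctx <- search_context(db_res, db_seq, nchar(qseq))
      score <- vapply(tgt$sequence, function(s) {
        smith_waterman(qseq, s, scheme)$score
      }, numeric(1), USE.NAMES = FALSE)
      raw_e <- karlin_altschul_evalue(score, ctx, scheme)
      hit <- tibble(query_id = qid, target_id = tgt$id,
                    raw_score = score, raw_evalue = raw_e,
                    backend = "builtin_local")
      hit <- dplyr::filter(hit, .data$raw_evalue <= report_ceiling)
      hit$normalized_evalue <- normalize_per_residue(hit$raw_evalue, db_res)
    } else {
      sp <- lapply(seq_len(nrow(tgt)), function(ti) {
        shuffle_pvalue(qseq, tgt$sequence[ti], scheme, n_shuffles,
                       seed = seed + qi * 1000L + ti)
      })
      hit <- tibble(query_id = qid, target_id = tgt$id,
                    raw_score = vapply(sp, function(x) as.numeric(x$score), numeric(1)),
                    raw_evalue = pmax(vapply(sp, `[[`, numeric(1), "p") * db_seq,
                                      .Machine$double.xmin),
                    backend = "builtin_global")
      hit <- dplyr::filter(hit, .data$raw_evalue <= report_ceiling)
      if (nrow(hit) > 0) {
        hit$normalized_evalue <- normalize_per_hit(hit$raw_evalue, nrow(hit))
      } else {
        hit$normalized_evalue <- numeric(0)
      }
    }
    rows[[qi]] <- hit
  }
  hits <- dplyr::bind_rows(rows)
  if (nrow(hits) == 0) {
    return(tibble(query_id = character(), target_id = character(),
                  raw_score = numeric(), raw_evalue = numeric(),
                  normalized_evalue = numeric(), backend = character()))
  }
  sort_hits(hits)[, c("query_id", "target_id", "raw_score", "raw_evalue",
                      "normalized_evalue", "backend")]
}

# global hit tie-break: normalized E ascending, raw score descending,
# target id lexicographic
sort_hits <- function(hits) {
  dplyr::arrange(hits, .data$query_id, .data$normalized_evalue,
                 dplyr::desc(.data$raw_score), .data$target_id)
}

#' Parse a 12-column tabular alignment hit file
#'
#' Reads the conventional 12-column tab-separated hit format of alignment
#' search tools (query, target, percent identity, alignment length,
#' mismatches, gap opens, query start/end, target start/end, E-value, bit
#' score; coordinates 1-based inclusive) and normalizes the E-values per
#' database residue.
#'
#' @param path Path to the tabular file.
#' @param db_residues Residue count of the database the search ran against.
#' @return A hits tibble as in [search_all_vs_all()], with
#'   `backend = "external_alignment"`; empty file gives an empty tibble.
#' @export
parse_alignment_tabular <- function(path, db_residues) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(query_id = character(), target_id = character(),
                  raw_score = numeric(), raw_evalue = numeric(),
                  normalized_evalue = numeric(), backend = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 12)) {
    bad <- which(nc != 12)[1]
    abort(paste0("line ", bad, ": expected 12 tab-separated columns, found ", nc[bad]))
  }
  ev <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 11)))
  bits <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 12)))
  if (anyNA(ev)) {
    abort(paste0("line ", which(is.na(ev))[1], ": malformed E-value"))
  }
  if (anyNA(bits)) {
    abort(paste0("line ", which(is.na(bits))[1], ": malformed bit score"))
  }
  hits <- tibble(query_id = vapply(parts, `[`, character(1), 1),
                 target_id = vapply(parts, `[`, character(1), 2),
                 raw_score = bits,
                 raw_evalue = ev,
                 normalized_evalue = normalize_per_residue(ev, db_residues),
                 backend = "external_alignment")
  sort_hits(hits)
}

#' Parse a per-target table from a probabilistic homology search
#'
#' Reads the whitespace-delimited per-target output of probabilistic
#' (profile-based) homology search tools: `#` comment lines are skipped and
#' the columns used are target name (1), query name (3), full-sequence
#' E-value (5) and score (6). Raw E-values are per-sequence statistics, so
#' each is normalized by the number of hits its query reported (per-query
#' hit counts, not the global row count).
#'
#' @param path Path to the tabular file.
#' @return A hits tibble as in [search_all_vs_all()], with
#'   `backend = "external_probabilistic"`; a comment-only or empty file gives
#'   an empty tibble.
#' @export
parse_probabilistic_tabular <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) {
    return(tibble(query_id = character(), target_id = character(),
                  raw_score = numeric(), raw_evalue = numeric(),
                  normalized_evalue = numeric(), backend = character()))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  nc <- lengths(parts)
  if (any(nc < 6)) {
    abort(paste0("line ", which(nc < 6)[1], ": expected >= 6 whitespace-delimited columns"))
  }
  ev <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 5)))
  if (anyNA(ev)) abort(paste0("line ", which(is.na(ev))[1], ": malformed E-value"))
  hits <- tibble(query_id = vapply(parts, `[`, character(1), 3),
                 target_id = vapply(parts, `[`, character(1), 1),
                 raw_score = suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 6))),
                 raw_evalue = ev,
                 backend = "external_probabilistic")
  hits <- dplyr::mutate(dplyr::group_by(hits, .data$query_id),
                        normalized_evalue = normalize_per_hit(.data$raw_evalue, dplyr::n()))
  sort_hits(dplyr::ungroup(hits))[, c("query_id", "target_id", "raw_score",
                                      "raw_evalue", "normalized_evalue", "backend")]
}

#' Write a hits table to TSV
#'
#' @param hits A hits tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  readr::write_tsv(hits, path)
  invisible(path)
}
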