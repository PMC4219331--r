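#' Read protein sequences from a FASTA file
#'
#' Parses a standard FASTA file of amino-acid sequences into a tibble.
#' Sequences are uppercased and a single trailing stop character (`*`) is
#' stripped; any other character outside the 20-letter amino-acid alphabet
#' plus `X` is an error.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`, in file order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "MKV", ">b", "GG"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate FASTA id(s): ", paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  for (i in seq_along(seqs)) validate_aa(seqs[i], ids[i])
  tibble(id = unname(ids), sequence = unname(seqs))
}

validate_aa <- function(seq, id = "?") {
  if (!nzchar(seq)) abort(paste0("empty sequence for id ", id))
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), AA_ALPHABET21)
  if (length(bad) > 0) {
    abort(paste0("sequence ", id, " contains illegal residue(s): ",
                 paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Write sequences to a FASTA file
#'
#' @param records A data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# TC family ids look like "2.A.1" (class.subclass.family); a full id may
# carry up to two further numeric parts ("2.A.1.1.2").
tc_pattern <- "^[0-9]+\\.[A-Z]\\.[0-9]+(\\.[0-9]+){0,2}$"

#' Truncate TC identifiers to the family level
#'
#' The Transporter Classification system is hierarchical
#' (class.subclass.family.subfamily...). Databases frequently disagree at the
#' fourth position, so all family comparisons here operate on the first three
#' parts.
#'
#' @param tc Character vector of TC identifiers.
#' @return Character vector of 3-part family ids.
#' @export
#' @examples
#' tc_family_of(c("3.A.1.1.2", "2.A.1"))
tc_family_of <- function(tc) {
  ok <- grepl(tc_pattern, tc)
  if (any(!ok)) {
    abort(paste0("malformed TC id(s): ", paste(unique(tc[!ok]), collapse = ", ")))
  }
  vapply(strsplit(tc, ".", fixed = TRUE),
         function(p) paste(p[1:3], collapse = "."), character(1))
}

#' Read a transporter annotation table
#'
#' Reads a tab-separated annotation table with header columns
#' `id`, `organism`, `tc_family`, `substrates` (the last a comma-joined,
#' possibly empty, list of substrate-class labels such as
#' `metal`, `phosphate`, `sugar`, `amino_acid`).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `id`, `organism`, `tc_family` (truncated to
#'   the 3-part family level) and `substrates` (comma-joined string, possibly
#'   empty).
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("id", "organism", "tc_family", "substrates")
  if (!all(need %in% names(ann))) {
    abort(paste0("annotation table must have columns: ", paste(need, collapse = ", ")))
  }
  ann$substrates[is.na(ann$substrates)] <- ""
  bad <- which(!grepl(tc_pattern, ann$tc_family))
  if (length(bad) > 0) {
    abort(paste0("malformed tc_family at data row ", bad[1], ": ", ann$tc_family[bad[1]]))
  }
  if (anyDuplicated(ann$id)) {
    abort(paste0("duplicate id(s) in annotation table: ",
                 paste(unique(ann$id[duplicated(ann$id)]), collapse = ", ")))
  }
  tibble(id = ann$id, organism = ann$organism,
         tc_family = tc_family_of(ann$tc_family), substrates = ann$substrates)
}

#' Assemble an annotated transporter dataset
#'
#' Joins sequences with their annotations into the canonical per-organism
#' dataset table used throughout the package.
#'
#' @param sequences A data frame with `id`, `sequence` (e.g. from
#'   [read_fasta()]).
#' @param annotations A data frame with `id`, `organism`, `tc_family`,
#'   `substrates` (e.g. from [read_annotations()]).
#' @param organism Optional organism name; defaults to the (single) organism
#'   present in `annotations`.
#' @return A tibble with columns `id`, `organism`, `sequence`, `tc_family`,
#'   `substrates`, carrying the organism name and the total residue count as
#'   attributes `organism` and `residue_count`.
#' @export
annotated_dataset <- function(sequences, annotations, organism = NULL) {
  ds <- dplyr::inner_join(as_tibble(sequences), as_tibble(annotations), by = "id")
  missing <- setdiff(sequences$id, ds$id)
  if (length(missing) > 0) {
    warn(paste0(length(missing), " sequence(s) without annotation dropped"))
  }
  organism <- organism %||% unique(ds$organism)
  if (length(organism) != 1) abort("dataset must contain exactly one organism")
  ds <- ds[, c("id", "organism", "sequence", "tc_family", "substrates")]
  attr(ds, "organism") <- organism
  attr(ds, "residue_count") <- residue_count(ds)
  ds
}

#' Total residue count of a dataset
#'
#' The sum of sequence lengths; this is the denominator used for per-residue
#' E-value normalization (the database size a search is performed against).
#'
#' @param dataset A data frame with a `sequence` column.
#' @return Integer residue count.
#' @export
residue_count <- function(dataset) {
  sum(nchar(dataset$sequence))
}

#' Expand dataset records into family labels
#'
#' Assigns each record its family label(s) under one of three labeling
#' schemes: TC family (`"tc"`), substrate class (`"substrate"`), or the
#' combined `"substrate_tc"` label rendered as e.g. `"sugar_2.A.1"`. Records
#' annotated with several substrates appear once per substrate label
#' (label-level duplication; the sequence itself is not copied).
#'
#' @param dataset A dataset tibble (see [annotated_dataset()]).
#' @param kind One of `"tc"`, `"substrate"`, `"substrate_tc"`.
#' @return A tibble with the dataset columns plus `label`; records without a
#'   substrate annotation drop out of the substrate-based kinds.
#' @export
family_labels <- function(dataset, kind = c("tc", "substrate", "substrate_tc")) {
  kind <- match.arg(kind)
  ds <- as_tibble(dataset)
  if (kind == "tc") {
    return(dplyr::mutate(ds, label = tc_family_of(.data$tc_family)))
  }
  ex <- tidyr::separate_rows(ds, "substrates", sep = ",")
  ex <- dplyr::filter(ex, nzchar(.data$substrates))
  if (kind == "substrate") {
    dplyr::mutate(ex, label = .data$substrates)
  } else {
    dplyr::mutate(ex, label = paste0(.data$substrates, "_", tc_family_of(.data$tc_family)))
  }
}

#' Parse a combined substrate_TC label
#'
#' @param label Character vector of labels such as `"sugar_2.A.1"`.
#' @return A tibble with columns `substrate` and `tc_family`.
#' @export
parse_substrate_tc <- function(label) {
  m <- regmatches(label, regexec("^(.+)_([0-9]+\\.[A-Z]\\.[0-9]+)$", label))
  bad <- lengths(m) != 3
  if (any(bad)) abort(paste0("unparseable substrate_tc label: ", label[bad][1]))
  tibble(substrate = vapply(m, `[`, character(1), 2),
         tc_family = vapply(m, `[`, character(1), 3))
}

#' Restrict two datasets to their shared families
#'
#' Keeps only records whose family label (under the chosen labeling kind)
#' occurs in both datasets, after first dropping, within each dataset,
#' families with fewer than `min_members` members. This mirrors the
#' benchmark's construction of shared-family test and reference sets: a
#' family can only be predicted if at least one other member exists.
#'
#' @param dataset_a,dataset_b Two annotated dataset tibbles.
#' @param kind Labeling kind, see [family_labels()].
#' @param min_members Minimum family size within each dataset (default 2;
#'   motif discovery conventionally uses 3).
#' @return A list with elements `ref_a`, `ref_b` (label-expanded tibbles
#'   restricted to shared families) and `shared` (sorted character vector of
#'   shared family labels).
#' @export
build_shared_dataset <- function(dataset_a, dataset_b,
                                 kind = c("tc", "substrate", "substrate_tc"),
                                 min_members = 2) {
  kind <- match.arg(kind)
  la <- family_labels(dataset_a, kind)
  lb <- family_labels(dataset_b, kind)
  keep_big <- function(x) {
    sizes <- table(x$label)
    dplyr::filter(x, .data$label %in% names(sizes)[sizes >= min_members])
  }
  la <- keep_big(la)
  lb <- keep_big(lb)
  shared <- sort(intersect(unique(la$label), unique(lb$label)))
  if (length(shared) == 0) abort("no shared families between the two datasets")
  list(ref_a = dplyr::filter(la, .data$label %in% shared),
       ref_b = dplyr::filter(lb, .data$label %in% shared),
       shared = shared)
}

#' Write a shared-dataset manifest
#'
#' @param shared A list as returned by [build_shared_dataset()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_shared_manifest <- function(shared, path) {
  man <- dplyr::bind_rows(shared$ref_a, shared$ref_b)[, c("id", "organism", "label")]
  readr::write_tsv(man, path)
  invisible(path)
}
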