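#' Protein scoring scheme
#'
#' Bundles a substitution matrix, affine gap penalties and Karlin-Altschul
#' parameters. The default is BLOSUM62 with gap open -11 / extend -1 and the
#' standard published gapped parameters lambda = 0.267, K = 0.041 for that
#' combination; the ungapped lambda for any matrix/background pair can be
#' solved numerically with [estimate_ungapped_lambda()].
#'
#' A gap of length k scores `gap_open + k * gap_extend`.
#'
#' @param matrix Symmetric integer substitution matrix with amino-acid
#'   dimnames; the default is BLOSUM62 restricted to the 20 standard residues
#'   plus `X`.
#' @param gap_open,gap_extend Negative integers.
#' @param lambda,K Positive Karlin-Altschul parameters matching the matrix
#'   and gap penalties.
#' @param background Length-20 residue frequency vector used for lambda
#'   estimation and shuffle nulls.
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = blosum62_matrix(),
                           gap_open = -11L, gap_extend = -1L,
                           lambda = 0.267, K = 0.041,
                           background = uniform_background()) {
  if (!isTRUE(all.equal(matrix, t(matrix)))) abort("substitution matrix must be symmetric")
  if (gap_open >= 0 || gap_extend >= 0) abort("gap penalties must be negative")
  if (lambda <= 0 || K <= 0) abort("lambda and K must be positive")
  background <- validate_background(background)
  aa <- intersect(rownames(matrix), AA_ALPHABET20)
  exp_score <- sum(outer(background[aa], background[aa]) * matrix[aa, aa])
  if (exp_score >= 0) abort("expected substitution score under background must be negative")
  structure(list(matrix = matrix, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K, background = background),
            class = "scoring_scheme")
}

#' @rdname scoring_scheme
#' @export
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[AA_ALPHABET21, AA_ALPHABET21]
}

#' Search context for E-value computation
#'
#' The Karlin-Altschul search-space description: `m` is the query length and
#' `n` the residue count of the searched database, whose product scales the
#' expected number of chance hits.
#'
#' @param db_residues Total residues in the searched database.
#' @param db_sequences Number of sequences in the database.
#' @param query_length Length of the query sequence.
#' @return A list of class `search_context`.
#' @export
search_context <- function(db_residues, db_sequences, query_length) {
  if (db_sequences < 1 || db_residues < db_sequences) {
    abort("need db_residues >= db_sequences >= 1")
  }
  if (query_length < 1) abort("query_length must be positive")
  structure(list(db_residues = db_residues, db_sequences = db_sequences,
                 query_length = query_length),
            class = "search_context")
}

#' Karlin-Altschul E-value for a local alignment score
#'
#' Computes `E = K * m * n * exp(-lambda * S)` with `m` the query length and
#' `n` the database residue count: the expected number of chance local
#' alignments scoring at least `S`. E is strictly decreasing in the score and
#' proportional to the database size -- the database-size dependence that
#' per-residue normalization removes.
#'
#' @param score Non-negative alignment score in matrix units.
#' @param context A [search_context()].
#' @param scheme A [scoring_scheme()] supplying `lambda` and `K`.
#' @return The raw E-value (positive real).
#' @export
karlin_altschul_evalue <- function(score, context, scheme = scoring_scheme()) {
  stopifnot(inherits(context, "search_context"))
  if (any(score < 0)) abort("score must be non-negative")
  if (context$query_length <= 0 || context$db_residues <= 0) {
    abort("query length and database residue count must be positive")
  }
  scheme$K * context$query_length * context$db_residues * exp(-scheme$lambda * score)
}

#' Solve for the ungapped Karlin-Altschul lambda
#'
#' Finds the unique positive root of
#' `sum_ij f_i f_j exp(lambda * s_ij) = 1` by bisection, to an absolute
#' function tolerance of 1e-9. A root exists iff the expected score under the
#' background is negative and some score is positive.
#'
#' @param matrix Square substitution matrix.
#' @param background Frequency vector matching the matrix dimension
#'   (or, if the matrix has amino-acid dimnames, a named 20-vector).
#' @return The positive lambda.
#' @export
estimate_ungapped_lambda <- function(matrix, background) {
  if (!is.null(rownames(matrix)) && all(AA_ALPHABET20 %in% rownames(matrix)) &&
      length(background) == 20) {
    background <- validate_background(background)
    matrix <- matrix[AA_ALPHABET20, AA_ALPHABET20]
  }
  stopifnot(nrow(matrix) == ncol(matrix), length(background) == nrow(matrix))
  fb <- as.numeric(background)
  w <- outer(fb, fb)
  exp_score <- sum(w * matrix)
  if (exp_score >= 0) abort("expected score under background must be negative (no positive root)")
  if (max(matrix) <= 0) abort("matrix has no positive score (no positive root)")
  f <- function(l) sum(w * exp(l * matrix)) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lo <- 0
  # bisection on f, which is convex with f(0) = 0, f'(0) < 0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v) < 1e-9) return(mid)
    if (v < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Normalize an E-value by database residue count
#'
#' Search tools scale the significance of a hit by the total residue count of
#' the searched database, so raw E-values from differently sized databases
#' are not comparable. Dividing by the database residue count removes this
#' dependence; thresholds quoted on the normalized scale must be multiplied
#' by the database size before being applied to raw tool output.
#'
#' @param raw_evalue Non-negative raw E-value(s).
#' @param db_residues Residue count of the searched database (>= 1).
#' @return `raw_evalue / db_residues`.
#' @export
#' @examples
#' normalize_per_residue(1e-58, 23567)
normalize_per_residue <- function(raw_evalue, db_residues) {
  if (any(db_residues < 1)) abort("db_residues must be >= 1")
  if (any(raw_evalue < 0)) abort("raw_evalue must be non-negative")
  raw_evalue / db_residues
}

#' Normalize an E-value by the number of reported hits
#'
#' The per-hit analogue of [normalize_per_residue()], used for search
#' backends whose E-values are per-sequence statistics (probabilistic
#' homology search, global-alignment shuffles): the raw E-value is divided by
#' the number of hits the search reported (per query).
#'
#' @param raw_evalue Non-negative raw E-value(s).
#' @param n_hits Number of reported hits (>= 1).
#' @return `raw_evalue / n_hits`.
#' @export
normalize_per_hit <- function(raw_evalue, n_hits) {
  if (any(n_hits == 0)) abort("cannot normalize with zero hits")
  if (any(n_hits < 1)) abort("n_hits must be >= 1")
  raw_evalue / n_hits
}
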