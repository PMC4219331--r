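# Shared test fixtures and independent oracles.

# A reduced 4-letter scoring scheme used for exhaustive oracle tests:
# match +2, mismatch -1 on residues {A, C, G, T-as-S}. Built as a full
# 21-letter matrix so the production aligner accepts it.
reduced_scheme <- function(match = 2L, mismatch = -1L,
                           gap_open = -3L, gap_extend = -1L) {
  m <- matrix(mismatch, 21, 21, dimnames = list(tcbench:::AA_ALPHABET21,
                                                tcbench:::AA_ALPHABET21))
  diag(m) <- match
  scoring_scheme(matrix = m, gap_open = gap_open, gap_extend = gap_extend,
                 lambda = 0.5, K = 0.1)
}

random_reduced_seq <- function(len, letters = c("A", "C", "G", "S")) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# Exhaustive affine-gap GLOBAL alignment score by enumeration of all
# monotone alignment paths; gap of length k costs gap_open + k * gap_extend.
# Completely independent of the DP implementation.
brute_global <- function(a, b, scheme) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  sub <- scheme$matrix
  go <- scheme$gap_open; ge <- scheme$gap_extend
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > n && j > m) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= n && j <= m) {
      rec(i + 1, j + 1, score + sub[av[i], bv[j]], "m")
    }
    if (i <= n) {  # gap in b, consume a[i]
      rec(i + 1, j, score + ge + if (state == "x") 0 else go, "x")
    }
    if (j <= m) {  # gap in a, consume b[j]
      rec(i, j + 1, score + ge + if (state == "y") 0 else go, "y")
    }
    invisible()
  }
  rec(1, 1, 0, "m")
  best
}

# Exhaustive LOCAL score: maximum of the empty alignment (0) and all global
# alignments of all non-empty substring pairs that start and end on a match
# column (optimal local alignments never begin or end with a gap).
brute_local <- function(a, b, scheme) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  best <- 0
  for (i1 in seq_len(n)) for (i2 in i1:n) {
    sa <- substr(a, i1, i2)
    for (j1 in seq_len(m)) for (j2 in j1:m) {
      best <- max(best, brute_global(sa, substr(b, j1, j2), scheme))
    }
  }
  best
}

# small two-family annotated datasets for seqdata tests
toy_dataset <- function(org, fam_sizes, seq_len = 30, seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (k in seq_along(fam_sizes)) {
      for (j in seq_len(fam_sizes[k])) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          id = sprintf("%s_f%d_m%d", org, k, j), organism = org,
          sequence = random_protein(seq_len),
          tc_family = sprintf("2.A.%d", k), substrates = "")
      }
    }
    dplyr::bind_rows(rows)
  })
}
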