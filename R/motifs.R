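# ZOOPS EM motif discovery and PWM scanning.
#
# Sequences are encoded as integer vectors over the 20-letter alphabet; X
# positions are treated as masked (no window may overlap them), as are
# positions claimed by previously discovered motifs.

encode_for_motifs <- function(sequences) {
  if (is.data.frame(sequences)) {
    ids <- sequences$id
    seqs <- sequences$sequence
  } else {
    seqs <- unname(sequences)
    ids <- names(sequences) %||% paste0("seq", seq_along(seqs))
  }
  list(ids = ids,
       codes = lapply(seqs, function(s) match(strsplit(s, "")[[1]], AA_ALPHABET20)))
}

# window matrix over all sequences: rows are candidate sites, columns motif
# positions; windows overlapping masked (NA) positions are dropped
window_matrix <- function(codes, width, masks) {
  out_idx <- list(); out_seq <- list(); out_start <- list()
  for (i in seq_along(codes)) {
    x <- codes[[i]]
    L <- length(x)
    if (L < width) next
    n_win <- L - width + 1L
    starts <- seq_len(n_win)
    keep <- !vapply(starts, function(s) {
      anyNA(x[s:(s + width - 1L)]) || any(masks[[i]][s:(s + width - 1L)])
    }, logical(1))
    starts <- starts[keep]
    if (length(starts) == 0) next
    win <- t(vapply(starts, function(s) x[s:(s + width - 1L)], integer(width)))
    out_idx[[length(out_idx) + 1L]] <- win
    out_seq[[length(out_seq) + 1L]] <- rep.int(i, length(starts))
    out_start[[length(out_start) + 1L]] <- starts
  }
  if (length(out_idx) == 0) {
    return(list(win = matrix(integer(0), 0, width), seq = integer(0), start = integer(0)))
  }
  list(win = do.call(rbind, out_idx), seq = unlist(out_seq), start = unlist(out_start))
}

# log-ratio window scores for a PWM against a window matrix
window_scores <- function(win, probs, background) {
  lr <- log(probs) - matrix(log(background), nrow(probs), 20, byrow = TRUE)
  s <- numeric(nrow(win))
  for (w in seq_len(ncol(win))) s <- s + lr[w, win[, w]]
  s
}

# one EM pass (E-step + M-step) for the ZOOPS model; returns updated model
# plus the observed-data log-likelihood and penalized objective of the
# *incoming* parameters
zoops_em_step <- function(win, seq_idx, n_seq, probs, gamma, background,
                          pseudo = 0.01, ll_const = 0) {
  width <- nrow(probs)
  m_i <- tabulate(seq_idx, n_seq)              # valid windows per sequence
  s <- window_scores(win, probs, background)
  odds <- exp(s) * (gamma / pmax(m_i[seq_idx], 1))
  denom_i <- (1 - gamma) + as.vector(rowsum(odds, seq_idx, reorder = TRUE))
  # sequences with no valid window contribute the no-site term only
  denom_full <- rep(1 - gamma, n_seq)
  denom_full[sort(unique(seq_idx))] <- denom_i
  ll <- sum(log(denom_full)) + ll_const
  prior <- pseudo * sum(matrix(background, width, 20, byrow = TRUE) * log(probs))
  z <- odds / denom_full[seq_idx]
  q_i <- as.vector(rowsum(z, seq_idx, reorder = TRUE))
  # M-step
  counts <- matrix(0, width, 20)
  for (w in seq_len(width)) {
    counts[w, ] <- vapply(split(z, factor(win[, w], levels = 1:20)),
                          function(v) sum(v), numeric(1))
  }
  counts[is.na(counts)] <- 0
  new_probs <- counts + pseudo * matrix(background, width, 20, byrow = TRUE)
  new_probs <- new_probs / rowSums(new_probs)
  new_gamma <- min(max(sum(q_i) / n_seq, 1e-6), 1 - 1e-6)
  list(probs = new_probs, gamma = new_gamma, ll = ll, objective = ll + prior,
       z = z, q = q_i)
}

#' Discover motifs in a sequence family by ZOOPS expectation-maximization
#'
#' Finds up to `n_motifs` ungapped motifs of fixed `width` in a family of
#' related sequences under the ZOOPS site model (each sequence carries zero
#' or one site per motif). Starting points are MEME-like: every distinct
#' window in the input seeds a smoothed one-hot PWM, each candidate gets one
#' EM pass, and the best is refined to convergence (relative change of the
#' objective below `tol`, or `max_iter` iterations). After a motif converges
#' its best site in every sequence with posterior site probability >= 0.5 is
#' hard-masked before the next motif is sought, so successive motifs occupy
#' disjoint sites.
#'
#' The PWM update uses a pseudocount of `pseudo` times the background
#' frequency (a Dirichlet prior); the quantity guaranteed non-decreasing
#' across iterations is therefore the penalized objective
#' (log-likelihood plus the prior term), recorded per iteration in
#' `$objective_trace` alongside the raw `$loglik_trace`.
#'
#' @param sequences A data frame with `id` and `sequence` columns, or a
#'   character vector of sequences.
#' @param width Motif width (>= 4); must not exceed the shortest sequence.
#' @param n_motifs Maximum number of motifs to return (default 3).
#' @param background Length-20 background frequency vector.
#' @param min_sequences Minimum number of input sequences (default 3).
#' @param pseudo Pseudocount weight (default 0.01).
#' @param tol,max_iter EM convergence controls.
#' @param max_candidates Cap on the number of seeding windows tried; when
#'   exceeded, a seeded subsample is used.
#' @param seed Integer seed (only consumed by candidate subsampling).
#' @param source_family Optional family label stored on each motif.
#' @return A list of `pwm_motif` objects; each has elements `width`, `probs`
#'   (width x 20, rows summing to 1), `background`, `consensus`, `n_sites`,
#'   `gamma`, `sites` (tibble: `sequence_id`, `start`, 0-based),
#'   `objective_trace`, `loglik_trace`, `source_family`.
#' @export
em_discover <- function(sequences, width = 15L, n_motifs = 3L,
                        background = uniform_background(),
                        min_sequences = 3L, pseudo = 0.01,
                        tol = 1e-6, max_iter = 200L,
                        max_candidates = 1000L, seed = 1L,
                        source_family = NA_character_) {
  enc <- encode_for_motifs(sequences)
  n_seq <- length(enc$codes)
  if (n_seq < min_sequences) {
    abort(paste0("need at least ", min_sequences, " sequences for motif discovery"))
  }
  if (width < 4) abort("motif width must be >= 4")
  min_len <- min(lengths(enc$codes))
  if (width > min_len) {
    abort(paste0("width ", width, " exceeds shortest sequence length ", min_len))
  }
  background <- validate_background(background)
  masks <- lapply(enc$codes, function(x) rep(FALSE, length(x)))
  ll_const <- sum(vapply(enc$codes, function(x) {
    sum(log(background[x[!is.na(x)]]))
  }, numeric(1)))

  motifs <- list()
  for (k in seq_len(n_motifs)) {
    wm <- window_matrix(enc$codes, width, masks)
    if (nrow(wm$win) == 0) break
    cand <- wm$win[!duplicated(wm$win), , drop = FALSE]
    if (nrow(cand) > max_candidates) {
      pick <- withr::with_seed(seed + k, sample(nrow(cand), max_candidates))
      cand <- cand[sort(pick), , drop = FALSE]
    }
    bgm <- matrix(background, width, 20, byrow = TRUE)
    best_obj <- -Inf; best_model <- NULL
    for (ci in seq_len(nrow(cand))) {
      probs0 <- 0.5 * bgm
      probs0[cbind(seq_len(width), cand[ci, ])] <-
        probs0[cbind(seq_len(width), cand[ci, ])] + 0.5
      st <- zoops_em_step(wm$win, wm$seq, n_seq, probs0, 0.5, background,
                          pseudo, ll_const)
      # objective of the updated parameters (one more half E-step would be
      # needed for the exact value; the next step's reported objective is it)
      st2 <- zoops_em_step(wm$win, wm$seq, n_seq, st$probs, st$gamma,
                           background, pseudo, ll_const)
      if (st2$objective > best_obj) {
        best_obj <- st2$objective
        best_model <- list(probs = st$probs, gamma = st$gamma)
      }
    }
    # refine best candidate to convergence
    probs <- best_model$probs; gamma <- best_model$gamma
    obj_trace <- numeric(0); ll_trace <- numeric(0)
    last <- NULL
    for (it in seq_len(max_iter)) {
      st <- zoops_em_step(wm$win, wm$seq, n_seq, probs, gamma, background,
                          pseudo, ll_const)
      obj_trace <- c(obj_trace, st$objective)
      ll_trace <- c(ll_trace, st$ll)
      conv <- it > 1 &&
        abs(st$objective - obj_trace[it - 1]) <
          tol * max(1, abs(obj_trace[it - 1]))
      last <- st
      probs <- st$probs; gamma <- st$gamma
      if (conv) break
    }
    # best site per sequence; mask sites in sequences with q >= 0.5
    s <- window_scores(wm$win, probs, background)
    ord <- order(wm$seq, -s)
    first <- !duplicated(wm$seq[ord])
    best_rows <- ord[first]
    site_seq <- wm$seq[best_rows]
    site_start <- wm$start[best_rows]
    q_full <- rep(0, n_seq)
    q_full[sort(unique(wm$seq))] <- last$q
    with_site <- q_full[site_seq] >= 0.5
    for (j in which(with_site)) {
      i <- site_seq[j]
      masks[[i]][site_start[j]:(site_start[j] + width - 1L)] <- TRUE
    }
    sites <- tibble(sequence_id = enc$ids[site_seq[with_site]],
                    start = site_start[with_site] - 1L)
    consensus <- paste(AA_ALPHABET20[apply(probs, 1, which.max)], collapse = "")
    colnames(probs) <- AA_ALPHABET20
    motifs[[k]] <- structure(
      list(width = as.integer(width), probs = probs, background = background,
           consensus = consensus, n_sites = sum(with_site), gamma = gamma,
           sites = sites, objective_trace = obj_trace, loglik_trace = ll_trace,
           source_family = source_family,
           name = paste0(ifelse(is.na(source_family), "motif", source_family),
                         "_m", k)),
      class = "pwm_motif")
    if (sum(with_site) == 0) break
  }
  motifs
}

#' @export
print.pwm_motif <- function(x, ...) {
  cat("PWM motif", x$name, "- width", x$width, "- sites", x$n_sites,
      "\nconsensus:", x$consensus, "\n")
  invisible(x)
}

#' Information content of a motif
#'
#' @param motif A `pwm_motif`.
#' @return Per-column information content in bits (relative entropy against
#'   the motif's background), as a numeric vector.
#' @export
motif_information <- function(motif) {
  bg <- matrix(motif$background, motif$width, 20, byrow = TRUE)
  rowSums(motif$probs * (log2(motif$probs) - log2(bg)))
}

#' @rdname tidy.benchmark_report
#' @export
tidy.pwm_motif <- function(x, ...) {
  probs <- as_tibble(x$probs)
  probs$position <- seq_len(x$width)
  out <- tidyr::pivot_longer(probs, -"position", names_to = "residue",
                             values_to = "probability")
  out$motif <- x$name
  out[, c("motif", "position", "residue", "probability")]
}

# exact distribution of the integer-scaled window score under the background,
# returned as a survival function lookup
score_null_distribution <- function(s_int, background) {
  width <- nrow(s_int)
  lo <- sum(apply(s_int, 1, min)); hi <- sum(apply(s_int, 1, max))
  p <- numeric(hi - lo + 1)
  cur_lo <- 0
  p[1 - lo + cur_lo] <- 1  # point mass at 0 before first column
  for (w in seq_len(width)) {
    np <- numeric(length(p))
    nz <- which(p > 0)
    for (a in 1:20) {
      sh <- s_int[w, a]
      np[nz + sh] <- np[nz + sh] + p[nz] * background[a]
    }
    p <- np
  }
  sf <- rev(cumsum(rev(p)))           # sf[k] = P(S >= k + lo - 1)
  list(lo = lo, hi = hi, sf = sf)
}

#' Scan sequences with a set of motifs
#'
#' MAST-style scanning: each position of each sequence is scored with the
#' motif's log-odds (log2 of PWM over background); the site p-value comes
#' from the exact distribution of the integer-scaled score (scale 100) under
#' the background, computed by dynamic programming; the sequence p-value is
#' `1 - (1 - p_best)^(L - W + 1)`; and the per-sequence combined p-value over
#' the k scanned motifs applies the product rule
#' `P = p * sum_{i=0}^{k-1} (-ln p)^i / i!` to the product `p` of the
#' sequence p-values. The combined E-value scales the combined p-value by the
#' number of test sequences.
#'
#' @param motifs A list of `pwm_motif` objects (see [em_discover()]).
#' @param sequences A data frame with `id`, `sequence`, or a character
#'   vector.
#' @param n_test Number of test sequences for the E-value scale (defaults to
#'   the number scanned).
#' @return A tibble with one row per (motif, sequence): `motif`,
#'   `sequence_id`, `position` (0-based best site), `site_pvalue`,
#'   `sequence_pvalue`, and the per-sequence `combined_pvalue` and
#'   `combined_evalue` (repeated across the sequence's rows). Sequences
#'   shorter than a motif are skipped for that motif with a message.
#' @export
scan_motifs <- function(motifs, sequences, n_test = NULL) {
  if (length(motifs) == 0) abort("no motifs to scan with")
  enc <- encode_for_motifs(sequences)
  n_seq <- length(enc$codes)
  n_test <- n_test %||% n_seq
  masks <- lapply(enc$codes, function(x) rep(FALSE, length(x)))

  per_motif <- list()
  for (mi in seq_along(motifs)) {
    m <- motifs[[mi]]
    s_int <- round(100 * (log2(m$probs) -
                            matrix(log2(m$background), m$width, 20, byrow = TRUE)))
    mode(s_int) <- "integer"
    null <- score_null_distribution(s_int, m$background)
    too_short <- which(lengths(enc$codes) < m$width)
    if (length(too_short) > 0) {
      message("motif ", m$name, ": skipping ", length(too_short),
              " sequence(s) shorter than width ", m$width)
    }
    wm <- window_matrix(enc$codes, m$width, masks)
    if (nrow(wm$win) == 0) next
    sc <- numeric(nrow(wm$win))
    for (w in seq_len(m$width)) sc <- sc + s_int[w, wm$win[, w]]
    p_site <- null$sf[pmin(pmax(sc, null$lo), null$hi) - null$lo + 1]
    ord <- order(wm$seq, p_site, wm$start)
    first <- !duplicated(wm$seq[ord])
    rows <- ord[first]
    n_win <- tabulate(wm$seq, n_seq)
    i <- wm$seq[rows]
    seq_p <- 1 - (1 - p_site[rows])^n_win[i]
    seq_p <- pmax(seq_p, .Machine$double.xmin)
    per_motif[[length(per_motif) + 1L]] <- tibble(
      motif = m$name, seq_index = i, sequence_id = enc$ids[i],
      position = wm$start[rows] - 1L,
      site_pvalue = p_site[rows], sequence_pvalue = seq_p)
  }
  hits <- dplyr::bind_rows(per_motif)
  if (nrow(hits) == 0) {
    return(tibble(motif = character(), sequence_id = character(),
                  position = integer(), site_pvalue = numeric(),
                  sequence_pvalue = numeric(), combined_pvalue = numeric(),
                  combined_evalue = numeric()))
  }
  comb <- dplyr::summarise(dplyr::group_by(hits, .data$seq_index),
                           combined_pvalue = combine_pvalues(.data$sequence_pvalue),
                           .groups = "drop")
  comb$combined_evalue <- comb$combined_pvalue * n_test
  out <- dplyr::left_join(hits, comb, by = "seq_index")
  dplyr::arrange(out[, c("motif", "sequence_id", "position", "site_pvalue",
                         "sequence_pvalue", "combined_pvalue", "combined_evalue")],
                 .data$sequence_id, .data$motif)
}

# product rule for k p-values: P = p * sum_{i=0}^{k-1} (-ln p)^i / i!
# computed in log space for numerical stability
combine_pvalues <- function(pvals) {
  k <- length(pvals)
  lp <- sum(log(pvals))
  if (lp >= 0) return(1)
  if (k == 1) return(exp(lp))
  terms <- lp + (0:(k - 1)) * log(-lp) - lgamma(1:k)
  mx <- max(terms)
  min(1, exp(mx + log(sum(exp(terms - mx)))))
}

#' Export a PWM as a bracket-notation regular expression
#'
#' Per motif column, all residues with probability at least
#' `majority_threshold` are emitted in descending probability order: a single
#' residue bare, several inside square brackets (e.g. `"F[AS][WI]"`). A
#' column where no residue reaches the threshold contributes its single most
#' probable residue.
#'
#' @param motif A `pwm_motif`.
#' @param majority_threshold Inclusion threshold in `(0, 1]`, default 0.2.
#' @return A regular-expression string over literals and character classes.
#' @export
pwm_to_regex <- function(motif, majority_threshold = 0.2) {
  if (majority_threshold <= 0 || majority_threshold > 1) {
    abort("majority_threshold must be in (0, 1]")
  }
  cols <- vapply(seq_len(motif$width), function(w) {
    p <- motif$probs[w, ]
    keep <- which(p >= majority_threshold)
    if (length(keep) == 0) keep <- which.max(p)
    letters <- AA_ALPHABET20[keep[order(p[keep], decreasing = TRUE)]]
    if (length(letters) == 1) letters else paste0("[", paste(letters, collapse = ""), "]")
  }, character(1))
  paste(cols, collapse = "")
}

# parse a bracket-notation pattern into a list of allowed-residue sets
parse_bracket_pattern <- function(pattern) {
  toks <- regmatches(pattern, gregexpr("\\[[A-Z]+\\]|[A-Z]", pattern))[[1]]
  if (paste(toks, collapse = "") != pattern) {
    abort(paste0("malformed pattern: ", pattern))
  }
  lapply(toks, function(t) {
    if (startsWith(t, "[")) strsplit(substr(t, 2, nchar(t) - 1), "")[[1]] else t
  })
}

#' Match a bracket-notation pattern against a sequence
#'
#' Finds all (possibly overlapping) occurrences of a motif regular
#' expression consisting of literals and character classes, as produced by
#' [pwm_to_regex()].
#'
#' @param pattern Pattern string (literals and `[...]` classes only).
#' @param sequence Sequence string.
#' @return A tibble with `start` (0-based) and `match` (the matched
#'   substring); zero rows when there is no match.
#' @export
#' @examples
#' regex_match("F[AS][WI]", "XFAWX")
regex_match <- function(pattern, sequence) {
  sets <- parse_bracket_pattern(pattern)
  w <- length(sets)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < w) return(tibble(start = integer(), match = character()))
  ok <- rep(TRUE, n - w + 1)
  for (j in seq_len(w)) {
    ok <- ok & chars[seq_len(n - w + 1) + j - 1] %in% sets[[j]]
  }
  starts <- which(ok)
  tibble(start = starts - 1L,
         match = vapply(starts, function(s) {
           paste(chars[s:(s + w - 1)], collapse = "")
         }, character(1)))
}

#' Write motifs in MEME minimal text format
#'
#' @param motifs List of `pwm_motif` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path) {
  bg <- motifs[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               paste0("ALPHABET= ", paste(AA_ALPHABET20, collapse = "")), "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", AA_ALPHABET20, bg), collapse = " "), ""),
             con)
  for (m in motifs) {
    writeLines(c(paste0("MOTIF ", m$name),
                 sprintf("letter-probability matrix: alength= 20 w= %d nsites= %d E= 0",
                         m$width, m$n_sites)), con)
    writeLines(apply(m$probs, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")),
               con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from MEME minimal text format
#'
#' @param path Path to a MEME minimal-format motif file.
#' @return A list of `pwm_motif` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("^MEME version", lines))) abort("not a MEME minimal format file")
  bg <- uniform_background()
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i) > 0) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), 2)])
    names(vals) <- toks[seq(1, length(toks), 2)]
    bg <- validate_background(vals)
  }
  motif_i <- grep("^MOTIF ", lines)
  motifs <- list()
  for (mi in seq_along(motif_i)) {
    name <- sub("^MOTIF\\s+", "", lines[motif_i[mi]])
    hdr_i <- motif_i[mi] + 1
    hdr <- lines[hdr_i]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    nsites <- as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr))
    rows <- lines[(hdr_i + 1):(hdr_i + w)]
    probs <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }))
    probs <- probs / rowSums(probs)
    colnames(probs) <- AA_ALPHABET20
    motifs[[mi]] <- structure(
      list(width = w, probs = probs, background = bg,
           consensus = paste(AA_ALPHABET20[apply(probs, 1, which.max)], collapse = ""),
           n_sites = nsites, gamma = NA_real_,
           sites = tibble(sequence_id = character(), start = integer()),
           objective_trace = numeric(0), loglik_trace = numeric(0),
           source_family = NA_character_, name = name),
      class = "pwm_motif")
  }
  motifs
}
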