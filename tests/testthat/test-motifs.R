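planted_family <- function(n = 20, len = 80, consensus = "WIVPSEIFPLERWAC",
                           conservation = 1.0, seed = 5) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      s <- random_protein(len)
      plant_motif(s, consensus, conservation, sample(0:(len - nchar(consensus)), 1))
    }, character(1))
  })
}

test_that("EM recovers a fully conserved planted motif", {
  cons <- "WIVPSEIFPLERWAC"
  seqs <- planted_family(consensus = cons)
  motifs <- em_discover(seqs, width = 15, n_motifs = 1, seed = 1)
  expect_length(motifs, 1)
  expect_equal(motifs[[1]]$consensus, cons)
  expect_equal(motifs[[1]]$n_sites, 20)
  # fully conserved columns approach log2(20) bits, within pseudocount slack
  expect_true(all(motif_information(motifs[[1]]) > log2(20) - 0.2))
  expect_equal(rowSums(motifs[[1]]$probs), rep(1, 15), tolerance = 1e-9)
})

test_that("the EM objective never decreases across iterations", {
  seqs <- planted_family(n = 8, len = 60, conservation = 0.8, seed = 11)
  motifs <- em_discover(seqs, width = 15, n_motifs = 2, seed = 2)
  for (m in motifs) {
    expect_gte(length(m$objective_trace), 2)
    expect_true(all(diff(m$objective_trace) >= -1e-8))
  }
})

test_that("successive motifs mask their sites and lose information", {
  seqs <- planted_family(n = 12, len = 90, seed = 13)
  motifs <- em_discover(seqs, width = 15, n_motifs = 3, seed = 3)
  expect_gte(length(motifs), 2)
  # motif 1 captured the planted signal; later motifs are weaker
  info <- vapply(motifs, function(m) mean(motif_information(m)), numeric(1))
  expect_true(all(info[-1] < info[1]))
  # per-sequence site sets are disjoint across motifs
  site_tbl <- dplyr::bind_rows(lapply(seq_along(motifs), function(k) {
    dplyr::mutate(motifs[[k]]$sites, motif = k)
  }))
  for (sid in unique(site_tbl$sequence_id)) {
    sites <- site_tbl[site_tbl$sequence_id == sid, ]
    if (nrow(sites) < 2) next
    covered <- unlist(lapply(sites$start, function(s) s:(s + 14)))
    expect_false(any(duplicated(covered)))
  }
})

test_that("EM input validation and degenerate input behave as documented", {
  expect_error(em_discover(c("MKVAW", "MKVAW"), width = 4), "at least 3")
  expect_error(em_discover(c("MKVAW", "MKVAW", "MKV"), width = 4), "exceeds")
  # identical sequences are degenerate but still yield a motif
  same <- rep("MKVAWLLGNNPQRSTYWIV", 4)
  motifs <- em_discover(same, width = 6, n_motifs = 1, min_sequences = 3)
  expect_length(motifs, 1)
})

test_that("EM discovery is deterministic given the seed", {
  seqs <- planted_family(n = 10, len = 60, conservation = 0.9, seed = 17)
  m1 <- em_discover(seqs, width = 15, n_motifs = 1, seed = 4)
  m2 <- em_discover(seqs, width = 15, n_motifs = 1, seed = 4)
  expect_identical(m1[[1]]$probs, m2[[1]]$probs)
})

test_that("scanning planted sequences yields tiny combined E-values", {
  cons <- "WIVPSEIFPLERWAC"
  train <- planted_family(n = 10, len = 80, consensus = cons, seed = 19)
  motifs <- em_discover(train, width = 15, n_motifs = 1, seed = 5)
  test_pos <- planted_family(n = 5, len = 80, consensus = cons, seed = 23)
  test_bg <- withr::with_seed(29, vapply(1:50, function(i) random_protein(80),
                                         character(1)))
  sc <- scan_motifs(motifs, c(setNames(test_pos, paste0("pos", 1:5)),
                              setNames(test_bg, paste0("bg", 1:50))))
  pos <- sc[grepl("^pos", sc$sequence_id), ]
  bg <- sc[grepl("^bg", sc$sequence_id), ]
  expect_true(all(pos$combined_evalue <= 1e-8))
  expect_gt(min(bg$combined_evalue), min(pos$combined_evalue))
})

test_that("a single motif's combined p-value equals its sequence p-value", {
  seqs <- planted_family(n = 6, len = 50, conservation = 0.9, seed = 31)
  motifs <- em_discover(seqs, width = 15, n_motifs = 1, seed = 6)
  sc <- scan_motifs(motifs, setNames(seqs, paste0("s", 1:6)))
  expect_equal(sc$combined_pvalue, sc$sequence_pvalue)
  expect_equal(sc$combined_evalue, sc$combined_pvalue * 6)
  expect_true(all(sc$site_pvalue > 0 & sc$site_pvalue <= 1))
})

test_that("sequences shorter than the motif are skipped with a message", {
  seqs <- planted_family(n = 5, len = 40, conservation = 1, seed = 37)
  motifs <- em_discover(seqs, width = 15, n_motifs = 1, seed = 7)
  mixed <- c(setNames(seqs, paste0("s", 1:5)), short = "MKVAW")
  expect_message(sc <- scan_motifs(motifs, mixed), "shorter than width")
  expect_false("short" %in% sc$sequence_id)
})

test_that("PWM regex export reproduces bracket notation", {
  rows <- list(c(F = 0.95, A = 0.05),
               c(A = 0.5, S = 0.4, W = 0.1),
               c(W = 0.46, I = 0.44, A = 0.1),
               c(M = 0.62, L = 0.20, V = 0.18))
  full <- matrix(0, 4, 20, dimnames = list(NULL, tcbench:::AA_ALPHABET20))
  for (i in 1:4) full[i, names(rows[[i]])] <- rows[[i]]
  motif <- structure(list(width = 4L, probs = full,
                          background = uniform_background(),
                          consensus = "FAWM", n_sites = 10L,
                          sites = tibble::tibble(), name = "m"),
                     class = "pwm_motif")
  expect_equal(pwm_to_regex(motif), "F[AS][WI][ML]")
  expect_equal(pwm_to_regex(motif, majority_threshold = 0.05),
               "[FA][ASW][WIA][MLV]")
})

test_that("bracket patterns match all overlapping occurrences", {
  hits <- regex_match("F[AS][WI]", "XFAWX")
  expect_equal(hits$start, 1L)
  expect_equal(hits$match, "FAW")
  expect_equal(nrow(regex_match("F[AS]", "GGGG")), 0)
  # overlapping matches are all reported
  expect_equal(regex_match("[AW][AW]", "WAW")$start, c(0L, 1L))
  expect_error(regex_match("F[AS", "FA"), "malformed")
})

test_that("a published-style sugar-transporter motif matches its own first-choice expansion", {
  pattern <- paste0("[GA][VI]G[LI][QP]F[FL]QQ[LF][TS]GIN[AV][VI][ML][FY]Y",
                    "[AS]P[VT][IL]F[QK][TK]AGF")
  expansion <- "GVGLQFFQQLTGINAVMFYAPVIFQTAGF"
  hits <- regex_match(pattern, expansion)
  expect_equal(hits$start, 0L)
  expect_equal(hits$match, expansion)
})

test_that("regex export round-trips: first-choice expansions always match", {
  seqs <- planted_family(n = 8, len = 60, conservation = 0.7, seed = 41)
  motifs <- em_discover(seqs, width = 15, n_motifs = 1, seed = 8)
  rx <- pwm_to_regex(motifs[[1]])
  sets <- tcbench:::parse_bracket_pattern(rx)
  first_choice <- paste(vapply(sets, `[`, character(1), 1), collapse = "")
  expect_equal(regex_match(rx, first_choice)$start, 0L)
})

test_that("MEME minimal format round-trips motifs", {
  seqs <- planted_family(n = 6, len = 50, conservation = 0.9, seed = 43)
  motifs <- em_discover(seqs, width = 15, n_motifs = 2, seed = 9,
                        source_family = "2.A.1")
  tf <- withr::local_tempfile(fileext = ".meme")
  write_meme(motifs, tf)
  back <- read_meme(tf)
  expect_length(back, length(motifs))
  for (k in seq_along(motifs)) {
    expect_equal(back[[k]]$name, motifs[[k]]$name)
    expect_equal(back[[k]]$width, motifs[[k]]$width)
    expect_equal(back[[k]]$n_sites, motifs[[k]]$n_sites)
    expect_equal(unname(back[[k]]$probs), unname(motifs[[k]]$probs),
                 tolerance = 1e-4)
  }
})
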