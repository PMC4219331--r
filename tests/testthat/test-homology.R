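test_that("Karlin-Altschul E-values follow E = K m n exp(-lambda S)", {
  sch <- scoring_scheme(lambda = 0.267, K = 0.041)
  ctx <- search_context(db_residues = 1000, db_sequences = 10, query_length = 100)
  expect_equal(karlin_altschul_evalue(50, ctx, sch),
               0.041 * 100 * 1000 * exp(-0.267 * 50))
  expect_equal(karlin_altschul_evalue(50, ctx, sch), 6.53e-3, tolerance = 1e-2)
  # linear in database size
  ctx2 <- search_context(2000, 10, 100)
  expect_equal(karlin_altschul_evalue(50, ctx2, sch),
               2 * karlin_altschul_evalue(50, ctx, sch))
  # strictly decreasing in score, vanishing in the limit
  e <- karlin_altschul_evalue(seq(0, 500, by = 50), ctx, sch)
  expect_true(all(diff(e) < 0))
  expect_lt(e[length(e)], 1e-50)
  expect_error(karlin_altschul_evalue(-1, ctx, sch), "non-negative")
})

test_that("ungapped lambda solves the Karlin-Altschul identity", {
  m <- matrix(-1, 4, 4); diag(m) <- 1
  lam <- estimate_ungapped_lambda(m, rep(0.25, 4))
  expect_equal(lam, log(3), tolerance = 1e-6)
  # residual actually vanishes at the root
  f <- sum(outer(rep(0.25, 4), rep(0.25, 4)) * exp(lam * m)) - 1
  expect_lt(abs(f), 1e-8)
  # doubling the matrix halves lambda
  expect_equal(estimate_ungapped_lambda(2 * m, rep(0.25, 4)), log(3) / 2,
               tolerance = 1e-6)
  # BLOSUM62 with uniform background has a positive finite root
  lam62 <- estimate_ungapped_lambda(blosum62_matrix(), uniform_background())
  expect_gt(lam62, 0)
  expect_lt(lam62, 2)
  # no root when the expected score is non-negative
  good <- matrix(1, 4, 4)
  expect_error(estimate_ungapped_lambda(good, rep(0.25, 4)), "negative")
})

test_that("per-residue normalization divides by database size", {
  expect_equal(normalize_per_residue(1e-58, 23567), 1e-58 / 23567)
  expect_equal(normalize_per_residue(1e-58, 23567), 4.24e-63, tolerance = 1e-2)
  expect_equal(normalize_per_residue(0, 100), 0)
  expect_error(normalize_per_residue(1, 0), "db_residues")
})

test_that("the same match searched in two databases normalizes consistently", {
  # one transporter hit reported at 1e-58 against a 23,567-residue dataset
  # and at 1e-53 against the 3,877,139,759-residue nr snapshot: after
  # per-residue normalization the two E-values agree within a factor of 2
  small <- normalize_per_residue(1e-58, 23567)
  large <- normalize_per_residue(1e-53, 3877139759)
  ratio <- small / large
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("per-hit normalization divides by the hit count", {
  expect_equal(normalize_per_hit(1e-6, 10), 1e-7)
  expect_equal(normalize_per_hit(5e-3, 1), 5e-3)
  e <- normalize_per_hit(1e-6, c(1, 2, 4, 8))
  expect_true(all(diff(e) < 0))
  expect_error(normalize_per_hit(1e-6, 0), "zero hits")
})

test_that("shuffle p-values are deterministic, sensitive, and degenerate-safe", {
  sch <- scoring_scheme()
  a <- withr::with_seed(7, random_protein(80))
  related <- shuffle_pvalue(a, a, sch, n_shuffles = 50, seed = 3)
  expect_lt(related$p, 1e-6)
  expect_identical(related, shuffle_pvalue(a, a, sch, n_shuffles = 50, seed = 3))
  expect_error(shuffle_pvalue(a, a, sch, n_shuffles = 10), ">= 30")
  homo <- paste(rep("A", 40), collapse = "")
  expect_warning(res <- shuffle_pvalue(homo, homo, sch, n_shuffles = 30),
                 "zero variance")
  expect_equal(res$p, 1)
  expect_true(res$degenerate)
})

test_that("unrelated shuffle p-values are roughly uniform", {
  sch <- scoring_scheme()
  ps <- vapply(1:12, function(i) {
    withr::with_seed(400 + i, {
      a <- random_protein(60); b <- random_protein(60)
      shuffle_pvalue(a, b, sch, n_shuffles = 40, seed = i)$p
    })
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})

test_that("chance local-alignment E-values are on the Karlin-Altschul scale", {
  # fraction of unrelated background pairs with raw E <= t stays within a
  # small constant of t itself (no finite-length edge correction is applied)
  sch <- scoring_scheme()
  e <- withr::with_seed(31, {
    replicate(150, {
      a <- random_protein(100); b <- random_protein(100)
      s <- smith_waterman(a, b, sch)$score
      karlin_altschul_evalue(s, search_context(100, 1, 100), sch)
    })
  })
  for (t in c(0.1, 0.01)) {
    frac <- mean(e <= t)
    expect_lte(frac, 4 * t + 3 * sqrt(t * (1 - t) / 150))
  }
})
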