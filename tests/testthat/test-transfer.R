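mk_hits <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(query_id = r[[1]], target_id = r[[2]],
                   raw_score = as.numeric(r[[3]]),
                   raw_evalue = as.numeric(r[[4]]),
                   normalized_evalue = as.numeric(r[[4]]),
                   backend = "external_alignment")
  }))
}

test_that("classification picks the best passing hit or UNCLASSIFIED", {
  hits <- mk_hits(list("q1", "t1", 100, 1e-10), list("q1", "t2", 80, 1e-6))
  labels <- tibble::tibble(id = c("t1", "t2"), label = c("2.A.1", "3.A.1"))
  res <- classify_queries(hits, c("q1", "q2"), labels, threshold = 1e-8)
  expect_equal(res$predicted[res$query_id == "q1"], "2.A.1")
  expect_equal(res$predicted[res$query_id == "q2"], "UNCLASSIFIED")
  # nothing passes a stricter threshold
  res2 <- classify_queries(hits, "q1", labels, threshold = 1e-12)
  expect_equal(res2$predicted, "UNCLASSIFIED")
  # boundary convention: passing means <= threshold
  res3 <- classify_queries(hits, "q1", labels, threshold = 1e-10)
  expect_equal(res3$predicted, "2.A.1")
  # a target without a label is an error
  expect_error(classify_queries(hits, "q1", labels[1, ], 1e-4), "without a reference label")
})

test_that("exact ties resolve to the lexicographically smaller target", {
  hits <- mk_hits(list("q1", "tB", 50, 1e-9), list("q1", "tA", 50, 1e-9))
  labels <- tibble::tibble(id = c("tA", "tB"), label = c("1.A.1", "2.A.1"))
  res <- classify_queries(hits, "q1", labels, 1e-8)
  expect_equal(res$best_target, "tA")
  expect_equal(res$predicted, "1.A.1")
})

test_that("per-family confusion cells partition the classified instances", {
  results <- tibble::tibble(
    true = c(rep("f1", 6), rep("f2", 4)),
    predicted = c(rep("f1", 6), rep("f2", 4)))
  cells <- confusion_by_family(results, c("f1", "f2"))
  expect_equal(unlist(cells[cells$label == "f1", c("tp", "fp", "fn", "tn")]),
               c(tp = 6, fp = 0, fn = 0, tn = 4))
  expect_equal(unlist(cells[cells$label == "f2", c("tp", "fp", "fn", "tn")]),
               c(tp = 4, fp = 0, fn = 0, tn = 6))
  # with errors: the four cells always partition the classified count
  res2 <- tibble::tibble(true = c("f1", "f1", "f2", "f2", "f1"),
                         predicted = c("f1", "f2", "f2", "f1", "UNCLASSIFIED"))
  cells2 <- confusion_by_family(res2, c("f1", "f2"))
  expect_equal(cells2$tp + cells2$fp + cells2$fn + cells2$tn, c(4L, 4L))
  # all-unclassified gives all-zero cells
  res3 <- tibble::tibble(true = "f1", predicted = "UNCLASSIFIED")
  expect_equal(sum(unlist(confusion_by_family(res3, "f1")[, c("tp", "fp", "fn", "tn")])), 0)
})

test_that("precision, recall and F-measure follow their defining identities", {
  expect_equal(precision_pct(9, 1), 90)
  expect_equal(recall_pct(9, 1), 90)
  expect_equal(f_measure_pct(90, 90), 90)   # harmonic mean at equality
  expect_equal(f_measure_pct(60, 100), 75)  # 2 * 6000 / 160
  expect_equal(precision_pct(0, 0), 0)
  expect_equal(f_measure_pct(0, 0), 0)
})

test_that("weighted averaging multiplies by member counts", {
  expect_equal(weighted_average(c(100, 80), c(10, 30)), 85)
  expect_equal(weighted_average(c(70, 90), c(5, 5)), 80)  # equal sizes: mean
  expect_equal(weighted_average(42, 7), 42)
  expect_error(weighted_average(c(1, 2), c(0, 0)), "zero")
})

test_that("unclassified fraction counts queries without passing hits", {
  res <- tibble::tibble(predicted = c(rep("UNCLASSIFIED", 4), rep("f", 16)))
  expect_equal(unclassified_fraction(res), 20)
  expect_equal(unclassified_fraction(tibble::tibble(predicted = "f")), 0)
  expect_error(unclassified_fraction(res[0, ]), "no classification")
})

sweep_fixture <- function() {
  # two queries per family; E-values chosen so that looser thresholds
  # classify strictly more queries (nested hit sets)
  hits <- mk_hits(
    list("a1", "b1", 90, 1e-22), list("a2", "b1", 70, 1e-14),
    list("a3", "b3", 80, 1e-9), list("a4", "b4", 60, 1e-5),
    list("a4", "b1", 50, 1e-5))
  list(hits = hits,
       q = tibble::tibble(id = paste0("a", 1:4),
                          label = c("f1", "f1", "f2", "f2")),
       t = tibble::tibble(id = paste0("b", 1:4),
                          label = c("f1", "f1", "f2", "f2")))
}

test_that("threshold sweeps classify monotonically more as thresholds loosen", {
  fx <- sweep_fixture()
  rep <- threshold_sweep(fx$hits, fx$q, fx$t)
  expect_s3_class(rep, "benchmark_report")
  uncls <- rep$report$unclassified
  expect_true(all(diff(uncls) <= 0))
  expect_equal(uncls, c(75, 75, 50, 25, 0))
  # everything that classifies here is correct
  expect_true(all(rep$report$precision[rep$report$unclassified < 100] == 100))
  # per-threshold cell sums track the classified counts
  for (th in rep$grid) {
    cells <- rep$cells[rep$cells$threshold == th, ]
    n_classified <- sum(rep$classifications$predicted != "UNCLASSIFIED" &
                          rep$classifications$threshold == th)
    expect_equal(sum(cells$tp), n_classified)  # all correct in this fixture
    expect_equal(sum(cells$tp + cells$fn), n_classified)
  }
})

test_that("weighted F equals weighted precision when every family has P = R", {
  fx <- sweep_fixture()
  rep <- threshold_sweep(fx$hits, fx$q, fx$t)
  cells <- rep$cells[rep$cells$threshold == 1e-4, ]
  p <- precision_pct(cells$tp, cells$fp)
  r <- recall_pct(cells$tp, cells$fn)
  expect_equal(p, r)
  row <- rep$report[rep$report$threshold == 1e-4, ]
  expect_equal(row$f_measure, row$precision)
})

test_that("weighted metrics ignore family relabeling and query order", {
  fx <- sweep_fixture()
  base <- threshold_sweep(fx$hits, fx$q, fx$t)$report
  relab <- function(x) dplyr::mutate(x, label = paste0("X_", label))
  renamed <- threshold_sweep(fx$hits, relab(fx$q), relab(fx$t))$report
  expect_equal(base, renamed)
  shuffled <- threshold_sweep(fx$hits[c(4, 2, 5, 1, 3), ],
                              fx$q[c(3, 1, 4, 2), ], fx$t)$report
  expect_equal(base, shuffled)
})

test_that("high unclassified fractions coexist with high recall", {
  # the strict-threshold pattern: most queries unclassified, but the few
  # classified ones are right, so weighted recall stays high
  n <- 20
  hits <- mk_hits(list("q1", "t1", 90, 1e-22), list("q2", "t1", 85, 1e-21),
                  list("q11", "t2", 80, 1e-23))
  q <- tibble::tibble(id = paste0("q", 1:n),
                      label = rep(c("f1", "f2"), each = n / 2))
  t <- tibble::tibble(id = c("t1", "t2"), label = c("f1", "f2"))
  rep <- threshold_sweep(hits, q, t, grid = c(1e-20, 1e-4))
  strict <- rep$report[rep$report$threshold == 1e-20, ]
  expect_gte(strict$unclassified, 80)
  expect_gte(strict$recall, 80)
})

test_that("reports round-trip through the four-row TSV layout", {
  fx <- sweep_fixture()
  rep <- threshold_sweep(fx$hits, fx$q, fx$t)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, tf)
  back <- read_report(tf)
  expect_equal(back$metric, c("Precision [%]", "Recall [%]",
                              "F-measure [%]", "Unclassified [%]"))
  expect_equal(unname(unlist(back[1, -1])), rep$report$precision)
  expect_equal(unname(unlist(back[4, -1])), rep$report$unclassified)
})

test_that("tidy, glance and autoplot expose report contents", {
  fx <- sweep_fixture()
  rep <- threshold_sweep(fx$hits, fx$q, fx$t)
  long <- tidy(rep)
  expect_setequal(unique(long$metric),
                  c("precision", "recall", "f_measure", "unclassified"))
  g <- glance(rep)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_queries, 4)
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("crosstab bins best family-pair E-values on the grid", {
  expect_equal(tcbench:::evalue_bin(c(1e-21, 1e-20, 1e-18, 1e-9, 1e-5, 1e-3)),
               c(4L, 4L, 3L, 1L, 0L, 0L))
  hits <- mk_hits(list("a1", "b1", 90, 1e-22), list("a1", "b2", 20, 1e-6),
                  list("a2", "b2", 30, 1e-9))
  q <- tibble::tibble(id = c("a1", "a2"), label = c("sugar_2.A.1", "metal_3.A.1"))
  t <- tibble::tibble(id = c("b1", "b2", "b3"),
                      label = c("sugar_2.A.1", "metal_3.A.1", "phosphate_2.A.55"))
  ct <- substrate_tc_crosstab(hits, q, t)
  tab <- ct$table
  expect_equal(tab$bin[tab$query_family == "sugar_2.A.1" &
                         tab$target_family == "sugar_2.A.1"], 4L)
  expect_equal(tab$bin[tab$query_family == "metal_3.A.1" &
                         tab$target_family == "metal_3.A.1"], 1L)
  # family pair with no hit at all is missing, not zero
  expect_true(is.na(tab$bin[tab$target_family == "phosphate_2.A.55"][1]))
  expect_s3_class(autoplot(ct), "ggplot")
})
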