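# independent brute-force recount used as the oracle for confusion counts
brute_confusion <- function(df, gold) {
  counts <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (i in seq_len(nrow(df))) {
    g <- gold[[df$record_id[[i]]]]
    p <- df$decision[[i]]
    k <- if (g == "include" && p == "include") "tp"
    else if (g == "exclude" && p == "exclude") "tn"
    else if (g == "exclude" && p == "include") "fp"
    else "fn"
    counts[[k]] <- counts[[k]] + 1
  }
  counts
}

random_decision_df <- function(n, seed) {
  set.seed(seed)
  data.frame(record_id = sprintf("r%03d", 1:n),
             decision = sample(c("include", "exclude"), n, replace = TRUE),
             exclusion_reason = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("confusion counts partition the decision set and match gold", {
  gold <- c(stats::setNames(rep("include", 10), sprintf("i%02d", 1:10)),
            stats::setNames(rep("exclude", 90), sprintf("e%02d", 1:90)))
  perfect <- data.frame(record_id = names(gold), decision = unname(gold),
                        stringsAsFactors = FALSE)
  cf <- confusion_from_decisions(perfect, gold)
  expect_equal(unlist(cf), c(tp = 10, tn = 90, fp = 0, fn = 0))
  one_fn <- perfect
  one_fn$decision[one_fn$record_id == "i01"] <- "exclude"
  expect_equal(confusion_from_decisions(one_fn, gold)$fn, 1)
  # missing gold id errors with the id named
  bad <- data.frame(record_id = "ghost", decision = "include",
                    stringsAsFactors = FALSE)
  expect_error(confusion_from_decisions(bad, gold),
               class = "validation_error", regexp = "ghost")
})

test_that("confusion counts equal a brute-force recount on random sets", {
  for (seed in 1:10) {
    set.seed(seed + 500)
    n <- 200
    ids <- sprintf("r%03d", 1:n)
    gold <- stats::setNames(sample(c("include", "exclude"), n, TRUE,
                                   prob = c(0.1, 0.9)), ids)
    df <- random_decision_df(n, seed)
    cf <- confusion_from_decisions(df, gold)
    expect_equal(unlist(cf), brute_confusion(df, gold))
    expect_equal(cf$tp + cf$tn + cf$fp + cf$fn, n)
  }
})

test_that("metric formulas and half-up percent rendering", {
  m <- compute_metrics(confusion_summary(tp = 8, tn = 88, fp = 2, fn = 2))
  expect_equal(m$accuracy_pct, 96.00)
  expect_equal(m$precision_pct, 80.00)
  expect_equal(m$recall_pct, 80.00)
  m <- compute_metrics(confusion_summary(tp = 10, tn = 90, fp = 0, fn = 0))
  expect_equal(c(m$accuracy_pct, m$precision_pct, m$recall_pct),
               c(100, 100, 100))
  # undefined denominators are flagged, not reported as 0
  m <- compute_metrics(confusion_summary(tp = 0, tn = 5, fp = 0, fn = 2))
  expect_false(m$precision_defined)
  expect_true(is.na(m$precision))
  m <- compute_metrics(confusion_summary(tp = 0, tn = 5, fp = 2, fn = 0))
  expect_false(m$recall_defined)
  expect_error(compute_metrics(confusion_summary(0, 0, 0, 0)),
               class = "validation_error")
  # half-up rounding at the second decimal
  expect_equal(round_half_up(99.375, 2), 99.38)
  expect_equal(round_half_up(0.125, 2), 0.13)
})

test_that("metric identities hold across confusion space", {
  for (seed in 1:30) {
    set.seed(seed)
    c4 <- as.list(stats::setNames(sample(0:30, 4, TRUE),
                                  c("tp", "tn", "fp", "fn")))
    if (sum(unlist(c4)) == 0) next
    m <- compute_metrics(do.call(confusion_summary, c4))
    expect_equal(m$accuracy == 1, c4$fp == 0 && c4$fn == 0)
  }
  # recall is monotone non-increasing in fn at fixed tp+fn
  rec <- vapply(0:10, function(fn)
    compute_metrics(confusion_summary(tp = 10 - fn, tn = 5, fp = 3,
                                      fn = fn))$recall, 1)
  expect_true(all(diff(rec) <= 0))
})

test_that("exclusion-reason concordance counts co-excluded matches", {
  df <- data.frame(
    record_id = c("a", "b", "c", "d", "e", "f"),
    decision = c("exclude", "exclude", "exclude", "exclude", "include",
                 "exclude"),
    exclusion_reason = c("Reason One", "reason  one", "Reason Two",
                         "Reason Three", NA, "Reason Four"),
    stringsAsFactors = FALSE)
  gold_r <- c(a = "reason one", b = "Reason One", c = "Reason Two",
              d = "A different reason", e = "ignored")
  # f is not gold-excluded, e is tool-included: 4 compared, 3 match
  cr <- exclusion_reason_concordance(df, gold_r)
  expect_equal(cr$compared, 4)
  expect_equal(cr$matched, 3)
  expect_equal(cr$rate, 0.75)
  # all-match and no-co-excluded cases
  cr2 <- exclusion_reason_concordance(df[3, ], gold_r)
  expect_equal(cr2$rate, 1)
  cr3 <- exclusion_reason_concordance(df[5, ], gold_r)
  expect_false(cr3$defined)
  expect_true(is.na(cr3$rate))
})

test_that("chi-square matches hand computation and the stats oracle", {
  res <- chi_square_2xk(matrix(c(20, 10, 5, 15), nrow = 2))
  expect_equal(res$statistic, 8.3333, tolerance = 1e-4)
  expect_equal(res$df, 1)
  # identical columns: statistic 0, p 1
  res0 <- chi_square_2xk(matrix(c(7, 3, 7, 3, 7, 3), nrow = 2))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # independent oracle: stats::chisq.test without continuity correction
  for (seed in 1:100) {
    set.seed(seed + 900)
    k <- sample(2:5, 1)
    tab <- matrix(sample(1:50, 2 * k, TRUE), nrow = 2)
    mine <- chi_square_2xk(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$df, unname(ref$parameter))
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-9)
  }
  expect_error(chi_square_2xk(matrix(c(0, 0, 3, 4), nrow = 2)),
               class = "validation_error")
  expect_error(chi_square_2xk(matrix(1:6, nrow = 3)),
               class = "validation_error")
})

test_that("compare_models composes metrics, concordance and chi-squares", {
  n <- 60
  set.seed(77)
  ids <- sprintf("r%03d", 1:n)
  gold <- stats::setNames(c(rep("include", 20), rep("exclude", 40)), ids)
  greasons <- stats::setNames(rep("gold reason", 40), ids[21:60])
  mk <- function(n_fn) {
    dec <- unname(gold)
    flip <- which(dec == "include")[seq_len(n_fn)]
    dec[flip] <- "exclude"
    data.frame(record_id = ids, decision = dec,
               exclusion_reason = ifelse(dec == "exclude", "gold reason",
                                         NA),
               stringsAsFactors = FALSE)
  }
  sets <- list(a = mk(0), b = mk(4), c = mk(8))
  rep <- compare_models(sets, gold, greasons)
  # recall chi-square equals the direct tp/fn table test
  tab <- vapply(sets, function(s) {
    cf <- confusion_from_decisions(s, gold)
    c(cf$tp, cf$fn)
  }, numeric(2))
  direct <- chi_square_2xk(tab)
  expect_equal(rep$recall_test$statistic, direct$statistic)
  expect_equal(rep$recall_test$df, 2)
  # identical sets: zero statistic, identical metrics
  rep0 <- compare_models(list(x = mk(2), y = mk(2), z = mk(2)), gold,
                         greasons)
  expect_equal(rep0$recall_test$statistic, 0)
  expect_false(rep0$recall_differs)
  expect_equal(rep0$metrics$x, rep0$metrics$z)
  # coverage mismatch errors
  short <- mk(0)[-1, ]
  expect_error(compare_models(list(a = mk(0), b = short), gold),
               class = "validation_error")
  # report renders and serializes
  txt <- render_report_text(rep)
  expect_match(txt, "Recall difference")
  f <- file.path(tempdir(), "report.json")
  write_report_json(rep, f)
  expect_true(jsonlite::validate(paste(readLines(f), collapse = "\n")))
})

test_that("a single decision set evaluates without a between-model test", {
  gold <- c(a = "include", b = "exclude", c = "exclude")
  df <- data.frame(record_id = c("a", "b", "c"),
                   decision = c("exclude", "exclude", "include"),
                   exclusion_reason = c("r", "r", NA),
                   stringsAsFactors = FALSE)
  rep1 <- compare_models(list(solo = df), gold, c(b = "r", c = "r"))
  expect_null(rep1$recall_test)
  expect_false(rep1$recall_differs)
  expect_equal(rep1$metrics$solo$accuracy, 1 / 3)
})
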