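test_that("confusion counts land in the right cells", {
  ct <- confusion_table(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(unlist(ct[c("N00", "N01", "N10", "N11")]),
               c(N00 = 2L, N01 = 0L, N10 = 0L, N11 = 2L))
  ct <- confusion_table(c(0, 1), c(1, 0))
  expect_equal(ct$N01, 1L)
  expect_equal(ct$N10, 1L)
  withr::with_seed(73, {
    truth <- rbinom(80, 1, 0.5); pred <- rbinom(80, 1, 0.5)
    ct <- confusion_table(truth, pred)
    expect_equal(ct$N00 + ct$N01 + ct$N10 + ct$N11, 80L)
  })
  expect_error(confusion_table(c(0, 1), c(0, 1, 1)), "equal length")
})

test_that("metrics reproduce the hand-computed 80-case table", {
  ct <- structure(list(N00 = 50L, N01 = 8L, N10 = 5L, N11 = 17L),
                  class = "sdam_confusion")
  m <- confusion_metrics(ct)
  expect_equal(m$accuracy, 0.8375)
  expect_equal(m$sensitivity, 50 / 58)
  expect_equal(m$specificity, 17 / 22)
  expect_equal(m$ppv, 50 / 55)
  expect_equal(m$npv, 17 / 25)
  expect_equal(m$balanced_accuracy, (50 / 55 + 17 / 25) / 2)
  expect_equal(round(unlist(m), 2),
               c(accuracy = 0.84, sensitivity = 0.86, specificity = 0.77,
                 ppv = 0.91, npv = 0.68, balanced_accuracy = 0.79))
})

test_that("symmetric and perfect tables give flat and unit metrics", {
  ct <- structure(list(N00 = 25L, N01 = 15L, N10 = 15L, N11 = 25L),
                  class = "sdam_confusion")
  expect_true(all(unlist(confusion_metrics(ct)) == 0.625))
  ct <- structure(list(N00 = 30L, N01 = 0L, N10 = 0L, N11 = 50L),
                  class = "sdam_confusion")
  expect_true(all(unlist(confusion_metrics(ct)) == 1))
})

test_that("balanced accuracy is the mean of the predictive values", {
  withr::with_seed(79, {
    for (rep in 1:50) {
      ct <- structure(as.list(setNames(rpois(4, 20) + 1L,
                                       c("N00", "N01", "N10", "N11"))),
                      class = "sdam_confusion")
      m <- confusion_metrics(ct)
      expect_identical(m$balanced_accuracy, (m$ppv + m$npv) / 2)
      # and reduces to accuracy when PPV = NPV
      ms <- confusion_metrics(ct, variant = "sens_spec")
      expect_identical(ms$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
    }
  })
  # PPV = NPV = accuracy on a balanced-margin table
  ct <- structure(list(N00 = 30L, N01 = 10L, N10 = 10L, N11 = 30L),
                  class = "sdam_confusion")
  m <- confusion_metrics(ct)
  expect_equal(m$ppv, m$npv)
  expect_equal(m$balanced_accuracy, m$accuracy)
})

test_that("swapping the 0/1 label convention swaps the paired metrics", {
  withr::with_seed(83, {
    for (rep in 1:20) {
      truth <- rbinom(60, 1, 0.4); pred <- rbinom(60, 1, 0.6)
      m <- confusion_metrics(confusion_table(truth, pred))
      ms <- confusion_metrics(confusion_table(1 - truth, 1 - pred))
      expect_equal(ms$accuracy, m$accuracy)
      expect_equal(ms$sensitivity, m$specificity)
      expect_equal(ms$specificity, m$sensitivity)
      expect_equal(ms$ppv, m$npv)
      expect_equal(ms$npv, m$ppv)
    }
  })
})

test_that("zero denominators surface as NaN with a flag, never as 0", {
  ct <- structure(list(N00 = 0L, N01 = 0L, N10 = 3L, N11 = 7L),
                  class = "sdam_confusion")
  m <- confusion_metrics(ct)
  expect_true(is.nan(m$sensitivity))
  expect_true("sensitivity" %in% attr(m, "undefined"))
  expect_error(
    confusion_metrics(structure(list(N00 = 0L, N01 = 0L, N10 = 0L, N11 = 0L),
                                class = "sdam_confusion")),
    "empty")
})

test_that("the exact binomial tail matches explicit summation", {
  expect_equal(binomial_onetailed(4, 4), 0.0625)
  expect_equal(binomial_onetailed(0, 10), 1)
  expect_lt(binomial_onetailed(67, 80), 1e-8)
  for (N in c(1, 2, 7, 33, 80, 200)) {
    for (matches in unique(c(0, 1, floor(N / 2), N))) {
      expect_equal(binomial_onetailed(matches, N),
                   binom_tail_sum(matches, N), tolerance = 1e-12)
    }
  }
})

test_that("phi equals the closed-form table formula", {
  a <- c(1, 1, 0, 0, 1)
  expect_equal(phi_correlation(a, a), 1)
  expect_equal(phi_correlation(a, 1 - a), -1)
  withr::with_seed(89, {
    for (rep in 1:30) {
      x <- rbinom(50, 1, 0.5); y <- rbinom(50, 1, 0.5)
      if (sd(x) == 0 || sd(y) == 0) next
      ct <- confusion_table(x, y)
      expect_equal(phi_correlation(x, y),
                   phi_from_table(ct$N00, ct$N01, ct$N10, ct$N11),
                   tolerance = 1e-12)
    }
  })
  expect_warning(p <- phi_correlation(rep(1, 5), c(0, 1, 1, 0, 1)),
                 "constant")
  expect_true(is.na(p))
})

test_that("Fisher-z averaging has the expected fixed points", {
  expect_equal(fisher_mean(c(0.4, 0.4)), 0.4)
  expect_equal(fisher_mean(0), 0)
  expect_equal(fisher_mean(c(0.5, -0.5)), 0)
  expect_error(fisher_mean(c(0.2, 1)), "Fisher")
  # nonlinear: differs from the arithmetic mean for spread values
  expect_gt(fisher_mean(c(0.1, 0.9)), (0.1 + 0.9) / 2)
})

test_that("rater screening drops exactly the inverted rater", {
  withr::with_seed(97, {
    base <- rbinom(40, 1, 0.5)
    panel <- matrix(NA_real_, 12, 40,
                    dimnames = list(paste0("r", 1:12), NULL))
    for (i in 1:11) {
      row <- base
      flip <- runif(40) < 0.15      # honest raters with mild disagreement
      row[flip] <- 1 - row[flip]
      panel[i, ] <- row
    }
    panel[12, ] <- 1 - base         # inverted rater
    scr <- screen_raters(panel)
    expect_equal(scr$dropped, "r12")
    expect_length(scr$retained, 11)
    expect_true(all(scr$loo_cor[1:11] > 0))
    expect_lt(scr$loo_cor["r12"], 0)
    # direct recomputation of one leave-one-out correlation
    expect_equal(scr$loo_cor[["r3"]],
                 cor(panel[3, ], colMeans(panel[-3, ])))
  })
})

test_that("a rater identical to a unanimous-ish panel is retained at cor 1", {
  panel <- matrix(rep(c(1, 0, 1, 1, 0), each = 5), 5, 5, byrow = FALSE)
  # all raters identical: each leave-one-out correlation is exactly 1
  scr <- screen_raters(panel)
  expect_true(all(scr$loo_cor == 1))
  expect_length(scr$retained, 5)
})

test_that("constant raters are retained with a warning", {
  panel <- rbind(rep(1, 10), rbinom(10, 1, 0.5), rbinom(10, 1, 0.5))
  while (sd(panel[2, ]) == 0 || sd(panel[3, ]) == 0)
    panel[2:3, ] <- rbinom(20, 1, 0.5)
  expect_warning(scr <- screen_raters(panel), "constant")
  expect_true("1" %in% scr$retained)
  expect_true(is.na(scr$loo_cor[1]))
})

test_that("panel aggregation gives majority and agreement fractions", {
  agg <- aggregate_panel(matrix(c(1, 1, 0), 3, 1))
  expect_equal(agg$majority, 1L)
  expect_equal(agg$P_E, 2 / 3)

  agg <- aggregate_panel(matrix(0, 5, 3))
  expect_equal(agg$majority, c(0L, 0L, 0L))
  expect_equal(agg$P_E, c(0, 0, 0))

  m <- matrix(0, 11, 1); m[1:6, 1] <- 1
  agg <- aggregate_panel(m)
  expect_equal(agg$majority, 1L)
  expect_equal(agg$P_E, 6 / 11)

  # even panel with a tie: flagged, resolved to 0
  m <- matrix(c(1, 1, 0, 0), 4, 1)
  expect_warning(agg <- aggregate_panel(m), "tied")
  expect_equal(agg$majority, 0L)
  expect_equal(agg$ties, 1L)
})

test_that("panel evaluation wires screening, majority and metrics together", {
  withr::with_seed(101, {
    truth <- rbinom(80, 1, 0.35)
    panel <- matrix(NA_real_, 11, 80)
    for (i in 1:11) {
      row <- truth
      flip <- runif(80) < 0.1
      row[flip] <- 1 - row[flip]
      panel[i, ] <- row
    }
    pred <- truth
    flip <- runif(80) < 0.15
    pred[flip] <- 1 - pred[flip]
    ev <- evaluate_against_panel(panel, pred)
    expect_length(ev$majority, 80)
    ct <- ev$confusion
    expect_equal(ct$N00 + ct$N01 + ct$N10 + ct$N11, 80L)
    expect_equal(ev$metrics$accuracy, mean(ev$majority == pred))
    expect_equal(ev$binomial_p,
                 binom_tail_sum(sum(ev$majority == pred), 80),
                 tolerance = 1e-12)
    expect_equal(ev$phi, cor(ev$majority, pred))
  })
})
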