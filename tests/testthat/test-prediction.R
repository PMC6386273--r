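test_that("AMPA declares competence iff a correct action is among the closest", {
  # branching task, executed (1,2,3): correct follow-ups {4,5}, but action 6
  # is closest to the most recent action 3 -> not competent
  bt <- branching_task()
  sit <- make_situation(bt, c(1, 2, 3))
  D <- matrix(5, 7, 7, dimnames = list(1:7, 1:7))
  diag(D) <- 0
  D["3", "6"] <- D["6", "3"] <- 0.5
  D["3", "4"] <- D["4", "3"] <- 1.0
  D["3", "5"] <- D["5", "3"] <- 1.2
  res <- ampa(D, sit)
  expect_equal(res$competent, 0L)
  expect_length(res$cmpa_set, 0)

  # make a correct action tie with the minimum: ties favor competence
  D["3", "4"] <- D["4", "3"] <- 0.5
  res <- ampa(D, sit)
  expect_equal(res$competent, 1L)
  expect_equal(res$cmpa_set, 4L)
})

test_that("AMPA with C_S equal to the whole candidate set is always competent", {
  task <- chain_task(2)  # executed (1): the only candidate, 2, is correct
  sit <- make_situation(task, 1L)
  D <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(1:2, 1:2))
  expect_equal(ampa(D, sit)$competent, 1L)
})

test_that("AMPA tie handling on the hand-enumerated 5-action case", {
  task <- chain_task(5)
  sit <- make_situation(task, c(1, 2))  # C_S = {3}, a_i = 1 excluded
  D <- matrix(5, 5, 5, dimnames = list(1:5, 1:5))
  diag(D) <- 0
  D["2", "3"] <- D["3", "2"] <- 0.5
  D["2", "4"] <- D["4", "2"] <- 0.5
  D["2", "5"] <- D["5", "2"] <- 0.9
  res <- ampa(D, sit)
  expect_equal(res$competent, 1L)
  expect_equal(res$cmpa_set, 3L)

  # previously executed actions other than a_i stay in the candidate set:
  # with executed (1,2,3,4), action 1 competes again
  sit2 <- make_situation(task, c(1, 2, 3, 4))
  D2 <- matrix(5, 5, 5, dimnames = list(1:5, 1:5))
  diag(D2) <- 0
  D2["4", "1"] <- D2["1", "4"] <- 0.1   # revisiting 1 looks most probable
  D2["4", "5"] <- D2["5", "4"] <- 0.9
  expect_equal(ampa(D2, sit2)$competent, 0L)
})

test_that("activation is the log-odds of the correlation", {
  expect_equal(rho_activation(0.5), 0)
  expect_equal(rho_activation(exp(1) / (1 + exp(1))), 1)
  expect_equal(rho_activation(0.9), log(9))
  expect_true(all(diff(rho_activation(seq(0.01, 0.99, 0.01))) > 0))
  expect_error(rho_activation(-0.2), "r <= 0")
  expect_error(rho_activation(0), "r <= 0")
  # clipping keeps r = 1 finite
  expect_true(is.finite(rho_activation(1)))
})

test_that("Lander's pi matches its closed form and stays positive", {
  expect_equal(pi_lander(0.39, 0.39), exp(-1))
  expect_equal(pi_lander(1, 0.39), 1)
  expect_equal(pi_lander(0, 0.39), exp(-1 / 0.61))
  expect_gt(pi_lander(-0.9, 0.39), 0)  # the documented drawback
  expect_error(pi_lander(0.5, 1), "r_krit")
})

test_that("CASPA reproduces the hand-derived softmax example", {
  task <- chain_task(4)
  sit <- make_situation(task, 1L)  # C_S = {2}, candidates {2,3,4}
  R <- sym_R(4, "1,2" = 0.6, "1,3" = 0.2, "1,4" = -0.1)
  p <- caspa_probability(R, sit, s = 0.4)
  expect_equal(p, 1.5^2.5 / (1.5^2.5 + 0.25^2.5), tolerance = 1e-12)
  expect_equal(round(p, 4), 0.9888)
})

test_that("CASPA boundary cases follow the applicability filter", {
  task <- chain_task(4)
  sit <- make_situation(task, 1L)

  # all applicable actions correct -> 1 (even though some are negative)
  R <- sym_R(4, "1,2" = 0.6, "1,3" = -0.2, "1,4" = -0.5)
  expect_equal(caspa_probability(R, sit), 1)

  # no correct applicable action -> 0
  R <- sym_R(4, "1,2" = -0.1, "1,3" = 0.4, "1,4" = 0.2)
  expect_equal(caspa_probability(R, sit), 0)

  # r exactly 0 is inapplicable (strict filter)
  R <- sym_R(4, "1,2" = 0, "1,3" = 0.4, "1,4" = 0.2)
  expect_equal(caspa_probability(R, sit), 0)

  # one correct, one incorrect, equal positive correlation -> 0.5
  R <- sym_R(4, "1,2" = 0.3, "1,3" = 0.3, "1,4" = -0.2)
  expect_equal(caspa_probability(R, sit), 0.5)

  # nothing applicable -> 0 with a warning
  R <- sym_R(4, "1,2" = -0.1, "1,3" = -0.4, "1,4" = 0)
  expect_warning(p <- caspa_probability(R, sit), "no applicable")
  expect_equal(p, 0)
})

test_that("stable CASPA equals naive direct summation", {
  task <- chain_task(8)
  withr::with_seed(53, {
    for (rep in 1:50) {
      R <- diag(8)
      vals <- runif(28, -0.99, 0.99)
      R[upper.tri(R)] <- vals
      R <- R + t(R) - diag(diag(R))
      diag(R) <- 1
      dimnames(R) <- list(1:8, 1:8)
      len <- sample(1:7, 1)
      sit <- make_situation(task, seq_len(len))
      p1 <- suppressWarnings(caspa_probability(R, sit))
      p2 <- suppressWarnings(naive_caspa(R, sit))
      expect_equal(p1, p2, tolerance = 1e-9)
    }
  })
})

test_that("softmax is invariant to a constant activation shift", {
  task <- chain_task(5)
  sit <- make_situation(task, c(1, 2))
  withr::with_seed(59, {
    for (rep in 1:20) {
      r <- runif(3, 0.05, 0.95)  # candidates 3,4,5
      R <- sym_R(5, "2,3" = r[1], "2,4" = r[2], "2,5" = r[3])
      delta <- runif(1, -3, 3)
      rho_shifted <- log(r / (1 - r)) + delta
      rs <- 1 / (1 + exp(-rho_shifted))
      Rs <- sym_R(5, "2,3" = rs[1], "2,4" = rs[2], "2,5" = rs[3])
      # shifting every activation by delta multiplies all weights by
      # exp(delta / s): P_S must not move
      p0 <- caspa_probability(R, sit)
      p1 <- caspa_probability(Rs, sit)
      expect_equal(p0, p1, tolerance = 1e-12)
    }
  })
})

test_that("raising a correct action's correlation never lowers P_S", {
  task <- chain_task(5)
  sit <- make_situation(task, c(1, 2))
  withr::with_seed(61, {
    for (rep in 1:20) {
      r <- runif(3, 0.05, 0.9)
      R <- sym_R(5, "2,3" = r[1], "2,4" = r[2], "2,5" = r[3])
      p0 <- caspa_probability(R, sit)
      r_up <- min(r[1] + runif(1, 0, 0.09), 0.999)
      R2 <- sym_R(5, "2,3" = r_up, "2,4" = r[2], "2,5" = r[3])
      expect_gte(caspa_probability(R2, sit), p0 - 1e-12)
    }
  })
})

test_that("the zero-temperature limit concentrates on the maximum", {
  task <- chain_task(5)
  sit <- make_situation(task, c(1, 2))
  # unique maximum is the correct action 3
  R <- sym_R(5, "2,3" = 0.8, "2,4" = 0.5, "2,5" = 0.3)
  expect_equal(caspa_probability(R, sit, s = 1e-4), 1, tolerance = 1e-9)
  # unique maximum is incorrect
  R <- sym_R(5, "2,3" = 0.5, "2,4" = 0.8, "2,5" = 0.3)
  expect_equal(caspa_probability(R, sit, s = 1e-4), 0, tolerance = 1e-9)
})

test_that("the pre-adjustment softmax variant coincides on default pools", {
  task <- chain_task(6)
  withr::with_seed(67, {
    for (rep in 1:10) {
      R <- diag(6)
      R[upper.tri(R)] <- runif(15, -0.9, 0.9)
      R <- R + t(R) - diag(diag(R)); diag(R) <- 1
      dimnames(R) <- list(1:6, 1:6)
      sit <- make_situation(task, seq_len(sample(1:5, 1)))
      expect_equal(suppressWarnings(caspa_probability(R, sit)),
                   caspa:::caspa_probability_explicit(R, sit))
    }
  })
})

test_that("thresholding utilities behave per the decision conventions", {
  expect_equal(informed_threshold(c(0.2, 0.4)), 0.3)
  expect_equal(informed_threshold(0.7), 0.7)
  expect_error(informed_threshold(numeric(0)), "at least one")
  withr::with_seed(71, {
    v <- runif(80)
    expect_equal(informed_threshold(v), sum(v) / 80, tolerance = 1e-12)
  })

  expect_equal(binarize(0.5, 0.5), 1L)  # boundary counts as competent
  expect_equal(binarize(0.3, 0.5), 0L)
  expect_equal(binarize(0.3, 0.2396), 1L)
  expect_equal(binarize(c(0, 1), 0.5), c(0L, 1L))
})
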