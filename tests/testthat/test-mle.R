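test_that("region-D membership reports exactly the violated inequalities", {
  r1 <- in_region_d(c(0.1, 0.3, 0.2))
  expect_true(r1$in_d)
  expect_length(r1$failed, 0)

  r2 <- in_region_d(b_statistics(counts_face))
  expect_false(r2$in_d)
  expect_identical(r2$failed, "product(B12*B13 < B23)")  # 0.036 > 0.02

  r3 <- in_region_d(b_statistics(counts_curve))
  expect_false(r3$in_d)
  expect_true(all(c("positivity(12)", "positivity(23)") %in% r3$failed))
})

test_that("the interior estimate inverts the pairwise-covariance map", {
  th <- interior_mle(c(0.1, 0.3, 0.2))
  expect_equal(th, c(sqrt(0.1 * 0.3 / 0.2), sqrt(0.1 * 0.2 / 0.3),
                     sqrt(0.3 * 0.2 / 0.1)), tolerance = 1e-12)
  expect_equal(th, c(0.387298, 0.258199, 0.774597), tolerance = 1e-6)
  # round trip: fitted covariances reproduce the data exactly
  expect_equal(c(th[1] * th[2], th[1] * th[3], th[2] * th[3]),
               c(0.1, 0.3, 0.2), tolerance = 1e-12)
  expect_true(all(th > 0 & th < 1))
  expect_error(interior_mle(b_statistics(counts_face)), "outside the interior region")
})

test_that("the solver reproduces both desk-scale boundary examples", {
  fit1 <- cfn_mle(counts_curve)
  expect_identical(fit1$regime, "curve_theta_zero")
  expect_identical(fit1$theta[2], 0)
  prod_row <- fit1$constraints[fit1$constraints$role == "product", ]
  expect_identical(prod_row$coordinate, "theta1*theta3")
  expect_identical(prod_row$value, 0.1)
  expect_equal(fit1$theta[1] * fit1$theta[3], 0.1, tolerance = 1e-12)
  # closed-form value equals both printed forms and the direct evaluation
  expect_equal(fit1$loglik, 55 * log(55 / 400) + 45 * log(45 / 400),
               tolerance = 1e-12)
  expect_equal(fit1$loglik,
               55 * log(1.1) + 45 * log(0.9) - 100 * log(8), tolerance = 1e-12)
  expect_equal(fit1$loglik, cfn_loglik(c(sqrt(0.1), 0, sqrt(0.1)), counts_curve),
               tolerance = 1e-9)

  fit2 <- cfn_mle(counts_face)
  expect_identical(fit2$regime, "face_theta_one")
  expect_identical(fit2$theta, c(1, 0.3, 0.12))
  expect_true(all(fit2$constraints$role == "fixed"))
  # value over the two pairs adjacent to the pinned leaf
  expected <- 65 * log(65 / (sqrt(2) * 100)) + 35 * log(35 / (sqrt(2) * 100)) +
    56 * log(56 / (sqrt(2) * 100)) + 44 * log(44 / (sqrt(2) * 100))
  expect_equal(fit2$loglik, expected, tolerance = 1e-12)
  expect_equal(fit2$loglik, cfn_loglik(c(1, 0.3, 0.12), counts_face),
               tolerance = 1e-9)
})

test_that("the interior regime fires iff B lies in D, with the entropy-form maximum", {
  s <- c(20, 8, 13, 10, 10, 12, 7, 20)  # sbar = (40, 20, 25, 15), B in D
  fit <- cfn_mle(s)
  expect_identical(fit$regime, "interior")
  expect_equal(fit$theta, c(0.387298, 0.258199, 0.774597), tolerance = 1e-6)
  sbar <- c(40, 20, 25, 15)
  expect_equal(fit$loglik, sum(sbar * log(sbar / 100)) - 100 * log(2),
               tolerance = 1e-12)
  expect_equal(fit$loglik, cfn_loglik(fit$theta, s), tolerance = 1e-9)
  expect_true(fit$region$in_d)
})

test_that("the independence regime fires when every pair is negatively correlated", {
  s <- boundary_scenario_counts("independence_union")
  fit <- cfn_mle(s)
  expect_identical(fit$regime, "independence_union")
  expect_identical(fit$theta, c(0, 0, 0))
  expect_equal(fit$loglik, -100 * log(8))
  # every point of the independence set attains the same value
  for (th in list(c(0, 0, 0.7), c(0.3, 0, 0), c(0, 1, 0), c(0, 0, 0))) {
    expect_equal(cfn_loglik(th, s), -100 * log(8), tolerance = 1e-12)
  }
})

test_that("the solver refuses non-generic data unless forced to the numeric fallback", {
  s_tied <- rep(10, 8)
  expect_error(cfn_mle(s_tied), class = "cfn3_genericity_error")
  forced <- cfn_mle(s_tied, force_numeric = TRUE, seed = 5)
  expect_identical(forced$regime, "numeric")
  # uniform data: likelihood is maximized at independence
  expect_equal(forced$loglik, -80 * log(8), tolerance = 1e-6)
})

test_that("sorted-pair bookkeeping matches the permutation labels on both examples", {
  fit1 <- cfn_mle(counts_curve)   # B23 < B12 < B13
  expect_identical(fit1$sorted$pair, c("23", "12", "13"))
  expect_identical(fit1$sorted$permutation, c("(123)", "(1)", "(132)"))
  fit2 <- cfn_mle(counts_face)    # B23 < B13 < B12
  expect_identical(fit2$sorted$pair, c("23", "13", "12"))
  expect_identical(fit2$sorted$permutation, c("(123)", "(132)", "(1)"))
})

test_that("exactly one regime fires for every generic B triple on an exact lattice", {
  # B values that are exact multiples of 1/25 at N = 100 (integer split counts)
  counts_from_sbar <- function(sbar) {
    c(sbar[1] - sbar[1] %/% 2, sbar[4] %/% 2, sbar[3] - sbar[3] %/% 2,
      sbar[2] %/% 2, sbar[2] - sbar[2] %/% 2, sbar[3] %/% 2,
      sbar[4] - sbar[4] %/% 2, sbar[1] %/% 2)
  }
  set.seed(17)
  grid_vals <- seq(-0.92, 0.92, by = 0.04)
  tried <- 0
  regimes_seen <- character(0)
  while (tried < 150) {
    b <- round(sample(grid_vals, 3), 10)
    sbar <- round(25 * (1 + c(sum(b), -b[1] - b[2] + b[3], -b[1] + b[2] - b[3],
                              b[1] - b[2] - b[3])))
    if (any(sbar <= 0)) next
    s <- counts_from_sbar(sbar)
    gen <- check_genericity(s)
    if (!gen$a1_holds || !gen$a2_holds) next
    tried <- tried + 1
    fit <- cfn_mle(s)
    bb <- b_statistics(s)$b
    expect_equal(bb, b, tolerance = 1e-12)   # exact lattice reconstruction
    nb_sorted <- sort(bb)
    expected <- if (in_region_d(b_statistics(s))$in_d) "interior"
      else if (nb_sorted[2] > 0) "face_theta_one"
      else if (nb_sorted[3] > 0) "curve_theta_zero"
      else "independence_union"
    expect_identical(fit$regime, expected)
    regimes_seen <- union(regimes_seen, fit$regime)
  }
  expect_setequal(regimes_seen,
                  c("interior", "face_theta_one", "curve_theta_zero",
                    "independence_union"))
})

test_that("regime log-likelihood ordering follows the comparison lemmas", {
  face_value <- function(b_tbl, n, pairs) {
    sum(vapply(pairs, function(p) {
      r <- b_tbl[b_tbl$pair == p, ]
      r$m_plus * log(r$m_plus / (sqrt(2) * n)) +
        r$m_minus * log(r$m_minus / (sqrt(2) * n))
    }, numeric(1)))
  }
  curve_value <- function(b_tbl, n, p) {
    r <- b_tbl[b_tbl$pair == p, ]
    r$m_plus * log(r$m_plus / (4 * n)) + r$m_minus * log(r$m_minus / (4 * n))
  }
  set.seed(23)
  n_interior <- 0
  for (rep in 1:200) {
    s <- rand_generic_counts(400)
    b_tbl <- b_statistics(s)
    n <- 400
    fit <- cfn_mle(s)
    # independence is never better than the winning regime
    expect_gte(fit$loglik, -n * log(8) - 1e-9)
    if (fit$regime == "interior") {
      n_interior <- n_interior + 1
      # the interior value strictly beats every boundary formula
      for (pin in c("12", "13", "23")) {
        other <- setdiff(c("12", "13", "23"), pin)
        expect_gt(fit$loglik, face_value(b_tbl, n, other))
        expect_gt(fit$loglik, curve_value(b_tbl, n, pin))
      }
      expect_gt(fit$loglik, -n * log(8))
    }
    # one positive correlation always beats full independence (Bmax in (0,1))
    bmax_pair <- b_tbl$pair[which.max(b_tbl$b)]
    if (max(b_tbl$b) > 0 && max(b_tbl$b) < 1) {
      expect_gt(curve_value(b_tbl, n, bmax_pair), -n * log(8))
    }
  }
  expect_gt(n_interior, 0)
})

test_that("tidy, glance, json and autoplot expose the fit coherently", {
  fit <- cfn_mle(counts_curve)
  td <- tidy(fit)
  expect_identical(td$term, paste0("theta", 1:3))
  expect_identical(td$role, c("free", "fixed", "free"))
  expect_identical(td$branch_length[2], Inf)
  gl <- glance(fit)
  expect_identical(gl$regime, "curve_theta_zero")
  expect_identical(gl$nobs, 100L)
  expect_false(gl$interior)
  js <- jsonlite::fromJSON(cfn_mle_json(fit))
  expect_identical(js$regime, "curve_theta_zero")
  expect_identical(js$branch_lengths[[2]], "inf")
  expect_identical(js$B$B13, 0.1)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
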