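test_that("the correlation line reproduces hand-worked examples", {
  la <- linear_agreement(c(1, 2, 3), 2 * c(1, 2, 3) + 1)
  expect_equal(la$m, 2)
  expect_equal(la$q, 1)
  expect_equal(la$r2, 1)

  ident <- linear_agreement(c(10, 20, 30), c(10, 20, 30))
  expect_equal(ident$m, 1)
  expect_equal(ident$q, 0)
  expect_equal(ident$r2, 1)

  # 3-point OLS against the normal-equation oracle
  la3 <- linear_agreement(c(10, 20, 30), c(12, 19, 33))
  o <- ols_oracle(c(10, 20, 30), c(12, 19, 33))
  expect_equal(la3$m, 1.05)
  expect_equal(la3$m, o$m, tolerance = 1e-12)
  expect_equal(la3$q, o$q, tolerance = 1e-12)
  expect_equal(la3$r2, o$r2, tolerance = 1e-12)

  expect_error(linear_agreement(c(5, 5, 5), c(1, 2, 3)), "degenerate")
  expect_error(linear_agreement(1, 2), "insufficient")
})

test_that("Bland-Altman uses gold-minus-device with an n-1 SD", {
  x <- c(3, 7, 11, 2)
  expect_equal(bland_altman(x, x),
               list(ba_mean = 0, ba_sd = 0, ba_loa = c(0, 0)))

  ba <- bland_altman(c(10, 20, 30), c(12, 19, 33))
  expect_equal(ba$ba_mean, -4 / 3)
  expect_equal(ba$ba_sd, 2.081666, tolerance = 1e-6)
  expect_equal(ba$ba_loa, ba$ba_mean + c(-1.96, 1.96) * ba$ba_sd)

  shift <- bland_altman(c(1, 2, 3), c(1, 2, 3) + 5)
  expect_equal(shift$ba_mean, -5)
  expect_equal(shift$ba_sd, 0)
})

test_that("percentage error follows the gold-relative definition", {
  pe <- percentage_error(c(1, 2, 3), c(1, 2, 3))
  expect_equal(pe$pct_error_mean, 0)

  expect_equal(percentage_error(100, 95)$pct_error_mean, 5)

  pe2 <- percentage_error(c(50, 100), c(55, 90))
  expect_equal(pe2$values, c(10, 10))
  expect_equal(pe2$pct_error_mean, 10)
  expect_equal(pe2$pct_error_sd, 0)

  # near-zero gold pairs excluded and counted
  pe3 <- percentage_error(c(0, 100), c(1, 90))
  expect_equal(pe3$n_excluded, 1)
  expect_equal(pe3$pct_error_mean, 10)
  expect_true(is.na(pe3$values[1]))
  expect_error(percentage_error(c(0, 0), c(1, 1)), "excluded")
})

test_that("statistics match brute-force oracles on random arrays", {
  set.seed(20)
  for (i in 1:40) {
    n <- sample(3:30, 1)
    gold <- rnorm(n, 50, 20)
    device <- 0.9 * gold + rnorm(n, 0, 5) + 2
    la <- linear_agreement(gold, device)
    o <- ols_oracle(gold, device)
    expect_equal(la$m, o$m, tolerance = 1e-10)
    expect_equal(la$q, o$q, tolerance = 1e-10)
    expect_equal(la$r2, o$r2, tolerance = 1e-10)
    ba <- bland_altman(gold, device)
    ob <- ba_oracle(gold, device)
    expect_equal(ba, ob, tolerance = 1e-10)
    pe <- percentage_error(gold, device)
    op <- pe_oracle(gold, device)
    expect_equal(pe$pct_error_mean, op$pct_error_mean, tolerance = 1e-10)
    expect_equal(pe$pct_error_sd, op$pct_error_sd, tolerance = 1e-10)
  }
})

test_that("the correlation line is equivariant under positive rescaling", {
  set.seed(2)
  gold <- rnorm(20, 40, 10)
  device <- 1.1 * gold + rnorm(20, 0, 3)
  base <- linear_agreement(gold, device)
  for (c_ in c(0.5, 3, 100)) {
    sc <- linear_agreement(c_ * gold, c_ * device)
    expect_equal(sc$m, base$m, tolerance = 1e-10)
    expect_equal(sc$r2, base$r2, tolerance = 1e-10)
    expect_equal(sc$q, c_ * base$q, tolerance = 1e-8)
  }
})

test_that("the normality gate routes to the right two-sample test", {
  set.seed(8)
  a <- rnorm(10)
  res <- compare_conditions(a, a)
  expect_equal(res$test_used, "t_test")
  expect_false(res$significant)
  expect_equal(res$p_value, 1)

  # 5-sigma separation: overwhelming power
  res2 <- compare_conditions(rnorm(30, 0, 1), rnorm(30, 5, 1))
  expect_true(res2$significant)
  expect_lt(res2$p_value, 1e-6)

  # heavy-tailed sample fails Shapiro-Wilk at n = 50
  set.seed(12)
  ln <- exp(rnorm(50, 0, 1.5))
  expect_lt(shapiro.test(ln)$p.value, 0.05)  # premise of the route
  res3 <- compare_conditions(ln, rnorm(50))
  expect_equal(res3$test_used, "mann_whitney")
  expect_equal(unname(res3$normality_p["a"]), shapiro.test(ln)$p.value)

  expect_error(compare_conditions(c(1, 2), rnorm(10)), "insufficient")
})

test_that("agreement_report bundles the three analyses consistently", {
  set.seed(31)
  gold <- runif(50, 10, 90)
  device <- 0.98 * gold + rnorm(50, 0, 2) + 0.3
  rep_ <- agreement_report(gold, device)
  expect_equal(rep_$m, linear_agreement(gold, device)$m)
  expect_equal(rep_$ba_mean, bland_altman(gold, device)$ba_mean)
  expect_equal(rep_$n, 50)
  expect_true(rep_$r2 >= 0 && rep_$r2 <= 1)
  expect_true(rep_$ba_loa[1] <= rep_$ba_loa[2])
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep_, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$m, rep_$m, tolerance = 1e-12)
})
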