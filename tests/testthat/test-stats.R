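test_that("MAAPE matches worked values and stays bounded", {
  expect_equal(maape_deg(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(maape_deg(1, 2), 45)
  # zero actual with nonzero forecast contributes the 90-degree limit
  expect_equal(maape_deg(c(0), c(5)), 90)
  expect_equal(maape_deg(c(0), c(0)), 0)
  set.seed(1)
  a <- rnorm(50); f <- rnorm(50, sd = 10)
  m <- maape_deg(a, f)
  expect_gte(m, 0); expect_lte(m, 90)
  # invariance under simultaneous sign flip
  expect_equal(maape_deg(-a, -f), m)
  expect_error(maape_deg(numeric(0), numeric(0)), "empty")
  expect_error(maape_deg(1:3, 1:2), "lengths")
})

test_that("windowed R-squared follows the standard definition", {
  months <- c(1, 6, 12, 24, 30, 36, 42, 48)
  a <- c(0.5, 2, 3.5, 5.5, 4, -1, -1.5, -1.2)
  expect_equal(r_squared(a, a, months, "all"), 1)
  # constant forecast away from the mean can go negative
  expect_lt(r_squared(a, rep(10, 8), months, "all"), 0)
  # the four named windows partition the study span as documented
  expect_equal(r_squared(a, a, months, "dmab"), 1)
  expect_error(r_squared(a, a, months, "nope"), "unknown window")
  expect_error(r_squared(a[1], a[1], months[1], c(0, 2)), "2 points")
  # windows select the right points: degrade only month 30 and watch dis
  f <- a; f[5] <- a[5] + 3
  expect_lt(r_squared(a, f, months, "dis"), 1)
  expect_equal(r_squared(a, f, months, "end"), 1)
})


test_that("mixed model recovers planted factorial effects within 2 SE", {
  tab <- simulate_factorial_table(seed = 7)
  fit <- fit_factorial_mixed_model(tab)
  est <- setNames(fit$main_effects$estimate, fit$main_effects$term)
  se <- setNames(fit$main_effects$se, fit$main_effects$term)
  expect_lt(abs(est[["P_A"]] - 2), 2 * se[["P_A"]])
  expect_lt(abs(est[["P_B"]] - 3), 2 * se[["P_B"]])
  expect_lt(abs(est[["P_C"]] - 0), 2 * se[["P_C"]])
  expect_lt(abs(est[["P_D"]] - 0), 2 * se[["P_D"]])
  expect_match(fit$method, "REML")
})

test_that("planted nonzero effects are detected and nulls are not overcalled", {
  tab <- simulate_factorial_table(beta = c(A = 4, B = 0, C = 0, D = 0),
                                  sigma = 0.5, seed = 2)
  fit <- fit_factorial_mixed_model(tab)
  p <- setNames(fit$main_effects$p, fit$main_effects$term)
  expect_lt(p[["P_A"]], 0.01)
  # under the null, p-values are roughly uniform: check no systematic
  # inflation across replicates
  ps <- replicate(20, {
    tabn <- simulate_factorial_table(beta = c(A = 0, B = 0, C = 0, D = 0),
                                     sigma = 1, seed = sample.int(1e6, 1))
    fitn <- suppressMessages(fit_factorial_mixed_model(tabn))
    fitn$main_effects$p[fitn$main_effects$term == "P_A"]
  })
  expect_gt(mean(ps > 0.05), 0.7) # about 95% expected; allow wide slack
})

test_that("missing factorial cells raise a singular-design error", {
  tab <- simulate_factorial_table()
  tab <- tab[!(tab$P_A == 1 & tab$P_B == 1 & tab$P_C == 1 & tab$P_D == 1), ]
  expect_error(fit_factorial_mixed_model(tab), "absent cells")
  expect_error(fit_factorial_mixed_model(
    simulate_factorial_table(n_phantom = 1)), "2 phantoms")
})

test_that("bias of the estimates shrinks as phantoms accumulate", {
  bias_at <- function(n, reps = 6) {
    mean(vapply(seq_len(reps), function(r) {
      tab <- simulate_factorial_table(n_phantom = n, seed = 100 + r)
      fit <- fit_factorial_mixed_model(tab)
      fit$main_effects$estimate[fit$main_effects$term == "P_B"] - 3
    }, numeric(1))^2)
  }
  expect_lt(bias_at(24), bias_at(3) + 0.5) # mse non-increasing within noise
})

test_that("clinical CSV reader validates and sorts", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(month = c(12, 1, 6), mean_pct_change = c(3, 1, 2)),
            tmp, row.names = FALSE)
  cl <- read_clinical_csv(tmp)
  expect_equal(cl$month, c(1, 6, 12))
  write.csv(data.frame(m = 1), tmp, row.names = FALSE)
  expect_error(read_clinical_csv(tmp), "needs columns")
})
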