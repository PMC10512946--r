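test_that("rmse matches hand arithmetic and closed forms", {
  expect_equal(rmse(prediction(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(rmse(prediction(c(1, 2, 3), c(1, 2, 5))), sqrt(4 / 3))
  set.seed(2)
  m <- rnorm(50)
  expect_equal(rmse(prediction(m + 3.2, m)), 3.2)
  expect_error(prediction(1:3, 1:4), "lengths")
})

test_that("pearson has the documented range, affine laws and null level", {
  set.seed(6)
  m <- rnorm(40)
  expect_equal(pearson(prediction(2 * m + 3, m)), 1)
  expect_equal(pearson(prediction(-m, m)), -1)
  expect_error(pearson(prediction(rep(1, 5), rnorm(5))), "zero variance")

  set.seed(123)
  a <- rnorm(10000); b <- rnorm(10000)
  expect_lt(abs(pearson(prediction(a, b))), 0.05)
  # invariance under positive affine transforms of either series
  p0 <- pearson(prediction(a, b))
  expect_equal(pearson(prediction(5 * a + 1, 0.3 * b - 2)), p0)
})

test_that("nrmse divides by the chosen normaliser of the measured series", {
  m <- c(0, 25, 50)
  p <- prediction(m + 5, m)
  expect_equal(nrmse(p), 5 / 50)
  expect_equal(nrmse(prediction(m, m)), 0)
  expect_equal(nrmse(p, "sd"), 5 / sd(m))
  expect_error(nrmse(prediction(c(1, 2), c(3, 3))), "zero")
})

test_that("r squared follows the variance-explained definition", {
  set.seed(9)
  m <- rnorm(30)
  expect_equal(r_squared(prediction(m, m)), 1)
  expect_equal(r_squared(prediction(rep(mean(m), 30), m)), 0)
  expect_lt(r_squared(prediction(m + 10, m)), 0)
})

test_that("metrics agree with brute-force references on random data", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    a <- rnorm(n); b <- rnorm(n)
    p <- prediction(a, b)
    brute_rmse <- { s <- 0; for (k in 1:n) s <- s + (a[k] - b[k])^2
                    sqrt(s / n) }
    expect_lt(abs(rmse(p) - brute_rmse) / max(brute_rmse, 1e-10), 1e-10)
    if (sd(a) > 0 && sd(b) > 0) {
      expect_lt(abs(pearson(p) - cor(a, b)), 1e-10)
      expect_lt(abs(r_squared(p) -
                      (1 - sum((a - b)^2) / sum((b - mean(b))^2))), 1e-10)
      expect_gte(pearson(p), -1)
      expect_lte(pearson(p), 1)
    }
  }
})

test_that("the comparison report reproduces printed-average arithmetic", {
  # per-task cohort averages: with/without quick-training RMSE and PC
  ave <- data.frame(
    task = rep(c("bulb", "screw", "hammer", "cup"), each = 2),
    subject = "ave",
    condition = rep(c("without_quick", "with_quick"), 4),
    rmse = c(43.98, 25.81, 53.64, 17.73, 6.68, 5.23, 7.92, 6.83),
    pc = c(0.53, 0.70, 0.57, 0.72, 0.24, 0.36, 0.31, 0.30))
  rep_ <- build_report(ave)
  expect_equal(rep_$task_summary$rmse_decrease_pct,
               c(41.31, 66.95, 21.71, 13.76), tolerance = 0.01)
  expect_equal(rep_$rmse_decrease_pct_mean, 35.93, tolerance = 0.01)
  expect_gte(rep_$rmse_decrease_pct_mean, 35)
})

test_that("identical conditions give zero percent change and absences drop", {
  same <- data.frame(task = "bulb", subject = rep(c("1", "2"), 2),
                     condition = rep(c("without_quick", "with_quick"),
                                     each = 2),
                     rmse = c(10, 20, 10, 20), pc = c(0.5, 0.7, 0.5, 0.7))
  r <- build_report(same)
  expect_equal(r$task_summary$rmse_decrease_pct, 0)
  expect_equal(r$task_summary$pc_increase_pct, 0)

  missing <- rbind(same,
                   data.frame(task = "bulb", subject = "3",
                              condition = "without_quick", rmse = 100,
                              pc = 0.1))
  rm_ <- build_report(missing)
  expect_equal(rm_$task_summary$rmse_without, mean(c(10, 20, 100)))
  expect_equal(rm_$task_summary$rmse_with, 15)   # subject 3 absent -> excluded

  expect_error(build_report(data.frame()), "non-empty")
})

test_that("report files are written and reproducible", {
  df <- data.frame(task = "cup", subject = c("1", "1"),
                   condition = c("without_quick", "with_quick"),
                   rmse = c(7.92, 6.83), pc = c(0.31, 0.30))
  d <- file.path(tempdir(), "reporttest")
  paths <- write_report(build_report(df), d)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[["summary"]])
  expect_equal(js$rmse_decrease_pct_mean, 100 * (7.92 - 6.83) / 7.92,
               tolerance = 1e-6)
})
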