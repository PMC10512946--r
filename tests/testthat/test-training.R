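test_that("the four-way split reproduces the study partition", {
  plan <- make_split(fake_manifest(24))
  expect_equal(nrow(plan$pretrain), 46L)
  expect_equal(nrow(plan$selection), 2L)
  expect_equal(nrow(plan$quick), 8L)
  expect_equal(nrow(plan$test), 16L)

  key <- function(df) paste(df$subject_id, df$trial)
  groups <- list(key(plan$pretrain), key(plan$selection), key(plan$quick),
                 key(plan$test))
  all_keys <- unlist(groups)
  expect_equal(anyDuplicated(all_keys), 0L)           # pairwise disjoint
  expect_setequal(all_keys, paste(fake_manifest(24)$entries$subject_id,
                                  fake_manifest(24)$entries$trial))

  expect_error(make_split(fake_manifest(10)), "10 subjects")
  boundary <- make_split(fake_manifest(16))
  expect_equal(nrow(boundary$quick), 0L)
  expect_equal(nrow(boundary$test), 0L)
})

test_that("learning-rate schedule halves every decay interval", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(cfg, 5), 1e-3)
  expect_equal(lr_at_epoch(cfg, 10), 5e-4)
  expect_equal(lr_at_epoch(cfg, 25), 2.5e-4)
  expect_error(lr_at_epoch(cfg, -1), "non-negative")
})

test_that("pretraining records the schedule, snapshots and best epoch", {
  set.seed(1)
  n <- 40
  feats <- array(rnorm(n * 20 * 2), c(n, 20, 2))
  labels <- 3 * apply(feats[, , 1], 1, mean) + rnorm(n, sd = 0.01)
  ws <- window_set(feats, labels)
  cfg <- train_config(epochs_pretrain = 12, batch_size = 16, seed = 4)
  fit <- pretrain(tiny_spec(), ws, ws, cfg)
  h <- fit$history$log
  expect_equal(nrow(h), 12L)
  expect_equal(h$lr, lr_at_epoch(cfg, h$epoch - 1L))
  expect_equal(h$lr[1:10], rep(1e-3, 10))
  expect_equal(h$lr[11:12], rep(5e-4, 2))
  expect_s3_class(fit$model, "inception_regressor")

  expect_error(pretrain(tiny_spec(), ws, ws,
                        train_config(epochs_pretrain = 0)), "positive")
})

test_that("training is reproducible under a fixed seed", {
  ws <- random_window_set(30, 20, 2, seed = 8)
  cfg <- train_config(epochs_pretrain = 3, batch_size = 10, seed = 11)
  f1 <- pretrain(tiny_spec(), ws, ws, cfg)
  f2 <- pretrain(tiny_spec(), ws, ws, cfg)
  expect_identical(f1$history$log$loss, f2$history$log$loss)
  expect_identical(predict(f1$model, ws), predict(f2$model, ws))
})

test_that("select_best maximises selection PC with earliest-epoch ties", {
  fake_history <- function(pcs) {
    ws <- random_window_set(4, 10, 1, seed = 2)
    cfg <- train_config(epochs_pretrain = length(pcs), batch_size = 4,
                        seed = 1)
    spec <- regressor_spec(depth = 1, kernel_sizes = c(3, 2, 2),
                           n_filters = 2, bottleneck_size = 2)
    fit <- pretrain(spec, ws, ws, cfg)
    fit$history$log$selection_pc <- pcs
    fit$history
  }
  h <- fake_history(c(0.3, 0.7, 0.5))
  best <- select_best(h)
  expect_identical(best$params, h$snapshots[[2]]$params)

  h2 <- fake_history(c(0.7, 0.7))
  expect_identical(select_best(h2)$params, h2$snapshots[[1]]$params)

  h3 <- fake_history(c(NA_real_, NA_real_))
  expect_error(select_best(h3), "undefined")
})

test_that("quick training adapts a copy and enforces its preconditions", {
  ws <- random_window_set(20, 20, 2, seed = 3)
  cfg <- train_config(epochs_pretrain = 2, epochs_quick = 2,
                      batch_size = 8, seed = 5)
  fit <- pretrain(tiny_spec(), ws, ws, cfg)

  noop_cfg <- cfg
  noop_cfg$epochs_quick <- 0L
  same <- quick_train(fit$model, ws, noop_cfg)
  expect_identical(predict(same, ws), predict(fit$model, ws))

  before <- predict(fit$model, ws)
  adapted <- quick_train(fit$model, ws, cfg)
  expect_false(identical(predict(adapted, ws), before))
  # the input model is left intact
  expect_identical(predict(fit$model, ws), before)

  two_subj <- ws
  two_subj$subject <- rep(c("s01", "s02"), each = 10)
  two_subj$trial <- rep(1L, 20)
  expect_error(quick_train(fit$model, two_subj, cfg), "several subjects")
  two_trials <- ws
  two_trials$subject <- rep("s01", 20)
  two_trials$trial <- rep(1:2, each = 10)
  expect_error(quick_train(fit$model, two_trials, cfg), "several trials")
})
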