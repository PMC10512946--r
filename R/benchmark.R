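# Desk-scale reproduction of the quick-training phenomenon: pre-train on
# a synthetic cohort, confront the model with domain-shifted new
# subjects, and measure how much adapting on a single trial recovers.

#' Run the subject-adaptation benchmark
#'
#' Simulates a cohort in which the first `n_cohort_subjects` subjects
#' (all trials of the first `n_cohort_subjects - 1` plus trial 1 of the
#' last; its trials 2-3 are the model-selection group) pre-train the
#' regressor, and `n_new_subjects` additional subjects with an extra
#' electrode-shift perturbation play the role of new users.  Each new
#' subject is evaluated on trials 2-3, pooled, both with the pre-trained
#' model as-is and after quick training on their first trial.  The whole
#' experiment is repeated for each seed and averaged.
#'
#' The default sizes are a deliberately scaled-down study: short trials
#' (2 movement repetitions), a depth-2 / 16-filter model with reduced
#' kernel lengths, and a coarser window stride than the deployment
#' default, keeping the runtime at desk scale while preserving the
#' pipeline end to end.
#'
#' @param seeds Integer vector; one full experiment per seed.
#' @param n_cohort_subjects Subjects feeding pre-training (incl. the
#'   selection subject).
#' @param n_new_subjects Shifted new subjects.
#' @param shift_severity Domain-shift severity in [0, 1].
#' @param task A [task_profile()].
#' @param spec A [regressor_spec()].
#' @param train_cfg A [train_config()]; its seed is overridden per run.
#' @param quick_batch_size Batch size during quick training (smaller than
#'   pre-training so that a single short trial still yields several
#'   optimisation steps per epoch).
#' @param prep A [preprocess_config()].
#' @return An object of class `adaptation_benchmark`: list with `results`
#'   (per seed/subject/condition metrics) and `summary` (means and the
#'   percent RMSE decrease / PC increase due to quick training).
#' @export
run_adaptation_benchmark <- function(
    seeds = 1:3,
    n_cohort_subjects = 10L,
    n_new_subjects = 4L,
    shift_severity = 0.5,
    task = task_profile("PS", n_repetitions = 2L, rest_duration_s = 0.5),
    spec = regressor_spec(depth = 2L, kernel_sizes = c(16L, 8L, 4L),
                          n_filters = 16L, bottleneck_size = 16L),
    train_cfg = train_config(epochs_pretrain = 30L, epochs_quick = 30L,
                             batch_size = 64L),
    quick_batch_size = 16L,
    prep = preprocess_config(overlap = 50L)) {
  n_total <- n_cohort_subjects + n_new_subjects
  rows <- list()
  for (seed in seeds) {
    cfg <- cohort_config(n_subjects = n_total, task = task,
                         shift_severity = shift_severity,
                         new_subject_start = n_cohort_subjects + 1L,
                         seed = seed)
    drawn <- draw_cohort_profiles(cfg)
    trial_data <- function(s, tr) {
      sim <- simulate_trial(drawn$profiles[[s]], task, cfg,
                            trial_seed = drawn$trial_seeds[s, tr])
      list(env = compute_envelope(sim$emg, prep),
           vel = differentiate(sim$angle), s = s, tr = tr)
    }
    trials <- list()
    for (s in seq_len(n_total))
      for (tr in 1:3)
        trials[[paste(s, tr)]] <- trial_data(s, tr)
    pre_keys <- c(as.vector(outer(seq_len(n_cohort_subjects - 1L), 1:3,
                                  paste)),
                  paste(n_cohort_subjects, 1))
    scaler <- fit_scaler(lapply(trials[pre_keys], `[[`, "env"))
    ws <- lapply(trials, function(tr) {
      env <- apply_scaler(tr$env, scaler)
      lab <- align_labels(tr$vel, env)
      slide_windows(env, lab, prep, subject = tr$s, trial = tr$tr)
    })
    sel_keys <- paste(n_cohort_subjects, 2:3)
    cfg_run <- train_cfg
    cfg_run$seed <- seed
    fit <- pretrain(spec, bind_window_sets(ws[pre_keys]),
                    bind_window_sets(ws[sel_keys]), cfg_run)
    cfg_quick <- cfg_run
    cfg_quick$batch_size <- as.integer(quick_batch_size)
    for (s in (n_cohort_subjects + 1L):n_total) {
      test_ws <- bind_window_sets(ws[paste(s, 2:3)])
      p_wo <- prediction(predict(fit$model, test_ws), test_ws$labels)
      adapted <- quick_train(fit$model, ws[[paste(s, 1)]], cfg_quick)
      p_w <- prediction(predict(adapted, test_ws), test_ws$labels)
      rows[[length(rows) + 1L]] <- cbind(
        seed = seed,
        rbind(evaluate_prediction(p_wo, subject = s, "without_quick",
                                  task = cfg$task_name),
              evaluate_prediction(p_w, subject = s, "with_quick",
                                  task = cfg$task_name)))
    }
  }
  results <- do.call(rbind, rows)
  agg <- function(cond, col)
    mean(results[results$condition == cond, col], na.rm = TRUE)
  rmse_wo <- agg("without_quick", "rmse")
  rmse_w <- agg("with_quick", "rmse")
  pc_wo <- agg("without_quick", "pc")
  pc_w <- agg("with_quick", "pc")
  structure(list(
    results = results,
    summary = list(
      rmse_without = rmse_wo, rmse_with = rmse_w,
      rmse_decrease_pct = 100 * (rmse_wo - rmse_w) / rmse_wo,
      pc_without = pc_wo, pc_with = pc_w,
      pc_increase_pct = 100 * (pc_w - pc_wo) / abs(pc_wo),
      n_seeds = length(seeds))),
    class = "adaptation_benchmark")
}

#' @export
print.adaptation_benchmark <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<adaptation_benchmark> %d seed(s)\n",
           "  RMSE without quick training: %6.2f deg/s\n",
           "  RMSE with quick training:    %6.2f deg/s  (%.1f%% decrease)\n",
           "  PC   without quick training: %6.3f\n",
           "  PC   with quick training:    %6.3f\n"),
    s$n_seeds, s$rmse_without, s$rmse_with, s$rmse_decrease_pct,
    s$pc_without, s$pc_with))
  invisible(x)
}
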