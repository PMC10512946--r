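# The four-way data split, pre-training with step learning-rate decay,
# model selection by Pearson correlation, and the quick-training
# subject-adaptation protocol.
#
# Split convention (one task): all trials of the first `n_pretrain_subjects`
# plus trial 1 of the selection subject form the pre-training group; the
# selection subject's trials 2-3 form the model-selection group; every
# later subject is "new": trial 1 is quick-training material, trials 2-3
# are test material.

#' Training configuration
#'
#' @param epochs_pretrain Pre-training epochs (>= 1).
#' @param epochs_quick Quick-training epochs (>= 0; 0 returns the model
#'   unchanged).
#' @param lr_initial Initial Adam learning rate (default 1e-3).
#' @param lr_decay_factor Multiplicative decay, default 0.5 (halving).
#' @param lr_decay_every Decay interval in epochs, default 10.
#' @param batch_size Windows per optimisation step.
#' @param seed Seed controlling weight initialisation and shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs_pretrain = 30L, epochs_quick = 30L,
                         lr_initial = 1e-3, lr_decay_factor = 0.5,
                         lr_decay_every = 10L, batch_size = 64L,
                         seed = 1L) {
  assert_scalar_num(epochs_pretrain, "epochs_pretrain")
  if (!is.numeric(epochs_quick) || length(epochs_quick) != 1L ||
      epochs_quick < 0)
    wv_stop("epochs_quick must be a non-negative integer")
  assert_scalar_num(lr_initial, "lr_initial")
  if (!is.numeric(lr_decay_factor) || lr_decay_factor <= 0 ||
      lr_decay_factor >= 1)
    wv_stop("lr_decay_factor must lie in (0, 1)")
  assert_scalar_num(lr_decay_every, "lr_decay_every")
  assert_scalar_num(batch_size, "batch_size")
  structure(list(epochs_pretrain = as.integer(epochs_pretrain),
                 epochs_quick = as.integer(epochs_quick),
                 lr_initial = lr_initial,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a (zero-based) epoch
#'
#' `lr_initial * lr_decay_factor ^ floor(epoch / lr_decay_every)`: with
#' the defaults the rate is 1e-3 for epochs 0-9, 5e-4 for 10-19, 2.5e-4
#' for 20-29, and so on.
#'
#' @param cfg A [train_config()].
#' @param epoch Zero-based epoch index.
#' @return The learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  stopifnot(inherits(cfg, "train_config"))
  if (any(epoch < 0)) wv_stop("epoch must be non-negative")
  cfg$lr_initial * cfg$lr_decay_factor^(epoch %/% cfg$lr_decay_every)
}

#' Partition a session manifest into the four training groups
#'
#' @param manifest A [session_manifest()] for a single task.
#' @param n_pretrain_subjects Subjects fully assigned to pre-training
#'   (study protocol: 15).
#' @param selection_subject_index 1-based index of the subject whose
#'   first trial joins pre-training and whose remaining trials form the
#'   model-selection group (study protocol: 16).
#' @return An object of class `split_plan` with data-frame fields
#'   `pretrain`, `selection`, `quick`, `test` (columns `subject_id`,
#'   `trial`).
#' @export
make_split <- function(manifest, n_pretrain_subjects = 15L,
                       selection_subject_index = 16L) {
  stopifnot(inherits(manifest, "session_manifest"))
  entries <- manifest$entries
  if (length(unique(entries$task)) > 1L)
    wv_stop("make_split expects a single-task manifest; got: ",
            paste(unique(entries$task), collapse = ", "))
  subjects <- unique(entries$subject_id)
  if (length(subjects) < selection_subject_index)
    wv_stop("manifest has ", length(subjects), " subjects but ",
            selection_subject_index, " are required")
  trials_per <- table(entries$subject_id)
  if (any(trials_per[subjects[seq_len(selection_subject_index)]] < 3L))
    wv_stop("each of the first ", selection_subject_index,
            " subjects needs 3 trials")
  pick <- function(subj, trials) {
    rows <- entries[entries$subject_id %in% subj & entries$trial %in% trials,
                    c("subject_id", "trial")]
    rownames(rows) <- NULL
    rows
  }
  pre_subj <- subjects[seq_len(n_pretrain_subjects)]
  sel_subj <- subjects[selection_subject_index]
  new_subj <- if (length(subjects) > selection_subject_index)
    subjects[(selection_subject_index + 1L):length(subjects)]
  else character(0)
  plan <- structure(list(
    pretrain = rbind(pick(pre_subj, 1:3), pick(sel_subj, 1L)),
    selection = pick(sel_subj, 2:3),
    quick = pick(new_subj, 1L),
    test = pick(new_subj, 2:3),
    selection_subject = sel_subj,
    new_subjects = new_subj,
    task = entries$task[1L]), class = "split_plan")
  if (length(new_subj) == 0L)
    wv_log("make_split: no new subjects left; quick and test groups empty",
           level = "WARN")
  plan
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf(
    "<split_plan> task %s: pretrain %d, selection %d, quick %d, test %d trials\n",
    x$task, nrow(x$pretrain), nrow(x$selection), nrow(x$quick),
    nrow(x$test)))
  invisible(x)
}

# One optimisation pass over a window set; mutates and returns the model
# plus epoch-mean loss.  `lr` is fixed within the epoch.
run_epoch <- function(model, X_all, labels, n_win_total, win_len,
                      batch_size, lr, adam_state) {
  order <- sample.int(n_win_total)
  losses <- numeric(0)
  for (start in seq(1L, n_win_total, by = batch_size)) {
    idx <- order[start:min(start + batch_size - 1L, n_win_total)]
    rows <- as.vector(outer(seq_len(win_len), (idx - 1L) * win_len, `+`))
    X <- X_all[rows, , drop = FALSE]
    lg <- nn_loss_grad(model, X, labels[idx], length(idx))
    if (!is.finite(lg$loss))
      wv_stop("training diverged: non-finite loss (lr = ", lr,
              ", batch of ", length(idx), " windows)")
    model$bn_state <- lg$bn_state
    upd <- adam_step(model$params, lg$grads, adam_state, lr)
    model$params <- upd$params
    adam_state <- upd$state
    losses <- c(losses, lg$loss)
  }
  list(model = model, adam_state = adam_state, loss = mean(losses))
}

#' Pre-train a regressor on the cohort and select the best epoch
#'
#' Trains for `epochs_pretrain` epochs with the mean-squared-error
#' objective and Adam under the step-decay schedule, evaluating Pearson
#' correlation on the model-selection windows after every epoch and
#' snapshotting the parameters.  The returned model is the snapshot with
#' the highest selection correlation (ties: earliest epoch).
#'
#' @param spec A [regressor_spec()].
#' @param pretrain_windows,selection_windows [window_set()]s normalised
#'   with the pre-training scaler.
#' @param cfg A [train_config()].
#' @return List with `model` (best snapshot) and `history`
#'   (a `training_history`).
#' @export
pretrain <- function(spec, pretrain_windows, selection_windows, cfg) {
  stopifnot(inherits(spec, "regressor_spec"),
            inherits(cfg, "train_config"))
  if (n_windows(pretrain_windows) == 0L)
    wv_stop("pretrain: empty pre-training window set")
  if (n_windows(selection_windows) == 0L)
    wv_stop("pretrain: empty selection window set")
  if (cfg$epochs_pretrain < 1L)
    wv_stop("pretrain: epochs_pretrain must be >= 1")
  d <- dim(pretrain_windows$features)
  history <- with_seed(cfg$seed, {
    model <- build_regressor(spec, input_len = d[2], n_channels = d[3])
    # standardise the regression target on the pre-training labels only;
    # the transform is stored on the model and inverted by predict()
    model$label_center <- mean(pretrain_windows$labels)
    sdev <- stats::sd(pretrain_windows$labels)
    model$label_scale <- if (is.finite(sdev) && sdev > 0) sdev else 1
    labels_std <- (pretrain_windows$labels - model$label_center) /
      model$label_scale
    X_all <- windows_to_matrix(pretrain_windows$features)
    adam_state <- adam_init(model$params)
    records <- vector("list", cfg$epochs_pretrain)
    snapshots <- vector("list", cfg$epochs_pretrain)
    for (ep in seq_len(cfg$epochs_pretrain)) {
      lr <- lr_at_epoch(cfg, ep - 1L)
      res <- run_epoch(model, X_all, labels_std, d[1], d[2],
                       cfg$batch_size, lr, adam_state)
      model <- res$model
      adam_state <- res$adam_state
      pc <- tryCatch(
        pearson(prediction(predict(model, selection_windows),
                           selection_windows$labels)),
        error = function(e) NA_real_)
      records[[ep]] <- data.frame(epoch = ep, loss = res$loss,
                                  selection_pc = pc, lr = lr)
      snapshots[[ep]] <- list(params = model$params,
                              bn_state = model$bn_state)
      wv_log(sprintf("pretrain epoch %d: loss %.4f, selection PC %.4f, lr %g",
                     ep, res$loss, pc, lr))
    }
    structure(list(log = do.call(rbind, records), snapshots = snapshots,
                   template = model), class = "training_history")
  })
  list(model = select_best(history), history = history)
}

#' @export
print.training_history <- function(x, ...) {
  cat(sprintf("<training_history> %d epochs, best selection PC %.4f\n",
              nrow(x$log), suppressWarnings(max(x$log$selection_pc,
                                                na.rm = TRUE))))
  invisible(x)
}

#' Pick the snapshot with the best selection-set Pearson correlation
#'
#' @param history A `training_history` from [pretrain()].
#' @return The selected `inception_regressor`.
#' @export
select_best <- function(history) {
  stopifnot(inherits(history, "training_history"))
  pc <- history$log$selection_pc
  if (!length(pc)) wv_stop("select_best: empty history")
  if (all(is.na(pc)))
    wv_stop("select_best: selection correlation undefined at every epoch")
  best <- which.max(pc)  # ties resolved to the earliest epoch
  model <- history$template
  model$params <- history$snapshots[[best]]$params
  model$bn_state <- history$snapshots[[best]]$bn_state
  model
}

#' Adapt a pre-trained model to a new subject (quick training)
#'
#' Continues optimisation of all parameters (no freezing) on a single
#' trial of the new subject, with a fresh Adam optimiser and a decay
#' schedule restarted at `lr_initial`.  The input model is not modified.
#'
#' @param model A pre-trained `inception_regressor`.
#' @param quick_windows A [window_set()] from exactly one trial of one
#'   subject, normalised with the pre-training scaler.
#' @param cfg A [train_config()]; `epochs_quick` epochs are run.
#' @return The adapted `inception_regressor`.
#' @export
quick_train <- function(model, quick_windows, cfg) {
  stopifnot(inherits(model, "inception_regressor"),
            inherits(cfg, "train_config"))
  if (n_windows(quick_windows) == 0L)
    wv_stop("quick_train: empty quick-training window set")
  if (!is.null(quick_windows$subject) &&
      length(unique(quick_windows$subject)) > 1L)
    wv_stop("quick_train: windows span several subjects (",
            paste(unique(quick_windows$subject), collapse = ", "),
            "); adaptation uses one subject's single trial")
  if (!is.null(quick_windows$trial) &&
      length(unique(quick_windows$trial)) > 1L)
    wv_stop("quick_train: windows span several trials; adaptation uses ",
            "a single trial")
  if (cfg$epochs_quick == 0L) return(model)
  d <- dim(quick_windows$features)
  with_seed(cfg$seed, {
    adapted <- model
    # reuse the pre-training label transform (frozen scaler discipline)
    labels_std <- (quick_windows$labels - model$label_center) /
      model$label_scale
    X_all <- windows_to_matrix(quick_windows$features)
    adam_state <- adam_init(adapted$params)
    for (ep in seq_len(cfg$epochs_quick)) {
      lr <- lr_at_epoch(cfg, ep - 1L)
      res <- run_epoch(adapted, X_all, labels_std, d[1], d[2],
                       cfg$batch_size, lr, adam_state)
      adapted <- res$model
      adam_state <- res$adam_state
      wv_log(sprintf("quick_train epoch %d: loss %.4f, lr %g",
                     ep, res$loss, lr))
    }
    adapted
  })
}
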