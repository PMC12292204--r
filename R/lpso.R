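#' Cross-validation configuration
#'
#' The leave-p%-subjects-out protocol: `n_iterations` independent
#' iterations, each driven by one seed from the inclusive range
#' `seed_start..seed_end` (42..141 by default, 100 seeds).  Each iteration
#' holds out a stratified `heldout_fraction` of the subjects of each
#' training group for validation, trains on the rest, and afterwards
#' scores the entire held-out test group (the dual-risk carriers) with
#' the trained model.
#'
#' @param n_iterations number of CV iterations.
#' @param seed_start,seed_end inclusive seed range;
#'   `seed_end - seed_start + 1` must equal `n_iterations`.
#' @param heldout_fraction p, fraction of each training group's subjects
#'   held out for validation (0 < p < 1).
#' @param training_groups the two groups used for training/validation;
#'   the second is the positive (risk) class.
#' @param test_group the group scored post hoc after each iteration.
#' @param task_filter `"ALL"` (pool both tasks) or a task name.
#' @return List of class `cv_config`.
#' @export
cv_config <- function(n_iterations = 100L, seed_start = 42L,
                      seed_end = 141L, heldout_fraction = 0.20,
                      training_groups = c("N", "A+P-"),
                      test_group = "A+P+", task_filter = "ALL") {
  if (seed_end - seed_start + 1L != n_iterations) {
    stop("seed range must contain exactly `n_iterations` seeds", call. = FALSE)
  }
  stopifnot(heldout_fraction > 0, heldout_fraction < 1,
            length(training_groups) == 2L)
  out <- list(n_iterations = as.integer(n_iterations),
              seed_start = as.integer(seed_start),
              seed_end = as.integer(seed_end),
              heldout_fraction = heldout_fraction,
              training_groups = training_groups,
              test_group = test_group,
              task_filter = task_filter)
  class(out) <- "cv_config"
  out
}

#' Seeds enumerated by a CV configuration
#'
#' @param config a [cv_config()].
#' @return Integer vector `seed_start..seed_end`.
#' @export
cv_seeds <- function(config = cv_config()) {
  seq.int(config$seed_start, config$seed_end)
}

#' Subject-level stratified split
#'
#' Randomly holds out `round(p * group size)` subjects (at least one) of
#' each training group for validation; the remainder train.  Subjects,
#' never trials, are split, so no individual contributes trials to both
#' sides.
#'
#' @param cohort an `eeg_cohort`.
#' @param p held-out fraction (0 < p < 1).
#' @param seed integer seed; the split is deterministic given it.
#' @param training_groups groups to split.
#' @return List of class `lpso_split` with `train_subjects` and
#'   `val_subjects`.
#' @export
split_subjects <- function(cohort, p = 0.2, seed = 42L,
                           training_groups = c("N", "A+P-")) {
  stopifnot(p > 0, p < 1)
  meta <- cohort$subjects %||% unique(cohort$meta[, c("subject", "group")])
  val <- character(0)
  train <- character(0)
  for (g in training_groups) {
    subs <- sort(meta$subject[meta$group == g])
    if (length(subs) < 2L) {
      stop(sprintf("group %s has fewer than 2 subjects", g), call. = FALSE)
    }
    k <- max(1L, round(p * length(subs)))
    if (k >= length(subs)) {
      stop(sprintf("held-out fraction leaves no training subjects in group %s", g),
           call. = FALSE)
    }
    sel <- with_seed(derive_seed(seed, match(g, training_groups)),
                     sample(subs, k))
    val <- c(val, sel)
    train <- c(train, setdiff(subs, sel))
  }
  out <- list(train_subjects = train, val_subjects = val)
  class(out) <- "lpso_split"
  out
}

#' Run the leave-p%-subjects-out cross-validation
#'
#' For every seed of the configuration: split the training-group subjects,
#' fit an [eegcnn()] on the training subjects' trials, compute validation
#' ROC AUC, Cohen's kappa and sensitivity (positive class = risk
#' carriers) on the held-out subjects' trials, then score all test-group
#' trials with the same trained model and record the test sensitivity.
#' The per-iteration seed drives three derived sub-seeds (split, weight
#' initialization, batch shuffling).  An iteration whose validation set
#' contains a single class is flagged invalid, recorded, and excluded
#' from summaries.
#'
#' @param cohort an `eeg_cohort` containing both training groups.
#' @param model_cfg an [model_config()]; inferred from the cohort if
#'   `NULL`.
#' @param control a [train_control()].
#' @param config a [cv_config()].
#' @param keep_models keep each fold's fitted model (memory permitting).
#' @return Object of class `lpso_cv`: list with `folds` (one row per
#'   seed: metrics, trial counts, epochs, `valid`), `config`, optionally
#'   `models`.
#' @export
run_lpso_cv <- function(cohort, model_cfg = NULL, control = train_control(),
                        config = cv_config(), keep_models = FALSE) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  groups_present <- unique(cohort$meta$group)
  for (g in config$training_groups) {
    if (!g %in% groups_present) {
      stop(sprintf("cohort is missing training group %s", g), call. = FALSE)
    }
  }
  if (is.null(model_cfg)) {
    model_cfg <- model_config(n_channels = cohort$spec$n_channels,
                              n_samples = cohort$spec$n_samples)
  }
  neg <- config$training_groups[1]
  pos <- config$training_groups[2]
  seeds <- cv_seeds(config)
  rows <- vector("list", length(seeds))
  models <- if (keep_models) vector("list", length(seeds)) else NULL

  for (i in seq_along(seeds)) {
    s <- seeds[i]
    split <- split_subjects(cohort, config$heldout_fraction,
                            seed = derive_seed(s, 1L),
                            training_groups = config$training_groups)
    tr_idx <- cohort_trials(cohort, groups = config$training_groups,
                            tasks = config$task_filter,
                            subjects = split$train_subjects)
    va_idx <- cohort_trials(cohort, groups = config$training_groups,
                            tasks = config$task_filter,
                            subjects = split$val_subjects)
    row <- data.frame(seed = s, condition = config$task_filter,
                      val_auc = NA_real_, val_kappa = NA_real_,
                      val_sensitivity = NA_real_,
                      test_sensitivity = NA_real_,
                      n_train_trials = length(tr_idx),
                      n_val_trials = length(va_idx),
                      best_epoch = NA_integer_, stop_epoch = NA_integer_,
                      valid = FALSE)
    ytr <- factor(cohort$meta$group[tr_idx], levels = c(neg, pos))
    yva <- factor(cohort$meta$group[va_idx], levels = c(neg, pos))
    if (length(unique(ytr)) == 2L && length(unique(yva)) == 2L &&
        length(va_idx) > 0L) {
      fit <- eegcnn(cohort$epochs[, , tr_idx, drop = FALSE], ytr,
                    cohort$epochs[, , va_idx, drop = FALSE], yva,
                    config = model_cfg, control = control,
                    seed = derive_seed(s, 2L))
      pr <- predict(fit, cohort$epochs[, , va_idx, drop = FALSE])
      cls <- predict(fit, cohort$epochs[, , va_idx, drop = FALSE],
                     type = "class")
      row$val_auc <- roc_auc(pr[, pos], yva)
      row$val_kappa <- cohen_kappa(cls, yva)
      row$val_sensitivity <- sensitivity(cls, yva, positive = pos)
      if (config$test_group %in% groups_present) {
        row$test_sensitivity <- evaluate_heldout_group(
          fit, cohort, group = config$test_group,
          task_filter = config$task_filter)
      }
      row$best_epoch <- fit$best_epoch
      row$stop_epoch <- fit$stop_epoch
      row$valid <- TRUE
      if (keep_models) models[[i]] <- fit
    } else {
      warning(sprintf("seed %d: single-class split; fold flagged invalid", s))
    }
    rows[[i]] <- row
  }

  out <- list(folds = do.call(rbind, rows), config = config,
              models = models)
  class(out) <- "lpso_cv"
  out
}

#' Score the held-out group with a trained model
#'
#' Fraction of the group's trials the model assigns to the positive
#' (risk) class -- the group's sensitivity under the convention that all
#' of its members carry risk.
#'
#' @param fit a fitted [eegcnn()] model whose second level is the risk
#'   class.
#' @param cohort an `eeg_cohort`.
#' @param group group label to score.
#' @param task_filter `"ALL"` or a task name.
#' @return Sensitivity in \[0, 1\].
#' @export
evaluate_heldout_group <- function(fit, cohort, group = "A+P+",
                                   task_filter = "ALL") {
  idx <- cohort_trials(cohort, groups = group, tasks = task_filter)
  if (!length(idx)) {
    stop(sprintf("no trials for group %s", group), call. = FALSE)
  }
  cls <- predict(fit, cohort$epochs[, , idx, drop = FALSE], type = "class")
  mean(cls == fit$levels[2])
}

#' Aggregate fold results
#'
#' Mean and sample SD (n - 1 denominator; 0 for a single fold) of every
#' metric, grouped by task condition, over the valid folds only.
#'
#' @param results an `lpso_cv` object or its `folds` data frame (rows of
#'   several runs/conditions may be concatenated).
#' @return Data frame of class `lpso_summary`: one row per condition x
#'   metric with `mean`, `sd`, `n_folds`.
#' @export
summarize_folds <- function(results) {
  folds <- if (inherits(results, "lpso_cv")) results$folds else results
  folds <- folds[folds$valid, , drop = FALSE]
  if (!nrow(folds)) stop("no valid folds to summarize", call. = FALSE)
  metrics <- c("val_auc", "val_kappa", "val_sensitivity", "test_sensitivity")
  rows <- list()
  for (cond in unique(folds$condition)) {
    sub <- folds[folds$condition == cond, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]]
      v <- v[!is.na(v)]
      if (!length(v)) next
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, metric = m, mean = mean(v),
        sd = if (length(v) > 1L) stats::sd(v) else 0,
        n_folds = length(v), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("lpso_summary", "data.frame")
  out
}

#' @export
print.lpso_cv <- function(x, ...) {
  nv <- sum(x$folds$valid)
  cat(sprintf("<lpso_cv> %d iterations (%d valid), seeds %d..%d, condition %s\n",
              nrow(x$folds), nv, x$config$seed_start, x$config$seed_end,
              x$config$task_filter))
  if (nv) print(summary(x))
  invisible(x)
}

#' @export
summary.lpso_cv <- function(object, ...) summarize_folds(object)

#' @export
print.lpso_summary <- function(x, ...) {
  labels <- c(val_auc = "Validation ROC AUC",
              val_kappa = "Validation Kappa",
              val_sensitivity = "Validation sensitivity",
              test_sensitivity = "Test sensitivity")
  for (cond in unique(x$condition)) {
    cat(sprintf("Condition %s:\n", cond))
    sub <- x[x$condition == cond, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("  %-24s %.4f ± %.4f  (%d folds)\n",
                  labels[[sub$metric[i]]], sub$mean[i], sub$sd[i],
                  sub$n_folds[i]))
    }
  }
  invisible(x)
}

#' Write fold results as CSV
#'
#' @param results an `lpso_cv` object.
#' @param path output CSV path.
#' @export
write_fold_results <- function(results, path) {
  stopifnot(inherits(results, "lpso_cv"))
  utils::write.csv(results$folds, path, row.names = FALSE)
  invisible(path)
}
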