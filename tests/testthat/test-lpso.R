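test_that("the CV configuration enumerates its seed range exactly", {
  cfg <- cv_config()
  expect_equal(cv_seeds(cfg), 42:141)
  expect_equal(length(cv_seeds(cfg)), 100L)
  expect_error(cv_config(n_iterations = 99), "exactly")
  expect_error(cv_config(heldout_fraction = 0))
})

test_that("subject splits are stratified, disjoint, complete, and seeded", {
  co <- subjects_only_cohort(8L, 8L)
  all_subj <- co$subjects$subject
  for (s in 1:200) {
    sp <- split_subjects(co, p = 0.2, seed = s)
    expect_length(intersect(sp$train_subjects, sp$val_subjects), 0)
    expect_setequal(c(sp$train_subjects, sp$val_subjects), all_subj)
    # stratification: round(0.2 * 8) = 2 per group
    expect_equal(sum(startsWith(sp$val_subjects, "A")), 2L)
    expect_equal(sum(startsWith(sp$val_subjects, "B")), 2L)
  }
  expect_identical(split_subjects(co, 0.2, seed = 7L),
                   split_subjects(co, 0.2, seed = 7L))
  expect_false(identical(split_subjects(co, 0.2, seed = 7L),
                         split_subjects(co, 0.2, seed = 8L)))
})

test_that("split edge cases follow the specification", {
  co4 <- subjects_only_cohort(4L, 4L)
  sp <- split_subjects(co4, p = 0.5, seed = 1L)
  expect_equal(sum(startsWith(sp$val_subjects, "A")), 2L)
  expect_equal(sum(startsWith(sp$val_subjects, "B")), 2L)
  co2 <- subjects_only_cohort(2L, 2L)
  # minimum of one held-out subject even when p * n rounds to zero
  sp2 <- split_subjects(co2, p = 0.1, seed = 1L)
  expect_equal(length(sp2$val_subjects), 2L)
  expect_error(split_subjects(co2, p = 0.9, seed = 1L), "no training subjects")
  co1 <- subjects_only_cohort(1L, 4L)
  expect_error(split_subjects(co1, p = 0.2, seed = 1L), "fewer than 2")
})

test_that("a small CV run produces in-range per-fold metrics and clean bookkeeping", {
  cs <- cohort_spec(scale = 0.006, master_seed = 11L)
  co <- generate_cohort(cs)
  cv <- run_lpso_cv(co,
                    control = train_control(max_epochs = 6L, patience = 3L),
                    config = cv_config(n_iterations = 2L, seed_start = 42L,
                                       seed_end = 43L))
  f <- cv$folds
  expect_equal(nrow(f), 2L)
  expect_equal(f$seed, c(42L, 43L))
  expect_true(all(f$valid))
  expect_true(all(f$val_auc >= 0 & f$val_auc <= 1))
  expect_true(all(f$val_kappa >= -1 & f$val_kappa <= 1))
  expect_true(all(f$val_sensitivity >= 0 & f$val_sensitivity <= 1))
  expect_true(all(f$test_sensitivity >= 0 & f$test_sensitivity <= 1))
  n_train_pool <- length(cohort_trials(co, groups = c("N", "A+P-")))
  expect_equal(f$n_train_trials + f$n_val_trials, rep(n_train_pool, 2L))
  # the engine refuses a cohort missing a training group
  co_sub <- co
  keep <- co$meta$group != "A+P-"
  co_sub$meta <- co$meta[keep, ]
  co_sub$epochs <- co$epochs[, , keep, drop = FALSE]
  co_sub$subjects <- co$subjects[co$subjects$group != "A+P-", ]
  expect_error(run_lpso_cv(co_sub), "A\\+P-")
})

test_that("task-condition filtering restricts the trials used", {
  cs <- cohort_spec(scale = 0.006, master_seed = 11L)
  co <- generate_cohort(cs)
  idx_stmt <- cohort_trials(co, groups = c("N", "A+P-"), tasks = "STMT")
  cv <- run_lpso_cv(co,
                    control = train_control(max_epochs = 3L, patience = 2L),
                    config = cv_config(n_iterations = 1L, seed_start = 42L,
                                       seed_end = 42L, task_filter = "STMT"))
  expect_equal(cv$folds$n_train_trials + cv$folds$n_val_trials,
               length(idx_stmt))
  expect_equal(cv$folds$condition, "STMT")
})

test_that("fold summaries aggregate with mean and sample SD", {
  folds <- data.frame(
    seed = 1:2, condition = "ALL",
    val_auc = c(0.6, 0.8), val_kappa = c(0.1, 0.3),
    val_sensitivity = c(0.5, 0.7), test_sensitivity = c(0.4, 0.6),
    valid = TRUE)
  sm <- summarize_folds(folds)
  expect_equal(sm$mean[sm$metric == "val_auc"], 0.7)
  expect_equal(sm$sd[sm$metric == "val_auc"], stats::sd(c(0.6, 0.8)))
  expect_true(all(sm$n_folds == 2L))
  # single fold: SD guarded to zero
  sm1 <- summarize_folds(folds[1, ])
  expect_equal(sm1$sd, rep(0, 4))
  # invalid folds are excluded, never silently averaged
  folds$valid[2] <- FALSE
  sm2 <- summarize_folds(folds)
  expect_equal(sm2$mean[sm2$metric == "val_auc"], 0.6)
  folds$valid <- FALSE
  expect_error(summarize_folds(folds), "no valid folds")
})

test_that("summaries equal an independent recomputation from the results CSV", {
  cs <- cohort_spec(scale = 0.006, master_seed = 11L)
  co <- generate_cohort(cs)
  cv <- run_lpso_cv(co,
                    control = train_control(max_epochs = 4L, patience = 2L),
                    config = cv_config(n_iterations = 2L, seed_start = 42L,
                                       seed_end = 43L))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_fold_results(cv, path)
  back <- utils::read.csv(path)
  sm <- summarize_folds(cv)
  expect_equal(sm$mean[sm$metric == "val_auc"], mean(back$val_auc),
               tolerance = 1e-12)
  expect_equal(sm$sd[sm$metric == "test_sensitivity"],
               stats::sd(back$test_sensitivity), tolerance = 1e-12)
})

test_that("held-out group scoring saturates and errors correctly", {
  cs <- cohort_spec(scale = 0.006, master_seed = 11L)
  co <- generate_cohort(cs)
  tf <- toy_fit()   # any fitted model with matching dims will not fit here
  expect_error(evaluate_heldout_group(tf$fit, co, group = "missing"),
               "no trials")
})
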