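test_that("epoch geometry enforces the sample-count invariant", {
  sp <- epoch_spec()
  expect_equal(sp$n_samples, 320L)
  expect_equal(sp$fs, 250)
  expect_equal((sp$t_end - sp$t_start) / 1000 * sp$fs, sp$n_samples)
  expect_error(epoch_spec(fs = 250, t_start = 0, t_end = 1001),
               "whole number of samples")
})

test_that("1/f background is reproducible, scalable, and has the right slope", {
  sp <- epoch_spec()
  expect_equal(generate_background(sp, scale = 0), matrix(0, 60, 320))
  b1 <- generate_background(sp, seed = 3L)
  b2 <- generate_background(sp, seed = 3L)
  expect_identical(b1, b2)
  expect_false(identical(b1, generate_background(sp, seed = 4L)))
  expect_lt(max(abs(rowMeans(b1))), 1e-8)

  # log-log periodogram slope close to -exponent, averaged over seeds
  long <- epoch_spec(fs = 256, t_start = 0, t_end = 8000, n_channels = 2L)
  slopes <- sapply(1:30, function(s) {
    x <- generate_background(long, exponent = 1, scale = 1, seed = s)
    pg <- eegsep:::periodogram(x, long$fs)
    keep <- pg$freq >= 1 & pg$freq <= 100
    mean(apply(log(pg$power[keep, , drop = FALSE]), 2, function(p) {
      stats::coef(stats::lm(p ~ log(pg$freq[keep])))[2]
    }))
  })
  expect_lt(abs(mean(slopes) + 1), 0.3)
})

test_that("planted band signatures add the expected in-band power", {
  sp <- epoch_spec()
  m <- build_montage(60)
  zero <- matrix(0, 60, 320)
  sig0 <- band_signature("alpha", "parietal", amplitude = 0)
  expect_identical(plant_band_signature(zero, sig0, m, seed = 1), zero)

  # amplitude A sinusoid -> in-band power ~ A^2 / 2 on target channels only
  A <- 2
  sig <- band_signature("alpha", "parietal", amplitude = A)
  ep <- plant_band_signature(zero, sig, m, seed = 11, spec = sp)
  pow <- band_power(ep, "alpha", sp)
  tgt <- m$region == "parietal"
  expect_equal(mean(pow[tgt]), A^2 / 2, tolerance = 0.1)
  expect_equal(pow[!tgt], rep(0, sum(!tgt)), tolerance = 1e-12)

  expect_error(plant_band_signature(zero, band_signature("theta", "parietal", 1),
                                    build_montage(1), seed = 1),
               "no montage channels")
})

test_that("theta signatures on posterior regions beat frontal channels in band power", {
  sp <- epoch_spec()
  m <- build_montage(60)
  sig <- band_signature("theta", c("parietal", "temporal"), amplitude = 4)
  post <- m$region %in% c("parietal", "temporal")
  front <- m$region == "frontal"
  diffs <- sapply(1:50, function(s) {
    ep <- generate_background(sp, seed = s)
    ep <- plant_band_signature(ep, sig, m, seed = s + 1000, spec = sp)
    pow <- band_power(ep, "theta", sp)
    mean(pow[post]) - mean(pow[front])
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.9)
})

test_that("planted in-band power increases monotonically with amplitude", {
  sp <- epoch_spec()
  m <- build_montage(60)
  tgt <- m$region == "parietal"
  mean_power <- function(A) {
    mean(sapply(1:30, function(s) {
      ep <- generate_background(sp, seed = s)
      sig <- band_signature("theta", "parietal", amplitude = A)
      ep <- plant_band_signature(ep, sig, m, seed = s + 500, spec = sp)
      mean(band_power(ep, "theta", sp)[tgt])
    }))
  }
  p <- sapply(c(2, 4, 6), mean_power)
  expect_true(all(diff(p) > 0))
})

test_that("artifacts have the advertised spectral and spatial footprint", {
  sp <- epoch_spec()
  m <- build_montage(60)
  zero <- matrix(0, 60, 320)
  expect_identical(add_artifact(zero, "ocular", 0, m, seed = 1), zero)
  expect_error(add_artifact(zero, "blink", 10, m))

  oc <- add_artifact(zero, "ocular", 200, m, seed = 2, spec = sp)
  dp <- band_power(oc, c(0.5, 4), sp)
  fp <- m$name %in% c("Fp1", "Fp2")
  expect_gt(min(dp[fp]), max(dp[!(m$region == "frontal")]))
  expect_equal(dp[m$region != "frontal"],
               rep(0, sum(m$region != "frontal")), tolerance = 1e-12)

  em <- add_artifact(zero, "emg", 50, m, seed = 3, spec = sp)
  bp <- band_power(em, c(20, 125), sp)
  tmp <- m$region == "temporal"
  expect_gt(min(bp[tmp]), 0)
  expect_equal(bp[!tmp], rep(0, sum(!tmp)), tolerance = 1e-12)
})

test_that("cohort plan reproduces the study bookkeeping exactly", {
  plan <- cohort_plan(cohort_spec())
  expect_equal(length(unique(plan$subject)), 51L)
  totals <- tapply(plan$n_trials, plan$group, sum)
  expect_equal(as.vector(totals[c("N", "A+P-", "A+P+")]),
               c(5618, 4871, 3102))
  by_task <- tapply(plan$n_trials, list(plan$group, plan$task), sum)
  expect_equal(by_task["N", "MSIT"], 3176)
  expect_equal(by_task["A+P-", "STMT"], 2151)
  # scaling preserves structure and allocates totals exactly
  plan_s <- cohort_plan(cohort_spec(scale = 0.1))
  expect_equal(length(unique(plan_s$subject)), 51L)
  expect_equal(sum(plan_s$n_trials[plan_s$group == "N" &
                                     plan_s$task == "MSIT"]),
               round(0.1 * 3176))
})

test_that("generated cohorts are deterministic and match their plan", {
  cs <- cohort_spec(scale = 0.004, master_seed = 17L)
  co1 <- generate_cohort(cs)
  co2 <- generate_cohort(cs)
  expect_identical(co1$epochs, co2$epochs)
  expect_identical(co1$meta, co2$meta)
  plan <- cohort_plan(cs)
  expect_equal(dim(co1$epochs)[3], sum(plan$n_trials))
  expect_equal(as.vector(table(co1$meta$group)[c("N", "A+P-", "A+P+")]),
               as.vector(tapply(plan$n_trials, plan$group,
                                sum)[c("N", "A+P-", "A+P+")]))
  expect_true(all(is.finite(co1$epochs)))
  # a different master seed changes the signal
  co3 <- generate_cohort(cohort_spec(scale = 0.004, master_seed = 18L))
  expect_false(identical(co1$epochs, co3$epochs))
})

test_that("zero-trial cohorts keep their subjects", {
  co <- generate_cohort(cohort_spec(scale = 0))
  expect_equal(dim(co$epochs)[3], 0L)
  expect_equal(nrow(co$subjects), 51L)
  expect_equal(nrow(co$meta), 0L)
})

test_that("subject-level amplitude offsets create between-subject variance", {
  mk <- function(sd) {
    cohort_spec(
      group_names = c("G1", "G2"), group_sizes = c(8L, 2L), tasks = "T1",
      trial_totals = matrix(c(48, 12), 2, 1,
                            dimnames = list(c("G1", "G2"), "T1")),
      signatures = list(
        G1 = list(band_signature("theta", "parietal", 6,
                                 amplitude_sd = sd, per_trial_jitter = 0.1)),
        G2 = list()),
      noise_scale = 2, artifact_rates = c(ocular = 0, emg = 0),
      master_seed = 33L)
  }
  subject_sd <- function(co) {
    m <- build_montage(60)
    tgt <- m$region == "parietal"
    idx <- cohort_trials(co, groups = "G1")
    pows <- sapply(idx, function(i) {
      mean(band_power(co$epochs[, , i], "theta", co$spec)[tgt])
    })
    stats::sd(tapply(pows, co$meta$subject[idx], mean))
  }
  sd_hier <- subject_sd(generate_cohort(mk(2)))
  sd_flat <- subject_sd(generate_cohort(mk(0)))
  expect_gt(sd_hier, sd_flat)
  expect_gt(sd_hier, 0)
})
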