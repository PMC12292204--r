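test_that("relevance maps are normalized, nonnegative, epoch-shaped", {
  cfg <- tiny_config()
  p <- build_model(cfg)
  e <- eegsep:::with_seed(1L, matrix(stats::rnorm(4 * 32), 4, 32))
  map <- compute_relevance(p, e, target_class = 1L)
  expect_equal(dim(map$weights), c(4L, 32L))
  expect_true(all(map$weights >= 0))
  expect_equal(sum(map$weights), 1, tolerance = 1e-6)
  p_bad <- p
  p_bad$dense[1, 1] <- NaN
  expect_error(compute_relevance(p_bad, e), "non-finite")
})

test_that("a single open pathway routes all relevance to its channel", {
  cfg <- model_config(n_channels = 8L, n_samples = 32L, spatial_filters = 2L,
                      temporal_kernel_len = 8L, depth_multiplier = 1L,
                      init_seed = 3L)
  p <- build_model(cfg)
  p$pointwise[] <- 0
  p$pointwise[1, 7] <- 1          # source 1 reads channel 7 only
  p$pointwise_bias[] <- 0
  p$dense[1, ] <- c(1, 0)         # target class listens to source 1 only
  e <- matrix(0, 8, 32)
  e[7, 10:20] <- 5                # planted burst
  map <- compute_relevance(p, e, target_class = 1L)
  mont <- structure(data.frame(name = paste0("ch", 1:8), x = 0, y = 0,
                               region = "r", stringsAsFactors = FALSE),
                    class = c("eeg_montage", "data.frame"))
  expect_gte(localization_score(map, "ch7", mont), 0.95)
})

test_that("zero read-out weight degenerates to the uniform map", {
  cfg <- tiny_config()
  p <- build_model(cfg)
  p$dense[1, ] <- 0
  e <- eegsep:::with_seed(2L, matrix(stats::rnorm(4 * 32), 4, 32))
  map <- compute_relevance(p, e, target_class = 1L)
  expect_equal(map$weights, matrix(1 / (4 * 32), 4, 32))
})

test_that("localization scores respect uniform and saturated baselines", {
  m <- build_montage(60)
  uniform <- structure(list(weights = matrix(1 / (60 * 320), 60, 320)),
                       class = "relevance_map")
  targets <- m$name[1:12]
  expect_equal(localization_score(uniform, targets, m), 0.2,
               tolerance = 1e-12)
  all_on <- structure(list(weights = rbind(matrix(1 / 320, 1, 320),
                                           matrix(0, 59, 320))),
                      class = "relevance_map")
  expect_equal(localization_score(all_on, m$name[1], m), 1.0)
  expect_error(localization_score(uniform, "Fp9", m), "unknown channel")
  rr <- region_relevance(uniform, m)
  expect_setequal(names(rr),
                  c("central", "frontal", "occipital", "parietal", "temporal"))
  expect_equal(stats::sd(rr), 0, tolerance = 1e-12)  # uniform per channel
})

test_that("relevance is invariant to input rescaling with compensated statistics", {
  cfg <- tiny_config(pointwise_bias = FALSE)
  p <- build_model(cfg)
  p$bn_mean <- rep(0.3, 8)
  p$bn_var <- rep(1.5, 8)
  e <- eegsep:::with_seed(4L, matrix(stats::rnorm(4 * 32), 4, 32))
  m1 <- compute_relevance(p, e, target_class = 1L)
  cc <- 2.5
  p2 <- p
  p2$bn_mean <- p$bn_mean * cc
  p2$bn_var <- p$bn_var * cc^2
  m2 <- compute_relevance(p2, e * cc, target_class = 1L)
  expect_equal(m1$weights, m2$weights, tolerance = 1e-3)
})

test_that("band power matches the Parseval closed form for sinusoids", {
  sp <- epoch_spec()
  tt <- (seq_len(320) - 1) / sp$fs
  e <- matrix(sin(2 * pi * 10 * tt), 1, 320)
  expect_equal(band_power(e, "alpha", sp)[1], 0.5, tolerance = 0.05 * 0.5)
  expect_lt(band_power(e, "theta", sp)[1], 0.01)
  expect_lt(band_power(e, "beta", sp)[1], 0.01)
  zeros <- matrix(0, 3, 320)
  for (b in band_defs()$band) {
    expect_equal(band_power(zeros, b, sp), rep(0, 3))
  }
  expect_error(band_power(e, c(100, 150), sp), "Nyquist")
})

test_that("white-noise band power is proportional to bandwidth", {
  sp <- epoch_spec()
  defs <- band_defs()
  dens <- matrix(0, 50, nrow(defs))
  for (s in 1:50) {
    e <- eegsep:::with_seed(s, matrix(stats::rnorm(320), 1, 320))
    for (b in seq_len(nrow(defs))) {
      dens[s, b] <- band_power(e, defs$band[b], sp)[1] /
        (defs$f_hi[b] - defs$f_lo[b])
    }
  }
  d <- colMeans(dens)
  expect_lt(max(d) / min(d), 1.2)
})

test_that("total periodogram mass approximates the signal variance", {
  long <- epoch_spec(fs = 256, t_start = 0, t_end = 8000, n_channels = 1L)
  rel_err <- sapply(1:10, function(s) {
    # flat spectrum: detrending then removes no genuine in-band mass
    e <- generate_background(long, exponent = 0, scale = 1, seed = s)
    pg <- eegsep:::periodogram(e, long$fs)
    bands <- sum(sapply(band_defs()$band,
                        function(b) band_power(e, b, long)[1]))
    total <- sum(pg$power[, 1])
    out_of_band <- total - bands
    expect_gte(out_of_band, 0)
    abs(total - stats::var(e[1, ])) / stats::var(e[1, ])
  })
  expect_lt(mean(rel_err), 0.05)
})

test_that("topographic interpolation honors its fixed points", {
  m <- build_montage(60)
  const <- topographic_grid(rep(3.3, 60), m, resolution = 24)
  expect_equal(range(const$z, na.rm = TRUE), c(3.3, 3.3), tolerance = 1e-9)
  v <- rep(0, 60)
  v[17] <- 1
  tg <- topographic_grid(v, m, resolution = 64)
  peak <- which(tg$z == max(tg$z, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_lt(abs(tg$x[peak[1]] - m$x[17]), 2 / 63 + 1e-9)
  expect_lt(abs(tg$y[peak[2]] - m$y[17]), 2 / 63 + 1e-9)
  vals <- eegsep:::with_seed(5L, stats::runif(60))
  back <- topographic_grid(vals, m, query = cbind(m$x, m$y))
  expect_equal(back, vals, tolerance = 1e-6)
  expect_error(topographic_grid(1:2, build_montage(2), resolution = 8),
               "at least 3")
})

test_that("trial selection mirrors the interpretability workflow", {
  tf <- toy_fit()
  toy <- tf$toy
  x <- toy$x[, , -tf$train_idx]
  labs <- toy$y[-tf$train_idx]
  conf <- select_trials(tf$fit, x, selection = "confident", k = 5L)
  expect_equal(nrow(conf), 5L)
  expect_true(all(diff(conf$max_prob) <= 1e-12))
  pr <- predict(tf$fit, x)
  expect_equal(max(conf$max_prob), max(apply(pr, 1, max)))
  mis <- suppressWarnings(
    select_trials(tf$fit, x, labels = labs, selection = "misclassified",
                  k = 60L))
  if (nrow(mis)) {
    pred <- predict(tf$fit, x, type = "class")
    expect_true(all(as.character(pred[mis$index]) !=
                      as.character(labs[mis$index])))
  }
  uncl <- suppressWarnings(
    select_trials(tf$fit, x, selection = "unclear", k = 60L,
                  threshold = 0.05))
  if (nrow(uncl)) expect_true(all(abs(uncl$prob_risk - 0.5) < 0.05))
  expect_warning(select_trials(tf$fit, x, selection = "confident", k = 1000L),
                 "only")
  expect_error(select_trials(tf$fit, x, selection = "misclassified"),
               "labels")
})
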