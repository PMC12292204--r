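#' Epoch geometry specification
#'
#' Describes the fixed stimulus-locked window every trial is cut to:
#' 60 channels and 320 samples spanning -80 to 1200 ms at 250 Hz by
#' default.  The invariant `n_samples == (t_end - t_start) / 1000 * fs`
#' is enforced.
#'
#' @param fs sampling rate in Hz.
#' @param t_start,t_end window limits in ms relative to stimulus onset.
#' @param n_channels number of channels.
#' @return A list of class `epoch_spec` with fields `fs`, `t_start`,
#'   `t_end`, `n_channels`, `n_samples`.
#' @examples
#' epoch_spec()$n_samples  # 320
#' @export
epoch_spec <- function(fs = 250, t_start = -80, t_end = 1200,
                       n_channels = 60L) {
  stop_if_not_scalar(fs, "fs")
  n_samples <- (t_end - t_start) / 1000 * fs
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop("window length times sampling rate must give a whole number of samples",
         call. = FALSE)
  }
  out <- list(fs = fs, t_start = t_start, t_end = t_end,
              n_channels = as.integer(n_channels),
              n_samples = as.integer(round(n_samples)))
  class(out) <- "epoch_spec"
  out
}

#' @export
print.epoch_spec <- function(x, ...) {
  cat(sprintf("<epoch_spec> %d ch x %d samples, %g Hz, %g..%g ms\n",
              x$n_channels, x$n_samples, x$fs, x$t_start, x$t_end))
  invisible(x)
}

#' Band-limited class signature
#'
#' Parameterizes a class-discriminative oscillation: a random-phase
#' sinusoid whose frequency is drawn uniformly within `band`, added with
#' amplitude `amplitude` (in uV) to every channel of the target region(s).
#' `amplitude_sd` is the between-subject SD of the amplitude and
#' `per_trial_jitter` the within-subject, across-trial SD; both enter as
#' additive Gaussian offsets truncated so the effective amplitude stays
#' nonnegative.
#'
#' @param band band name, see [band_defs()].
#' @param region one or more region names of the montage.
#' @param amplitude mean oscillation amplitude, uV.
#' @param amplitude_sd across-subject amplitude SD, uV.
#' @param per_trial_jitter across-trial amplitude SD, uV.
#' @return A list of class `band_signature`.
#' @export
band_signature <- function(band, region, amplitude, amplitude_sd = 0,
                           per_trial_jitter = 0) {
  resolve_band(band)
  if (!is.numeric(amplitude) || amplitude < 0) {
    stop("`amplitude` must be >= 0", call. = FALSE)
  }
  out <- list(band = band, region = region, amplitude = amplitude,
              amplitude_sd = amplitude_sd,
              per_trial_jitter = per_trial_jitter)
  class(out) <- "band_signature"
  out
}

#' Default group signatures
#'
#' The non-carrier group (N) leans on frontal activity; both risk-carrier
#' groups express elevated theta and alpha oscillations over the parietal
#' and temporal regions, with the dual-risk group (A+P+) carrying the same
#' bands and regions at a shifted (reduced) amplitude so it resembles, but
#' does not duplicate, the single-risk group.
#'
#' @param risk_amplitude mean theta amplitude (uV) of the single-risk
#'   signatures; the alpha component uses 3/4 of it.
#' @param frontal_amplitude mean amplitude (uV) of the non-carrier frontal
#'   signature.
#' @param amplitude_sd across-subject SD, uV.
#' @param per_trial_jitter across-trial SD, uV.
#' @param heldout_shift multiplicative amplitude shift of the dual-risk
#'   group relative to the single-risk group.
#' @return Named list of `band_signature` lists, one entry per group.
#' @export
default_signatures <- function(risk_amplitude = 4, frontal_amplitude = 3,
                               amplitude_sd = 1, per_trial_jitter = 0.5,
                               heldout_shift = 0.75) {
  post <- c("parietal", "temporal")
  risk <- list(
    band_signature("theta", post, risk_amplitude, amplitude_sd,
                   per_trial_jitter),
    band_signature("alpha", post, 0.75 * risk_amplitude, amplitude_sd,
                   per_trial_jitter)
  )
  shifted <- lapply(risk, function(s) {
    s$amplitude <- heldout_shift * s$amplitude
    s
  })
  list(
    "N" = list(band_signature("alpha", "frontal", frontal_amplitude,
                              amplitude_sd, per_trial_jitter)),
    "A+P-" = risk,
    "A+P+" = shifted
  )
}

#' 1/f background EEG noise
#'
#' Generates zero-mean Gaussian noise whose power spectrum falls off as
#' \eqn{1/f^{exponent}}, independently per channel, standardized so each
#' channel has SD `scale` uV.  Synthesized in the frequency domain: a white
#' spectrum is shaped by \eqn{f^{-exponent/2}} (DC removed) and inverted.
#'
#' @param spec an [epoch_spec()].
#' @param exponent spectral slope (>= 0; 1 gives classic pink noise).
#' @param scale per-channel SD in uV; 0 yields an all-zero epoch.
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @param n_channels number of channels (defaults to the spec's).
#' @return `n_channels x n_samples` matrix.
#' @export
generate_background <- function(spec = epoch_spec(), exponent = 1, scale = 10,
                                seed = 1L, n_channels = spec$n_channels) {
  if (exponent < 0) stop("`exponent` must be >= 0", call. = FALSE)
  if (scale < 0) stop("`scale` must be >= 0", call. = FALSE)
  n <- spec$n_samples
  if (is.null(n) || n <= 0) stop("non-positive number of samples", call. = FALSE)
  C <- as.integer(n_channels)
  if (scale == 0) return(matrix(0, C, n))
  with_seed(seed, {
    W <- matrix(stats::rnorm(n * C), n, C)
    X <- stats::mvfft(W)
    kf <- c(0, pmin(1:(n - 1), n - 1:(n - 1)))   # symmetric |frequency| index
    f <- kf * spec$fs / n
    g <- c(0, f[-1]^(-exponent / 2))             # kill DC, shape the rest
    X <- X * g
    x <- Re(stats::mvfft(X, inverse = TRUE)) / n
    x <- sweep(x, 2, colMeans(x))
    s <- apply(x, 2, stats::sd)
    s[s == 0] <- 1
    t(sweep(x, 2, s, "/") * scale)
  })
}

#' Plant a band-limited oscillation into an epoch
#'
#' Adds a sinusoid of amplitude `sig$amplitude` with frequency drawn
#' uniformly within the signature's band and a random phase, to exactly
#' the channels whose montage region matches `sig$region`; all other
#' channels are untouched.  One frequency/phase pair is drawn per call, so
#' the oscillation is spatially coherent across the target region.
#'
#' @param epoch channels x samples matrix (rows ordered as `montage`).
#' @param sig a [band_signature()].
#' @param montage an [build_montage()] montage.
#' @param seed integer seed.
#' @param spec an [epoch_spec()] supplying the sampling rate.
#' @param amplitude optional amplitude override (uV), e.g. after applying
#'   subject/trial offsets; defaults to `sig$amplitude`.
#' @return The modified epoch matrix.
#' @export
plant_band_signature <- function(epoch, sig, montage, seed = 1L,
                                 spec = epoch_spec(), amplitude = NULL) {
  fr <- resolve_band(sig$band)
  targets <- which(montage$region %in% sig$region)
  if (!length(targets)) {
    stop("no montage channels in region(s): ",
         paste(sig$region, collapse = ", "), call. = FALSE)
  }
  a <- amplitude %||% sig$amplitude
  if (a == 0) return(epoch)
  n <- ncol(epoch)
  with_seed(seed, {
    f <- stats::runif(1, fr[1], fr[2])
    ph <- stats::runif(1, 0, 2 * pi)
    tt <- (seq_len(n) - 1) / spec$fs
    wave <- a * sin(2 * pi * f * tt + ph)
    epoch[targets, ] <- epoch[targets, ] +
      matrix(wave, length(targets), n, byrow = TRUE)
    epoch
  })
}

#' Add a physiological artifact to an epoch
#'
#' `ocular`: a slow (< 4 Hz) Gaussian-windowed transient confined to the
#' frontal channels, with spatial weights decaying with distance from the
#' anterior pole so the prefrontal pair (Fp1/Fp2) carries the most mass --
#' emulating blink/eye-movement contamination.  `emg`: a broadband
#' (> 20 Hz) Hann-windowed burst of random-phase sinusoids on the temporal
#' channels with random per-channel gain -- emulating peripheral muscle
#' activity.
#'
#' @param epoch channels x samples matrix (rows ordered as `montage`).
#' @param kind `"ocular"` or `"emg"`.
#' @param amplitude peak amplitude in uV; 0 leaves the epoch unchanged.
#' @param montage the montage.
#' @param seed integer seed.
#' @param spec an [epoch_spec()].
#' @return The modified epoch matrix.
#' @export
add_artifact <- function(epoch, kind = c("ocular", "emg"), amplitude,
                         montage, seed = 1L, spec = epoch_spec()) {
  kind <- match.arg(kind)
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  if (amplitude == 0) return(epoch)
  n <- ncol(epoch)
  tt <- (seq_len(n) - 1) / spec$fs
  with_seed(seed, {
    if (kind == "ocular") {
      targets <- which(montage$region == "frontal")
      if (!length(targets)) stop("montage has no frontal channels", call. = FALSE)
      d <- sqrt(montage$x[targets]^2 + (montage$y[targets] - 1)^2)
      wgt <- exp(-3 * d)
      tc <- stats::runif(1, 0.15, max(tt) - 0.15)
      sigma <- 0.12                        # s; spectral content well below 4 Hz
      pulse <- amplitude * exp(-(tt - tc)^2 / (2 * sigma^2))
      epoch[targets, ] <- epoch[targets, ] + outer(wgt, pulse)
    } else {
      targets <- which(montage$region == "temporal")
      if (!length(targets)) stop("montage has no temporal channels", call. = FALSE)
      nyq <- spec$fs / 2
      fhi <- max(25, 0.9 * nyq)
      freqs <- stats::runif(40, 22, min(fhi, 0.95 * nyq))
      phases <- stats::runif(40, 0, 2 * pi)
      burst <- colSums(sin(outer(2 * pi * freqs, tt) + phases))
      tc <- stats::runif(1, 0.15, max(tt) - 0.15)
      halfw <- 0.1                         # s
      win <- ifelse(abs(tt - tc) < halfw,
                    0.5 + 0.5 * cos(pi * (tt - tc) / halfw), 0)
      burst <- burst * win
      burst <- amplitude * burst / max(abs(burst))
      gains <- stats::runif(length(targets), 0.5, 1)
      epoch[targets, ] <- epoch[targets, ] + outer(gains, burst)
    }
    epoch
  })
}

#' Cohort specification
#'
#' Describes a synthetic study cohort: three genotype groups (non-carriers
#' N, single-risk carriers A+P-, dual-risk carriers A+P+) of 21/18/12
#' subjects by default, recorded under two task conditions (MSIT, STMT)
#' with per-group trial totals of 3176/2442, 2720/2151 and 1738/1364.
#' Group signatures, the 1/f background, and artifact rates are all
#' configurable; `scale` multiplies every trial total (rounded) for
#' desk-scale runs.
#'
#' @param group_names group labels; the first two are the training groups.
#' @param group_sizes subjects per group.
#' @param tasks task-condition labels.
#' @param trial_totals groups x tasks matrix of total trial counts at
#'   `scale = 1`.
#' @param scale multiplicative factor on trial totals.
#' @param signatures named list (by group) of lists of [band_signature()].
#' @param noise_exponent 1/f spectral slope of the background.
#' @param noise_scale background SD per channel, uV.
#' @param artifact_rates named per-trial probabilities for `ocular`/`emg`.
#' @param artifact_amplitudes named peak amplitudes (uV) for each artifact.
#' @param master_seed integer; the entire cohort is a pure function of the
#'   spec including this seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(group_names = c("N", "A+P-", "A+P+"),
                        group_sizes = c(21L, 18L, 12L),
                        tasks = c("MSIT", "STMT"),
                        trial_totals = NULL,
                        scale = 1,
                        signatures = default_signatures(),
                        noise_exponent = 1,
                        noise_scale = 10,
                        artifact_rates = c(ocular = 0.05, emg = 0.05),
                        artifact_amplitudes = c(ocular = 60, emg = 15),
                        master_seed = 1L) {
  if (is.null(trial_totals)) {
    trial_totals <- matrix(c(3176, 2720, 1738, 2442, 2151, 1364),
                           nrow = 3,
                           dimnames = list(c("N", "A+P-", "A+P+"),
                                           c("MSIT", "STMT")))
    trial_totals <- trial_totals[group_names, tasks, drop = FALSE]
  }
  stopifnot(length(group_sizes) == length(group_names),
            all(group_sizes >= 0),
            nrow(trial_totals) == length(group_names),
            ncol(trial_totals) == length(tasks),
            all(trial_totals >= 0), scale >= 0,
            all(artifact_rates >= 0), all(artifact_rates <= 1))
  missing_sig <- setdiff(group_names, names(signatures))
  if (length(missing_sig)) {
    stop("signatures missing for group(s): ",
         paste(missing_sig, collapse = ", "), call. = FALSE)
  }
  out <- list(group_names = group_names,
              group_sizes = as.integer(group_sizes),
              tasks = tasks,
              trial_totals = trial_totals,
              scale = scale,
              signatures = signatures,
              noise_exponent = noise_exponent,
              noise_scale = noise_scale,
              artifact_rates = artifact_rates,
              artifact_amplitudes = artifact_amplitudes,
              master_seed = as.integer(master_seed))
  class(out) <- "cohort_spec"
  out
}

# Canonical subject identifiers for the default 21/18/12 cohort.
canonical_subject_ids <- function() {
  list(
    "N" = c(1, 2, 6, 7, 8, 10, 13, 14, 15, 16, 17, 18, 19, 22, 23, 24, 25,
            26, 28, 29, 31),
    "A+P-" = c(47, 53, 57, 58, 59, 60, 62, 63, 65, 67, 70, 73, 74, 75, 77,
               78, 79, 80),
    "A+P+" = c(32, 34, 35, 37, 39, 40, 41, 42, 44, 48, 52, 54)
  )
}

#' Cohort bookkeeping plan
#'
#' Expands a [cohort_spec()] into a per-subject, per-task table of trial
#' counts without generating any signal.  Scaled group totals
#' (`round(scale * total)`) are allocated exactly: every subject receives
#' `floor(total / n)` trials and the first `total %% n` subjects one more,
#' so group totals always match the (scaled) specification exactly.
#'
#' @param spec a [cohort_spec()].
#' @return Data frame with columns `subject`, `group`, `task`, `n_trials`.
#' @examples
#' plan <- cohort_plan(cohort_spec())
#' sum(plan$n_trials[plan$group == "N"])  # 5618
#' @export
cohort_plan <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  canon <- canonical_subject_ids()
  rows <- list()
  for (g in seq_along(spec$group_names)) {
    gname <- spec$group_names[g]
    nsub <- spec$group_sizes[g]
    if (nsub == 0L) next
    ids <- if (!is.null(canon[[gname]]) && length(canon[[gname]]) == nsub) {
      sprintf("S%03d", canon[[gname]])
    } else {
      sprintf("G%d_S%02d", g, seq_len(nsub))
    }
    for (t in seq_along(spec$tasks)) {
      total <- round(spec$scale * spec$trial_totals[g, t])
      base <- total %/% nsub
      extra <- total %% nsub
      counts <- rep(base, nsub) + c(rep(1L, extra), rep(0L, nsub - extra))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = ids, group = gname, task = spec$tasks[t],
        n_trials = counts, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic EEG cohort
#'
#' Builds a full epoched dataset from a [cohort_spec()]: per trial, a 1/f
#' background plus every group signature (with hierarchical amplitude:
#' subject-level Gaussian offset, then trial-level jitter, truncated at
#' zero) plus Bernoulli-sampled ocular/EMG artifacts.  The result is a
#' pure function of the spec -- the same spec and `master_seed` reproduce
#' the dataset bit for bit.
#'
#' @param spec a [cohort_spec()].
#' @param eps an [epoch_spec()].
#' @param montage montage to use; defaults to
#'   `build_montage(eps$n_channels)`.
#' @return An object of class `eeg_cohort`: list with `spec` (epoch spec),
#'   `cohort_spec`, `montage`, `epochs` (channels x samples x trials
#'   array), and `meta` (data frame: `subject`, `group`, `task`).
#' @examples
#' co <- generate_cohort(cohort_spec(scale = 0.002), epoch_spec())
#' table(co$meta$group)
#' @export
generate_cohort <- function(spec, eps = epoch_spec(),
                            montage = build_montage(eps$n_channels)) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(eps, "epoch_spec"))
  if (nrow(montage) != eps$n_channels) {
    stop("montage size does not match epoch spec", call. = FALSE)
  }
  plan <- cohort_plan(spec)
  n_total <- sum(plan$n_trials)
  epochs <- array(0, c(eps$n_channels, eps$n_samples, n_total))
  meta <- data.frame(subject = character(n_total),
                     group = character(n_total),
                     task = character(n_total),
                     stringsAsFactors = FALSE)

  subjects <- unique(plan[, c("subject", "group")])
  # subject-level amplitude offsets per signature
  offsets <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject[i]
    sigs <- spec$signatures[[subjects$group[i]]]
    off <- numeric(length(sigs))
    for (j in seq_along(sigs)) {
      off[j] <- with_seed(derive_seed(spec$master_seed, 1L, i, j),
                          stats::rnorm(1, 0, sigs[[j]]$amplitude_sd))
    }
    offsets[[sid]] <- off
  }

  pos <- 0L
  for (r in seq_len(nrow(plan))) {
    sid <- plan$subject[r]
    grp <- plan$group[r]
    task <- plan$task[r]
    sigs <- spec$signatures[[grp]]
    off <- offsets[[sid]]
    si <- match(sid, subjects$subject)
    ti <- match(task, spec$tasks)
    nt <- plan$n_trials[r]
    for (k in seq_len(nt)) {
      tseed <- derive_seed(spec$master_seed, 2L, si, ti, k)
      ep <- generate_background(eps, spec$noise_exponent, spec$noise_scale,
                                seed = tseed)
      for (j in seq_along(sigs)) {
        amp <- with_seed(derive_seed(tseed, 10L + j),
                         max(0, sigs[[j]]$amplitude + off[j] +
                               stats::rnorm(1, 0, sigs[[j]]$per_trial_jitter)))
        ep <- plant_band_signature(ep, sigs[[j]], montage,
                                   seed = derive_seed(tseed, 20L + j),
                                   spec = eps, amplitude = amp)
      }
      for (a in names(spec$artifact_rates)) {
        p <- spec$artifact_rates[[a]]
        if (p > 0) {
          hit <- with_seed(derive_seed(tseed, 30L + match(a, names(spec$artifact_rates))),
                           stats::runif(1) < p)
          if (hit) {
            ep <- add_artifact(ep, a, spec$artifact_amplitudes[[a]], montage,
                               seed = derive_seed(tseed, 40L +
                                                    match(a, names(spec$artifact_rates))),
                               spec = eps)
          }
        }
      }
      pos <- pos + 1L
      epochs[, , pos] <- ep
      meta$subject[pos] <- sid
      meta$group[pos] <- grp
      meta$task[pos] <- task
    }
  }

  subj_tab <- unique(plan[, c("subject", "group")])
  rownames(subj_tab) <- NULL
  out <- list(spec = eps, cohort_spec = spec, montage = montage,
              epochs = epochs, meta = meta, subjects = subj_tab)
  class(out) <- "eeg_cohort"
  out
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("<eeg_cohort> %d trials, %d subjects, %d ch x %d samples\n",
              dim(x$epochs)[3], length(unique(x$meta$subject)),
              x$spec$n_channels, x$spec$n_samples))
  print(table(group = x$meta$group, task = x$meta$task))
  invisible(x)
}

#' Select trial indices of a cohort
#'
#' @param cohort an `eeg_cohort`.
#' @param groups,tasks,subjects optional filters; `tasks = "ALL"` (or
#'   `NULL`) keeps every task condition.
#' @return Integer vector of trial indices.
#' @export
cohort_trials <- function(cohort, groups = NULL, tasks = NULL,
                          subjects = NULL) {
  keep <- rep(TRUE, nrow(cohort$meta))
  if (!is.null(groups)) keep <- keep & cohort$meta$group %in% groups
  if (!is.null(tasks) && !identical(tasks, "ALL")) {
    keep <- keep & cohort$meta$task %in% tasks
  }
  if (!is.null(subjects)) keep <- keep & cohort$meta$subject %in% subjects
  which(keep)
}
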