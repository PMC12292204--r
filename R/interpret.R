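#' Class-activation-style relevance map for one epoch
#'
#' Reconstructs the decision evidence of the network as a nonnegative
#' channels x time map summing to one.  For the target class: each
#' feature map's temporal relevance is its dense read-out weight times
#' the rectified post-batch-norm activation; the D maps of each demixed
#' source are summed and linearly upsampled from the convolution-valid
#' length back to the epoch length; source relevance is then redistributed
#' over input channels proportionally to the absolute pointwise demixing
#' weights; finally negative mass is clipped and the map normalized.  A
#' map with no positive evidence (e.g. a zero read-out row) falls back to
#' the uniform map -- the documented degenerate contract.
#'
#' @param object a fitted [eegcnn()] model or `eegcnn_params`.
#' @param epoch channels x samples matrix.
#' @param target_class class index (1-based) or label; defaults to the
#'   predicted class.
#' @param activations `"post_bn"` (default) uses rectified
#'   post-batch-norm activations, `"pre_bn"` the ReLU outputs.
#' @return Object of class `relevance_map`: list with `weights`
#'   (channels x samples, nonnegative, sums to 1), `predicted_class`,
#'   `target_class`, `log_probs`.
#' @export
compute_relevance <- function(object, epoch, target_class = NULL,
                              activations = c("post_bn", "pre_bn")) {
  activations <- match.arg(activations)
  lev <- if (inherits(object, "eegcnn")) object$levels else NULL
  params <- if (inherits(object, "eegcnn")) object$params else object
  stopifnot(inherits(params, "eegcnn_params"))
  if (!all(vapply(params[c("pointwise", "depthwise", "dense")],
                  function(p) all(is.finite(p)), logical(1)))) {
    stop("model parameters contain non-finite values", call. = FALSE)
  }
  cfg <- params$config
  act <- nn_activations(params, epoch)
  pred <- which.max(act$log_probs)
  tc <- target_class %||% pred
  if (is.character(tc)) {
    tc <- match(tc, lev)
    if (is.na(tc)) stop("unknown target class label", call. = FALSE)
  }

  S <- cfg$spatial_filters; D <- cfg$depth_multiplier
  Tn <- cfg$n_samples
  A <- if (activations == "post_bn") pmax(act$bn_out, 0) else act$relu_out
  w <- params$dense[tc, ]                       # length S*D
  rmap <- A * w                                 # (S*D) x Tp, row-recycled
  # sum the D maps of each demixed source
  src <- rowsum(rmap, rep(seq_len(S), each = D))  # S x Tp
  Tp <- ncol(src)
  up <- t(apply(src, 1, function(v) {
    stats::approx(seq_len(Tp), v, xout = seq(1, Tp, length.out = Tn))$y
  }))                                            # S x T

  Aw <- abs(params$pointwise)                    # S x C
  rs <- rowSums(Aw)
  rs[rs == 0] <- 1
  Aw <- Aw / rs
  map <- t(Aw) %*% up                            # C x T
  map <- pmax(map, 0)
  tot <- sum(map)
  if (!is.finite(tot) || tot <= .Machine$double.eps) {
    map <- matrix(1 / (nrow(map) * ncol(map)), nrow(map), ncol(map))
  } else {
    map <- map / tot
  }
  out <- list(weights = map,
              predicted_class = if (!is.null(lev)) lev[pred] else pred,
              target_class = if (!is.null(lev)) lev[tc] else tc,
              log_probs = act$log_probs)
  class(out) <- "relevance_map"
  out
}

#' @export
print.relevance_map <- function(x, ...) {
  cat(sprintf("<relevance_map> %d x %d, predicted %s (target %s)\n",
              nrow(x$weights), ncol(x$weights),
              as.character(x$predicted_class), as.character(x$target_class)))
  invisible(x)
}

#' Relevance mass on a channel set
#'
#' Total relevance (summed over time) carried by the named channels; a
#' uniform map yields `length(target_channels) / n_channels`.
#'
#' @param map a [compute_relevance()] map.
#' @param target_channels channel names.
#' @param montage the montage the map's rows follow.
#' @return Fraction in \[0, 1\].
#' @export
localization_score <- function(map, target_channels, montage) {
  stopifnot(inherits(map, "relevance_map"))
  if (!length(target_channels)) stop("empty target channel set", call. = FALSE)
  idx <- match(target_channels, montage$name)
  if (anyNA(idx)) {
    stop("unknown channel(s): ",
         paste(target_channels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  sum(map$weights[idx, ])
}

#' Per-region relevance mass
#'
#' @param map a [compute_relevance()] map.
#' @param montage the montage.
#' @param per_channel divide each region's mass by its channel count so
#'   regions of different sizes compare fairly.
#' @return Named numeric vector over regions.
#' @export
region_relevance <- function(map, montage, per_channel = TRUE) {
  stopifnot(inherits(map, "relevance_map"))
  mass <- rowSums(map$weights)
  out <- tapply(mass, montage$region, sum)
  if (per_channel) {
    out <- out / as.numeric(table(montage$region)[names(out)])
  }
  structure(as.numeric(out), names = names(out))
}

#' Interpolate per-channel values onto a scalp grid
#'
#' Inverse-distance-weighted interpolation of a per-channel quantity
#' (band power, relevance mass) onto a square grid over the unit disc,
#' masked (NA) outside the disc.  Grid points closer than 1e-9 to an
#' electrode take that electrode's value exactly.
#'
#' @param values per-channel numeric vector (montage order).
#' @param montage the montage (>= 3 channels).
#' @param resolution grid size per side.
#' @param power inverse-distance exponent.
#' @param query optional n x 2 matrix of (x, y) points; if given, returns
#'   the interpolated values there instead of a grid.
#' @return List of class `eeg_topography` with `x`, `y`, `z` (matrix,
#'   NA outside the disc), or a numeric vector in query mode.
#' @export
topographic_grid <- function(values, montage, resolution = 64L, power = 2,
                             query = NULL) {
  if (nrow(montage) < 3L) stop("need at least 3 channels", call. = FALSE)
  stopifnot(length(values) == nrow(montage))
  px <- montage$x
  py <- montage$y
  interp1 <- function(qx, qy) {
    d2 <- (px - qx)^2 + (py - qy)^2
    j <- which.min(d2)
    if (d2[j] < 1e-18) return(values[j])
    w <- 1 / d2^(power / 2)
    sum(w * values) / sum(w)
  }
  if (!is.null(query)) {
    query <- as.matrix(query)
    return(vapply(seq_len(nrow(query)),
                  function(i) interp1(query[i, 1], query[i, 2]), numeric(1)))
  }
  gx <- seq(-1, 1, length.out = resolution)
  gy <- seq(-1, 1, length.out = resolution)
  z <- matrix(NA_real_, resolution, resolution)
  for (i in seq_along(gx)) {
    for (j in seq_along(gy)) {
      if (gx[i]^2 + gy[j]^2 <= 1) z[i, j] <- interp1(gx[i], gy[j])
    }
  }
  out <- list(x = gx, y = gy, z = z)
  class(out) <- "eeg_topography"
  out
}

#' @export
plot.eeg_topography <- function(x, montage = NULL, ...) {
  graphics::image(x$x, x$y, x$z, asp = 1, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th))
  if (!is.null(montage)) graphics::points(montage$x, montage$y, pch = 20,
                                          cex = 0.5)
  invisible(x)
}

#' Select representative trials from model predictions
#'
#' Mirrors the interpretability workflow's trial picks: the most
#' confidently classified trials, misclassified trials, or "unclear"
#' trials whose risk probability sits near 0.5.
#'
#' @param fit a fitted [eegcnn()] model.
#' @param x epochs array.
#' @param labels optional true labels (required for `"misclassified"`).
#' @param selection `"confident"`, `"misclassified"` or `"unclear"`.
#' @param k number of trials to return (fewer, with a warning, if not
#'   enough qualify).
#' @param threshold half-width of the unclear probability window around
#'   0.5.
#' @return Data frame with `index`, `predicted`, `prob_risk`, `max_prob`
#'   ordered by the selection criterion.
#' @export
select_trials <- function(fit, x, labels = NULL,
                          selection = c("confident", "misclassified",
                                        "unclear"),
                          k = 6L, threshold = 0.05) {
  selection <- match.arg(selection)
  pr <- predict(fit, x)
  prob_risk <- pr[, 2]
  max_prob <- apply(pr, 1, max)
  pred <- factor(fit$levels[max.col(pr, ties.method = "first")],
                 levels = fit$levels)
  cand <- switch(selection,
    confident = order(max_prob, decreasing = TRUE),
    misclassified = {
      if (is.null(labels)) {
        stop("`labels` required for misclassified selection", call. = FALSE)
      }
      mis <- which(as.character(pred) != as.character(labels))
      mis[order(max_prob[mis], decreasing = TRUE)]
    },
    unclear = {
      un <- which(abs(prob_risk - 0.5) < threshold)
      un[order(abs(prob_risk[un] - 0.5))]
    })
  if (length(cand) < k) {
    warning(sprintf("only %d trial(s) match selection '%s' (requested %d)",
                    length(cand), selection, k))
  }
  sel <- utils::head(cand, k)
  data.frame(index = sel, predicted = pred[sel],
             prob_risk = prob_risk[sel], max_prob = max_prob[sel])
}
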