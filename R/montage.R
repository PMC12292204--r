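#' Build a 10-10 electrode montage
#'
#' Constructs a deterministic scalp montage drawn from the extended 10-20
#' (``10-10``) nomenclature, with schematic 2D positions on the unit disc
#' (nose up) and a scalp-region assignment for every channel.  The full
#' 60-channel montage covers nine anterior-to-posterior electrode rows with
#' the midline fronto-central site (FCz, a common online reference) omitted.
#'
#' Regions follow conventional usage: prefrontal/frontal and
#' fronto-central rows are `frontal`; FT7/FT8, T7/T8 and TP7/TP8 are
#' `temporal`; the central row is `central`; centro-parietal and parietal
#' rows are `parietal`; parieto-occipital and occipital rows are
#' `occipital`.
#'
#' @param n_channels number of channels, at most 60.  Channels are taken in
#'   anterior-to-posterior order; `n_channels = 1` yields a single channel
#'   placed at the origin.
#' @return A data frame of class `eeg_montage` with columns `name`, `x`,
#'   `y` and `region`.
#' @examples
#' m <- build_montage(60)
#' subset(m, name %in% c("T8", "P2", "P4", "Fp1", "FC2"))
#' @export
build_montage <- function(n_channels = 60L) {
  rows <- list(
    list(y = 0.90, labels = c("Fp1", "Fpz", "Fp2"), region = "frontal"),
    list(y = 0.72, labels = c("AF7", "AF3", "AFz", "AF4", "AF8"),
         region = "frontal"),
    list(y = 0.50,
         labels = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
         region = "frontal"),
    list(y = 0.26,
         labels = c("FT7", "FC5", "FC3", "FC1", "FC2", "FC4", "FC6", "FT8"),
         region = "frontal"),
    list(y = 0.00,
         labels = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
         region = "central"),
    list(y = -0.26,
         labels = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
                    "TP8"),
         region = "parietal"),
    list(y = -0.50,
         labels = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
         region = "parietal"),
    list(y = -0.72, labels = c("PO7", "PO3", "POz", "PO4", "PO8"),
         region = "occipital"),
    list(y = -0.90, labels = c("O1", "Oz", "O2"), region = "occipital")
  )
  temporal <- c("FT7", "FT8", "T7", "T8", "TP7", "TP8")

  name <- character(0); x <- numeric(0); y <- numeric(0); region <- character(0)
  for (row in rows) {
    k <- length(row$labels)
    w <- 0.92 * sqrt(max(0, 1 - row$y^2))
    xs <- if (k == 1L) 0 else seq(-1, 1, length.out = k) * w
    name <- c(name, row$labels)
    x <- c(x, xs)
    y <- c(y, rep(row$y, k))
    region <- c(region, rep(row$region, k))
  }
  region[name %in% temporal] <- "temporal"

  if (!is.numeric(n_channels) || length(n_channels) != 1L ||
      n_channels < 1L || n_channels > length(name)) {
    stop(sprintf("`n_channels` must be between 1 and %d", length(name)),
         call. = FALSE)
  }
  n_channels <- as.integer(n_channels)
  idx <- seq_len(n_channels)
  out <- data.frame(name = name[idx], x = x[idx], y = y[idx],
                    region = region[idx], stringsAsFactors = FALSE)
  if (n_channels == 1L) {
    out$x <- 0
    out$y <- 0
  }
  class(out) <- c("eeg_montage", "data.frame")
  out
}

#' Channels belonging to one or more scalp regions
#'
#' @param montage an `eeg_montage` data frame.
#' @param regions character vector of region names.
#' @return Character vector of channel names.
#' @export
region_channels <- function(montage, regions) {
  bad <- setdiff(regions, unique(montage$region))
  if (length(bad)) {
    stop("unknown region(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  montage$name[montage$region %in% regions]
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels\n", nrow(x)))
  tab <- table(x$region)
  cat("  regions:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write / read a montage as CSV
#'
#' Plain-text serialization (`name,x,y,region`) of an electrode montage.
#'
#' @param montage an `eeg_montage`.
#' @param path file path.
#' @return `read_montage` returns an `eeg_montage`.
#' @export
write_montage <- function(montage, path) {
  utils::write.csv(as.data.frame(montage), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "x", "y", "region") %in% names(out)))
  class(out) <- c("eeg_montage", "data.frame")
  out
}
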