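#' Write / read an epoched cohort on disk
#'
#' The on-disk container keeps signal and metadata apart so each piece is
#' independently inspectable: the epochs array as an RDS payload
#' (`epochs.rds`), trial metadata as CSV (`meta.csv`), the montage as CSV
#' (`montage.csv`, `name,x,y,region`), and a JSON sidecar
#' (`cohort.json`) holding the epoch geometry, group/task bookkeeping and
#' the master seed.  Writing the same cohort twice produces byte-identical
#' payloads.
#'
#' @param cohort an `eeg_cohort`.
#' @param dir target directory (created if missing).
#' @return `read_cohort` returns the restored `eeg_cohort`;
#'   `write_cohort` returns `dir` invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(cohort$epochs, file.path(dir, "epochs.rds"))
  utils::write.csv(cohort$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  write_montage(cohort$montage, file.path(dir, "montage.csv"))
  sp <- cohort$spec
  counts <- table(cohort$meta$group, cohort$meta$task)
  sidecar <- list(
    epoch_spec = list(fs = sp$fs, t_start = sp$t_start, t_end = sp$t_end,
                      n_channels = sp$n_channels, n_samples = sp$n_samples),
    n_trials = dim(cohort$epochs)[3],
    n_subjects = length(unique(cohort$meta$subject)),
    groups = dimnames(counts)[[1]],
    tasks = dimnames(counts)[[2]],
    trial_counts = as.data.frame.matrix(counts),
    master_seed = cohort$cohort_spec$master_seed,
    scale = cohort$cohort_spec$scale
  )
  jsonlite::write_json(sidecar, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "cohort.json"),
                              simplifyVector = TRUE)
  es <- side$epoch_spec
  spec <- epoch_spec(fs = es$fs, t_start = es$t_start, t_end = es$t_end,
                     n_channels = es$n_channels)
  epochs <- readRDS(file.path(dir, "epochs.rds"))
  meta <- utils::read.csv(file.path(dir, "meta.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(subject = "character"))
  montage <- read_montage(file.path(dir, "montage.csv"))
  out <- list(spec = spec, cohort_spec = NULL, montage = montage,
              epochs = epochs, meta = meta)
  class(out) <- "eeg_cohort"
  out
}
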