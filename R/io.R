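## Plain-text, lossless on-disk container for synthetic datasets.
## Layout of a dataset directory:
##   meta.json            schema version, config, per-subject scalars, seeds
##   behavior.csv         subject_id, trial, wait_time_s, w_report_s, w_delay_s, task_label
##   epochs_s<id>.csv     one trials-by-time epoch matrix per subject
## Numbers are written with 17 significant digits so a write/read round
## trip reproduces every array bitwise.

SCHEMA_VERSION <- "1.0"

fmt_num <- function(x) sprintf("%.17g", x)

write_matrix_csv <- function(m, path) {
  txt <- apply(m, 1L, function(r) paste(fmt_num(r), collapse = ","))
  writeLines(txt, path)
}

read_matrix_csv <- function(path) {
  as.matrix(utils::read.csv(path, header = FALSE, colClasses = "numeric"))
}

#' Write a synthetic dataset to a directory
#'
#' Serializes a cohort (or a single subject wrapped as a one-subject
#' cohort) losslessly as plain text: a JSON header with the schema
#' version, generator configuration and all seeds, a behavioural table,
#' and one epoch matrix per subject. [read_dataset()] restores the
#' object bitwise.
#'
#' @param x An `rp_cohort` or `subject_dataset`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path) {
  if (inherits(x, "subject_dataset")) {
    x <- structure(list(subjects = list(x), config = NULL), class = "rp_cohort")
  }
  stopifnot(inherits(x, "rp_cohort"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    schema_version = SCHEMA_VERSION,
    config = x$config[setdiff(names(x$config), NULL)],
    subjects = lapply(x$subjects, function(s) {
      list(subject_id = s$subject_id, beta = s$beta, threshold = s$threshold,
           w_threshold = s$w_threshold, seed = s$seed,
           times = s$times, n_trials = nrow(s$epochs))
    })
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  beh <- do.call(rbind, lapply(x$subjects, function(s) {
    data.frame(subject_id = s$subject_id, trial = seq_along(s$wait_times),
               wait_time_s = fmt_num(s$wait_times),
               w_report_s = fmt_num(s$w_reports),
               w_delay_s = fmt_num(s$w_delays),
               task_label = s$task_label)
  }))
  utils::write.csv(beh, file.path(path, "behavior.csv"), row.names = FALSE,
                   quote = FALSE)
  for (s in x$subjects) {
    write_matrix_csv(s$epochs, file.path(path, sprintf("epochs_s%02d.csv",
                                                       s$subject_id)))
  }
  invisible(path)
}

#' Read a synthetic dataset from a directory
#'
#' Restores a dataset written by [write_dataset()], validating the schema
#' version and the presence of every block. A dataset whose major schema
#' version differs is rejected; a differing minor version is read with a
#' warning.
#'
#' @param path Dataset directory.
#' @return An `rp_cohort` (with a single subject if written from one).
#' @export
read_dataset <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("dataset is missing its `meta.json` block", call. = FALSE)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(meta$schema_version)) {
    stop("dataset header lacks a schema version", call. = FALSE)
  }
  have <- strsplit(as.character(meta$schema_version), ".", fixed = TRUE)[[1]]
  want <- strsplit(SCHEMA_VERSION, ".", fixed = TRUE)[[1]]
  if (have[1] != want[1]) {
    stop(sprintf("dataset schema version %s is incompatible with %s",
                 meta$schema_version, SCHEMA_VERSION), call. = FALSE)
  }
  if (length(have) < 2L || have[2] != want[2]) {
    warning(sprintf("dataset schema version %s read as %s",
                    meta$schema_version, SCHEMA_VERSION), call. = FALSE)
  }
  bf <- file.path(path, "behavior.csv")
  if (!file.exists(bf)) stop("dataset is missing its `behavior.csv` block", call. = FALSE)
  beh <- utils::read.csv(bf, colClasses = c(subject_id = "integer",
                                            trial = "integer",
                                            wait_time_s = "numeric",
                                            w_report_s = "numeric",
                                            w_delay_s = "numeric",
                                            task_label = "character"))
  subs_meta <- meta$subjects
  if (is.data.frame(subs_meta)) {
    subs_meta <- lapply(seq_len(nrow(subs_meta)), function(i) {
      as.list(subs_meta[i, , drop = FALSE])
    })
  }
  subjects <- lapply(subs_meta, function(sm) {
    id <- as.integer(sm$subject_id)
    ef <- file.path(path, sprintf("epochs_s%02d.csv", id))
    if (!file.exists(ef)) {
      stop(sprintf("dataset is missing its `epochs_s%02d.csv` block", id),
           call. = FALSE)
    }
    b <- beh[beh$subject_id == id, , drop = FALSE]
    structure(
      list(subject_id = id, beta = as.numeric(sm$beta),
           threshold = as.numeric(sm$threshold),
           w_threshold = as.numeric(sm$w_threshold),
           epochs = unname(read_matrix_csv(ef)),
           times = as.numeric(unlist(sm$times)),
           wait_times = b$wait_time_s, w_delays = b$w_delay_s,
           w_reports = b$w_report_s, task_label = b$task_label,
           seed = as.integer(sm$seed)),
      class = "subject_dataset"
    )
  })
  cfg <- meta$config
  if (!is.null(cfg)) {
    cfg <- lapply(cfg, function(v) if (is.list(v)) unlist(v) else v)
    class(cfg) <- "cohort_config"
  }
  structure(list(subjects = subjects, config = cfg), class = "rp_cohort")
}
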