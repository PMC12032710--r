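# Plain-text artifact I/O: TSV matrices for trials and profiles, JSON for
# models, events and metadata. All numeric fields round-trip at full
# precision.

#' Write / read a trial envelope matrix as TSV
#'
#' Rows are time samples, columns are channels, header holds the muscle
#' codes. Values are serialized at full double precision.
#'
#' @param mat numeric matrix (e.g. 101 x 30 envelope).
#' @param path file path.
#' @export
write_trial_tsv <- function(mat, path) {
  if (is.null(colnames(mat))) {
    colnames(mat) <- if (ncol(mat) == 30) muscle_channel_table()$code
                     else paste0("col_", seq_len(ncol(mat)))
  }
  df <- as.data.frame(format(mat, digits = 17, trim = TRUE, scientific = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_tsv
#' @return `read_trial_tsv` returns the matrix with its column names.
#' @export
read_trial_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (ncol(df) < 1) stop("malformed trial TSV: no columns in ", path)
  mat <- as.matrix(df)
  if (!is.numeric(mat)) stop("malformed trial TSV: non-numeric values in ", path)
  mat
}

#' Write / read a synergy model as JSON
#'
#' Factors, reconstruction quality and protocol settings are serialized
#' with `jsonlite` at full precision (`digits = NA`).
#'
#' @param model a `synergy_model`.
#' @param path file path.
#' @export
write_model_json <- function(model, path) {
  payload <- list(
    kind = model$kind, n = model$n,
    trial_independent = model$trial_independent,
    trial_dependent = model$trial_dependent,
    r2_train = model$r2_train, objective = model$objective)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @return `read_model_json` returns a `synergy_model` (without the
#'   objective trace).
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$trial_independent <- as.matrix(x$trial_independent)
  if (!is.null(x$trial_dependent))
    x$trial_dependent <- lapply(x$trial_dependent, as.matrix)
  class(x) <- "synergy_model"
  x
}

#' Write a cohort of envelope trials to a directory
#'
#' One TSV matrix per trial plus a JSON metadata sidecar
#' (`metadata.json`); a ground-truth JSON is written when the cohort
#' carries one.
#'
#' @param cohort a cohort list (`trials`, `metadata`, optionally
#'   `ground_truth`).
#' @param dir output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$trials)) {
    tr <- cohort$trials[[i]]
    mat <- if (!is.null(tr$envelope)) tr$envelope else tr
    write_trial_tsv(mat, file.path(dir, sprintf("trial_%04d.tsv", i)))
  }
  jsonlite::write_json(cohort$metadata, file.path(dir, "metadata.json"),
                       digits = NA, dataframe = "rows")
  if (!is.null(cohort$ground_truth)) {
    gt <- cohort$ground_truth
    gt_out <- list(
      strategies = lapply(gt$strategies, function(s)
        s[c("name", "movement", "floor", "n_synergies", "peaks", "widths",
            "weightings")]),
      support_effects = gt$support_effects, noise = gt$noise,
      events = gt$events, seed = gt$seed)
    jsonlite::write_json(gt_out, file.path(dir, "ground_truth.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Read an envelope cohort written by [write_cohort()]
#' @param dir cohort directory.
#' @return List with `trials` (each carrying `envelope` and `meta`) and
#'   `metadata`.
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^trial_\\d+\\.tsv$",
                           full.names = TRUE))
  trials <- lapply(seq_along(files), function(i)
    list(envelope = read_trial_tsv(files[i]),
         meta = as.list(meta[i, ])))
  list(trials = trials, metadata = meta)
}
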