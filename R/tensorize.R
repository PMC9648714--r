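#' Time-window specification
#'
#' Windows are contiguous, non-overlapping, half-open intervals counting
#' backwards from each patient's index date. Window `j = n_windows` is the
#' most recent one, ending just before the index date (the index date itself
#' is excluded: the history is strictly prior to it); window `j = 1` is the
#' oldest. An event `days_before` days before the index date falls in window
#' `j = n_windows + 1 - ceiling(days_before / window_days)`.
#'
#' @param n_windows number of windows `w` (>= 1). The case-study preset uses
#'   24 windows over 2 years; the synthetic example preset uses 26.
#' @param window_days window length in days (>= 1; fractional allowed,
#'   e.g. 30.44 for calendar months).
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(n_windows, window_days) {
  if (n_windows < 1L) stop("n_windows must be >= 1")
  if (window_days < 1) stop("window_days must be >= 1")
  structure(list(n_windows = as.integer(n_windows),
                 window_days = as.numeric(window_days)),
            class = "window_spec")
}

#' Case-study and worked-example window presets
#'
#' `spec_case_study()`: 2 years of history in 24 windows of 30.44 days.
#' `spec_example()`: 2 years in 26 windows of 28 days.
#' @return A [window_spec()].
#' @export
spec_case_study <- function() window_spec(24L, 30.44)

#' @rdname spec_case_study
#' @export
spec_example <- function() window_spec(26L, 28)

# window index for vectors of dates; NA when outside [1, w]
window_index <- function(event_date, index_date, spec) {
  days_before <- as.numeric(index_date - event_date)
  j <- spec$n_windows + 1 - ceiling(days_before / spec$window_days)
  j[days_before <= 0 | j < 1] <- NA_integer_
  as.integer(j)
}

#' Per-patient activity-by-window count matrix
#'
#' Cell (i, j) is the number of occurrences of activity label i among the
#' patient's events dated inside time window j. Events older than the
#' observation period are dropped (their number is available via
#' `attr(, "n_dropped")`); an event dated after the index date is an error.
#'
#' @param log an `event_log` whose `label_set` fixes the row order.
#' @param patient a patient id present in the log's outcomes.
#' @param spec a [window_spec()].
#' @return Integer `l x w` matrix with `rownames = log$label_set`.
#' @export
count_matrix <- function(log, patient, spec) {
  oc <- log$outcomes
  k <- match(patient, oc$patient_id)
  if (is.na(k)) stop("unknown patient: ", patient)
  index_date <- oc$index_date[k]
  ev <- log$events[log$events$patient_id == patient, , drop = FALSE]
  l <- length(log$label_set)
  m <- matrix(0L, nrow = l, ncol = spec$n_windows,
              dimnames = list(log$label_set, NULL))
  if (nrow(ev) == 0L) return(structure(m, n_dropped = 0L))
  if (any(ev$date > index_date))
    stop("patient ", patient, " has event(s) dated after the index date")
  j <- window_index(ev$date, index_date, spec)
  keep <- !is.na(j) & ev$code %in% log$label_set
  dropped <- sum(ev$count[is.na(j)])
  ev <- ev[keep, , drop = FALSE]
  j <- j[keep]
  if (nrow(ev) > 0L) {
    i <- match(ev$code, log$label_set)
    for (r in seq_along(i)) m[i[r], j[r]] <- m[i[r], j[r]] + ev$count[r]
  }
  structure(m, n_dropped = as.integer(dropped))
}

#' Tensorize an event log into a matrix dataset
#'
#' Builds the count matrix of every patient, then rescales counts into
#' [0, 1] by a single global factor (the maximum training-count cell).
#' When `rescale_factor` is supplied (test-time use), cells exceeding it
#' are clipped to 1.
#'
#' @param log an `event_log`.
#' @param spec a [window_spec()].
#' @param rescale_factor `NULL` to learn the factor from this dataset
#'   (training), or a positive number persisted from training.
#' @return Object of class `matrix_dataset`: list with `values`
#'   (`n x p` matrix, each row a patient's `l x w` matrix flattened
#'   column-major), `row_labels`, `patient_ids`, `classes`, `systems`
#'   (label -> system tag), `window` and `rescale_factor`.
#' @export
tensorize <- function(log, spec, rescale_factor = NULL) {
  ids <- sort(log$outcomes$patient_id)
  l <- length(log$label_set)
  if (l == 0L) stop("empty label_set")
  counts <- matrix(0, nrow = length(ids), ncol = l * spec$n_windows)
  for (k in seq_along(ids))
    counts[k, ] <- as.vector(count_matrix(log, ids[k], spec))
  ds <- rescale_counts(counts, rescale_factor = rescale_factor)
  ds$row_labels <- log$label_set
  ds$patient_ids <- ids
  ds$classes <- log$outcomes$outcome[match(ids, log$outcomes$patient_id)]
  sysmap <- unique(log$events[, c("code", "system")])
  ds$systems <- stats::setNames(sysmap$system, sysmap$code)[log$label_set]
  ds$window <- spec
  ds
}

#' Rescale integer count grids into [0, 1]
#'
#' Divides every cell by one global factor, the maximum cell value observed
#' in the (training) dataset, so relative intensities between activities are
#' preserved and the mapping is invertible on training data. Test-time
#' values above the factor are clipped to 1.
#'
#' @param counts `n x p` matrix of non-negative counts (rows = patients).
#' @param rescale_factor `NULL` to use `max(counts)` (floored at 1), or a
#'   previously learned positive factor.
#' @return A `matrix_dataset` (without label/patient metadata).
#' @export
rescale_counts <- function(counts, rescale_factor = NULL) {
  if (!is.matrix(counts) || nrow(counts) == 0L) stop("counts must be a non-empty matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  learned <- is.null(rescale_factor)
  if (learned) rescale_factor <- max(counts, 1)
  if (rescale_factor < 1) stop("rescale_factor must be >= 1")
  values <- counts / rescale_factor
  if (!learned) values <- pmin(values, 1)
  structure(list(values = values, rescale_factor = rescale_factor),
            class = "matrix_dataset")
}

#' @export
print.matrix_dataset <- function(x, ...) {
  l <- length(x$row_labels); w <- if (!is.null(x$window)) x$window$n_windows else NA
  cat(sprintf("Pathway matrix dataset: %d patients, l = %d activities, w = %s windows\n",
              nrow(x$values), l, w))
  cat(sprintf("  rescale_factor = %g; positives = %d\n",
              x$rescale_factor, sum(x$classes)))
  invisible(x)
}

#' Extract one patient's matrix from a dataset
#' @param ds a `matrix_dataset`.
#' @param k row index or patient id.
#' @return `l x w` matrix with label rownames.
#' @export
patient_matrix <- function(ds, k) {
  if (is.character(k)) k <- match(k, ds$patient_ids)
  unflatten(ds$values[k, ], length(ds$row_labels), ds$window$n_windows,
            ds$row_labels)
}

# flatten/unflatten between l x w matrices and length-p rows (column-major)
unflatten <- function(v, l, w, labels = NULL) {
  matrix(v, nrow = l, ncol = w, dimnames = list(labels, NULL))
}

#' Subset a matrix dataset by patients
#' @param ds a `matrix_dataset`.
#' @param idx logical or integer row index.
#' @return The subsetted `matrix_dataset`.
#' @export
subset_patients <- function(ds, idx) {
  ds$values <- ds$values[idx, , drop = FALSE]
  ds$patient_ids <- ds$patient_ids[idx]
  ds$classes <- ds$classes[idx]
  ds
}

#' List-of-features export: whole-history activity counts
#'
#' One feature per retained label: the total number of appearances of that
#' label anywhere in the patient's recorded history (no window cut-off).
#'
#' @param log an `event_log`.
#' @return `n x l` matrix, rows named by patient id, columns by label.
#' @export
features_lof <- function(log) {
  ids <- sort(log$outcomes$patient_id)
  l <- length(log$label_set)
  m <- matrix(0L, nrow = length(ids), ncol = l,
              dimnames = list(ids, log$label_set))
  ev <- log$events[log$events$code %in% log$label_set, , drop = FALSE]
  if (nrow(ev) > 0L) {
    i <- match(ev$patient_id, ids)
    jj <- match(ev$code, log$label_set)
    for (r in seq_along(i)) m[i[r], jj[r]] <- m[i[r], jj[r]] + ev$count[r]
  }
  m
}

#' Coarse time-window feature export
#'
#' Splits the observation period covered by `spec` into `n_blocks` equal
#' spans and concatenates one list-of-features vector per span, earliest
#' block first, giving `n_blocks * l` features per patient (the case study
#' used 4 blocks over 962 labels = 3,848 features).
#'
#' @param log an `event_log`.
#' @param spec a [window_spec()] defining the observation period.
#' @param n_blocks number of spans (>= 1); `n_blocks = 1` equals
#'   [features_lof()] restricted to the observation period.
#' @return `n x (n_blocks*l)` matrix; columns named `<label>__tw<k>`.
#' @export
features_tw <- function(log, spec, n_blocks = 4L) {
  if (n_blocks < 1L) stop("n_blocks must be >= 1")
  total_days <- spec$n_windows * spec$window_days
  block_spec <- window_spec(n_blocks, total_days / n_blocks)
  ids <- sort(log$outcomes$patient_id)
  l <- length(log$label_set)
  m <- matrix(0L, nrow = length(ids), ncol = n_blocks * l,
              dimnames = list(ids, paste0(rep(log$label_set, n_blocks), "__tw",
                                          rep(seq_len(n_blocks), each = l))))
  for (k in seq_along(ids))
    m[k, ] <- as.vector(count_matrix(log, ids[k], block_spec))
  m
}

#' Persist / load a matrix dataset as plain text
#'
#' Values go to `<stem>_values.csv` (one row per patient, flattened
#' column-major) and metadata (labels, classes, window geometry, rescale
#' factor) to `<stem>_meta.json`.
#'
#' @param ds a `matrix_dataset`.
#' @param stem path stem without extension.
#' @return `write_matrix_dataset`: the stem, invisibly;
#'   `read_matrix_dataset`: the `matrix_dataset`.
#' @export
write_matrix_dataset <- function(ds, stem) {
  vals <- as.data.frame(ds$values)
  names(vals) <- paste0("v", seq_len(ncol(vals)))
  utils::write.csv(cbind(patient_id = ds$patient_ids, vals),
                   paste0(stem, "_values.csv"), row.names = FALSE, quote = FALSE)
  meta <- list(row_labels = ds$row_labels,
               systems = as.list(stats::setNames(as.character(ds$systems), ds$row_labels)),
               classes = ds$classes,
               n_windows = ds$window$n_windows,
               window_days = ds$window$window_days,
               rescale_factor = ds$rescale_factor)
  jsonlite::write_json(meta, paste0(stem, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_matrix_dataset
#' @export
read_matrix_dataset <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  tab <- utils::read.csv(paste0(stem, "_values.csv"), stringsAsFactors = FALSE,
                         colClasses = NA, check.names = FALSE)
  structure(list(values = unname(as.matrix(tab[, -1, drop = FALSE])),
                 row_labels = meta$row_labels,
                 patient_ids = as.character(tab$patient_id),
                 classes = as.integer(meta$classes),
                 systems = stats::setNames(unlist(meta$systems), names(meta$systems)),
                 window = window_spec(meta$n_windows, meta$window_days),
                 rescale_factor = meta$rescale_factor),
            class = "matrix_dataset")
}
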