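#' Construct an event log
#'
#' An event log holds, for every patient, dated events made of coded medical
#' activities (diagnoses, procedures, devices, biology, consultations), a
#' binary outcome and an index date anchoring the observation window. An
#' event is the set of activities recorded on one calendar day; activities
#' repeated on the same day are kept as multiplicities (`count`).
#'
#' @param events data.frame with columns `patient_id`, `date` (Date),
#'   `code`, `system`, `count` (positive integer multiplicity). Rows with
#'   identical (`patient_id`, `date`, `code`) are merged by summing counts.
#' @param outcomes data.frame with columns `patient_id`, `outcome` (0/1)
#'   and `index_date` (Date), one row per patient.
#' @param label_set optional character vector of retained activity labels;
#'   defaults to the sorted set of codes present in `events`.
#' @return An object of class `event_log`.
#' @export
event_log <- function(events, outcomes, label_set = NULL) {
  req <- c("patient_id", "date", "code", "system")
  miss <- setdiff(req, names(events))
  if (length(miss) > 0L)
    stop("events is missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(c("patient_id", "outcome", "index_date"), names(outcomes))
  if (length(miss) > 0L)
    stop("outcomes is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(outcomes$outcome %in% c(0L, 1L)))
    stop("outcome values must be 0 or 1")
  if (anyDuplicated(outcomes$patient_id))
    stop("duplicated patient_id in outcomes")

  events$patient_id <- as.character(events$patient_id)
  events$date <- as.Date(events$date)
  events$code <- as.character(events$code)
  events$system <- as.character(events$system)
  if (is.null(events$count)) events$count <- 1L
  events$count <- as.integer(events$count)
  if (any(events$count < 1L)) stop("event counts must be >= 1")

  outcomes$patient_id <- as.character(outcomes$patient_id)
  outcomes$outcome <- as.integer(outcomes$outcome)
  outcomes$index_date <- as.Date(outcomes$index_date)

  unknown <- setdiff(unique(events$patient_id), outcomes$patient_id)
  if (length(unknown) > 0L)
    stop("patient(s) present in events but absent from outcomes: ",
         paste(utils::head(unknown, 10L), collapse = ", "))

  # one system per code
  sys_map <- unique(events[, c("code", "system")])
  if (anyDuplicated(sys_map$code))
    stop("a code maps to more than one system; codes must be unique identifiers")

  events <- merge_same_day(events)
  if (is.null(label_set)) label_set <- sort(unique(events$code))
  if (anyDuplicated(label_set)) stop("label_set has duplicates")

  structure(list(events = events, outcomes = outcomes,
                 label_set = as.character(label_set)),
            class = "event_log")
}

# collapse rows sharing (patient_id, date, code) into multiset counts,
# in a canonical row order
merge_same_day <- function(events) {
  key <- paste(events$patient_id, format(events$date), events$code, sep = "\r")
  agg <- tapply(events$count, key, sum)
  first <- !duplicated(key)
  out <- events[first, , drop = FALSE]
  out$count <- as.integer(agg[key[first]])
  o <- order(out$patient_id, out$date, out$code)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.event_log <- function(x, ...) {
  cat("Patient-pathway event log\n")
  cat(sprintf("  patients: %d (%d positive)\n", nrow(x$outcomes),
              sum(x$outcomes$outcome)))
  cat(sprintf("  events:   %d patient-days\n", n_events(x)))
  cat(sprintf("  activities: %d occurrences of %d labels (label_set: %d)\n",
              sum(x$events$count), length(unique(x$events$code)),
              length(x$label_set)))
  invisible(x)
}

#' Count events (distinct patient-days) and activity occurrences
#'
#' @param log an `event_log`.
#' @return `n_events`: number of events, an event being all activities of a
#'   patient on one date. `n_activities`: total activity occurrences
#'   (multiplicities included).
#' @export
n_events <- function(log) {
  nrow(unique(log$events[, c("patient_id", "date")]))
}

#' @rdname n_events
#' @export
n_activities <- function(log) sum(log$events$count)

# sniff the delimiter of a delimited text file: comma, semicolon or tab
sniff_sep <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  cands <- c(",", ";", "\t")
  hits <- vapply(cands, function(s) lengths(regmatches(line, gregexpr(s, line, fixed = TRUE))), 1L)
  if (all(hits == 0L)) stop("cannot sniff delimiter of ", path)
  cands[which.max(hits)]
}

read_table_auto <- function(path) {
  utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                    stringsAsFactors = FALSE, colClasses = "character",
                    fileEncoding = "UTF-8")
}

#' Read an event log from delimited text files
#'
#' The events file must have header `patient_id,date,code,system` and the
#' outcomes file `patient_id,outcome,index_date`; dates are ISO 8601.
#' Comma, semicolon and tab delimiters are auto-detected. Rows sharing a
#' (patient, date) are merged into one event; a code repeated on the same
#' date contributes multiplicity.
#'
#' @param events_path,outcomes_path paths to the two files.
#' @return An [event_log()].
#' @export
read_event_log <- function(events_path, outcomes_path) {
  ev <- read_table_auto(events_path)
  oc <- read_table_auto(outcomes_path)
  for (cn in c("patient_id", "date", "code", "system"))
    if (is.null(ev[[cn]])) stop("events file missing column: ", cn)
  for (cn in c("patient_id", "outcome", "index_date"))
    if (is.null(oc[[cn]])) stop("outcomes file missing column: ", cn)
  ev$date <- as.Date(ev$date)
  if (anyNA(ev$date)) stop("unparseable date(s) in events file")
  oc$index_date <- as.Date(oc$index_date)
  oc$outcome <- as.integer(oc$outcome)
  event_log(ev, oc)
}

#' Write an event log back to delimited text files
#'
#' Multiplicities are expanded so that `read_event_log()` round-trips to the
#' same canonical event multiset.
#'
#' @param log an `event_log`.
#' @param events_path,outcomes_path output CSV paths.
#' @return Invisibly, the paths.
#' @export
write_event_log <- function(log, events_path, outcomes_path) {
  ev <- log$events
  ev <- ev[rep(seq_len(nrow(ev)), ev$count), c("patient_id", "date", "code", "system")]
  ev$date <- format(ev$date)
  utils::write.csv(ev, events_path, row.names = FALSE, quote = FALSE)
  oc <- log$outcomes
  oc$index_date <- format(oc$index_date)
  utils::write.csv(oc, outcomes_path, row.names = FALSE, quote = FALSE)
  invisible(c(events_path, outcomes_path))
}

#' Construct a code hierarchy
#'
#' A single-parent forest of medical codes (ICD-10 chapters, CCAM, ATC-like).
#' Each code has at most one parent; roots have parent `NA` (empty string in
#' files). Ancestor chains must terminate at a root within 10 steps.
#'
#' @param edges data.frame with columns `code`, `parent` (NA or "" = root)
#'   and optionally `system`.
#' @return Object of class `code_hierarchy`.
#' @export
code_hierarchy <- function(edges) {
  if (is.null(edges$code)) stop("hierarchy missing column: code")
  if (is.null(edges$parent)) stop("hierarchy missing column: parent")
  edges$code <- as.character(edges$code)
  edges$parent <- as.character(edges$parent)
  edges$parent[!is.na(edges$parent) & edges$parent == ""] <- NA_character_
  if (is.null(edges$system)) edges$system <- NA_character_
  edges$system <- as.character(edges$system)
  if (anyDuplicated(edges$code))
    stop("poly-hierarchy rejected: code(s) with more than one parent row: ",
         paste(unique(edges$code[duplicated(edges$code)]), collapse = ", "))
  known <- edges$code
  bad <- setdiff(edges$parent[!is.na(edges$parent)], known)
  if (length(bad) > 0L)
    stop("parent code(s) not themselves declared: ", paste(bad, collapse = ", "))
  h <- structure(list(edges = edges[, c("code", "parent", "system")]),
                 class = "code_hierarchy")
  # acyclicity + depth bound via ancestor walk
  for (code in edges$code) ancestors(h, code)
  h
}

#' Read a code hierarchy from a delimited file with header `code,parent,system`
#'
#' @param path file path; empty `parent` denotes a root.
#' @return A [code_hierarchy()].
#' @export
read_hierarchy <- function(path) {
  code_hierarchy(read_table_auto(path))
}

#' Ancestor chain of a code
#'
#' @param h a `code_hierarchy`.
#' @param code a code present in `h`.
#' @return Character vector of ancestors from immediate parent up to the
#'   root (empty for roots).
#' @export
ancestors <- function(h, code) {
  parent <- stats::setNames(h$edges$parent, h$edges$code)
  if (is.na(match(code, h$edges$code))) stop("code not in hierarchy: ", code)
  chain <- character(0)
  cur <- code
  for (step in seq_len(11L)) {
    p <- parent[[cur]]
    if (is.na(p)) return(chain)
    if (p %in% c(chain, code) || step > 10L)
      stop("hierarchy cycle or depth > 10 at code: ", code)
    chain <- c(chain, p)
    cur <- p
  }
  chain
}

#' Hierarchy level of each code (0 = root)
#' @param h a `code_hierarchy`.
#' @return Named integer vector.
#' @export
hierarchy_depths <- function(h) {
  vapply(h$edges$code, function(cd) length(ancestors(h, cd)), 1L)
}

#' Enrich an event log with hierarchy roll-up activities
#'
#' For each occurrence of an activity, one occurrence of each of its
#' ancestor codes is added to the same event, so every aggregation level of
#' the hierarchy coexists in the log. An ancestor's multiplicity in an event
#' equals the sum of the multiplicities of its descendants present in that
#' event, plus its own recorded occurrences.
#'
#' @param log an `event_log` of leaf-level recordings.
#' @param h a [code_hierarchy()] covering the log's codes.
#' @param on_missing what to do with codes absent from `h`: `"error"`
#'   (default) or `"root"` (warn once and treat them as roots).
#' @return The enriched `event_log` (label_set refreshed, sorted).
#' @export
enrich_with_hierarchy <- function(log, h, on_missing = c("error", "root")) {
  on_missing <- match.arg(on_missing)
  ev <- log$events
  codes <- unique(ev$code)
  absent <- setdiff(codes, h$edges$code)
  if (length(absent) > 0L) {
    if (on_missing == "error")
      stop("code(s) absent from hierarchy: ", paste(absent, collapse = ", "),
           " (use on_missing = \"root\" to keep them as roots)")
    warning("treating ", length(absent), " code(s) absent from hierarchy as roots")
  }
  anc <- lapply(codes, function(cd)
    if (cd %in% absent) character(0) else ancestors(h, cd))
  names(anc) <- codes
  n_anc <- lengths(anc)
  has <- n_anc[ev$code] > 0L
  if (any(has)) {
    idx <- rep(which(has), n_anc[ev$code[has]])
    extra <- ev[idx, , drop = FALSE]
    extra$code <- unlist(anc[ev$code[has]], use.names = FALSE)
    sysmap <- c(stats::setNames(h$edges$system, h$edges$code))
    extra$system <- ifelse(is.na(sysmap[extra$code]), extra$system,
                           sysmap[extra$code])
    ev <- rbind(ev, extra)
  }
  event_log(ev, log$outcomes)
}

#' Total occurrence count per label
#' @param log an `event_log`.
#' @return Named integer vector over the labels present in the events.
#' @export
label_counts <- function(log) {
  cnt <- tapply(log$events$count, log$events$code, sum)
  stats::setNames(as.integer(cnt), names(cnt))
}

#' Discard infrequent activity labels
#'
#' Removes every label whose total occurrence count across the log (all
#' patients, multiplicities included) is below `min_occurrences`. Apply
#' after hierarchy enrichment so that roll-up levels are counted too.
#'
#' @param log an enriched `event_log`.
#' @param min_occurrences non-negative threshold; the case study used 500.
#' @return List with `log` (filtered) and `retained_labels` (sorted).
#' @export
filter_infrequent <- function(log, min_occurrences) {
  if (length(min_occurrences) != 1L || is.na(min_occurrences) || min_occurrences < 0)
    stop("min_occurrences must be a non-negative number")
  cnt <- label_counts(log)
  retained <- sort(names(cnt)[cnt >= min_occurrences])
  list(log = apply_label_set(log, retained), retained_labels = retained)
}

#' Restrict an event log to a fixed label set
#'
#' Used to filter a test log by the labels retained on the training log.
#'
#' @param log an `event_log`.
#' @param labels non-empty character vector of labels to keep.
#' @return The filtered `event_log` with `label_set` set to `labels`
#'   (sorted).
#' @export
apply_label_set <- function(log, labels) {
  if (length(labels) == 0L) stop("labels must be non-empty")
  labels <- sort(unique(as.character(labels)))
  ev <- log$events[log$events$code %in% labels, , drop = FALSE]
  rownames(ev) <- NULL
  out <- event_log(ev, log$outcomes, label_set = labels)
  out
}

#' Stratified train/test split by patient
#'
#' Patients are partitioned so that each outcome class contributes
#' `test_fraction` of its patients (rounded) to the test log; no patient
#' appears in both. Deterministic for a fixed seed.
#'
#' @param log an `event_log` with both classes present.
#' @param test_fraction proportion in (0, 1); the case study used 0.2.
#' @param seed integer RNG seed.
#' @return List with `train` and `test` event logs (shared `label_set`).
#' @export
split_train_test <- function(log, test_fraction = 0.2, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  oc <- log$outcomes
  for (cl in c(0L, 1L))
    if (sum(oc$outcome == cl) < 2L)
      stop("class ", cl, " has fewer than 2 patients; cannot split")
  test_ids <- character(0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (cl in c(0L, 1L)) {
    ids <- sort(oc$patient_id[oc$outcome == cl])
    k <- round(test_fraction * length(ids))
    k <- max(1L, min(length(ids) - 1L, k))
    test_ids <- c(test_ids, sample(ids, k))
  }
  subset_log <- function(keep) {
    ev <- log$events[log$events$patient_id %in% keep, , drop = FALSE]
    rownames(ev) <- NULL
    structure(list(events = ev,
                   outcomes = oc[oc$patient_id %in% keep, , drop = FALSE],
                   label_set = log$label_set),
              class = "event_log")
  }
  list(train = subset_log(setdiff(oc$patient_id, test_ids)),
       test = subset_log(test_ids))
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
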