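#' Simulation configuration for synthetic event logs
#'
#' Describes a population of patients with independent Bernoulli background
#' activity per (patient, window, activity) cell, a binary outcome, and a
#' temporal motif — an ordered list of (activity, window) cells — planted in
#' a fraction (`pattern_penetrance`) of the positive class. A fraction of
#' negatives may carry the first half of the motif as confusing noise.
#'
#' @param n_patients population size.
#' @param positive_fraction outcome prevalence in (0, 1); default 0.4,
#'   matching the case study's 40.4% observed prevalence.
#' @param l_background number of background (leaf) activity labels.
#' @param w,window_days time-window geometry (windows count back from the
#'   index date).
#' @param background_rate per-cell Bernoulli activation probability.
#' @param pattern data.frame with columns `step` (label index into the
#'   activity set) and `window`; `NULL` for an automatic 6-step motif whose
#'   last step sits in the final window.
#' @param pattern_penetrance fraction of positives carrying the motif.
#' @param noise_in_negatives fraction of negatives carrying a partial
#'   (first-half) motif.
#' @param n_systems,branching,depth hierarchy shape: each system is a tree
#'   with `branching^depth` leaves; leaves supply the activity labels.
#' @param seed integer seed; every draw derives from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 2000L, positive_fraction = 0.4,
                              l_background = 20L, w = 26L, window_days = 28,
                              background_rate = 0.02, pattern = NULL,
                              pattern_penetrance = 0.9,
                              noise_in_negatives = 0.05,
                              n_systems = 2L, branching = 4L, depth = 2L,
                              seed = 1L) {
  if (positive_fraction <= 0 || positive_fraction >= 1)
    stop("positive_fraction must be in (0, 1)")
  for (pp in c(background_rate, pattern_penetrance, noise_in_negatives))
    if (pp < 0 || pp > 1) stop("probabilities must lie in [0, 1]")
  if (is.null(pattern)) {
    steps <- c(2L, 1L, 5L, 3L, 6L, 4L)
    steps <- steps[steps <= l_background]
    gap <- min(3L, max(1L, (w - 1L) %/% length(steps)))
    pattern <- data.frame(step = steps,
                          window = w - gap * (length(steps) - seq_along(steps)))
  }
  if (any(pattern$window < 1L | pattern$window > w))
    stop("pattern windows must lie within [1, w]")
  if (any(pattern$step < 1L | pattern$step > l_background))
    stop("pattern steps must index the background activities")
  structure(list(n_patients = as.integer(n_patients),
                 positive_fraction = positive_fraction,
                 l_background = as.integer(l_background),
                 w = as.integer(w), window_days = window_days,
                 background_rate = background_rate, pattern = pattern,
                 pattern_penetrance = pattern_penetrance,
                 noise_in_negatives = noise_in_negatives,
                 n_systems = as.integer(n_systems),
                 branching = as.integer(branching), depth = as.integer(depth),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Preset matching the paper-style worked example
#'
#' Seven activities, 26 four-weekly windows over two years, and the
#' six-step motif on activities (1-based) 2, 1, 5, 3, 2, 6 — i.e. the
#' 0-based sequence 1 -> 0 -> 4 -> 2 -> 1 -> 5 — planted at evenly spaced
#' windows. Background noise is light so the pattern dominates.
#'
#' @param seed integer seed.
#' @return A [simulation_config()].
#' @export
example1_config <- function(seed = 1L) {
  simulation_config(n_patients = 1000L, positive_fraction = 0.5,
                    l_background = 7L, w = 26L, window_days = 28,
                    background_rate = 0.02,
                    pattern = data.frame(step = c(2L, 1L, 5L, 3L, 2L, 6L),
                                         window = c(4L, 8L, 12L, 16L, 20L, 24L)),
                    pattern_penetrance = 1, noise_in_negatives = 0,
                    n_systems = 1L, branching = 7L, depth = 1L, seed = seed)
}

#' Default 2,000-patient benchmark preset
#'
#' 20 background activities from a 2-system hierarchy, 26 windows, 40%
#' prevalence, 6-activity motif ending in the last window, penetrance 0.9
#' and 5% partial-motif negatives.
#'
#' @param seed integer seed.
#' @return A [simulation_config()].
#' @export
benchmark_config <- function(seed = 1L) simulation_config(seed = seed)

#' Generate a deterministic code hierarchy
#'
#' Each system is a rooted tree: root tag (e.g. `DIAG`), `branching`
#' children per node, `depth` levels below the root. Codes are dotted paths
#' (`DIAG.2.3`); leaves (deepest level) serve as recordable activity codes.
#'
#' @param n_systems number of trees (tags drawn from DIAG, PROC, DEV, BIO,
#'   CONSULT, then SYS6...).
#' @param branching children per internal node (>= 1).
#' @param depth levels below each root (>= 1).
#' @param l_background required minimum number of leaves (error if the
#'   shape cannot supply them).
#' @return A [code_hierarchy()]; leaf codes in `attr(, "leaves")`.
#' @export
generate_hierarchy <- function(n_systems = 2L, branching = 4L, depth = 2L,
                               l_background = NULL) {
  if (branching < 1L || depth < 1L) stop("branching and depth must be >= 1")
  tags <- c("DIAG", "PROC", "DEV", "BIO", "CONSULT")
  if (n_systems > length(tags))
    tags <- c(tags, paste0("SYS", seq(length(tags) + 1L, n_systems)))
  tags <- tags[seq_len(n_systems)]
  rows <- list()
  leaves <- character(0)
  for (tag in tags) {
    level <- tag                      # codes at current level
    rows[[length(rows) + 1L]] <- data.frame(code = tag, parent = NA_character_,
                                            system = tag)
    for (dpt in seq_len(depth)) {
      child <- as.vector(t(outer(level, seq_len(branching), paste, sep = ".")))
      rows[[length(rows) + 1L]] <- data.frame(code = child,
                                              parent = rep(level, each = branching),
                                              system = tag)
      level <- child
    }
    leaves <- c(leaves, level)
  }
  if (!is.null(l_background) && length(leaves) < l_background)
    stop("hierarchy shape yields only ", length(leaves),
         " leaves; need >= ", l_background)
  h <- code_hierarchy(do.call(rbind, rows))
  attr(h, "leaves") <- leaves
  h
}

# deterministic event date for a cell: mid-window day
cell_date <- function(index_date, window, spec_w, window_days) {
  days_before <- (spec_w - window) * window_days + ceiling(window_days / 2)
  index_date - round(days_before)
}

#' Generate a synthetic event log with planted class structure
#'
#' Background events are independent Bernoulli draws per (patient, window,
#' activity); each motif carrier additionally receives the motif's
#' activities at their window offsets (event dates sit mid-window, so
#' tensorizing with the config's geometry recovers the planted cells
#' exactly). Fully deterministic for a fixed config seed.
#'
#' @param config a [simulation_config()].
#' @return List with `log` (an [event_log()]), `hierarchy` (the generating
#'   [code_hierarchy()]) and `truth` (planted cells as a data.frame
#'   `label, window`, carrier patient ids, and the config).
#' @export
generate_event_log <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  h <- generate_hierarchy(config$n_systems, config$branching, config$depth,
                          config$l_background)
  labels <- sort(attr(h, "leaves"))[seq_len(config$l_background)]
  sysmap <- stats::setNames(h$edges$system, h$edges$code)
  n <- config$n_patients; l <- config$l_background; w <- config$w
  ids <- sprintf("P%05d", seq_len(n))
  n_pos <- round(config$positive_fraction * n)
  classes <- stats::setNames(integer(n), ids)
  classes[sample.int(n, n_pos)] <- 1L
  index_dates <- stats::setNames(as.Date("2010-01-01") + sample.int(365, n, replace = TRUE) - 1L,
                                 ids)

  # background: one Bernoulli per (patient, activity, window)
  hits <- which(array(stats::runif(n * l * w) < config$background_rate,
                      dim = c(n, l, w)), arr.ind = TRUE)
  ev <- data.frame(patient_id = ids[hits[, 1]],
                   date = cell_date(index_dates[hits[, 1]], hits[, 3],
                                    w, config$window_days),
                   code = labels[hits[, 2]], stringsAsFactors = FALSE)

  # planted motif: full in carriers, first half in noisy negatives
  carriers <- ids[classes == 1L][stats::runif(n_pos) < config$pattern_penetrance]
  n_neg <- n - n_pos
  half <- config$pattern[seq_len(ceiling(nrow(config$pattern) / 2)), , drop = FALSE]
  noisy <- ids[classes == 0L][stats::runif(n_neg) < config$noise_in_negatives]
  plant <- function(who, pat) {
    if (length(who) == 0L || nrow(pat) == 0L) return(NULL)
    data.frame(patient_id = rep(who, each = nrow(pat)),
               date = cell_date(rep(index_dates[who], each = nrow(pat)),
                                rep(pat$window, length(who)),
                                w, config$window_days),
               code = labels[rep(pat$step, length(who))],
               stringsAsFactors = FALSE)
  }
  ev <- rbind(ev, plant(carriers, config$pattern), plant(noisy, half))
  ev$system <- unname(sysmap[ev$code])
  ev$count <- 1L

  outcomes <- data.frame(patient_id = ids, outcome = unname(classes),
                         index_date = unname(index_dates),
                         stringsAsFactors = FALSE)
  log <- event_log(ev, outcomes, label_set = labels)
  truth <- list(pattern = data.frame(label = labels[config$pattern$step],
                                     window = config$pattern$window,
                                     stringsAsFactors = FALSE),
                carriers = carriers, noisy_negatives = noisy, config = config)
  list(log = log, hierarchy = h, truth = truth)
}

#' The hand-worked hierarchy example pathway
#'
#' One patient over 9 daily windows with leaf activities A0, A1, B0, B1
#' under chapter parents A and B. After hierarchy enrichment its count
#' matrix is the 6 x 9 binary grid used throughout the documentation.
#'
#' @return List with `log`, `hierarchy` and `spec` (a 9-window daily
#'   [window_spec()]).
#' @export
fig_example_log <- function() {
  h <- code_hierarchy(data.frame(
    code = c("A", "B", "A0", "A1", "B0", "B1"),
    parent = c(NA, NA, "A", "A", "B", "B"),
    system = "DIAG", stringsAsFactors = FALSE))
  index <- as.Date("2010-01-10")
  spec <- window_spec(9L, 1)
  day <- function(j) index - (10L - j)      # window j -> its single day
  ev <- data.frame(
    patient_id = "P1",
    date = day(c(1L, 2L, 4L, 4L, 7L, 9L)),
    code = c("A0", "B0", "A1", "B1", "A0", "B1"),
    system = "DIAG", stringsAsFactors = FALSE)
  oc <- data.frame(patient_id = "P1", outcome = 1L, index_date = index,
                   stringsAsFactors = FALSE)
  list(log = event_log(ev, oc), hierarchy = h, spec = spec)
}

#' Write a suite of synthetic fixture files
#'
#' Emits, under `dir`: the hand-worked hierarchy example
#' (`fig_events.csv`, `fig_outcomes.csv`, `fig_hierarchy.csv`), a
#' 200-patient toy log (`toy_*.csv`), the 2,000-patient benchmark
#' (`benchmark_*.csv`) with its hierarchy and `ground_truth.json`, plus a
#' `manifest.json` of MD5 checksums. Byte-identical for a fixed seed.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed for the generated logs.
#' @return The manifest as a named list of checksums, invisibly.
#' @export
generate_fixture_suite <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(dir, f)
  write_hier <- function(h, path) {
    e <- h$edges
    e$parent[is.na(e$parent)] <- ""
    utils::write.csv(e, path, row.names = FALSE, quote = FALSE)
  }

  fx <- fig_example_log()
  write_event_log(fx$log, pth("fig_events.csv"), pth("fig_outcomes.csv"))
  write_hier(fx$hierarchy, pth("fig_hierarchy.csv"))

  toy <- generate_event_log(simulation_config(n_patients = 200L, seed = seed))
  write_event_log(toy$log, pth("toy_events.csv"), pth("toy_outcomes.csv"))

  bench <- generate_event_log(benchmark_config(seed = seed))
  write_event_log(bench$log, pth("benchmark_events.csv"),
                  pth("benchmark_outcomes.csv"))
  write_hier(bench$hierarchy, pth("benchmark_hierarchy.csv"))
  jsonlite::write_json(list(pattern = bench$truth$pattern,
                            carriers = bench$truth$carriers,
                            seed = seed),
                       pth("ground_truth.json"), auto_unbox = TRUE, digits = NA)

  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- as.list(tools::md5sum(files))
  names(manifest) <- basename(files)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
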