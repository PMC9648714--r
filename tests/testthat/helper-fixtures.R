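# Shared fixtures, all built in code at test time.

# small random event log with a fixed seed; events stay inside a 30-day
# window before a common index date
rand_log <- function(n_patients = 6L, n_codes = 5L, n_days = 30L,
                     n_rows = 50L, seed = 1L) {
  set.seed(seed)
  ids <- paste0("P", seq_len(n_patients))
  index <- as.Date("2010-06-30")
  ev <- data.frame(
    patient_id = sample(ids, n_rows, replace = TRUE),
    date = index - sample.int(n_days, n_rows, replace = TRUE),
    code = paste0("C", sample.int(n_codes, n_rows, replace = TRUE)),
    system = "DIAG", stringsAsFactors = FALSE)
  oc <- data.frame(patient_id = ids,
                   outcome = rep(c(0L, 1L), length.out = n_patients),
                   index_date = index, stringsAsFactors = FALSE)
  event_log(ev, oc)
}

# two-level hierarchy over C1..C5: parents PA (C1-C3) and PB (C4, C5)
rand_hierarchy <- function() {
  code_hierarchy(data.frame(
    code = c("PA", "PB", "C1", "C2", "C3", "C4", "C5"),
    parent = c(NA, NA, "PA", "PA", "PA", "PB", "PB"),
    system = "DIAG", stringsAsFactors = FALSE))
}

# small planted-pattern dataset for fast training tests
tiny_dataset <- function(n = 80L, l = 6L, w = 8L, seed = 3L) {
  set.seed(seed)
  cls <- rep(c(0L, 1L), length.out = n)
  X <- matrix(as.numeric(runif(n * l * w) < 0.05), n, l * w)
  # positives carry three fixed cells
  cells <- c(2L, 11L, 29L)
  X[cls == 1L, cells] <- 1
  ds <- rescale_counts(X)
  ds$row_labels <- paste0("A", seq_len(l))
  ds$patient_ids <- sprintf("T%03d", seq_len(n))
  ds$classes <- cls
  ds$systems <- stats::setNames(rep("DIAG", l), ds$row_labels)
  ds$window <- window_spec(w, 28)
  ds
}

# cache slow acceptance artifacts (benchmark data, trained models) so the
# criteria that share a run do not retrain
acc_env <- new.env(parent = emptyenv())

acc_benchmark <- function() {
  if (is.null(acc_env$train)) {
    gen <- generate_event_log(benchmark_config(seed = 1L))
    split <- split_train_test(gen$log, 0.2, seed = 1L)
    spec <- window_spec(26L, 28)
    train <- tensorize(split$train, spec)
    test <- tensorize(split$test, spec, rescale_factor = train$rescale_factor)
    acc_env$gen <- gen
    acc_env$train <- train
    acc_env$test <- test
  }
  acc_env
}

acc_vae_inverse <- function() {
  e <- acc_benchmark()
  if (is.null(e$vae))
    e$vae <- pathway_autoencoder(e$train, strategy = "inverse",
                                 architecture = "vae", max_epochs = 150L,
                                 seed = 1L)
  e
}
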