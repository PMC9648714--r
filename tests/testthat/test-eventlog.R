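test_that("reading a delimited log parses, merges same-day rows and validates", {
  d <- withr::local_tempdir()
  writeLines(c("patient_id,date,code,system",
               "P1,2010-01-03,C1,DIAG",
               "P1,2010-01-05,C2,DIAG",
               "P1,2010-01-05,C2,DIAG"),
             file.path(d, "ev.csv"))
  writeLines(c("patient_id,outcome,index_date", "P1,1,2010-02-01"),
             file.path(d, "oc.csv"))
  log <- read_event_log(file.path(d, "ev.csv"), file.path(d, "oc.csv"))
  expect_equal(n_events(log), 2L)
  expect_equal(log$events$count[log$events$code == "C2"], 2L)
  expect_equal(n_activities(log), 3L)

  # missing column named in the error; unknown patient listed
  writeLines(c("patient_id,date,system", "P1,2010-01-03,DIAG"),
             file.path(d, "bad.csv"))
  expect_error(read_event_log(file.path(d, "bad.csv"), file.path(d, "oc.csv")),
               "code")
  writeLines(c("patient_id,date,code,system", "P9,2010-01-03,C1,DIAG"),
             file.path(d, "orphan.csv"))
  expect_error(read_event_log(file.path(d, "orphan.csv"), file.path(d, "oc.csv")),
               "P9")

  # semicolon and tab delimiters are sniffed
  writeLines(c("patient_id;date;code;system", "P1;2010-01-03;C1;DIAG"),
             file.path(d, "semi.csv"))
  expect_equal(n_events(read_event_log(file.path(d, "semi.csv"),
                                       file.path(d, "oc.csv"))), 1L)
})

test_that("random log counts equal an independent group-by oracle", {
  set.seed(11)
  ids <- paste0("P", 1:4)
  raw <- data.frame(
    patient_id = sample(ids, 50, replace = TRUE),
    date = as.Date("2010-06-30") - sample.int(20, 50, replace = TRUE),
    code = paste0("C", sample.int(4, 50, replace = TRUE)),
    system = "DIAG", stringsAsFactors = FALSE)
  oc <- data.frame(patient_id = ids, outcome = c(0L, 1L, 0L, 1L),
                   index_date = as.Date("2010-06-30"))
  d <- withr::local_tempdir()
  utils::write.csv(raw, file.path(d, "ev.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(transform(oc, index_date = format(index_date)),
                   file.path(d, "oc.csv"), row.names = FALSE, quote = FALSE)
  log <- read_event_log(file.path(d, "ev.csv"), file.path(d, "oc.csv"))

  # oracle: brute-force tallies on the raw rows
  expect_equal(n_activities(log), nrow(raw))
  expect_equal(n_events(log), nrow(unique(raw[, c("patient_id", "date")])))
  oracle <- table(paste(raw$patient_id, raw$date, raw$code))
  got <- stats::setNames(log$events$count,
                         paste(log$events$patient_id, log$events$date,
                               log$events$code))
  expect_equal(sort(got), sort(stats::setNames(as.integer(oracle),
                                               names(oracle))))
})

test_that("write/read round-trip reproduces the canonical event multiset", {
  log <- rand_log(seed = 7)
  d <- withr::local_tempdir()
  write_event_log(log, file.path(d, "ev.csv"), file.path(d, "oc.csv"))
  back <- read_event_log(file.path(d, "ev.csv"), file.path(d, "oc.csv"))
  expect_equal(back$events, log$events)
  expect_equal(back$outcomes$outcome, log$outcomes$outcome)
})

test_that("hierarchy enrichment adds one ancestor occurrence per descendant occurrence", {
  h <- rand_hierarchy()
  log <- rand_log(seed = 2)
  enr <- enrich_with_hierarchy(log, h)

  # oracle: per (patient, date, parent), sum of leaf multiplicities
  parent_of <- c(C1 = "PA", C2 = "PA", C3 = "PA", C4 = "PB", C5 = "PB")
  ev <- log$events
  for (par in c("PA", "PB")) {
    kids <- names(parent_of)[parent_of == par]
    sub <- ev[ev$code %in% kids, , drop = FALSE]
    oracle <- tapply(sub$count, paste(sub$patient_id, sub$date), sum)
    got <- enr$events[enr$events$code == par, ]
    expect_equal(stats::setNames(got$count, paste(got$patient_id, got$date)),
                 stats::setNames(as.integer(oracle), names(oracle))[
                   paste(got$patient_id, got$date)])
    expect_equal(nrow(got), length(oracle))
  }
  # enrichment never removes occurrences
  expect_gte(n_activities(enr), n_activities(log))
  # original occurrences preserved
  expect_equal(sum(apply_label_set(enr, paste0("C", 1:5))$events$count),
               n_activities(log))
})

test_that("events holding only root codes are unchanged by enrichment", {
  h <- rand_hierarchy()
  ev <- data.frame(patient_id = "P1", date = as.Date("2010-01-05"),
                   code = "PA", system = "DIAG")
  oc <- data.frame(patient_id = "P1", outcome = 1L,
                   index_date = as.Date("2010-02-01"))
  log <- event_log(ev, oc)
  enr <- enrich_with_hierarchy(log, h)
  expect_equal(enr$events, log$events)
})

test_that("codes absent from the hierarchy error unless declared roots", {
  h <- rand_hierarchy()
  ev <- data.frame(patient_id = "P1", date = as.Date("2010-01-05"),
                   code = "ZZZ", system = "DIAG")
  oc <- data.frame(patient_id = "P1", outcome = 0L,
                   index_date = as.Date("2010-02-01"))
  log <- event_log(ev, oc)
  expect_error(enrich_with_hierarchy(log, h), "ZZZ")
  expect_warning(enr <- enrich_with_hierarchy(log, h, on_missing = "root"),
                 "root")
  expect_equal(enr$events$code, "ZZZ")
})

test_that("poly-hierarchies and cycles are rejected at load", {
  expect_error(code_hierarchy(data.frame(code = c("A", "A"),
                                         parent = c("B", "C"))),
               "poly-hierarchy")
  expect_error(code_hierarchy(data.frame(code = c("A", "B"),
                                         parent = c("B", "A"))),
               "cycle")
})

test_that("the worked hierarchy example yields l = 6 labels after enrichment", {
  fx <- fig_example_log()
  enr <- enrich_with_hierarchy(fx$log, fx$hierarchy)
  expect_equal(length(enr$label_set), 6L)
  expect_setequal(enr$label_set, c("A", "A0", "A1", "B", "B0", "B1"))
})

test_that("infrequent-label filtering matches an exhaustive tally oracle", {
  log <- rand_log(seed = 4)
  expect_error(filter_infrequent(log, -1), "non-negative")
  # threshold 0 leaves the log unchanged
  f0 <- filter_infrequent(log, 0L)
  expect_equal(f0$log$events, log$events)
  expect_equal(f0$retained_labels, sort(unique(log$events$code)))
  # threshold 8: oracle counts every occurrence
  oracle <- tapply(log$events$count, log$events$code, sum)
  f8 <- filter_infrequent(log, 8L)
  expect_equal(f8$retained_labels, sort(names(oracle)[oracle >= 8]))
  expect_true(all(f8$log$events$code %in% f8$retained_labels))
  # second application with the retained threshold is idempotent
  again <- filter_infrequent(f8$log, 8L)
  expect_equal(again$log$events, f8$log$events)
})

test_that("apply_label_set restricts the log exactly", {
  log <- rand_log(seed = 5)
  expect_equal(apply_label_set(log, log$label_set)$events, log$events)
  one <- apply_label_set(log, "C1")
  expect_true(all(one$events$code == "C1"))
  keep <- c("C2", "C4")
  sub <- apply_label_set(log, keep)
  expect_equal(sum(sub$events$count),
               sum(log$events$count[log$events$code %in% keep]))
  expect_equal(sub$label_set, sort(keep))
})

test_that("stratified split respects class ratios, determinism and partition", {
  set.seed(8)
  ids <- sprintf("P%03d", 1:100)
  oc <- data.frame(patient_id = ids,
                   outcome = c(rep(1L, 40), rep(0L, 60)),
                   index_date = as.Date("2010-06-30"))
  ev <- data.frame(patient_id = sample(ids, 300, replace = TRUE),
                   date = as.Date("2010-06-01"),
                   code = "C1", system = "DIAG")
  log <- event_log(ev, oc)
  sp <- split_train_test(log, 0.2, seed = 42)
  expect_equal(nrow(sp$test$outcomes), 20L)
  expect_equal(sum(sp$test$outcomes$outcome), 8L)
  expect_equal(nrow(sp$train$outcomes), 80L)
  # exact partition of the patient set
  expect_setequal(c(sp$train$outcomes$patient_id, sp$test$outcomes$patient_id),
                  ids)
  expect_length(intersect(sp$train$outcomes$patient_id,
                          sp$test$outcomes$patient_id), 0L)
  # determinism
  sp2 <- split_train_test(log, 0.2, seed = 42)
  expect_identical(sp$test$outcomes$patient_id, sp2$test$outcomes$patient_id)
  # degenerate class
  oc1 <- oc; oc1$outcome <- c(1L, rep(0L, 99))
  expect_error(split_train_test(event_log(ev, oc1), 0.2, 1), "fewer than 2")
})
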