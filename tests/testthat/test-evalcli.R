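# Metrics, attention diagnostics and the command-line interface.

test_that("metrics match the hand-computed worked case", {
  cm <- matrix(c(30, 10, 5, 8), 2)  # rows = true, cols = predicted
  rep <- compute_metrics(cm)
  expect_equal(rep$accuracy, 0.71698, tolerance = 1e-5)
  expect_equal(rep$f1, c(0.80000, 0.51613), tolerance = 1e-5)
  expect_equal(rep$weighted_f1, 0.70359, tolerance = 1e-4)
  expect_equal(rep$n, 53)
  perfect <- compute_metrics(diag(c(7, 9)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$weighted_f1, 1)
  expect_error(compute_metrics(matrix(0, 2, 2)), "all-zero")
})

test_that("a degenerate all-one-class predictor scores as expected", {
  cm <- matrix(c(10, 10, 0, 0), 2)  # predict everything class 1
  w <- capture_warnings(rep <- compute_metrics(cm))
  expect_true(any(grepl("zero denominator", w)))
  expect_equal(rep$accuracy, 0.5)
  expect_equal(rep$f1[2], 0)
})

test_that("metrics equal an independent per-class tally on random matrices", {
  oracle <- function(cm) {
    N <- sum(cm); C <- nrow(cm)
    prec <- rec <- f1 <- numeric(C)
    for (c in 1:C) {
      tp <- cm[c, c]
      fp <- sum(cm[-c, c]); fn <- sum(cm[c, -c])
      prec[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1[c] <- if (prec[c] + rec[c] > 0) 2 * prec[c] * rec[c] / (prec[c] + rec[c]) else 0
    }
    list(acc = sum(diag(cm)) / N,
         wf1 = sum(rowSums(cm) / N * f1), prec = prec, rec = rec)
  }
  set.seed(33)
  for (i in 1:1000) {
    C <- sample(2:4, 1)
    cm <- matrix(rpois(C * C, 4), C)
    if (sum(cm) == 0) cm[1, 1] <- 1
    rep <- suppressWarnings(compute_metrics(cm))
    o <- oracle(cm)
    expect_equal(rep$accuracy, o$acc, tolerance = 1e-12)
    expect_equal(rep$weighted_f1, o$wf1, tolerance = 1e-12)
    expect_equal(rep$precision, o$prec, tolerance = 1e-12)
    expect_equal(rep$recall, o$rec, tolerance = 1e-12)
  }
})

test_that("weighted F1 is invariant to class relabeling", {
  set.seed(44)
  cm <- matrix(rpois(9, 6) + 1, 3)
  perm <- c(3, 1, 2)
  r1 <- compute_metrics(cm)
  r2 <- compute_metrics(cm[perm, perm])
  expect_equal(r1$weighted_f1, r2$weighted_f1, tolerance = 1e-12)
  expect_equal(r1$accuracy, r2$accuracy, tolerance = 1e-12)
  expect_equal(r1$f1[perm], r2$f1, tolerance = 1e-12)
})

test_that("attention reports are simplex-consistent with saliency masses", {
  ds <- tiny_dataset()
  m <- pm_init_model(pm_config(), seed = 12)
  rep <- attention_report(m, ds, ids = ds$manifest$session_id[1:6],
                          alpha_g = 1.5)
  for (r in rep) {
    expect_equal(sum(r$softmax), 1, tolerance = 1e-9)
    expect_equal(sum(r$entmax), 1, tolerance = 1e-9)
    if (!is.null(r$n_event_chunks) && r$n_event_chunks > 0) {
      off_mass <- sum(r$entmax) - r$event_mass_entmax
      expect_equal(r$event_mass_entmax + off_mass, 1, tolerance = 1e-9)
      expect_gte(r$event_mass_entmax, 0)
    }
  }
  # uniform weights over T chunks have entropy log T (singleton: 0)
  one <- rep[[1]]
  expect_equal(one$entropy_softmax, shannon_entropy(one$softmax))
  short <- ds
  short$waveforms[[ds$manifest$session_id[1]]] <- rnorm(50)
  expect_warning(attention_report(m, short, ids = ds$manifest$session_id[1]),
                 "skipped")
})

test_that("ablation bookkeeping yields one row per run plus medians", {
  ds <- tiny_dataset()
  tab <- suppressWarnings(ablation_suite(
    ds, c("pooling:average", "curriculum:direct"), seeds = c(1, 2),
    epochs = c(1L, 0L, 1L)))
  expect_equal(sum(tab$stat == "run"), 4)
  expect_equal(sum(tab$stat == "median"), 2)
  med <- tab[tab$stat == "median" & tab$variant == "pooling:average", ]
  runs <- tab[tab$stat == "run" & tab$variant == "pooling:average", ]
  expect_equal(med$accuracy, median(runs$accuracy))
  expect_error(ablation_suite(ds, "pooling:rococo", seeds = 1), "unknown variant")
})

test_that("the CLI pipeline runs synth/split/train/eval deterministically", {
  dir <- withr::local_tempdir()
  data_dir <- file.path(dir, "data")
  run_dir <- file.path(dir, "run")
  rep_file <- file.path(dir, "report.json")
  expect_equal(run_cli(c("synth", "--n-sessions", "12", "--duration", "43",
                         "--noise-sd", "0.05", "--event-min", "2",
                         "--event-max", "3", "--seed", "7",
                         "--out-dir", data_dir)), 0L)
  expect_true(file.exists(file.path(data_dir, "manifest.json")))
  expect_equal(run_cli(c("split", "--dir", data_dir, "--fractions",
                         "0.5", "0.25", "0.25", "--seed", "7")), 0L)
  man <- jsonlite::fromJSON(file.path(data_dir, "manifest.json"))
  expect_equal(sort(unique(man$split)), c("test", "train", "val"))
  expect_equal(run_cli(c("train", "--dir", data_dir, "--target", "arousal",
                         "--seed", "7", "--epochs", "1,1,1",
                         "--out", run_dir)), 0L)
  expect_equal(suppressWarnings(
    run_cli(c("eval", "--run", run_dir, "--dir", data_dir,
              "--out", rep_file))), 0L)
  rep <- jsonlite::fromJSON(rep_file)
  expect_true(rep$accuracy >= 0 && rep$accuracy <= 1)
  expect_match(rep$convention, "rows = true")
  # determinism of the full pipeline report
  rep_file2 <- file.path(dir, "report2.json")
  run_dir2 <- file.path(dir, "run2")
  expect_equal(run_cli(c("train", "--dir", data_dir, "--target", "arousal",
                         "--seed", "7", "--epochs", "1,1,1",
                         "--out", run_dir2)), 0L)
  expect_equal(suppressWarnings(
    run_cli(c("eval", "--run", run_dir2, "--dir", data_dir,
              "--out", rep_file2))), 0L)
  expect_identical(readLines(rep_file), readLines(rep_file2))
  # attention report over the CLI
  att_file <- file.path(dir, "att.jsonl")
  expect_equal(run_cli(c("attend", "--run", run_dir, "--dir", data_dir,
                         "--out", att_file)), 0L)
  expect_gt(length(readLines(att_file)), 0)
})

test_that("the CLI rejects bad invocations with exit code 2", {
  expect_equal(suppressMessages(run_cli(character(0))), 2L)
  expect_equal(suppressMessages(run_cli(c("trainify"))), 2L)
  expect_equal(suppressMessages(
    run_cli(c("train", "--dir", "x", "--target", "mood", "--out", "y"))), 2L)
  expect_equal(suppressMessages(
    run_cli(c("eval", "--run", "/nonexistent", "--dir", "x", "--out", "y"))), 2L)
  dir <- withr::local_tempdir()
  yaml::write_yaml(list(bogus_key = 1), file.path(dir, "bad.yaml"))
  expect_equal(suppressMessages(
    run_cli(c("describe", "--config", file.path(dir, "bad.yaml")))), 2L)
  expect_equal(run_cli("describe"), 0L)
})
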