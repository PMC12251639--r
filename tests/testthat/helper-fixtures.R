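# Shared fixtures. The tiny dataset and smoke-scale training runs are built
# once per test session and reused across test files.

.fixture_env <- new.env(parent = emptyenv())

# Small split dataset for IO / training plumbing tests: 20 sessions of
# 10 chunks each.
tiny_dataset <- function() {
  if (is.null(.fixture_env$tiny)) {
    ds <- generate_dataset(20, 0.5, c(2, 3), duration_s = 43,
                           noise_sd = 0.05, seed = 401)
    ds$manifest <- split_manifest(ds$manifest, seed = 401)
    .fixture_env$tiny <- ds
  }
  .fixture_env$tiny
}

# The synthetic end-to-end benchmark: 200 sessions x 20 chunks, 3 event
# chunks in every high-arousal session, trained 5/5/10 epochs at batch 8.
# Trained once and shared by every test that inspects it.
benchmark_fit <- function() {
  if (is.null(.fixture_env$bench)) {
    ds <- generate_dataset(200, 0.5, c(3, 3), duration_s = 86,
                           noise_sd = 0.05, seed = 11)
    ds$manifest <- split_manifest(ds$manifest, seed = 11)
    fit <- run_curriculum(ds, "arousal", epochs = c(5L, 5L, 10L), seed = 1)
    .fixture_env$bench <- list(dataset = ds, fit = fit)
  }
  .fixture_env$bench
}

# Reduced-scale ablation benchmark runs (100 sessions x 10 chunks,
# 1/4/3 epochs, 3 seeds); each named configuration is trained on demand and
# cached so shared baselines are reused across comparisons. The split is
# stratified by class so the small test set always contains both classes
# and accuracy comparisons are informative.
ablation_accuracy <- function(key, seeds = 1:3) {
  if (is.null(.fixture_env$abl)) {
    .fixture_env$abl_ds <- local({
      ds <- generate_dataset(100, 0.5, c(2, 3), duration_s = 43,
                             noise_sd = 0.05, seed = 202)
      man <- ds$manifest
      hi <- binarize_rating(man$rating_arousal) == "high"
      man2 <- rbind(split_manifest(man[hi, ], seed = 202),
                    split_manifest(man[!hi, ], seed = 203))
      ds$manifest <- man2[match(man$session_id, man2$session_id), ]
      ds
    })
    .fixture_env$abl <- list()
  }
  # full curriculum + gated pooling + 3 branches is the shared canonical
  # baseline of all three directional comparisons; train it only once
  if (key %in% c("full", "gated", "branch3")) key <- "canonical"
  runs <- vapply(seeds, function(sd) {
    id <- paste0(key, "#", sd)
    if (is.null(.fixture_env$abl[[id]])) {
      cfg <- switch(key,
        canonical = pm_config(), direct = pm_config(),
        average = pm_config(pooling = "average"),
        branch1 = pm_config(n_branches = 1))
      curr <- if (key == "direct") "direct" else "full"
      fit <- run_curriculum(.fixture_env$abl_ds, "arousal", config = cfg,
                            epochs = c(1L, 4L, 3L), seed = sd,
                            curriculum = curr)
      rep <- suppressWarnings(evaluate_model(fit, .fixture_env$abl_ds))
      .fixture_env$abl[[id]] <- rep$accuracy
    }
    .fixture_env$abl[[id]]
  }, numeric(1))
  stats::median(runs)
}
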