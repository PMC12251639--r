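# Evaluation: confusion matrices, accuracy / per-class precision-recall-F1 /
# weighted F1, attention diagnostics against known saliency masks, and the
# ablation runner.
#
# Convention (stated in every output): rows = true class, columns =
# predicted class; class 2 ("high") is the positive class.

#' Confusion matrix from true and predicted class indices
#'
#' @param true,pred Integer vectors of 1-based class indices.
#' @param n_classes Number of classes.
#' @return `n_classes x n_classes` integer matrix, rows = true,
#'   columns = predicted.
#' @export
confusion_matrix <- function(true, pred, n_classes = 2L) {
  if (length(true) != length(pred)) stop("confusion_matrix: length mismatch")
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = seq_len(n_classes),
                               pred = seq_len(n_classes)))
  for (i in seq_along(true)) cm[true[i], pred[i]] <- cm[true[i], pred[i]] + 1L
  cm
}

#' Metrics from a confusion matrix
#'
#' Accuracy, per-class precision / recall / F1 and the class-frequency
#' weighted F1. Rows are true classes, columns predicted. Classes with a
#' zero denominator get metric 0 with a warning.
#'
#' @param confusion Square matrix of non-negative counts (rows = true).
#' @return List with `accuracy`, `precision`, `recall`, `f1`,
#'   `weighted_f1`, `n_per_class`, `n`, `confusion`.
#' @export
#' @examples
#' compute_metrics(matrix(c(30, 10, 5, 8), 2))$accuracy  # 38/53
compute_metrics <- function(confusion) {
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm)) stop("compute_metrics: matrix must be square")
  N <- sum(cm)
  if (N == 0) stop("compute_metrics: all-zero confusion matrix")
  C <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den, what) {
    out <- numeric(length(num))
    zero <- den == 0
    if (any(zero)) warning("compute_metrics: zero denominator in ", what,
                           "; metric set to 0")
    out[!zero] <- num[!zero] / den[!zero]
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "F1")
  n_c <- rowSums(cm)
  list(accuracy = sum(tp) / N,
       precision = precision, recall = recall, f1 = f1,
       weighted_f1 = sum(n_c / N * f1),
       n_per_class = n_c, n = N, confusion = cm)
}

#' Evaluate a trained model on one split of a dataset
#'
#' @param fit A `pm_fit` from [run_curriculum()], or a bare `pm_model`
#'   (then `alpha_g` should be given).
#' @param dataset A `pm_dataset` with split tags.
#' @param split Which split to evaluate (`"test"` by default).
#' @param target Affect dimension; defaults to the fit's target.
#' @param alpha_g Pooling entmax alpha; defaults to the fit's
#'   best-checkpoint value.
#' @return An evaluation report (see [compute_metrics()]) with an extra
#'   `predictions` data.frame (`session_id`, `true`, `pred`).
#' @export
evaluate_model <- function(fit, dataset, split = "test", target = NULL,
                           alpha_g = NULL) {
  if (inherits(fit, "pm_fit")) {
    model <- fit$model
    if (is.null(target)) target <- fit$target
    if (is.null(alpha_g)) alpha_g <- fit$alpha_g_best
  } else {
    model <- fit
    if (is.null(target)) target <- "arousal"
    if (is.null(alpha_g)) alpha_g <- 1.5
  }
  sessions <- prep_sessions(dataset, target)
  sessions <- sessions[vapply(sessions, function(s) s$split, character(1)) == split]
  if (length(sessions) == 0) stop("evaluate_model: no sessions in split '", split, "'")
  pr <- predict_core(model$config, model$par, model$sigma, sessions, alpha_g)
  rep <- compute_metrics(confusion_matrix(pr$labels, pr$preds,
                                          model$config$n_classes))
  rep$predictions <- data.frame(
    session_id = vapply(sessions, function(s) s$id, character(1)),
    true = pr$labels, pred = pr$preds)
  rep
}

#' Attention diagnostics per session
#'
#' For each session, emits the chunk-weight distribution under softmax and
#' under alpha-entmax attention, the Shannon entropies of both, and — when a
#' saliency mask is available — the fraction of entmax and softmax attention
#' mass falling on event chunks. Sessions shorter than one chunk are
#' skipped with a warning.
#'
#' @param fit A `pm_fit` or `pm_model`.
#' @param dataset A `pm_dataset` (masks are taken from `dataset$masks`).
#' @param ids Session ids to report; default all.
#' @param alpha_g Entmax alpha for the sparse distribution; defaults to the
#'   fit's best-checkpoint value (1.5 for a bare model).
#' @param out_file Optional path: one JSON object per line is written.
#' @return List of per-session records, invisibly the path if written.
#' @export
attention_report <- function(fit, dataset, ids = NULL, alpha_g = NULL,
                             out_file = NULL) {
  if (inherits(fit, "pm_fit")) {
    model <- fit$model
    if (is.null(alpha_g)) alpha_g <- fit$alpha_g_best
  } else {
    model <- fit
    if (is.null(alpha_g)) alpha_g <- 1.5
  }
  man <- dataset$manifest
  if (is.null(ids)) ids <- man$session_id
  out <- list()
  for (id in ids) {
    w <- dataset$waveforms[[id]]
    if (length(w) < model$config$chunk_len) {
      warning("attention_report: session ", id, " shorter than one chunk; skipped")
      next
    }
    ch <- chunk_waveform(w, model$config$chunk_len)
    H <- t(mtde_forward(model, ch))
    sc <- scorer_fwd(model$par, H, model$sigma, training = FALSE)
    ent <- if (ncol(H) == 1L) 1 else entmax_bisect(sc$scaled, alpha_g)
    sm <- softmax(sc$scaled)
    rec <- list(session_id = id, n_chunks = ncol(H),
                softmax = sm, entmax = ent,
                entropy_softmax = shannon_entropy(sm),
                entropy_entmax = shannon_entropy(ent))
    mask <- dataset$masks[[id]]
    if (!is.null(mask)) {
      m <- mask[seq_len(ncol(H))]
      rec$event_mass_entmax <- sum(ent[m == 1])
      rec$event_mass_softmax <- sum(sm[m == 1])
      rec$n_event_chunks <- sum(m)
    }
    out[[id]] <- rec
  }
  if (!is.null(out_file)) {
    lines <- vapply(out, function(r)
      jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA), character(1))
    writeLines(lines, out_file)
  }
  out
}

ablation_levels <- list(
  pooling = c("gated", "attention", "average"),
  branches = c("1", "2", "3", "4"),
  curriculum = c("full", "no-topk", "no-aux", "no-supcon", "direct")
)

#' Run an ablation suite
#'
#' Trains and evaluates one model per (variant, seed) pair on a dataset and
#' reports test accuracy and weighted F1 plus per-variant medians. Variants
#' are `"family:level"` strings with families `pooling`
#' (gated/attention/average), `branches` (1/2/3/4) and `curriculum`
#' (full/no-topk/no-aux/no-supcon/direct); each is applied to the canonical
#' baseline.
#'
#' @param dataset A split `pm_dataset`.
#' @param variants Character vector of `"family:level"` variant names.
#' @param seeds Integer vector of training seeds.
#' @param target Affect dimension.
#' @param epochs Per-phase epoch counts passed to [run_curriculum()].
#' @param out_csv Optional CSV path for the results table.
#' @param ... Further arguments to [run_curriculum()].
#' @return data.frame with one row per (variant, seed) and one `median` row
#'   per variant (`stat` column distinguishes them).
#' @export
ablation_suite <- function(dataset, variants, seeds = 1:3,
                           target = "arousal", epochs = c(3L, 3L, 6L),
                           out_csv = NULL, ...) {
  parse_variant <- function(v) {
    parts <- strsplit(v, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[1] %in% names(ablation_levels) ||
        !parts[2] %in% ablation_levels[[parts[1]]]) {
      stop("ablation_suite: unknown variant '", v, "'")
    }
    parts
  }
  specs <- lapply(variants, parse_variant)
  rows <- list()
  for (k in seq_along(specs)) {
    fam <- specs[[k]][1]; lev <- specs[[k]][2]
    for (sd in seeds) {
      cfg <- switch(fam,
        pooling = pm_config(pooling = lev),
        branches = pm_config(n_branches = as.integer(lev)),
        curriculum = pm_config())
      curr <- if (fam == "curriculum") lev else "full"
      fit <- run_curriculum(dataset, target = target, config = cfg,
                            epochs = epochs, seed = sd, curriculum = curr, ...)
      rep <- suppressWarnings(evaluate_model(fit, dataset))
      rows[[length(rows) + 1]] <- data.frame(
        variant = variants[k], seed = sd, stat = "run",
        accuracy = rep$accuracy, weighted_f1 = rep$weighted_f1)
    }
  }
  tab <- do.call(rbind, rows)
  med <- do.call(rbind, lapply(unique(tab$variant), function(v) {
    sub <- tab[tab$variant == v, ]
    data.frame(variant = v, seed = NA_integer_, stat = "median",
               accuracy = stats::median(sub$accuracy),
               weighted_f1 = stats::median(sub$weighted_f1))
  }))
  out <- rbind(tab, med)
  rownames(out) <- NULL
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
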