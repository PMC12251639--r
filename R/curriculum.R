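# Three-phase curriculum: representation learning (supervised contrastive +
# entropy regularization), Top-K focal chunk discrimination, and session-
# level fine-tuning, with module freezing, Top-K and alpha_g annealing,
# AdamW and per-phase cosine-annealed learning rates.

#' Phase configuration at a given epoch
#'
#' Phase 0 trains the encoder, attention scorer and projection head with the
#' contrastive + entropy objective (lr 3e-4, weight decay 1e-4). Phase 1
#' freezes the projection and trains encoder, scorer and the chunk auxiliary
#' classifier on the Top-K focal loss (lr 2e-4, wd 5e-4) while the Top-K
#' ratio anneals from 0.9 to 0.3; two thirds of the way through, the gate /
#' pooling parameters are unfrozen although the session loss is not yet
#' active. Phase 2 fine-tunes everything on the session cross-entropy alone
#' (lr 1e-4, scorer at 0.1x) while the pooling entmax alpha_g anneals from
#' 1.5 to 1.8. Learning rates are cosine-annealed within each phase.
#'
#' @param epoch 0-based epoch.
#' @param epochs Integer vector `(phase0, phase1, phase2)` epoch counts;
#'   the default `(15, 15, 21)` spans epochs 0-50.
#' @param lambda_entropy Weight of the entropy regularizer in Phase 0.
#' @param topk_range Top-K ratio endpoints annealed across Phase 1.
#' @param alpha_g_range Pooling entmax alpha endpoints annealed across
#'   Phase 2.
#' @param scorer_alpha Entmax alpha used by the scorer for chunk selection.
#' @param lrs,wds Per-phase base learning rates and weight decays.
#' @return A `phase_config` list (phase id, learning rate, active losses,
#'   trainable module groups, Top-K ratio, alpha_g, ...).
#' @export
phase_schedule <- function(epoch, epochs = c(15L, 15L, 21L),
                           lambda_entropy = 0.01,
                           topk_range = c(0.9, 0.3),
                           alpha_g_range = c(1.5, 1.8),
                           scorer_alpha = 1.5,
                           lrs = c(3e-4, 2e-4, 1e-4),
                           wds = c(1e-4, 5e-4, 5e-4)) {
  stopifnot(epoch >= 0, length(epochs) == 3, sum(epochs) >= 1)
  e0 <- epochs[1]; e1 <- epochs[2]; e2 <- epochs[3]
  total <- e0 + e1 + e2
  if (epoch >= total) epoch <- total - 1
  phase <- if (epoch < e0) 0L else if (epoch < e0 + e1) 1L else 2L
  phase_start <- c(0, e0, e0 + e1)[phase + 1L]
  phase_len <- c(e0, e1, e2)[phase + 1L]
  i <- epoch - phase_start
  lr <- lrs[phase + 1L] * 0.5 * (1 + cos(pi * i / max(phase_len, 1)))
  topk_ratio <- if (e1 > 1) {
    schedule_value(linear_schedule(e0, e0 + e1 - 1, topk_range[1], topk_range[2]), epoch)
  } else topk_range[2]
  alpha_g <- if (e2 > 1) {
    schedule_value(linear_schedule(e0 + e1, total - 1, alpha_g_range[1], alpha_g_range[2]), epoch)
  } else alpha_g_range[1]
  gate_unfreeze_epoch <- e0 + ceiling(2 * e1 / 3)
  trainable <- switch(phase + 1L,
    c("mtde", "scorer", "projection"),
    c("mtde", "scorer", "classifier",
      if (epoch >= gate_unfreeze_epoch) "gate"),
    c("mtde", "scorer", "gate", "classifier"))
  lr_mult <- c(mtde = 1, scorer = if (phase == 2L) 0.1 else 1,
               gate = 1, classifier = 1, projection = 1)
  structure(list(
    phase = phase, epoch = epoch, phase_start = phase_start,
    phase_len = phase_len, lr = lr, weight_decay = wds[phase + 1L],
    lambda_entropy = lambda_entropy, topk_ratio = topk_ratio,
    alpha_g = alpha_g, scorer_alpha = scorer_alpha,
    active_losses = switch(phase + 1L, c("supcon", "entropy"), "focal",
                           "session_ce"),
    trainable = trainable, lr_mult = lr_mult
  ), class = "phase_config")
}

#' Hand the chunk auxiliary classifier over to the main classifier
#'
#' The auxiliary and main classifiers share one parameter set, so the
#' handover is the identity; this function validates the shapes and logs
#' the event.
#'
#' @param aux_state List with `cls1_W`, `cls1_b`, `cls2_W`, `cls2_b`.
#' @param config The model configuration the main head must match.
#' @return The (unchanged) classifier state.
#' @export
handover_classifier <- function(aux_state, config = pm_config()) {
  expect_dims <- function(x, d) !is.null(x) && all(dim(as.matrix(x)) == d)
  if (!expect_dims(aux_state$cls1_W, c(config$classifier_hidden, config$embed_dim)) ||
      !expect_dims(aux_state$cls2_W, c(config$n_classes, config$classifier_hidden))) {
    stop("handover_classifier: auxiliary head shapes do not match the main classifier")
  }
  message("handover_classifier: shared parameter set; identity handover")
  aux_state
}

# ---- internal training machinery ------------------------------------------

prep_sessions <- function(dataset, target) {
  man <- dataset$manifest
  rating <- if (target == "arousal") man$rating_arousal else man$rating_valence
  lab <- ifelse(binarize_rating(rating) == "high", 2L, 1L)
  lapply(seq_len(nrow(man)), function(i) {
    ch <- chunk_waveform(dataset$waveforms[[man$session_id[i]]])
    list(id = man$session_id[i], flat = as.vector(t(ch)), T = nrow(ch),
         label = lab[i], split = man$split[i])
  })
}

adam_init <- function(par) list(m = zero_grads(par), v = zero_grads(par), t = 0)

adam_update <- function(par, grads, adam, lr, wd, names_upd, lr_mult_by_name) {
  adam$t <- adam$t + 1
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  c1 <- 1 - b1^adam$t; c2 <- 1 - b2^adam$t
  for (n in names_upd) {
    g <- grads[[n]]
    adam$m[[n]] <- b1 * adam$m[[n]] + (1 - b1) * g
    adam$v[[n]] <- b2 * adam$v[[n]] + (1 - b2) * g * g
    step <- (adam$m[[n]] / c1) / (sqrt(adam$v[[n]] / c2) + eps)
    lrn <- lr * lr_mult_by_name[[n]]
    decay <- if (grepl("_W$", n) || n == "pool_w") wd else 0
    par[[n]] <- par[[n]] - lrn * (step + decay * par[[n]])
  }
  list(par = par, adam = adam)
}

# Inference over a list of prepared sessions; returns predictions and
# per-session attention distributions.
predict_core <- function(config, par, sigma, sessions, alpha_g,
                         want_attention = FALSE) {
  model <- structure(list(config = config, par = par), class = "pm_model")
  n <- length(sessions)
  preds <- integer(n); labels <- integer(n)
  probs <- matrix(NA_real_, n, config$n_classes)
  att <- if (want_attention) vector("list", n) else NULL
  for (i in seq_len(n)) {
    s <- sessions[[i]]
    H <- mtde_fwd(model, s$flat, s$T, keep_cache = FALSE)$H
    sc <- scorer_fwd(par, H, sigma, training = FALSE)
    alpha <- if (ncol(H) == 1L) 1 else entmax_bisect(sc$scaled, alpha_g)
    gp <- gate_pool_fwd(par, H, alpha, config$pooling)
    p <- as.vector(classifier_fwd(par, matrix(gp$pooled, ncol = 1))$probs)
    preds[i] <- which.max(p)
    labels[i] <- s$label
    probs[i, ] <- p
    if (want_attention) {
      att[[i]] <- list(id = s$id, entmax = alpha,
                       softmax = softmax(sc$scaled))
    }
  }
  list(preds = preds, labels = labels, probs = probs, attention = att)
}

#' Train a model with the three-phase curriculum
#'
#' Executes Phases 0 -> 1 -> 2 with AdamW, per-phase cosine-annealed
#' learning rates, per-session attention normalization (chunks from
#' different sessions are never mixed), epoch logging and retention of the
#' best-validation checkpoint. Fully reproducible given `seed`.
#'
#' @param dataset A `pm_dataset` whose manifest carries train/val/test split
#'   tags (see [split_manifest()]), or a directory path readable by
#'   [read_dataset()].
#' @param target `"arousal"` or `"valence"` (one binary model per affect
#'   dimension).
#' @param config A [pm_config()].
#' @param epochs Integer vector of per-phase epoch counts.
#' @param batch_sessions Sessions per optimizer step (default 8).
#' @param seed Integer seed for initialization, shuffling and subsampling.
#' @param curriculum `"full"`, or an ablation variant: `"no-topk"` (Top-K
#'   ratio held at 1), `"no-aux"` (Phase 1 skipped), `"no-supcon"` (Phase 0
#'   skipped), `"direct"` (Phase 2 only).
#' @param lambda_entropy,tau,topk_range,alpha_g_range,scorer_alpha,lrs,wds
#'   Curriculum hyperparameters (see [phase_schedule()]; `tau` is the
#'   contrastive temperature).
#' @param max_contrast_chunks Per-session cap on chunks entering the
#'   contrastive batch.
#' @param verbose Print one line per epoch?
#' @return A `pm_fit` list: `model` (best-validation), `final_model`,
#'   `log` (one data.frame row per epoch), `target`, `seed`,
#'   `alpha_g_final`.
#' @export
run_curriculum <- function(dataset, target = c("arousal", "valence"),
                           config = pm_config(), epochs = c(15L, 15L, 21L),
                           batch_sessions = 8L, seed = 1L,
                           curriculum = c("full", "no-topk", "no-aux",
                                          "no-supcon", "direct"),
                           lambda_entropy = 0.01, tau = 0.1,
                           topk_range = c(0.9, 0.3),
                           alpha_g_range = c(1.5, 1.8), scorer_alpha = 1.5,
                           lrs = c(3e-4, 2e-4, 1e-4),
                           wds = c(1e-4, 5e-4, 5e-4),
                           max_contrast_chunks = 32L, verbose = FALSE) {
  target <- match.arg(target)
  curriculum <- match.arg(curriculum)
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  epochs <- as.integer(epochs)
  if (curriculum == "no-aux") epochs[2] <- 0L
  if (curriculum == "no-supcon") epochs[1] <- 0L
  if (curriculum == "direct") epochs[1:2] <- 0L
  if (curriculum == "no-topk") topk_range <- c(1, 1)
  total_epochs <- sum(epochs)
  if (total_epochs < 1) stop("run_curriculum: no epochs to run")

  sessions <- prep_sessions(dataset, target)
  if (any(vapply(sessions, function(s) s$T, integer(1)) < 1)) {
    stop("run_curriculum: a session is shorter than one chunk")
  }
  splits <- vapply(sessions, function(s) s$split, character(1))
  train_set <- sessions[splits == "train"]
  val_set <- sessions[splits == "val"]
  if (length(train_set) == 0) stop("run_curriculum: empty training split")

  set.seed(seed)
  model <- pm_init_model(config, seed = sample.int(.Machine$integer.max - 1L, 1))
  par <- model$par
  sigma <- model$sigma
  adam <- adam_init(par)
  groups <- param_groups(par)

  # focal class weights: inverse class frequency on the training split,
  # normalized to mean 1
  tr_lab <- vapply(train_set, function(s) s$label, integer(1))
  freq <- tabulate(tr_lab, nbins = config$n_classes)
  alpha_t <- ifelse(freq > 0, 1 / freq, 0)
  alpha_t <- alpha_t / mean(alpha_t[freq > 0])

  log_rows <- vector("list", total_epochs)
  best <- list(acc = -Inf, par = NULL, sigma = NULL, epoch = NA, alpha_g = NA)

  for (epoch in 0:(total_epochs - 1)) {
    ph <- phase_schedule(epoch, epochs, lambda_entropy, topk_range,
                         alpha_g_range, scorer_alpha, lrs, wds)
    ord <- sample.int(length(train_set))
    batch_starts <- seq(1, length(train_set), by = batch_sessions)
    epoch_loss <- 0; n_batches <- 0
    trainable_names <- unlist(groups[ph$trainable], use.names = FALSE)
    lr_mult_by_name <- stats::setNames(
      rep(1, length(trainable_names)), trainable_names)
    for (grp in names(groups)) {
      lr_mult_by_name[intersect(trainable_names, groups[[grp]])] <- ph$lr_mult[[grp]]
    }

    for (bs in batch_starts) {
      idx <- ord[bs:min(bs + batch_sessions - 1, length(train_set))]
      batch <- train_set[idx]
      step <- train_step(config, par, sigma, batch, ph, tau, alpha_t,
                         max_contrast_chunks)
      sigma <- step$sigma
      if (!is.finite(step$loss)) {
        stop("run_curriculum: divergent (non-finite) loss at epoch ", epoch)
      }
      upd <- adam_update(par, step$grads, adam, ph$lr, ph$weight_decay,
                         trainable_names, lr_mult_by_name)
      par <- upd$par; adam <- upd$adam
      epoch_loss <- epoch_loss + step$loss; n_batches <- n_batches + 1
    }

    val <- if (length(val_set) > 0) {
      pr <- predict_core(config, par, sigma, val_set, ph$alpha_g)
      cm <- confusion_matrix(pr$labels, pr$preds, config$n_classes)
      rep <- suppressWarnings(compute_metrics(cm))
      list(acc = rep$accuracy, wf1 = rep$weighted_f1)
    } else list(acc = NA_real_, wf1 = NA_real_)

    log_rows[[epoch + 1]] <- data.frame(
      epoch = epoch, phase = ph$phase, loss = epoch_loss / max(n_batches, 1),
      lr = ph$lr, topk_ratio = ph$topk_ratio, alpha_g = ph$alpha_g,
      val_accuracy = val$acc, val_weighted_f1 = val$wf1, seed = seed)
    if (verbose) {
      message(sprintf("epoch %3d phase %d loss %.4f val_acc %s", epoch,
                      ph$phase, epoch_loss / max(n_batches, 1),
                      format(val$acc, digits = 4)))
    }
    if (!is.na(val$acc) && val$acc >= best$acc) {
      best <- list(acc = val$acc, par = par, sigma = sigma, epoch = epoch,
                   alpha_g = ph$alpha_g)
    }
  }

  if (is.null(best$par)) {
    best <- list(acc = NA_real_, par = par, sigma = sigma,
                 epoch = total_epochs - 1,
                 alpha_g = phase_schedule(total_epochs - 1, epochs)$alpha_g)
  }
  final_alpha_g <- phase_schedule(total_epochs - 1, epochs, lambda_entropy,
                                  topk_range, alpha_g_range)$alpha_g
  mk_model <- function(p, s) structure(
    list(config = config, par = p, sigma = s), class = "pm_model")
  structure(list(
    model = mk_model(best$par, best$sigma),
    final_model = mk_model(par, sigma),
    log = do.call(rbind, log_rows),
    target = target, seed = seed, epochs = epochs,
    curriculum = curriculum,
    best_epoch = best$epoch,
    alpha_g_best = best$alpha_g,
    alpha_g_final = final_alpha_g
  ), class = "pm_fit")
}

# One optimizer step over a batch of sessions: forward, phase loss,
# backward; returns mean loss, parameter gradients and the updated
# sigma-gamma state.
train_step <- function(config, par, sigma, batch, ph, tau, alpha_t,
                       max_contrast_chunks) {
  model <- structure(list(config = config, par = par), class = "pm_model")
  nb <- length(batch)
  Ts <- vapply(batch, function(s) s$T, integer(1))
  flat <- unlist(lapply(batch, function(s) s$flat), use.names = FALSE)
  fwd <- mtde_fwd(model, flat, sum(Ts), keep_cache = TRUE)
  H <- fwd$H
  col0 <- cumsum(c(0L, Ts))
  grads <- zero_grads(par)
  dH <- matrix(0, nrow(H), ncol(H))
  loss <- 0

  if (ph$phase == 0L) {
    # contrastive term over (subsampled) chunks of the whole batch
    sel_cols <- integer(0); sel_labels <- integer(0)
    for (i in seq_len(nb)) {
      cols <- (col0[i] + 1L):col0[i + 1L]
      if (length(cols) > max_contrast_chunks) {
        cols <- sort(sample(cols, max_contrast_chunks))
      }
      sel_cols <- c(sel_cols, cols)
      sel_labels <- c(sel_labels, rep(batch[[i]]$label, length(cols)))
    }
    pf <- projection_fwd(par, H[, sel_cols, drop = FALSE])
    sc <- supcon_loss_grad(t(pf$Z), sel_labels, tau)
    loss <- loss + sc$loss
    pb <- projection_bwd(par, pf$cache, t(sc$grad), grads)
    grads <- pb$grads
    dH[, sel_cols] <- dH[, sel_cols] + pb$dH
    # entropy regularization of the scorer's internal softmax, per session
    ent_loss <- 0
    for (i in seq_len(nb)) {
      cols <- (col0[i] + 1L):col0[i + 1L]
      sf <- scorer_fwd(par, H[, cols, drop = FALSE], sigma, training = TRUE)
      sigma <- sf$state
      p <- softmax(sf$scaled)
      ent_loss <- ent_loss + sum(p * log(pmax(p, 1e-300)))
      gp <- log(pmax(p, 1e-300)) + 1
      dscaled <- p * (gp - sum(p * gp))
      dscaled <- dscaled * ph$lambda_entropy / nb
      sb <- scorer_bwd(par, sf$cache, dscaled, grads)
      grads <- sb$grads
      dH[, cols] <- dH[, cols] + sb$dH
    }
    loss <- loss + ph$lambda_entropy * ent_loss / nb
  } else if (ph$phase == 1L) {
    # Top-K focal chunk loss; chunks inherit the session label. Each
    # selected chunk's focal term is weighted by its renormalized entmax
    # attention, so the scorer is actively trained in this phase: gradients
    # reach it through the entmax Jacobian.
    for (i in seq_len(nb)) {
      cols <- (col0[i] + 1L):col0[i + 1L]
      sf <- scorer_fwd(par, H[, cols, drop = FALSE], sigma, training = TRUE)
      sigma <- sf$state
      alpha <- if (length(cols) == 1L) 1 else
        entmax_bisect(sf$scaled, ph$scorer_alpha)
      sel <- topk_support(alpha, ph$topk_ratio)
      cf <- classifier_fwd(par, H[, cols[sel], drop = FALSE])
      y <- batch[[i]]$label
      fvals <- vapply(seq_along(sel), function(j)
        focal_chunk_loss(cf$probs[, j], y, gamma = 2, alpha_t), numeric(1))
      asum <- sum(alpha[sel])
      w <- if (asum > 0) alpha[sel] / asum else rep(1 / length(sel), length(sel))
      sess_loss <- sum(w * fvals)
      loss <- loss + sess_loss / nb
      dlogits <- matrix(0, config$n_classes, length(sel))
      for (j in seq_along(sel)) {
        dlogits[, j] <- w[j] * focal_dlogits(cf$probs[, j], y, 2, alpha_t[y])
      }
      dlogits <- dlogits / nb
      cb <- classifier_bwd(par, cf$cache, dlogits, grads)
      grads <- cb$grads
      dH[, cols[sel]] <- dH[, cols[sel]] + cb$dX
      if (length(cols) > 1L && asum > 0) {
        dalpha <- numeric(length(cols))
        dalpha[sel] <- (fvals - sess_loss) / (asum * nb)
        dscaled <- entmax_jvp(sf$scaled, ph$scorer_alpha, alpha, dalpha)
        sb <- scorer_bwd(par, sf$cache, dscaled, grads)
        grads <- sb$grads
        dH[, cols] <- dH[, cols] + sb$dH
      }
    }
  } else {
    # session cross-entropy through entmax attention and gated pooling
    for (i in seq_len(nb)) {
      cols <- (col0[i] + 1L):col0[i + 1L]
      Hs <- H[, cols, drop = FALSE]
      sf <- scorer_fwd(par, Hs, sigma, training = TRUE)
      sigma <- sf$state
      alpha <- if (length(cols) == 1L) 1 else
        entmax_bisect(sf$scaled, ph$alpha_g)
      gp <- gate_pool_fwd(par, Hs, alpha, config$pooling)
      cf <- classifier_fwd(par, matrix(gp$pooled, ncol = 1))
      y <- batch[[i]]$label
      probs <- as.vector(cf$probs)
      loss <- loss + session_ce_loss(probs, y) / nb
      dlogits <- probs
      dlogits[y] <- dlogits[y] - 1
      dlogits <- matrix(dlogits / nb, ncol = 1)
      cb <- classifier_bwd(par, cf$cache, dlogits, grads)
      grads <- cb$grads
      gb <- gate_pool_bwd(par, gp$cache, as.vector(cb$dX), grads)
      grads <- gb$grads
      dH[, cols] <- dH[, cols] + gb$dH
      if (length(cols) > 1L && config$pooling != "average") {
        dscaled <- entmax_jvp(sf$scaled, ph$alpha_g, alpha, gb$dalpha)
        sb <- scorer_bwd(par, sf$cache, dscaled, grads)
        grads <- sb$grads
        dH[, cols] <- dH[, cols] + sb$dH
      }
    }
  }

  grads <- mtde_bwd(model, fwd$cache, dH, grads)
  list(loss = loss, grads = grads, sigma = sigma)
}
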