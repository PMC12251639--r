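# Curriculum losses: supervised contrastive, entropy regularization,
# Top-K focal chunk loss and session cross-entropy, plus their gradient
# forms used by the trainer.

#' Supervised contrastive loss
#'
#' For each anchor `i` with at least one positive (another vector sharing
#' its label), averages `-log( exp(z_i.z_p / tau) / sum_{a != i}
#' exp(z_i.z_a / tau) )` over the positives `p`, then averages over anchors.
#' Anchors without positives are skipped; if no anchor has a positive the
#' loss is 0 with a warning.
#'
#' @param z Matrix of unit-norm embeddings, one per row.
#' @param labels Vector of class labels, one per row of `z`.
#' @param tau Temperature (> 0).
#' @return Scalar loss.
#' @export
supcon_loss <- function(z, labels, tau = 0.1) {
  supcon_loss_grad(z, labels, tau, want_grad = FALSE)$loss
}

# Loss plus gradient with respect to the (already normalized) embeddings.
supcon_loss_grad <- function(z, labels, tau = 0.1, want_grad = TRUE) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (n < 2) stop("supcon_loss: need a batch of at least 2 embeddings")
  if (tau <= 0) stop("supcon_loss: tau must be positive")
  if (length(labels) != n) stop("supcon_loss: one label per embedding required")
  S <- tcrossprod(z) / tau
  same <- outer(labels, labels, "==")
  diag(same) <- FALSE
  n_pos <- rowSums(same)
  anchors <- which(n_pos > 0)
  if (length(anchors) == 0) {
    warning("supcon_loss: no positives in batch; loss is 0")
    return(list(loss = 0, grad = if (want_grad) matrix(0, n, ncol(z)) else NULL))
  }
  M <- matrix(0, n, n)
  loss <- 0
  for (i in anchors) {
    s <- S[i, -i]
    mx <- max(s)
    lse <- mx + log(sum(exp(s - mx)))
    pos <- which(same[i, ])
    loss <- loss + sum(lse - S[i, pos]) / n_pos[i]
    if (want_grad) {
      q <- numeric(n)
      q[-i] <- exp(S[i, -i] - lse)
      q[pos] <- q[pos] - 1 / n_pos[i]
      M[i, ] <- q
    }
  }
  loss <- loss / length(anchors)
  grad <- NULL
  if (want_grad) {
    M <- M / length(anchors)
    grad <- (M + t(M)) %*% z / tau
  }
  list(loss = loss, grad = grad)
}

#' Entropy regularization loss
#'
#' Returns `-H(p)`; minimizing it maximizes the Shannon entropy of the
#' attention distribution, encouraging uniform early attention.
#'
#' @param p Probability vector.
#' @return Scalar loss (`<= 0`).
#' @export
entropy_reg_loss <- function(p) -shannon_entropy(p)

#' Phase-0 total loss
#'
#' `supcon + lambda_entropy * entropy_loss`.
#'
#' @param supcon Supervised contrastive loss value.
#' @param entropy_loss Entropy regularization loss value (`-H`).
#' @param lambda_entropy Non-negative weight.
#' @return Scalar total loss.
#' @export
phase0_total <- function(supcon, entropy_loss, lambda_entropy) {
  if (lambda_entropy < 0) stop("phase0_total: lambda_entropy must be >= 0")
  supcon + lambda_entropy * entropy_loss
}

#' Focal loss over selected chunks
#'
#' Mean over the selected chunks of `-alpha_t (1 - p_t)^gamma log p_t`,
#' where `p_t` is each chunk's predicted probability of the session label
#' (weak-label multiple-instance learning: chunks inherit the session
#' label).
#'
#' @param chunk_probs Matrix of class probabilities, one selected chunk per
#'   row (or a vector for a single chunk).
#' @param session_label 1-based class index of the session's label.
#' @param gamma Focusing parameter (>= 0, default 2).
#' @param alpha_t Per-class balancing weights (default 1 for every class).
#' @return Scalar loss.
#' @export
focal_chunk_loss <- function(chunk_probs, session_label, gamma = 2,
                             alpha_t = NULL) {
  if (gamma < 0) stop("focal_chunk_loss: gamma must be >= 0")
  P <- if (is.null(dim(chunk_probs))) matrix(chunk_probs, nrow = 1) else as.matrix(chunk_probs)
  if (is.null(alpha_t)) alpha_t <- rep(1, ncol(P))
  if (any(alpha_t <= 0)) stop("focal_chunk_loss: alpha_t must be positive")
  pt <- pmax(P[, session_label], 1e-12)
  mean(-alpha_t[session_label] * (1 - pt)^gamma * log(pt))
}

# d/dlogits of the focal loss for one chunk, given its softmax probs.
focal_dlogits <- function(probs, target, gamma, alpha) {
  pt <- max(probs[target], 1e-12)
  dfdpt <- -alpha * (-gamma * (1 - pt)^(max(gamma - 1, 0)) * log(pt) +
                       (1 - pt)^gamma / pt)
  dpt_dlogit <- -pt * probs
  dpt_dlogit[target] <- dpt_dlogit[target] + pt
  dfdpt * dpt_dlogit
}

#' Session-level cross-entropy loss
#'
#' `-log y_hat[y]`; probabilities below 1e-12 are clamped with a warning.
#'
#' @param y_hat Predicted class-probability vector.
#' @param y 1-based index of the true class.
#' @return Scalar loss.
#' @export
session_ce_loss <- function(y_hat, y) {
  p <- y_hat[y]
  if (p < 1e-12) {
    warning("session_ce_loss: probability clamped at 1e-12")
    p <- 1e-12
  }
  -log(p)
}
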