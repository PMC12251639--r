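# Numerics for sparse attention: stable softmax, exact alpha-entmax via
# bisection, Shannon entropy, sigma-gamma score scaling, Top-K support
# selection and linear annealing schedules. All functions are pure except
# sigma_gamma_scale, which threads an explicit state object.

#' Numerically stable softmax
#'
#' Maps a real score vector onto the probability simplex via
#' \eqn{p_i \propto \exp(z_i - \max z)}.
#'
#' @param z Numeric vector of finite scores.
#' @return Numeric vector on the simplex (non-negative, sums to 1).
#' @export
#' @examples
#' softmax(c(1, 0))
softmax <- function(z) {
  if (length(z) == 0L) stop("softmax: empty score vector")
  if (!all(is.finite(z))) stop("softmax: scores must be finite")
  e <- exp(z - max(z))
  e / sum(e)
}

#' Exact alpha-entmax via tau bisection
#'
#' Computes the alpha-entmax transformation, the unique maximizer of
#' \eqn{p \cdot z + H_\alpha(p)} over the probability simplex, where
#' \eqn{H_\alpha} is the Tsallis entropy. alpha = 1 recovers softmax
#' (only via `allow_softmax`), alpha = 2 is sparsemax; alpha between 1 and 2
#' yields sparse distributions that can assign exactly zero weight.
#' The threshold tau solving
#' \eqn{\sum_i [(\alpha-1) z_i - \tau]_+^{1/(\alpha-1)} = 1} is found by
#' bisection on the bracket \eqn{[\max((\alpha-1)z) - 1, \max((\alpha-1)z)]}.
#'
#' @param z Numeric vector of finite scores.
#' @param alpha Sparsity parameter, must exceed 1 (see `allow_softmax`).
#' @param iters Number of bisection iterations (default 50).
#' @param allow_softmax If TRUE, alpha <= 1 falls back to [softmax()];
#'   otherwise alpha <= 1 is an error.
#' @return Numeric vector on the simplex; entries can be exactly zero.
#' @export
#' @examples
#' entmax_bisect(c(0.5, -0.5), alpha = 2)  # sparsemax: c(1, 0)
entmax_bisect <- function(z, alpha, iters = 50L, allow_softmax = FALSE) {
  if (length(z) == 0L) stop("entmax_bisect: empty score vector")
  if (!all(is.finite(z))) stop("entmax_bisect: scores must be finite")
  if (alpha <= 1) {
    if (allow_softmax) return(softmax(z))
    stop("entmax_bisect: alpha must be > 1 (set allow_softmax = TRUE for the softmax limit)")
  }
  am1 <- alpha - 1
  zs <- am1 * z
  lo <- max(zs) - 1
  hi <- max(zs)
  inv <- 1 / am1
  for (i in seq_len(iters)) {
    tau <- (lo + hi) / 2
    p <- pmax(zs - tau, 0)^inv
    if (sum(p) >= 1) lo <- tau else hi <- tau
  }
  tau <- (lo + hi) / 2
  p <- pmax(zs - tau, 0)^inv
  s <- sum(p)
  if (s <= 0) {  # degenerate numerical corner: put all mass on the argmax
    p <- as.numeric(seq_along(z) == which.max(z))
    return(p)
  }
  p / s
}

#' Jacobian-vector product of alpha-entmax
#'
#' For `p = entmax_bisect(z, alpha)`, returns \eqn{J v} where \eqn{J} is the
#' Jacobian \eqn{\partial p / \partial z}. On the support,
#' \eqn{J = diag(s) - s s^\top / \sum s} with \eqn{s_i = p_i^{2-\alpha}};
#' off-support rows/columns are zero. J is symmetric, so the same routine
#' serves as the vector-Jacobian product in backpropagation.
#'
#' @param z Score vector at which the entmax was evaluated.
#' @param alpha Sparsity parameter (> 1).
#' @param p The entmax output at `z` (as from [entmax_bisect()]).
#' @param v Vector to multiply (same length as `z`).
#' @return Numeric vector \eqn{J v}.
#' @export
entmax_jvp <- function(z, alpha, p, v) {
  n <- length(z)
  if (length(p) != n || length(v) != n) {
    stop("entmax_jvp: z, p and v must have equal lengths")
  }
  s <- ifelse(p > 0, p^(2 - alpha), 0)
  sv <- s * v
  ssum <- sum(s)
  if (ssum <= 0) return(numeric(n))
  sv - s * (sum(sv) / ssum)
}

#' Shannon entropy of a probability vector
#'
#' \eqn{H(p) = -\sum_i p_i \ln p_i} in nats, with the convention
#' \eqn{0 \ln 0 = 0}.
#'
#' @param p Probability vector (non-negative, sums to 1).
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(p) {
  pos <- p[p > 0]
  -sum(pos * log(pos))
}

#' Create a sigma-gamma scaling state
#'
#' Running-standard-deviation gain control for attention scores: scores are
#' divided by a running estimate of their standard deviation and multiplied
#' by a learnable gain gamma.
#'
#' @param momentum Exponential-moving-average momentum for the running std.
#' @param gamma Initial gain (trainable during curriculum training).
#' @param epsilon Small positive stabilizer added to the running std.
#' @param running_sigma Initial running std estimate.
#' @return A `scale_state` list.
#' @export
scale_state <- function(momentum = 0.99, gamma = 1.0, epsilon = 1e-5,
                        running_sigma = 1.0) {
  stopifnot(momentum > 0, momentum < 1, epsilon > 0, running_sigma > 0)
  structure(list(running_sigma = running_sigma, momentum = momentum,
                 gamma = gamma, epsilon = epsilon),
            class = "scale_state")
}

#' Apply sigma-gamma scaling to raw attention scores
#'
#' In training mode the running std is updated from the sample standard
#' deviation of the incoming scores (one session's chunk scores at a time);
#' in evaluation mode the state is frozen. The scaled scores always use the
#' running estimate, so evaluation is deterministic.
#'
#' @param raw_scores Numeric vector of raw scores (>= 2 in training mode).
#' @param state A [scale_state()] object.
#' @param training Logical; update the running std?
#' @return List with `scores` (scaled) and `state` (possibly updated).
#' @export
sigma_gamma_scale <- function(raw_scores, state, training = FALSE) {
  stopifnot(inherits(state, "scale_state"))
  if (training) {
    if (length(raw_scores) < 2L) {
      stop("sigma_gamma_scale: need >= 2 scores to update the running std")
    }
    sdv <- stats::sd(raw_scores)
    if (sdv > 0) {
      state$running_sigma <- state$momentum * state$running_sigma +
        (1 - state$momentum) * sdv
    } else {
      warning("sigma_gamma_scale: zero-variance batch; running std unchanged")
    }
  }
  scores <- state$gamma * raw_scores / (state$running_sigma + state$epsilon)
  list(scores = scores, state = state)
}

#' Top-K support selection over attention weights
#'
#' Selects the `K = max(1, ceiling(ratio * T))` indices with the largest
#' weights; ties are broken in favor of the smaller index.
#'
#' @param weights Probability vector over T items.
#' @param ratio Fraction of items to keep, in (0, 1].
#' @return Integer vector of selected (1-based) indices, in rank order.
#' @export
topk_support <- function(weights, ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio > 1) {
    stop("topk_support: ratio must be a single value in (0, 1]")
  }
  T <- length(weights)
  K <- max(1L, as.integer(ceiling(ratio * T)))
  ord <- order(-weights, seq_along(weights))
  ord[seq_len(K)]
}

#' Linear annealing schedule
#'
#' @param start_epoch,end_epoch Integer epoch endpoints (`end > start`).
#' @param start_value,end_value Values at the endpoints.
#' @return A `linear_schedule` list.
#' @export
linear_schedule <- function(start_epoch, end_epoch, start_value, end_value) {
  if (end_epoch <= start_epoch) stop("linear_schedule: end_epoch must exceed start_epoch")
  structure(list(start_epoch = start_epoch, end_epoch = end_epoch,
                 start_value = start_value, end_value = end_value),
            class = "linear_schedule")
}

#' Evaluate a linear schedule at an epoch
#'
#' Linear interpolation between the endpoints, clamped outside
#' `[start_epoch, end_epoch]`.
#'
#' @param schedule A [linear_schedule()].
#' @param epoch Epoch at which to evaluate.
#' @return Numeric value.
#' @export
#' @examples
#' s <- linear_schedule(30, 50, 1.5, 1.8)
#' schedule_value(s, 40)  # 1.65
schedule_value <- function(schedule, epoch) {
  stopifnot(inherits(schedule, "linear_schedule"))
  f <- (epoch - schedule$start_epoch) /
    (schedule$end_epoch - schedule$start_epoch)
  f <- min(1, max(0, f))
  schedule$start_value + f * (schedule$end_value - schedule$start_value)
}

# Closed-form sparsemax (Euclidean projection onto the simplex). Kept as an
# independent oracle for entmax at alpha = 2; not used by the model path.
sparsemax_closed <- function(z) {
  n <- length(z)
  u <- sort(z, decreasing = TRUE)
  css <- cumsum(u)
  k <- max(which(u + (1 - css) / seq_len(n) > 0))
  tau <- (css[k] - 1) / k
  pmax(z - tau, 0)
}
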