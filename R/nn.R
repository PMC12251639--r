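# Forward/backward primitives. Activations are stored channels x time with
# the 128-sample chunks of a batch concatenated along columns; dilated
# convolutions use same-length zero padding and never leak across chunk
# boundaries (gather indices are built per chunk). All heavy steps are BLAS
# matrix products, so a batch of sessions trains at practical speed on CPU.

# Gather-column indices for a dilated conv tap structure. Returns a list of
# k integer vectors of length L*T; out-of-chunk positions point at the
# appended zero column (index N + 1).
conv_gather_idx <- function(kernel, dilation, L, T) {
  N <- L * T
  pl <- ((kernel - 1L) * dilation) %/% 2L
  offsets <- (seq_len(T) - 1L) * L
  idx <- vector("list", kernel)
  for (j in seq_len(kernel)) {
    shift <- (j - 1L) * dilation - pl
    src0 <- (0:(L - 1L)) + shift
    valid <- src0 >= 0L & src0 <= L - 1L
    colmat <- outer(src0 + 1L, offsets, "+")
    colmat[!valid, ] <- N + 1L
    idx[[j]] <- as.integer(colmat)
  }
  idx
}

conv_fwd <- function(X, W, b, dilation, L) {
  k <- dim(W)[3]
  N <- ncol(X)
  T <- N %/% L
  if (k == 1L) {
    Y <- matrix(W[, , 1], dim(W)[1], dim(W)[2]) %*% X + b
    return(list(Y = Y, cache = list(X = X, W = W, idx = NULL, L = L)))
  }
  idx <- conv_gather_idx(k, dilation, L, T)
  Xz <- cbind(X, 0)
  Y <- matrix(0, dim(W)[1], N)
  for (j in seq_len(k)) {
    Y <- Y + matrix(W[, , j], dim(W)[1], dim(W)[2]) %*% Xz[, idx[[j]], drop = FALSE]
  }
  Y <- Y + b
  list(Y = Y, cache = list(X = X, W = W, idx = idx, L = L))
}

conv_bwd <- function(dY, cache, need_dX = TRUE) {
  X <- cache$X; W <- cache$W; idx <- cache$idx
  k <- dim(W)[3]
  N <- ncol(X)
  dW <- array(0, dim(W))
  db <- rowSums(dY)
  if (k == 1L) {
    dW[, , 1] <- tcrossprod(dY, X)
    dX <- if (need_dX) crossprod(matrix(W[, , 1], dim(W)[1], dim(W)[2]), dY) else NULL
    return(list(dW = dW, db = db, dX = dX))
  }
  Xz <- cbind(X, 0)
  dX <- if (need_dX) matrix(0, nrow(X), N) else NULL
  for (j in seq_len(k)) {
    ij <- idx[[j]]
    dW[, , j] <- tcrossprod(dY, Xz[, ij, drop = FALSE])
    if (need_dX) {
      Cj <- crossprod(matrix(W[, , j], dim(W)[1], dim(W)[2]), dY)
      ok <- ij <= N
      cols <- ij[ok]
      dX[, cols] <- dX[, cols, drop = FALSE] + Cj[, ok, drop = FALSE]
    }
  }
  list(dW = dW, db = db, dX = dX)
}

# GELU, tanh approximation (the form used by default in the major deep-
# learning frameworks; much cheaper than the exact Gaussian CDF). The
# forward pass caches the tanh term so the backward pass is purely
# polynomial — the transcendental is the dominant cost at these activation
# volumes.
gelu_fwd <- function(x) {
  out <- gelu_fwd_cpp(x)
  dim(out$y) <- dim(x)
  out
}
gelu_grad_t <- function(x, t) {
  g <- gelu_grad_t_cpp(x, t)
  dim(g) <- dim(x)
  g
}
gelu <- function(x) gelu_fwd(x)$y
gelu_grad <- function(x) {
  f <- gelu_fwd(x)
  gelu_grad_t(x, f$t)
}

# Conv stack (list of par name prefixes) + GELU after every convolution.
stack_fwd <- function(X, par, specs, prefixes, L) {
  caches <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    cf <- conv_fwd(X, par[[paste0(prefixes[i], "_W")]],
                   par[[paste0(prefixes[i], "_b")]],
                   specs[[i]]$dilation, L)
    gf <- gelu_fwd(cf$Y)
    caches[[i]] <- list(conv = cf$cache, pre = cf$Y, t = gf$t)
    X <- gf$y
  }
  list(Y = X, caches = caches)
}

stack_bwd <- function(dY, caches, prefixes, grads, need_dX = TRUE) {
  for (i in rev(seq_along(caches))) {
    dpre <- dY * gelu_grad_t(caches[[i]]$pre, caches[[i]]$t)
    first <- (i == 1L)
    cb <- conv_bwd(dpre, caches[[i]]$conv, need_dX = need_dX || !first)
    grads[[paste0(prefixes[i], "_W")]] <- grads[[paste0(prefixes[i], "_W")]] + cb$dW
    grads[[paste0(prefixes[i], "_b")]] <- grads[[paste0(prefixes[i], "_b")]] + cb$db
    dY <- cb$dX
  }
  list(dX = dY, grads = grads)
}

# Intra-chunk softmax attention pooling: per chunk, scores from an affine
# 256 -> 1 map over the 128 time steps, softmax over time, weighted sum.
intrapool_fwd <- function(X, w, b, L) {
  N <- ncol(X); T <- N %/% L
  s <- as.vector(crossprod(matrix(w, ncol = 1), X)) + b
  S <- matrix(s, L, T)
  S <- sweep(S, 2, apply(S, 2, max))
  E <- exp(S)
  A <- sweep(E, 2, colSums(E), "/")
  H <- matrix(0, nrow(X), T)
  for (t in seq_len(T)) {
    cols <- ((t - 1L) * L + 1L):(t * L)
    H[, t] <- X[, cols, drop = FALSE] %*% A[, t]
  }
  list(H = H, cache = list(X = X, A = A, L = L))
}

intrapool_bwd <- function(dH, cache, w) {
  X <- cache$X; A <- cache$A; L <- cache$L
  T <- ncol(dH)
  dX <- matrix(0, nrow(X), ncol(X))
  dw <- numeric(length(w)); db <- 0
  for (t in seq_len(T)) {
    cols <- ((t - 1L) * L + 1L):(t * L)
    Xb <- X[, cols, drop = FALSE]
    a <- A[, t]; dh <- dH[, t]
    da <- as.vector(crossprod(Xb, dh))
    ds <- a * (da - sum(a * da))
    dX[, cols] <- tcrossprod(dh, a) + tcrossprod(w, ds)
    dw <- dw + as.vector(Xb %*% ds)
    db <- db + sum(ds)
  }
  list(dX = dX, dw = dw, db = db)
}

# MTDE forward over a batch of chunks. `chunks` is a numeric vector of
# length 128 * T (chunks concatenated). Returns embeddings (embed x T).
mtde_fwd <- function(model, chunks_flat, T, keep_cache = TRUE) {
  cfg <- model$config; par <- model$par
  L <- cfg$chunk_len
  X0 <- matrix(chunks_flat, nrow = 1)
  stem <- stack_fwd(X0, par, cfg$stem, paste0("stem", seq_along(cfg$stem)), L)
  branch_out <- vector("list", length(cfg$branches))
  branch_caches <- vector("list", length(cfg$branches))
  for (i in seq_along(cfg$branches)) {
    bn <- names(cfg$branches)[i]
    prefixes <- paste0("br_", bn, "_", seq_along(cfg$branches[[bn]]))
    bf <- stack_fwd(stem$Y, par, cfg$branches[[bn]], prefixes, L)
    branch_out[[i]] <- bf$Y
    branch_caches[[i]] <- bf$caches
  }
  Ccat <- do.call(rbind, branch_out)
  fus <- conv_fwd(Ccat, par$fus_W, par$fus_b, 1L, L)
  gf <- gelu_fwd(fus$Y)
  pool <- intrapool_fwd(gf$y, par$pool_w, par$pool_b, L)
  cache <- NULL
  if (keep_cache) {
    cache <- list(stem = stem$caches, branches = branch_caches,
                  fus = fus$cache, fus_pre = fus$Y, fus_t = gf$t,
                  pool = pool$cache,
                  branch_rows = vapply(branch_out, nrow, integer(1)))
  }
  list(H = pool$H, cache = cache)
}

mtde_bwd <- function(model, cache, dH, grads) {
  cfg <- model$config; par <- model$par
  pb <- intrapool_bwd(dH, cache$pool, par$pool_w)
  grads$pool_w <- grads$pool_w + pb$dw
  grads$pool_b <- grads$pool_b + pb$db
  dFpre <- pb$dX * gelu_grad_t(cache$fus_pre, cache$fus_t)
  fb <- conv_bwd(dFpre, cache$fus, need_dX = TRUE)
  grads$fus_W <- grads$fus_W + fb$dW
  grads$fus_b <- grads$fus_b + fb$db
  dCcat <- fb$dX
  rows <- cache$branch_rows
  row0 <- cumsum(c(0L, rows))
  dStem <- NULL
  for (i in seq_along(cfg$branches)) {
    bn <- names(cfg$branches)[i]
    prefixes <- paste0("br_", bn, "_", seq_along(cfg$branches[[bn]]))
    dB <- dCcat[(row0[i] + 1L):row0[i + 1L], , drop = FALSE]
    sb <- stack_bwd(dB, cache$branches[[i]], prefixes, grads, need_dX = TRUE)
    grads <- sb$grads
    dStem <- if (is.null(dStem)) sb$dX else dStem + sb$dX
  }
  sb <- stack_bwd(dStem, cache$stem, paste0("stem", seq_along(cfg$stem)),
                  grads, need_dX = FALSE)
  sb$grads
}

# Attention-scorer MLP (embed -> hidden -> 1) with GELU, then sigma-gamma
# scaling using the model's running std. Returns raw and scaled scores.
scorer_fwd <- function(par, H, sigma_state, training = FALSE) {
  Z1 <- par$sc1_W %*% H + par$sc1_b
  A1 <- gelu(Z1)
  r <- as.vector(par$sc2_W %*% A1) + par$sc2_b
  sg <- sigma_gamma_scale_gamma(r, sigma_state, par$sc_gamma, training)
  list(raw = r, scaled = sg$scores, state = sg$state,
       cache = list(H = H, Z1 = Z1, A1 = A1, r = r,
                    denom = sg$state$running_sigma + sg$state$epsilon))
}

# sigma_gamma_scale with gamma supplied separately (the trainable copy lives
# in the parameter list during curriculum training).
sigma_gamma_scale_gamma <- function(raw, state, gamma, training) {
  state$gamma <- gamma
  sigma_gamma_scale(raw, state, training)
}

scorer_bwd <- function(par, cache, dscaled, grads) {
  dr <- par$sc_gamma * dscaled / cache$denom
  grads$sc_gamma <- grads$sc_gamma + sum(dscaled * cache$r) / cache$denom
  dr_row <- matrix(dr, 1)
  grads$sc2_W <- grads$sc2_W + tcrossprod(dr_row, cache$A1)
  grads$sc2_b <- grads$sc2_b + sum(dr)
  dA1 <- crossprod(par$sc2_W, dr_row)
  dZ1 <- dA1 * gelu_grad(cache$Z1)
  grads$sc1_W <- grads$sc1_W + tcrossprod(dZ1, cache$H)
  grads$sc1_b <- grads$sc1_b + rowSums(dZ1)
  list(dH = crossprod(par$sc1_W, dZ1), grads = grads)
}

# Gated temporal pooling: pooled = sum_i alpha_i * (g_i . h_i).
gate_pool_fwd <- function(par, H, alpha, mode = "gated") {
  T <- ncol(H)
  if (length(alpha) != T) stop("gate_pool_fwd: attention/embedding length mismatch")
  if (mode == "average") alpha <- rep(1 / T, T)
  if (mode == "gated") {
    Zg <- par$gate_W %*% H + par$gate_b
    G <- 1 / (1 + exp(-Zg))
  } else {
    G <- matrix(1, nrow(H), T)
  }
  M <- G * H
  pooled <- as.vector(M %*% alpha)
  list(pooled = pooled,
       cache = list(H = H, G = G, M = M, alpha = alpha, mode = mode))
}

gate_pool_bwd <- function(par, cache, dpooled, grads) {
  H <- cache$H; G <- cache$G; alpha <- cache$alpha
  dM <- tcrossprod(dpooled, alpha)
  dalpha <- as.vector(crossprod(cache$M, dpooled))
  if (cache$mode == "gated") {
    dG <- dM * H
    dH <- dM * G
    dZg <- dG * G * (1 - G)
    grads$gate_W <- grads$gate_W + tcrossprod(dZg, H)
    grads$gate_b <- grads$gate_b + rowSums(dZg)
    dH <- dH + crossprod(par$gate_W, dZg)
  } else {
    dH <- dM
  }
  list(dH = dH, dalpha = dalpha, grads = grads)
}

# Shared chunk/session classifier: affine -> GELU -> affine -> softmax.
classifier_fwd <- function(par, X) {
  X <- as.matrix(X)
  Z1 <- par$cls1_W %*% X + par$cls1_b
  A1 <- gelu(Z1)
  logits <- par$cls2_W %*% A1 + par$cls2_b
  P <- apply(logits, 2, softmax)
  list(probs = P, logits = logits, cache = list(X = X, Z1 = Z1, A1 = A1))
}

classifier_bwd <- function(par, cache, dlogits, grads, need_dX = TRUE) {
  grads$cls2_W <- grads$cls2_W + tcrossprod(dlogits, cache$A1)
  grads$cls2_b <- grads$cls2_b + rowSums(dlogits)
  dA1 <- crossprod(par$cls2_W, dlogits)
  dZ1 <- dA1 * gelu_grad(cache$Z1)
  grads$cls1_W <- grads$cls1_W + tcrossprod(dZ1, cache$X)
  grads$cls1_b <- grads$cls1_b + rowSums(dZ1)
  dX <- if (need_dX) crossprod(par$cls1_W, dZ1) else NULL
  list(dX = dX, grads = grads)
}

# Contrastive projection: affine embed -> 128, then L2 normalization.
projection_fwd <- function(par, H) {
  P <- par$proj_W %*% H + par$proj_b
  nrm <- sqrt(colSums(P^2))
  if (any(nrm < 1e-12)) {
    warning("projection_fwd: near-zero projection; epsilon-stabilized normalization")
    nrm <- pmax(nrm, 1e-12)
  }
  Z <- sweep(P, 2, nrm, "/")
  list(Z = Z, cache = list(H = H, Z = Z, nrm = nrm))
}

projection_bwd <- function(par, cache, dZ, grads) {
  Z <- cache$Z
  dots <- colSums(Z * dZ)
  dP <- sweep(dZ - sweep(Z, 2, dots, "*"), 2, cache$nrm, "/")
  grads$proj_W <- grads$proj_W + tcrossprod(dP, cache$H)
  grads$proj_b <- grads$proj_b + rowSums(dP)
  list(dH = crossprod(par$proj_W, dP), grads = grads)
}

zero_grads <- function(par) {
  lapply(par, function(p) if (is.array(p)) array(0, dim(p)) else numeric(length(p)) * 0)
}
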