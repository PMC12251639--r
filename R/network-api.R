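# User-facing model operations. Internally activations are channels x time;
# these wrappers take and return chunk-major matrices (rows = chunks).

#' Encode chunks with the multi-scale temporal dynamics encoder
#'
#' Each 128-sample chunk passes through the two-layer stem, the parallel
#' dilated branches, channel concatenation, a 1x1 fusion to the embedding
#' width and softmax temporal attention pooling over the 128 time steps.
#'
#' @param model A [pm_init_model()] model.
#' @param chunks `T x 128` matrix, one chunk per row (as from
#'   [chunk_waveform()]).
#' @return `T x embed_dim` matrix of chunk embeddings.
#' @export
mtde_forward <- function(model, chunks) {
  stopifnot(inherits(model, "pm_model"))
  chunks <- as.matrix(chunks)
  if (ncol(chunks) != model$config$chunk_len) {
    stop("mtde_forward: chunks must have exactly ", model$config$chunk_len,
         " samples")
  }
  out <- mtde_fwd(model, as.vector(t(chunks)), nrow(chunks), keep_cache = FALSE)
  t(out$H)
}

#' Score chunk embeddings with the attention scorer
#'
#' Two-layer MLP (embed -> 81 -> 1, GELU) followed by sigma-gamma scaling.
#' In training mode the running std in `state` is updated from this
#' session's raw scores.
#'
#' @param model A `pm_model`.
#' @param embeddings `T x embed_dim` matrix of chunk embeddings.
#' @param state A [scale_state()]; defaults to the model's own state.
#' @param training Update the running std?
#' @return List with `raw`, `scaled` (length-T score vectors) and `state`.
#' @export
score_chunks <- function(model, embeddings, state = model$sigma,
                         training = FALSE) {
  stopifnot(inherits(model, "pm_model"))
  sf <- scorer_fwd(model$par, t(as.matrix(embeddings)), state, training)
  list(raw = sf$raw, scaled = sf$scaled, state = sf$state)
}

#' Gated temporal pooling of chunk embeddings
#'
#' `pooled = sum_i alpha_i * (g_i * h_i)` with per-chunk gate vectors
#' `g_i = sigmoid(W h_i + b)`. Mode `"attention"` forces the gates to 1;
#' `"average"` additionally forces uniform attention (the ablation variants).
#'
#' @param model A `pm_model`.
#' @param embeddings `T x embed_dim` matrix.
#' @param attention Probability vector over the T chunks.
#' @param mode `"gated"`, `"attention"` or `"average"`; defaults to the
#'   model configuration's pooling mode.
#' @return Numeric session representation of length `embed_dim`.
#' @export
gated_pool <- function(model, embeddings, attention,
                       mode = model$config$pooling) {
  stopifnot(inherits(model, "pm_model"))
  H <- t(as.matrix(embeddings))
  if (length(attention) != ncol(H)) {
    stop("gated_pool: attention length must match the number of chunks")
  }
  gate_pool_fwd(model$par, H, attention, mode)$pooled
}

#' Classify a representation (shared chunk/session head)
#'
#' The same affine -> GELU -> affine -> softmax parameter set serves as the
#' chunk-level auxiliary classifier (applied to chunk embeddings) and the
#' session classifier (applied to the pooled representation).
#'
#' @param model A `pm_model`.
#' @param x Length-`embed_dim` vector, or a matrix with one representation
#'   per row.
#' @return Class-probability vector (or matrix, one row per input).
#' @export
classify <- function(model, x) {
  stopifnot(inherits(model, "pm_model"))
  single <- is.null(dim(x))
  X <- if (single) matrix(x, ncol = 1) else t(as.matrix(x))
  if (nrow(X) != model$config$embed_dim) {
    stop("classify: input dimension must be ", model$config$embed_dim)
  }
  P <- classifier_fwd(model$par, X)$probs
  if (single) as.vector(P) else t(P)
}

#' Project embeddings for the supervised contrastive loss
#'
#' Affine map to the projection width followed by L2 normalization; outputs
#' lie on the unit sphere.
#'
#' @param model A `pm_model`.
#' @param embeddings Length-`embed_dim` vector or `T x embed_dim` matrix.
#' @return Unit-norm vector of length `projection_dim` (or matrix, one row
#'   per input).
#' @export
project_for_contrast <- function(model, embeddings) {
  stopifnot(inherits(model, "pm_model"))
  single <- is.null(dim(embeddings))
  H <- if (single) matrix(embeddings, ncol = 1) else t(as.matrix(embeddings))
  Z <- projection_fwd(model$par, H)$Z
  if (single) as.vector(Z) else t(Z)
}
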