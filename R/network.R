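# Model definition: configuration, parameter initialization and exact
# parameter accounting for the multi-scale temporal dynamics encoder (MTDE),
# attention scorer, gate, classifier and contrastive projection head.
#
# The canonical layer shapes reproduce simultaneously the receptive fields
# of the three physiology-aligned branches (0.2 s / 2.2 s / 4.3 s at 30 fps)
# and the exact parameter budgets (164,996 inference / 197,892 training).

conv_spec <- function(in_ch, out_ch, kernel, dilation = 1L) {
  stopifnot(kernel >= 1, dilation >= 1)
  list(in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
       kernel = as.integer(kernel), dilation = as.integer(dilation))
}

branch_library <- function() {
  list(
    short   = list(conv_spec(16, 64, 2, 1)),
    medium  = list(conv_spec(16, 32, 3, 15), conv_spec(32, 64, 2, 31)),
    long    = list(conv_spec(16, 32, 3, 31), conv_spec(32, 64, 3, 31)),
    medium2 = list(conv_spec(16, 32, 3, 8),  conv_spec(32, 64, 2, 15))
  )
}

#' Model configuration
#'
#' Builds the model configuration. The default (`n_branches = 3`,
#' `pooling = "gated"`) is the canonical model; other branch counts and
#' pooling modes are the ablation variants and do not need to meet the
#' canonical parameter budget.
#'
#' @param n_branches 1 (long only, TCN-like), 2 (short + long), 3
#'   (short + medium + long, canonical) or 4 (adds a second medium branch
#'   with dilations 8/15).
#' @param pooling `"gated"`, `"attention"` (gates forced to 1) or
#'   `"average"` (uniform attention and unit gates).
#' @param embed_dim Chunk embedding width (256).
#' @param scorer_hidden Attention-scorer hidden width (81).
#' @param classifier_hidden Classifier hidden width (47).
#' @param projection_dim Contrastive projection width (128).
#' @param n_classes Number of output classes (2).
#' @param chunk_len Samples per chunk (128).
#' @return A `pm_config` list.
#' @export
pm_config <- function(n_branches = 3L, pooling = c("gated", "attention", "average"),
                      embed_dim = 256L, scorer_hidden = 81L,
                      classifier_hidden = 47L, projection_dim = 128L,
                      n_classes = 2L, chunk_len = 128L) {
  pooling <- match.arg(pooling)
  lib <- branch_library()
  branches <- switch(as.character(n_branches),
    "1" = lib["long"],
    "2" = lib[c("short", "long")],
    "3" = lib[c("short", "medium", "long")],
    "4" = lib[c("short", "medium", "medium2", "long")],
    stop("pm_config: n_branches must be 1, 2, 3 or 4"))
  stem <- list(conv_spec(1, 16, 3, 1), conv_spec(16, 16, 3, 1))
  concat_ch <- sum(vapply(branches, function(b) b[[length(b)]]$out_ch, integer(1)))
  structure(list(
    stem = stem,
    branches = branches,
    fusion = conv_spec(concat_ch, embed_dim, 1, 1),
    embed_dim = as.integer(embed_dim),
    scorer_hidden = as.integer(scorer_hidden),
    classifier_hidden = as.integer(classifier_hidden),
    projection_dim = as.integer(projection_dim),
    n_classes = as.integer(n_classes),
    chunk_len = as.integer(chunk_len),
    pooling = pooling,
    n_branches = as.integer(n_branches)
  ), class = "pm_config")
}

#' Effective receptive field of a stride-1 dilated convolution stack
#'
#' `frames = 1 + sum (kernel - 1) * dilation`; `seconds = frames / 30`
#' at the 30 Hz sampling rate.
#'
#' @param layers Ordered list of layers, each a list with `kernel` and
#'   `dilation` entries (as produced inside [pm_config()]).
#' @return List with `frames` (integer) and `seconds` (numeric).
#' @export
#' @examples
#' cfg <- pm_config()
#' receptive_field(c(cfg$stem, cfg$branches$long))$seconds  # 4.3
receptive_field <- function(layers) {
  if (length(layers) == 0L) stop("receptive_field: empty layer stack")
  frames <- 1L + sum(vapply(layers, function(l) (l$kernel - 1L) * l$dilation,
                            integer(1)))
  list(frames = frames, seconds = frames / 30)
}

conv_par_count <- function(l) l$out_ch * l$in_ch * l$kernel + l$out_ch

#' Count trainable parameters
#'
#' Exact sum of weight and bias element counts. The `"inference"` scope
#' covers the MTDE (stem, branches, fusion, intra-chunk pool scorer), the
#' attention scorer (including its gamma gain), the gate and the shared
#' chunk/session classifier; `"training"` adds the contrastive projection
#' head.
#'
#' @param config A [pm_config()].
#' @param scope `"inference"` or `"training"`.
#' @return Integer parameter count.
#' @export
#' @examples
#' count_trainable(pm_config(), "inference")  # 164996
count_trainable <- function(config, scope = c("inference", "training")) {
  scope <- match.arg(scope)
  stopifnot(inherits(config, "pm_config"))
  cc <- component_counts(config)
  n <- cc$mtde + cc$scorer + cc$gate + cc$classifier
  if (scope == "training") n <- n + cc$projection
  as.integer(n)
}

# Per-component parameter counts (used by count_trainable and `describe`).
component_counts <- function(config) {
  stem <- sum(vapply(config$stem, conv_par_count, numeric(1)))
  branches <- vapply(config$branches, function(b)
    sum(vapply(b, conv_par_count, numeric(1))), numeric(1))
  fusion <- conv_par_count(config$fusion)
  pool <- config$embed_dim + 1                       # intra-chunk softmax scorer
  mtde <- stem + sum(branches) + fusion + pool
  scorer <- config$scorer_hidden * config$embed_dim + config$scorer_hidden +
    config$scorer_hidden + 1 + 1                     # MLP + gamma
  gate <- config$embed_dim * config$embed_dim + config$embed_dim
  classifier <- config$classifier_hidden * config$embed_dim +
    config$classifier_hidden +
    config$n_classes * config$classifier_hidden + config$n_classes
  projection <- config$projection_dim * config$embed_dim + config$projection_dim
  list(stem = stem, branches = branches, fusion = fusion, pool = pool,
       mtde = mtde, scorer = scorer, gate = gate, classifier = classifier,
       projection = projection)
}

init_conv <- function(l) {
  fan_in <- l$in_ch * l$kernel
  W <- array(stats::rnorm(l$out_ch * l$in_ch * l$kernel, 0, sqrt(2 / fan_in)),
             dim = c(l$out_ch, l$in_ch, l$kernel))
  list(W = W, b = numeric(l$out_ch))
}

init_affine <- function(n_out, n_in) {
  list(W = matrix(stats::rnorm(n_out * n_in, 0, sqrt(2 / n_in)), n_out, n_in),
       b = numeric(n_out))
}

#' Initialize a model
#'
#' He-scaled Gaussian weights, zero biases, gamma gain 1; deterministic
#' given `seed`.
#'
#' @param config A [pm_config()].
#' @param seed Integer seed.
#' @return A `pm_model` list holding `config`, the flat parameter list
#'   `par` and the sigma-gamma running state `sigma`.
#' @export
pm_init_model <- function(config = pm_config(), seed = 1L) {
  stopifnot(inherits(config, "pm_config"))
  set.seed(seed)
  par <- list()
  for (i in seq_along(config$stem)) {
    cv <- init_conv(config$stem[[i]])
    par[[paste0("stem", i, "_W")]] <- cv$W
    par[[paste0("stem", i, "_b")]] <- cv$b
  }
  for (bn in names(config$branches)) {
    layers <- config$branches[[bn]]
    for (j in seq_along(layers)) {
      cv <- init_conv(layers[[j]])
      par[[paste0("br_", bn, "_", j, "_W")]] <- cv$W
      par[[paste0("br_", bn, "_", j, "_b")]] <- cv$b
    }
  }
  fz <- init_conv(config$fusion)
  par$fus_W <- fz$W
  par$fus_b <- fz$b
  par$pool_w <- stats::rnorm(config$embed_dim, 0, sqrt(1 / config$embed_dim))
  par$pool_b <- 0
  sc1 <- init_affine(config$scorer_hidden, config$embed_dim)
  par$sc1_W <- sc1$W; par$sc1_b <- sc1$b
  sc2 <- init_affine(1L, config$scorer_hidden)
  par$sc2_W <- sc2$W; par$sc2_b <- sc2$b
  par$sc_gamma <- 1.0
  gt <- init_affine(config$embed_dim, config$embed_dim)
  par$gate_W <- gt$W
  # gates start mostly open (sigmoid(2) ~ 0.88) so the pooled representation
  # matches the scale of the chunk embeddings the classifier was pretrained
  # on at the Phase-2 handover
  par$gate_b <- rep(2, config$embed_dim)
  c1 <- init_affine(config$classifier_hidden, config$embed_dim)
  par$cls1_W <- c1$W; par$cls1_b <- c1$b
  c2 <- init_affine(config$n_classes, config$classifier_hidden)
  par$cls2_W <- c2$W; par$cls2_b <- c2$b
  pj <- init_affine(config$projection_dim, config$embed_dim)
  par$proj_W <- pj$W; par$proj_b <- pj$b
  structure(list(config = config, par = par, sigma = scale_state()),
            class = "pm_model")
}

# Parameter-name groups used for phase freezing and learning-rate scaling.
param_groups <- function(par) {
  nm <- names(par)
  list(
    mtde = nm[grepl("^(stem|br_|fus_|pool_)", nm)],
    scorer = nm[grepl("^sc[12]_|^sc_gamma$", nm)],
    gate = nm[grepl("^gate_", nm)],
    classifier = nm[grepl("^cls", nm)],
    projection = nm[grepl("^proj_", nm)]
  )
}
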