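# Model architecture: receptive fields, exact parameter accounting, encoder
# forward contracts, scoring, pooling identities, the shared classifier and
# the contrastive projection.

test_that("receptive fields of the canonical stacks are exact", {
  cfg <- pm_config()
  expect_equal(receptive_field(cfg$stem)$frames, 5L)
  rf_s <- receptive_field(c(cfg$stem, cfg$branches$short))
  rf_m <- receptive_field(c(cfg$stem, cfg$branches$medium))
  rf_l <- receptive_field(c(cfg$stem, cfg$branches$long))
  expect_equal(rf_s$frames, 6L)
  expect_equal(rf_m$frames, 66L)
  expect_equal(rf_l$frames, 129L)
  expect_equal(rf_s$seconds, 0.2)
  expect_equal(rf_m$seconds, 2.2)
  expect_equal(rf_l$seconds, 4.3)
  expect_error(receptive_field(list()), "empty")
})

test_that("per-component parameter counts match the canonical accounting", {
  cfg <- pm_config()
  cc <- pulsemil:::component_counts(cfg)
  expect_equal(cc$stem, 848)
  expect_equal(unname(cc$branches), c(2112, 5728, 7776))
  expect_equal(cc$fusion, 49408)
  expect_equal(cc$pool, 257)
  expect_equal(cc$mtde, 66129)
  expect_equal(cc$gate, 65792)
  expect_equal(cc$scorer, 20900)
  expect_equal(cc$classifier, 12175)
  expect_equal(cc$projection, 32896)
  expect_equal(count_trainable(cfg, "inference"), 164996L)
  expect_equal(count_trainable(cfg, "training"), 197892L)
  # the counts describe the actual parameter tensors
  m <- pm_init_model(cfg, seed = 1)
  expect_equal(sum(lengths(m$par)), 197892L)
})

test_that("encoder output contract: shape, finiteness, batch independence", {
  m <- pm_init_model(pm_config(), seed = 2)
  ch <- matrix(rnorm(4 * 128), 4, 128)
  H <- mtde_forward(m, ch)
  expect_equal(dim(H), c(4L, 256L))
  expect_true(all(is.finite(H)))
  H0 <- mtde_forward(m, matrix(0, 1, 128))
  expect_true(all(is.finite(H0)))
  perm <- c(3, 1, 4, 2)
  expect_equal(mtde_forward(m, ch[perm, ]), H[perm, ], tolerance = 1e-12)
  expect_error(mtde_forward(m, matrix(0, 2, 100)), "128")
})

test_that("branch-count ablation configs encode and differ in width", {
  for (nb in c(1L, 2L, 4L)) {
    cfg <- pm_config(n_branches = nb)
    m <- pm_init_model(cfg, seed = 3)
    H <- mtde_forward(m, matrix(rnorm(2 * 128), 2, 128))
    expect_equal(dim(H), c(2L, 256L))
  }
  expect_equal(pm_config(n_branches = 1)$fusion$in_ch, 64L)
  expect_equal(pm_config(n_branches = 4)$fusion$in_ch, 256L)
  expect_error(pm_config(n_branches = 5), "n_branches")
})

test_that("chunk scoring is shape-correct, frozen in eval and pointwise", {
  m <- pm_init_model(pm_config(), seed = 4)
  H <- mtde_forward(m, matrix(rnorm(6 * 128), 6, 128))
  s1 <- score_chunks(m, H)
  expect_length(s1$scaled, 6)
  s2 <- score_chunks(m, H)
  expect_identical(s1$scaled, s2$scaled)
  Hdup <- H[c(1, 1, 3:6), ]
  sd <- score_chunks(m, Hdup)
  expect_equal(sd$raw[1], sd$raw[2])
})

test_that("gated pooling satisfies the selection and convexity identities", {
  m <- pm_init_model(pm_config(), seed = 5)
  H <- mtde_forward(m, matrix(rnorm(4 * 128), 4, 128))
  onehot <- c(0, 0, 1, 0)
  expect_equal(gated_pool(m, H, onehot, mode = "attention"), as.vector(H[3, ]),
               tolerance = 1e-12)
  h2 <- matrix(0, 2, 256); h2[1, 1] <- 1; h2[2, 2] <- 1
  pooled <- gated_pool(m, h2, c(0.5, 0.5), mode = "attention")
  expect_equal(pooled[1:3], c(0.5, 0.5, 0))
  # attention pooling stays inside the per-coordinate convex hull
  al <- softmax(rnorm(4))
  pa <- gated_pool(m, H, al, mode = "attention")
  expect_true(all(pa >= apply(H, 2, min) - 1e-12 &
                    pa <= apply(H, 2, max) + 1e-12))
  # loop-oracle equality on a small random case
  set.seed(9)
  Hs <- matrix(rnorm(4 * 256), 4, 256)
  alpha <- softmax(rnorm(4))
  pg <- gated_pool(m, Hs, alpha, mode = "gated")
  acc <- numeric(256)
  for (i in 1:4) {
    g <- 1 / (1 + exp(-(m$par$gate_W %*% Hs[i, ] + m$par$gate_b)))
    acc <- acc + alpha[i] * as.vector(g) * Hs[i, ]
  }
  expect_equal(pg, acc, tolerance = 1e-12)
  # average mode ignores the supplied attention
  expect_equal(gated_pool(m, Hs, c(1, 0, 0, 0), mode = "average"),
               gated_pool(m, Hs, alpha, mode = "average"), tolerance = 1e-12)
  expect_error(gated_pool(m, Hs, c(0.5, 0.5)), "length")
})

test_that("the shared classifier behaves identically as aux and main head", {
  m <- pm_init_model(pm_config(), seed = 6)
  x <- rnorm(256)
  p_session <- classify(m, x)
  p_chunk <- classify(m, matrix(x, 1, 256))
  expect_equal(p_session, as.vector(p_chunk))
  expect_length(p_session, 2)
  expect_equal(sum(p_session), 1)
  # hand-set final layer: logits (ln 9, 0) -> probabilities (0.9, 0.1)
  m$par$cls1_W[] <- 0; m$par$cls1_b[] <- 0
  m$par$cls2_W[] <- 0
  m$par$cls2_b <- c(log(9), 0)
  expect_equal(classify(m, x), c(0.9, 0.1))
  expect_error(classify(m, rnorm(100)), "dimension")
})

test_that("the contrastive projection lands on the unit sphere", {
  m <- pm_init_model(pm_config(), seed = 7)
  H <- mtde_forward(m, matrix(rnorm(3 * 128), 3, 128))
  Z <- project_for_contrast(m, H)
  expect_equal(dim(Z), c(3L, 128L))
  expect_equal(sqrt(rowSums(Z^2)), rep(1, 3), tolerance = 1e-9)
  # homogeneity: scaling the pre-normalization output leaves the result
  m2 <- m
  m2$par$proj_W <- 3.7 * m$par$proj_W
  m2$par$proj_b <- 3.7 * m$par$proj_b
  expect_equal(project_for_contrast(m2, H), Z, tolerance = 1e-9)
  z1 <- project_for_contrast(m, H[1, ])
  expect_length(z1, 128)
})

test_that("classifier handover is the identity on shared parameters", {
  cfg <- pm_config()
  m <- pm_init_model(cfg, seed = 8)
  aux <- m$par[c("cls1_W", "cls1_b", "cls2_W", "cls2_b")]
  expect_message(hand <- handover_classifier(aux, cfg), "identity")
  expect_identical(hand, aux)
  x <- rnorm(256)
  m2 <- m; m2$par[names(hand)] <- hand
  expect_identical(classify(m, x), classify(m2, x))
  expect_equal(sum(lengths(m2$par)), sum(lengths(m$par)))
  bad <- aux; bad$cls1_W <- matrix(0, 10, 256)
  expect_error(handover_classifier(bad, cfg), "shapes")
})
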