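# Channel networks, fusion and predictor: shape ledger, analytic identities
# and ablation oracles.

test_that("mlp_block composes linear, batch-norm and LeakyReLU as stated", {
  # eval mode with running stats (0, 1) and identity weights is the identity
  # on positive inputs (up to the batch-norm epsilon)
  x <- matrix(c(0.5, 1.2, 2.0, 0.1, 3.3, 0.7), 2, 3)
  out <- mlp_block(x, diag(3), diag(3))
  expect_equal(out, x, tolerance = 1e-4)

  # negative pre-activations pass through the 0.01 slope
  xn <- matrix(c(-1, -2, -0.5), 1, 3)
  expect_equal(mlp_block(xn, diag(3), diag(3)), 0.01 * xn,
               tolerance = 1e-4)

  # independent composed-arithmetic oracle with seeded weights
  set.seed(13)
  W1 <- matrix(rnorm(12), 3, 4); W2 <- matrix(rnorm(8), 4, 2)
  xb <- matrix(rnorm(15), 5, 3)
  st <- mseddi:::bn_state_new(4)
  got <- mlp_block(xb, W1, W2, mode = "train", state = st)
  z <- xb %*% W1
  mu <- colMeans(z)
  va <- colMeans(sweep(z, 2, mu)^2)
  zh <- sweep(sweep(z, 2, mu), 2, sqrt(va + 1e-5), "/")
  lr <- ifelse(zh > 0, zh, 0.01 * zh)
  expect_matrix_equal(got, lr %*% W2, tol = 1e-10)

  # train mode needs a batch: a single row has undefined variance
  expect_error(mlp_block(matrix(1, 1, 3), diag(3), diag(3), mode = "train"),
               "at least 2")
})

test_that("network channel stacks two shared-MLP rows", {
  model <- small_model()
  s <- small_setup()
  h1 <- s$feats$H_kge[1, ]
  h2 <- s$feats$H_kge[2, ]
  P <- network_channel(h1, h2, model)
  expect_equal(dim(P), c(2L, 8L))
  # identical inputs give identical rows (shared weights)
  Psame <- network_channel(h1, h1, model)
  expect_equal(Psame[1, ], Psame[2, ])
  # swapping the drugs swaps the rows exactly
  Pswap <- network_channel(h2, h1, model)
  expect_equal(Pswap[1, ], P[2, ])
  expect_equal(Pswap[2, ], P[1, ])
})

test_that("sequence channel has the contracted shape and pooling arithmetic", {
  model <- small_model()
  s <- small_setup()
  Hi <- s$feats$H_sne[1:100, ]
  Hj <- s$feats$H_sne[101:200, ]
  P <- sequence_channel(Hi, Hj, model)
  expect_equal(dim(P), c(50L, 8L))   # 100 x 2 / 4 pooled positions
  expect_error(sequence_channel(Hi[1:99, ], Hj, model), "100 rows")
})

test_that("zeroed feed-forward isolates the residual path", {
  s <- small_setup()
  Hi <- s$feats$H_sne[1:100, ]
  Hj <- s$feats$H_sne[101:200, ]

  zero_ff <- function(m) {
    m$params$seq_ff1[] <- 0
    m$params$seq_ff2[] <- 0
    m
  }
  m_res <- zero_ff(small_model())
  m_nores <- zero_ff(small_model(use_residual = FALSE))
  out_nores <- sequence_channel(Hi, Hj, m_nores)
  # LN(GELU(x %*% 0) %*% 0) = LN(0) = 0 with identity-initialized LN
  expect_true(all(abs(out_nores) < 1e-12))
  # with the residual the channel reduces to the convolutional-stage
  # features, which the attention path no longer influences once its output
  # projection is zeroed
  m_ps1 <- zero_ff(small_model())
  m_ps1$params$seq_Wo[] <- 0
  ps1 <- sequence_channel(Hi, Hj, m_ps1)
  expect_equal(sequence_channel(Hi, Hj, m_res), ps1, tolerance = 1e-10)
  expect_gt(max(abs(ps1)), 0)
})

test_that("graph channel stacks three independent MLPs with a convolution", {
  model <- small_model()
  cfg <- graph_encoder_config(dim_cse = 8, rounds = 2, seed = 5)
  gi <- smiles_to_molgraph("CCO")
  gj <- smiles_to_molgraph("CCN")
  Hc <- function(g) {
    sapply(c("mpnn", "weave", "afp"), function(v) {
      encode_molecule(g, cfg, variant = v)
    }, simplify = FALSE)
  }
  Hi <- Hc(gi); Hj <- Hc(gj)
  P <- graph_channel(Hi, Hj, model)
  expect_equal(dim(P), c(6L, 8L))
  expect_error(graph_channel(Hi[c("mpnn", "weave")], Hj, model), "afp")

  # no weight sharing: permuting which variant feeds which MLP changes rows
  Hi2 <- Hi[c("weave", "mpnn", "afp")]
  names(Hi2) <- c("mpnn", "weave", "afp")
  P2 <- graph_channel(Hi2, Hj, model)
  expect_gt(max(abs(P - P2)), 1e-6)

  # identity-kernel oracle: centre tap I, zero side taps, BN at identity
  # running stats -> the channel output equals LeakyReLU of the raw
  # six-row per-variant MLP stack
  m_id <- small_model()
  m_id$params$gconv_p[] <- 0
  m_id$params$gconv_n[] <- 0
  m_id$params$gconv_c <- diag(8)
  P_id <- graph_channel(Hi, Hj, m_id)
  stack14 <- rbind(
    mlp_block(matrix(Hi$mpnn, 1), m_id$params$g_mpnn_W1, m_id$params$g_mpnn_W2),
    mlp_block(matrix(Hj$mpnn, 1), m_id$params$g_mpnn_W1, m_id$params$g_mpnn_W2),
    mlp_block(matrix(Hi$weave, 1), m_id$params$g_weave_W1, m_id$params$g_weave_W2),
    mlp_block(matrix(Hj$weave, 1), m_id$params$g_weave_W1, m_id$params$g_weave_W2),
    mlp_block(matrix(Hi$afp, 1), m_id$params$g_afp_W1, m_id$params$g_afp_W2),
    mlp_block(matrix(Hj$afp, 1), m_id$params$g_afp_W1, m_id$params$g_afp_W2))
  lrelu <- function(x) ifelse(x > 0, x, 0.01 * x)
  expect_matrix_equal(P_id, lrelu(stack14), tol = 1e-3)
})

test_that("fusion stacks 2+50+6 rows, flattens to 58*dim and normalizes", {
  model <- small_model()
  s <- small_setup()
  P_kge <- network_channel(s$feats$H_kge[1, ], s$feats$H_kge[2, ], model)
  P_sne <- sequence_channel(s$feats$H_sne[1:100, ], s$feats$H_sne[101:200, ],
                            model)
  cfg <- graph_encoder_config(dim_cse = 8, rounds = 2, seed = 5)
  Hc <- function(g) sapply(c("mpnn", "weave", "afp"), function(v)
    encode_molecule(g, cfg, variant = v), simplify = FALSE)
  P_cse <- graph_channel(Hc(smiles_to_molgraph("CCO")),
                         Hc(smiles_to_molgraph("CCN")), model)
  out <- fuse_and_predict(P_kge, P_sne, P_cse, model = model)
  expect_equal(nrow(out$stack), 58L)
  expect_length(out$probs, 4L)
  expect_equal(sum(out$probs), 1, tolerance = 1e-9)

  # flattened predictor width at the reference dim: 58 * 64 = 3712
  expect_equal(58L * 64L, 3712L)
  ref <- init_mseddi(mseddi_config(dim = 64, Nl = 4, seed = 1),
                     dim_kge = 8, dim_sne = 8,
                     n_atom_features = 29, n_bond_features = 8)
  expect_equal(nrow(ref$params$pred_W1), 3712L)

  # single-channel mask still runs (network-only variant)
  m_nc <- small_model(channel_mask = "network")
  out_nc <- fuse_and_predict(P_kge = P_kge, model = m_nc)
  expect_equal(nrow(out_nc$stack), 2L)
  expect_equal(sum(out_nc$probs), 1, tolerance = 1e-9)
  expect_error(fuse_and_predict(model = m_nc), "no channel")
})

test_that("eval-mode forwards are deterministic, train mode is seeded", {
  model <- small_model()
  s <- small_setup()
  h1 <- s$feats$H_kge[1, ]; h2 <- s$feats$H_kge[2, ]
  expect_identical(network_channel(h1, h2, model),
                   network_channel(h1, h2, model))
  # dropout makes train-mode stochastic unless the RNG is fixed
  set.seed(5); a <- network_channel(h1, h2, model, mode = "train")
  set.seed(5); b <- network_channel(h1, h2, model, mode = "train")
  expect_identical(a, b)
})
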