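# The three chemical-structure encoders: readout contracts, permutation
# invariance, determinism and gradient correctness.

enc_params <- function(dg = 6, dim_cse = 6, Fa = 29, Fb = 8, seed = 2) {
  mseddi:::with_local_seed(seed, {
    mseddi:::init_encoder_params(Fa, Fb, graph_encoder_config(dim_cse, 3))
  })
}

test_that("weave readout with an identity tail is the node sum", {
  p <- enc_params()
  p$weave_out <- diag(6)
  h <- matrix(rep(c(1, -2, 0.5, 3, 0, 1), each = 4), 4, 6)
  out <- readout(h, "weave", p)
  expect_equal(out, 4 * h[1, ])
  expect_error(readout(matrix(0, 0, 6), "weave", p), "empty")
})

test_that("readouts are permutation-invariant", {
  set.seed(3)
  p <- enc_params()
  h <- matrix(rnorm(5 * 6), 5, 6)
  perm <- c(3, 1, 5, 2, 4)
  for (v in c("mpnn", "weave", "afp")) {
    expect_equal(readout(h, v, p), readout(h[perm, ], v, p),
                 tolerance = 1e-6)
  }
})

test_that("afp pooling with equalized attention reduces to mean pooling", {
  set.seed(4)
  p <- enc_params()
  p$afp_att <- matrix(0, 6, 6)   # all attention logits equal -> uniform
  h <- matrix(rnorm(4 * 6), 4, 6)
  out <- readout(h, "afp", p)
  # oracle: recompute the three layers with explicit uniform weights
  lrelu <- function(x) ifelse(x > 0, x, 0.01 * x)
  s <- colMeans(h)
  for (l in 1:3) {
    r <- colSums(h * (1 / 4))
    s <- lrelu(c(s, r) %*% p$afp_upd)
  }
  expect_equal(out, drop(s %*% p$afp_out), tolerance = 1e-8)
})

test_that("molecule encoding is deterministic and relabeling-invariant", {
  cfg <- graph_encoder_config(dim_cse = 6, rounds = 2, seed = 9)
  g <- smiles_to_molgraph("CCO")
  for (v in c("mpnn", "weave", "afp")) {
    e1 <- encode_molecule(g, cfg, variant = v)
    e2 <- encode_molecule(g, cfg, variant = v)
    expect_identical(e1, e2)
  }
  # isomorphic graphs with permuted atom order: OCC lists the same molecule
  # with atoms in reverse order
  g2 <- smiles_to_molgraph("OCC")
  expect_equal(g2$element, rev(g$element))
  for (v in c("mpnn", "weave", "afp")) {
    expect_equal(encode_molecule(g, cfg, variant = v),
                 encode_molecule(g2, cfg, variant = v), tolerance = 1e-6)
  }
})

test_that("single-atom molecules encode via the zero-aggregate path", {
  cfg <- graph_encoder_config(dim_cse = 6, rounds = 3, seed = 9)
  e <- encode_molecule(smiles_to_molgraph("C"), cfg, variant = "mpnn")
  expect_length(e, 6L)
  expect_true(all(is.finite(e)))
})

test_that("encoder gradients agree with finite differences on a 3-atom molecule", {
  g <- smiles_to_molgraph("CCO")
  ug <- mseddi:::union_graph(list(g))
  p <- enc_params(dg = 4, dim_cse = 4)
  for (v in c("mpnn", "weave", "afp")) {
    loss_of <- function(params) {
      tape <- mseddi:::ad_tape()
      ctx <- mseddi:::ad_context(tape, params)
      out <- mseddi:::encoder_forward(ctx, v, ug, rounds = 2)
      list(val = sum(out$val^2), out = out, ctx = ctx, tape = tape)
    }
    fw <- loss_of(p)
    mseddi:::ad_backward(fw$out, 2 * fw$out$val)
    gr <- fw$ctx$grads()
    for (nm in c(paste0(v, "_msg_h"), paste0(v, "_emb"))) {
      gmat <- gr[[nm]]
      for (idx in c(1L, 5L)) {
        eps <- 1e-5
        pp <- p; pp[[nm]][idx] <- pp[[nm]][idx] + eps
        pm <- p; pm[[nm]][idx] <- pm[[nm]][idx] - eps
        fd <- (loss_of(pp)$val - loss_of(pm)$val) / (2 * eps)
        expect_equal(gmat[idx], fd, tolerance = 1e-4)
      }
    }
  }
})
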