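# SMILES tokenization, CBOW forward/training, sequence embedding and the
# fold/pad rule.

# helper reproducing the seeded CBOW initialization
with_seed_matrix <- function(seed, v, u) {
  mseddi:::with_local_seed(seed, {
    matrix(stats::runif(v * u, -0.5 / u, 0.5 / u), v, u)
  })
}

test_that("tokenization merges two-character halogens and bracket atoms", {
  expect_equal(tokenize_smiles("CCO"), c("C", "C", "O"))
  expect_equal(tokenize_smiles("CCl"), c("C", "Cl"))
  expect_equal(tokenize_smiles("C[NH4+]C"), c("C", "[NH4+]", "C"))
  expect_equal(tokenize_smiles("BrCC"), c("Br", "C", "C"))
  expect_equal(tokenize_smiles("c1ccccc1"),
               c("c", "1", "c", "c", "c", "c", "c", "1"))
  expect_error(tokenize_smiles("C[NH4+C"), "unbalanced")
  expect_error(tokenize_smiles("CC]O"), "unbalanced")
  expect_error(tokenize_smiles(""), "non-empty")
})

test_that("CBOW forward is a softmax over the projected context mean", {
  set.seed(7)
  W1 <- matrix(rnorm(5 * 3), 5, 3)
  W2 <- matrix(rnorm(3 * 5), 3, 5)
  p <- cbow_forward(c(1L, 4L), W1, W2)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  # zero output weights give the uniform distribution
  expect_equal(cbow_forward(2L, W1, matrix(0, 3, 5)), rep(0.2, 5))
  # independent step-by-step arithmetic oracle
  h <- (W1[1L, ] + W1[4L, ]) / 2
  z <- as.vector(h %*% W2)
  expect_equal(p, exp(z) / sum(exp(z)), tolerance = 1e-12)
  # order of context tokens does not matter (mean is symmetric)
  expect_equal(cbow_forward(c(4L, 1L), W1, W2), p)
  expect_error(cbow_forward(integer(0), W1, W2), "non-empty")
})

test_that("CBOW training is deterministic and learns co-occurrence", {
  corpus <- lapply(c("CCO", "CCN", "OCC"), tokenize_smiles)
  cfg <- w2v_config(dim_sne = 6, epochs = 10, seed = 2)
  f1 <- train_cbow(corpus, cfg)
  f2 <- train_cbow(corpus, cfg)
  expect_identical(f1$W1, f2$W1)

  # distributional-equivalence oracle: A and B occur in identical contexts
  templ <- list(c("X", "A", "Y"), c("X", "B", "Y"), c("Z", "A", "W"),
                c("Z", "B", "W"), c("Q", "R", "S"))
  corpus2 <- rep(templ, 8)
  fit <- train_cbow(corpus2, w2v_config(dim_sne = 8, window = 1,
                                        epochs = 40, seed = 5))
  W <- fit$W1
  cs <- function(a, b) sum(W[a, ] * W[b, ]) /
    sqrt(sum(W[a, ]^2) * sum(W[b, ]^2))
  others <- setdiff(rownames(W), c("A", "B"))
  pairs <- t(utils::combn(others, 2))
  base <- mean(apply(pairs, 1L, function(p) cs(p[1], p[2])))
  expect_gt(cs("A", "B"), base)
})

test_that("a single-token corpus triggers no updates", {
  cfg <- w2v_config(dim_sne = 4, epochs = 5, seed = 3)
  fit <- train_cbow(list("C"), cfg)
  init <- with_seed_matrix(cfg$seed, nrow(fit$W1), 4)
  expect_equal(unname(fit$W1), init)
})

test_that("sequence embedding is the one-hot lookup of W1 rows", {
  set.seed(8)
  W1 <- matrix(rnorm(4 * 3), 4, 3,
               dimnames = list(c("C", "O", "N", "Cl"), NULL))
  m <- embed_sequence(c("C", "O"), W1)
  expect_equal(m[1, ], W1["C", ])
  expect_equal(m[2, ], W1["O", ])
  expect_equal(nrow(embed_sequence(character(0), W1)), 0L)
  expect_warning(m2 <- embed_sequence(c("C", "Zz"), W1), "Zz")
  expect_equal(m2[2, ], rep(0, 3))
})

test_that("fold/pad zero-pads short and mask-aware-averages long input", {
  m40 <- matrix(1, 40, 3)
  out <- fold_and_pad(m40)
  expect_equal(dim(out), c(100L, 3L))
  expect_true(all(out[1:40, ] == 1))
  expect_true(all(out[41:100, ] == 0))

  m150 <- matrix(1, 150, 2)
  out150 <- fold_and_pad(m150)
  expect_true(all(out150 == 1))   # padding never dilutes the mean

  # derived enumeration oracle: len 250, row value = global row index
  m250 <- matrix(rep(1:250, 2), 250, 2)
  out250 <- fold_and_pad(m250)
  for (j in 1:100) {
    chunk_rows <- c(j, j + 100, if (j <= 50) j + 200)
    expect_equal(out250[j, 1], mean(chunk_rows))
  }

  # idempotence on short inputs: the nonzero block equals the input
  short <- matrix(rnorm(30), 10, 3)
  expect_equal(fold_and_pad(short)[1:10, ], short)
  expect_equal(fold_and_pad(fold_and_pad(short)), fold_and_pad(short))
})
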