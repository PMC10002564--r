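# Cold-start splitting, supervised training and evaluation wiring.

test_that("cold-start split partitions drugs and routes pairs correctly", {
  # complete DDI graph on 10 drugs: C(10,2) = 45 pairs; with 2 new drugs per
  # fold the enumeration gives C(8,2) = 28 train, 2*8 = 16 task1, 1 task2
  gb <- generate_bundle(synth_config(n_drugs = 10, n_classes = 2,
                                     n_events = 3, label_noise = 0,
                                     seed = 2))
  splits <- cold_start_split(gb$bundle, k = 5, seed = 4)
  expect_length(splits, 5L)
  all_new <- unlist(lapply(splits, function(s) s$new_drugs))
  expect_setequal(all_new, gb$bundle$drugs$drug_id)
  expect_equal(length(all_new), 10L)
  for (s in splits) {
    expect_length(s$new_drugs, 2L)
    expect_equal(nrow(s$train_pairs), 28L)
    expect_equal(nrow(s$task1_pairs), 16L)
    expect_equal(nrow(s$task2_pairs), 1L)
  }
})

test_that("split invariants hold fold by fold", {
  gb <- generate_bundle(synth_config(n_drugs = 17, n_classes = 3,
                                     n_events = 5, seed = 6))
  splits <- cold_start_split(gb$bundle, k = 4, seed = 8)
  for (s in splits) {
    expect_length(intersect(s$known_drugs, s$new_drugs), 0L)
    expect_setequal(c(s$known_drugs, s$new_drugs), gb$bundle$drugs$drug_id)
    expect_equal(nrow(s$train_pairs) + nrow(s$task1_pairs) +
                   nrow(s$task2_pairs), nrow(gb$bundle$ddis))
    expect_true(all(s$train_pairs$drug_i %in% s$known_drugs) &&
                  all(s$train_pairs$drug_j %in% s$known_drugs))
    t1_new <- (s$task1_pairs$drug_i %in% s$new_drugs) +
      (s$task1_pairs$drug_j %in% s$new_drugs)
    expect_true(all(t1_new == 1L))
    expect_true(all(s$task2_pairs$drug_i %in% s$new_drugs) &&
                  all(s$task2_pairs$drug_j %in% s$new_drugs))
  }
  expect_identical(cold_start_split(gb$bundle, k = 4, seed = 8), splits)
  expect_error(cold_start_split(gb$bundle, k = 20), "exceeds")
})

test_that("training runs, decreases the loss and never sees new drugs", {
  s <- small_setup()
  splits <- cold_start_split(s$gb$bundle, k = 3, seed = 1)
  cfg <- mseddi_config(dim = 8, attn_heads = 2, Nl = 4, dim_cse = 8,
                       rounds = 2, seed = 2)
  tc <- train_config(batch_size = 16, epochs = 8, lr = 2e-3, seed = 2)
  fit <- train_model(splits[[1]], s$feats, cfg, tc)
  expect_length(fit$loss_trace, 8L)
  expect_true(all(is.finite(fit$loss_trace)))
  expect_lt(mean(fit$loss_trace[7:8]), fit$loss_trace[1])
  # cold-start contract: the drugs the model saw are exactly train drugs
  expect_true(all(fit$drugs_seen %in% splits[[1]]$known_drugs))

  expect_error(train_model(list(train_pairs = s$gb$bundle$ddis[0, ]),
                           s$feats, cfg, tc), "empty train_pairs")
})

test_that("the L2 penalty is wired into the updates", {
  s <- small_setup()
  splits <- cold_start_split(s$gb$bundle, k = 3, seed = 1)
  cfg <- mseddi_config(dim = 8, attn_heads = 2, Nl = 4, dim_cse = 8,
                       rounds = 2, seed = 2, channel_mask = "network")
  f0 <- train_model(splits[[1]], s$feats, cfg,
                    train_config(weight_decay = 0, batch_size = 16,
                                 epochs = 2, lr = 1e-3, seed = 2))
  f1 <- train_model(splits[[1]], s$feats, cfg,
                    train_config(weight_decay = 1e-2, batch_size = 16,
                                 epochs = 2, lr = 1e-3, seed = 2))
  expect_gt(max(abs(f0$model$params$net_W1 - f1$model$params$net_W1)), 0)
})

test_that("evaluation and prediction are deterministic and well-formed", {
  s <- small_setup()
  splits <- cold_start_split(s$gb$bundle, k = 3, seed = 1)
  cfg <- mseddi_config(dim = 8, attn_heads = 2, Nl = 4, dim_cse = 8,
                       rounds = 2, seed = 2)
  tc <- train_config(batch_size = 16, epochs = 2, lr = 1e-3, seed = 2)
  fit <- train_model(splits[[1]], s$feats, cfg, tc)
  pr1 <- predict(fit, splits[[1]]$task1_pairs)
  pr2 <- predict(fit, splits[[1]]$task1_pairs)
  expect_identical(attr(pr1, "probs"), attr(pr2, "probs"))
  expect_true(all(abs(rowSums(attr(pr1, "probs")) - 1) < 1e-9))
  m <- evaluate(fit, splits[[1]]$task1_pairs)
  expect_true(all(c(m$acc, m$auc_micro, m$aupr_micro, m$f1_macro) >= 0))
  expect_true(all(c(m$acc, m$auc_micro, m$aupr_micro, m$f1_macro) <= 1))
  expect_error(evaluate(fit, splits[[1]]$task1_pairs[0, ]), "empty")

  # same seeds reproduce the whole fit bit-identically
  fit2 <- train_model(splits[[1]], s$feats, cfg, tc)
  expect_identical(fit$model$params, fit2$model$params)
  expect_identical(attr(predict(fit2, splits[[1]]$task1_pairs), "probs"),
                   attr(pr1, "probs"))
})

test_that("channel-mask ablations run through the experiment config", {
  s <- small_setup()
  splits <- cold_start_split(s$gb$bundle, k = 3, seed = 1)
  tc <- train_config(batch_size = 16, epochs = 2, lr = 1e-3, seed = 2)
  for (mask in list("network", "sequence", "graph")) {
    cfg <- mseddi_config(dim = 8, attn_heads = 2, Nl = 4, dim_cse = 8,
                         rounds = 2, seed = 2, channel_mask = mask)
    fit <- train_model(splits[[1]], s$feats, cfg, tc)
    m <- evaluate(fit, splits[[1]]$task1_pairs)
    expect_true(is.finite(m$acc))
  }
})

test_that("tidiers and plots expose the fitted objects", {
  s <- small_setup()
  g <- glance(s$transe)
  expect_equal(g$n_entities, nrow(s$transe$entities))
  splits <- cold_start_split(s$gb$bundle, k = 3, seed = 1)
  cfg <- mseddi_config(dim = 8, attn_heads = 2, Nl = 4, dim_cse = 8,
                       rounds = 2, seed = 2, channel_mask = "network")
  fit <- train_model(splits[[1]], s$feats, cfg,
                     train_config(batch_size = 16, epochs = 2, lr = 1e-3,
                                  seed = 2))
  m <- evaluate(fit, splits[[1]]$task1_pairs)
  expect_s3_class(tidy(m), "tbl_df")
  expect_equal(nrow(glance(m)), 1L)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(m), "ggplot")
})
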