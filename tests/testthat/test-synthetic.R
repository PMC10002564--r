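# The planted-structure generator: class-pair event map, determinism,
# label-noise behaviour and the learnability self-test.

test_that("class-pair event map is round-robin, symmetric and surjective", {
  m <- class_pair_event_map(2, 3)
  expect_equal(m$event, c(0L, 1L, 2L))
  expect_equal(class_pair_event_map(1, 1)$event, 0L)
  m48 <- class_pair_event_map(4, 8)
  expect_equal(nrow(m48), 10L)          # enumeration of unordered pairs
  expect_setequal(unique(m48$event), 0:7)
  # symmetry: lookup is on the sorted pair
  expect_equal(mseddi:::.pair_event(m48, 1, 3),
               mseddi:::.pair_event(m48, 3, 1))
})

test_that("noise-free events are the deterministic class-pair function", {
  cfg <- synth_config(n_drugs = 40, n_classes = 4, n_events = 8,
                      label_noise = 0, seed = 1)
  gb <- generate_bundle(cfg)
  cls <- stats::setNames(gb$assignment$class, gb$assignment$drug_id)
  m <- class_pair_event_map(4, 8)
  expected <- mseddi:::.pair_event(m, cls[gb$bundle$ddis$drug_i],
                                   cls[gb$bundle$ddis$drug_j])
  expect_equal(gb$bundle$ddis$event, as.integer(expected))
})

test_that("generation is byte-identical under the same seed", {
  cfg <- synth_config(seed = 42)
  g1 <- generate_bundle(cfg)
  g2 <- generate_bundle(cfg)
  expect_identical(g1$bundle$drugs, g2$bundle$drugs)
  expect_identical(g1$bundle$ddis, g2$bundle$ddis)
  expect_identical(g1$bundle$triplets, g2$bundle$triplets)
  expect_identical(g1$assignment, g2$assignment)
})

test_that("full label noise leaves ~1/Nl agreement with the noise-free rule", {
  # binomial oracle: with Nl = 2 every flipped label moves to the other
  # event, so agreement is Bernoulli(0) on flipped and 1 otherwise; with
  # label_noise = 1 every pair flips, agreement should be ~0; use Nl = 2 and
  # compare against the complementary rate 1/2 via a fresh assignment rule:
  cfg <- synth_config(n_drugs = 40, n_classes = 2, n_events = 2,
                      label_noise = 1, seed = 9)
  gb <- generate_bundle(cfg)
  cls <- stats::setNames(gb$assignment$class, gb$assignment$drug_id)
  m <- class_pair_event_map(2, 2)
  rule <- mseddi:::.pair_event(m, cls[gb$bundle$ddis$drug_i],
                               cls[gb$bundle$ddis$drug_j])
  agree <- mean(gb$bundle$ddis$event == rule)
  expect_equal(agree, 0)   # Nl = 2: flipping always leaves the rule event

  # with Nl = 4 a noise-free run then full-noise run agree ~0 and the
  # flipped labels are uniform over the 3 other events (3-sigma binomial)
  cfg4 <- synth_config(n_drugs = 40, n_classes = 4, n_events = 4,
                       label_noise = 1, seed = 9)
  gb4 <- generate_bundle(cfg4)
  cls4 <- stats::setNames(gb4$assignment$class, gb4$assignment$drug_id)
  rule4 <- mseddi:::.pair_event(class_pair_event_map(4, 4),
                                cls4[gb4$bundle$ddis$drug_i],
                                cls4[gb4$bundle$ddis$drug_j])
  expect_equal(mean(gb4$bundle$ddis$event == rule4), 0)
  shifted <- (gb4$bundle$ddis$event - rule4) %% 4
  n <- length(shifted)
  p_hat <- mean(shifted == 1)
  expect_lt(abs(p_hat - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / n))
})

test_that("majority vote over true class pairs is perfect without noise", {
  gb <- generate_bundle(synth_config(label_noise = 0, seed = 3))
  cls <- stats::setNames(gb$assignment$class, gb$assignment$drug_id)
  key <- paste(pmin(cls[gb$bundle$ddis$drug_i], cls[gb$bundle$ddis$drug_j]),
               pmax(cls[gb$bundle$ddis$drug_i], cls[gb$bundle$ddis$drug_j]))
  vote <- tapply(gb$bundle$ddis$event, key, function(e) {
    as.integer(names(which.max(table(e))))
  })
  expect_equal(as.integer(vote[key]), gb$bundle$ddis$event)
})

test_that("every library SMILES parses into a valid molecular graph", {
  lib <- unlist(mseddi:::.synth_smiles_library)
  for (s in lib) {
    g <- smiles_to_molgraph(s)
    expect_gte(g$n_atoms, 1L)
  }
})

test_that("infeasible configurations are rejected", {
  expect_error(synth_config(n_classes = 1, n_events = 2), "infeasible")
  expect_error(synth_config(n_classes = 7), "SMILES family")
})
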