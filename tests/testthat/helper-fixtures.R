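# Shared fixtures, built in code. Expensive objects (pretrained embeddings
# for a small synthetic bundle) are memoised across test files.

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# a tiny consistent bundle for I/O and wiring tests
tiny_bundle <- function() {
  drugs <- tibble::tibble(drug_id = c("D1", "D2", "D3"),
                          smiles = c("CCO", "CCN", "c1ccccc1"))
  vocab <- event_vocabulary(c("e0", "e1"))
  ddis <- tibble::tibble(drug_i = c("D1", "D2"), drug_j = c("D2", "D3"),
                         event = c(0L, 1L), event_label = c("e0", "e1"))
  kg <- tibble::tibble(head = c("D1", "D2", "D3", "P1"),
                       relation = c("targets", "targets", "targets", "binds"),
                       tail = c("P1", "P1", "P2", "P2"))
  assemble_bundle(drugs, ddis, kg, vocab)
}

# memoised small synthetic setup with pretrained features (cheap settings)
.fixture_env <- new.env()
small_setup <- function() {
  if (is.null(.fixture_env$setup)) {
    gb <- generate_bundle(synth_config(n_drugs = 14, n_classes = 3,
                                       n_events = 4, label_noise = 0,
                                       kg_noise_triplets = 20, seed = 11))
    transe <- train_transe(gb$bundle$triplets,
                           transe_config(dim_kge = 16, epochs = 60,
                                         seed = 11))
    cbow <- train_cbow(lapply(gb$bundle$drugs$smiles, tokenize_smiles),
                       w2v_config(dim_sne = 8, epochs = 5, seed = 11))
    feats <- drug_features(gb$bundle, transe, cbow)
    .fixture_env$setup <- list(gb = gb, transe = transe, cbow = cbow,
                               feats = feats)
  }
  .fixture_env$setup
}

# a small untrained model over the small_setup feature dimensions
small_model <- function(Nl = 4, dim = 8, ...) {
  s <- small_setup()
  init_mseddi(mseddi_config(dim = dim, attn_heads = 2, Nl = Nl,
                            dim_cse = 8, seed = 3, ...),
              dim_kge = s$feats$dim_kge, dim_sne = s$feats$dim_sne,
              n_atom_features = s$feats$n_atom_features,
              n_bond_features = s$feats$n_bond_features)
}

expect_matrix_equal <- function(a, b, tol = 1e-8) {
  expect_equal(dim(a), dim(b))
  expect_lt(max(abs(a - b)), tol)
}
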