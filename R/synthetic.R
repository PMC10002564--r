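# Synthetic DDI benchmark with planted, recoverable structure. Every channel
# of the model sees class signal: SMILES are drawn from per-class chemical
# families, the toy knowledge graph links each drug to its class node, and
# the event of a drug pair is a deterministic round-robin function of the
# unordered class pair, optionally corrupted by label noise.

# Hard-coded families of valid SMILES, one per latent class, so the generator
# needs no chemistry dependency. Validity is asserted once in the test suite
# via the molecular-graph parser.
.synth_smiles_library <- list(
  alkanol = c("CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CCO", "CCCO", "CCCCO",
              "OCCO", "CCOC", "CCCOC", "CC(C)O", "CCC(C)O", "CCOCC", "OCCCO",
              "CCCCCO", "COC", "COCC", "CC(C)CO", "CCOCCC"),
  aromatic = c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1",
               "COc1ccccc1", "Cc1ccc(C)cc1", "Oc1ccc(C)cc1", "CCOc1ccccc1",
               "Nc1ccccc1", "CNc1ccccc1", "Cc1ccccc1O", "c1ccncc1",
               "Cc1ccncc1", "Oc1ccncc1", "CCc1ccncc1", "c1ccc2ccccc2c1",
               "Cc1cccc(C)c1", "COc1ccc(C)cc1", "Oc1cccc(O)c1", "CCCc1ccccc1"),
  halogen = c("CCl", "CCCl", "CCBr", "ClCCCl", "CC(Cl)C", "BrCCBr", "CCCBr",
              "ClCCl", "FCC", "CC(F)C", "ClC(Cl)Cl", "CCCCl", "BrCC(C)C",
              "FCCF", "CCC(Cl)C", "ICC", "CCCCCl", "BrCCC", "FCCCF",
              "ClCCCCl"),
  amine = c("CN", "CCN", "CNC", "CCNC", "NCCN", "CC(N)C", "CCCN", "CN(C)C",
            "C[NH3+]", "CC[NH3+]", "CC(=O)[O-]", "CC(=O)O", "CCC(=O)O",
            "NCCO", "CNCC", "CC(=O)N", "CCC(N)C", "NCCCN", "CCN(C)C",
            "NCC(=O)O"),
  thio = c("CS", "CCS", "CSC", "CCSC", "SCCS", "CC(S)C", "CCCS", "CSCC",
           "CCSCC", "SCCCS", "OCS", "OCCS", "CSCCS", "CCCCS", "SC(C)C",
           "CSCSC", "CCSCSC", "SCCO", "CC(S)CC", "CCCSC"),
  alkene = c("C=C", "CC=C", "C#C", "CC#C", "C=CC=C", "CC=CC", "C#CC",
             "CC(=C)C", "C=CCO", "CC=CCC", "C#CCC", "C=C(C)C", "C=CCC=C",
             "CC#CC", "C=CCCO", "OC=CC", "C=CCN", "CC=C(C)C", "C#CCO",
             "C=CCCC")
)
#' Configuration for the synthetic-data generator
#'
#' Defaults define the package's reference study conditions: 40 drugs in 4
#' latent classes, 8 event types, 5% label noise.
#'
#' @param n_drugs Number of drugs.
#' @param n_classes Number of latent drug classes `C` (at most 6, the number
#'   of built-in SMILES families).
#' @param n_events Number of DDI event types `Nl`; must not exceed the
#'   `C*(C+1)/2` distinct unordered class pairs.
#' @param label_noise Probability that a pair's event is flipped to a
#'   uniformly chosen different event.
#' @param kg_noise_triplets Number of uniformly random auxiliary triplets
#'   added to the knowledge graph.
#' @param pair_fraction Fraction of all unordered drug pairs that receive a
#'   DDI record.
#' @param seed Integer seed; all generation is reproducible from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_drugs = 40, n_classes = 4, n_events = 8,
                         label_noise = 0.05, kg_noise_triplets = 60,
                         pair_fraction = 1, seed = 1) {
  stopifnot(n_drugs >= 2, n_classes >= 1, n_events >= 1,
            label_noise >= 0, label_noise <= 1,
            kg_noise_triplets >= 0, pair_fraction > 0, pair_fraction <= 1)
  if (n_classes > length(.synth_smiles_library)) {
    stop("n_classes must be at most ", length(.synth_smiles_library),
         " (one SMILES family per class)")
  }
  if (n_events > n_classes * (n_classes + 1) / 2) {
    stop("infeasible config: n_events (", n_events, ") exceeds the ",
         n_classes * (n_classes + 1) / 2, " distinct unordered class pairs")
  }
  structure(list(n_drugs = n_drugs, n_classes = n_classes,
                 n_events = n_events, label_noise = label_noise,
                 kg_noise_triplets = kg_noise_triplets,
                 pair_fraction = pair_fraction, seed = as.integer(seed)),
            class = "synth_config")
}

#' Deterministic event assignment for unordered class pairs
#'
#' Unordered class pairs `(a, b)`, `a <= b`, are enumerated in lexicographic
#' order and events `0..Nl-1` are assigned round-robin, so the map is
#' symmetric in the pair and surjective whenever `C*(C+1)/2 >= Nl`.
#'
#' @param C Number of classes.
#' @param Nl Number of events.
#' @return A tibble with columns `class_a`, `class_b` (0-based, `a <= b`) and
#'   `event`.
#' @export
class_pair_event_map <- function(C, Nl) {
  stopifnot(C >= 1, Nl >= 1)
  pairs <- expand.grid(class_b = 0:(C - 1), class_a = 0:(C - 1))
  pairs <- pairs[pairs$class_a <= pairs$class_b, c("class_a", "class_b")]
  pairs <- pairs[order(pairs$class_a, pairs$class_b), ]
  tibble::tibble(class_a = pairs$class_a, class_b = pairs$class_b,
                 event = (seq_len(nrow(pairs)) - 1L) %% as.integer(Nl))
}

# event for one unordered class pair under the round-robin map
.pair_event <- function(map, ci, cj) {
  a <- pmin(ci, cj); b <- pmax(ci, cj)
  idx <- match(paste(a, b), paste(map$class_a, map$class_b))
  map$event[idx]
}

#' Generate a synthetic dataset bundle
#'
#' Produces a self-contained [assemble_bundle()] output whose three input
#' modalities all carry the same planted class signal:
#' \itemize{
#'   \item each drug's SMILES is drawn from its class's chemical family
#'     (sequence and molecular-graph channels);
#'   \item the knowledge graph contains a `(drug, has_class, class node)`
#'     triplet for every drug plus uniformly random noise triplets over
#'     auxiliary entities (knowledge-graph channel);
#'   \item each sampled drug pair's event is the round-robin function of its
#'     unordered class pair ([class_pair_event_map()]), flipped to a uniform
#'     different event with probability `label_noise`.
#' }
#'
#' @param cfg A [synth_config()].
#' @return A list with `bundle` (a `ddi_bundle`) and `assignment`, a tibble
#'   `(drug_id, class)` giving the latent class of every drug.
#' @export
generate_bundle <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_local_seed(cfg$seed, {
    C <- cfg$n_classes
    n <- cfg$n_drugs
    drug_id <- sprintf("D%03d", seq_len(n))
    class <- sample(rep_len(0:(C - 1), n))
    fams <- .synth_smiles_library[seq_len(C)]
    smiles <- vapply(class, function(cl) sample(fams[[cl + 1L]], 1L),
                     character(1))
    drugs <- tibble::tibble(drug_id = drug_id, smiles = smiles)

    # knowledge graph: class membership plus auxiliary noise
    kg <- tibble::tibble(head = drug_id, relation = "has_class",
                         tail = sprintf("CLASS%d", class))
    if (cfg$kg_noise_triplets > 0L) {
      aux <- sprintf("AUX%02d", 1:10)
      rels <- c("assoc_a", "assoc_b")
      noise <- tibble::tibble(
        head = sample(aux, cfg$kg_noise_triplets, replace = TRUE),
        relation = sample(rels, cfg$kg_noise_triplets, replace = TRUE),
        tail = sample(aux, cfg$kg_noise_triplets, replace = TRUE))
      kg <- dplyr::bind_rows(kg, noise)
    }

    # DDI events over sampled unordered pairs
    map <- class_pair_event_map(C, cfg$n_events)
    idx <- utils::combn(n, 2L)
    if (cfg$pair_fraction < 1) {
      keep <- sort(sample(ncol(idx), ceiling(cfg$pair_fraction * ncol(idx))))
      idx <- idx[, keep, drop = FALSE]
    }
    ev <- .pair_event(map, class[idx[1L, ]], class[idx[2L, ]])
    if (cfg$label_noise > 0 && cfg$n_events > 1L) {
      flip <- stats::runif(ncol(idx)) < cfg$label_noise
      if (any(flip)) {
        ev[flip] <- vapply(ev[flip], function(e) {
          sample(setdiff(0:(cfg$n_events - 1L), e), 1L)
        }, integer(1))
      }
    }
    vocab <- event_vocabulary(sprintf("event%02d", 0:(cfg$n_events - 1L)))
    ddis <- tibble::tibble(
      drug_i = drug_id[idx[1L, ]],
      drug_j = drug_id[idx[2L, ]],
      event = as.integer(ev),
      event_label = vocab$labels[ev + 1L])
    bundle <- assemble_bundle(drugs, ddis, kg, vocab)
    list(bundle = bundle,
         assignment = tibble::tibble(drug_id = drug_id, class = class))
  })
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
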