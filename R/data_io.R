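#' Read a DDI event table
#'
#' Reads a tab-separated file of drug-drug interaction events with columns
#' `(drug_a, drug_b, event)` and no header by default. The event vocabulary
#' is built from the unique labels in first-appearance order unless one is
#' supplied, so the label-to-index assignment is a deterministic function of
#' the file content.
#'
#' @param path Path to a TSV file with three columns and no header.
#' @param events Optional event vocabulary (from [event_vocabulary()]); when
#'   given, every label in the file must already be in it.
#' @param header Skip one header line when `TRUE`.
#' @return A list with `ddis`, a tibble of records
#'   (`drug_i`, `drug_j`, `event` as 0-based index, `event_label`), and
#'   `events`, the vocabulary.
#' @details Records are validated: a self pair (`drug_i == drug_j`) or a
#'   duplicate unordered pair is an error. Blank lines are skipped.
#' @examples
#' f <- tempfile()
#' writeLines(c("D1\tD2\tincrease_risk", "D1\tD3\tdecrease_metab"), f)
#' read_ddi_table(f)$events$labels
#' @export
read_ddi_table <- function(path, events = NULL, header = FALSE) {
  rows <- read_tsv3(path, header, what = "DDI table")
  if (nrow(rows) == 0L) {
    vocab <- if (is.null(events)) event_vocabulary(character(0)) else events
    return(list(ddis = tibble::tibble(drug_i = character(0),
                                      drug_j = character(0),
                                      event = integer(0),
                                      event_label = character(0)),
                events = vocab))
  }
  labels <- rows[[3]]
  if (is.null(events)) {
    vocab <- event_vocabulary(unique(labels))
  } else {
    vocab <- events
    unknown <- setdiff(labels, vocab$labels)
    if (length(unknown) > 0L) {
      stop("DDI table contains event labels absent from the supplied ",
           "vocabulary: ", paste(unique(unknown), collapse = ", "))
    }
  }
  self <- rows[[1]] == rows[[2]]
  if (any(self)) {
    stop("self pair (same drug on both sides) at line ",
         paste(rows$line[self], collapse = ", "))
  }
  key <- pair_key(rows[[1]], rows[[2]])
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate unordered drug pair(s): ",
         paste(unique(key[dup]), collapse = ", "))
  }
  ddis <- tibble::tibble(
    drug_i = rows[[1]],
    drug_j = rows[[2]],
    event = match(labels, vocab$labels) - 1L,
    event_label = labels
  )
  list(ddis = ddis, events = vocab)
}

#' Read a drug table
#'
#' Tab-separated `(drug_id, smiles)`, no header by default.
#'
#' @inheritParams read_ddi_table
#' @return A tibble with columns `drug_id` and `smiles`.
#' @export
read_drug_table <- function(path, header = FALSE) {
  rows <- read_tsvn(path, 2L, header, what = "drug table")
  drugs <- tibble::tibble(drug_id = rows[[1]], smiles = rows[[2]])
  validate_drugs(drugs)
  drugs
}

#' Read knowledge-graph triplets
#'
#' Tab-separated `(head, relation, tail)` triplets, no header by default.
#' Blank lines are skipped; duplicate triplets are retained (the training set
#' is a multiset).
#'
#' @inheritParams read_ddi_table
#' @return A tibble with columns `head`, `relation`, `tail`.
#' @export
read_kg_triplets <- function(path, header = FALSE) {
  rows <- read_tsv3(path, header, what = "KG triplet file")
  trip <- tibble::tibble(head = rows[[1]], relation = rows[[2]],
                         tail = rows[[3]])
  bad <- !nzchar(trip$head) | !nzchar(trip$relation) | !nzchar(trip$tail)
  if (any(bad)) {
    stop("empty field in KG triplet at line ",
         paste(rows$line[bad], collapse = ", "))
  }
  trip
}

#' Event vocabulary
#'
#' An ordered set of event labels; the 0-based position of a label is its
#' event index throughout the package.
#'
#' @param labels Character vector of unique event names.
#' @return An object of class `event_vocabulary` with fields `labels` and
#'   `Nl`.
#' @export
event_vocabulary <- function(labels) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("event labels must be unique")
  structure(list(labels = labels, Nl = length(labels)),
            class = "event_vocabulary")
}

#' Assemble a dataset bundle
#'
#' Cross-checks the parsed components and packs them into the container used
#' by every downstream stage. A DDI record that references a drug absent from
#' the drug table is an error; a drug that never occurs as a knowledge-graph
#' entity is allowed (it will receive a zero KG vector downstream) and is
#' recorded in the bundle's warning list.
#'
#' @param drugs Tibble `(drug_id, smiles)`.
#' @param ddis Tibble of DDI records as returned by [read_ddi_table()].
#' @param triplets Tibble `(head, relation, tail)`.
#' @param events An [event_vocabulary()].
#' @return A `ddi_bundle` object: list with `drugs`, `ddis`, `triplets`,
#'   `events`, `warnings` (drug ids missing from the KG).
#' @export
assemble_bundle <- function(drugs, ddis, triplets, events) {
  validate_drugs(drugs)
  unknown <- setdiff(unique(c(ddis$drug_i, ddis$drug_j)), drugs$drug_id)
  if (length(unknown) > 0L) {
    stop("DDI records reference unknown drug id(s): ",
         paste(unknown, collapse = ", "))
  }
  if (nrow(ddis) > 0L &&
      (any(ddis$event < 0L) || any(ddis$event >= events$Nl))) {
    stop("DDI event index outside the vocabulary range [0, ", events$Nl, ")")
  }
  kg_entities <- unique(c(triplets$head, triplets$tail))
  missing_kg <- setdiff(drugs$drug_id, kg_entities)
  structure(list(drugs = drugs, ddis = ddis, triplets = triplets,
                 events = events, warnings = missing_kg),
            class = "ddi_bundle")
}

#' @export
print.ddi_bundle <- function(x, ...) {
  cat("<ddi_bundle> ", nrow(x$drugs), " drugs, ", nrow(x$ddis),
      " DDI records, ", nrow(x$triplets), " KG triplets, ",
      x$events$Nl, " events\n", sep = "")
  if (length(x$warnings) > 0L) {
    cat("  drugs absent from the KG: ", length(x$warnings), "\n", sep = "")
  }
  invisible(x)
}

#' Write a bundle to a directory of TSV files
#'
#' Writes `ddis.tsv`, `drugs.tsv`, `kg.tsv` and `events.tsv` in the package's
#' tab-separated dialect so that reading them back reproduces the bundle
#' exactly (records, ordering and event indices).
#'
#' @param bundle A `ddi_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_plain <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_plain(bundle$ddis[, c("drug_i", "drug_j", "event_label")], "ddis.tsv")
  write_plain(bundle$drugs, "drugs.tsv")
  write_plain(bundle$triplets, "kg.tsv")
  writeLines(bundle$events$labels, file.path(dir, "events.tsv"))
  invisible(dir)
}

#' Read a bundle back from a directory written by [write_bundle()]
#'
#' @param dir Directory containing `ddis.tsv`, `drugs.tsv`, `kg.tsv`,
#'   `events.tsv`.
#' @return A `ddi_bundle`.
#' @export
read_bundle <- function(dir) {
  labels <- readLines(file.path(dir, "events.tsv"))
  vocab <- event_vocabulary(labels[nzchar(labels)])
  dd <- read_ddi_table(file.path(dir, "ddis.tsv"), events = vocab)
  drugs <- read_drug_table(file.path(dir, "drugs.tsv"))
  kg <- read_kg_triplets(file.path(dir, "kg.tsv"))
  assemble_bundle(drugs, dd$ddis, kg, vocab)
}

## ---- internal helpers -----------------------------------------------------

# unordered pair key
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

validate_drugs <- function(drugs) {
  if (anyDuplicated(drugs$drug_id)) {
    stop("duplicate drug_id(s): ",
         paste(unique(drugs$drug_id[duplicated(drugs$drug_id)]),
               collapse = ", "))
  }
  if (any(!nzchar(drugs$smiles))) {
    stop("empty SMILES for drug(s): ",
         paste(drugs$drug_id[!nzchar(drugs$smiles)], collapse = ", "))
  }
  invisible(drugs)
}

read_tsvn <- function(path, ncols, header, what) {
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  if (header && length(lines) > 0L) {
    lines <- lines[-1L]
    lineno <- lineno[-1L]
  }
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L) {
    out <- tibble::as_tibble(stats::setNames(
      replicate(ncols, character(0), simplify = FALSE),
      paste0("V", seq_len(ncols))))
    out$line <- integer(0)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(parts)
  if (any(nfld != ncols)) {
    bad <- which(nfld != ncols)[1L]
    stop("malformed row in ", what, " at line ", lineno[bad], ": expected ",
         ncols, " tab-separated fields, found ", nfld[bad])
  }
  m <- do.call(rbind, parts)
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  names(out) <- paste0("V", seq_len(ncols))
  out$line <- lineno
  out
}

read_tsv3 <- function(path, header, what) read_tsvn(path, 3L, header, what)
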