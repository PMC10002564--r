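# SMILES -> attributed molecular graph. Parsing, ring perception and
# aromaticity come from ChemmineR/OpenBabel; the remaining atom attributes
# (implicit hydrogens, hybridization, conjugation) are derived from the
# parsed bonds with documented valence heuristics. Hydrogens are implicit:
# the graph has one node per heavy atom and one undirected edge per bond.

.element_set <- c("C", "N", "O", "S", "F", "Cl", "Br", "P", "I")
.element_mass <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                   F = 18.998, Cl = 35.45, Br = 79.904, P = 30.974,
                   I = 126.904)

#' Parse a SMILES string into an attributed molecular graph
#'
#' One node per heavy atom, one edge per bond. Atom nodes carry eight
#' attribute groups (element one-hot over the common organic set, heavy-atom
#' degree one-hot, formal charge, chirality one-hot, implicit-hydrogen count
#' one-hot, hybridization one-hot, aromaticity flag, scaled atomic mass);
#' bonds carry four groups (bond-type one-hot with aromatic as its own type,
#' conjugation flag, ring flag, stereo one-hot).
#'
#' @param s A chemically valid SMILES string.
#' @return A `molgraph`: list with `n_atoms`, `element`, `atom_features`
#'   (matrix, one row per atom), `bonds` (tibble `u`, `v`, `order`,
#'   `aromatic`, `ring`), `bond_features` (one row per bond), `smiles`.
#' @export
smiles_to_molgraph <- function(s) {
  if (!is.character(s) || length(s) != 1L || !nzchar(s)) {
    stop("SMILES must be a single non-empty string")
  }
  # one-atom molecules are not representable in the SDF backend; build them
  # directly from the (single) atom token
  atom_tokens <- tryCatch(tokenize_smiles(s), error = function(e) NULL)
  if (is.null(atom_tokens)) stop("cannot parse SMILES string: ", s)
  is_atom <- grepl("^\\[.*\\]$", atom_tokens) |
    atom_tokens %in% c(.element_set, tolower(c("b", "c", "n", "o", "p", "s")))
  if (sum(is_atom) == 1L) {
    return(single_atom_molgraph(s, atom_tokens[is_atom]))
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(s, "m"))),
    error = function(e) NULL)
  if (is.null(sdf) || length(sdf) == 0L) {
    stop("cannot parse SMILES string: ", s)
  }
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  if (is.null(ab) || nrow(ab) == 0L ||
      !all(grepl("_", rownames(ab), fixed = TRUE))) {
    stop("cannot parse SMILES string: ", s)
  }
  n <- nrow(ab)
  element <- sub("_.*$", "", rownames(ab))

  # formal charge from the V2000 charge-code column (3 -> +1, 5 -> -1, ...)
  code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n)
  charge <- unname(c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                     `6` = -2, `7` = -3)[as.character(code)])
  charge[is.na(charge)] <- 0
  valence <- default_valence(element)

  bb <- ChemmineR::bondblock(mol)
  if (is.null(bb) || nrow(bb) == 0L) {
    bonds <- tibble::tibble(u = integer(0), v = integer(0),
                            order = integer(0), aromatic = logical(0),
                            ring = logical(0))
  } else {
    bonds <- tibble::tibble(u = as.integer(bb[, 1]), v = as.integer(bb[, 2]),
                            order = as.integer(bb[, 3]),
                            aromatic = FALSE, ring = FALSE)
  }

  # ring and aromatic perception
  if (n >= 3L && nrow(bonds) >= 3L) {
    rl <- tryCatch(ChemmineR::rings(mol, type = "all", arom = TRUE),
                   error = function(e) list(RINGS = list(), AROMATIC = logical(0)))
    ring_atoms <- lapply(rl$RINGS, function(rg) {
      as.integer(sub("^.*_", "", rg))
    })
    arom <- rl$AROMATIC
    bond_key <- paste(pmin(bonds$u, bonds$v), pmax(bonds$u, bonds$v))
    for (k in seq_along(ring_atoms)) {
      ra <- ring_atoms[[k]]
      eu <- ra
      ev <- c(ra[-1L], ra[1L])
      keys <- paste(pmin(eu, ev), pmax(eu, ev))
      in_ring <- bond_key %in% keys
      bonds$ring <- bonds$ring | in_ring
      if (isTRUE(arom[k])) bonds$aromatic <- bonds$aromatic | in_ring
    }
  }
  atom_aromatic <- rep(FALSE, n)
  if (nrow(bonds) > 0L && any(bonds$aromatic)) {
    atom_aromatic[unique(c(bonds$u[bonds$aromatic],
                           bonds$v[bonds$aromatic]))] <- TRUE
  }

  degree <- tabulate(c(bonds$u, bonds$v), nbins = n)
  order_sum <- numeric(n)
  if (nrow(bonds) > 0L) {
    for (k in seq_len(nrow(bonds))) {
      order_sum[bonds$u[k]] <- order_sum[bonds$u[k]] + bonds$order[k]
      order_sum[bonds$v[k]] <- order_sum[bonds$v[k]] + bonds$order[k]
    }
  }
  n_double <- tabulate(c(bonds$u[bonds$order == 2L],
                         bonds$v[bonds$order == 2L]), nbins = n)
  n_triple <- tabulate(c(bonds$u[bonds$order == 3L],
                         bonds$v[bonds$order == 3L]), nbins = n)
  implicit_h <- pmax(0L, valence - order_sum + charge)
  hyb <- ifelse(n_triple > 0 | n_double >= 2, "sp",
                ifelse(atom_aromatic | n_double == 1, "sp2", "sp3"))

  atom_features <- atom_feature_matrix(element, degree, charge, implicit_h,
                                       hyb, atom_aromatic)
  # conjugation heuristic: aromatic bonds; single bonds bridging two
  # multiple-bond-bearing atoms; multiple bonds adjacent to another
  # multiple bond through a shared atom
  multi <- n_double > 0 | n_triple > 0 | atom_aromatic
  if (nrow(bonds) > 0L) {
    nbrs <- lapply(seq_len(n), function(a) {
      c(bonds$v[bonds$u == a], bonds$u[bonds$v == a])
    })
    is_mult <- bonds$order >= 2L
    conj <- vapply(seq_len(nrow(bonds)), function(k) {
      u <- bonds$u[k]; v <- bonds$v[k]
      if (bonds$aromatic[k]) return(TRUE)
      if (!is_mult[k]) return(multi[u] && multi[v])
      # a multiple bond is conjugated when a third atom adjacent to either
      # endpoint also bears a multiple bond
      any(multi[setdiff(nbrs[[u]], v)]) || any(multi[setdiff(nbrs[[v]], u)])
    }, logical(1))
  } else {
    conj <- logical(0)
  }
  bond_features <- bond_feature_matrix(bonds, conj)

  structure(list(n_atoms = n, element = element,
                 atom_features = atom_features, bonds = bonds,
                 bond_features = bond_features, smiles = s),
            class = "molgraph")
}

# usual organic valences; elements outside the table get no implicit H
default_valence <- function(element) {
  tab <- c(C = 4, N = 3, O = 2, S = 2, F = 1, Cl = 1, Br = 1, I = 1,
           P = 3, B = 3)
  v <- unname(tab[element])
  v[is.na(v)] <- 0
  v
}

# build a molgraph for a single-atom SMILES ("C", "[NH4+]", ...)
single_atom_molgraph <- function(s, token) {
  if (grepl("^\\[", token)) {
    m <- regmatches(token,
                    regexec("^\\[[0-9]*([A-Za-z][a-z]?)@{0,2}(H[0-9]*)?([+-][0-9]*|\\++|-+)?\\]$",
                            token))[[1]]
    if (length(m) == 0L) stop("cannot parse SMILES string: ", s)
    element <- m[2]
    hfield <- m[3]
    cfield <- m[4]
    implicit_h <- if (!nzchar(hfield)) 0L
      else if (hfield == "H") 1L else as.integer(sub("H", "", hfield))
    charge <- if (!nzchar(cfield)) 0L
      else if (cfield %in% c("+", "-")) ifelse(cfield == "+", 1L, -1L)
      else if (grepl("^\\++$", cfield)) nchar(cfield)
      else if (grepl("^-+$", cfield)) -nchar(cfield)
      else as.integer(cfield)
  } else {
    element <- toupper(token)
    charge <- 0L
    implicit_h <- default_valence(element)
  }
  element <- paste0(toupper(substr(element, 1, 1)),
                    substring(element, 2))
  atom_features <- atom_feature_matrix(element, degree = 0L,
                                       charge = charge,
                                       implicit_h = implicit_h,
                                       hyb = "sp3", aromatic = FALSE)
  bonds <- tibble::tibble(u = integer(0), v = integer(0), order = integer(0),
                          aromatic = logical(0), ring = logical(0))
  structure(list(n_atoms = 1L, element = element,
                 atom_features = atom_features, bonds = bonds,
                 bond_features = bond_feature_matrix(bonds, logical(0)),
                 smiles = s),
            class = "molgraph")
}

# eight atom attribute groups, fixed layout
atom_feature_matrix <- function(element, degree, charge, implicit_h, hyb,
                                aromatic) {
  n <- length(element)
  onehot <- function(x, levels) {
    m <- matrix(0, n, length(levels))
    idx <- match(x, levels)
    idx[is.na(idx)] <- length(levels)
    m[cbind(seq_len(n), idx)] <- 1
    m
  }
  el <- onehot(element, c(.element_set, "other"))
  dg <- onehot(pmin(degree, 4L), c(0:3, "4"))
  ch <- matrix(charge, n, 1L)
  # chirality: tag perception is out of scope of the parser backend; all
  # atoms carry the "none" tag (slot 2 reserved for tagged centres)
  chir <- cbind(rep(1, n), rep(0, n))
  hc <- onehot(pmin(implicit_h, 4L), c(0:3, "4"))
  hy <- onehot(hyb, c("sp", "sp2", "sp3", "other"))
  ar <- matrix(as.numeric(aromatic), n, 1L)
  mass <- matrix(unname(.element_mass[element]), n, 1L)
  mass[is.na(mass)] <- 0
  mass <- mass / 100
  out <- cbind(el, dg, ch, chir, hc, hy, ar, mass)
  colnames(out) <- c(paste0("el_", c(.element_set, "other")),
                     paste0("deg_", c(0:3, "4p")), "charge",
                     "chir_none", "chir_tag",
                     paste0("h_", c(0:3, "4p")),
                     paste0("hyb_", c("sp", "sp2", "sp3", "other")),
                     "aromatic", "mass")
  out
}

# four bond attribute groups: type, conjugated, ring, stereo
bond_feature_matrix <- function(bonds, conj) {
  nb <- nrow(bonds)
  type <- matrix(0, nb, 4L)
  if (nb > 0L) {
    t_idx <- ifelse(bonds$aromatic, 4L, pmin(bonds$order, 3L))
    type[cbind(seq_len(nb), t_idx)] <- 1
  }
  out <- cbind(type, matrix(as.numeric(conj), nb, 1L),
               matrix(as.numeric(bonds$ring), nb, 1L),
               matrix(rep(c(1, 0), each = nb), nb, 2L))
  colnames(out) <- c("bond_single", "bond_double", "bond_triple",
                     "bond_aromatic", "conjugated", "ring",
                     "stereo_none", "stereo_tag")
  out
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", x$smiles, ": ", x$n_atoms, " atoms, ", nrow(x$bonds),
      " bonds\n", sep = "")
  invisible(x)
}

#' One round of synchronous message passing (reference form)
#'
#' Computes `a_x = sum_{y in N(x)} A(h_x, h_y, e_xy)` followed by
#' `h_x <- U(h_x, a_x)` for every node simultaneously. This is the plain
#' functional form used for verification; the trainable encoders implement
#' the same scheme with linear layers on the differentiable path.
#'
#' @param graph A `molgraph`.
#' @param state Numeric matrix, one row per atom.
#' @param A Aggregation function `A(h_x, h_y, e_xy) -> vector` (same width
#'   as `state`).
#' @param U Update function `U(h_x, a_x) -> vector`.
#' @return Updated state matrix.
#' @export
message_pass <- function(graph, state, A, U) {
  if (!is.matrix(state)) state <- as.matrix(state)
  stopifnot(nrow(state) == graph$n_atoms)
  n <- graph$n_atoms
  agg <- matrix(0, n, ncol(state))
  if (nrow(graph$bonds) > 0L) {
    src <- c(graph$bonds$u, graph$bonds$v)
    dst <- c(graph$bonds$v, graph$bonds$u)
    ef <- rbind(graph$bond_features, graph$bond_features)
    for (k in seq_along(src)) {
      x <- dst[k]; y <- src[k]
      agg[x, ] <- agg[x, ] + A(state[x, ], state[y, ], ef[k, ])
    }
  }
  out <- t(vapply(seq_len(n), function(x) U(state[x, ], agg[x, ]),
                  numeric(ncol(state))))
  if (ncol(state) == 1L) out <- matrix(out, ncol = 1L)
  out
}
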