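#' Construct a molecule record
#'
#' The package's central container for one compound: a connection table
#' (elements, bonds, formal charges, optional 3D coordinates in Angstrom),
#' an optional binding affinity, and bookkeeping labels. Synthetic benchmark
#' "molecules" use the same container with precomputed feature sites and
#' per-atom pharmacophore classes attached.
#'
#' @param id Unique compound identifier (non-empty string).
#' @param atoms Data frame with columns `elem` (element symbol), `x`, `y`,
#'   `z` (Angstrom; may be `NA` when no 3D coordinates are known) and
#'   optionally `charge` (formal charge, default 0) and `nh` (attached
#'   hydrogen count; computed from standard valences when missing).
#' @param bonds Data frame with columns `a1`, `a2` (1-based atom indices)
#'   and `order` (1, 2, 3, or 4 for aromatic). May have zero rows.
#' @param ki Binding affinity in molar units, or `NA`.
#' @param name Optional human-readable name.
#' @param set_label One of `"train"`, `"test"`, `"external"`, `"active"`,
#'   `"decoy"`, `"unlabeled"`.
#' @param source_ref Free-text provenance.
#' @param smiles Optional SMILES string (kept verbatim; used to build 3D
#'   coordinates on demand).
#' @param sites Optional precomputed feature-site data frame (see
#'   [perceive_features()]); used by the synthetic benchmark where sites are
#'   planted rather than perceived.
#' @param atom_class Optional per-atom pharmacophore class vector
#'   (see [assign_atom_classes()]).
#'
#' @return An object of class `phmol`. Fields `pki` and `activity_class`
#'   are derived from `ki` ([ki_to_pki()], [classify_activity()]).
#' @export
phmol <- function(id, atoms, bonds = NULL, ki = NA_real_, name = NULL,
                  set_label = "unlabeled", source_ref = "",
                  smiles = NULL, sites = NULL, atom_class = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("elem", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  } else {
    bonds <- as.data.frame(bonds)
    stopifnot(all(c("a1", "a2", "order") %in% names(bonds)))
    if (any(bonds$a1 < 1 | bonds$a2 < 1 | bonds$a1 > nrow(atoms) |
            bonds$a2 > nrow(atoms))) {
      stop("bond indices out of range for molecule '", id, "'")
    }
  }
  if (is.null(atoms$nh)) atoms$nh <- implicit_h_counts(atoms, bonds)
  set_label <- match.arg(set_label,
                         c("train", "test", "external", "active", "decoy",
                           "unlabeled"))
  if (!is.na(ki) && ki <= 0) stop("ki must be positive (molecule '", id, "')")
  mol <- structure(
    list(id = id, name = if (is.null(name)) id else name,
         atoms = atoms, bonds = bonds,
         ki = as.numeric(ki),
         pki = if (is.na(ki)) NA_real_ else ki_to_pki(ki),
         activity_class = if (is.na(ki)) "unknown" else classify_activity(ki),
         set_label = set_label, source_ref = source_ref,
         smiles = smiles, sites = sites, atom_class = atom_class),
    class = "phmol")
  mol
}

#' @export
print.phmol <- function(x, ...) {
  cat(sprintf("<phmol %s> %d atoms, %d bonds", x$id, nrow(x$atoms),
              nrow(x$bonds)))
  if (!is.na(x$ki)) {
    cat(sprintf(", Ki = %.3g M (pKi %.2f, %s)", x$ki, x$pki,
                x$activity_class))
  }
  cat(sprintf(" [%s]\n", x$set_label))
  invisible(x)
}

# Standard valences used to infer attached-H counts from a heavy-atom
# connection table; formal charge shifts N/O valence in the usual way.
.standard_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1,
                       Br = 1, I = 1, B = 3, Si = 4)

implicit_h_counts <- function(atoms, bonds) {
  n <- nrow(atoms)
  bsum <- numeric(n)
  if (nrow(bonds)) {
    ord <- ifelse(bonds$order == 4, 1.5, bonds$order)
    for (i in seq_len(nrow(bonds))) {
      bsum[bonds$a1[i]] <- bsum[bonds$a1[i]] + ord[i]
      bsum[bonds$a2[i]] <- bsum[bonds$a2[i]] + ord[i]
    }
  }
  bsum <- ceiling(bsum)  # two aromatic bonds count as 3
  val <- .standard_valence[atoms$elem]
  val[is.na(val)] <- 0
  chg <- atoms$charge
  # N+ gains a bonding slot, O-/N- lose one; halogen/carbanion cases ignored
  val <- val + ifelse(atoms$elem %in% c("N", "P"), pmax(pmin(chg, 1), -1),
                      ifelse(atoms$elem %in% c("O", "S"),
                             pmax(pmin(chg, 1), -1), 0))
  pmax(0L, as.integer(round(val - bsum)))
}

#' Convert a binding affinity to pKi
#'
#' `pKi = -log10(Ki)` with `Ki` in molar units; the regression response used
#' throughout the 3D-QSAR workflow.
#'
#' @param ki Binding affinity in molar units (vectorized, all > 0).
#' @return Numeric vector of pKi values.
#' @examples
#' ki_to_pki(1e-6)    # 6
#' ki_to_pki(3.3e-9)  # 8.48 (a ~3 nM potent blocker)
#' @export
ki_to_pki <- function(ki) {
  if (any(!is.finite(ki)) || any(ki <= 0)) {
    stop("ki must be finite and positive (molar units)")
  }
  -log10(ki)
}

#' Convert pKi back to Ki (molar)
#' @param pki pKi value(s).
#' @return Ki in molar units.
#' @export
pki_to_ki <- function(pki) 10^(-pki)

#' Classify hERG inhibitory potency from Ki
#'
#' Thresholds follow the convention used for hERG displacement data:
#' potent when Ki is at most 50 nM, moderate between 50 nM and 5 uM,
#' inactive at 5 uM and above. Exactly 50 nM is potent (the potent class is
#' quoted inclusively); exactly 5 uM is classed inactive, the safer
#' (flagging) side of an ambiguous boundary.
#'
#' @param ki Binding affinity in molar units (vectorized, all > 0).
#' @return Character vector: `"potent"`, `"moderate"`, or `"inactive"`.
#' @export
classify_activity <- function(ki) {
  if (any(!is.finite(ki)) || any(ki <= 0)) {
    stop("ki must be finite and positive (molar units)")
  }
  ifelse(ki <= 5e-8, "potent", ifelse(ki < 5e-6, "moderate", "inactive"))
}

#' Heavy-atom coordinate matrix of a molecule
#'
#' @param mol A `phmol`.
#' @return Numeric matrix (n_heavy x 3); rows follow `mol$atoms` with
#'   hydrogens removed.
#' @export
heavy_coords <- function(mol) {
  keep <- mol$atoms$elem != "H"
  m <- as.matrix(mol$atoms[keep, c("x", "y", "z")])
  storage.mode(m) <- "double"
  m
}

heavy_index <- function(mol) which(mol$atoms$elem != "H")
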