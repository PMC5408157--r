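#' Conformer ensemble container
#'
#' An ordered set of conformers for one molecule. Invariants: relative
#' energies ascending with the first at 0; every energy within the retention
#' window; every pair of kept conformers at least `rmsd_cutoff` apart in
#' heavy-atom RMSD after optimal superposition.
#'
#' @param molecule_id Molecule identifier.
#' @param conformers List of `list(coords = n x 3 matrix, rel_energy = kJ/mol)`;
#'   `coords` covers all atoms of the molecule in order.
#' @param heavy Integer indices of heavy atoms within `coords` rows.
#' @param engine Free-text engine tag recorded for provenance.
#' @return Object of class `ph_ensemble`.
#' @export
ph_ensemble <- function(molecule_id, conformers, heavy = NULL,
                        engine = "phore3d-torsion-scan") {
  stopifnot(length(conformers) >= 1L)
  e <- vapply(conformers, `[[`, 0, "rel_energy")
  if (is.unsorted(e)) stop("conformer energies must be ascending")
  if (abs(e[1]) > 1e-9) stop("first relative energy must be 0")
  if (is.null(heavy)) heavy <- seq_len(nrow(conformers[[1]]$coords))
  structure(list(molecule_id = molecule_id, conformers = conformers,
                 heavy = heavy, engine = engine),
            class = "ph_ensemble")
}

#' @export
print.ph_ensemble <- function(x, ...) {
  cat(sprintf("<ph_ensemble %s> %d conformer(s), dE max %.2f kJ/mol [%s]\n",
              x$molecule_id, length(x$conformers),
              max(vapply(x$conformers, `[[`, 0, "rel_energy")), x$engine))
  invisible(x)
}

# Bondi van der Waals radii (Angstrom); fallback 1.7 for unlisted elements.
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
                S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92,
                Si = 2.10)

vdw_radius <- function(elem) {
  r <- .vdw_radii[elem]
  r[is.na(r)] <- 1.70
  unname(r)
}

bond_graph <- function(mol) {
  igraph::graph_from_data_frame(
    data.frame(from = mol$bonds$a1, to = mol$bonds$a2),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol$atoms))))
}

rotatable_bonds <- function(mol) {
  if (!nrow(mol$bonds)) return(mol$bonds[0, ])
  g <- bond_graph(mol)
  br <- igraph::bridges(g)
  bridge_pairs <- igraph::as_edgelist(g)[as.integer(br), , drop = FALSE]
  storage.mode(bridge_pairs) <- "integer"
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  is_bridge <- key(mol$bonds$a1, mol$bonds$a2) %in%
    key(bridge_pairs[, 1], bridge_pairs[, 2])
  heavy_deg <- tabulate(c(mol$bonds$a1[mol$atoms$elem[mol$bonds$a2] != "H"],
                          mol$bonds$a2[mol$atoms$elem[mol$bonds$a1] != "H"]),
                        nbins = nrow(mol$atoms))
  ok <- mol$bonds$order == 1L & is_bridge &
    heavy_deg[mol$bonds$a1] >= 2L & heavy_deg[mol$bonds$a2] >= 2L &
    mol$atoms$elem[mol$bonds$a1] != "H" & mol$atoms$elem[mol$bonds$a2] != "H"
  mol$bonds[ok, , drop = FALSE]
}

# atoms on the a2 side once bond a1-a2 is cut (a bridge)
moving_side <- function(g, a1, a2) {
  g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(a1, a2)))
  comp <- igraph::components(g2)$membership
  as.integer(names(comp)[comp == comp[as.character(a2)]])
}

rotate_coords <- function(coords, axis_from, axis_to, idx, angle) {
  u <- axis_to - axis_from
  u <- u / sqrt(sum(u^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  rot <- matrix(c(
    c_ + ux^2 * (1 - c_), ux * uy * (1 - c_) - uz * s_, ux * uz * (1 - c_) + uy * s_,
    uy * ux * (1 - c_) + uz * s_, c_ + uy^2 * (1 - c_), uy * uz * (1 - c_) - ux * s_,
    uz * ux * (1 - c_) - uy * s_, uz * uy * (1 - c_) + ux * s_, c_ + uz^2 * (1 - c_)),
    3, 3, byrow = TRUE)
  pts <- sweep(coords[idx, , drop = FALSE], 2, axis_from)
  coords[idx, ] <- sweep(pts %*% t(rot), 2, axis_from, `+`)
  coords
}

dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  bn <- sqrt(sum(b2^2))
  atan2(sum(m1 * n2) / bn, sum(n1 * n2))
}

# United-atom conformer strain: 12-6 steric term over heavy-atom pairs more
# than three bonds apart plus a 3-fold torsional barrier per rotatable bond.
conformer_energy <- function(coords, mol, gdist, rot, tors_ref,
                             eps = 0.4, barrier = 12) {
  heavy <- heavy_index(mol)
  e <- 0
  if (length(heavy) >= 2L) {
    far <- gdist[heavy, heavy, drop = FALSE] >= 3
    far[lower.tri(far, diag = TRUE)] <- FALSE
    idx <- which(far, arr.ind = TRUE)
    if (nrow(idx)) {
      i <- heavy[idx[, 1]]; j <- heavy[idx[, 2]]
      d <- sqrt(rowSums((coords[i, , drop = FALSE] -
                         coords[j, , drop = FALSE])^2))
      r0 <- 0.95 * (vdw_radius(mol$atoms$elem[i]) +
                    vdw_radius(mol$atoms$elem[j]))
      q <- (r0 / pmax(d, 0.3))^6
      e <- e + eps * sum(q^2 - 2 * q)
    }
  }
  if (nrow(rot)) {
    for (b in seq_len(nrow(rot))) {
      tr <- tors_ref[[b]]
      if (is.null(tr)) next
      phi <- dihedral(coords[tr[1], ], coords[tr[2], ], coords[tr[3], ],
                      coords[tr[4], ])
      e <- e + barrier / 2 * (1 + cos(3 * phi))
    }
  }
  e
}

#' Generate a conformer ensemble under the retention contract
#'
#' Samples torsion space of the molecule's rotatable bonds (full 60-degree
#' grid when small enough, seeded random torsions otherwise), scores each
#' geometry with a united-atom steric + 3-fold torsional strain energy, and
#' retains conformers through [prune_ensemble()]: within the energy window
#' (default 21 kJ/mol) and mutually non-redundant at the heavy-atom RMSD
#' cutoff (default 0.5 Angstrom). Rigid molecules yield exactly one
#' conformer. Deterministic for a fixed seed.
#'
#' @param mol A [phmol] with 3D coordinates.
#' @param max_confs Maximum conformers retained (default 200).
#' @param energy_window Retention window in kJ/mol (default 21).
#' @param rmsd_cutoff Redundancy cutoff in Angstrom (default 0.5).
#' @param seed Integer seed.
#' @return A [ph_ensemble].
#' @export
generate_ensemble <- function(mol, max_confs = 200L, energy_window = 21,
                              rmsd_cutoff = 0.5, seed = 42L) {
  if (nrow(mol$atoms) < 1L) stop("molecule '", mol$id, "' has no atoms")
  if (anyNA(mol$atoms[, c("x", "y", "z")])) {
    stop("molecule '", mol$id, "' lacks 3D coordinates")
  }
  if (max_confs < 1L) stop("max_confs must be >= 1")
  coords0 <- as.matrix(mol$atoms[, c("x", "y", "z")])
  storage.mode(coords0) <- "double"
  rot <- rotatable_bonds(mol)
  heavy <- heavy_index(mol)
  if (nrow(rot) == 0L) {
    return(ph_ensemble(mol$id,
                       list(list(coords = coords0, rel_energy = 0)),
                       heavy = heavy))
  }
  g <- bond_graph(mol)
  gdist <- igraph::distances(g)
  gdist <- gdist[order(as.integer(rownames(gdist))),
                 order(as.integer(colnames(gdist)))]
  movers <- lapply(seq_len(nrow(rot)),
                   function(b) moving_side(g, rot$a1[b], rot$a2[b]))
  nbrs <- function(a, excl) {
    nb <- c(mol$bonds$a2[mol$bonds$a1 == a], mol$bonds$a1[mol$bonds$a2 == a])
    nb <- setdiff(nb[mol$atoms$elem[nb] != "H"], excl)
    if (length(nb)) min(nb) else NA_integer_
  }
  tors_ref <- lapply(seq_len(nrow(rot)), function(b) {
    a1 <- rot$a1[b]; a2 <- rot$a2[b]
    p0 <- nbrs(a1, a2); p3 <- nbrs(a2, a1)
    if (is.na(p0) || is.na(p3)) NULL else c(p0, a1, a2, p3)
  })
  k <- nrow(rot)
  angle_sets <- withr::with_seed(as.integer(seed), {
    if (6^k <= max(729L, 4L * max_confs)) {
      as.matrix(do.call(expand.grid,
                        rep(list(seq(0, 300, by = 60) * pi / 180), k)))
    } else {
      rbind(matrix(0, 1, k),
            matrix(stats::runif(4L * max_confs * k, 0, 2 * pi),
                   ncol = k))
    }
  })
  confs <- vector("list", nrow(angle_sets))
  for (s in seq_len(nrow(angle_sets))) {
    cc <- coords0
    for (b in seq_len(k)) {
      ang <- angle_sets[s, b]
      if (abs(ang) < 1e-12) next
      cc <- rotate_coords(cc, cc[rot$a1[b], ], cc[rot$a2[b], ],
                          movers[[b]], ang)
    }
    confs[[s]] <- list(coords = cc,
                       rel_energy = conformer_energy(cc, mol, gdist, rot,
                                                     tors_ref))
  }
  e <- vapply(confs, `[[`, 0, "rel_energy")
  confs <- lapply(confs[order(e)], function(cf) {
    cf$rel_energy <- cf$rel_energy - min(e); cf
  })
  ens <- ph_ensemble(mol$id, confs[seq_len(min(length(confs), 10000L))],
                     heavy = heavy)
  ens <- prune_ensemble(ens, energy_window, rmsd_cutoff)
  if (length(ens$conformers) > max_confs) {
    ens$conformers <- ens$conformers[seq_len(max_confs)]
  }
  if (length(ens$conformers) == 0L) {
    stop("no conformers survive retention for molecule '", mol$id, "'")
  }
  ens
}

#' Apply the retention contract to an existing ensemble
#'
#' Greedy retention in ascending-energy order: a conformer is kept iff its
#' relative energy is within `energy_window` of the ensemble minimum and its
#' superposed heavy-atom RMSD to every previously kept conformer is at least
#' `rmsd_cutoff`. Idempotent.
#'
#' @param ensemble A [ph_ensemble] (possibly violating the window/redundancy
#'   invariants).
#' @param energy_window kJ/mol (default 21).
#' @param rmsd_cutoff Angstrom (default 0.5).
#' @return A [ph_ensemble] satisfying all invariants.
#' @export
prune_ensemble <- function(ensemble, energy_window = 21, rmsd_cutoff = 0.5) {
  confs <- ensemble$conformers
  if (!length(confs)) return(ensemble)
  e <- vapply(confs, `[[`, 0, "rel_energy")
  confs <- confs[order(e)]
  e <- sort(e) - min(e)
  heavy <- ensemble$heavy
  kept <- list()
  for (i in seq_along(confs)) {
    if (e[i] > energy_window) next
    ci <- confs[[i]]$coords[heavy, , drop = FALSE]
    redundant <- FALSE
    for (kc in kept) {
      if (heavy_atom_rmsd(ci, kc$coords[heavy, , drop = FALSE]) <
          rmsd_cutoff) { redundant <- TRUE; break }
    }
    if (!redundant) {
      cf <- confs[[i]]
      cf$rel_energy <- e[i]
      kept[[length(kept) + 1L]] <- cf
    }
  }
  ph_ensemble(ensemble$molecule_id, kept, heavy = heavy,
              engine = ensemble$engine)
}
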