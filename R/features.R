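#' Feature perception rule table
#'
#' The pharmacophore feature alphabet is A (hydrogen-bond acceptor),
#' D (donor), H (hydrophobic group), N (negative ionizable), P (positive
#' ionizable) and R (aromatic ring). The rules deciding which atoms carry
#' which feature are shipped as an editable CSV
#' (`system.file("extdata", "feature_rules.csv", package = "phore3d")`);
#' disabling a row turns the corresponding rule off.
#'
#' @param path Optional path to an alternative rule table.
#' @return Data frame of rules.
#' @export
feature_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "feature_rules.csv", package = "phore3d")
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

empty_sites <- function() {
  data.frame(kind = character(), x = numeric(), y = numeric(), z = numeric(),
             dx = numeric(), dy = numeric(), dz = numeric(),
             atoms = character())
}

site_row <- function(kind, pos, dir = c(NA_real_, NA_real_, NA_real_),
                     atoms = integer()) {
  data.frame(kind = kind, x = pos[1], y = pos[2], z = pos[3],
             dx = dir[1], dy = dir[2], dz = dir[3],
             atoms = paste(atoms, collapse = ","))
}

neighbors_of <- function(mol, a) {
  c(mol$bonds$a2[mol$bonds$a1 == a], mol$bonds$a1[mol$bonds$a2 == a])
}

bond_orders_of <- function(mol, a) {
  c(mol$bonds$order[mol$bonds$a1 == a], mol$bonds$order[mol$bonds$a2 == a])
}

# Small-ring perception: for every bond, the shortest cycle through it
# (BFS on the graph with that bond removed); unique rings of size 5-6.
small_rings <- function(mol, max_size = 6L) {
  if (nrow(mol$bonds) < 3L) return(list())
  g <- bond_graph(mol)
  rings <- list()
  seen <- character()
  for (b in seq_len(nrow(mol$bonds))) {
    a1 <- mol$bonds$a1[b]; a2 <- mol$bonds$a2[b]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(a1, a2)))
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = as.character(a1),
                             to = as.character(a2))$vpath[[1]])
    if (length(sp) < 3L || length(sp) > max_size) next
    ring <- sort(as.integer(names(sp)))
    key <- paste(ring, collapse = "-")
    if (key %in% seen) next
    seen <- c(seen, key)
    rings[[length(rings) + 1L]] <- as.integer(names(sp))  # in cycle order
  }
  rings
}

ring_is_aromatic <- function(mol, ring) {
  n <- length(ring)
  if (n < 5L || n > 6L) return(FALSE)
  if (!all(mol$atoms$elem[ring] %in% c("C", "N", "O", "S"))) return(FALSE)
  pairs <- cbind(ring, ring[c(2:n, 1)])
  orders <- apply(pairs, 1, function(p) {
    hit <- (mol$bonds$a1 == p[1] & mol$bonds$a2 == p[2]) |
           (mol$bonds$a1 == p[2] & mol$bonds$a2 == p[1])
    if (!any(hit)) return(NA_integer_)
    mol$bonds$order[which(hit)[1]]
  })
  if (anyNA(orders)) return(FALSE)
  if (all(orders == 4L)) return(TRUE)
  ndouble <- sum(orders == 2L)
  if (n == 6L) return(ndouble == 3L)
  # 5-ring: Kekule aromatic needs two double bonds and one lone-pair donor
  ndouble == 2L && any(mol$atoms$elem[ring] %in% c("N", "O", "S"))
}

aromatic_atoms <- function(mol, rings = NULL) {
  if (is.null(rings)) rings <- small_rings(mol)
  arom <- rep(FALSE, nrow(mol$atoms))
  for (r in rings) if (ring_is_aromatic(mol, r)) arom[r] <- TRUE
  # explicit aromatic bond orders outside perceived rings
  ab <- mol$bonds$order == 4L
  arom[unique(c(mol$bonds$a1[ab], mol$bonds$a2[ab]))] <- TRUE
  arom
}

is_amide_n <- function(mol, a) {
  for (nb in neighbors_of(mol, a)) {
    if (mol$atoms$elem[nb] != "C") next
    for (nb2 in neighbors_of(mol, nb)) {
      hit <- (mol$bonds$a1 == nb & mol$bonds$a2 == nb2) |
             (mol$bonds$a1 == nb2 & mol$bonds$a2 == nb)
      if (mol$atoms$elem[nb2] == "O" && any(mol$bonds$order[hit] == 2L)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

lone_pair_direction <- function(mol, coords, a) {
  nb <- neighbors_of(mol, a)
  if (!length(nb)) return(c(NA_real_, NA_real_, NA_real_))
  v <- coords[a, ] - colMeans(coords[nb, , drop = FALSE])
  nv <- sqrt(sum(v^2))
  if (nv < 1e-8) return(c(NA_real_, NA_real_, NA_real_))
  v / nv
}

#' Perceive pharmacophore feature sites
#'
#' Applies the shipped rule table (see [feature_rules()]) to one conformer of
#' a molecule and returns its feature sites: acceptors and donors on the
#' bearing heavy atom (acceptors with a lone-pair direction), positive and
#' negative ionizable centers, hydrophobic group centroids, and aromatic
#' ring centroids with ring normals. Deterministic. Synthetic benchmark
#' molecules carry planted sites, which are returned as-is.
#'
#' @param mol A [phmol] with formal charges assigned.
#' @param coords Optional n_atoms x 3 conformer coordinates (defaults to the
#'   molecule's own).
#' @param rules Rule table from [feature_rules()].
#' @return Data frame of sites: `kind`, `x`, `y`, `z`, direction `dx`, `dy`,
#'   `dz` (`NA` when undefined), and contributing `atoms`.
#' @export
perceive_features <- function(mol, coords = NULL, rules = feature_rules()) {
  if (!is.null(mol$sites)) {
    if (is.null(coords)) return(mol$sites)
    # planted sites move rigidly with the (rigid) synthetic molecule
    tr <- superpose(heavy_coords(mol), coords[heavy_index(mol), , drop = FALSE])
    s <- mol$sites
    s[, c("x", "y", "z")] <- tr$transform(as.matrix(s[, c("x", "y", "z")]))
    return(s)
  }
  if (is.null(coords)) coords <- as.matrix(mol$atoms[, c("x", "y", "z")])
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (anyNA(coords)) stop("molecule '", mol$id, "' lacks 3D coordinates")
  on <- function(id) any(rules$rule_id == id & rules$enabled)
  atoms <- mol$atoms
  rings <- small_rings(mol)
  arom <- aromatic_atoms(mol, rings)
  out <- list()
  add <- function(row) out[[length(out) + 1L]] <<- row

  for (a in seq_len(nrow(atoms))) {
    el <- atoms$elem[a]; chg <- atoms$charge[a]; nh <- atoms$nh[a]
    # acceptors
    if (on("acceptor_oxygen") && el == "O" && chg <= 0) {
      add(site_row("A", coords[a, ], lone_pair_direction(mol, coords, a), a))
    }
    if (on("acceptor_nitrogen") && el == "N" && chg <= 0 &&
        !(arom[a] && nh > 0) && !is_amide_n(mol, a) &&
        (length(neighbors_of(mol, a)) + nh) <= 3L) {
      add(site_row("A", coords[a, ], lone_pair_direction(mol, coords, a), a))
    }
    # donors
    if (on("donor_heavy") && el %in% c("N", "O", "S") && nh >= 1L) {
      add(site_row("D", coords[a, ], atoms = a))
    }
    # positive ionizable
    pos_chg <- on("positive_charged") && chg > 0
    pos_amine <- on("positive_basic_amine") && el == "N" && chg == 0 &&
      all(bond_orders_of(mol, a) == 1L) && !arom[a] && !is_amide_n(mol, a) &&
      !any(arom[neighbors_of(mol, a)])
    if (pos_chg || pos_amine) add(site_row("P", coords[a, ], atoms = a))
    # negative ionizable (charged)
    if (on("negative_charged") && chg < 0) {
      add(site_row("N", coords[a, ], atoms = a))
    }
    # neutral carboxylic acid
    if (on("negative_carboxyl") && el == "C") {
      nb <- neighbors_of(mol, a)
      os <- nb[atoms$elem[nb] == "O"]
      if (length(os) == 2L) {
        ords <- vapply(os, function(o) {
          hit <- (mol$bonds$a1 == a & mol$bonds$a2 == o) |
                 (mol$bonds$a1 == o & mol$bonds$a2 == a)
          mol$bonds$order[which(hit)[1]]
        }, 0L)
        if (any(ords == 2L) && any(ords == 1L & atoms$nh[os] >= 1L)) {
          add(site_row("N", colMeans(coords[os, , drop = FALSE]),
                       atoms = os))
        }
      }
    }
  }

  # hydrophobic groups: connected components of qualifying atoms
  if (on("hydrophobic_group")) {
    polar <- c("N", "O", "F")
    qual <- vapply(seq_len(nrow(atoms)), function(a) {
      el <- atoms$elem[a]
      if (el %in% c("Cl", "Br", "I")) return(TRUE)
      if (el != "C" || arom[a]) return(FALSE)
      !any(atoms$elem[neighbors_of(mol, a)] %in% polar)
    }, TRUE)
    if (any(qual)) {
      qi <- which(qual)
      keep <- mol$bonds$a1 %in% qi & mol$bonds$a2 %in% qi
      gg <- igraph::graph_from_data_frame(
        data.frame(from = mol$bonds$a1[keep], to = mol$bonds$a2[keep]),
        directed = FALSE, vertices = data.frame(name = qi))
      comp <- igraph::components(gg)$membership
      for (grp in split(as.integer(names(comp)), comp)) {
        add(site_row("H", colMeans(coords[grp, , drop = FALSE]),
                     atoms = grp))
      }
    }
  }

  # aromatic rings: centroid + normal
  if (on("aromatic_ring")) {
    for (r in rings) {
      if (!ring_is_aromatic(mol, r)) next
      pts <- coords[r, , drop = FALSE]
      ctr <- colMeans(pts)
      sv <- svd(sweep(pts, 2, ctr))
      nrm <- sv$v[, 3]
      add(site_row("R", ctr, nrm / sqrt(sum(nrm^2)), r))
    }
  }

  if (!length(out)) return(empty_sites())
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[order(df$kind, df$x, df$y, df$z), , drop = FALSE]
}

site_coords <- function(sites) {
  m <- as.matrix(sites[, c("x", "y", "z")])
  storage.mode(m) <- "double"
  m
}

site_dirs <- function(sites) {
  m <- as.matrix(sites[, c("dx", "dy", "dz")])
  storage.mode(m) <- "double"
  m
}
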