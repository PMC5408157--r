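#' Read molecules and affinities from SDF or SMILES CSV
#'
#' SDF (V2000/V3000) files are parsed with ChemmineR; binding affinities are
#' taken from the nanomolar property field (default `Ki_nM`) and converted to
#' molar internally. CSV input needs columns `id` and `smiles`, plus optional
#' `ki_nM` and `set`. Rows/records with an unparsable affinity keep the
#' structure but drop the affinity; rows with no usable structure are skipped
#' with a warning and counted in the `n_skipped` attribute.
#'
#' @param path Input file.
#' @param format `"sdf"` or `"smiles_csv"`.
#' @param ki_field SDF property (or CSV column) holding the affinity in
#'   nanomolar. Default `"Ki_nM"` (`"ki_nM"` also recognized in CSV).
#' @return List of [phmol] records, attribute `n_skipped`.
#' @export
read_molecules <- function(path, format = c("sdf", "smiles_csv"),
                           ki_field = "Ki_nM") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  recs <- switch(format,
                 sdf = read_molecules_sdf(path, ki_field),
                 smiles_csv = read_molecules_csv(path, ki_field))
  if (length(recs) == 0L) stop("no valid molecules in '", path, "'")
  ids <- vapply(recs, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate molecule ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  recs
}

# old V2000 atom-line charge codes
.chg_code <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)

read_molecules_sdf <- function(path, ki_field) {
  sdfset <- ChemmineR::read.SDFset(path)
  ok <- ChemmineR::validSDF(sdfset)
  n_skipped <- sum(!ok)
  if (n_skipped) warning(n_skipped, " invalid SDF record(s) skipped")
  sdfset <- sdfset[ok]
  # ChemmineR keeps only the atom-line charge column; fold in M CHG blocks,
  # which modern writers use instead (they reset atom-line codes to 0).
  chg_blocks <- read_mchg_blocks(path)[ok]
  recs <- vector("list", length(sdfset))
  for (i in seq_along(sdfset)) {
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    elem <- sub("_.*$", "", rownames(ab))
    charge <- rep(0L, nrow(ab))
    if (ncol(ab) >= 5) {
      code <- as.character(ab[, 5])
      charge <- ifelse(code %in% names(.chg_code), .chg_code[code], 0L)
    }
    mchg <- chg_blocks[[i]]
    if (length(mchg)) charge[as.integer(names(mchg))] <- mchg
    atoms <- data.frame(elem = elem, x = ab[, 1], y = ab[, 2], z = ab[, 3],
                        charge = as.integer(charge))
    bb <- ChemmineR::bondblock(sdf)
    bonds <- if (NROW(bb)) {
      data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    } else NULL
    db <- ChemmineR::datablock(sdf)
    nm <- ChemmineR::header(sdf)[["Molecule_Name"]]
    id <- if (!is.null(db) && "id" %in% names(db)) db[["id"]]
          else if (!is.na(nm) && nzchar(trimws(nm))) trimws(nm)
          else sprintf("mol_%03d", i)
    ki <- parse_ki_nM(if (ki_field %in% names(db)) db[[ki_field]] else NA)
    set_label <- if ("set" %in% names(db)) db[["set"]] else "unlabeled"
    ac <- if ("atom_class" %in% names(db)) {
      strsplit(db[["atom_class"]], " ")[[1]]
    } else NULL
    sites <- if ("sites" %in% names(db)) {
      s <- as.data.frame(jsonlite::fromJSON(db[["sites"]]))
      for (cc in c("dx", "dy", "dz")) {
        if (is.null(s[[cc]])) s[[cc]] <- NA_real_
        s[[cc]] <- as.numeric(s[[cc]])
      }
      s
    } else NULL
    recs[[i]] <- phmol(id, atoms, bonds, ki = ki, name = id,
                       set_label = set_label,
                       source_ref = paste0("sdf:", basename(path)),
                       atom_class = ac, sites = sites)
  }
  structure(recs, n_skipped = n_skipped)
}

read_mchg_blocks <- function(path) {
  txt <- readLines(path, warn = FALSE)
  ends <- grep("^\\${4}", txt)
  if (!length(ends)) ends <- length(txt)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(starts), function(i) {
    lines <- grep("^M  CHG", txt[starts[i]:ends[i]], value = TRUE)
    out <- integer()
    for (ln in lines) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      k <- f[1]
      idx <- f[seq(2, by = 2, length.out = k)]
      val <- f[seq(3, by = 2, length.out = k)]
      out[as.character(idx)] <- val
    }
    out
  })
}

parse_ki_nM <- function(x) {
  if (length(x) != 1L || is.na(x)) return(NA_real_)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v) || v <= 0) return(NA_real_)
  v * 1e-9
}

read_molecules_csv <- function(path, ki_field) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "smiles")
  if (!all(need %in% names(df))) {
    stop("smiles_csv needs columns id, smiles; found: ",
         paste(names(df), collapse = ", "))
  }
  kcol <- intersect(c(ki_field, "ki_nM", "Ki_nM"), names(df))[1]
  n_skipped <- 0L
  recs <- list()
  for (i in seq_len(nrow(df))) {
    smi <- df$smiles[i]
    if (is.na(smi) || !nzchar(smi)) {
      warning("row ", i, ": empty SMILES, skipped"); n_skipped <- n_skipped + 1L
      next
    }
    ki <- NA_real_
    if (!is.na(kcol)) {
      raw <- df[[kcol]][i]
      ki <- parse_ki_nM(raw)
      if (is.na(ki) && !is.na(raw) && nzchar(trimws(as.character(raw)))) {
        warning("row ", i, " (", df$id[i], "): unparsable affinity '", raw,
                "', record skipped")
        n_skipped <- n_skipped + 1L
        next
      }
    }
    mol <- tryCatch(mol_from_smiles(df$id[i], smi), error = function(e) {
      warning("row ", i, " (", df$id[i], "): ", conditionMessage(e),
              ", skipped")
      NULL
    })
    if (is.null(mol)) { n_skipped <- n_skipped + 1L; next }
    mol$ki <- ki
    mol$pki <- if (is.na(ki)) NA_real_ else ki_to_pki(ki)
    mol$activity_class <- if (is.na(ki)) "unknown" else classify_activity(ki)
    if ("set" %in% names(df) && !is.na(df$set[i]) && nzchar(df$set[i])) {
      mol$set_label <- df$set[i]
    }
    mol$source_ref <- paste0("csv:", basename(path), ":", i)
    recs[[length(recs) + 1L]] <- mol
  }
  structure(recs, n_skipped = n_skipped)
}

#' Build a molecule (with 3D coordinates) from a SMILES string
#'
#' Conversion and 3D embedding are delegated to Open Babel via ChemmineOB.
#' @param id Identifier for the new record.
#' @param smiles SMILES string.
#' @return A [phmol] with 3D coordinates.
#' @export
mol_from_smiles <- function(id, smiles) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("SMILES input requires the ChemmineOB package")
  }
  sdfstr <- ChemmineOB::convertFormat(
    "SMI", "SDF", paste0(smiles, " ", id),
    options = data.frame(names = "gen3D", args = ""))
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdfstr, tf)
  recs <- read_molecules_sdf(tf, "Ki_nM")
  if (!length(recs)) stop("could not build 3D structure for '", smiles, "'")
  mol <- recs[[1]]
  mol$id <- id
  mol$name <- id
  mol$smiles <- smiles
  mol
}

#' Reproducible train/test split
#'
#' Randomly partitions records into a training and a test set (the workflow
#' default mirrors a 60/40 split). Deterministic for a fixed seed; the
#' concatenated output is always a permutation of the input.
#'
#' @param records List of [phmol].
#' @param train_fraction Proportion in (0, 1); `round(train_fraction * n)`
#'   records go to the training set.
#' @param seed Integer seed recorded with the split.
#' @param stratify If `TRUE`, the split is drawn within each activity class.
#' @return List with elements `train` and `test` (set labels updated), and
#'   attribute `seed`.
#' @export
split_train_test <- function(records, train_fraction = 0.6, seed = 42L,
                             stratify = FALSE) {
  n <- length(records)
  if (n < 2L) stop("need at least 2 records to split")
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must be in (0, 1)")
  }
  idx <- withr::with_seed(as.integer(seed), {
    if (stratify) {
      cls <- vapply(records, `[[`, "", "activity_class")
      unlist(lapply(split(seq_len(n), cls), function(g) {
        sample(g, round(train_fraction * length(g)))
      }), use.names = FALSE)
    } else {
      sample(seq_len(n), round(train_fraction * n))
    }
  })
  train <- records[sort(idx)]
  test <- records[setdiff(seq_len(n), idx)]
  train <- lapply(train, function(m) { m$set_label <- "train"; m })
  test <- lapply(test, function(m) { m$set_label <- "test"; m })
  structure(list(train = train, test = test), seed = as.integer(seed))
}

#' Write screening/prediction rows to CSV
#'
#' @param rows Data frame (or list of lists) with columns `id`, `pred_pKi`,
#'   `matched_sites`, `align_rmsd`.
#' @param path Output file.
#' @return `path`, invisibly. Numbers are written at 4 decimals, row order
#'   preserved.
#' @export
write_predictions <- function(rows, path) {
  if (is.list(rows) && !is.data.frame(rows)) {
    rows <- do.call(rbind, lapply(rows, function(r) {
      as.data.frame(stats::setNames(as.list(r),
        c("id", "pred_pKi", "matched_sites", "align_rmsd")))
    }))
  }
  if (NROW(rows) == 0L) stop("write_predictions: no rows")
  out <- data.frame(id = rows$id,
                    pred_pKi = sprintf("%.4f", rows$pred_pKi),
                    matched_sites = rows$matched_sites,
                    align_rmsd = sprintf("%.4f", rows$align_rmsd))
  tryCatch(utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop("cannot write '", path, "': ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Write molecules to an SDF file
#'
#' Serializes records (including synthetic point-set molecules, which have
#' no bonds) through ChemmineR, attaching `Ki_nM` and `set` property fields
#' so that [read_molecules()] round-trips.
#'
#' @param mols List of [phmol].
#' @param path Output file.
#' @param extra_props Optional named list of per-molecule property vectors.
#' @return `path`, invisibly.
#' @export
write_molecules_sdf <- function(mols, path, extra_props = NULL) {
  stopifnot(length(mols) > 0L)
  sdfs <- lapply(seq_along(mols), function(i) {
    mol <- mols[[i]]
    ab <- as.matrix(mol$atoms[, c("x", "y", "z")])
    code <- c(`3` = 1L, `2` = 2L, `1` = 3L, `-1` = 5L, `-2` = 6L,
              `-3` = 7L)[as.character(mol$atoms$charge)]
    code[is.na(code)] <- 0L
    ab <- cbind(ab, 0, code)
    rownames(ab) <- paste(mol$atoms$elem, seq_len(nrow(ab)), sep = "_")
    colnames(ab) <- c("C1", "C2", "C3", "C5", "C6")
    bb <- if (nrow(mol$bonds)) {
      m <- cbind(mol$bonds$a1, mol$bonds$a2, mol$bonds$order, 0)
      colnames(m) <- c("C1", "C2", "C3", "C4")
      m
    } else matrix(0, 0, 4, dimnames = list(NULL, c("C1", "C2", "C3", "C4")))
    db <- c(id = mol$id, set = mol$set_label)
    if (!is.na(mol$ki)) db <- c(db, Ki_nM = format(mol$ki * 1e9, digits = 10))
    if (!is.null(mol$atom_class)) {
      db <- c(db, atom_class = paste(mol$atom_class, collapse = " "))
    }
    if (!is.null(mol$sites)) {
      db <- c(db, sites = as.character(jsonlite::toJSON(mol$sites,
                                                        digits = NA)))
    }
    if (!is.null(extra_props)) {
      db <- c(db, vapply(extra_props, function(p) as.character(p[[i]]), ""))
    }
    methods::new(methods::getClass("SDF", where = asNamespace("ChemmineR")),
                 header = c(Molecule_Name = mol$id, Source = "phore3d",
                            Comment = "",
                            Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                                  nrow(ab), nrow(bb))),
                 atomblock = ab, bondblock = bb, datablock = db)
  })
  # container ids must be unique for serialization; the true (possibly
  # duplicated) ids live in the datablock and header
  sdfset <- methods::new(
    methods::getClass("SDFset", where = asNamespace("ChemmineR")),
    SDF = sdfs, ID = make.unique(vapply(mols, `[[`, "", "id")))
  ChemmineR::write.SDF(sdfset, path, cid = TRUE)
  invisible(path)
}
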