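#' Default pipeline configuration
#'
#' Every tunable of the end-to-end workflow with its default: conformer
#' retention window 21 kJ/mol and 0.5 Angstrom redundancy cutoff, grid
#' spacing 0.5 Angstrom, at most 7 PLS factors, 60/40 train/test split,
#' potent class at Ki <= 50 nM, screening hit list of ~1% of the database,
#' per-site tolerance 2 Angstrom with 4-of-5 minimum matching for
#' screening and full matching for hypothesis construction. The config is
#' serialized (with its hash) into every pipeline output for provenance.
#'
#' @param ... Overrides for any field.
#' @return Named list of settings.
#' @export
default_config <- function(...) {
  cfg <- list(
    actives_sdf = NULL, decoys_sdf = NULL, activities_csv = NULL,
    workdir = NULL,
    seed = 42L,
    train_fraction = 0.6,
    energy_window = 21, rmsd_cutoff = 0.5, max_confs = 200L,
    n_features = 5L, must_match = 0.9, bin_size = 1.0,
    site_tolerance = 2.0, min_sites_screen = 4L,
    grid_spacing = 0.5, grid_margin = 2.0, min_occupancy = 2L,
    max_factors = 7L, cv_folds = 10L,
    hit_fraction = 0.01, cutoff = NULL,
    potent_ki = 5e-8,
    engine = "phore3d-torsion-scan")
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                              digits = NA, null = "null"), tf)
  unname(tools::md5sum(tf))
}

files_hash <- function(paths) {
  paths <- paths[!vapply(paths, is.null, TRUE)]
  paths <- unlist(paths)
  paths <- paths[file.exists(paths)]
  paste(unname(tools::md5sum(sort(paths))), collapse = "")
}

#' Serialize a fitted PLS model (with grid) to JSON
#' @param model A `ph_pls` fitted on a `ph_featmat`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(
    list(schema = "phore3d-model-1", n_factors = model$n_factors,
         intercepts = model$intercepts, coefs = model$coefs,
         col_ids = model$col_ids,
         grid = list(origin = model$grid$origin,
                     spacing = model$grid$spacing, dims = model$grid$dims,
                     classes = model$grid$classes),
         y_train = model$y, row_ids = model$row_ids),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model written by [write_model()]
#' @param path Model JSON file.
#' @return A `ph_pls`-compatible model usable by [predict_pls()] and
#'   [rank_database()].
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- structure(list(origin = j$grid$origin, spacing = j$grid$spacing,
                         dims = as.integer(j$grid$dims),
                         classes = j$grid$classes),
                    class = "ph_grid")
  coefs <- if (is.matrix(j$coefs)) {
    # a list of equal-length vectors simplifies to a row-per-factor matrix
    lapply(seq_len(nrow(j$coefs)), function(i) as.numeric(j$coefs[i, ]))
  } else if (is.list(j$coefs)) {
    lapply(j$coefs, as.numeric)
  } else list(as.numeric(j$coefs))
  structure(list(n_factors = j$n_factors,
                 coefs = coefs,
                 intercepts = as.numeric(j$intercepts),
                 col_ids = as.integer(j$col_ids), grid = grid,
                 y = as.numeric(j$y_train), row_ids = j$row_ids),
            class = "ph_pls")
}

align_and_encode <- function(mols, hyp, grid = NULL, min_sites = 4L,
                             spacing = 0.5, margin = 2.0) {
  entries <- ligand_entries(mols)
  matches <- lapply(entries, match_ligand, hyp = hyp,
                    min_sites = min_sites)
  ok <- !vapply(matches, is.null, TRUE)
  aligned <- vector("list", length(mols))
  for (i in which(ok)) {
    aligned[[i]] <- align_ligand(hyp, matches[[i]], entries[[i]])
  }
  if (is.null(grid)) {
    coords <- lapply(which(ok), function(i) {
      aligned[[i]]$coords_aligned[entries[[i]]$heavy, , drop = FALSE]
    })
    grid <- build_grid(coords, spacing = spacing, margin = margin)
  }
  rows <- vector("list", length(mols))
  for (i in which(ok)) {
    cl <- assign_atom_classes(mols[[i]])
    rows[[i]] <- encode_ligand(
      aligned[[i]]$coords_aligned[entries[[i]]$heavy, , drop = FALSE],
      cl, grid)
  }
  list(matched = ok, matches = matches, aligned = aligned, rows = rows,
       grid = grid, entries = entries)
}

#' Run the synthetic benchmark end-to-end
#'
#' Generates a benchmark bundle, searches for the common pharmacophore on
#' the potent training actives, aligns and encodes the training set, fits
#' PLS models up to `max_factors`, cross-validates, predicts the held-out
#' test actives, and screens a fresh set of unseen actives against the
#' decoys. The hypothesis search bin is calibrated to the generator: with
#' one rigid conformer per molecule, inter-site distances jitter with
#' standard deviation `sqrt(2) * site_jitter_sigma`, so boxes of edge
#' `6 * sqrt(2) * sigma` (2.5 Angstrom at the default sigma = 0.3) are
#' needed for most molecules to co-locate on all ten distance axes.
#'
#' @param spec A [synthetic_spec()].
#' @param max_factors PLS factors (default 7).
#' @param cv_folds Cross-validation folds (default 10).
#' @param n_screen_actives Unseen actives in the screening set
#'   (default 100).
#' @param must_match Hypothesis coverage fraction (default 0.4; the planted
#'   box holds most molecules but adaptive box placement can shave a
#'   boundary tail).
#' @param quiet Suppress progress messages.
#' @return List: `bundle`, `hypothesis`, `model`, `stats_table` (per-factor
#'   r2/SD/F/P/RMSE/Q2/Pearson panel), `cv`, `test_stats`, `screen`,
#'   `enrichment`, `bin_size`.
#' @export
benchmark_pipeline <- function(spec = synthetic_spec(), max_factors = 7L,
                               cv_folds = 10L, n_screen_actives = 100L,
                               must_match = 0.4, quiet = TRUE) {
  say <- function(...) if (!quiet) message(...)
  say("generating benchmark bundle (seed ", spec$seed, ")")
  bundle <- make_benchmark(spec)
  train <- bundle$train; test <- bundle$test
  pki_tr <- vapply(train, `[[`, 0, "pki")
  potent <- train[vapply(train, `[[`, "", "activity_class") == "potent"]
  if (length(potent) < 10L) {
    potent <- train[order(-pki_tr)][seq_len(min(20L, length(train)))]
  }
  bin <- max(1.0, 6 * sqrt(2) * spec$site_jitter_sigma)
  say("hypothesis search on ", length(potent), " potent actives, bin ",
      round(bin, 2), " A")
  hyps <- find_common_hypotheses(ligand_entries(potent), n_features = 5L,
                                 must_match = must_match, bin_size = bin,
                                 tol = 2.0)
  if (!length(hyps)) stop("no common hypothesis found")
  hyp <- hyps[[1]]
  say("top hypothesis ", hyp$id, " score ", round(hyp$score, 3))
  enc <- align_and_encode(train, hyp, min_sites = 4L)
  if (!all(enc$matched)) {
    say(sum(!enc$matched), " training actives failed to match; dropped")
  }
  keep <- which(enc$matched)
  fm <- assemble_matrix(enc$rows[keep],
                        vapply(train[keep], `[[`, "", "id"), enc$grid,
                        min_occupancy = 2L)
  y <- pki_tr[keep]
  maxf <- min(max_factors, length(keep) - 1L)
  model <- fit_pls(fm, y, n_factors = maxf)
  cv <- cross_validate(fm, y, n_factors = model$n_factors,
                       folds = cv_folds, seed = spec$seed)
  # held-out test actives, encoded on the training grid
  enc_te <- align_and_encode(test, hyp, grid = enc$grid, min_sites = 4L)
  kt <- which(enc_te$matched)
  test_pred <- rep(min(y), length(test))
  test_pred[kt] <- predict_pls(model, enc_te$rows[kt])
  y_te <- vapply(test, `[[`, 0, "pki")
  test_stats <- regression_stats(y_te, test_pred, model$n_factors)
  stats_table <- do.call(rbind, lapply(seq_len(model$n_factors),
                                       function(a) {
    s <- regression_stats(y, model$fitted[, a], a)
    data.frame(factors = a, r2 = s$r2, sd = s$sd, f = s$f, p = s$p,
               rmse = s$rmse,
               q2 = if (a <= length(cv$q2)) cv$q2[a] else NA_real_,
               pearson_r = stats::cor(y_te, {
                 tp <- rep(min(y), length(test))
                 tp[kt] <- predict_pls(model, enc_te$rows[kt],
                                       n_factors = a)
                 tp
               }))
  }))
  say("screening ", n_screen_actives, " unseen actives vs ",
      length(bundle$decoys), " decoys")
  spec_scr <- synthetic_spec(
    seed = spec$seed + 7L, n_actives = n_screen_actives,
    n_decoys = spec$n_decoys,
    site_jitter_sigma = spec$site_jitter_sigma,
    n_distractor_sites = spec$n_distractor_sites,
    activity_intercept = spec$activity_intercept,
    activity_coefficients = spec$activity_coefficients,
    noise_sigma = spec$noise_sigma, ki_range = spec$ki_range)
  scr_actives <- generate_actives(spec_scr, bundle$hypothesis,
                                  anchors = bundle$anchors)
  db <- c(scr_actives, bundle$decoys)
  # validation screen requires the complete pharmacophore: inactives are
  # expected to fail to fulfil all features, which is what separates them
  screen <- rank_database(model, hyp, db,
                          min_sites = nrow(hyp$sites),
                          active_ids = vapply(scr_actives, `[[`, "", "id"))
  enr <- enrichment_report(screen)
  list(bundle = bundle, hypothesis = hyp, model = model,
       stats_table = stats_table, cv = cv, test_stats = test_stats,
       screen = screen, enrichment = enr, bin_size = bin,
       feature_matrix_dim = dim(fm$X))
}

read_stage <- function(manifest, stage) {
  for (st in manifest$stages) if (st$stage == stage) return(st)
  NULL
}

#' Run the file-based pipeline with content-hash caching
#'
#' Orchestrates import -> hypothesize -> align/train -> screen -> report on
#' a directory of input files (e.g. a [make_benchmark()] bundle). Each
#' stage records an input content hash (md5 of its input files plus the
#' config) in `manifest.json`; a rerun with unchanged inputs skips the
#' stage and reuses its outputs. Any stage failure aborts with the stage
#' named; outputs of completed stages are retained.
#'
#' @param config A [default_config()] with at least `actives_sdf` and
#'   `workdir` set (`decoys_sdf` enables the screening stage).
#' @return The workdir path, invisibly; side effects are the artifact
#'   files: `hypothesis.json`, `model.json`, `stats.csv`,
#'   `predictions.csv`, `report.json`, `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$actives_sdf) || is.null(config$workdir)) {
    stop("config needs actives_sdf and workdir")
  }
  wd <- config$workdir
  dir.create(wd, showWarnings = FALSE, recursive = TRUE)
  chash <- config_hash(config)
  manifest_path <- file.path(wd, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  } else list(config_hash = chash, stages = list())
  if (!identical(manifest$config_hash, chash)) {
    manifest <- list(config_hash = chash, stages = list())
  }
  stage_done <- function(stage, in_hash, outputs) {
    st <- read_stage(manifest, stage)
    !is.null(st) && identical(st$inputs_hash, in_hash) &&
      all(file.exists(file.path(wd, unlist(outputs))))
  }
  record <- function(stage, in_hash, outputs, secs) {
    manifest$stages <<- Filter(function(s) s$stage != stage,
                               manifest$stages)
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = stage, inputs_hash = in_hash, outputs = outputs,
           wall_time_s = round(secs, 3), cached = FALSE)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA)
  }
  mark_cached <- function(stage) {
    for (i in seq_along(manifest$stages)) {
      if (manifest$stages[[i]]$stage == stage) {
        manifest$stages[[i]]$cached <<- TRUE
      }
    }
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA)
  }
  run_stage <- function(stage, inputs, outputs, fun) {
    in_hash <- paste0(chash, ":", files_hash(inputs))
    if (stage_done(stage, in_hash, outputs)) {
      mark_cached(stage)
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    record(stage, in_hash, outputs, proc.time()[["elapsed"]] - t0)
    invisible(NULL)
  }

  pth <- function(f) file.path(wd, f)
  run_stage("hypothesize", list(config$actives_sdf), "hypothesis.json",
            function() {
    actives <- read_molecules(config$actives_sdf, "sdf")
    pki <- vapply(actives, `[[`, 0, "pki")
    potent <- actives[!is.na(pki) &
                      vapply(actives, `[[`, "", "activity_class") ==
                        "potent"]
    if (length(potent) < 5L) {
      potent <- actives[order(-pki)][seq_len(min(20L, length(actives)))]
    }
    hyps <- find_common_hypotheses(ligand_entries(potent),
                                   n_features = config$n_features,
                                   must_match = config$must_match,
                                   bin_size = config$bin_size,
                                   tol = config$site_tolerance)
    if (!length(hyps)) stop("no common hypothesis found")
    write_hypothesis(hyps[[1]], pth("hypothesis.json"))
  })

  run_stage("train",
            list(config$actives_sdf, pth("hypothesis.json")),
            c("model.json", "stats.csv"), function() {
    actives <- read_molecules(config$actives_sdf, "sdf")
    hyp <- read_hypothesis(pth("hypothesis.json"))
    train <- actives[vapply(actives, `[[`, "", "set_label") == "train"]
    if (!length(train)) {
      train <- split_train_test(actives, config$train_fraction,
                                seed = config$seed)$train
    }
    enc <- align_and_encode(train, hyp,
                            min_sites = config$min_sites_screen,
                            spacing = config$grid_spacing,
                            margin = config$grid_margin)
    keep <- which(enc$matched)
    if (length(keep) < 3L) stop("fewer than 3 training actives match")
    fm <- assemble_matrix(enc$rows[keep],
                          vapply(train[keep], `[[`, "", "id"), enc$grid,
                          min_occupancy = config$min_occupancy)
    y <- vapply(train[keep], `[[`, 0, "pki")
    model <- fit_pls(fm, y, n_factors = min(config$max_factors,
                                            length(keep) - 1L))
    cv <- cross_validate(fm, y, n_factors = model$n_factors,
                         folds = config$cv_folds, seed = config$seed)
    tab <- do.call(rbind, lapply(seq_len(model$n_factors), function(a) {
      s <- regression_stats(y, model$fitted[, a], a)
      data.frame(factors = a, r2 = s$r2, sd = s$sd, f = s$f, p = s$p,
                 rmse = s$rmse,
                 q2 = if (a <= length(cv$q2)) cv$q2[a] else NA_real_)
    }))
    utils::write.csv(tab, pth("stats.csv"), row.names = FALSE)
    write_model(model, pth("model.json"))
  })

  if (!is.null(config$decoys_sdf)) {
    run_stage("screen",
              list(config$actives_sdf, config$decoys_sdf,
                   pth("model.json"), pth("hypothesis.json")),
              c("predictions.csv", "report.json"), function() {
      actives <- read_molecules(config$actives_sdf, "sdf")
      decoys <- read_molecules(config$decoys_sdf, "sdf")
      hyp <- read_hypothesis(pth("hypothesis.json"))
      model <- read_model(pth("model.json"))
      test <- actives[vapply(actives, `[[`, "", "set_label") == "test"]
      if (!length(test)) test <- actives
      db <- c(test, decoys)
      scr <- rank_database(model, hyp, db,
                           min_sites = config$min_sites_screen,
                           active_ids = vapply(test, `[[`, "", "id"))
      rk <- scr$ranking
      write_predictions(
        data.frame(id = rk$id, pred_pKi = rk$pred_pKi,
                   matched_sites = rk$n_matched,
                   align_rmsd = ifelse(is.na(rk$align_rmsd), 0,
                                       rk$align_rmsd)),
        pth("predictions.csv"))
      cutoff <- if (!is.null(config$cutoff)) config$cutoff else
        ceiling(config$hit_fraction * nrow(rk))
      enr <- enrichment_report(scr, cutoff = cutoff)
      jsonlite::write_json(
        list(schema = "phore3d-report-1", config_hash = chash,
             d = enr$d, a = enr$a, ht = enr$ht, ha = enr$ha,
             ef = enr$ef, gh = enr$gh, pct_ya = enr$pct_ya,
             pct_ra = enr$pct_ra, auc = enr$auc),
        pth("report.json"), auto_unbox = TRUE, digits = NA)
    })
  }
  invisible(wd)
}
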