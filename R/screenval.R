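#' Enrichment factor
#'
#' `EF = (Ha/Ht) / (A/D)`: the concentration of known actives in the
#' hit list relative to the database baseline. Returned at full precision;
#' display rounding is the caller's concern.
#'
#' @param ha Actives within the hit list.
#' @param ht Hit-list size (> 0).
#' @param a Total actives in the database (> 0).
#' @param d Database size (> 0).
#' @return EF (fold enrichment).
#' @export
enrichment_factor <- function(ha, ht, a, d) {
  check_counts(ha, ht, a, d)
  (ha / ht) / (a / d)
}

#' Guener-Henry goodness-of-hit score
#'
#' `GH = [Ha (3A + Ht) / (4 Ht A)] * [1 - (Ht - Ha)/(D - A)]`, a composite
#' of hit-list yield and active recall penalized by false positives; 0 for a
#' null model, 1 for an ideal one.
#'
#' @inheritParams enrichment_factor
#' @return GH score in `[0, 1]`.
#' @export
goodness_of_hit <- function(ha, ht, a, d) {
  check_counts(ha, ht, a, d)
  if (d <= a) stop("need d > a for the false-positive penalty")
  (ha * (3 * a + ht) / (4 * ht * a)) * (1 - (ht - ha) / (d - a))
}

#' Percent yield of actives
#'
#' `%YA = 100 Ha / Ht` — the hit list's precision.
#' @inheritParams enrichment_factor
#' @return Percentage.
#' @export
yield_of_actives <- function(ha, ht) {
  if (ht <= 0) stop("ht must be positive")
  if (ha < 0 || ha > ht) stop("need 0 <= ha <= ht")
  100 * ha / ht
}

#' Percent ratio of actives
#'
#' `%RA = 100 Ha / A` — the recall of known actives.
#' @inheritParams enrichment_factor
#' @return Percentage.
#' @export
ratio_of_actives <- function(ha, a) {
  if (a <= 0) stop("a must be positive")
  if (ha < 0 || ha > a) stop("need 0 <= ha <= a")
  100 * ha / a
}

check_counts <- function(ha, ht, a, d) {
  if (ht <= 0 || a <= 0 || d <= 0) stop("ht, a, d must be positive")
  if (ha < 0) stop("ha must be >= 0")
  if (ha > ht) stop("ha cannot exceed ht")
  if (ha > a) stop("ha cannot exceed a")
  if (a > d) stop("a cannot exceed d")
  if (ht > d) stop("ht cannot exceed d")
  # hit-list inactives cannot exceed database inactives
  if (ht - ha > d - a) stop("ht - ha cannot exceed d - a")
  invisible(TRUE)
}

#' ROC curve and AUC of a ranked screen
#'
#' AUC is the Mann-Whitney pair statistic (probability that a random active
#' outscores a random decoy, ties counted 1/2); the emitted curve steps
#' through distinct score levels (so tied scores produce a diagonal
#' segment), and its trapezoidal area equals the pair statistic to
#' numerical precision.
#'
#' @param scores Predicted scores (higher = more active).
#' @param is_active Logical vector.
#' @return List: `roc` (data frame `fpr`, `tpr` from (0,0) to (1,1)),
#'   `auc`.
#' @export
roc_curve_auc <- function(scores, is_active) {
  is_active <- as.logical(is_active)
  npos <- sum(is_active); nneg <- sum(!is_active)
  if (npos == 0L || nneg == 0L) {
    stop("need at least one active and one inactive")
  }
  # Mann-Whitney via midranks
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[is_active]) - npos * (npos + 1) / 2) / (npos * nneg)
  lv <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum(vapply(lv, function(s) sum(is_active & scores == s), 0))
  fp <- cumsum(vapply(lv, function(s) sum(!is_active & scores == s), 0))
  roc <- data.frame(fpr = c(0, fp / nneg), tpr = c(0, tp / npos))
  list(roc = roc, auc = auc)
}

#' Rank a screening database with a QSAR model and hypothesis
#'
#' Each molecule is matched against the hypothesis (minimum-site policy),
#' aligned, encoded on the model grid and predicted. Molecules that fail
#' the match receive the floor prediction (by default the training-set
#' minimum pKi) and rank below all matched molecules, internally ordered by
#' id; matched molecules are ordered by predicted pKi descending with ties
#' broken by id. Deterministic and invariant to input order.
#'
#' @param model A `ph_pls` fitted on a `ph_featmat`.
#' @param hyp The alignment hypothesis.
#' @param mols Database molecules (list of [phmol]).
#' @param ensembles Optional conformer ensembles aligned with `mols`.
#' @param min_sites Minimum matched sites for a prediction (default 4).
#' @param floor_pred Prediction assigned to no-match molecules (default:
#'   training minimum pKi).
#' @param active_ids Character ids of known actives (for enrichment).
#' @return Object of class `ph_screen`: data frame `ranking` with columns
#'   `rank`, `id`, `pred_pKi`, `is_active`, `no_match`, `n_matched`,
#'   `align_rmsd`.
#' @export
rank_database <- function(model, hyp, mols, ensembles = NULL,
                          min_sites = 4L, floor_pred = NULL,
                          active_ids = character()) {
  if (!length(mols)) stop("empty screening database")
  if (is.null(floor_pred)) floor_pred <- min(model$y)
  entries <- ligand_entries(mols, ensembles)
  classings <- lapply(mols, assign_atom_classes)
  n <- length(mols)
  pred <- numeric(n); nm <- logical(n)
  nmatched <- integer(n); rmsd <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    m <- match_ligand(hyp, entries[[i]], min_sites = min_sites)
    if (is.null(m)) {
      pred[i] <- floor_pred; nm[i] <- TRUE
      next
    }
    al <- align_ligand(hyp, m, entries[[i]])
    ids <- encode_ligand(al$coords_aligned[entries[[i]]$heavy, ,
                                           drop = FALSE],
                         classings[[i]], model$grid)
    pred[i] <- predict_pls(model, list(ids))
    nmatched[i] <- m$n_matched
    rmsd[i] <- m$rmsd
  }
  ids_all <- vapply(mols, `[[`, "", "id")
  df <- data.frame(id = ids_all, pred_pKi = pred,
                   is_active = ids_all %in% active_ids,
                   no_match = nm, n_matched = nmatched, align_rmsd = rmsd)
  ord <- order(df$no_match, -df$pred_pKi, df$id)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(n)
  rownames(df) <- NULL
  structure(list(ranking = df[, c("rank", "id", "pred_pKi", "is_active",
                                  "no_match", "n_matched", "align_rmsd")],
                 min_sites = min_sites, floor_pred = floor_pred),
            class = "ph_screen")
}

#' Enrichment report for a ranked screen
#'
#' Counts known actives in the top `cutoff` rows and assembles the full
#' validation panel: EF, GH, %YA, %RA, ROC curve and AUC. The default
#' cutoff is 1% of the database, rounded up.
#'
#' @param result A `ph_screen` from [rank_database()], or a data frame with
#'   columns `pred_pKi`, `is_active` (ranked or not).
#' @param cutoff Hit-list size (default `ceiling(0.01 * D)`).
#' @return Object of class `ph_enrichment`: counts `d`, `a`, `ht`, `ha`
#'   and metrics `ef`, `gh`, `pct_ya`, `pct_ra`, `roc`, `auc`.
#' @export
enrichment_report <- function(result, cutoff = NULL) {
  df <- if (inherits(result, "ph_screen")) result$ranking else
    as.data.frame(result)
  if (is.null(df$rank)) {
    df <- df[order(-df$pred_pKi, df$id %||% seq_len(nrow(df))), ,
             drop = FALSE]
  } else df <- df[order(df$rank), , drop = FALSE]
  d <- nrow(df)
  if (is.null(cutoff)) cutoff <- ceiling(0.01 * d)
  if (cutoff < 1L || cutoff > d) stop("cutoff must be in 1..D")
  a <- sum(df$is_active)
  ha <- sum(df$is_active[seq_len(cutoff)])
  roc <- roc_curve_auc(df$pred_pKi, df$is_active)
  structure(list(d = d, a = a, ht = as.integer(cutoff), ha = ha,
                 ef = enrichment_factor(ha, cutoff, a, d),
                 gh = goodness_of_hit(ha, cutoff, a, d),
                 pct_ya = yield_of_actives(ha, cutoff),
                 pct_ra = ratio_of_actives(ha, a),
                 roc = roc$roc, auc = roc$auc),
            class = "ph_enrichment")
}

#' @export
print.ph_enrichment <- function(x, ...) {
  cat(sprintf(
    "<ph_enrichment> D=%d A=%d Ht=%d Ha=%d | EF=%.2f GH=%.2f %%YA=%.1f %%RA=%.1f AUC=%.3f\n",
    x$d, x$a, x$ht, x$ha, x$ef, x$gh, x$pct_ya, x$pct_ra, x$auc))
  invisible(x)
}
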