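#' Fit the top-ranked random-forest models into a prediction ensemble
#'
#' Trains one random-forest classifier per top-ranked feature subset on the
#' standardized full panel of the given layer. The per-feature center/scale
#' of the panel is stored so external profiles can be put on the same scale.
#'
#' @param layer Feature matrix or tibble (`material` + features).
#' @param labeling Hazard labeling for the panel.
#' @param feature_sets List of character feature subsets (e.g. the `features`
#'   list-column of the `top` rows of [composite_rank()]).
#' @param ntree Trees per forest.
#' @param seed Integer seed.
#' @return An object of class `hazard_ensemble`.
#' @export
fit_hazard_ensemble <- function(layer, labeling, feature_sets, ntree = 500,
                                seed = 1L) {
  if (length(feature_sets) < 1) abort("need at least one feature set")
  s <- layer_setup(layer, labeling)
  std <- standardize_train_apply(s$x)
  models <- purrr::map(seq_along(feature_sets), function(i) {
    feats <- feature_sets[[i]]
    if (length(feats) == 0) abort("feature set ", i, " is empty")
    missing <- setdiff(feats, colnames(std$train))
    if (length(missing) > 0) {
      abort(paste0("features absent from layer: ", paste(head(missing, 5), collapse = ", ")))
    }
    set.seed(derive_seed(seed, paste0("ensemble", i)))
    list(
      features = feats,
      rf = randomForest::randomForest(
        std$train[, feats, drop = FALSE], s$y,
        ntree = ntree
      )
    )
  })
  structure(
    list(
      models = models, center = std$center, scale = std$scale,
      classes = levels(s$y), layer = s$layer_name
    ),
    class = "hazard_ensemble"
  )
}

#' @export
print.hazard_ensemble <- function(x, ...) {
  cat(
    "<hazard_ensemble>", length(x$models), "RF models, classes:",
    paste(x$classes, collapse = " < "), "\n"
  )
  invisible(x)
}

#' Predict hazard classes for external expression profiles
#'
#' Each ensemble member's features are matched to the external columns by
#' exact id. A model is usable for a profile only when at least
#' `min_coverage` of its features are present; missing features of usable
#' models are filled with `fill` on the standardized scale. The usable
#' models' class-probability vectors are averaged, renormalized, and
#' labeled by the highest-probability class (ties resolve toward the less
#' severe class and are flagged).
#'
#' @param newdata Tibble with optional `exposure`/`dose` columns and feature
#'   columns, or a numeric matrix.
#' @param ensemble A [fit_hazard_ensemble()] object.
#' @param min_coverage Minimum fraction of a model's features that must be
#'   present (default 0.8).
#' @param fill Standardized-scale value imputed for missing features
#'   (default 0, the training mean).
#' @return Tibble of class `ensemble_prediction`: `exposure`, `dose`, one
#'   probability column per class, `label`, `tie`, `n_models_used`.
#' @export
predict_external <- function(newdata, ensemble, min_coverage = 0.8, fill = 0) {
  meta_cols <- intersect(c("exposure", "dose"), colnames(newdata))
  if (is.data.frame(newdata)) {
    meta <- as_tibble(newdata[meta_cols])
    x <- as.matrix(newdata[setdiff(colnames(newdata), meta_cols)])
    storage.mode(x) <- "double"
  } else {
    meta <- tibble(.rows = nrow(newdata))
    x <- newdata
  }
  if (nrow(meta) == 0 || ncol(meta) == 0) {
    meta <- tibble(
      exposure = sprintf("row%03d", seq_len(nrow(x))),
      dose = 1
    )
  }
  if (!"exposure" %in% names(meta)) meta$exposure <- sprintf("row%03d", seq_len(nrow(x)))
  if (!"dose" %in% names(meta)) meta$dose <- 1

  usable <- purrr::keep(ensemble$models, function(m) {
    mean(m$features %in% colnames(x)) >= min_coverage
  })
  if (length(usable) == 0) {
    abort("no ensemble model reaches the required feature coverage; no prediction possible")
  }
  prob_sum <- matrix(0, nrow(x), length(ensemble$classes),
    dimnames = list(NULL, ensemble$classes)
  )
  for (m in usable) {
    z <- matrix(fill, nrow(x), length(m$features),
      dimnames = list(NULL, m$features)
    )
    present <- intersect(m$features, colnames(x))
    z[, present] <- sweep(
      sweep(x[, present, drop = FALSE], 2, ensemble$center[present]),
      2, ensemble$scale[present], "/"
    )
    prob_sum <- prob_sum + predict(m$rf, z, type = "prob")[, ensemble$classes, drop = FALSE]
  }
  probs <- prob_sum / length(usable)
  probs <- probs / rowSums(probs)
  lab <- label_from_probs(meta$exposure, probs)
  out <- dplyr::bind_cols(
    meta[c("exposure", "dose")],
    lab[setdiff(names(lab), "exposure")],
    tibble(n_models_used = length(usable))
  )
  class(out) <- c("ensemble_prediction", class(out))
  out
}

#' Average per-dose predictions of the same exposure
#'
#' @param predictions An `ensemble_prediction` tibble with `exposure` and
#'   class-probability columns.
#' @return One row per exposure with averaged, renormalized probabilities,
#'   `label`, `tie` and `n_doses`.
#' @export
average_over_doses <- function(predictions) {
  cls <- intersect(c("NoL", "M", "MH", "H"), names(predictions))
  agg <- predictions |>
    dplyr::group_by(.data$exposure) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(cls), mean),
      n_doses = dplyr::n(), .groups = "drop"
    )
  probs <- as.matrix(agg[cls])
  probs <- probs / rowSums(probs)
  out <- dplyr::bind_cols(
    label_from_probs(agg$exposure, probs),
    agg["n_doses"]
  )
  class(out) <- c("ensemble_prediction", class(out))
  out
}

#' Summarize ordinal predictions per exposure group by the median
#'
#' Predictions are coded NoL = 1, M = 2, H = 3 and the median over the
#' biological systems of each group is reported on a five-level ordinal
#' scale: half-integer medians map to the two intermediate levels
#' (1.5 = low-to-medium, 2.5 = medium-to-high).
#'
#' @param predictions Tibble with a grouping column `group` (or `exposure`)
#'   and a `label` column of hazard classes.
#' @return Tibble (`group`, `median_code`, `level`), `level` one of
#'   `low`, `low-to-medium`, `medium`, `medium-to-high`, `high`.
#' @export
#' @examples
#' summarize_median(tibble::tibble(group = "a", label = c("NoL", "M")))
summarize_median <- function(predictions) {
  gcol <- intersect(c("group", "exposure"), names(predictions))[1]
  if (is.na(gcol)) abort("need a `group` or `exposure` column")
  if (nrow(predictions) == 0) abort("empty prediction group")
  code <- c(NoL = 1, M = 2, H = 3)
  lv <- c("low", "low-to-medium", "medium", "medium-to-high", "high")
  predictions |>
    dplyr::group_by(dplyr::across(dplyr::all_of(gcol))) |>
    dplyr::summarise(
      median_code = median(code[as.character(.data$label)]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      level = factor(lv[2 * .data$median_code - 1], levels = lv, ordered = TRUE)
    ) |>
    dplyr::rename(group = dplyr::all_of(gcol))
}

#' Distance dendrogram between prediction tables of different cell models
#'
#' The distance between two cell models is the mean absolute difference of
#' their class-probability matrices over shared exposures; average-linkage
#' hierarchical clustering of the distances gives the dendrogram, serialized
#' as a newick tree with branch heights.
#'
#' @param tables Named list (>= 2) of prediction tibbles with `exposure` and
#'   class-probability columns `NoL`, `M`, `H`, over identical exposures.
#' @return Object of class `model_dendrogram`: list with `dist` (distance
#'   matrix), `hclust`, `newick`.
#' @export
model_distance_dendrogram <- function(tables) {
  if (length(tables) < 2) abort("need at least 2 cell-model prediction tables")
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("model", seq_along(tables))
  }
  cls <- c("NoL", "M", "H")
  ids <- tables[[1]]$exposure
  mats <- lapply(tables, function(t) {
    if (!identical(t$exposure, ids)) abort("tables must share aligned exposure ids")
    as.matrix(t[cls])
  })
  k <- length(mats)
  d <- matrix(0, k, k, dimnames = list(names(tables), names(tables)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d[i, j] <- d[j, i] <- mean(abs(mats[[i]] - mats[[j]]))
    }
  }
  hc <- hclust(as.dist(d), method = "average")
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(
    list(dist = d, hclust = hc, newick = newick),
    class = "model_dendrogram"
  )
}

#' @export
print.model_dendrogram <- function(x, ...) {
  cat("<model_dendrogram>", x$newick, "\n")
  invisible(x)
}
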