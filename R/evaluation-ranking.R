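#' Dice-Sorensen selection stability
#'
#' Mean over all unordered pairs of feature subsets of
#' `2 |A intersect B| / (|A| + |B|)`, always in \[0, 1\]: 1 for identical
#' subsets, 0 for disjoint ones. A pair of empty subsets is treated as
#' identical (contributes 1); an empty subset paired with a non-empty one
#' contributes 0.
#'
#' @param feature_sets List of at least two character vectors of feature ids.
#' @return Scalar stability in \[0, 1\].
#' @export
#' @examples
#' dice_stability(list(c("g1", "g2"), c("g2", "g3")))
dice_stability <- function(feature_sets) {
  if (length(feature_sets) < 2) abort("need at least 2 feature sets")
  pair_dice <- function(a, b) {
    a <- unique(a)
    b <- unique(b)
    if (length(a) == 0 && length(b) == 0) return(1)
    if (length(a) == 0 || length(b) == 0) return(0)
    2 * length(intersect(a, b)) / (length(a) + length(b))
  }
  pairs <- combn(length(feature_sets), 2)
  mean(apply(pairs, 2, function(ij) {
    pair_dice(feature_sets[[ij[1]]], feature_sets[[ij[2]]])
  }))
}

#' Ranking configuration
#'
#' @param w_accuracy,w_stability Non-negative weights summing to 1
#'   (defaults 0.5 / 0.5).
#' @param top_n Number of models flagged as top-ranked (default 10).
#' @return A list of class `ranking_config`.
#' @export
ranking_config <- function(w_accuracy = 0.5, w_stability = 0.5, top_n = 10) {
  if (w_accuracy < 0 || w_stability < 0 ||
    abs(w_accuracy + w_stability - 1) > 1e-9) {
    abort("weights must be >= 0 and sum to 1")
  }
  structure(
    list(w_accuracy = w_accuracy, w_stability = w_stability, top_n = as.integer(top_n)),
    class = "ranking_config"
  )
}

#' Evaluate a fixed feature subset over repeated splits
#'
#' A random-forest classifier is trained on the standardized training rows
#' restricted to the subset and scored by overall accuracy on each test
#' split; the mean and 95% t-interval over splits are reported.
#'
#' @inheritParams univariate_screen
#' @param features Character vector of feature ids (subset of the layer).
#' @param ntree Trees per forest.
#' @return List with `accuracies`, `mean_accuracy`, `ci_lo`, `ci_hi`.
#' @export
evaluate_model <- function(layer, labeling, features, scheme = split_scheme(),
                           ntree = 500) {
  if (length(features) == 0) abort("feature subset is empty")
  s <- layer_setup(layer, labeling)
  missing <- setdiff(features, colnames(s$x))
  if (length(missing) > 0) {
    abort(paste0("features absent from layer: ", paste(head(missing, 5), collapse = ", ")))
  }
  splits <- make_splits(s$y, scheme)
  acc <- numeric(length(splits))
  for (r in seq_along(splits)) {
    tr <- splits[[r]]
    te <- setdiff(seq_len(nrow(s$x)), tr)
    std <- standardize_train_apply(
      s$x[tr, features, drop = FALSE],
      s$x[te, features, drop = FALSE]
    )
    set.seed(derive_seed(scheme$seed, paste0("eval", r)))
    fit <- randomForest::randomForest(std$train, droplevels(s$y[tr]), ntree = ntree)
    pred <- predict(fit, std$test)
    acc[r] <- mean(as.character(pred) == as.character(s$y[te]))
  }
  ci <- t_ci(acc)
  list(
    accuracies = acc, mean_accuracy = unname(ci["mean"]),
    ci_lo = unname(ci["lo"]), ci_hi = unname(ci["hi"])
  )
}

#' Attach Dice stability to selector models
#'
#' Computes [dice_stability()] over each model's per-repeat subsets.
#' Selectors that do not produce subsets (LR-PCA) keep `NA` stability and
#' are later ranked by accuracy alone.
#'
#' @param models List of `biomarker_model` objects.
#' @return The list with `stability` filled in.
#' @export
add_stability <- function(models) {
  lapply(models, function(m) {
    if (!is.null(m$feature_sets) && length(m$feature_sets) >= 2) {
      m$stability <- dice_stability(m$feature_sets)
    }
    m
  })
}

#' Rank biomarker models by the accuracy/stability composite
#'
#' The composite score is `w_accuracy * mean_accuracy + w_stability * dice`
#' (defaults 0.5 / 0.5). Models without a defined stability (LR-PCA) are
#' scored by accuracy alone and flagged in `stability_used`. Ties are broken
#' by smaller feature-set size, then model id.
#'
#' @param models List of `biomarker_model` objects (after [add_stability()]),
#'   or a tibble with columns `model_id`, `layer`, `selector`, `n_features`,
#'   `mean_accuracy`, `dice`.
#' @param config A [ranking_config()].
#' @return Tibble of class `ranked_models`, sorted by decreasing
#'   `rank_score`, with a `top` flag on the first `top_n` rows.
#' @export
composite_rank <- function(models, config = ranking_config()) {
  tbl <- if (is.data.frame(models)) {
    as_tibble(models)
  } else {
    purrr::map_dfr(seq_along(models), function(i) {
      m <- models[[i]]
      tibble(
        model_id = paste0(m$layer, ".", m$selector, ".", i),
        layer = m$layer, selector = m$selector,
        n_features = length(m$features),
        mean_accuracy = m$mean_accuracy,
        ci_lo = m$ci_lo, ci_hi = m$ci_hi,
        dice = m$stability,
        features = list(m$features)
      )
    })
  }
  tbl <- tbl |>
    dplyr::mutate(
      stability_used = !is.na(.data$dice),
      rank_score = dplyr::if_else(
        .data$stability_used,
        config$w_accuracy * .data$mean_accuracy + config$w_stability * .data$dice,
        .data$mean_accuracy
      )
    ) |>
    dplyr::arrange(
      dplyr::desc(.data$rank_score), .data$n_features, .data$model_id
    ) |>
    dplyr::mutate(rank = dplyr::row_number(), top = .data$rank <= config$top_n)
  class(tbl) <- c("ranked_models", class(tbl))
  tbl
}

#' Combine per-layer class-probability tables into one ensemble prediction
#'
#' The per-layer class-probability vectors of each material/exposure are
#' averaged without weights, renormalized to sum 1, and labeled by the
#' highest-probability class; probability ties resolve toward the less
#' severe class (conservative hazard claims are flagged, not inflated).
#'
#' @param tables List of tibbles, each with an id column (`exposure` or
#'   `material`) and class-probability columns `NoL`, `M`, `H`, over
#'   identical ids.
#' @return Tibble with the id column, averaged probabilities, `label`, and
#'   `tie` flag.
#' @export
ensemble_across_layers <- function(tables) {
  if (length(tables) < 1) abort("need at least one table")
  id_col <- intersect(c("exposure", "material"), names(tables[[1]]))[1]
  if (is.na(id_col)) abort("tables need an `exposure` or `material` id column")
  ids <- tables[[1]][[id_col]]
  for (t in tables[-1]) {
    if (!identical(t[[id_col]], ids)) abort("tables must share identical ids")
  }
  cls <- c("NoL", "M", "H")
  probs <- Reduce(`+`, lapply(tables, function(t) as.matrix(t[cls]))) / length(tables)
  probs <- probs / rowSums(probs)
  label_from_probs(ids, probs, id_col)
}

# Shared labeling of a probability matrix: argmax with least-severe
# tie-break (class columns ordered by severity ascending).
label_from_probs <- function(ids, probs, id_col = "exposure") {
  cls <- colnames(probs)
  win <- apply(probs, 1, which.max)
  tie <- apply(probs, 1, function(p) sum(abs(p - max(p)) < 1e-12) > 1)
  out <- dplyr::bind_cols(
    tibble(!!id_col := ids), as_tibble(probs),
    tibble(
      label = factor(cls[win], levels = cls, ordered = TRUE),
      tie = tie
    )
  )
  out
}

#' Write a ranked-model table as TSV
#'
#' @param ranked A `ranked_models` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ranked_models <- function(ranked, path) {
  out <- ranked |>
    dplyr::mutate(features = purrr::map_chr(.data$features, paste, collapse = ","))
  readr::write_tsv(out, path)
  invisible(path)
}
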