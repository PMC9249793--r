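#' Repeated stratified train/test split scheme
#'
#' The evaluation backbone shared by every selector: the materials are split
#' into 70% training / 30% testing, five times; feature selection and all
#' fitted quantities use training rows only, test rows are touched solely
#' for accuracy reporting. Stratified draws keep every hazard class present
#' in every training split; non-stratified draws are re-drawn (bounded
#' retries) when a class is missing.
#'
#' @param train_fraction Proportion of materials in each training split.
#' @param n_repeats Number of independent splits.
#' @param stratified Stratify draws by class?
#' @param inner_folds Folds for nested cross-validation (LASSO, GA fitness).
#' @param seed Integer seed.
#' @return A list of class `split_scheme`.
#' @export
split_scheme <- function(train_fraction = 0.70, n_repeats = 5,
                         stratified = TRUE, inner_folds = 5, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be in (0, 1)")
  }
  structure(
    list(
      train_fraction = train_fraction, n_repeats = as.integer(n_repeats),
      stratified = isTRUE(stratified), inner_folds = as.integer(inner_folds),
      seed = as.integer(seed)
    ),
    class = "split_scheme"
  )
}

# Draw the scheme's training index sets for a class vector.
make_splits <- function(y, scheme, max_retry = 100) {
  y <- factor(y)
  n <- length(y)
  lapply(seq_len(scheme$n_repeats), function(r) {
    set.seed(derive_seed(scheme$seed, paste0("split", r)))
    if (scheme$stratified) {
      idx <- unlist(lapply(levels(y), function(lv) {
        rows <- which(y == lv)
        n_tr <- max(1, round(scheme$train_fraction * length(rows)))
        if (n_tr == length(rows) && length(rows) > 1) n_tr <- length(rows) - 1
        sample(rows, n_tr)
      }))
      return(sort(idx))
    }
    for (try in seq_len(max_retry)) {
      idx <- sort(sample(n, max(2, round(scheme$train_fraction * n))))
      if (all(levels(y) %in% y[idx]) && length(idx) < n) return(idx)
    }
    abort("could not draw a split containing every class; check class sizes")
  })
}

# Stratified inner-CV fold assignment for training rows.
make_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in levels(factor(y))) {
    rows <- which(y == lv)
    fold[rows] <- sample(rep_len(seq_len(n_folds), length(rows)))
  }
  fold
}

#' Standardize training data and apply the learned transform to test data
#'
#' Each training column is centered to mean 0 and scaled to standard
#' deviation 1 (sample sd, denominator n - 1); the identical transform is
#' applied to the test rows. Zero-variance training columns cannot be
#' standardized and are excluded from both matrices, with the exclusions
#' reported.
#'
#' @param train,test Numeric matrices with shared columns (`test` may be
#'   `NULL`).
#' @return List with `train`, `test`, `center`, `scale`, `dropped`
#'   (character vector of excluded zero-variance columns).
#' @export
standardize_train_apply <- function(train, test = NULL) {
  if (nrow(train) < 2) abort("train must have at least 2 rows")
  center <- colMeans(train)
  scale <- apply(train, 2, sd)
  keep <- scale > 0
  dropped <- colnames(train)[!keep]
  tr <- sweep(sweep(train[, keep, drop = FALSE], 2, center[keep]), 2, scale[keep], "/")
  te <- NULL
  if (!is.null(test)) {
    te <- sweep(sweep(test[, keep, drop = FALSE], 2, center[keep]), 2, scale[keep], "/")
  }
  list(train = tr, test = te, center = center[keep], scale = scale[keep], dropped = dropped)
}

# --- BiomarkerModel ---------------------------------------------------------

new_biomarker_model <- function(layer_name, selector, features, feature_sets,
                                accuracies, extra = list()) {
  ci <- t_ci(accuracies)
  structure(
    c(
      list(
        layer = layer_name, selector = selector,
        features = features, feature_sets = feature_sets,
        accuracies = accuracies,
        mean_accuracy = unname(ci["mean"]),
        ci_lo = unname(ci["lo"]), ci_hi = unname(ci["hi"]),
        stability = NA_real_,
        config_hash = substr(
          paste(selector, layer_name, length(features),
            paste(features, collapse = ","),
            sep = "|"
          ), 1, 200
        )
      ),
      extra
    ),
    class = "biomarker_model"
  )
}

#' @export
print.biomarker_model <- function(x, ...) {
  cat(sprintf(
    "<biomarker_model> %s on %s: %d features, mean accuracy %.3f [%.3f, %.3f]%s\n",
    x$selector, x$layer, length(x$features), x$mean_accuracy, x$ci_lo, x$ci_hi,
    if (is.na(x$stability)) "" else sprintf(", dice %.3f", x$stability)
  ))
  invisible(x)
}

# Canonical subset of a selector run: the best-accuracy repeat's subset
# (ties -> first repeat); all per-repeat subsets are kept for stability.
canonical_features <- function(feature_sets, accuracies) {
  feature_sets[[which.max(accuracies)]]
}

# Shared scaffolding: iterate over splits, standardize, delegate.
layer_setup <- function(layer, labeling, layer_name = NULL) {
  m <- if (is.matrix(layer)) layer else as_layer_matrix(layer)
  y <- align_labels(m, labeling)
  list(x = m, y = y, layer_name = layer_name %||% "layer")
}

#' Univariate logistic screening of single features
#'
#' Each feature is standardized on the training rows and used as the sole
#' predictor of a multinomial (softmax) logistic model; test-set accuracy is
#' recorded per split and features are ranked by mean accuracy with a 95%
#' t-interval over the splits.
#'
#' @param layer Feature matrix or tibble (`material` + features).
#' @param labeling Hazard labeling tibble or named factor.
#' @param scheme A [split_scheme()].
#' @param top_n Number of top features flagged (default 10).
#' @return Tibble (`feature`, `mean_accuracy`, `ci_lo`, `ci_hi`, `rank`,
#'   `top`) sorted by decreasing mean accuracy.
#' @export
univariate_screen <- function(layer, labeling, scheme = split_scheme(),
                              top_n = 10) {
  s <- layer_setup(layer, labeling)
  splits <- make_splits(s$y, scheme)
  acc <- matrix(NA_real_, ncol(s$x), length(splits),
    dimnames = list(colnames(s$x), NULL)
  )
  for (r in seq_along(splits)) {
    tr <- splits[[r]]
    te <- setdiff(seq_len(nrow(s$x)), tr)
    std <- standardize_train_apply(s$x[tr, , drop = FALSE], s$x[te, , drop = FALSE])
    ytr <- droplevels(s$y[tr])
    yte <- s$y[te]
    for (f in colnames(std$train)) {
      d_tr <- data.frame(y = ytr, x = std$train[, f])
      fit <- nnet::multinom(y ~ x, data = d_tr, trace = FALSE, maxit = 200)
      pred <- predict(fit, newdata = data.frame(x = std$test[, f]))
      acc[f, r] <- mean(as.character(pred) == as.character(yte))
    }
  }
  out <- purrr::map_dfr(rownames(acc), function(f) {
    ci <- t_ci(acc[f, ][!is.na(acc[f, ])])
    tibble(
      feature = f, mean_accuracy = unname(ci["mean"]),
      ci_lo = unname(ci["lo"]), ci_hi = unname(ci["hi"])
    )
  }) |>
    dplyr::arrange(dplyr::desc(.data$mean_accuracy), .data$feature) |>
    dplyr::mutate(rank = dplyr::row_number(), top = .data$rank <= top_n)
  out
}

#' PCA-logistic biomarker model (LR-PCA)
#'
#' PCA is fitted on the standardized training rows; the first two principal
#' component scores feed a multinomial logistic classifier evaluated on the
#' projected test rows. Rank-1 training data falls back to a single
#' component (flagged). Because the model uses a projection of the whole
#' layer rather than a feature subset, no per-repeat subsets are produced
#' and stability is not defined for this selector.
#'
#' @inheritParams univariate_screen
#' @param n_components Number of leading components (default 2).
#' @return A `biomarker_model` whose `features` record the full layer.
#' @export
select_lr_pca <- function(layer, labeling, scheme = split_scheme(),
                          n_components = 2) {
  s <- layer_setup(layer, labeling)
  splits <- make_splits(s$y, scheme)
  acc <- numeric(length(splits))
  rank_deficient <- FALSE
  for (r in seq_along(splits)) {
    tr <- splits[[r]]
    te <- setdiff(seq_len(nrow(s$x)), tr)
    std <- standardize_train_apply(s$x[tr, , drop = FALSE], s$x[te, , drop = FALSE])
    if (ncol(std$train) < 2) abort("need at least 2 non-constant features")
    pc <- prcomp(std$train, center = FALSE, scale. = FALSE)
    usable <- sum(pc$sdev > 1e-8)
    nc <- min(n_components, usable)
    if (nc < n_components) rank_deficient <- TRUE
    tr_sc <- pc$x[, seq_len(nc), drop = FALSE]
    te_sc <- std$test %*% pc$rotation[, seq_len(nc), drop = FALSE]
    d_tr <- data.frame(y = droplevels(s$y[tr]), tr_sc)
    fit <- nnet::multinom(y ~ ., data = d_tr, trace = FALSE, maxit = 500)
    pred <- predict(fit, newdata = data.frame(te_sc))
    acc[r] <- mean(as.character(pred) == as.character(s$y[te]))
  }
  new_biomarker_model(
    s$layer_name, "lrpca",
    features = colnames(s$x), feature_sets = NULL, accuracies = acc,
    extra = list(n_components = n_components, rank_deficient = rank_deficient)
  )
}

#' LASSO configuration
#'
#' @param lambda_grid Geometric grid of regularization strengths inside
#'   `[2^-3, 2^-1]` (default 20 points, descending).
#' @param one_sd_rule Apply the one-standard-deviation parsimony rule?
#' @return A list of class `lasso_config`.
#' @export
lasso_config <- function(lambda_grid = exp(seq(log(2^-1), log(2^-3), length.out = 20)),
                         one_sd_rule = TRUE) {
  if (min(lambda_grid) < 2^-3 - 1e-12 || max(lambda_grid) > 2^-1 + 1e-12) {
    abort("lambda_grid must lie within [2^-3, 2^-1]")
  }
  if (is.unsorted(rev(lambda_grid))) abort("lambda_grid must be sorted decreasing")
  structure(
    list(lambda_grid = lambda_grid, one_sd_rule = isTRUE(one_sd_rule)),
    class = "lasso_config"
  )
}

#' Multinomial LASSO biomarker selection with nested cross-validation
#'
#' Within each training split, an inner stratified `inner_folds`-fold
#' cross-validation estimates misclassification error over the lambda grid;
#' the chosen lambda is the largest (most parsimonious) one whose CV error
#' is within one standard deviation of the minimum (or the minimizer itself
#' when `one_sd_rule` is off). The model is then refitted on the whole
#' training split at the chosen lambda and scored on the test split. The
#' selected subset is the union of features with a nonzero coefficient in
#' any class. An all-zero solution yields an empty subset, flagged rather
#' than raised.
#'
#' @inheritParams univariate_screen
#' @param config A [lasso_config()].
#' @return A `biomarker_model` (selector `"lasso"`), with per-repeat subsets
#'   in `feature_sets` and chosen lambdas in `lambda_chosen`.
#' @export
select_lasso <- function(layer, labeling, scheme = split_scheme(),
                         config = lasso_config()) {
  s <- layer_setup(layer, labeling)
  splits <- make_splits(s$y, scheme)
  acc <- numeric(length(splits))
  sets <- vector("list", length(splits))
  lambdas <- numeric(length(splits))
  for (r in seq_along(splits)) {
    tr <- splits[[r]]
    te <- setdiff(seq_len(nrow(s$x)), tr)
    std <- standardize_train_apply(s$x[tr, , drop = FALSE], s$x[te, , drop = FALSE])
    ytr <- droplevels(s$y[tr])
    foldid <- make_folds(ytr, scheme$inner_folds,
      seed = derive_seed(scheme$seed, paste0("lassofold", r))
    )
    # glmnet warns about classes with < 8 observations on every fit; that is
    # the nature of a ~31-material panel, so the warning is muffled here
    cv <- withCallingHandlers(
      glmnet::cv.glmnet(std$train, ytr,
        family = "multinomial", lambda = config$lambda_grid,
        foldid = foldid, type.measure = "class", standardize = FALSE
      ),
      warning = function(w) {
        if (grepl("fewer than 8", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    lam <- if (config$one_sd_rule) cv$lambda.1se else cv$lambda.min
    lambdas[r] <- lam
    if (r == 1) lambda_min <- numeric(length(splits))
    lambda_min[r] <- cv$lambda.min
    co <- coef(cv$glmnet.fit, s = lam)
    nz <- unique(unlist(lapply(co, function(b) {
      rn <- rownames(b)[as.vector(b != 0)]
      setdiff(rn, "(Intercept)")
    })))
    sets[[r]] <- sort(nz)
    pred <- predict(cv$glmnet.fit, newx = std$test, s = lam, type = "class")
    acc[r] <- mean(as.character(pred) == as.character(s$y[te]))
  }
  new_biomarker_model(
    s$layer_name, "lasso",
    features = canonical_features(sets, acc), feature_sets = sets,
    accuracies = acc,
    extra = list(
      lambda_chosen = lambdas,
      lambda_min = lambda_min,
      empty_model = any(lengths(sets) == 0)
    )
  )
}

#' Random-forest backward elimination (varSelRF-style)
#'
#' Within each training split, a random forest is fitted repeatedly; at each
#' iteration the least important `drop_fraction` of the remaining features
#' (permutation importance) is removed and the out-of-bag (OOB) error
#' recorded. The returned subset is the smallest one whose OOB error is
#' within one standard error (binomial SE) of the minimum OOB error. The
#' subset's test accuracy is then scored with a fresh forest.
#'
#' @inheritParams univariate_screen
#' @param drop_fraction Fraction of features dropped per iteration.
#' @param ntree Trees per forest.
#' @return A `biomarker_model` (selector `"rfback"`).
#' @export
select_rf_backward <- function(layer, labeling, scheme = split_scheme(),
                               drop_fraction = 0.2, ntree = 500) {
  s <- layer_setup(layer, labeling)
  splits <- make_splits(s$y, scheme)
  acc <- numeric(length(splits))
  sets <- vector("list", length(splits))
  for (r in seq_along(splits)) {
    tr <- splits[[r]]
    te <- setdiff(seq_len(nrow(s$x)), tr)
    std <- standardize_train_apply(s$x[tr, , drop = FALSE], s$x[te, , drop = FALSE])
    ytr <- droplevels(s$y[tr])
    set.seed(derive_seed(scheme$seed, paste0("rfback", r)))
    vars <- colnames(std$train)
    history <- list()
    while (length(vars) >= 2) {
      fit <- randomForest::randomForest(
        std$train[, vars, drop = FALSE], ytr,
        ntree = ntree, importance = TRUE
      )
      oob <- unname(fit$err.rate[ntree, "OOB"])
      history[[length(history) + 1]] <- list(vars = vars, oob = oob)
      n_drop <- max(1, floor(drop_fraction * length(vars)))
      if (length(vars) - n_drop < 2) break
      imp <- randomForest::importance(fit, type = 1)[, 1]
      vars <- names(sort(imp, decreasing = TRUE))[seq_len(length(vars) - n_drop)]
    }
    oobs <- vapply(history, `[[`, numeric(1), "oob")
    sizes <- vapply(history, function(h) length(h$vars), integer(1))
    i_min <- which.min(oobs)
    se <- sqrt(oobs[i_min] * (1 - oobs[i_min]) / length(ytr))
    eligible <- which(oobs <= oobs[i_min] + se)
    best <- eligible[which.min(sizes[eligible])]
    sel <- sort(history[[best]]$vars)
    sets[[r]] <- sel
    fit <- randomForest::randomForest(
      std$train[, sel, drop = FALSE], ytr,
      ntree = ntree
    )
    pred <- predict(fit, std$test[, sel, drop = FALSE])
    acc[r] <- mean(as.character(pred) == as.character(s$y[te]))
  }
  new_biomarker_model(
    s$layer_name, "rfback",
    features = canonical_features(sets, acc), feature_sets = sets,
    accuracies = acc
  )
}

#' Genetic-algorithm wrapper configuration (fuzzy accuracy/size trade-off)
#'
#' @param population_size,n_generations GA size and length.
#' @param mutation_rate,crossover_rate Operator probabilities in \[0, 1\].
#' @param max_subset_size Largest admissible subset.
#' @param fitness_folds Inner stratified CV folds for the RF fitness.
#' @param elitism_count Elite individuals copied unchanged each generation.
#' @param acc_mid,acc_slope Midpoint/slope of the increasing accuracy
#'   sigmoid membership.
#' @param size_mid,size_slope Midpoint/slope of the decreasing subset-size
#'   sigmoid membership.
#' @param ntree Trees per fitness forest.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 30, n_generations = 25,
                      mutation_rate = 0.1, crossover_rate = 0.8,
                      max_subset_size = 10, fitness_folds = 5,
                      elitism_count = 2,
                      acc_mid = 0.7, acc_slope = 10,
                      size_mid = 20, size_slope = 0.5,
                      ntree = 100) {
  if (max_subset_size < 1) abort("invalid ga_config: max_subset_size must be >= 1")
  if (mutation_rate < 0 || mutation_rate > 1 || crossover_rate < 0 || crossover_rate > 1) {
    abort("invalid ga_config: rates must lie in [0, 1]")
  }
  structure(
    list(
      population_size = as.integer(population_size),
      n_generations = as.integer(n_generations),
      mutation_rate = mutation_rate, crossover_rate = crossover_rate,
      max_subset_size = as.integer(max_subset_size),
      fitness_folds = as.integer(fitness_folds),
      elitism_count = as.integer(elitism_count),
      acc_mid = acc_mid, acc_slope = acc_slope,
      size_mid = size_mid, size_slope = size_slope,
      ntree = as.integer(ntree)
    ),
    class = "ga_config"
  )
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Fuzzy fitness of a feature subset
#'
#' The fitness is the fuzzy minimum of two memberships: an increasing
#' sigmoid of the subset's inner-CV random-forest accuracy and a decreasing
#' sigmoid of the subset size. The RF seed is derived deterministically from
#' the subset's feature indices and `seed`, so fitness is a pure function of
#' the subset — the property that makes exhaustive-oracle comparisons of the
#' GA search meaningful.
#'
#' @param x Standardized training matrix.
#' @param y Class factor.
#' @param subset Integer column indices of the candidate subset.
#' @param config A [ga_config()].
#' @param seed Base seed for the fitness stream.
#' @return List with `fitness`, `accuracy`, `size`.
#' @export
garbo_fitness <- function(x, y, subset, config = ga_config(), seed = 1L) {
  subset <- sort(unique(subset))
  key <- paste(subset, collapse = "-")
  set.seed(derive_seed(seed, paste0("fit:", key)))
  fold <- make_folds(y, config$fitness_folds,
    seed = derive_seed(seed, paste0("fold:", key))
  )
  pred <- rep(NA_character_, length(y))
  for (f in seq_len(config$fitness_folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < nlevels(droplevels(y))) next
    fit <- randomForest::randomForest(
      x[tr, subset, drop = FALSE], droplevels(y[tr]),
      ntree = config$ntree
    )
    pred[!tr] <- as.character(predict(fit, x[!tr, subset, drop = FALSE]))
  }
  accuracy <- mean(pred == as.character(y), na.rm = TRUE)
  m_acc <- sigmoid(config$acc_slope * (accuracy - config$acc_mid))
  m_size <- sigmoid(-config$size_slope * (length(subset) - config$size_mid))
  list(fitness = min(m_acc, m_size), accuracy = accuracy, size = length(subset))
}

# Deterministic comparison: higher fitness, then smaller size, then
# lexicographically smaller id string.
better_individual <- function(a, b) {
  if (abs(a$fitness - b$fitness) > 1e-12) return(a$fitness > b$fitness)
  if (a$size != b$size) return(a$size < b$size)
  paste(a$subset, collapse = "-") < paste(b$subset, collapse = "-")
}

#' GA search over feature subsets with memoized fuzzy fitness
#'
#' Tournament selection (size 2), uniform crossover on the union of the
#' parents' features, mutation by feature swap/add/remove, elitism, and a
#' hard cap on subset size. Returns the best-ever individual; the elite
#' fitness trace is non-decreasing by construction.
#'
#' @param x Standardized training matrix.
#' @param y Class factor aligned to rows of `x`.
#' @param config A [ga_config()].
#' @param seed Integer seed driving both the GA stream and the fitness
#'   streams.
#' @return List with `subset` (sorted indices), `features`, `fitness`,
#'   `accuracy`, `size`, `history` (per-generation elite fitness),
#'   `n_evaluated` (distinct subsets scored).
#' @export
garbo_search <- function(x, y, config = ga_config(), seed = 1L) {
  p <- ncol(x)
  if (config$max_subset_size < 1) abort("invalid ga_config: max_subset_size must be >= 1")
  cache <- new.env(parent = emptyenv())
  evaluate <- function(subset) {
    subset <- sort(unique(subset))
    key <- paste(subset, collapse = "-")
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- garbo_fitness(x, y, subset, config, seed = seed)
    res$subset <- subset
    cache[[key]] <- res
    res
  }
  rand_subset <- function() sort(sample(p, sample(config$max_subset_size, 1)))
  mutate_subset <- function(s) {
    op <- sample(c("swap", "add", "remove"), 1)
    if (op == "add" && length(s) < config$max_subset_size && length(s) < p) {
      s <- c(s, sample(setdiff(seq_len(p), s), 1))
    } else if (op == "remove" && length(s) > 1) {
      s <- s[-sample(length(s), 1)]
    } else {
      out <- setdiff(seq_len(p), s)
      if (length(out) > 0) s[sample(length(s), 1)] <- sample(out, 1)
    }
    sort(unique(s))
  }
  crossover <- function(a, b) {
    u <- sort(unique(c(a, b)))
    child <- u[runif(length(u)) < 0.5]
    if (length(child) == 0) child <- sample(u, 1)
    if (length(child) > config$max_subset_size) {
      child <- sort(sample(child, config$max_subset_size))
    }
    child
  }

  set.seed(derive_seed(seed, "ga"))
  pop <- lapply(seq_len(config$population_size), function(i) evaluate(rand_subset()))
  best <- pop[[1]]
  for (ind in pop[-1]) if (better_individual(ind, best)) best <- ind
  history <- numeric(config$n_generations)
  for (g in seq_len(config$n_generations)) {
    ord <- order(
      vapply(pop, `[[`, numeric(1), "fitness"),
      -vapply(pop, `[[`, numeric(1), "size"),
      decreasing = TRUE
    )
    elite <- pop[ord[seq_len(min(config$elitism_count, length(pop)))]]
    tournament <- function() {
      pair <- sample(length(pop), 2)
      if (better_individual(pop[[pair[1]]], pop[[pair[2]]])) {
        pop[[pair[1]]]
      } else {
        pop[[pair[2]]]
      }
    }
    offspring <- list()
    while (length(offspring) < config$population_size - length(elite)) {
      pa <- tournament()
      pb <- tournament()
      child <- if (runif(1) < config$crossover_rate) {
        crossover(pa$subset, pb$subset)
      } else {
        pa$subset
      }
      if (runif(1) < config$mutation_rate) child <- mutate_subset(child)
      # novelty pressure: nudge already-scored offspring toward unexplored
      # neighbors so the search keeps covering new subsets
      tries <- 0
      while (!is.null(cache[[paste(sort(unique(child)), collapse = "-")]]) &&
        tries < 5) {
        child <- mutate_subset(child)
        tries <- tries + 1
      }
      offspring[[length(offspring) + 1]] <- evaluate(child)
    }
    pop <- c(elite, offspring)
    for (ind in pop) if (better_individual(ind, best)) best <- ind
    history[g] <- best$fitness
  }
  list(
    subset = best$subset, features = colnames(x)[best$subset],
    fitness = best$fitness, accuracy = best$accuracy, size = best$size,
    history = history, n_evaluated = length(ls(cache))
  )
}

#' GARBO-style genetic-algorithm biomarker selection
#'
#' Runs [garbo_search()] on the standardized training rows of each split,
#' selecting a compact subset that optimizes the fuzzy trade-off between
#' inner-CV random-forest accuracy and subset size; the subset's test
#' accuracy is then scored on the held-out split.
#'
#' @inheritParams univariate_screen
#' @param config A [ga_config()].
#' @return A `biomarker_model` (selector `"garbo"`), with per-repeat
#'   subsets, fitnesses, and elite-fitness histories.
#' @export
select_garbo <- function(layer, labeling, scheme = split_scheme(),
                         config = ga_config()) {
  s <- layer_setup(layer, labeling)
  splits <- make_splits(s$y, scheme)
  acc <- numeric(length(splits))
  sets <- vector("list", length(splits))
  fitnesses <- numeric(length(splits))
  histories <- vector("list", length(splits))
  for (r in seq_along(splits)) {
    tr <- splits[[r]]
    te <- setdiff(seq_len(nrow(s$x)), tr)
    std <- standardize_train_apply(s$x[tr, , drop = FALSE], s$x[te, , drop = FALSE])
    ytr <- droplevels(s$y[tr])
    res <- garbo_search(std$train, ytr, config,
      seed = derive_seed(scheme$seed, paste0("garbo", r))
    )
    sets[[r]] <- sort(res$features)
    fitnesses[r] <- res$fitness
    histories[[r]] <- res$history
    set.seed(derive_seed(scheme$seed, paste0("garboeval", r)))
    fit <- randomForest::randomForest(
      std$train[, res$features, drop = FALSE], ytr,
      ntree = config$ntree
    )
    pred <- predict(fit, std$test[, res$features, drop = FALSE])
    acc[r] <- mean(as.character(pred) == as.character(s$y[te]))
  }
  new_biomarker_model(
    s$layer_name, "garbo",
    features = canonical_features(sets, acc), feature_sets = sets,
    accuracies = acc,
    extra = list(fitness = fitnesses, history = histories)
  )
}
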