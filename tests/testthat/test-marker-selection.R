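test_that("standardization learns on train and applies to test, excluding constants", {
  train <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 2, 4))
  test <- cbind(a = c(2, 4), b = c(5, 9), c = c(2, 6))
  std <- standardize_train_apply(train, test)
  expect_equal(unname(std$train[, "a"]), c(-1, 0, 1))
  expect_identical(std$dropped, "b")
  expect_length(std$dropped, 1)
  # a test value equal to the train mean maps to 0
  expect_equal(unname(std$test[1, "a"]), 0)
  expect_equal(unname(std$test[1, "c"]), 0)
  expect_equal(colMeans(std$train), c(a = 0, c = 0))
  expect_equal(apply(std$train, 2, sd), c(a = 1, c = 1))
  expect_error(standardize_train_apply(train[1, , drop = FALSE]), "2 rows")
})

test_that("split schemes keep every class in every training split", {
  y <- factor(rep(c("NoL", "M", "H"), times = c(12, 10, 9)))
  for (strat in c(TRUE, FALSE)) {
    scheme <- split_scheme(stratified = strat, n_repeats = 10, seed = 3)
    splits <- enmhazard:::make_splits(y, scheme)
    for (tr in splits) {
      expect_setequal(unique(as.character(y[tr])), c("NoL", "M", "H"))
      expect_lt(length(tr), length(y))
    }
  }
  expect_error(split_scheme(train_fraction = 1), "train_fraction")
})

test_that("univariate screening ranks a class-indicator feature at accuracy 1", {
  study <- simulate_study(tiny_config(seed = 2, features_per_layer = c(mrna = 10)))
  lab <- label_neu(study$materials)
  layer <- study$panel$mrna
  layer$oracle_feature <- as.integer(factor(lab$class)) * 10
  out <- univariate_screen(layer, lab, split_scheme(seed = 5))
  expect_identical(out$feature[1], "oracle_feature")
  expect_equal(out$mean_accuracy[1], 1)
  expect_true(all(out$ci_lo <= out$mean_accuracy & out$mean_accuracy <= out$ci_hi))
  # pure-noise features hover near chance for 3 roughly balanced classes
  noise_acc <- out$mean_accuracy[!out$feature %in%
    c("oracle_feature", study$truth_features$mrna)]
  expect_gt(mean(noise_acc), 0.15)
  expect_lt(mean(noise_acc), 0.5)
})

test_that("planted features reach the univariate top 10 at strong effect", {
  hits <- vapply(1:5, function(s) {
    study <- simulate_study(tiny_config(seed = 20 + s, features_per_layer = c(mrna = 60)))
    lab <- label_neu(study$materials)
    out <- univariate_screen(study$panel$mrna, lab, split_scheme(seed = s))
    sum(study$truth_features$mrna %in% out$feature[1:10])
  }, numeric(1))
  expect_gte(mean(hits / 5), 0.8)
})

test_that("LR-PCA on two-dimensional data matches the direct logistic fit", {
  study <- simulate_study(tiny_config(seed = 3, features_per_layer = c(mrna = 2), n_informative = 2))
  lab <- label_neu(study$materials)
  scheme <- split_scheme(seed = 4)
  pca_model <- select_lr_pca(study$panel$mrna, lab, scheme)
  # direct fit: same splits, multinom on both standardized features
  m <- layer_mat(study, "mrna")
  y <- label_vec(lab)[rownames(m)]
  splits <- enmhazard:::make_splits(y, scheme)
  acc <- vapply(seq_along(splits), function(r) {
    tr <- splits[[r]]
    te <- setdiff(seq_len(nrow(m)), tr)
    std <- standardize_train_apply(m[tr, ], m[te, ])
    fit <- nnet::multinom(y ~ ., data = data.frame(y = droplevels(y[tr]), std$train),
      trace = FALSE, maxit = 500
    )
    mean(as.character(predict(fit, data.frame(std$test))) == as.character(y[te]))
  }, numeric(1))
  expect_equal(pca_model$accuracies, acc, tolerance = 1e-6)
  expect_identical(
    select_lr_pca(study$panel$mrna, lab, scheme)$accuracies,
    pca_model$accuracies
  )
})

test_that("LR-PCA under shuffled labels sits near chance", {
  study <- simulate_study(tiny_config(seed = 7, features_per_layer = c(mrna = 30)))
  lab <- label_neu(study$materials)
  set.seed(1)
  lab$class <- sample(lab$class)
  model <- select_lr_pca(study$panel$mrna, lab, split_scheme(seed = 2, n_repeats = 10))
  expect_lt(model$mean_accuracy, 0.6)
})

test_that("lasso obeys the one-SD parsimony rule and its grid bounds", {
  expect_error(lasso_config(lambda_grid = c(0.6, 0.2)), "2\\^-3")
  expect_error(lasso_config(lambda_grid = c(0.2, 0.4)), "decreasing")
  grid <- lasso_config()$lambda_grid
  expect_equal(max(grid), 2^-1)
  expect_equal(min(grid), 2^-3)
  expect_length(grid, 20)

  # chosen lambda never smaller than the CV minimizer (parsimony direction)
  study <- simulate_study(tiny_config(seed = 5, features_per_layer = c(mrna = 40)))
  lab <- label_neu(study$materials)
  model <- select_lasso(study$panel$mrna, lab, split_scheme(seed = 6))
  expect_true(all(model$lambda_chosen >= model$lambda_min - 1e-12))

  # pure noise: near-flat CV curves push the rule toward heavy shrinkage;
  # empty models are flagged, never raised
  noise <- simulate_study(tiny_config(
    seed = 8, effect_size = 0,
    features_per_layer = c(mrna = 40)
  ))
  nl <- label_neu(noise$materials)
  nm <- select_lasso(noise$panel$mrna, nl, split_scheme(seed = 2))
  expect_true(all(nm$lambda_chosen >= nm$lambda_min))
  expect_lte(mean(lengths(nm$feature_sets)), mean(lengths(model$feature_sets)))
  expect_type(nm$empty_model, "logical")
})

test_that("lasso recovers the planted signal at strong effect", {
  recall <- vapply(1:6, function(s) {
    study <- simulate_study(tiny_config(seed = 30 + s, features_per_layer = c(mrna = 100)))
    lab <- label_neu(study$materials)
    model <- select_lasso(study$panel$mrna, lab, split_scheme(seed = s))
    mean(study$truth_features$mrna %in% model$features)
  }, numeric(1))
  expect_gte(mean(recall), 0.6)
})

test_that("RF backward elimination keeps strong features and shrinks noise layers", {
  informative_kept <- vapply(1:10, function(s) {
    study <- simulate_study(tiny_config(
      seed = 40 + s, effect_size = 3,
      features_per_layer = c(physchem = 52), n_informative = 2
    ))
    lab <- label_neu(study$materials)
    model <- select_rf_backward(study$panel$physchem, lab,
      split_scheme(seed = s, n_repeats = 2),
      ntree = 200
    )
    mean(study$truth_features$physchem %in% model$features)
  }, numeric(1))
  expect_gte(mean(informative_kept), 0.8)

  noise <- simulate_study(tiny_config(
    seed = 51, effect_size = 0,
    features_per_layer = c(physchem = 30)
  ))
  nl <- label_neu(noise$materials)
  nm <- select_rf_backward(noise$panel$physchem, nl,
    split_scheme(seed = 1, n_repeats = 2),
    ntree = 150
  )
  expect_lte(length(nm$features), 30)
  expect_lt(nm$mean_accuracy, 0.7)
  nm2 <- select_rf_backward(noise$panel$physchem, nl,
    split_scheme(seed = 1, n_repeats = 2),
    ntree = 150
  )
  expect_identical(nm$feature_sets, nm2$feature_sets)
})

test_that("the GA returns a perfect compact subset when one exists", {
  study <- simulate_study(tiny_config(seed = 9, features_per_layer = c(mrna = 15)))
  lab <- label_neu(study$materials)
  m <- layer_mat(study, "mrna")
  y <- droplevels(label_vec(lab)[rownames(m)])
  m <- cbind(m, oracle_feature = as.integer(y) * 5)
  std <- standardize_train_apply(m)
  res <- garbo_search(std$train, y, small_ga(max_subset_size = 2), seed = 3)
  expect_equal(res$accuracy, 1)
  expect_lte(res$size, 2)
  expect_true("oracle_feature" %in% res$features)
  # determinism and monotone elite fitness
  res2 <- garbo_search(std$train, y, small_ga(max_subset_size = 2), seed = 3)
  expect_identical(res$subset, res2$subset)
  expect_false(is.unsorted(res$history))
  expect_error(ga_config(max_subset_size = 0), "max_subset_size")
  expect_error(ga_config(mutation_rate = 2), "rates")
})

test_that("selectors never read held-out rows for selection", {
  study <- simulate_study(tiny_config(seed = 12, features_per_layer = c(mrna = 40)))
  lab <- label_neu(study$materials)
  scheme <- split_scheme(seed = 13, n_repeats = 3)
  m <- layer_mat(study, "mrna")
  y <- label_vec(lab)[rownames(m)]
  splits <- enmhazard:::make_splits(y, scheme)
  # corrupt a row held out of the first split: the subset selected on that
  # split must be unchanged, since selection may only read training rows
  held_out <- setdiff(seq_len(nrow(m)), splits[[1]])[1]
  corrupted <- study$panel$mrna
  set.seed(99)
  corrupted[held_out, -1] <- as.list(rnorm(ncol(m), mean = 100))
  for (selector in list(select_lasso, select_rf_backward)) {
    a <- selector(study$panel$mrna, lab, scheme)
    b <- selector(corrupted, lab, scheme)
    expect_identical(a$feature_sets[[1]], b$feature_sets[[1]])
  }
})

test_that("stronger planted effects never hurt selector recall", {
  effects <- c(0.5, 1.5, 3)
  mean_recall <- function(selector_fun) {
    vapply(effects, function(e) {
      mean(vapply(1:6, function(s) {
        study <- simulate_study(tiny_config(
          seed = 60 + s, effect_size = e,
          features_per_layer = c(mrna = 50)
        ))
        lab <- label_neu(study$materials)
        model <- selector_fun(study$panel$mrna, lab, split_scheme(seed = s, n_repeats = 3))
        if (length(model$features) == 0) 0 else mean(study$truth_features$mrna %in% model$features)
      }, numeric(1)))
    }, numeric(1))
  }
  for (fun in list(
    select_lasso,
    function(l, y, s) select_rf_backward(l, y, s, ntree = 150)
  )) {
    r <- mean_recall(fun)
    # allow one small sampling-noise violation across the three levels
    expect_true(sum(diff(r) < -0.1) <= 1)
    expect_gt(r[3], r[1])
  }
})
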