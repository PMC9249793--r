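test_that("Dice stability matches its closed form on constructed subsets", {
  expect_equal(dice_stability(list(c("g1", "g2", "g3"), c("g1", "g2", "g3"))), 1)
  expect_equal(dice_stability(list(c("g1", "g2"), c("g3", "g4"))), 0)
  expect_equal(dice_stability(list(c("g1", "g2"), c("g2", "g3"))), 0.5)
  expect_equal(dice_stability(list(character(0), character(0))), 1)
  expect_equal(dice_stability(list(character(0), "g1")), 0)
  # three sets: mean of the three pairwise values
  expect_equal(
    dice_stability(list(c("a", "b"), c("b", "c"), c("a", "b"))),
    mean(c(0.5, 1, 0.5))
  )
  expect_error(dice_stability(list("g1")), "2")
})

test_that("Dice stability always stays inside [0, 1]", {
  set.seed(1)
  for (i in 1:25) {
    sets <- lapply(1:4, function(j) sample(letters, sample(0:10, 1)))
    d <- dice_stability(sets)
    expect_gte(d, 0)
    expect_lte(d, 1)
  }
})

test_that("the composite rank applies the 0.5/0.5 weighting and its tie-breaks", {
  tbl <- tibble::tibble(
    model_id = c("a", "b", "c"),
    layer = "mrna", selector = "lasso",
    n_features = c(5, 2, 2),
    mean_accuracy = c(1.0, 0.8, 0.7),
    dice = c(0.0, 0.6, 0.7)
  )
  ranked <- composite_rank(tbl, ranking_config(top_n = 2))
  expect_equal(ranked$rank_score[ranked$model_id == "a"], 0.5)
  expect_equal(ranked$rank_score[ranked$model_id == "b"], 0.7)
  expect_equal(ranked$rank_score[ranked$model_id == "c"], 0.7)
  # tie at 0.7: both have 2 features, id breaks it
  expect_identical(ranked$model_id[1:2], c("b", "c"))
  expect_identical(ranked$top, c(TRUE, TRUE, FALSE))
  # models without stability rank on accuracy alone, flagged
  tbl$dice[1] <- NA
  r2 <- composite_rank(tbl)
  expect_false(r2$stability_used[r2$model_id == "a"])
  expect_equal(r2$rank_score[r2$model_id == "a"], 1.0)
  expect_error(ranking_config(0.7, 0.7), "sum to 1")
})

test_that("when accuracy equals stability the ordering is the accuracy ordering", {
  tbl <- tibble::tibble(
    model_id = paste0("m", 1:4), layer = "x", selector = "s",
    n_features = 3,
    mean_accuracy = c(0.4, 0.9, 0.6, 0.75),
    dice = c(0.4, 0.9, 0.6, 0.75)
  )
  ranked <- composite_rank(tbl)
  expect_identical(ranked$model_id, tbl$model_id[order(-tbl$mean_accuracy)])
  # re-ranking the same input reproduces the same table
  expect_identical(ranked, composite_rank(tbl))
})

test_that("evaluate_model scores separable subsets perfectly and shuffled labels at chance", {
  study <- simulate_study(tiny_config(seed = 4, features_per_layer = c(mrna = 20)))
  lab <- label_neu(study$materials)
  layer <- study$panel$mrna
  layer$oracle_feature <- as.integer(factor(lab$class)) * 3
  res <- evaluate_model(layer, lab, "oracle_feature", split_scheme(seed = 5), ntree = 100)
  expect_equal(res$mean_accuracy, 1)
  set.seed(2)
  shuffled <- lab
  shuffled$class <- sample(shuffled$class)
  null_res <- evaluate_model(layer, shuffled, names(layer)[2:6],
    split_scheme(seed = 6, n_repeats = 10),
    ntree = 100
  )
  expect_gt(null_res$mean_accuracy, 0.05)
  expect_lt(null_res$mean_accuracy, 0.62)
  res2 <- evaluate_model(layer, lab, "oracle_feature", split_scheme(seed = 5), ntree = 100)
  expect_identical(res$accuracies, res2$accuracies)
  expect_error(evaluate_model(layer, lab, character(0)), "empty")
  expect_error(evaluate_model(layer, lab, "not_a_gene"), "absent")
})

test_that("layer ensembling averages probabilities with the conservative tie-break", {
  t1 <- tibble::tibble(exposure = c("e1", "e2"), NoL = c(1, 0), M = c(0, 1), H = c(0, 0))
  t2 <- tibble::tibble(exposure = c("e1", "e2"), NoL = c(0, 0), M = c(1, 1), H = c(0, 0))
  one <- ensemble_across_layers(list(t1))
  expect_equal(as.matrix(one[c("NoL", "M", "H")]), as.matrix(t1[c("NoL", "M", "H")]))
  both <- ensemble_across_layers(list(t1, t2))
  expect_equal(unlist(both[1, c("NoL", "M", "H")], use.names = FALSE), c(0.5, 0.5, 0))
  expect_identical(as.character(both$label[1]), "NoL") # tie -> less severe
  expect_true(both$tie[1])
  expect_false(both$tie[2])
  expect_lt(max(abs(rowSums(as.matrix(both[c("NoL", "M", "H")])) - 1)), 1e-9)
  t3 <- t2
  t3$exposure <- c("e2", "e1")
  expect_error(ensemble_across_layers(list(t1, t3)), "identical ids")
})

test_that("hybrid physchem + omics ensembles do not underperform physchem alone", {
  delta <- vapply(1:8, function(s) {
    study <- simulate_study(tiny_config(
      seed = 70 + s,
      features_per_layer = c(mrna = 40, physchem = 12)
    ))
    lab <- label_neu(study$materials)
    scheme <- split_scheme(seed = s, n_repeats = 3)
    m_phys <- layer_mat(study, "physchem")
    m_omic <- layer_mat(study, "mrna")
    y <- label_vec(lab)[rownames(m_phys)]
    splits <- enmhazard:::make_splits(y, scheme)
    accs <- vapply(seq_along(splits), function(r) {
      tr <- splits[[r]]
      te <- setdiff(seq_len(nrow(m_phys)), tr)
      probs <- lapply(list(m_phys, m_omic), function(m) {
        std <- standardize_train_apply(m[tr, ], m[te, ])
        set.seed(enmhazard:::derive_seed(s, paste0("hybrid", r)))
        fit <- randomForest::randomForest(std$train, droplevels(y[tr]), ntree = 150)
        p <- predict(fit, std$test, type = "prob")
        tibble::tibble(
          material = rownames(m)[te],
          NoL = p[, "NoL"], M = p[, "M"], H = p[, "H"]
        )
      })
      phys_label <- probs[[1]][c("NoL", "M", "H")] |>
        as.matrix() |>
        apply(1, which.max)
      ens <- ensemble_across_layers(probs)
      c(
        phys = mean(c("NoL", "M", "H")[phys_label] == as.character(y[te])),
        ens = mean(as.character(ens$label) == as.character(y[te]))
      )
    }, numeric(2))
    mean(accs["ens", ]) - mean(accs["phys", ])
  }, numeric(1))
  expect_gte(mean(delta), -0.02)
})

test_that("stability attaches to subset-producing selectors only", {
  study <- simulate_study(tiny_config(seed = 6, features_per_layer = c(mrna = 30)))
  lab <- label_neu(study$materials)
  scheme <- split_scheme(seed = 7, n_repeats = 3)
  models <- add_stability(list(
    lasso = select_lasso(study$panel$mrna, lab, scheme),
    lrpca = select_lr_pca(study$panel$mrna, lab, scheme)
  ))
  expect_false(is.na(models$lasso$stability))
  expect_gte(models$lasso$stability, 0)
  expect_lte(models$lasso$stability, 1)
  expect_true(is.na(models$lrpca$stability))
  g <- glance(models$lasso)
  expect_identical(g$dice, models$lasso$stability)
  expect_equal(nrow(tidy(models$lasso)), scheme$n_repeats)
})
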