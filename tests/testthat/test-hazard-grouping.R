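test_that("single-component spherical GMM matches the closed-form MLE", {
  set.seed(1)
  x <- matrix(rnorm(60, mean = 3), 20, 3)
  fit <- fit_spherical_gmm(x, k = 1)
  expect_equal(as.numeric(fit$means), colMeans(x))
  expect_equal(fit$sigma2, mean(sweep(x, 2, colMeans(x))^2))
})

test_that("EM separates two distant clouds with near-hard responsibilities", {
  set.seed(2)
  x <- rbind(matrix(rnorm(30), 10, 3), matrix(rnorm(30, mean = 12), 10, 3))
  fit1 <- fit_spherical_gmm(x, k = 1)
  fit2 <- fit_spherical_gmm(x, k = 2, seed = 3)
  expect_gt(fit2$loglik, fit1$loglik)
  expect_true(all(pmax(fit2$responsibilities[, 1], fit2$responsibilities[, 2]) > 0.999))
  # determinism under a fixed seed
  expect_identical(fit2$loglik, fit_spherical_gmm(x, k = 2, seed = 3)$loglik)
})

test_that("spherical GMM log-likelihood agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  x <- separated_clouds(n_per = 8, d = 3, gap = 6, seed = 4)
  ours <- fit_spherical_gmm(x, k = 3, seed = 1, var_floor = 1e-12)
  ref <- mclust::Mclust(x, G = 3, modelNames = "VII", verbose = FALSE)
  expect_lt(abs(ours$loglik - ref$loglik) / abs(ref$loglik), 1e-3)
})

test_that("bic_score implements -2 loglik + m log n", {
  expect_identical(bic_score(0, 0, 10), 0)
  expect_equal(bic_score(-100, 10, 31), 200 + 10 * log(31))
  expect_lt(bic_score(-90, 10, 31), bic_score(-100, 10, 31))
})

test_that("assess_k is reproducible, sized by n_restarts, and improves loglik with k", {
  x <- separated_clouds(seed = 5)
  a1 <- assess_k(x, k_range = 2:4, n_restarts = 1, seed = 9)
  expect_equal(nrow(a1$samples), 3)
  a <- assess_k(x, k_range = 2:5, n_restarts = 25, seed = 9)
  b <- assess_k(x, k_range = 2:5, n_restarts = 25, seed = 9)
  expect_identical(a$samples, b$samples)
  # restart-best log-likelihood non-decreasing in k
  expect_true(all(diff(a$summary$best_loglik) > -1e-6))
  expect_error(assess_k(x, k_range = 2:40), "k_range")
})

test_that("a single isotropic cloud shows growing BIC spread with k", {
  set.seed(11)
  x <- matrix(rnorm(31 * 4), 31, 4)
  rownames(x) <- sprintf("M%02d", 1:31)
  a <- assess_k(x, k_range = c(2, 6), n_restarts = 40, seed = 2)
  expect_gt(
    a$summary$var_bic[a$summary$k == 6],
    a$summary$var_bic[a$summary$k == 2]
  )
})

test_that("k-means CYT grouping orders clusters by severity and ignores row order", {
  x <- separated_clouds(n_per = 10, d = 4, gap = 3, seed = 6) + 1
  lab <- cluster_cyt(x, k = 3, seed = 1)
  expect_identical(levels(lab$class), c("NoL", "M", "H"))
  # construction: blocks of rows have increasing mean, so labels follow blocks
  expect_true(all(lab$class[1:10] == "NoL"))
  expect_true(all(lab$class[21:30] == "H"))
  perm <- sample(nrow(x))
  lab2 <- cluster_cyt(x[perm, ], k = 3, seed = 1)
  merged <- dplyr::inner_join(lab, lab2, by = "material")
  expect_identical(as.character(merged$class.x), as.character(merged$class.y))
  expect_error(cluster_cyt(x[c(1, 1, 1), ], k = 3), "distinct")
})

test_that("severity ordering maps mean scores to ordered names with stable tie-breaks", {
  scores <- matrix(c(rep(1.2, 3), rep(3.0, 3), rep(5.5, 3)), 9, 1)
  rownames(scores) <- paste0("m", 1:9)
  labels <- setNames(rep(c(2L, 3L, 1L), each = 3), rownames(scores))
  out <- order_clusters_by_severity(labels, scores)
  expect_identical(as.character(out$class), rep(c("NoL", "M", "H"), each = 3))
  # two-cluster variant uses the NoL/H pair
  l2 <- setNames(rep(1:2, each = 3), paste0("m", 1:6))
  out2 <- order_clusters_by_severity(l2, scores[1:6, , drop = FALSE])
  expect_identical(levels(out2$class), c("NoL", "H"))
  # equal means: deterministic across repeated calls
  eq <- matrix(rep(2, 8), 8, 1, dimnames = list(paste0("m", 1:8), NULL))
  le <- setNames(rep(1:2, 4), rownames(eq))
  expect_identical(
    order_clusters_by_severity(le, eq)$class,
    order_clusters_by_severity(le, eq)$class
  )
})

test_that("the fused SNF matrix is symmetric, non-negative and row-stochastic", {
  study <- simulate_study(tiny_config(seed = 3, features_per_layer = c(mrna = 5)))
  scores <- score_assays(study$assay_readouts, default_rubric(study$assay_readouts))
  m <- as.matrix(scores[, -1])
  rownames(m) <- scores$material
  views <- list(m[, 1:3], m[, 4:5], m[, 6:8])
  fused <- snf_fuse(views)
  expect_identical(unclass(fused), t(unclass(fused)))
  expect_true(all(fused >= 0))
  expect_lt(max(abs(rowSums(fused) - 1)), 1e-8)
  expect_identical(rownames(fused), scores$material)
})

test_that("duplicated identical views are a fixed point of the cross-diffusion", {
  x <- separated_clouds(n_per = 6, d = 3, gap = 5, seed = 7)
  cfg <- snf_config(k_neighbors = 4, t_iter = 10)
  f2 <- snf_fuse(list(x, x), cfg)
  f3 <- snf_fuse(list(x, x, x), cfg)
  expect_lt(max(abs(f2 - f3)), 1e-6)
  # independent single-view oracle: self-diffusion with the same operators
  w <- enmhazard:::snf_affinity(x, k_neighbors = 4)
  p <- enmhazard:::snf_normalize_full(w)
  s <- enmhazard:::snf_local(w, 4)
  for (t in 1:10) {
    p <- enmhazard:::snf_normalize_full(s %*% p %*% t(s))
    p <- (p + t(p)) / 2
  }
  oracle <- enmhazard:::sinkhorn_symmetric((p + t(p)) / 2)
  expect_lt(max(abs(f2 - oracle)), 1e-6)
})

test_that("snf_fuse validates its inputs", {
  x <- separated_clouds(n_per = 4, d = 3, gap = 5, seed = 8)
  expect_error(snf_fuse(list(x)), "2 views")
  y <- x
  rownames(y) <- rev(rownames(y))
  expect_error(snf_fuse(list(x, y)), "identical material ids")
  expect_error(snf_fuse(list(x, x), snf_config(k_neighbors = 50)), "k_neighbors")
})

test_that("block-structured views stay block-structured after fusion", {
  set.seed(9)
  n <- 8
  x <- rbind(
    matrix(rnorm(n * 3), n, 3),
    matrix(rnorm(n * 3, mean = 30), n, 3)
  )
  rownames(x) <- sprintf("M%02d", 1:(2 * n))
  fused <- snf_fuse(list(x, x + rnorm(length(x), sd = 0.1)),
    snf_config(k_neighbors = 3, t_iter = 10)
  )
  within <- c(fused[1:n, 1:n], fused[(n + 1):(2 * n), (n + 1):(2 * n)])
  across <- fused[1:n, (n + 1):(2 * n)]
  expect_lt(max(across), min(diag(fused)))
  expect_gt(sum(within), 100 * sum(across))
  # spectral cut at the block count recovers the blocks exactly
  lab <- cluster_int(fused, cbind(total = rowMeans(x)), n_clusters = 2, seed = 1)
  expect_identical(length(unique(lab$class[1:n])), 1L)
  expect_identical(length(unique(lab$class[(n + 1):(2 * n)])), 1L)
  expect_false(lab$class[1] == lab$class[n + 1])
})

test_that("INT grouping recovers planted classes from fused assay views", {
  hits <- vapply(1:20, function(s) {
    study <- simulate_study(tiny_config(
      seed = 100 + s, features_per_layer = c(mrna = 5),
      effect_size = 1.5
    ))
    scores <- score_assays(study$assay_readouts, default_rubric(study$assay_readouts))
    m <- as.matrix(scores[, -1])
    rownames(m) <- scores$material
    fused <- snf_fuse(list(m[, 1:3], m[, 4:5], m[, 6:8]))
    lab <- cluster_int(fused, m, n_clusters = 3, seed = 1)
    mean(as.character(lab$class) == as.character(study$materials$true_class))
  }, numeric(1))
  expect_gte(mean(hits), 0.8)
})

test_that("hazard labelings survive the TSV round trip", {
  lab <- label_neu(c(a = 0.2, b = 3, c = 50))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_labeling(lab, path)
  back <- read_labeling(path)
  expect_identical(as.character(back$class), as.character(lab$class))
  expect_identical(back$material, lab$material)
})
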