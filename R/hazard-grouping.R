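#' Fit a spherical Gaussian mixture model by EM
#'
#' Each mixture component has an isotropic covariance sigma^2 I. EM runs
#' from a random initialization (k distinct rows as means) until the
#' relative change in log-likelihood falls below `tol` or `max_iter` is hit.
#' Component collapse (an empty component) triggers an internal restart, up
#' to `max_restarts` attempts.
#'
#' @param x Numeric matrix or score tibble (rows = materials); ordinal score
#'   tables are treated as continuous.
#' @param k Number of components.
#' @param seed Integer seed for the initialization.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param var_floor Lower bound on component variances; by default 1% of
#'   the mean per-dimension variance of the data, which stops components
#'   from collapsing onto duplicated score rows (degenerate likelihood
#'   spikes) while leaving genuine clusters untouched.
#' @param max_restarts Retry budget on component collapse.
#' @return List with `loglik`, `weights`, `means` (k x d), `sigma2` (length
#'   k), `responsibilities`, `n_iter`, `converged`, `k`, `n`, `d`.
#' @export
fit_spherical_gmm <- function(x, k, seed = 1L, tol = 1e-6, max_iter = 500,
                              var_floor = NULL, max_restarts = 10) {
  m <- if (is.matrix(x)) x else as_layer_matrix(x)
  storage.mode(m) <- "double"
  n <- nrow(m)
  d <- ncol(m)
  var_floor <- var_floor %||% max(1e-6, 0.01 * mean(apply(m, 2, var)))
  if (k < 1) abort("k must be >= 1")
  if (k > n) abort("k cannot exceed the number of rows")
  if (any(!is.finite(m))) abort("data must be finite")

  if (k == 1) {
    mu <- matrix(colMeans(m), 1, d)
    s2 <- max(mean(sweep(m, 2, mu[1, ])^2), var_floor)
    ll <- sum(dnorm_sph(m, mu[1, ], s2))
    return(list(
      loglik = ll, weights = 1, means = mu, sigma2 = s2,
      responsibilities = matrix(1, n, 1), n_iter = 0L, converged = TRUE,
      k = 1L, n = n, d = d
    ))
  }

  set.seed(seed)
  for (attempt in seq_len(max_restarts)) {
    mu <- m[kmeanspp_init(m, k), , drop = FALSE]
    s2 <- rep(max(mean(apply(m, 2, var)), var_floor), k)
    w <- rep(1 / k, k)
    ll_old <- -Inf
    ok <- TRUE
    converged <- FALSE
    iter <- 0L
    r <- NULL
    while (iter < max_iter) {
      iter <- iter + 1L
      # E-step in log space
      logdens <- vapply(
        seq_len(k),
        function(j) log(w[j]) + dnorm_sph(m, mu[j, ], s2[j]),
        numeric(n)
      )
      mx <- apply(logdens, 1, max)
      lse <- mx + log(rowSums(exp(logdens - mx)))
      ll <- sum(lse)
      r <- exp(logdens - lse)
      nk <- colSums(r)
      if (any(nk < 1e-8)) {
        ok <- FALSE
        break
      }
      # M-step
      w <- nk / n
      mu <- crossprod(r, m) / nk
      s2 <- vapply(seq_len(k), function(j) {
        sq <- rowSums(sweep(m, 2, mu[j, ])^2)
        max(sum(r[, j] * sq) / (d * nk[j]), var_floor)
      }, numeric(1))
      if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
        converged <- TRUE
        ll_old <- ll
        break
      }
      ll_old <- ll
    }
    if (ok) {
      return(list(
        loglik = ll_old, weights = w, means = mu, sigma2 = s2,
        responsibilities = r, n_iter = iter, converged = converged,
        k = as.integer(k), n = n, d = d
      ))
    }
  }
  abort("GMM component collapsed on every restart; data may be degenerate")
}

# k-means++ seeding: first center uniform, later centers drawn with
# probability proportional to squared distance from the nearest chosen one.
kmeanspp_init <- function(m, k) {
  n <- nrow(m)
  centers <- sample(n, 1)
  if (k > 1) {
    d2 <- rowSums(sweep(m, 2, m[centers, ])^2)
    for (j in 2:k) {
      prob <- d2 / sum(d2)
      if (all(d2 == 0)) prob <- rep(1 / n, n)
      centers <- c(centers, sample(n, 1, prob = prob))
      d2 <- pmin(d2, rowSums(sweep(m, 2, m[centers[j], ])^2))
    }
  }
  centers
}

# log density of an isotropic Gaussian, rowwise
dnorm_sph <- function(m, mu, s2) {
  d <- ncol(m)
  -0.5 * d * log(2 * pi * s2) - rowSums(sweep(m, 2, mu)^2) / (2 * s2)
}

#' Bayesian information criterion
#'
#' `BIC = -2 loglik + n_params log(n_obs)`; lower is better. For a spherical
#' Gaussian mixture with k components in d dimensions the parameter count is
#' `k d` means + `k` variances + `k - 1` free weights.
#'
#' @param loglik Maximized log-likelihood.
#' @param n_params Number of free parameters.
#' @param n_obs Number of observations.
#' @return Scalar BIC.
#' @export
#' @examples
#' bic_score(-100, 10, 31)
bic_score <- function(loglik, n_params, n_obs) {
  if (n_obs < 1) abort("n_obs must be >= 1")
  -2 * loglik + n_params * log(n_obs)
}

spherical_gmm_n_params <- function(k, d) k * d + k + (k - 1)

#' Assess the number of hazard clusters by BIC restart stability
#'
#' For each candidate k, fits the spherical GMM from `n_restarts` random
#' initializations and records the full BIC distribution. A wide BIC spread
#' signals sensitivity to initialization (overfitting risk); the selection
#' rule picks the smallest k whose mean BIC is within one standard
#' deviation of the best mean BIC and whose BIC coefficient of variation is
#' below `cv_cap` — an operational form of the accuracy/stability trade-off.
#'
#' @param scores Score table (tibble or matrix), treated as continuous.
#' @param k_range Candidate cluster numbers (default 2:6).
#' @param n_restarts Random restarts per k (default 250).
#' @param seed Integer seed.
#' @param cv_cap Stability cap on the BIC coefficient of variation.
#' @return An object of class `bic_assessment`: list with `samples`
#'   (tibble k/restart/loglik/bic), `summary` (per-k mean, sd, var, cv),
#'   and `k_selected`.
#' @export
assess_k <- function(scores, k_range = 2:6, n_restarts = 250, seed = 1L,
                     cv_cap = 0.05) {
  m <- if (is.matrix(scores)) scores else as_layer_matrix(scores)
  if (any(apply(m, 2, var) == 0) && all(apply(m, 2, var) == 0)) {
    abort("degenerate data: zero variance in every column")
  }
  if (max(k_range) > nrow(m) - 1 || min(k_range) < 2) {
    abort("k_range must lie within [2, n_materials - 1]")
  }
  samples <- purrr::map_dfr(k_range, function(k) {
    purrr::map_dfr(seq_len(n_restarts), function(r) {
      fit <- fit_spherical_gmm(m, k, seed = derive_seed(seed, sprintf("k%d_r%d", k, r)))
      tibble(
        k = k, restart = r, loglik = fit$loglik,
        bic = bic_score(fit$loglik, spherical_gmm_n_params(k, ncol(m)), nrow(m))
      )
    })
  })
  summary <- samples |>
    dplyr::group_by(k) |>
    dplyr::summarise(
      mean_bic = mean(.data$bic),
      sd_bic = sd(.data$bic),
      var_bic = var(.data$bic),
      cv_bic = sd(.data$bic) / abs(mean(.data$bic)),
      best_bic = min(.data$bic),
      best_loglik = max(.data$loglik),
      .groups = "drop"
    )
  i_min <- which.min(summary$mean_bic)
  thr <- summary$mean_bic[i_min] + summary$sd_bic[i_min]
  candidates <- summary$k[summary$mean_bic <= thr & summary$cv_bic <= cv_cap]
  k_selected <- if (length(candidates) > 0) min(candidates) else summary$k[i_min]
  structure(
    list(samples = samples, summary = summary, k_selected = as.integer(k_selected)),
    class = "bic_assessment"
  )
}

#' @export
print.bic_assessment <- function(x, ...) {
  cat("<bic_assessment> k selected:", x$k_selected, "\n")
  print(x$summary)
  invisible(x)
}

#' Cluster materials by cytotoxicity score profiles (CYT task)
#'
#' k-means on the homogenized cytotoxicity score table, with clusters
#' renamed to ordered hazard classes by mean total score
#' (via [order_clusters_by_severity()]).
#'
#' @param scores Score table (tibble or matrix).
#' @param k Number of hazard classes (default 3).
#' @param seed Integer seed.
#' @param nstart k-means restarts.
#' @return A hazard labeling tibble (task `"CYT"`).
#' @export
cluster_cyt <- function(scores, k = 3, seed = 1L, nstart = 25) {
  m <- if (is.matrix(scores)) scores else as_layer_matrix(scores)
  if (k > nrow(unique(as.data.frame(m)))) {
    abort("k exceeds the number of distinct score profiles")
  }
  set.seed(seed)
  km <- kmeans(m, centers = k, nstart = nstart)
  order_clusters_by_severity(
    setNames(km$cluster, rownames(m)), m,
    task = "CYT", provenance = sprintf("kmeans k=%d seed=%d", k, seed)
  )
}

#' Similarity network fusion configuration
#'
#' @param k_neighbors Neighborhood size for the local affinity; default
#'   `max(3, ceiling(n / 10))` when `NULL`.
#' @param alpha Kernel bandwidth factor of the scaled exponential kernel.
#' @param t_iter Number of cross-diffusion iterations.
#' @param n_clusters Number of hazard classes cut from the fused network.
#' @return A list of class `snf_config`.
#' @export
snf_config <- function(k_neighbors = NULL, alpha = 0.5, t_iter = 20, n_clusters = 3) {
  if (t_iter < 1) abort("t_iter must be >= 1")
  if (alpha <= 0) abort("alpha must be positive")
  structure(
    list(
      k_neighbors = k_neighbors, alpha = alpha,
      t_iter = as.integer(t_iter), n_clusters = as.integer(n_clusters)
    ),
    class = "snf_config"
  )
}

# Scaled exponential-kernel affinity of one view (Euclidean distances,
# locally adaptive bandwidth from the k nearest neighbors).
snf_affinity <- function(m, k_neighbors, alpha = 0.5) {
  d <- as.matrix(dist(m))
  n <- nrow(d)
  kn <- min(k_neighbors, n - 1)
  mean_knn <- apply(d, 1, function(r) mean(sort(r)[2:(kn + 1)]))
  eps <- (outer(mean_knn, mean_knn, "+") + d) / 3
  eps[eps <= 0] <- .Machine$double.eps
  w <- exp(-d^2 / (2 * (alpha * eps)^2))
  (w + t(w)) / 2
}

# Full-kernel row normalization: off-diagonal mass 1/2, diagonal 1/2.
snf_normalize_full <- function(w) {
  p <- w
  diag(p) <- 0
  rs <- rowSums(p)
  rs[rs == 0] <- 1
  p <- p / (2 * rs)
  diag(p) <- 0.5
  p
}

# kNN-sparsified, row-normalized local affinity.
snf_local <- function(w, k_neighbors) {
  n <- nrow(w)
  kn <- min(k_neighbors, n - 1)
  s <- matrix(0, n, n, dimnames = dimnames(w))
  for (i in seq_len(n)) {
    ord <- order(w[i, -i], decreasing = TRUE)
    nbr <- seq_len(n)[-i][ord[seq_len(kn)]]
    s[i, nbr] <- w[i, nbr] / sum(w[i, nbr])
  }
  s
}

# Symmetric Sinkhorn scaling: D^{-1/2} A D^{-1/2} iterated until rows (and,
# by symmetry, columns) sum to 1. Preserves symmetry exactly.
sinkhorn_symmetric <- function(a, tol = 1e-10, max_iter = 1000) {
  for (i in seq_len(max_iter)) {
    r <- rowSums(a)
    if (max(abs(r - 1)) < tol) break
    s <- 1 / sqrt(r)
    a <- a * outer(s, s)
  }
  (a + t(a)) / 2
}

#' Fuse multiple assay views by similarity network fusion
#'
#' Builds a scaled-exponential-kernel affinity per view, forms the
#' row-normalized full matrix and the k-nearest-neighbor local matrix, and
#' runs the cross-diffusion update for `t_iter` iterations: each view's full
#' matrix is replaced by `S %*% mean(other views' full matrices) %*% t(S)`,
#' renormalized and symmetrized. The final fused matrix is the average of
#' the views' diffused matrices, made exactly symmetric and doubly
#' stochastic by symmetric Sinkhorn scaling (the package's chosen output
#' normalization), so rows sum to 1 and the matrix is symmetric.
#'
#' @param views List (>= 2) of materials-by-features matrices or tibbles
#'   sharing identical material ids in identical order.
#' @param config An [snf_config()].
#' @return Fused affinity matrix (class `snf_fused`), materials by
#'   materials, symmetric, non-negative, rows summing to 1.
#' @export
snf_fuse <- function(views, config = snf_config()) {
  if (length(views) < 2) abort("need at least 2 views")
  mats <- lapply(views, function(v) if (is.matrix(v)) v else as_layer_matrix(v))
  ids <- rownames(mats[[1]])
  for (v in mats[-1]) {
    if (!identical(rownames(v), ids)) abort("views must share identical material ids")
  }
  n <- length(ids)
  kn <- config$k_neighbors %||% max(3, ceiling(n / 10))
  if (kn >= n) abort("k_neighbors must be smaller than the number of materials")

  w <- lapply(mats, snf_affinity, k_neighbors = kn, alpha = config$alpha)
  p <- lapply(w, snf_normalize_full)
  s <- lapply(w, snf_local, k_neighbors = kn)
  nv <- length(p)
  for (t in seq_len(config$t_iter)) {
    p_new <- vector("list", nv)
    for (v in seq_len(nv)) {
      pbar <- Reduce(`+`, p[-v]) / (nv - 1)
      upd <- s[[v]] %*% pbar %*% t(s[[v]])
      upd <- snf_normalize_full(upd)
      p_new[[v]] <- (upd + t(upd)) / 2
    }
    p <- p_new
  }
  fused <- Reduce(`+`, p) / nv
  fused <- sinkhorn_symmetric((fused + t(fused)) / 2)
  dimnames(fused) <- list(ids, ids)
  structure(fused, class = c("snf_fused", "matrix", "array"))
}

# Connected components of the positive-support graph of w.
graph_components <- function(w, eps = 1e-12) {
  n <- nrow(w)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nbr <- which(w[v, ] > eps & is.na(comp))
      comp[nbr] <- cur
      queue <- c(queue, nbr)
    }
  }
  comp
}

# Spectral clustering on an affinity matrix: symmetric normalized Laplacian,
# leading eigenvectors, row-normalized, k-means.
spectral_cluster <- function(w, k, seed = 1L, nstart = 25) {
  diag_w <- diag(w)
  comp <- graph_components(w)
  n_comp <- max(comp)
  if (n_comp >= k) {
    # disconnected-graph fallback: components are the clusters
    return(comp)
  }
  d <- rowSums(w)
  d[d <= 0] <- .Machine$double.eps
  l <- w / sqrt(outer(d, d))
  e <- eigen((l + t(l)) / 2, symmetric = TRUE)
  u <- e$vectors[, seq_len(k), drop = FALSE]
  u <- u / pmax(sqrt(rowSums(u^2)), 1e-12)
  set.seed(seed)
  kmeans(u, centers = k, nstart = nstart)$cluster
}

#' Cluster the fused network into hazard classes (INT task)
#'
#' Spectral clustering on the fused affinity from [snf_fuse()]; clusters are
#' then renamed to ordered hazard classes by mean total toxicity score. When
#' the affinity graph is disconnected into at least `n_clusters` components,
#' the components themselves are used as clusters.
#'
#' @param fused Fused affinity matrix from [snf_fuse()].
#' @param scores Score table used to order clusters by severity.
#' @param n_clusters Number of hazard classes (default 3).
#' @param seed Integer seed.
#' @return A hazard labeling tibble (task `"INT"`).
#' @export
cluster_int <- function(fused, scores, n_clusters = 3, seed = 1L) {
  cl <- spectral_cluster(unclass(fused), n_clusters, seed = seed)
  m <- if (is.matrix(scores)) scores else as_layer_matrix(scores)
  order_clusters_by_severity(
    setNames(cl, rownames(fused)), m[rownames(fused), , drop = FALSE],
    task = "INT",
    provenance = sprintf("snf+spectral k=%d seed=%d", n_clusters, seed)
  )
}

#' Rename clusters to ordered hazard classes by severity
#'
#' Clusters are ranked by the mean total toxicity score of their members;
#' the lowest becomes `NoL`, the highest `H`. Ties in mean score are broken
#' deterministically by cluster size (larger first), then by cluster id.
#'
#' @param labels Integer cluster assignment named by material.
#' @param scores Score matrix or tibble aligned to the same materials.
#' @param task Task tag stored on the labeling (`"CYT"`, `"INT"`, `"NEU"`).
#' @param provenance Free-text provenance stored on the labeling.
#' @return A hazard labeling tibble with ordered class levels.
#' @export
order_clusters_by_severity <- function(labels, scores, task = "CYT",
                                       provenance = "manual") {
  m <- if (is.matrix(scores)) scores else as_layer_matrix(scores)
  ids <- names(labels)
  if (is.null(ids)) abort("labels must be named by material")
  total <- rowSums(m[ids, , drop = FALSE])
  cl_ids <- sort(unique(labels))
  stats_tbl <- tibble(
    cluster = cl_ids,
    mean_score = vapply(cl_ids, function(c) mean(total[labels == c]), numeric(1)),
    size = vapply(cl_ids, function(c) sum(labels == c), numeric(1))
  ) |>
    dplyr::arrange(.data$mean_score, dplyr::desc(.data$size), .data$cluster)
  k <- length(cl_ids)
  lv <- hazard_levels(k)
  mapping <- setNames(lv, stats_tbl$cluster)
  new_hazard_labeling(
    ids,
    factor(mapping[as.character(labels)], levels = lv, ordered = TRUE),
    task = task, provenance = provenance
  )
}

#' Write/read a hazard labeling as two-column TSV
#'
#' @param labeling A hazard labeling tibble.
#' @param path File path.
#' @return `read_labeling` returns the labeling; `write_labeling` returns
#'   `path` invisibly.
#' @export
write_labeling <- function(labeling, path) {
  readr::write_tsv(tibble(
    material = labeling$material,
    class = as.character(labeling$class)
  ), path)
  invisible(path)
}

#' @rdname write_labeling
#' @param task Task tag to attach on read.
#' @export
read_labeling <- function(path, task = "NEU") {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  lv <- intersect(c("NoL", "M", "MH", "H"), unique(x$class))
  new_hazard_labeling(
    as.character(x$material),
    factor(x$class, levels = lv, ordered = TRUE),
    task = task, provenance = paste0("file:", path)
  )
}
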