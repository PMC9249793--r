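#' Configure a synthetic nanomaterial study
#'
#' Builds a validated configuration for [simulate_study()]. The defaults
#' emulate a grid-designed panel of 31 engineered nanomaterials (ENMs)
#' profiled across several molecular layers (mRNA, miRNA, proteomics,
#' protein corona, physicochemical properties), with three latent hazard
#' classes, a small number of planted class-discriminative features per
#' layer, continuous assay readouts that increase with latent hazard, and
#' bronchoalveolar-lavage (BAL) neutrophil counts whose per-class
#' log-normal distributions straddle the regulatory cut-points 1 and 10.
#'
#' @param n_materials Number of materials in the panel.
#' @param n_classes Number of latent hazard classes.
#' @param features_per_layer Named integer vector, features per data layer.
#' @param n_informative Planted discriminative features per layer; must not
#'   exceed any layer's feature count.
#' @param effect_size Standardized mean shift between adjacent classes on
#'   planted features (unitless; values are already on a standardized scale).
#' @param noise_sd Residual standard deviation of every feature.
#' @param class_proportions Simplex vector of class prevalences.
#' @param rho Optional equicorrelation among the planted features of a layer
#'   (co-regulated block); 0 keeps features independent.
#' @param neutrophil_params Data frame with columns `meanlog`, `sdlog`, one
#'   row per class (severity ascending), parameterizing per-class log-normal
#'   BAL neutrophil counts.
#' @param endpoints Character vector of in vitro assay endpoint names.
#' @param assay_gap Mean shift of assay readouts between adjacent classes.
#' @param seed Integer master seed; per-layer streams are derived from it.
#'
#' @return An object of class `sim_config` (validated list).
#' @seealso [simulate_study()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$n_materials
sim_config <- function(n_materials = 31,
                       n_classes = 3,
                       features_per_layer = c(
                         mrna = 200, mirna = 80, proteomics = 120,
                         corona = 60, physchem = 15
                       ),
                       n_informative = 5,
                       effect_size = 1,
                       noise_sd = 1,
                       class_proportions = rep(1 / n_classes, n_classes),
                       rho = 0,
                       neutrophil_params = NULL,
                       endpoints = c(
                         "viability_thp1", "viability_beas2b", "viability_jurkat",
                         "dna_damage", "chromosome_damage",
                         "cytokine_il1b", "cytokine_tnf", "cytokine_il6"
                       ),
                       assay_gap = 1.5,
                       seed = 1L) {
  if (is.null(neutrophil_params)) {
    # class log-normal locations chosen so NoL mass sits below 1, M between
    # 1 and 10, H above 10 (cell counts straddle both thresholds)
    neutrophil_params <- tibble(
      meanlog = c(log(0.3), log(3), log(30))[seq_len(min(n_classes, 3))],
      sdlog = rep(0.5, min(n_classes, 3))
    )
    if (n_classes > 3) {
      extra <- n_classes - 3
      neutrophil_params <- dplyr::bind_rows(
        neutrophil_params,
        tibble(meanlog = log(30) + seq_len(extra), sdlog = rep(0.5, extra))
      )
    }
  }
  cfg <- structure(
    list(
      n_materials = as.integer(n_materials),
      n_classes = as.integer(n_classes),
      features_per_layer = features_per_layer,
      n_informative = as.integer(n_informative),
      effect_size = effect_size,
      noise_sd = noise_sd,
      class_proportions = class_proportions,
      rho = rho,
      neutrophil_params = as_tibble(neutrophil_params),
      endpoints = endpoints,
      assay_gap = assay_gap,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  err <- function(field, msg) abort(paste0("invalid sim_config$", field, ": ", msg))
  if (cfg$n_materials < 1) err("n_materials", "must be positive")
  if (cfg$n_classes < 1) err("n_classes", "must be positive")
  if (length(cfg$features_per_layer) < 1 || any(cfg$features_per_layer < 1)) {
    err("features_per_layer", "all layer sizes must be positive")
  }
  if (is.null(names(cfg$features_per_layer)) || any(names(cfg$features_per_layer) == "")) {
    err("features_per_layer", "layers must be named")
  }
  if (cfg$n_informative < 0) err("n_informative", "must be non-negative")
  if (any(cfg$n_informative > cfg$features_per_layer)) {
    err("n_informative", "exceeds the feature count of at least one layer")
  }
  if (length(cfg$class_proportions) != cfg$n_classes) {
    err("class_proportions", "length must equal n_classes")
  }
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9 || any(cfg$class_proportions <= 0)) {
    err("class_proportions", "must be a positive vector summing to 1 (tol 1e-9)")
  }
  if (cfg$noise_sd <= 0) err("noise_sd", "must be positive")
  if (cfg$rho < 0 || cfg$rho >= 1) err("rho", "must be in [0, 1)")
  if (nrow(cfg$neutrophil_params) != cfg$n_classes) {
    err("neutrophil_params", "one row per class required")
  }
  invisible(cfg)
}

#' Simulate a complete synthetic nanomaterial study
#'
#' Generates a multi-layer study with known ground truth: per-layer feature
#' matrices with `n_informative` planted features whose class-conditional
#' means are shifted by `effect_size` between adjacent hazard classes
#' (remaining features are class-independent noise), continuous assay
#' readouts that increase monotonically with the latent class, and BAL
#' neutrophil counts drawn from per-class log-normals. All randomness flows
#' from the master seed through documented per-layer streams (R's default
#' Mersenne-Twister generator), so a fixed seed gives bit-identical output.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_study`: a list with
#'   \describe{
#'     \item{panel}{named list of layer tibbles (`material` + feature columns)}
#'     \item{materials}{tibble of material id, true class and BAL neutrophil count}
#'     \item{truth_features}{named list of planted feature ids per layer}
#'     \item{assay_readouts}{tibble of material by endpoint continuous readouts}
#'     \item{config}{the generating configuration}
#'   }
#' @export
#' @examples
#' study <- simulate_study(sim_config(seed = 1))
#' dplyr::count(study$materials, true_class)
simulate_study <- function(config) {
  validate_sim_config(config)
  n <- config$n_materials
  k <- config$n_classes

  set.seed(derive_seed(config$seed, "design"))
  ids <- sprintf("ENM%02d", seq_len(n))
  # balanced-as-possible class assignment honouring class_proportions
  base <- floor(config$class_proportions * n)
  rem <- n - sum(base)
  if (rem > 0) {
    top_up <- order(config$class_proportions * n - base, decreasing = TRUE)[seq_len(rem)]
    base[top_up] <- base[top_up] + 1
  }
  classes <- sample(rep(seq_len(k), times = base))

  panel <- list()
  truth_features <- list()
  for (layer in names(config$features_per_layer)) {
    p <- config$features_per_layer[[layer]]
    set.seed(derive_seed(config$seed, paste0("layer:", layer)))
    feat_ids <- sprintf("%s_f%04d", layer, seq_len(p))
    informative <- if (config$n_informative > 0) {
      sort(sample(p, config$n_informative))
    } else {
      integer(0)
    }
    x <- matrix(rnorm(n * p, sd = config$noise_sd), n, p,
      dimnames = list(ids, feat_ids)
    )
    if (length(informative) > 0 && config$rho > 0) {
      # equicorrelated block among planted features: shared factor construction
      g <- rnorm(n)
      x[, informative] <- sqrt(config$rho) * g * config$noise_sd +
        sqrt(1 - config$rho) * x[, informative]
    }
    if (length(informative) > 0) {
      # class c mean shift: (c-1) * effect_size on the standardized scale
      shift <- (classes - 1) * config$effect_size * config$noise_sd
      x[, informative] <- x[, informative] + shift
    }
    panel[[layer]] <- layer_as_tibble(x)
    truth_features[[layer]] <- feat_ids[informative]
  }

  set.seed(derive_seed(config$seed, "assays"))
  assay <- matrix(
    rnorm(n * length(config$endpoints), sd = config$noise_sd),
    n, length(config$endpoints),
    dimnames = list(ids, config$endpoints)
  )
  assay <- assay + (classes - 1) * config$assay_gap
  assay_readouts <- layer_as_tibble(assay)

  set.seed(derive_seed(config$seed, "bal"))
  np <- config$neutrophil_params
  bal <- rlnorm(n, meanlog = np$meanlog[classes], sdlog = np$sdlog[classes])

  structure(
    list(
      panel = panel,
      materials = tibble(
        material = ids,
        true_class = factor(hazard_levels(k)[classes],
          levels = hazard_levels(k), ordered = TRUE
        ),
        neutrophil_count = bal
      ),
      truth_features = truth_features,
      assay_readouts = assay_readouts,
      config = config
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>", x$config$n_materials, "materials,",
    x$config$n_classes, "classes\n"
  )
  cat("  layers:", paste(
    sprintf("%s(%d)", names(x$config$features_per_layer), x$config$features_per_layer),
    collapse = ", "
  ), "\n")
  invisible(x)
}

#' Simulate external expression exposures for prediction testing
#'
#' Draws new expression rows from the generative model of one layer of a
#' synthetic study, mimicking external transcriptome datasets: one or more
#' exposures, each measured at several doses, with only a fraction of the
#' layer's feature ids retained (to exercise feature-id matching in the
#' prediction ensemble).
#'
#' @param study A [simulate_study()] result.
#' @param n_doses Number of dose rows per exposure.
#' @param feature_subset_fraction Fraction of the layer's features retained
#'   (in (0, 1]).
#' @param seed Integer seed.
#' @param layer Layer to draw from (default `"mrna"`).
#' @param classes True hazard class of each exposure (character vector of
#'   class names; one exposure is generated per element). Defaults to one
#'   exposure per class.
#' @return A list with `expression` (tibble: `exposure`, `dose`, features)
#'   and `metadata` (tibble: `exposure`, `dose`, `true_class`).
#' @export
simulate_external_exposure <- function(study, n_doses = 3,
                                       feature_subset_fraction = 1,
                                       seed = 1L,
                                       layer = "mrna",
                                       classes = NULL) {
  stopifnot(inherits(study, "synthetic_study"))
  if (feature_subset_fraction <= 0 || feature_subset_fraction > 1) {
    abort("feature_subset_fraction must be in (0, 1]")
  }
  if (!layer %in% names(study$panel)) abort(paste0("unknown layer: ", layer))
  cfg <- study$config
  lv <- hazard_levels(cfg$n_classes)
  classes <- classes %||% lv
  if (!all(classes %in% lv)) abort("unknown class name in `classes`")

  m <- as_layer_matrix(study$panel[[layer]])
  p <- ncol(m)
  keep_n <- round(feature_subset_fraction * p)
  if (keep_n < 1) abort("requested feature subset is empty")

  set.seed(derive_seed(seed, paste0("external:", layer)))
  keep <- if (keep_n == p) seq_len(p) else sort(sample(p, keep_n))
  feat_ids <- colnames(m)[keep]
  informative <- match(study$truth_features[[layer]], colnames(m))

  rows <- list()
  meta <- list()
  for (e in seq_along(classes)) {
    cls_idx <- match(classes[e], lv)
    for (d in seq_len(n_doses)) {
      x <- rnorm(p, sd = cfg$noise_sd)
      if (length(informative) > 0) {
        x[informative] <- x[informative] + (cls_idx - 1) * cfg$effect_size * cfg$noise_sd
      }
      rows[[length(rows) + 1]] <- x[keep]
      meta[[length(meta) + 1]] <- tibble(
        exposure = sprintf("EXP%02d", e), dose = d, true_class = classes[e]
      )
    }
  }
  expr <- do.call(rbind, rows)
  colnames(expr) <- feat_ids
  metadata <- dplyr::bind_rows(meta)
  list(
    expression = dplyr::bind_cols(metadata[c("exposure", "dose")], as_tibble(expr)),
    metadata = metadata
  )
}

#' Write a synthetic study to delimited text files
#'
#' Each layer is written as a TSV matrix (first column `material`, header =
#' feature ids), plus a metadata table (material, true class, neutrophil
#' count), the assay readouts, and a `manifest.tsv` listing all paths.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a tibble manifest of the written files.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  for (layer in names(study$panel)) {
    f <- file.path(dir, paste0("layer_", layer, ".tsv"))
    readr::write_tsv(study$panel[[layer]], f)
    paths <- c(paths, setNames(f, paste0("layer_", layer)))
  }
  f <- file.path(dir, "materials.tsv")
  readr::write_tsv(study$materials, f)
  paths <- c(paths, setNames(f, "materials"))
  f <- file.path(dir, "assay_readouts.tsv")
  readr::write_tsv(study$assay_readouts, f)
  paths <- c(paths, setNames(f, "assay_readouts"))
  manifest <- tibble(name = names(paths), path = unname(paths))
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}
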