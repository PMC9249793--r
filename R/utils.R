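# Shared internal helpers: seed streams, hazard level sets, layer coercion.

# Deterministic child seed from a master seed and a character stream label.
# Keeps results reproducible while giving independent-looking streams per
# layer/restart. Always below 2^31 - 1.
derive_seed <- function(seed, label) {
  codes <- utf8ToInt(paste0(label))
  h <- as.double(seed %% 2147483647L)
  for (c in codes) h <- (h * 31 + c) %% 2147483629
  as.integer(h)
}

# Ordered hazard class names for k groups (severity ascending).
hazard_levels <- function(k) {
  switch(as.character(k),
    "2" = c("NoL", "H"),
    "3" = c("NoL", "M", "H"),
    "4" = c("NoL", "M", "MH", "H"),
    paste0("S", seq_len(k))
  )
}

# Coerce a layer (tibble with `material` column, or matrix with rownames)
# to a numeric matrix with material row names.
as_layer_matrix <- function(layer) {
  if (is.matrix(layer)) {
    if (is.null(rownames(layer))) abort("matrix layer must have material row names")
    storage.mode(layer) <- "double"
    return(layer)
  }
  if (!is.data.frame(layer)) abort("layer must be a data frame or matrix")
  if (!"material" %in% names(layer)) abort("layer data frame must have a `material` column")
  ids <- as.character(layer$material)
  m <- as.matrix(layer[setdiff(names(layer), "material")])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

layer_as_tibble <- function(m) {
  dplyr::bind_cols(tibble(material = rownames(m)), as_tibble(m))
}

# Extract a named class factor from a hazard labeling (tibble with
# material/class columns, or a named factor/character vector).
labeling_classes <- function(labeling) {
  if (is.data.frame(labeling)) {
    if (!all(c("material", "class") %in% names(labeling))) {
      abort("labeling must have `material` and `class` columns")
    }
    return(setNames(factor(labeling$class), as.character(labeling$material)))
  }
  if (is.null(names(labeling))) abort("labeling vector must be named by material")
  setNames(factor(labeling), names(labeling))
}

# Align a labeling to the rows of a layer matrix; error on mismatch.
align_labels <- function(m, labeling) {
  cls <- labeling_classes(labeling)
  missing <- setdiff(rownames(m), names(cls))
  if (length(missing) > 0) {
    abort(paste0("labeling missing materials: ", paste(head(missing, 5), collapse = ", ")))
  }
  droplevels(cls[rownames(m)])
}

# Mean and two-sided 95% t-interval over a small vector of repeat estimates.
t_ci <- function(x, level = 0.95) {
  n <- length(x)
  m <- mean(x)
  if (n < 2 || sd(x) == 0) return(c(mean = m, lo = m, hi = m))
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd(x) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half)
}

`%||%` <- rlang::`%||%`
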