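#' Build a scoring rubric for assay homogenization
#'
#' A rubric maps each continuous assay endpoint onto an ordinal toxicity
#' score from 1 (no toxicity) to 6 (highest toxicity) through five strictly
#' increasing bin edges. Bins are half-open and lower-inclusive on the toxic
#' side: a readout equal to an edge falls in the more severe bin, the same
#' boundary convention as the neutrophil rule (1 <= count < 10 is medium).
#'
#' @param endpoints Character vector of endpoint names.
#' @param edges Either a single numeric vector of 5 strictly increasing
#'   finite edges applied to all endpoints, or a named list of such vectors
#'   (one per endpoint).
#' @param direction `"increasing"` if larger readouts are more toxic,
#'   `"decreasing"` for inverse endpoints (e.g. viability); recycled.
#' @return A tibble of class `scoring_rubric` with columns `endpoint`,
#'   `direction` and a list-column `edges`.
#' @seealso [default_rubric()], [score_assays()]
#' @export
scoring_rubric <- function(endpoints, edges, direction = "increasing") {
  if (!is.list(edges)) edges <- setNames(rep(list(edges), length(endpoints)), endpoints)
  direction <- rep(direction, length.out = length(endpoints))
  for (e in endpoints) {
    v <- edges[[e]]
    if (is.null(v)) abort(paste0("no edges supplied for endpoint ", e))
    if (length(v) != 5 || any(!is.finite(v)) || any(diff(v) <= 0)) {
      abort(paste0("endpoint ", e, ": edges must be 5 strictly increasing finite values"))
    }
  }
  if (!all(direction %in% c("increasing", "decreasing"))) {
    abort("direction must be 'increasing' or 'decreasing'")
  }
  structure(
    tibble(endpoint = endpoints, direction = direction, edges = edges[endpoints]),
    class = c("scoring_rubric", class(tibble()))
  )
}

#' Default rubric estimated from a reference panel
#'
#' The published rubric's exact cell values live outside the main analysis
#' record, so the default derives edges from data: the five interior
#' sextile quantiles of each endpoint's readouts in a reference panel, giving
#' six equal-mass severity bins. Ties among quantiles are broken by adding
#' a vanishing increment so edges stay strictly monotone.
#'
#' @param readouts Tibble of reference readouts (`material` + endpoint columns).
#' @param direction Direction flag(s) as in [scoring_rubric()].
#' @return A `scoring_rubric`.
#' @export
default_rubric <- function(readouts, direction = "increasing") {
  m <- as_layer_matrix(readouts)
  edges <- lapply(colnames(m), function(ep) {
    q <- unname(quantile(m[, ep], probs = seq_len(5) / 6, type = 7))
    # enforce strict monotonicity on tied quantiles
    eps <- max(diff(range(m[, ep])), 1) * 1e-9
    for (i in seq_along(q)[-1]) if (q[i] <= q[i - 1]) q[i] <- q[i - 1] + eps
    q
  })
  names(edges) <- colnames(m)
  scoring_rubric(colnames(m), edges, direction)
}

#' Score one endpoint's readouts on the 1-6 ordinal scale
#'
#' @param readouts Numeric vector of finite assay readouts.
#' @param edges Five strictly increasing finite bin edges.
#' @param direction `"increasing"` (higher readout is more toxic) or
#'   `"decreasing"`.
#' @return Integer vector of scores in 1..6; 1 means no toxicity, 6 highest.
#' @details Missing or non-finite readouts raise an error rather than being
#'   imputed: a silent score of 1 would bias downstream grouping toward
#'   "no toxicity".
#' @export
#' @examples
#' score_endpoint(c(5, 25, 99), edges = c(10, 20, 30, 40, 50))
score_endpoint <- function(readouts, edges, direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  if (any(!is.finite(readouts))) {
    abort("readouts contain missing/non-finite values; supply complete assay data")
  }
  if (length(edges) != 5 || any(!is.finite(edges)) || any(diff(edges) <= 0)) {
    abort("edges must be 5 strictly increasing finite values")
  }
  if (direction == "decreasing") {
    readouts <- -readouts
    edges <- sort(-edges)
  }
  # lower-inclusive on the toxic side: readout == edge enters the severer bin
  vapply(readouts, function(x) 1L + sum(x >= edges), integer(1))
}

#' Homogenize an assay readout table into a toxicity score table
#'
#' @param readouts Tibble (`material` + endpoint columns) of continuous
#'   readouts.
#' @param rubric A [scoring_rubric()] covering every endpoint.
#' @return A tibble (`material` + endpoint columns) of integer scores in
#'   1..6, classed `tox_score_table`.
#' @export
score_assays <- function(readouts, rubric) {
  m <- as_layer_matrix(readouts)
  missing <- setdiff(colnames(m), rubric$endpoint)
  if (length(missing) > 0) {
    abort(paste0("rubric lacks endpoints: ", paste(missing, collapse = ", ")))
  }
  scored <- vapply(colnames(m), function(ep) {
    i <- match(ep, rubric$endpoint)
    score_endpoint(m[, ep], rubric$edges[[i]], rubric$direction[i])
  }, integer(nrow(m)))
  scored <- matrix(scored,
    nrow = nrow(m),
    dimnames = list(rownames(m), colnames(m))
  )
  out <- layer_as_tibble(scored)
  class(out) <- c("tox_score_table", class(out))
  out
}

#' Neutrophil count thresholds for in vivo hazard labels
#'
#' @param t_low Boundary below which counts are no-to-low hazard (default 1).
#' @param t_high Boundary at or above which counts are high hazard (default 10).
#' @return A list of class `neu_thresholds`.
#' @export
neu_thresholds <- function(t_low = 1, t_high = 10) {
  if (!(t_low > 0 && t_low < t_high)) abort("need 0 < t_low < t_high")
  structure(list(t_low = t_low, t_high = t_high), class = "neu_thresholds")
}

#' Assign in vivo (NEU) hazard labels from BAL neutrophil counts
#'
#' Materials are labeled no-to-low (`NoL`) when the count is below `t_low`,
#' medium (`M`) when `t_low <= count < t_high`, and high (`H`) when the
#' count is at or above `t_high`.
#'
#' @param counts Either a tibble with `material` and `neutrophil_count`
#'   columns, or a numeric vector of counts (optionally named by material).
#' @param thresholds A [neu_thresholds()].
#' @return A hazard labeling tibble (`material`, `class`) with ordered
#'   classes `NoL < M < H`; attributes record the task (`"NEU"`) and
#'   provenance.
#' @export
#' @examples
#' label_neu(c(a = 0.5, b = 1, c = 10))
label_neu <- function(counts, thresholds = neu_thresholds()) {
  if (is.data.frame(counts)) {
    ids <- as.character(counts$material)
    v <- counts$neutrophil_count
  } else {
    v <- as.numeric(counts)
    ids <- names(counts) %||% sprintf("M%03d", seq_along(v))
  }
  if (any(!is.finite(v)) || any(v < 0)) abort("neutrophil counts must be finite and >= 0")
  cls <- ifelse(v < thresholds$t_low, "NoL", ifelse(v < thresholds$t_high, "M", "H"))
  new_hazard_labeling(
    ids, factor(cls, levels = c("NoL", "M", "H"), ordered = TRUE),
    task = "NEU",
    provenance = sprintf(
      "thresholds t_low=%g t_high=%g", thresholds$t_low, thresholds$t_high
    )
  )
}

new_hazard_labeling <- function(material, class, task, provenance) {
  out <- tibble(material = material, class = class)
  attr(out, "task") <- task
  attr(out, "provenance") <- provenance
  class(out) <- c("hazard_labeling", class(out))
  out
}

#' Read/write toxicity score tables as TSV
#'
#' @param x A `tox_score_table` tibble.
#' @param path File path.
#' @return `read_score_table` returns the score tibble; `write_score_table`
#'   returns `path` invisibly.
#' @export
write_score_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as_layer_matrix(out)
  if (any(m %% 1 != 0) || any(m < 1) || any(m > 6)) {
    abort("score table entries must be integers in 1..6")
  }
  class(out) <- c("tox_score_table", class(out))
  out
}
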