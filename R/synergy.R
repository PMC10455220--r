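# Bliss-independence synergy scoring of dose-response viability matrices
# and inhibitor-class aggregation across cell-line panels.

#' Fractional inhibition from percent viability
#'
#' `y = 1 - viability/100`, clamped to `[0, 1]` (growth stimulation above
#' 100 percent viability counts as zero inhibition).
#'
#' @param viability_pct numeric percent viability
#' @return Inhibition fraction(s) in `[0, 1]`.
#' @export
percent_inhibition <- function(viability_pct) {
  if (any(!is.finite(viability_pct))) stop_located("viability must be finite")
  pmin(pmax(1 - viability_pct / 100, 0), 1)
}

#' Bliss-independence expected inhibition
#'
#' Under independent drug action the expected combined inhibition is
#' `y_a + y_b - y_a * y_b`.
#'
#' @param y_a,y_b inhibition fractions in `[0, 1]`
#' @return Expected combined inhibition in `[0, 1]`.
#' @export
bliss_expected <- function(y_a, y_b) {
  if (any(y_a < 0 | y_a > 1 | y_b < 0 | y_b > 1))
    stop_located("inhibition values must lie in [0, 1]")
  y_a + y_b - y_a * y_b
}

#' Bliss excess matrix and synergy score of a dose-response matrix
#'
#' For every combination cell (both concentrations positive) the excess is
#' `(observed inhibition - expected inhibition) * 100`, where the expected
#' inhibition is [bliss_expected()] of the two monotherapy inhibitions at
#' the cell's concentrations. The Bliss score is the arithmetic mean excess
#' over all combination cells; a score above 0 is classified synergistic,
#' below 0 antagonistic, exactly 0 additive.
#'
#' @param m a [dose_matrix()] object
#' @return A `synergy_result`: list with `drug_a`, `drug_b`, `excess`
#'   (matrix over the combination grid, percent scale), `bliss_score`, and
#'   `label`.
#' @export
bliss_matrix_score <- function(m) {
  stopifnot(inherits(m, "dose_matrix"))
  if (length(m$conc_a) < 2 || length(m$conc_b) < 2)
    stop_located("need at least one non-control cell")
  y <- percent_inhibition(m$viability)
  mono_a <- y[-1, 1]
  mono_b <- y[1, -1]
  expected <- outer(mono_a, mono_b, bliss_expected)
  excess <- (y[-1, -1, drop = FALSE] - expected) * 100
  score <- mean(excess)
  label <- if (score > 0) "synergistic" else if (score < 0) "antagonistic" else "additive"
  structure(list(drug_a = m$drug_a, drug_b = m$drug_b, excess = excess,
                 bliss_score = score, label = label),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat("Bliss score ", x$drug_a, " + ", x$drug_b, ": ",
      format(x$bliss_score, digits = 4), " (", x$label, ")\n", sep = "")
  invisible(x)
}

#' Aggregate Bliss scores per inhibitor class across a cell-line panel
#'
#' Averages member-combination Bliss scores per (cell line, class), labels
#' each mean, and counts per class the cell lines with synergistic
#' (mean > 0) and antagonistic (mean < 0) responses.
#'
#' @param records data.frame with columns `cell_line`, `class`,
#'   `bliss_score` (one row per scored combination)
#' @return List with `per_cell_line` (data.frame: `cell_line`, `class`,
#'   `mean_bliss`, `n_combinations`, `label`) and `per_class` (data.frame:
#'   `class`, `n_cell_lines`, `n_synergistic`, `n_antagonistic`).
#' @export
aggregate_class_synergy <- function(records) {
  need <- c("cell_line", "class", "bliss_score")
  if (!all(need %in% names(records)) || !nrow(records))
    stop_located("records must have >= 1 row with columns: ",
                 paste(need, collapse = ", "))
  key <- interaction(records$cell_line, records$class, drop = TRUE, sep = "\r")
  per <- do.call(rbind, lapply(split(records, key), function(g) {
    mb <- mean(g$bliss_score)
    data.frame(cell_line = g$cell_line[1], class = g$class[1],
               mean_bliss = mb, n_combinations = nrow(g),
               label = if (mb > 0) "synergistic" else if (mb < 0)
                 "antagonistic" else "additive",
               stringsAsFactors = FALSE)
  }))
  per <- per[order(per$class, per$cell_line), , drop = FALSE]
  rownames(per) <- NULL
  per_class <- do.call(rbind, lapply(split(per, per$class), function(g) {
    data.frame(class = g$class[1], n_cell_lines = nrow(g),
               n_synergistic = sum(g$mean_bliss > 0),
               n_antagonistic = sum(g$mean_bliss < 0),
               stringsAsFactors = FALSE)
  }))
  rownames(per_class) <- NULL
  list(per_cell_line = per, per_class = per_class)
}
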