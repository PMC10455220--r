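# Association of binary genomic alterations with combination-synergy
# scores: one-way (optionally covariate-adjusted) ANOVA with Cohen's d,
# Storey-Tibshirani q-values, and the high/low synergy split.

#' ANOVA association of a binary marker with synergy scores
#'
#' Fixed-effects ANOVA of `synergy ~ mutated` (optionally
#' `synergy ~ covariate + mutated`, testing the marker after the
#' covariate). With a binary factor and no covariate the F statistic equals
#' the squared pooled two-sample t statistic and the p-value matches the
#' t-test's. The effect size is Cohen's d with pooled standard deviation.
#'
#' @param synergy numeric vector of synergy scores
#' @param mutated 0/1 (or logical) vector, same length
#' @param covariate optional categorical covariate (e.g. tissue)
#' @return List with `f_stat`, `pvalue`, `cohens_d`, `delta_mean`
#'   (mutant minus wild-type mean), `n_mut`, `n_wt`.
#' @export
anova_association <- function(synergy, mutated, covariate = NULL) {
  if (length(synergy) != length(mutated))
    stop_located("synergy and mutation vectors differ in length")
  mutated <- as.integer(as.logical(mutated))
  if (any(is.na(synergy)) || any(is.na(mutated)))
    stop_located("missing values not allowed")
  g1 <- synergy[mutated == 1]
  g0 <- synergy[mutated == 0]
  n1 <- length(g1)
  n0 <- length(g0)
  if (n1 < 2 || n0 < 2)
    stop_located("both groups need >= 2 observations")
  pooled_var <- ((n1 - 1) * var(g1) + (n0 - 1) * var(g0)) / (n1 + n0 - 2)
  delta <- mean(g1) - mean(g0)
  d <- if (pooled_var > 0) delta / sqrt(pooled_var) else
    if (delta == 0) 0 else Inf * sign(delta)
  dat <- data.frame(y = synergy, mut = factor(mutated, levels = c(0, 1)))
  if (is.null(covariate)) {
    fit <- lm(y ~ mut, data = dat)
  } else {
    dat$cov <- factor(covariate)
    fit <- lm(y ~ cov + mut, data = dat)
  }
  # a zero-residual fit warns and yields NaN; resolved explicitly below
  an <- suppressWarnings(anova(fit))
  f <- an["mut", "F value"]
  p <- an["mut", "Pr(>F)"]
  if (is.na(p)) { # zero residual variance
    p <- if (delta == 0) 1 else 0
    f <- if (delta == 0) 0 else Inf
  }
  list(f_stat = f, pvalue = p, cohens_d = d, delta_mean = delta,
       n_mut = n1, n_wt = n0)
}

#' Storey-Tibshirani q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05, 0.10, ...,
#' 0.95 as `#\{p > lambda\} / (n (1 - lambda))`, smooths the estimates with
#' a natural cubic spline (df = 3) and evaluates it at the largest lambda,
#' clamping to (0, 1]. Q-values are the step-up minimum
#' `min_{j >= i} pi0 * n * p_(j) / j`, capped at 1. Forcing `pi0 = 1`
#' reproduces Benjamini-Hochberg adjustment exactly.
#'
#' @param pvalues numeric vector in `[0, 1]`
#' @param lambda grid for pi0 estimation
#' @param pi0 optional override of the estimated pi0
#' @return List with `qvalues` (same order as input) and `pi0`.
#' @export
storey_qvalues <- function(pvalues, lambda = seq(0.05, 0.95, by = 0.05),
                           pi0 = NULL) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop_located("p-values must lie in [0, 1]")
  n <- length(pvalues)
  if (is.null(pi0)) {
    pi0_l <- vapply(lambda, function(l) sum(pvalues > l) / (n * (1 - l)),
                    numeric(1))
    pi0 <- if (n < 2 || length(unique(pi0_l)) == 1) {
      pi0_l[length(pi0_l)]
    } else {
      sp <- smooth.spline(lambda, pi0_l, df = 3)
      predict(sp, x = max(lambda))$y
    }
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
  } else {
    if (pi0 <= 0 || pi0 > 1) stop_located("pi0 must lie in (0, 1]")
  }
  ord <- order(pvalues, decreasing = TRUE)
  q <- pi0 * n * pvalues[ord] / rank(pvalues, ties.method = "max")[ord]
  q <- pmin(cummin(q), 1)
  qvalues <- numeric(n)
  qvalues[ord] <- q
  list(qvalues = qvalues, pi0 = pi0)
}

#' Scan every genomic alteration for association with synergy
#'
#' Aligns the mutation matrix with the synergy vector on shared cell lines,
#' tests every gene with at least `min_group` mutant and `min_group`
#' wild-type lines via [anova_association()], computes Storey q-values over
#' exactly the tested set, and flags genes with `pvalue < p_max` and
#' `qvalue < fdr_max`.
#'
#' @param mutations binary matrix, cell lines x genes (see
#'   [read_mutation_matrix()])
#' @param synergy named numeric vector of per-cell-line synergy scores
#' @param min_group minimum group size on both sides (default 3)
#' @param p_max p-value threshold (default 0.001)
#' @param fdr_max q-value threshold (default 0.25)
#' @param covariate optional named categorical covariate per cell line
#' @return data.frame sorted by p-value: `gene`, `n_mut`, `n_wt`,
#'   `delta_mean`, `cohens_d`, `f_stat`, `pvalue`, `qvalue`,
#'   `significant`. Attribute `pi0` records the estimated null proportion.
#' @export
run_association_scan <- function(mutations, synergy, min_group = 3,
                                 p_max = 0.001, fdr_max = 0.25,
                                 covariate = NULL) {
  shared <- intersect(rownames(mutations), names(synergy))
  dropped <- setdiff(union(rownames(mutations), names(synergy)), shared)
  if (length(dropped))
    message(length(dropped), " cell line(s) without both mutation and ",
            "synergy data dropped")
  if (length(shared) < 2 * min_group)
    stop_located("too few shared cell lines for the scan")
  m <- mutations[shared, , drop = FALSE]
  s <- synergy[shared]
  cov <- if (!is.null(covariate)) covariate[shared] else NULL
  n_mut <- colSums(m)
  testable <- names(n_mut)[n_mut >= min_group &
                           (length(shared) - n_mut) >= min_group]
  if (!length(testable)) {
    warning("no testable gene at min_group = ", min_group)
    out <- data.frame(gene = character(), n_mut = integer(), n_wt = integer(),
                      delta_mean = numeric(), cohens_d = numeric(),
                      f_stat = numeric(), pvalue = numeric(),
                      qvalue = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
    attr(out, "pi0") <- NA_real_
    return(out)
  }
  rows <- lapply(sort(testable), function(g) {
    r <- anova_association(s, m[, g], covariate = cov)
    data.frame(gene = g, n_mut = r$n_mut, n_wt = r$n_wt,
               delta_mean = r$delta_mean, cohens_d = r$cohens_d,
               f_stat = r$f_stat, pvalue = r$pvalue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  st <- storey_qvalues(out$pvalue)
  out$qvalue <- st$qvalues
  out$significant <- out$pvalue < p_max & out$qvalue < fdr_max
  out <- out[order(out$pvalue, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pi0") <- st$pi0
  out
}

#' Split cell lines into higher- and lower-synergy halves
#'
#' Ranks by score descending; the top `ceiling(n/2)` lines are labelled
#' `"higher"`, the rest `"lower"`. Ties at the boundary are broken by
#' cell-line name ascending.
#'
#' @param synergy named numeric vector of per-cell-line synergy scores
#'   (n >= 2)
#' @return Named character vector of labels `"higher"`/`"lower"`, in the
#'   input order.
#' @export
split_high_low <- function(synergy) {
  n <- length(synergy)
  if (n < 2) stop_located("need at least two cell lines")
  if (is.null(names(synergy))) names(synergy) <- as.character(seq_len(n))
  ord <- order(-synergy, names(synergy))
  labels <- setNames(rep("lower", n), names(synergy)[ord])
  labels[seq_len(ceiling(n / 2))] <- "higher"
  labels[names(synergy)]
}
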