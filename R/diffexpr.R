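# Differential expression: TMM normalization, fixed-dispersion NB exact
# test on pooled replicates, BH adjustment, and the |log2FC| > 1 & FDR < 0.05
# call rule producing directional DE gene sets.

#' Trimmed mean of M-values normalization factors
#'
#' Library-composition scaling factors for count data. The reference sample
#' is the one whose 75th-percentile count fraction is closest to the mean of
#' those fractions. For each sample, per-gene log2 proportion ratios (M) and
#' average log2 abundances (A) are computed against the reference over genes
#' non-zero in both; the 30 percent most extreme M and 5 percent most
#' extreme A values are trimmed (intersection kept) and the factor is 2 to
#' the precision-weighted mean M. Factors are rescaled so their geometric
#' mean is 1.
#'
#' @param counts a [counts_matrix()] object or a non-negative numeric matrix
#'   (genes x samples)
#' @param logratio_trim,sum_trim trim fractions for M and A (defaults 0.3,
#'   0.05)
#' @return Named numeric vector of scaling factors, one per sample,
#'   geometric mean 1.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  m <- if (inherits(counts, "counts_matrix")) counts$counts else as.matrix(counts)
  if (ncol(m) < 1) stop_located("need at least one sample")
  lib <- colSums(m)
  if (any(lib == 0)) stop_located("sample with zero total count")
  # reference: 75th-percentile count fraction closest to the mean fraction
  q75 <- apply(m, 2, function(x) quantile(x, 0.75)) / lib
  ref_i <- which.min(abs(q75 - mean(q75)))
  ref <- m[, ref_i]
  f <- vapply(seq_len(ncol(m)), function(j) {
    .tmm_pair(m[, j], ref, lib[j], lib[ref_i], logratio_trim, sum_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(m)
  f
}

.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) {
    warning("sample shares no nonzero gene with the reference; factor set to 1")
    return(1)
  }
  p_o <- obs[keep] / n_obs
  p_r <- ref[keep] / n_ref
  M <- log2(p_o / p_r)
  A <- (log2(p_o) + log2(p_r)) / 2
  # asymptotic delta-method precision weights (binomial sampling variance)
  w <- (n_obs - obs[keep]) / (n_obs * obs[keep]) +
       (n_ref - ref[keep]) / (n_ref * ref[keep])
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1
  hi_a <- n + 1 - lo_a
  rM <- rank(M)
  rA <- rank(A)
  keep2 <- rM >= lo_m & rM <= hi_m & rA >= lo_a & rA <= hi_a
  if (!any(keep2)) return(1)
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

#' Fixed-dispersion negative-binomial exact test
#'
#' Per gene, conditional on the total `t = a + b` of the two pooled group
#' counts, the two-sided exact p-value is the sum of the probabilities of
#' all splits of `t` whose conditional probability does not exceed that of
#' the observed split (minimum-likelihood method). Both group counts are
#' modelled as NB with the given dispersion and a common conditional mean of
#' `t/2`; with dispersion 0 this reduces to the conditional Binomial(t, 1/2)
#' test. Group library sizes are assumed equalized beforehand (see
#' [de_table()]).
#'
#' @param counts_treat,counts_ref integer vectors of pooled group counts,
#'   one entry per gene
#' @param dispersion NB dispersion (>= 0) of each pooled group count
#' @param method `"minlik"` (default): sum outcomes no more likely than the
#'   observed one; `"double"`: twice the smaller tail (capped at 1).
#'   Tie handling differs between the two.
#' @return Numeric vector of p-values in (0, 1].
#' @export
nb_exact_test <- function(counts_treat, counts_ref, dispersion,
                          method = c("minlik", "double")) {
  method <- match.arg(method)
  if (length(counts_treat) != length(counts_ref))
    stop_located("group count vectors differ in length")
  if (dispersion < 0) stop_located("dispersion must be >= 0")
  vapply(seq_along(counts_treat), function(i) {
    .nb_exact_one(counts_treat[i], counts_ref[i], dispersion, method)
  }, numeric(1))
}

.nb_exact_one <- function(a, b, dispersion, method) {
  t <- a + b
  if (t == 0) return(1)
  k <- 0:t
  if (dispersion == 0) {
    logp <- dbinom(k, t, 0.5, log = TRUE)
  } else {
    size <- 1 / dispersion
    logp <- dnbinom(k, size = size, mu = t / 2, log = TRUE) +
            dnbinom(t - k, size = size, mu = t / 2, log = TRUE)
    logp <- logp - log(sum(exp(logp - max(logp)))) - max(logp)
  }
  p_obs <- logp[a + 1]
  if (method == "minlik") {
    p <- sum(exp(logp[logp <= p_obs + 1e-8]))
  } else {
    lower <- sum(exp(logp[k <= a]))
    upper <- sum(exp(logp[k >= a]))
    p <- 2 * min(lower, upper)
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement; output is in the order
#' of the input.
#'
#' @param pvalues numeric vector in `[0, 1]`
#' @return Adjusted p-values (FDR), same order as input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop_located("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Differential-expression table for one treatment vs. reference contrast
#'
#' Runs the full DE computation for one cell line and treatment against the
#' reference (DMSO) condition: TMM factors over the involved samples,
#' equalization of each sample to the common (geometric-mean) effective
#' library size, pooling of replicates within each group, the
#' fixed-dispersion NB exact test on the pooled counts, BH adjustment, and a
#' log2 fold change computed on normalized counts-per-million with a
#' pseudo-count offset.
#'
#' Replicates are pooled after normalization; because the sum of n iid NB
#' counts with common dispersion phi has dispersion phi/n, the exact test is
#' run at `dispersion * 2 / (n_treat + n_ref)`.
#'
#' @param x a [counts_matrix()] object
#' @param cell_line,treatment contrast to test
#' @param reference reference treatment (default `"DMSO"`)
#' @param dispersion per-sample NB dispersion (default 0.16, i.e. BCV 0.4)
#' @param pseudo_cpm pseudo-count on the CPM scale for the fold change
#'   (default 0.5)
#' @param method tie-handling method passed to [nb_exact_test()]
#' @return data.frame with columns `gene`, `log2fc`, `pvalue`, `fdr`; one
#'   row per gene, in the input gene order.
#' @export
de_table <- function(x, cell_line, treatment, reference = "DMSO",
                     dispersion = 0.16, pseudo_cpm = 0.5,
                     method = "minlik") {
  stopifnot(inherits(x, "counts_matrix"))
  sel_t <- x$meta$cell_line == cell_line & x$meta$treatment == treatment
  sel_r <- x$meta$cell_line == cell_line & x$meta$treatment == reference
  if (!any(sel_t))
    stop_located("no samples for (", cell_line, ", ", treatment, ")")
  if (!any(sel_r))
    stop_located("no ", reference, " reference samples for cell line ", cell_line)
  sub <- x$counts[, sel_t | sel_r, drop = FALSE]
  grp_treat <- colnames(x$counts)[sel_t]
  f <- tmm_factors(sub)
  eff <- colSums(sub) * f
  target <- exp(mean(log(eff)))
  scaled <- sweep(sub, 2, target / eff, `*`)
  pooled_t <- round(rowSums(scaled[, colnames(sub) %in% grp_treat, drop = FALSE]))
  pooled_r <- round(rowSums(scaled[, !colnames(sub) %in% grp_treat, drop = FALSE]))
  n_t <- sum(sel_t)
  n_r <- sum(sel_r)
  disp_pooled <- dispersion * 2 / (n_t + n_r)
  p <- nb_exact_test(pooled_t, pooled_r, disp_pooled, method = method)
  cpm_t <- pooled_t / (n_t * target) * 1e6
  cpm_r <- pooled_r / (n_r * target) * 1e6
  log2fc <- log2((cpm_t + pseudo_cpm) / (cpm_r + pseudo_cpm))
  data.frame(gene = rownames(x$counts), log2fc = log2fc, pvalue = p,
             fdr = bh_adjust(p), row.names = NULL, stringsAsFactors = FALSE)
}

#' Call directional DE gene sets from a DE table
#'
#' Significance rule: `log2fc > lfc_min` (up) or `log2fc < -lfc_min` (down)
#' with `fdr < fdr_max`; both inequalities strict.
#'
#' @param table data.frame from [de_table()] (columns `gene`, `log2fc`,
#'   `fdr`)
#' @param cell_line,treatment labels recorded in the result
#' @param lfc_min log2 fold-change threshold (default 1)
#' @param fdr_max FDR threshold (default 0.05)
#' @return A `de_gene_set`: list with `cell_line`, `treatment`, `up`,
#'   `down` (sorted character vectors) and `table`.
#' @export
call_de <- function(table, cell_line = NA_character_,
                    treatment = NA_character_, lfc_min = 1, fdr_max = 0.05) {
  if (anyDuplicated(table$gene)) stop_located("one row per gene required")
  up <- sort(table$gene[table$log2fc > lfc_min & table$fdr < fdr_max])
  down <- sort(table$gene[table$log2fc < -lfc_min & table$fdr < fdr_max])
  structure(list(cell_line = cell_line, treatment = treatment,
                 up = up, down = down, table = table),
            class = "de_gene_set")
}

#' @export
print.de_gene_set <- function(x, ...) {
  cat("de_gene_set (", x$cell_line, ", ", x$treatment, "): ",
      length(x$up), " up, ", length(x$down), " down\n", sep = "")
  invisible(x)
}

de_key <- function(cell_line, treatment) paste(cell_line, treatment, sep = ".")

#' Run differential expression for every (cell line, treatment) contrast
#'
#' @inheritParams de_table
#' @param lfc_min,fdr_max call thresholds passed to [call_de()]
#' @return Named list of `de_gene_set` objects keyed
#'   `"<cell_line>.<treatment>"`, covering every non-reference treatment
#'   observed for each cell line.
#' @export
de_all <- function(x, reference = "DMSO", dispersion = 0.16, lfc_min = 1,
                   fdr_max = 0.05, method = "minlik") {
  stopifnot(inherits(x, "counts_matrix"))
  out <- list()
  for (cl in unique(x$meta$cell_line)) {
    trts <- setdiff(unique(x$meta$treatment[x$meta$cell_line == cl]), reference)
    for (tr in sort(trts)) {
      tab <- de_table(x, cl, tr, reference = reference,
                      dispersion = dispersion, method = method)
      out[[de_key(cl, tr)]] <- call_de(tab, cl, tr, lfc_min, fdr_max)
    }
  }
  out
}

#' Overlap of down-regulated genes with an essential-gene list
#'
#' @param down character vector of down-regulated genes
#' @param essential character vector of essential genes (same symbol space)
#' @return List with `count` and sorted `members`.
#' @export
essential_overlap <- function(down, essential) {
  members <- sort(intersect(down, essential))
  list(count = length(members), members = members)
}
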