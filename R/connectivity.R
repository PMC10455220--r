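# Connectivity-Map-style scoring of query up/down signatures against a
# ranked perturbagen library: weighted-KS enrichment score (ES), two-sided
# WTCS, sign-stratified normalized connectivity score (NCS), and the
# candidate filtering/ranking that predicts combination partners.

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' GSEA-style running sum over a ranked reference signature: at each hit the
#' sum increases by `|score|^weight / sum(|score|^weight over hits)` (weight
#' 0 gives `1/n_hits`), at each miss it decreases by `1/(N - n_hits)`. The
#' enrichment score is the signed maximum deviation of the running sum from
#' zero; on an exact magnitude tie the positive deviation is returned.
#'
#' Query genes absent from the ranked list are ignored. If no query gene is
#' present the score is 0 with a warning.
#'
#' @param query character vector of gene symbols
#' @param ranked a [ranked_signature()] object
#' @param weight non-negative score-weighting exponent (default 0, pure KS)
#' @return Enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(query, ranked, weight = 0) {
  if (weight < 0) stop_located("weight must be >= 0")
  hit <- ranked$genes %in% query
  n_hit <- sum(hit)
  N <- length(ranked$genes)
  if (n_hit == 0) {
    warning("no query gene present in the ranked signature; es = 0")
    return(0)
  }
  if (n_hit == N) return(1)
  inc <- if (weight == 0) rep(1 / n_hit, n_hit) else {
    w <- abs(ranked$scores[hit])^weight
    if (sum(w) == 0) rep(1 / n_hit, n_hit) else w / sum(w)
  }
  step <- numeric(N)
  step[hit] <- inc
  step[!hit] <- -1 / (N - n_hit)
  run <- cumsum(step)
  hi <- max(run)
  lo <- min(run)
  if (hi >= -lo - 1e-12) hi else lo
}

#' Weighted two-sided connectivity score (WTCS)
#'
#' Combines the enrichment scores of the up and down query sets against one
#' ranked reference signature: with `a = es(up)` and `b = es(down)`,
#' `wtcs = (a - b)/2` when the two have opposite signs and 0 otherwise.
#' If one set is empty the other's score carries the result alone (the
#' down-set score negated). Positive WTCS means the perturbagen mimics the
#' query; negative means it reverses it.
#'
#' @param up,down disjoint character vectors of gene symbols (one may be
#'   empty)
#' @param ranked a [ranked_signature()] object
#' @param weight passed to [enrichment_score()]
#' @return List with `es_up`, `es_down`, `wtcs`.
#' @export
wtcs <- function(up, down, ranked, weight = 0) {
  if (length(intersect(up, down)))
    stop_located("up and down query sets overlap")
  if (!length(up) && !length(down))
    stop_located("both query sets empty")
  es_up <- if (length(up)) enrichment_score(up, ranked, weight) else NA_real_
  es_down <- if (length(down)) enrichment_score(down, ranked, weight) else NA_real_
  w <- if (!length(up)) {
    -es_down
  } else if (!length(down)) {
    es_up
  } else if (sign(es_up) != sign(es_down)) {
    (es_up - es_down) / 2
  } else 0
  list(es_up = es_up, es_down = es_down, wtcs = w)
}

#' Score a query signature against every library signature
#'
#' @param signature an [expression_signature()]
#' @param library list of [ranked_signature()] objects
#' @param weight passed to [enrichment_score()]
#' @return data.frame with one row per library signature: `perturbagen_id`,
#'   `pert_type`, `target_gene`, `cell_line`, `es_up`, `es_down`, `wtcs`.
#' @export
connectivity_scores <- function(signature, library, weight = 0) {
  if (!length(library)) stop_located("empty signature library")
  rows <- lapply(library, function(s) {
    r <- wtcs(signature$up, signature$down, s, weight)
    data.frame(perturbagen_id = s$id, pert_type = s$pert_type,
               target_gene = s$target_gene, cell_line = s$cell_line,
               es_up = r$es_up, es_down = r$es_down, wtcs = r$wtcs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$perturbagen_id, out$cell_line), , drop = FALSE]
}

#' Sign-stratified normalization of connectivity scores
#'
#' Within each (cell_line, pert_type) group, each WTCS is divided by the
#' mean absolute WTCS of the same-sign members of the group:
#' `ncs = wtcs / mean(|wtcs|)` over the group members sharing its sign.
#' Zero WTCS gives zero NCS. After normalization the mean |NCS| within each
#' sign stratum of a group is 1.
#'
#' @param results data.frame from [connectivity_scores()]
#' @return The same data.frame with an `ncs` column appended.
#' @export
normalize_scores <- function(results) {
  stopifnot(all(c("cell_line", "pert_type", "wtcs") %in% names(results)))
  ncs <- rep(NA_real_, nrow(results))
  grp <- paste(results$cell_line, results$pert_type, sep = "\r")
  for (g in unique(grp)) {
    idx <- which(grp == g)
    w <- results$wtcs[idx]
    for (sgn in c(1, -1)) {
      sel <- idx[sign(w) == sgn]
      if (!length(sel)) next
      ncs[sel] <- results$wtcs[sel] / mean(abs(results$wtcs[sel]))
    }
    ncs[idx[w == 0]] <- 0
  }
  results$ncs <- ncs
  results
}

#' Predict combination partners from resistance/response connectivity
#'
#' Scores both query profiles against the library, normalizes (NCS), and
#' keeps perturbagens that reverse the resistance profile
#' (`ncs_resist <= -ncs_min`) while mimicking the response profile
#' (`ncs_response >= ncs_min`) in at least one cell line. Ambiguous
#' discoveries are removed: (a) knockdown/overexpression perturbagens of a
#' target whose KD and OE signatures are sign-concordant against the
#' resistance profile; (b) perturbagens scoring in the same direction
#' against both profiles at `|ncs| >= ncs_min`. Compounds are kept only
#' when a knockdown signature of their annotated target is sign-concordant
#' with the compound against the resistance profile (unannotated compounds
#' are dropped). Survivors are aggregated into classes by target annotation
#' (unannotated perturbagens form singleton classes) and ranked by the
#' number of supporting cell lines, then by `|mean ncs vs. resistance|`,
#' then class name.
#'
#' @param resist,response [expression_signature()] query profiles
#' @param library list of [ranked_signature()] objects
#' @param ncs_min NCS magnitude defining an observed transcriptional effect
#'   in a cell line (default 1)
#' @param weight passed to [enrichment_score()]
#' @return data.frame, one row per candidate class, ranked: `class`,
#'   `n_support_cell_lines`, `mean_ncs_resist`, `mean_ncs_response`,
#'   `members` (comma-separated perturbagen ids),
#'   `unambiguous_kd_oe`, `single_profile`, `target_concordant` (all TRUE
#'   for listed candidates). Attribute `scores` holds the merged per-
#'   (perturbagen, cell line) score table.
#' @export
predict_partners <- function(resist, response, library, ncs_min = 1,
                             weight = 0) {
  if (!length(library)) stop_located("empty signature library")
  a <- suppressWarnings(normalize_scores(connectivity_scores(resist, library, weight)))
  b <- suppressWarnings(normalize_scores(connectivity_scores(response, library, weight)))
  tab <- a[, c("perturbagen_id", "pert_type", "target_gene", "cell_line")]
  tab$ncs_resist <- a$ncs
  tab$ncs_response <- b$ncs[match(
    paste(a$perturbagen_id, a$cell_line),
    paste(b$perturbagen_id, b$cell_line))]

  # per-perturbagen means across cell lines
  mean_by <- function(v, k) tapply(v, k, mean)
  m_res <- mean_by(tab$ncs_resist, tab$perturbagen_id)
  m_resp <- mean_by(tab$ncs_response, tab$perturbagen_id)

  # (a) ambiguous KD/OE targets: mean resistance-profile NCS of the target's
  # knockdown and overexpression signatures share a (nonzero) sign
  kd <- tab[tab$pert_type == "knockdown", ]
  oe <- tab[tab$pert_type == "overexpression", ]
  kd_sign <- sign(mean_by(kd$ncs_resist, kd$target_gene))
  oe_sign <- sign(mean_by(oe$ncs_resist, oe$target_gene))
  both <- intersect(names(kd_sign), names(oe_sign))
  ambiguous_targets <- both[kd_sign[both] == oe_sign[both] &
                            kd_sign[both] != 0]
  flag_a <- !(tab$pert_type %in% c("knockdown", "overexpression") &
              tab$target_gene %in% ambiguous_targets)

  # (b) same-direction effect on both profiles at threshold magnitude
  dual <- abs(tab$ncs_resist) >= ncs_min & abs(tab$ncs_response) >= ncs_min &
          sign(tab$ncs_resist) == sign(tab$ncs_response)
  dual_perts <- unique(tab$perturbagen_id[dual])
  flag_b <- !(tab$perturbagen_id %in% dual_perts)

  # (c) compound-target concordance via the target's knockdown signature
  kd_sign_any <- kd_sign[kd_sign != 0]
  pert_target <- tapply(tab$target_gene, tab$perturbagen_id, `[`, 1)
  is_compound <- tab$pert_type == "compound"
  conc <- vapply(seq_len(nrow(tab)), function(i) {
    if (!is_compound[i]) return(TRUE)
    tg <- tab$target_gene[i]
    if (!nzchar(tg) || !(tg %in% names(kd_sign_any))) return(FALSE)
    s <- sign(m_res[[tab$perturbagen_id[i]]])
    s != 0 && s == kd_sign_any[[tg]]
  }, logical(1))

  keep <- flag_a & flag_b & conc
  support <- keep & tab$ncs_resist <= -ncs_min & tab$ncs_response >= ncs_min
  cand_perts <- unique(tab$perturbagen_id[support])
  if (!length(cand_perts)) {
    out <- data.frame(class = character(), n_support_cell_lines = integer(),
                      mean_ncs_resist = numeric(), mean_ncs_response = numeric(),
                      members = character(), unambiguous_kd_oe = logical(),
                      single_profile = logical(), target_concordant = logical(),
                      stringsAsFactors = FALSE)
    attr(out, "scores") <- tab
    return(out)
  }
  cls <- ifelse(nzchar(pert_target[cand_perts]), pert_target[cand_perts],
                cand_perts)
  rows <- lapply(sort(unique(cls)), function(cl) {
    members <- sort(cand_perts[cls == cl])
    sel <- tab$perturbagen_id %in% members
    n_sup <- length(unique(tab$cell_line[sel & support]))
    data.frame(class = cl, n_support_cell_lines = n_sup,
               mean_ncs_resist = mean(tab$ncs_resist[sel]),
               mean_ncs_response = mean(tab$ncs_response[sel]),
               members = paste(members, collapse = ","),
               unambiguous_kd_oe = TRUE, single_profile = TRUE,
               target_concordant = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_support_cell_lines, -abs(out$mean_ncs_resist),
                   out$class), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scores") <- tab
  out
}
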