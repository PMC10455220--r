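# Resistance/response expression signatures from cross-cell-line DE set
# algebra, treatment/cell-line overlap tallies, and hypergeometric
# over-representation analysis.

#' Construct an expression signature
#'
#' An up-set and a down-set of gene symbols; the unit queried against a
#' perturbagen reference library.
#'
#' @param up,down character vectors of gene symbols (disjoint, not both
#'   empty)
#' @param label signature label, e.g. `"DNRResist"`, `"DNRResponse"` or a
#'   user label
#' @return An `expression_signature` object.
#' @export
expression_signature <- function(up, down, label = "user") {
  up <- sort(unique(as.character(up)))
  down <- sort(unique(as.character(down)))
  if (length(intersect(up, down)))
    stop_located("up and down sets overlap: ",
                 paste(intersect(up, down), collapse = ", "))
  if (!length(up) && !length(down))
    stop_located("signature must have at least one gene")
  structure(list(label = label, up = up, down = down),
            class = "expression_signature")
}

#' @export
print.expression_signature <- function(x, ...) {
  cat("expression_signature '", x$label, "': ", length(x$up), " up, ",
      length(x$down), " down\n", sep = "")
  invisible(x)
}

.get_de <- function(de, cell_line, treatment) {
  key <- de_key(cell_line, treatment)
  if (is.null(de[[key]]))
    stop_located("missing DE set for (", cell_line, ", ", treatment, ")")
  de[[key]]
}

#' Build the resistance signature
#'
#' Gene expression changes seen in the resistant cell line after the drug
#' only, and absent (same direction) from every sensitive line under both
#' the drug and the combination: `up = up(resistant, drug)` minus the union
#' of the up-sets of every sensitive line under `{drug, combo}`; `down`
#' analogously. Exclusion is direction-specific: a gene up in the resistant
#' line and down in a sensitive line is retained.
#'
#' @param de named list of `de_gene_set` objects keyed
#'   `"<cell_line>.<treatment>"` (see [de_all()])
#' @param resistant resistant cell line id
#' @param sensitive character vector of sensitive cell line ids
#' @param drug,combo treatment ids of the monotherapy and the combination
#' @param strict also exclude the resistant line's own combination changes
#'   (default `FALSE`: the profile is built from the resistant line's
#'   monotherapy condition only)
#' @param label signature label (default `"DNRResist"`)
#' @return An [expression_signature()].
#' @export
build_resist_profile <- function(de, resistant, sensitive, drug, combo,
                                 strict = FALSE, label = "DNRResist") {
  res <- .get_de(de, resistant, drug)
  excl_up <- character()
  excl_down <- character()
  for (cl in sensitive) {
    for (tr in c(drug, combo)) {
      s <- .get_de(de, cl, tr)
      excl_up <- union(excl_up, s$up)
      excl_down <- union(excl_down, s$down)
    }
  }
  if (strict) {
    s <- .get_de(de, resistant, combo)
    excl_up <- union(excl_up, s$up)
    excl_down <- union(excl_down, s$down)
  }
  expression_signature(setdiff(res$up, excl_up), setdiff(res$down, excl_down),
                       label = label)
}

#' Build the response signature
#'
#' Gene expression changes common to every sensitive cell line under both
#' the drug and the combination, and absent (same direction) from the
#' resistant line under either: `up` is the intersection over all
#' sensitive-line `{drug, combo}` up-sets minus
#' `up(resistant, drug) U up(resistant, combo)`; `down` analogously.
#'
#' @inheritParams build_resist_profile
#' @param relaxed require presence only in the sensitive lines' drug
#'   condition (default `FALSE`: presence in all four sensitive-condition
#'   sets is required)
#' @param label signature label (default `"DNRResponse"`)
#' @return An [expression_signature()].
#' @export
build_response_profile <- function(de, resistant, sensitive, drug, combo,
                                   relaxed = FALSE, label = "DNRResponse") {
  conds <- if (relaxed) drug else c(drug, combo)
  up <- NULL
  down <- NULL
  for (cl in sensitive) {
    for (tr in conds) {
      s <- .get_de(de, cl, tr)
      up <- if (is.null(up)) s$up else intersect(up, s$up)
      down <- if (is.null(down)) s$down else intersect(down, s$down)
    }
  }
  r_drug <- .get_de(de, resistant, drug)
  r_combo <- .get_de(de, resistant, combo)
  expression_signature(setdiff(up, union(r_drug$up, r_combo$up)),
                       setdiff(down, union(r_drug$down, r_combo$down)),
                       label = label)
}

#' Pairwise overlap report of DE gene sets
#'
#' Tallies shared up- and down-regulated genes between DE sets, either
#' across cell lines within each treatment (`mode = "by_cell_line"`) or
#' across treatments within each cell line (`mode = "by_treatment"`).
#' Percentages are reported against three recorded denominators: the first
#' set, the second set, and the union of all compared sets of that stratum
#' and direction (the 100 percent convention for treatment comparisons).
#'
#' @param de named list of `de_gene_set` objects (see [de_all()])
#' @param mode `"by_cell_line"` or `"by_treatment"`
#' @return data.frame with one row per (stratum, pair, direction):
#'   `stratum`, `set_a`, `set_b`, `direction`, `n_a`, `n_b`, `n_shared`,
#'   `denominator`, `pct_of_a`, `pct_of_b`, `pct_of_union`.
#' @export
overlap_report <- function(de, mode = c("by_cell_line", "by_treatment")) {
  mode <- match.arg(mode)
  cls <- vapply(de, function(s) s$cell_line, character(1))
  trs <- vapply(de, function(s) s$treatment, character(1))
  strata <- if (mode == "by_cell_line") sort(unique(trs)) else sort(unique(cls))
  rows <- list()
  for (st in strata) {
    keys <- names(de)[if (mode == "by_cell_line") trs == st else cls == st]
    labels <- if (mode == "by_cell_line") cls[keys] else trs[keys]
    if (length(keys) < 2) next
    ord <- order(labels)
    keys <- keys[ord]
    labels <- labels[ord]
    for (dir in c("up", "down")) {
      all_union <- sort(unique(unlist(lapply(de[keys], `[[`, dir))))
      denom <- length(all_union)
      for (i in seq_len(length(keys) - 1)) {
        for (j in seq(i + 1, length(keys))) {
          a <- de[[keys[i]]][[dir]]
          b <- de[[keys[j]]][[dir]]
          shared <- length(intersect(a, b))
          pct <- function(n, d) if (d > 0) 100 * n / d else NA_real_
          rows[[length(rows) + 1]] <- data.frame(
            stratum = st, set_a = labels[i], set_b = labels[j],
            direction = dir, n_a = length(a), n_b = length(b),
            n_shared = shared, denominator = denom,
            pct_of_a = pct(shared, length(a)),
            pct_of_b = pct(shared, length(b)),
            pct_of_union = pct(shared, denom),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric test of the overlap between a query
#' gene set and each set of a collection, within a stated gene universe,
#' with BH adjustment across the collection. Query members outside the
#' universe are dropped with a warning; each collection set is intersected
#' with the universe.
#'
#' @param query character vector of gene symbols
#' @param collection a `gene_set_collection` (see [read_gene_sets()])
#' @param universe character vector defining the background (conventionally
#'   all genes tested for DE)
#' @param alpha adjusted-p significance threshold for the `significant`
#'   flag (default 0.05)
#' @return data.frame sorted by p-value with columns `set`, `k` (overlap),
#'   `n` (query size), `K` (set size in universe), `N` (universe size),
#'   `pvalue`, `padj`, `significant`.
#' @export
ora_enrichment <- function(query, collection, universe, alpha = 0.05) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0) stop_located("empty universe")
  outside <- setdiff(query, universe)
  if (length(outside))
    warning(length(outside), " query gene(s) outside the universe dropped")
  query <- intersect(unique(query), universe)
  n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, n = n, K = K, N = N, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$pvalue)
  out$significant <- out$padj < alpha
  out[order(out$pvalue, out$set), , drop = FALSE]
}
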