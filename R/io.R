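# On-disk formats: TSV counts + metadata, GMT gene sets, long-TSV signature
# library, CSV dose matrices and mutation matrices, plain-text gene lists.
# Readers validate; writers produce files the readers round-trip bit-exactly.

#' Construct a counts matrix with per-sample metadata
#'
#' The pipeline entry point: an integer gene x sample matrix plus a metadata
#' table assigning each sample a cell line, a treatment and a replicate
#' number. Gene symbols are case-sensitive and must be unique.
#'
#' @param counts integer matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids). All entries non-negative
#'   integers.
#' @param meta data.frame with columns `sample`, `cell_line`, `treatment`,
#'   `replicate`; one row per column of `counts`.
#' @return An object of class `counts_matrix`: a list with elements
#'   `counts` and `meta`.
#' @export
counts_matrix <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_located("counts must have gene rownames and sample colnames")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop_located("duplicate gene symbol(s): ", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop_located("duplicate sample id(s)")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stop_located("non-integer or negative count at gene '",
                 rownames(counts)[bad[1, 1]], "', sample '",
                 colnames(counts)[bad[1, 2]], "'")
  storage.mode(counts) <- "integer"
  need <- c("sample", "cell_line", "treatment", "replicate")
  if (!all(need %in% names(meta)))
    stop_located("metadata must have columns: ", paste(need, collapse = ", "))
  meta <- as.data.frame(meta)[, need]
  missing <- setdiff(colnames(counts), meta$sample)
  if (length(missing))
    stop_located("sample(s) in counts missing from metadata: ",
                 paste(missing, collapse = ", "))
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  if (any(meta$replicate < 1 | meta$replicate != round(meta$replicate)))
    stop_located("replicate must be a positive integer")
  structure(list(counts = counts, meta = meta), class = "counts_matrix")
}

#' @export
print.counts_matrix <- function(x, ...) {
  cat("counts_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("cell lines:", paste(unique(x$meta$cell_line), collapse = ", "), "\n")
  cat("treatments:", paste(unique(x$meta$treatment), collapse = ", "), "\n")
  invisible(x)
}

#' Read a gene counts table and its sample metadata
#'
#' @param path TSV with a header row of sample ids; first column gene symbols.
#' @param meta_path TSV with columns `sample`, `cell_line`, `treatment`,
#'   `replicate`.
#' @return A [counts_matrix()] object; gene row order is preserved.
#' @export
read_counts_table <- function(path, meta_path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop_located("counts table needs >= 1 sample column")
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)
    stop_located("non-numeric count at row ", bad[1, 1], ", column ",
                 colnames(m)[bad[1, 2]])
  }
  rownames(m) <- genes
  meta <- read.delim(meta_path, check.names = FALSE, stringsAsFactors = FALSE)
  counts_matrix(m, meta)
}

#' Write a counts matrix and its metadata as TSV
#'
#' @param x a [counts_matrix()] object
#' @param path,meta_path output TSV paths
#' @return invisibly, `x`
#' @export
write_counts_table <- function(x, path, meta_path) {
  stopifnot(inherits(x, "counts_matrix"))
  tab <- data.frame(gene = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT semantics: one set per line, fields
#' `name TAB description TAB member1 TAB member2 ...`.
#'
#' @param path GMT file path
#' @return A `gene_set_collection`: a named list of character vectors with
#'   a `descriptions` attribute (named character vector).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop_located("GMT line ", i, ": fewer than 3 fields")
    nm <- f[1]
    if (nm %in% names(sets))
      stop_located("duplicate gene set name: ", nm)
    members <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (!length(members))
      stop_located("GMT line ", i, ": empty member list")
    sets[[nm]] <- members
    desc[nm] <- f[2]
  }
  gene_set_collection(sets, desc)
}

#' @rdname read_gene_sets
#' @param sets named list of character vectors (unique names, non-empty sets)
#' @param descriptions optional named character vector of set descriptions
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop_located("set names must be present and unique")
  if (any(lengths(sets) == 0)) stop_located("empty gene set")
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  }
  structure(lapply(sets, as.character), descriptions = descriptions[names(sets)],
            class = "gene_set_collection")
}

#' Write a gene set collection to GMT
#'
#' @param x a `gene_set_collection`
#' @param path output path
#' @return invisibly, `x`
#' @export
write_gene_sets <- function(x, path) {
  desc <- attr(x, "descriptions") %||% setNames(rep("", length(x)), names(x))
  lines <- vapply(names(x), function(nm) {
    paste(c(nm, desc[[nm]] %||% "", x[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(x)
}

PERT_TYPES <- c("compound", "knockdown", "overexpression")

#' Construct a ranked reference signature
#'
#' One perturbagen profile: genes ranked by descending differential-expression
#' score, ties broken by ascending gene symbol.
#'
#' @param id perturbagen id
#' @param pert_type one of `"compound"`, `"knockdown"`, `"overexpression"`
#' @param target_gene annotated target symbol; may be `""` for compounds,
#'   must be non-empty for knockdown/overexpression
#' @param cell_line cell line id
#' @param genes character vector of gene symbols
#' @param scores numeric differential-expression statistics, one per gene
#' @return A `ranked_signature` object (list with the fields above; `genes`
#'   and `scores` stored in rank order).
#' @export
ranked_signature <- function(id, pert_type, target_gene, cell_line, genes, scores) {
  pert_type <- match.arg(pert_type, PERT_TYPES)
  if (pert_type != "compound" && !nzchar(target_gene))
    stop_located("perturbagen '", id, "': ", pert_type,
                 " signatures must name a target gene")
  if (length(genes) != length(scores))
    stop_located("genes and scores differ in length")
  if (anyDuplicated(genes))
    stop_located("perturbagen '", id, "': duplicate gene in signature")
  ord <- order(-scores, genes)
  structure(list(id = id, pert_type = pert_type, target_gene = target_gene,
                 cell_line = cell_line, genes = genes[ord],
                 scores = scores[ord]),
            class = "ranked_signature")
}

#' Read a perturbagen reference-signature library
#'
#' Long TSV with columns `perturbagen_id`, `pert_type`, `target_gene`,
#' `cell_line`, `gene`, `score`; one [ranked_signature()] is built per
#' (perturbagen_id, cell_line).
#'
#' @param path TSV path
#' @return A list of `ranked_signature` objects, ordered by
#'   (perturbagen_id, cell_line).
#' @export
read_signature_library <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = NULL, colClasses = list(target_gene = "character"))
  need <- c("perturbagen_id", "pert_type", "target_gene", "cell_line",
            "gene", "score")
  if (!all(need %in% names(tab)))
    stop_located("signature library needs columns: ", paste(need, collapse = ", "))
  bad_type <- setdiff(unique(tab$pert_type), PERT_TYPES)
  if (length(bad_type))
    stop_located("unknown pert_type: ", paste(bad_type, collapse = ", "))
  key <- paste(tab$perturbagen_id, tab$cell_line, tab$gene, sep = "\r")
  if (anyDuplicated(key)) {
    d <- tab[duplicated(key), , drop = FALSE][1, ]
    stop_located("duplicate (perturbagen, cell_line, gene) row: ",
                 d$perturbagen_id, ", ", d$cell_line, ", ", d$gene)
  }
  tab$target_gene[is.na(tab$target_gene)] <- ""
  grp <- split(tab, paste(tab$perturbagen_id, tab$cell_line, sep = "\r"))
  lib <- lapply(grp, function(g) {
    if (length(unique(g$pert_type)) != 1L)
      stop_located("perturbagen '", g$perturbagen_id[1],
                   "': inconsistent pert_type")
    ranked_signature(g$perturbagen_id[1], g$pert_type[1], g$target_gene[1],
                     g$cell_line[1], g$gene, g$score)
  })
  unname(lib[order(names(lib))])
}

#' Write a signature library as long TSV
#'
#' @param library list of [ranked_signature()] objects
#' @param path output TSV path
#' @return invisibly, `library`
#' @export
write_signature_library <- function(library, path) {
  tabs <- lapply(library, function(s) {
    data.frame(perturbagen_id = s$id, pert_type = s$pert_type,
               target_gene = s$target_gene, cell_line = s$cell_line,
               gene = s$genes, score = s$scores, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  tab <- tab[order(tab$perturbagen_id, tab$cell_line, tab$gene), ]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(library)
}

#' Construct a dose-response viability matrix
#'
#' Percent viability over a concentration grid; row/column 0 are the single
#' agents and cell (0,0) the untreated control, anchored to 100 percent.
#'
#' @param drug_a,drug_b drug names
#' @param conc_a,conc_b strictly ascending non-negative concentrations (uM),
#'   first element 0
#' @param viability numeric matrix, `length(conc_a)` x `length(conc_b)`,
#'   percent viability; will be rescaled so `viability[1, 1] == 100`
#' @return A `dose_matrix` object.
#' @export
dose_matrix <- function(drug_a, drug_b, conc_a, conc_b, viability) {
  viability <- as.matrix(viability)
  for (nm in c("conc_a", "conc_b")) {
    v <- get(nm)
    if (length(v) < 2 || v[1] != 0 || any(diff(v) <= 0) || any(v < 0))
      stop_located(nm, " must be strictly ascending, non-negative, starting at 0")
  }
  if (!all(dim(viability) == c(length(conc_a), length(conc_b))))
    stop_located("viability grid does not match concentration vectors")
  if (any(!is.finite(viability)))
    stop_located("viability contains missing or non-finite cells")
  if (viability[1, 1] <= 0)
    stop_located("untreated (0,0) anchor must be positive")
  viability <- viability * (100 / viability[1, 1])
  dimnames(viability) <- list(format(conc_a, trim = TRUE),
                              format(conc_b, trim = TRUE))
  structure(list(drug_a = drug_a, drug_b = drug_b, conc_a = conc_a,
                 conc_b = conc_b, viability = viability),
            class = "dose_matrix")
}

#' Read a dose-response matrix from CSV
#'
#' Layout: cell (1,1) holds `drugA/drugB` (or is blank); the rest of row 1
#' are drug B concentrations, the rest of column 1 drug A concentrations
#' (both including 0); the body is percent viability. Viability is rescaled
#' so the untreated (0,0) cell equals 100.
#'
#' @param path CSV path
#' @param drug_a,drug_b optional drug names overriding the header cell
#' @return A [dose_matrix()] object.
#' @export
read_dose_matrix <- function(path, drug_a = NULL, drug_b = NULL) {
  raw <- as.matrix(read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                            check.names = FALSE))
  hdr <- raw[1, 1]
  nms <- strsplit(ifelse(is.na(hdr), "", hdr), "/", fixed = TRUE)[[1]]
  conc_a <- suppressWarnings(as.numeric(raw[-1, 1]))
  conc_b <- suppressWarnings(as.numeric(raw[1, -1]))
  if (any(is.na(conc_a)) || any(is.na(conc_b)))
    stop_located("non-numeric concentration in header row/column")
  if (conc_a[1] != 0 || conc_b[1] != 0)
    stop_located("missing (0,0) anchor: concentration vectors must start at 0")
  body <- suppressWarnings(apply(raw[-1, -1, drop = FALSE], c(1, 2), as.numeric))
  if (any(is.na(body))) {
    bad <- which(is.na(body), arr.ind = TRUE)[1, ]
    stop_located("non-numeric viability at grid cell (", bad[1], ",", bad[2], ")")
  }
  dose_matrix(drug_a %||% (if (length(nms) >= 1 && nzchar(nms[1])) nms[1] else "drug_a"),
              drug_b %||% (if (length(nms) >= 2) nms[2] else "drug_b"),
              conc_a, conc_b, body)
}

#' Write a dose-response matrix as CSV
#'
#' @param x a [dose_matrix()] object
#' @param path output CSV path
#' @return invisibly, `x`
#' @export
write_dose_matrix <- function(x, path) {
  stopifnot(inherits(x, "dose_matrix"))
  out <- rbind(c(paste0(x$drug_a, "/", x$drug_b), format(x$conc_b, trim = TRUE)),
               cbind(format(x$conc_a, trim = TRUE),
                     format(x$viability, trim = TRUE, digits = 15)))
  write.table(out, path, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(x)
}

#' Read a binary cell line x gene mutation matrix from CSV
#'
#' First column cell line ids, remaining columns genes; entries 0/1.
#'
#' @param path CSV path
#' @return Integer matrix, cell lines in rows, genes in columns.
#' @export
read_mutation_matrix <- function(path) {
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  lines <- as.character(tab[[1]])
  if (anyDuplicated(lines))
    stop_located("duplicate cell line id: ", lines[duplicated(lines)][1])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!all(m %in% c(0, 1)))
    stop_located("mutation matrix entries must be 0 or 1")
  storage.mode(m) <- "integer"
  rownames(m) <- lines
  m
}

#' Write a mutation matrix as CSV
#'
#' @param m binary matrix (cell lines x genes)
#' @param path output CSV path
#' @return invisibly, `m`
#' @export
write_mutation_matrix <- function(m, path) {
  tab <- data.frame(cell_line = rownames(m), m, check.names = FALSE)
  write.table(tab, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(m)
}

#' Read a plain-text gene list (one symbol per line)
#'
#' @param path file path
#' @return Character vector of unique symbols, order preserved.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path))
  unique(lines[nzchar(lines)])
}
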