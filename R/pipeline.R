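# End-to-end orchestration: one config drives DE, overlap/essential/ORA
# reporting, profile construction, partner prediction, Bliss scoring and
# the genomic association scan, with per-stage skipping for absent
# optional inputs and a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects input paths, cell-line roles, treatment ids and thresholds.
#' Paths may be `NULL`; stages whose inputs are absent are skipped (with a
#' logged reason), so the transcriptomics-only and synergy-only halves run
#' independently.
#'
#' @param counts,meta counts TSV and metadata TSV (required for the DE
#'   half)
#' @param library signature library TSV (optional)
#' @param essential essential-gene list, one symbol per line (optional)
#' @param gene_sets GMT file for ORA (optional)
#' @param dose_dir directory of dose-matrix CSVs (optional)
#' @param mutations mutation matrix CSV (optional)
#' @param synergy per-cell-line synergy TSV with columns `cell_line`,
#'   `bliss_score` (optional; required with `mutations`)
#' @param resistant,sensitive cell-line roles
#' @param reference,drug,combo treatment ids
#' @param lfc_min,fdr_max,dispersion,ncs_min,min_group,p_max,fdr_max_assoc
#'   stage thresholds
#' @param seed integer seed recorded in the manifest
#' @param out_dir output directory
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts = NULL, meta = NULL, library = NULL,
                            essential = NULL, gene_sets = NULL,
                            dose_dir = NULL, mutations = NULL, synergy = NULL,
                            resistant = "RESIST1",
                            sensitive = c("SENS1", "SENS2"),
                            reference = "DMSO", drug = "DNR",
                            combo = "COMBO", lfc_min = 1, fdr_max = 0.05,
                            dispersion = 0.16, ncs_min = 1, min_group = 3,
                            p_max = 0.001, fdr_max_assoc = 0.25, seed = 1L,
                            out_dir = "synergyseek_run") {
  cfg <- as.list(environment())
  for (nm in c("counts", "meta", "library", "essential", "gene_sets",
               "mutations", "synergy")) {
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]]))
      stop_located("config path for '", nm, "' does not exist: ", cfg[[nm]])
  }
  if (!is.null(dose_dir) && !dir.exists(dose_dir))
    stop_located("dose_dir does not exist: ", dose_dir)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys match the arguments of [pipeline_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (nm in c("counts", "meta", "library", "essential", "gene_sets",
               "dose_dir", "mutations", "synergy")) {
    if (!is.null(vals[[nm]]) && !grepl("^/", vals[[nm]]))
      vals[[nm]] <- file.path(base, vals[[nm]])
  }
  do.call(pipeline_config, vals)
}

.pipeline_log <- function(log, stage, status, detail = "") {
  log[[length(log) + 1]] <- list(stage = stage, status = status,
                                 detail = detail)
  message("[", stage, "] ", status, if (nzchar(detail)) paste0(": ", detail))
  log
}

#' Run the full pipeline
#'
#' Stages, in order: differential expression per (cell line, treatment);
#' overlap report; essential-gene overlap; ORA; resistance/response profile
#' construction; partner prediction against the signature library; Bliss
#' scoring of any dose matrices; the genomic association scan. Each stage
#' writes deterministic, sorted outputs under `config$out_dir`, and a
#' `manifest.json` records inputs, thresholds, seed and per-stage row
#' counts. Stages with missing inputs are skipped with a logged reason;
#' contract violations abort with the stage name.
#'
#' @param config a [pipeline_config()]
#' @return Invisibly, a list of in-memory stage results plus the run log.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  results <- list()
  counts_n <- list()

  de <- NULL
  if (!is.null(config$counts) && !is.null(config$meta)) {
    cm <- read_counts_table(config$counts, config$meta)
    de <- de_all(cm, reference = config$reference,
                 dispersion = config$dispersion, lfc_min = config$lfc_min,
                 fdr_max = config$fdr_max)
    de_dir <- file.path(out, "de")
    dir.create(de_dir, showWarnings = FALSE)
    for (key in sort(names(de))) {
      s <- de[[key]]
      tab <- s$table
      tab$call <- ifelse(tab$gene %in% s$up, "up",
                         ifelse(tab$gene %in% s$down, "down", "ns"))
      tab <- tab[order(tab$gene), ]
      write.table(tab, file.path(de_dir, paste0(key, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    counts_n$de <- length(de)
    log <- .pipeline_log(log, "de", "ok", paste(length(de), "contrasts"))
    results$de <- de

    rep_rows <- rbind(overlap_report(de, "by_cell_line"),
                      overlap_report(de, "by_treatment"))
    write.table(rep_rows, file.path(out, "overlap_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    counts_n$overlap <- nrow(rep_rows)
    log <- .pipeline_log(log, "overlap", "ok")
    results$overlap <- rep_rows
  } else {
    log <- .pipeline_log(log, "de", "skipped", "no counts/meta input")
  }

  if (!is.null(de) && !is.null(config$essential)) {
    ess <- read_gene_list(config$essential)
    rows <- do.call(rbind, lapply(sort(names(de)), function(key) {
      ov <- essential_overlap(de[[key]]$down, ess)
      data.frame(contrast = key, n_down = length(de[[key]]$down),
                 n_essential_down = ov$count,
                 members = paste(ov$members, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    write.table(rows, file.path(out, "essential_overlap.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    log <- .pipeline_log(log, "essential", "ok")
    results$essential <- rows
  } else {
    log <- .pipeline_log(log, "essential", "skipped",
                         "no essential list or no DE stage")
  }

  profiles <- NULL
  if (!is.null(de)) {
    profiles <- list(
      resist = build_resist_profile(de, config$resistant, config$sensitive,
                                    config$drug, config$combo),
      response = build_response_profile(de, config$resistant,
                                        config$sensitive, config$drug,
                                        config$combo))
    jsonlite::write_json(
      list(resist = list(label = profiles$resist$label,
                         up = profiles$resist$up,
                         down = profiles$resist$down),
           response = list(label = profiles$response$label,
                           up = profiles$response$up,
                           down = profiles$response$down),
           roles = list(resistant = config$resistant,
                        sensitive = config$sensitive,
                        drug = config$drug, combo = config$combo)),
      file.path(out, "profiles.json"), pretty = TRUE, auto_unbox = TRUE)
    log <- .pipeline_log(log, "profiles", "ok",
                         sprintf("resist %d+%d, response %d+%d",
                                 length(profiles$resist$up),
                                 length(profiles$resist$down),
                                 length(profiles$response$up),
                                 length(profiles$response$down)))
    results$profiles <- profiles
  } else {
    log <- .pipeline_log(log, "profiles", "skipped", "no DE stage")
  }

  if (!is.null(de) && !is.null(config$gene_sets)) {
    gs <- read_gene_sets(config$gene_sets)
    universe <- de[[1]]$table$gene
    ora <- do.call(rbind, lapply(c("resist", "response"), function(which) {
      prof <- profiles[[which]]
      do.call(rbind, lapply(c("up", "down"), function(dir) {
        q <- prof[[dir]]
        if (!length(q)) return(NULL)
        r <- suppressWarnings(ora_enrichment(q, gs, universe))
        cbind(profile = which, direction = dir, r)
      }))
    }))
    if (!is.null(ora))
      write.table(ora, file.path(out, "ora.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    log <- .pipeline_log(log, "ora", "ok")
    results$ora <- ora
  } else {
    log <- .pipeline_log(log, "ora", "skipped",
                         "no gene sets or no DE stage")
  }

  if (!is.null(profiles) && !is.null(config$library)) {
    lib <- read_signature_library(config$library)
    cand <- predict_partners(profiles$resist, profiles$response, lib,
                             ncs_min = config$ncs_min)
    write.table(cand, file.path(out, "candidates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    log <- .pipeline_log(log, "connect", "ok",
                         paste(nrow(cand), "candidate classes"))
    results$candidates <- cand
  } else {
    log <- .pipeline_log(log, "connect", "skipped",
                         "no signature library or no profiles")
  }

  if (!is.null(config$dose_dir)) {
    files <- sort(list.files(config$dose_dir, pattern = "\\.csv$",
                             full.names = TRUE))
    if (length(files)) {
      rows <- do.call(rbind, lapply(files, function(f) {
        r <- bliss_matrix_score(read_dose_matrix(f))
        data.frame(file = basename(f), drug_a = r$drug_a, drug_b = r$drug_b,
                   bliss_score = r$bliss_score, label = r$label,
                   stringsAsFactors = FALSE)
      }))
      write.table(rows, file.path(out, "synergy.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      log <- .pipeline_log(log, "bliss", "ok",
                           paste(nrow(rows), "matrices"))
      results$synergy <- rows
    } else {
      log <- .pipeline_log(log, "bliss", "skipped", "no CSV in dose_dir")
    }
  } else {
    log <- .pipeline_log(log, "bliss", "skipped", "no dose matrices")
  }

  if (!is.null(config$mutations) && !is.null(config$synergy)) {
    mut <- read_mutation_matrix(config$mutations)
    syn_tab <- read.delim(config$synergy, stringsAsFactors = FALSE)
    syn <- setNames(syn_tab$bliss_score, syn_tab$cell_line)
    assoc <- suppressMessages(
      run_association_scan(mut, syn, min_group = config$min_group,
                           p_max = config$p_max,
                           fdr_max = config$fdr_max_assoc))
    write.table(assoc, file.path(out, "association.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    split <- split_high_low(syn)
    write.table(data.frame(cell_line = names(split), synergy_group = split),
                file.path(out, "high_low_split.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    log <- .pipeline_log(log, "assoc", "ok",
                         paste(sum(assoc$significant), "significant"))
    results$association <- assoc
  } else {
    log <- .pipeline_log(log, "assoc", "skipped",
                         "no mutation matrix or synergy vector")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("synergyseek")),
    seed = config$seed,
    inputs = config[c("counts", "meta", "library", "essential", "gene_sets",
                      "dose_dir", "mutations", "synergy")],
    roles = config[c("resistant", "sensitive", "reference", "drug", "combo")],
    thresholds = config[c("lfc_min", "fdr_max", "dispersion", "ncs_min",
                          "min_group", "p_max", "fdr_max_assoc")],
    stages = log)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       pretty = TRUE, auto_unbox = TRUE, force = TRUE,
                       null = "null")
  results$log <- log
  invisible(results)
}
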