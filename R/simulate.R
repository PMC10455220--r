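# Synthetic-data generators with planted ground truth: NB counts with
# induction-dominated treatment DE and cell-line-specific resistance and
# response programs, a perturbagen library with planted reversers, decoys
# and knockdown/overexpression pairs, Bliss dose matrices with a planted
# excess, and mutation matrices with planted synergy-shifting genes.
# All generators are pure functions of (config, seed).

#' Simulation configuration
#'
#' Defaults describe the emulated study design: three cell lines (one
#' resistant, two sensitive), four treatments (DMSO reference, two
#' monotherapies, their combination), three replicates per condition,
#' NB dispersion 0.16 (BCV 0.4) and 79 percent of treatment-evoked changes
#' being inductions. Planted effects (log2FC floor 2.5, resistance program
#' 60 up + 30 down, response program 40 up + 10 down) are strong,
#' unambiguous program genes sized by a priori power analysis at this
#' design so recovery fractions are estimable.
#'
#' @param n_genes number of genes
#' @param n_cell_lines number of cell lines (first is the resistant one)
#' @param n_reps replicates per (cell line, treatment)
#' @param fraction_up fraction of planted background DE that is up (0.79)
#' @param de_lfc_mean floor of planted |log2 fold change| (2.5); magnitudes
#'   are `de_lfc_mean + Exp(1)`
#' @param nb_dispersion NB dispersion of counts (0.16)
#' @param library_size_mean expected per-sample library size (5e5)
#' @param n_de_shared treatment-wide DE genes planted in every cell line
#' @param n_de_private condition-private DE genes
#' @param program_sizes list with `resist_up`, `resist_down`,
#'   `response_up`, `response_down`
#' @param library list: `n_perturbagens` (decoy compounds), `n_reversers`
#'   (planted partner compounds), `kd_oe_pairs` (decoy KD/OE target pairs),
#'   `n_ambiguous` (of those, pairs planted concordant), `n_cell_lines`
#'   (library cell lines), `planted_scale` (score magnitude of planted
#'   genes)
#' @param dose list: `conc_a`, `conc_b` (concentration grids incl. 0),
#'   `planted_delta` (true Bliss excess, percent), `noise_sd` (Gaussian
#'   viability noise, percent), `emax_a`, `emax_b`, `ec50_a`, `ec50_b`,
#'   `hill`
#' @param assoc list: `n_cell_lines`, `n_genes`, `n_assoc` (planted
#'   associated genes), `effect_d` (standardized synergy shift in
#'   carriers), `mut_freq` (mutation probability)
#' @param seed integer RNG seed
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       n_cell_lines = 3,
                       n_reps = 3,
                       fraction_up = 0.79,
                       de_lfc_mean = 2.5,
                       nb_dispersion = 0.16,
                       library_size_mean = 5e5,
                       n_de_shared = 100,
                       n_de_private = 80,
                       program_sizes = list(resist_up = 60, resist_down = 30,
                                            response_up = 40, response_down = 10),
                       library = list(n_perturbagens = 30, n_reversers = 2,
                                      kd_oe_pairs = 6, n_ambiguous = 2,
                                      n_cell_lines = 2, planted_scale = 4),
                       dose = list(conc_a = c(0, 0.1, 0.3, 1, 3, 10),
                                   conc_b = c(0, 0.3, 1, 3),
                                   planted_delta = 15, noise_sd = 3,
                                   emax_a = 0.5, emax_b = 0.4,
                                   ec50_a = 1, ec50_b = 1, hill = 1),
                       assoc = list(n_cell_lines = 30, n_genes = 20,
                                    n_assoc = 1, effect_d = 3,
                                    mut_freq = 0.3),
                       seed = 1L) {
  cfg <- list(n_genes = n_genes, n_cell_lines = n_cell_lines, n_reps = n_reps,
              fraction_up = fraction_up, de_lfc_mean = de_lfc_mean,
              nb_dispersion = nb_dispersion,
              library_size_mean = library_size_mean,
              n_de_shared = n_de_shared, n_de_private = n_de_private,
              program_sizes = program_sizes, library = library, dose = dose,
              assoc = assoc, seed = as.integer(seed))
  sizes <- c(n_genes, n_cell_lines, n_reps, library_size_mean,
             unlist(program_sizes), library$n_perturbagens,
             assoc$n_cell_lines, assoc$n_genes)
  if (any(sizes <= 0)) stop_located("all sizes must be positive")
  if (fraction_up < 0 || fraction_up > 1)
    stop_located("fraction_up must lie in [0, 1]")
  if (nb_dispersion < 0) stop_located("nb_dispersion must be >= 0")
  if (library$n_reversers > library$n_perturbagens)
    stop_located("n_reversers exceeds n_perturbagens")
  if (library$n_ambiguous > library$kd_oe_pairs)
    stop_located("n_ambiguous exceeds kd_oe_pairs")
  need <- 3 * n_de_shared + 3 * n_cell_lines * n_de_private +
    sum(unlist(program_sizes))
  if (sum(unlist(program_sizes)) > n_genes)
    stop_located("program sizes exceed n_genes")
  if (need > n_genes)
    stop_located("planted gene demand (", need, ") exceeds n_genes")
  structure(cfg, class = "sim_config")
}

.sim_gene_ids <- function(n) sprintf("G%05d", seq_len(n))

.sim_cell_lines <- function(n) {
  c("RESIST1", sprintf("SENS%d", seq_len(n - 1)))
}

.sim_lfc <- function(n, floor_lfc) floor_lfc + rexp(n, rate = 1)

#' Simulate treatment-response counts with planted ground truth
#'
#' Generates an NB gene x sample count matrix over
#' `n_cell_lines x {DMSO, DNR, AraC, COMBO} x n_reps`. Planted DE genes
#' carry `|log2FC| >= de_lfc_mean`; the up:down ratio of background DE is
#' `fraction_up`. A resistance program is planted only in the resistant
#' line's DNR condition; a response program is planted in every sensitive
#' line's DNR and COMBO conditions. Shared drug-response genes are planted
#' in every cell line per treatment so that profile construction has real
#' exclusion work to do. Program and DE genes are drawn from moderately-to-
#' highly expressed genes (baseline mean >= 20) so their recovery is
#' determined by the planted effect, not by counting noise.
#'
#' @param config a [sim_config()]
#' @return List with `counts` (a [counts_matrix()]) and `truth` (a
#'   `sim_truth` list: `planted_de` per condition, per-gene `lfc`
#'   magnitudes, `resist_program`, `response_program`, the design labels,
#'   and the generating `base_mean` and per-sample `depth_factors` so
#'   count marginals can be checked against the planted NB means).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, .simulate_counts_impl(config))
}

.simulate_counts_impl <- function(config) {
  genes <- .sim_gene_ids(config$n_genes)
  lines <- .sim_cell_lines(config$n_cell_lines)
  resistant <- lines[1]
  sensitive <- lines[-1]
  treatments <- c("DMSO", "DNR", "AraC", "COMBO")
  ps <- config$program_sizes
  n_shared <- config$n_de_shared
  n_private <- config$n_de_private
  if (config$de_lfc_mean <= 0) {
    # zero planted effect: no differential expression at all, empty truth
    ps <- list(resist_up = 0, resist_down = 0, response_up = 0,
               response_down = 0)
    n_shared <- 0
    n_private <- 0
  }

  base_mu <- exp(rnorm(config$n_genes, log(50), 1.5))
  base_mu <- pmin(base_mu, 2e4)
  names(base_mu) <- genes
  eligible <- genes[base_mu >= 20]
  need <- 3 * n_shared +
    3 * config$n_cell_lines * n_private + sum(unlist(ps))
  if (length(eligible) < need)
    stop_located("planted gene demand (", need, ") exceeds the ",
                 "moderately-expressed pool (", length(eligible),
                 "); increase n_genes or reduce planted set sizes")

  draw <- function(pool, n) {
    picked <- sample(pool, n)
    list(picked = picked, rest = setdiff(pool, picked))
  }
  d <- draw(eligible, ps$resist_up);    resist_up <- d$picked
  d <- draw(d$rest, ps$resist_down);    resist_down <- d$picked
  d <- draw(d$rest, ps$response_up);    response_up <- d$picked
  d <- draw(d$rest, ps$response_down);  response_down <- d$picked
  pool <- d$rest

  split_updown <- function(g, frac_up) {
    n_up <- rbinom(1, length(g), frac_up)
    up <- if (n_up > 0) g[seq_len(n_up)] else character()
    list(up = up, down = setdiff(g, up))
  }

  # shared per-treatment response (all cell lines) and per-condition
  # private DE, all disjoint from the programs
  shared <- list()
  for (tr in c("DNR", "AraC", "COMBO")) {
    d <- draw(pool, n_shared); pool <- d$rest
    shared[[tr]] <- split_updown(sample(d$picked), config$fraction_up)
  }
  planted <- list()
  lfc_map <- setNames(numeric(0), character(0))
  assign_lfc <- function(g) {
    new <- setdiff(g, names(lfc_map))
    if (length(new)) {
      lfc_map[new] <<- .sim_lfc(length(new), config$de_lfc_mean)
    }
  }
  for (cl in lines) {
    for (tr in c("DNR", "AraC", "COMBO")) {
      d <- draw(pool, n_private); pool <- d$rest
      priv <- split_updown(sample(d$picked), config$fraction_up)
      up <- union(shared[[tr]]$up, priv$up)
      down <- union(shared[[tr]]$down, priv$down)
      if (cl == resistant && tr == "DNR") {
        up <- union(up, resist_up)
        down <- union(down, resist_down)
      }
      if (cl %in% sensitive && tr %in% c("DNR", "COMBO")) {
        up <- union(up, response_up)
        down <- union(down, response_down)
      }
      assign_lfc(c(up, down))
      planted[[de_key(cl, tr)]] <- list(cell_line = cl, treatment = tr,
                                        up = sort(up), down = sort(down))
    }
  }

  n_samp <- length(lines) * length(treatments) * config$n_reps
  sample_ids <- character(n_samp)
  meta <- data.frame(sample = character(n_samp), cell_line = character(n_samp),
                     treatment = character(n_samp), replicate = integer(n_samp),
                     stringsAsFactors = FALSE)
  counts <- matrix(0L, config$n_genes, n_samp,
                   dimnames = list(genes, NULL))
  depth_scale <- config$library_size_mean / sum(base_mu)
  depth_factors <- numeric(n_samp)
  i <- 0
  for (cl in lines) {
    for (tr in treatments) {
      mu <- base_mu
      if (tr != "DMSO") {
        pl <- planted[[de_key(cl, tr)]]
        mu[pl$up] <- mu[pl$up] * 2^lfc_map[pl$up]
        mu[pl$down] <- mu[pl$down] * 2^(-lfc_map[pl$down])
      }
      for (r in seq_len(config$n_reps)) {
        i <- i + 1
        depth <- depth_scale * exp(rnorm(1, 0, 0.15))
        depth_factors[i] <- depth
        counts[, i] <- rnbinom(config$n_genes,
                               size = 1 / max(config$nb_dispersion, 1e-8),
                               mu = mu * depth)
        sample_ids[i] <- sprintf("%s_%s_r%d", cl, tr, r)
        meta[i, ] <- list(sample_ids[i], cl, tr, r)
      }
    }
  }
  colnames(counts) <- sample_ids
  names(depth_factors) <- sample_ids

  lfc_signed <- lfc_map
  truth <- structure(list(
    planted_de = planted,
    lfc = lfc_signed,
    resist_program = list(up = sort(resist_up), down = sort(resist_down)),
    response_program = list(up = sort(response_up), down = sort(response_down)),
    resistant = resistant, sensitive = sensitive,
    drug = "DNR", combo = "COMBO", reference = "DMSO",
    genes = genes, base_mean = base_mu,
    depth_factors = depth_factors), class = "sim_truth")
  list(counts = counts_matrix(counts, meta), truth = truth)
}

#' Simulate a perturbagen reference-signature library
#'
#' Builds a library over the simulated gene universe for
#' `library$n_cell_lines` cell lines containing: decoy compounds
#' (exchangeable N(0,1) scores, no target annotation), planted reverser
#' compounds whose scores place resistance-program up-genes at the bottom,
#' resistance-program down-genes at the top, and response-program genes
#' concordantly (so they reverse the resistance profile and mimic the
#' response profile), one concordant target-gene knockdown signature per
#' reverser (targets `TGT1`, `TGT2`, ...) plus a discordant overexpression
#' partner, and `kd_oe_pairs` decoy knockdown/overexpression target pairs
#' of which `n_ambiguous` are planted concordant with the reverser pattern
#' in both KD and OE (removed by the ambiguity filter).
#'
#' @param config a [sim_config()]
#' @param truth the `sim_truth` from [simulate_counts()]
#' @return List with `library` (list of [ranked_signature()]) and
#'   `planted_partners` (ids of the planted reverser compounds),
#'   `planted_classes` (their class labels), `ambiguous_targets`.
#' @export
simulate_signature_library <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  with_local_seed(config$seed + 1000L, .simulate_library_impl(config, truth))
}

.simulate_library_impl <- function(config, truth) {
  lc <- config$library
  genes <- truth$genes
  lib_lines <- sprintf("LIBCELL%d", seq_len(lc$n_cell_lines))
  sc <- lc$planted_scale

  plant_pattern <- function(scores, flip = 1) {
    # reverser pattern: low on resist-up, high on resist-down,
    # high on response-up, low on response-down; flip = -1 inverts
    plant <- function(g, sgn) {
      scores[g] <<- sgn * flip * (sc + rexp(length(g), 1))
    }
    plant(truth$resist_program$up, -1)
    plant(truth$resist_program$down, +1)
    plant(truth$response_program$up, +1)
    plant(truth$response_program$down, -1)
    scores
  }
  new_scores <- function() setNames(rnorm(length(genes)), genes)

  library <- list()
  add <- function(id, type, target, cell, scores) {
    library[[length(library) + 1]] <<-
      ranked_signature(id, type, target, cell, genes, unname(scores))
  }

  reverser_ids <- sprintf("REV%02d", seq_len(lc$n_reversers))
  reverser_targets <- sprintf("TGT%d", seq_len(lc$n_reversers))
  for (i in seq_len(lc$n_reversers)) {
    for (cell in lib_lines) {
      add(reverser_ids[i], "compound", reverser_targets[i], cell,
          plant_pattern(new_scores()))
      add(paste0("KD_", reverser_targets[i]), "knockdown",
          reverser_targets[i], cell, plant_pattern(new_scores()))
      add(paste0("OE_", reverser_targets[i]), "overexpression",
          reverser_targets[i], cell, plant_pattern(new_scores(), flip = -1))
    }
  }
  n_decoy <- lc$n_perturbagens - lc$n_reversers
  for (i in seq_len(n_decoy)) {
    for (cell in lib_lines) {
      add(sprintf("DECOY%03d", i), "compound", "", cell, new_scores())
    }
  }
  amb_targets <- sprintf("AMB%d", seq_len(lc$n_ambiguous))
  for (i in seq_len(lc$kd_oe_pairs)) {
    amb <- i <= lc$n_ambiguous
    tgt <- if (amb) amb_targets[i] else sprintf("DTGT%d", i - lc$n_ambiguous)
    for (cell in lib_lines) {
      kd_scores <- if (amb) plant_pattern(new_scores()) else new_scores()
      oe_scores <- if (amb) plant_pattern(new_scores()) else new_scores()
      add(paste0("KD_", tgt), "knockdown", tgt, cell, kd_scores)
      add(paste0("OE_", tgt), "overexpression", tgt, cell, oe_scores)
    }
  }
  list(library = library, planted_partners = reverser_ids,
       planted_classes = reverser_targets, ambiguous_targets = amb_targets)
}

#' Simulate a dose-response matrix with a planted Bliss excess
#'
#' Monotherapy viabilities follow Hill-type inhibition curves; each
#' combination cell's viability is the Bliss-expected viability minus
#' `dose$planted_delta` (percent), plus Gaussian noise of sd
#' `dose$noise_sd`, clamped to `[0, 120]`. The untreated anchor is 100.
#' Curve maxima are capped (defaults 0.5/0.4) so expected combination
#' viability stays well clear of the clamp.
#'
#' @param config a [sim_config()]
#' @param drug_a,drug_b drug names recorded in the matrix
#' @return List with `matrix` (a [dose_matrix()]) and `truth` (list with
#'   `planted_delta`).
#' @export
simulate_dose_matrix <- function(config, drug_a = "DNR", drug_b = "PARTNER") {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed + 2000L, {
    dc <- config$dose
    hill <- function(conc, emax, ec50, h) {
      ifelse(conc == 0, 0, emax * conc^h / (conc^h + ec50^h))
    }
    y_a <- hill(dc$conc_a, dc$emax_a, dc$ec50_a, dc$hill)
    y_b <- hill(dc$conc_b, dc$emax_b, dc$ec50_b, dc$hill)
    expected <- outer(y_a, y_b, bliss_expected)
    viab <- 100 * (1 - expected)
    combo <- outer(dc$conc_a > 0, dc$conc_b > 0, `&`)
    viab[combo] <- viab[combo] - dc$planted_delta
    if (dc$noise_sd > 0) {
      noise <- matrix(rnorm(length(viab), 0, dc$noise_sd), nrow(viab))
      noise[1, 1] <- 0
      viab <- viab + noise
    }
    viab <- pmin(pmax(viab, 0), 120)
    viab[1, 1] <- 100
    list(matrix = dose_matrix(drug_a, drug_b, dc$conc_a, dc$conc_b, viab),
         truth = list(planted_delta = dc$planted_delta))
  })
}

#' Simulate a mutation matrix and synergy vector with planted associations
#'
#' Mutations are independent Bernoulli(`assoc$mut_freq`); synergy is
#' standard normal, shifted by `assoc$effect_d` in carriers of the
#' `assoc$n_assoc` planted genes. Warns when a planted gene's carrier count
#' falls below the association scan's minimum group size (truth then
#' unrecoverable).
#'
#' @param config a [sim_config()]
#' @param min_group the scan minimum used for the warning check (default 3)
#' @return List with `mutations` (binary matrix), `synergy` (named
#'   vector) and `truth` (list with `assoc_genes`, `effect_d`).
#' @export
simulate_mutation_synergy <- function(config, min_group = 3) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed + 3000L, {
    ac <- config$assoc
    lines <- sprintf("CL%03d", seq_len(ac$n_cell_lines))
    genes <- sprintf("MUT%03d", seq_len(ac$n_genes))
    m <- matrix(rbinom(ac$n_cell_lines * ac$n_genes, 1, ac$mut_freq),
                ac$n_cell_lines, ac$n_genes,
                dimnames = list(lines, genes))
    assoc_genes <- genes[seq_len(ac$n_assoc)]
    synergy <- rnorm(ac$n_cell_lines, 0, 1)
    for (g in assoc_genes) {
      synergy <- synergy + ac$effect_d * m[, g]
    }
    names(synergy) <- lines
    low <- assoc_genes[colSums(m[, assoc_genes, drop = FALSE]) < min_group |
                       (ac$n_cell_lines -
                        colSums(m[, assoc_genes, drop = FALSE])) < min_group]
    if (length(low))
      warning("planted gene(s) below the scan minimum group size: ",
              paste(low, collapse = ", "))
    list(mutations = m, synergy = synergy,
         truth = list(assoc_genes = assoc_genes, effect_d = ac$effect_d))
  })
}

#' Write a complete synthetic study to disk
#'
#' Runs all generators and writes counts TSV + metadata TSV, signature
#' library TSV, dose matrix CSV, mutation matrix CSV, an essential-gene
#' list (a sample of planted down-regulated genes), and a ground-truth
#' JSON.
#'
#' @param config a [sim_config()]
#' @param dir output directory (created if needed)
#' @return Invisibly, a list of the generated objects.
#' @export
simulate_study <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cm <- simulate_counts(config)
  lib <- simulate_signature_library(config, cm$truth)
  dm <- simulate_dose_matrix(config)
  ms <- simulate_mutation_synergy(config)
  write_counts_table(cm$counts, file.path(dir, "counts.tsv"),
                     file.path(dir, "meta.tsv"))
  write_signature_library(lib$library, file.path(dir, "library.tsv"))
  dir.create(file.path(dir, "dose"), showWarnings = FALSE)
  write_dose_matrix(dm$matrix, file.path(dir, "dose", "DNR_PARTNER.csv"))
  write_mutation_matrix(ms$mutations, file.path(dir, "mutations.csv"))
  write.table(data.frame(cell_line = names(ms$synergy),
                         bliss_score = unname(ms$synergy)),
              file.path(dir, "synergy.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ess <- with_local_seed(config$seed + 4000L, {
    all_down <- unique(unlist(lapply(cm$truth$planted_de, `[[`, "down")))
    sample(all_down, min(50, length(all_down)))
  })
  writeLines(sort(ess), file.path(dir, "essential.txt"))
  truth <- list(
    resist_program = cm$truth$resist_program,
    response_program = cm$truth$response_program,
    planted_de = lapply(cm$truth$planted_de, function(p)
      list(up = p$up, down = p$down)),
    planted_partners = lib$planted_partners,
    planted_classes = lib$planted_classes,
    ambiguous_targets = lib$ambiguous_targets,
    planted_delta = dm$truth$planted_delta,
    assoc_genes = ms$truth$assoc_genes,
    effect_d = ms$truth$effect_d,
    resistant = cm$truth$resistant, sensitive = cm$truth$sensitive,
    drug = cm$truth$drug, combo = cm$truth$combo,
    reference = cm$truth$reference, seed = config$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(counts = cm$counts, truth = cm$truth, library = lib,
                 dose = dm, assoc = ms))
}
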