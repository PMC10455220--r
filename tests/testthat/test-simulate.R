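# Generator contracts: determinism, planted structure, count marginals
# matching the planted NB means, and configuration validation.

test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(seed = 19)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$resist_program, b$truth$resist_program)

  la <- simulate_signature_library(cfg, a$truth)
  lb <- simulate_signature_library(cfg, b$truth)
  expect_identical(la$library[[1]]$scores, lb$library[[1]]$scores)

  da <- simulate_dose_matrix(cfg)
  db <- simulate_dose_matrix(cfg)
  expect_identical(da$matrix$viability, db$matrix$viability)

  ma <- simulate_mutation_synergy(cfg)
  mb <- simulate_mutation_synergy(cfg)
  expect_identical(ma$mutations, mb$mutations)
  expect_identical(ma$synergy, mb$synergy)

  # different seed, different draw
  c2 <- simulate_counts(sim_config(seed = 20))
  expect_false(identical(a$counts$counts, c2$counts$counts))
})

test_that("planted structure obeys the configured design", {
  cfg <- sim_config(seed = 23)
  sim <- simulate_counts(cfg)
  tr <- sim$truth
  # programs disjoint
  expect_length(intersect(unlist(tr$resist_program),
                          unlist(tr$response_program)), 0)
  # resistance program only in the resistant line's drug condition
  for (key in names(tr$planted_de)) {
    pl <- tr$planted_de[[key]]
    in_up <- any(tr$resist_program$up %in% pl$up)
    if (pl$cell_line == tr$resistant && pl$treatment == tr$drug) {
      expect_true(all(tr$resist_program$up %in% pl$up))
      expect_true(all(tr$resist_program$down %in% pl$down))
    } else {
      expect_false(in_up)
    }
    # response program in every sensitive drug/combo condition, nowhere else
    should_have <- pl$cell_line %in% tr$sensitive &&
      pl$treatment %in% c(tr$drug, tr$combo)
    expect_identical(all(tr$response_program$up %in% pl$up), should_have)
  }
  # planted |lfc| respects the configured floor
  expect_true(all(tr$lfc >= cfg$de_lfc_mean))
  # up:down ratio of planted background DE close to fraction_up
  ups <- sum(lengths(lapply(tr$planted_de, `[[`, "up")))
  downs <- sum(lengths(lapply(tr$planted_de, `[[`, "down")))
  expect_equal(ups / (ups + downs), cfg$fraction_up, tolerance = 0.08)
})

test_that("count marginals match the planted NB means", {
  cfg <- sim_config(seed = 29)
  sim <- simulate_counts(cfg)
  tr <- sim$truth
  counts <- sim$counts$counts
  meta <- sim$counts$meta
  # DMSO samples carry no planted effect: expected mean is
  # base_mean * depth_factor; z-scores under the NB variance should be
  # standard-normal-ish in aggregate
  dmso <- meta$sample[meta$treatment == "DMSO"]
  mu <- outer(tr$base_mean, tr$depth_factors[dmso])
  v <- mu + cfg$nb_dispersion * mu^2
  z <- (counts[, dmso] - mu) / sqrt(v)
  expect_lt(abs(mean(z)), 0.02)
  expect_equal(sd(as.vector(z)), 1, tolerance = 0.05)
  # chi-square-style check on per-gene standardized means
  zg <- rowMeans(z) * sqrt(ncol(z))
  expect_equal(mean(zg^2), 1, tolerance = 0.15)
})

test_that("configuration validation rejects impossible designs", {
  expect_error(sim_config(n_genes = 100), "exceed")
  expect_error(sim_config(fraction_up = 1.2), "fraction_up")
  expect_error(sim_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(sim_config(library = list(n_perturbagens = 2, n_reversers = 3,
                                         kd_oe_pairs = 2, n_ambiguous = 1,
                                         n_cell_lines = 1, planted_scale = 4)),
               "n_reversers")
  big <- sim_config()
  big$program_sizes$resist_up <- 5000
  expect_error(do.call(sim_config, unclass(big)[setdiff(names(big), "")]),
               "exceed")
})

test_that("zero planted effect size yields empty truth sets", {
  cfg <- sim_config(seed = 61, de_lfc_mean = 0)
  sim <- simulate_counts(cfg)
  expect_length(unlist(sim$truth$resist_program), 0)
  expect_length(unlist(sim$truth$response_program), 0)
  expect_true(all(vapply(sim$truth$planted_de, function(p)
    length(p$up) + length(p$down), numeric(1)) == 0))
})

test_that("mutation generator warns when a planted gene is too rare to test", {
  cfg <- sim_config(seed = 3, assoc = list(n_cell_lines = 12, n_genes = 5,
                                           n_assoc = 1, effect_d = 3,
                                           mut_freq = 0.05))
  expect_warning(simulate_mutation_synergy(cfg, min_group = 6),
                 "minimum group size")
})

test_that("simulate_study writes a complete, readable study directory", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 37)
  simulate_study(cfg, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "counts.tsv", "meta.tsv", "library.tsv", "mutations.csv",
    "synergy.tsv", "essential.txt", "truth.json")))))
  cm <- read_counts_table(file.path(dir, "counts.tsv"),
                          file.path(dir, "meta.tsv"))
  expect_equal(nrow(cm$counts), cfg$n_genes)
  lib <- read_signature_library(file.path(dir, "library.tsv"))
  expect_gt(length(lib), 0)
  dm <- read_dose_matrix(file.path(dir, "dose", "DNR_PARTNER.csv"))
  expect_equal(dm$viability[1, 1], 100)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(unlist(truth$planted_classes),
                   c("TGT1", "TGT2"))
})
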