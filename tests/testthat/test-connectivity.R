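# Enrichment score against a brute-force running-sum oracle, WTCS
# conventions, sign-stratified normalization, and the partner-prediction
# filters on planted libraries.

test_that("enrichment score hits closed-form extremes and the hand-worked case", {
  r10 <- make_ranked(10)
  expect_equal(enrichment_score(genes_at_ranks(1:2), r10), 1)
  expect_equal(enrichment_score(genes_at_ranks(9:10), r10), -1)
  r4 <- make_ranked(4)
  expect_equal(enrichment_score(genes_at_ranks(c(1, 3)), r4), 0.5)
  expect_warning(es0 <- enrichment_score("absent", r10), "no query gene")
  expect_equal(es0, 0)
})

test_that("enrichment score equals the brute-force oracle for all subsets, N <= 12", {
  for (N in c(5, 8, 12)) {
    r <- make_ranked(N)
    for (mask in seq_len(2^N - 1)) {
      ranks <- which(bitwAnd(mask, 2^(seq_len(N) - 1)) > 0)
      expect_equal(enrichment_score(genes_at_ranks(ranks), r),
                   oracle_es(ranks, N), tolerance = 1e-12)
    }
  }
})

test_that("reversing the ranked list negates the enrichment score", {
  set.seed(21)
  N <- 30
  fwd <- ranked_signature("f", "compound", "", "C1", paste0("g", 1:N),
                          scores = N:1)
  rev_ <- ranked_signature("r", "compound", "", "C1", paste0("g", 1:N),
                           scores = 1:N)
  for (i in 1:50) {
    q <- paste0("g", sample(N, sample(2:10, 1)))
    a <- enrichment_score(q, fwd)
    b <- enrichment_score(q, rev_)
    if (abs(abs(a) - abs(b)) < 1e-12 && abs(a + b) > 1e-12) next # exact tie
    expect_equal(b, -a, tolerance = 1e-12)
  }
})

test_that("WTCS combines opposite-sign scores and handles empty sets", {
  # ranks 1..10: up at top, down at bottom -> strong positive wtcs
  r <- make_ranked(10)
  res <- wtcs(genes_at_ranks(1:2), genes_at_ranks(9:10), r)
  expect_equal(res$wtcs, (1 - (-1)) / 2)
  # same-sign rule: both sets at the top
  res2 <- wtcs(genes_at_ranks(1:2), genes_at_ranks(3:4), r)
  expect_true(sign(res2$es_up) == sign(res2$es_down))
  expect_equal(res2$wtcs, 0)
  # single-set convention: down-set es negated
  res3 <- wtcs(character(), genes_at_ranks(9:10), r)
  expect_equal(res3$wtcs, 1)  # es_down = -1 at the extreme bottom
  expect_error(wtcs(c("g1"), c("g1"), r), "overlap")
})

test_that("WTCS is invariant to relabeling genes outside the query sets", {
  set.seed(4)
  N <- 20
  scores <- sort(rnorm(N), decreasing = TRUE)
  g1 <- paste0("g", 1:N)
  g2 <- g1
  outside <- setdiff(seq_len(N), c(2, 5, 15, 18))
  g2[outside] <- paste0("h", outside)   # relabel non-query genes
  r1 <- ranked_signature("a", "compound", "", "C", g1, scores)
  r2 <- ranked_signature("b", "compound", "", "C", g2, scores)
  up <- g1[c(2, 5)]
  down <- g1[c(15, 18)]
  expect_equal(wtcs(up, down, r1)$wtcs, wtcs(up, down, r2)$wtcs)
})

test_that("NCS normalizes by the same-sign group mean", {
  df <- data.frame(perturbagen_id = c("p1", "p2", "p3", "p4"),
                   pert_type = "compound", target_gene = "",
                   cell_line = "C1",
                   es_up = 0, es_down = 0,
                   wtcs = c(0.2, 0.4, -0.5, 0))
  out <- normalize_scores(df)
  expect_equal(out$ncs[1:2], c(0.2, 0.4) / 0.3)
  expect_equal(out$ncs[3], -1)   # singleton negative stratum
  expect_equal(out$ncs[4], 0)
  # post-condition: mean |ncs| per sign stratum is 1
  expect_equal(mean(abs(out$ncs[out$ncs > 0])), 1)
})

test_that("partner prediction recovers planted reversers and applies all filters", {
  cfg <- sim_config(seed = 31)
  sim <- simulate_counts(cfg)
  lib <- simulate_signature_library(cfg, sim$truth)
  resist <- expression_signature(sim$truth$resist_program$up,
                                 sim$truth$resist_program$down, "DNRResist")
  response <- expression_signature(sim$truth$response_program$up,
                                   sim$truth$response_program$down,
                                   "DNRResponse")
  cand <- predict_partners(resist, response, lib$library)
  expect_true(cand$class[1] %in% lib$planted_classes)
  expect_true(all(cand$n_support_cell_lines >= 1))
  # planted ambiguous KD/OE pairs removed
  members <- unlist(strsplit(cand$members, ","))
  expect_length(intersect(members, paste0("KD_", lib$ambiguous_targets)), 0)
  expect_length(intersect(members, paste0("OE_", lib$ambiguous_targets)), 0)
  expect_false(any(lib$ambiguous_targets %in% cand$class))
  # unannotated decoy compounds dropped by target concordance
  expect_false(any(grepl("^DECOY", members)))

  # invariant to library row order
  cand2 <- predict_partners(resist, response, rev(lib$library))
  expect_equal(cand2, cand, ignore_attr = TRUE)

  # decoy-only library yields an empty ranking
  decoys <- Filter(function(s) grepl("^DECOY", s$id), lib$library)
  cand3 <- predict_partners(resist, response, decoys)
  expect_equal(nrow(cand3), 0)
  expect_error(predict_partners(resist, response, list()), "empty")
})
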