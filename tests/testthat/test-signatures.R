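# Resistance/response profile set algebra, overlap tallies, and the
# hypergeometric over-representation test against a pmf-enumeration oracle.

resist_fixture <- function() {
  make_de_map(
    list(cell_line = "R", treatment = "DNR",
         up = c("u_only", "u_shared", "u_flip", "u_combo"),
         down = c("d_only", "d_shared")),
    list(cell_line = "R", treatment = "COMBO", up = "rc_up", down = character()),
    list(cell_line = "S1", treatment = "DNR",
         up = c("u_shared", "resp1"), down = c("u_flip", "resp_d")),
    list(cell_line = "S1", treatment = "COMBO",
         up = c("u_combo", "resp1"), down = "resp_d"),
    list(cell_line = "S2", treatment = "DNR",
         up = "resp1", down = c("d_shared", "resp_d")),
    list(cell_line = "S2", treatment = "COMBO",
         up = "resp1", down = "resp_d"))
}

test_that("resist profile keeps resistant-only changes, direction-specifically", {
  de <- resist_fixture()
  p <- build_resist_profile(de, "R", c("S1", "S2"), "DNR", "COMBO")
  # u_shared excluded (up in S1 drug); u_combo excluded (up in S1 combo);
  # u_flip retained: it is down, not up, in S1 (direction-specific rule)
  expect_identical(p$up, sort(c("u_only", "u_flip")))
  expect_identical(p$down, "d_only")

  # never shares a same-direction gene with any sensitive drug/combo set
  for (cl in c("S1", "S2")) for (tr in c("DNR", "COMBO")) {
    s <- de[[paste(cl, tr, sep = ".")]]
    expect_length(intersect(p$up, s$up), 0)
    expect_length(intersect(p$down, s$down), 0)
  }

  # strict mode additionally excludes the resistant line's combo changes
  de$R.DNR$up <- c(de$R.DNR$up, "rc_up")
  p2 <- build_resist_profile(de, "R", c("S1", "S2"), "DNR", "COMBO",
                             strict = TRUE)
  expect_false("rc_up" %in% p2$up)
  expect_error(build_resist_profile(de, "R", "S3", "DNR", "COMBO"),
               "S3")
})

test_that("response profile is the sensitive four-way intersection minus resistant changes", {
  de <- make_de_map(
    list(cell_line = "R", treatment = "DNR", up = "in_resist", down = character()),
    list(cell_line = "R", treatment = "COMBO", up = "in_resist_combo",
         down = character()),
    list(cell_line = "S1", treatment = "DNR",
         up = c("all4", "in_resist", "in_resist_combo", "s1_only"),
         down = "d_all4"),
    list(cell_line = "S1", treatment = "COMBO",
         up = c("all4", "in_resist", "in_resist_combo"), down = "d_all4"),
    list(cell_line = "S2", treatment = "DNR",
         up = c("all4", "in_resist", "in_resist_combo"), down = "d_all4"),
    list(cell_line = "S2", treatment = "COMBO",
         up = c("all4", "in_resist", "in_resist_combo"), down = "d_all4"))
  p <- build_response_profile(de, "R", c("S1", "S2"), "DNR", "COMBO")
  expect_identical(p$up, "all4")       # s1_only fails the intersection
  expect_identical(p$down, "d_all4")
  # subset of every sensitive-line condition set, same direction
  for (cl in c("S1", "S2")) for (tr in c("DNR", "COMBO")) {
    s <- de[[paste(cl, tr, sep = ".")]]
    expect_true(all(p$up %in% s$up))
    expect_true(all(p$down %in% s$down))
  }
  # relaxed mode: drug-condition intersection only
  p2 <- build_response_profile(de, "R", c("S1", "S2"), "DNR", "COMBO",
                               relaxed = TRUE)
  expect_identical(p2$up, "all4")
})

test_that("overlap report covers identical, disjoint and partial overlaps", {
  de <- make_de_map(
    list(cell_line = "A", treatment = "DNR", up = c("a", "b"), down = "x"),
    list(cell_line = "B", treatment = "DNR", up = c("b", "c"), down = "y"),
    list(cell_line = "C", treatment = "DNR", up = c("a", "b"), down = "x"))
  rep <- overlap_report(de, "by_cell_line")
  up <- rep[rep$direction == "up", ]
  ab <- up[up$set_a == "A" & up$set_b == "B", ]
  expect_equal(ab$n_shared, 1)
  expect_equal(ab$pct_of_a, 50)           # |A ∩ B| / |A|
  ac <- up[up$set_a == "A" & up$set_b == "C", ]
  expect_equal(ac$pct_of_a, 100)          # identical sets
  dn <- rep[rep$direction == "down" & rep$set_a == "A" & rep$set_b == "B", ]
  expect_equal(dn$pct_of_a, 0)            # disjoint sets
  expect_equal(unique(up$denominator), 3) # union {a, b, c}
  expect_true(all(rep$pct_of_union >= 0 & rep$pct_of_union <= 100,
                  na.rm = TRUE))
})

test_that("ORA matches the hypergeometric enumeration oracle", {
  universe <- paste0("g", 1:20)
  qry <- paste0("g", 1:5)
  coll <- gene_set_collection(list(exact = qry))
  r <- ora_enrichment(qry, coll, universe)
  expect_equal(r$pvalue, 1 / choose(20, 5))

  # query disjoint from a pathway: upper tail from k = 0 is 1
  coll2 <- gene_set_collection(list(other = paste0("g", 6:10)))
  r2 <- ora_enrichment(qry, coll2, universe)
  expect_equal(r2$pvalue, 1)

  # randomized oracle equivalence for N <= 30
  set.seed(9)
  for (i in 1:50) {
    N <- sample(10:30, 1)
    uni <- paste0("g", seq_len(N))
    q <- sample(uni, sample(2:(N - 2), 1))
    s <- sample(uni, sample(2:(N - 2), 1))
    r <- ora_enrichment(q, gene_set_collection(list(s = s)), uni)
    expect_equal(r$pvalue,
                 oracle_hyper_p(length(intersect(q, s)), length(s), N,
                                length(q)),
                 tolerance = 1e-12)
  }
  expect_error(ora_enrichment(qry, coll, character()), "universe")
  expect_warning(ora_enrichment(c(qry, "outside"), coll, universe),
                 "outside the universe")
})
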