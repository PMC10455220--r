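# TMM normalization, the fixed-dispersion NB exact test against brute-force
# enumeration oracles, BH adjustment, the DE call rule and essential-gene
# overlap.

test_that("TMM factors are 1 for identical or depth-scaled samples and have geometric mean 1", {
  set.seed(1)
  base <- rpois(10, 50) + 1
  same <- cbind(a = base, b = base, c = base)
  expect_equal(unname(tmm_factors(same)), rep(1, 3))

  two <- cbind(a = base, b = 2L * base)
  expect_equal(unname(tmm_factors(two)), c(1, 1))

  m <- matrix(rpois(400, 30) + 1, 40, 10,
              dimnames = list(NULL, paste0("s", 1:10)))
  f <- tmm_factors(m)
  expect_equal(exp(mean(log(f))), 1)

  # a sample sharing no nonzero gene with the reference gets factor 1
  disjoint <- cbind(a = c(10L, 20L, 0L, 0L), b = c(12L, 18L, 0L, 0L),
                    c = c(0L, 0L, 15L, 25L))
  w <- capture_warnings(fd <- tmm_factors(disjoint))
  expect_true(any(grepl("no nonzero gene", w)))
  expect_equal(length(fd), 3)
})

test_that("TMM factors agree with the edgeR reference implementation", {
  set.seed(7)
  for (i in 1:5) {
    m <- matrix(rnbinom(200 * 6, mu = exp(runif(200, 1, 6)), size = 5),
                200, 6, dimnames = list(NULL, paste0("s", 1:6)))
    m <- m[rowSums(m) > 0, ]
    f_pkg <- tmm_factors(m)
    f_ref <- edgeR::calcNormFactors(m, method = "TMM")
    expect_equal(unname(f_pkg), unname(f_ref), tolerance = 1e-6)
  }
})

test_that("NB exact test matches enumeration oracles", {
  # symmetric split and a one-sided extreme
  expect_equal(nb_exact_test(3L, 3L, 0), 1)
  expect_equal(nb_exact_test(5L, 0L, 0), 2 / 32)

  # dispersion 0: conditional binomial oracle over all totals <= 50
  set.seed(11)
  for (i in 1:200) {
    t <- sample(1:50, 1)
    a <- sample(0:t, 1)
    expect_equal(nb_exact_test(a, t - a, 0), oracle_cond_binom_p(a, t - a),
                 tolerance = 1e-12)
  }

  # positive dispersion: conditional NB-split oracle
  for (i in 1:100) {
    t <- sample(1:60, 1)
    a <- sample(0:t, 1)
    disp <- runif(1, 0.01, 0.5)
    expect_equal(nb_exact_test(a, t - a, disp),
                 oracle_cond_nb_p(a, t - a, disp), tolerance = 1e-10)
  }
  expect_error(nb_exact_test(1L, 1L, -0.1), "dispersion")
})

test_that("doubling-the-tail method gives the doubled smaller tail", {
  p_min <- nb_exact_test(4L, 1L, 0, method = "minlik")
  p_dbl <- nb_exact_test(4L, 1L, 0, method = "double")
  expect_equal(p_min, 2 * (choose(5, 0) + choose(5, 1)) / 32)
  expect_equal(p_dbl, 2 * (choose(5, 4) + choose(5, 5)) / 32)
  expect_true(all(nb_exact_test(c(0L, 3L, 9L), c(6L, 3L, 2L), 0.1,
                                method = "double") <= 1))
})

test_that("BH adjustment matches the hand oracle and rejects bad input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(3)
  p <- runif(50)^2
  expect_equal(bh_adjust(p), oracle_bh(p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DE call rule uses strict inequalities in both directions", {
  tab <- data.frame(gene = c("a", "b", "c", "d", "e"),
                    log2fc = c(1.2, 1.0, -1.5, -1.5, 0.2),
                    pvalue = 0.001,
                    fdr = c(0.01, 0.001, 0.2, 0.01, 0.01))
  s <- call_de(tab, "CL", "T")
  expect_identical(s$up, "a")       # b fails strict lfc > 1, e fails lfc
  expect_identical(s$down, "d")     # c fails fdr
  expect_length(intersect(s$up, s$down), 0)
  expect_error(call_de(rbind(tab, tab[1, ]), "CL", "T"), "one row per gene")
})

test_that("de_table log2FC sign agrees with normalized mean difference for called genes", {
  set.seed(5)
  mu <- exp(runif(150, 2, 7))
  trt <- mu
  up_idx <- 1:20
  down_idx <- 21:35
  trt[up_idx] <- trt[up_idx] * 6
  trt[down_idx] <- trt[down_idx] / 6
  cm <- make_tiny_counts(rpois(150, mu), rpois(150, trt), n_reps = 3)
  tab <- de_table(cm, "CL1", "DRUG", dispersion = 0.05)
  s <- call_de(tab, "CL1", "DRUG")
  expect_true(all(paste0("g", up_idx) %in% s$up))
  expect_true(all(paste0("g", down_idx) %in% s$down))
  expect_length(intersect(s$up, s$down), 0)
  # sign coherence on every called gene
  called <- tab[tab$gene %in% c(s$up, s$down), ]
  expect_true(all(sign(called$log2fc) ==
                  ifelse(called$gene %in% s$up, 1, -1)))
})

test_that("essential overlap is an exact sorted intersection", {
  expect_equal(essential_overlap(c("a", "b", "c"), c("d", "c", "b")),
               list(count = 2L, members = c("b", "c")))
  expect_equal(essential_overlap(c("a", "b"), c("x", "y"))$count, 0L)
  expect_equal(essential_overlap(c("a", "b"), c("c", "b", "a"))$count, 2L)
})
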