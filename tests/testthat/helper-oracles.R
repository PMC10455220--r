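# Independent brute-force oracles and small fixture builders shared by the
# test files. Oracles deliberately use different primitives than the
# implementation (choose()/lgamma() instead of dbinom()/dnbinom(), explicit
# loops instead of vectorized running sums).

# Two-sided conditional binomial p-value by explicit enumeration of the
# pmf via choose(); minimum-likelihood tail definition.
oracle_cond_binom_p <- function(a, b) {
  t <- a + b
  if (t == 0) return(1)
  pmf <- vapply(0:t, function(k) choose(t, k) / 2^t, numeric(1))
  sum(pmf[pmf <= pmf[a + 1] * (1 + 1e-10)])
}

# Conditional NB-split p-value with the pmf written out via lgamma().
oracle_cond_nb_p <- function(a, b, dispersion) {
  t <- a + b
  if (t == 0) return(1)
  r <- 1 / dispersion
  mu <- t / 2
  lognb <- function(k) {
    lgamma(k + r) - lgamma(r) - lfactorial(k) +
      r * log(r / (r + mu)) + k * log(mu / (r + mu))
  }
  logp <- vapply(0:t, function(k) lognb(k) + lognb(t - k), numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[p <= p[a + 1] * (1 + 1e-10)])
}

# Unweighted KS enrichment score by explicit stepping; query given as rank
# positions in a list of length N. Positive deviation wins magnitude ties.
oracle_es <- function(query_ranks, N) {
  n_hit <- length(query_ranks)
  if (n_hit == 0) return(0)
  if (n_hit == N) return(1)
  run <- 0
  hi <- -Inf
  lo <- Inf
  for (i in seq_len(N)) {
    run <- run + if (i %in% query_ranks) 1 / n_hit else -1 / (N - n_hit)
    hi <- max(hi, run)
    lo <- min(lo, run)
  }
  if (hi >= -lo - 1e-12) hi else lo
}

# Upper-tail hypergeometric p by summing the pmf written out via choose().
oracle_hyper_p <- function(k, K, N, n) {
  kk <- max(0, n + K - N):min(n, K)
  pmf <- vapply(kk, function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }, numeric(1))
  sum(pmf[kk >= k])
}

# Hand-rolled BH step-up.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p, decreasing = TRUE)
  adj <- pmin(cummin(n / (n:1) * p[ord]), 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

# A ranked signature over genes g1..gN with strictly decreasing scores, so
# rank positions map 1:1 onto gene indices.
make_ranked <- function(N, id = "P1", type = "compound", target = "",
                        cell = "C1") {
  ranked_signature(id, type, target, cell, paste0("g", seq_len(N)),
                   scores = rev(seq_len(N)))
}

genes_at_ranks <- function(ranks) paste0("g", ranks)

# Minimal counts_matrix: one cell line, DMSO + one treatment, n reps each.
make_tiny_counts <- function(counts_ref, counts_trt, n_reps = 1) {
  n_genes <- length(counts_ref)
  genes <- paste0("g", seq_len(n_genes))
  m <- cbind(matrix(rep(counts_ref, n_reps), ncol = n_reps),
             matrix(rep(counts_trt, n_reps), ncol = n_reps))
  rownames(m) <- genes
  colnames(m) <- c(paste0("ref", seq_len(n_reps)),
                   paste0("trt", seq_len(n_reps)))
  meta <- data.frame(sample = colnames(m), cell_line = "CL1",
                     treatment = rep(c("DMSO", "DRUG"), each = n_reps),
                     replicate = rep(seq_len(n_reps), 2))
  counts_matrix(m, meta)
}

# DE-set map built directly from up/down vectors, keyed like de_all().
make_de_map <- function(...) {
  specs <- list(...)
  out <- list()
  for (s in specs) {
    tab <- data.frame(gene = c(s$up, s$down),
                      log2fc = c(rep(2, length(s$up)), rep(-2, length(s$down))),
                      pvalue = 1e-6, fdr = 1e-6, stringsAsFactors = FALSE)
    out[[paste(s$cell_line, s$treatment, sep = ".")]] <-
      structure(list(cell_line = s$cell_line, treatment = s$treatment,
                     up = sort(s$up), down = sort(s$down), table = tab),
                class = "de_gene_set")
  }
  out
}
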