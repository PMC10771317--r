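# Shared fixtures and independent oracles.

random_matrix <- function(nr, nc, prefix_r = "f", prefix_c = "S") {
  m <- matrix(stats::runif(nr * nc, 0, 50), nr, nc,
              dimnames = list(sprintf("%s%03d", prefix_r, seq_len(nr)),
                              sprintf("%s%03d", prefix_c, seq_len(nc))))
  m
}

small_cfg <- function(...) {
  sim_config(n_genes = 50L, n_families = 15L, n_samples = 30L, n_pairs = 20L,
             n_per_group = 12L, ...)
}

# Site-level brute-force numTS oracle: walks every individual site record
# and accumulates fpkm * (1 if proximal else pdui), skipping gene-sample
# pairs with missing PDUI. Independent of the matrix algebra in
# compute_numts_matrix.
oracle_numts <- function(sites, apa, expr) {
  fams <- sort(unique(sites$mirna_family))
  out <- matrix(0, length(fams), ncol(expr),
                dimnames = list(fams, colnames(expr)))
  for (i in seq_len(nrow(sites))) {
    g <- sites$gene_id[i]
    if (!g %in% rownames(expr)) next
    row <- match(g, apa$genes$gene_id)
    for (s in colnames(expr)) {
      if (is.na(row)) {            # no APA record: full-length UTR
        w <- 1
      } else {
        p <- apa$pdui[row, s]
        if (is.na(p)) next         # gene skipped for this sample
        w <- if (sites$site_end[i] <= apa$genes$boundary[row]) 1 else p
      }
      out[sites$mirna_family[i], s] <- out[sites$mirna_family[i], s] +
        w * expr[g, s]
    }
  }
  out
}

# Textbook BH step-up: q_(i) = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Rank-substitution Spearman: Pearson correlation of average ranks.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# Hand-enumerated Cox log partial likelihood (Breslow = Efron when all event
# times are distinct): sum over events of x_i*b - log(sum over risk set of
# exp(x*b)).
oracle_cox_loglik <- function(x, time, event, beta) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

tiny_apa <- function(gene_ids, boundary, pdui) {
  # builds a plus-strand apa_table with given transcript-local boundaries
  L <- 200L
  genes <- data.frame(gene_id = gene_ids, chrom = "chr1", start = 1L,
                      end = L, strand = "+",
                      proximal_boundary = as.integer(boundary),
                      stringsAsFactors = FALSE)
  numts:::new_apa_table(genes, pdui)
}
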