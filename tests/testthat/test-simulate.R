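test_that("simulation is deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 101L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c2 <- simulate_cohort(small_cfg(seed = 102L))
  expect_false(identical(a$expr, c2$expr))
})

test_that("generated tables pass the format validators and round-trip via the readers", {
  co <- simulate_cohort(small_cfg(seed = 103L, missing_pdui_rate = 0.05))
  dir <- withr::local_tempdir()
  write_cohort(co, dir, provenance = "fixture")
  expect_identical(read_matrix(file.path(dir, "gene_expr.tsv"), "gene_expr"),
                   co$expr)
  expect_identical(read_matrix(file.path(dir, "mirna_expr.tsv"), "mirna_expr"),
                   co$mirna_expr)
  back_apa <- read_apa_table(file.path(dir, "apa.tsv"))
  expect_identical(back_apa$pdui, co$apa$pdui)
  back_sites <- read_site_table(file.path(dir, "sites.tsv"))
  expect_equal(nrow(back_sites), nrow(co$sites))
  expect_s3_class(read_clinical_table(file.path(dir, "clinical.tsv")),
                  "clinical_table")
})

test_that("ground-truth numTS is self-consistent with the pipeline computation", {
  for (seed in c(104L, 105L)) {
    co <- simulate_cohort(small_cfg(seed = seed, missing_pdui_rate = 0.1))
    counts <- partition_sites(co$sites, co$apa)
    nm <- compute_numts_matrix(co$expr, co$apa, counts)
    shared <- intersect(rownames(nm), rownames(co$truth$numts))
    expect_lt(max(abs(nm[shared, ] - co$truth$numts[shared, ])), 1e-9)
  }
})

test_that("expression coupling hits the target Spearman correlation", {
  cfg <- sim_config(n_genes = 100L, n_families = 40L, n_samples = 500L,
                    coupling_rho_normal = 0.8, seed = 106L)
  co <- simulate_cohort(cfg, tissue = "normal")
  rho <- vapply(rownames(co$truth$numts), function(f) {
    if (sd(co$truth$numts[f, ]) == 0) return(NA_real_)
    cor(co$truth$numts[f, ], co$mirna_expr[f, ], method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rho, na.rm = TRUE) - 0.8), 0.05)

  co0 <- simulate_cohort(cfg, tissue = "tumor")   # rho target 0
  rho0 <- vapply(rownames(co0$truth$numts), function(f) {
    if (sd(co0$truth$numts[f, ]) == 0) return(NA_real_)
    cor(co0$truth$numts[f, ], co0$mirna_expr[f, ], method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rho0, na.rm = TRUE)), 0.05)
})

test_that("tumor PDUI shift lowers numTS linearly through the distal counts", {
  co <- simulate_cohort(small_cfg(seed = 107L))
  counts <- partition_sites(co$sites, co$apa)
  nm <- compute_numts_matrix(co$expr, co$apa, counts)
  # shift every PDUI down by a constant delta (entries kept in range):
  # by linearity, numTS must drop by exactly t(D) %*% (delta * FPKM)
  delta <- 0.1
  shifted <- co$apa
  ok <- !is.na(shifted$pdui) & shifted$pdui >= delta
  shifted$pdui[ok] <- shifted$pdui[ok] - delta
  shifted$pdui[!ok & !is.na(shifted$pdui)] <- 0
  nm2 <- compute_numts_matrix(co$expr, shifted, counts)
  genes <- intersect(rownames(co$expr), unique(counts$gene_id))
  D <- matrix(0, length(genes), nrow(nm),
              dimnames = list(genes, rownames(nm)))
  D[cbind(match(counts$gene_id, genes), match(counts$mirna_family, rownames(nm)))] <-
    counts$dutr_count
  drop_expected <- t(D) %*% ((co$apa$pdui[genes, ] -
                                shifted$pdui[genes, ]) * co$expr[genes, ])
  expect_equal(nm - nm2, drop_expected, tolerance = 1e-9)

  # realized tumor PDUI mean sits near the shifted Beta mean
  cfg <- sim_config(n_genes = 200L, n_families = 10L, n_samples = 100L,
                    tumor_pdui_shift = 0.3, seed = 108L)
  tum <- simulate_cohort(cfg, tissue = "tumor")
  m0 <- cfg$pdui_beta[1] / sum(cfg$pdui_beta)
  expect_lt(abs(mean(tum$apa$pdui) - (m0 - 0.3)), 0.01)
})

test_that("paired cohorts have exactly one tumor and one normal sample per patient", {
  co <- simulate_paired_cohort(small_cfg(seed = 109L))
  tab <- table(co$clinical$patient_id, co$clinical$tissue)
  expect_true(all(tab == 1))
  expect_equal(ncol(co$truth$numts), 2L * 20L)
})

test_that("null outcome scores are uncorrelated with numTS features", {
  cfg <- sim_config(n_genes = 80L, n_families = 15L, n_samples = 100L,
                    outcome_effect_size = 0, seed = 110L)
  co <- simulate_cohort(cfg)
  rho <- apply(co$truth$numts, 1L, function(z)
    if (sd(z) == 0) NA_real_ else cor(z, co$outcome, method = "spearman"))
  expect_lt(max(abs(rho), na.rm = TRUE), 0.4)
})

test_that("survival generator hits the target censoring rate and honors the null", {
  cfg <- sim_config(n_genes = 60L, n_families = 10L, n_pairs = 500L,
                    censoring_rate = 0.3, seed = 111L)
  ss <- simulate_survival(cfg)
  expect_lt(abs(ss$truth$censoring_fraction - 0.3), 0.05)
  expect_true(all(ss$clinical$surv_time >= 0))
  expect_true(all(ss$clinical$event %in% c(0L, 1L)))

  cfg0 <- sim_config(n_genes = 60L, n_families = 10L, n_pairs = 200L,
                     log_hr = 0, clinical_log_hr = c(age = 0),
                     censoring_rate = 0, seed = 112L)
  ss0 <- simulate_survival(cfg0)
  expect_equal(ss0$truth$censoring_fraction, 0)
  # global null: median-split groups on any feature overlap
  z <- as.vector(scale(ss0$delta_numts[1, ]))
  fit <- fit_cox(data.frame(z = z), ss0$clinical$surv_time, ss0$clinical$event)
  expect_lt(abs(fit$coefficients[["z"]]), 0.25)
})

test_that("ICB cohort honors group sizes and plants the shift in responder-post only", {
  cfg <- small_cfg(seed = 113L, icb_group_shift = 1.5)
  co <- simulate_icb_groups(cfg)
  grp <- paste(co$clinical$response, co$clinical$timepoint, sep = "_")
  expect_equal(unname(table(grp)), rep(12L, 4), ignore_attr = TRUE)
  planted <- co$truth$planted_outcome_families
  rp <- grp == "responder_post"
  others <- !rp
  m_shift <- rowMeans(co$truth$numts[planted, rp, drop = FALSE])
  m_base <- rowMeans(co$truth$numts[planted, others, drop = FALSE])
  expect_true(all(m_shift > m_base))
  # the three unshifted groups share a common mean (no planted differences)
  pre_r <- rowMeans(co$truth$numts[planted, grp == "responder_pre", drop = FALSE])
  pre_n <- rowMeans(co$truth$numts[planted, grp == "non_responder_pre", drop = FALSE])
  expect_lt(max(abs(pre_r - pre_n) / pmax(pre_r, 1)), 0.5)

  # zero shift is the null
  co0 <- simulate_icb_groups(small_cfg(seed = 113L, icb_group_shift = 0))
  m0_shift <- rowMeans(co0$truth$numts[planted, rp, drop = FALSE])
  m0_base <- rowMeans(co0$truth$numts[planted, others, drop = FALSE])
  expect_lt(max(abs(m0_shift - m0_base) / pmax(m0_base, 1)), 0.5)
})
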