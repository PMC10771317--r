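test_that("site partition assigns proximal, distal, and straddling sites", {
  pdui <- matrix(0.5, 1, 2, dimnames = list("g1", c("A", "B")))
  apa <- tiny_apa("g1", boundary = 100L, pdui)
  sites <- data.frame(gene_id = "g1", mirna_family = c("f1", "f1", "f1"),
                      site_start = c(10L, 150L, 98L),
                      site_end = c(16L, 156L, 104L))
  class(sites) <- c("site_table", "data.frame")
  counts <- partition_sites(sites, apa)
  # fully proximal -> pUTR; fully distal and boundary-straddling -> dUTR
  expect_equal(counts$putr_count, 1L)
  expect_equal(counts$dutr_count, 2L)
})

test_that("straddling-site assignment matches an isoform-enumeration oracle", {
  # enumerate the two isoforms as sequences of positions: the short isoform
  # is [0, boundary), the long isoform [0, L). a site is carried by an
  # isoform iff its whole interval fits inside it.
  set.seed(31)
  boundary <- 100L
  for (i in 1:50) {
    s <- sample(0:193, 1)
    site <- c(s, s + 7L)
    short_iso <- seq(0, boundary - 1L)
    long_iso <- seq(0, 199L)
    on_short <- all(site[1]:(site[2] - 1L) %in% short_iso)
    on_long <- all(site[1]:(site[2] - 1L) %in% long_iso)
    expect_true(on_long)
    pdui <- matrix(1, 1, 1, dimnames = list("g1", "A"))
    st <- data.frame(gene_id = "g1", mirna_family = "f1",
                     site_start = site[1], site_end = site[2])
    class(st) <- c("site_table", "data.frame")
    counts <- partition_sites(st, tiny_apa("g1", boundary, pdui))
    # constitutive iff intact on the short isoform
    expect_equal(counts$putr_count == 1L, on_short)
  }
})

test_that("sites outside the locus are rejected", {
  pdui <- matrix(0.5, 1, 1, dimnames = list("g1", "A"))
  st <- data.frame(gene_id = "g1", mirna_family = "f1",
                   site_start = 198L, site_end = 205L)
  class(st) <- c("site_table", "data.frame")
  expect_error(partition_sites(st, tiny_apa("g1", 100L, pdui)),
               "outside the 3'UTR")
})

test_that("per-gene site abundance follows the weighted-count formula", {
  expect_equal(gene_family_site_abundance(2, 3, 0, 1), 2)
  expect_equal(gene_family_site_abundance(2, 3, 1, 1), 5)
  expect_equal(gene_family_site_abundance(1, 4, 0.25, 10), 20)
  expect_error(gene_family_site_abundance(1, 1, 1.2, 1), "pdui")
  expect_error(gene_family_site_abundance(1, 1, 0.5, -1), "fpkm")
})

test_that("numTS matrix sums per-gene contributions", {
  pdui <- matrix(c(0.25, 0.5), 2, 1, dimnames = list(c("g1", "g2"), "A"))
  apa <- tiny_apa(c("g1", "g2"), c(100L, 100L), pdui)
  counts <- data.frame(gene_id = c("g1", "g2"),
                       mirna_family = c("f1", "f1"),
                       putr_count = c(1L, 2L), dutr_count = c(4L, 0L))
  expr <- matrix(c(10, 1), 2, 1, dimnames = list(c("g1", "g2"), "A"))
  nm <- compute_numts_matrix(expr, apa, counts)
  expect_equal(nm["f1", "A"], 20 + 2)  # (1 + 4*.25)*10 + (2 + 0)*1
})

test_that("vectorized numTS equals the per-site brute-force oracle", {
  set.seed(42)
  for (rep in 1:20) {
    cfg <- sim_config(n_genes = 30L, n_families = 5L, n_samples = 8L,
                      missing_pdui_rate = 0.1, seed = 1000L + rep)
    co <- simulate_cohort(cfg)
    counts <- partition_sites(co$sites, co$apa)
    nm <- compute_numts_matrix(co$expr, co$apa, counts)
    oracle <- oracle_numts(co$sites, co$apa, co$expr)
    expect_lt(max(abs(nm[rownames(oracle), ] - oracle)), 1e-9)
  }
})

test_that("genes absent from the APA table count as full-length (all sites constitutive)", {
  pdui <- matrix(0.5, 1, 1, dimnames = list("g1", "A"))
  apa <- tiny_apa("g1", 100L, pdui)
  counts <- data.frame(gene_id = c("g1", "g_noapa"),
                       mirna_family = c("f1", "f1"),
                       putr_count = c(1L, 2L), dutr_count = c(1L, 3L))
  expr <- matrix(c(1, 1), 2, 1, dimnames = list(c("g1", "g_noapa"), "A"))
  nm <- compute_numts_matrix(expr, apa, counts)
  # g1: 1 + 1*0.5; g_noapa: PDUI treated as 1 -> all 5 sites count
  expect_equal(nm["f1", "A"], 1.5 + 5)
})

test_that("missing PDUI handling: skip zeroes the gene, mean imputes the cohort mean", {
  pdui <- matrix(c(0.2, NA, 0.8, 0.4), 1, 4,
                 dimnames = list("g1", paste0("S", 1:4)))
  apa <- tiny_apa("g1", 100L, pdui)
  counts <- data.frame(gene_id = "g1", mirna_family = "f1",
                       putr_count = 1L, dutr_count = 2L)
  expr <- matrix(3, 1, 4, dimnames = list("g1", paste0("S", 1:4)))
  skip <- compute_numts_matrix(expr, apa, counts, missing_pdui = "skip")
  expect_equal(unname(skip["f1", "S2"]), 0)
  imputed <- compute_numts_matrix(expr, apa, counts, missing_pdui = "mean")
  expect_equal(unname(imputed["f1", "S2"]),
               (1 + 2 * mean(c(0.2, 0.8, 0.4))) * 3)
  # observed samples unaffected by the flag
  expect_equal(skip[, c("S1", "S3", "S4")], imputed[, c("S1", "S3", "S4")])
})

test_that("numTS is monotone in PDUI, homogeneous in FPKM, and hits the PDUI limits", {
  set.seed(7)
  cfg <- sim_config(n_genes = 25L, n_families = 6L, n_samples = 5L, seed = 7L)
  co <- simulate_cohort(cfg)
  counts <- partition_sites(co$sites, co$apa)
  base <- compute_numts_matrix(co$expr, co$apa, counts)

  # homogeneity: scaling all FPKM by c scales numTS by c
  scaled <- compute_numts_matrix(co$expr * 3.7, co$apa, counts)
  expect_equal(scaled, base * 3.7)

  # monotonicity: raising every PDUI cannot decrease any entry
  up <- co$apa
  up$pdui <- pmin(up$pdui + 0.1, 1)
  expect_true(all(compute_numts_matrix(co$expr, up, counts) >= base - 1e-12))

  # limits: PDUI = 1 -> total counts x FPKM; PDUI = 0 -> pUTR only
  one <- co$apa; one$pdui[] <- 1
  zero <- co$apa; zero$pdui[] <- 0
  tot <- rowsum((counts$putr_count + counts$dutr_count) *
                  co$expr[counts$gene_id, , drop = FALSE],
                counts$mirna_family)
  putr_only <- rowsum(counts$putr_count *
                        co$expr[counts$gene_id, , drop = FALSE],
                      counts$mirna_family)
  nm1 <- compute_numts_matrix(co$expr, one, counts)
  nm0 <- compute_numts_matrix(co$expr, zero, counts)
  expect_equal(nm1[rownames(tot), ], as.matrix(tot), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(nm0[rownames(putr_only), ], as.matrix(putr_only),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("delta numTS matches the stated transform and a per-patient loop oracle", {
  nm <- matrix(c(3, 1, 1, 1, 5, 5, 2, 8), 2, 4,
               dimnames = list(c("f1", "f2"),
                               c("p1_T", "p1_N", "p2_T", "p2_N")))
  clinical <- validate_clinical_table(data.frame(
    sample_id = colnames(nm), patient_id = rep(c("p1", "p2"), each = 2),
    tissue = rep(c("tumor", "normal"), 2)))
  d <- delta_numts(nm, clinical)
  expect_equal(d["f1", "p1"], log2(4) - log2(2))
  # identical pair -> zero
  expect_equal(d["f2", "p1"], 0)
  # raw transform
  d_raw <- delta_numts(nm, clinical, transform = "raw")
  expect_equal(d_raw["f1", "p1"], 2)

  set.seed(13)
  co <- simulate_paired_cohort(small_cfg(seed = 13))
  d2 <- delta_numts(co$truth$numts, co$clinical)
  for (p in sample(colnames(d2), 5)) {
    ts <- co$clinical$sample_id[co$clinical$patient_id == p &
                                  co$clinical$tissue == "tumor"]
    ns <- co$clinical$sample_id[co$clinical$patient_id == p &
                                  co$clinical$tissue == "normal"]
    expect_equal(d2[, p],
                 log2(co$truth$numts[, ts] + 1) - log2(co$truth$numts[, ns] + 1))
  }
  # patients lacking a pair are dropped; zero pairs is an error
  cl_un <- validate_clinical_table(data.frame(
    sample_id = colnames(nm)[1:2], patient_id = c("p1", "p9"),
    tissue = c("tumor", "normal")))
  expect_error(delta_numts(nm[, 1:2], cl_un), "both tumor and normal")
})
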