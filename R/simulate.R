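#' Simulation configuration
#'
#' Defines the synthetic-cohort generating process: lognormal gene FPKM and
#' miRNA TPM marginals, Beta-distributed PDUI with a downward (3'UTR
#' shortening) mean shift in tumor tissue, Poisson target-site counts split
#' between the proximal and distal UTR segments, a Gaussian-copula rank
#' coupling between each family's true numTS and its expression (strong in
#' normal tissue, absent in tumor), linear numTS-driven outcome scores, and
#' Weibull proportional-hazards survival with planted numTS-change effects.
#'
#' @param n_genes,n_families,n_samples Cohort dimensions (defaults 300 genes,
#'   100 miRNA families, 200 samples).
#' @param n_pairs Patients in paired tumor/normal designs (default 40).
#' @param n_per_group Samples per group in the four-group ICB design
#'   (default 25, i.e. about 100 samples).
#' @param sites_per_gene_family Poisson mean of target sites per (gene,
#'   family) pair (default 0.5; most pairs carry no site).
#' @param fpkm_logmean,fpkm_logsd Lognormal FPKM parameters (defaults 2, 1).
#' @param tpm_logmean,tpm_logsd Lognormal miRNA TPM parameters (defaults 1, 1).
#' @param pdui_beta Length-2 Beta shape parameters of baseline (normal) PDUI
#'   (default `c(5, 2)`, mean about 0.71).
#' @param tumor_pdui_shift Downward shift of the tumor PDUI mean (default
#'   0.2), the 3'UTR-shortening signal.
#' @param coupling_rho_normal,coupling_rho_tumor Target Spearman correlation
#'   between a family's numTS and its expression within each tissue
#'   (defaults 0.8 and 0).
#' @param n_planted_outcome_features Families whose numTS drives the outcome
#'   score (default 5).
#' @param outcome_effect_size Coefficient on each planted (standardized)
#'   numTS feature (default 1).
#' @param noise_sd Outcome noise standard deviation (default 1).
#' @param n_planted_hazard_features Families whose numTS change carries a
#'   survival hazard (default 3).
#' @param log_hr Log hazard ratio per standard deviation of planted numTS
#'   change (default 0.7).
#' @param clinical_log_hr Named vector of clinical log-hazard effects
#'   (default `c(age = 0.02, stage = 0.3)`, age centered at 65).
#' @param censoring_rate Target fraction of censored subjects (default 0.3).
#' @param weibull_shape,weibull_rate Baseline Weibull hazard parameters
#'   (defaults 1.5 and 0.001).
#' @param icb_group_shift log2 fold-change applied to the FPKM of planted
#'   families' target genes in responder-post samples (default 1; about
#'   2-5 within-group SDs of the planted families' numTS at default scales).
#' @param missing_pdui_rate Fraction of PDUI entries set missing (default 0).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 300L, n_families = 100L, n_samples = 200L,
                       n_pairs = 40L, n_per_group = 25L,
                       sites_per_gene_family = 0.5,
                       fpkm_logmean = 2, fpkm_logsd = 1,
                       tpm_logmean = 1, tpm_logsd = 1,
                       pdui_beta = c(5, 2), tumor_pdui_shift = 0.2,
                       coupling_rho_normal = 0.8, coupling_rho_tumor = 0,
                       n_planted_outcome_features = 5L,
                       outcome_effect_size = 1, noise_sd = 1,
                       n_planted_hazard_features = 3L, log_hr = 0.7,
                       clinical_log_hr = c(age = 0.02, stage = 0.3),
                       censoring_rate = 0.3,
                       weibull_shape = 1.5, weibull_rate = 0.001,
                       icb_group_shift = 1, missing_pdui_rate = 0,
                       seed = 1L) {
  stopifnot(length(pdui_beta) == 2L, all(pdui_beta > 0),
            tumor_pdui_shift >= 0, noise_sd >= 0,
            abs(coupling_rho_normal) <= 1, abs(coupling_rho_tumor) <= 1,
            censoring_rate >= 0, censoring_rate < 1,
            missing_pdui_rate >= 0, missing_pdui_rate < 1,
            icb_group_shift >= 0)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# Normal-scores Gaussian-copula coupling: draws a vector whose Spearman
# correlation with x targets rho (Pearson r = 2*sin(pi*rho/6) on the latent
# normal scale), then maps it through the lognormal TPM marginal.
couple_to <- function(x, rho, meanlog, sdlog) {
  n <- length(x)
  if (stats::sd(x) == 0 || rho == 0) {
    z2 <- stats::rnorm(n)
  } else {
    r <- 2 * sin(pi * rho / 6)
    z1 <- stats::qnorm(rank(x, ties.method = "average") / (n + 1))
    z1 <- z1 / stats::sd(z1)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  }
  stats::qlnorm(stats::pnorm(z2), meanlog = meanlog, sdlog = sdlog)
}

beta_params_shifted <- function(pdui_beta, shift) {
  m0 <- pdui_beta[1L] / sum(pdui_beta)
  m1 <- max(0.02, m0 - shift)
  kappa <- sum(pdui_beta)
  c(m1 * kappa, (1 - m1) * kappa)
}

# Shared scaffolding: gene loci, target sites, and the per-gene boundary.
sim_gene_universe <- function(cfg) {
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  families <- sprintf("fam%03d", seq_len(cfg$n_families))
  utr_len <- sample(600:3000, cfg$n_genes, replace = TRUE)
  boundary <- pmax(8L, as.integer(round(utr_len * stats::runif(cfg$n_genes, 0.3, 0.7))))
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  start <- sample(1e4:1e6, cfg$n_genes, replace = TRUE)
  end <- start + utr_len - 1L
  pb <- ifelse(strand == "+", start + boundary - 1L, end - boundary + 1L)
  gene_df <- data.frame(gene_id = genes, chrom = "chr1", start = start,
                        end = end, strand = strand, proximal_boundary = pb,
                        stringsAsFactors = FALSE)
  n_sites <- stats::rpois(cfg$n_genes * cfg$n_families,
                          cfg$sites_per_gene_family)
  pair_gene <- rep(seq_len(cfg$n_genes), times = cfg$n_families)
  pair_fam <- rep(seq_len(cfg$n_families), each = cfg$n_genes)
  gi <- rep(pair_gene, n_sites)
  fi <- rep(pair_fam, n_sites)
  site_start <- as.integer(floor(stats::runif(length(gi)) * (utr_len[gi] - 7L)))
  sites <- data.frame(gene_id = genes[gi], mirna_family = families[fi],
                      site_start = site_start, site_end = site_start + 7L,
                      stringsAsFactors = FALSE)
  class(sites) <- c("site_table", "data.frame")
  list(genes = genes, families = families, gene_df = gene_df,
       utr_len = utr_len, boundary = boundary, sites = sites)
}

# Direct (per-gene loop) numTS accumulation used as the generator's own
# ground truth; intentionally written independently of compute_numts_matrix.
truth_numts <- function(uni, pdui, fpkm) {
  gi <- match(uni$sites$gene_id, uni$genes)
  fi <- match(uni$sites$mirna_family, uni$families)
  prox <- uni$sites$site_end <= uni$boundary[gi]
  out <- matrix(0, length(uni$families), ncol(fpkm),
                dimnames = list(uni$families, colnames(fpkm)))
  for (i in seq_along(gi)) {
    p <- pdui[gi[i], ]
    w <- if (prox[i]) as.numeric(!is.na(p)) else ifelse(is.na(p), 0, p)
    out[fi[i], ] <- out[fi[i], ] + w * fpkm[gi[i], ]
  }
  out
}

sim_pdui <- function(uni, n, shapes, missing_rate, sample_ids) {
  pdui <- matrix(stats::rbeta(length(uni$genes) * n, shapes[1L], shapes[2L]),
                 length(uni$genes), n,
                 dimnames = list(uni$genes, sample_ids))
  if (missing_rate > 0) {
    drop <- stats::runif(length(pdui)) < missing_rate
    pdui[drop] <- NA_real_
  }
  pdui
}

sim_fpkm <- function(uni, n, cfg, sample_ids) {
  matrix(stats::rlnorm(length(uni$genes) * n, cfg$fpkm_logmean, cfg$fpkm_logsd),
         length(uni$genes), n, dimnames = list(uni$genes, sample_ids))
}

#' Simulate a single-tissue cohort
#'
#' Generates every table the pipeline consumes — gene FPKM, APA table with
#' per-sample PDUI, target-site table, miRNA-family TPM coupled to the true
#' numTS, clinical table, and a numTS-driven outcome score — together with a
#' ground-truth record (true numTS computed by a direct per-site loop,
#' planted outcome families and coefficients).
#'
#' @param cfg A [sim_config()].
#' @param tissue `"tumor"` (PDUI mean shifted down, weak coupling) or
#'   `"normal"` (baseline PDUI, strong coupling).
#' @return A list of class `synthetic_cohort` with elements `expr`, `apa`,
#'   `sites`, `mirna_expr`, `clinical`, `outcome`, `truth`.
#' @export
simulate_cohort <- function(cfg = sim_config(), tissue = c("tumor", "normal")) {
  tissue <- match.arg(tissue)
  set.seed(cfg$seed)
  uni <- sim_gene_universe(cfg)
  n <- cfg$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))
  shapes <- if (tissue == "tumor")
    beta_params_shifted(cfg$pdui_beta, cfg$tumor_pdui_shift) else cfg$pdui_beta
  pdui <- sim_pdui(uni, n, shapes, cfg$missing_pdui_rate, sample_ids)
  fpkm <- sim_fpkm(uni, n, cfg, sample_ids)
  apa <- new_apa_table(uni$gene_df, pdui)
  truth <- truth_numts(uni, pdui, fpkm)
  rho <- if (tissue == "tumor") cfg$coupling_rho_tumor else cfg$coupling_rho_normal
  mirna <- t(vapply(rownames(truth), function(f)
    couple_to(truth[f, ], rho, cfg$tpm_logmean, cfg$tpm_logsd), numeric(n)))
  colnames(mirna) <- sample_ids
  planted <- head(rownames(truth)[apply(truth, 1L, stats::sd) > 0],
                  cfg$n_planted_outcome_features)
  beta <- stats::setNames(rep(cfg$outcome_effect_size, length(planted)), planted)
  Z <- t(scale(t(truth[planted, , drop = FALSE])))
  y <- drop(crossprod(Z, beta)) + stats::rnorm(n, 0, cfg$noise_sd)
  names(y) <- sample_ids
  clinical <- validate_clinical_table(data.frame(
    sample_id = sample_ids, patient_id = sample_ids, tissue = tissue,
    age = round(stats::rnorm(n, 65, 10)),
    gender = sample(c("F", "M"), n, replace = TRUE),
    stage = sample(1:4, n, replace = TRUE),
    stringsAsFactors = FALSE))
  structure(list(expr = fpkm, apa = apa, sites = uni$sites,
                 mirna_expr = mirna, clinical = clinical, outcome = y,
                 truth = list(numts = truth, planted_outcome_families = planted,
                              beta = beta, coupling_rho = rho)),
            class = "synthetic_cohort")
}

#' Simulate a paired tumor/normal cohort
#'
#' Every patient contributes one normal and one tumor sample. PDUI is drawn
#' from the baseline Beta in normal tissue and from the shifted Beta in
#' tumor tissue; the numTS-expression coupling uses `coupling_rho_normal`
#' within normal samples and `coupling_rho_tumor` within tumor samples.
#'
#' @param cfg A [sim_config()].
#' @return A `synthetic_cohort`; `clinical` carries the patient pairing, and
#'   `truth$numts` covers all `2 * n_pairs` samples.
#' @export
simulate_paired_cohort <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  uni <- sim_gene_universe(cfg)
  np <- cfg$n_pairs
  patients <- sprintf("P%04d", seq_len(np))
  ids_n <- paste0(patients, "_N")
  ids_t <- paste0(patients, "_T")
  shapes_t <- beta_params_shifted(cfg$pdui_beta, cfg$tumor_pdui_shift)
  pdui <- cbind(sim_pdui(uni, np, cfg$pdui_beta, cfg$missing_pdui_rate, ids_n),
                sim_pdui(uni, np, shapes_t, cfg$missing_pdui_rate, ids_t))
  fpkm <- cbind(sim_fpkm(uni, np, cfg, ids_n), sim_fpkm(uni, np, cfg, ids_t))
  apa <- new_apa_table(uni$gene_df, pdui)
  truth <- truth_numts(uni, pdui, fpkm)
  mirna <- matrix(NA_real_, nrow(truth), ncol(truth),
                  dimnames = dimnames(truth))
  for (f in rownames(truth)) {
    mirna[f, ids_n] <- couple_to(truth[f, ids_n], cfg$coupling_rho_normal,
                                 cfg$tpm_logmean, cfg$tpm_logsd)
    mirna[f, ids_t] <- couple_to(truth[f, ids_t], cfg$coupling_rho_tumor,
                                 cfg$tpm_logmean, cfg$tpm_logsd)
  }
  clinical <- validate_clinical_table(data.frame(
    sample_id = c(ids_n, ids_t),
    patient_id = rep(patients, 2L),
    tissue = rep(c("normal", "tumor"), each = np),
    age = rep(round(stats::rnorm(np, 65, 10)), 2L),
    gender = rep(sample(c("F", "M"), np, replace = TRUE), 2L),
    stage = rep(sample(1:4, np, replace = TRUE), 2L),
    stringsAsFactors = FALSE))
  structure(list(expr = fpkm, apa = apa, sites = uni$sites,
                 mirna_expr = mirna, clinical = clinical, outcome = NULL,
                 truth = list(numts = truth,
                              coupling_rho = c(normal = cfg$coupling_rho_normal,
                                               tumor = cfg$coupling_rho_tumor))),
            class = "synthetic_cohort")
}

#' Simulate survival outcomes on a paired cohort
#'
#' Draws Weibull proportional-hazards survival times per patient with linear
#' predictor `gamma_clin . clinical + sum(log_hr * z(delta_numts_planted))`,
#' where `z()` standardizes each planted family's tumor-minus-normal numTS
#' change, and applies independent uniform censoring calibrated to the
#' target censoring rate.
#'
#' @param cfg A [sim_config()].
#' @param cohort A paired `synthetic_cohort` (from
#'   [simulate_paired_cohort()]); defaults to generating one from `cfg`.
#' @return List with `clinical` (patient-level data.frame: `age`, `gender`,
#'   `stage`, `surv_time`, `event`), `delta_numts` (the log2 numTS-change
#'   matrix), and `truth` (planted hazard families, `log_hr`, the linear
#'   predictor, realized censoring fraction).
#' @export
simulate_survival <- function(cfg = sim_config(), cohort = NULL) {
  if (is.null(cohort)) cohort <- simulate_paired_cohort(cfg)
  set.seed(cfg$seed + 1L)
  delta <- delta_numts(cohort$truth$numts, cohort$clinical)
  patients <- colnames(delta)
  cl <- cohort$clinical[match(patients, cohort$clinical$patient_id), ]
  variable <- rownames(delta)[apply(delta, 1L, stats::sd) > 0]
  planted <- head(variable, cfg$n_planted_hazard_features)
  lp <- rep(0, length(patients))
  if (length(planted) > 0L && cfg$log_hr != 0) {
    Z <- t(scale(t(delta[planted, , drop = FALSE])))
    lp <- lp + drop(crossprod(Z, rep(cfg$log_hr, length(planted))))
  }
  if ("age" %in% names(cfg$clinical_log_hr))
    lp <- lp + cfg$clinical_log_hr[["age"]] * (cl$age - 65)
  if ("stage" %in% names(cfg$clinical_log_hr))
    lp <- lp + cfg$clinical_log_hr[["stage"]] * (cl$stage - mean(cl$stage))
  k <- cfg$weibull_shape
  lambda <- cfg$weibull_rate
  t_event <- (-log(stats::runif(length(lp))) / (lambda * exp(lp)))^(1 / k)
  if (cfg$censoring_rate > 0) {
    # P(C < T_i) with C ~ U(0, cmax) is min(T_i/cmax, 1); calibrate cmax.
    target <- function(cmax) mean(pmin(t_event / cmax, 1)) - cfg$censoring_rate
    cmax <- stats::uniroot(target, lower = min(t_event) * 1e-3,
                           upper = max(t_event) * 1e3, extendInt = "downX")$root
    cens <- stats::runif(length(lp), 0, cmax)
  } else {
    cens <- rep(Inf, length(lp))
  }
  event <- as.integer(t_event <= cens)
  surv_time <- pmin(t_event, cens)
  clinical <- data.frame(patient_id = patients, age = cl$age,
                         gender = cl$gender, stage = cl$stage,
                         surv_time = surv_time, event = event,
                         stringsAsFactors = FALSE)
  list(clinical = clinical, delta_numts = delta,
       truth = list(planted_hazard_families = planted, log_hr = cfg$log_hr,
                    lp = lp, censoring_fraction = mean(1 - event)))
}

#' Simulate a four-group immunotherapy cohort
#'
#' Generates `4 * n_per_group` tumor samples labeled responder/non-responder
#' crossed with pre/post treatment. A log2 fold-change of `icb_group_shift`
#' is applied to the FPKM of the genes carrying target sites of the planted
#' families, in responder-post samples only, so those families' numTS mean
#' shifts in exactly one group; the other three groups share a common mean.
#'
#' @param cfg A [sim_config()].
#' @return A `synthetic_cohort` whose `clinical` table carries `response`
#'   and `timepoint` columns; `truth` records the planted families and the
#'   shifted gene set.
#' @export
simulate_icb_groups <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  uni <- sim_gene_universe(cfg)
  n <- 4L * cfg$n_per_group
  sample_ids <- sprintf("S%04d", seq_len(n))
  response <- rep(c("responder", "non_responder"), each = 2L * cfg$n_per_group)
  timepoint <- rep(rep(c("pre", "post"), each = cfg$n_per_group), 2L)
  shapes <- beta_params_shifted(cfg$pdui_beta, cfg$tumor_pdui_shift)
  pdui <- sim_pdui(uni, n, shapes, cfg$missing_pdui_rate, sample_ids)
  fpkm <- sim_fpkm(uni, n, cfg, sample_ids)
  site_fams <- unique(uni$sites$mirna_family)
  planted <- head(sort(site_fams), cfg$n_planted_outcome_features)
  shifted_genes <- unique(uni$sites$gene_id[uni$sites$mirna_family %in% planted])
  target_samples <- response == "responder" & timepoint == "post"
  fpkm[shifted_genes, target_samples] <-
    fpkm[shifted_genes, target_samples] * 2^cfg$icb_group_shift
  apa <- new_apa_table(uni$gene_df, pdui)
  truth <- truth_numts(uni, pdui, fpkm)
  mirna <- t(vapply(rownames(truth), function(f)
    couple_to(truth[f, ], cfg$coupling_rho_tumor, cfg$tpm_logmean,
              cfg$tpm_logsd), numeric(n)))
  colnames(mirna) <- sample_ids
  clinical <- validate_clinical_table(data.frame(
    sample_id = sample_ids, patient_id = sample_ids, tissue = "tumor",
    age = round(stats::rnorm(n, 60, 10)),
    gender = sample(c("F", "M"), n, replace = TRUE),
    stage = sample(3:4, n, replace = TRUE),
    response = response, timepoint = timepoint,
    stringsAsFactors = FALSE))
  structure(list(expr = fpkm, apa = apa, sites = uni$sites,
                 mirna_expr = mirna, clinical = clinical, outcome = NULL,
                 truth = list(numts = truth, planted_outcome_families = planted,
                              shifted_genes = shifted_genes,
                              group = paste(response, timepoint, sep = "_"))),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$expr), "genes,", nrow(x$mirna_expr),
      "miRNA families,", ncol(x$expr), "samples\n")
  invisible(x)
}

#' Write all tables of a synthetic cohort to a directory
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @param provenance Optional provenance comment line for every file.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, provenance = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(cohort$expr, file.path(dir, "gene_expr.tsv"), provenance)
  write_matrix(cohort$mirna_expr, file.path(dir, "mirna_expr.tsv"), provenance)
  write_apa_table(cohort$apa, file.path(dir, "apa.tsv"), provenance)
  con <- file(file.path(dir, "sites.tsv"), "w")
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(as.data.frame(cohort$sites), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  close(con)
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.tsv"),
                       provenance)
  if (!is.null(cohort$outcome)) {
    con <- file(file.path(dir, "outcome.tsv"), "w")
    if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
    utils::write.table(
      data.frame(sample_id = names(cohort$outcome), score = cohort$outcome),
      con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(dir)
}
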