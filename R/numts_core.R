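#' Partition target sites at the proximal polyA boundary
#'
#' Assigns every predicted target site to the constitutive proximal 3'UTR
#' segment (pUTR, present on all isoforms) or the distal segment (dUTR,
#' present only on the long isoform), splitting at the gene's predicted
#' proximal polyA boundary, and sums counts per (gene, miRNA family).
#'
#' A site is proximal only if it lies entirely 5' of the boundary
#' (`site_end <= boundary`). Sites straddling the boundary are assigned to
#' dUTR: proximal polyadenylation truncates them, so only the long isoform
#' carries an intact copy. Genes without an APA record are treated as
#' non-APA (full-length 3'UTR); all their sites are constitutive.
#'
#' @param sites A `site_table` (transcript-local 0-based half-open intervals).
#' @param apa An `apa_table`.
#' @return A `site_counts` data.frame: `gene_id, mirna_family, putr_count,
#'   dutr_count`.
#' @export
partition_sites <- function(sites, apa) {
  stopifnot(inherits(sites, "site_table"), inherits(apa, "apa_table"))
  idx <- match(sites$gene_id, apa$genes$gene_id)
  boundary <- apa$genes$boundary[idx]
  utr_len <- apa$genes$utr_length[idx]
  known <- !is.na(idx)
  outside <- known & (sites$site_end > utr_len | sites$site_start < 0L)
  if (any(outside))
    stop("site interval outside the 3'UTR locus for gene(s): ",
         paste(unique(sites$gene_id[outside]), collapse = ", "))
  # no APA record => full-length UTR, every site constitutive
  is_proximal <- ifelse(known, sites$site_end <= boundary, TRUE)
  key <- interaction(sites$gene_id, sites$mirna_family, drop = TRUE, sep = "\r")
  putr <- tapply(as.integer(is_proximal), key, sum)
  dutr <- tapply(as.integer(!is_proximal), key, sum)
  parts <- strsplit(names(putr), "\r", fixed = TRUE)
  counts <- data.frame(gene_id = vapply(parts, `[[`, "", 1L),
                       mirna_family = vapply(parts, `[[`, "", 2L),
                       putr_count = as.integer(putr),
                       dutr_count = as.integer(dutr),
                       stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  validate_site_counts(counts)
}

#' Weighted target-site abundance of one gene for one miRNA family
#'
#' The per-gene term of the numTS sum:
#' `(putr + dutr * pdui) * fpkm` — constitutive sites count fully, distal
#' sites are weighted by the fraction of transcripts carrying the long
#' 3'UTR isoform (PDUI), and the total is scaled by the gene's transcript
#' abundance.
#'
#' @param putr,dutr Non-negative site counts in the proximal/distal segment.
#' @param pdui Distal polyA usage index in `[0, 1]`.
#' @param fpkm Non-negative transcript abundance.
#' @return Non-negative numeric; vectorized over all arguments.
#' @export
gene_family_site_abundance <- function(putr, dutr, pdui, fpkm) {
  if (any(pdui < 0 | pdui > 1, na.rm = TRUE))
    stop("pdui must lie in [0, 1]")
  if (any(fpkm < 0, na.rm = TRUE)) stop("fpkm must be >= 0")
  (putr + dutr * pdui) * fpkm
}

#' Compute the numTS matrix (miRNA family x sample)
#'
#' For each miRNA family j and sample s, sums the PDUI-weighted,
#' FPKM-scaled site abundance over all expressed genes:
#' `numTS[j, s] = sum_x (pUTR(x,j) + dUTR(x,j) * PDUI_s(x)) * FPKM_s(x)`.
#'
#' Genes present in the expression matrix but absent from the APA table are
#' treated as non-APA: PDUI fixed at 1 (equivalently, all their sites
#' constitutive). Missing PDUI is handled per `missing_pdui`: `"skip"` (the
#' gene contributes nothing to that sample) or `"mean"` (impute the gene's
#' cohort-mean PDUI).
#'
#' @param expr Gene FPKM matrix (genes x samples).
#' @param apa An `apa_table`, sample-aligned with `expr`.
#' @param counts A `site_counts` data.frame.
#' @param missing_pdui `"skip"` or `"mean"`.
#' @return Numeric matrix, families x samples, non-negative.
#' @export
compute_numts_matrix <- function(expr, apa, counts,
                                 missing_pdui = c("skip", "mean")) {
  missing_pdui <- match.arg(missing_pdui)
  stopifnot(is.matrix(expr), inherits(apa, "apa_table"))
  counts <- validate_site_counts(counts)
  if (!identical(colnames(expr), colnames(apa$pdui)))
    stop("expression and APA tables are not sample-aligned; run align_samples()")
  genes <- intersect(rownames(expr), unique(counts$gene_id))
  if (length(genes) == 0L)
    stop("no overlapping genes between expression matrix and site counts")
  families <- sort(unique(counts$mirna_family))
  # gene x family count matrices
  gi <- match(counts$gene_id, genes)
  fi <- match(counts$mirna_family, families)
  keep <- !is.na(gi)
  P <- matrix(0, length(genes), length(families),
              dimnames = list(genes, families))
  D <- P
  P[cbind(gi[keep], fi[keep])] <- counts$putr_count[keep]
  D[cbind(gi[keep], fi[keep])] <- counts$dutr_count[keep]

  fpkm <- expr[genes, , drop = FALSE]
  pdui <- matrix(1, length(genes), ncol(expr),
                 dimnames = list(genes, colnames(expr)))
  in_apa <- intersect(genes, apa$genes$gene_id)
  pdui[in_apa, ] <- apa$pdui[in_apa, , drop = FALSE]
  if (missing_pdui == "mean" && anyNA(pdui)) {
    row_mean <- rowMeans(pdui, na.rm = TRUE)
    row_mean[is.nan(row_mean)] <- NA_real_
    na_idx <- which(is.na(pdui), arr.ind = TRUE)
    pdui[na_idx] <- row_mean[na_idx[, 1L]]
  }
  # a gene with (still) missing PDUI contributes 0 to that sample entirely
  observed <- !is.na(pdui)
  pdui0 <- ifelse(observed, pdui, 0)
  w_const <- fpkm * observed
  w_distal <- fpkm * pdui0
  numts <- t(P) %*% w_const + t(D) %*% w_distal
  dimnames(numts) <- list(families, colnames(expr))
  numts
}

#' Tumor-minus-normal change in numTS per patient
#'
#' For every patient with both a tumor and a normal sample, computes the
#' per-family difference `transform(tumor) - transform(normal)`. The default
#' transform is `log2(x + 1)`, keeping differences scale-stable across
#' families; `"raw"` gives plain differences.
#'
#' @param numts Family x sample numTS matrix.
#' @param clinical A `clinical_table` covering the numts samples.
#' @param transform `"log2"` (default) or `"raw"`.
#' @return Family x patient matrix of differences; patients lacking a
#'   complete tumor/normal pair are omitted.
#' @export
delta_numts <- function(numts, clinical, transform = c("log2", "raw")) {
  transform <- match.arg(transform)
  stopifnot(is.matrix(numts))
  cl <- clinical[clinical$sample_id %in% colnames(numts), , drop = FALSE]
  tumor <- cl[cl$tissue == "tumor", c("patient_id", "sample_id")]
  normal <- cl[cl$tissue == "normal", c("patient_id", "sample_id")]
  patients <- sort(intersect(tumor$patient_id, normal$patient_id))
  if (length(patients) == 0L)
    stop("no patient has both tumor and normal samples")
  ts <- tumor$sample_id[match(patients, tumor$patient_id)]
  ns <- normal$sample_id[match(patients, normal$patient_id)]
  f <- if (transform == "log2") function(x) log2(x + 1) else identity
  delta <- f(numts[, ts, drop = FALSE]) - f(numts[, ns, drop = FALSE])
  colnames(delta) <- patients
  delta
}
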