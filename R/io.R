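#' Read a feature-by-sample expression matrix
#'
#' Reads a TSV with a header row of sample IDs and a first column of feature
#' IDs (genes, miRNA families, or numTS features). Lines starting with `#`
#' (provenance headers) are skipped. Values must be finite and non-negative;
#' feature and sample IDs must be unique.
#'
#' @param path Path to a TSV file.
#' @param kind One of `"gene_expr"`, `"mirna_expr"`, `"numts"`. Only used for
#'   error messages and the class tag; the on-disk layout is identical.
#' @return A numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix <- function(path, kind = c("gene_expr", "mirna_expr", "numts")) {
  kind <- match.arg(kind)
  df <- read_tsv_checked(path)
  if (ncol(df) < 2L)
    stop("malformed header in ", path, ": need a feature-ID column plus >=1 sample column")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate feature IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample IDs in header of ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2L, as.numeric))) &
                   !is.na(as.matrix(df[, -1L, drop = FALSE])), arr.ind = TRUE)
    stop("non-numeric value in ", path, " at row ", ids[bad[1L, 1L]],
         ", column ", samples[bad[1L, 2L]])
  }
  rownames(m) <- ids
  validate_expression_matrix(m, what = kind)
  m
}

#' Write a feature-by-sample matrix as TSV
#'
#' Inverse of [read_matrix()]: first column `feature_id`, then one column per
#' sample. An optional provenance comment line is written first.
#'
#' @param m Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @param provenance Optional single string written as a leading `# ` comment.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, provenance = NULL) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  df <- data.frame(feature_id = rownames(m), fmt_num(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# 17 significant digits: doubles survive the text round trip bit-exactly.
fmt_num <- function(m) {
  out <- sprintf("%.17g", m)
  out[is.na(m)] <- "NA"
  dim(out) <- dim(m)
  dimnames(out) <- dimnames(m)
  out
}

#' Read an APA (alternative polyadenylation) table
#'
#' Accepts two dialects:
#' * plain: columns `gene_id, chrom, start, end, strand, proximal_boundary`,
#'   then one PDUI column per sample;
#' * DaPars result: a composite first column `gene|transcript|chr|strand`
#'   named `Gene`, a `Loci` column `chr:start-end`, a
#'   `Predicted_Proximal_APA` column, then per-sample PDUI columns. The
#'   composite ID is split on `|` and its first token becomes `gene_id`.
#'
#' Genomic coordinates are 1-based inclusive on input. The proximal polyA
#' boundary is converted to a transcript-local offset (0-based, measured from
#' the 5' end of the 3'UTR in transcript orientation) so downstream code is
#' strand-free: on the minus strand the proximal UTR segment is the one
#' between the stop codon (locus end) and the boundary.
#'
#' PDUI values must lie in `[0, 1]`; missing values (`NA`) are preserved.
#'
#' @param path Path to a TSV file.
#' @return An `apa_table`: list with `genes` (data.frame `gene_id, chrom,
#'   start, end, strand, proximal_boundary, utr_length, boundary`) and `pdui`
#'   (genes x samples numeric matrix, rownames = gene IDs).
#' @export
read_apa_table <- function(path) {
  df <- read_tsv_checked(path)
  cn <- colnames(df)
  if ("Gene" %in% cn && "Predicted_Proximal_APA" %in% cn) {
    # DaPars dialect
    parts <- strsplit(as.character(df$Gene), "|", fixed = TRUE)
    if (any(lengths(parts) < 4L))
      stop("malformed DaPars composite ID in ", path)
    gene_id <- vapply(parts, `[[`, "", 1L)
    strand <- vapply(parts, `[[`, "", 4L)
    loci <- strsplit(sub(":", "-", as.character(df$Loci)), "-", fixed = TRUE)
    chrom <- vapply(loci, `[[`, "", 1L)
    start <- as.integer(vapply(loci, `[[`, "", 2L))
    end <- as.integer(vapply(loci, `[[`, "", 3L))
    pb <- as.integer(df$Predicted_Proximal_APA)
    pdui_cols <- setdiff(cn, c("Gene", "Loci", "Predicted_Proximal_APA",
                               "fit_value"))
  } else {
    need <- c("gene_id", "chrom", "start", "end", "strand", "proximal_boundary")
    if (!all(need %in% cn))
      stop("APA table ", path, " lacks required columns: ",
           paste(setdiff(need, cn), collapse = ", "))
    gene_id <- as.character(df$gene_id)
    chrom <- as.character(df$chrom)
    start <- as.integer(df$start)
    end <- as.integer(df$end)
    strand <- as.character(df$strand)
    pb <- as.integer(df$proximal_boundary)
    pdui_cols <- setdiff(cn, need)
  }
  if (length(pdui_cols) == 0L) stop("APA table ", path, " has no PDUI sample columns")
  pdui <- as.matrix(df[, pdui_cols, drop = FALSE])
  storage.mode(pdui) <- "double"
  rownames(pdui) <- gene_id
  genes <- data.frame(gene_id = gene_id, chrom = chrom, start = start,
                      end = end, strand = strand, proximal_boundary = pb,
                      stringsAsFactors = FALSE)
  new_apa_table(genes, pdui)
}

# Constructor + validation for the apa_table class; boundary is converted to
# a transcript-local 0-based offset here, once.
new_apa_table <- function(genes, pdui) {
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene IDs in APA table: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(genes$start > genes$end)) stop("locus start > end")
  out_of_locus <- genes$proximal_boundary < genes$start |
    genes$proximal_boundary > genes$end
  if (any(out_of_locus))
    stop("proximal boundary outside locus for gene(s): ",
         paste(genes$gene_id[out_of_locus], collapse = ", "))
  bad <- which(!is.na(pdui) & (pdui < 0 | pdui > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("PDUI outside [0,1] at gene ", genes$gene_id[bad[1L, 1L]],
         ", sample ", colnames(pdui)[bad[1L, 2L]],
         " (value ", pdui[bad[1L, , drop = FALSE]], ")")
  genes$utr_length <- genes$end - genes$start + 1L
  genes$boundary <- ifelse(genes$strand == "+",
                           genes$proximal_boundary - genes$start + 1L,
                           genes$end - genes$proximal_boundary + 1L)
  structure(list(genes = genes, pdui = pdui), class = "apa_table")
}

#' @export
print.apa_table <- function(x, ...) {
  cat("apa_table:", nrow(x$genes), "genes x", ncol(x$pdui), "samples;",
      sum(is.na(x$pdui)), "missing PDUI values\n")
  invisible(x)
}

#' Write an APA table (plain dialect)
#' @param apa An `apa_table`.
#' @param path Output path.
#' @param provenance Optional provenance comment line.
#' @return `path`, invisibly.
#' @export
write_apa_table <- function(apa, path, provenance = NULL) {
  stopifnot(inherits(apa, "apa_table"))
  g <- apa$genes[, c("gene_id", "chrom", "start", "end", "strand",
                     "proximal_boundary")]
  df <- cbind(g, as.data.frame(fmt_num(apa$pdui), check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a miRNA target-site table
#'
#' Two layouts are accepted: per-site records
#' `(gene_id, mirna_family, site_start, site_end)` with intervals in
#' transcript-local 3'UTR coordinates (0-based half-open), or precomputed
#' counts `(gene_id, mirna_family, putr_count, dutr_count)`.
#'
#' @param path Path to a TSV file.
#' @return A data.frame of class `site_table` (per-site) or `site_counts`
#'   (precomputed).
#' @export
read_site_table <- function(path) {
  df <- read_tsv_checked(path)
  cn <- colnames(df)
  if (all(c("gene_id", "mirna_family", "site_start", "site_end") %in% cn)) {
    out <- data.frame(gene_id = as.character(df$gene_id),
                      mirna_family = as.character(df$mirna_family),
                      site_start = as.integer(df$site_start),
                      site_end = as.integer(df$site_end),
                      stringsAsFactors = FALSE)
    if (any(out$site_start >= out$site_end))
      stop("site_start >= site_end in ", path)
    if (any(out$site_start < 0L)) stop("negative site coordinate in ", path)
    class(out) <- c("site_table", "data.frame")
  } else if (all(c("gene_id", "mirna_family", "putr_count", "dutr_count") %in% cn)) {
    out <- data.frame(gene_id = as.character(df$gene_id),
                      mirna_family = as.character(df$mirna_family),
                      putr_count = as.integer(df$putr_count),
                      dutr_count = as.integer(df$dutr_count),
                      stringsAsFactors = FALSE)
    out <- validate_site_counts(out)
  } else {
    stop("unrecognized site-table columns in ", path)
  }
  out
}

validate_site_counts <- function(counts) {
  stopifnot(is.data.frame(counts))
  need <- c("gene_id", "mirna_family", "putr_count", "dutr_count")
  if (!all(need %in% colnames(counts)))
    stop("site counts need columns: ", paste(need, collapse = ", "))
  if (any(counts$putr_count < 0L) || any(counts$dutr_count < 0L))
    stop("negative site counts")
  key <- paste(counts$gene_id, counts$mirna_family, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (gene, family) pairs in site counts")
  class(counts) <- c("site_counts", "data.frame")
  counts
}

#' Read a clinical table
#'
#' TSV with columns `sample_id`, `patient_id`, `tissue` (`tumor`/`normal`),
#' and any of `age`, `gender`, `stage`, `smoking`, `surv_time`, `event`,
#' `response` (`responder`/`non_responder`), `timepoint` (`pre`/`post`).
#'
#' @param path Path to a TSV file.
#' @return A validated data.frame of class `clinical_table`.
#' @export
read_clinical_table <- function(path) {
  df <- read_tsv_checked(path)
  validate_clinical_table(df)
}

#' Validate a clinical table built in code
#'
#' Applies the same checks as [read_clinical_table()] to an in-memory
#' data.frame and tags it with the `clinical_table` class.
#'
#' @param df Data.frame with at least `sample_id`, `patient_id`, `tissue`.
#' @return The validated `clinical_table`.
#' @export
validate_clinical_table <- function(df) {
  if (!all(c("sample_id", "patient_id", "tissue") %in% colnames(df)))
    stop("clinical table needs sample_id, patient_id, tissue columns")
  df$sample_id <- as.character(df$sample_id)
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample IDs in clinical table")
  if (!all(df$tissue %in% c("tumor", "normal")))
    stop("tissue must be 'tumor' or 'normal'")
  if ("surv_time" %in% colnames(df) && any(df$surv_time < 0, na.rm = TRUE))
    stop("negative survival time")
  if ("event" %in% colnames(df) && !all(df$event %in% c(0L, 1L, NA)))
    stop("event must be 0/1")
  if ("response" %in% colnames(df) &&
      !all(df$response %in% c("responder", "non_responder", NA)))
    stop("response must be 'responder' or 'non_responder'")
  if ("timepoint" %in% colnames(df) && !all(df$timepoint %in% c("pre", "post", NA)))
    stop("timepoint must be 'pre' or 'post'")
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Write a clinical table as TSV
#' @param clinical A `clinical_table` data.frame.
#' @param path Output path.
#' @param provenance Optional provenance comment line.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(as.data.frame(clinical), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Restrict tables to a common sample set
#'
#' Takes matrices (samples in columns), `apa_table`s (samples in PDUI
#' columns) and `clinical_table`s (samples in rows), and restricts all of
#' them to the same samples in a canonical (sorted) order.
#'
#' @param tables A list of >= 2 tables.
#' @param mode `"intersect"` drops samples absent from any table; `"strict"`
#'   errors unless all tables already carry identical sample sets.
#' @return The list with every element restricted to the common samples.
#' @export
align_samples <- function(tables, mode = c("intersect", "strict")) {
  mode <- match.arg(mode)
  stopifnot(is.list(tables), length(tables) >= 2L)
  sample_sets <- lapply(tables, table_samples)
  common <- Reduce(intersect, sample_sets)
  if (mode == "strict") {
    same <- all(vapply(sample_sets, function(s) setequal(s, sample_sets[[1L]]),
                       logical(1L)))
    if (!same) stop("sample sets differ across tables (strict mode)")
  }
  if (length(common) == 0L) stop("no samples common to all tables")
  common <- sort(common)
  lapply(tables, restrict_samples, samples = common)
}

table_samples <- function(x) {
  if (inherits(x, "apa_table")) return(colnames(x$pdui))
  if (inherits(x, "clinical_table") || (is.data.frame(x) && "sample_id" %in% colnames(x)))
    return(x$sample_id)
  if (is.matrix(x)) return(colnames(x))
  stop("cannot determine samples for object of class ", paste(class(x), collapse = "/"))
}

restrict_samples <- function(x, samples) {
  if (inherits(x, "apa_table")) {
    x$pdui <- x$pdui[, samples, drop = FALSE]
    return(x)
  }
  if (inherits(x, "clinical_table") || (is.data.frame(x) && "sample_id" %in% colnames(x))) {
    out <- x[match(samples, x$sample_id), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  x[, samples, drop = FALSE]
}

#' Filter miRNA families by mean expression
#'
#' Keeps families whose mean TPM across samples is at least `min_mean_tpm`
#' (inclusive). Row order of survivors is preserved.
#'
#' @param expr miRNA-family TPM matrix (families x samples).
#' @param min_mean_tpm Inclusive threshold on the per-family mean; default
#'   0.01 TPM.
#' @return The filtered matrix.
#' @export
filter_mirna_families <- function(expr, min_mean_tpm = 0.01) {
  stopifnot(is.matrix(expr))
  expr[rowMeans(expr) >= min_mean_tpm, , drop = FALSE]
}

# Shared TSV reader: skips "#" provenance lines, keeps sample-ID columns as-is.
read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop("empty table: ", path)
  df
}

validate_expression_matrix <- function(m, what = "matrix") {
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("invalid ", what, " value (must be finite and >= 0) at row ",
         rownames(m)[bad[1L, 1L]], ", column ", colnames(m)[bad[1L, 2L]])
  invisible(m)
}
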