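# Readers and writers for the standard pipeline inputs, with the gene and
# recurrence filters applied on ingestion and a reconciling filter log.

.SILENT_CLASSES <- c("Silent", "Synonymous", "synonymous_variant", "RNA",
                     "Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "IGR")

#' Read a binary mutation matrix from TSV or MAF-like long format
#'
#' Binary format: samples in rows (first column `sample`), one 0/1 column
#' per gene.  MAF-like format: one row per variant with sample, gene and
#' variant-classification columns (`Tumor_Sample_Barcode`/`sample`,
#' `Hugo_Symbol`/`gene`, `Variant_Classification`/`variant_classification`,
#' case-insensitive); silent variants are discarded and the rest collapsed
#' to per-sample indicators.  Genes mutated in no more than `min_recurrence`
#' samples are dropped (strictly greater-than rule by default; set
#' `inclusive = TRUE` for a greater-or-equal rule) and recorded in the
#' `filter_log` attribute.
#'
#' @param path TSV file path.
#' @param format `"auto"` (default, detected from the header), `"binary"`
#'   or `"maf"`.
#' @param min_recurrence recurrence threshold (default 10).
#' @param inclusive keep genes with exactly `min_recurrence` mutated
#'   samples (default `FALSE`: strictly more are required).
#' @return Binary samples x genes matrix with attribute `filter_log`.
#' @export
read_mutation_matrix <- function(path, format = c("auto", "binary", "maf"),
                                 min_recurrence = 10, inclusive = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (nrow(raw) == 0 || ncol(raw) == 0) {
    stop("empty mutation input: ", path, call. = FALSE)
  }
  lc <- tolower(colnames(raw))
  maf_cols <- c(sample = NA, gene = NA, vc = NA)
  maf_cols["sample"] <- match(TRUE, lc %in% c("tumor_sample_barcode", "sample"))
  maf_cols["gene"] <- match(TRUE, lc %in% c("hugo_symbol", "gene"))
  maf_cols["vc"] <- match(TRUE, lc %in% c("variant_classification"))
  if (format == "auto") {
    format <- if (!anyNA(maf_cols)) "maf" else "binary"
  }
  if (format == "maf") {
    if (anyNA(maf_cols)) {
      stop("MAF-like input needs sample, gene and variant-classification ",
           "columns", call. = FALSE)
    }
    sm <- raw[[maf_cols["sample"]]]
    gn <- raw[[maf_cols["gene"]]]
    vc <- raw[[maf_cols["vc"]]]
    bad <- which(is.na(sm) | sm == "" | is.na(gn) | gn == "" |
                   is.na(vc) | vc == "")
    if (length(bad)) {
      stop("malformed MAF rows (missing fields) at line(s): ",
           paste(utils::head(bad + 1, 10), collapse = ", "), call. = FALSE)
    }
    nonsilent <- !(vc %in% .SILENT_CLASSES)
    n_silent <- sum(!nonsilent)
    sm <- sm[nonsilent]; gn <- gn[nonsilent]
    samples <- sort(unique(raw[[maf_cols["sample"]]]))
    genes <- sort(unique(gn))
    M <- matrix(0, length(samples), length(genes),
                dimnames = list(samples, genes))
    if (length(sm)) M[cbind(match(sm, samples), match(gn, genes))] <- 1
    log <- list(silent_variants_discarded = n_silent)
  } else {
    samples <- as.character(raw[[1]])
    M <- as.matrix(raw[, -1, drop = FALSE])
    if (!is.numeric(M) || !all(M %in% c(0, 1))) {
      bad <- which(!(M %in% c(0, 1)), arr.ind = TRUE)
      stop(sprintf("non-binary cell(s), e.g. row %d column '%s'",
                   bad[1, 1] + 1, colnames(M)[bad[1, 2]]), call. = FALSE)
    }
    rownames(M) <- samples
    log <- list(silent_variants_discarded = 0L)
  }
  counts <- colSums(M)
  keep <- if (inclusive) counts >= min_recurrence else counts > min_recurrence
  dropped <- data.frame(gene = colnames(M)[!keep],
                        mutated_samples = unname(counts[!keep]),
                        stringsAsFactors = FALSE)
  M <- M[, keep, drop = FALSE]
  log$min_recurrence <- min_recurrence
  log$inclusive <- inclusive
  log$genes_dropped <- dropped
  log$genes_kept <- ncol(M)
  attr(M, "filter_log") <- log
  M
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' First column holds gene identifiers; remaining columns are samples.
#' Rows with missing/empty identifiers or with all values missing are
#' dropped (when `drop_unnamed` is `TRUE`) and counted in the
#' `filter_log` attribute; duplicate gene identifiers are an error.
#'
#' @param path TSV file path.
#' @param drop_unnamed drop rows with missing identifiers or all-missing
#'   values (default `TRUE`).
#' @return Numeric genes x samples matrix with attribute `filter_log`.
#' @export
read_expression_matrix <- function(path, drop_unnamed = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0) stop("empty expression input: ", path, call. = FALSE)
  genes <- raw[[1]]
  vals <- raw[, -1, drop = FALSE]
  num <- suppressWarnings(
    vapply(vals, as.numeric, numeric(nrow(vals)))
  )
  if (is.null(dim(num))) num <- matrix(num, nrow = nrow(vals),
                                       dimnames = list(NULL, colnames(vals)))
  bad <- which(is.na(num) & !(is.na(vals) | vals == "" | toupper(as.matrix(vals)) == "NA"),
               arr.ind = TRUE)
  if (length(bad)) {
    stop(sprintf("non-numeric expression value at row %d ('%s'), column '%s'",
                 bad[1, 1] + 1, genes[bad[1, 1]], colnames(num)[bad[1, 2]]),
         call. = FALSE)
  }
  unnamed <- is.na(genes) | genes == ""
  allmiss <- rowSums(!is.na(num)) == 0
  drop <- (unnamed | allmiss)
  n_dropped <- 0L
  if (drop_unnamed && any(drop)) {
    n_dropped <- sum(drop)
    genes <- genes[!drop]
    num <- num[!drop, , drop = FALSE]
  }
  dup <- genes[duplicated(genes)]
  if (length(dup)) {
    stop("duplicate gene identifier(s): ",
         paste(utils::head(unique(dup), 10), collapse = ", "), call. = FALSE)
  }
  rownames(num) <- genes
  attr(num, "filter_log") <- list(rows_dropped = n_dropped,
                                  rows_kept = nrow(num))
  num
}

#' Read a clinical table from TSV
#'
#' @param path TSV file path with a mandatory header including `sample`.
#' @return `data.frame` with one row per sample.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample" %in% colnames(df)) {
    stop("clinical table needs a 'sample' column", call. = FALSE)
  }
  df$sample <- as.character(df$sample)
  rownames(df) <- df$sample
  df
}

#' Align mutation, expression and clinical components into one cohort
#'
#' Retains the intersection of sample identifiers (optionally after
#' truncating TCGA-style barcodes to their first 12 or 15 characters),
#' reorders every component identically, and logs per-source exclusions.
#'
#' @param mutations samples x genes binary matrix.
#' @param expression genes x samples matrix.
#' @param clinical clinical `data.frame` with a `sample` column.
#' @param truncate_barcodes `NULL` (exact matching) or 12 or 15.
#' @return Object of class `cohort_bundle`: list with aligned `mutations`,
#'   `expression`, `clinical` and a `provenance` log.
#' @export
align_cohort <- function(mutations, expression, clinical,
                         truncate_barcodes = NULL) {
  if (nrow(mutations) == 0 || ncol(expression) == 0 || nrow(clinical) == 0) {
    stop("empty cohort component", call. = FALSE)
  }
  trunc <- function(x) {
    if (is.null(truncate_barcodes)) x else substr(x, 1, truncate_barcodes)
  }
  id_mut <- trunc(rownames(mutations))
  id_expr <- trunc(colnames(expression))
  id_clin <- trunc(clinical$sample)
  shared <- sort(Reduce(intersect, list(id_mut, id_expr, id_clin)))
  if (length(shared) == 0) {
    stop("no shared samples across mutations, expression and clinical",
         call. = FALSE)
  }
  mut <- mutations[match(shared, id_mut), , drop = FALSE]
  expr <- expression[, match(shared, id_expr), drop = FALSE]
  clin <- clinical[match(shared, id_clin), , drop = FALSE]
  rownames(mut) <- shared
  colnames(expr) <- shared
  clin$sample <- shared
  rownames(clin) <- shared
  provenance <- list(
    n_shared = length(shared),
    excluded = c(mutations = length(id_mut) - length(shared),
                 expression = length(id_expr) - length(shared),
                 clinical = length(id_clin) - length(shared)),
    truncate_barcodes = truncate_barcodes,
    filter_logs = list(mutations = attr(mutations, "filter_log"),
                       expression = attr(expression, "filter_log"))
  )
  structure(list(mutations = mut, expression = expr, clinical = clin,
                 provenance = provenance),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Aligned cohort bundle\n")
  cat(sprintf("  shared samples: %d (excluded: mutations %d, expression %d, clinical %d)\n",
              x$provenance$n_shared, x$provenance$excluded["mutations"],
              x$provenance$excluded["expression"],
              x$provenance$excluded["clinical"]))
  cat(sprintf("  drivers: %d, genes: %d\n", ncol(x$mutations),
              nrow(x$expression)))
  invisible(x)
}

#' Write PCA stage outputs (scores, loadings, explained variance, overlay)
#'
#' @param pca an [fit_pca()] result.
#' @param dir output directory.
#' @param overlay optional [overlay_table()] result.
#' @return Invisibly, the paths written.
#' @export
write_pca <- function(pca, dir, overlay = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("pca_scores.tsv", "pca_loadings.tsv",
                            "pca_variance.tsv"))
  .write_matrix_tsv(pca$scores, paths[1], id_col = "sample")
  .write_matrix_tsv(pca$loadings, paths[2], id_col = "gene")
  utils::write.table(summary(pca), paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(overlay)) {
    p <- file.path(dir, "pca_overlay.tsv")
    utils::write.table(overlay, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write gene-fit stage outputs (per-gene table and long coefficients)
#'
#' @param fits a (preferably moderated) `gene_fits`.
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_gene_fits <- function(fits, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(gene = fits$genes,
                    sigma2 = fits$sigma2,
                    df_residual = fits$df_residual,
                    r_squared = fits$r_squared,
                    stringsAsFactors = FALSE)
  if (!is.null(fits$moderated)) {
    tab$s2_post <- fits$moderated$s2_post
    tab$moderated_F <- fits$moderated$F
    tab$p_value <- fits$moderated$p
    tab$q_value <- fits$moderated$q
  }
  p1 <- file.path(dir, "gene_fits.tsv")
  utils::write.table(tab, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  B <- fits$coefficients[, fits$mutation_cols, drop = FALSE]
  long <- data.frame(gene = rep(fits$genes, times = ncol(B)),
                     mutation = rep(colnames(B), each = nrow(B)),
                     beta = as.vector(B), stringsAsFactors = FALSE)
  if (!is.null(fits$moderated)) {
    long$q_value <- as.vector(fits$moderated$coef_q)
  }
  p2 <- file.path(dir, "gene_coefficients.tsv")
  utils::write.table(long, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Write target-gene sets in GMT-style text
#'
#' One line per mutation: identifier, description, then member genes.
#'
#' @param target_sets named list of [target_genes()] results.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_target_sets <- function(target_sets, path) {
  lines <- vapply(names(target_sets), function(m) {
    s <- target_sets[[m]]
    paste(c(m, sprintf("q<%g", attr(s, "q_threshold")), s$gene),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
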