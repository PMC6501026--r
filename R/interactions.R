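# Pairwise mutation co-occurrence / mutual exclusivity and target-set
# overlap statistics.

#' Pairwise co-occurrence and mutual exclusivity of driver mutations
#'
#' For every pair of drivers, the 2x2 co-mutation table is summarized by a
#' log odds ratio (with the Haldane-Anscombe 0.5 correction applied to all
#' cells when any cell is zero), a two-sided Fisher exact p-value, and
#' Benjamini-Hochberg q-values across pairs.  Positive log odds ratios mark
#' co-occurrence, negative ones mutual exclusivity.
#'
#' @param mutations binary samples x drivers matrix (>= 2 drivers).
#' @return Object of class `mutation_pairs`: long-format `data.frame` with
#'   one row per unordered pair (`gene_a` < `gene_b` in column order):
#'   `n11`, `n10`, `n01`, `n00`, `log_or`, `fisher_p`, `fisher_q`.
#' @export
cooccurrence <- function(mutations) {
  .check_binary_matrix(mutations)
  m <- ncol(mutations)
  if (m < 2) stop("need at least two mutation columns", call. = FALSE)
  gn <- colnames(mutations)
  pairs <- utils::combn(m, 2)
  res <- apply(pairs, 2, function(jk) {
    a <- mutations[, jk[1]]; b <- mutations[, jk[2]]
    n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
    n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
    cells <- c(n11, n10, n01, n00)
    cc <- if (any(cells == 0)) cells + 0.5 else cells
    log_or <- log(cc[1] * cc[4] / (cc[2] * cc[3]))
    p <- stats::fisher.test(matrix(cells, 2, 2))$p.value
    c(n11, n10, n01, n00, log_or, p)
  })
  out <- data.frame(
    gene_a = gn[pairs[1, ]], gene_b = gn[pairs[2, ]],
    n11 = res[1, ], n10 = res[2, ], n01 = res[3, ], n00 = res[4, ],
    log_or = res[5, ], fisher_p = res[6, ],
    stringsAsFactors = FALSE
  )
  out$fisher_q <- stats::p.adjust(out$fisher_p, method = "BH")
  structure(out, class = c("mutation_pairs", "data.frame"))
}

#' @export
print.mutation_pairs <- function(x, ...) {
  cat(sprintf("Pairwise mutation statistics: %d pairs\n", nrow(x)))
  ord <- order(x$fisher_q)
  print.data.frame(utils::head(x[ord, ], 8), digits = 3)
  invisible(x)
}

#' Pairwise overlap of mutation target-gene sets
#'
#' For every pair of target sets drawn from the same gene universe:
#' overlap count, Jaccard index, a one-sided hypergeometric enrichment
#' p-value for at-least-observed overlap, and BH q-values across pairs.
#'
#' @param target_sets named list of [target_genes()] results or character
#'   vectors of gene identifiers.
#' @param universe_size size of the common gene universe (> 0).
#' @return Object of class `target_overlap_pairs`: long-format `data.frame`
#'   with `set_a`, `set_b`, `size_a`, `size_b`, `overlap`, `jaccard`,
#'   `hyper_p`, `hyper_q`.
#' @export
target_overlap <- function(target_sets, universe_size) {
  if (universe_size < 1) stop("empty gene universe", call. = FALSE)
  sets <- lapply(target_sets, function(s) {
    if (inherits(s, "target_gene_set")) s$gene else as.character(s)
  })
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("'target_sets' must be named", call. = FALSE)
  }
  if (any(lengths(sets) > universe_size)) {
    stop("a set exceeds the universe size", call. = FALSE)
  }
  m <- length(sets)
  if (m < 2) stop("need at least two sets", call. = FALSE)
  pairs <- utils::combn(m, 2)
  rows <- apply(pairs, 2, function(jk) {
    A <- sets[[jk[1]]]; B <- sets[[jk[2]]]
    k <- length(intersect(A, B))
    un <- length(union(A, B))
    jac <- if (un == 0) 0 else k / un
    # P(overlap >= k) drawing |B| from universe with |A| marked
    p <- stats::phyper(k - 1, length(A), universe_size - length(A),
                       length(B), lower.tail = FALSE)
    c(length(A), length(B), k, jac, p)
  })
  out <- data.frame(
    set_a = names(sets)[pairs[1, ]], set_b = names(sets)[pairs[2, ]],
    size_a = rows[1, ], size_b = rows[2, ], overlap = rows[3, ],
    jaccard = rows[4, ], hyper_p = rows[5, ],
    stringsAsFactors = FALSE
  )
  out$hyper_q <- stats::p.adjust(out$hyper_p, method = "BH")
  structure(out, class = c("target_overlap_pairs", "data.frame"))
}

#' @export
print.target_overlap_pairs <- function(x, ...) {
  cat(sprintf("Target-set overlap statistics: %d pairs\n", nrow(x)))
  print.data.frame(utils::head(x[order(x$hyper_q), ], 8), digits = 3)
  invisible(x)
}

#' Combined pairwise matrix (co-mutation above, overlap below the diagonal)
#'
#' Assembles the square matrix view: the upper triangle holds the
#' co-occurrence log odds ratios, the lower triangle the chosen overlap
#' statistic (count, Jaccard, or -log10 enrichment p).
#'
#' @param cooc a [cooccurrence()] result.
#' @param overlap a [target_overlap()] result on the same drivers.
#' @param lower which overlap statistic fills the lower triangle.
#' @return Square numeric matrix with driver names on both dimensions.
#' @export
combine_pairwise <- function(cooc, overlap,
                             lower = c("overlap", "jaccard", "neglog10p")) {
  lower <- match.arg(lower)
  gn <- unique(c(cooc$gene_a, cooc$gene_b))
  M <- matrix(NA_real_, length(gn), length(gn), dimnames = list(gn, gn))
  for (i in seq_len(nrow(cooc))) {
    M[cooc$gene_a[i], cooc$gene_b[i]] <- cooc$log_or[i]
  }
  val <- switch(lower,
                overlap = overlap$overlap,
                jaccard = overlap$jaccard,
                neglog10p = -log10(pmax(overlap$hyper_p, 1e-300)))
  for (i in seq_len(nrow(overlap))) {
    a <- overlap$set_a[i]; b <- overlap$set_b[i]
    if (a %in% gn && b %in% gn) M[b, a] <- val[i]
  }
  M
}
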