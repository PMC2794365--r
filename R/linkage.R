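# Linkage matrix: eQTL likelihood (regression LOD) per (marker, gene),
# plus locus-effect summaries (variance explained, two-locus analysis).

#' eQTL likelihood score for one marker-gene pair
#'
#' Two-class regression LOD for a haploid cross:
#' `LOD = (n/2) * log10(RSS0 / RSS1)` where `RSS0` is the residual sum of
#' squares about the grand expression mean and `RSS1` about the per-allele
#' class means, over the `n` segregants with both values observed (pairwise
#' deletion). A constant trait (`RSS0 = 0`) scores 0; a degenerate perfect
#' fit (`RSS1 = 0` with `RSS0 > 0`) scores the cap. The score is invariant
#' to adding a constant to the expression values and to swapping the allele
#' labels.
#'
#' @param genotype_calls Allele vector in \{0, 1, NA\}, one per segregant.
#' @param expression Expression vector aligned with `genotype_calls`.
#' @param cap Upper bound for degenerate/near-perfect fits (default 50).
#' @return Non-negative LOD score, or `NA` when either allele class has
#'   fewer than 3 non-missing pairs (excluded downstream).
#' @export
eqtl_likelihood <- function(genotype_calls, expression, cap = 50) {
  ok <- !is.na(genotype_calls) & !is.na(expression)
  g <- genotype_calls[ok]
  x <- expression[ok]
  n0 <- sum(g == 0)
  n1 <- sum(g == 1)
  if (n0 < 3L || n1 < 3L) return(NA_real_)
  n <- n0 + n1
  rss0 <- sum((x - mean(x))^2)
  if (rss0 <= 0) return(0)
  x0 <- x[g == 0]; x1 <- x[g == 1]
  rss1 <- sum((x0 - mean(x0))^2) + sum((x1 - mean(x1))^2)
  if (rss1 == 0) return(cap)
  lod <- (n / 2) * log10(rss0 / rss1)
  min(max(lod, 0), cap)
}

#' Compute the markers-by-genes linkage matrix
#'
#' Applies [eqtl_likelihood()] to every (marker, gene) pair over the shared
#' segregants, vectorized per marker. Cells whose score is missing (an
#' allele class with fewer than 3 observations) are set to 0 and counted in
#' a message.
#'
#' @param genotypes A [genotype_matrix()].
#' @param expression An [expression_matrix()].
#' @param min_shared Minimum number of shared segregant ids (default 20).
#' @param cap LOD cap for degenerate fits.
#' @return Object of class `linkage_matrix`: `marker_ids`, `gene_ids`,
#'   `scores` (markers x genes, all finite and >= 0).
#' @export
compute_linkage_matrix <- function(genotypes, expression, min_shared = 20,
                                   cap = 50) {
  shared <- intersect(genotypes$segregant_ids, expression$sample_ids)
  if (length(shared) == 0L) stop("no shared segregants between inputs")
  if (length(shared) < min_shared)
    stop(sprintf("only %d shared segregants (need >= %d)", length(shared),
                 min_shared))
  d_g <- length(genotypes$segregant_ids) - length(shared)
  d_e <- length(expression$sample_ids) - length(shared)
  if (d_g + d_e > 0)
    message(sprintf("segregant join dropped %d genotype / %d expression ids",
                    d_g, d_e))
  G <- genotypes$calls[, shared, drop = FALSE]
  X <- expression$values[, shared, drop = FALSE]
  M <- !is.na(X)
  Xz <- X; Xz[!M] <- 0
  X2 <- Xz^2
  nm <- nrow(G); ng <- nrow(X)
  scores <- matrix(0, nm, ng, dimnames = list(genotypes$marker_ids,
                                              expression$gene_ids))
  n_missing <- 0L
  for (i in seq_len(nm)) {
    g <- G[i, ]
    i0 <- which(!is.na(g) & g == 0L)
    i1 <- which(!is.na(g) & g == 1L)
    n0 <- rowSums(M[, i0, drop = FALSE]); n1 <- rowSums(M[, i1, drop = FALSE])
    s0 <- rowSums(Xz[, i0, drop = FALSE]); s1 <- rowSums(Xz[, i1, drop = FALSE])
    q0 <- rowSums(X2[, i0, drop = FALSE]); q1 <- rowSums(X2[, i1, drop = FALSE])
    n <- n0 + n1
    rss0 <- pmax(q0 + q1 - (s0 + s1)^2 / pmax(n, 1L), 0)
    rss1 <- pmax(q0 - s0^2 / pmax(n0, 1L), 0) +
            pmax(q1 - s1^2 / pmax(n1, 1L), 0)
    lod <- ifelse(rss0 <= 0, 0,
           ifelse(rss1 == 0, cap,
                  pmin(pmax((n / 2) * log10(rss0 / rss1), 0), cap)))
    bad <- n0 < 3L | n1 < 3L
    n_missing <- n_missing + sum(bad)
    lod[bad] <- 0
    scores[i, ] <- lod
  }
  if (n_missing > 0L)
    message(sprintf("%d marker-gene scores missing (allele class < 3); set to 0",
                    n_missing))
  structure(list(marker_ids = genotypes$marker_ids,
                 gene_ids = expression$gene_ids, scores = scores),
            class = "linkage_matrix")
}

#' Fraction of expression variance explained by one locus
#'
#' Per gene, `R^2 = 1 - RSS1/RSS0` from the allele-class-mean model
#' (pairwise deletion per gene); a zero-variance gene contributes 0. The
#' mean R^2 across the gene set is returned.
#'
#' @param genotype_calls Allele vector in \{0, 1, NA\}.
#' @param expression_rows Numeric matrix (genes x segregants) aligned with
#'   the calls; a single gene may be given as a vector.
#' @return Mean R^2 in \[0, 1\], with the per-gene values in attribute
#'   `"per_gene"`.
#' @export
variance_explained <- function(genotype_calls, expression_rows) {
  X <- if (is.matrix(expression_rows)) expression_rows else
    matrix(expression_rows, nrow = 1L)
  if (nrow(X) < 1L) stop("need at least one gene")
  r2 <- apply(X, 1L, function(x) r2_classes(list(genotype_calls), x))
  structure(mean(r2), per_gene = r2)
}

# R^2 of the class-mean model for an arbitrary class coding: `factors` is a
# list of allele vectors; classes are their joint levels.
r2_classes <- function(factors, x) {
  ok <- !is.na(x)
  for (f in factors) ok <- ok & !is.na(f)
  x <- x[ok]
  cls <- interaction(lapply(factors, function(f) f[ok]), drop = TRUE)
  rss0 <- sum((x - mean(x))^2)
  if (rss0 <= 0) return(0)
  fitted <- stats::ave(x, cls)
  rss1 <- sum((x - fitted)^2)
  max(0, 1 - rss1 / rss0)
}

#' Two-locus additive summary for a gene set
#'
#' For two markers, reports the mean expression of the four genotype classes
#' (each segregant's expression first averaged over the gene set, then
#' averaged over segregants within the class) and the joint R^2 of the
#' four-class-mean model (per gene, then averaged), alongside the marginal
#' single-locus R^2 values. An additive two-locus effect shows as parallel
#' class-mean shifts and a joint R^2 exceeding both marginals.
#'
#' @param calls_A,calls_B Aligned allele vectors for the two markers.
#' @param expression_rows Genes-by-segregants matrix (or vector for one gene).
#' @return List with `class_means` (named `"0-0"`, `"0-1"`, `"1-0"`,
#'   `"1-1"`; `NA` for an empty class), `joint_r2`, `marginal_r2_A`,
#'   `marginal_r2_B`, `n_per_class`.
#' @export
two_locus_summary <- function(calls_A, calls_B, expression_rows) {
  X <- if (is.matrix(expression_rows)) expression_rows else
    matrix(expression_rows, nrow = 1L)
  per_seg <- colMeans(X, na.rm = TRUE)
  cls_lab <- paste(calls_A, calls_B, sep = "-")
  cls_lab[is.na(calls_A) | is.na(calls_B)] <- NA
  levels4 <- c("0-0", "0-1", "1-0", "1-1")
  class_means <- vapply(levels4, function(l) {
    v <- per_seg[!is.na(cls_lab) & cls_lab == l & !is.nan(per_seg)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  n_per_class <- vapply(levels4, function(l)
    sum(!is.na(cls_lab) & cls_lab == l), integer(1))
  joint <- mean(apply(X, 1L, function(x)
    r2_classes(list(calls_A, calls_B), x)))
  list(class_means = class_means,
       joint_r2 = joint,
       marginal_r2_A = as.numeric(variance_explained(calls_A, X)),
       marginal_r2_B = as.numeric(variance_explained(calls_B, X)),
       n_per_class = n_per_class)
}

#' Write a linkage matrix to TSV (markers x genes)
#' @param x A `linkage_matrix`.
#' @param path Output path.
#' @export
write_linkage_matrix <- function(x, path) {
  write_id_matrix(x$scores, "marker_id", path)
}
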