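# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use the naive formulation (explicit enumeration, lm fits, closed-form
# combinatorics) so they stay independent of the package's optimized paths.

# Minimal rel_matrix-like object for biclustering/annotation tests.
make_rel <- function(score, chrom = rep("I", nrow(score)), pos_kb = NULL,
                     hit_genes = NULL, protein_of = NULL,
                     gene_ids = character(), n_tests = length(score)) {
  nm <- nrow(score); ns <- ncol(score)
  marker_ids <- rownames(score)
  if (is.null(marker_ids)) marker_ids <- sprintf("m%03d", seq_len(nm))
  signature_ids <- colnames(score)
  if (is.null(signature_ids)) signature_ids <- sprintf("s%02d", seq_len(ns))
  dimnames(score) <- list(marker_ids, signature_ids)
  if (is.null(pos_kb)) {
    pos_kb <- stats::ave(seq_len(nm), chrom, FUN = seq_along) * 10
  }
  if (is.null(hit_genes)) {
    hit_genes <- vector("list", nm * ns)
    dim(hit_genes) <- c(nm, ns)
  }
  if (is.null(protein_of))
    protein_of <- stats::setNames(paste0("P_", signature_ids), signature_ids)
  structure(list(marker_ids = marker_ids, signature_ids = signature_ids,
                 chrom = chrom, pos_kb = pos_kb, score = score,
                 direction = NULL, threshold = NULL, hyper_p = NULL,
                 p_t = NULL, n_high = NULL, hit_genes = hit_genes,
                 n_tests = n_tests, protein_of = protein_of,
                 gene_ids = gene_ids),
            class = "rel_matrix")
}

make_module <- function(rel, start_idx, end_idx, signatures) {
  structure(list(chromosome = rel$chrom[start_idx],
                 start_idx = start_idx, end_idx = end_idx,
                 marker_ids = rel$marker_ids[start_idx:end_idx],
                 start_kb = rel$pos_kb[start_idx],
                 end_kb = rel$pos_kb[end_idx],
                 signatures = signatures,
                 module_score = mean(rel$score[start_idx:end_idx,
                                               signatures, drop = FALSE]),
                 seed = c(marker = start_idx, signature = 1L),
                 n_iter = 1L),
            class = "rel_module")
}

# Exhaustive threshold scan: every observed score value x both directions,
# upper-tail hypergeometric; ties toward smaller threshold, then "up".
bf_select_threshold <- function(scores, over, under) {
  N <- length(scores)
  best <- NULL
  for (d in c("up", "down")) {
    grp <- if (d == "up") over else under
    K <- length(intersect(grp, names(scores)))
    if (K == 0L) next
    for (t in sort(unique(as.vector(scores)))) {
      high <- names(scores)[scores >= t]
      x <- length(intersect(high, grp))
      p <- stats::phyper(x - 1, K, N - K, length(high), lower.tail = FALSE)
      better <- is.null(best) || p < best$hypergeom_p ||
        (p == best$hypergeom_p && t < best$threshold) ||
        (p == best$hypergeom_p && t == best$threshold &&
         d == "up" && best$direction == "down")
      if (better)
        best <- list(threshold = t, direction = d, hypergeom_p = p,
                     n_high = length(high))
    }
  }
  best
}

# O(m^2) best contiguous interval maximizing sum(x); smallest start then
# smallest end among ties; NULL when every element is negative.
bf_best_interval <- function(x) {
  m <- length(x)
  best <- list(gain = -Inf)
  for (s in seq_len(m)) for (e in s:m) {
    gain <- sum(x[s:e])
    if (gain > best$gain) best <- list(gain = gain, start = s, end = e)
  }
  if (best$gain < 0 && all(x < 0)) NULL else best
}

# Connected components by repeated closure over an adjacency matrix --
# independent of the union-find inside deduplicate().
bf_components <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Closed-form upper-tail hypergeometric from binomial coefficients.
bf_hyper_upper <- function(x, K, N, n) {
  kk <- x:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Regression-LOD oracle via two explicit lm() fits.
bf_lod <- function(g, x) {
  ok <- !is.na(g) & !is.na(x)
  g <- g[ok]; x <- x[ok]
  rss0 <- sum(stats::resid(stats::lm(x ~ 1))^2)
  rss1 <- sum(stats::resid(stats::lm(x ~ factor(g)))^2)
  (length(x) / 2) * log10(rss0 / rss1)
}

# Planted-block score matrix: `blocks` is a list of list(rows, cols, value).
planted_matrix <- function(nm, ns, blocks, noise = 0) {
  m <- matrix(noise, nm, ns)
  for (b in blocks) m[b$rows, b$cols] <- b$value
  m
}

# A module's entry-cell set, recomputed independently for overlap checks.
module_cells_test <- function(m) {
  as.vector(outer(m$marker_ids, m$signatures, paste, sep = "\r"))
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

# Small genotype/expression pair with known structure for linkage tests.
toy_cross <- function(n_seg = 40, n_markers = 4, n_genes = 6, seed = 42) {
  set.seed(seed)
  calls <- matrix(rbinom(n_markers * n_seg, 1L, 0.5), n_markers, n_seg,
                  dimnames = list(sprintf("m%d", 1:n_markers),
                                  sprintf("s%02d", 1:n_seg)))
  expr <- matrix(rnorm(n_genes * n_seg), n_genes, n_seg,
                 dimnames = list(sprintf("g%d", 1:n_genes),
                                 sprintf("s%02d", 1:n_seg)))
  expr[1, ] <- calls[1, ] + rnorm(n_seg, 0, 0.3)  # gene 1 linked to marker 1
  list(genotypes = genotype_matrix(calls), expression = expression_matrix(expr))
}
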