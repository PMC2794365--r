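# ReL test: per (marker, signature) pair, choose the eQTL-likelihood
# threshold by a hypergeometric scan over all observed score values, compare
# signature values of high-linkage genes vs the rest by a Welch t-test,
# Bonferroni-correct over all pairs, and record the hit genes.

#' Split a regulatory signature about its mean
#'
#' Genes with value strictly above the signature mean form the
#' over-expressed group, strictly below the under-expressed group; genes
#' exactly at the mean belong to neither.
#'
#' @param signature_values Named numeric vector (gene -> log2 ratio) with at
#'   least two distinct finite values.
#' @return List with `over`, `under` (gene id vectors) and `mean`.
#' @export
split_signature <- function(signature_values) {
  v <- signature_values[is.finite(signature_values)]
  if (length(unique(v)) < 2L)
    stop("degenerate signature: all values identical")
  mu <- mean(v)
  list(over = names(v)[v > mu], under = names(v)[v < mu], mean = mu)
}

#' Select the eQTL-likelihood threshold for one (marker, signature) pair
#'
#' Every observed linkage score is a candidate threshold; for each candidate
#' `t` and each direction (up = over-expressed group, down = under-expressed
#' group) the upper-tail hypergeometric P of the overlap between the
#' high-linkage set (score >= t, inclusive) and the group is computed, over
#' the universe of all scored genes. The (threshold, direction) minimizing P
#' is returned; ties are broken toward the smaller threshold, then direction
#' up.
#'
#' @param linkage_column Named numeric vector: the marker's eQTL likelihood
#'   scores over genes.
#' @param over_set,under_set Gene id vectors from [split_signature()].
#' @return List: `threshold`, `direction` ("up"/"down"), `hypergeom_p`,
#'   `n_high`.
#' @export
select_threshold <- function(linkage_column, over_set, under_set) {
  scores <- linkage_column[is.finite(linkage_column)]
  genes <- names(scores)
  N <- length(scores)
  if (N < 1L) stop("no scored genes")
  if (!length(over_set) && !length(under_set))
    stop("both expression groups are empty")
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- as.vector(scores[ord])
  ends <- cumsum(rle(s_sorted)$lengths)  # n_high per candidate
  thr <- s_sorted[ends]                  # candidates, descending
  best <- NULL
  for (d in c("up", "down")) {
    grp <- if (d == "up") over_set else under_set
    if (!length(grp)) next
    memb <- genes[ord] %in% grp
    K <- sum(memb)
    if (K == 0L) next
    x <- cumsum(memb)[ends]
    p <- stats::phyper(x - 1, K, N - K, ends, lower.tail = FALSE)
    j <- which(p == min(p))
    j <- j[length(j)]  # descending candidates: last tie = smallest threshold
    cand <- list(threshold = thr[j], direction = d, hypergeom_p = p[j],
                 n_high = ends[j])
    if (is.null(best) ||
        cand$hypergeom_p < best$hypergeom_p ||
        (cand$hypergeom_p == best$hypergeom_p &&
         cand$threshold < best$threshold))
      best <- cand
  }
  if (is.null(best)) stop("both expression groups are empty")
  best
}

# Welch two-sample t-test P (two-sided) from raw samples; P floored at
# 1e-300 so -log10 stays finite. Zero pooled standard error: P = 1 if the
# means agree, else the floor.
welch_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 <= 0) return(if (m1 == m2) 1 else 1e-300)
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  max(2 * stats::pt(-abs(tstat), df), 1e-300)
}

#' Compute one ReL matrix entry
#'
#' Runs the full ReL test for a (marker, signature) pair: signature split,
#' hypergeometric threshold scan, Welch t-test of the signature values of
#' high-linkage genes vs all remaining scored genes, Bonferroni correction
#' by `n_tests`, and hit-gene extraction (high-linkage genes on the
#' entry's direction side of the signature mean).
#'
#' @param marker_id,signature_id Identifiers recorded in the entry.
#' @param linkage_column Named numeric vector of the marker's scores.
#' @param signature_values Named numeric vector of the signature.
#' @param n_tests Bonferroni correction factor (number of marker x signature
#'   pairs in the run).
#' @return Object of class `rel_entry`: `rel_score` (-log10 corrected P,
#'   >= 0), `direction`, `threshold`, `hypergeom_p`, `p_t` (uncorrected
#'   t-test P), `hit_genes`, `n_high_linkage`, `note` ("" if clean,
#'   otherwise why the entry was scored 0).
#' @export
rel_entry <- function(marker_id, signature_id, linkage_column,
                      signature_values, n_tests) {
  shared <- intersect(names(linkage_column), names(signature_values))
  sc <- linkage_column[shared]
  sv <- signature_values[shared]
  ok <- is.finite(sc) & is.finite(sv)
  sc <- sc[ok]; sv <- sv[ok]
  zero_entry <- function(note) {
    structure(list(marker_id = marker_id, signature_id = signature_id,
                   rel_score = 0, direction = NA_character_,
                   threshold = NA_real_, hypergeom_p = NA_real_,
                   p_t = NA_real_, hit_genes = character(),
                   n_high_linkage = NA_integer_, note = note),
              class = "rel_entry")
  }
  if (length(unique(sv)) < 2L) return(zero_entry("degenerate_signature"))
  sp <- split_signature(sv)
  sel <- select_threshold(sc, sp$over, sp$under)
  high <- names(sc)[sc >= sel$threshold]
  rest <- setdiff(names(sc), high)
  if (length(high) < 2L || length(rest) < 2L) {
    e <- zero_entry("small_subset")
    e$direction <- sel$direction; e$threshold <- sel$threshold
    e$hypergeom_p <- sel$hypergeom_p; e$n_high_linkage <- length(high)
    return(e)
  }
  p <- welch_p(sv[high], sv[rest])
  p_corr <- min(1, p * n_tests)
  hit <- if (sel$direction == "up") high[sv[high] > sp$mean]
         else high[sv[high] < sp$mean]
  structure(list(marker_id = marker_id, signature_id = signature_id,
                 rel_score = max(0, -log10(p_corr)),
                 direction = sel$direction, threshold = sel$threshold,
                 hypergeom_p = sel$hypergeom_p, p_t = p,
                 hit_genes = hit, n_high_linkage = length(high),
                 note = ""),
            class = "rel_entry")
}

# Fast equivalent of rel_entry for the all-finite case inside
# compute_rel_matrix: the marker's ordering (and candidate thresholds) are
# precomputed once per marker, the signature vector arrives already
# permuted to that ordering, and the Welch test is evaluated from prefix
# sums. Threshold/direction tie-breaking matches select_threshold exactly.
rel_entry_sorted <- function(marker_id, signature_id, x, gene_sorted,
                             ends, thr, N, n_tests) {
  zero_entry <- function(note) {
    structure(list(marker_id = marker_id, signature_id = signature_id,
                   rel_score = 0, direction = NA_character_,
                   threshold = NA_real_, hypergeom_p = NA_real_,
                   p_t = NA_real_, hit_genes = character(),
                   n_high_linkage = NA_integer_, note = note),
              class = "rel_entry")
  }
  mu <- mean(x)
  over <- x > mu
  under <- x < mu
  if (!any(over) && !any(under)) return(zero_entry("degenerate_signature"))
  best <- NULL
  for (d in c("up", "down")) {
    memb <- if (d == "up") over else under
    K <- sum(memb)
    if (K == 0L) next
    cx <- cumsum(memb)[ends]
    p <- stats::phyper(cx - 1, K, N - K, ends, lower.tail = FALSE)
    jj <- which(p == min(p))
    jj <- jj[length(jj)]
    cand <- list(threshold = thr[jj], direction = d, hypergeom_p = p[jj],
                 n_high = ends[jj])
    if (is.null(best) ||
        cand$hypergeom_p < best$hypergeom_p ||
        (cand$hypergeom_p == best$hypergeom_p &&
         cand$threshold < best$threshold))
      best <- cand
  }
  k <- best$n_high
  if (k < 2L || N - k < 2L) {
    e <- zero_entry("small_subset")
    e$direction <- best$direction; e$threshold <- best$threshold
    e$hypergeom_p <- best$hypergeom_p; e$n_high_linkage <- k
    return(e)
  }
  cx <- cumsum(x); cx2 <- cumsum(x^2)
  s1 <- cx[k]; q1 <- cx2[k]
  s2 <- cx[N] - s1; q2 <- cx2[N] - q1
  n2 <- N - k
  m1 <- s1 / k; m2 <- s2 / n2
  v1 <- max(0, (q1 - s1^2 / k) / (k - 1))
  v2 <- max(0, (q2 - s2^2 / n2) / (n2 - 1))
  se2 <- v1 / k + v2 / n2
  p <- if (se2 <= 0) { if (m1 == m2) 1 else 1e-300 } else {
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / k)^2 / (k - 1) + (v2 / n2)^2 / (n2 - 1))
    max(2 * stats::pt(-abs(tstat), df), 1e-300)
  }
  p_corr <- min(1, p * n_tests)
  high_x <- x[seq_len(k)]
  hit <- if (best$direction == "up") gene_sorted[seq_len(k)][high_x > mu]
         else gene_sorted[seq_len(k)][high_x < mu]
  structure(list(marker_id = marker_id, signature_id = signature_id,
                 rel_score = max(0, -log10(p_corr)),
                 direction = best$direction, threshold = best$threshold,
                 hypergeom_p = best$hypergeom_p, p_t = p,
                 hit_genes = hit, n_high_linkage = k, note = ""),
            class = "rel_entry")
}

#' Bonferroni correction factor of a ReL run
#' @param n_markers,n_signatures Dimensions of the ReL matrix.
#' @return `n_markers * n_signatures` as a double.
#' @export
bonferroni_factor <- function(n_markers, n_signatures) {
  as.numeric(n_markers) * as.numeric(n_signatures)
}

#' Compute the complete ReL matrix
#'
#' One [rel_entry()] per (marker, signature) pair over the genes shared
#' between the linkage matrix and the compendium. Markers are ordered
#' genomically (chromosomes in order of first appearance in the marker map,
#' then by position); every marker of the linkage matrix must appear in the
#' map.
#'
#' @param linkage A `linkage_matrix`.
#' @param compendium A [signature_compendium()].
#' @param map A [marker_map()] covering all markers.
#' @param n_tests Bonferroni factor; defaults to
#'   [bonferroni_factor()] of the run's dimensions.
#' @param min_shared_genes Minimum gene overlap between linkage matrix and
#'   compendium (default 100).
#' @return Object of class `rel_matrix` with per-entry matrices `score`,
#'   `direction`, `threshold`, `hyper_p`, `p_t`, `n_high`, a list-matrix
#'   `hit_genes`, marker annotations `chrom`/`pos_kb`, and `n_tests`.
#' @export
compute_rel_matrix <- function(linkage, compendium, map,
                               n_tests = NULL, min_shared_genes = 100) {
  genes <- intersect(linkage$gene_ids, compendium$gene_ids)
  if (length(genes) < min_shared_genes)
    stop(sprintf("only %d genes shared between linkage matrix and compendium (need >= %d)",
                 length(genes), min_shared_genes))
  dropped <- length(linkage$gene_ids) - length(genes) +
    length(compendium$gene_ids) - length(genes)
  if (dropped > 0)
    message(sprintf("gene join dropped %d ids not shared by both inputs",
                    dropped))
  missing_map <- setdiff(linkage$marker_ids, map$marker_id)
  if (length(missing_map))
    stop("marker missing from map: ", missing_map[1L])
  map <- map[match(linkage$marker_ids, map$marker_id), , drop = FALSE]
  chrom_order <- match(map$chromosome, unique(map$chromosome))
  ord <- order(chrom_order, map$position_kb)
  marker_ids <- linkage$marker_ids[ord]
  chrom <- map$chromosome[ord]
  pos_kb <- map$position_kb[ord]
  L <- linkage$scores[ord, genes, drop = FALSE]
  S <- compendium$values[genes, , drop = FALSE]
  nm <- length(marker_ids)
  ns <- length(compendium$signature_ids)
  if (is.null(n_tests)) n_tests <- bonferroni_factor(nm, ns)
  dn <- list(marker_ids, compendium$signature_ids)
  score <- hyper_p <- p_t <- threshold <- matrix(NA_real_, nm, ns,
                                                 dimnames = dn)
  n_high <- matrix(NA_integer_, nm, ns, dimnames = dn)
  direction <- matrix(NA_character_, nm, ns, dimnames = dn)
  hits <- vector("list", nm * ns)
  dim(hits) <- c(nm, ns); dimnames(hits) <- dn
  n_degenerate <- 0L
  all_finite <- all(is.finite(S))
  for (i in seq_len(nm)) {
    sc <- L[i, ]
    # per-marker ordering and candidate thresholds, shared by all signatures
    ord <- order(sc, decreasing = TRUE)
    ends <- cumsum(rle(as.vector(sc[ord]))$lengths)
    thr <- as.vector(sc[ord])[ends]
    N <- length(sc)
    gene_sorted <- genes[ord]
    for (j in seq_len(ns)) {
      e <- if (all_finite)
        rel_entry_sorted(marker_ids[i], compendium$signature_ids[j],
                         S[ord, j], gene_sorted, ends, thr, N, n_tests)
      else
        rel_entry(marker_ids[i], compendium$signature_ids[j],
                  sc, S[, j], n_tests)
      score[i, j] <- e$rel_score
      direction[i, j] <- e$direction
      threshold[i, j] <- e$threshold
      hyper_p[i, j] <- e$hypergeom_p
      p_t[i, j] <- e$p_t
      n_high[i, j] <- e$n_high_linkage
      hits[[i, j]] <- e$hit_genes
      if (nzchar(e$note)) n_degenerate <- n_degenerate + 1L
    }
  }
  if (n_degenerate > 0L)
    message(sprintf("%d degenerate entries scored 0", n_degenerate))
  structure(list(marker_ids = marker_ids,
                 signature_ids = compendium$signature_ids,
                 chrom = chrom, pos_kb = pos_kb,
                 score = score, direction = direction, threshold = threshold,
                 hyper_p = hyper_p, p_t = p_t, n_high = n_high,
                 hit_genes = hits, n_tests = n_tests,
                 protein_of = compendium$protein_of,
                 gene_ids = genes),
            class = "rel_matrix")
}

#' Threshold-sensitivity report for a ReL entry
#'
#' Recomputes the entry's t-test at the observed score values adjacent to
#' the chosen threshold (one candidate up, one down), quantifying how much
#' the ReL score moves if the scan's choice is perturbed.
#'
#' @param rel A `rel_matrix`.
#' @param marker_id,signature_id Entry coordinates.
#' @param linkage A `linkage_matrix` (source of the marker's scores).
#' @param compendium The [signature_compendium()] used for the run.
#' @return Data frame: candidate threshold, n_high, uncorrected t-test P and
#'   rel score at the chosen threshold and its neighbours.
#' @export
threshold_sensitivity <- function(rel, marker_id, signature_id, linkage,
                                  compendium) {
  sc <- linkage$scores[marker_id, rel$gene_ids]
  sv <- compendium$values[rel$gene_ids, signature_id]
  names(sc) <- names(sv) <- rel$gene_ids
  ok <- is.finite(sc) & is.finite(sv)
  sc <- sc[ok]; sv <- sv[ok]
  cand <- sort(unique(as.vector(sc)), decreasing = TRUE)
  chosen <- rel$threshold[marker_id, signature_id]
  k <- which(cand == chosen)
  ks <- unique(pmax(1L, pmin(length(cand), c(k - 1L, k, k + 1L))))
  rows <- lapply(cand[ks], function(t) {
    high <- names(sc)[sc >= t]
    rest <- setdiff(names(sc), high)
    p <- if (length(high) >= 2L && length(rest) >= 2L)
      welch_p(sv[high], sv[rest]) else NA_real_
    data.frame(threshold = t, n_high = length(high), p_t = p,
               rel_score = max(0, -log10(min(1, p * rel$n_tests))))
  })
  do.call(rbind, rows)
}

#' Write ReL scores to TSV plus a JSON sidecar
#'
#' The TSV holds the score matrix (markers x signatures); the sidecar
#' (`<path>.json`) records per-entry thresholds, directions and hit-gene
#' lists.
#' @param rel A `rel_matrix`.
#' @param path Output TSV path.
#' @return Invisibly, the sidecar path.
#' @export
write_rel_matrix <- function(rel, path) {
  write_id_matrix(rel$score, "marker_id", path)
  side <- list(
    marker_ids = rel$marker_ids, signature_ids = rel$signature_ids,
    chrom = rel$chrom, pos_kb = rel$pos_kb, n_tests = rel$n_tests,
    threshold = rel$threshold, direction = rel$direction,
    hit_genes = apply(rel$hit_genes, c(1, 2), function(h) h))
  json_path <- paste0(path, ".json")
  jsonlite::write_json(side, json_path, digits = NA, null = "null")
  invisible(json_path)
}
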