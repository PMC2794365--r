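# Contiguity-constrained iterative signature algorithm (ISA) over the ReL
# matrix: alternate signature-set refinement and dynamic-programming
# optimization of a single contiguous marker interval, from single-entry
# seeds, with deduplication and column-permutation significance.

#' ISA parameter set
#'
#' @param tau_row Marker inclusion threshold: the interval maximizes the sum
#'   of (per-marker mean ReL score - tau_row). Default 3, aligned with the
#'   module score floor.
#' @param tau_col Signature inclusion threshold on the interval-mean ReL
#'   score. Default 3.
#' @param max_iter Iteration cap for one seed (default 50).
#' @param min_signatures,min_markers Minimum module dimensions (default 1).
#' @param score_floor Module reporting cutoff on the mean ReL score
#'   (default 3).
#' @return List of class `isa_params`.
#' @export
isa_params <- function(tau_row = 3, tau_col = 3, max_iter = 50,
                       min_signatures = 1, min_markers = 1,
                       score_floor = 3) {
  stopifnot(tau_row >= 0, tau_col >= 0, max_iter >= 1)
  structure(list(tau_row = tau_row, tau_col = tau_col, max_iter = max_iter,
                 min_signatures = min_signatures, min_markers = min_markers,
                 score_floor = score_floor),
            class = "isa_params")
}

#' Signatures whose interval-mean ReL score reaches the threshold
#'
#' @param rel A `rel_matrix`.
#' @param interval Integer vector `c(start, end)` of marker indices
#'   (genomic order, inclusive).
#' @param tau_col Inclusion threshold (mean >= tau_col; the boundary is
#'   included).
#' @return Character vector of signature ids (possibly empty).
#' @export
update_signatures <- function(rel, interval, tau_col) {
  sub <- rel$score[interval[1L]:interval[2L], , drop = FALSE]
  mu <- colMeans(sub)
  rel$signature_ids[mu >= tau_col]
}

#' Best contiguous marker interval for a signature set
#'
#' Per marker `m` of the chromosome, `g(m)` is the mean ReL score over the
#' signatures; the contiguous interval maximizing `sum(g(m) - tau_row)` is
#' found by maximum-subarray dynamic programming (Kadane). Among equal-gain
#' intervals the earliest (smallest start, then smallest end) is returned.
#'
#' @param rel A `rel_matrix`.
#' @param signatures Non-empty signature id vector.
#' @param chromosome Chromosome label restricting the search.
#' @param tau_row Marker threshold.
#' @return `c(start, end)` as global marker indices, or `NULL` when every
#'   `g(m)` is below `tau_row`.
#' @export
optimize_interval <- function(rel, signatures, chromosome, tau_row) {
  idx <- which(rel$chrom == chromosome)
  if (!length(idx)) return(NULL)
  g <- rowMeans(rel$score[idx, signatures, drop = FALSE])
  if (all(g < tau_row)) return(NULL)
  x <- g - tau_row
  best <- -Inf; best_s <- best_e <- NA_integer_
  cur <- 0; cur_s <- 1L
  for (i in seq_along(x)) {
    cur <- cur + x[i]
    if (cur > best) { best <- cur; best_s <- cur_s; best_e <- i }
    if (cur < 0) { cur <- 0; cur_s <- i + 1L }
  }
  c(idx[best_s], idx[best_e])
}

#' Seed entries for the ISA scan
#'
#' All ReL matrix entries at or above a score cutoff, ordered by descending
#' score. `min_seed_score = 0` restores the literal every-entry seeding
#' rule; the default 3 keeps only entries that could anchor a reportable
#' module (identical attractors, far fewer seeds).
#'
#' @param rel A `rel_matrix`.
#' @param min_seed_score Seed score cutoff (default 3).
#' @return Data frame: `marker_idx`, `signature_idx`, `score`.
#' @export
seed_entries <- function(rel, min_seed_score = 3) {
  keep <- which(rel$score >= min_seed_score, arr.ind = TRUE)
  sc <- rel$score[keep]
  ord <- order(sc, decreasing = TRUE)
  data.frame(marker_idx = keep[ord, 1L], signature_idx = keep[ord, 2L],
             score = sc[ord], row.names = NULL)
}

#' Run the constrained ISA from one seed entry
#'
#' Starting from a single (marker, signature) cell, alternately refines the
#' signature set ([update_signatures()]) and the contiguous marker interval
#' ([optimize_interval()], restricted to the seed marker's chromosome, which
#' the interval then never leaves) until the (interval, signature-set) state
#' repeats exactly. A cycle longer than one state within `max_iter`
#' iterations counts as non-convergence. The iteration itself is
#' deterministic: no randomness is involved.
#'
#' @param rel A `rel_matrix`.
#' @param seed_marker,seed_signature Seed entry coordinates (indices into
#'   the ReL matrix's genomic marker order / signature list).
#' @param params An [isa_params()].
#' @return An object of class `rel_module` (fields `chromosome`,
#'   `start_idx`, `end_idx`, `marker_ids`, `start_kb`, `end_kb`,
#'   `signatures`, `module_score`, `seed`, `n_iter`) or `NULL` when the seed
#'   dies out, oscillates, or converges below the minimum sizes.
#' @export
run_isa <- function(rel, seed_marker, seed_signature,
                    params = isa_params()) {
  chromosome <- rel$chrom[seed_marker]
  interval <- c(seed_marker, seed_marker)
  sigs <- rel$signature_ids[seed_signature]
  seen <- character()
  state_key <- function(iv, sg) paste(iv[1L], iv[2L], paste(sort(sg),
                                                            collapse = ","))
  key <- state_key(interval, sigs)
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(params$max_iter)) {
    n_iter <- it
    sigs <- update_signatures(rel, interval, params$tau_col)
    if (!length(sigs)) return(NULL)
    interval_new <- optimize_interval(rel, sigs, chromosome, params$tau_row)
    if (is.null(interval_new)) return(NULL)
    interval <- interval_new
    new_key <- state_key(interval, sigs)
    if (new_key == key) { converged <- TRUE; break }
    if (new_key %in% seen) return(NULL)  # cycle without fixed point
    seen <- c(seen, key)
    key <- new_key
  }
  if (!converged) return(NULL)
  n_markers <- interval[2L] - interval[1L] + 1L
  if (n_markers < params$min_markers ||
      length(sigs) < params$min_signatures) return(NULL)
  score <- mean(rel$score[interval[1L]:interval[2L], sigs, drop = FALSE])
  structure(list(chromosome = chromosome,
                 start_idx = interval[1L], end_idx = interval[2L],
                 marker_ids = rel$marker_ids[interval[1L]:interval[2L]],
                 start_kb = rel$pos_kb[interval[1L]],
                 end_kb = rel$pos_kb[interval[2L]],
                 signatures = sigs, module_score = score,
                 seed = c(marker = seed_marker, signature = seed_signature),
                 n_iter = n_iter),
            class = "rel_module")
}

module_cells <- function(m) {
  as.vector(outer(m$marker_ids, m$signatures, paste, sep = "\r"))
}

#' Merge near-duplicate modules
#'
#' Modules whose entry sets (interval x signatures cells) overlap with
#' Jaccard index at or above the cutoff are merged transitively; each
#' component keeps its highest-scoring representative. Output is sorted by
#' module score, descending.
#'
#' @param modules List of `rel_module`.
#' @param jaccard_cutoff Merge threshold in \[0, 1\] (default 0.5).
#' @return Deduplicated, sorted module list.
#' @export
deduplicate <- function(modules, jaccard_cutoff = 0.5) {
  k <- length(modules)
  if (k <= 1L) return(modules)
  cells <- lapply(modules, module_cells)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    inter <- length(intersect(cells[[i]], cells[[j]]))
    uni <- length(cells[[i]]) + length(cells[[j]]) - inter
    if (uni > 0 && inter / uni >= jaccard_cutoff)
      parent[find(j)] <- find(i)
  }
  comp <- vapply(seq_len(k), find, integer(1))
  reps <- vapply(split(seq_len(k), comp), function(ix)
    ix[which.max(vapply(modules[ix], function(m) m$module_score,
                        numeric(1)))], integer(1))
  out <- modules[reps]
  out[order(vapply(out, function(m) m$module_score, numeric(1)),
            decreasing = TRUE)]
}

#' Extract all ReL modules from a ReL matrix
#'
#' Runs [run_isa()] from every seed entry, keeps converged modules at or
#' above the score floor and minimum sizes, and deduplicates.
#'
#' @param rel A `rel_matrix`.
#' @param params An [isa_params()].
#' @param min_seed_score Seed cutoff for [seed_entries()]; defaults to the
#'   score floor. Set 0 to seed from every entry.
#' @param jaccard_cutoff Deduplication threshold.
#' @return List of `rel_module`, sorted by score descending.
#' @export
find_modules <- function(rel, params = isa_params(),
                         min_seed_score = params$score_floor,
                         jaccard_cutoff = 0.5) {
  seeds <- seed_entries(rel, min_seed_score)
  mods <- list()
  seen_states <- character()
  for (i in seq_len(nrow(seeds))) {
    m <- run_isa(rel, seeds$marker_idx[i], seeds$signature_idx[i], params)
    if (is.null(m) || m$module_score < params$score_floor) next
    key <- paste(m$start_idx, m$end_idx,
                 paste(sort(m$signatures), collapse = ","))
    if (key %in% seen_states) next
    seen_states <- c(seen_states, key)
    mods[[length(mods) + 1L]] <- m
  }
  deduplicate(mods, jaccard_cutoff)
}

#' Permutation P-value for a module's size and intensity
#'
#' The null model shuffles ReL scores independently within each signature
#' column (preserving each signature's score distribution, destroying the
#' marker-range structure), reruns the ISA from the best entry of the
#' permuted matrix, and records the achieved module area x mean score. The
#' observed statistic is the module's own area x score;
#' `P = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param module A `rel_module`.
#' @param rel The `rel_matrix` it came from.
#' @param n_perm Number of permutations (>= 1).
#' @param rng_seed Seed for the permutation stream (the caller's RNG state
#'   is restored afterwards).
#' @param params [isa_params()] used for the null reruns; defaults match the
#'   observed run.
#' @return P-value in (0, 1].
#' @export
module_size_pvalue <- function(module, rel, n_perm, rng_seed,
                               params = isa_params()) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  observed <- module_area_score(module)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(rng_seed)
  nm <- length(rel$marker_ids)
  null_stat <- numeric(n_perm)
  perm_rel <- rel
  for (b in seq_len(n_perm)) {
    perm_rel$score <- apply(rel$score, 2L, sample, size = nm)
    dimnames(perm_rel$score) <- dimnames(rel$score)
    top <- arrayInd(which.max(perm_rel$score), dim(perm_rel$score))
    m0 <- run_isa(perm_rel, top[1L], top[2L], params)
    null_stat[b] <- if (is.null(m0)) 0 else module_area_score(m0)
  }
  (1 + sum(null_stat >= observed)) / (1 + n_perm)
}

module_area_score <- function(m) {
  (m$end_idx - m$start_idx + 1L) * length(m$signatures) * m$module_score
}

#' @export
print.rel_module <- function(x, ...) {
  cat(sprintf("ReL module %s (%d markers x %d signatures), score %.2f\n",
              format_interval(x), x$end_idx - x$start_idx + 1L,
              length(x$signatures), x$module_score))
  cat("  signatures:", paste(x$signatures, collapse = ", "), "\n")
  invisible(x)
}
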