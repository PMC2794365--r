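# Module annotation: target genes (with cis exclusion), regulatory-protein
# scores, process enrichment, telomere flagging, causal-regulator rules.

#' Target genes of a module
#'
#' Genes hit in at least `frac` of the module's interval x signature entries
#' (hit sets from the ReL matrix), minus cis genes: genes located inside the
#' linkage interval, or fewer than `cis_gene_window` genes away from its
#' boundaries in gene-order index on the interval's chromosome. A hit gene
#' with no position cannot be cis-excluded and is retained with a warning.
#'
#' @param module A `rel_module`.
#' @param rel The `rel_matrix` it came from (provides hit-gene sets and
#'   marker positions).
#' @param gene_positions Data frame: gene_id, chromosome, position_kb.
#' @param frac Minimum hit fraction (default 0.6; "at least", so exactly
#'   60\% qualifies).
#' @param cis_gene_window Cis-exclusion distance in genes (default 30: a
#'   gene 29 genes away is excluded, 30 genes away is kept).
#' @return Character vector of target gene ids.
#' @export
target_genes <- function(module, rel, gene_positions, frac = 0.6,
                         cis_gene_window = 30) {
  mi <- module$start_idx:module$end_idx
  si <- match(module$signatures, rel$signature_ids)
  hits <- rel$hit_genes[mi, si, drop = FALSE]
  n_entries <- length(hits)
  counts <- table(unlist(hits, use.names = FALSE))
  cand <- names(counts)[as.vector(counts) + 1e-9 >= frac * n_entries]
  if (!length(cand)) return(character())
  cis <- cis_genes(module, gene_positions, cis_gene_window)
  unplaced <- setdiff(cand, gene_positions$gene_id)
  if (length(unplaced))
    warning(sprintf("%d hit genes lack positions and cannot be cis-excluded",
                    length(unplaced)))
  setdiff(cand, cis)
}

# Genes inside the interval's kb range on its chromosome, plus genes fewer
# than `window` gene-order steps from the interval boundary genes.
cis_genes <- function(module, gene_positions, window = 30) {
  gp <- gene_positions[gene_positions$chromosome == module$chromosome, ,
                       drop = FALSE]
  if (!nrow(gp)) return(character())
  gp <- gp[order(gp$position_kb), , drop = FALSE]
  inside <- gp$position_kb >= module$start_kb &
            gp$position_kb <= module$end_kb
  n <- nrow(gp)
  if (any(inside)) {
    a <- min(which(inside)); b <- max(which(inside))
  } else {
    # empty interval: distances measured from the insertion point
    a <- match(TRUE, gp$position_kb > module$end_kb, nomatch = n + 1L)
    b <- a - 1L
  }
  lo <- max(1L, a - (window - 1L))
  hi <- min(n, b + (window - 1L))
  if (lo > hi) return(character())
  gp$gene_id[lo:hi]
}

#' Regulatory-protein scores of a module
#'
#' A signature's score is its mean ReL score over the linkage interval; a
#' protein's score is the mean over its signatures' scores. The argmax is
#' the module's best-scoring regulatory protein.
#'
#' @param module A `rel_module`.
#' @param rel The `rel_matrix`.
#' @param protein_of Signature -> protein map; defaults to the one stored in
#'   the ReL matrix.
#' @return Named numeric vector (protein -> score), sorted descending.
#' @export
protein_scores <- function(module, rel, protein_of = rel$protein_of) {
  mi <- module$start_idx:module$end_idx
  sig_mean <- colMeans(rel$score[mi, module$signatures, drop = FALSE])
  prot <- protein_of[module$signatures]
  out <- vapply(split(sig_mean, prot), mean, numeric(1))
  sort(out, decreasing = TRUE)
}

#' Hypergeometric process enrichment of a target-gene set
#'
#' Per annotation term, the upper-tail hypergeometric P of the overlap
#' between the targets and the term's genes within the universe, corrected
#' over all tested terms. The best-scoring significant term is the module's
#' primary biological process.
#'
#' @param targets Target gene ids.
#' @param annotation An [annotation_set()].
#' @param universe Gene universe; defaults to the annotation's. Both targets
#'   and terms are intersected with it.
#' @param alpha Significance level on the corrected P (default 0.05).
#' @param method Multiple-testing correction, `"bonferroni"` (default) or
#'   any `stats::p.adjust` method.
#' @return List: `table` (term, name, overlap, term size, p, p_adj, sorted
#'   by p_adj) and `primary` (term id or `NA` when nothing is significant).
#' @export
enrich <- function(targets, annotation, universe = annotation$universe,
                   alpha = 0.05, method = "bonferroni") {
  targets <- intersect(targets, universe)
  empty <- list(table = data.frame(term = character(), name = character(),
                                   overlap = integer(), size = integer(),
                                   p = numeric(), p_adj = numeric()),
                primary = NA_character_)
  if (!length(targets) || !length(annotation$terms)) return(empty)
  N <- length(universe)
  n <- length(targets)
  rows <- lapply(names(annotation$terms), function(tm) {
    term_genes <- intersect(annotation$terms[[tm]], universe)
    K <- length(term_genes)
    x <- length(intersect(targets, term_genes))
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, name = unname(annotation$term_names[tm]),
               overlap = x, size = K, p = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- stats::p.adjust(tab$p, method = method)
  tab <- tab[order(tab$p_adj, tab$p, tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  sig <- tab[tab$p_adj < alpha, , drop = FALSE]
  list(table = tab,
       primary = if (nrow(sig)) sig$term[1L] else NA_character_)
}

#' Putative causal regulators of a module
#'
#' Every gene located inside the module's linkage interval is tested against
#' three criteria: (i) it is annotated with the module's primary biological
#' process; (ii) the interaction network contains a direct edge between it
#' and any of the module's regulatory proteins; (iii) its binding-target set
#' is significantly enriched (hypergeometric, Bonferroni over the interval
#' genes tested, corrected P < `alpha`) among the module's target genes.
#' Candidates meet at least one criterion and are ranked by the number of
#' criteria met, then by the criterion-(iii) P, then by gene id.
#'
#' @param module A `rel_module`.
#' @param rel The `rel_matrix` (for the signature -> protein map).
#' @param gene_positions Data frame: gene_id, chromosome, position_kb.
#' @param targets The module's target genes.
#' @param primary_process Primary process term id, or `NA` (criterion (i)
#'   is then skipped).
#' @param annotation An [annotation_set()] (may be empty).
#' @param network An [interaction_network()] (may be empty).
#' @param binding_targets Named list regulator -> bound targets (may be
#'   empty).
#' @param universe Gene universe for criterion (iii); defaults to the genes
#'   of the ReL run.
#' @param alpha Significance level for criterion (iii).
#' @return Data frame: gene, process, interaction, binding (logicals),
#'   binding_p, n_criteria; ranked, candidates only.
#' @export
causal_candidates <- function(module, rel, gene_positions, targets,
                              primary_process = NA_character_,
                              annotation = NULL, network = NULL,
                              binding_targets = NULL,
                              universe = rel$gene_ids, alpha = 0.05) {
  gp <- gene_positions[gene_positions$chromosome == module$chromosome &
                       gene_positions$position_kb >= module$start_kb &
                       gene_positions$position_kb <= module$end_kb, ,
                       drop = FALSE]
  interval_genes <- sort(unique(gp$gene_id))
  empty <- data.frame(gene = character(), process = logical(),
                      interaction = logical(), binding = logical(),
                      binding_p = numeric(), n_criteria = integer(),
                      stringsAsFactors = FALSE)
  if (!length(interval_genes)) return(empty)
  process_genes <- if (!is.na(primary_process) && !is.null(annotation))
    annotation$terms[[primary_process]] %||% character() else character()
  proteins <- unique(unname(rel$protein_of[module$signatures]))
  linked <- if (!is.null(network) && nrow(network)) {
    touches <- (network$node_a %in% interval_genes &
                network$node_b %in% proteins) |
               (network$node_b %in% interval_genes &
                network$node_a %in% proteins)
    unique(c(network$node_a[touches], network$node_b[touches]))
  } else character()
  targ_u <- intersect(targets, universe)
  N <- length(universe)
  bind_p <- vapply(interval_genes, function(g) {
    bt <- if (!is.null(binding_targets)) binding_targets[[g]] else NULL
    if (is.null(bt)) return(NA_real_)
    K <- length(intersect(bt, universe))
    if (!K || !length(targ_u)) return(NA_real_)
    x <- length(intersect(bt, targ_u))
    stats::phyper(x - 1, K, N - K, length(targ_u), lower.tail = FALSE)
  }, numeric(1))
  bind_p_adj <- pmin(1, bind_p * length(interval_genes))  # Bonferroni
  out <- data.frame(
    gene = interval_genes,
    process = interval_genes %in% process_genes,
    interaction = interval_genes %in% linked,
    binding = !is.na(bind_p_adj) & bind_p_adj < alpha,
    binding_p = bind_p,
    stringsAsFactors = FALSE)
  out$n_criteria <- out$process + out$interaction + out$binding
  out <- out[out$n_criteria >= 1L, , drop = FALSE]
  ord <- order(-out$n_criteria, ifelse(is.na(out$binding_p), Inf,
                                       out$binding_p), out$gene)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Telomere-enrichment flag for a target set
#'
#' TRUE when at least `min_frac` of the positioned target genes lie within
#' `telomere_kb` of either end of their chromosome (boundary inclusive) and
#' those telomeric genes span at least `min_chroms` chromosomes. Targets
#' without a position are ignored with a warning.
#'
#' @param targets Target gene ids.
#' @param gene_positions Data frame: gene_id, chromosome, position_kb.
#' @param chrom_lengths Named numeric vector of chromosome lengths (kb).
#' @param telomere_kb Telomeric window (default 30).
#' @param min_frac Minimum telomeric fraction (default 0.5).
#' @param min_chroms Minimum number of chromosomes spanned (default 3).
#' @return Logical flag.
#' @export
telomere_flag <- function(targets, gene_positions, chrom_lengths,
                          telomere_kb = 30, min_frac = 0.5,
                          min_chroms = 3) {
  gp <- gene_positions[gene_positions$gene_id %in% targets, , drop = FALSE]
  n_unplaced <- length(setdiff(targets, gp$gene_id))
  if (n_unplaced)
    warning(sprintf("%d target genes lack positions; ignored in telomere flag",
                    n_unplaced))
  if (!nrow(gp)) return(FALSE)
  len <- chrom_lengths[gp$chromosome]
  dist_end <- pmin(gp$position_kb, len - gp$position_kb)
  telo <- !is.na(dist_end) & dist_end <= telomere_kb
  mean(telo) >= min_frac && length(unique(gp$chromosome[telo])) >= min_chroms
}

#' Fully annotate a ReL module
#'
#' Derives the target genes, regulatory-protein scores, process enrichments
#' and primary process, causal-candidate list, and telomere flag.
#'
#' @param module A `rel_module`.
#' @param rel The `rel_matrix` it came from.
#' @param gene_positions Data frame: gene_id, chromosome, position_kb.
#' @param annotation Optional [annotation_set()].
#' @param network Optional [interaction_network()].
#' @param binding_targets Optional regulator -> targets list.
#' @param chrom_lengths Optional named chromosome lengths (kb); without it
#'   the telomere flag is `NA`.
#' @param frac,cis_gene_window See [target_genes()].
#' @param alpha Significance level for enrichment and criterion (iii).
#' @return Object of class `annotated_module`: `base`, `target_genes`,
#'   `protein_scores`, `enrichments`, `primary_process`,
#'   `causal_candidates`, `telomere_flag`.
#' @export
annotate_module <- function(module, rel, gene_positions,
                            annotation = NULL, network = NULL,
                            binding_targets = NULL, chrom_lengths = NULL,
                            frac = 0.6, cis_gene_window = 30,
                            alpha = 0.05) {
  targ <- target_genes(module, rel, gene_positions, frac, cis_gene_window)
  ps <- protein_scores(module, rel)
  en <- if (!is.null(annotation))
    enrich(targ, annotation, universe = intersect(rel$gene_ids,
                                                  annotation$universe),
           alpha = alpha)
  else list(table = NULL, primary = NA_character_)
  cc <- causal_candidates(module, rel, gene_positions, targ,
                          primary_process = en$primary,
                          annotation = annotation, network = network,
                          binding_targets = binding_targets, alpha = alpha)
  tf <- if (!is.null(chrom_lengths))
    telomere_flag(targ, gene_positions, chrom_lengths)
  else NA
  structure(list(base = module, target_genes = targ, protein_scores = ps,
                 enrichments = en$table, primary_process = en$primary,
                 causal_candidates = cc, telomere_flag = tf),
            class = "annotated_module")
}
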