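# Synthetic segregating-population generator with planted regulatory-linkage
# modules and a machine-readable truth set for recovery testing. Emulates a
# haploid two-parent cross: Mendelian 0/1 genotypes with Markov
# recombination along chromosomes, trans-linked gene groups shifted by a
# causal marker's allele, and mutant signatures in which the same gene
# groups are coherently over-expressed against background noise.

#' Planted-module description
#'
#' @param causal_marker Global marker index of the causal locus.
#' @param member_genes Gene ids whose expression follows the causal allele.
#' @param signatures Signature ids of the planted regulator (>= 1).
#' @param protein Name of the mutated regulatory protein behind those
#'   signatures.
#' @param beta Expression shift per allele (non-zero).
#' @param delta Log2 shift of member genes in the regulator signatures
#'   (non-zero).
#' @return List of class `planted_module`.
#' @export
planted_module <- function(causal_marker, member_genes, signatures,
                           protein, beta = 1, delta = 2) {
  stopifnot(beta != 0, delta != 0, length(signatures) >= 1)
  structure(list(causal_marker = causal_marker,
                 member_genes = member_genes, signatures = signatures,
                 protein = protein, beta = beta, delta = delta),
            class = "planted_module")
}

#' Simulation configuration
#'
#' Defaults emulate the statistical structure of a 112-segregant haploid
#' yeast cross at desk scale: 3 chromosomes of 100 evenly spaced markers
#' over 1000 kb, recombination probability 0.1 between adjacent markers,
#' 1000 genes, a 40-signature compendium, and 3 planted modules (40 member
#' genes and 3 regulator signatures each, one regulatory protein per
#' module, causal marker 50 of each chromosome, members always on a
#' different chromosome than their causal marker so the cis-exclusion rule
#' never removes true targets).
#'
#' @param n_segregants Population size (default 112).
#' @param chromosomes Data frame: label, n_markers, length_kb.
#' @param inter_marker_recomb Recombination probability r between adjacent
#'   markers, in \[0, 0.5\].
#' @param n_genes,n_signatures Dataset dimensions.
#' @param planted List of [planted_module()]; `NULL` builds the default
#'   three. Member gene sets must be disjoint.
#' @param noise_sd Expression noise sigma (default 0.5).
#' @param signature_noise_sd Compendium noise sigma (default 0.3).
#' @param rng_seed Seed making the whole bundle reproducible.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_segregants = 112,
                       chromosomes = data.frame(
                         label = c("I", "II", "III"),
                         n_markers = 100, length_kb = 1000,
                         stringsAsFactors = FALSE),
                       inter_marker_recomb = 0.1,
                       n_genes = 1000, n_signatures = 40,
                       planted = NULL,
                       noise_sd = 0.5, signature_noise_sd = 0.3,
                       rng_seed = 1) {
  stopifnot(inter_marker_recomb >= 0, inter_marker_recomb <= 0.5,
            n_segregants > 0, n_genes > 0, n_signatures > 0)
  cfg <- structure(list(n_segregants = n_segregants,
                        chromosomes = chromosomes,
                        inter_marker_recomb = inter_marker_recomb,
                        n_genes = n_genes, n_signatures = n_signatures,
                        planted = planted, noise_sd = noise_sd,
                        signature_noise_sd = signature_noise_sd,
                        rng_seed = rng_seed),
                   class = "sim_config")
  if (is.null(cfg$planted)) cfg$planted <- default_planted(cfg)
  members <- unlist(lapply(cfg$planted, `[[`, "member_genes"))
  if (anyDuplicated(members))
    stop("planted member gene sets must be disjoint")
  n_markers_total <- sum(chromosomes$n_markers)
  cm <- vapply(cfg$planted, `[[`, numeric(1), "causal_marker")
  if (any(cm < 1 | cm > n_markers_total))
    stop("planted causal marker out of bounds")
  cfg
}

sim_gene_ids <- function(n) sprintf("g%04d", seq_len(n))
sim_sig_ids <- function(n) sprintf("s%02d", seq_len(n))

# Genes are dealt round-robin across chromosomes; module k's members are the
# first block of genes on the chromosome after its causal one, guaranteeing
# trans placement.
default_planted <- function(cfg) {
  nc <- nrow(cfg$chromosomes)
  if (nc < 2L) return(list())  # trans placement impossible
  genes <- sim_gene_ids(cfg$n_genes)
  gene_chrom_idx <- (seq_len(cfg$n_genes) - 1L) %% nc + 1L
  sigs <- sim_sig_ids(cfg$n_signatures)
  k_mod <- min(3L, nc, cfg$n_signatures %/% 3L)
  offsets <- c(0L, cumsum(cfg$chromosomes$n_markers))
  lapply(seq_len(k_mod), function(k) {
    # module k's members live on the chromosome after its causal one, so
    # each of the <= 3 modules draws from a distinct chromosome
    member_chrom <- k %% nc + 1L
    on_chrom <- genes[gene_chrom_idx == member_chrom]
    planted_module(
      causal_marker = offsets[k] + min(50L, cfg$chromosomes$n_markers[k]),
      member_genes = on_chrom[seq_len(min(40L, length(on_chrom)))],
      signatures = sigs[((k - 1L) * 3L + 1L):(k * 3L)],
      protein = sprintf("REG%d", k), beta = 1, delta = 2)
  })
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate genotypes for a haploid cross
#'
#' Per segregant and chromosome, the first marker's allele is
#' Bernoulli(0.5); each subsequent marker switches parent with probability
#' `inter_marker_recomb` (Markov recombination). Positions are evenly
#' spaced along each chromosome.
#'
#' @param config A [sim_config()].
#' @return List: `genotypes` ([genotype_matrix()]), `map` ([marker_map()]).
#' @export
simulate_genotypes <- function(config) {
  with_seed(config$rng_seed, {
    n_seg <- config$n_segregants
    r <- config$inter_marker_recomb
    blocks <- lapply(seq_len(nrow(config$chromosomes)), function(ci) {
      nm <- config$chromosomes$n_markers[ci]
      calls <- matrix(0L, nm, n_seg)
      calls[1L, ] <- stats::rbinom(n_seg, 1L, 0.5)
      if (nm > 1L) for (i in 2L:nm) {
        flip <- stats::rbinom(n_seg, 1L, r)
        calls[i, ] <- bitwXor(calls[i - 1L, ], flip)
      }
      calls
    })
    calls <- do.call(rbind, blocks)
    lab <- config$chromosomes$label
    marker_ids <- unlist(lapply(seq_along(lab), function(ci)
      sprintf("m%s_%03d", lab[ci],
              seq_len(config$chromosomes$n_markers[ci]))))
    seg_ids <- sprintf("seg%03d", seq_len(n_seg))
    dimnames(calls) <- list(marker_ids, seg_ids)
    pos <- unlist(lapply(seq_along(lab), function(ci) {
      nm <- config$chromosomes$n_markers[ci]
      round(seq_len(nm) * config$chromosomes$length_kb[ci] / (nm + 1), 3)
    }))
    list(genotypes = genotype_matrix(calls),
         map = marker_map(marker_ids,
                          rep(lab, config$chromosomes$n_markers), pos))
  })
}

#' Simulate the expression matrix
#'
#' A member gene of a planted module follows `beta * allele(causal marker) +
#' N(0, noise_sd^2)`; every other gene is pure noise.
#'
#' @param genotypes The [genotype_matrix()] from [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @return An [expression_matrix()].
#' @export
simulate_expression <- function(genotypes, config) {
  with_seed(config$rng_seed + 1L, {
    genes <- sim_gene_ids(config$n_genes)
    X <- matrix(stats::rnorm(config$n_genes * config$n_segregants,
                             0, config$noise_sd),
                config$n_genes, config$n_segregants,
                dimnames = list(genes, genotypes$segregant_ids))
    for (pm in config$planted) {
      allele <- genotypes$calls[pm$causal_marker, ]
      X[pm$member_genes, ] <- X[pm$member_genes, ] +
        pm$beta * matrix(allele, length(pm$member_genes),
                         config$n_segregants, byrow = TRUE)
    }
    expression_matrix(X)
  })
}

#' Simulate the regulatory-signature compendium
#'
#' Member genes of each planted module carry `delta` plus noise in that
#' module's regulator signatures; all other cells are
#' `N(0, signature_noise_sd^2)`. Every regulator signature of a module maps
#' to the module's protein; background signatures each map to their own
#' protein.
#'
#' @param config A [sim_config()].
#' @return A [signature_compendium()].
#' @export
simulate_compendium <- function(config) {
  with_seed(config$rng_seed + 2L, {
    genes <- sim_gene_ids(config$n_genes)
    sigs <- sim_sig_ids(config$n_signatures)
    C <- matrix(stats::rnorm(config$n_genes * config$n_signatures,
                             0, config$signature_noise_sd),
                config$n_genes, config$n_signatures,
                dimnames = list(genes, sigs))
    protein_of <- stats::setNames(sprintf("BG%02d", seq_along(sigs)), sigs)
    for (pm in config$planted) {
      C[pm$member_genes, pm$signatures] <-
        C[pm$member_genes, pm$signatures] + pm$delta
      protein_of[pm$signatures] <- pm$protein
    }
    signature_compendium(C, protein_of)
  })
}

# Gene positions consistent with default_planted's round-robin chromosome
# assignment; evenly spaced along each chromosome.
sim_gene_positions <- function(config) {
  nc <- nrow(config$chromosomes)
  genes <- sim_gene_ids(config$n_genes)
  ci <- (seq_len(config$n_genes) - 1L) %% nc + 1L
  rank_on <- stats::ave(seq_len(config$n_genes), ci, FUN = seq_along)
  n_on <- tabulate(ci, nc)
  data.frame(gene_id = genes,
             chromosome = config$chromosomes$label[ci],
             position_kb = round(rank_on * config$chromosomes$length_kb[ci] /
                                   (n_on[ci] + 1), 3),
             stringsAsFactors = FALSE)
}

#' Simulate a complete dataset in memory
#'
#' @param config A [sim_config()].
#' @return List: `genotypes`, `map`, `expression`, `compendium`,
#'   `gene_positions`, `chrom_lengths`, `truth` (per planted module: causal
#'   marker id and index, chromosome, member genes, signatures, protein,
#'   beta, delta).
#' @export
simulate_dataset <- function(config) {
  g <- simulate_genotypes(config)
  expr <- simulate_expression(g$genotypes, config)
  comp <- simulate_compendium(config)
  truth <- lapply(config$planted, function(pm) {
    list(causal_marker = g$genotypes$marker_ids[pm$causal_marker],
         causal_marker_index = pm$causal_marker,
         chromosome = g$map$chromosome[pm$causal_marker],
         member_genes = pm$member_genes, signatures = pm$signatures,
         protein = pm$protein, beta = pm$beta, delta = pm$delta)
  })
  list(genotypes = g$genotypes, map = g$map, expression = expr,
       compendium = comp, gene_positions = sim_gene_positions(config),
       chrom_lengths = stats::setNames(config$chromosomes$length_kb,
                                       config$chromosomes$label),
       truth = truth)
}

#' Write a simulated bundle to a directory
#'
#' Emits genotypes.tsv, marker_map.tsv, expression.tsv, compendium.tsv,
#' compendium_meta.tsv, gene_positions.tsv, chrom_lengths.tsv and
#' truth.json, all reproducible byte-for-byte from `rng_seed`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty directory (default FALSE: error).
#' @return Invisibly, the bundle file paths.
#' @export
generate_dataset <- function(config, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force)
    stop("output directory exists and is not empty: ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- simulate_dataset(config)
  p <- function(f) file.path(out_dir, f)
  write_genotypes(d$genotypes, p("genotypes.tsv"))
  write_marker_map(d$map, p("marker_map.tsv"))
  write_expression(d$expression, p("expression.tsv"))
  write_compendium(d$compendium, p("compendium.tsv"),
                   p("compendium_meta.tsv"))
  utils::write.table(d$gene_positions, p("gene_positions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(chromosome = names(d$chrom_lengths),
                                length_kb = unname(d$chrom_lengths)),
                     p("chrom_lengths.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(d$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(vapply(c("genotypes.tsv", "marker_map.tsv", "expression.tsv",
                     "compendium.tsv", "compendium_meta.tsv",
                     "gene_positions.tsv", "chrom_lengths.tsv",
                     "truth.json"), p, character(1)))
}
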