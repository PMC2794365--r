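# Pipeline orchestration: simulate -> linkage -> relscore -> modules ->
# annotate, with a resolved-config record in every run directory, plus a
# thin command-line front end (see inst/scripts/relmod).

#' Default pipeline configuration
#'
#' Input paths plus every tunable of the downstream stages. `NULL` paths
#' mark optional inputs (annotation, network, binding targets, gene
#' positions, chromosome lengths); without gene positions target genes
#' cannot be cis-excluded and modules are reported unannotated.
#'
#' @param genotypes,marker_map,expression,compendium,compendium_meta Input
#'   TSV paths (required).
#' @param gene_positions,annotation,network,binding_targets,chrom_lengths
#'   Optional input TSV paths.
#' @param out_dir Run directory (created; must be empty unless `force`).
#' @param min_shared_segregants,min_shared_genes Join guards.
#' @param lod_cap Cap for degenerate eQTL likelihood fits.
#' @param tau_row,tau_col,max_iter,min_signatures,min_markers,score_floor
#'   ISA parameters, see [isa_params()].
#' @param min_seed_score Seed cutoff; 0 seeds from every entry.
#' @param jaccard_cutoff Module deduplication threshold.
#' @param n_perm Permutations for module significance (0 skips the test).
#' @param rng_seed Seed for the permutation stream.
#' @param frac,cis_gene_window Target-gene rule, see [target_genes()].
#' @param alpha Significance level for enrichment / causal criterion (iii).
#' @param force Overwrite a non-empty run directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(genotypes, marker_map, expression, compendium,
                       compendium_meta, out_dir,
                       gene_positions = NULL, annotation = NULL,
                       network = NULL, binding_targets = NULL,
                       chrom_lengths = NULL,
                       min_shared_segregants = 20, min_shared_genes = 100,
                       lod_cap = 50,
                       tau_row = 3, tau_col = 3, max_iter = 50,
                       min_signatures = 1, min_markers = 1, score_floor = 3,
                       min_seed_score = score_floor, jaccard_cutoff = 0.5,
                       n_perm = 0, rng_seed = 1,
                       frac = 0.6, cis_gene_window = 30, alpha = 0.05,
                       force = FALSE) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Run the full regulatory-linkage pipeline
#'
#' Reads the inputs, computes the linkage and ReL matrices, extracts and
#' (when gene positions are available) annotates modules, optionally
#' attaches permutation P-values, and writes all stage outputs plus the
#' resolved configuration to the run directory. Any stage failure aborts
#' with the stage name; outputs of completed stages are retained.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the computed objects (`linkage`, `rel`,
#'   `modules`, `annotated`, `report_path`) and per-stage counts.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (dir.exists(config$out_dir) && length(dir(config$out_dir)) &&
      !config$force)
    stop("run directory exists and is not empty: ", config$out_dir)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(config, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)

  inputs <- stage("read_inputs", {
    for (f in c("genotypes", "marker_map", "expression", "compendium",
                "compendium_meta"))
      if (!file.exists(config[[f]]))
        stop("missing input file '", config[[f]], "' (", f, ")")
    list(genotypes = read_genotypes(config$genotypes),
         map = read_marker_map(config$marker_map),
         expression = read_expression(config$expression),
         compendium = read_compendium(config$compendium,
                                      config$compendium_meta),
         gene_positions = if (!is.null(config$gene_positions))
           read_gene_positions(config$gene_positions),
         annotation = if (!is.null(config$annotation))
           read_annotations(config$annotation),
         network = if (!is.null(config$network))
           read_network(config$network),
         binding_targets = if (!is.null(config$binding_targets))
           read_binding_targets(config$binding_targets),
         chrom_lengths = if (!is.null(config$chrom_lengths))
           read_chrom_lengths(config$chrom_lengths))
  })

  linkage <- stage("linkage", compute_linkage_matrix(
    inputs$genotypes, inputs$expression,
    min_shared = config$min_shared_segregants, cap = config$lod_cap))
  stage("linkage", write_linkage_matrix(
    linkage, file.path(config$out_dir, "linkage_matrix.tsv")))

  rel <- stage("relscore", compute_rel_matrix(
    linkage, inputs$compendium, inputs$map,
    min_shared_genes = config$min_shared_genes))
  stage("relscore", write_rel_matrix(
    rel, file.path(config$out_dir, "rel_scores.tsv")))

  params <- isa_params(tau_row = config$tau_row, tau_col = config$tau_col,
                       max_iter = config$max_iter,
                       min_signatures = config$min_signatures,
                       min_markers = config$min_markers,
                       score_floor = config$score_floor)
  modules <- stage("modules", find_modules(
    rel, params, min_seed_score = config$min_seed_score,
    jaccard_cutoff = config$jaccard_cutoff))
  perm_p <- if (config$n_perm > 0)
    stage("modules", vapply(modules, module_size_pvalue, numeric(1),
                            rel = rel, n_perm = config$n_perm,
                            rng_seed = config$rng_seed, params = params))
  else rep(NA_real_, length(modules))

  annotated <- stage("annotate", {
    if (!is.null(inputs$gene_positions))
      lapply(modules, annotate_module, rel = rel,
             gene_positions = inputs$gene_positions,
             annotation = inputs$annotation, network = inputs$network,
             binding_targets = inputs$binding_targets,
             chrom_lengths = inputs$chrom_lengths,
             frac = config$frac, cis_gene_window = config$cis_gene_window,
             alpha = config$alpha)
    else modules
  })

  report_path <- file.path(config$out_dir, "modules.tsv")
  stage("report", write_module_report(annotated, report_path))
  counts <- list(
    n_markers = length(rel$marker_ids),
    n_signatures = length(rel$signature_ids),
    n_shared_genes = length(rel$gene_ids),
    n_tests = rel$n_tests,
    n_entries_significant = sum(rel$score > 0),
    n_seeds = nrow(seed_entries(rel, config$min_seed_score)),
    n_modules = length(modules),
    module_perm_p = perm_p)
  jsonlite::write_json(counts, file.path(config$out_dir, "counts.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("pipeline: %d markers x %d signatures, %d modules",
                  counts$n_markers, counts$n_signatures, counts$n_modules))
  invisible(list(linkage = linkage, rel = rel, modules = modules,
                 annotated = annotated, module_perm_p = perm_p,
                 counts = counts, report_path = report_path))
}

# ---- command-line front end -------------------------------------------------

cli_parse <- function(argv) {
  opts <- list(); positional <- character()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[[i]]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3L))
      if (i < length(argv) && !startsWith(argv[[i + 1L]], "--")) {
        opts[[key]] <- argv[[i + 1L]]; i <- i + 2L
      } else { opts[[key]] <- TRUE; i <- i + 1L }
    } else { positional <- c(positional, a); i <- i + 1L }
  }
  list(opts = opts, positional = positional)
}

cli_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic bundle), `linkage`,
#' `relscore`, `modules`, and `run` (full pipeline). Flags mirror the
#' [run_config()] / [sim_config()] fields with dashes, e.g.
#' `--tau-row 3 --n-perm 100 --rng-seed 7`. Used by the `relmod` script in
#' `inst/scripts/`.
#'
#' @param argv Character vector of command-line arguments (subcommand
#'   first).
#' @return Exit status, 0 on success (invisibly).
#' @export
relmod_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    cat("usage: relmod <simulate|linkage|relscore|modules|run> [--flags]\n")
    return(invisible(1L))
  }
  cmd <- argv[[1L]]
  p <- cli_parse(argv[-1L])
  o <- p$opts
  status <- tryCatch({
    switch(cmd,
      simulate = {
        cfg <- sim_config(
          n_segregants = cli_num(o, "n_segregants", 112),
          inter_marker_recomb = cli_num(o, "r", 0.1),
          n_genes = cli_num(o, "n_genes", 1000),
          n_signatures = cli_num(o, "n_signatures", 40),
          noise_sd = cli_num(o, "noise_sd", 0.5),
          signature_noise_sd = cli_num(o, "signature_noise_sd", 0.3),
          rng_seed = cli_num(o, "rng_seed", 1))
        generate_dataset(cfg, o$out_dir %||% "simdata",
                         force = isTRUE(o$force))
      },
      linkage = {
        lk <- compute_linkage_matrix(read_genotypes(o$genotypes),
                                     read_expression(o$expression),
                                     min_shared = cli_num(o, "min_shared", 20))
        write_linkage_matrix(lk, o$out %||% "linkage_matrix.tsv")
      },
      relscore = {
        lk <- compute_linkage_matrix(read_genotypes(o$genotypes),
                                     read_expression(o$expression))
        rel <- compute_rel_matrix(
          lk, read_compendium(o$compendium, o$compendium_meta),
          read_marker_map(o$marker_map),
          min_shared_genes = cli_num(o, "min_shared_genes", 100))
        write_rel_matrix(rel, o$out %||% "rel_scores.tsv")
      },
      modules = ,
      run = {
        cfg <- run_config(
          genotypes = o$genotypes, marker_map = o$marker_map,
          expression = o$expression, compendium = o$compendium,
          compendium_meta = o$compendium_meta,
          out_dir = o$out_dir %||% "rel_run",
          gene_positions = o$gene_positions, annotation = o$annotation,
          network = o$network, binding_targets = o$binding_targets,
          chrom_lengths = o$chrom_lengths,
          tau_row = cli_num(o, "tau_row", 3),
          tau_col = cli_num(o, "tau_col", 3),
          score_floor = cli_num(o, "score_floor", 3),
          min_markers = cli_num(o, "min_markers", 1),
          min_signatures = cli_num(o, "min_signatures", 1),
          min_seed_score = if (isTRUE(o$seed_all)) 0
                           else cli_num(o, "min_seed_score",
                                        cli_num(o, "score_floor", 3)),
          n_perm = cli_num(o, "n_perm", 0),
          rng_seed = cli_num(o, "rng_seed", 1),
          force = isTRUE(o$force))
        run_pipeline(cfg)
      },
      stop("unknown subcommand: ", cmd))
    0L
  }, error = function(e) {
    message("relmod ", cmd, ": ", conditionMessage(e))
    1L
  })
  invisible(status)
}
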