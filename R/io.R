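# Readers, writers and validated containers for all external representations.
# All tabular files are UTF-8 tab-delimited; matrices carry a header row of
# column ids and row ids in the first column. The marker map alone is
# headerless (BED-like: chromosome, position_kb, marker_id).

#' Construct a validated genotype matrix
#'
#' Holds biallelic calls for a haploid segregating population: 0 codes the
#' parent-A allele, 1 the parent-B allele, `NA` a missing call.
#'
#' @param calls Integer matrix, markers in rows, segregants in columns;
#'   entries in \{0, 1, NA\}.
#' @param marker_ids,segregant_ids Unique character vectors matching the
#'   matrix dimensions. Defaults taken from `dimnames(calls)`.
#' @return An object of class `genotype_matrix` with fields `marker_ids`,
#'   `segregant_ids` and `calls`.
#' @export
genotype_matrix <- function(calls, marker_ids = rownames(calls),
                            segregant_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(marker_ids) || is.null(segregant_ids))
    stop("genotype matrix needs marker and segregant ids")
  if (nrow(calls) != length(marker_ids) || ncol(calls) != length(segregant_ids))
    stop("genotype matrix dimensions do not match id lists")
  if (anyDuplicated(marker_ids))
    stop("duplicate marker id: ", marker_ids[duplicated(marker_ids)][1L])
  if (anyDuplicated(segregant_ids))
    stop("duplicate segregant id: ", segregant_ids[duplicated(segregant_ids)][1L])
  bad <- !is.na(calls) & !(calls %in% c(0L, 1L))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary genotype call '%s' at marker '%s', segregant '%s'",
                 calls[bad][1L], marker_ids[idx[1L]], segregant_ids[idx[2L]]))
  }
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(marker_ids, segregant_ids)
  structure(list(marker_ids = marker_ids, segregant_ids = segregant_ids,
                 calls = calls),
            class = "genotype_matrix")
}

#' Read a genotype matrix from TSV
#'
#' Expects a header row of segregant ids, marker ids in the first column, and
#' calls in \{0, 1, NA\}. Row and column order are preserved.
#'
#' @param path Path to the tab-delimited file.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          na.strings = "NA")
  if (ncol(df) < 2L) stop("genotype file needs marker ids plus >=1 segregant")
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  bad <- !is.na(m) & !(m %in% c("0", "1"))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary genotype call '%s' at marker '%s', segregant '%s'",
                 m[bad][1L], ids[idx[1L]], colnames(m)[idx[2L]]))
  }
  storage.mode(m) <- "integer"
  genotype_matrix(m, marker_ids = ids, segregant_ids = colnames(m))
}

#' Write a genotype matrix to TSV (inverse of [read_genotypes()])
#' @param x A `genotype_matrix`.
#' @param path Output path.
#' @export
write_genotypes <- function(x, path) {
  write_id_matrix(x$calls, "marker_id", path)
}

#' Construct a validated expression matrix
#'
#' Log-ratio expression values for genes (rows) across samples (columns);
#' `NA` marks a missing measurement, all other values must be finite.
#'
#' @param values Numeric matrix.
#' @param gene_ids,sample_ids Unique id vectors matching the dimensions.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("expression matrix needs gene and sample ids")
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids))
    stop("expression matrix dimensions do not match id lists")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  if (any(!is.na(values) & !is.finite(values)))
    stop("expression values must be finite or NA")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(gene_ids = gene_ids, sample_ids = sample_ids,
                 values = values),
            class = "expression_matrix")
}

#' Read an expression matrix from TSV
#' @param path Path; header row of sample ids, first column gene ids.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = "NA")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  expression_matrix(m, gene_ids = ids, sample_ids = colnames(m))
}

#' Write an expression matrix to TSV (inverse of [read_expression()])
#' @param x An `expression_matrix`.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  write_id_matrix(x$values, "gene_id", path)
}

#' Construct a marker map
#'
#' @param marker_id Character vector of unique marker ids.
#' @param chromosome Chromosome label per marker.
#' @param position_kb Non-negative position in kilobases. Positions are kept
#'   as given; no unit conversion. Rows need not be sorted: consumers order
#'   markers genomically themselves (chromosomes in order of first appearance
#'   in the map, then by position).
#' @return A data frame of class `marker_map`.
#' @export
marker_map <- function(marker_id, chromosome, position_kb) {
  marker_id <- as.character(marker_id)
  chromosome <- as.character(chromosome)
  position_kb <- as.numeric(position_kb)
  if (anyDuplicated(marker_id))
    stop("duplicate marker id in map: ", marker_id[duplicated(marker_id)][1L])
  if (any(is.na(position_kb)) || any(position_kb < 0))
    stop("marker positions must be non-negative numbers")
  structure(data.frame(marker_id = marker_id, chromosome = chromosome,
                       position_kb = position_kb, stringsAsFactors = FALSE),
            class = c("marker_map", "data.frame"))
}

#' Read a marker map (BED-like, headerless TSV)
#'
#' Columns: chromosome, position_kb, marker_id.
#' @param path Path to the file.
#' @return A [marker_map()].
#' @export
read_marker_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, check.names = FALSE,
                          colClasses = c("character", "numeric", "character"))
  marker_map(marker_id = df[[3L]], chromosome = df[[1L]],
             position_kb = df[[2L]])
}

#' Write a marker map (inverse of [read_marker_map()])
#' @param x A `marker_map`.
#' @param path Output path.
#' @export
write_marker_map <- function(x, path) {
  utils::write.table(x[, c("chromosome", "position_kb", "marker_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}

#' Construct a signature compendium
#'
#' Genes-by-signatures matrix of log2 mutant/wild-type ratios plus the map
#' from each signature to its mutated regulatory protein. Several signatures
#' may map to the same protein, but each signature maps to exactly one.
#'
#' @param values Numeric matrix, genes in rows, signatures in columns.
#' @param protein_of Named character vector: signature id -> protein name,
#'   covering every signature exactly once.
#' @param gene_ids,signature_ids Id vectors; default from dimnames.
#' @return An object of class `signature_compendium`.
#' @export
signature_compendium <- function(values, protein_of,
                                 gene_ids = rownames(values),
                                 signature_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(gene_ids) || ncol(values) != length(signature_ids))
    stop("compendium dimensions do not match id lists")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id in compendium")
  if (anyDuplicated(signature_ids))
    stop("duplicate signature id in compendium")
  if (anyDuplicated(names(protein_of)))
    stop("signature listed twice in metadata: ",
         names(protein_of)[duplicated(names(protein_of))][1L])
  missing_meta <- setdiff(signature_ids, names(protein_of))
  if (length(missing_meta))
    stop("signature without metadata: ", missing_meta[1L])
  protein_of <- protein_of[signature_ids]
  dimnames(values) <- list(gene_ids, signature_ids)
  structure(list(gene_ids = gene_ids, signature_ids = signature_ids,
                 values = values, protein_of = protein_of),
            class = "signature_compendium")
}

#' Read a signature compendium (matrix + metadata TSVs)
#'
#' @param matrix_path Genes-by-signatures TSV (header = signature ids, first
#'   column = gene ids).
#' @param meta_path Two-column TSV with header: signature_id, protein.
#' @return A [signature_compendium()].
#' @export
read_compendium <- function(matrix_path, meta_path) {
  df <- utils::read.delim(matrix_path, check.names = FALSE, na.strings = "NA")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            colClasses = "character")
  protein_of <- stats::setNames(meta[[2L]], meta[[1L]])
  signature_compendium(m, protein_of, gene_ids = ids,
                       signature_ids = colnames(m))
}

#' Write a signature compendium (inverse of [read_compendium()])
#' @param x A `signature_compendium`.
#' @param matrix_path,meta_path Output paths for the matrix and metadata.
#' @export
write_compendium <- function(x, matrix_path, meta_path) {
  write_id_matrix(x$values, "gene_id", matrix_path)
  utils::write.table(
    data.frame(signature_id = names(x$protein_of), protein = x$protein_of),
    meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Construct an annotation set
#'
#' @param gene Character vector of annotated genes (one row per
#'   gene-term pair of the flattened annotation table).
#' @param term Parallel vector of term ids.
#' @param universe Gene universe; defaults to the annotated genes. Annotated
#'   genes outside the universe are dropped.
#' @param term_name Optional parallel vector of human-readable term names.
#' @return Object of class `annotation_set`: `terms` (named list of gene
#'   sets), `term_names`, `universe`.
#' @export
annotation_set <- function(gene, term, universe = unique(gene),
                           term_name = term) {
  gene <- as.character(gene); term <- as.character(term)
  keep <- gene %in% universe
  terms <- lapply(split(gene[keep], term[keep]), unique)
  nm <- tapply(as.character(term_name), term, function(v) v[[1L]])
  structure(list(terms = terms,
                 term_names = stats::setNames(as.character(nm[names(terms)]),
                                              names(terms)),
                 universe = unique(as.character(universe))),
            class = "annotation_set")
}

#' Read a flattened gene-to-process annotation table
#'
#' TSV with header; first column gene id, second column term id, optional
#' third column term name.
#' @param path Path to the table.
#' @param universe Optional gene universe (defaults to annotated genes).
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, universe = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (is.null(universe)) universe <- unique(df[[1L]])
  annotation_set(df[[1L]], df[[2L]], universe = universe,
                 term_name = if (ncol(df) >= 3L) df[[3L]] else df[[2L]])
}

#' Construct an interaction network
#'
#' Undirected edges over the shared gene/protein namespace.
#' @param node_a,node_b Endpoint name vectors.
#' @param kind Edge kind, `"protein-protein"` or `"protein-DNA"`.
#' @return Data frame of class `interaction_network`.
#' @export
interaction_network <- function(node_a, node_b,
                                kind = rep("protein-protein",
                                           length(node_a))) {
  kind <- as.character(kind)
  bad <- !(kind %in% c("protein-protein", "protein-DNA"))
  if (any(bad)) stop("unknown edge kind: ", kind[bad][1L])
  structure(data.frame(node_a = as.character(node_a),
                       node_b = as.character(node_b),
                       kind = kind, stringsAsFactors = FALSE),
            class = c("interaction_network", "data.frame"))
}

#' Read a protein interaction edge list
#'
#' TSV with header: node_a, node_b, optional kind column.
#' @param path Path to the edge list.
#' @return An [interaction_network()].
#' @export
read_network <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  interaction_network(df[[1L]], df[[2L]],
                      kind = if (ncol(df) >= 3L) df[[3L]]
                             else rep("protein-protein", nrow(df)))
}

#' Read a regulator-to-binding-target table
#' @param path TSV with header: regulator, target.
#' @return Named list: regulator -> character vector of bound targets.
#' @export
read_binding_targets <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  lapply(split(df[[2L]], df[[1L]]), unique)
}

#' Read a gene position table
#' @param path TSV with header: gene_id, chromosome, position_kb.
#' @return Data frame with those three columns.
#' @export
read_gene_positions <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  data.frame(gene_id = as.character(df[[1L]]),
             chromosome = as.character(df[[2L]]),
             position_kb = as.numeric(df[[3L]]),
             stringsAsFactors = FALSE)
}

#' Read a chromosome length table
#' @param path TSV with header: chromosome, length_kb.
#' @return Named numeric vector of lengths in kb.
#' @export
read_chrom_lengths <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

#' Write the module summary report
#'
#' One TSV row per module (id, ReL score, interval, counts, primary process,
#' best-scoring regulatory protein, causal candidates) plus a JSON sidecar
#' (`<path>.json`) holding the full member lists. Intervals are reported
#' inclusive of both endpoint markers, as `chrom:start-end` in kb with an
#' en dash.
#'
#' @param modules List of annotated modules (see [annotate_module()]); plain
#'   `rel_module` objects are accepted and reported without annotation fields.
#' @param path Output TSV path.
#' @return Invisibly, the path of the JSON sidecar.
#' @export
write_module_report <- function(modules, path) {
  rows <- lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    b <- if (inherits(m, "annotated_module")) m$base else m
    data.frame(
      module_id = i,
      rel_score = b$module_score,
      interval = format_interval(b),
      n_signatures = length(b$signatures),
      n_target_genes = if (!is.null(m$target_genes))
        length(m$target_genes) else NA_integer_,
      primary_process = if (!is.null(m$primary_process) &&
                            !is.na(m$primary_process))
        m$primary_process else "",
      best_protein = if (length(m$protein_scores))
        names(m$protein_scores)[which.max(m$protein_scores)] else "",
      causal_candidates = if (!is.null(m$causal_candidates) &&
                              nrow(m$causal_candidates))
        paste(m$causal_candidates$gene, collapse = ",") else "",
      stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module_id = integer(), rel_score = numeric(),
               interval = character(), n_signatures = integer(),
               n_target_genes = integer(), primary_process = character(),
               best_protein = character(), causal_candidates = character())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  side <- lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    b <- if (inherits(m, "annotated_module")) m$base else m
    list(module_id = i,
         chromosome = b$chromosome,
         marker_ids = as.list(b$marker_ids),
         start_kb = b$start_kb, end_kb = b$end_kb,
         signatures = as.list(b$signatures),
         module_score = b$module_score,
         target_genes = as.list(m$target_genes %||% character()),
         protein_scores = as.list(m$protein_scores %||% numeric()),
         primary_process = m$primary_process %||% NA,
         telomere_flag = m$telomere_flag %||% NA,
         causal_candidates = if (!is.null(m$causal_candidates))
           m$causal_candidates else NULL)
  })
  json_path <- paste0(path, ".json")
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(json_path)
}

#' Read back the JSON sidecar written by [write_module_report()]
#' @param json_path Path to the sidecar.
#' @return List of module records.
#' @export
read_module_report <- function(json_path) {
  jsonlite::read_json(json_path, simplifyVector = FALSE)
}

# interval string, e.g. "II:352-376" (en dash), positions trimmed of
# trailing zeros to match kb notation
format_interval <- function(module) {
  fmt <- function(p) sub("^\\s+", "", formatC(p, format = "fg", digits = 15))
  sprintf("%s:%s–%s", module$chromosome, fmt(module$start_kb),
          fmt(module$end_kb))
}

write_id_matrix <- function(m, id_col, path) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
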