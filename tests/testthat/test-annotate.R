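# Fixture: one chromosome ("II") carrying the linkage interval, genes laid
# out one per kb so gene-order distance equals kb distance; target genes on
# chromosome "IV" are trans by construction.
annotate_fixture <- function() {
  nm <- 5L
  score <- matrix(6, nm, 1, dimnames = list(sprintf("m%d", 1:nm), "s1"))
  hit <- vector("list", nm); dim(hit) <- c(nm, 1L)
  # "far" hit in 5/5 entries, "sixty" in exactly 3/5, "forty" in 2/5,
  # "near" (cis) in 5/5
  hit[[1L, 1L]] <- c("far", "sixty", "near")
  hit[[2L, 1L]] <- c("far", "sixty", "near", "forty")
  hit[[3L, 1L]] <- c("far", "sixty", "near", "forty")
  hit[[4L, 1L]] <- c("far", "near")
  hit[[5L, 1L]] <- c("far", "near")
  rel <- make_rel(score, chrom = rep("II", nm),
                  pos_kb = c(49.2, 49.5, 49.9, 50.2, 50.5),
                  hit_genes = hit,
                  gene_ids = c("far", "sixty", "forty", "near",
                               sprintf("ii_g%03d", 1:120)))
  gp <- data.frame(
    gene_id = c(sprintf("ii_g%03d", 1:120), "far", "sixty", "forty"),
    chromosome = c(rep("II", 120), "IV", "IV", "IV"),
    position_kb = c(1:120, 200, 300, 400),
    stringsAsFactors = FALSE)
  # "near" sits 10 genes downstream of the interval gene at index 50
  gp <- rbind(gp, data.frame(gene_id = "near", chromosome = "II",
                             position_kb = 60.2))
  module <- make_module(rel, 1L, 5L, "s1")
  list(rel = rel, gp = gp, module = module)
}

test_that("target genes honour the 60% hit rule and the cis window", {
  fx <- annotate_fixture()
  tg <- target_genes(fx$module, fx$rel, fx$gp)
  expect_true("far" %in% tg)       # hit in all entries, trans
  expect_true("sixty" %in% tg)     # hit in exactly 60% ("at least 60%")
  expect_false("forty" %in% tg)    # hit in 40% only
  expect_false("near" %in% tg)     # 10 genes from the interval: cis
})

test_that("cis exclusion counts gene-order distance: 29 out, 30 in", {
  fx <- annotate_fixture()
  # drop "near" so chromosome II holds exactly genes 1..120 in order;
  # interval covers positions 49.2-50.5, so gene index 50 is the only one
  # inside and genes 21..79 are < 30 genes away
  fx$gp <- fx$gp[fx$gp$gene_id != "near", ]
  hit_all <- lapply(1:5, function(i) c("ii_g021", "ii_g079", "ii_g080",
                                       "ii_g020", "far"))
  dim(hit_all) <- c(5L, 1L)
  fx$rel$hit_genes <- hit_all
  tg <- target_genes(fx$module, fx$rel, fx$gp)
  expect_false("ii_g079" %in% tg)  # 29 genes from the boundary: excluded
  expect_false("ii_g021" %in% tg)
  expect_true("ii_g080" %in% tg)   # 30 genes away: included
  expect_true("ii_g020" %in% tg)
})

test_that("unpositioned hit genes are kept with a warning", {
  fx <- annotate_fixture()
  fx$rel$hit_genes[[1L, 1L]] <- c(fx$rel$hit_genes[[1L, 1L]], "ghost")
  for (i in 2:5) fx$rel$hit_genes[[i, 1L]] <-
      c(fx$rel$hit_genes[[i, 1L]], "ghost")
  expect_warning(tg <- target_genes(fx$module, fx$rel, fx$gp),
                 "cannot be cis-excluded")
  expect_true("ghost" %in% tg)
})

test_that("protein scores average signature interval means per protein", {
  score <- cbind(s1 = c(4, 6), s2 = c(2, 4), s3 = c(0, 0.5))
  rel <- make_rel(score, protein_of = c(s1 = "PA", s2 = "PA", s3 = "PB"))
  m1 <- make_module(rel, 1L, 2L, "s1")
  expect_equal(protein_scores(m1, rel), c(PA = 5))
  m2 <- make_module(rel, 1L, 2L, c("s1", "s2"))
  expect_equal(protein_scores(m2, rel), c(PA = mean(c(5, 3))))
  m3 <- make_module(rel, 1L, 2L, c("s1", "s2", "s3"))
  ps <- protein_scores(m3, rel)
  expect_equal(names(ps)[1], "PA")       # best-scoring protein first
  expect_equal(unname(ps), c(4, 0.25))
})

test_that("enrichment P equals the closed-form hypergeometric tail", {
  universe <- sprintf("u%02d", 1:20)
  ann <- annotation_set(gene = universe[1:5], term = rep("T1", 5),
                        universe = universe)
  targets <- c(universe[1:3], universe[10])      # overlap 3 of 4 draws
  res <- enrich(targets, ann)
  expect_equal(res$table$p, bf_hyper_upper(3, 5, 20, 4), tolerance = 1e-12)
  expect_equal(res$primary, "T1")

  whole <- annotation_set(gene = universe, term = rep("ALL", 20),
                          universe = universe)
  expect_equal(enrich(targets, whole)$table$p, 1)
  expect_true(is.na(enrich(targets, whole)$primary))

  # two significant terms: the smaller corrected P wins
  ann2 <- annotation_set(gene = c(universe[1:4], universe[1:3]),
                         term = c(rep("TIGHT", 4), rep("LOOSE", 3)),
                         universe = universe)
  res2 <- enrich(universe[1:4], ann2)
  expect_equal(res2$primary, "TIGHT")
  expect_equal(res2$table$term[1], "TIGHT")
  expect_equal(enrich(character(), ann2)$primary, NA_character_)
})

test_that("enrichment P-values are super-uniform under random target draws", {
  set.seed(40)
  universe <- sprintf("u%03d", 1:200)
  ann <- annotation_set(
    gene = unlist(lapply(c(5, 10, 20, 40), function(k) sample(universe, k))),
    term = rep(paste0("T", 1:4), times = c(5, 10, 20, 40)),
    universe = universe)
  p <- replicate(1000, enrich(sample(universe, 15), ann)$table$p)
  for (alpha in c(0.01, 0.05, 0.2)) {
    frac <- mean(p <= alpha)
    expect_lte(frac, alpha + 3 * sqrt(alpha * (1 - alpha) / length(p)))
  }
})

test_that("causal candidates apply the three criteria and rank correctly", {
  # modeled on the nucleobase-biosynthesis case: the causal gene shares the
  # targets' process and physically interacts with the module's protein
  score <- matrix(8, 2, 1, dimnames = list(c("mA", "mB"), "s1"))
  rel <- make_rel(score, chrom = c("V", "V"), pos_kb = c(73, 166),
                  protein_of = c(s1 = "PPR1"),
                  gene_ids = sprintf("y%02d", 1:30))
  module <- make_module(rel, 1L, 2L, "s1")
  gp <- data.frame(gene_id = c("URA3", "BYSTANDER", "EDGEONLY"),
                   chromosome = "V", position_kb = c(100, 120, 140),
                   stringsAsFactors = FALSE)
  targets <- c("y01", "y02", "y03")
  ann <- annotation_set(gene = c("URA3", "y01", "y02", "y03"),
                        term = rep("nucleobase", 4),
                        universe = c(rel$gene_ids, "URA3"))
  net <- interaction_network(c("URA3", "EDGEONLY"), c("PPR1", "PPR1"))
  cc <- causal_candidates(module, rel, gp, targets,
                          primary_process = "nucleobase",
                          annotation = ann, network = net)
  expect_equal(cc$gene[1], "URA3")       # two criteria: ranked first
  expect_true(cc$process[1] && cc$interaction[1])
  expect_equal(cc$n_criteria[1], 2L)
  expect_true("EDGEONLY" %in% cc$gene)   # one criterion
  expect_false("BYSTANDER" %in% cc$gene) # no criterion

  none <- causal_candidates(module, rel, gp, targets,
                            primary_process = NA_character_)
  expect_equal(nrow(none), 0L)
})

test_that("binding-target enrichment matches the combinatorial oracle", {
  universe <- sprintf("y%02d", 1:30)
  score <- matrix(8, 1, 1, dimnames = list("mA", "s1"))
  rel <- make_rel(score, chrom = "V", pos_kb = 100,
                  protein_of = c(s1 = "PX"), gene_ids = universe)
  module <- make_module(rel, 1L, 1L, "s1")
  gp <- data.frame(gene_id = c("REG", "OTHER"), chromosome = "V",
                   position_kb = c(100, 100), stringsAsFactors = FALSE)
  binding <- list(REG = universe[1:8])
  targets <- c(universe[1:6], universe[20:23])   # overlap 6 of 10
  cc <- causal_candidates(module, rel, gp, targets,
                          binding_targets = binding)
  expect_equal(cc$gene, "REG")
  expect_equal(cc$binding_p, bf_hyper_upper(6, 8, 30, 10),
               tolerance = 1e-12)
  expect_true(cc$binding)                # Bonferroni x2 still < 0.05

  # stability under row-order permutation of the input tables
  gp2 <- gp[2:1, ]
  cc2 <- causal_candidates(module, rel, gp2, targets,
                           binding_targets = binding)
  expect_equal(cc2, cc)
})

test_that("telomere flag needs a telomeric majority on several chromosomes", {
  lens <- c(I = 500, II = 600, III = 700, IV = 800)
  mid <- data.frame(gene_id = paste0("m", 1:6),
                    chromosome = rep(c("I", "II", "III"), 2),
                    position_kb = 250, stringsAsFactors = FALSE)
  expect_false(telomere_flag(mid$gene_id, mid, lens))

  telo <- data.frame(
    gene_id = paste0("t", 1:10),
    chromosome = c("I", "I", "II", "II", "III", "IV", "I", "II", "III", "IV"),
    position_kb = c(5, 495, 10, 590, 15, 790, 250, 300, 350, 400),
    stringsAsFactors = FALSE)
  expect_true(telomere_flag(telo$gene_id, telo, lens))   # 60% telomeric

  # boundary: exactly telomere_kb from the end counts as telomeric
  edge <- data.frame(gene_id = c("e1", "e2", "e3"),
                     chromosome = c("I", "II", "III"),
                     position_kb = c(30, 570, 30), stringsAsFactors = FALSE)
  expect_true(telomere_flag(edge$gene_id, edge, lens))
  expect_warning(telomere_flag(c("e1", "ghost"), edge, lens), "positions")
})

test_that("annotate_module assembles a consistent annotated record", {
  fx <- annotate_fixture()
  ann <- annotation_set(gene = c("far", "sixty"), term = rep("procA", 2),
                        universe = c(fx$rel$gene_ids))
  am <- annotate_module(fx$module, fx$rel, fx$gp, annotation = ann,
                        chrom_lengths = c(II = 150, IV = 500))
  expect_s3_class(am, "annotated_module")
  expect_true(all(c("far", "sixty") %in% am$target_genes))
  expect_equal(am$primary_process, "procA")
  expect_equal(names(am$protein_scores), "P_s1")
  expect_false(am$telomere_flag)
  # target set never intersects the cis zone when positions are complete
  cis_zone <- fx$gp$gene_id[fx$gp$chromosome == "II"]
  expect_length(intersect(am$target_genes, cis_zone[21:79]), 0L)
})
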