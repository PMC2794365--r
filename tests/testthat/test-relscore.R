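test_that("split_signature partitions strictly about the mean", {
  v <- c(g1 = -1, g2 = 0, g3 = 1)
  sp <- split_signature(v)
  expect_equal(sp$over, "g3")
  expect_equal(sp$under, "g1")
  expect_equal(sp$mean, 0)
  expect_error(split_signature(rep(5, 4)), "degenerate")

  set.seed(8)
  v2 <- stats::setNames(rnorm(1000), paste0("g", 1:1000))
  sp2 <- split_signature(v2)
  expect_equal(length(sp2$over) + length(sp2$under), 1000)
  expect_lt(abs(length(sp2$over) - 500), 3 * sqrt(250) + 1)
})

test_that("select_threshold finds the planted high-linkage block", {
  genes <- paste0("g", 1:500)
  scores <- stats::setNames(rep(0, 500), genes)
  scores[1:20] <- 5
  over <- genes[1:50]
  under <- genes[51:100]
  sel <- select_threshold(scores, over, under)
  expect_equal(sel$threshold, 5)
  expect_equal(sel$direction, "up")
  expect_equal(sel$n_high, 20L)
  ref <- bf_select_threshold(scores, over, under)
  expect_equal(sel$hypergeom_p, ref$hypergeom_p, tolerance = 1e-12)

  one_value <- stats::setNames(rep(2, 20), paste0("g", 1:20))
  sel1 <- select_threshold(one_value, paste0("g", 1:5), paste0("g", 6:10))
  expect_equal(sel1$threshold, 2)       # single candidate
  expect_error(select_threshold(scores, character(), character()), "empty")
})

test_that("select_threshold equals the exhaustive scan on random instances", {
  set.seed(101)
  for (i in 1:50) {
    G <- sample(30:80, 1)
    genes <- paste0("g", seq_len(G))
    scores <- stats::setNames(round(rexp(G), 1), genes)  # rounded: ties
    sv <- rnorm(G)
    over <- genes[sv > mean(sv)]
    under <- genes[sv < mean(sv)]
    got <- select_threshold(scores, over, under)
    ref <- bf_select_threshold(scores, over, under)
    expect_equal(got$hypergeom_p, ref$hypergeom_p, tolerance = 1e-12)
    expect_equal(got$threshold, ref$threshold)
    expect_equal(got$direction, ref$direction)
  }
})

test_that("rel_entry matches an independent Welch t-test oracle", {
  set.seed(77)
  genes <- paste0("g", 1:500)
  scores <- stats::setNames(c(rep(4, 20), abs(rnorm(480, 0, 0.5))), genes)
  sv <- stats::setNames(rnorm(500), genes)
  sv[1:20] <- sv[1:20] + 2              # high-linkage genes shifted +2 sigma
  n_tests <- 1000
  e <- rel_entry("m1", "s1", scores, sv, n_tests)

  ref_sel <- bf_select_threshold(scores, genes[sv > mean(sv)],
                                 genes[sv < mean(sv)])
  high <- genes[scores >= ref_sel$threshold]
  ref_p <- stats::t.test(sv[high], sv[setdiff(genes, high)])$p.value
  expect_equal(e$rel_score, -log10(min(1, ref_p * n_tests)),
               tolerance = 1e-8)
  expect_equal(e$direction, "up")
  expect_setequal(e$hit_genes, high[sv[high] > mean(sv)])
})

test_that("null entries floor at zero and the Bonferroni factor is the pair count", {
  set.seed(13)
  genes <- paste0("g", 1:200)
  scores <- stats::setNames(rexp(200), genes)
  sv <- stats::setNames(rnorm(200), genes)
  e <- rel_entry("m1", "s1", scores, sv, bonferroni_factor(2956, 283))
  expect_identical(e$rel_score, 0)      # corrected P hits 1, floored
  expect_equal(bonferroni_factor(2956, 283), 836548)

  e_deg <- rel_entry("m1", "s1", scores,
                     stats::setNames(rep(1, 200), genes), 10)
  expect_identical(e_deg$rel_score, 0)
  expect_equal(e_deg$note, "degenerate_signature")
})

test_that("compute_rel_matrix composes rel_entry and orders markers genomically", {
  set.seed(31)
  genes <- paste0("g", 1:120)
  lk <- structure(list(
    marker_ids = c("mB", "mA", "mC"),
    gene_ids = genes,
    scores = matrix(rexp(3 * 120), 3, dimnames = list(c("mB", "mA", "mC"),
                                                      genes))),
    class = "linkage_matrix")
  cvals <- matrix(rnorm(120 * 2), 120, dimnames = list(genes, c("s1", "s2")))
  cvals[5, 2] <- NA                      # exercises the NA fallback path
  comp <- signature_compendium(cvals, c(s1 = "P1", s2 = "P2"))
  map <- marker_map(c("mA", "mB", "mC"), c("I", "I", "I"), c(20, 10, 30))
  rel <- compute_rel_matrix(lk, comp, map, min_shared_genes = 50)

  expect_equal(rel$marker_ids, c("mB", "mA", "mC"))  # genomic order
  expect_equal(rel$n_tests, 6)
  for (m in rel$marker_ids) for (s in rel$signature_ids) {
    ref <- rel_entry(m, s, lk$scores[m, ], cvals[, s], rel$n_tests)
    expect_equal(rel$score[m, s], ref$rel_score, tolerance = 1e-8)
    expect_equal(rel$direction[m, s], ref$direction)
    expect_setequal(rel$hit_genes[[m, s]], ref$hit_genes)
  }
  expect_error(compute_rel_matrix(lk, comp, map, min_shared_genes = 200),
               "shared")
})

test_that("ReL scores depend only on the linkage score ordering", {
  set.seed(57)
  genes <- paste0("g", 1:150)
  scores <- matrix(round(rexp(2 * 150), 1), 2,
                   dimnames = list(c("m1", "m2"), genes))
  lk <- structure(list(marker_ids = c("m1", "m2"), gene_ids = genes,
                       scores = scores), class = "linkage_matrix")
  comp <- signature_compendium(
    matrix(rnorm(150), 150, dimnames = list(genes, "s1")), c(s1 = "P"))
  map <- marker_map(c("m1", "m2"), c("I", "I"), c(1, 2))
  rel1 <- compute_rel_matrix(lk, comp, map, min_shared_genes = 50)
  lk$scores <- lk$scores^3               # strictly monotone, tie-preserving
  rel2 <- compute_rel_matrix(lk, comp, map, min_shared_genes = 50)
  expect_equal(rel2$score, rel1$score, tolerance = 1e-10)
  expect_equal(rel2$direction, rel1$direction)
  expect_equal(rel2$n_high, rel1$n_high)
})

test_that("hit genes always lie on the entry's direction side of the mean", {
  set.seed(91)
  genes <- paste0("g", 1:100)
  lk <- structure(list(marker_ids = paste0("m", 1:5), gene_ids = genes,
                       scores = matrix(rexp(500), 5,
                                       dimnames = list(paste0("m", 1:5),
                                                       genes))),
                  class = "linkage_matrix")
  cv <- matrix(rnorm(300), 100, dimnames = list(genes, paste0("s", 1:3)))
  comp <- signature_compendium(cv, stats::setNames(paste0("P", 1:3),
                                                   paste0("s", 1:3)))
  map <- marker_map(paste0("m", 1:5), rep("I", 5), 1:5)
  rel <- compute_rel_matrix(lk, comp, map, min_shared_genes = 50)
  expect_true(all(rel$score >= 0))
  for (m in rel$marker_ids) for (s in rel$signature_ids) {
    hits <- rel$hit_genes[[m, s]]
    if (!length(hits)) next
    mu <- mean(cv[, s])
    if (rel$direction[m, s] == "up") expect_true(all(cv[hits, s] > mu))
    else expect_true(all(cv[hits, s] < mu))
    expect_true(all(lk$scores[m, hits] >= rel$threshold[m, s]))
  }
})

test_that("perturbing the chosen threshold does not flip a planted block", {
  set.seed(19)
  genes <- paste0("g", 1:400)
  scores <- matrix(c(rep(6, 30), abs(rnorm(370, 0, 0.5))), 1,
                   dimnames = list("m1", genes))
  lk <- structure(list(marker_ids = "m1", gene_ids = genes, scores = scores),
                  class = "linkage_matrix")
  sv <- rnorm(400); sv[1:30] <- sv[1:30] + 3
  comp <- signature_compendium(matrix(sv, 400, dimnames = list(genes, "s1")),
                               c(s1 = "P"))
  map <- marker_map("m1", "I", 1)
  rel <- compute_rel_matrix(lk, comp, map, min_shared_genes = 50)
  expect_gt(rel$score["m1", "s1"], 3)
  sens <- threshold_sensitivity(rel, "m1", "s1", lk, comp)
  expect_true(all(sens$rel_score > 3))   # adjacent thresholds stay significant
})
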