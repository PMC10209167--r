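toy_ranking_model <- function(seed = 1) {
  set.seed(seed)
  mat <- matrix(rnorm(12 * 8), 12, 8,
                dimnames = list(c(paste0("g", 1:10), "dis", "word"), NULL))
  toy_embedding(mat, cutoff = 2005L, entities = c(paste0("g", 1:10), "dis"))
}

test_that("genome-wide rankings are sorted, tie-broken and permutation stable", {
  m <- toy_ranking_model()
  r <- rank_genes_for_disease(m, "dis", paste0("g", 1:10))
  expect_equal(r$rank, 1:10)
  expect_true(all(diff(r$score) <= 0))
  r2 <- rank_genes_for_disease(m, "dis", sample(paste0("g", 1:10)))
  expect_equal(r$gene_id, r2$gene_id)
  # universe of one gene: rank 1 regardless of score
  r1 <- rank_genes_for_disease(m, "dis", "g3")
  expect_equal(r1$rank, 1L)
  # out-of-vocabulary genes are excluded with a message
  expect_message(r3 <- rank_genes_for_disease(m, "dis",
                                              c(paste0("g", 1:10), "gX")),
                 "excluded")
  expect_false("gX" %in% r3$gene_id)
  expect_error(rank_genes_for_disease(m, "noDis", "g1"), "noDis")
})

test_that("novel filtering keeps never-co-mentioned genes in rank order", {
  m <- toy_ranking_model()
  r <- rank_genes_for_disease(m, "dis", paste0("g", 1:10))
  cm <- data.frame(gene_id = paste0("g", c(1:7)), disease_id = "dis",
                   first_year = c(rep(2000L, 6), 2010L))
  out <- novel_top_k(r, cm, cutoff_year = 2005, k = 3)
  # oracle: filter then sort
  novel <- setdiff(r$gene_id, paste0("g", 1:6))
  expect_equal(out, r$gene_id[r$gene_id %in% novel][1:3])
  all_cm <- data.frame(gene_id = paste0("g", 1:10), disease_id = "dis",
                       first_year = 2000L)
  expect_warning(res <- novel_top_k(r, all_cm, 2005, k = 5), "only 0")
  expect_length(res, 0L)
  expect_error(novel_top_k(r, cm, 2005, k = 0), "k must be")
})

test_that("prospective precision is cumulative, monotone and exact", {
  cm <- data.frame(gene_id = c("a", "b", "c"), disease_id = "dis",
                   first_year = c(2006L, 2008L, 2009L))
  curve <- prospective_precision(c("a", "b", "c", "d", "e"), cm, "dis",
                                 2005, 4)
  expect_equal(unname(curve), c(1, 1, 2, 3) / 5)
  expect_true(all(diff(curve) >= 0))
  none <- prospective_precision(c("x", "y"), cm, "dis", 2005, 3)
  expect_equal(unname(none), c(0, 0, 0))
  expect_error(prospective_precision(character(0), cm, "dis", 2005, 3),
               "empty")
  expect_error(prospective_precision("a", cm, "dis", 2007, 2), "novel")
})

test_that("bootstrap baseline matches the analytic without-replacement mean", {
  # m of N novel genes eventually reported: mean terminal precision = m/N
  N <- 40; m <- 8
  genes <- paste0("g", 1:N)
  cm <- data.frame(gene_id = genes[1:m], disease_id = "dis",
                   first_year = 2007L)
  bb <- bootstrap_baseline(genes, cm, "dis", 2005, 3, k = 10, B = 4000,
                           seed = 3)
  se <- sd(bb$terminal) / sqrt(bb$B)
  expect_lt(abs(bb$mean[3] - m / N), 3 * se + 1e-12)
  # single-iteration runs are reproducible
  b1 <- bootstrap_baseline(genes, cm, "dis", 2005, 3, k = 10, B = 1, seed = 5)
  b2 <- bootstrap_baseline(genes, cm, "dis", 2005, 3, k = 10, B = 1, seed = 5)
  expect_identical(b1$terminal, b2$terminal)
  expect_error(bootstrap_baseline(genes[1:5], cm, "dis", 2005, 3, k = 10,
                                  B = 10, seed = 1), "smaller than k")
})

test_that("linking words sit close to both pair members", {
  set.seed(21)
  mat <- matrix(rnorm(8 * 6), 8, 6,
                dimnames = list(c("gene", "dis", paste0("w", 1:6)), NULL))
  mat["dis", ] <- mat["gene", ] # identical vectors: degenerate case
  m <- toy_embedding(mat, entities = c("gene", "dis"))
  lw <- contextual_linking_words(m, "gene", "dis", top_n = 3)
  sims <- sort(vapply(paste0("w", 1:6), function(w)
    cooccurrence_likelihood(m, w, "gene"), 0), decreasing = TRUE)
  expect_equal(lw$word, names(sims)[1:3]) # common nearest neighbours
  expect_equal(lw$score, lw$sim_gene)
  expect_false(any(c("gene", "dis") %in% lw$word))
  # min combiner: score is the worse of the two similarities
  mat2 <- mat; mat2["dis", ] <- rnorm(6)
  m2 <- toy_embedding(mat2, entities = c("gene", "dis"))
  lw2 <- contextual_linking_words(m2, "gene", "dis", top_n = 6)
  expect_equal(lw2$score, pmin(lw2$sim_gene, lw2$sim_disease))
})

test_that("clinical-stage scores follow the most advanced phase", {
  expect_equal(chembl_score(c("phase 1", "phase 3")), 0.7)
  expect_equal(chembl_score(character(0)), 0)
  expect_equal(chembl_score("approved"), 1.0)
  expect_equal(chembl_score("2"), 0.2)
  expect_error(chembl_score("phase 7"), "unknown phase")
  # monotone in phase ordering
  scores <- vapply(list("1", c("1", "2"), c("1", "2", "3"),
                        c("1", "2", "3", "approved")), chembl_score, 0)
  expect_true(all(diff(scores) > 0))
})

test_that("quantile z-scoring centres, preserves order and matches qnorm", {
  x <- setNames(c(5, 3, 8, 1, 9, 2, 7, 4, 6, 10) / 10, paste0("g", 1:10))
  z <- zscore_rankings(x)
  expect_equal(mean(z), 0, tolerance = 1e-6)
  expect_equal(order(z), order(x))
  # closed-form oracle: rank -> normal quantile
  expect_equal(unname(z), unname(qnorm((rank(x) - 0.5) / 10)))
  # unscored genes are filled below the minimum scored value
  y <- c(x, gNA1 = NA, gNA2 = NA)
  zy <- zscore_rankings(y, fill_seed = 4)
  expect_true(all(zy[c("gNA1", "gNA2")] < min(zy[names(x)])))
  expect_identical(zy, zscore_rankings(y, fill_seed = 4))
  expect_error(zscore_rankings(setNames(rep(1, 5), paste0("g", 1:5))),
               "identical")
})

test_that("the tuning grid has 60 models and names round-trip", {
  g <- clinical_grid()
  expect_equal(nrow(g), 60L)
  expect_equal(nrow(unique(g[, 1:3])), 60L)
  parsed <- parse_model_name(g$name)
  expect_equal(parsed$hidden_size, g$hidden_size)
  expect_equal(parsed$hidden_layers, g$hidden_layers)
  expect_equal(parsed$dropout, g$dropout)
  expect_equal(format_model_name(100, 2, 0.2), "H100-N2-D0.2")
  expect_error(parse_model_name("X100"), "unparseable")
})

test_that("clinical-score regression learns a linear score map and guards leakage", {
  set.seed(31)
  dim <- 6
  genes <- paste0("g", 1:30)
  diseases <- paste0("d", 1:12)
  ge <- matrix(rnorm(30 * dim), 30, dim, dimnames = list(genes, NULL))
  de <- matrix(rnorm(12 * dim), 12, dim, dimnames = list(diseases, NULL))
  pairs <- expand.grid(target = genes, disease = diseases,
                       stringsAsFactors = FALSE)
  beta <- rnorm(2 * dim, sd = 0.5)
  feats <- cbind(ge[pairs$target, ], de[pairs$disease, ])
  pairs$score <- as.numeric(feats %*% beta)
  split <- list(train = diseases[1:9], test = diseases[10:12])
  small_grid <- clinical_grid()[c(1, 51), ] # one tiny, one wide 1-layer spec
  fit <- fit_clinical_score_regressor(ge, de, pairs, grid = small_grid,
                                      disease_split = split, seed = 2,
                                      epochs = 800, patience = 100,
                                      batch_size = 16)
  expect_gt(fit$r2_test, 0.9)
  expect_equal(nrow(fit$grid_results), 2L)
  expect_error(fit_clinical_score_regressor(
    ge, de, pairs, grid = small_grid,
    disease_split = list(train = diseases, test = diseases[1])),
    "leakage")
})

test_that("per-disease top-k trial precision counts hits exactly", {
  pred <- data.frame(target = rep(paste0("g", 1:4), 2),
                     disease = rep(c("d1", "d2"), each = 4),
                     pred = c(0.9, 0.8, 0.2, 0.1, 0.3, 0.9, 0.8, 0.1))
  hits <- data.frame(target = c("g1", "g3"), disease = c("d1", "d2"))
  out <- topk_trial_precision(pred, hits, k = 2)
  expect_equal(unname(out["d1"]), 0.5) # g1 in top 2
  expect_equal(unname(out["d2"]), 0.5) # g3 in top 2 of d2
  expect_equal(attr(out, "mean"), 0.5)
})
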