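toy_dtset <- function() {
  drug_target_set(data.frame(
    compound = c("c1", "c2", "c2", "c3", "c3", "c3"),
    gene = c("g1", "g1", "g2", "g1", "g2", "g3")))
}

test_that("promiscuous negatives are the cross product minus the positives", {
  dt <- toy_dtset()
  neg <- promiscuous_negatives(dt, n_proteins = 3, n_compounds = 3)
  # brute force: 3 x 3 cross product minus 6 positives = 3
  cross <- expand.grid(compound_id = c("c1", "c2", "c3"),
                       gene_id = c("g1", "g2", "g3"),
                       stringsAsFactors = FALSE)
  pos <- paste(dt$pairs$compound_id, dt$pairs$gene_id)
  oracle <- cross[!(paste(cross$compound_id, cross$gene_id) %in% pos), ]
  expect_equal(nrow(neg), nrow(oracle))
  expect_setequal(paste(neg$compound_id, neg$gene_id),
                  paste(oracle$compound_id, oracle$gene_id))
  # never intersects the positives, for arbitrary inputs
  set.seed(30)
  rnd <- drug_target_set(data.frame(
    compound = sample(paste0("c", 1:8), 60, replace = TRUE),
    gene = sample(paste0("g", 1:10), 60, replace = TRUE)))
  neg2 <- promiscuous_negatives(rnd, 5, 5)
  expect_length(intersect(paste(neg2$compound_id, neg2$gene_id),
                          paste(rnd$pairs$compound_id, rnd$pairs$gene_id)),
                0L)
  # positives covering the whole cross product leave nothing
  full <- drug_target_set(expand.grid(compound = c("a", "b"),
                                      gene = c("x", "y"),
                                      stringsAsFactors = FALSE))
  expect_warning(none <- promiscuous_negatives(full, 2, 2), "no negatives")
  expect_equal(nrow(none), 0L)
  expect_error(promiscuous_negatives(dt, 10, 3), "exceeds available")
})

test_that("the model zoo has 26 members with parseable MLP names", {
  zoo <- compound_model_zoo()
  expect_equal(nrow(zoo), 26L)
  expect_equal(sum(zoo$type == "mlp"), 24L)
  expect_true(all(c("Logistic Regression", "RFC") %in% zoo$name))
  mlp <- zoo[zoo$type == "mlp", ]
  parsed <- parse_model_name(mlp$name)
  expect_equal(parsed$hidden_size, mlp$hidden_size)
  expect_true("H100-N2-D0.2" %in% mlp$name)
})

test_that("the zoo separates planted compound-target structure", {
  set.seed(31)
  n <- 400; dim <- 6
  feats <- matrix(rnorm(n * 2 * dim), n, 2 * dim)
  # separable-with-margin rule using one coordinate of each embedding half
  sc <- feats[, 1] + feats[, dim + 1]
  keep <- abs(sc) > 0.5
  feats <- feats[keep, ]
  labels <- as.integer(sc[keep] > 0)
  n <- nrow(feats)
  split <- rep("train", n)
  split[sample.int(n, 40)] <- "val"
  idx <- which(split == "train")
  split[sample(idx, 70)] <- "test"
  zoo <- compound_model_zoo()
  specs <- zoo[c(1, 2, which(zoo$name == "H100-N2-D0.0")), ]
  fit <- train_compound_target_models(feats, labels, specs = specs,
                                      split = split, seed = 32,
                                      epochs = 300, patience = 20)
  expect_equal(nrow(fit$results), 3L)
  expect_true(all(diff(fit$results$mcc) <= 0)) # ranked by MCC
  expect_gt(min(fit$results$mcc), 0.8) # all non-degenerate models separate
})

test_that("promiscuity strata report per-class metrics that pool exactly", {
  dt <- toy_dtset()
  set.seed(33)
  preds <- data.frame(
    compound_id = rep(c("c1", "c2", "c3"), each = 4),
    gene_id = rep(paste0("g", 1:4), 3),
    label = rep(c(1, 1, 0, 0), 3),
    pred = c(1, 1, 0, 0,  1, 0, 0, 1,  1, 1, 1, 0))
  out <- promiscuity_stratified_metrics(preds, dt)
  expect_setequal(unique(out$stratum), c("1", "2", ">2"))
  # single-compound stratum oracle (c1 has 1 target, predicted perfectly)
  one <- out[out$stratum == "1" & out$class == "pharmacologically_active", ]
  expect_equal(one$precision, 1)
  expect_equal(one$recall, 1)
  # recount oracle per stratum
  for (s in unique(out$stratum)) {
    idx <- dt$target_counts[preds$compound_id]
    idx <- if (s == ">2") idx > 2 else idx == as.integer(s)
    m <- classification_metrics(preds$pred[idx], preds$label[idx])
    got <- out[out$stratum == s & out$class == "pharmacologically_active", ]
    expect_equal(got$precision, unname(m["precision"]))
    expect_equal(got$accuracy, unname(m["accuracy"]))
  }
  # pooled confusion matrix equals the global one
  expect_equal(sum(out$n[out$class == "pharmacologically_active"]),
               nrow(preds))
})

test_that("motif druggability equals the exact hypergeometric tail", {
  # motif present in 5 genes, all drugged; universe 100 with 10 drugged
  universe <- sprintf("g%03d", 1:100)
  drugged <- universe[1:10]
  membership <- data.frame(gene_id = universe[1:5], motif_id = "m1")
  out <- motif_druggability(membership, drugged, universe)
  p_exact <- choose(10, 5) * choose(90, 0) / choose(100, 5)
  expect_equal(out$motifs$p, p_exact, tolerance = 1e-12)
  expect_equal(out$genes$score[out$genes$gene_id == "g001"],
               -log10(p_exact), tolerance = 1e-9)
  # genes without motifs score zero
  expect_equal(out$genes$score[out$genes$gene_id == "g050"], 0)
  # a motif carried by everyone is uninformative
  all_m <- data.frame(gene_id = universe, motif_id = "mAll")
  out2 <- motif_druggability(all_m, drugged, universe)
  expect_equal(out2$motifs$p, 1)
  expect_equal(max(out2$genes$score), 0)
  # relabeling invariance
  relab <- membership; relab$motif_id <- "zz9"
  out3 <- motif_druggability(relab, drugged, universe)
  expect_equal(out3$genes$score, out$genes$score)
  expect_error(motif_druggability(membership, drugged, character(0)),
               "empty gene universe")
})

test_that("compound target rankings are deterministic and find planted targets", {
  set.seed(35)
  dim <- 6
  genes <- sprintf("g%02d", 1:40)
  vec <- matrix(rnorm(41 * dim), 41, dim,
                dimnames = list(c(genes, "cmpd"), NULL))
  vec["g07", ] <- vec["cmpd", ] + rnorm(dim, sd = 0.1) # planted target
  emb <- toy_embedding(vec)
  # classifier: positive when halves align (as the zoo learns)
  feats <- rbind(cbind(vec[genes, ], vec[rep("cmpd", 40), ]))
  labels <- as.integer(rowSums(feats[, 1:dim] * feats[, dim + 1:dim]) >
                         quantile(rowSums(feats[, 1:dim] *
                                            feats[, dim + 1:dim]), 0.8))
  fit <- mlp_fit(feats, labels, hidden = 16, seed = 36, epochs = 150,
                 patience = 15)
  r1 <- rank_targets_for_compound(fit, "cmpd", genes, emb)
  r2 <- rank_targets_for_compound(fit, "cmpd", genes, emb)
  expect_identical(r1, r2)
  expect_lte(r1$rank[r1$gene_id == "g07"], 4L) # top decile of 40
  expect_error(rank_targets_for_compound(fit, "missing", genes, emb),
               "not in model vocabulary")
})

test_that("the variant filter applies all four criteria strictly", {
  v <- data.frame(
    gene = c("GCKR", "CD40", "AEBP1", "ACLY", "EDGE", "LOWP", "ONE", "NOLI",
             "MISS", "SYN"),
    rsid = paste0("rs", 1:10),
    amino_acid_change = c("Glu77Gly", "Ser124Leu", "Ile444Leu", "Arg582Gln",
                          "Ala10Gly", "Gly5Arg", "Arg7Gln", "Lys9Met",
                          "Thr3Ser", "Phe150Phe"),
    beta = -1,
    minus_log10_p = c(20.18, 12.21, 9.589, 14.644, 9, 5, 12, 15, NA, 22),
    n_studies_consistent = c(2, 2, 2, 2, 2, 2, 1, 2, 2, 2),
    likelihood = c(0.8, 0.5, 0.4, 0.6, 0.7, 0.9, 0.8, 0.3, 0.5, 0.9))
  out <- suppressMessages(variant_candidate_filter(v))
  # independent row-wise predicate oracle
  aa <- v$amino_acid_change
  nonsyn <- substr(aa, 1, 3) != substr(aa, nchar(aa) - 2, nchar(aa))
  oracle <- v[!is.na(v$minus_log10_p) & nonsyn & v$minus_log10_p > 9 &
                v$n_studies_consistent >= 2 & v$likelihood > 0.3, ]
  expect_setequal(out$rsid, oracle$rsid)
  expect_true("GCKR" %in% out$gene)             # flagship retained
  expect_false("EDGE" %in% out$gene)            # p exactly 1e-9: strict
  expect_false("SYN" %in% out$gene)             # synonymous change
  expect_false("NOLI" %in% out$gene)            # likelihood at the bound
  expect_equal(out$gene[1], "GCKR")             # sorted by significance
  # likelihoods can be joined from a named vector
  v2 <- v[, setdiff(names(v), "likelihood")]
  lk <- setNames(v$likelihood, v$gene)
  out2 <- suppressMessages(variant_candidate_filter(v2, likelihoods = lk))
  expect_setequal(out2$rsid, out$rsid)
})
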