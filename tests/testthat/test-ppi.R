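random_iset <- function(n_prot = 20, n_pairs = 40, seed = 1,
                        name = "toy", year = 2005L) {
  set.seed(seed)
  prots <- sprintf("P%02d", 1:n_prot)
  a <- sample(prots, n_pairs * 2, replace = TRUE)
  b <- sample(prots, n_pairs * 2, replace = TRUE)
  keep <- a != b
  interaction_set(data.frame(a[keep], b[keep])[1:min(n_pairs, sum(keep)), ],
                  name = name, release_year = year)
}

test_that("pair canonicalisation sorts symbols and rejects self-pairs", {
  expect_equal(canonical_pair("ZNF44", "A1BG"), c("A1BG", "ZNF44"))
  expect_null(canonical_pair("EGFR", "EGFR"))
  p <- canonical_pair("B", "A")
  expect_equal(canonical_pair(p[1], p[2]), p) # idempotent
  expect_error(canonical_pair("", "A"), "empty symbol")
})

test_that("interaction loading deduplicates and drops self-pairs with counts", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ZNF44\tA1BG", "A1BG\tZNF44", "EGFR\tEGFR"), path)
  iset <- suppressMessages(load_interactions(path, "mini", 2005))
  expect_equal(nrow(iset$pairs), 1L)
  expect_equal(iset$pairs$a, "A1BG")
  expect_equal(iset$n_self_dropped, 1L)
  expect_equal(iset$n_dup_dropped, 1L)
  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_error(load_interactions(empty), "empty")
})

test_that("sticky negatives exclude known positives but keep sticky non-pairs", {
  # a hub structure: DVL2 and TRAF2 interact (positive), NIF3L1 is sticky
  # but unconnected to DVL2
  hubs <- c("DVL2", "TRAF2", "NIF3L1")
  others <- sprintf("X%02d", 1:27)
  pairs <- rbind(
    data.frame(a = "DVL2", b = others[1:10]),
    data.frame(a = "TRAF2", b = others[1:12]),
    data.frame(a = "NIF3L1", b = others[1:9]),
    data.frame(a = "DVL2", b = "TRAF2"))
  iset <- interaction_set(pairs, "hub", 2005)
  # 15 proteins in total; the top 20% by degree are the three hubs
  neg <- sticky_negatives(iset, fraction = 0.2)
  expect_setequal(attr(neg, "sticky"), hubs)
  keys <- paste(neg$a, neg$b)
  expect_false("DVL2 TRAF2" %in% keys)   # in the positive set
  expect_true("DVL2 NIF3L1" %in% keys)   # sticky pair, never positive
  # complete graph on the sticky proteins leaves nothing
  expect_equal(nrow(suppressMessages(sticky_negatives(
    interaction_set(rbind(iset$pairs,
                          data.frame(a = "DVL2", b = "NIF3L1"),
                          data.frame(a = "NIF3L1", b = "TRAF2")), "full"),
    fraction = 0.2))), 0L)
  expect_error(sticky_negatives(interaction_set(
    data.frame(a = "A", b = "B"), "tiny"), fraction = 0.1),
    "fewer than 2")
})

test_that("the protein-level split isolates test proteins completely", {
  iset <- random_iset(seed = 2)
  sp <- protein_level_split(iset$pairs, seed = 3)
  test_prots <- sp$proteins$test
  touches_test <- iset$pairs$a %in% test_prots | iset$pairs$b %in% test_prots
  expect_true(all(sp$split[touches_test] == "test"))
  expect_false(any(sp$split[!touches_test] == "test"))
  # oracle recount of the test pair total
  expect_equal(sum(sp$split == "test"), sum(touches_test))
  sp2 <- protein_level_split(iset$pairs, seed = 3)
  expect_identical(sp$split, sp2$split)
  expect_error(protein_level_split(data.frame(a = c("A", "B"),
                                              b = c("B", "C"))),
               "at least 8")
})

test_that("pair datasets carry 2 x dim features and drop OOV proteins", {
  set.seed(4)
  prots <- sprintf("P%02d", 1:20)
  vec <- matrix(rnorm(19 * 6), 19, 6, dimnames = list(prots[-20], NULL))
  emb <- toy_embedding(vec, cutoff = 2005L)
  iset <- random_iset(seed = 5)
  neg <- sticky_negatives(iset, fraction = 0.35)
  expect_message(ds <- build_pair_dataset(iset, neg, emb, seed = 2),
                 "out-of-vocabulary")
  expect_equal(ncol(ds$features), 12L)
  expect_false("P20" %in% c(ds$pairs$a, ds$pairs$b))
  expect_equal(nrow(ds$features), nrow(ds$pairs))
})

test_that("grid training finds a separating model and scores symmetrically", {
  set.seed(6)
  prots <- sprintf("P%02d", 1:24)
  # embeddings encode two modules; within-module pairs interact
  module <- rep(0:1, each = 12)
  vec <- matrix(rnorm(24 * 8, sd = 0.3), 24, 8,
                dimnames = list(prots, NULL))
  vec[, 1] <- vec[, 1] + 2 * module
  emb <- toy_embedding(vec, cutoff = 2005L)
  cmb <- t(combn(prots, 2))
  same <- module[match(cmb[, 1], prots)] == module[match(cmb[, 2], prots)]
  pos <- interaction_set(data.frame(cmb[same, ]), "mod", 2005)
  neg <- data.frame(a = cmb[!same, 1], b = cmb[!same, 2])[1:80, ]
  ds <- build_pair_dataset(pos, neg, emb, seed = 7)
  grid <- ppi_grid()[c(10, 52), ]
  fit <- train_ppi_grid(ds, grid = grid, seed = 8)
  expect_gt(max(fit$results$mcc), 0.95)
  s1 <- score_pairs(fit$best_model, emb, data.frame(a = "P01", b = "P05"))
  s2 <- score_pairs(fit$best_model, emb, data.frame(a = "P05", b = "P01"))
  expect_identical(s1, s2)
  expect_equal(nrow(ppi_grid()), 60L)
})

test_that("upset cells are exclusive, exhaustive and match inclusion-exclusion", {
  s1 <- random_iset(seed = 11, name = "r1")
  s2 <- random_iset(seed = 12, name = "r2")
  s3 <- random_iset(seed = 13, name = "r3")
  u <- upset_counts(list(s1, s2, s3))
  expect_equal(sum(u$count), attr(u, "union_size"))
  # per-pair membership signature oracle
  keys <- lapply(list(s1, s2, s3), function(s) paste(s$pairs$a, s$pairs$b))
  all_keys <- unique(unlist(keys))
  sig <- sapply(all_keys, function(k)
    paste(as.integer(vapply(keys, function(x) k %in% x, TRUE)),
          collapse = ""))
  oracle <- table(sig)
  for (i in seq_len(nrow(u))) {
    s <- paste(as.integer(unlist(u[i, c("r1", "r2", "r3")])), collapse = "")
    expected <- if (s %in% names(oracle)) as.integer(oracle[[s]]) else 0L
    expect_equal(u$count[i], expected)
  }
  # two identical sets: a single non-zero cell
  s2b <- interaction_set(s1$pairs, name = "copy")
  u2 <- upset_counts(list(s1, s2b))
  expect_equal(sum(u2$count > 0), 1L)
  expect_equal(u2$count[u2$r1 & u2$copy], nrow(s1$pairs))
  expect_error(upset_counts(list(s1)), "at least 2")
})

test_that("era-matched PU evaluation has no future positives and exact FP counts", {
  set.seed(20)
  prots <- sprintf("P%02d", 1:24)
  vec <- matrix(rnorm(24 * 6), 24, 6, dimnames = list(prots, NULL))
  emb <- toy_embedding(vec, cutoff = 2005L)
  r1 <- random_iset(n_prot = 24, n_pairs = 30, seed = 21, name = "r1",
                    year = 2005L)
  extra <- data.frame(a = "P01", b = sprintf("P%02d", 10:15))
  r2 <- interaction_set(rbind(r1$pairs, extra), "r2", 2014L)
  neg <- sticky_negatives(r1, fraction = 0.2)
  ds <- build_pair_dataset(r1, neg, emb, seed = 22)
  fit <- train_ppi_grid(ds, grid = ppi_grid()[10, ], seed = 23, epochs = 30)
  pu <- prospective_ppi_eval(
    list("2005" = list(classifier = fit$best_model, embeddings = emb)),
    list("2005" = r1, "2014" = r2))
  own <- pu[pu$dataset_era == 2005, ]
  expect_equal(own$n_future_positives, 0L)
  # confusion-matrix oracle recount for the era-matched row
  pool <- unique(rbind(r2$pairs, neg[, c("a", "b")]))
  sc <- score_pairs(fit$best_model, emb, pool)
  lab <- paste(pool$a, pool$b) %in% paste(r1$pairs$a, r1$pairs$b)
  expect_equal(own$fp, sum(sc >= 0.5 & !lab))
  expect_equal(own$tp, sum(sc >= 0.5 & lab))
  # FP counts never increase across releases for a fixed model
  fps <- pu$fp[order(pu$dataset_era)]
  expect_true(all(diff(fps) <= 0))
  bad_emb <- toy_embedding(vec, cutoff = 2014L)
  expect_error(prospective_ppi_eval(
    list("2005" = list(classifier = fit$best_model, embeddings = bad_emb)),
    list("2005" = r1, "2014" = r2)), "era mismatch")
})
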