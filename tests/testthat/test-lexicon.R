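test_that("lexicon loading canonicalises synonym groups and counts ids", {
  path <- write_lexicon_tsv(data.frame(s = c("Her2", "ERBB2", "Neu"),
                                       id = "G1"))
  lex <- load_lexicon(path, "gene")
  expect_length(lex$entries, 3L)
  expect_equal(lex$id_universe, "G1")

  # 10 synonyms over 4 ids: id universe size by direct enumeration
  rows <- data.frame(s = paste0("syn", 1:10),
                     id = paste0("G", c(1, 1, 1, 2, 2, 3, 3, 3, 4, 4)))
  lex2 <- load_lexicon(write_lexicon_tsv(rows), "gene")
  expect_length(lex2$entries, 10L)
  expect_equal(length(lex2$id_universe), length(unique(rows$id)))
})

test_that("ambiguous synonyms are dropped; fully ambiguous lexicon errors", {
  path <- write_lexicon_tsv(data.frame(s = c("abc", "abc"),
                                       id = c("G1", "G2")))
  expect_error(suppressMessages(load_lexicon(path, "gene")),
               "empty lexicon after ambiguity")
  path2 <- write_lexicon_tsv(data.frame(s = c("abc", "abc", "def"),
                                        id = c("G1", "G2", "G3")))
  lex <- suppressMessages(load_lexicon(path2, "gene"))
  expect_named(lex$entries, "def")
  expect_error(load_lexicon(tempfile(), "gene"), "not found")
})

test_that("tagging replaces synonyms with canonical ids and fills id sets", {
  genes <- load_lexicon(write_lexicon_tsv(
    data.frame(s = c("Her2", "ERBB2"), id = "g1")), "gene")
  diseases <- load_lexicon(write_lexicon_tsv(
    data.frame(s = "breast cancer", id = "d_breast")), "disease")
  doc <- list(doc_id = "x", year = 2001,
              title = "Her2 is amplified in breast cancer", abstract = "")
  td <- tag_and_canonicalise(doc, genes, diseases)
  expect_equal(td$tokens, c("g1", "is", "amplified", "in", "d_breast"))
  expect_equal(td$gene_ids, "g1")
  expect_equal(td$disease_ids, "d_breast")

  # no synonyms: tokens unchanged, empty id sets
  doc2 <- list(doc_id = "y", year = 2001, title = "plain words only",
               abstract = "")
  td2 <- tag_and_canonicalise(doc2, genes, diseases)
  expect_equal(td2$tokens, c("plain", "words", "only"))
  expect_length(td2$gene_ids, 0L)

  # missing year is a logged rejection, not an error
  expect_message(out <- tag_and_canonicalise(list(doc_id = "z", title = "t"),
                                             genes, diseases),
                 "missing year")
  expect_null(out)
})

test_that("nested synonyms resolve to the longest match, maximising coverage", {
  diseases <- load_lexicon(write_lexicon_tsv(data.frame(
    s = c("non small cell lung carcinoma", "lung carcinoma"),
    id = c("d_nsclc", "d_lc"))), "disease")
  doc <- list(doc_id = "x", year = 2000,
              title = "therapy of non-small cell lung carcinoma patients",
              abstract = "")
  td <- tag_and_canonicalise(doc, diseases = diseases)
  expect_true("d_nsclc" %in% td$tokens)
  expect_false("d_lc" %in% td$tokens)

  # brute-force oracle: over all non-overlapping synonym tilings of the
  # token stream, the maximum number of covered tokens matches the tagger
  tokens <- clean_text(doc$title)
  syns <- strsplit(names(diseases$entries), " ", fixed = TRUE)
  spans <- do.call(rbind, lapply(syns, function(s) {
    hits <- which(vapply(seq_len(length(tokens) - length(s) + 1L), function(i)
      all(tokens[i:(i + length(s) - 1L)] == s), TRUE))
    if (!length(hits)) return(NULL)
    data.frame(start = hits, end = hits + length(s) - 1L)
  }))
  best <- 0L
  for (pick in seq_len(2^nrow(spans)) - 1L) {
    sel <- spans[bitwAnd(pick, 2^(seq_len(nrow(spans)) - 1L)) > 0L, ,
                 drop = FALSE]
    ok <- TRUE
    if (nrow(sel) > 1L)
      for (i in seq_len(nrow(sel) - 1L))
        for (j in (i + 1L):nrow(sel))
          if (sel$start[i] <= sel$end[j] && sel$start[j] <= sel$end[i])
            ok <- FALSE
    if (ok) best <- max(best, sum(sel$end - sel$start + 1L))
  }
  covered <- length(tokens) - (length(td$tokens) -
                                 sum(td$tokens %in% diseases$id_universe))
  expect_equal(covered, best)
})

test_that("tagging is idempotent and never inflates id counts", {
  genes <- load_lexicon(write_lexicon_tsv(
    data.frame(s = c("her2", "erbb2", "kras"), id = c("g1", "g1", "g2"))),
    "gene")
  lex <- list(gene = genes$entries)
  tokens <- clean_text("her2 and kras signalling in erbb2 positive tumours")
  once <- pwas:::tag_tokens(tokens, lex)
  twice <- pwas:::tag_tokens(once$tokens, lex)
  expect_identical(once$tokens, twice$tokens)
  expect_identical(once$ids$gene, twice$ids$gene)
  expect_lte(length(once$ids$gene), length(once$synonyms$gene))
})

test_that("mention reduction statistics match an independent recount", {
  genes <- load_lexicon(write_lexicon_tsv(
    data.frame(s = c("her2", "erbb2", "neu"), id = "g1")), "gene")
  raw <- list(
    list(doc_id = "a", year = 2000, title = "her2 and neu in cancer"),
    list(doc_id = "b", year = 2001, title = "erbb2 amplification and her2"))
  corpus <- tag_corpus(raw, genes = genes)
  st <- mention_reduction_stats(corpus, genes)
  expect_equal(st$n_distinct_synonyms, 3L)
  expect_equal(st$n_distinct_ids, 1L)
  expect_equal(st$fold_reduction, 3.0)

  # independent oracle for single-token synonyms: set intersection of the
  # cleaned raw text with the lexicon keys
  seen <- unique(unlist(lapply(raw, function(d) clean_text(d$title))))
  expect_equal(st$n_distinct_synonyms,
               length(intersect(seen, names(genes$entries))))
  expect_error(mention_reduction_stats(make_corpus(), genes), "empty corpus")
})
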