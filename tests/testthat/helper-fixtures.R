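# Shared fixture builders; everything is generated in code at test time.

make_doc <- function(id, year, tokens, genes = character(0),
                     diseases = character(0)) {
  structure(list(doc_id = id, year = as.integer(year), tokens = tokens,
                 gene_ids = genes, disease_ids = diseases,
                 gene_synonyms = genes, disease_synonyms = diseases),
            class = "pwas_doc")
}

make_corpus <- function(...) structure(list(...), class = "pwas_corpus")

# embedding model wrapped around an explicit vector matrix
toy_embedding <- function(mat, cutoff = NA_integer_,
                          entities = character(0)) {
  structure(list(vectors = mat, norms = sqrt(rowSums(mat^2)),
                 cutoff_year = cutoff, hyperparams = NULL,
                 vocab_counts = NULL, entity_tokens = entities),
            class = "pwas_embedding")
}

write_lexicon_tsv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}

# tiny training corpus: two topic blocks that never co-occur
two_block_corpus <- function(n_docs = 120, seed = 5) {
  set.seed(seed)
  blocks <- list(paste0("a", 1:6), paste0("b", 1:6))
  docs <- lapply(seq_len(n_docs), function(i) {
    blk <- blocks[[(i %% 2) + 1]]
    make_doc(paste0("d", i), 2000,
             sample(c(sample(blk, 8, replace = TRUE),
                      sample(paste0("bg", 1:20), 8, replace = TRUE))))
  })
  structure(docs, class = "pwas_corpus")
}

fast_hp <- function(dim = 16L, epochs = 15L, seed = 1L, ...) {
  embedding_hyperparams(dim = dim, epochs = epochs, seed = seed, ...)
}
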