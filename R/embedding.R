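#' Embedding training hyperparameters
#'
#' Defaults mirror the production configuration for literature models: CBOW,
#' 256 dimensions, window 10 (the median gene-disease token distance in
#' abstracts), 50 epochs with the learning rate decayed linearly from 0.01
#' to 0.0001, frequent-token subsampling at 1e-4 and 5 negative samples.
#'
#' @param task `"cbow"` or `"sg"` (skip-gram).
#' @param dim embedding dimension (grid values 128/256/512 at paper scale).
#' @param window one-sided context window in tokens (grid 5/10/15).
#' @param epochs training epochs.
#' @param lr_start,lr_end linear learning-rate decay endpoints.
#' @param subsample frequent-word subsampling threshold.
#' @param negative number of negative samples per target.
#' @param seed integer seed; training is single-threaded and bit-reproducible
#'   given the seed.
#' @return a `pwas_hyperparams` list.
#' @export
embedding_hyperparams <- function(task = c("cbow", "sg"), dim = 256L,
                                  window = 10L, epochs = 50L,
                                  lr_start = 0.01, lr_end = 1e-4,
                                  subsample = 1e-4, negative = 5L,
                                  seed = 1L) {
  task <- match.arg(task)
  stopifnot(dim > 0, window > 0, lr_start > lr_end, lr_end > 0, epochs >= 1)
  structure(list(task = task, dim = as.integer(dim), window = as.integer(window),
                 epochs = as.integer(epochs), lr_start = lr_start,
                 lr_end = lr_end, subsample = subsample,
                 negative = as.integer(negative), seed = as.integer(seed)),
            class = "pwas_hyperparams")
}

#' Train an embedding model on a corpus slice
#'
#' CBOW (or skip-gram) with negative sampling over the slice's documents,
#' restricted to the supplied vocabulary. Out-of-vocabulary tokens are
#' dropped from the training stream. Training is deterministic for a given
#' seed (single worker).
#'
#' @param slice a `pwas_slice` (or plain list of tagged documents).
#' @param vocab a [build_vocabulary()] result.
#' @param hp an [embedding_hyperparams()] configuration.
#' @return a `pwas_embedding`: token-by-dimension matrix plus metadata
#'   (`cutoff_year`, `hyperparams`, `entity_tokens`).
#' @export
train_embeddings <- function(slice, vocab, hp = embedding_hyperparams()) {
  docs <- if (inherits(slice, "pwas_slice")) slice$documents else slice
  cutoff <- if (inherits(slice, "pwas_slice")) slice$cutoff_year else NA_integer_
  if (length(vocab$counts) == 0L) stop("empty vocabulary")
  tokens <- names(vocab$counts)
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_along(tokens)) assign(tokens[i], i, envir = idx)
  sentences <- lapply(docs, function(d) {
    m <- match(d$tokens, tokens)
    as.integer(m[!is.na(m)] - 1L) # 0-based for C++
  })
  sentences <- sentences[vapply(sentences, length, 0L) > 0L]
  if (length(sentences) == 0L) stop("no in-vocabulary tokens in slice")
  vec <- w2v_train_cpp(sentences, as.numeric(vocab$counts), hp$dim, hp$window,
                       hp$epochs, hp$lr_start, hp$lr_end, hp$subsample,
                       hp$negative, hp$task == "cbow", hp$seed)
  rownames(vec) <- tokens
  stopifnot(all(is.finite(vec)))
  structure(list(vectors = vec,
                 norms = sqrt(rowSums(vec^2)),
                 cutoff_year = cutoff,
                 hyperparams = hp,
                 vocab_counts = vocab$counts,
                 entity_tokens = vocab$protected),
            class = "pwas_embedding")
}

#' @export
print.pwas_embedding <- function(x, ...) {
  cat("<pwas_embedding> cutoff", x$cutoff_year, "-", nrow(x$vectors),
      "tokens x", ncol(x$vectors), "dims (", x$hyperparams$task, ")\n")
  invisible(x)
}

#' Train one model per historical cut-off year
#'
#' Each yearly model is trained independently from scratch on the slice of
#' documents up to 31 December of its year (checkpoint-per-December
#' convention); vocabularies are rebuilt per slice, so they grow with the
#' cut-off.
#'
#' @param corpus a `pwas_corpus`.
#' @param years ascending cut-off years.
#' @param hp an [embedding_hyperparams()].
#' @param protected canonical identifier tokens (see [build_vocabulary()]).
#' @param min_count vocabulary frequency floor.
#' @return named list, `year -> pwas_embedding`.
#' @export
checkpoint_series <- function(corpus, years, hp = embedding_hyperparams(),
                              protected = character(0), min_count = 10L) {
  if (is.unsorted(years)) stop("years must be ascending")
  slices <- slice_corpus(corpus, years)
  models <- lapply(slices, function(s) {
    vocab <- build_vocabulary(s, protected = protected, min_count = min_count)
    train_embeddings(s, vocab, hp)
  })
  names(models) <- as.character(years)
  models
}

model_vector <- function(model, token) {
  i <- match(token, rownames(model$vectors))
  if (is.na(i)) stop("token not in model vocabulary: ", token)
  model$vectors[i, ]
}

#' Co-occurrence likelihood of two tokens
#'
#' The likelihood an embedding model assigns to a pair of words or phrases
#' co-occurring, usable even for pairs never seen together: implemented as
#' the cosine similarity of their vectors, so it is symmetric and bounded in
#' \[-1, 1\].
#'
#' @param model a `pwas_embedding`.
#' @param token_a,token_b vocabulary tokens.
#' @return cosine similarity.
#' @export
cooccurrence_likelihood <- function(model, token_a, token_b) {
  va <- model_vector(model, token_a)
  vb <- model_vector(model, token_b)
  sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
}

# cosine similarity of one token against all rows; returns named vector
similarity_to_all <- function(model, token) {
  v <- model_vector(model, token)
  sims <- as.numeric(model$vectors %*% v) / (model$norms * sqrt(sum(v^2)))
  names(sims) <- rownames(model$vectors)
  sims
}

#' Analogy rank
#'
#' For an analogy "a is to b as c is to answer", ranks every vocabulary
#' token (excluding a, b, c) by cosine similarity to the offset vector
#' `vector(b) - vector(a) + vector(c)` and returns the 1-based rank of
#' `answer`. Rank 1 means the model's top candidate is the answer.
#'
#' @param model a `pwas_embedding`.
#' @param a,b,c,answer vocabulary tokens.
#' @return positive integer rank.
#' @export
analogy_rank <- function(model, a, b, c, answer) {
  q <- model_vector(model, b) - model_vector(model, a) + model_vector(model, c)
  qn <- sqrt(sum(q^2))
  if (qn == 0) stop("degenerate analogy query (zero vector)")
  sims <- as.numeric(model$vectors %*% q) / (model$norms * qn)
  names(sims) <- rownames(model$vectors)
  sims <- sims[!(names(sims) %in% c(a, b, c))]
  if (!(answer %in% names(sims))) stop("token not in model vocabulary: ", answer)
  ord <- order(-sims, names(sims))
  which(names(sims)[ord] == answer)
}

#' Write / read embeddings in word2vec text format
#'
#' Header line "V dim", then one line per token with space-separated values.
#'
#' @param model a `pwas_embedding`.
#' @param path output path.
#' @return `path` invisibly / a `pwas_embedding` (metadata-less on read).
#' @export
write_word2vec <- function(model, path) {
  vec <- model$vectors
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(vec), ncol(vec)), con)
  lines <- vapply(seq_len(nrow(vec)), function(i)
    paste(rownames(vec)[i], paste(format(vec[i, ], digits = 17, trim = TRUE,
                                         scientific = TRUE),
                                  collapse = " ")), "")
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_word2vec
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  body <- strsplit(lines[-1], " ", fixed = TRUE)
  stopifnot(length(body) == hdr[1])
  toks <- vapply(body, `[`, "", 1L)
  vec <- t(vapply(body, function(x) as.numeric(x[-1L]), numeric(hdr[2])))
  rownames(vec) <- toks
  structure(list(vectors = vec, norms = sqrt(rowSums(vec^2)),
                 cutoff_year = NA_integer_, hyperparams = NULL,
                 vocab_counts = NULL, entity_tokens = character(0)),
            class = "pwas_embedding")
}
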