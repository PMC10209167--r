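#' Train a clinical-target classifier from gene embeddings
#'
#' Single-hidden-layer feed-forward classifier with a class-balanced loss,
#' the Adam optimiser and patience-2 early stopping, predicting whether a
#' gene is a clinical-stage target (in an active trial, approved, or the
#' composite of both) from its embedding alone. Genes are split 80/20 into
#' train and test; the same gene never appears on both sides.
#'
#' @param embeddings matrix of gene embeddings (row names = gene ids).
#' @param labels named logical/0-1 vector over (a subset of) the rows.
#' @param label_kind free-text tag stored with the classifier
#'   (e.g. "in_trial", "approved", "composite").
#' @param hidden hidden-layer size (default 100).
#' @param test_fraction held-out gene fraction (default 0.2).
#' @param seed RNG seed.
#' @param epochs,lr,batch_size training controls.
#' @return list: `model`, `test` (gene, label, prob, pred), `metrics`,
#'   `label_kind`.
#' @export
train_target_classifier <- function(embeddings, labels, label_kind = "target",
                                    hidden = 100L, test_fraction = 0.2,
                                    seed = 1L, epochs = 100L, lr = 0.01,
                                    batch_size = 16L) {
  genes <- intersect(rownames(embeddings), names(labels))
  if (length(genes) < 10L) stop("too few labelled genes in the embedding")
  y <- as.numeric(labels[genes])
  if (length(unique(y)) < 2L) stop("labels are single-class")
  x <- embeddings[genes, , drop = FALSE]
  n <- length(genes)
  test_idx <- with_seed(seed, sample.int(n, max(1L, round(test_fraction * n))))
  stopifnot(length(intersect(genes[test_idx], genes[-test_idx])) == 0L)
  fit <- mlp_fit(x[-test_idx, , drop = FALSE], y[-test_idx],
                 hidden = hidden, task = "classification", balanced = TRUE,
                 epochs = epochs, lr = lr, batch_size = batch_size,
                 seed = seed)
  prob <- predict(fit, x[test_idx, , drop = FALSE])
  test <- data.frame(gene = genes[test_idx], label = y[test_idx],
                     prob = prob, pred = as.integer(prob >= 0.5),
                     stringsAsFactors = FALSE)
  list(model = fit, test = test,
       metrics = classification_metrics(test$pred, test$label),
       label_kind = label_kind)
}

#' Bootstrap confidence intervals for classification metrics
#'
#' Resamples the test set `B` times, each resample balanced (equal numbers
#' of positives and negatives drawn with replacement), and reports the mean
#' and the empirical 5th/95th percentiles of accuracy, F1, precision and
#' recall.
#'
#' @param test data.frame with columns `label` and `pred` (as produced by
#'   [train_target_classifier()]).
#' @param B bootstrap iterations (default 100).
#' @param seed RNG seed.
#' @return data.frame (metric, point, lo, hi).
#' @export
bootstrap_metrics <- function(test, B = 100L, seed = 1L) {
  if (B < 2L) stop("B must be >= 2")
  pos <- which(test$label == 1)
  neg <- which(test$label == 0)
  if (!length(pos) || !length(neg)) stop("test set must contain both classes")
  m <- min(length(pos), length(neg))
  mets <- c("accuracy", "f1", "precision", "recall")
  draws <- with_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      idx <- c(sample(pos, m, replace = TRUE), sample(neg, m, replace = TRUE))
      classification_metrics(test$pred[idx], test$label[idx])[mets]
    }, setNames(numeric(4), mets)))
  })
  data.frame(metric = mets,
             point = colMeans(draws, na.rm = TRUE),
             lo = apply(draws, 2L, quantile, 0.05, na.rm = TRUE, names = FALSE),
             hi = apply(draws, 2L, quantile, 0.95, na.rm = TRUE, names = FALSE),
             row.names = NULL)
}

#' Multi-task tractability classifier
#'
#' A shared-input, two-output logistic model (a single linear layer with two
#' sigmoid outputs, trained jointly with a balanced loss) that estimates,
#' from a gene's embedding, the probability that the target is tractable by
#' small molecules (SM) and by monoclonal antibodies (AB).
#'
#' @param embeddings matrix of gene embeddings (row names = gene ids).
#' @param sm_labels,ab_labels named 0/1 vectors over the same gene universe.
#' @param seed RNG seed.
#' @param epochs,lr training controls.
#' @return list: `model` and `probs`, a data.frame (gene, p_sm, p_ab).
#' @export
tractability_multitask <- function(embeddings, sm_labels, ab_labels,
                                   seed = 1L, epochs = 200L, lr = 0.05) {
  if (!setequal(names(sm_labels), names(ab_labels)))
    stop("SM and AB label universes differ")
  genes <- intersect(rownames(embeddings), names(sm_labels))
  x <- embeddings[genes, , drop = FALSE]
  y <- cbind(sm = as.numeric(sm_labels[genes]),
             ab = as.numeric(ab_labels[genes]))
  fit <- mlp_fit(x, y, hidden = integer(0), task = "classification",
                 balanced = TRUE, epochs = epochs, lr = lr, seed = seed)
  p <- predict(fit, x)
  list(model = fit,
       probs = data.frame(gene = genes, p_sm = p[, 1L], p_ab = p[, 2L],
                          stringsAsFactors = FALSE))
}

# mean pairwise cosine distance within a set of row vectors
mean_cosine_distance <- function(vec) {
  v <- vec / sqrt(rowSums(vec^2))
  s <- tcrossprod(v)
  n <- nrow(v)
  d <- 1 - s[upper.tri(s)]
  mean(d)
}

pairwise_cosine_distances <- function(vec) {
  v <- vec / sqrt(rowSums(vec^2))
  s <- tcrossprod(v)
  1 - s[upper.tri(s)]
}

#' Gene-family coherence in embedding space
#'
#' Compares intra-family pairwise cosine distances (1 - cosine similarity)
#' against the all-gene background, with a two-sided Welch t-test and a
#' Mann-Whitney U test per family, plus the mean silhouette width of the
#' family labelling under cosine distance. When the universe exceeds
#' `max_exact` genes the background is a seeded subsample of
#' `n_background_pairs` random pairs. All statistics are invariant to
#' uniform scaling of the vectors.
#'
#' @param model a `pwas_embedding` or a plain embedding matrix.
#' @param family_assignments named character vector, gene id -> family.
#' @param max_exact use exact all-pairs background up to this universe size.
#' @param n_background_pairs subsample size above `max_exact`.
#' @param seed RNG seed for the subsample.
#' @return list: `families` data.frame (family, n, mean_intra_distance,
#'   t_p, mw_p), `background_mean_distance`, `silhouette`.
#' @export
family_cluster_stats <- function(model, family_assignments,
                                 max_exact = 2000L,
                                 n_background_pairs = 1e5L, seed = 1L) {
  vec <- if (inherits(model, "pwas_embedding")) model$vectors else model
  genes <- intersect(names(family_assignments), rownames(vec))
  fam <- family_assignments[genes]
  n_by_fam <- table(fam)
  if (any(n_by_fam < 2L))
    stop("family with < 2 in-vocabulary members: ",
         paste(names(n_by_fam)[n_by_fam < 2L], collapse = ", "))
  # background: all genes in the matrix, not only family members
  if (nrow(vec) <= max_exact) {
    bg <- pairwise_cosine_distances(vec)
  } else {
    bg <- with_seed(seed, {
      i <- sample.int(nrow(vec), n_background_pairs, replace = TRUE)
      j <- sample.int(nrow(vec), n_background_pairs, replace = TRUE)
      ok <- i != j
      v <- vec / sqrt(rowSums(vec^2))
      1 - rowSums(v[i[ok], , drop = FALSE] * v[j[ok], , drop = FALSE])
    })
  }
  fams <- sort(unique(fam))
  rows <- lapply(fams, function(f) {
    d <- pairwise_cosine_distances(vec[genes[fam == f], , drop = FALSE])
    data.frame(family = f, n = sum(fam == f),
               mean_intra_distance = mean(d),
               t_p = t.test(d, bg)$p.value,
               mw_p = wilcox.test(d, bg, exact = FALSE)$p.value,
               stringsAsFactors = FALSE)
  })
  # silhouette of the family labelling under cosine distance
  v <- vec[genes, , drop = FALSE]
  v <- v / sqrt(rowSums(v^2))
  dmat <- 1 - tcrossprod(v)
  sil <- if (length(fams) > 1L) {
    s <- cluster::silhouette(as.integer(factor(fam)), dmatrix = dmat)
    mean(s[, "sil_width"])
  } else NA_real_ # silhouette undefined for a single family
  list(families = do.call(rbind, rows),
       background_mean_distance = mean(bg),
       silhouette = sil)
}
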