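#' First co-mention index of a tagged corpus
#'
#' Novelty is abstract-level: a gene and a disease are co-mentioned when
#' their canonical identifiers appear in the same document; "first reported"
#' is the earliest such document year.
#'
#' @param corpus a `pwas_corpus` of tagged documents.
#' @return data.frame (gene_id, disease_id, first_year), one row per
#'   ever-co-mentioned pair.
#' @export
comention_index <- function(corpus) {
  rows <- lapply(corpus, function(d) {
    if (length(d$gene_ids) == 0L || length(d$disease_ids) == 0L) return(NULL)
    expand.grid(gene_id = d$gene_ids, disease_id = d$disease_ids,
                year = d$year, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(gene_id = character(0), disease_id = character(0),
                      first_year = integer(0)))
  key <- paste(rows$gene_id, rows$disease_id, sep = "\x01")
  first <- tapply(rows$year, key, min)
  parts <- strsplit(names(first), "\x01", fixed = TRUE)
  out <- data.frame(gene_id = vapply(parts, `[`, "", 1L),
                    disease_id = vapply(parts, `[`, "", 2L),
                    first_year = as.integer(first),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene_id, out$disease_id), , drop = FALSE]
}

# vectorized first co-mention year lookup (NA when never co-mentioned)
first_comention_year <- function(comentions, gene_ids, disease_id) {
  key <- paste(gene_ids, disease_id, sep = "\x01")
  idx <- match(key, paste(comentions$gene_id, comentions$disease_id,
                          sep = "\x01"))
  comentions$first_year[idx]
}

#' Genome-wide gene ranking for a disease
#'
#' Scores every in-vocabulary gene of the universe by its co-occurrence
#' likelihood (cosine similarity) with the disease token and sorts in
#' decreasing order; ties are broken by gene identifier. Genes absent from
#' the model vocabulary (never mentioned before the cut-off) are excluded
#' with a message.
#'
#' @param model a `pwas_embedding`.
#' @param disease_id canonical disease token (must be in the vocabulary).
#' @param gene_universe character vector of canonical gene ids.
#' @return a `pwas_ranking` data.frame (gene_id, score, rank) with
#'   attributes `disease_id`, `model_year`, `universe_size`.
#' @export
rank_genes_for_disease <- function(model, disease_id, gene_universe) {
  sims <- similarity_to_all(model, disease_id)
  in_vocab <- gene_universe[gene_universe %in% names(sims)]
  n_out <- length(gene_universe) - length(in_vocab)
  if (n_out > 0)
    message(n_out, " gene(s) absent from the ", model$cutoff_year,
            " model vocabulary were excluded from the ranking")
  if (length(in_vocab) == 0L) stop("no universe gene is in the vocabulary")
  s <- sims[in_vocab]
  ord <- order(-s, names(s))
  out <- data.frame(gene_id = names(s)[ord], score = unname(s[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "disease_id") <- disease_id
  attr(out, "model_year") <- model$cutoff_year
  attr(out, "universe_size") <- length(gene_universe)
  class(out) <- c("pwas_ranking", "data.frame")
  out
}

#' Top novel predictions from a ranking
#'
#' Filters a genome-wide ranking to genes never co-mentioned with the
#' ranking's disease at or before the cut-off year, and returns the first
#' `k` in rank order (fewer, with a warning, when the novel pool is small).
#'
#' @param ranking a `pwas_ranking`.
#' @param comentions a [comention_index()] table.
#' @param cutoff_year model cut-off year.
#' @param k number of predictions (default 50).
#' @return character vector of gene ids in rank order.
#' @export
novel_top_k <- function(ranking, comentions, cutoff_year, k = 50L) {
  if (k < 1L) stop("k must be >= 1")
  disease <- attr(ranking, "disease_id")
  fy <- first_comention_year(comentions, ranking$gene_id, disease)
  novel <- is.na(fy) | fy > cutoff_year
  genes <- ranking$gene_id[novel]
  if (length(genes) < k) {
    warning("only ", length(genes), " novel genes available (k = ", k, ")")
    return(genes)
  }
  genes[seq_len(k)]
}

#' Cumulative prospective precision
#'
#' For predictions made at a cut-off year, the fraction first co-mentioned
#' with the disease within 1, 2, ... `horizon_years` years after the
#' cut-off. The curve is monotone non-decreasing by construction.
#'
#' @param predictions character vector of predicted gene ids (novel at the
#'   cut-off).
#' @param comentions a [comention_index()] table.
#' @param disease_id the disease.
#' @param cutoff_year prediction year.
#' @param horizon_years number of test years.
#' @return numeric curve named by year offset.
#' @export
prospective_precision <- function(predictions, comentions, disease_id,
                                  cutoff_year, horizon_years) {
  if (length(predictions) == 0L) stop("empty predictions")
  fy <- first_comention_year(comentions, predictions, disease_id)
  if (any(!is.na(fy) & fy <= cutoff_year))
    stop("predictions must be novel at the cut-off year")
  ts <- seq_len(horizon_years)
  curve <- vapply(ts, function(t)
    mean(!is.na(fy) & fy <= cutoff_year + t), 0)
  names(curve) <- as.character(ts)
  curve
}

#' Bootstrap baseline for prospective precision
#'
#' Draws `B` samples of `k` genes without replacement from the novel-gene
#' universe of a disease and computes the prospective precision curve of
#' each, giving the null expectation a ranking must beat. Dispersion is the
#' standard deviation across iterations.
#'
#' @param gene_universe candidate gene ids.
#' @param comentions a [comention_index()] table.
#' @param disease_id the disease.
#' @param cutoff_year prediction year.
#' @param horizon_years number of test years.
#' @param k sample size per iteration (default 50).
#' @param B iterations (default 10000).
#' @param seed RNG seed.
#' @return list with `mean` and `sd` curves, the `terminal` values of all
#'   iterations, and the novel universe used.
#' @export
bootstrap_baseline <- function(gene_universe, comentions, disease_id,
                               cutoff_year, horizon_years, k = 50L,
                               B = 10000L, seed = 1L) {
  fy <- first_comention_year(comentions, gene_universe, disease_id)
  novel <- is.na(fy) | fy > cutoff_year
  universe <- gene_universe[novel]
  fy <- fy[novel]
  N <- length(universe)
  if (N < k) stop("novel universe (", N, ") smaller than k = ", k)
  offset <- fy - cutoff_year # NA = never reported
  offset[!is.na(offset) & offset > horizon_years] <- NA
  curves <- matrix(0, B, horizon_years)
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(N, k)
      off <- offset[idx]
      off <- off[!is.na(off)]
      if (length(off))
        curves[b, ] <- cumsum(tabulate(off, nbins = horizon_years)) / k
    }
  })
  list(mean = setNames(colMeans(curves), seq_len(horizon_years)),
       sd = setNames(apply(curves, 2L, sd), seq_len(horizon_years)),
       terminal = curves[, horizon_years],
       universe = universe, k = k, B = B)
}

#' Contextual linking words for a predicted pair
#'
#' The non-entity vocabulary tokens most similar to *both* members of a
#' gene-disease pair: the published intermediate vocabulary that explains an
#' inferred association (e.g. hyperinsulinemia-style phenotype terms linking
#' a lipase gene to a fatty-liver disease). The default combiner is the
#' minimum of the two similarities, so a word must be close to both tokens.
#'
#' @param model a `pwas_embedding` (entity tokens are taken from its
#'   protected vocabulary).
#' @param gene_id,disease_id the pair (both in vocabulary).
#' @param top_n number of words returned.
#' @param combine similarity combiner: `"min"` (default), `"product"` or
#'   `"mean"`.
#' @return data.frame (word, score, sim_gene, sim_disease) sorted by
#'   decreasing score.
#' @export
contextual_linking_words <- function(model, gene_id, disease_id, top_n = 10L,
                                     combine = c("min", "product", "mean")) {
  combine <- match.arg(combine)
  sg <- similarity_to_all(model, gene_id)
  sd_ <- similarity_to_all(model, disease_id)
  drop <- unique(c(model$entity_tokens, gene_id, disease_id))
  keep <- setdiff(names(sg), drop)
  sg <- sg[keep]; sd_ <- sd_[keep]
  score <- switch(combine,
                  min = pmin(sg, sd_),
                  product = sg * sd_,
                  mean = (sg + sd_) / 2)
  ord <- order(-score, keep)
  head(data.frame(word = keep[ord], score = unname(score[ord]),
                  sim_gene = unname(sg[ord]), sim_disease = unname(sd_[ord]),
                  stringsAsFactors = FALSE), top_n)
}

#' Clinical-stage ("chembl") score of a target-disease pair
#'
#' Scores the most advanced clinical phase reached: 0.1 for phase 1, 0.2 for
#' phase 2, 0.7 for phase 3, 1.0 for an approved and launched drug, and 0
#' when the pair has no phase records.
#'
#' @param phases character vector of phase records for one pair (any of
#'   "1"/"2"/"3"/"phase 1".../"approved"/"launched"/"registered").
#' @return numeric score.
#' @export
chembl_score <- function(phases) {
  if (length(phases) == 0L) return(0)
  lab <- gsub("^phase[ _]?", "", tolower(trimws(as.character(phases))))
  map <- c("1" = 0.1, "2" = 0.2, "3" = 0.7,
           "approved" = 1.0, "launched" = 1.0, "registered" = 1.0)
  unknown <- setdiff(lab, names(map))
  if (length(unknown)) stop("unknown phase label(s): ",
                            paste(unknown, collapse = ", "))
  max(map[lab])
}

#' The 60-model feed-forward tuning grid
#'
#' Hidden layers in \{1, 2\}, dropout in \{0, 0.1, 0.2, 0.3, 0.4\} and hidden
#' size in \{1, 5, 10, 20, 50, 100\}: 60 combinations, shared by the
#' clinical-score regressor and the PPI link-prediction grid.
#'
#' @return data.frame with columns hidden_layers, dropout, hidden_size, name.
#' @export
clinical_grid <- function() {
  g <- expand.grid(hidden_layers = c(1L, 2L),
                   dropout = c(0, 0.1, 0.2, 0.3, 0.4),
                   hidden_size = c(1L, 5L, 10L, 20L, 50L, 100L),
                   KEEP.OUT.ATTRS = FALSE)
  g$name <- format_model_name(g$hidden_size, g$hidden_layers, g$dropout)
  g
}

#' @rdname clinical_grid
#' @export
ppi_grid <- clinical_grid

#' Model-name formatting and parsing
#'
#' Grid models are named `H<size>-N<layers>-D<dropout>` (e.g. H100-N2-D0.2);
#' `parse_model_name()` inverts the encoding.
#'
#' @param hidden_size,hidden_layers,dropout grid coordinates (vectorised).
#' @return character names / a data.frame of coordinates.
#' @export
format_model_name <- function(hidden_size, hidden_layers, dropout) {
  sprintf("H%d-N%d-D%.1f", as.integer(hidden_size), as.integer(hidden_layers),
          dropout)
}

#' @rdname format_model_name
#' @param name model name(s) like "H100-N2-D0.2".
#' @export
parse_model_name <- function(name) {
  m <- regmatches(name, regexec("^H([0-9]+)-N([0-9]+)-D([0-9.]+)$", name))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop("unparseable model name(s): ",
                     paste(name[bad], collapse = ", "))
  data.frame(hidden_size = vapply(m, function(x) as.integer(x[2]), 0L),
             hidden_layers = vapply(m, function(x) as.integer(x[3]), 0L),
             dropout = vapply(m, function(x) as.numeric(x[4]), 0))
}

#' Regress clinical-stage scores from pair embeddings
#'
#' Trains feed-forward regressors over the tuning grid on concatenated
#' (gene, disease) embeddings to predict the clinical-stage score of each
#' pair. Whole diseases are assigned to train or test (a pair's disease
#' determines its side; leakage is an error), and model selection uses a
#' validation subset carved from the *training* diseases, never the future
#' test set.
#'
#' @param gene_embeddings,disease_embeddings matrices with entity ids as row
#'   names.
#' @param scores data.frame (target, disease, score).
#' @param grid tuning grid (default [clinical_grid()], 60 models).
#' @param disease_split list with `train` and `test` disease-id vectors.
#' @param val_fraction fraction of training diseases held out for model
#'   selection.
#' @param seed RNG seed.
#' @param epochs,lr,batch_size,patience training controls passed to
#'   [mlp_fit()].
#' @return list: `best_model`, `best_name`, `grid_results`, `test`
#'   predictions and `r2_test`.
#' @export
fit_clinical_score_regressor <- function(gene_embeddings, disease_embeddings,
                                         scores, grid = clinical_grid(),
                                         disease_split, val_fraction = 0.2,
                                         seed = 1L, epochs = 200L, lr = 0.01,
                                         batch_size = 8L, patience = 10L) {
  leak <- intersect(disease_split$train, disease_split$test)
  if (length(leak)) stop("disease leakage between train and test: ",
                         paste(head(leak, 5L), collapse = ", "))
  missing_d <- setdiff(scores$disease, c(disease_split$train,
                                         disease_split$test))
  if (length(missing_d)) stop("diseases missing from the split: ",
                              paste(head(missing_d, 5L), collapse = ", "))
  feats <- cbind(gene_embeddings[scores$target, , drop = FALSE],
                 disease_embeddings[scores$disease, , drop = FALSE])
  side <- ifelse(scores$disease %in% disease_split$test, "test", "train")
  val_dis <- with_seed(seed, sample(disease_split$train,
                                    max(1L, ceiling(val_fraction *
                                                    length(disease_split$train)))))
  side[side == "train" & scores$disease %in% val_dis] <- "val"
  if (!any(side == "train") || !any(side == "test"))
    stop("train or test side is empty")
  xs <- split.data.frame(feats, side)
  ys <- split(scores$score, side)
  results <- grid
  results$val_loss <- NA_real_
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- mlp_fit(xs$train, ys$train,
                         hidden = rep(grid$hidden_size[i],
                                      grid$hidden_layers[i]),
                         dropout = grid$dropout[i], task = "regression",
                         x_val = xs$val, y_val = ys$val,
                         epochs = epochs, lr = lr, batch_size = batch_size,
                         patience = patience, seed = seed + i)
    results$val_loss[i] <- fits[[i]]$val_loss
  }
  best_i <- order(results$val_loss, results$name)[1L]
  best <- fits[[best_i]]
  pred <- predict(best, xs$test)
  test <- data.frame(target = scores$target[side == "test"],
                     disease = scores$disease[side == "test"],
                     score = ys$test, pred = pred,
                     stringsAsFactors = FALSE)
  ss_res <- sum((test$score - test$pred)^2)
  ss_tot <- sum((test$score - mean(test$score))^2)
  list(best_model = best, best_name = results$name[best_i],
       grid_results = results, test = test,
       r2_test = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}

#' Per-disease top-k trial precision
#'
#' For each test disease, the fraction of its `k` highest-scoring targets
#' that subsequently entered a clinical trial.
#'
#' @param pred_table data.frame (target, disease, pred).
#' @param entered_trials data.frame (target, disease) of pairs that entered
#'   trials during the evaluation horizon.
#' @param k number of suggestions per disease (default 200).
#' @return named numeric vector (per disease) with the mean as attribute
#'   `"mean"`.
#' @export
topk_trial_precision <- function(pred_table, entered_trials, k = 200L) {
  hit_key <- paste(entered_trials$target, entered_trials$disease, sep = "\x01")
  out <- vapply(split(pred_table, pred_table$disease), function(df) {
    df <- df[order(-df$pred, df$target), , drop = FALSE]
    top <- head(df, k)
    mean(paste(top$target, top$disease, sep = "\x01") %in% hit_key)
  }, 0)
  attr(out, "mean") <- mean(out)
  out
}

#' Quantile z-scoring of method rankings
#'
#' Maps arbitrary per-gene method scores onto standard normal quantiles so
#' that rankings from different methods are comparable. Genes the method did
#' not score are first filled with uniform random values between zero and
#' the method's minimum score (seeded), then all scores are rank-transformed
#' to `qnorm((rank - 0.5) / n)`. The transform is monotone, so the order of
#' originally scored genes is preserved.
#'
#' @param scores named numeric vector over the gene universe; `NA` marks
#'   unscored genes.
#' @param fill_seed seed for the uniform fill.
#' @return named numeric z-scores (mean 0 by construction).
#' @export
zscore_rankings <- function(scores, fill_seed = 1L) {
  scored <- !is.na(scores)
  if (!any(scored)) stop("no scored genes")
  vals <- scores[scored]
  if (length(unique(vals)) == 1L && sum(!scored) == 0L)
    stop("all scores identical")
  if (any(!scored)) {
    m <- min(vals)
    lo <- min(m, 0); hi <- max(m, 0)
    scores[!scored] <- with_seed(fill_seed, runif(sum(!scored), lo, hi))
  }
  n <- length(scores)
  z <- qnorm((rank(scores, ties.method = "average") - 0.5) / n)
  names(z) <- names(scores)
  z
}

#' Write a ranking as TSV
#'
#' Columns: disease_id, gene_id, score, rank, model_year.
#' @param ranking a `pwas_ranking`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_ranking_tsv <- function(ranking, path) {
  out <- data.frame(disease_id = attr(ranking, "disease_id"),
                    gene_id = ranking$gene_id, score = ranking$score,
                    rank = ranking$rank,
                    model_year = attr(ranking, "model_year"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
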