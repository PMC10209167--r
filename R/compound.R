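#' Construct a drug-target positive set
#'
#' @param pairs data.frame (compound_id, gene_id); duplicates dropped.
#' @return a `pwas_dtset`: unique `pairs` plus `target_counts`, the number
#'   of distinct targets per compound (the promiscuity measure).
#' @export
drug_target_set <- function(pairs) {
  cid <- as.character(pairs[[1]])
  gid <- as.character(pairs[[2]])
  if (any(!nzchar(cid) | !nzchar(gid))) stop("empty compound or gene id")
  key <- paste(cid, gid, sep = "\x01")
  keep <- !duplicated(key)
  df <- data.frame(compound_id = cid[keep], gene_id = gid[keep],
                   stringsAsFactors = FALSE)
  tc <- table(df$compound_id)
  structure(list(pairs = df,
                 target_counts = setNames(as.integer(tc), names(tc))),
            class = "pwas_dtset")
}

#' Hard negatives from promiscuous entities
#'
#' Crosses the `n_proteins` most frequently targeted proteins with the
#' `n_compounds` least specific compounds (most reported targets) and
#' removes anything in the positive set: a deliberately hard negative set
#' so that classifiers cannot get away with predicting that every
#' staurosporine-like compound hits every kinase. Ties are broken by
#' identifier order for determinism.
#'
#' @param positives a `pwas_dtset`.
#' @param n_proteins,n_compounds entity counts (400 x 400 at paper scale).
#' @return data.frame (compound_id, gene_id) of negative pairs (with a
#'   warning if empty).
#' @export
promiscuous_negatives <- function(positives, n_proteins = 400L,
                                  n_compounds = 400L) {
  prot_freq <- table(positives$pairs$gene_id)
  comp_freq <- positives$target_counts
  if (n_proteins > length(prot_freq))
    stop("n_proteins (", n_proteins, ") exceeds available proteins (",
         length(prot_freq), ")")
  if (n_compounds > length(comp_freq))
    stop("n_compounds (", n_compounds, ") exceeds available compounds (",
         length(comp_freq), ")")
  top_prot <- names(prot_freq)[order(-as.integer(prot_freq),
                                     names(prot_freq))][seq_len(n_proteins)]
  top_comp <- names(comp_freq)[order(-as.integer(comp_freq),
                                     names(comp_freq))][seq_len(n_compounds)]
  cross <- expand.grid(compound_id = sort(top_comp), gene_id = sort(top_prot),
                       stringsAsFactors = FALSE)
  pos_keys <- paste(positives$pairs$compound_id, positives$pairs$gene_id,
                    sep = "\x01")
  keep <- !(paste(cross$compound_id, cross$gene_id, sep = "\x01") %in% pos_keys)
  out <- cross[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("positive set covers the whole cross product; no negatives")
  out
}

#' The compound-target model zoo
#'
#' Logistic regression, a 100-tree balanced random forest, and a multilayer
#' perceptron grid with hidden sizes \{1, 10, 50, 100\}, \{1, 2, 3\} hidden
#' layers and dropout \{0, 0.2\} - 26 models in total, all with a balanced
#' loss.
#'
#' @return data.frame (name, type, hidden_size, hidden_layers, dropout).
#' @export
compound_model_zoo <- function() {
  g <- expand.grid(hidden_size = c(1L, 10L, 50L, 100L),
                   hidden_layers = c(1L, 2L, 3L),
                   dropout = c(0, 0.2), KEEP.OUT.ATTRS = FALSE)
  mlps <- data.frame(name = format_model_name(g$hidden_size, g$hidden_layers,
                                              g$dropout),
                     type = "mlp", g, stringsAsFactors = FALSE)
  rbind(data.frame(name = "Logistic Regression", type = "lr",
                   hidden_size = NA_integer_, hidden_layers = NA_integer_,
                   dropout = NA_real_, stringsAsFactors = FALSE),
        data.frame(name = "RFC", type = "rf", hidden_size = NA_integer_,
                   hidden_layers = NA_integer_, dropout = NA_real_,
                   stringsAsFactors = FALSE),
        mlps)
}

#' Train and rank the compound-target model zoo
#'
#' Fits every model of the zoo on concatenated (gene, compound) embedding
#' features with a balanced loss and reports the test-set Matthews
#' correlation, precision and recall per model, ranked by decreasing MCC.
#' MCC is defined as 0 when its denominator vanishes (a degenerate model
#' that collapses to one class scores 0, as the smallest networks do).
#'
#' @param features numeric matrix of pair features (gene embedding first,
#'   then compound embedding).
#' @param labels 0/1 vector.
#' @param specs model table (default [compound_model_zoo()]).
#' @param split factor train/val/test per row.
#' @param seed RNG seed.
#' @param epochs,lr,batch_size,patience MLP training controls.
#' @param threshold classification threshold.
#' @return list: `results` (ranked metrics table), `models`, `best_name`.
#' @export
train_compound_target_models <- function(features, labels,
                                         specs = compound_model_zoo(),
                                         split, seed = 1L, epochs = 200L,
                                         lr = 0.01, batch_size = 8L,
                                         patience = 10L, threshold = 0.5) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(features), length(split) == nrow(features))
  if (length(unique(labels)) < 2L) stop("labels are single-class")
  tr <- split == "train"; va <- split == "val"; te <- split == "test"
  x_va <- if (any(va)) features[va, , drop = FALSE] else NULL
  y_va <- if (any(va)) labels[va] else NULL
  n1 <- sum(labels[tr] == 1); n0 <- sum(labels[tr] == 0)
  w <- ifelse(labels[tr] == 1, sum(tr) / (2 * n1), sum(tr) / (2 * n0))
  models <- vector("list", nrow(specs))
  names(models) <- specs$name
  results <- specs
  results$mcc <- results$precision <- results$recall <- NA_real_
  for (i in seq_len(nrow(specs))) {
    type <- specs$type[i]
    if (type == "lr") {
      df_tr <- data.frame(y = labels[tr], features[tr, , drop = FALSE])
      fit <- suppressWarnings(glm(y ~ ., data = df_tr, family = binomial(),
                                  weights = w))
      prob <- predict(fit, data.frame(features[te, , drop = FALSE]),
                      type = "response")
    } else if (type == "rf") {
      yf <- factor(labels[tr], levels = c(0, 1))
      fit <- with_seed(seed, randomForest::randomForest(
        x = features[tr, , drop = FALSE], y = yf, ntree = 100L,
        classwt = c("0" = sum(tr) / (2 * n0), "1" = sum(tr) / (2 * n1))))
      prob <- predict(fit, features[te, , drop = FALSE],
                      type = "prob")[, "1"]
    } else {
      fit <- mlp_fit(features[tr, , drop = FALSE], labels[tr],
                     hidden = rep(specs$hidden_size[i],
                                  specs$hidden_layers[i]),
                     dropout = specs$dropout[i], task = "classification",
                     balanced = TRUE, x_val = x_va, y_val = y_va,
                     epochs = epochs, lr = lr, batch_size = batch_size,
                     patience = patience, seed = seed + i)
      prob <- predict(fit, features[te, , drop = FALSE])
    }
    models[[i]] <- fit
    m <- classification_metrics(as.integer(prob >= threshold), labels[te])
    results$mcc[i] <- m["mcc"]
    results$precision[i] <- m["precision"]
    results$recall[i] <- m["recall"]
  }
  ord <- order(-results$mcc, results$name)
  list(results = results[ord, , drop = FALSE],
       models = models, best_name = results$name[ord][1L])
}

#' Promiscuity-stratified classification metrics
#'
#' Groups scored compound-target pairs by the compound's number of reported
#' targets (1, 2, more than 2) and reports, within each stratum, the shared
#' accuracy plus per-class precision/recall/F1: the "pharmacologically
#' active" column treats positive pairs as the positive class, the "no
#' active" column treats negative pairs as the positive class. Empty strata
#' are omitted with a message. Pooling the strata reproduces the global
#' confusion matrix.
#'
#' @param predictions data.frame (compound_id, gene_id, label, pred) with
#'   0/1 `pred`.
#' @param positives a `pwas_dtset` supplying per-compound target counts.
#' @return data.frame, one row per (stratum, class) with n, accuracy,
#'   precision, recall, f1.
#' @export
promiscuity_stratified_metrics <- function(predictions, positives) {
  tc <- positives$target_counts[predictions$compound_id]
  if (any(is.na(tc)))
    stop("compound(s) without a target count: ",
         paste(head(unique(predictions$compound_id[is.na(tc)]), 5L),
               collapse = ", "))
  stratum <- cut(tc, breaks = c(0, 1, 2, Inf), labels = c("1", "2", ">2"))
  rows <- list()
  for (s in c(">2", "2", "1")) {
    idx <- stratum == s
    if (!any(idx)) {
      message("stratum '", s, " target(s)' is empty; omitted")
      next
    }
    for (cls in c(0, 1)) {
      m <- classification_metrics(predictions$pred[idx],
                                  predictions$label[idx], positive = cls)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s,
        class = if (cls == 1) "pharmacologically_active" else "no_active",
        n = sum(idx), accuracy = m["accuracy"], precision = m["precision"],
        recall = m["recall"], f1 = m["f1"], row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Motif-enrichment druggability scores
#'
#' For every protein motif, a one-sided Fisher's exact test asks whether the
#' motif is enriched among drugged genes in the universe; the motif score is
#' `-log10(p)` and each gene inherits the maximum score over its
#' constituent motifs. A gene with no motifs scores 0, and a motif carried
#' by every gene is uninformative (p = 1, score 0). The construction gives
#' non-trivial scores to undrugged proteins whose motifs occur in drugged
#' ones.
#'
#' @param motif_membership data.frame (gene_id, motif_id).
#' @param drugged_genes character vector (subset of the universe).
#' @param universe gene universe (default: genes in `motif_membership`;
#'   pass explicitly to include motif-less genes).
#' @return list: `genes` data.frame (gene_id, score, best_motif) and
#'   `motifs` data.frame (motif_id, n_with, n_with_drugged, p, score).
#' @export
motif_druggability <- function(motif_membership, drugged_genes,
                               universe = NULL) {
  gm <- data.frame(gene_id = as.character(motif_membership[[1]]),
                   motif_id = as.character(motif_membership[[2]]),
                   stringsAsFactors = FALSE)
  if (is.null(universe)) universe <- sort(unique(gm$gene_id))
  if (length(universe) == 0L) stop("empty gene universe")
  if (!all(drugged_genes %in% universe))
    stop("drugged_genes must be a subset of the universe")
  gm <- gm[gm$gene_id %in% universe, , drop = FALSE]
  N <- length(universe)
  K <- length(unique(drugged_genes))
  motifs <- sort(unique(gm$motif_id))
  mrows <- lapply(motifs, function(m) {
    carriers <- unique(gm$gene_id[gm$motif_id == m])
    a <- sum(carriers %in% drugged_genes)        # motif & drugged
    b <- length(carriers) - a                    # motif & undrugged
    c_ <- K - a                                  # no motif & drugged
    d <- N - length(carriers) - c_               # no motif & undrugged
    p <- fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE),
                     alternative = "greater")$p.value
    data.frame(motif_id = m, n_with = length(carriers), n_with_drugged = a,
               p = p, score = -log10(p), stringsAsFactors = FALSE)
  })
  motif_tab <- do.call(rbind, mrows)
  gene_score <- setNames(rep(0, N), universe)
  gene_best <- setNames(rep(NA_character_, N), universe)
  for (g in unique(gm$gene_id)) {
    ms <- gm$motif_id[gm$gene_id == g]
    sc <- motif_tab$score[match(ms, motif_tab$motif_id)]
    j <- order(-sc, ms)[1L]
    gene_score[g] <- sc[j]
    gene_best[g] <- ms[j]
  }
  list(genes = data.frame(gene_id = universe, score = unname(gene_score),
                          best_motif = unname(gene_best),
                          stringsAsFactors = FALSE),
       motifs = motif_tab)
}

#' Genome-wide target ranking for a compound
#'
#' Scores every in-vocabulary gene of the universe with the compound-target
#' classifier (features: gene embedding first, compound embedding second)
#' and ranks by decreasing modulation likelihood, ties broken by gene id.
#'
#' @param classifier a fitted `pwas_mlp` (or any model with a `predict`
#'   method returning probabilities from the feature matrix).
#' @param compound_id compound token (must be in the embedding vocabulary).
#' @param gene_universe candidate gene ids.
#' @param model a `pwas_embedding` holding both gene and compound vectors.
#' @return data.frame (gene_id, score, rank).
#' @export
rank_targets_for_compound <- function(classifier, compound_id, gene_universe,
                                      model) {
  vocab <- rownames(model$vectors)
  if (!(compound_id %in% vocab))
    stop("compound not in model vocabulary: ", compound_id)
  genes <- gene_universe[gene_universe %in% vocab]
  if (!length(genes)) stop("no universe gene is in the vocabulary")
  feats <- cbind(model$vectors[genes, , drop = FALSE],
                 matrix(model$vectors[compound_id, ], length(genes),
                        ncol(model$vectors), byrow = TRUE))
  prob <- as.numeric(predict(classifier, feats))
  ord <- order(-prob, genes)
  data.frame(gene_id = genes[ord], score = prob[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Filter GWAS variants against model likelihoods
#'
#' Keeps candidate variants that are non-synonymous (reference and
#' alternate residues differ in the amino-acid change), genome-wide
#' significant below p = 1e-9 (strict: `minus_log10_p > 9`), consistent in
#' the beta-coefficient sign across at least two studies, and assigned a
#' model likelihood strictly greater than 0.3. Records with missing fields
#' are excluded with a message.
#'
#' @param variants data.frame with columns gene, rsid, amino_acid_change
#'   (e.g. "Glu77Gly"), beta, minus_log10_p, n_studies_consistent, and
#'   optionally likelihood.
#' @param likelihoods optional named vector (gene -> likelihood), used when
#'   the table has no likelihood column.
#' @param p_threshold_log10 significance bound on -log10(p) (default 9).
#' @param likelihood_threshold minimum model likelihood (default 0.3).
#' @return the filtered rows, sorted by decreasing `minus_log10_p`.
#' @export
variant_candidate_filter <- function(variants, likelihoods = NULL,
                                     p_threshold_log10 = 9,
                                     likelihood_threshold = 0.3) {
  v <- variants
  if (!("likelihood" %in% names(v))) {
    if (is.null(likelihoods)) stop("no likelihood column and no likelihoods")
    v$likelihood <- unname(likelihoods[v$gene])
  }
  req <- c("gene", "rsid", "amino_acid_change", "minus_log10_p",
           "n_studies_consistent", "likelihood")
  missing_col <- setdiff(req, names(v))
  if (length(missing_col)) stop("missing column(s): ",
                                paste(missing_col, collapse = ", "))
  complete <- stats::complete.cases(v[, req])
  if (any(!complete))
    message("excluding ", sum(!complete), " record(s) with missing fields")
  v <- v[complete, , drop = FALSE]
  m <- regmatches(v$amino_acid_change,
                  regexec("^([A-Za-z]{3})[0-9]+([A-Za-z]{3})$",
                          v$amino_acid_change))
  parseable <- vapply(m, length, 0L) == 3L
  if (any(!parseable))
    message("excluding ", sum(!parseable),
            " record(s) with unparseable amino-acid change")
  v <- v[parseable, , drop = FALSE]
  m <- m[parseable]
  nonsyn <- vapply(m, function(x) tolower(x[2]) != tolower(x[3]), TRUE)
  keep <- nonsyn &
    v$minus_log10_p > p_threshold_log10 &
    v$n_studies_consistent >= 2 &
    v$likelihood > likelihood_threshold
  out <- v[keep, , drop = FALSE]
  out[order(-out$minus_log10_p), , drop = FALSE]
}
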