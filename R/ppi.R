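pair_key <- function(a, b) paste(a, b, sep = "\x01")

#' Canonicalise a protein pair
#'
#' Sorts the two gene symbols alphabetically (so "ZNF44-A1BG" becomes
#' "A1BG-ZNF44") and rejects self-interactions. Rejection is a signal, not
#' an error: `NULL` is returned so callers can count discarded pairs.
#'
#' @param a,b non-empty gene symbols.
#' @return character vector `c(smaller, larger)`, or `NULL` for a self-pair.
#' @export
canonical_pair <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty symbol in pair")
  if (a == b) return(NULL)
  if (a < b) c(a, b) else c(b, a)
}

#' Construct an interaction set from a pair table
#'
#' Canonicalises (alphabetical order), drops self-pairs with a count
#' message, and deduplicates.
#'
#' @param pairs data.frame or 2-column matrix of symbols.
#' @param name dataset label (e.g. "H-I-05", "HI-II-14", "HuRI", "HI-union").
#' @param release_year release year.
#' @return a `pwas_iset`: `name`, `release_year`, `pairs` (data.frame a, b
#'   with a < b), `n_self_dropped`, `n_dup_dropped`.
#' @export
interaction_set <- function(pairs, name = "custom", release_year = NA_integer_) {
  a <- as.character(pairs[[1]])
  b <- as.character(pairs[[2]])
  if (any(!nzchar(a) | !nzchar(b))) stop("empty symbol in pair list")
  self <- a == b
  n_self <- sum(self)
  if (n_self) message(name, ": discarded ", n_self, " self-interaction(s)")
  a2 <- pmin(a[!self], b[!self])
  b2 <- pmax(a[!self], b[!self])
  key <- pair_key(a2, b2)
  dup <- duplicated(key)
  n_dup <- sum(dup)
  df <- data.frame(a = a2[!dup], b = b2[!dup], stringsAsFactors = FALSE)
  df <- df[order(df$a, df$b), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(name = name, release_year = as.integer(release_year),
                 pairs = df, n_self_dropped = n_self, n_dup_dropped = n_dup),
            class = "pwas_iset")
}

#' @export
print.pwas_iset <- function(x, ...) {
  cat("<pwas_iset>", x$name, "(", x$release_year, "):", nrow(x$pairs),
      "unique pairs\n")
  invisible(x)
}

#' Load an interactome release from TSV
#'
#' Two-column symbol TSV (header optional); pairs are canonicalised,
#' self-interactions discarded and duplicates removed, with counts logged.
#'
#' @param path TSV path.
#' @param name,release_year dataset metadata.
#' @return a `pwas_iset`.
#' @export
load_interactions <- function(path, name = basename(path),
                              release_year = NA_integer_) {
  if (!file.exists(path)) stop("interaction file not found: ", path)
  if (file.size(path) == 0L) stop("empty interaction file: ", path)
  raw <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                    colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty interaction file: ", path)
  if (ncol(raw) < 2L) stop("single-column rows in ", path)
  if (tolower(raw[1, 1]) %in% c("symbol_a", "gene_a", "a", "protein_a"))
    raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0L) stop("empty interaction file after header: ", path)
  interaction_set(raw[, 1:2], name = name, release_year = release_year)
}

# per-protein interaction degree within an interaction set
protein_degrees <- function(iset) {
  tab <- table(c(iset$pairs$a, iset$pairs$b))
  setNames(as.integer(tab), names(tab))
}

#' Sticky-protein negative pairs
#'
#' The interactome has no bona fide negative set; instead, all combinations
#' of the top `fraction` (default 10\%) of proteins by interaction degree
#' ("sticky" proteins, the ones most likely to produce false positives) are
#' taken as negatives, minus any pair already in the positive set. Ties at
#' the degree boundary are broken by symbol order for determinism.
#'
#' @param iset a `pwas_iset` of positive pairs.
#' @param fraction sticky fraction of proteins (default 0.1).
#' @return data.frame (a, b) of negative pairs, with the sticky proteins as
#'   attribute `"sticky"`.
#' @export
sticky_negatives <- function(iset, fraction = 0.1) {
  deg <- protein_degrees(iset)
  n_sticky <- ceiling(fraction * length(deg))
  ord <- order(-deg, names(deg))
  sticky <- names(deg)[ord][seq_len(n_sticky)]
  if (length(sticky) < 2L) stop("fewer than 2 sticky proteins")
  sticky <- sort(sticky)
  cmb <- t(combn(sticky, 2L))
  pos_keys <- pair_key(iset$pairs$a, iset$pairs$b)
  keep <- !(pair_key(cmb[, 1L], cmb[, 2L]) %in% pos_keys)
  out <- data.frame(a = cmb[keep, 1L], b = cmb[keep, 2L],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "sticky") <- sticky
  out
}

#' Protein-level train/validation/test split
#'
#' A random quarter of the proteins (seeded) and every pair touching them
#' form the test set, so test proteins are never seen during training; a
#' further fraction of the remaining proteins carves out the validation
#' pairs used for early stopping.
#'
#' @param pairs data.frame (a, b) covering positives and negatives.
#' @param test_fraction fraction of proteins held out (default 0.25).
#' @param val_fraction fraction of the remaining proteins for validation.
#' @param seed RNG seed.
#' @return list: `split` (factor train/val/test per row of `pairs`) and
#'   `proteins` (the protein assignment).
#' @export
protein_level_split <- function(pairs, test_fraction = 0.25,
                                val_fraction = 0.1, seed = 1L) {
  prots <- sort(unique(c(pairs$a, pairs$b)))
  if (length(prots) < 8L) stop("need at least 8 proteins to split")
  with_seed(seed, {
    test_p <- sample(prots, max(1L, round(test_fraction * length(prots))))
    rest <- setdiff(prots, test_p)
    val_p <- sample(rest, max(1L, round(val_fraction * length(rest))))
  })
  split <- ifelse(pairs$a %in% test_p | pairs$b %in% test_p, "test",
                  ifelse(pairs$a %in% val_p | pairs$b %in% val_p, "val",
                         "train"))
  split <- factor(split, levels = c("train", "val", "test"))
  if (!any(split == "test") || !any(split == "train"))
    stop("empty train or test side after protein split")
  list(split = split,
       proteins = list(train = setdiff(rest, val_p), val = sort(val_p),
                       test = sort(test_p)))
}

# concatenated embedding features, lexicographically smaller symbol first
pair_features <- function(pairs, model) {
  va <- model$vectors[pairs$a, , drop = FALSE]
  vb <- model$vectors[pairs$b, , drop = FALSE]
  unname(cbind(va, vb))
}

#' Build a labelled pair dataset
#'
#' Combines positive and negative pairs, drops pairs with a protein absent
#' from the era's embedding vocabulary (counted in a message), attaches
#' concatenated embedding features (smaller symbol first) and a
#' protein-level split.
#'
#' @param positives a `pwas_iset`.
#' @param negatives data.frame (a, b), e.g. from [sticky_negatives()].
#' @param model the era's `pwas_embedding`.
#' @param split optional [protein_level_split()] result computed on the
#'   combined in-vocabulary pairs; computed internally when `NULL`.
#' @param seed seed for the internal split.
#' @return a `pwas_pair_dataset`: `pairs` (a, b, label, split), `features`
#'   matrix of width 2 x dim, `dim`.
#' @export
build_pair_dataset <- function(positives, negatives, model, split = NULL,
                               seed = 1L) {
  pairs <- rbind(cbind(positives$pairs, label = 1L),
                 cbind(negatives[, c("a", "b")], label = 0L))
  vocab <- rownames(model$vectors)
  ok <- pairs$a %in% vocab & pairs$b %in% vocab
  if (any(!ok))
    message("dropping ", sum(!ok), " pair(s) with out-of-vocabulary proteins")
  pairs <- pairs[ok, , drop = FALSE]
  rownames(pairs) <- NULL
  if (is.null(split)) {
    # with small negative sets a random protein split can strand one class
    # entirely; redraw deterministically until train and test hold both
    for (try in 0:49) {
      cand <- protein_level_split(pairs, seed = seed + try)
      balanced <- all(vapply(c("train", "val", "test"), function(s)
        length(unique(pairs$label[cand$split == s])) == 2L, TRUE))
      if (balanced) {
        split <- cand
        if (try > 0)
          message("protein split redrawn ", try,
                  " time(s) to keep both classes in train and test")
        break
      }
    }
    if (is.null(split))
      stop("no protein split with both classes in train and test")
  }
  pairs$split <- split$split
  for (s in c("train", "test"))
    if (length(unique(pairs$label[pairs$split == s])) < 2L)
      stop("degenerate labels in ", s, " split")
  structure(list(pairs = pairs, features = pair_features(pairs, model),
                 dim = ncol(model$vectors)),
            class = "pwas_pair_dataset")
}

# features with the two halves swapped (reversed gene order augmentation)
swap_halves <- function(x, dim) {
  cbind(x[, (dim + 1L):(2L * dim), drop = FALSE],
        x[, 1:dim, drop = FALSE])
}

#' Train the PPI model grid
#'
#' Trains one balanced-loss feed-forward classifier per grid row on the
#' training pairs (augmented by reversing the gene order of each pair),
#' early-stops on the validation pairs, and reports test metrics including
#' the Matthews correlation coefficient per specification; the best model by
#' test MCC is returned together with the full table (the contour-plot
#' data).
#'
#' @param dataset a `pwas_pair_dataset`.
#' @param grid tuning grid (default [ppi_grid()], 60 models).
#' @param seed RNG seed.
#' @param epochs,lr,batch_size,patience training controls; pair datasets are
#'   small, so training runs many short epochs with small minibatches and a
#'   generous early-stopping patience.
#' @param threshold classification threshold (default 0.5).
#' @return list: `results` data.frame (name, layers, size, dropout, mcc,
#'   precision, recall, accuracy), `best_name`, `best_model`.
#' @export
train_ppi_grid <- function(dataset, grid = ppi_grid(), seed = 1L,
                           epochs = 200L, lr = 0.01, batch_size = 8L,
                           patience = 10L, threshold = 0.5) {
  p <- dataset$pairs
  tr <- p$split == "train"; va <- p$split == "val"; te <- p$split == "test"
  x_tr <- rbind(dataset$features[tr, , drop = FALSE],
                swap_halves(dataset$features[tr, , drop = FALSE], dataset$dim))
  y_tr <- rep(p$label[tr], 2L)
  x_va <- dataset$features[va, , drop = FALSE]
  y_va <- p$label[va]
  if (!length(y_va)) { x_va <- NULL; y_va <- NULL }
  results <- grid
  results$mcc <- results$precision <- results$recall <- results$accuracy <- NA_real_
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- mlp_fit(x_tr, y_tr,
                         hidden = rep(grid$hidden_size[i],
                                      grid$hidden_layers[i]),
                         dropout = grid$dropout[i], task = "classification",
                         balanced = TRUE, x_val = x_va, y_val = y_va,
                         epochs = epochs, lr = lr, batch_size = batch_size,
                         patience = patience, seed = seed + i)
    prob <- predict(fits[[i]], dataset$features[te, , drop = FALSE])
    m <- classification_metrics(as.integer(prob >= threshold), p$label[te])
    results$mcc[i] <- m["mcc"]
    results$precision[i] <- m["precision"]
    results$recall[i] <- m["recall"]
    results$accuracy[i] <- m["accuracy"]
  }
  best_i <- order(-results$mcc, results$name)[1L]
  list(results = results[order(-results$mcc, results$name), , drop = FALSE],
       best_name = results$name[best_i], best_model = fits[[best_i]])
}

#' Score protein pairs with a trained classifier
#'
#' Pairs are canonicalised before feature construction, so the score is
#' invariant to the input orientation.
#'
#' @param classifier a `pwas_mlp` from [train_ppi_grid()].
#' @param model the matching era's `pwas_embedding`.
#' @param pairs data.frame (a, b) in any orientation.
#' @return numeric scores (NA for out-of-vocabulary pairs).
#' @export
score_pairs <- function(classifier, model, pairs) {
  a <- pmin(pairs$a, pairs$b)
  b <- pmax(pairs$a, pairs$b)
  vocab <- rownames(model$vectors)
  ok <- a %in% vocab & b %in% vocab
  out <- rep(NA_real_, length(a))
  if (any(ok))
    out[ok] <- predict(classifier,
                       pair_features(data.frame(a = a[ok], b = b[ok]), model))
  out
}

#' Prospective positive-unlabeled evaluation across releases
#'
#' Classifiers trained on an old interactome release are scored against a
#' fixed candidate pool (the newest release's positives plus the model era's
#' sticky negatives). For each release, pairs that are positive only in the
#' future are labelled negative - the positive-unlabeled setting - and
#' false positives at the threshold are counted; as releases accumulate,
#' highly scored future interactions convert to true positives and the
#' false-positive count falls.
#'
#' @param models_by_era named list, era -> list(classifier, embeddings);
#'   each classifier must have been trained with its own era's embeddings
#'   (`embeddings$cutoff_year` must equal the era, else an era mismatch
#'   error).
#' @param datasets_by_era named list, era -> `pwas_iset`, ascending eras.
#' @param threshold classification threshold (default 0.5).
#' @param sticky_fraction sticky fraction for the model-era negatives.
#' @return data.frame with one row per (model era, dataset era >= model
#'   era): counts of future-only positives, false/true positives, precision
#'   and the mean scores of future positives and permanent negatives.
#' @export
prospective_ppi_eval <- function(models_by_era, datasets_by_era,
                                 threshold = 0.5, sticky_fraction = 0.1) {
  eras <- as.integer(names(datasets_by_era))
  if (is.unsorted(eras)) stop("datasets_by_era must be in ascending era order")
  final <- datasets_by_era[[length(datasets_by_era)]]
  all_pos_keys <- lapply(datasets_by_era, function(s)
    pair_key(s$pairs$a, s$pairs$b))
  rows <- list()
  for (me in names(models_by_era)) {
    entry <- models_by_era[[me]]
    emb <- entry$embeddings
    if (!is.na(emb$cutoff_year) && emb$cutoff_year != as.integer(me))
      stop("era mismatch: model era ", me, " vs embedding cutoff ",
           emb$cutoff_year)
    if (!(me %in% names(datasets_by_era)))
      stop("no dataset for model era ", me)
    own <- datasets_by_era[[me]]
    neg <- sticky_negatives(own, fraction = sticky_fraction)
    pool <- unique(rbind(final$pairs, neg[, c("a", "b")]))
    score <- score_pairs(entry$classifier, emb, pool)
    keep <- !is.na(score)
    pool <- pool[keep, , drop = FALSE]
    score <- score[keep]
    keys <- pair_key(pool$a, pool$b)
    own_keys <- all_pos_keys[[me]]
    permanent_neg <- !(keys %in% all_pos_keys[[length(all_pos_keys)]])
    for (de in names(datasets_by_era)) {
      if (as.integer(de) < as.integer(me)) next
      pos <- keys %in% all_pos_keys[[de]]
      future <- pos & !(keys %in% own_keys)
      fp <- sum(score >= threshold & !pos)
      tp <- sum(score >= threshold & pos)
      rows[[length(rows) + 1L]] <- data.frame(
        model_era = as.integer(me), dataset_era = as.integer(de),
        n_pool = length(keys), n_future_positives = sum(future),
        fp = fp, tp = tp,
        precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
        mean_score_future_pos = if (any(future)) mean(score[future]) else NA_real_,
        mean_score_permanent_neg = if (any(permanent_neg))
          mean(score[permanent_neg]) else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Exclusive intersection counts for an upset plot
#'
#' For every non-empty subset of the input interaction sets, the number of
#' pairs belonging to exactly those sets. Cells are disjoint and sum to the
#' size of the union.
#'
#' @param isets list of two or more `pwas_iset` objects (uniquely named).
#' @return data.frame with one logical membership column per set plus
#'   `count`; the union size is attached as attribute `"union_size"`.
#' @export
upset_counts <- function(isets) {
  if (length(isets) < 2L) stop("need at least 2 interaction sets")
  nms <- vapply(isets, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("interaction sets must have unique names")
  keys <- lapply(isets, function(s) pair_key(s$pairs$a, s$pairs$b))
  all_keys <- unique(unlist(keys))
  member <- vapply(keys, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1L)
  colnames(member) <- nms
  sig <- apply(member, 1L, function(r) paste(as.integer(r), collapse = ""))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(isets)),
                        KEEP.OUT.ATTRS = FALSE)
  names(combos) <- nms
  combos <- combos[rowSums(combos) > 0L, , drop = FALSE]
  combo_sig <- apply(combos, 1L, function(r)
    paste(as.integer(r), collapse = ""))
  counts <- as.integer(table(factor(sig, levels = combo_sig)))
  out <- cbind(combos, count = counts)
  rownames(out) <- NULL
  attr(out, "union_size") <- length(all_keys)
  out
}

#' Interactome release accounting
#'
#' Runs the canonicalisation / self-pair / deduplication pipeline over the
#' four systematic human-interactome releases and reports the summary
#' quantities of the record: the unique HI-union pair count, the
#' HuRI-HI-union and all-four intersections, and selected H-I-05 degrees.
#' Expects a directory containing `H-I-05.tsv`, `HI-II-14.tsv`, `HuRI.tsv`
#' and `HI-union.tsv` (two-column symbol TSVs). These releases are external
#' data and are not shipped with the package.
#'
#' @param dir directory holding the four release TSVs.
#' @return list: `hi_union_pairs`, `huri_hi_union_intersection`,
#'   `all_four_intersection`, `h_i_05_degrees` (DVL2, TRAF2, NIF3L1), and
#'   the loaded `sets`.
#' @export
interactome_accounting <- function(dir) {
  files <- c("H-I-05" = "H-I-05.tsv", "HI-II-14" = "HI-II-14.tsv",
             "HuRI" = "HuRI.tsv", "HI-union" = "HI-union.tsv")
  years <- c("H-I-05" = 2005L, "HI-II-14" = 2014L, "HuRI" = 2020L,
             "HI-union" = 2020L)
  paths <- file.path(dir, files)
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing interactome release file(s): ",
         paste(files[missing], collapse = ", "),
         " (download the releases into ", dir, ")")
  sets <- Map(load_interactions, paths, names(files), years)
  names(sets) <- names(files)
  keys <- lapply(sets, function(s) pair_key(s$pairs$a, s$pairs$b))
  deg <- protein_degrees(sets[["H-I-05"]])
  list(hi_union_pairs = nrow(sets[["HI-union"]]$pairs),
       huri_hi_union_intersection =
         length(intersect(keys[["HuRI"]], keys[["HI-union"]])),
       all_four_intersection = length(Reduce(intersect, keys)),
       h_i_05_degrees = deg[c("DVL2", "TRAF2", "NIF3L1")],
       sets = sets)
}
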