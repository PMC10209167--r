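#' Synthetic literature configuration
#'
#' Defines a synthetic corpus of time-stamped bag-of-token "abstracts" with
#' planted structure mirroring what the real pipeline must detect:
#' gene-disease associations that emerge in a known year, preceded by
#' "bridge" vocabulary co-occurring with the gene and with the disease in
#' separate documents; gene families sharing family vocabulary; pathway
#' modules of interacting proteins whose pairs are revealed across
#' successive interactome releases; and compounds co-mentioned with their
#' targets. Documents are bags of tokens because window-based embedding
#' training only consumes co-occurrence statistics.
#'
#' @param n_genes,n_diseases,n_compounds entity counts.
#' @param years inclusive publication-year range.
#' @param docs_per_year exact number of documents generated per year.
#' @param doc_length tokens per document.
#' @param topic_vocab_size topic words per entity.
#' @param background_vocab_size size of the shared background vocabulary.
#' @param n_planted_associations planted gene-disease pairs (assigned to the
#'   last genes, round-robin over diseases).
#' @param emergence_years emergence year per planted pair (default: spread
#'   over the three years starting three years before the end of the range).
#' @param n_bridge_words unique bridge words per planted pair.
#' @param bridge_lead_years bridge documents start this many years before
#'   emergence.
#' @param bridge_docs_per_year bridge documents per pair side per year.
#' @param comention_docs_per_year direct co-mention documents per emerged
#'   pair per year.
#' @param n_families,family_size,family_vocab_size gene-family structure
#'   (families take the first genes).
#' @param n_pathways,pathway_size,pathway_vocab_size PPI pathway modules
#'   (drawn from the genes after the families).
#' @param ppi_release_years interactome release years (ascending).
#' @param ppi_reveal_fractions cumulative fraction of within-pathway pairs
#'   revealed at each release.
#' @param ppi_docs_per_year PPI-related documents per year.
#' @param compound_target_counts targets per compound (promiscuity mix).
#' @param seed RNG seed; generation is byte-identical given the seed.
#' @return a `pwas_synth_config` list.
#' @export
synthetic_config <- function(n_genes = 200L, n_diseases = 5L,
                             n_compounds = 10L, years = 2000:2012,
                             docs_per_year = 450L, doc_length = 30L,
                             topic_vocab_size = 3L,
                             background_vocab_size = 500L,
                             n_planted_associations = 10L,
                             emergence_years = NULL,
                             n_bridge_words = 5L, bridge_lead_years = 3L,
                             bridge_docs_per_year = 3L,
                             comention_docs_per_year = 2L,
                             n_families = 4L, family_size = 10L,
                             family_vocab_size = 3L,
                             n_pathways = 12L, pathway_size = 6L,
                             pathway_vocab_size = 3L,
                             ppi_release_years = NULL,
                             ppi_reveal_fractions = c(0.5, 0.75, 1),
                             ppi_docs_per_year = 60L,
                             compound_target_counts = NULL,
                             seed = 1L) {
  if (doc_length < 3L) stop("infeasible config: doc_length < 3")
  if (bridge_lead_years < 1L) stop("bridge_lead_years must be >= 1")
  # one emergence cohort by default: every planted pair then has a
  # full-length bridge window behind the shared pre-emergence cut-off, so
  # bridge recovery measures the linking-word machinery, not partial
  # exposure; staggered cohorts remain available via emergence_years
  e0 <- max(years) - 4L
  if (is.null(emergence_years))
    emergence_years <- rep(e0 + 1L, n_planted_associations)
  if (any(!(emergence_years %in% years)))
    stop("emergence years must fall inside the year range")
  if (is.null(ppi_release_years))
    ppi_release_years <- c(e0 - 2L, e0, e0 + 2L)
  if (length(ppi_release_years) != length(ppi_reveal_fractions))
    stop("one reveal fraction per release year")
  if (is.null(compound_target_counts))
    compound_target_counts <- rep(c(1L, 1L, 2L, 2L, 3L),
                                  length.out = n_compounds)
  counts <- c(n_genes, n_diseases, docs_per_year, doc_length,
              topic_vocab_size, background_vocab_size, n_bridge_words)
  if (any(counts <= 0L)) stop("all counts must be positive")
  if (n_families * family_size + n_pathways * pathway_size +
      n_planted_associations > n_genes)
    stop("infeasible config: families, pathways and planted genes overlap")
  structure(list(n_genes = n_genes, n_diseases = n_diseases,
                 n_compounds = n_compounds, years = years,
                 docs_per_year = docs_per_year, doc_length = doc_length,
                 topic_vocab_size = topic_vocab_size,
                 background_vocab_size = background_vocab_size,
                 n_planted_associations = n_planted_associations,
                 emergence_years = emergence_years,
                 n_bridge_words = n_bridge_words,
                 bridge_lead_years = bridge_lead_years,
                 bridge_docs_per_year = bridge_docs_per_year,
                 comention_docs_per_year = comention_docs_per_year,
                 n_families = n_families, family_size = family_size,
                 family_vocab_size = family_vocab_size,
                 n_pathways = n_pathways, pathway_size = pathway_size,
                 pathway_vocab_size = pathway_vocab_size,
                 ppi_release_years = ppi_release_years,
                 ppi_reveal_fractions = ppi_reveal_fractions,
                 ppi_docs_per_year = ppi_docs_per_year,
                 compound_target_counts = compound_target_counts,
                 seed = seed),
            class = "pwas_synth_config")
}

#' Generate a synthetic corpus with ground truth
#'
#' Produces exactly `docs_per_year` tagged documents per year:
#' per-entity mention documents (entity token plus its topic and family
#' words), bridge documents in the window before each planted emergence
#' (the gene with the pair's bridge words, and the disease with the same
#' bridge words, in separate documents), direct co-mention documents from
#' the emergence year on, pathway documents for protein pairs (single
#' protein with pathway words before the pair's release, both proteins
#' after), compound-target co-mention documents, and background filler. By
#' construction no planted pair is co-mentioned before its emergence year.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `corpus` (a `pwas_corpus` of tagged documents) and
#'   `truth` (planted association, family, PPI and drug-target tables plus
#'   the entity id sets).
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "pwas_synth_config"))
  genes <- sprintf("G%03d", seq_len(cfg$n_genes))
  diseases <- sprintf("D%02d", seq_len(cfg$n_diseases))
  compounds <- sprintf("C%02d", seq_len(cfg$n_compounds))
  bg <- sprintf("w%04d", seq_len(cfg$background_vocab_size))
  topics <- lapply(setNames(nm = c(genes, diseases, compounds)), function(e)
    sprintf("t_%s_%d", tolower(e), seq_len(cfg$topic_vocab_size)))

  # families over the first genes
  fam_genes <- genes[seq_len(cfg$n_families * cfg$family_size)]
  families <- data.frame(
    gene = fam_genes,
    family = rep(sprintf("fam%d", seq_len(cfg$n_families)),
                 each = cfg$family_size),
    stringsAsFactors = FALSE)
  fam_vocab <- lapply(setNames(nm = unique(families$family)), function(f)
    sprintf("f_%s_%d", f, seq_len(cfg$family_vocab_size)))
  fam_of <- setNames(families$family, families$gene)

  # pathway modules over the genes after the families
  off <- length(fam_genes)
  pw_genes <- genes[off + seq_len(cfg$n_pathways * cfg$pathway_size)]
  pathway_of <- setNames(rep(sprintf("pw%d", seq_len(cfg$n_pathways)),
                             each = cfg$pathway_size), pw_genes)
  pw_vocab <- lapply(setNames(nm = unique(pathway_of)), function(p)
    sprintf("p_%s_%d", p, seq_len(cfg$pathway_vocab_size)))

  # planted gene-disease associations use the last genes
  pl_genes <- genes[(cfg$n_genes - cfg$n_planted_associations + 1L):cfg$n_genes]
  assoc <- data.frame(
    gene = pl_genes,
    disease = diseases[((seq_along(pl_genes) - 1L) %% cfg$n_diseases) + 1L],
    emergence_year = cfg$emergence_years,
    stringsAsFactors = FALSE)
  bridges <- lapply(seq_len(nrow(assoc)), function(i)
    sprintf("b_pair%d_%d", i, seq_len(cfg$n_bridge_words)))
  assoc$bridge_words <- vapply(bridges, paste, "", collapse = ",")

  # drug-target pairs: targets drawn from the pathway genes (plenty of them)
  tgt_pool <- pw_genes
  dt_rows <- list()
  pos <- 1L
  for (j in seq_len(cfg$n_compounds)) {
    k <- cfg$compound_target_counts[j]
    tgts <- tgt_pool[((pos - 1L + seq_len(k) - 1L) %% length(tgt_pool)) + 1L]
    pos <- pos + k
    dt_rows[[j]] <- data.frame(compound = compounds[j], gene = tgts,
                               stringsAsFactors = FALSE)
  }
  drug_targets <- do.call(rbind, dt_rows)

  with_seed(cfg$seed, {
    # within-pathway true pairs, revealed cumulatively across releases
    true_pairs <- do.call(rbind, lapply(unique(pathway_of), function(p) {
      members <- sort(names(pathway_of)[pathway_of == p])
      cmb <- t(combn(members, 2L))
      data.frame(a = cmb[, 1L], b = cmb[, 2L], pathway = p,
                 stringsAsFactors = FALSE)
    }))
    n_tp <- nrow(true_pairs)
    reveal_order <- sample.int(n_tp)
    cum_n <- pmin(n_tp, ceiling(cfg$ppi_reveal_fractions * n_tp))
    release_year <- rep(NA_integer_, n_tp)
    prev <- 0L
    for (r in seq_along(cfg$ppi_release_years)) {
      idx <- reveal_order[seq_len(cum_n[r])]
      idx <- setdiff(idx, reveal_order[seq_len(prev)])
      release_year[idx] <- cfg$ppi_release_years[r]
      prev <- cum_n[r]
    }
    true_pairs$release_year <- release_year

    doc_len <- cfg$doc_length
    make_doc <- function(must, gene_ids = character(0),
                         disease_ids = character(0)) {
      if (length(must) > doc_len)
        stop("infeasible config: required tokens exceed doc_length")
      toks <- c(must, sample(bg, doc_len - length(must), replace = TRUE))
      list(tokens = sample(toks), gene_ids = sort(unique(gene_ids)),
           disease_ids = sort(unique(disease_ids)))
    }

    docs <- list()
    for (year in cfg$years) {
      ydocs <- list()
      add <- function(d) ydocs[[length(ydocs) + 1L]] <<- d
      for (g in genes) {
        must <- c(g, rep(topics[[g]], 2L))
        if (g %in% names(fam_of))
          must <- c(must, rep(fam_vocab[[fam_of[[g]]]], 2L))
        add(make_doc(must, gene_ids = g))
      }
      for (d in diseases)
        for (r in 1:2)
          add(make_doc(c(d, rep(topics[[d]], 2L)), disease_ids = d))
      for (cp in compounds)
        add(make_doc(c(cp, rep(topics[[cp]], 2L))))
      for (i in seq_len(nrow(drug_targets)))
        add(make_doc(c(drug_targets$compound[i], drug_targets$gene[i],
                       topics[[drug_targets$compound[i]]]),
                     gene_ids = drug_targets$gene[i]))
      for (i in seq_len(nrow(assoc))) {
        em <- assoc$emergence_year[i]
        g <- assoc$gene[i]; d <- assoc$disease[i]
        brw <- bridges[[i]]
        if (year >= em - cfg$bridge_lead_years && year < em) {
          for (r in seq_len(cfg$bridge_docs_per_year)) {
            add(make_doc(c(g, rep(brw, 2L)), gene_ids = g))
            add(make_doc(c(d, rep(brw, 2L)), disease_ids = d))
          }
        }
        if (year >= em)
          for (r in seq_len(cfg$comention_docs_per_year))
            add(make_doc(c(g, d, brw), gene_ids = g, disease_ids = d))
      }
      slots <- sample.int(n_tp, cfg$ppi_docs_per_year, replace = TRUE)
      for (s in slots) {
        pr <- true_pairs[s, ]
        pw <- pw_vocab[[pr$pathway]]
        if (year >= pr$release_year) {
          add(make_doc(c(pr$a, pr$b, rep(pw, 2L)),
                       gene_ids = c(pr$a, pr$b)))
        } else {
          prot <- if (runif(1) < 0.5) pr$a else pr$b
          add(make_doc(c(prot, rep(pw, 2L)), gene_ids = prot))
        }
      }
      if (length(ydocs) > cfg$docs_per_year)
        stop("infeasible config: ", length(ydocs),
             " required documents exceed docs_per_year = ", cfg$docs_per_year)
      while (length(ydocs) < cfg$docs_per_year)
        add(make_doc(character(0)))
      ydocs <- ydocs[sample.int(length(ydocs))]
      for (i in seq_along(ydocs)) {
        d <- ydocs[[i]]
        docs[[length(docs) + 1L]] <- structure(
          list(doc_id = sprintf("Y%d_%04d", year, i), year = year,
               tokens = d$tokens, gene_ids = d$gene_ids,
               disease_ids = d$disease_ids,
               gene_synonyms = d$gene_ids, disease_synonyms = d$disease_ids),
          class = "pwas_doc")
      }
    }
    truth <- list(associations = assoc,
                  bridge_words = setNames(bridges,
                                          paste(assoc$gene, assoc$disease,
                                                sep = "|")),
                  families = families,
                  ppi = true_pairs,
                  ppi_release_years = cfg$ppi_release_years,
                  drug_targets = drug_targets,
                  genes = genes, diseases = diseases, compounds = compounds,
                  config = cfg)
    list(corpus = structure(docs, class = "pwas_corpus"), truth = truth)
  })
}

#' Evaluate recovery of planted structure
#'
#' Runs the full pipeline at pre-emergence cut-offs on a synthetic corpus
#' and measures how well the planted signal is recovered: the rank
#' percentile of each planted gene in its disease's genome-wide ranking
#' from the latest pre-emergence model, the prospective precision of the
#' top-`k` novel predictions against the bootstrap baseline (averaged
#' across diseases, one-sided empirical p), the fraction of planted bridge
#' words recovered among the top contextual linking words, and (optionally)
#' the positive-unlabeled PPI evaluation: an early-era classifier's scores
#' on future-release interactions versus permanent negatives, with
#' false-positive counts per release.
#'
#' @param corpus,truth a [generate_corpus()] result.
#' @param cutoff_years model cut-off years (default: the three years before
#'   the earliest emergence).
#' @param hp embedding hyperparameters (default CBOW, dim 64, seed from the
#'   generator config).
#' @param k predictions per disease (default 50).
#' @param B bootstrap iterations (default 10000).
#' @param top_n_linking linking words inspected per pair (default 10).
#' @param include_ppi run the PPI positive-unlabeled block.
#' @param ppi_hidden,ppi_layers,ppi_dropout the single PPI classifier spec
#'   used here (the full 60-model grid is a separate operation).
#' @param ppi_sticky_fraction sticky fraction for the toy-scale PU block; at
#'   a few dozen proteins the production 10\% rule leaves too few negative
#'   pairs to train on, so the block defaults to 20\%.
#' @param min_count vocabulary threshold.
#' @param seed evaluation seed (bootstrap, splits, classifier).
#' @return a recovery report list; see Details in the package vignette.
#' @export
evaluate_recovery <- function(corpus, truth, cutoff_years = NULL,
                              hp = NULL, k = 50L, B = 10000L,
                              top_n_linking = 10L, include_ppi = TRUE,
                              ppi_hidden = 20L, ppi_layers = 2L,
                              ppi_dropout = 0.2, ppi_sticky_fraction = 0.2,
                              min_count = 10L, seed = 1L) {
  assoc <- truth$associations
  first_em <- min(assoc$emergence_year)
  if (is.null(cutoff_years)) cutoff_years <- (first_em - 3L):(first_em - 1L)
  max_year <- max(vapply(corpus, `[[`, 0L, "year"))
  if (all(cutoff_years >= max(assoc$emergence_year)))
    stop("all cut-offs are at or after the last emergence; nothing to predict")
  if (is.null(hp))
    hp <- embedding_hyperparams(dim = 64L, seed = truth$config$seed)
  protected <- c(truth$genes, truth$diseases, truth$compounds)
  models <- checkpoint_series(corpus, cutoff_years, hp,
                              protected = protected, min_count = min_count)
  cutoff <- max(cutoff_years)
  model <- models[[as.character(cutoff)]]
  comentions <- comention_index(corpus)
  horizon <- max_year - cutoff

  eval_assoc <- assoc[assoc$emergence_year > cutoff, , drop = FALSE]
  eval_diseases <- sort(unique(eval_assoc$disease))
  percentiles <- list()
  curves <- list()
  terminal_draws <- NULL
  obs_terminal <- numeric(0)
  base_mean_terminal <- numeric(0)
  for (di in seq_along(eval_diseases)) {
    d <- eval_diseases[di]
    ranking <- rank_genes_for_disease(model, d, truth$genes)
    pg <- eval_assoc$gene[eval_assoc$disease == d]
    pr <- ranking$rank[match(pg, ranking$gene_id)] / nrow(ranking) * 100
    percentiles[[d]] <- data.frame(gene = pg, disease = d, percentile = pr,
                                   stringsAsFactors = FALSE)
    preds <- novel_top_k(ranking, comentions, cutoff, k = k)
    curves[[d]] <- prospective_precision(preds, comentions, d, cutoff, horizon)
    bb <- bootstrap_baseline(truth$genes, comentions, d, cutoff, horizon,
                             k = k, B = B, seed = seed + di)
    obs_terminal <- c(obs_terminal, curves[[d]][horizon])
    base_mean_terminal <- c(base_mean_terminal, bb$mean[horizon])
    terminal_draws <- if (is.null(terminal_draws)) bb$terminal
    else terminal_draws + bb$terminal
  }
  terminal_draws <- terminal_draws / length(eval_diseases)
  observed <- mean(obs_terminal)
  p_boot <- (1 + sum(terminal_draws >= observed)) / (B + 1)

  rank_tab <- do.call(rbind, percentiles)
  bridge_rec <- vapply(seq_len(nrow(eval_assoc)), function(i) {
    g <- eval_assoc$gene[i]; d <- eval_assoc$disease[i]
    brw <- truth$bridge_words[[paste(g, d, sep = "|")]]
    in_vocab <- brw[brw %in% rownames(model$vectors)]
    if (!length(in_vocab)) return(0)
    lw <- contextual_linking_words(model, g, d, top_n = top_n_linking)
    sum(brw %in% lw$word) / length(brw)
  }, 0)

  out <- list(cutoff_year = cutoff, models = models,
              rank_percentiles = rank_tab,
              mean_rank_percentile = mean(rank_tab$percentile),
              precision_curves = curves,
              observed_terminal_precision = observed,
              baseline_mean_terminal_precision = mean(base_mean_terminal),
              bootstrap_p = p_boot,
              bridge_recovery = bridge_rec,
              bridge_recovery_rate = mean(bridge_rec))

  if (include_ppi) {
    rel <- truth$ppi_release_years
    old_era <- rel[1L]
    if (!(as.character(old_era) %in% names(models)))
      stop("no checkpointed model for PPI era ", old_era)
    isets <- lapply(rel, function(r) {
      keep <- truth$ppi$release_year <= r
      interaction_set(truth$ppi[keep, c("a", "b")],
                      name = paste0("release", r), release_year = r)
    })
    names(isets) <- as.character(rel)
    emb <- models[[as.character(old_era)]]
    neg <- sticky_negatives(isets[[1L]], fraction = ppi_sticky_fraction)
    ds <- build_pair_dataset(isets[[1L]], neg, emb, seed = seed)
    spec <- data.frame(hidden_layers = ppi_layers, dropout = ppi_dropout,
                       hidden_size = ppi_hidden,
                       name = format_model_name(ppi_hidden, ppi_layers,
                                                ppi_dropout))
    fit <- train_ppi_grid(ds, grid = spec, seed = seed)
    pu <- prospective_ppi_eval(
      models_by_era = setNames(list(list(classifier = fit$best_model,
                                         embeddings = emb)),
                               as.character(old_era)),
      datasets_by_era = isets, sticky_fraction = ppi_sticky_fraction)
    last <- nrow(pu) # newest release: all future positives are visible there
    out$ppi <- list(eval = pu,
                    fp_by_release = setNames(pu$fp, pu$dataset_era),
                    future_score_gap =
                      pu$mean_score_future_pos[last] -
                      pu$mean_score_permanent_neg[last],
                    classifier_results = fit$results)
  }
  out
}
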