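#' Text-cleaning configuration
#'
#' @param leading_statements section labels stripped from text.
#' @param number_mask single token replacing decimal and percentage numbers.
#'   Bare integers without a decimal point or percent sign are kept: they are
#'   often meaningful identifiers (e.g. "p53", "type 2").
#' @param min_year,max_year accepted publication-year range.
#' @return a `pwas_clean_config` list.
#' @export
clean_config <- function(leading_statements = c("background:", "abstract:",
                                                "introduction:"),
                         number_mask = "<number>",
                         min_year = 1900L, max_year = 2100L) {
  stopifnot(length(number_mask) == 1L, !grepl("\\s", number_mask))
  structure(list(leading_statements = tolower(leading_statements),
                 number_mask = number_mask,
                 min_year = as.integer(min_year),
                 max_year = as.integer(max_year)),
            class = "pwas_clean_config")
}

# Numeric literals that get masked: decimals (with optional percent sign)
# and integer percentages. Documented here as the package's exact rule.
.number_regex <- "[0-9]+\\.[0-9]+[[:space:]]*%?|[0-9]+[[:space:]]*%"

#' Clean raw text into tokens
#'
#' Lower-cases and deaccents the text, strips leading section statements
#' ("Background:", ...), replaces decimal and percentage numbers by the mask
#' token, removes punctuation and tokenizes on whitespace. Stop words are
#' retained.
#'
#' @param raw a character scalar (UTF-8).
#' @param cfg a [clean_config()].
#' @return character vector of tokens (empty input gives an empty vector).
#' @export
clean_text <- function(raw, cfg = clean_config()) {
  if (length(raw) == 0L || is.na(raw) || !nzchar(raw)) return(character(0))
  x <- tolower(raw)
  x <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT", sub = " ")
  for (ls in cfg$leading_statements)
    x <- gsub(ls, " ", x, fixed = TRUE)
  mask <- paste0(" ", cfg$number_mask, " ")
  x <- gsub(.number_regex, mask, x)
  # keep word characters plus the mask token's angle brackets and
  # underscores (phrase delimiter); everything else separates tokens
  x <- gsub("[^a-z0-9_<>]+", " ", x)
  tokens <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  tokens[nzchar(tokens)]
}

#' Learn an NPMI phrase model
#'
#' Collocation mining in repeated passes: in each pass, adjacent token pairs
#' seen at least `min_count` times with normalized pointwise mutual
#' information above `threshold` are merged into a single underscore-joined
#' token, and counts are re-estimated on the merged corpus for the next
#' pass. Three passes can build up to 8-grams. NPMI is
#' `ln(p(ab)/(p(a)p(b))) / (-ln p(ab))` with all probabilities normalised by
#' the total token count, so a pair that always co-occurs scores exactly 1.
#' Protected tokens (canonical gene/disease/compound identifiers) never
#' participate in merges and stay atomic.
#'
#' @param corpus_tokens list of token vectors (one per document).
#' @param min_count minimum pair count (default 10).
#' @param threshold NPMI threshold, pairs must score strictly above it.
#' @param passes number of merge passes (default 3).
#' @param delimiter join character.
#' @param protected tokens excluded from merging.
#' @return a `pwas_phrases` model with one scored pair table per pass.
#' @export
learn_phrases <- function(corpus_tokens, min_count = 10L, threshold = 0.7,
                          passes = 3L, delimiter = "_",
                          protected = character(0)) {
  if (passes < 1L) stop("passes must be >= 1")
  if (length(corpus_tokens) == 0L) stop("empty corpus")
  pass_tables <- vector("list", passes)
  toks <- corpus_tokens
  for (p in seq_len(passes)) {
    tab <- score_bigrams(toks, protected)
    keep <- tab[tab$count >= min_count & tab$npmi > threshold, , drop = FALSE]
    keep <- keep[order(keep$token_a, keep$token_b), , drop = FALSE]
    rownames(keep) <- NULL
    pass_tables[[p]] <- keep
    if (nrow(keep) == 0L) {
      if (p < passes)
        pass_tables[(p + 1L):passes] <- rep(list(keep), passes - p)
      break
    }
    merge_set <- paste(keep$token_a, keep$token_b, sep = "\x01")
    toks <- lapply(toks, merge_pass, merge_set = merge_set,
                   delimiter = delimiter)
  }
  pass_tables <- pass_tables[!vapply(pass_tables, is.null, TRUE)]
  structure(list(passes = pass_tables, min_count = as.integer(min_count),
                 threshold = threshold, delimiter = delimiter,
                 protected = protected),
            class = "pwas_phrases")
}

score_bigrams <- function(corpus_tokens, protected) {
  all_tok <- unlist(corpus_tokens, use.names = FALSE)
  n_total <- length(all_tok)
  uni <- table(all_tok)
  pair_keys <- unlist(lapply(corpus_tokens, function(t) {
    if (length(t) < 2L) return(character(0))
    a <- t[-length(t)]
    b <- t[-1L]
    ok <- !(a %in% protected) & !(b %in% protected)
    paste(a[ok], b[ok], sep = "\x01")
  }), use.names = FALSE)
  if (length(pair_keys) == 0L)
    return(data.frame(token_a = character(0), token_b = character(0),
                      count = integer(0), npmi = numeric(0)))
  bi <- table(pair_keys)
  parts <- strsplit(names(bi), "\x01", fixed = TRUE)
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, `[`, "", 2L)
  p_ab <- as.numeric(bi) / n_total
  p_a <- as.numeric(uni[a]) / n_total
  p_b <- as.numeric(uni[b]) / n_total
  npmi <- log(p_ab / (p_a * p_b)) / (-log(p_ab))
  data.frame(token_a = a, token_b = b, count = as.integer(bi), npmi = npmi,
             stringsAsFactors = FALSE)
}

merge_pass <- function(tokens, merge_set, delimiter) {
  n <- length(tokens)
  if (n < 2L) return(tokens)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    if (i < n && paste(tokens[i], tokens[i + 1L], sep = "\x01") %in% merge_set) {
      out <- c(out, paste(tokens[i], tokens[i + 1L], sep = delimiter))
      i <- i + 2L
    } else {
      out <- c(out, tokens[i])
      i <- i + 1L
    }
  }
  out
}

#' Apply a frozen phrase model
#'
#' Deterministically replays each pass's merges over a token vector.
#' Application is idempotent once the model is frozen.
#'
#' @param tokens character vector of tokens.
#' @param model a `pwas_phrases` model.
#' @return merged token vector.
#' @export
apply_phrases <- function(tokens, model) {
  stopifnot(inherits(model, "pwas_phrases"))
  for (tab in model$passes) {
    if (nrow(tab) == 0L) next
    merge_set <- paste(tab$token_a, tab$token_b, sep = "\x01")
    tokens <- merge_pass(tokens, merge_set, model$delimiter)
  }
  tokens
}

#' Serialize / read a phrase model as TSV
#'
#' Columns: pass, token_a, token_b, count, npmi.
#' @param model a `pwas_phrases` model.
#' @param path TSV path.
#' @return `path` invisibly / a `pwas_phrases` model.
#' @export
write_phrase_model <- function(model, path) {
  rows <- do.call(rbind, lapply(seq_along(model$passes), function(p) {
    tab <- model$passes[[p]]
    if (nrow(tab) == 0L) return(NULL)
    cbind(pass = p, tab)
  }))
  if (is.null(rows))
    rows <- data.frame(pass = integer(0), token_a = character(0),
                       token_b = character(0), count = integer(0),
                       npmi = numeric(0))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phrase_model
#' @param min_count,threshold,delimiter,protected model metadata to restore.
#' @export
read_phrase_model <- function(path, min_count = 10L, threshold = 0.7,
                              delimiter = "_", protected = character(0)) {
  rows <- read.delim(path, stringsAsFactors = FALSE)
  passes <- lapply(seq_len(max(rows$pass, 0L)), function(p)
    rows[rows$pass == p, c("token_a", "token_b", "count", "npmi")])
  structure(list(passes = passes, min_count = min_count,
                 threshold = threshold, delimiter = delimiter,
                 protected = protected),
            class = "pwas_phrases")
}

#' Slice a corpus at historical cut-off years
#'
#' Each slice holds exactly the documents published on or before 31 December
#' of its cut-off year; slices at increasing cut-offs are nested.
#'
#' @param corpus a `pwas_corpus` (list of tagged documents with `year`).
#' @param cutoff_years ascending integer vector of cut-off years.
#' @return list of `pwas_slice` objects (`cutoff_year`, `documents`).
#' @export
slice_corpus <- function(corpus, cutoff_years) {
  if (is.unsorted(cutoff_years)) stop("cutoff_years must be sorted ascending")
  years <- vapply(corpus, function(d) {
    if (is.null(d$year) || is.na(d$year)) stop("document lacking year: ",
                                               d$doc_id %||% "<no id>")
    as.integer(d$year)
  }, 0L)
  lapply(cutoff_years, function(cy) {
    docs <- corpus[years <= cy]
    if (length(docs) == 0L)
      message("slice ", cy, " is empty (cut-off precedes earliest document)")
    structure(list(cutoff_year = as.integer(cy), documents = docs),
              class = "pwas_slice")
  })
}

#' Build a training vocabulary for a corpus slice
#'
#' Keeps every token mentioned strictly more than `min_count` times, plus
#' protected canonical identifiers at any count of at least one. Identifiers
#' never mentioned in the slice are absent (and so cannot be ranked by the
#' resulting model).
#'
#' @param slice a `pwas_slice`, or a plain list of tagged documents.
#' @param protected canonical identifier tokens kept regardless of frequency.
#' @param min_count frequency floor for unprotected tokens (kept if
#'   count > min_count).
#' @return a `pwas_vocab`: named count vector (decreasing) plus the protected
#'   tokens actually present.
#' @export
build_vocabulary <- function(slice, protected = character(0), min_count = 10L) {
  docs <- if (inherits(slice, "pwas_slice")) slice$documents else slice
  if (length(docs) == 0L) stop("empty slice")
  counts <- table(unlist(lapply(docs, `[[`, "tokens"), use.names = FALSE))
  counts <- setNames(as.integer(counts), names(counts))
  keep <- counts > min_count | (names(counts) %in% protected)
  counts <- counts[keep]
  if (length(counts) == 0L) stop("vocabulary is empty at min_count = ", min_count)
  counts <- counts[order(-counts, names(counts))]
  structure(list(counts = counts,
                 protected = intersect(protected, names(counts)),
                 min_count = as.integer(min_count)),
            class = "pwas_vocab")
}

#' @export
print.pwas_vocab <- function(x, ...) {
  cat("<pwas_vocab>", length(x$counts), "tokens (",
      length(x$protected), "protected entity ids ), min_count",
      x$min_count, "\n")
  invisible(x)
}
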