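#' Construct a document
#'
#' A document is the basic record of a corpus: a unique identifier, an
#' ordered list of tokens, and a set of categorical metadata fields.  Each
#' metadata field maps to a character vector of one or more values (a
#' document may, for instance, carry several countries or authors).
#'
#' @param doc_id Unique document identifier (scalar character).
#' @param tokens Character vector of tokens (may be empty).
#' @param metadata Named list of character vectors of categorical values.
#' @return An object of class `"document"`.
#' @seealso [corpus()], [tokenize()]
#' @export
document <- function(doc_id, tokens = character(), metadata = list()) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, !is.na(doc_id))
  if (is.null(tokens)) tokens <- character()
  stopifnot(is.character(tokens))
  stopifnot(is.list(metadata))
  if (length(metadata)) {
    stopifnot(!is.null(names(metadata)), all(nzchar(names(metadata))))
    metadata <- lapply(metadata, function(v) as.character(v[!is.na(v)]))
    metadata <- metadata[vapply(metadata, length, 0L) > 0L]
  }
  structure(list(doc_id = doc_id, tokens = tokens, metadata = metadata),
            class = "document")
}

#' Construct a corpus
#'
#' Bundles a list of documents and derives the vocabulary as the union of
#' the documents' distinct tokens.  Document identifiers must be unique.
#'
#' @param documents List of [document()] objects.
#' @return An object of class `"corpus"` with elements `documents` and
#'   `vocabulary`.
#' @export
corpus <- function(documents) {
  stopifnot(is.list(documents),
            all(vapply(documents, inherits, TRUE, "document")))
  ids <- vapply(documents, `[[`, "", "doc_id")
  if (anyDuplicated(ids))
    stop("duplicate doc_id in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vocab <- sort(unique(unlist(lapply(documents, `[[`, "tokens"),
                              use.names = FALSE)))
  if (is.null(vocab)) vocab <- character()
  structure(list(documents = documents, vocabulary = vocab),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat("Corpus:", length(x$documents), "documents,",
      length(x$vocabulary), "distinct terms\n")
  invisible(x)
}

#' @export
print.document <- function(x, ...) {
  cat("Document", x$doc_id, "-", length(x$tokens), "tokens")
  if (length(x$metadata))
    cat("; metadata:", paste(names(x$metadata), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Tokenize a text string
#'
#' Deterministic, language-independent tokenisation: the text is lowercased
#' and split on runs of characters that are neither alphanumeric nor
#' underscore.  Underscores are preserved so that previously merged
#' collocations (e.g. `"stem_cells"`) survive a round trip through text.
#' No stemming, lemmatisation or stop-word removal is performed: the block
#' model is left to discover such patterns itself.
#'
#' @param text Character vector of texts.
#' @return For a single text, a character vector of tokens; for a vector of
#'   texts, a list of such vectors.
#' @examples
#' tokenize("Breast cancer; breast cancer.")
#' @export
tokenize <- function(text) {
  one <- function(s) {
    if (is.na(s) || !nzchar(s)) return(character())
    parts <- strsplit(tolower(s), "[^\\p{L}\\p{N}_]+", perl = TRUE)[[1L]]
    parts[nzchar(parts)]
  }
  if (length(text) == 1L) one(text) else lapply(text, one)
}

#' Detect bigram collocations in a corpus
#'
#' Scores every ordered pair of adjacent tokens with the discounted
#' normalised score \eqn{s(a,b) = N (c_{ab} - \delta) / (c_a c_b)}, where
#' \eqn{c_a}, \eqn{c_b} are unigram counts, \eqn{c_{ab}} the adjacent
#' bigram count, \eqn{N} the total token count and \eqn{\delta} a discount
#' that suppresses rare pairs.  Pairs with \eqn{s \ge} `threshold` and
#' \eqn{c_{ab} > \delta} are accepted for merging.  A single pass is made:
#' only bigrams, not higher n-grams, are detected.
#'
#' @param corpus A [corpus()] of tokenized documents.
#' @param delta Discount subtracted from bigram counts (default 5).
#' @param threshold Minimum score for acceptance (default 10).
#' @return An object of class `"collocation_table"` with the counts, the
#'   parameters, a score table and the set of accepted (merged) bigrams.
#' @export
detect_collocations <- function(corpus, delta = 5, threshold = 10) {
  stopifnot(inherits(corpus, "corpus"), delta >= 0, threshold > 0)
  toks <- lapply(corpus$documents, `[[`, "tokens")
  all_tok <- unlist(toks, use.names = FALSE)
  n_total <- length(all_tok)
  uni <- if (n_total) table(all_tok) else table(character())
  pair_a <- character(); pair_b <- character()
  for (tk in toks) {
    if (length(tk) >= 2L) {
      pair_a <- c(pair_a, tk[-length(tk)])
      pair_b <- c(pair_b, tk[-1L])
    }
  }
  if (length(pair_a)) {
    key <- paste(pair_a, pair_b, sep = "\r")
    big <- table(key)
    ka <- sub("\r.*$", "", names(big))
    kb <- sub("^.*\r", "", names(big))
    c_ab <- as.integer(big)
    c_a <- as.integer(uni[ka])
    c_b <- as.integer(uni[kb])
    score <- n_total * (c_ab - delta) / (c_a * c_b)
    ok <- score >= threshold & c_ab > delta
    scores <- data.frame(first = ka, second = kb, c_a = c_a, c_b = c_b,
                         c_ab = c_ab, score = score, merged = ok,
                         stringsAsFactors = FALSE, row.names = NULL)
    scores <- scores[order(-scores$score, scores$first, scores$second), ]
    rownames(scores) <- NULL
  } else {
    scores <- data.frame(first = character(), second = character(),
                         c_a = integer(), c_b = integer(), c_ab = integer(),
                         score = numeric(), merged = logical())
  }
  merged <- scores[scores$merged, c("first", "second")]
  structure(list(unigram_counts = uni, n_tokens = n_total,
                 delta = delta, threshold = threshold,
                 scores = scores,
                 merged = paste(merged$first, merged$second, sep = "\r")),
            class = "collocation_table")
}

#' @export
print.collocation_table <- function(x, ...) {
  cat("Collocation table:", nrow(x$scores), "adjacent pairs scored,",
      length(x$merged), "accepted (delta =", x$delta,
      ", threshold =", x$threshold, ")\n")
  invisible(x)
}

#' Replace accepted collocations in a document or corpus
#'
#' Performs a greedy left-to-right, non-overlapping replacement of accepted
#' adjacent bigrams by the joined token `"a_b"`.  When a token has been
#' consumed by a merge it cannot participate in the next pair.
#'
#' @param x A [document()] or [corpus()].
#' @param table A [detect_collocations()] result built on the same corpus.
#' @return Object of the same class with merged tokens.
#' @export
apply_collocations <- function(x, table) {
  stopifnot(inherits(table, "collocation_table"))
  merged_set <- table$merged
  merge_tokens <- function(tk) {
    n <- length(tk)
    if (n < 2L || !length(merged_set)) return(tk)
    out <- character(0)
    i <- 1L
    while (i <= n) {
      if (i < n && paste(tk[i], tk[i + 1L], sep = "\r") %in% merged_set) {
        out <- c(out, paste(tk[i], tk[i + 1L], sep = "_"))
        i <- i + 2L
      } else {
        out <- c(out, tk[i])
        i <- i + 1L
      }
    }
    out
  }
  if (inherits(x, "document")) {
    x$tokens <- merge_tokens(x$tokens)
    x
  } else if (inherits(x, "corpus")) {
    docs <- lapply(x$documents, function(d) {
      d$tokens <- merge_tokens(d$tokens)
      d
    })
    corpus(docs)
  } else stop("x must be a document or a corpus")
}

#' Read a corpus from a JSON-lines file
#'
#' Each line is a JSON object with an identifier field, a text field and
#' arbitrary further fields treated as categorical metadata.  The text is
#' passed through [tokenize()].
#'
#' @param path Path to a UTF-8 JSON-lines file.
#' @param text_field Name of the text field (default `"text"`).
#' @param id_field Name of the identifier field (default `"id"`).
#' @return A [corpus()].
#' @export
read_corpus_jsonl <- function(path, text_field = "text", id_field = "id") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  docs <- lapply(seq_along(lines), function(i) {
    rec <- jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE)
    if (is.null(rec[[id_field]]))
      stop("line ", i, ": missing id field '", id_field, "'")
    txt <- rec[[text_field]]
    if (is.null(txt)) txt <- ""
    meta <- rec[setdiff(names(rec), c(id_field, text_field))]
    meta <- lapply(meta, as.character)
    document(as.character(rec[[id_field]]), tokenize(paste(txt, collapse = " ")),
             metadata = meta)
  })
  corpus(docs)
}

#' Read a corpus from a delimited file
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param text_field Name of the column holding the text.
#' @param id_field Name of the identifier column; if absent, row numbers
#'   are used.
#' @param sep Field separator (default `"\t"`; use `","` for CSV).
#' @return A [corpus()]; every column other than the id and text columns
#'   becomes a single-valued metadata field.
#' @export
read_corpus_table <- function(path, text_field = "text", id_field = "id",
                              sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          fileEncoding = "UTF-8", check.names = FALSE)
  if (!text_field %in% names(df))
    stop("text column '", text_field, "' not found")
  ids <- if (id_field %in% names(df)) as.character(df[[id_field]])
         else as.character(seq_len(nrow(df)))
  meta_cols <- setdiff(names(df), c(text_field, id_field))
  docs <- lapply(seq_len(nrow(df)), function(i) {
    meta <- lapply(df[meta_cols], function(col) as.character(col[i]))
    document(ids[i], tokenize(df[[text_field]][i]), metadata = meta)
  })
  corpus(docs)
}

#' One-call corpus preprocessing
#'
#' Convenience wrapper chaining [detect_collocations()] and
#' [apply_collocations()].
#'
#' @param corpus A tokenized [corpus()].
#' @param delta,threshold Collocation parameters, see
#'   [detect_collocations()].
#' @return A list with elements `corpus` (the processed corpus) and
#'   `collocations` (the table).
#' @export
preprocess_corpus <- function(corpus, delta = 5, threshold = 10) {
  tab <- detect_collocations(corpus, delta = delta, threshold = threshold)
  list(corpus = apply_collocations(corpus, tab), collocations = tab)
}
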