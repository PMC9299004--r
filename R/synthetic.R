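#' Specification of a planted-structure corpus
#'
#' Describes a synthetic corpus with known ground truth: documents belong
#' to planted domains, each domain draws its terms from a characteristic
#' mixture over planted topics (term blocks), contaminated by a uniform
#' background component, and may carry a year whose distribution drifts
#' across domains (planted eras).  Generated corpora exercise the same
#' structure the block model assumes -- binary document-term incidence
#' with blockwise connectivity -- which is what makes recovery testable;
#' real corpora add burstiness, fat-tailed vocabulary growth and
#' correlated metadata that the generator deliberately omits.
#'
#' @param n_docs Total number of documents.
#' @param n_terms Number of planted (signal) terms.
#' @param n_domains Number of planted level-1 domains; documents are
#'   split evenly.
#' @param n_topics Number of planted level-1 topics; signal terms are
#'   split evenly (requires `n_terms >= n_topics`).
#' @param mixture Optional `n_domains x n_topics` matrix of topic
#'   mixtures (rows sum to 1); defaults to a shifted, peaked mixture
#'   making every topic profile distinct across domains.
#' @param terms_per_doc Mean number of term draws per document (the
#'   distinct term count is slightly lower after deduplication).
#' @param dispersion Negative-binomial size parameter for the draw count
#'   (large = near-Poisson).
#' @param epsilon Background mixing weight in `[0, 1)`: with this
#'   probability a draw is uniform over the whole vocabulary, emulating
#'   the stop-word-like background the model isolates into its own
#'   topics.
#' @param n_background_terms Extra terms reachable only through the
#'   background component (0 = none).
#' @param n_years Number of year values (0 = no year metadata).
#' @param eras List of integer vectors partitioning `1:n_years` into
#'   consecutive eras (default: two halves).
#' @param domain_era Integer vector of length `n_domains` assigning each
#'   domain to an era.
#' @param era_weight Probability that a document's year falls inside its
#'   domain's era.
#' @param seed Seed used by [generate_corpus()].
#' @return An object of class `"planted_spec"`.
#' @export
planted_spec <- function(n_docs = 300L, n_terms = 60L, n_domains = 3L,
                         n_topics = 4L, mixture = NULL,
                         terms_per_doc = 25, dispersion = 50,
                         epsilon = 0.05, n_background_terms = 0L,
                         n_years = 0L, eras = NULL, domain_era = NULL,
                         era_weight = 0.9, seed = 1L) {
  stopifnot(n_docs >= n_domains, n_terms >= n_topics,
            epsilon >= 0, epsilon < 1, terms_per_doc > 0)
  if (is.null(mixture)) {
    # strong-signal default: each domain owns one topic exclusively
    # (weight 0.75); topics beyond the owned ones are shared evenly by
    # all domains, giving every topic a distinct cross-domain profile
    mixture <- matrix(0, n_domains, n_topics)
    for (d in seq_len(n_domains)) {
      own <- (d - 1L) %% n_topics + 1L
      mixture[d, own] <- 0.75
      shared <- if (n_topics > n_domains)
        seq.int(n_domains + 1L, n_topics) else setdiff(seq_len(n_topics),
                                                       own)
      mixture[d, shared] <- mixture[d, shared] + 0.25 / length(shared)
    }
  }
  stopifnot(nrow(mixture) == n_domains, ncol(mixture) == n_topics,
            all(abs(rowSums(mixture) - 1) < 1e-8), all(mixture >= 0))
  if (n_years > 0L) {
    if (is.null(eras))
      eras <- list(seq_len(floor(n_years / 2)),
                   seq.int(floor(n_years / 2) + 1L, n_years))
    if (is.null(domain_era))
      domain_era <- rep(seq_along(eras), length.out = n_domains)
    stopifnot(length(domain_era) == n_domains,
              all(domain_era %in% seq_along(eras)),
              setequal(unlist(eras), seq_len(n_years)))
  }
  structure(list(n_docs = as.integer(n_docs), n_terms = as.integer(n_terms),
                 n_domains = as.integer(n_domains),
                 n_topics = as.integer(n_topics), mixture = mixture,
                 terms_per_doc = terms_per_doc, dispersion = dispersion,
                 epsilon = epsilon,
                 n_background_terms = as.integer(n_background_terms),
                 n_years = as.integer(n_years), eras = eras,
                 domain_era = domain_era, era_weight = era_weight,
                 seed = as.integer(seed)),
            class = "planted_spec")
}

#' Generate a planted-structure corpus
#'
#' Draws a corpus from a [planted_spec()]: each document picks its number
#' of term draws from a negative binomial, then for each draw either a
#' uniform background term (probability `epsilon`) or a topic from its
#' domain's mixture followed by a uniform term within the topic.  The
#' document's term set is deduplicated, matching the binary incidence
#' the model works on.  Years, when present, are drawn from the domain's
#' era with probability `era_weight`, uniformly otherwise.  Fully
#' deterministic given the spec's seed.
#'
#' @param spec A [planted_spec()].
#' @return A list with `corpus` (a [corpus()]) and `truth`: a list with
#'   per-document domain labels (`domains`), per-term topic labels
#'   (`topics`, 0 marks background terms), `doc_ids`, `terms`, the
#'   realised domain-by-topic draw counts (`topic_draws`, before
#'   deduplication) and, if years were generated, `years` and `eras`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  set.seed(spec$seed)
  n_vocab <- spec$n_terms + spec$n_background_terms
  width <- nchar(as.character(n_vocab))
  terms <- sprintf(paste0("term%0", width, "d"), seq_len(n_vocab))
  term_topic <- c(rep(seq_len(spec$n_topics),
                      each = ceiling(spec$n_terms / spec$n_topics))[
                        seq_len(spec$n_terms)],
                  rep(0L, spec$n_background_terms))
  topic_members <- split(seq_len(spec$n_terms),
                         term_topic[seq_len(spec$n_terms)])
  doc_domain <- sort(rep(seq_len(spec$n_domains),
                         length.out = spec$n_docs))
  doc_ids <- sprintf(paste0("doc%0", nchar(as.character(spec$n_docs)),
                            "d"), seq_len(spec$n_docs))
  docs <- vector("list", spec$n_docs)
  years <- if (spec$n_years > 0L) integer(spec$n_docs) else NULL
  topic_draws <- matrix(0L, spec$n_domains, spec$n_topics)
  for (i in seq_len(spec$n_docs)) {
    d <- doc_domain[i]
    n_draw <- max(1L, stats::rnbinom(1L, size = spec$dispersion,
                                     mu = spec$terms_per_doc))
    is_bg <- stats::runif(n_draw) < spec$epsilon
    n_sig <- sum(!is_bg)
    drawn <- integer(0)
    if (n_sig > 0L) {
      tps <- sample.int(spec$n_topics, n_sig, replace = TRUE,
                        prob = spec$mixture[d, ])
      topic_draws[d, ] <- topic_draws[d, ] + tabulate(tps, spec$n_topics)
      drawn <- vapply(tps, function(tp) {
        mem <- topic_members[[tp]]
        mem[sample.int(length(mem), 1L)]
      }, 0L)
    }
    if (any(is_bg))
      drawn <- c(drawn, sample.int(n_vocab, sum(is_bg), replace = TRUE))
    toks <- terms[sort(unique(drawn))]
    meta <- list()
    if (spec$n_years > 0L) {
      era <- spec$domain_era[d]
      own <- spec$eras[[era]]
      other <- setdiff(seq_len(spec$n_years), own)
      yr <- if (!length(other) || stats::runif(1L) < spec$era_weight)
        own[sample.int(length(own), 1L)]
      else other[sample.int(length(other), 1L)]
      years[i] <- yr
      meta$year <- as.character(yr)
    }
    docs[[i]] <- document(doc_ids[i], toks, metadata = meta)
  }
  truth <- list(domains = doc_domain, topics = term_topic,
                doc_ids = doc_ids, terms = terms,
                topic_draws = topic_draws)
  if (!is.null(years)) {
    truth$years <- years
    truth$eras <- spec$eras
  }
  list(corpus = corpus(docs), truth = truth)
}

#' Write a generated corpus as JSON-lines plus ground truth
#'
#' @param gen Result of [generate_corpus()].
#' @param corpus_path Output JSON-lines file (one document per line with
#'   `id`, `text` and metadata fields).
#' @param truth_path Optional output JSON file for the ground truth.
#' @return Invisibly, `corpus_path`.
#' @export
write_corpus_jsonl <- function(gen, corpus_path, truth_path = NULL) {
  lines <- vapply(gen$corpus$documents, function(d) {
    rec <- c(list(id = d$doc_id, text = paste(d$tokens, collapse = " ")),
             lapply(d$metadata, function(v)
               if (length(v) == 1L) v else as.list(v)))
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, "")
  writeLines(lines, corpus_path, useBytes = TRUE)
  if (!is.null(truth_path))
    writeLines(as.character(jsonlite::toJSON(gen$truth,
                                             auto_unbox = FALSE)),
               truth_path)
  invisible(corpus_path)
}
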