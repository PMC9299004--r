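test_that("tokenization lowercases, splits on non-alphanumerics and keeps underscores", {
  expect_identical(tokenize(""), character())
  expect_identical(tokenize("Breast cancer; breast cancer."),
                   c("breast", "cancer", "breast", "cancer"))
  expect_identical(tokenize("stem_cells rock"), c("stem_cells", "rock"))
  expect_identical(tokenize("HER2-positive (n=42)"),
                   c("her2", "positive", "n", "42"))
  # deterministic
  expect_identical(tokenize("A b C"), tokenize("A b C"))
})

test_that("collocation scores follow the discounted normalised formula", {
  # c_a=10, c_b=12, c_ab=9, N=1000 -> score = 1000 * (9-5) / 120
  docs <- list()
  # build a corpus realising exactly these counts: 9 adjacent "a b" pairs,
  # 1 extra "a" (separated), 3 extra "b", filler tokens to reach N = 1000
  toks <- c(rep(c("a", "b", "x"), 9), "a", "y", rep("b", 3),
            paste0("f", seq_len(1000 - 27 - 5)))
  cps <- corpus(list(document("d1", toks)))
  tab <- detect_collocations(cps, delta = 5, threshold = 10)
  row <- tab$scores[tab$scores$first == "a" & tab$scores$second == "b", ]
  expect_equal(row$c_a, 10)
  expect_equal(row$c_b, 12)
  expect_equal(row$c_ab, 9)
  expect_equal(row$score, 1000 * 4 / 120)
  expect_true(row$merged)
})

test_that("rare pairs are suppressed by the discount and scores ignore document order", {
  docs <- list(document("d1", c("p", "q", "r")),
               document("d2", c("s", "p", "q")))
  t1 <- detect_collocations(corpus(docs), delta = 5, threshold = 10)
  expect_length(t1$merged, 0)          # all c_ab <= 2 <= delta
  t2 <- detect_collocations(corpus(rev(docs)), delta = 5, threshold = 10)
  expect_equal(t1$scores[order(t1$scores$first), ]$score,
               t2$scores[order(t2$scores$first), ]$score)
})

test_that("frequent pair is merged, rare companion is discounted away", {
  docs <- c(lapply(1:20, function(i) document(paste0("d", i),
                                              c("stem", "cells"))),
            list(document("d21", c("stem", "therapy"))))
  # delta = 1 removes single-occurrence pairs via the c_ab > delta guard
  tab <- detect_collocations(corpus(docs), delta = 1, threshold = 1)
  expect_true("stem\rcells" %in% tab$merged)
  expect_false("stem\rtherapy" %in% tab$merged)
  out <- apply_collocations(document("x", c("stem", "cells", "now")), tab)
  expect_identical(out$tokens, c("stem_cells", "now"))
})

test_that("collocation replacement is greedy, left-to-right and non-overlapping", {
  tab <- structure(list(merged = c("a\rb", "b\rc"), delta = 0,
                        threshold = 1,
                        scores = data.frame()),
                   class = "collocation_table")
  d <- apply_collocations(document("x", c("a", "b", "b", "c")), tab)
  expect_identical(d$tokens, c("a_b", "b_c"))
  d2 <- apply_collocations(document("x", c("a", "b", "c")), tab)
  expect_identical(d2$tokens, c("a_b", "c"))     # first pair wins
  # empty merged set leaves tokens unchanged
  tab$merged <- character()
  expect_identical(apply_collocations(document("x", c("a", "b")),
                                      tab)$tokens, c("a", "b"))
  # the canonical oncology bigram
  tab$merged <- "breast\rcancer"
  expect_identical(apply_collocations(
    document("x", c("breast", "cancer", "care")), tab)$tokens,
    c("breast_cancer", "care"))
})

test_that("document-term graph uses distinct terms and drops empty documents", {
  cps <- toy_corpus()
  g <- build_doc_term_graph(cps)
  expect_equal(nrow(g$edges), sum(vapply(cps$documents, function(d)
    length(unique(d$tokens)), 0L)))
  # local repetitions collapse to one edge
  g2 <- build_doc_term_graph(corpus(list(
    document("a", c("pain", "pain", "pain")),
    document("b", c("pain", "relief")))))
  expect_equal(nrow(g2$edges), 3L)
  expect_equal(length(g2$right), 2L)
  # 2 docs of 3 terms sharing 1 term: 6 edges, 5 term nodes
  g3 <- build_doc_term_graph(corpus(list(
    document("a", c("x", "y", "z")), document("b", c("z", "u", "v")))))
  expect_equal(nrow(g3$edges), 6L)
  expect_equal(length(g3$right), 5L)
  expect_warning(build_doc_term_graph(corpus(list(
    document("a", c("x")), document("b", character())))),
    "dropping")
})

test_that("document-metadata graph links documents to each value of a field", {
  cps <- toy_corpus()
  gy <- build_doc_metadata_graph(cps, "year")
  expect_equal(length(gy$right), 2L)            # 1995, 1996
  expect_equal(nrow(gy$edges), 3L)              # d2, d3, d4
  expect_false("d1" %in% gy$left)               # no year -> omitted
  gc <- build_doc_metadata_graph(cps, "country")
  expect_equal(nrow(gc$edges), 2L)              # multi-valued: fr + br
  expect_error(build_doc_metadata_graph(cps, "journal"), "no document")
})

test_that("corpus reading round-trips through JSON-lines and TSV", {
  gen <- generate_corpus(planted_spec(n_docs = 12, n_terms = 15,
                                      n_topics = 3, n_years = 4,
                                      seed = 5))
  f <- tempfile(fileext = ".jsonl")
  write_corpus_jsonl(gen, f)
  cps <- read_corpus_jsonl(f)
  expect_equal(length(cps$documents), 12L)
  expect_identical(cps$vocabulary, gen$corpus$vocabulary)
  expect_identical(lapply(cps$documents, `[[`, "tokens"),
                   lapply(gen$corpus$documents, function(d)
                     sort(d$tokens)))
  expect_identical(cps$documents[[1L]]$metadata$year,
                   gen$corpus$documents[[1L]]$metadata$year)
  # TSV
  f2 <- tempfile(fileext = ".tsv")
  df <- data.frame(id = c("a", "b"), text = c("tumor growth", "cell line"),
                   year = c(1995L, 1996L))
  utils::write.table(df, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  cps2 <- read_corpus_table(f2)
  expect_equal(cps2$documents[[2L]]$tokens, c("cell", "line"))
  expect_equal(cps2$documents[[1L]]$metadata$year, "1995")
})

test_that("preprocessing is deterministic end to end", {
  gen <- generate_corpus(planted_spec(n_docs = 20, n_terms = 12,
                                      n_topics = 3, seed = 9))
  run <- function() {
    pp <- preprocess_corpus(gen$corpus, delta = 0, threshold = 2)
    g <- build_doc_term_graph(pp$corpus)
    list(g$left, g$right, g$edges)
  }
  expect_identical(run(), run())
})
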