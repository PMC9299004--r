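chained_fixture <- function(seed, era_weight = 0.9) {
  gen <- generate_corpus(planted_spec(seed = seed, n_years = 10,
                                      era_weight = era_weight))
  g <- build_doc_term_graph(gen$corpus)
  m <- fit_dtm(g, fit_config(seed = seed))
  gy <- build_doc_metadata_graph(gen$corpus, "year")
  ch <- fit_chained(gy, m, fit_config(seed = seed))
  list(gen = gen, model = m, graph = gy, chained = ch)
}

test_that("a single metadata value yields one block at every level", {
  gen <- generate_corpus(planted_spec(n_docs = 40, n_terms = 20,
                                      n_topics = 2, seed = 2))
  docs <- lapply(gen$corpus$documents, function(d) {
    d$metadata$year <- "2000"
    d
  })
  cps <- corpus(docs)
  m <- fit_dtm(build_doc_term_graph(cps), fit_config(seed = 2))
  ch <- fit_chained(build_doc_metadata_graph(cps, "year"), m,
                    fit_config(seed = 2))
  for (l in seq_len(n_levels(ch)))
    expect_equal(unname(n_blocks(ch, l)["right"]), 1L)
})

test_that("planted eras are recovered as contiguous level-1 periods", {
  fx <- chained_fixture(seed = 3)
  mem <- membership(fx$chained, 1, "right")
  planted <- ifelse(as.integer(fx$chained$graph$right) <= 5, 1L, 2L)
  expect_equal(ari(mem, planted), 1)
  ps <- period_summary(fx$chained)
  expect_true(all(ps$table$contiguous[ps$table$level == 1]))
})

test_that("document blocks are frozen: assignments identical before and after", {
  fx <- chained_fixture(seed = 8)
  idx <- match(fx$chained$graph$left, fx$model$graph$left)
  for (l in seq_len(min(n_levels(fx$model), n_levels(fx$chained)))) {
    before <- membership(fx$model, l, "left")[idx]
    after <- membership(fx$chained, l, "left")
    expect_identical(digest_vec(before), digest_vec(after))
  }
})

test_that("chained DL is invariant to metadata node presentation order", {
  fx <- chained_fixture(seed = 5)
  g <- fx$graph
  set.seed(99)
  perm <- sample(length(g$right))
  g2 <- domtopics:::bipartite_graph(g$left, g$right[perm],
                                    cbind(g$edges[, 1],
                                          match(g$edges[, 2], perm)),
                                    right_type = g$right_type)
  ch2 <- fit_chained(g2, fx$model, fit_config(seed = 5))
  expect_equal(ch2$dl$total, fx$chained$dl$total, tolerance = 1e-8)
})

test_that("period summary flags non-contiguous blocks and the highest split", {
  # hand-built chained-like object: years 1995-1997, block {1995,1997}
  g <- domtopics:::bipartite_graph(
    paste0("d", 1:3), c("1995", "1996", "1997"),
    cbind(1:3, 1:3), right_type = "year")
  part <- nested_partition(list(
    list(left = c(1L, 1L, 1L), right = c(1L, 2L, 1L)),
    list(left = 1L, right = c(1L, 1L))))
  ch <- structure(list(graph = g, partition = part,
                       left_labels = list("L1D0", "L2D0")),
                  class = "chained_model")
  ps <- period_summary(ch)
  l1 <- ps$table[ps$table$level == 1, ]
  expect_false(l1$contiguous[l1$block == 1])
  expect_true(l1$contiguous[l1$block == 2])
  expect_equal(ps$highest_split_level, 1L)
})

test_that("sub-corpus re-chaining restricts documents and keeps block order", {
  fx <- chained_fixture(seed = 6)
  keep <- fx$model$graph$left[membership(fx$model, 1, "left") != 1L]
  sub <- subset_graph(fx$graph, keep)
  expect_true(all(sub$left %in% keep))
  ch <- fit_chained(sub, fx$model, fit_config(seed = 6))
  # frozen blocks present are exactly the domains of the kept documents
  expect_identical(
    ch$doc_blocks_present,
    sort(unique(membership(fx$model, 1, "left")[
      match(sub$left, fx$model$graph$left)])))
  idx <- match(sub$left, fx$model$graph$left)
  raw <- membership(fx$model, 1, "left")[idx]
  expect_identical(membership(ch, 1, "left"),
                   match(raw, sort(unique(raw))))
})
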