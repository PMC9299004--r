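test_that("block labels follow the level/kind/index convention", {
  expect_equal(block_label(2, "T", 29), "L2T29")
  expect_equal(block_label(3, "D", 40), "L3D40")
  p <- parse_block_label("L2T29")
  expect_equal(p$level, 2L); expect_equal(p$kind, "T")
  expect_equal(p$index, 29L)
  expect_error(parse_block_label("T29"), "malformed")
  # domain indices start after the topic indices within a level
  gen <- generate_corpus(planted_spec(n_docs = 60, n_terms = 30,
                                      n_topics = 3, seed = 2))
  m <- fit_dtm(build_doc_term_graph(gen$corpus), fit_config(seed = 2))
  labs <- domtopics:::model_labels(m)
  BT <- n_blocks(m, 1)["right"]
  expect_equal(labs$right[[1]][1], block_label(1, "T", 0))
  expect_equal(labs$left[[1]][1], block_label(1, "D", BT))
  expect_false(anyDuplicated(unlist(labs)) > 0)
})

test_that("the half-sum topic rule selects the smallest qualifying prefix", {
  expect_equal(select_topics(c(a = 5, b = 3, c = 2, d = -1)), "a")
  expect_equal(select_topics(c(a = 4, b = 4, c = 2)), c("a", "b"))
  expect_equal(select_topics(c(a = -1, b = -2)), character())
  # boundary: prefix reaching exactly half qualifies
  expect_equal(select_topics(c(a = 5, b = 5)), "a")
  # input order does not matter
  expect_equal(select_topics(c(c = 2, a = 5, d = -1, b = 3)), "a")
  # -Inf values never qualify
  expect_equal(select_topics(c(a = 2, b = -Inf)), "a")
})

test_that("the half-max term rule keeps values strictly above half the peak", {
  expect_equal(select_terms(c(w = 10, x = 6, y = 5, z = 4)), c("w", "x"))
  expect_equal(select_terms(c(only = 3)), "only")
  expect_equal(select_terms(c(a = 2, b = 2, c = 2)), c("a", "b", "c"))
  # all non-positive: fall back to the single best
  expect_equal(select_terms(c(a = -1, b = -3)), "a")
})

test_that("domain-topic tables nest common and specific topics correctly", {
  mix <- matrix(0, 6, 8)
  for (d in 1:6) {
    mix[d, d + (d > 3)] <- 0.6
    mix[d, if (d <= 3) 4 else 8] <- 0.4
  }
  gen <- generate_corpus(planted_spec(n_docs = 360, n_terms = 80,
                                      n_domains = 6, n_topics = 8,
                                      mixture = mix, seed = 11))
  g <- build_doc_term_graph(gen$corpus)
  m <- fit_dtm(g, fit_config(seed = 11))
  skip_if(n_levels(m) < 3, "hierarchy did not form at this seed")
  labs <- domtopics:::model_labels(m)
  focal <- labs$left[[2]][1]
  tab <- domain_topic_table(m, focal)
  df <- tab$table
  expect_equal(df$kind[df$level >= 2], rep("commonality",
                                           sum(df$level >= 2)))
  expect_equal(df$kind[df$level == 1], rep("specificity",
                                           sum(df$level == 1)))
  # every level-1 subdomain of the focal domain appears
  kids <- block_children(m, 2, "left", 1)
  expect_true(all(labs$left[[1]][kids] %in% df$domain))
  # the group-shared topic is common to the focal domain and each child's
  # own topic is its top specific topic
  common <- df$topics[df$domain == focal]
  expect_true(nzchar(common))
  for (k in kids) {
    own <- names(which.max(nested_specificity(m, labs$left[[1]][k])))
    expect_true(grepl(own, df$topics[df$domain == labs$left[[1]][k]],
                      fixed = TRUE))
  }
  expect_error(domain_topic_table(m, labs$left[[1]][1]), "level >= 2")
  # table and map agree: the top specific topic of a level-1 domain is
  # the argmax-relevance topic under that domain's selection
  d1 <- labs$left[[1]][kids[1]]
  own <- names(which.max(nested_specificity(m, d1)))
  mp <- map_export(m, selection = d1)
  # walk the topic tree collecting level-1 relevance
  rel1 <- c(); lab1 <- c()
  walk <- function(nd) {
    if (nd$level == 1) { rel1 <<- c(rel1, nd$relevance);
                         lab1 <<- c(lab1, nd$label) }
    for (ch in nd$children %||% list()) walk(ch)
  }
  walk(mp$topics)
  expect_equal(lab1[which.max(rel1)], own)
})

test_that("map export normalises relevance and preserves volume sums", {
  gen <- generate_corpus(planted_spec(n_docs = 90, n_terms = 30,
                                      n_topics = 3, n_years = 6,
                                      seed = 6))
  g <- build_doc_term_graph(gen$corpus)
  m <- fit_dtm(g, fit_config(seed = 6))
  yrs <- vapply(gen$corpus$documents, function(d) d$metadata$year, "")
  names(yrs) <- vapply(gen$corpus$documents, `[[`, "", "doc_id")
  mp <- map_export(m, years = yrs)
  # children volumes sum to parent volume on both sides
  check_sums <- function(nd) {
    kids <- nd$children %||% list()
    if (length(kids)) {
      expect_equal(sum(vapply(kids, `[[`, 0, "volume")), nd$volume)
      for (ch in kids) check_sums(ch)
    }
  }
  check_sums(mp$domains); check_sums(mp$topics)
  # root volumes: all documents / all edges
  expect_equal(mp$domains$volume, length(g$left))
  expect_equal(mp$topics$volume, nrow(g$edges))
  # per-level max relevance is 1
  rels <- list()
  walk <- function(nd) {
    rels[[as.character(nd$level)]] <<-
      c(rels[[as.character(nd$level)]], nd$relevance)
    for (ch in nd$children %||% list()) walk(ch)
  }
  walk(mp$domains)
  for (lv in rels) expect_equal(max(lv), 1)
  # histogram covers all years; restricted under a domain selection
  expect_equal(sum(mp$histogram$n_documents), length(g$left))
  labs <- domtopics:::model_labels(m)
  mp2 <- map_export(m, selection = labs$left[[1]][1], years = yrs)
  expect_equal(sum(mp2$histogram$n_documents),
               sum(membership(m, 1, "left") == 1L))
  # topic selection: domain relevance proportional to p(t|d), max 1
  tsel <- labs$right[[1]][1]
  mp3 <- map_export(m, selection = tsel)
  rel1 <- c(); ids <- c()
  walk2 <- function(nd) {
    if (nd$level == 1) { rel1 <<- c(rel1, nd$relevance);
                         ids <<- c(ids, nd$label) }
    for (ch in nd$children %||% list()) walk2(ch)
  }
  walk2(mp3$domains)
  p <- vapply(ids, function(dd) unname(topic_usage(m, dd)[tsel]), 0)
  expect_equal(unname(rel1), unname(p / max(p)), tolerance = 1e-12)
  expect_error(map_export(m, selection = "L1T99"), "unknown")
  # search index maps each term to its level-1 topic
  expect_equal(unname(unlist(mp$term_index[g$right[1]])),
               labs$right[[1]][m$partition$levels[[1]]$right[1]])
})

test_that("bump-chart volumes, shares and ranks follow the stated rules", {
  gen <- generate_corpus(planted_spec(seed = 4, n_years = 10))
  g <- build_doc_term_graph(gen$corpus)
  m <- fit_dtm(g, fit_config(seed = 4))
  gy <- build_doc_metadata_graph(gen$corpus, "year")
  ch <- fit_chained(gy, m, fit_config(seed = 4))
  bc <- bump_chart_data(m, ch, level = 1)
  for (p in unique(bc$period)) {
    sl <- bc[bc$period == p, ]
    expect_equal(sort(sl$rank), seq_len(nrow(sl)))   # a permutation
    expect_lte(sum(sl$relative), 1 + 1e-12)
    n_years <- sum(ch$partition$levels[[1]]$right ==
                     which(domtopics:::model_labels(ch)$right[[1]] == p))
    expect_equal(sl$absolute, sl$n_docs / n_years)
  }
  # equal volumes break ties by label index
  rk <- domtopics:::rank_by_volume(c(5, 5, 1), c("L1D9", "L1D8", "L1D10"))
  expect_equal(rk, c(2L, 1L, 3L))
})
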