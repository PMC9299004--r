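# model with a known 3-level hierarchy for hand checks
hier_model <- function(seed = 11) {
  mix <- matrix(0, 6, 8)
  for (d in 1:6) {
    mix[d, d + (d > 3)] <- 0.6
    mix[d, if (d <= 3) 4 else 8] <- 0.4
  }
  gen <- generate_corpus(planted_spec(n_docs = 360, n_terms = 80,
                                      n_domains = 6, n_topics = 8,
                                      mixture = mix, seed = seed))
  g <- build_doc_term_graph(gen$corpus)
  m <- fit_dtm(g, fit_config(seed = seed))
  list(gen = gen, graph = g, model = m)
}

test_that("topic usage is an edge-fraction distribution with dominance", {
  fx <- hier_model()
  m <- fx$model
  labs <- domtopics:::model_labels(m)
  for (lab in labs$left[[1]][1:3]) {
    p <- topic_usage(m, lab)
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
  }
  # hand count: fraction of a domain's edges landing in each topic
  bl <- m$partition$levels[[1]]$left
  br <- m$partition$levels[[1]]$right
  in_d <- bl[m$graph$edges[, 1]] == 1L
  cnt <- tabulate(br[m$graph$edges[in_d, 2]], max(br))
  expect_equal(unname(topic_usage(m, labs$left[[1]][1])), cnt / sum(cnt))
  # dominance: ancestor usage positive wherever the domain's is
  if (n_levels(m) >= 2) {
    p_d <- topic_usage(m, labs$left[[1]][1])
    anc <- m$partition$levels[[2]]$left[1]
    p_a <- topic_usage(m, list(side = "left", level = 2, id = anc))
    expect_true(all(p_a[p_d > 0] > 0))
  }
})

test_that("specificity matches a hand evaluation of the displayed formula", {
  # p_dt = 0.5, ancestors 0.25 and 0.125
  s <- domtopics:::specificity_from_p(c(0.5, 0.5),
                                      list(c(0.25, 0.75),
                                           c(0.125, 0.875)))
  expect_equal(s[1], (0.5 * log(2) + 0.5 * log(4)) / 2, tolerance = 1e-12)
  # identical distributions score zero; absent topic scores zero
  expect_equal(domtopics:::specificity_from_p(
    c(0.3, 0.7), list(c(0.3, 0.7))), c(0, 0))
  expect_equal(domtopics:::specificity_from_p(
    c(0, 1), list(c(0.4, 0.6)))[1], 0)
})

test_that("commonality matches a hand evaluation, including the -Inf limit", {
  # two subdomains p = (0.4, 0.2), one ancestor p = 0.25
  cc <- domtopics:::commonality_from_p(
    list(c(0.4, 0.6), c(0.2, 0.8)), list(c(0.25, 0.75)))
  expect_equal(cc$cstar[1], (log(0.4 / 0.25) + log(0.2 / 0.25)) / 2,
               tolerance = 1e-12)
  expect_equal(cc$chat[1], 0.3 * cc$cstar[1], tolerance = 1e-12)
  # topic missing from one subdomain but not all: -Inf
  cc2 <- domtopics:::commonality_from_p(
    list(c(0, 1), c(0.2, 0.8)), list(c(0.1, 0.9)))
  expect_identical(cc2$chat[1], -Inf)
  # missing from every subdomain: weight 0 resolves to 0
  cc3 <- domtopics:::commonality_from_p(
    list(c(0, 1), c(0, 1)), list(c(0, 1)))
  expect_identical(cc3$chat[1], 0)
})

test_that("measures agree with an independent transcription on random models", {
  n_checked <- 0L
  for (s in 1:30) {
    g <- random_bipartite(12, 10, 0.35, seed = 400 + s)
    p <- random_nested_partition(12, 10, seed = 500 + s)
    m <- dtm_from_state(g, p)
    L <- n_levels(m)
    if (L < 2) next
    for (lev in seq_len(L - 1)) {
      for (id in seq_len(n_blocks(m, lev)["left"])) {
        ref <- list(side = "left", level = lev, id = id)
        got <- nested_specificity(m, ref)
        want <- oracle_specificity(g, p, "left", lev, id)
        expect_equal(unname(got), want, tolerance = 1e-12)
        expect_gte(sum(got), -1e-12)     # sum of KL terms is nonnegative
        expect_true(all(is.finite(got)))
        if (lev >= 2) {
          gotc <- nested_commonality(m, ref)
          wantc <- oracle_commonality(g, p, "left", lev, id)$chat
          expect_equal(unname(gotc), wantc, tolerance = 1e-12)
        }
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gte(n_checked, 50L)
})

test_that("scores are invariant to block relabeling", {
  g <- random_bipartite(10, 8, 0.4, seed = 610)
  p <- random_nested_partition(10, 8, seed = 611)
  if (n_levels(p) >= 2) {
    # relabel level-1 right blocks by reversing ids
    BR <- max(p$levels[[1]]$right)
    perm <- rev(seq_len(BR))
    lv <- p$levels
    lv[[1]]$right <- perm[lv[[1]]$right]
    lv[[2]]$right <- lv[[2]]$right[order(perm)]
    p2 <- nested_partition(lapply(lv, identity))
    m1 <- dtm_from_state(g, p)
    m2 <- dtm_from_state(g, p2)
    lev <- 1
    s1 <- nested_specificity(m1, list(side = "left", level = lev, id = 1))
    s2 <- nested_specificity(m2, list(side = "left", level = lev, id = 1))
    expect_equal(sort(unname(s1)), sort(unname(s2)), tolerance = 1e-12)
  }
})

test_that("element and transposed scores behave as expected", {
  fx <- hier_model()
  m <- fx$model
  labs <- domtopics:::model_labels(m)
  # a term exclusive to one domain has positive specificity there
  dom1 <- labs$left[[1]][1]
  es <- nested_specificity(m, dom1, granularity = "element")
  expect_true(all(is.finite(es)))
  own_topic <- names(which.max(nested_specificity(m, dom1)))
  tid <- domtopics:::resolve_block(m, own_topic)$id
  own_terms <- m$graph$right[m$partition$levels[[1]]$right == tid]
  expect_gt(max(es[own_terms]), 0)
  # transposed: the domain most associated with a topic is the argmax of
  # the transposed specificity
  ts <- nested_specificity(m, own_topic)
  expect_equal(names(which.max(ts)), dom1)
})

test_that("prevalence change is the difference of within-period shares", {
  # 10/100 docs in P1, 30/150 in P2 -> +0.10, computed via a hand-built
  # chained state
  n1 <- 100; n2 <- 150
  docs <- paste0("d", seq_len(n1 + n2))
  in_dom <- c(rep(TRUE, 10), rep(FALSE, 90), rep(TRUE, 30), rep(FALSE, 120))
  year <- c(rep("2000", n1), rep("2010", n2))
  g <- domtopics:::bipartite_graph(docs, c("2000", "2010"),
                                   cbind(seq_along(docs),
                                         ifelse(year == "2000", 1L, 2L)),
                                   right_type = "year")
  # model: two domains over the same docs, one term each
  gm <- domtopics:::bipartite_graph(docs, c("a", "b"),
                                    cbind(seq_along(docs),
                                          ifelse(in_dom, 1L, 2L)))
  pm <- domtopics:::flat_partition(ifelse(in_dom, 1L, 2L), c(1L, 2L))
  model <- dtm_from_state(gm, pm)
  pc <- nested_partition(list(list(left = pm$levels[[1]]$left,
                                   right = c(1L, 2L)),
                              list(left = c(1L, 1L), right = c(1L, 1L))))
  ch <- structure(list(graph = g, partition = pc,
                       left_labels = list(c("L1D2", "L1D3"), "L2D2")),
                  class = "chained_model")
  expect_equal(prevalence_change(model, ch, "L1D2", c(1L, 2L)), 0.1)
  # equal shares cancel
  expect_equal(prevalence_change(model, ch, "L1D2", c(1L, 1L)), 0)
})
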