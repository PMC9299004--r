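# Shared fixtures and independent oracles for the test suite.

# tiny corpus built by hand
toy_corpus <- function() {
  corpus(list(
    document("d1", c("the", "patient", "surgery")),
    document("d2", c("patient", "tumor", "response"),
             metadata = list(year = "1995")),
    document("d3", c("tumor", "cells", "assay"),
             metadata = list(year = "1995", country = c("fr", "br"))),
    document("d4", c("cells", "culture", "assay"),
             metadata = list(year = "1996"))
  ))
}

# random connected-ish bipartite graph (every node has >= 1 edge)
random_bipartite <- function(nl, nr, p, seed) {
  set.seed(seed)
  repeat {
    a <- matrix(stats::runif(nl * nr) < p, nl, nr)
    if (all(rowSums(a) > 0) && all(colSums(a) > 0)) break
  }
  idx <- which(a, arr.ind = TRUE)
  domtopics:::bipartite_graph(paste0("d", seq_len(nl)),
                              paste0("t", seq_len(nr)), idx)
}

# all set partitions of n items, as assignment vectors (Bell(n) of them)
set_partitions <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in set_partitions(n - 1L))
    for (b in seq_len(max(p) + 1L))
      out[[length(out) + 1L]] <- c(p, b)
  out
}

# random valid nested partition for a graph: random level-1 blocks, then
# random groupings until one block per side
random_nested_partition <- function(nl, nr, seed) {
  set.seed(seed)
  rand_assign <- function(n) {
    B <- sample.int(max(1L, n), 1L)
    b <- sample.int(B, n, replace = TRUE)
    match(b, unique(b))
  }
  levels <- list(list(left = rand_assign(nl), right = rand_assign(nr)))
  repeat {
    prev <- levels[[length(levels)]]
    BL <- max(prev$left); BR <- max(prev$right)
    if (BL == 1L && BR == 1L) break
    grp <- function(B) {
      if (B == 1L) return(1L)
      g <- sample.int(max(1L, B - 1L), B, replace = TRUE)
      match(g, unique(g))
    }
    levels[[length(levels) + 1L]] <- list(left = grp(BL), right = grp(BR))
  }
  nested_partition(levels)
}

# Independent transcription of the specificity / commonality formulas,
# computed from raw edge lists by direct counting -- no shared code with
# the package implementation.
oracle_usage <- function(graph, partition, side, level, id) {
  mem <- partition$levels[[1L]][[side]]
  l <- 2L
  while (l <= level) {
    mem <- partition$levels[[l]][[side]][mem]
    l <- l + 1L
  }
  col <- if (side == "left") 1L else 2L
  opp_col <- if (side == "left") 2L else 1L
  opp_mem <- partition$levels[[1L]][[if (side == "left") "right" else
                                       "left"]]
  in_block <- mem[graph$edges[, col]] == id
  stopifnot(any(in_block))
  cnt <- tabulate(opp_mem[graph$edges[in_block, opp_col]], max(opp_mem))
  cnt / sum(cnt)
}

oracle_specificity <- function(graph, partition, side, level, id) {
  L <- length(partition$levels)
  p_d <- oracle_usage(graph, partition, side, level, id)
  total <- 0
  cur <- id
  for (l in seq.int(level + 1L, L)) {
    cur <- partition$levels[[l]][[side]][cur]
    p_a <- oracle_usage(graph, partition, side, l, cur)
    total <- total + ifelse(p_d > 0, p_d * log(p_d / p_a), 0)
  }
  total / (L - level)
}

oracle_commonality <- function(graph, partition, side, level, id) {
  L <- length(partition$levels)
  kids <- which(partition$levels[[level]][[side]] == id)
  p_kids <- lapply(kids, function(k)
    oracle_usage(graph, partition, side, level - 1L, k))
  nt <- length(p_kids[[1L]])
  cstar <- numeric(nt)
  cur <- id
  n_anc <- 0L
  for (l in seq.int(level + 1L, L)) {
    cur <- partition$levels[[l]][[side]][cur]
    p_a <- oracle_usage(graph, partition, side, l, cur)
    inner <- numeric(nt)
    for (pk in p_kids) {
      r <- ifelse(pk > 0, log(pk / ifelse(p_a > 0, p_a, 1)),
                  ifelse(p_a > 0, -Inf, 0))
      inner <- inner + r
    }
    cstar <- cstar + inner / length(p_kids)
    n_anc <- n_anc + 1L
  }
  cstar <- cstar / n_anc
  w <- Reduce(`+`, p_kids) / length(p_kids)
  chat <- ifelse(w > 0, w * cstar, 0)
  list(cstar = cstar, chat = chat)
}

# adjusted Rand index (mclust is available in the test environment)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# stable fingerprint of an assignment vector
digest_vec <- function(x) paste(as.integer(x), collapse = ",")

`%||%` <- function(a, b) if (is.null(a)) b else a
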