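# log of the multiset coefficient multiset(n, m) = C(n + m - 1, m):
# the number of ways to distribute m indistinct items into n slots.
lmultiset <- function(n, m) {
  ifelse(m <= 0 | n <= 0, 0, lchoose(n + m - 1, m))
}

lfact <- function(x) lgamma(x + 1)

#' Description length of a nested partition
#'
#' Evaluates, in nats, the microcanonical description length of a
#' bipartite graph under the nested degree-corrected stochastic block
#' model, for a given type-pure nested partition.  This is the quantity
#' that [fit_dtm()] minimises.  The components are:
#'
#' * `edges`: the microcanonical degree-corrected likelihood of the simple
#'   graph given the level-1 blocks, degrees and block edge counts,
#'   \eqn{\sum_r \ln e_r! - \sum_{rs} \ln e_{rs}! - \sum_i \ln k_i!}
#'   (bipartite: all block pairs cross sides, no within-block edges);
#' * `degrees`: a uniform prior over degree sequences given block degree
#'   totals, \eqn{\sum_r \ln \binom{n_r + e_r - 1}{e_r}};
#' * `partitions`: per level and per side, the cost of the partition,
#'   \eqn{\ln \binom{n-1}{B-1} + \ln n! - \sum_r \ln n_r!};
#' * `edge_matrix`: per level, the cost of the block-pair edge counts
#'   given the grouping one level up, \eqn{\sum_{RS} \ln \left(\!\!\binom{m_R
#'   m_S}{e_{RS}}\!\!\right)}; the hierarchy closes at the top with a
#'   single block per side.
#'
#' The total is invariant under block relabeling and node reordering, and
#' finite for any valid state.
#'
#' @param graph A `bipartite_graph`.
#' @param partition A [nested_partition()] whose level-1 vectors match the
#'   graph's node counts.
#' @return An object of class `"description_length"`: a list with `total`
#'   (nats) and a `components` list.
#' @export
description_length <- function(graph, partition) {
  stopifnot(inherits(graph, "bipartite_graph"),
            inherits(partition, "nested_partition"))
  nL <- length(graph$left); nR <- length(graph$right)
  if (length(partition$levels[[1L]]$left) != nL ||
      length(partition$levels[[1L]]$right) != nR)
    stop("partition does not match graph node counts")
  E <- nrow(graph$edges)
  bl <- partition$levels[[1L]]$left
  br <- partition$levels[[1L]]$right
  B <- c(max(bl), max(br))

  # level-1 block aggregates
  kL <- tabulate(graph$edges[, 1L], nL)
  kR <- tabulate(graph$edges[, 2L], nR)
  e1 <- block_matrix(graph, bl, br)
  e_rL <- rowSums(e1); e_rR <- colSums(e1)
  n_rL <- tabulate(bl, B[1L]); n_rR <- tabulate(br, B[2L])

  s_edges <- sum(lfact(e_rL)) + sum(lfact(e_rR)) - sum(lfact(e1)) -
    sum(lfact(kL)) - sum(lfact(kR))
  s_deg <- sum(lmultiset(n_rL, e_rL)) + sum(lmultiset(n_rR, e_rR))

  part_cost <- function(n, sizes) {
    Bs <- length(sizes)
    lchoose(n - 1, Bs - 1) + lfact(n) - sum(lfact(sizes))
  }
  s_part <- part_cost(nL, n_rL) + part_cost(nR, n_rR)
  s_part_levels <- s_part

  # upper levels: the level-(l-1) block multigraph is modeled by the
  # level-l grouping; the final level has one block per side, so its edge
  # matrix is the scalar E with zero residual cost.
  e_cur <- e1
  s_mg_levels <- numeric(0)
  L <- length(partition$levels)
  for (l in seq_len(L)[-1L]) {
    gl <- partition$levels[[l]]$left
    gr <- partition$levels[[l]]$right
    m_L <- tabulate(gl, max(gl)); m_R <- tabulate(gr, max(gr))
    e_up <- rowsum(t(rowsum(e_cur, gl)), gr)    # aggregate rows then cols
    e_up <- t(e_up)                             # groups_left x groups_right
    s_mg <- sum(lmultiset(outer(m_L, m_R), e_up))
    s_pl <- part_cost(length(gl), m_L) + part_cost(length(gr), m_R)
    s_mg_levels <- c(s_mg_levels, s_mg)
    s_part_levels <- c(s_part_levels, s_pl)
    s_part <- s_part + s_pl
    e_cur <- e_up
  }
  if (L == 1L && (B[1L] != 1L || B[2L] != 1L))
    stop("a one-level partition must have a single block per side")
  s_mg_total <- sum(s_mg_levels)

  total <- s_edges + s_deg + s_part + s_mg_total
  structure(list(total = total,
                 components = list(edges = s_edges, degrees = s_deg,
                                   partitions = s_part_levels,
                                   edge_matrix = s_mg_levels)),
            class = "description_length")
}

#' @export
print.description_length <- function(x, ...) {
  cat(sprintf("Description length: %.4f nats\n", x$total))
  cat(sprintf("  graph given model : %.4f\n", x$components$edges))
  cat(sprintf("  degree sequences  : %.4f\n", x$components$degrees))
  cat(sprintf("  partitions        : %.4f\n", sum(x$components$partitions)))
  cat(sprintf("  edge matrices     : %.4f\n", sum(x$components$edge_matrix)))
  invisible(x)
}

# Edge counts between left and right blocks at level 1.
block_matrix <- function(graph, bl, br) {
  BL <- max(bl); BR <- max(br)
  m <- matrix(0, BL, BR)
  if (nrow(graph$edges)) {
    idx <- (br[graph$edges[, 2L]] - 1L) * BL + bl[graph$edges[, 1L]]
    tab <- tabulate(idx, BL * BR)
    m[] <- tab
  }
  m
}
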