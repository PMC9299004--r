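#' Nested partition of a bipartite graph
#'
#' Represents per-level, type-pure block assignments for both sides of a
#' bipartite graph.  Level 1 assigns nodes to blocks; each higher level
#' assigns the previous level's blocks to superblocks, so nesting
#' consistency holds by construction.  The top level has exactly one block
#' per side.
#'
#' @param levels List of levels; each level is a list with integer vectors
#'   `left` and `right` giving 1-based block assignments (dense ids
#'   `1..B`).  `levels[[1]]` is over nodes, `levels[[l]]` over the blocks
#'   of level `l - 1`.
#' @return An object of class `"nested_partition"`.
#' @export
nested_partition <- function(levels) {
  stopifnot(is.list(levels), length(levels) >= 1L)
  for (l in seq_along(levels)) {
    lv <- levels[[l]]
    stopifnot(is.list(lv), !is.null(lv$left), !is.null(lv$right))
    for (s in c("left", "right")) {
      b <- as.integer(lv[[s]])
      if (any(is.na(b)) || any(b < 1L))
        stop("invalid block ids at level ", l, " side ", s)
      if (length(unique(b)) != max(b))
        stop("block ids must be dense 1..B at level ", l, " side ", s)
      levels[[l]][[s]] <- b
    }
    if (l > 1L) {
      for (s in c("left", "right"))
        if (length(levels[[l]][[s]]) != max(levels[[l - 1L]][[s]]))
          stop("level ", l, " side ", s,
               " must assign each block of level ", l - 1L)
    }
  }
  top <- levels[[length(levels)]]
  if (max(top$left) != 1L || max(top$right) != 1L)
    stop("top level must have exactly one block per side")
  structure(list(levels = levels), class = "nested_partition")
}

#' @export
print.nested_partition <- function(x, ...) {
  L <- length(x$levels)
  cat("Nested partition with", L, "level(s):\n")
  for (l in seq_len(L))
    cat(sprintf("  level %d: %d left block(s), %d right block(s)\n",
                l, max(x$levels[[l]]$left), max(x$levels[[l]]$right)))
  invisible(x)
}

#' Number of levels of a nested partition or model
#' @param x A `nested_partition` or `domain_topic_model`.
#' @return Integer.
#' @export
n_levels <- function(x) {
  if (inherits(x, "domain_topic_model") || inherits(x, "chained_model"))
    x <- x$partition
  length(x$levels)
}

#' Block counts per side at one level
#' @param x A `nested_partition` or model.
#' @param level Level index (1 = base).
#' @return Named integer vector `c(left = , right = )`.
#' @export
n_blocks <- function(x, level = 1L) {
  if (inherits(x, "domain_topic_model") || inherits(x, "chained_model"))
    x <- x$partition
  lv <- x$levels[[level]]
  c(left = max(lv$left), right = max(lv$right))
}

#' Node-level block membership at any level
#'
#' Composes the per-level assignments so that each node is mapped to its
#' block at the requested level.
#'
#' @param x A `nested_partition` or model.
#' @param level Level index.
#' @param side `"left"` (documents) or `"right"` (terms / metadata).
#' @return Integer vector of block ids over nodes.
#' @export
membership <- function(x, level = 1L, side = c("left", "right")) {
  if (inherits(x, "domain_topic_model") || inherits(x, "chained_model"))
    x <- x$partition
  side <- match.arg(side)
  b <- x$levels[[1L]][[side]]
  l <- 2L
  while (l <= level) {
    b <- x$levels[[l]][[side]][b]
    l <- l + 1L
  }
  b
}

#' Children of a block at the level below
#' @param x A `nested_partition` or model.
#' @param level Level of the block (must be >= 2).
#' @param side `"left"` or `"right"`.
#' @param block Block id at `level`.
#' @return Integer ids of the level `level - 1` blocks contained in it.
#' @export
block_children <- function(x, level, side, block) {
  if (inherits(x, "domain_topic_model") || inherits(x, "chained_model"))
    x <- x$partition
  stopifnot(level >= 2L)
  which(x$levels[[level]][[side]] == block)
}

# Renumber blocks at every level by first occurrence, keeping the nesting
# representation consistent.  Accepts non-dense ids.  Deterministic given
# node order.
canonicalize_partition <- function(levels) {
  for (l in seq_along(levels)) {
    for (s in c("left", "right")) {
      b <- levels[[l]][[s]]
      uq <- unique(b)                      # old ids in first-occurrence order
      levels[[l]][[s]] <- match(b, uq)     # new dense ids
      if (l < length(levels)) {
        # next level indexes blocks by old id; re-index by new id
        nxt <- levels[[l + 1L]][[s]]
        levels[[l + 1L]][[s]] <- nxt[uq]
      }
    }
  }
  levels
}

# Flat partition helper: wrap base-level assignments into a valid nested
# partition by closing with a trivial top level when needed.
flat_partition <- function(left, right) {
  left <- as.integer(left); right <- as.integer(right)
  lv1 <- list(left = match(left, unique(left)),
              right = match(right, unique(right)))
  if (max(lv1$left) == 1L && max(lv1$right) == 1L)
    nested_partition(list(lv1))
  else
    nested_partition(list(lv1, list(left = rep(1L, max(lv1$left)),
                                    right = rep(1L, max(lv1$right)))))
}
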