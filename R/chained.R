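# Renumber one side's blocks at every level by first occurrence (or by a
# supplied order at level 1), re-indexing the next level accordingly.
canonicalize_side <- function(levels, side) {
  for (l in seq_along(levels)) {
    b <- levels[[l]][[side]]
    uq <- unique(b)
    levels[[l]][[side]] <- match(b, uq)
    if (l < length(levels))
      levels[[l + 1L]][[side]] <- levels[[l + 1L]][[side]][uq]
  }
  levels
}

#' Fit a domain-chained model
#'
#' Clusters the values of one metadata dimension (e.g. publication years
#' into periods) against the frozen domain hierarchy of a previously
#' fitted domain-topic model.  The documents' nested block assignments are
#' transposed onto the document-metadata graph and held immutable at every
#' level; only the metadata nodes are partitioned, so the best fit
#' reflects their connectivity to the lexically structured domains.  The
#' metadata hierarchy has the same depth as the document hierarchy;
#' levels at which no statistically significant metadata distinction
#' exists collapse to a single block.
#'
#' Sub-corpus re-chaining is supported by passing a graph restricted with
#' [subset_graph()]: document blocks absent from the restriction are
#' dropped and the remaining blocks keep their relative order, so
#' assignments stay comparable to the source model.
#'
#' @param graph A `bipartite_graph` from [build_doc_metadata_graph()].
#' @param model The source `domain_topic_model` (or its
#'   [nested_partition()] together with `doc_ids`).
#' @param config A [fit_config()].
#' @param doc_ids Character vector naming the documents of the partition,
#'   required when `model` is a bare partition.
#' @return An object of class `"chained_model"`: the metadata graph, the
#'   combined [nested_partition()] (left = frozen domains, right =
#'   inferred metadata blocks), its description length, the level-1 block
#'   edge counts and the metadata field name.
#' @export
fit_chained <- function(graph, model, config = fit_config(),
                        doc_ids = NULL) {
  stopifnot(inherits(graph, "bipartite_graph"))
  if (inherits(model, "domain_topic_model")) {
    doc_partition <- model$partition
    doc_ids <- model$graph$left
  } else if (inherits(model, "nested_partition")) {
    doc_partition <- model
    if (is.null(doc_ids))
      stop("doc_ids is required when passing a bare partition")
  } else stop("model must be a domain_topic_model or a nested_partition")

  idx <- match(graph$left, doc_ids)
  if (anyNA(idx))
    stop("document(s) in the metadata graph are unknown to the model: ",
         paste(utils::head(graph$left[is.na(idx)], 5L), collapse = ", "))

  # frozen level-1 blocks, compacted to the blocks actually present, in
  # ascending source-block order so labels stay comparable
  L <- length(doc_partition$levels)
  raw1 <- doc_partition$levels[[1L]]$left[idx]
  present <- sort(unique(raw1))
  frozen1 <- match(raw1, present)
  # frozen groupings for levels 2..L over the present blocks
  doc_groups <- list()
  present_chain <- list(present)
  prev_present <- present
  for (l in seq_len(L)[-1L]) {
    g_raw <- doc_partition$levels[[l]]$left[prev_present]
    pres <- sort(unique(g_raw))
    doc_groups[[l - 1L]] <- match(g_raw, pres)
    prev_present <- pres
    present_chain[[l]] <- pres
  }

  set.seed(config$seed)
  base <- fit_base_level(graph, config, frozen_left = frozen1,
                         prior_left = FALSE)
  lv1 <- list(left = frozen1,
              right = match(base$right, unique(base$right)))
  e_cur <- block_matrix(graph, lv1$left, lv1$right)
  levels <- list(lv1)
  for (l in seq_len(L)[-1L]) {
    gl <- doc_groups[[l - 1L]]
    BR <- ncol(e_cur)
    if (length(gl) == 1L && BR == 1L) break
    if (l == L) {
      gr <- rep(1L, BR)                   # top level closes both sides
    } else {
      res <- fit_upper_level(e_cur, config, frozen_left = gl,
                             prior_left = FALSE)
      gr <- match(res$right, unique(res$right))
    }
    levels[[l]] <- list(left = gl, right = gr)
    e_cur <- t(rowsum(t(rowsum(e_cur, gl)), gr))
  }
  # if the metadata side is still split when the domain hierarchy tops
  # out, grow metadata-only levels until it closes
  while (ncol(e_cur) > 1L && length(levels) < config$max_levels) {
    BR <- ncol(e_cur)
    trivial_obj <- lmultiset(BR, sum(e_cur))
    res <- fit_upper_level(e_cur, config, frozen_left = 1L,
                           prior_left = FALSE)
    gr <- match(res$right, unique(res$right))
    if (max(gr) == BR || res$dl >= trivial_obj - 1e-10) gr <- rep(1L, BR)
    levels[[length(levels) + 1L]] <- list(left = 1L, right = gr)
    e_cur <- t(rowsum(t(rowsum(e_cur, 1L)), gr))
  }
  if (ncol(e_cur) > 1L)
    levels[[length(levels) + 1L]] <-
      list(left = 1L, right = rep(1L, ncol(e_cur)))

  levels <- canonicalize_side(levels, "right")
  partition <- nested_partition(levels)
  dl <- description_length(graph, partition)
  e1 <- block_matrix(graph, partition$levels[[1L]]$left,
                     partition$levels[[1L]]$right)
  # carry the source model's domain labels for the blocks present
  left_labels <- vector("list", length(partition$levels))
  src_labels <- if (inherits(model, "domain_topic_model"))
    model_labels(model)$left else NULL
  for (l in seq_along(partition$levels)) {
    if (l <= length(present_chain)) {
      raw <- present_chain[[l]]
      left_labels[[l]] <- if (!is.null(src_labels)) src_labels[[l]][raw]
        else vapply(raw - 1L, function(j) block_label(l, "D", j), "")
    } else {
      left_labels[[l]] <- block_label(l, "D", 0L)
    }
  }
  structure(list(graph = graph, partition = partition, dl = dl, e1 = e1,
                 field = graph$right_type, doc_blocks_present = present,
                 left_labels = left_labels,
                 config = config, seed = config$seed),
            class = "chained_model")
}

#' @export
print.chained_model <- function(x, ...) {
  B <- vapply(x$partition$levels, function(lv)
    c(max(lv$left), max(lv$right)), c(0, 0))
  cat("Domain-chained model of field '", x$field, "': ",
      length(x$graph$left), " documents, ", length(x$graph$right),
      " values\n", sep = "")
  cat("  metadata blocks per level:", paste(B[2L, ], collapse = " "), "\n")
  cat(sprintf("  description length: %.2f nats\n", x$dl$total))
  invisible(x)
}

#' Summarise the periods of a year-chained model
#'
#' Lists, per level, the metadata blocks with their member values, flags
#' whether each block is chronologically contiguous (no foreign value
#' falls strictly inside its range -- contiguity is emergent, never
#' enforced, since years are modeled as categorical), and reports the
#' highest level that still distinguishes more than one block.
#'
#' @param chained A `chained_model` whose metadata values sort naturally
#'   (e.g. years).
#' @return A list with `table` (data.frame: level, block, label, members,
#'   n_docs, contiguous) and `highest_split_level`.
#' @export
period_summary <- function(chained) {
  stopifnot(inherits(chained, "chained_model"))
  vals <- chained$graph$right
  ord <- order(suppressWarnings(as.numeric(vals)), vals)
  rank_of <- integer(length(vals)); rank_of[ord] <- seq_along(vals)
  L <- length(chained$partition$levels)
  rows <- list()
  highest <- 1L
  for (l in seq_len(L)) {
    mem <- membership(chained, l, "right")
    B <- max(mem)
    if (B > 1L) highest <- max(highest, l)
    for (bk in seq_len(B)) {
      members <- vals[mem == bk]
      rk <- sort(rank_of[mem == bk])
      contig <- all(diff(rk) == 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        level = l, block = bk,
        label = block_label(l, "P", bk - 1L),
        members = paste(members[order(rank_of[mem == bk])], collapse = ","),
        n_values = length(members),
        contiguous = contig, stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), highest_split_level = highest)
}
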