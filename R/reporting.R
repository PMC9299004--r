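#' Select topics by the half-sum rule
#'
#' Orders scores decreasingly and keeps the smallest prefix whose
#' cumulative score reaches half the sum of the positive scores.  Only
#' positively scored entries can be selected; with no positive mass the
#' selection is empty.  The result does not depend on input order.
#'
#' @param scores Named numeric vector of topic scores (specificity or
#'   commonality; may contain negative values and `-Inf`).
#' @return Character vector of selected names (or integer indices when
#'   unnamed), in decreasing score order.
#' @export
select_topics <- function(scores) {
  if (is.null(names(scores))) names(scores) <- as.character(seq_along(scores))
  pos <- scores[is.finite(scores) & scores > 0]
  if (!length(pos)) return(character())
  pos <- pos[order(-pos, names(pos))]
  half <- sum(pos) / 2
  k <- which(cumsum(pos) >= half - 1e-12)[1L]
  names(pos)[seq_len(k)]
}

#' Select terms by the half-max rule
#'
#' Keeps the entries whose value is strictly greater than half the
#' highest value.  Within a topic, terms share a connectivity pattern, so
#' only the strongest contributors are listed.
#'
#' @param values Named numeric vector of per-term scores within one topic.
#' @return Character vector of selected names, in decreasing value order;
#'   if no value qualifies (all non-positive), the single best term.
#' @export
select_terms <- function(values) {
  stopifnot(length(values) >= 1L)
  if (is.null(names(values))) names(values) <- as.character(seq_along(values))
  values <- values[order(-values, names(values))]
  top <- values[1L]
  keep <- is.finite(values) & values > top / 2
  if (!any(keep)) return(names(values)[1L])
  names(values)[keep]
}

# Terms of one level-1 topic, with a block's element-level scores
# restricted to them and filtered by the half-max rule.
topic_terms_for_block <- function(model, block_label_str, topic_label,
                                  kind) {
  elem <- if (kind == "specificity")
    nested_specificity(model, block_label_str, granularity = "element")
  else nested_commonality(model, block_label_str, granularity = "element")
  tref <- resolve_block(model, topic_label)
  members <- which(model$partition$levels[[1L]]$right == tref$id)
  vals <- elem[members]
  select_terms(vals)
}

#' Domain-topic table
#'
#' The static, publication-friendly description of a group of domains:
#' for a focal domain at level >= 2, lists recursively every subdomain
#' with, for domains above level 1, the topics *common* to their
#' immediate subdomains, and for level-1 domains their *specific* topics.
#' Topics are chosen by the half-sum rule ([select_topics()]) on the
#' corresponding measure and represented by their selected terms
#' ([select_terms()] on the measure at term granularity).  The same
#' construction applies to other block pairs (e.g. country-domain tables
#' of a chained model).
#'
#' @param model A `domain_topic_model` (or `chained_model`).
#' @param focal Focal domain reference (label such as `"L3D7"`), level
#'   >= 2.
#' @return An object of class `"domain_topic_table"`: a nested list
#'   (`label`, `level`, `kind`, `topics`, `children`) plus a flat
#'   `data.frame` rendering in `$table`.
#' @export
domain_topic_table <- function(model, focal) {
  ref <- resolve_block(model, focal)
  if (ref$level < 2L) stop("the focal domain must be at level >= 2")
  labs <- model_labels(model)
  L <- length(model$partition$levels)

  describe <- function(level, id) {
    lab <- labs[[ref$side]][[level]][id]
    kind <- if (level >= 2L) "commonality" else "specificity"
    topics <- character(); entries <- list()
    # a block needs a strict ancestor to be scored; the top-level block
    # gets structure but no topics of its own
    if (level >= 2L && level < L) {
      sc <- nested_commonality(model, lab)
      topics <- select_topics(sc)
    } else if (level == 1L) {
      sc <- nested_specificity(model, lab)
      topics <- select_topics(sc)
    }
    for (tp in topics) {
      entries[[tp]] <- list(topic = tp, score = unname(sc[tp]),
                            terms = topic_terms_for_block(model, lab, tp,
                                                          kind))
    }
    children <- list()
    if (level >= 2L) {
      for (k in block_children(model, level, ref$side, id))
        children[[length(children) + 1L]] <- describe(level - 1L, k)
    }
    list(label = lab, level = level, kind = kind, topics = entries,
         children = children)
  }

  tree <- describe(ref$level, ref$id)
  rows <- list()
  flatten <- function(node) {
    tps <- vapply(node$topics, `[[`, "", "topic")
    trm <- vapply(node$topics, function(e)
      paste(e$terms, collapse = " "), "")
    rows[[length(rows) + 1L]] <<- data.frame(
      level = node$level, domain = node$label, kind = node$kind,
      topics = paste(tps, collapse = ", "),
      terms = paste(sprintf("%s[%s]", tps, trm), collapse = "; "),
      stringsAsFactors = FALSE)
    for (ch in node$children) flatten(ch)
  }
  flatten(tree)
  structure(list(tree = tree, table = do.call(rbind, rows),
                 focal = tree$label),
            class = "domain_topic_table")
}

#' @export
print.domain_topic_table <- function(x, ...) {
  cat("Domain-topic table for", x$focal, "\n")
  print(x$table, right = FALSE)
  invisible(x)
}

#' Write a domain-topic table to TSV or Markdown
#' @param x A `domain_topic_table`.
#' @param path Output file.
#' @param format `"tsv"` or `"markdown"`.
#' @return Invisibly, `path`.
#' @export
write_domain_topic_table <- function(x, path, format = c("tsv",
                                                         "markdown")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    df <- x$table
    lines <- c(paste("#", "Domain-topic table for", x$focal), "",
               paste("|", paste(names(df), collapse = " | "), "|"),
               paste("|", paste(rep("---", ncol(df)), collapse = " | "),
                     "|"),
               vapply(seq_len(nrow(df)), function(i)
                 paste("|", paste(unlist(df[i, ]), collapse = " | "), "|"),
                 ""))
    writeLines(lines, path)
  }
  invisible(path)
}

# Per-level relevance of one side's blocks: default volumes, or usage of
# / in the selected block.  Values normalised to max 1 within each level.
side_relevance <- function(model, side, selection_ref = NULL) {
  L <- length(model$partition$levels)
  out <- vector("list", L)
  if (!is.null(selection_ref)) {
    Jf <- joint_counts(model, side, "block")
    sel_units <- selection_units(model, selection_ref)
  }
  for (l in seq_len(L)) {
    mem1 <- blocks_at_level(model, side, l)
    if (is.null(selection_ref)) {
      vol <- side_volumes(model, side, l)
      out[[l]] <- vol / max(vol)
    } else {
      # fraction of each block's edges landing in the selected block
      B <- max(mem1)
      rel <- vapply(seq_len(B), function(bk) {
        rows <- which(mem1 == bk)
        cnt <- sum(Jf[rows, sel_units, drop = FALSE])
        tot <- sum(Jf[rows, , drop = FALSE])
        if (tot == 0) 0 else cnt / tot
      }, 0)
      out[[l]] <- if (max(rel) > 0) rel / max(rel) else rel
    }
  }
  out
}

# level-1 block -> block at level l, for one side
blocks_at_level <- function(model, side, level) {
  b <- seq_len(n_blocks(model, 1L)[[if (side == "left") "left" else
                                      "right"]])
  l <- 2L
  while (l <= level) {
    b <- model$partition$levels[[l]][[side]][b]
    l <- l + 1L
  }
  b
}

# level-1 counterpart columns covered by a selection (a block at any
# level of the opposite side)
selection_units <- function(model, ref) {
  b <- blocks_at_level(model, ref$side, ref$level)
  which(b == ref$id)
}

# block volumes at one level: documents per domain, edge endpoints per
# topic
side_volumes <- function(model, side, level) {
  mem <- membership(model, level, side)
  if (side == "left") tabulate(mem, max(mem))
  else {
    deg <- tabulate(model$graph$edges[, 2L], length(model$graph$right))
    vapply(seq_len(max(mem)), function(bk) sum(deg[mem == bk]), 0)
  }
}

#' Export map data for the interactive domain-topic map
#'
#' Produces the JSON-ready data behind the two-sided hierarchical map:
#' both hierarchies as nested blocks with heights proportional to their
#' volume (document counts for domains, term-usage counts for topics),
#' per-level colour relevance normalised so the strongest block of each
#' level is 1, per-domain document lists, an optional per-year histogram
#' and a term-to-topic search index.  Without a selection, relevance is
#' each side's volume share; with a selection, the opposite side's
#' relevance becomes its usage of (or in) the selected block, as in the
#' interactive map's cross-selection colouring.
#'
#' @param model A `domain_topic_model`.
#' @param selection Optional block reference (label) to colour against.
#' @param years Optional named vector mapping document ids to years, for
#'   the histogram; when a domain is selected the histogram is restricted
#'   to its documents.
#' @return A list (class `"map_document"`) ready for
#'   [jsonlite::toJSON()]; see [write_map_json()].
#' @export
map_export <- function(model, selection = NULL, years = NULL) {
  sel_ref <- if (!is.null(selection)) resolve_block(model, selection)
  labs <- model_labels(model)
  L <- length(model$partition$levels)

  build_side <- function(side) {
    rel <- if (!is.null(sel_ref) && sel_ref$side != side)
      side_relevance(model, side, sel_ref)
    else side_relevance(model, side, NULL)
    vols <- lapply(seq_len(L), function(l) side_volumes(model, side, l))
    node <- function(level, id) {
      kids <- if (level >= 2L)
        lapply(block_children(model, level, side, id),
               function(k) node(level - 1L, k))
      else list()
      out <- list(label = labs[[side]][[level]][id], level = level,
                  volume = vols[[level]][id],
                  height = vols[[level]][id],
                  relevance = rel[[level]][id])
      if (length(kids)) out$children <- kids
      out
    }
    node(L, 1L)
  }

  doc_lists <- split(model$graph$left,
                     model$partition$levels[[1L]]$left)
  names(doc_lists) <- labs$left[[1L]]

  hist_data <- NULL
  if (!is.null(years)) {
    docs <- model$graph$left
    if (!is.null(sel_ref) && sel_ref$side == "left") {
      mem <- membership(model, sel_ref$level, "left")
      docs <- docs[mem == sel_ref$id]
    }
    yr <- years[docs]
    tab <- table(yr)
    hist_data <- list(year = names(tab), n_documents = as.integer(tab))
  }

  term_index <- as.list(labs$right[[1L]][
    model$partition$levels[[1L]]$right])
  names(term_index) <- model$graph$right

  structure(list(format = "domtopics-map/1",
                 selection = if (!is.null(sel_ref))
                   labs[[sel_ref$side]][[sel_ref$level]][sel_ref$id],
                 domains = build_side("left"),
                 topics = build_side("right"),
                 documents = doc_lists,
                 histogram = hist_data,
                 term_index = term_index),
            class = "map_document")
}

#' Write map data as JSON
#' @param map A `map_document` from [map_export()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_map_json <- function(map, path) {
  json <- jsonlite::toJSON(unclass(map), auto_unbox = TRUE, digits = NA,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Bump-chart data for domains across periods
#'
#' For each (domain, period) pair: the absolute volume (documents of the
#' domain in the period, averaged per year of the period), the relative
#' volume (the domain's share of the period's documents) and the rank of
#' the domain within the period by absolute volume (ties broken by label
#' index).
#'
#' @param model The source `domain_topic_model`.
#' @param chained A year-chained `chained_model`.
#' @param level Domain level to chart (default 2).
#' @param domains Optional character vector of domain labels to restrict
#'   to (default: all domains of the level).
#' @param period_level Level of the chained model giving the periods
#'   (default 1).
#' @return A `data.frame` with columns `period`, `domain`, `n_docs`,
#'   `absolute`, `relative`, `rank`.
#' @export
bump_chart_data <- function(model, chained, level = 2L, domains = NULL,
                            period_level = 1L) {
  labs_d <- model_labels(model)$left[[level]]
  if (is.null(domains)) domains <- labs_d
  dom_ids <- match(domains, labs_d)
  if (anyNA(dom_ids)) stop("unknown domain(s): ",
                           paste(domains[is.na(dom_ids)], collapse = ", "))
  year_block <- membership(chained, period_level, "right")
  nP <- max(year_block)
  if (any(tabulate(year_block, nP) == 0L)) stop("empty period")
  first_edge <- match(seq_along(chained$graph$left),
                      chained$graph$edges[, 1L])
  doc_period <- year_block[chained$graph$edges[first_edge, 2L]]
  doc_dom <- membership(model, level, "left")[
    match(chained$graph$left, model$graph$left)]
  labs_p <- model_labels(chained)$right[[period_level]]
  out <- list()
  for (p in seq_len(nP)) {
    in_p <- doc_period == p
    n_in_p <- sum(in_p)
    n_years <- sum(year_block == p)
    n_docs <- vapply(dom_ids, function(d) sum(in_p & doc_dom == d,
                                              na.rm = TRUE), 0)
    absolute <- n_docs / n_years
    relative <- n_docs / n_in_p
    rk <- rank_by_volume(absolute, domains)
    out[[p]] <- data.frame(period = labs_p[p], domain = domains,
                           n_docs = n_docs, absolute = absolute,
                           relative = relative, rank = rk,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# descending rank with ties broken by the numeric label index
rank_by_volume <- function(vol, labels) {
  idx <- vapply(labels, function(l) parse_block_label(l)$index, 0L)
  ord <- order(-vol, idx)
  rk <- integer(length(vol)); rk[ord] <- seq_along(vol)
  rk
}
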