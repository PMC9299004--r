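# Joint count matrix between the focal side's level-1 blocks and the
# counterpart units: the opposite side's level-1 blocks ("block"
# granularity) or its individual nodes ("element" granularity).  Rows are
# focal level-1 blocks.
joint_counts <- function(model, focal_side, granularity = c("block",
                                                            "element")) {
  granularity <- match.arg(granularity)
  if (granularity == "block") {
    if (focal_side == "left") model$e1 else t(model$e1)
  } else {
    g <- model$graph
    if (focal_side == "left") {
      bl <- model$partition$levels[[1L]]$left
      m <- matrix(0, max(bl), length(g$right))
      idx <- cbind(bl[g$edges[, 1L]], g$edges[, 2L])
    } else {
      br <- model$partition$levels[[1L]]$right
      m <- matrix(0, max(br), length(g$left))
      idx <- cbind(br[g$edges[, 2L]], g$edges[, 1L])
    }
    tab <- tabulate((idx[, 2L] - 1L) * nrow(m) + idx[, 1L],
                    nrow(m) * ncol(m))
    m[] <- tab
    m
  }
}

# Usage distribution of a block at any level over the counterpart units:
# aggregated counterpart counts of its level-1 descendants, normalised.
usage_distribution <- function(model, side, level, id, J) {
  # rows of J are level-1 blocks; map them up to blocks at `level`
  b <- seq_len(nrow(J))
  l <- 2L
  while (l <= level) {
    b <- model$partition$levels[[l]][[side]][b]
    l <- l + 1L
  }
  rows <- which(b == id)
  if (!length(rows)) stop("block has no level-1 descendants")
  cnt <- colSums(J[rows, , drop = FALSE])
  tot <- sum(cnt)
  if (tot == 0) stop("block has no edges")
  cnt / tot
}

#' Topic-usage distribution of a domain
#'
#' The probability distribution of a domain (at any level) over the
#' level-1 topics: the fraction of the domain's document-term edges that
#' land in each level-1 topic.  Ancestor distributions aggregate the
#' counts of their descendants, so whenever a domain uses a topic, all of
#' its ancestors do too (dominance).
#'
#' @param model A `domain_topic_model` (or `chained_model`, in which case
#'   the distribution is over level-1 metadata blocks).
#' @param domain A block reference: label such as `"L2D5"`, or
#'   `list(side =, level =, id =)`.
#' @return Named numeric vector summing to one, named by level-1 block
#'   labels of the counterpart side.
#' @export
topic_usage <- function(model, domain) {
  ref <- resolve_block(model, domain)
  J <- joint_counts(model, ref$side, "block")
  p <- usage_distribution(model, ref$side, ref$level, ref$id, J)
  opp <- if (ref$side == "left") "right" else "left"
  names(p) <- model_labels(model)[[opp]][[1L]]
  p
}

# Ancestor usage distributions of a block: list over levels strictly
# above `level`, up to the top.
ancestor_distributions <- function(model, side, level, id, J) {
  L <- length(model$partition$levels)
  if (level >= L) stop("top-level block has no ancestors")
  out <- list()
  cur <- id
  for (l in (level + 1L):L) {
    cur <- model$partition$levels[[l]][[side]][cur]
    out[[length(out) + 1L]] <- usage_distribution(model, side, l, cur, J)
  }
  out
}

# Pointwise measures on explicit distributions (the displayed formulas).
# p_d: focal distribution; p_anc: list of ancestor distributions;
# p_children: list of child distributions.
specificity_from_p <- function(p_d, p_anc) {
  terms <- vapply(p_anc, function(pa)
    ifelse(p_d > 0, p_d * log(p_d / pa), 0), numeric(length(p_d)))
  if (length(p_d) == 1L) terms <- matrix(terms, nrow = 1L)
  rowMeans(terms)
}

commonality_from_p <- function(p_children, p_anc) {
  nt <- length(p_children[[1L]])
  # Ĉ*: ladder- and child-averaged pointwise log ratio
  cstar <- numeric(nt)
  for (t in seq_len(nt)) {
    acc <- 0
    for (pa in p_anc) {
      s <- 0
      for (pc in p_children) {
        if (pc[t] > 0) s <- s + log(pc[t] / pa[t])
        else if (pa[t] > 0) s <- s - Inf
        # pc == 0 and pa == 0: whole branch lacks the topic; contributes 0
      }
      acc <- acc + s / length(p_children)
    }
    cstar[t] <- acc / length(p_anc)
  }
  w <- rowMeans(do.call(cbind, p_children))
  chat <- ifelse(w > 0, w * cstar, 0)     # 0 * (-Inf) resolved to 0
  list(cstar = cstar, chat = chat)
}

#' Nested specificity of a topic for a domain
#'
#' Quantifies how distinctive a topic is of a domain: the
#' expectation-weighted pointwise relative entropy of the topic between
#' the domain's usage distribution and each of its ancestors', averaged
#' over the superdomain ladder:
#' \deqn{\hat S_{dt} = \frac{1}{|d^+ \supset d|} \sum_{d^+ \supset d}
#'   p_{dt} \log\frac{p_{dt}}{p_{d^+t}}}
#' with the convention \eqn{0 \log(0/q) = 0}.  The ladder runs over every
#' level strictly above the domain, up to and including the top; the
#' domain itself is excluded.  Specificity is always finite because
#' ancestors aggregate their descendants' counts.  Summed over topics,
#' each ladder term is a Kullback-Leibler divergence, so
#' \eqn{\sum_t \hat S_{dt} \ge 0}.
#'
#' @param model A `domain_topic_model` or `chained_model`.
#' @param domain Block reference (label or list); must not be the
#'   top-level block.
#' @param topic Optional counterpart reference (level-1 block label) or
#'   index; `NULL` returns the full named vector.
#' @param granularity `"block"` scores level-1 counterpart blocks
#'   (topics); `"element"` scores individual counterpart nodes (terms).
#' @return Numeric scalar or named vector (nats).
#' @export
nested_specificity <- function(model, domain, topic = NULL,
                               granularity = c("block", "element")) {
  granularity <- match.arg(granularity)
  ref <- resolve_block(model, domain)
  J <- joint_counts(model, ref$side, granularity)
  p_d <- usage_distribution(model, ref$side, ref$level, ref$id, J)
  p_anc <- ancestor_distributions(model, ref$side, ref$level, ref$id, J)
  s <- specificity_from_p(p_d, p_anc)
  opp <- if (ref$side == "left") "right" else "left"
  names(s) <- if (granularity == "block") model_labels(model)[[opp]][[1L]]
              else if (opp == "right") model$graph$right else model$graph$left
  pick_counterpart(model, s, topic)
}

#' Nested commonality of a topic for a domain
#'
#' Quantifies the extent to which a topic is specific to *all* immediate
#' subdomains of a domain, relative to its superdomains:
#' \deqn{\hat C^*_{dt} = \frac{1}{|d^+ \supset d|} \sum_{d^+ \supset d}
#'   \frac{1}{|d^- \subset d|} \sum_{d^- \subset d}
#'   \log\frac{p_{d^-t}}{p_{d^+t}}, \qquad
#'   \hat C_{dt} = \frac{1}{|d^- \subset d|} \sum_{d^- \subset d}
#'   p_{d^-t}\, \hat C^*_{dt}}
#' It is positive when the topic is overrepresented in every subdomain,
#' and reaches minus infinity when the topic is missing from any
#' subdomain that matters (i.e. whenever some subdomain lacks the topic
#' while the average subdomain weight is positive); if the topic is
#' absent from all subdomains the weight vanishes and the score is 0.
#'
#' @inheritParams nested_specificity
#' @param domain Block reference at level >= 2, not the top level.
#' @param value `"chat"` returns \eqn{\hat C_{dt}} (default), `"cstar"`
#'   the unweighted \eqn{\hat C^*_{dt}}.
#' @return Numeric scalar or named vector (nats; may be `-Inf`).
#' @export
nested_commonality <- function(model, domain, topic = NULL,
                               granularity = c("block", "element"),
                               value = c("chat", "cstar")) {
  granularity <- match.arg(granularity)
  value <- match.arg(value)
  ref <- resolve_block(model, domain)
  if (ref$level < 2L) stop("commonality requires a block at level >= 2")
  J <- joint_counts(model, ref$side, granularity)
  kids <- block_children(model, ref$level, ref$side, ref$id)
  p_children <- lapply(kids, function(k)
    usage_distribution(model, ref$side, ref$level - 1L, k, J))
  p_anc <- ancestor_distributions(model, ref$side, ref$level, ref$id, J)
  cc <- commonality_from_p(p_children, p_anc)
  s <- cc[[value]]
  opp <- if (ref$side == "left") "right" else "left"
  names(s) <- if (granularity == "block") model_labels(model)[[opp]][[1L]]
              else if (opp == "right") model$graph$right else model$graph$left
  pick_counterpart(model, s, topic)
}

pick_counterpart <- function(model, s, topic) {
  if (is.null(topic)) return(s)
  if (is.character(topic)) {
    if (!topic %in% names(s)) stop("unknown counterpart: ", topic)
    return(unname(s[topic]))
  }
  unname(s[as.integer(topic)])
}

#' Ranked block characterisation scores
#'
#' Tidy table of nested specificity or commonality scores of one block
#' against all counterpart units, sorted by decreasing score.  Setting
#' `granularity = "element"` scores individual terms (or documents /
#' metadata values when transposed); passing a topic as the focal block
#' yields the characteristic domains of that topic.
#'
#' @inheritParams nested_specificity
#' @param block Focal block reference.
#' @param kind `"specificity"` or `"commonality"`.
#' @return A `data.frame` with columns `level`, `block`, `counterpart`,
#'   `kind`, `score`.
#' @export
block_scores <- function(model, block, kind = c("specificity",
                                                "commonality"),
                         granularity = c("block", "element")) {
  kind <- match.arg(kind)
  granularity <- match.arg(granularity)
  ref <- resolve_block(model, block)
  s <- if (kind == "specificity")
    nested_specificity(model, block, granularity = granularity)
  else nested_commonality(model, block, granularity = granularity)
  lab <- model_labels(model)[[ref$side]][[ref$level]][ref$id]
  out <- data.frame(level = ref$level, block = lab,
                    counterpart = names(s), kind = kind,
                    score = unname(s), stringsAsFactors = FALSE)
  out[order(-out$score, out$counterpart), , drop = FALSE]
}

#' Prevalence change of a domain between two periods
#'
#' The share of the later period's documents that belong to the domain,
#' minus the same share in the earlier period.  Shares are within-period
#' fractions, so the overall growth of the corpus does not masquerade as
#' domain growth.
#'
#' @param model The source `domain_topic_model`.
#' @param chained A year-chained `chained_model` on the same documents.
#' @param domain Domain block reference (label or list).
#' @param periods Length-2 vector of period block ids (or `"L{i}P{j}"`
#'   labels) giving the earlier and later period.
#' @param period_level Level of the chained model at which the periods
#'   live (ignored when labels are given).
#' @return Signed fraction: positive when the domain grew.
#' @export
prevalence_change <- function(model, chained, domain, periods = c(1L, 2L),
                              period_level = 1L) {
  stopifnot(inherits(chained, "chained_model"), length(periods) == 2L)
  if (is.character(periods)) {
    refs <- lapply(periods, resolve_block, model = chained)
    period_level <- refs[[1L]]$level
    periods <- vapply(refs, `[[`, 0L, "id")
  }
  ref <- resolve_block(model, domain)
  stopifnot(ref$side == "left")
  # documents of each period: those connected to the period's years
  year_block <- membership(chained, period_level, "right")
  doc_period <- year_block[chained$graph$edges[
    match(seq_along(chained$graph$left), chained$graph$edges[, 1L]), 2L]]
  # domain membership of the chained documents, via the source model
  doc_dom <- membership(model, ref$level, "left")[
    match(chained$graph$left, model$graph$left)]
  share <- function(p) {
    docs <- which(doc_period == p)
    if (!length(docs)) stop("empty period: ", p)
    mean(doc_dom[docs] == ref$id, na.rm = TRUE)
  }
  share(periods[2L]) - share(periods[1L])
}
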