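#' Fit configuration
#'
#' Collects the tuning parameters of the description-length search.  The
#' seed fixes the full random stream, so identical configurations yield
#' byte-identical models.
#'
#' @param seed Integer seed for the random stream.
#' @param n_restarts Independent search restarts; the best state wins.
#' @param sweeps Metropolis sweeps per agglomeration stage and per
#'   inverse temperature.
#' @param sigma Agglomeration shrink factor (> 1): each stage reduces the
#'   number of blocks from `B` to `floor(B / sigma)`.
#' @param betas Inverse-temperature schedule for the sweeps; `Inf` means
#'   greedy descent.
#' @param max_levels Cap on the number of hierarchy levels.
#' @param n_candidates Candidate partners sampled per block when choosing
#'   merges.
#' @return An object of class `"fit_config"`.
#' @export
fit_config <- function(seed = 1L, n_restarts = 5L, sweeps = 10L,
                       sigma = 1.5, betas = c(1, Inf), max_levels = 10L,
                       n_candidates = 8L) {
  stopifnot(n_restarts >= 1L, sweeps >= 0L, sigma > 1, max_levels >= 1L,
            n_candidates >= 1L, all(betas > 0))
  structure(list(seed = as.integer(seed), n_restarts = as.integer(n_restarts),
                 sweeps = as.integer(sweeps), sigma = sigma,
                 betas = as.numeric(betas),
                 max_levels = as.integer(max_levels),
                 n_candidates = as.integer(n_candidates)),
            class = "fit_config")
}

# One base-level search (kind A), best of n_restarts.
fit_base_level <- function(graph, config, frozen_left = integer(),
                           prior_left = TRUE) {
  nL <- length(graph$left); nR <- length(graph$right)
  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    res <- cpp_fit_level(graph$edges, rep(1, nrow(graph$edges)), nL, nR,
                         TRUE, prior_left, TRUE, frozen_left,
                         nL, nR, config$sigma, config$sweeps, config$betas,
                         config$n_candidates, integer(), integer(), TRUE)
    if (is.null(best) || res$dl < best$dl - 1e-10) best <- res
  }
  best
}

# One upper-level search (kind B) on a block multigraph given as a dense
# count matrix e (prev left blocks x prev right blocks).  frozen_left, if
# nonempty, preassigns the left blocks to groups.
fit_upper_level <- function(e_mat, config, frozen_left = integer(),
                            prior_left = TRUE) {
  BL <- nrow(e_mat); BR <- ncol(e_mat)
  nz <- which(e_mat > 0, arr.ind = TRUE)
  edges <- cbind(nz[, 1L], nz[, 2L])
  weights <- e_mat[nz]
  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    res <- cpp_fit_level(edges, weights, BL, BR,
                         FALSE, prior_left, TRUE, frozen_left,
                         BL, BR, config$sigma, config$sweeps, config$betas,
                         config$n_candidates, integer(), integer(), TRUE)
    if (is.null(best) || res$dl < best$dl - 1e-10) best <- res
  }
  best
}

# Grow upper levels on top of a base assignment.  Returns the list of
# per-level assignment vectors (each over the previous level's blocks),
# closing with a trivial top level.  A level is kept only if its fitted
# grouping beats the flat closure it replaces; levels are capped at
# config$max_levels.
grow_levels <- function(e1, config) {
  levels <- list()
  e_cur <- e1
  l <- 1L
  repeat {
    BL <- nrow(e_cur); BR <- ncol(e_cur)
    if (BL == 1L && BR == 1L) break
    if (l + 1L > config$max_levels) {
      levels[[length(levels) + 1L]] <-
        list(left = rep(1L, BL), right = rep(1L, BR))
      break
    }
    trivial_obj <- lmultiset(BL * BR, sum(e_cur))
    res <- fit_upper_level(e_cur, config)
    gl <- match(res$left, unique(res$left))
    gr <- match(res$right, unique(res$right))
    nontrivial <- max(gl) > 1L || max(gr) > 1L
    if (!nontrivial || res$dl >= trivial_obj - 1e-10) {
      levels[[length(levels) + 1L]] <-
        list(left = rep(1L, BL), right = rep(1L, BR))
      break
    }
    levels[[length(levels) + 1L]] <- list(left = gl, right = gr)
    e_cur <- t(rowsum(t(rowsum(e_cur, gl)), gr))
    l <- l + 1L
  }
  levels
}

#' Fit a domain-topic model
#'
#' Fits the nested, degree-corrected, non-overlapping stochastic block
#' model to a bipartite document-term graph by minimising the description
#' length, with blocks constrained to be type-pure: documents cluster into
#' domains, terms into topics.  Both the number of blocks at each level
#' and the number of levels are inferred; nothing is taken as input.  The
#' single best state found across restarts is returned.
#'
#' @param graph A `bipartite_graph` from [build_doc_term_graph()].
#' @param config A [fit_config()].
#' @return An object of class `"domain_topic_model"`: the graph, the
#'   [nested_partition()], the description length (see
#'   [description_length()]), cached level-1 block edge counts, the
#'   configuration and seed.
#' @seealso [refine_dtm()], [fit_chained()], [description_length()]
#' @export
fit_dtm <- function(graph, config = fit_config()) {
  stopifnot(inherits(graph, "bipartite_graph"), inherits(config, "fit_config"))
  if (length(graph$left) == 0L || nrow(graph$edges) == 0L)
    stop("cannot fit an empty graph")
  set.seed(config$seed)
  base <- fit_base_level(graph, config)
  lv1 <- list(left = match(base$left, unique(base$left)),
              right = match(base$right, unique(base$right)))
  e1 <- block_matrix(graph, lv1$left, lv1$right)
  upper <- grow_levels(e1, config)
  levels <- canonicalize_partition(c(list(lv1), upper))
  partition <- nested_partition(levels)
  dtm_from_state(graph, partition, config = config)
}

#' Build a model object from a graph and a given partition
#'
#' Assembles a `domain_topic_model` without running any search, evaluating
#' the description length of the supplied state.  Useful for comparing
#' hand-constructed states and for testing.
#'
#' @param graph A `bipartite_graph`.
#' @param partition A [nested_partition()] valid for the graph.
#' @param config Optional [fit_config()] to record.
#' @return A `domain_topic_model`.
#' @export
dtm_from_state <- function(graph, partition, config = NULL) {
  dl <- description_length(graph, partition)
  e1 <- block_matrix(graph, partition$levels[[1L]]$left,
                     partition$levels[[1L]]$right)
  structure(list(graph = graph, partition = partition, dl = dl, e1 = e1,
                 config = config,
                 seed = if (!is.null(config)) config$seed else NA_integer_),
            class = "domain_topic_model")
}

#' @export
print.domain_topic_model <- function(x, ...) {
  B <- vapply(x$partition$levels, function(lv)
    c(max(lv$left), max(lv$right)), c(0, 0))
  cat("Domain-topic model:", length(x$graph$left), "documents,",
      length(x$graph$right), "terms,", nrow(x$graph$edges), "edges\n")
  cat("  levels:", ncol(B), "\n")
  cat("  domains per level:", paste(B[1L, ], collapse = " "), "\n")
  cat("  topics per level: ", paste(B[2L, ], collapse = " "), "\n")
  cat(sprintf("  description length: %.2f nats\n", x$dl$total))
  invisible(x)
}

#' Continue the search from an existing model
#'
#' Runs additional sweeps at the base level from the model's current
#' state, rebuilds the upper levels, and returns whichever of the old and
#' new state has the lower description length.  The returned description
#' length is therefore never worse than the input's; with `sweeps = 0`
#' the input model is returned unchanged.
#'
#' @param model A `domain_topic_model`.
#' @param config A [fit_config()]; its seed restarts the random stream.
#' @return A `domain_topic_model`.
#' @export
refine_dtm <- function(model, config = fit_config()) {
  stopifnot(inherits(model, "domain_topic_model"))
  if (config$sweeps == 0L) return(model)
  set.seed(config$seed)
  graph <- model$graph
  nL <- length(graph$left); nR <- length(graph$right)
  res <- cpp_fit_level(graph$edges, rep(1, nrow(graph$edges)), nL, nR,
                       TRUE, TRUE, TRUE, integer(), nL, nR,
                       config$sigma, config$sweeps, config$betas,
                       config$n_candidates,
                       model$partition$levels[[1L]]$left,
                       model$partition$levels[[1L]]$right, FALSE)
  lv1 <- list(left = match(res$left, unique(res$left)),
              right = match(res$right, unique(res$right)))
  e1 <- block_matrix(graph, lv1$left, lv1$right)
  upper <- grow_levels(e1, config)
  levels <- canonicalize_partition(c(list(lv1), upper))
  cand <- dtm_from_state(graph, nested_partition(levels), config = config)
  if (cand$dl$total < model$dl$total - 1e-10) cand else model
}
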