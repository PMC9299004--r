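#' Render a block label
#'
#' Blocks are referred to as `L{i}{kind}{j}`: e.g. `L2T29` is the topic
#' with index 29 at level 2, `L3D40` the domain with index 40 at level 3,
#' `L1P0` the first level-1 period of a chained model.  Within a level,
#' topic indices start at 0 and domain indices continue from the highest
#' topic index, so domain and topic indices never coincide at a level.
#'
#' @param level Level index (1 = base).
#' @param kind `"D"` (domain), `"T"` (topic) or `"P"` (metadata block).
#' @param index Block index within the level (see above).
#' @return Character label.
#' @export
block_label <- function(level, kind, index) {
  stopifnot(kind %in% c("D", "T", "P"))
  sprintf("L%d%s%d", as.integer(level), kind, as.integer(index))
}

#' Parse a block label
#' @param label Label such as `"L2D29"`.
#' @return List with `level`, `kind`, `index`.
#' @export
parse_block_label <- function(label) {
  m <- regmatches(label, regexec("^L([0-9]+)([DTP])([0-9]+)$", label))[[1L]]
  if (length(m) != 4L) stop("malformed block label: ", label)
  list(level = as.integer(m[2L]), kind = m[3L], index = as.integer(m[4L]))
}

# Labels of all blocks of a model, per level and side.  For a
# domain-topic model the domain indices are offset by the level's topic
# count; chained models carry the source model's domain labels.
model_labels <- function(model) {
  L <- length(model$partition$levels)
  left <- vector("list", L); right <- vector("list", L)
  for (l in seq_len(L)) {
    B <- unname(n_blocks(model, l))      # c(left, right)
    if (inherits(model, "chained_model")) {
      left[[l]] <- unname(unlist(model$left_labels[[l]]))
      right[[l]] <- sprintf("L%dP%d", l, seq_len(B[2L]) - 1L)
    } else {
      right[[l]] <- sprintf("L%dT%d", l, seq_len(B[2L]) - 1L)
      left[[l]] <- sprintf("L%dD%d", l, B[2L] + seq_len(B[1L]) - 1L)
    }
  }
  list(left = left, right = right)
}

# Resolve a user-facing block reference into list(side, level, id) with a
# 1-based internal block id.  Accepts a label string or a list with
# elements side, level, id.
resolve_block <- function(model, block) {
  if (is.list(block) && !is.null(block$side))
    return(list(side = block$side, level = as.integer(block$level),
                id = as.integer(block$id)))
  stopifnot(is.character(block), length(block) == 1L)
  p <- parse_block_label(block)
  labs <- model_labels(model)
  side <- if (p$kind == "D") "left" else "right"
  pool <- labs[[side]][[p$level]]
  id <- match(block, pool)
  if (is.na(id)) stop("unknown block: ", block)
  list(side = side, level = p$level, id = id)
}
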