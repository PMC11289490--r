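# Reverse-mode automatic differentiation on dense arrays.
#
# A computation graph node is an environment holding the forward value, a
# list of parent nodes and a closure that maps the node's output gradient to
# the list of parent gradients. Nodes are numbered at creation; because
# parents are always created before children, decreasing creation order is a
# valid reverse topological order for backpropagation.

.ad_env <- new.env(parent = emptyenv())
.ad_env$counter <- 0L

#' @keywords internal
ad_node <- function(value, parents = list(), backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$parents <- parents
  n$backward <- backward
  n$grad <- NULL
  .ad_env$counter <- .ad_env$counter + 1L
  n$id <- .ad_env$counter
  class(n) <- "ad_node"
  n
}

#' Wrap a numeric array as a graph leaf
#'
#' Leaves created with `ad_leaf()` accumulate gradients during
#' [ad_backward()]; use them for trainable parameters and for inputs whose
#' gradient is wanted (e.g. finite-difference checks of losses with respect
#' to the fused image).
#'
#' @param x numeric vector, matrix or array.
#' @return an `ad_node`.
#' @keywords internal
ad_leaf <- function(x) ad_node(x)

is_ad <- function(x) inherits(x, "ad_node")

#' Coerce to node: plain numerics become constant leaves.
#' @keywords internal
as_ad <- function(x) if (is_ad(x)) x else ad_node(x)

#' Forward value of a node (identity on plain numerics).
#' @keywords internal
ad_value <- function(x) if (is_ad(x)) x$value else x

#' Run backpropagation from a scalar root
#'
#' Accumulates gradients into every node reachable from `root`. Gradients
#' from previous calls are cleared on the reachable set first.
#'
#' @param root an `ad_node` whose value has length 1.
#' @keywords internal
ad_backward <- function(root) {
  stopifnot(is_ad(root), length(root$value) == 1L)
  # collect reachable nodes (iterative DFS; recursion would overflow on
  # deep graphs)
  seen <- new.env(parent = emptyenv())
  nodes <- vector("list", 256L)
  nn <- 0L
  stack <- list(root)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- nd
    if (length(nd$parents)) stack <- c(stack, nd$parents)
  }
  nodes <- nodes[seq_len(nn)]
  for (nd in nodes) nd$grad <- NULL
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  root$grad <- 1
  for (i in ord) {
    nd <- nodes[[i]]
    if (is.null(nd$backward) || is.null(nd$grad)) next
    gs <- nd$backward(nd$grad)
    for (j in seq_along(nd$parents)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- nd$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

#' Gradient stored on a leaf after [ad_backward()] (zeros if unreached).
#' @keywords internal
ad_grad <- function(x) {
  if (is.null(x$grad)) array(0, dim(x$value) %||% length(x$value)) else x$grad
}

`%||%` <- function(a, b) if (is.null(a)) b else a
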