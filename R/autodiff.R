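# Reverse-mode automatic differentiation on a dynamic tape.
#
# Every differentiable quantity is an `ad_node`: an environment holding the
# forward value, the accumulated gradient, the parent nodes and a backward
# closure. Operations (ops.R) create nodes in topological order on a global
# tape; ad_backward() walks the tape in reverse. Parameters are leaf nodes
# that persist across steps, so their gradients survive tape disposal.

.ad <- new.env(parent = emptyenv())
.ad$active <- FALSE
.ad$nodes <- list()
.ad$n <- 0L

#' Start recording a fresh gradient tape
#'
#' Subsequent tensor operations record backward closures until [ad_end()] is
#' called. Only one tape is active at a time; training code opens one tape per
#' optimization sub-problem (generator side, then discriminator side).
#' @return Invisibly, `NULL`.
#' @keywords internal
#' @export
ad_begin <- function() {
  .ad$nodes <- vector("list", 1024L)
  .ad$n <- 0L
  .ad$active <- TRUE
  invisible(NULL)
}

#' Stop recording and discard the current tape
#' @return Invisibly, `NULL`.
#' @keywords internal
#' @export
ad_end <- function() {
  .ad$active <- FALSE
  .ad$nodes <- list()
  .ad$n <- 0L
  invisible(NULL)
}

ad_record <- function(node) {
  n <- .ad$n + 1L
  if (n > length(.ad$nodes)) length(.ad$nodes) <- 2L * n
  .ad$nodes[[n]] <- node
  .ad$n <- n
  node
}

# Create an interior node. Backward closures are only kept while a tape is
# active; during inference nodes are value-only shells.
nd_op <- function(value, parents, backward) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  class(e) <- "ad_node"
  if (isTRUE(.ad$active)) {
    e$parents <- parents
    e$backward <- backward
    ad_record(e)
  }
  e
}

#' Create a trainable parameter node
#' @param value Numeric array/matrix/vector of initial values.
#' @return An `ad_node` flagged as a leaf; its gradient accumulates across a
#'   backward pass and is consumed by the optimizer.
#' @keywords internal
#' @export
nd_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$leaf <- TRUE
  class(e) <- "ad_node"
  e
}

#' Wrap a constant in a node (no gradient tracked)
#' @param value Numeric data.
#' @return An `ad_node` with no parents.
#' @keywords internal
#' @export
nd_const <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  class(e) <- "ad_node"
  e
}

is_node <- function(x) inherits(x, "ad_node")

# does this node want a gradient? (leaf parameter or recorded interior node)
needs_grad <- function(x) isTRUE(x$leaf) || !is.null(x$backward)

#' Extract the forward value of a node (or pass plain numerics through)
#' @param x An `ad_node` or numeric.
#' @return The numeric value.
#' @keywords internal
#' @export
val <- function(x) if (is_node(x)) x$value else x

acc_grad <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

#' Back-propagate from a scalar loss node through the active tape
#'
#' Gradients accumulate into every upstream node; leaf parameters keep theirs
#' until [zero_grads()].
#' @param loss Scalar `ad_node`.
#' @return Invisibly, `NULL`.
#' @keywords internal
#' @export
ad_backward <- function(loss) {
  stopifnot(is_node(loss), length(loss$value) == 1L)
  if (!isTRUE(.ad$active)) stop("no active tape; call ad_begin() before the forward pass")
  loss$grad <- 1
  for (i in seq.int(.ad$n, 1L)) {
    nd <- .ad$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      if (!is.null(gs[[j]])) acc_grad(ps[[j]], gs[[j]])
    }
    nd$grad <- NULL
    nd$backward <- NULL
  }
  invisible(NULL)
}

#' Flatten a nested model structure into a named list of parameter nodes
#' @param x A model (nested named lists containing `ad_node` leaves).
#' @param prefix Name prefix used during recursion.
#' @return Named list of `ad_node` parameters, names joined with `.`.
#' @keywords internal
#' @export
collect_params <- function(x, prefix = "") {
  if (is_node(x)) {
    if (isTRUE(x$leaf)) return(stats::setNames(list(x), prefix))
    return(list())
  }
  if (is.list(x)) {
    out <- list()
    nms <- names(x)
    for (i in seq_along(x)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      sub <- collect_params(x[[i]], if (nzchar(prefix)) paste0(prefix, ".", nm) else nm)
      if (length(sub)) out <- c(out, sub)
    }
    return(out)
  }
  list()
}

#' Reset accumulated gradients on a set of parameters
#' @param params Named list of parameter nodes.
#' @return Invisibly, `NULL`.
#' @keywords internal
#' @export
zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- Adam optimizer (adaptive moment estimation) ----

#' Create an Adam optimizer state for a parameter set
#' @param params Named list of parameter nodes.
#' @param beta1,beta2 Exponential decay rates for the first/second moments.
#'   Defaults (0.5, 0.999) follow the usual unpaired-GAN convention.
#' @param eps Numerical stabilizer.
#' @return An optimizer object for [adam_step()].
#' @export
adam_new <- function(params, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  st <- list(
    params = params,
    m = lapply(params, function(p) p$value * 0),
    v = lapply(params, function(p) p$value * 0),
    t = 0L, beta1 = beta1, beta2 = beta2, eps = eps
  )
  structure(st, class = "octstain_adam")
}

#' Apply one Adam update in place
#' @param opt Optimizer from [adam_new()].
#' @param lr Learning rate for this step.
#' @return The updated optimizer object (parameter values are modified in
#'   place inside their nodes).
#' @export
adam_step <- function(opt, lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t
  c2 <- 1 - b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g * g
    mhat <- opt$m[[i]] / c1
    vhat <- opt$v[[i]] / c2
    p$value <- p$value - lr * mhat / (sqrt(vhat) + opt$eps)
  }
  opt
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
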