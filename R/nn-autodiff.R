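# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Tensors flowing through the network are R arrays with dim c(H, W, C, N)
# (rows, columns, channels, batch).  A "node" is an environment holding the
# value, the accumulated gradient, its parent nodes and a backward closure.
# While a tape is active every op records its node; nn_backward() replays the
# tape in reverse.  Outside a tape (inference) the same ops run but record
# nothing, so there is a single forward code path.

.nn <- new.env(parent = emptyenv())
.nn$tape <- NULL

#' Start recording operations for backpropagation
#' @keywords internal
tape_start <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  .nn$tape <- tp
  invisible(tp)
}

#' Stop recording and drop the current tape
#' @keywords internal
tape_stop <- function() {
  .nn$tape <- NULL
  invisible(NULL)
}

recording <- function() !is.null(.nn$tape)

node_new <- function(v, parents = list(), bw = NULL, param_ref = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- v
  nd$grad <- NULL
  tp <- .nn$tape
  if (!is.null(tp)) {
    nd$parents <- parents
    nd$bw <- bw
    nd$param_ref <- param_ref
    tp$n <- tp$n + 1L
    if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
    tp$nodes[[tp$n]] <- nd
  }
  nd
}

#' Create a trainable parameter
#'
#' Parameters live outside any tape; gradients from nn_backward() accumulate
#' in `$grad` and Adam moment estimates in `$m` / `$u`.
#' @param v initial value (numeric array)
#' @return an environment of class `nn_param`
#' @keywords internal
nn_param <- function(v) {
  p <- new.env(parent = emptyenv())
  p$v <- v
  p$grad <- NULL
  p$m <- 0
  p$u <- 0
  class(p) <- "nn_param"
  p
}

is_param <- function(x) inherits(x, "nn_param")

# Wrap a parameter (or plain array) as a graph node for one forward pass.
as_node <- function(x) {
  if (is.environment(x) && !is_param(x)) return(x)    # already a node
  if (is_param(x)) return(node_new(x$v, param_ref = x))
  node_new(x)
}

acc_grad <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

#' Backpropagate from a scalar loss node through the active tape
#' @keywords internal
nn_backward <- function(loss) {
  tp <- .nn$tape
  if (is.null(tp)) stop("nn_backward() called with no active tape")
  loss$grad <- 1
  for (i in seq.int(tp$n, 1L)) {
    nd <- tp$nodes[[i]]
    g <- nd$grad
    if (is.null(g)) next
    if (!is.null(nd$param_ref)) {
      p <- nd$param_ref
      if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
    }
    if (!is.null(nd$bw)) {
      gs <- nd$bw(g)
      for (j in seq_along(gs)) {
        if (!is.null(gs[[j]])) acc_grad(nd$parents[[j]], gs[[j]])
      }
    }
    nd$grad <- NULL   # free memory as we go
  }
  invisible(NULL)
}

# Recursively collect nn_param objects from a nested model list (batch-norm
# states contribute their gamma/beta).
collect_params <- function(x) {
  if (is_param(x)) return(list(x))
  if (inherits(x, "nn_bn")) return(list(x$gamma, x$beta))
  if (is.list(x)) return(unlist(lapply(x, collect_params), recursive = FALSE))
  list()
}

#' One Adam update over a parameter list
#'
#' @param params list of `nn_param` (see [collect_params()])
#' @param lr learning rate
#' @param t step counter (1-based) for bias correction
#' @keywords internal
adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  b1t <- 1 - beta1^t
  b2t <- 1 - beta2^t
  for (p in params) {
    g <- p$grad
    if (is.null(g)) next
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$u <- beta2 * p$u + (1 - beta2) * g * g
    p$v <- p$v - lr * (p$m / b1t) / (sqrt(p$u / b2t) + eps)
    p$grad <- NULL
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# He-normal initialisation for a conv weight of dim (k, k, Cin_per_group, Cout).
init_conv_w <- function(k, cin, cout, gain = 2) {
  fan_in <- k * k * cin
  nn_param(array(stats::rnorm(k * k * cin * cout, sd = sqrt(gain / fan_in)),
                 dim = c(k, k, cin, cout)))
}
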