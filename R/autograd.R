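#' @useDynLib icseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal reverse-mode automatic differentiation.
#
# Tensors are environments holding a numeric array ($val), an accumulated
# gradient ($grad), a creation id used for topological ordering, the parent
# tensors and a backward closure mapping the output gradient to a list of
# parent gradients. Graphs are built eagerly during the forward pass and
# freed by the garbage collector once the results go out of scope.
#
# Constant folding: an op whose parents all have requires = FALSE returns a
# plain constant tensor, so inference-only code pays no graph overhead.
# ---------------------------------------------------------------------------

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0L

ag_next_id <- function() {
  .ag$counter <- .ag$counter + 1L
  .ag$counter
}

#' Create an autodiff tensor
#'
#' Wraps a numeric array (or matrix/vector) as a node of the computation
#' graph. Leaf tensors created with `requires_grad = TRUE` accumulate
#' gradients during [ag_backward()].
#'
#' @param val numeric array, matrix or vector.
#' @param requires_grad should gradients be accumulated for this leaf?
#' @return an object of class `ag_tensor`.
#' @keywords internal
ag_tensor <- function(val, requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$id <- ag_next_id()
  e$parents <- NULL
  e$backfn <- NULL
  e$requires <- isTRUE(requires_grad)
  class(e) <- "ag_tensor"
  e
}

ag_param <- function(val) ag_tensor(val, requires_grad = TRUE)
ag_const <- function(val) ag_tensor(val, requires_grad = FALSE)

is_ag <- function(x) inherits(x, "ag_tensor")
ag_val <- function(x) if (is_ag(x)) x$val else x
as_ag <- function(x) if (is_ag(x)) x else ag_const(x)

# Build an op node; skip graph bookkeeping when no parent needs gradients.
ag_node <- function(val, parents, backfn) {
  req <- FALSE
  for (p in parents) if (p$requires) { req <- TRUE; break }
  out <- ag_tensor(val, requires_grad = FALSE)
  if (req) {
    out$parents <- parents
    out$backfn <- backfn
    out$requires <- TRUE
  }
  out
}

ag_accumulate <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Reverse-mode backward pass
#'
#' Propagates gradients from a scalar loss tensor to every reachable leaf
#' created with `requires_grad = TRUE`. Interior gradients are dropped as
#' soon as they have been consumed.
#'
#' @param loss an `ag_tensor` holding a single number.
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(is_ag(loss), length(loss$val) == 1L)
  # Collect reachable subgraph (nodes with backfn or gradient-requiring leaves)
  nodes <- new.env(parent = emptyenv())
  stack <- list(loss)
  while (length(stack) > 0L) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(nodes[[key]])) next
    nodes[[key]] <- n
    if (!is.null(n$parents)) {
      for (p in n$parents) if (p$requires) stack[[length(stack) + 1L]] <- p
    }
  }
  all_nodes <- as.list(nodes)
  ids <- vapply(all_nodes, function(n) n$id, integer(1))
  ordering <- order(ids, decreasing = TRUE)
  loss$grad <- if (is.null(dim(loss$val))) 1 else array(1, dim = dim(loss$val))
  for (i in ordering) {
    n <- all_nodes[[i]]
    if (is.null(n$backfn) || is.null(n$grad)) next
    grads <- n$backfn(n$grad)
    for (j in seq_along(n$parents)) {
      p <- n$parents[[j]]
      if (p$requires && !is.null(grads[[j]])) ag_accumulate(p, grads[[j]])
    }
    n$grad <- NULL  # free interior gradient
  }
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# --------------------------- elementwise algebra ---------------------------

# shape-preserving reshape of gradient to a parent's value shape
.g_as <- function(g, ref) {
  if (is.null(dim(ref))) as.vector(g) else array(g, dim = dim(ref))
}

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  la <- length(a$val); lb <- length(b$val)
  val <- if (la == lb) a$val + b$val else if (lb == 1L) a$val + as.numeric(b$val) else a$val + b$val
  ag_node(val, list(a, b), function(g) {
    ga <- if (la == length(g)) .g_as(g, a$val) else sum(g)
    gb <- if (lb == length(g)) .g_as(g, b$val) else sum(g)
    list(ga, gb)
  })
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  la <- length(a$val); lb <- length(b$val)
  ag_node(a$val - if (lb == 1L) as.numeric(b$val) else b$val, list(a, b), function(g) {
    ga <- if (la == length(g)) .g_as(g, a$val) else sum(g)
    gb <- if (lb == length(g)) -.g_as(g, b$val) else -sum(g)
    list(ga, gb)
  })
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  la <- length(a$val); lb <- length(b$val)
  av <- a$val; bv <- b$val
  val <- if (lb == 1L) av * as.numeric(bv) else if (la == 1L) as.numeric(av) * bv else av * bv
  ag_node(val, list(a, b), function(g) {
    ga <- if (la == length(g)) .g_as(g * (if (lb == 1L) as.numeric(bv) else bv), a$val) else sum(g * bv)
    gb <- if (lb == length(g)) .g_as(g * (if (la == 1L) as.numeric(av) else av), b$val) else sum(g * av)
    list(ga, gb)
  })
}

ag_div <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  la <- length(a$val); lb <- length(b$val)
  av <- a$val; bv <- b$val
  val <- if (lb == 1L) av / as.numeric(bv) else av / bv
  ag_node(val, list(a, b), function(g) {
    ga <- if (la == length(g)) .g_as(g / (if (lb == 1L) as.numeric(bv) else bv), a$val) else sum(g / bv)
    gb_full <- -g * av / (if (lb == 1L) as.numeric(bv)^2 else bv^2)
    gb <- if (lb == length(g)) .g_as(gb_full, b$val) else sum(gb_full)
    list(ga, gb)
  })
}

ag_smul <- function(a, k) {   # multiply by plain numeric constant
  a <- as_ag(a)
  ag_node(a$val * k, list(a), function(g) list(.g_as(g * k, a$val)))
}

ag_exp <- function(a) {
  a <- as_ag(a); v <- exp(a$val)
  ag_node(v, list(a), function(g) list(.g_as(g * v, a$val)))
}

ag_log <- function(a) {
  a <- as_ag(a)
  ag_node(log(a$val), list(a), function(g) list(.g_as(g / a$val, a$val)))
}

ag_sigmoid <- function(a) {
  a <- as_ag(a); v <- 1 / (1 + exp(-a$val))
  ag_node(v, list(a), function(g) list(.g_as(g * v * (1 - v), a$val)))
}

ag_gelu <- function(a) {
  # tanh approximation of GELU (standard fast variant)
  a <- as_ag(a); x <- a$val
  k <- sqrt(2 / pi)
  inner <- k * (x + 0.044715 * x^3)
  th <- tanh(inner)
  v <- 0.5 * x * (1 + th)
  ag_node(v, list(a), function(g) {
    dinner <- k * (1 + 3 * 0.044715 * x^2)
    dv <- 0.5 * (1 + th) + 0.5 * x * (1 - th^2) * dinner
    list(.g_as(g * dv, a$val))
  })
}

ag_elu <- function(a) {
  a <- as_ag(a); x <- a$val
  v <- ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
  ag_node(v, list(a), function(g)
    list(.g_as(g * ifelse(x > 0, 1, exp(pmin(x, 0))), a$val)))
}

# ------------------------------- reductions --------------------------------

ag_sum <- function(a) {
  a <- as_ag(a)
  ag_node(sum(a$val), list(a), function(g) {
    gv <- as.numeric(g)
    list(.g_as(array(gv, dim = dim(a$val) %||% length(a$val)), a$val))
  })
}

ag_mean <- function(a) {
  a <- as_ag(a); n <- length(a$val)
  ag_node(mean(a$val), list(a), function(g) {
    gv <- as.numeric(g) / n
    list(.g_as(array(gv, dim = dim(a$val) %||% n), a$val))
  })
}

ag_rowsums <- function(a) {
  a <- as_ag(a)
  ag_node(rowSums(a$val), list(a), function(g) {
    gv <- as.vector(g)
    list(matrix(gv, nrow = nrow(a$val), ncol = ncol(a$val)))
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# --------------------------- linear algebra / shape -------------------------

ag_matmul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$val %*% b$val, list(a, b), function(g) {
    g <- matrix(g, nrow = nrow(a$val))
    list(g %*% t(b$val), crossprod(a$val, g))
  })
}

ag_t <- function(a) {
  a <- as_ag(a)
  ag_node(t(a$val), list(a), function(g) list(t(g)))
}

# dense layer y = x %*% t(W) + b (bias broadcast across rows)
ag_dense <- function(x, W, b) {
  x <- as_ag(x); W <- as_ag(W); b <- as_ag(b)
  n <- nrow(x$val)
  val <- x$val %*% t(W$val) + matrix(b$val, n, length(b$val), byrow = TRUE)
  ag_node(val, list(x, W, b), function(g) {
    g <- matrix(g, nrow = n)
    list(g %*% W$val, crossprod(g, x$val), colSums(g))
  })
}

ag_reshape <- function(a, dims) {
  a <- as_ag(a)
  v <- a$val; dim(v) <- dims
  ag_node(v, list(a), function(g) list(.g_as(g, a$val)))
}

ag_aperm <- function(a, perm) {
  a <- as_ag(a)
  inv <- order(perm)
  ag_node(aperm(a$val, perm), list(a), function(g) list(aperm(g, inv)))
}

ag_rbind <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  na <- nrow(a$val)
  ag_node(rbind(a$val, b$val), list(a, b), function(g) {
    g <- matrix(g, ncol = ncol(a$val))
    list(g[seq_len(na), , drop = FALSE], g[-seq_len(na), , drop = FALSE])
  })
}

ag_cbind <- function(...) {
  args <- lapply(list(...), as_ag)
  ncols <- vapply(args, function(x) ncol(as.matrix(x$val)) %||% 1L, integer(1))
  val <- do.call(cbind, lapply(args, function(x) x$val))
  ends <- cumsum(ncols); starts <- c(1L, utils::head(ends, -1L) + 1L)
  ag_node(val, args, function(g) {
    g <- matrix(g, ncol = sum(ncols))
    lapply(seq_along(args), function(i) {
      gi <- g[, starts[i]:ends[i], drop = FALSE]
      if (is.null(dim(args[[i]]$val))) as.vector(gi) else gi
    })
  })
}

# gather/scatter on flat (column-major) indices of a matrix/array
ag_gather <- function(a, idx) {
  a <- as_ag(a)
  ag_node(a$val[idx], list(a), function(g) {
    out <- array(0, dim = dim(a$val) %||% length(a$val))
    # accumulate duplicates correctly
    acc <- rowsum(as.vector(g), group = idx)
    out[as.integer(rownames(acc))] <- acc[, 1L]
    list(out)
  })
}

ag_gather_rows <- function(a, idx) {
  a <- as_ag(a)
  ag_node(a$val[idx, , drop = FALSE], list(a), function(g) {
    g <- matrix(g, ncol = ncol(a$val))
    out <- matrix(0, nrow(a$val), ncol(a$val))
    acc <- rowsum(g, group = idx)
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

# copy of `a` with flat positions idx replaced by vals (a vector tensor)
ag_index_put <- function(a, idx, vals) {
  a <- as_ag(a); vals <- as_ag(vals)
  v <- a$val
  v[idx] <- vals$val
  ag_node(v, list(a, vals), function(g) {
    ga <- .g_as(g, a$val)
    gv <- g[idx]
    ga[idx] <- 0
    list(ga, as.vector(gv))
  })
}

# ------------------------------ normalization -------------------------------

# z-score over all axes but the last (sample axis) of a 4D (H, W, C, N) array.
ag_layernorm <- function(a, eps = 1e-6) {
  a <- as_ag(a); x <- a$val
  d <- dim(x); N <- d[length(d)]
  m <- length(x) / N
  xm <- matrix(x, nrow = m, ncol = N)
  mu <- colMeans(xm)
  cen <- sweep(xm, 2, mu)
  va <- colMeans(cen^2)
  sd_ <- sqrt(va + eps)
  y <- sweep(cen, 2, sd_, "/")
  val <- array(y, dim = d)
  ag_node(val, list(a), function(g) {
    gm <- matrix(g, nrow = m, ncol = N)
    gmu <- colMeans(gm)
    gy <- colMeans(gm * y)
    dx <- sweep(sweep(gm, 2, gmu) - sweep(y, 2, gy, "*"), 2, sd_, "/")
    list(array(dx, dim = d))
  })
}

# --------------------------------- softmax ----------------------------------

ag_softmax_rows <- function(a) {
  a <- as_ag(a); x <- a$val
  x <- x - apply(x, 1, max)
  e <- exp(x)
  p <- e / rowSums(e)
  ag_node(p, list(a), function(g) {
    g <- matrix(g, nrow = nrow(p))
    list(p * (g - rowSums(g * p)))
  })
}

# row-rescale A so each row sums to target; rows with (near) zero sum stay 0.
ag_safe_rowscale <- function(a, target, eps = 1e-12) {
  a <- as_ag(a); target <- as_ag(target)
  A <- a$val; tg <- as.vector(target$val)
  r <- rowSums(A)
  f <- ifelse(r > eps, tg / r, 0)
  val <- A * f
  ag_node(val, list(a, target), function(g) {
    g <- matrix(g, nrow = nrow(A))
    # d/dA_il [A_il t_i / r_i] = f_i - (t_i / r_i^2) * sum_j g_ij A_ij
    gA_rows <- rowSums(g * A)
    dA <- g * f - outer(ifelse(r > eps, tg / r^2, 0) * gA_rows, rep(1, ncol(A)))
    dt <- ifelse(r > eps, gA_rows / r, 0)
    list(dA, if (is.null(dim(target$val))) dt else .g_as(dt, target$val))
  })
}
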