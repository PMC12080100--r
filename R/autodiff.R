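# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every value on the tape is a base-R double matrix; operations are coarse
# (matrix products, segment reductions, row-wise normalization), so the
# interpretation overhead is negligible next to the BLAS calls.  Nodes are
# environments carrying the forward value, the parent nodes and one closure
# per parent that maps the incoming gradient to that parent's gradient.

.ad_env <- new.env(parent = emptyenv())
.ad_env$counter <- 0L

ad_node <- function(value, parents = list(), grad_fns = list()) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$grad_fns <- grad_fns
  e$grad <- NULL
  # gradient only flows where a parameter sits upstream; constants prune
  # whole backward branches (e.g. the fixed smeared edge features)
  e$requires <- any(vapply(parents, function(p) isTRUE(p$requires),
                           logical(1L)))
  .ad_env$counter <- .ad_env$counter + 1L
  e$idx <- .ad_env$counter
  class(e) <- "ad"
  e
}

is_ad <- function(x) inherits(x, "ad")

#' Wrap a constant matrix for use on the autodiff tape
#'
#' Constants receive no gradient. Vectors are promoted to column matrices.
#'
#' @param x numeric matrix or vector.
#' @return an `ad` tape node.
#' @keywords internal
ad_const <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  ad_node(x)
}

#' Wrap a parameter matrix (gradient-carrying leaf)
#' @param x numeric matrix or vector.
#' @return an `ad` tape node flagged as a parameter.
#' @keywords internal
ad_param <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  n <- ad_node(x)
  n$is_param <- TRUE
  n$requires <- TRUE
  n
}

ad_value <- function(x) if (is_ad(x)) x$value else x

# Topological sweep: collect reachable nodes, then push gradients in reverse
# creation order (creation order is a valid topological order of the tape).
ad_backward <- function(root, seed = NULL) {
  stopifnot(is_ad(root))
  if (is.null(seed)) seed <- matrix(1, nrow(root$value), ncol(root$value))
  nodes <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$idx)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$idx, integer(1L)), decreasing = TRUE)
  root$grad <- seed
  for (nd in nodes[ord]) {
    g <- nd$grad
    if (is.null(g)) next
    if (length(nd$parents)) {
      for (i in seq_along(nd$parents)) {
        p <- nd$parents[[i]]
        if (!isTRUE(p$requires)) next
        pg <- nd$grad_fns[[i]](g)
        p$grad <- if (is.null(p$grad)) pg else p$grad + pg
      }
    }
  }
  invisible(root)
}

ad_zero_grads <- function(root) {
  # walk and clear; used between steps when nodes are reused (params are
  # re-wrapped each step, so normally unnecessary)
  invisible(NULL)
}

## ---- primitive operations ----

ad_matmul <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_node(A %*% B, list(a, b), list(
    function(g) tcrossprod(g, B),
    function(g) crossprod(A, g)
  ))
}

# x %*% W + b with b a 1 x k bias row broadcast over rows
ad_linear <- function(x, W, b) {
  X <- ad_value(x); Wv <- ad_value(W); bv <- ad_value(b)
  out <- X %*% Wv
  out <- out + rep(bv, each = nrow(out))
  ad_node(out, list(x, W, b), list(
    function(g) tcrossprod(g, Wv),
    function(g) crossprod(X, g),
    function(g) matrix(colSums(g), 1L)
  ))
}

ad_add <- function(a, b) {
  ad_node(ad_value(a) + ad_value(b), list(a, b),
          list(function(g) g, function(g) g))
}

ad_sub <- function(a, b) {
  ad_node(ad_value(a) - ad_value(b), list(a, b),
          list(function(g) g, function(g) -g))
}

ad_scalar_mul <- function(x, s) {
  ad_node(ad_value(x) * s, list(x), list(function(g) g * s))
}

# elementwise product of two same-shaped nodes
ad_mul <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_node(A * B, list(a, b),
          list(function(g) g * B, function(g) g * A))
}

# shifted softplus ln(1 + e^x) - ln 2, numerically stable
ssp_mat <- function(x) pmax(x, 0) + log1p(exp(-abs(x))) - log(2)

ad_ssp <- function(x) {
  X <- ad_value(x)
  ad_node(ssp_mat(X), list(x), list(function(g) g * stats::plogis(X)))
}

# gather rows; backward scatter-adds
ad_rows <- function(x, idx) {
  X <- ad_value(x)
  n <- nrow(X)
  ad_node(X[idx, , drop = FALSE], list(x), list(function(g) {
    acc <- rowsum(g, group = idx)
    out <- matrix(0, n, ncol(g))
    out[as.integer(rownames(acc)), ] <- acc
    out
  }))
}

# sum rows of x within segments 1..nseg (empty segments give zero rows)
ad_segment_sum <- function(x, seg, nseg) {
  X <- ad_value(x)
  acc <- rowsum(X, group = seg)
  out <- matrix(0, nseg, ncol(X))
  out[as.integer(rownames(acc)), ] <- acc
  ad_node(out, list(x), list(function(g) g[seg, , drop = FALSE]))
}

ad_segment_mean <- function(x, seg, nseg) {
  cnt <- tabulate(seg, nbins = nseg)
  cnt[cnt == 0L] <- 1L
  s <- ad_segment_sum(x, seg, nseg)
  X <- ad_value(s)
  ad_node(X / cnt, list(s), list(function(g) g / cnt))
}

# softmax of a column-vector score within segments (attention normalization)
ad_segment_softmax <- function(s, seg, nseg) {
  S <- ad_value(s)  # n x 1
  mx <- tapply(S[, 1L], seg, max)
  full_mx <- rep(-Inf, nseg)
  full_mx[as.integer(names(mx))] <- mx
  ex <- exp(S[, 1L] - full_mx[seg])
  den <- rowsum(ex, group = seg)
  full_den <- rep(1, nseg)
  full_den[as.integer(rownames(den))] <- den
  a <- ex / full_den[seg]
  A <- matrix(a, ncol = 1L)
  ad_node(A, list(s), list(function(g) {
    gd <- g[, 1L] * a
    dot <- rowsum(gd, group = seg)
    full <- rep(0, nseg)
    full[as.integer(rownames(dot))] <- dot
    matrix(gd - a * full[seg], ncol = 1L)
  }))
}

# scale row i of x by s[i]; s may be an ad column vector (attention weights)
ad_scale_rows <- function(x, s) {
  X <- ad_value(x)
  sv <- ad_value(s)[, 1L]
  if (is_ad(s)) {
    ad_node(X * sv, list(x, s), list(
      function(g) g * sv,
      function(g) matrix(rowSums(g * X), ncol = 1L)
    ))
  } else {
    ad_node(X * sv, list(x), list(function(g) g * sv))
  }
}

ad_rowsums <- function(x) {
  X <- ad_value(x)
  k <- ncol(X)
  ad_node(matrix(rowSums(X), ncol = 1L), list(x), list(function(g) {
    matrix(g[, 1L], nrow(X), k)
  }))
}

ad_colmeans <- function(x) {
  X <- ad_value(x)
  n <- nrow(X)
  ad_node(matrix(colMeans(X), 1L), list(x), list(function(g) {
    matrix(rep(g[1L, ] / n, each = n), n)
  }))
}

ad_cbind <- function(...) {
  args <- list(...)
  vals <- lapply(args, ad_value)
  widths <- vapply(vals, ncol, integer(1L))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  grad_fns <- lapply(seq_along(args), function(i) {
    force(i)
    function(g) g[, starts[i]:ends[i], drop = FALSE]
  })
  ad_node(do.call(cbind, vals), args, grad_fns)
}

ad_rbind <- function(args) {
  vals <- lapply(args, ad_value)
  heights <- vapply(vals, nrow, integer(1L))
  ends <- cumsum(heights)
  starts <- c(1L, head(ends, -1L) + 1L)
  grad_fns <- lapply(seq_along(args), function(i) {
    force(i)
    function(g) g[starts[i]:ends[i], , drop = FALSE]
  })
  ad_node(do.call(rbind, vals), args, grad_fns)
}

# row-wise LayerNorm with learned affine (gamma, beta are 1 x k)
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  X <- ad_value(x)
  gv <- ad_value(gamma)[1L, ]
  k <- ncol(X)
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- xhat * rep(gv, each = nrow(X)) + rep(ad_value(beta)[1L, ], each = nrow(X))
  ad_node(out, list(x, gamma, beta), list(
    function(g) {
      dxhat <- g * rep(gv, each = nrow(g))
      m1 <- rowMeans(dxhat)
      m2 <- rowMeans(dxhat * xhat)
      (dxhat - m1 - xhat * m2) * inv
    },
    function(g) matrix(colSums(g * xhat), 1L),
    function(g) matrix(colSums(g), 1L)
  ))
}

# dropout with caller-supplied keep mask (already scaled decisions)
ad_dropout <- function(x, p, mask) {
  X <- ad_value(x)
  sc <- mask / (1 - p)
  ad_node(X * sc, list(x), list(function(g) g * sc))
}

# mean squared error over masked-in entries; target/mask are plain matrices.
# Masked-out entries contribute exactly zero to value and gradient, and the
# denominator counts masked-in entries only.
ad_masked_mse <- function(pred, target, mask) {
  P <- ad_value(pred)
  n_in <- sum(mask)
  if (n_in == 0) {
    warning("all targets masked out in batch; loss defined as 0")
    return(ad_node(matrix(0, 1L, 1L), list(pred),
                   list(function(g) matrix(0, nrow(P), ncol(P)))))
  }
  diff <- (P - target) * mask
  val <- sum(diff * diff) / n_in
  ad_node(matrix(val, 1L, 1L), list(pred), list(function(g) {
    g[1L] * 2 * diff / n_in
  }))
}

## ---- parameter tree helpers ----

# wrap every numeric leaf of a nested list as an ad parameter
ad_wrap_params <- function(params) {
  rapply(params, ad_param, classes = c("matrix", "numeric", "array"),
         how = "replace")
}

# collect gradients back into the same nested shape (zeros where untouched)
ad_collect_grads <- function(wrapped) {
  rapply(wrapped, function(nd) {
    if (is.null(nd$grad)) matrix(0, nrow(nd$value), ncol(nd$value)) else nd$grad
  }, classes = "ad", how = "replace")
}

param_keys <- function(x) {
  nms <- names(x)
  if (is.null(nms)) as.character(seq_along(x)) else nms
}

# flatten a nested list of matrices to a named flat list (for the optimizer);
# unnamed list levels are keyed by position
flatten_params <- function(params, prefix = "") {
  out <- list()
  keys <- param_keys(params)
  for (i in seq_along(params)) {
    x <- params[[i]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", keys[i]) else keys[i]
    if (is.list(x)) out <- c(out, flatten_params(x, key))
    else out[[key]] <- x
  }
  out
}

# write a flat named list back into the nested shape of `template`
unflatten_params <- function(flat, template, prefix = "") {
  keys <- param_keys(template)
  for (i in seq_along(template)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", keys[i]) else keys[i]
    if (is.list(template[[i]])) {
      template[[i]] <- unflatten_params(flat, template[[i]], key)
    } else {
      template[[i]] <- flat[[key]]
    }
  }
  template
}
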