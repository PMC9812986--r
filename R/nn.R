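# Compact CPU convolutional-network engine.
#
# Networks are small static graphs of primitive ops (stride-1 'same' 3x3/1x1
# convolution, ReLU, 2x2 max-pool, 2x2 stride-2 transposed convolution,
# channel concatenation, elementwise add, sigmoid). The forward pass records
# per-node values; reverse-mode backpropagation walks the graph backwards.
# Heavy kernels live in src/ (RcppArmadillo); graph bookkeeping stays in R.
# Tensors are H x W x C arrays.

graph_new <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g$pdims <- list()   # parameter shape registry
  g
}

g_add_node <- function(g, op, inputs = integer(0), ...) {
  g$nodes[[length(g$nodes) + 1L]] <- c(list(op = op, inputs = as.integer(inputs)),
                                       list(...))
  length(g$nodes)
}

g_param <- function(g, dim) {
  g$pdims[[length(g$pdims) + 1L]] <- as.integer(dim)
  length(g$pdims)
}

g_input <- function(g) g_add_node(g, "input")

g_conv <- function(g, x, cin, cout, k = 3L) {
  w <- g_param(g, c(k * k * cin, cout))
  b <- g_param(g, cout)
  g_add_node(g, "conv", x, w = w, b = b, k = as.integer(k), cin = cin, cout = cout)
}

g_relu <- function(g, x) g_add_node(g, "relu", x)
g_pool <- function(g, x) g_add_node(g, "pool", x)

g_convtr <- function(g, x, cin, cout) {
  w <- g_param(g, c(cin, 4L * cout))
  b <- g_param(g, cout)
  g_add_node(g, "convtr", x, w = w, b = b, cin = cin, cout = cout)
}

g_concat <- function(g, a, b) g_add_node(g, "concat", c(a, b))
g_sum <- function(g, a, b) g_add_node(g, "add", c(a, b))
g_sigmoid <- function(g, x) g_add_node(g, "sigmoid", x)

# convenience: conv + relu
g_cr <- function(g, x, cin, cout, k = 3L) g_relu(g, g_conv(g, x, cin, cout, k))

nn_count_params <- function(g) {
  sum(vapply(g$pdims, prod, numeric(1)))
}

# He-style initialization; deterministic under `seed`
nn_init_params <- function(g, seed = 1L) {
  with_seed(seed, lapply(g$pdims, function(d) {
    if (length(d) == 1L) return(numeric(d))  # biases start at zero
    fan_in <- d[1]
    matrix(rnorm(prod(d), 0, sqrt(2 / fan_in)), d[1], d[2])
  }))
}

as_cube <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

nn_forward <- function(g, params, x) {
  n <- length(g$nodes)
  vals <- vector("list", n)
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    nd <- g$nodes[[i]]
    vals[[i]] <- switch(nd$op,
      input = as_cube(x),
      conv = .nn_conv2d_fwd(vals[[nd$inputs]], params[[nd$w]], params[[nd$b]], nd$k),
      relu = { v <- vals[[nd$inputs]]; v[v < 0] <- 0; v },
      pool = {
        r <- .nn_maxpool2_fwd(vals[[nd$inputs]])
        caches[[i]] <- r$idx
        r$y
      },
      convtr = .nn_convtr2_fwd(vals[[nd$inputs]], params[[nd$w]], params[[nd$b]]),
      concat = {
        a <- vals[[nd$inputs[1]]]; b <- vals[[nd$inputs[2]]]
        da <- dim(a); db <- dim(b)
        array(c(a, b), dim = c(da[1], da[2], da[3] + db[3]))
      },
      add = vals[[nd$inputs[1]]] + vals[[nd$inputs[2]]],
      sigmoid = 1 / (1 + exp(-vals[[nd$inputs]])),
      stop("unknown op ", nd$op)
    )
  }
  list(vals = vals, caches = caches, out = vals[[n]])
}

# Backpropagate `gout` (gradient w.r.t. node `at`, default the last node)
# through the graph.
nn_backward <- function(g, params, fw, gout, at = length(g$nodes)) {
  n <- length(g$nodes)
  vals <- fw$vals
  gvals <- vector("list", n)
  gparams <- lapply(g$pdims, function(d) array(0, dim = d))
  gvals[[at]] <- as_cube(gout)
  acc <- function(i, gx) {
    gvals[[i]] <<- if (is.null(gvals[[i]])) gx else gvals[[i]] + gx
  }
  for (i in rev(seq_len(n))) {
    gy <- gvals[[i]]
    if (is.null(gy)) next
    nd <- g$nodes[[i]]
    switch(nd$op,
      input = NULL,
      conv = {
        r <- .nn_conv2d_bwd(vals[[nd$inputs]], params[[nd$w]], gy, nd$k)
        acc(nd$inputs, r$gx)
        gparams[[nd$w]] <- gparams[[nd$w]] + r$gw
        gparams[[nd$b]] <- gparams[[nd$b]] + as.numeric(r$gb)
      },
      relu = acc(nd$inputs, gy * (vals[[i]] > 0)),
      pool = {
        d <- dim(vals[[nd$inputs]])
        acc(nd$inputs, .nn_maxpool2_bwd(gy, fw$caches[[i]], d[1], d[2]))
      },
      convtr = {
        r <- .nn_convtr2_bwd(vals[[nd$inputs]], params[[nd$w]], gy)
        acc(nd$inputs, r$gx)
        gparams[[nd$w]] <- gparams[[nd$w]] + r$gw
        gparams[[nd$b]] <- gparams[[nd$b]] + as.numeric(r$gb)
      },
      concat = {
        ca <- dim(vals[[nd$inputs[1]]])[3]
        acc(nd$inputs[1], gy[, , seq_len(ca), drop = FALSE])
        acc(nd$inputs[2], gy[, , -seq_len(ca), drop = FALSE])
      },
      add = {
        acc(nd$inputs[1], gy)
        acc(nd$inputs[2], gy)
      },
      sigmoid = {
        s <- vals[[i]]
        acc(nd$inputs, gy * s * (1 - s))
      }
    )
    gvals[[i]] <- NULL  # free as we go
  }
  gparams
}

# Numerically stable mean binary cross entropy evaluated from logits `z`;
# the gradient w.r.t. z is (sigmoid(z) - y) / n, which never vanishes on a
# saturated wrong-side prediction. `w` is an optional 0/1 weight plane.
nn_bce_logits <- function(z, y, w = NULL) {
  if (is.null(w)) {
    n <- length(z)
    loss <- sum(pmax(z, 0) - z * y + log1p(exp(-abs(z)))) / n
    grad <- (1 / (1 + exp(-z)) - y) / n
  } else {
    n <- max(1, sum(w))
    loss <- sum(w * (pmax(z, 0) - z * y + log1p(exp(-abs(z))))) / n
    grad <- w * (1 / (1 + exp(-z)) - y) / n
  }
  list(loss = loss, grad = grad)
}

# Mean per-pixel binary cross entropy of a sigmoid output `p` against a
# {0,1} target; returns loss and the gradient w.r.t. p.
nn_bce <- function(p, y) {
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  n <- length(p)
  loss <- -sum(y * log(pc) + (1 - y) * log(1 - pc)) / n
  grad <- (-(y / pc) + (1 - y) / (1 - pc)) / n
  list(loss = loss, grad = grad)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))),
       v = lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    mhat <- state$m[[i]] / bc1
    vhat <- state$v[[i]] / bc2
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
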