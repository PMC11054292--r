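# Static-graph CNN engine.
#
# A "plan" is a DAG of nodes over (H, W, C) double arrays; ops are input,
# conv (im2col + GEMM, optional fused ReLU), maxpool, upsample2 (nearest),
# concat (channel-wise) and add (residual, optional fused ReLU).  Shapes are
# resolved at plan-build time, so architecture audits need no weights; the
# same plan is instantiated with weights for training/inference.  Backprop
# is implemented per-op against cached forward intermediates.

g_new <- function(input_size, in_channels = 1L) {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g$stages <- list()
  g$outputs <- list()
  g_add_node(g, list(op = "input", inputs = integer(),
                     shape = c(input_size, input_size, in_channels)))
  g
}

g_add_node <- function(g, node) {
  node$id <- length(g$nodes) + 1L
  g$nodes[[node$id]] <- node
  node$id
}

g_shape <- function(g, id) {
  force(id)  # nested builder calls mutate `g`; resolve them first
  g$nodes[[id]]$shape
}

g_conv <- function(g, input, cout, k = 3L, stride = 1L, act = "relu",
                   bias_init = 0) {
  s <- g_shape(g, input)
  pad <- (k - 1L) %/% 2L
  ho <- (s[1] + 2L * pad - k) %/% stride + 1L
  wo <- (s[2] + 2L * pad - k) %/% stride + 1L
  g_add_node(g, list(op = "conv", inputs = input, k = as.integer(k),
                     stride = as.integer(stride), pad = pad,
                     cin = s[3], cout = as.integer(cout), act = act,
                     bias_init = bias_init, shape = c(ho, wo, cout)))
}

g_maxpool <- function(g, input, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  s <- g_shape(g, input)
  ho <- (s[1] + 2L * pad - k) %/% stride + 1L
  wo <- (s[2] + 2L * pad - k) %/% stride + 1L
  g_add_node(g, list(op = "maxpool", inputs = input, k = as.integer(k),
                     stride = as.integer(stride), pad = as.integer(pad),
                     shape = c(ho, wo, s[3])))
}

g_upsample2 <- function(g, input) {
  s <- g_shape(g, input)
  g_add_node(g, list(op = "upsample2", inputs = input,
                     shape = c(2L * s[1], 2L * s[2], s[3])))
}

g_concat <- function(g, inputs) {
  shapes <- lapply(inputs, g_shape, g = g)
  hw <- shapes[[1]][1:2]
  stopifnot(all(vapply(shapes, function(s) all(s[1:2] == hw), TRUE)))
  g_add_node(g, list(op = "concat", inputs = as.integer(inputs),
                     shape = c(hw, sum(vapply(shapes, `[`, 0, 3)))))
}

g_add2 <- function(g, a, b, act = "linear") {
  sa <- g_shape(g, a)
  stopifnot(all(sa == g_shape(g, b)))
  g_add_node(g, list(op = "add", inputs = c(a, b), act = act, shape = sa))
}

g_mark_stage <- function(g, name, kind, c1, c2, in_id, out_id) {
  g$stages[[length(g$stages) + 1L]] <- list(
    name = name, kind = kind, c1 = c1, c2 = c2, in_id = in_id, out_id = out_id)
}

# ---- weights ---------------------------------------------------------------

net_init_params <- function(plan, seed) {
  with_seed(seed, {
    lapply(plan$nodes, function(nd) {
      if (nd$op != "conv") return(NULL)
      fan_in <- nd$k^2 * nd$cin
      list(W = matrix(rnorm(fan_in * nd$cout, sd = sqrt(2 / fan_in)),
                      fan_in, nd$cout),
           b = rep(nd$bias_init, nd$cout))
    })
  })
}

# ---- forward / backward ----------------------------------------------------

net_graph_forward <- function(plan, params, x, cache = FALSE) {
  vals <- vector("list", length(plan$nodes))
  cch <- if (cache) vector("list", length(plan$nodes))
  for (nd in plan$nodes) {
    y <- switch(nd$op,
      input = {
        if (!is.array(x) || length(dim(x)) != 3) x <- array(x, c(dim(x), 1))
        stopifnot(all(dim(x) == nd$shape))
        x
      },
      conv = {
        fw <- .cc_conv_forward(vals[[nd$inputs]], params[[nd$id]]$W,
                               params[[nd$id]]$b, nd$k, nd$stride, nd$pad,
                               cache, nd$act == "relu")
        if (cache) cch[[nd$id]] <- list(col = fw$col)
        fw$y
      },
      maxpool = {
        fw <- .cc_maxpool_forward(vals[[nd$inputs]], nd$k, nd$stride, nd$pad)
        if (cache) cch[[nd$id]] <- list(idx = fw$idx)
        fw$y
      },
      upsample2 = .cc_upsample2_forward(vals[[nd$inputs]]),
      concat = {
        parts <- vals[nd$inputs]
        out <- array(0, nd$shape)
        at <- 0L
        for (p in parts) {
          cc <- dim(p)[3]
          out[, , at + seq_len(cc)] <- p
          at <- at + cc
        }
        out
      },
      add = {
        y <- vals[[nd$inputs[1]]] + vals[[nd$inputs[2]]]
        if (nd$act == "relu") pmax(y, 0) else y
      },
      stop("unknown op: ", nd$op))
    vals[[nd$id]] <- y
  }
  list(vals = vals, cache = cch)
}

# `head_grads`: named list mapping output node id (as character) to the
# gradient array on that node's output.  Returns per-node weight gradients.
net_graph_backward <- function(plan, params, fwd, head_grads) {
  n <- length(plan$nodes)
  dvals <- vector("list", n)
  for (nm in names(head_grads)) {
    id <- as.integer(nm)
    dvals[[id]] <- accum_grad(dvals[[id]], head_grads[[nm]])
  }
  gW <- vector("list", n)
  for (id in rev(seq_len(n))) {
    nd <- plan$nodes[[id]]
    dy <- dvals[[id]]
    if (is.null(dy)) next
    switch(nd$op,
      input = NULL,
      conv = {
        if (nd$act == "relu") dy <- .cc_relu_backward(dy, fwd$vals[[id]])
        ins <- plan$nodes[[nd$inputs]]$shape
        need_dx <- plan$nodes[[nd$inputs]]$op != "input"
        bw <- .cc_conv_backward(dy, fwd$cache[[id]]$col, params[[id]]$W,
                                ins[1], ins[2], ins[3], nd$k, nd$stride,
                                nd$pad, need_dx)
        gW[[id]] <- list(W = bw$dW, b = as.numeric(bw$db))
        if (need_dx)
          dvals[[nd$inputs]] <- accum_grad(dvals[[nd$inputs]], bw$dx)
      },
      maxpool = {
        ins <- plan$nodes[[nd$inputs]]$shape
        dx <- .cc_maxpool_backward(dy, fwd$cache[[id]]$idx,
                                   ins[1], ins[2], ins[3])
        dvals[[nd$inputs]] <- accum_grad(dvals[[nd$inputs]], dx)
      },
      upsample2 = {
        dvals[[nd$inputs]] <- accum_grad(dvals[[nd$inputs]],
                                         .cc_upsample2_backward(dy))
      },
      concat = {
        at <- 0L
        for (inp in nd$inputs) {
          cc <- plan$nodes[[inp]]$shape[3]
          dvals[[inp]] <- accum_grad(dvals[[inp]],
                                     dy[, , at + seq_len(cc), drop = FALSE])
          at <- at + cc
        }
      },
      add = {
        if (nd$act == "relu") dy <- .cc_relu_backward(dy, fwd$vals[[id]])
        for (inp in nd$inputs)
          dvals[[inp]] <- accum_grad(dvals[[inp]], dy)
      })
    dvals[[id]] <- NULL  # free
  }
  gW
}

accum_grad <- function(cur, g) if (is.null(cur)) g else cur + g

# ---- Adam ------------------------------------------------------------------

adam_new <- function(params) {
  list(m = rapply(params, function(x) x * 0, how = "replace"),
       v = rapply(params, function(x) x * 0, how = "replace"),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (id in seq_along(params)) {
    if (is.null(params[[id]])) next
    for (nm in c("W", "b")) {
      gr <- grads[[id]][[nm]]
      if (is.null(gr)) next
      state$m[[id]][[nm]] <- beta1 * state$m[[id]][[nm]] + (1 - beta1) * gr
      state$v[[id]][[nm]] <- beta2 * state$v[[id]][[nm]] + (1 - beta2) * gr^2
      params[[id]][[nm]] <- params[[id]][[nm]] -
        lr * (state$m[[id]][[nm]] / bc1) /
        (sqrt(state$v[[id]][[nm]] / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

# elementwise scale+sum of two gradient sets with the same structure
grads_axpy <- function(acc, g, scale = 1) {
  if (is.null(acc)) {
    return(lapply(g, function(p)
      if (is.null(p)) NULL else list(W = p$W * scale, b = p$b * scale)))
  }
  for (id in seq_along(g)) {
    if (is.null(g[[id]])) next
    acc[[id]]$W <- acc[[id]]$W + g[[id]]$W * scale
    acc[[id]]$b <- acc[[id]]$b + g[[id]]$b * scale
  }
  acc
}
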