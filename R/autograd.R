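# A minimal reverse-mode automatic-differentiation tape over 4-D (H, W, C, N)
# arrays, sufficient for the nested-U generator and its composite loss.
# Nodes are environments appended to a tape in execution order; backward()
# walks the tape in reverse, so the execution order is the topological order.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tape_push <- function(tape, node) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

# A leaf (input or parameter). grad is accumulated only when requires_grad.
ag_leaf <- function(tape, value, requires_grad = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$requires_grad <- requires_grad
  nd$parents <- list()
  nd$backfn <- NULL
  tape_push(tape, nd)
}

ag_op <- function(tape, value, parents, backfn) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$requires_grad <- TRUE
  nd$parents <- parents
  nd$backfn <- backfn
  tape_push(tape, nd)
}

acc_grad <- function(node, g) {
  if (!node$requires_grad) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar node through the whole tape.
ag_backward <- function(tape, node) {
  node$grad <- array(1, dim = c(1, 1, 1, 1))
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$backfn) && !is.null(nd$grad)) nd$backfn(nd)
  }
  invisible(NULL)
}

dim4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected a dim-ed array")
  d
}

# ---- primitive ops -------------------------------------------------------

ag_conv2d <- function(tape, x, w, b, pad, dil = 1L) {
  y <- cpp_conv2d_fwd(x$value, w$value, b$value, as.integer(pad), as.integer(dil))
  ag_op(tape, y, list(x = x, w = w, b = b), local({
    pad <- as.integer(pad); dil <- as.integer(dil)
    function(nd) {
      g <- cpp_conv2d_bwd(nd$parents$x$value, nd$parents$w$value, nd$grad, pad, dil)
      acc_grad(nd$parents$x, g$gx)
      acc_grad(nd$parents$w, g$gw)
      acc_grad(nd$parents$b, as.numeric(g$gb))
    }
  }))
}

ag_relu <- function(tape, x) {
  keep <- x$value > 0
  y <- x$value * keep
  ag_op(tape, y, list(x = x), function(nd) {
    acc_grad(nd$parents$x, nd$grad * keep)
  })
}

ag_maxpool2 <- function(tape, x) {
  d <- dim4(x$value)
  r <- cpp_maxpool2_fwd(x$value)
  ag_op(tape, r$y, list(x = x), function(nd) {
    acc_grad(nd$parents$x, cpp_maxpool2_bwd(r$idx, nd$grad, d[1], d[2]))
  })
}

ag_resize <- function(tape, x, h, w) {
  d <- dim4(x$value)
  if (d[1] == h && d[2] == w) return(x)
  y <- cpp_resize_bilinear_fwd(x$value, as.integer(h), as.integer(w))
  ag_op(tape, y, list(x = x), function(nd) {
    acc_grad(nd$parents$x, cpp_resize_bilinear_bwd(nd$grad, d[1], d[2]))
  })
}

ag_concat <- function(tape, xs) {
  ds <- lapply(xs, function(x) dim4(x$value))
  cs <- vapply(ds, `[`, integer(1), 3L)
  d1 <- ds[[1]]
  y <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (i in seq_along(xs)) {
    y[, , at + seq_len(cs[i]), ] <- xs[[i]]$value
    at <- at + cs[i]
  }
  ag_op(tape, y, xs, function(nd) {
    at <- 0L
    for (i in seq_along(nd$parents)) {
      acc_grad(nd$parents[[i]], nd$grad[, , at + seq_len(cs[i]), , drop = FALSE])
      at <- at + cs[i]
    }
  })
}

ag_add <- function(tape, a, b) {
  ag_op(tape, a$value + b$value, list(a = a, b = b), function(nd) {
    acc_grad(nd$parents$a, nd$grad)
    acc_grad(nd$parents$b, nd$grad)
  })
}

ag_sub <- function(tape, a, b) {
  ag_op(tape, a$value - b$value, list(a = a, b = b), function(nd) {
    acc_grad(nd$parents$a, nd$grad)
    acc_grad(nd$parents$b, -nd$grad)
  })
}

ag_mul <- function(tape, a, b) {
  ag_op(tape, a$value * b$value, list(a = a, b = b), function(nd) {
    acc_grad(nd$parents$a, nd$grad * nd$parents$b$value)
    acc_grad(nd$parents$b, nd$grad * nd$parents$a$value)
  })
}

ag_div <- function(tape, a, b) {
  ag_op(tape, a$value / b$value, list(a = a, b = b), function(nd) {
    acc_grad(nd$parents$a, nd$grad / nd$parents$b$value)
    acc_grad(nd$parents$b, -nd$grad * nd$parents$a$value / nd$parents$b$value^2)
  })
}

ag_scale_shift <- function(tape, x, scale = 1, shift = 0) {
  ag_op(tape, x$value * scale + shift, list(x = x), function(nd) {
    acc_grad(nd$parents$x, nd$grad * scale)
  })
}

ag_abs <- function(tape, x) {
  sg <- sign(x$value)
  ag_op(tape, abs(x$value), list(x = x), function(nd) {
    acc_grad(nd$parents$x, nd$grad * sg)
  })
}

scalar4 <- function(v) array(v, c(1, 1, 1, 1))

ag_mean <- function(tape, x) {
  n <- length(x$value)
  ag_op(tape, scalar4(sum(x$value) / n), list(x = x), function(nd) {
    g <- as.numeric(nd$grad)
    acc_grad(nd$parents$x, array(g / n, dim4(nd$parents$x$value)))
  })
}

# Mean of x over positions where mask == 1 (mask is a plain array, no grad).
# Empty mask -> 0 (the lesion term vanishes on lesion-free slices).
ag_masked_mean <- function(tape, x, mask) {
  s <- sum(mask)
  if (s == 0) {
    return(ag_op(tape, scalar4(0), list(x = x), function(nd) {
      acc_grad(nd$parents$x, array(0, dim4(nd$parents$x$value)))
    }))
  }
  ag_op(tape, scalar4(sum(x$value * mask) / s), list(x = x), function(nd) {
    g <- as.numeric(nd$grad)
    acc_grad(nd$parents$x, g * mask / s)
  })
}

# Sliding-window (valid) mean, the workhorse of the SSIM map.
ag_winmean <- function(tape, x, k) {
  d <- dim4(x$value)
  y <- cpp_winmean_fwd(x$value, as.integer(k))
  ag_op(tape, y, list(x = x), function(nd) {
    acc_grad(nd$parents$x, cpp_winmean_bwd(nd$grad, d[1], d[2], as.integer(k)))
  })
}

# Select a single channel (keeps a C=1 axis).
ag_channel <- function(tape, x, ch) {
  d <- dim4(x$value)
  y <- x$value[, , ch, , drop = FALSE]
  ag_op(tape, y, list(x = x), function(nd) {
    g <- array(0, d)
    g[, , ch, ] <- nd$grad
    acc_grad(nd$parents$x, g)
  })
}

# Channel-wise normalization over (H, W, N) with learnable gain/shift.
# Statistics are recomputed from the incoming activations at both training
# and inference time, so the layer is stateless and deterministic.
ag_norm <- function(tape, x, gamma, beta, eps = 1e-5) {
  r <- cpp_norm_fwd(x$value, gamma$value, beta$value, eps)
  ag_op(tape, r$y, list(x = x, gamma = gamma, beta = beta), function(nd) {
    g <- cpp_norm_bwd(nd$parents$x$value, nd$parents$gamma$value,
                      r$mu, r$inv, nd$grad)
    acc_grad(nd$parents$x, g$gx)
    acc_grad(nd$parents$gamma, as.numeric(g$ggamma))
    acc_grad(nd$parents$beta, as.numeric(g$gbeta))
  })
}
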