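# Minimal reverse-mode automatic differentiation for image-to-image
# networks, written against base R matrix algebra (BLAS). Feature maps are
# stored as (H*W) x C matrices with the spatial size in attribute "hw";
# convolutions are im2col gathers followed by a single matrix product, and
# their input gradient is the full convolution with the flipped kernel, so
# no scatter-add is ever needed. This is deliberately small: just the ops
# the multi-scale residual reconstruction network requires.

new_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t$cache <- new.env(parent = emptyenv())  # conv/pool index tables per (H,W)
  t
}

node_hw <- function(x) attr(x$val, "hw")

make_node <- function(tape, val, hw, parents = list(), backfn = NULL) {
  n <- new.env(parent = emptyenv())
  attr(val, "hw") <- hw
  n$val <- val
  n$grad <- NULL
  n$parents <- parents
  n$backfn <- backfn
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      length(tape$nodes) <- 2L * length(tape$nodes)
    }
    tape$nodes[[tape$n]] <- n
  }
  n
}

nn_input <- function(tape, val, hw) make_node(tape, val, hw)

nn_param <- function(val, hw = c(1L, 1L)) {
  n <- make_node(NULL, val, hw)
  n$is_param <- TRUE
  n$m <- val * 0  # Adam moments
  n$v <- val * 0
  n
}

add_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# run backward from a scalar loss node
tape_backward <- function(tape, loss) {
  loss$grad <- matrix(1, 1, 1)
  for (i in seq(tape$n, 1L)) {
    n <- tape$nodes[[i]]
    if (!is.null(n$grad) && !is.null(n$backfn)) n$backfn(n)
  }
  invisible(NULL)
}

# ---- cached index tables ----------------------------------------------------

conv_indices <- function(tape, h, w, k) {
  key <- sprintf("conv_%d_%d_%d", h, w, k)
  hit <- tape$cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- (k - 1L) %/% 2L
  hp <- h + 2L * r; wp <- w + 2L * r
  rows <- rep(seq_len(h), times = w)
  cols <- rep(seq_len(w), each = h)
  interior <- (cols + r - 1L) * hp + (rows + r)
  offsets <- expand.grid(dy = seq(-r, r), dx = seq(-r, r))  # dy fastest
  nb <- matrix(0L, h * w, k * k)
  for (o in seq_len(k * k)) {
    nb[, o] <- (cols + r + offsets$dx[o] - 1L) * hp +
               (rows + r + offsets$dy[o])
  }
  out <- list(interior = interior, nb = as.vector(nb), npad = hp * wp,
              k2 = k * k)
  tape$cache[[key]] <- out
  out
}

pool_indices <- function(tape, h, w) {
  key <- sprintf("pool_%d_%d", h, w)
  hit <- tape$cache[[key]]
  if (!is.null(hit)) return(hit)
  stopifnot(h %% 2L == 0L, w %% 2L == 0L)
  h2 <- h %/% 2L; w2 <- w %/% 2L
  ro <- rep(seq_len(h2), times = w2)
  co <- rep(seq_len(w2), each = h2)
  lin <- function(rr, cc) (cc - 1L) * h + rr
  out <- list(
    i1 = lin(2L * ro - 1L, 2L * co - 1L), i2 = lin(2L * ro, 2L * co - 1L),
    i3 = lin(2L * ro - 1L, 2L * co), i4 = lin(2L * ro, 2L * co),
    h2 = h2, w2 = w2
  )
  tape$cache[[key]] <- out
  out
}

# im2col gather: (H*W) x C matrix -> (H*W) x (k2*C), zero padded
im2col <- function(x, ci, nC) {
  hw <- nrow(x)
  xpad <- matrix(0, ci$npad, nC)
  xpad[ci$interior, ] <- x
  matrix(xpad[ci$nb, , drop = FALSE], hw, ci$k2 * nC)
}

# ---- layers -----------------------------------------------------------------

# 2-d convolution, stride 1, same zero padding. W is (k2*Cin) x Cout with
# rows ordered offset-fastest within input channel; b has length Cout.
nn_conv <- function(tape, x, W, b, k) {
  hw <- node_hw(x)
  cin <- ncol(x$val)
  cout <- ncol(W$val)
  if (k == 1L) {
    y <- x$val %*% W$val
    xcol <- NULL
  } else {
    ci <- conv_indices(tape, hw[1], hw[2], k)
    xcol <- im2col(x$val, ci, cin)
    y <- xcol %*% W$val
  }
  y <- sweep(y, 2L, as.vector(b$val), "+")
  k2 <- k * k
  # flipped/transposed kernel for the input gradient, built lazily
  make_node(tape, y, hw, parents = list(x, W, b), backfn = function(n) {
    dy <- n$grad
    add_grad(b, matrix(colSums(dy), 1L))
    if (k == 1L) {
      add_grad(W, crossprod(x$val, dy))
      add_grad(x, dy %*% t(W$val))
    } else {
      add_grad(W, crossprod(xcol, dy))
      ci <- conv_indices(tape, hw[1], hw[2], k)
      dycol <- im2col(dy, ci, cout)
      # Wt[(cout-1)*k2 + o, cin] = W[(cin-1)*k2 + (k2+1-o), cout]
      Warr <- array(W$val, dim = c(k2, cin, cout))
      Wt <- matrix(aperm(Warr[k2:1, , , drop = FALSE], c(1, 3, 2)),
                   k2 * cout, cin)
      add_grad(x, dycol %*% Wt)
    }
  })
}

nn_relu <- function(tape, x) {
  y <- pmax(x$val, 0)
  make_node(tape, y, node_hw(x), list(x), function(n) {
    add_grad(x, n$grad * (x$val > 0))
  })
}

nn_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$val))
  make_node(tape, s, node_hw(x), list(x), function(n) {
    add_grad(x, n$grad * s * (1 - s))
  })
}

nn_add <- function(tape, a, b) {
  make_node(tape, a$val + b$val, node_hw(a), list(a, b), function(n) {
    add_grad(a, n$grad); add_grad(b, n$grad)
  })
}

# multiply feature map by a 1 x C channel attention vector
nn_scale_channels <- function(tape, x, a) {
  hw <- nrow(x$val)
  av <- rep(as.vector(a$val), each = hw)
  make_node(tape, x$val * av, node_hw(x), list(x, a), function(n) {
    add_grad(x, n$grad * av)
    add_grad(a, matrix(colSums(n$grad * x$val), 1L))
  })
}

# multiply feature map by an (H*W) x 1 spatial attention map
nn_scale_spatial <- function(tape, x, a) {
  av <- as.vector(a$val)
  make_node(tape, x$val * av, node_hw(x), list(x, a), function(n) {
    add_grad(x, n$grad * av)
    add_grad(a, matrix(rowSums(n$grad * x$val), ncol = 1L))
  })
}

nn_gap <- function(tape, x) {
  hw <- nrow(x$val)
  y <- matrix(colMeans(x$val), 1L)
  make_node(tape, y, c(1L, 1L), list(x), function(n) {
    add_grad(x, matrix(rep(n$grad / hw, each = hw), hw, ncol(x$val)))
  })
}

nn_avgpool2 <- function(tape, x) {
  hw <- node_hw(x)
  pi <- pool_indices(tape, hw[1], hw[2])
  y <- (x$val[pi$i1, , drop = FALSE] + x$val[pi$i2, , drop = FALSE] +
        x$val[pi$i3, , drop = FALSE] + x$val[pi$i4, , drop = FALSE]) / 4
  make_node(tape, y, c(pi$h2, pi$w2), list(x), function(n) {
    g <- n$grad / 4
    dx <- matrix(0, hw[1] * hw[2], ncol(x$val))
    dx[pi$i1, ] <- g; dx[pi$i2, ] <- g; dx[pi$i3, ] <- g; dx[pi$i4, ] <- g
    add_grad(x, dx)
  })
}

nn_upnearest2 <- function(tape, x) {
  hw <- node_hw(x)
  h2 <- 2L * hw[1]; w2 <- 2L * hw[2]
  pi <- pool_indices(tape, h2, w2)  # groups outputs by their source pixel
  src <- integer(h2 * w2)
  src[pi$i1] <- seq_len(hw[1] * hw[2])
  src[pi$i2] <- seq_len(hw[1] * hw[2])
  src[pi$i3] <- seq_len(hw[1] * hw[2])
  src[pi$i4] <- seq_len(hw[1] * hw[2])
  y <- x$val[src, , drop = FALSE]
  make_node(tape, y, c(h2, w2), list(x), function(n) {
    g <- n$grad
    add_grad(x, g[pi$i1, , drop = FALSE] + g[pi$i2, , drop = FALSE] +
                g[pi$i3, , drop = FALSE] + g[pi$i4, , drop = FALSE])
  })
}

nn_concat_channels <- function(tape, xs) {
  y <- do.call(cbind, lapply(xs, function(x) x$val))
  widths <- vapply(xs, function(x) ncol(x$val), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  make_node(tape, y, node_hw(xs[[1]]), xs, function(n) {
    for (i in seq_along(xs)) {
      add_grad(xs[[i]], n$grad[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

# per-pixel channel mean and max -> (H*W) x 2 (spatial attention input)
nn_chanpool <- function(tape, x) {
  hw <- nrow(x$val)
  nC <- ncol(x$val)
  mi <- max.col(x$val, ties.method = "first")
  y <- cbind(rowMeans(x$val), x$val[cbind(seq_len(hw), mi)])
  make_node(tape, y, node_hw(x), list(x), function(n) {
    dx <- matrix(n$grad[, 1] / nC, hw, nC)
    dx[cbind(seq_len(hw), mi)] <- dx[cbind(seq_len(hw), mi)] + n$grad[, 2]
    add_grad(x, dx)
  })
}

# stack L vectors (1 x C) into an L x C matrix
nn_stack <- function(tape, xs) {
  y <- do.call(rbind, lapply(xs, function(x) x$val))
  make_node(tape, y, c(length(xs), 1L), xs, function(n) {
    for (i in seq_along(xs)) {
      add_grad(xs[[i]], n$grad[i, , drop = FALSE])
    }
  })
}

# softmax over rows (streams), independently per column (channel)
nn_softmax_rows <- function(tape, x) {
  e <- exp(sweep(x$val, 2L, apply(x$val, 2L, max)))
  s <- sweep(e, 2L, colSums(e), "/")
  make_node(tape, s, node_hw(x), list(x), function(n) {
    dot <- colSums(n$grad * s)
    add_grad(x, s * sweep(n$grad, 2L, dot))
  })
}

nn_row <- function(tape, x, i) {
  make_node(tape, x$val[i, , drop = FALSE], c(1L, 1L), list(x), function(n) {
    dx <- matrix(0, nrow(x$val), ncol(x$val))
    dx[i, ] <- n$grad
    add_grad(x, dx)
  })
}

# MRAE loss against a constant target, with denominator clamp eps
nn_mrae_loss <- function(tape, pred, target, eps) {
  denom <- pmax(target, eps)
  nels <- length(target)
  val <- matrix(mean(abs(pred$val - target) / denom), 1L, 1L)
  make_node(tape, val, c(1L, 1L), list(pred), function(n) {
    g <- as.numeric(n$grad)
    add_grad(pred, g * sign(pred$val - target) / (denom * nels))
  })
}
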