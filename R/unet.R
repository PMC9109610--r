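# 2-D convolutional network primitives on (H, W, C, N) arrays, implemented
# with im2col gathers and BLAS matrix multiplies. All convolutions are
# stride-1 SAME; gradients of a SAME 3x3 convolution are again SAME 3x3
# convolutions with the spatially flipped, channel-transposed kernel, so the
# backward pass reuses the same machinery. Correctness is pinned by a
# finite-difference gradient check in the test suite.

# (H, W, C, N) -> (H*W*N) x (9*C), rows ordered (pixel, sample), columns
# ordered (patch offset fastest, then channel). Hot path: done in C.
im2col3 <- function(x) .im2col3(x, dim(x))

# He-normal initialised convolution layer; W rows are (patch offset, cin).
conv_layer <- function(k, cin, cout) {
  sd <- sqrt(2 / (k * k * cin))
  list(W = matrix(rnorm(k * k * cin * cout, sd = sd), k * k * cin, cout),
       b = numeric(cout), k = k, cin = cin, cout = cout)
}

conv_fwd <- function(x, layer) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; N <- d[4]
  if (layer$k == 1L) {
    xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = layer$cin)
    y <- xm %*% layer$W
  } else {
    y <- im2col3(x) %*% layer$W
  }
  y <- y + rep(layer$b, each = H * W * N)
  aperm(array(y, dim = c(H, W, N, layer$cout)), c(1, 2, 4, 3))
}

# Returns list(dx, dW, db); x is the cached forward input.
conv_bwd <- function(dy, x, layer) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; N <- d[4]
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = layer$cout)
  db <- colSums(dym)
  if (layer$k == 1L) {
    xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = layer$cin)
    dW <- crossprod(xm, dym)
    dxm <- dym %*% t(layer$W)
  } else {
    dW <- crossprod(im2col3(x), dym)
    Wr <- array(layer$W, dim = c(9L, layer$cin, layer$cout))
    Wf <- Wr[9:1, , , drop = FALSE]             # flip both spatial offsets
    Wt <- aperm(Wf, c(1, 3, 2))                 # rows become (offset, cout)
    dim(Wt) <- c(9L * layer$cout, layer$cin)
    dxm <- im2col3(dy) %*% Wt
  }
  dx <- aperm(array(dxm, dim = c(H, W, N, layer$cin)), c(1, 2, 4, 3))
  list(dx = dx, dW = dW, db = db)
}

maxpool_fwd <- function(x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; CN <- d[3] * d[4]
  a <- array(x, dim = c(2L, H %/% 2L, 2L, W %/% 2L, CN))
  s11 <- a[1, , 1, , , drop = TRUE]; dim(s11) <- c(H %/% 2L, W %/% 2L, CN)
  s21 <- a[2, , 1, , , drop = TRUE]; dim(s21) <- dim(s11)
  s12 <- a[1, , 2, , , drop = TRUE]; dim(s12) <- dim(s11)
  s22 <- a[2, , 2, , , drop = TRUE]; dim(s22) <- dim(s11)
  m <- pmax(s11, s21, s12, s22)
  arg <- array(4L, dim = dim(m))
  arg[s12 == m] <- 3L
  arg[s21 == m] <- 2L
  arg[s11 == m] <- 1L
  out <- m
  dim(out) <- c(H %/% 2L, W %/% 2L, d[3], d[4])
  list(out = out, arg = arg, dim_in = d)
}

maxpool_bwd <- function(dy, pool) {
  d <- pool$dim_in
  H <- d[1]; W <- d[2]; CN <- d[3] * d[4]
  dya <- dy
  dim(dya) <- c(H %/% 2L, W %/% 2L, CN)
  g <- array(0, dim = c(2L, H %/% 2L, 2L, W %/% 2L, CN))
  put <- function(k, a, b) {
    gk <- array(0, dim = dim(dya))
    sel <- pool$arg == k
    gk[sel] <- dya[sel]
    g[a, , b, , ] <<- gk
  }
  put(1L, 1L, 1L); put(2L, 2L, 1L); put(3L, 1L, 2L); put(4L, 2L, 2L)
  dim(g) <- d
  g
}

upsample_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

upsample_bwd <- function(dy) {
  d <- dim(dy)
  H <- d[1] %/% 2L; W <- d[2] %/% 2L; CN <- d[3] * d[4]
  a <- array(dy, dim = c(2L, H, 2L, W, CN))
  s <- a[1, , 1, , , drop = TRUE] + a[2, , 1, , , drop = TRUE] +
    a[1, , 2, , , drop = TRUE] + a[2, , 2, , , drop = TRUE]
  array(s, dim = c(H, W, d[3], d[4]))
}

concat_channels <- function(a, b) {
  d <- dim(a)
  out <- array(0, dim = c(d[1], d[2], d[3] + dim(b)[3], d[4]))
  out[, , seq_len(d[3]), ] <- a
  out[, , d[3] + seq_len(dim(b)[3]), ] <- b
  out
}

#' U-net configuration
#'
#' @param input_mode `"phases10"` (10 phase channels), `"phases2"` (T00 and
#'   T50 only) or `"phases10_adjacent"` (2.5-D: each phase contributes its
#'   slice and the two axial neighbours, 30 channels).
#' @param in_plane_size square input size; must be divisible by `2^depth`.
#' @param depth number of down-sampling levels.
#' @param base_filters filters of the first encoder block (doubling per
#'   level).
#' @param dropout_rate dropout applied after each encoder block.
#' @param output_nonneg apply a final ReLU so predictions are nonnegative
#'   (ventilation references are count-derived).
#' @return An object of class `ventimap_model_config`.
#' @export
model_config <- function(input_mode = c("phases10", "phases2",
                                        "phases10_adjacent"),
                         in_plane_size = 192L, depth = 4L, base_filters = 64L,
                         dropout_rate = 0.2, output_nonneg = TRUE) {
  input_mode <- match.arg(input_mode)
  in_plane_size <- as.integer(in_plane_size)
  depth <- as.integer(depth)
  if (in_plane_size %% 2L^depth != 0L)
    vm_stop("in_plane_size must be divisible by 2^depth",
            "ventimap_config_error")
  channels <- switch(input_mode, phases10 = 10L, phases2 = 2L,
                     phases10_adjacent = 30L)
  structure(list(input_mode = input_mode, in_plane_size = in_plane_size,
                 depth = depth, base_filters = as.integer(base_filters),
                 dropout_rate = dropout_rate, output_nonneg = output_nonneg,
                 channels = channels),
            class = "ventimap_model_config")
}

#' Build a U-net regressor
#'
#' Encoder of `depth` blocks (two 3x3 convolutions with ReLU, dropout, 2x2
#' max-pool of stride 2, filters doubling from `base_filters`), a two-
#' convolution bottleneck, a mirrored decoder (2x2 up-sampling followed by a
#' 3x3 convolution and ReLU, concatenation with the matching encoder
#' activation, then two 3x3 convolutions with ReLU), and a head of one 3x3
#' convolution with ReLU plus a 1x1 convolution (ReLU if the output is
#' constrained nonnegative). Weights are He-normal initialised from the
#' supplied seed, so two builds with the same seed are identical.
#'
#' @param config a [model_config()].
#' @param seed weight-initialisation seed.
#' @return An object of class `ventimap_unet` (parameters + config).
#' @export
build_unet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "ventimap_model_config"))
  with_seed(derive_seed(seed, "unet_init"), {
    p <- list()
    cin <- config$channels
    for (i in seq_len(config$depth)) {
      f <- config$base_filters * 2L^(i - 1L)
      p[[paste0("enc", i, "c1")]] <- conv_layer(3L, cin, f)
      p[[paste0("enc", i, "c2")]] <- conv_layer(3L, f, f)
      cin <- f
    }
    fb <- config$base_filters * 2L^config$depth
    p[["botc1"]] <- conv_layer(3L, cin, fb)
    p[["botc2"]] <- conv_layer(3L, fb, fb)
    cur <- fb
    for (i in seq(config$depth, 1L)) {
      f <- config$base_filters * 2L^(i - 1L)
      p[[paste0("dec", i, "up")]] <- conv_layer(3L, cur, f)
      p[[paste0("dec", i, "c1")]] <- conv_layer(3L, 2L * f, f)
      p[[paste0("dec", i, "c2")]] <- conv_layer(3L, f, f)
      cur <- f
    }
    p[["headc3"]] <- conv_layer(3L, cur, cur)
    p[["head1x1"]] <- conv_layer(1L, cur, 1L)
    # start the rectified output unit active: a zero-initialised bias lets
    # the nonnegative head die for some seeds before it ever fires
    if (config$output_nonneg) p[["head1x1"]]$b[] <- 0.01
    structure(list(params = p, config = config), class = "ventimap_unet")
  })
}

#' @export
print.ventimap_unet <- function(x, ...) {
  np <- sum(vapply(x$params, function(l) length(l$W) + length(l$b), numeric(1)))
  cat(sprintf("<ventimap_unet> %s input %dx%dx%d, depth %d, base %d, %s parameters\n",
              x$config$input_mode, x$config$in_plane_size,
              x$config$in_plane_size, x$config$channels, x$config$depth,
              x$config$base_filters, format(np, big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters of a U-net
#' @param model a [build_unet()] result.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, function(l) length(l$W) + length(l$b), numeric(1)))
}

# Forward pass. x: (H, W, C, N). Returns list(out, cache) when cache = TRUE.
# Dropout draws from the current RNG stream when train = TRUE.
unet_forward <- function(model, x, train = FALSE, keep_cache = train) {
  cfg <- model$config
  p <- model$params
  cache <- if (keep_cache) list() else NULL
  put <- function(nm, v) if (keep_cache) cache[[nm]] <<- v
  conv_relu <- function(h, nm) {
    put(paste0(nm, "_in"), h)
    h <- conv_fwd(h, p[[nm]])
    h <- pmax(h, 0)
    put(paste0(nm, "_act"), h)
    h
  }
  h <- x
  skips <- list()
  for (i in seq_len(cfg$depth)) {
    h <- conv_relu(h, paste0("enc", i, "c1"))
    h <- conv_relu(h, paste0("enc", i, "c2"))
    if (train && cfg$dropout_rate > 0) {
      mask <- (array(runif(length(h)), dim = dim(h)) >= cfg$dropout_rate) /
        (1 - cfg$dropout_rate)
      h <- h * mask
      put(paste0("drop", i), mask)
    }
    skips[[i]] <- h
    mp <- maxpool_fwd(h)
    put(paste0("pool", i), mp[c("arg", "dim_in")])
    h <- mp$out
  }
  h <- conv_relu(h, "botc1")
  h <- conv_relu(h, "botc2")
  for (i in seq(cfg$depth, 1L)) {
    h <- upsample_fwd(h)
    h <- conv_relu(h, paste0("dec", i, "up"))
    put(paste0("skipdim", i), dim(h)[3])
    h <- concat_channels(h, skips[[i]])
    h <- conv_relu(h, paste0("dec", i, "c1"))
    h <- conv_relu(h, paste0("dec", i, "c2"))
  }
  h <- conv_relu(h, "headc3")
  put("head1x1_in", h)
  out <- conv_fwd(h, p[["head1x1"]])
  if (cfg$output_nonneg) {
    out <- pmax(out, 0)
    put("out_act", out)
  }
  list(out = out, cache = cache)
}

# Backward pass for the mean-squared-error loss; returns gradients named like
# the parameter list, each list(dW, db).
unet_backward <- function(model, fw, dout) {
  cfg <- model$config
  p <- model$params
  cache <- fw$cache
  grads <- list()
  bwd_conv_relu <- function(dy, nm) {
    act <- cache[[paste0(nm, "_act")]]
    dy <- dy * (act > 0)
    g <- conv_bwd(dy, cache[[paste0(nm, "_in")]], p[[nm]])
    grads[[nm]] <<- list(dW = g$dW, db = g$db)
    g$dx
  }
  if (cfg$output_nonneg) dout <- dout * (cache[["out_act"]] > 0)
  g <- conv_bwd(dout, cache[["head1x1_in"]], p[["head1x1"]])
  grads[["head1x1"]] <- list(dW = g$dW, db = g$db)
  dh <- bwd_conv_relu(g$dx, "headc3")
  dskips <- list()
  for (i in seq_len(cfg$depth)) {
    dh <- bwd_conv_relu(dh, paste0("dec", i, "c2"))
    dh <- bwd_conv_relu(dh, paste0("dec", i, "c1"))
    nup <- cache[[paste0("skipdim", i)]]
    dskips[[i]] <- dh[, , -seq_len(nup), , drop = FALSE]
    dh <- dh[, , seq_len(nup), , drop = FALSE]
    dh <- bwd_conv_relu(dh, paste0("dec", i, "up"))
    dh <- upsample_bwd(dh)
  }
  dh <- bwd_conv_relu(dh, "botc2")
  dh <- bwd_conv_relu(dh, "botc1")
  for (i in seq(cfg$depth, 1L)) {
    pool <- cache[[paste0("pool", i)]]
    dh <- maxpool_bwd(dh, pool)
    dh <- dh + dskips[[i]]
    dmask <- cache[[paste0("drop", i)]]
    if (!is.null(dmask)) dh <- dh * dmask
    dh <- bwd_conv_relu(dh, paste0("enc", i, "c2"))
    dh <- bwd_conv_relu(dh, paste0("enc", i, "c1"))
  }
  grads
}
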