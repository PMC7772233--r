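#' Sub-pixel rearrangement (pixel shuffle)
#'
#' Pure index rearrangement that turns an `H x W x (C*r^2)` tensor into an
#' `rH x rW x C` tensor: the `r^2` channels belonging to each output channel
#' tile the corresponding `r x r` output block in row-major sub-pixel order,
#' i.e. `out[i, j, c] = in[ceil(i/r), ceil(j/r), (c-1)*r^2 + ((i-1) %% r)*r +
#' (j-1) %% r + 1]`. Every input value appears exactly once in the output,
#' so the map is a bijection.
#'
#' @param x Numeric array `H x W x (C*r^2)`.
#' @param r Integer upscale factor >= 1.
#' @return Numeric array `rH x rW x C`.
#' @examples
#' x <- array(1:4, c(1, 1, 4))
#' subpixel_rearrange(x, 2)[, , 1]  # rbind(c(1, 2), c(3, 4))
#' @export
subpixel_rearrange <- function(x, r) {
  d <- dim(x)
  if (length(d) != 3L) stopf("x must be a 3-D array (H x W x channels)")
  r <- as.integer(r)
  if (r < 1L) stopf("r must be a positive integer")
  if (d[3] %% (r * r) != 0L)
    stopf("channel count %d is not divisible by r^2 = %d", d[3], r * r)
  if (r == 1L) return(x)
  C <- d[3] %/% (r * r)
  out <- array(0, c(d[1] * r, d[2] * r, C))
  for (cc in seq_len(C))
    for (si in 0:(r - 1))
      for (sj in 0:(r - 1))
        out[seq(si + 1, by = r, length.out = d[1]),
            seq(sj + 1, by = r, length.out = d[2]), cc] <-
          x[, , (cc - 1) * r * r + si * r + sj + 1]
  out
}

# Exact inverse of subpixel_rearrange (also its backward pass, since the op
# is a permutation).
subpixel_inverse <- function(y, r) {
  d <- dim(y)
  r <- as.integer(r)
  if (r == 1L) return(y)
  if (d[1] %% r != 0L || d[2] %% r != 0L)
    stopf("spatial dims must be multiples of r")
  H <- d[1] %/% r
  W <- d[2] %/% r
  out <- array(0, c(H, W, d[3] * r * r))
  for (cc in seq_len(d[3]))
    for (si in 0:(r - 1))
      for (sj in 0:(r - 1))
        out[, , (cc - 1) * r * r + si * r + sj + 1] <-
          y[seq(si + 1, by = r, length.out = H),
            seq(sj + 1, by = r, length.out = W), cc]
  out
}

#' One sub-pixel convolution stage
#'
#' Convolution with learned weights and bias followed by
#' [subpixel_rearrange()]; the upsampling unit of the decoder. Output
#' spatial dimensions are exactly `r` times the input's.
#'
#' @param x Input feature map `H x W x Cin`.
#' @param w Kernel array `kh x kw x Cin x (C*r^2)`.
#' @param b Bias vector of length `C*r^2`.
#' @param r Integer upscale factor.
#' @param pad Zero padding; defaults to `floor(kh/2)` ("same" for odd
#'   kernels).
#' @return Feature map `rH x rW x C`.
#' @export
subpixel_stage <- function(x, w, b, r, pad = NULL) {
  dw <- dim(w)
  if (length(dw) != 4L) stopf("w must be a 4-D kernel array")
  if (dim(x)[3] != dw[3])
    stopf("input has %d channels but kernel expects %d", dim(x)[3], dw[3])
  if (dw[4] %% (as.integer(r)^2) != 0L)
    stopf("kernel output channels %d not divisible by r^2 = %d",
          dw[4], as.integer(r)^2)
  if (is.null(pad)) pad <- dw[1] %/% 2L
  y <- .conv2d_fwd(x, matrix(w, ncol = dw[4]), as.numeric(b),
                   dw[1], dw[2], 1L, as.integer(pad))
  subpixel_rearrange(y, r)
}

#' Configure the segmentation network
#'
#' An encoder-decoder with a residual convolutional encoder and a decoder
#' built solely from sub-pixel convolution stages, optionally concatenating
#' encoder features at matching resolutions (skip connections). The product
#' of the per-stage upscale factors always equals the encoder's total
#' downsampling factor, so output spatial size equals input spatial size.
#'
#' @param encoder `"small"` (a 4-stage residual encoder with downsampling
#'   pattern 1, 2, 2, 2; total factor 8) or `"resnet34"` (the standard
#'   34-layer residual topology, total factor 32, without batch
#'   normalization).
#' @param pretrained Only meaningful for `"resnet34"`. No pretrained weights
#'   ship with the package, so `TRUE` raises an error instructing the
#'   random-initialization fallback.
#' @param num_classes Number of segmentation classes `C >= 2`.
#' @param upscale_factor Per-decoder-stage upscale `r`.
#' @param decoder_channels Output channels of each decoder stage; its length
#'   fixes the number of stages.
#' @param skip_connections Concatenate encoder features into the decoder.
#' @param seed Integer seed for deterministic weight initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(encoder = c("small", "resnet34"),
                         pretrained = FALSE,
                         num_classes = 2L,
                         upscale_factor = 2L,
                         decoder_channels = NULL,
                         skip_connections = TRUE,
                         seed = 1L) {
  encoder <- match.arg(encoder)
  if (is.null(decoder_channels))
    decoder_channels <- if (encoder == "small") c(16L, 12L, 8L)
                        else c(64L, 48L, 32L, 24L, 16L)
  cfg <- structure(list(
    encoder = encoder,
    pretrained = isTRUE(pretrained),
    num_classes = as.integer(num_classes),
    upscale_factor = as.integer(upscale_factor),
    decoder_channels = as.integer(decoder_channels),
    skip_connections = isTRUE(skip_connections),
    seed = as.integer(seed)
  ), class = "model_config")
  if (cfg$num_classes < 2L) stopf("num_classes must be >= 2")
  total <- encoder_downsample(cfg)
  if (cfg$upscale_factor^length(cfg$decoder_channels) != total)
    stopf(paste("upscale_factor^n_stages (%d^%d) must equal the encoder's",
                "total downsampling factor %d"),
          cfg$upscale_factor, length(cfg$decoder_channels), total)
  cfg
}

encoder_downsample <- function(config) {
  if (config$encoder == "small") 8L else 32L
}

# Encoder widths and skip-feature channels per pyramid level (level = log2 of
# the downsampling factor at that resolution).
arch_info <- function(config) {
  if (config$encoder == "small") {
    widths <- c(8L, 16L, 24L, 32L)
    list(widths = widths,
         skip_ch = c(`0` = 8L, `1` = 16L, `2` = 24L),
         bottom_ch = 32L, bottom_lev = 3L)
  } else {
    list(blocks = c(3L, 4L, 6L, 3L),
         stage_ch = c(64L, 128L, 256L, 512L),
         skip_ch = c(`1` = 64L, `2` = 64L, `3` = 128L, `4` = 256L),
         bottom_ch = 512L, bottom_lev = 5L)
  }
}

#' Build the segmentation model
#'
#' Instantiates the network described by a [model_config()] with
#' He-initialized weights; initialization is fully deterministic given the
#' config seed. The forward pass maps an `H x W x 3` image to an
#' `H x W x C` probability map through a terminal softmax.
#'
#' @param config A [model_config()].
#' @return An object of class `thinseg_model` with fields `config` and
#'   `params` (named list of kernel/bias arrays).
#' @export
build_model <- function(config) {
  if (config$pretrained)
    stopf(paste("pretrained ResNet-34 weights are not bundled and cannot be",
                "downloaded here; rebuild with pretrained = FALSE to use",
                "random initialization"))
  P <- new.env(parent = emptyenv())
  conv_init <- function(name, kh, kw, cin, cout, norm = TRUE) {
    P[[paste0(name, "_w")]] <- array(
      stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
      c(kh, kw, cin, cout))
    P[[paste0(name, "_b")]] <- numeric(cout)
    if (norm) {
      P[[paste0(name, "_n_g")]] <- rep(1, cout)
      P[[paste0(name, "_n_bt")]] <- numeric(cout)
    }
  }
  ai <- arch_info(config)
  with_seed(config$seed, {
    if (config$encoder == "small") {
      w <- ai$widths
      conv_init("stem", 3, 3, 3, w[1])
      for (i in 1:3) {
        conv_init(paste0("down", i), 3, 3, w[i], w[i + 1])
        conv_init(paste0("res", i), 3, 3, w[i + 1], w[i + 1])
      }
    } else {
      conv_init("stem", 7, 7, 3, 64L)
      cin <- 64L
      for (s in 1:4) {
        ch <- ai$stage_ch[s]
        for (b in seq_len(ai$blocks[s])) {
          nm <- sprintf("s%db%d", s, b)
          conv_init(paste0(nm, "_c1"), 3, 3, if (b == 1) cin else ch, ch)
          conv_init(paste0(nm, "_c2"), 3, 3, ch, ch)
          if (b == 1 && (cin != ch || s > 1))
            conv_init(paste0(nm, "_proj"), 1, 1, cin, ch)
        }
        cin <- ch
      }
    }
    r2 <- config$upscale_factor^2
    cur <- ai$bottom_ch
    lev <- ai$bottom_lev
    for (j in seq_along(config$decoder_channels)) {
      cj <- config$decoder_channels[j]
      conv_init(paste0("dec", j), 3, 3, cur, cj * r2, norm = FALSE)
      P[[paste0("dec", j, "_pn_g")]] <- rep(1, cj)
      P[[paste0("dec", j, "_pn_bt")]] <- numeric(cj)
      lev <- lev - as.integer(log2(config$upscale_factor))
      cur <- cj
      sk <- ai$skip_ch[as.character(lev)]
      if (config$skip_connections && !is.na(sk)) cur <- cur + sk
    }
    conv_init("head", 1, 1, cur, config$num_classes, norm = FALSE)
  })
  structure(list(config = config, params = as.list(P)),
            class = "thinseg_model")
}

#' @export
print.thinseg_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<thinseg_model> encoder=%s, %d classes, %d decoder stages (r=%d), skips=%s, %s parameters\n",
              x$config$encoder, x$config$num_classes,
              length(x$config$decoder_channels), x$config$upscale_factor,
              x$config$skip_connections, format(np, big.mark = ",")))
  invisible(x)
}

## ---- computation tape -------------------------------------------------

new_tape <- function(params) {
  e <- new.env(parent = emptyenv())
  e$nodes <- list()
  e$params <- params
  e
}

node_add <- function(tp, node) {
  force(node)
  tp$nodes[[length(tp$nodes) + 1L]] <- node
  length(tp$nodes)
}

tp_data <- function(tp, id) tp$nodes[[id]]$out

tp_input <- function(tp, x) node_add(tp, list(op = "input", out = x))

tp_conv <- function(tp, id, name, stride, pad) {
  force(id)
  w <- tp$params[[paste0(name, "_w")]]
  dw <- dim(w)
  y <- .conv2d_fwd(tp_data(tp, id), matrix(w, ncol = dw[4]),
                   tp$params[[paste0(name, "_b")]],
                   dw[1], dw[2], as.integer(stride), as.integer(pad))
  node_add(tp, list(op = "conv", in_ = id, name = name,
                    stride = as.integer(stride), pad = as.integer(pad),
                    out = y))
}

tp_relu <- function(tp, id) {
  force(id)
  x <- tp_data(tp, id)
  y <- x * (x > 0)
  node_add(tp, list(op = "relu", in_ = id, out = y))
}

tp_add <- function(tp, a, b) {
  force(a); force(b)
  node_add(tp, list(op = "add", in_ = c(a, b),
                    out = tp_data(tp, a) + tp_data(tp, b)))
}

tp_concat <- function(tp, a, b) {
  force(a); force(b)
  xa <- tp_data(tp, a)
  xb <- tp_data(tp, b)
  da <- dim(xa)
  db <- dim(xb)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- xa
  out[, , da[3] + seq_len(db[3])] <- xb
  node_add(tp, list(op = "concat", in_ = c(a, b), ca = da[3], out = out))
}

# Per-channel (instance) normalization with learnable affine; stabilizes
# training of the normalization-free residual blocks at small batch sizes.
tp_inorm <- function(tp, id, name) {
  force(id)
  x <- tp_data(tp, id)
  d <- dim(x)
  g <- tp$params[[paste0(name, "_g")]]
  b <- tp$params[[paste0(name, "_bt")]]
  n <- d[1] * d[2]
  y <- x
  cache <- list(invstd = numeric(d[3]), xhat = x)
  for (cc in seq_len(d[3])) {
    v <- x[, , cc]
    mu <- mean(v)
    istd <- 1 / sqrt(mean((v - mu)^2) + 1e-5)
    xh <- (v - mu) * istd
    cache$invstd[cc] <- istd
    cache$xhat[, , cc] <- xh
    y[, , cc] <- g[cc] * xh + b[cc]
  }
  node_add(tp, list(op = "inorm", in_ = id, name = name, cache = cache,
                    out = y))
}

tp_subpixel <- function(tp, id, r) {
  force(id)
  node_add(tp, list(op = "subpixel", in_ = id, r = as.integer(r),
                    out = subpixel_rearrange(tp_data(tp, id), r)))
}

tp_maxpool <- function(tp, id, k, stride, pad) {
  force(id)
  res <- .maxpool_fwd(tp_data(tp, id), as.integer(k), as.integer(stride),
                      as.integer(pad))
  node_add(tp, list(op = "maxpool", in_ = id, arg = res$arg,
                    indim = dim(tp_data(tp, id)), out = res$y))
}

gacc <- function(a, b) if (is.null(a)) b else a + b

# Reverse sweep: seed the gradient at `out_id` and return parameter
# gradients; gradients w.r.t. inputs are discarded.
net_backward <- function(tp, out_id, gout) {
  n <- length(tp$nodes)
  g <- vector("list", n)
  g[[out_id]] <- gout
  grads <- list()
  for (i in rev(seq_len(n))) {
    gi <- g[[i]]
    if (is.null(gi)) next
    nd <- tp$nodes[[i]]
    switch(nd$op,
      input = NULL,
      conv = {
        w <- tp$params[[paste0(nd$name, "_w")]]
        dw <- dim(w)
        r <- .conv2d_bwd(tp_data(tp, nd$in_), matrix(w, ncol = dw[4]), gi,
                         dw[1], dw[2], nd$stride, nd$pad)
        g[[nd$in_]] <- gacc(g[[nd$in_]], r$gx)
        grads[[paste0(nd$name, "_w")]] <-
          gacc(grads[[paste0(nd$name, "_w")]], array(r$gw, dw))
        grads[[paste0(nd$name, "_b")]] <-
          gacc(grads[[paste0(nd$name, "_b")]], as.numeric(r$gb))
      },
      relu = {
        g[[nd$in_]] <- gacc(g[[nd$in_]], gi * (tp_data(tp, nd$in_) > 0))
      },
      add = {
        g[[nd$in_[1]]] <- gacc(g[[nd$in_[1]]], gi)
        g[[nd$in_[2]]] <- gacc(g[[nd$in_[2]]], gi)
      },
      concat = {
        d <- dim(gi)
        g[[nd$in_[1]]] <- gacc(g[[nd$in_[1]]],
                               gi[, , seq_len(nd$ca), drop = FALSE])
        g[[nd$in_[2]]] <- gacc(g[[nd$in_[2]]],
                               gi[, , (nd$ca + 1):d[3], drop = FALSE])
      },
      subpixel = {
        g[[nd$in_]] <- gacc(g[[nd$in_]], subpixel_inverse(gi, nd$r))
      },
      inorm = {
        gm <- tp$params[[paste0(nd$name, "_g")]]
        xh <- nd$cache$xhat
        dx <- gi
        dgam <- numeric(length(gm))
        dbet <- numeric(length(gm))
        for (cc in seq_along(gm)) {
          gic <- gi[, , cc]
          xhc <- xh[, , cc]
          dgam[cc] <- sum(gic * xhc)
          dbet[cc] <- sum(gic)
          dxh <- gic * gm[cc]
          dx[, , cc] <- nd$cache$invstd[cc] *
            (dxh - mean(dxh) - xhc * mean(dxh * xhc))
        }
        g[[nd$in_]] <- gacc(g[[nd$in_]], dx)
        grads[[paste0(nd$name, "_g")]] <-
          gacc(grads[[paste0(nd$name, "_g")]], dgam)
        grads[[paste0(nd$name, "_bt")]] <-
          gacc(grads[[paste0(nd$name, "_bt")]], dbet)
      },
      maxpool = {
        g[[nd$in_]] <- gacc(g[[nd$in_]],
                            .maxpool_bwd(gi, nd$arg, nd$indim[1], nd$indim[2]))
      })
    g[[i]] <- NULL
  }
  grads
}

## ---- architectures ----------------------------------------------------

cni <- function(tp, id, name, stride, pad) {
  tp_inorm(tp, tp_conv(tp, id, name, stride, pad), paste0(name, "_n"))
}

fwd_encoder_small <- function(tp, xid) {
  f0 <- tp_relu(tp, cni(tp, xid, "stem", 1, 1))
  skips <- list(`0` = f0)
  cur <- f0
  for (i in 1:3) {
    d <- tp_relu(tp, cni(tp, cur, paste0("down", i), 2, 1))
    r <- cni(tp, d, paste0("res", i), 1, 1)
    cur <- tp_relu(tp, tp_add(tp, d, r))
    skips[[as.character(i)]] <- cur
  }
  list(bottom = cur, skips = skips)
}

fwd_encoder_resnet34 <- function(tp, xid, ai) {
  stem <- tp_relu(tp, cni(tp, xid, "stem", 2, 3))
  cur <- tp_maxpool(tp, stem, 3, 2, 1)
  skips <- list(`1` = stem)
  for (s in 1:4) {
    stride1 <- if (s == 1) 1L else 2L
    for (b in seq_len(ai$blocks[s])) {
      nm <- sprintf("s%db%d", s, b)
      st <- if (b == 1) stride1 else 1L
      h <- tp_relu(tp, cni(tp, cur, paste0(nm, "_c1"), st, 1))
      h <- cni(tp, h, paste0(nm, "_c2"), 1, 1)
      sc <- if (!is.null(tp$params[[paste0(nm, "_proj_w")]]))
        cni(tp, cur, paste0(nm, "_proj"), st, 0) else cur
      cur <- tp_relu(tp, tp_add(tp, h, sc))
    }
    skips[[as.character(s + 1L)]] <- cur
  }
  skips[[as.character(5L)]] <- NULL   # bottom is not a skip
  list(bottom = cur, skips = skips)
}

fwd_decoder <- function(tp, enc, config, ai) {
  cur <- enc$bottom
  lev <- ai$bottom_lev
  for (j in seq_along(config$decoder_channels)) {
    cur <- tp_relu(tp, tp_inorm(tp,
      tp_subpixel(tp, tp_conv(tp, cur, paste0("dec", j), 1, 1),
                  config$upscale_factor),
      paste0("dec", j, "_pn")))
    lev <- lev - as.integer(log2(config$upscale_factor))
    sk <- enc$skips[[as.character(lev)]]
    if (config$skip_connections && !is.null(sk))
      cur <- tp_concat(tp, cur, sk)
  }
  tp_conv(tp, cur, "head", 1, 0)
}

# Full forward pass to logits; returns the tape for the backward sweep.
forward_net <- function(model, x) {
  tp <- new_tape(model$params)
  xid <- tp_input(tp, x)
  ai <- arch_info(model$config)
  enc <- if (model$config$encoder == "small") fwd_encoder_small(tp, xid)
         else fwd_encoder_resnet34(tp, xid, ai)
  logits_id <- fwd_decoder(tp, enc, model$config, ai)
  list(tape = tp, logits_id = logits_id, logits = tp_data(tp, logits_id))
}

# Channel-wise softmax over an H x W x C logit array.
softmax_hw <- function(z) {
  C <- dim(z)[3]
  m <- z[, , 1]
  for (cc in seq_len(C)[-1]) m <- pmax(m, z[, , cc])
  e <- exp(z - array(m, dim(z)))
  s <- e[, , 1]
  for (cc in seq_len(C)[-1]) s <- s + e[, , cc]
  e / array(s, dim(e))
}

# Pad spatial dims up to a multiple of `d` with zeros (bottom/right).
pad_to_multiple <- function(x, d) {
  dm <- dim(x)
  H2 <- ceiling(dm[1] / d) * d
  W2 <- ceiling(dm[2] / d) * d
  if (H2 == dm[1] && W2 == dm[2]) return(list(x = x, H = dm[1], W = dm[2]))
  y <- array(0, c(H2, W2, dm[3]))
  y[seq_len(dm[1]), seq_len(dm[2]), ] <- x
  list(x = y, H = dm[1], W = dm[2])
}

#' Run the model forward on one image
#'
#' Inputs whose spatial dimensions are not multiples of the encoder's
#' downsampling factor are zero-padded, predicted, and cropped back.
#'
#' @param model A [build_model()] result (or a fitted [thinseg()] object's
#'   `$model`).
#' @param image Numeric `H x W x 3` array (grayscale replicated; see
#'   [volume_to_samples()]).
#' @return `H x W x C` probability map; each pixel's class probabilities sum
#'   to 1.
#' @export
model_forward <- function(model, image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stopf("image must be an H x W x 3 array")
  p <- pad_to_multiple(image, encoder_downsample(model$config))
  fw <- forward_net(model, p$x)
  prob <- softmax_hw(fw$logits)
  prob[seq_len(p$H), seq_len(p$W), , drop = FALSE]
}
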