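# The 2.5D U-like segmentation network: an encoder-decoder of dense
# convolution blocks whose first encoder levels are 3D (the three adjacent
# input slices treated as a depth-3, single-channel volume), with a hybrid
# spatial + channel attention module gating every skip connection.

#' Network configuration
#'
#' @param in_size In-plane input size (square or `(rows, cols)`); must be
#'   divisible by `2^n_blocks`. Default 224.
#' @param n_blocks Number of dense blocks per path (encoder and decoder).
#' @param base_channels Width of the first level; levels double in width.
#' @param dense_layers Convolution layers per dense block.
#' @param growth Channels added by each dense-block layer (default
#'   `base_channels`).
#' @param n3d_blocks How many leading encoder blocks use 3D convolutions on
#'   the depth-3 slice stack (`<= n_blocks`).
#' @param attention `"hybrid"` (spatial + channel gates on skips) or
#'   `"none"` (plain skips; the ablation arm).
#' @param norm Per-conv normalization: `"instance"` (default; batch size 1
#'   makes batch statistics degenerate) or `"none"`.
#' @return An object of class `model_config`.
#' @export
model_config <- function(in_size = c(224L, 224L), n_blocks = 4L,
                         base_channels = 32L, dense_layers = 6L,
                         growth = base_channels, n3d_blocks = 2L,
                         attention = c("hybrid", "none"),
                         norm = c("instance", "none")) {
  attention <- match.arg(attention)
  norm <- match.arg(norm)
  in_size <- as.integer(rep(in_size, length.out = 2L))
  n_blocks <- as.integer(n_blocks)
  n3d_blocks <- as.integer(n3d_blocks)
  stopifnot(n_blocks >= 1L, base_channels >= 1L, dense_layers >= 1L,
            growth >= 1L, n3d_blocks >= 0L)
  if (n3d_blocks > n_blocks) stop("n3d_blocks must be <= n_blocks")
  if (any(in_size %% (2L^n_blocks) != 0L)) {
    stop("in_size must be divisible by 2^n_blocks")
  }
  structure(list(in_size = in_size, n_blocks = n_blocks,
                 base_channels = as.integer(base_channels),
                 dense_layers = as.integer(dense_layers),
                 growth = as.integer(growth), n3d_blocks = n3d_blocks,
                 attention = attention, norm = norm),
            class = "model_config")
}

# ---- parameter initialization ----------------------------------------------

.add_conv <- function(P, name, cin, cout, k = 3L, dims = 2L) {
  fan <- as.integer(k)^dims * cin
  P[[paste0(name, ".W")]] <- matrix(stats::rnorm(fan * cout, sd = sqrt(2 / fan)),
                                    fan, cout)
  P[[paste0(name, ".b")]] <- numeric(cout)
}

.add_norm <- function(P, name, c) {
  P[[paste0(name, ".g")]] <- rep(1, c)
  P[[paste0(name, ".s")]] <- numeric(c)
}

.add_linear <- function(P, name, cin, cout) {
  P[[paste0(name, ".W")]] <- matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)),
                                    cin, cout)
  P[[paste0(name, ".b")]] <- numeric(cout)
}

.add_dense_block <- function(P, name, cin, layers, growth, cout, norm, dims) {
  c_run <- cin
  for (j in seq_len(layers)) {
    .add_conv(P, paste0(name, ".l", j), c_run, growth, 3L, dims)
    if (norm == "instance") .add_norm(P, paste0(name, ".n", j), growth)
    c_run <- c_run + growth
  }
  .add_conv(P, paste0(name, ".t"), c_run, cout, 1L, dims)
  if (norm == "instance") .add_norm(P, paste0(name, ".tn"), cout)
}

.add_attention <- function(P, name, c) {
  mid <- max(c %/% 2L, 1L)
  .add_conv(P, paste0(name, ".ym"), 2L * c, c, 1L, 2L)
  .add_conv(P, paste0(name, ".s1"), c, mid, 1L, 2L)
  .add_conv(P, paste0(name, ".s2"), mid, 1L, 1L, 2L)
  .add_linear(P, paste0(name, ".sh"), 3L * c, c)
}

# ---- forward helpers -------------------------------------------------------

.leaf_cache <- function(tape, P) {
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!exists(name, envir = cache, inherits = FALSE)) {
      assign(name, nd_leaf(tape, get(name, envir = P, inherits = FALSE),
                           name = name),
             envir = cache)
    }
    get(name, envir = cache, inherits = FALSE)
  }
}

.fw_conv <- function(tape, x, pl, name, k = 3L, dims = 2L) {
  W <- pl(paste0(name, ".W"))
  b <- pl(paste0(name, ".b"))
  if (dims == 2L) op_conv2d(tape, x, W, b, k) else op_conv3d(tape, x, W, b, k)
}

.fw_norm <- function(tape, x, pl, name) {
  op_instnorm(tape, x, pl(paste0(name, ".g")), pl(paste0(name, ".s")))
}

.fw_dense_block <- function(tape, x, pl, name, layers, norm, dims) {
  feats <- list(x)
  for (j in seq_len(layers)) {
    inp <- if (length(feats) == 1L) feats[[1]] else op_concat(tape, feats)
    h <- .fw_conv(tape, inp, pl, paste0(name, ".l", j), 3L, dims)
    if (norm == "instance") h <- .fw_norm(tape, h, pl, paste0(name, ".n", j))
    h <- op_relu(tape, h)
    feats <- c(feats, list(h))
  }
  out <- .fw_conv(tape, op_concat(tape, feats), pl, paste0(name, ".t"), 1L, dims)
  if (norm == "instance") out <- .fw_norm(tape, out, pl, paste0(name, ".tn"))
  op_relu(tape, out)
}

.fw_spatial_att <- function(tape, x, y, pl, name) {
  yu <- op_upsample2(tape, y)
  ym <- .fw_conv(tape, yu, pl, paste0(name, ".ym"), 1L)
  f <- op_add(tape, x, ym)
  h <- op_relu(tape, .fw_conv(tape, f, pl, paste0(name, ".s1"), 1L))
  m <- op_sigmoid(tape, .fw_conv(tape, h, pl, paste0(name, ".s2"), 1L))
  m2 <- op_reshape(tape, m, dim(m$value)[1:2])
  op_mul_map(tape, x, m2)
}

.fw_channel_att <- function(tape, x, y, pl, name) {
  yu <- op_upsample2(tape, y)
  z <- op_concat(tape, list(x, yu))
  a <- op_linear(tape, op_gap(tape, z), pl(paste0(name, ".sh.W")),
                 pl(paste0(name, ".sh.b")))
  b <- op_linear(tape, op_gmp(tape, z), pl(paste0(name, ".sh.W")),
                 pl(paste0(name, ".sh.b")))
  w <- op_sigmoid(tape, op_add(tape, a, b))
  op_mul_chan(tape, x, w)
}

.fw_hybrid_att <- function(tape, x, y, pl, name) {
  op_add(tape,
         .fw_spatial_att(tape, x, y, pl, name),
         .fw_channel_att(tape, x, y, pl, name))
}

# ---- model -----------------------------------------------------------------

.level_width <- function(cfg, k) cfg$base_channels * 2L^(k - 1L)

#' Build a segmentation model
#'
#' Assembles the encoder-decoder: `n_blocks` dense blocks per path with 2x
#' max-pool downsampling between encoder blocks and bilinear 2x upsampling in
#' the decoder; the first `n3d_blocks` encoder blocks run 3x3x3 convolutions
#' on the depth-3 input stack, after which depth is folded into channels.
#' Each skip connection at level `k` is gated by the hybrid attention module
#' with `X` = level-`k` encoder features and `Y` = level-`k+1` encoder
#' features; skips from 3D levels are depth-folded and passed through a
#' learned 1x1 projection back to the level's nominal width first. The head
#' is a 1x1 convolution plus sigmoid giving the centre-slice foreground
#' probability map.
#'
#' @param cfg A [model_config].
#' @param seed Optional integer seed for weight initialization.
#' @return An object of class `seg_model`.
#' @export
build_model <- function(cfg = model_config(), seed = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  if (!is.null(seed)) set.seed(seed)
  P <- new.env(parent = emptyenv())
  n <- cfg$n_blocks
  n3 <- cfg$n3d_blocks
  for (k in seq_len(n)) {
    this3d <- k <= n3
    ck <- .level_width(cfg, k)
    cin <- if (k == 1L) {
      if (this3d) 1L else 3L
    } else {
      prev3d <- (k - 1L) <= n3
      if (prev3d && !this3d) 3L * .level_width(cfg, k - 1L) else .level_width(cfg, k - 1L)
    }
    .add_dense_block(P, paste0("enc", k), cin, cfg$dense_layers, cfg$growth,
                     ck, cfg$norm, if (this3d) 3L else 2L)
    if (this3d) .add_conv(P, paste0("sproj", k), 3L * ck, ck, 1L, 2L)
    if (cfg$attention == "hybrid" && k < n) .add_attention(P, paste0("att", k), ck)
  }
  for (k in if (n > 1L) seq(n - 1L, 1L) else integer(0)) {
    .add_dense_block(P, paste0("dec", k),
                     .level_width(cfg, k + 1L) + .level_width(cfg, k),
                     cfg$dense_layers, cfg$growth, .level_width(cfg, k),
                     cfg$norm, 2L)
  }
  .add_conv(P, "head", .level_width(cfg, 1L), 1L, 1L, 2L)
  structure(list(config = cfg, params = P), class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<seg_model> %dx%d input, %d blocks (%d of them 3D), base %d, attention %s: %s parameters\n",
    cfg$in_size[1], cfg$in_size[2], cfg$n_blocks, cfg$n3d_blocks,
    cfg$base_channels, cfg$attention,
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model A `seg_model`.
#' @return Total number of trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(ls(model$params),
             function(nm) length(get(nm, envir = model$params)), numeric(1)))
}

# Forward pass; x is (H, W, 3) on the 0..255 intensity scale. Returns the
# output node; gradients flow when `tape` is a tape.
.forward_seg <- function(model, x, tape = NULL) {
  cfg <- model$config
  P <- model$params
  d <- dim(x)
  if (length(d) != 3L || d[3] != 3L || d[1] != cfg$in_size[1] || d[2] != cfg$in_size[2]) {
    stop("input must be (", cfg$in_size[1], ", ", cfg$in_size[2], ", 3)")
  }
  pl <- .leaf_cache(tape, P)
  n <- cfg$n_blocks
  n3 <- cfg$n3d_blocks
  xin <- unclass(x) / 255
  if (n3 > 0L) dim(xin) <- c(d[1], d[2], 3L, 1L)
  cur <- nd_leaf(tape, xin)
  skips <- vector("list", n)
  for (k in seq_len(n)) {
    this3d <- k <= n3
    cur <- .fw_dense_block(tape, cur, pl, paste0("enc", k), cfg$dense_layers,
                           cfg$norm, if (this3d) 3L else 2L)
    skips[[k]] <- if (this3d) {
      dk <- dim(cur$value)
      folded <- op_reshape(tape, cur, c(dk[1], dk[2], dk[3] * dk[4]))
      .fw_conv(tape, folded, pl, paste0("sproj", k), 1L)
    } else cur
    if (k < n) {
      cur <- op_maxpool2(tape, cur)
      if (this3d && (k + 1L) > n3) {
        dk <- dim(cur$value)
        cur <- op_reshape(tape, cur, c(dk[1], dk[2], dk[3] * dk[4]))
      }
    }
  }
  dnode <- skips[[n]]
  if (n > 1L) {
    for (k in seq(n - 1L, 1L)) {
      up <- op_upsample2(tape, dnode)
      ak <- if (cfg$attention == "hybrid") {
        .fw_hybrid_att(tape, skips[[k]], skips[[k + 1L]], pl, paste0("att", k))
      } else skips[[k]]
      dnode <- .fw_dense_block(tape, op_concat(tape, list(up, ak)), pl,
                               paste0("dec", k), cfg$dense_layers, cfg$norm, 2L)
    }
  }
  logit <- .fw_conv(tape, dnode, pl, "head", 1L)
  prob <- op_sigmoid(tape, logit)
  op_reshape(tape, prob, dim(prob$value)[1:2])
}

#' Predict the centre-slice probability map for one 2.5D input
#'
#' @param model A trained `seg_model`.
#' @param x An `input25d` (or `(H, W, 3)` array) matching the model's
#'   `in_size`, intensities on the 0..255 preprocessing scale.
#' @return `(H, W)` matrix of foreground probabilities in `(0, 1)`.
#' @export
predict_slice <- function(model, x) {
  stopifnot(inherits(model, "seg_model"))
  .forward_seg(model, x, tape = NULL)$value
}

# ---- standalone module operations (plain-array surface) --------------------

#' Per-channel global average and max pooling
#'
#' `gap_c = mean(I_c)`, `gmp_c = max(I_c)` over the spatial extent of each
#' channel — average pooling summarizes smoothly, max pooling retains the
#' most salient response.
#'
#' @param x `(H, W, C)` (or `(H, W, D, C)`) numeric array.
#' @return List with numeric vectors `gap` and `gmp` of length `C`.
#' @export
channel_pool <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) < 3L || prod(d[-length(d)]) == 0L) {
    stop("x must be a nonempty array with a trailing channel dimension")
  }
  C <- d[length(d)]
  m <- matrix(x, prod(d[-length(d)]), C)
  list(gap = colMeans(m), gmp = apply(m, 2L, max))
}

#' Create (or zero) a standalone attention module's parameters
#'
#' The hybrid attention module gates features `X` of width `c` using deeper
#' features `Y` of width `2c` at half resolution. Parameters: a 1x1
#' channel-match for upsampled `Y` (`2c -> c`), two 1x1 convolutions in the
#' spatial branch (`c -> c/2 -> 1`), and a shared linear map (`3c -> c`) in
#' the channel branch.
#'
#' @param channels Width `c` of the gated feature map `X`.
#' @param zero_init If `TRUE`, all weights and biases start at zero (then
#'   both branches output `0.5 * X` and their sum is `X`).
#' @return Named list of parameter arrays.
#' @export
attention_params <- function(channels, zero_init = FALSE) {
  P <- new.env(parent = emptyenv())
  .add_attention(P, "att", as.integer(channels))
  out <- as.list(P)
  if (isTRUE(zero_init)) out <- lapply(out, function(p) p * 0)
  out
}

.att_check <- function(x, y) {
  dx <- dim(x)
  dy <- dim(y)
  if (length(dx) != 3L || length(dy) != 3L) stop("x and y must be (H, W, C) arrays")
  if (dy[1] * 2L != dx[1] || dy[2] * 2L != dx[2]) {
    stop("y spatial dims must be exactly half of x")
  }
  if (dy[3] != 2L * dx[3]) stop("y must have exactly twice the channels of x")
}

.att_run <- function(x, y, params, fwd) {
  .att_check(x, y)
  P <- list2env(params, parent = emptyenv())
  pl <- .leaf_cache(NULL, P)
  fwd(NULL, nd_leaf(NULL, x), nd_leaf(NULL, y), pl, "att")$value
}

#' Spatial attention gate
#'
#' `SA = X * sigma(conv(f(X, Y)))`: `Y` is upsampled 2x, channel-matched and
#' added to `X`; two 1x1 convolutions and a sigmoid produce a single-channel
#' weight map in `(0, 1)` that multiplies `X` (broadcast over channels).
#'
#' @param x `(H, W, C)` feature map to gate.
#' @param y `(H/2, W/2, 2C)` deeper encoder feature map.
#' @param params From [attention_params].
#' @return Gated array, same shape as `x`.
#' @export
spatial_attention <- function(x, y, params) .att_run(x, y, params, .fw_spatial_att)

#' Channel attention gate
#'
#' Upsampled `Y` is concatenated with `X` (3C channels); global average and
#' max pooling give two channel descriptors which pass through one shared
#' linear map (`3C -> C`), are summed, and squashed by a sigmoid into
#' per-channel weights that scale `X`.
#'
#' @inheritParams spatial_attention
#' @return Gated array, same shape as `x`.
#' @export
channel_attention <- function(x, y, params) .att_run(x, y, params, .fw_channel_att)

#' Hybrid attention
#'
#' Elementwise sum of [spatial_attention] and [channel_attention].
#'
#' @inheritParams spatial_attention
#' @return Gated array, same shape as `x`.
#' @export
hybrid_attention <- function(x, y, params) .att_run(x, y, params, .fw_hybrid_att)

#' Create a standalone dense block's parameters
#'
#' @param c_in Input channel count.
#' @param out_channels Block output width (1x1 transition target).
#' @param dense_layers Number of 3x3 convolution layers (default 6; the
#'   stacked receptive field is `1 + 2 * dense_layers`).
#' @param growth Channels added per layer.
#' @param norm `"instance"` or `"none"`.
#' @param dims 2 for 2D convolutions, 3 for 3x3x3.
#' @return Named list of parameter arrays plus a `spec` attribute.
#' @export
dense_block_params <- function(c_in, out_channels, dense_layers = 6L,
                               growth = out_channels,
                               norm = c("instance", "none"), dims = 2L) {
  norm <- match.arg(norm)
  P <- new.env(parent = emptyenv())
  .add_dense_block(P, "blk", as.integer(c_in), as.integer(dense_layers),
                   as.integer(growth), as.integer(out_channels), norm,
                   as.integer(dims))
  structure(as.list(P),
            spec = list(dense_layers = as.integer(dense_layers), norm = norm,
                        dims = as.integer(dims), c_in = as.integer(c_in),
                        out_channels = as.integer(out_channels)))
}

#' Apply a dense convolution block
#'
#' Each 3x3 layer sees the concatenation of the block input and all previous
#' layer outputs (dense connectivity); a 1x1 transition maps the final
#' concatenation to the block width. Spatial shape is preserved.
#'
#' @param x `(H, W, C)` array (or `(H, W, D, C)` for `dims = 3`).
#' @param params From [dense_block_params].
#' @return Array with `out_channels` channels, same spatial shape.
#' @export
dense_block <- function(x, params) {
  spec <- attr(params, "spec")
  d <- dim(x)
  if (d[length(d)] != spec$c_in) stop("channel mismatch: block expects ", spec$c_in)
  P <- list2env(params, parent = emptyenv())
  pl <- .leaf_cache(NULL, P)
  .fw_dense_block(NULL, nd_leaf(NULL, x), pl, "blk", spec$dense_layers,
                  spec$norm, spec$dims)$value
}

# ---- serialization ---------------------------------------------------------

#' Save / load a model
#'
#' `save_model()` writes `<prefix>.rds` (weights + config) and a
#' `<prefix>.json` sidecar holding the configuration so a checkpoint can be
#' inspected without loading it.
#'
#' @param model A `seg_model`.
#' @param prefix Output path prefix (no extension).
#' @return `save_model()`: the `.rds` path, invisibly. `load_model()`: a
#'   `seg_model`.
#' @export
save_model <- function(model, prefix) {
  stopifnot(inherits(model, "seg_model"))
  payload <- list(config = unclass(model$config), params = as.list(model$params))
  rds <- paste0(prefix, ".rds")
  saveRDS(payload, rds)
  jsonlite::write_json(payload$config, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(rds)
}

#' @rdname save_model
#' @param path Path to a `.rds` checkpoint (or its prefix).
#' @export
load_model <- function(path) {
  if (!grepl("\\.rds$", path)) path <- paste0(path, ".rds")
  payload <- readRDS(path)
  cfg <- do.call(model_config, payload$config)
  structure(list(config = cfg,
                 params = list2env(payload$params, parent = emptyenv())),
            class = "seg_model")
}
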