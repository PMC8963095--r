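#' Architecture specification for the inception U-Net
#'
#' The network is a 3D U-Net whose basic block is an inception module: four
#' parallel convolutional branches (kernel sizes 1, 3 and 5, plus a 3^3
#' max-pool followed by a 1^3 convolution), each emitting `filters` feature
#' maps, concatenated to 4 x `filters` maps. Every convolution is followed
#' by a ReLU, and every inception module by an instance-normalization
#' layer. The encoder has four stages (module + norm + stride-2 max-pool),
#' the bottleneck chains two modules, and the decoder mirrors the encoder
#' with stride-2 transposed convolutions and skip concatenations, for 10
#' inception modules in total. A dropout layer precedes the final
#' single-filter convolution, whose sigmoid output is the predicted mask
#' probability.
#'
#' `encoder_filters` lists the filter parameter of the four encoder modules
#' plus the first bottleneck module; `decoder_filters` the second
#' bottleneck module plus the four decoder modules.
#'
#' @param encoder_filters integer vector of length 5 (default
#'   `c(16, 16, 32, 64, 128)`).
#' @param decoder_filters integer vector of length 5 (default
#'   `c(128, 64, 32, 16, 16)`).
#' @param dropout_rate dropout fraction before the output convolution
#'   (default 0.3).
#' @param spatial_rank must be 3; the implementation is 3D-only.
#' @param input_channels,output_channels channel counts (defaults 1).
#' @return An `arch_spec` list.
#' @seealso [build_unet()]
#' @export
arch_spec <- function(encoder_filters = c(16, 16, 32, 64, 128),
                      decoder_filters = c(128, 64, 32, 16, 16),
                      dropout_rate = 0.3,
                      spatial_rank = 3,
                      input_channels = 1,
                      output_channels = 1) {
  if (length(encoder_filters) != length(decoder_filters)) {
    stop("encoder and decoder filter sequences must have equal length")
  }
  if (length(encoder_filters) != 5) {
    stop("the four-stage U-Net needs 5 encoder and 5 decoder filter counts")
  }
  if (any(encoder_filters <= 0) || any(decoder_filters <= 0)) {
    stop("filter counts must be positive")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)")
  }
  if (spatial_rank != 3) {
    stop("only spatial_rank = 3 is implemented")
  }
  structure(list(encoder_filters = as.integer(encoder_filters),
                 decoder_filters = as.integer(decoder_filters),
                 dropout_rate = dropout_rate,
                 spatial_rank = 3L,
                 input_channels = as.integer(input_channels),
                 output_channels = as.integer(output_channels)),
            class = "arch_spec")
}

#' A reduced specification for desk-scale experiments
#'
#' Same topology as the default network with the filter schedule shrunk to
#' `4, 4, 8, 16, 32` / `32, 16, 8, 4, 4`, small enough to train on CPU.
#'
#' @inheritParams arch_spec
#' @return An `arch_spec`.
#' @export
arch_spec_tiny <- function(dropout_rate = 0.3) {
  arch_spec(encoder_filters = c(4, 4, 8, 16, 32),
            decoder_filters = c(32, 16, 8, 4, 4),
            dropout_rate = dropout_rate)
}

# parameter shapes of one inception module
inception_param_shapes <- function(cin, f) {
  list(w1 = c(1, 1, 1, cin, f), b1 = f,
       w3 = c(3, 3, 3, cin, f), b3 = f,
       w5 = c(5, 5, 5, cin, f), b5 = f,
       wp = c(1, 1, 1, cin, f), bp = f)
}

#' Build a standalone inception module
#'
#' Mainly a test surface: returns the module's parameters plus its channel
#' bookkeeping. The concatenated output has `4 * filter_param` feature
#' maps and the same spatial shape as the input.
#'
#' @param filter_param feature maps per branch (> 0).
#' @param in_channels input feature maps (default 1).
#' @param spatial_rank must be 3.
#' @return An `inception_module` list with `params`, `in_channels`,
#'   `out_channels`.
#' @export
build_inception_module <- function(filter_param, in_channels = 1,
                                   spatial_rank = 3) {
  if (filter_param <= 0) stop("filter_param must be positive")
  if (spatial_rank != 3) stop("only spatial_rank = 3 is implemented")
  shapes <- inception_param_shapes(in_channels, filter_param)
  params <- lapply(shapes, function(s) {
    if (length(s) == 1) rep(0, s) else he_init(s)
  })
  structure(list(params = params,
                 in_channels = as.integer(in_channels),
                 out_channels = 4L * as.integer(filter_param),
                 filter_param = as.integer(filter_param)),
            class = "inception_module")
}

#' Run one inception module forward
#'
#' @param module an `inception_module`.
#' @param x 4D input array (X, Y, Z, in_channels).
#' @return The concatenated 4D output (X, Y, Z, 4 * filter_param).
#' @export
inception_forward <- function(module, x) {
  fw_inception(x, module$params)$out
}

fw_inception <- function(x, p) {
  r1 <- relu_fw(conv3d_fw(x, p$w1, p$b1))
  r3 <- relu_fw(conv3d_fw(x, p$w3, p$b3))
  r5 <- relu_fw(conv3d_fw(x, p$w5, p$b5))
  mp <- maxpool3d_fw(x, size = 3, stride = 1, pad = 1)
  rp <- relu_fw(conv3d_fw(mp$y, p$wp, p$bp))
  out <- concat_ch(concat_ch(r1, r3), concat_ch(r5, rp))
  list(out = out, cache = list(x = x, r1 = r1, r3 = r3, r5 = r5,
                               rp = rp, mp = mp))
}

bw_inception <- function(gout, cache, p) {
  f <- dim(cache$r1)[4]
  d <- dim(gout)
  n <- prod(d[1:3])
  grab <- function(i) array(gout[(n * f * (i - 1) + 1):(n * f * i)],
                            dim = c(d[1:3], f))
  g1 <- relu_bw(cache$r1, grab(1))
  g3 <- relu_bw(cache$r3, grab(2))
  g5 <- relu_bw(cache$r5, grab(3))
  gp <- relu_bw(cache$rp, grab(4))
  b1 <- conv3d_bw(cache$x, p$w1, g1)
  b3 <- conv3d_bw(cache$x, p$w3, g3)
  b5 <- conv3d_bw(cache$x, p$w5, g5)
  bp <- conv3d_bw(cache$mp$y, p$wp, gp)
  gx <- b1$gx + b3$gx + b5$gx + maxpool3d_bw(cache$mp, bp$gx)
  list(gx = gx,
       gparams = list(w1 = b1$gw, b1 = b1$gb, w3 = b3$gw, b3 = b3$gb,
                      w5 = b5$gw, b5 = b5$gb, wp = bp$gw, bp = bp$gb))
}

#' Build the inception U-Net
#'
#' Instantiates all weights (He initialization, seeded by the caller's RNG
#' state) and records the block graph: 10 inception modules, each followed
#' by instance normalization, four stride-2 max-pool downsamplings, four
#' stride-2 transposed-convolution upsamplings with encoder skip
#' concatenations, dropout, and a final 1-filter convolution with sigmoid
#' activation.
#'
#' @param spec an [arch_spec()].
#' @return An `inception_unet`: list with `spec`, `params` (named flat list
#'   of arrays) and `graph` (data frame of blocks with channel counts and
#'   spatial scales).
#' @examples
#' net <- build_unet(arch_spec_tiny())
#' sum(net$graph$type == "inception")
#' @export
build_unet <- function(spec) {
  if (!inherits(spec, "arch_spec")) spec <- do.call(arch_spec, spec)
  ef <- spec$encoder_filters
  df <- spec$decoder_filters
  params <- list()
  graph <- list()
  add_block <- function(name, type, filters, cin, cout, scale) {
    graph[[length(graph) + 1]] <<- data.frame(
      block = name, type = type, filters = filters,
      in_channels = cin, out_channels = cout, scale = scale,
      stringsAsFactors = FALSE)
  }
  add_inception <- function(name, cin, f, scale) {
    shapes <- inception_param_shapes(cin, f)
    for (nm in names(shapes)) {
      s <- shapes[[nm]]
      params[[paste0(name, ".", nm)]] <<-
        if (length(s) == 1) rep(0, s) else he_init(s)
    }
    add_block(name, "inception", f, cin, 4L * f, scale)
    params[[paste0(name, ".gamma")]] <<- rep(1, 4L * f)
    params[[paste0(name, ".beta")]] <<- rep(0, 4L * f)
    add_block(paste0(name, ".norm"), "instance_norm", NA, 4L * f, 4L * f,
              scale)
    4L * f
  }
  ch <- spec$input_channels
  scale <- 1L
  for (i in 1:4) {
    ch <- add_inception(paste0("enc", i), ch, ef[i], scale)
    add_block(paste0("pool", i), "maxpool", NA, ch, ch, scale * 2L)
    scale <- scale * 2L
  }
  ch <- add_inception("bot1", ch, ef[5], scale)
  ch <- add_inception("bot2", ch, df[1], scale)
  for (j in 1:4) {
    up_out <- ch %/% 2L
    params[[paste0("up", j, ".w")]] <- he_init(c(2, 2, 2, ch, up_out))
    params[[paste0("up", j, ".b")]] <- rep(0, up_out)
    scale <- scale %/% 2L
    add_block(paste0("up", j), "transposed_conv", NA, ch, up_out, scale)
    skip_ch <- 4L * ef[5 - j]
    add_block(paste0("skip", 5 - j), "concat", NA, skip_ch + up_out,
              skip_ch + up_out, scale)
    ch <- add_inception(paste0("dec", j), skip_ch + up_out, df[j + 1], scale)
  }
  add_block("dropout", "dropout", NA, ch, ch, scale)
  params[["out.w"]] <- he_init(c(1, 1, 1, ch, spec$output_channels))
  params[["out.b"]] <- rep(0, spec$output_channels)
  add_block("out", "conv_sigmoid", NA, ch, spec$output_channels, scale)
  structure(list(spec = spec, params = params,
                 graph = do.call(rbind, graph)),
            class = "inception_unet")
}

#' @export
print.inception_unet <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("<inception_unet> ", sum(x$graph$type == "inception"),
      " inception modules, ", np, " parameters\n", sep = "")
  print(x$graph, row.names = FALSE)
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model an `inception_unet`.
#' @return Integer count of scalar parameters.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Per-module output feature-map counts
#'
#' Reports, in network order, the number of feature maps each inception
#' module emits (always 4 x its filter parameter).
#'
#' @param model an `inception_unet` (or its graph data frame).
#' @return Named integer vector over the 10 inception modules.
#' @export
count_feature_maps <- function(model) {
  graph <- if (is.data.frame(model)) model else model$graph
  inc <- graph[graph$type == "inception", ]
  stats::setNames(inc$out_channels, inc$block)
}

get_module_params <- function(params, name) {
  list(w1 = params[[paste0(name, ".w1")]], b1 = params[[paste0(name, ".b1")]],
       w3 = params[[paste0(name, ".w3")]], b3 = params[[paste0(name, ".b3")]],
       w5 = params[[paste0(name, ".w5")]], b5 = params[[paste0(name, ".b5")]],
       wp = params[[paste0(name, ".wp")]], bp = params[[paste0(name, ".bp")]])
}

check_input_shape <- function(dims) {
  if (any(dims[1:3] %% 16 != 0)) {
    stop(sprintf(paste0(
      "input spatial shape %s is not divisible by 16 (four stride-2 ",
      "halvings); pad the volume, e.g. crop_to_mask(..., pad_multiple = 16)"),
      paste(dims[1:3], collapse = "x")))
  }
  invisible(TRUE)
}

#' Forward pass of the inception U-Net
#'
#' @param model an `inception_unet`.
#' @param x 4D input array (X, Y, Z, input_channels) or 3D array (a single
#'   channel is assumed); spatial sides must be divisible by 16.
#' @param training if `TRUE`, applies dropout and keeps the caches needed
#'   for the backward pass.
#' @return If `training`, a list with `out` (sigmoid probabilities) and
#'   `cache`; otherwise the probability array.
#' @export
unet_forward <- function(model, x, training = FALSE) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  check_input_shape(dim(x))
  p <- model$params
  caches <- list()
  skips <- list()
  s <- x
  for (i in 1:4) {
    nm <- paste0("enc", i)
    fi <- fw_inception(s, get_module_params(p, nm))
    no <- instnorm_fw(fi$out, p[[paste0(nm, ".gamma")]],
                      p[[paste0(nm, ".beta")]])
    skips[[i]] <- no$y
    mp <- maxpool3d_fw(no$y, size = 2, stride = 2, pad = 0)
    s <- mp$y
    caches[[nm]] <- list(inc = fi$cache, norm = no$cache, pool = mp)
  }
  for (nm in c("bot1", "bot2")) {
    fi <- fw_inception(s, get_module_params(p, nm))
    no <- instnorm_fw(fi$out, p[[paste0(nm, ".gamma")]],
                      p[[paste0(nm, ".beta")]])
    s <- no$y
    caches[[nm]] <- list(inc = fi$cache, norm = no$cache)
  }
  for (j in 1:4) {
    up_in <- s
    s <- tconv3d_fw(s, p[[paste0("up", j, ".w")]], p[[paste0("up", j, ".b")]])
    skip <- skips[[5 - j]]
    cat_in <- concat_ch(skip, s)
    nm <- paste0("dec", j)
    fi <- fw_inception(cat_in, get_module_params(p, nm))
    no <- instnorm_fw(fi$out, p[[paste0(nm, ".gamma")]],
                      p[[paste0(nm, ".beta")]])
    caches[[nm]] <- list(up_in = up_in, skip_ch = dim(skip)[4],
                         inc = fi$cache, norm = no$cache)
    s <- no$y
  }
  do <- if (training) dropout_fw(s, model$spec$dropout_rate) else
    list(y = s, mask = NULL)
  z <- conv3d_fw(do$y, p[["out.w"]], p[["out.b"]])
  out <- sigmoid(z)
  if (!training) return(out)
  caches[["head"]] <- list(do_in = do$y, do_mask = do$mask, out = out)
  list(out = out, cache = caches)
}

# Backward pass: gout is the gradient of the loss w.r.t. the sigmoid
# output. Returns gradients as a named list parallel to model$params.
unet_backward <- function(model, cache, gout) {
  p <- model$params
  g <- list()
  head <- cache[["head"]]
  gz <- gout * head$out * (1 - head$out)
  bo <- conv3d_bw(head$do_in, p[["out.w"]], gz)
  g[["out.w"]] <- bo$gw
  g[["out.b"]] <- bo$gb
  gs <- dropout_bw(head$do_mask, bo$gx)
  gskips <- vector("list", 4)
  for (j in 4:1) {
    nm <- paste0("dec", j)
    cc <- cache[[nm]]
    bn <- instnorm_bw(cc$norm, p[[paste0(nm, ".gamma")]], gs)
    g[[paste0(nm, ".gamma")]] <- bn$ggamma
    g[[paste0(nm, ".beta")]] <- bn$gbeta
    bi <- bw_inception(bn$gx, cc$inc, get_module_params(p, nm))
    for (pn in names(bi$gparams)) g[[paste0(nm, ".", pn)]] <- bi$gparams[[pn]]
    sp <- split_ch(bi$gx, cc$skip_ch)
    gskips[[5 - j]] <- sp$a
    bu <- tconv3d_bw(cc$up_in, p[[paste0("up", j, ".w")]], sp$b)
    g[[paste0("up", j, ".w")]] <- bu$gw
    g[[paste0("up", j, ".b")]] <- bu$gb
    gs <- bu$gx
  }
  for (nm in c("bot2", "bot1")) {
    cc <- cache[[nm]]
    bn <- instnorm_bw(cc$norm, p[[paste0(nm, ".gamma")]], gs)
    g[[paste0(nm, ".gamma")]] <- bn$ggamma
    g[[paste0(nm, ".beta")]] <- bn$gbeta
    bi <- bw_inception(bn$gx, cc$inc, get_module_params(p, nm))
    for (pn in names(bi$gparams)) g[[paste0(nm, ".", pn)]] <- bi$gparams[[pn]]
    gs <- bi$gx
  }
  for (i in 4:1) {
    nm <- paste0("enc", i)
    cc <- cache[[nm]]
    gpool <- maxpool3d_bw(cc$pool, gs)
    gnorm_out <- gpool + gskips[[i]]
    bn <- instnorm_bw(cc$norm, p[[paste0(nm, ".gamma")]], gnorm_out)
    g[[paste0(nm, ".gamma")]] <- bn$ggamma
    g[[paste0(nm, ".beta")]] <- bn$gbeta
    bi <- bw_inception(bn$gx, cc$inc, get_module_params(p, nm))
    for (pn in names(bi$gparams)) g[[paste0(nm, ".", pn)]] <- bi$gparams[[pn]]
    gs <- bi$gx
  }
  g
}
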