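#' Segmentation training configuration
#'
#' Bundles the training recipe for the U-Net++ tongue segmenter. Defaults
#' follow the full-scale recipe (256 px inputs, Adam at 1e-4, batch 16,
#' 100 epochs, 5 folds, equally weighted binary cross-entropy and
#' soft-Dice loss). `width` multiplies the standard U-Net++ filter
#' complement (32, 64, 128, ... at successive depths); `depth` is the
#' number of pooling stages.
#'
#' @param input_size Square input side in pixels; must be a multiple of 16
#'   and divisible by `2^depth`.
#' @param epochs Number of training epochs (>= 1).
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size (>= 1).
#' @param n_folds Number of participant-grouped cross-validation folds.
#' @param w_bce,w_dice Loss weights for the cross-entropy and soft-Dice terms.
#' @param width Width multiplier applied to the base 32-filter complement.
#' @param depth Number of pooling stages (encoder depth).
#' @param deep_supervision If `TRUE`, averages the side outputs of all
#'   full-resolution nested nodes instead of using only the final one.
#' @param batch_norm Use batch normalization after every convolution
#'   (standard U-Net++ conv blocks); running statistics are accumulated
#'   during training and used at inference.
#' @param threshold Probability threshold used to binarize predicted maps.
#' @param calibrate_threshold If `TRUE`, cross-validation replaces the
#'   fixed threshold per fold with the value maximizing mean Dice on the
#'   *training* images (an operating-point calibration; the validation
#'   fold is never consulted).
#' @param seed Integer seed controlling weight initialization and batching.
#' @return An object of class `seg_train_config`.
#' @export
seg_train_config <- function(input_size = 256L, epochs = 100L,
                             learning_rate = 1e-4, batch_size = 16L,
                             n_folds = 5L, w_bce = 1, w_dice = 1,
                             width = 1, depth = 4L,
                             deep_supervision = FALSE, batch_norm = TRUE,
                             threshold = 0.5,
                             calibrate_threshold = FALSE, seed = 1L) {
  check_number(input_size, "input_size", lower = 16)
  check_number(epochs, "epochs", lower = 1)
  check_number(batch_size, "batch_size", lower = 1)
  check_number(n_folds, "n_folds", lower = 1)
  check_number(learning_rate, "learning_rate", lower = 0)
  check_number(width, "width", lower = 1 / 32)
  check_number(depth, "depth", lower = 1, upper = 6)
  check_number(threshold, "threshold", lower = 0, upper = 1)
  check_flag(deep_supervision, "deep_supervision")
  check_flag(batch_norm, "batch_norm")
  check_flag(calibrate_threshold, "calibrate_threshold")
  if (input_size %% 16 != 0)
    stop_param("`input_size` must be a multiple of 16 (got %d)", input_size)
  if (input_size %% (2^depth) != 0)
    stop_param("`input_size` %d is not divisible by 2^depth = %d",
               input_size, 2^depth)
  structure(list(
    input_size = as.integer(input_size), epochs = as.integer(epochs),
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    n_folds = as.integer(n_folds), w_bce = w_bce, w_dice = w_dice,
    width = width, depth = as.integer(depth),
    deep_supervision = deep_supervision, batch_norm = batch_norm,
    threshold = threshold,
    calibrate_threshold = calibrate_threshold,
    seed = as.integer(seed)
  ), class = "seg_train_config")
}

#' Reduced-scale training profile
#'
#' A width-reduced recipe (128 px inputs, width 1/4, depth 3, 15 epochs,
#' 2 grouped folds) for small synthetic benchmarks on a single CPU; the
#' full-scale recipe of [seg_train_config()] remains the default
#' elsewhere.
#'
#' @param ... Overrides passed on to [seg_train_config()].
#' @return A `seg_train_config`.
#' @export
desk_profile <- function(...) {
  args <- list(...)
  # short-budget training yields under-confident probability maps whose
  # spatial discrimination is nevertheless good; the train-calibrated
  # operating threshold exploits that without touching validation data
  defaults <- list(input_size = 128L, epochs = 15L, width = 0.25,
                   n_folds = 2L, depth = 3L, calibrate_threshold = TRUE)
  do.call(seg_train_config, utils::modifyList(defaults, args))
}

node_key <- function(i, j) paste0("x", i, "_", j)

unetpp_channels <- function(config) {
  base <- max(1L, as.integer(round(32 * config$width)))
  base * 2^(0:config$depth)
}

# He-normal initial weight matrix for a kxk conv, [k*k*cin, cout]
init_conv <- function(k, cin, cout) {
  matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
         nrow = k * k * cin, ncol = cout)
}

#' Build a U-Net++ segmentation network
#'
#' Constructs an encoder--decoder network with the nested, densely
#' connected skip topology of U-Net++: node \eqn{X^{i,j}} receives the
#' concatenation of all same-level predecessors \eqn{X^{i,0..j-1}} and the
#' 2x upsampled output of \eqn{X^{i+1,j-1}}. Each node is two 3x3
#' convolutions with ReLU; the head is a 1x1 convolution producing a
#' single-channel sigmoid probability map. Weights are He-initialized
#' under the configuration seed, so identical seeds give identical
#' initial weights.
#'
#' @param config A [seg_train_config()].
#' @param in_channels Number of input image channels (3 for RGB).
#' @return An object of class `unetpp_model` (untrained).
#' @export
build_model <- function(config, in_channels = 3L) {
  stopifnot(inherits(config, "seg_train_config"))
  L <- config$depth
  ch <- unetpp_channels(config)
  set.seed(config$seed)
  params <- list()
  bn_stats <- list()
  add_block <- function(key, cin, cout) {
    params[[paste0(key, ".w1")]] <<- init_conv(3, cin, cout)
    params[[paste0(key, ".b1")]] <<- numeric(cout)
    params[[paste0(key, ".w2")]] <<- init_conv(3, cout, cout)
    params[[paste0(key, ".b2")]] <<- numeric(cout)
    if (config$batch_norm) {
      params[[paste0(key, ".g1")]] <<- rep(1, cout)
      params[[paste0(key, ".be1")]] <<- numeric(cout)
      params[[paste0(key, ".g2")]] <<- rep(1, cout)
      params[[paste0(key, ".be2")]] <<- numeric(cout)
      bn_stats[[key]] <<- list(m1 = numeric(cout), v1 = rep(1, cout),
                               m2 = numeric(cout), v2 = rep(1, cout))
    }
  }
  for (i in 0:L) {
    cin <- if (i == 0) in_channels else ch[i]      # ch[i] is level i-1 (1-based)
    add_block(node_key(i, 0), cin, ch[i + 1])
  }
  if (L >= 1) {
    for (j in 1:L) {
      for (i in 0:(L - j)) {
        cin <- j * ch[i + 1] + ch[i + 2]
        add_block(node_key(i, j), cin, ch[i + 1])
      }
    }
  }
  heads <- if (config$deep_supervision && L >= 1) 1:L else L
  for (j in heads) {
    params[[paste0("head", j, ".w")]] <- init_conv(1, ch[1], 1)
    params[[paste0("head", j, ".b")]] <- numeric(1)
  }
  bn_env <- new.env(parent = emptyenv())
  bn_env$stats <- bn_stats
  structure(list(config = config, in_channels = as.integer(in_channels),
                 channels = ch, heads = heads, params = params,
                 bn_env = bn_env, bn_eps = 1e-5, bn_momentum = 0.1,
                 trained = FALSE, history = NULL),
            class = "unetpp_model")
}

#' Number of trainable parameters
#' @param model A `unetpp_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# `x_parts` is a list of [H,W,Ci,B] arrays whose channel concatenation is
# the block input; the conv kernels gather the parts internally. Each
# half of the block is conv (+ batch norm) + ReLU. During training, batch
# statistics feed the running averages stored in the model's bn
# environment; at inference the running averages are used.
conv_block_fwd <- function(model, key, x_parts, training) {
  params <- model$params
  bn <- model$config$batch_norm
  p <- function(s) params[[paste0(key, ".", s)]]
  half <- function(x_in, wi) {
    a <- cpp_conv_fwd(x_in, p(paste0("w", wi)), p(paste0("b", wi)),
                      relu = !bn)
    if (!bn) return(list(a = a, h = a, mean = NULL, var = NULL))
    if (training) {
      r <- cpp_bn_fwd(a, p(paste0("g", wi)), p(paste0("be", wi)),
                      model$bn_eps, relu = TRUE)
      st <- model$bn_env$stats[[key]]
      mom <- model$bn_momentum
      st[[paste0("m", wi)]] <- (1 - mom) * st[[paste0("m", wi)]] + mom * r$mean
      st[[paste0("v", wi)]] <- (1 - mom) * st[[paste0("v", wi)]] + mom * r$var
      model$bn_env$stats[[key]] <- st
      list(a = a, h = r$y, mean = r$mean, var = r$var)
    } else {
      st <- model$bn_env$stats[[key]]
      h <- cpp_bn_eval(a, p(paste0("g", wi)), p(paste0("be", wi)),
                       st[[paste0("m", wi)]], st[[paste0("v", wi)]],
                       model$bn_eps, relu = TRUE)
      list(a = a, h = h, mean = NULL, var = NULL)
    }
  }
  s1 <- half(x_parts, 1)
  s2 <- half(list(s1$h), 2)
  list(x = x_parts, a1 = s1$a, h1 = s1$h, bn1 = s1[c("mean", "var")],
       a2 = s2$a, h2 = s2$h, bn2 = s2[c("mean", "var")])
}

conv_block_bwd <- function(model, key, cache, d_out) {
  params <- model$params
  bn <- model$config$batch_norm
  p <- function(s) params[[paste0(key, ".", s)]]
  grads <- list()
  if (bn) {
    b2 <- cpp_bn_bwd(cache$a2, p("g2"), cache$bn2$mean, cache$bn2$var,
                     model$bn_eps, d_out, cache$h2, relu = TRUE)
    grads[[paste0(key, ".g2")]] <- b2$dgamma
    grads[[paste0(key, ".be2")]] <- b2$dbeta
    d_a2 <- b2$dx
  } else {
    d_a2 <- cpp_relu_bwd(d_out, cache$h2)
  }
  r2 <- cpp_conv_bwd(list(cache$h1), p("w2"), d_a2)
  if (bn) {
    b1 <- cpp_bn_bwd(cache$a1, p("g1"), cache$bn1$mean, cache$bn1$var,
                     model$bn_eps, r2$dx[[1]], cache$h1, relu = TRUE)
    grads[[paste0(key, ".g1")]] <- b1$dgamma
    grads[[paste0(key, ".be1")]] <- b1$dbeta
    d_a1 <- b1$dx
  } else {
    d_a1 <- cpp_relu_bwd(r2$dx[[1]], cache$h1)
  }
  r1 <- cpp_conv_bwd(cache$x, p("w1"), d_a1)
  grads[paste0(key, c(".w1", ".b1", ".w2", ".b2"))] <-
    list(r1$dw, r1$db, r2$dw, r2$db)
  list(d_in = r1$dx, grads = grads)
}

# Forward pass; returns logits [H,W,1,B] and (optionally) all caches
# needed for backprop.
unetpp_forward <- function(model, x, keep_cache = TRUE, training = FALSE) {
  cfg <- model$config
  L <- cfg$depth
  p <- model$params
  nodes <- list()
  pools <- list()
  for (i in 0:L) {
    inp <- if (i == 0) x else {
      pl <- cpp_maxpool_fwd(nodes[[node_key(i - 1, 0)]]$h2)
      pools[[node_key(i, 0)]] <- pl$idx
      pl$y
    }
    nodes[[node_key(i, 0)]] <- conv_block_fwd(model, node_key(i, 0),
                                              list(inp), training)
  }
  if (L >= 1) {
    for (j in 1:L) {
      for (i in 0:(L - j)) {
        up <- cpp_upsample_fwd(nodes[[node_key(i + 1, j - 1)]]$h2)
        parts <- lapply(0:(j - 1), function(jj) nodes[[node_key(i, jj)]]$h2)
        nodes[[node_key(i, j)]] <- conv_block_fwd(model, node_key(i, j),
                                                  c(parts, list(up)),
                                                  training)
      }
    }
  }
  logit_list <- lapply(model$heads, function(j)
    cpp_conv_fwd(list(nodes[[node_key(0, j)]]$h2),
                 p[[paste0("head", j, ".w")]], p[[paste0("head", j, ".b")]]))
  logits <- Reduce(`+`, logit_list) / length(logit_list)
  if (!keep_cache) return(list(logits = logits))
  list(logits = logits, nodes = nodes, pools = pools)
}

unetpp_backward <- function(model, fwd, d_logits) {
  cfg <- model$config
  L <- cfg$depth
  p <- model$params
  ch <- model$channels
  grads <- list()
  dX <- list()
  acc <- function(key, d) {
    dX[[key]] <<- if (is.null(dX[[key]])) d else dX[[key]] + d
  }
  dh <- d_logits / length(model$heads)
  for (j in model$heads) {
    r <- cpp_conv_bwd(list(fwd$nodes[[node_key(0, j)]]$h2),
                      p[[paste0("head", j, ".w")]], dh)
    grads[[paste0("head", j, ".w")]] <- r$dw
    grads[[paste0("head", j, ".b")]] <- r$db
    acc(node_key(0, j), r$dx[[1]])
  }
  if (L >= 1) {
    for (j in L:1) {
      for (i in 0:(L - j)) {
        key <- node_key(i, j)
        d <- dX[[key]]
        if (is.null(d)) next
        bb <- conv_block_bwd(model, key, fwd$nodes[[key]], d)
        grads <- c(grads, bb$grads)
        for (jj in 0:(j - 1)) acc(node_key(i, jj), bb$d_in[[jj + 1]])
        acc(node_key(i + 1, j - 1), cpp_upsample_bwd(bb$d_in[[j + 1]]))
      }
    }
  }
  for (i in L:0) {
    key <- node_key(i, 0)
    bb <- conv_block_bwd(model, key, fwd$nodes[[key]], dX[[key]])
    grads <- c(grads, bb$grads)
    if (i > 0) {
      below <- fwd$nodes[[node_key(i - 1, 0)]]$h2
      acc(node_key(i - 1, 0),
          cpp_maxpool_bwd(fwd$pools[[key]], bb$d_in[[1]], dim(below)))
    }
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# Stack a list of [H,W,C] images (or [H,W] masks) into a [H,W,C,B] array.
stack_batch <- function(lst, channels = NULL) {
  x1 <- lst[[1]]
  d <- dim(x1)
  if (length(d) == 2) d <- c(d, 1L)
  if (!is.null(channels)) d[3] <- channels
  out <- array(0, c(d[1], d[2], d[3], length(lst)))
  for (k in seq_along(lst)) out[, , , k] <- lst[[k]]
  out
}

#' Train a U-Net++ model
#'
#' Optimizes the combined binary cross-entropy + soft-Dice loss with Adam.
#' Training consumes only images, masks and the configuration: no group or
#' diagnostic label enters this function.
#'
#' @param model A `unetpp_model` from [build_model()].
#' @param images List of `[H,W,C]` arrays with values in `[0,1]`, all at
#'   the configured input size.
#' @param masks List of matching binary `[H,W]` masks.
#' @param verbose Print per-epoch loss.
#' @return The trained model, with `$history` holding per-epoch mean loss
#'   and `$step_loss` the per-step running loss.
#' @export
train_unetpp <- function(model, images, masks, verbose = FALSE) {
  stopifnot(inherits(model, "unetpp_model"), length(images) == length(masks),
            length(images) > 0)
  cfg <- model$config
  n <- length(images)
  xall <- stack_batch(images, channels = model$in_channels)
  yall <- stack_batch(lapply(masks, function(m) array(m, c(dim(m)[1:2], 1L))))
  params <- model$params
  state <- adam_init(params)
  history <- numeric(cfg$epochs)
  step_loss <- numeric(0)
  set.seed(derive_seed(cfg$seed, "train"))
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    b0 <- 1
    while (b0 <= n) {
      ids <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
      b0 <- b0 + cfg$batch_size
      xb <- xall[, , , ids, drop = FALSE]
      yb <- yall[, , , ids, drop = FALSE]
      model$params <- params
      fwd <- unetpp_forward(model, xb, keep_cache = TRUE, training = TRUE)
      lg <- loss_grad_from_logits(fwd$logits, yb, cfg$w_bce, cfg$w_dice)
      grads <- unetpp_backward(model, fwd, lg$d_logits)
      upd <- adam_step(params, grads, state, cfg$learning_rate)
      params <- upd$params
      state <- upd$state
      losses <- c(losses, lg$loss)
    }
    history[ep] <- mean(losses)
    step_loss <- c(step_loss, losses)
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f", ep, cfg$epochs, history[ep]))
  }
  model$params <- params
  model$trained <- TRUE
  model$history <- history
  model$step_loss <- step_loss
  model
}

#' Predict probability maps
#'
#' @param model A trained (or untrained, for smoke checks) `unetpp_model`.
#' @param x A single `[H,W,C]` image or a `[H,W,C,B]` batch at the model
#'   input size.
#' @return A `[H,W]` matrix (single image) or `[H,W,1,B]` array of
#'   sigmoid probabilities in `[0,1]`.
#' @export
unetpp_predict <- function(model, x) {
  single <- length(dim(x)) == 3
  if (single) x <- array(x, c(dim(x), 1L))
  out <- unetpp_forward(model, x, keep_cache = FALSE)$logits
  p <- 1 / (1 + exp(-out))
  if (single) matrix(p, dim(p)[1], dim(p)[2]) else p
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file embedding the weights and the full
#' training configuration.
#'
#' @param model A `unetpp_model`.
#' @param path File path for the checkpoint.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `unetpp_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "unetpp_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "unetpp_model")) stop_param("not a unetpp checkpoint")
  model
}

#' @export
print.unetpp_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "U-Net++ segmenter: depth %d, base width %d, input %dx%d, %s\n",
    cfg$depth, x$channels[1], cfg$input_size, cfg$input_size,
    if (x$trained) "trained" else "untrained"))
  cat(sprintf("  parameters: %d; deep supervision: %s\n",
              n_params(x), cfg$deep_supervision))
  invisible(x)
}
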