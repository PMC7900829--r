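#' Configuration of the vein-segmentation network
#'
#' A compact encoder-decoder convolutional network mapping a square NIR image
#' to a per-pixel vein probability map of the same size. The encoder applies
#' `depth` stages of 3x3 convolution + ReLU + 2x2 max pooling; a bottleneck
#' convolution follows; the decoder mirrors the encoder with 2x2 nearest
#' upsampling, optional skip concatenation from the matching encoder stage,
#' and 3x3 convolution + ReLU; a final 1x1 convolution with sigmoid emits the
#' probability map. Filter counts double per stage starting at
#' `base_filters`. Trained with binary cross-entropy and Adam; every random
#' draw (weight initialization, batch shuffling) flows from `seed`, so a
#' fixed configuration reproduces bit-identical weights and loss histories
#' on a fixed platform (the shipped conv/pool primitives accumulate in a
#' fixed order; only an aggressively reordering BLAS could perturb the last
#' bits of the GEMM products).
#'
#' @param input_size Side length of the square input, px; must be divisible
#'   by `2^depth`.
#' @param depth Number of pooling stages (>= 1).
#' @param base_filters Filters in the first encoder stage.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param skip_connections Concatenate encoder features into the decoder.
#' @param threshold Probability threshold for the binary mask (mask is
#'   `prob >= threshold`).
#' @param normalize Gray-level divisor applied to inputs (255 for 8-bit-style
#'   images).
#' @param seed Integer seed for initialization and shuffling.
#' @return An object of class `segnet_config`.
#' @export
segnet_config <- function(input_size = 256L, depth = 2L, base_filters = 8L,
                          epochs = 20L, batch_size = 2L,
                          learning_rate = 5e-3, skip_connections = TRUE,
                          threshold = 0.5, normalize = 255, seed = 1L) {
  input_size <- as.integer(input_size)
  depth <- as.integer(depth)
  if (depth < 1L) abort("`depth` must be >= 1.")
  if (input_size %% as.integer(2^depth) != 0L) {
    abort(sprintf(
      "`input_size` (%d) must be divisible by 2^depth (%d).",
      input_size, 2^depth
    ))
  }
  if (base_filters < 1L) abort("`base_filters` must be >= 1.")
  structure(
    list(
      input_size = input_size, depth = depth,
      base_filters = as.integer(base_filters),
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      learning_rate = learning_rate, skip_connections = skip_connections,
      threshold = threshold, normalize = normalize, seed = as.integer(seed)
    ),
    class = "segnet_config"
  )
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

# Channel plan and weight initialization (He scaling); caller seeds the RNG.
segnet_params <- function(cfg) {
  d <- cfg$depth
  filters <- cfg$base_filters * 2^(seq_len(d) - 1L)
  params <- list()
  in_ch <- 1L
  for (i in seq_len(d)) {
    params[[paste0("w_enc", i)]] <- he_init(9L * in_ch, filters[i], 9L * in_ch)
    params[[paste0("b_enc", i)]] <- rep(0, filters[i])
    in_ch <- filters[i]
  }
  bott <- cfg$base_filters * 2^d
  params$w_bott <- he_init(9L * in_ch, bott, 9L * in_ch)
  params$b_bott <- rep(0, bott)
  in_ch <- bott
  for (i in rev(seq_len(d))) {
    cat_ch <- in_ch + if (cfg$skip_connections) filters[i] else 0L
    params[[paste0("w_dec", i)]] <- he_init(9L * cat_ch, filters[i], 9L * cat_ch)
    params[[paste0("b_dec", i)]] <- rep(0, filters[i])
    in_ch <- filters[i]
  }
  params$w_out <- he_init(in_ch, 1L, in_ch)
  params$b_out <- 0
  params
}

#' Build the segmentation network
#'
#' Initializes a network from a configuration with seeded He-scaled weights;
#' two builds from the same configuration carry identical initial weights.
#'
#' @param cfg A [segnet_config()].
#' @return An object of class `segnet` (configuration + weights).
#' @export
build_segnet <- function(cfg) {
  stopifnot(inherits(cfg, "segnet_config"))
  params <- with_seed(cfg$seed, segnet_params(cfg))
  structure(list(cfg = cfg, params = params, trained = FALSE), class = "segnet")
}

#' @export
print.segnet <- function(x, ...) {
  n_par <- sum(purrr::map_int(x$params, length))
  cat(sprintf(
    "<segnet> %dx%d input, depth %d, base %d filters, %s, %d parameter(s)%s\n",
    x$cfg$input_size, x$cfg$input_size, x$cfg$depth, x$cfg$base_filters,
    if (x$cfg$skip_connections) "skips on" else "skips off", n_par,
    if (x$trained) ", trained" else ""
  ))
  invisible(x)
}

as_cube <- function(m) array(m, dim = c(nrow(m), ncol(m), 1L))

concat_ch <- function(a, b) {
  array(c(a, b), dim = c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

# Forward pass on one normalized image (matrix in [0, 1]).
segnet_forward <- function(model, x, want_cache = FALSE) {
  cfg <- model$cfg
  p <- model$params
  d <- cfg$depth
  cache <- list(
    enc_ch = vector("list", d), enc_cols = vector("list", d),
    enc_pre = vector("list", d),
    enc_act = vector("list", d), pool_idx = vector("list", d),
    dec_ch = vector("list", d), dec_cols = vector("list", d),
    dec_pre = vector("list", d), up_ch = vector("list", d)
  )
  conv <- function(cur, w, b) {
    if (want_cache) cpp_conv3_fwd_ws(cur, w, b) else list(y = cpp_conv3_fwd(cur, w, b))
  }
  cur <- as_cube(x)
  for (i in seq_len(d)) {
    cache$enc_ch[[i]] <- dim(cur)[3]
    cv <- conv(cur, p[[paste0("w_enc", i)]], p[[paste0("b_enc", i)]])
    act <- pmax(cv$y, 0)
    pl <- cpp_maxpool2_fwd(act)
    cache$enc_cols[[i]] <- cv$cols
    cache$enc_pre[[i]] <- cv$y
    cache$enc_act[[i]] <- act
    cache$pool_idx[[i]] <- pl$idx
    cur <- pl$y
  }
  cache$bott_ch <- dim(cur)[3]
  cv <- conv(cur, p$w_bott, p$b_bott)
  cache$bott_cols <- cv$cols
  cache$bott_pre <- cv$y
  cur <- pmax(cv$y, 0)
  for (i in rev(seq_len(d))) {
    up <- cpp_upsample2_fwd(cur)
    cache$up_ch[[i]] <- dim(up)[3]
    cur <- if (cfg$skip_connections) concat_ch(up, cache$enc_act[[i]]) else up
    cache$dec_ch[[i]] <- dim(cur)[3]
    cv <- conv(cur, p[[paste0("w_dec", i)]], p[[paste0("b_dec", i)]])
    cache$dec_cols[[i]] <- cv$cols
    cache$dec_pre[[i]] <- cv$y
    cur <- pmax(cv$y, 0)
  }
  cache$out_in <- cur
  h <- dim(cur)[1]
  w <- dim(cur)[2]
  logits <- matrix(p$b_out, h, w)
  for (ch in seq_len(dim(cur)[3])) {
    logits <- logits + cur[, , ch] * p$w_out[ch, 1]
  }
  prob <- 1 / (1 + exp(-logits))
  list(prob = prob, logits = logits, cache = if (want_cache) cache else NULL)
}

# Backward pass; `dlogits` is dLoss/dlogits. Returns gradients named like
# the parameters. Mirrors segnet_forward exactly, in reverse.
segnet_backward <- function(model, cache, dlogits) {
  cfg <- model$cfg
  p <- model$params
  d <- cfg$depth
  grads <- list()

  # final 1x1 conv
  out_in <- cache$out_in
  n_ch <- dim(out_in)[3]
  gw_out <- matrix(0, n_ch, 1)
  gcur <- array(0, dim = dim(out_in))
  for (ch in seq_len(n_ch)) {
    gw_out[ch, 1] <- sum(dlogits * out_in[, , ch])
    gcur[, , ch] <- dlogits * p$w_out[ch, 1]
  }
  grads$w_out <- gw_out
  grads$b_out <- sum(dlogits)

  # decoder stages, shallowest (i = 1) back to deepest (i = d)
  skip_grad <- vector("list", d)
  for (i in seq_len(d)) {
    gpre <- gcur * (cache$dec_pre[[i]] > 0)
    bw <- cpp_conv3_bwd_ws(
      cache$dec_cols[[i]], p[[paste0("w_dec", i)]], gpre, cache$dec_ch[[i]]
    )
    grads[[paste0("w_dec", i)]] <- bw$gw
    grads[[paste0("b_dec", i)]] <- as.numeric(bw$gb)
    k <- cache$up_ch[[i]]
    gup <- bw$gx[, , seq_len(k), drop = FALSE]
    if (cfg$skip_connections) {
      skip_grad[[i]] <- bw$gx[, , -seq_len(k), drop = FALSE]
    }
    gcur <- cpp_upsample2_bwd(gup)
  }

  # bottleneck
  gpre <- gcur * (cache$bott_pre > 0)
  bw <- cpp_conv3_bwd_ws(cache$bott_cols, p$w_bott, gpre, cache$bott_ch)
  grads$w_bott <- bw$gw
  grads$b_bott <- as.numeric(bw$gb)
  gcur <- bw$gx

  # encoder stages, deepest back to first; gcur is the gradient at the
  # pooled output of stage i; the first stage's input gradient is unused
  for (i in rev(seq_len(d))) {
    act_dim <- dim(cache$enc_act[[i]])
    gact <- cpp_maxpool2_bwd(gcur, cache$pool_idx[[i]], act_dim[1], act_dim[2])
    if (cfg$skip_connections && !is.null(skip_grad[[i]])) {
      gact <- gact + skip_grad[[i]]
    }
    gpre <- gact * (cache$enc_pre[[i]] > 0)
    bw <- cpp_conv3_bwd_ws(
      cache$enc_cols[[i]], p[[paste0("w_enc", i)]], gpre, cache$enc_ch[[i]],
      need_gx = i > 1L
    )
    grads[[paste0("w_enc", i)]] <- bw$gw
    grads[[paste0("b_enc", i)]] <- as.numeric(bw$gb)
    if (i > 1L) gcur <- bw$gx
  }
  grads
}

bce_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

crop_center <- function(image, sz) {
  d <- dim(image)
  if (d[1] < sz || d[2] < sz) {
    abort(sprintf("Input %dx%d is smaller than the network size %d.", d[1], d[2], sz))
  }
  if (d[1] > sz || d[2] > sz) {
    r0 <- floor((d[1] - sz) / 2)
    c0 <- floor((d[2] - sz) / 2)
    image <- image[r0 + seq_len(sz), c0 + seq_len(sz)]
  }
  image
}

# Crop to the network size and map gray units to a zero-centred range; the
# centring matters because NIR frames are dominated by the bright skin
# background and an uncentred input slows the short training schedule.
prep_image <- function(image, cfg) {
  crop_center(image, cfg$input_size) / cfg$normalize - 0.5
}

#' Train the segmentation network on image/mask pairs
#'
#' Minibatch gradient descent (Adam) on the mean per-pixel binary
#' cross-entropy. The per-epoch loss reported in the history is the mean of
#' the batch losses evaluated before each update. All randomness (batch
#' shuffling) is drawn from the configuration seed, so training twice from
#' the same built model gives identical histories and weights.
#'
#' @param model A [build_segnet()] network.
#' @param images List of grayscale matrices (gray units, e.g. 0-255); larger
#'   images are center-cropped to the network size.
#' @param masks List of binary matrices (0/1 or logical), same count and,
#'   after cropping, same size.
#' @param epochs,batch_size,learning_rate Optional overrides of the
#'   configuration values.
#' @return A list with `model` (trained) and `history` (tibble: `epoch`,
#'   `loss`).
#' @export
train_segnet <- function(model, images, masks,
                         epochs = NULL, batch_size = NULL,
                         learning_rate = NULL) {
  stopifnot(inherits(model, "segnet"))
  cfg <- model$cfg
  if (length(images) == 0L) abort("Empty training set.")
  if (length(images) < 4L) abort("Need at least 4 image/mask pairs.")
  if (length(images) != length(masks)) abort("images/masks counts differ.")
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  lr <- learning_rate %||% cfg$learning_rate
  xs <- purrr::map(images, prep_image, cfg = cfg)
  ys <- purrr::map(masks, function(m) (crop_center(m, cfg$input_size) > 0.5) * 1)
  for (i in seq_along(xs)) {
    if (!all(dim(xs[[i]]) == dim(ys[[i]]))) abort("Image/mask shape mismatch.")
  }
  p <- model$params
  mom <- purrr::map(p, function(w) w * 0)
  vel <- purrr::map(p, function(w) w * 0)
  beta1 <- 0.9
  beta2 <- 0.999
  eps <- 1e-8
  step <- 0
  n <- length(xs)
  history <- numeric(epochs)
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      batch_losses <- c()
      for (b0 in seq(1, n, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1L, n)]
        gsum <- NULL
        loss <- 0
        for (j in idx) {
          fw <- segnet_forward(list(cfg = cfg, params = p), xs[[j]], want_cache = TRUE)
          loss <- loss + bce_loss(fw$prob, ys[[j]])
          dlog <- (fw$prob - ys[[j]]) / length(ys[[j]])
          g <- segnet_backward(list(cfg = cfg, params = p), fw$cache, dlog)
          gsum <- if (is.null(gsum)) g else purrr::map2(gsum, g[names(gsum)], `+`)
        }
        gsum <- purrr::map(gsum, function(g) g / length(idx))
        loss <- loss / length(idx)
        batch_losses <- c(batch_losses, loss)
        step <- step + 1
        for (nm in names(p)) {
          g <- gsum[[nm]]
          mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * g
          vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * g^2
          mhat <- mom[[nm]] / (1 - beta1^step)
          vhat <- vel[[nm]] / (1 - beta2^step)
          p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      history[ep] <- mean(batch_losses)
    }
  })
  model$params <- p
  model$trained <- TRUE
  list(model = model, history = tibble::tibble(epoch = seq_len(epochs), loss = history))
}

#' Predict a vein-segmentation mask
#'
#' Runs the network forward and thresholds the probability map. Inputs
#' larger than the network size are center-cropped (tiling is not
#' implemented); smaller inputs error.
#'
#' @param model A `segnet`.
#' @param image Grayscale matrix in gray units.
#' @param threshold Probability cutoff; the binary mask is
#'   `prob >= threshold`. Defaults to the configuration threshold.
#' @param image_id Optional identifier carried into the result.
#' @return An object of class `mask_prediction`: list with `prob` (matrix in
#'   `[0, 1]`), `mask` (integer 0/1 matrix), `threshold`, `image_id`.
#' @export
predict_mask <- function(model, image, threshold = NULL, image_id = NA_character_) {
  stopifnot(inherits(model, "segnet"))
  threshold <- threshold %||% model$cfg$threshold
  x <- prep_image(image, model$cfg)
  fw <- segnet_forward(model, x)
  structure(
    list(
      prob = fw$prob, mask = (fw$prob >= threshold) * 1L,
      threshold = threshold, image_id = image_id
    ),
    class = "mask_prediction"
  )
}

#' @export
print.mask_prediction <- function(x, ...) {
  cat(sprintf(
    "<mask_prediction> %dx%d, %.1f%% vessel at threshold %.2f\n",
    nrow(x$mask), ncol(x$mask), 100 * mean(x$mask), x$threshold
  ))
  invisible(x)
}

#' Turn a mask prediction into a measurable NIR-like image
#'
#' The calliper measures intensity dips, so the probability map is rendered
#' as a dark-vessel image: `background * (1 - prob)`. On a well-trained
#' network the FWHM of this rendered dip matches the vessel's ground-truth
#' diameter, since the mask is the half-maximum region by construction.
#'
#' @param prediction A [predict_mask()] result.
#' @param background Gray level of the non-vessel background.
#' @return A numeric matrix.
#' @export
masked_image <- function(prediction, background = 255) {
  stopifnot(inherits(prediction, "mask_prediction"))
  background * (1 - prediction$prob)
}

#' Dice overlap between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are empty
#' (perfect agreement on absence).
#'
#' @param mask_a,mask_b Binary matrices (0/1 or logical) of equal shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) abort("Mask shapes differ.")
  a <- mask_a > 0.5
  b <- mask_b > 0.5
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    return(1)
  }
  2 * sum(a & b) / denom
}

#' Read a manual mask from a PNG file
#'
#' Loads a user-supplied manual segmentation mask (PNG, vessel bright,
#' e.g. 0/255) and binarizes it at half intensity.
#'
#' @param path PNG file path.
#' @return Integer 0/1 matrix.
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  (m > 0.5) * 1L
}

#' Save / load network weights
#'
#' Weights and configuration are stored as a plain JSON document so trained
#' networks can be exchanged and versioned as text.
#'
#' @param model A `segnet`.
#' @param path File path (`.json`).
#' @return `save_segnet` returns `path` invisibly; `load_segnet` a `segnet`.
#' @export
save_segnet <- function(model, path) {
  stopifnot(inherits(model, "segnet"))
  payload <- list(
    cfg = unclass(model$cfg),
    trained = model$trained,
    params = purrr::map(model$params, function(w) {
      if (is.matrix(w)) list(dim = dim(w), values = as.numeric(w)) else list(dim = NULL, values = as.numeric(w))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_segnet
#' @export
load_segnet <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(segnet_config, payload$cfg[c(
    "input_size", "depth", "base_filters", "epochs", "batch_size",
    "learning_rate", "skip_connections", "threshold", "normalize", "seed"
  )])
  params <- purrr::map(payload$params, function(w) {
    if (!is.null(w$dim) && length(w$dim) == 2L) {
      matrix(w$values, w$dim[1], w$dim[2])
    } else if (length(w$values) == 1L) {
      w$values
    } else {
      as.numeric(w$values)
    }
  })
  structure(list(cfg = cfg, params = params, trained = isTRUE(payload$trained)),
    class = "segnet"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
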