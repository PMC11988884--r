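# Vision Transformer backbone: a deterministic forward pass mapping a square
# image to a fixed-length feature vector. The geometry follows ViT-B/16 at
# default scale (224 px image, 16 px patches, 197 tokens of width 768, 12
# pre-norm encoder blocks) and is configurable down to toy scale.

#' Configuration for the Vision Transformer backbone
#'
#' Defaults reproduce the ViT-B/16 geometry: 224 x 224 input, 16 x 16
#' patches (so 196 patch tokens plus one class token = 197), 768-wide tokens,
#' 12 encoder blocks of 12 attention heads, a 4x GELU MLP, and a 1000-wide
#' feature head. The encoder's class-token representation (width `embed_dim`)
#' passes through a final linear head of width `feature_dim`; this is the
#' feature vector handed to the ELM classifier.
#'
#' @param image_size Image side length in pixels after preprocessing.
#' @param patch_size Patch side length in pixels; must divide `image_size`.
#' @param channels Number of image channels (greyscale inputs are replicated).
#' @param embed_dim Token width; must be divisible by `n_heads`.
#' @param depth Number of encoder blocks.
#' @param n_heads Attention heads per block.
#' @param mlp_ratio Hidden/embed width ratio of the block MLP.
#' @param feature_dim Length of the output feature vector.
#' @param dropout_rate Dropout probability in `[0, 1)`; 0 at inference.
#' @param norm_mean,norm_sd Per-pixel normalisation constants applied to the
#'   `[0, 1]`-scaled image at the start of the forward pass.
#' @param seed Default seed for [init_backbone()].
#' @return A `backbone_config` list; `$n_tokens` is
#'   `(image_size / patch_size)^2 + 1`.
#' @examples
#' cfg <- backbone_config()
#' cfg$n_tokens # 197
#' @export
backbone_config <- function(image_size = 224L, patch_size = 16L, channels = 3L,
                            embed_dim = 768L, depth = 12L, n_heads = 12L,
                            mlp_ratio = 4, feature_dim = 1000L,
                            dropout_rate = 0, norm_mean = 0.5, norm_sd = 0.5,
                            seed = NULL) {
  for (nm in c("image_size", "patch_size", "channels", "embed_dim", "depth",
               "n_heads", "feature_dim")) {
    if (!is_count(get(nm))) {
      abort_vitelm(paste0("`", nm, "` must be a positive integer"),
                   "invalid_config")
    }
  }
  if (image_size %% patch_size != 0) {
    abort_vitelm("`image_size` must be divisible by `patch_size`",
                 "invalid_config")
  }
  if (embed_dim %% n_heads != 0) {
    abort_vitelm("`embed_dim` must be divisible by `n_heads`",
                 "invalid_config")
  }
  if (mlp_ratio <= 0) abort_vitelm("`mlp_ratio` must be positive", "invalid_config")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort_vitelm("`dropout_rate` must be in [0, 1)", "invalid_config")
  }
  structure(
    list(
      image_size = as.integer(image_size), patch_size = as.integer(patch_size),
      channels = as.integer(channels), embed_dim = as.integer(embed_dim),
      depth = as.integer(depth), n_heads = as.integer(n_heads),
      mlp_ratio = mlp_ratio, feature_dim = as.integer(feature_dim),
      dropout_rate = dropout_rate, norm_mean = norm_mean, norm_sd = norm_sd,
      n_tokens = as.integer((image_size %/% patch_size)^2 + 1L),
      seed = seed
    ),
    class = "backbone_config"
  )
}

#' @export
print.backbone_config <- function(x, ...) {
  cat(sprintf(
    "<backbone_config> %dpx/%dpx patches, %d tokens x %d, depth %d, %d heads, %d features\n",
    x$image_size, x$patch_size, x$n_tokens, x$embed_dim, x$depth, x$n_heads,
    x$feature_dim
  ))
  invisible(x)
}

#' Randomly initialised backbone weights
#'
#' Samples every weight array from a small-variance Gaussian (sd = 0.02,
#' biases and LayerNorm offsets zero, LayerNorm scales one), reproducibly
#' from `seed`. This produces an untrained backbone: a fixed random feature
#' extractor adequate for desk-scale experiments; pretrained weights can be
#' substituted via [load_pretrained_checkpoint()].
#'
#' @param config A [backbone_config()].
#' @param seed Integer seed; defaults to `config$seed`, then 1.
#' @return A `backbone_weights` list holding the patch projection, class
#'   token, position embeddings, per-block attention/MLP/LayerNorm
#'   parameters, the final LayerNorm and the feature head. The generating
#'   config is attached as `$config`.
#' @export
init_backbone <- function(config, seed = NULL) {
  if (!inherits(config, "backbone_config")) {
    abort_vitelm("`config` must be a backbone_config", "invalid_config")
  }
  seed <- seed %||% config$seed %||% 1L
  d <- config$embed_dim
  p_dim <- config$patch_size^2 * config$channels
  hid <- as.integer(round(d * config$mlp_ratio))
  g <- function(n_row, n_col) matrix(rnorm(n_row * n_col, sd = 0.02), n_row, n_col)
  with_opt_seed(seed, {
    blocks <- lapply(seq_len(config$depth), function(i) {
      list(
        ln1_scale = rep(1, d), ln1_offset = rep(0, d),
        wq = g(d, d), bq = rep(0, d),
        wk = g(d, d), bk = rep(0, d),
        wv = g(d, d), bv = rep(0, d),
        wo = g(d, d), bo = rep(0, d),
        ln2_scale = rep(1, d), ln2_offset = rep(0, d),
        w1 = g(d, hid), b1 = rep(0, hid),
        w2 = g(hid, d), b2 = rep(0, d)
      )
    })
    structure(
      list(
        patch_proj = g(p_dim, d), patch_bias = rep(0, d),
        cls_token = rnorm(d, sd = 0.02),
        pos_embed = g(config$n_tokens, d),
        blocks = blocks,
        ln_f_scale = rep(1, d), ln_f_offset = rep(0, d),
        head_w = g(d, config$feature_dim), head_b = rep(0, config$feature_dim),
        config = config, seed = as.integer(seed)
      ),
      class = "backbone_weights"
    )
  })
}

#' @export
print.backbone_weights <- function(x, ...) {
  cat(sprintf("<backbone_weights> seed %d; ", x$seed))
  print(x$config)
  invisible(x)
}

#' A single labelled image sample
#'
#' The unit flowing through the pipeline: a square pixel array in `[0, 1]`
#' with an optional class label and patient identifier.
#'
#' @param pixels Numeric array, `side x side` or `side x side x channels`,
#'   values in `[0, 1]`.
#' @param label `"pes_planus"`, `"not_pes_planus"`, or `NA` if unlabelled.
#' @param patient_id Opaque identifier used for grouped data splits.
#' @return An `image_sample` list.
#' @export
image_sample <- function(pixels, label = NA_character_,
                         patient_id = NA_character_) {
  if (!is.numeric(pixels) || length(dim(pixels) %||% 0) < 2) {
    abort_vitelm("`pixels` must be a numeric matrix or array", "invalid_input")
  }
  d <- dim(pixels)
  if (d[1] != d[2]) abort_vitelm("image must be square", "invalid_input")
  rng <- range(pixels)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    abort_vitelm("pixel values must lie in [0, 1]", "invalid_input")
  }
  structure(list(pixels = pixels, label = label, patient_id = patient_id),
            class = "image_sample")
}

sample_pixels <- function(x) {
  if (inherits(x, "image_sample")) x$pixels else x
}

#' Preprocess a raw image for the backbone
#'
#' Scales pixel values to `[0, 1]` (inputs with a maximum above 1 are assumed
#' 8-bit and divided by 255), bilinearly resizes to
#' `config$image_size` square, and replicates single-channel input across
#' `config$channels`.
#'
#' @param image Numeric matrix (greyscale) or `h x w x c` array with 1 or 3
#'   channels.
#' @inheritParams image_sample
#' @param config A [backbone_config()].
#' @return An [image_sample()] of size
#'   `image_size x image_size x channels` with values in `[0, 1]`.
#' @export
preprocess <- function(image, config = backbone_config(),
                       label = NA_character_, patient_id = NA_character_) {
  if (!is.numeric(image) || length(image) == 0) {
    abort_vitelm("image must be a nonempty numeric array", "invalid_input")
  }
  d <- dim(image) %||% integer()
  if (length(d) == 2) dim(image) <- d <- c(d, 1L)
  if (length(d) != 3 || any(d[1:2] == 0)) {
    abort_vitelm("image must have positive height and width", "invalid_input")
  }
  if (!d[3] %in% c(1L, 3L)) {
    abort_vitelm("image must have 1 or 3 channels", "invalid_input")
  }
  if (max(image) > 1) image <- image / 255
  image <- pmin(pmax(image, 0), 1)
  s <- config$image_size
  if (d[1] != s || d[2] != s) {
    # EBImage indexes (x, y): transpose in and out so our row/col convention
    # survives the resize.
    resized <- vapply(seq_len(d[3]), function(ch) {
      t(EBImage::imageData(EBImage::resize(EBImage::Image(t(image[, , ch])),
                                           w = s, h = s)))
    }, matrix(0, s, s))
    image <- resized
  }
  if (dim(image)[3] == 1L && config$channels == 3L) {
    image <- array(rep(image, 3L), dim = c(s, s, 3L))
  }
  if (dim(image)[3] != config$channels) {
    abort_vitelm("channel count incompatible with config", "invalid_input")
  }
  image <- pmin(pmax(image, 0), 1)
  image_sample(image, label = label, patient_id = patient_id)
}

#' Split an image into flattened patch vectors
#'
#' Non-overlapping `patch_size x patch_size` patches ordered row-major from
#' the top-left. Each patch is flattened column-major over
#' (row, column, channel), so concatenating the patch vectors loses no pixel.
#'
#' @param sample An [image_sample()] or a numeric pixel array.
#' @param patch_size Patch side length; must divide the image side.
#' @return A `(side / patch_size)^2 x (patch_size^2 * channels)` matrix,
#'   one patch per row.
#' @export
patchify <- function(sample, patch_size) {
  px <- sample_pixels(sample)
  d <- dim(px)
  if (length(d) == 2) dim(px) <- d <- c(d, 1L)
  side <- d[1]
  if (side %% patch_size != 0) {
    abort_vitelm("image side must be divisible by `patch_size`",
                 "invalid_config")
  }
  n_side <- side %/% patch_size
  out <- matrix(0, n_side^2, patch_size^2 * d[3])
  i <- 0L
  for (r in seq_len(n_side)) {
    rows <- ((r - 1L) * patch_size + 1L):(r * patch_size)
    for (cc in seq_len(n_side)) {
      cols <- ((cc - 1L) * patch_size + 1L):(cc * patch_size)
      i <- i + 1L
      out[i, ] <- as.vector(px[rows, cols, , drop = FALSE])
    }
  }
  out
}

#' Embed patches into the token sequence
#'
#' Token 1 is the class token plus its position embedding; token `i + 1` is
#' the linear projection of patch `i` (plus projection bias) plus position
#' embedding `i + 1`.
#'
#' @param patches Matrix of flattened patches, one per row (see [patchify()]).
#' @param weights A `backbone_weights` object.
#' @return An `n_tokens x embed_dim` token matrix.
#' @export
embed_tokens <- function(patches, weights) {
  if (nrow(patches) + 1L != nrow(weights$pos_embed) ||
      ncol(patches) != nrow(weights$patch_proj)) {
    abort_vitelm("patch shape incompatible with weights", "invalid_weights")
  }
  proj <- sweep(patches %*% weights$patch_proj, 2L, weights$patch_bias, "+")
  rbind(weights$cls_token, proj) + weights$pos_embed
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V` where `d_k` is the key width; every softmax
#' row sums to one.
#'
#' @param queries,keys,values Real matrices; `queries` and `keys` share a
#'   column count, `keys` and `values` a row count.
#' @return A `nrow(queries) x ncol(values)` matrix.
#' @export
scaled_attention <- function(queries, keys, values) {
  if (length(queries) == 0 || length(keys) == 0 || length(values) == 0) {
    abort_vitelm("attention inputs must be nonempty", "invalid_input")
  }
  if (ncol(queries) != ncol(keys)) {
    abort_vitelm("queries and keys must share column count", "invalid_input")
  }
  if (nrow(keys) != nrow(values)) {
    abort_vitelm("keys and values must share row count", "invalid_input")
  }
  scores <- queries %*% t(keys) / sqrt(ncol(keys))
  softmax_rows(scores) %*% values
}

multi_head_attention <- function(x, blk, n_heads) {
  d <- ncol(x)
  hd <- d %/% n_heads
  q <- sweep(x %*% blk$wq, 2L, blk$bq, "+")
  k <- sweep(x %*% blk$wk, 2L, blk$bk, "+")
  v <- sweep(x %*% blk$wv, 2L, blk$bv, "+")
  heads <- lapply(seq_len(n_heads), function(h) {
    cols <- ((h - 1L) * hd + 1L):(h * hd)
    scaled_attention(q[, cols, drop = FALSE], k[, cols, drop = FALSE],
                     v[, cols, drop = FALSE])
  })
  sweep(do.call(cbind, heads) %*% blk$wo, 2L, blk$bo, "+")
}

maybe_dropout <- function(x, rate, train) {
  if (!train || rate <= 0) return(x)
  mask <- matrix(runif(length(x)) >= rate, nrow(x), ncol(x))
  x * mask / (1 - rate)
}

#' One pre-norm Transformer encoder block
#'
#' `x + MHA(LN1(x))` followed by `y + MLP_GELU(LN2(y))`; token-matrix shape
#' is preserved. With all attention and MLP weights zero the block is the
#' identity map.
#'
#' @param tokens Token matrix (`n_tokens x embed_dim`).
#' @param blk One element of `backbone_weights$blocks`.
#' @param n_heads Attention heads.
#' @param dropout_rate,train Dropout applied to both residual branches when
#'   `train = TRUE`.
#' @return Token matrix of the same shape.
#' @export
encoder_block <- function(tokens, blk, n_heads, dropout_rate = 0,
                          train = FALSE) {
  if (anyNA(tokens) || any(!is.finite(tokens))) {
    abort_vitelm("non-finite values in token matrix", "numeric_error")
  }
  a <- multi_head_attention(layer_norm(tokens, blk$ln1_scale, blk$ln1_offset),
                            blk, n_heads)
  h <- tokens + maybe_dropout(a, dropout_rate, train)
  z <- layer_norm(h, blk$ln2_scale, blk$ln2_offset)
  z <- sweep(gelu(sweep(z %*% blk$w1, 2L, blk$b1, "+")) %*% blk$w2,
             2L, blk$b2, "+")
  h + maybe_dropout(z, dropout_rate, train)
}

#' Full backbone forward pass
#'
#' Normalise pixels, patchify, embed with position information, run every
#' encoder block, apply the final LayerNorm, take the class-token row, and
#' project it through the feature head. Deterministic given `weights`
#' (dropout is only active with `train = TRUE`).
#'
#' @param sample A preprocessed [image_sample()] (or bare pixel array) of
#'   side `config$image_size`.
#' @param weights A `backbone_weights` object.
#' @param config Backbone configuration; defaults to the one stored in
#'   `weights`.
#' @param train Enable dropout.
#' @return Numeric feature vector of length `config$feature_dim`.
#' @export
forward_features <- function(sample, weights, config = weights$config,
                             train = FALSE) {
  px <- sample_pixels(sample)
  d <- dim(px)
  if (length(d) == 2) dim(px) <- d <- c(d, 1L)
  if (d[1] != config$image_size || d[2] != config$image_size) {
    abort_vitelm("sample size does not match config; run preprocess() first",
                 "invalid_input")
  }
  if (nrow(weights$pos_embed) != config$n_tokens ||
      ncol(weights$pos_embed) != config$embed_dim ||
      length(weights$blocks) != config$depth ||
      ncol(weights$head_w) != config$feature_dim) {
    abort_vitelm("weights incompatible with config", "invalid_weights")
  }
  px <- (px - config$norm_mean) / config$norm_sd
  tok <- embed_tokens(patchify(px, config$patch_size), weights)
  for (blk in weights$blocks) {
    tok <- encoder_block(tok, blk, config$n_heads,
                         dropout_rate = config$dropout_rate, train = train)
  }
  tok <- layer_norm(tok, weights$ln_f_scale, weights$ln_f_offset)
  cls <- tok[1L, , drop = FALSE]
  as.numeric(cls %*% weights$head_w + weights$head_b)
}

#' Extract backbone features for a dataset
#'
#' Runs [forward_features()] over every image in a dataset tibble and returns
#' a tidy feature table suitable for [oelm()] and [run_crossval()].
#'
#' @param data Tibble with a `pixels` list-column (as produced by
#'   [gen_dataset()] or [read_image_dataset()]) and optionally `label`,
#'   `patient_id`, `image_id` columns, which are carried through.
#' @param weights A `backbone_weights` object.
#' @param config Backbone configuration; defaults to `weights$config`.
#' @return Tibble with feature columns `f1 ... f<feature_dim>` followed by
#'   the carried metadata columns.
#' @export
extract_features <- function(data, weights, config = weights$config) {
  if (!"pixels" %in% names(data)) {
    abort_vitelm("`data` must contain a `pixels` list-column", "invalid_input")
  }
  feats <- vapply(data$pixels, function(px) {
    forward_features(px, weights, config)
  }, numeric(config$feature_dim))
  feats <- t(matrix(feats, nrow = config$feature_dim))
  colnames(feats) <- paste0("f", seq_len(config$feature_dim))
  meta <- intersect(c("image_id", "patient_id", "label", "angle"), names(data))
  bind_cols(as_tibble(feats), data[meta])
}
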