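# Dataset and model input/output. The on-disk dataset layout is one
# directory per class of PNG/JPG images named `<patientID>_<index>.<ext>`,
# optionally accompanied by a `manifest.csv` (path, patient_id, label,
# angle). Models are stored in a versioned, checksummed archive.

MODEL_FORMAT <- "vitelm-model"
MODEL_VERSION <- 1L

#' Write an image dataset to disk
#'
#' Creates one subdirectory per class under `root`, writes each image as
#' `<image_id>.png`, and a `manifest.csv` mapping paths to patient ids,
#' labels and (if present) generating angles.
#'
#' @param data Dataset tibble with `pixels`, `image_id`, `patient_id`,
#'   `label` columns (as from [gen_dataset()]).
#' @param root Output directory (created if needed).
#' @return `root`, invisibly.
#' @export
write_image_dataset <- function(data, root) {
  for (cl in unique(data$label)) {
    dir.create(file.path(root, cl), recursive = TRUE, showWarnings = FALSE)
  }
  rel <- file.path(data$label, paste0(data$image_id, ".png"))
  for (i in seq_len(nrow(data))) {
    png::writePNG(data$pixels[[i]], file.path(root, rel[i]))
  }
  manifest <- tibble(path = rel, patient_id = data$patient_id,
                     label = data$label)
  if ("angle" %in% names(data)) manifest$angle <- data$angle
  readr::write_csv(manifest, file.path(root, "manifest.csv"))
  invisible(root)
}

decode_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
  } else {
    # EBImage indexes (x, y): permute back to row/col(/channel).
    img <- EBImage::imageData(EBImage::readImage(path))
    px <- if (length(dim(img)) == 2L) t(img) else aperm(img, c(2L, 1L, 3L))
  }
  px
}

#' Read a class-per-directory image dataset
#'
#' Every decodable JPG/PNG under a class subdirectory becomes one sample;
#' the label is the directory name. Patient ids come from `manifest.csv`
#' when present, otherwise from the `<patientID>_<index>` filename pattern,
#' falling back to one patient per file with a warning. Undecodable files
#' are skipped with a warning.
#'
#' @param root Dataset root containing one subdirectory per class.
#' @return Tibble with `patient_id`, `image_id`, `label`, `path`, a `pixels`
#'   list-column, and `angle` when the manifest provides it.
#' @export
read_image_dataset <- function(root) {
  if (!dir.exists(root)) abort_vitelm("dataset root not found", "invalid_dataset")
  class_dirs <- list.dirs(root, recursive = FALSE)
  if (length(class_dirs) == 0) {
    abort_vitelm("no class directories under dataset root", "invalid_dataset")
  }
  manifest <- NULL
  mpath <- file.path(root, "manifest.csv")
  if (file.exists(mpath)) {
    manifest <- readr::read_csv(mpath, show_col_types = FALSE)
  }
  rows <- list()
  for (cd in class_dirs) {
    files <- list.files(cd, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                        full.names = TRUE)
    for (fp in files) {
      px <- tryCatch(decode_image(fp), error = function(e) {
        warn(paste0("skipping undecodable file: ", fp))
        NULL
      })
      if (is.null(px)) next
      stem <- tools::file_path_sans_ext(basename(fp))
      rel <- file.path(basename(cd), basename(fp))
      pid <- NA_character_; angle <- NA_real_
      if (!is.null(manifest) && rel %in% manifest$path) {
        m <- manifest[match(rel, manifest$path), ]
        pid <- as.character(m$patient_id)
        if ("angle" %in% names(m)) angle <- m$angle
      } else if (grepl("^(.+)_[0-9]+$", stem)) {
        pid <- sub("^(.+)_[0-9]+$", "\\1", stem)
      } else {
        warn(paste0("no patient id pattern in `", stem,
                    "`; using one patient per file"))
        pid <- stem
      }
      rows[[length(rows) + 1L]] <- tibble(
        patient_id = pid, image_id = stem, label = basename(cd),
        path = rel, angle = angle, pixels = list(px)
      )
    }
  }
  if (length(rows) == 0) {
    abort_vitelm("no decodable images under dataset root", "invalid_dataset")
  }
  out <- list_rbind(rows)
  if (all(is.na(out$angle))) out$angle <- NULL
  arrange(out, .data$image_id)
}

#' Write / read a feature table
#'
#' CSV round-trip for extracted feature tables (`f1 ... fd` + metadata
#' columns).
#'
#' @param data Feature tibble.
#' @param path CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the tibble.
#' @export
write_feature_table <- function(data, path) {
  data <- select(data, -dplyr::any_of("pixels"))
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Save / load a model bundle
#'
#' The archive is a versioned envelope around a deterministic serialisation
#' of the bundle (hidden layer, output weights, class order, configs, and
#' optionally backbone weights), protected by an MD5 checksum. Two saves of
#' the same model produce byte-identical archives; loading verifies the
#' format tag, version, and checksum.
#'
#' @param model Any model bundle (e.g. an `oelm_fit`, or a list with
#'   `fit` and `backbone` elements).
#' @param path Archive path.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the bundle.
#' @export
save_model <- function(model, path) {
  payload <- serialize(model, NULL, xdr = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeBin(payload, tmp)
  md5 <- unname(tools::md5sum(tmp))
  saveRDS(list(format = MODEL_FORMAT, version = MODEL_VERSION,
               md5 = md5, payload = payload),
          path, version = 3L)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    abort_vitelm(paste0("cannot read model archive: ", conditionMessage(e)),
                 "checksum_error")
  })
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT)) {
    abort_vitelm("not a vitelm model archive", "checksum_error")
  }
  if (!identical(obj$version, MODEL_VERSION)) {
    abort_vitelm(sprintf("unsupported model archive version %s",
                         as.character(obj$version)),
                 "unsupported_version")
  }
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeBin(obj$payload, tmp)
  if (!identical(unname(tools::md5sum(tmp)), obj$md5)) {
    abort_vitelm("model archive checksum mismatch", "checksum_error")
  }
  unserialize(obj$payload)
}

#' Import backbone weights from a flat named-array checkpoint
#'
#' Reads an RDS file holding a flat named list of arrays that follows the
#' naming convention of the common pretrained ViT-B/16 release
#' (`vit-base-patch16-224`) and maps it onto a `backbone_weights` object:
#'
#' * `cls_token` `(D)` or `(1, 1, D)`; `pos_embed` `(T, D)` or `(1, T, D)`
#' * `patch_embed.proj.weight` `(D, C, p, p)` conv kernel and `.bias` `(D)`
#' * per block `i` (0-based): `blocks.i.norm1.weight/.bias`,
#'   `blocks.i.attn.qkv.weight` `(3D, D)` and `.bias` `(3D)`,
#'   `blocks.i.attn.proj.weight/.bias`, `blocks.i.norm2.weight/.bias`,
#'   `blocks.i.mlp.fc1.weight` `(H, D)` / `.bias`,
#'   `blocks.i.mlp.fc2.weight` `(D, H)` / `.bias`
#' * `norm.weight/.bias`; `head.weight` `(K, D)` / `head.bias` `(K)`
#'
#' Linear weights use the `(out, in)` convention and are transposed; the
#' conv kernel is flattened to match [patchify()]'s (row, column, channel)
#' patch order.
#'
#' @param path RDS file containing the named list.
#' @param config A [backbone_config()] the arrays must match.
#' @return A `backbone_weights` object.
#' @export
load_pretrained_checkpoint <- function(path, config = backbone_config()) {
  arrs <- readRDS(path)
  if (!is.list(arrs) || is.null(names(arrs))) {
    abort_vitelm("checkpoint must be a named list of arrays", "invalid_weights")
  }
  get_arr <- function(nm) {
    if (!nm %in% names(arrs)) {
      abort_vitelm(paste0("checkpoint missing array `", nm, "`"),
                   "invalid_weights")
    }
    arrs[[nm]]
  }
  d <- config$embed_dim
  p <- config$patch_size
  squeeze <- function(a) {
    dm <- dim(a) %||% length(a)
    array(a, dim = dm[dm > 1L])
  }
  cls <- as.numeric(squeeze(get_arr("cls_token")))
  pos <- squeeze(get_arr("pos_embed"))
  if (length(cls) != d || !all(dim(pos) == c(config$n_tokens, d))) {
    abort_vitelm("checkpoint geometry does not match config", "invalid_weights")
  }
  conv <- get_arr("patch_embed.proj.weight") # (D, C, p, p)
  patch_proj <- aperm(conv, c(3L, 4L, 2L, 1L)) # (p_row, p_col, C, D)
  dim(patch_proj) <- c(p * p * config$channels, d)
  blocks <- lapply(seq_len(config$depth) - 1L, function(i) {
    pre <- paste0("blocks.", i, ".")
    qkv_w <- get_arr(paste0(pre, "attn.qkv.weight")) # (3D, D)
    qkv_b <- as.numeric(get_arr(paste0(pre, "attn.qkv.bias")))
    list(
      ln1_scale = as.numeric(get_arr(paste0(pre, "norm1.weight"))),
      ln1_offset = as.numeric(get_arr(paste0(pre, "norm1.bias"))),
      wq = t(qkv_w[1:d, , drop = FALSE]), bq = qkv_b[1:d],
      wk = t(qkv_w[(d + 1):(2 * d), , drop = FALSE]), bk = qkv_b[(d + 1):(2 * d)],
      wv = t(qkv_w[(2 * d + 1):(3 * d), , drop = FALSE]),
      bv = qkv_b[(2 * d + 1):(3 * d)],
      wo = t(get_arr(paste0(pre, "attn.proj.weight"))),
      bo = as.numeric(get_arr(paste0(pre, "attn.proj.bias"))),
      ln2_scale = as.numeric(get_arr(paste0(pre, "norm2.weight"))),
      ln2_offset = as.numeric(get_arr(paste0(pre, "norm2.bias"))),
      w1 = t(get_arr(paste0(pre, "mlp.fc1.weight"))),
      b1 = as.numeric(get_arr(paste0(pre, "mlp.fc1.bias"))),
      w2 = t(get_arr(paste0(pre, "mlp.fc2.weight"))),
      b2 = as.numeric(get_arr(paste0(pre, "mlp.fc2.bias")))
    )
  })
  structure(
    list(patch_proj = patch_proj,
         patch_bias = as.numeric(get_arr("patch_embed.proj.bias")),
         cls_token = cls, pos_embed = pos, blocks = blocks,
         ln_f_scale = as.numeric(get_arr("norm.weight")),
         ln_f_offset = as.numeric(get_arr("norm.bias")),
         head_w = t(get_arr("head.weight")),
         head_b = as.numeric(get_arr("head.bias")),
         config = config, seed = NA_integer_),
    class = "backbone_weights"
  )
}
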