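# Synthetic foot-radiograph generator. Each image is a bright foot-like
# silhouette with a heel-to-midfoot "arch band" inclined at a controllable
# angle; the class label is the arch angle thresholded at 18 degrees,
# emulating the calcaneal-tilt labelling rule for pes planus. Realism is a
# non-goal: the renderer provides controllable difficulty so the full
# pipeline is testable without any image download.

#' Configuration for the synthetic radiograph generator
#'
#' Defaults emulate the study cohort at reduced desk scale: 60 patients with
#' 2 images each (the real dataset averages 2 images per patient), class
#' arch-angle means of 10 degrees (pes planus) and 26 degrees (not pes
#' planus) straddling the 18-degree diagnostic threshold, a 3-degree
#' between-patient angle spread, a 0.5-degree within-patient jitter, and
#' mild Gaussian pixel noise.
#'
#' @param n_patients Number of synthetic patients.
#' @param images_per_patient Images per patient.
#' @param image_size Image side length in pixels.
#' @param angle_threshold Diagnostic threshold in degrees: an arch angle
#'   below it is labelled `pes_planus`.
#' @param class_angle_means Named or length-2 numeric: mean arch angle for
#'   the pes-planus and not-pes-planus classes; they must straddle
#'   `angle_threshold`.
#' @param angle_sd Between-patient angle standard deviation (degrees).
#' @param jitter_sd Within-patient per-image angle jitter (degrees).
#' @param noise_sd Gaussian pixel-noise standard deviation (pixel-value
#'   units; images are clipped back to `[0, 1]`).
#' @param class_balance Fraction of patients drawn from the pes-planus
#'   angle distribution.
#' @param seed Generator seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 60L, images_per_patient = 2L,
                             image_size = 224L, angle_threshold = 18,
                             class_angle_means = c(pes_planus = 10,
                                                   not_pes_planus = 26),
                             angle_sd = 3, jitter_sd = 0.5, noise_sd = 0.05,
                             class_balance = 0.5, seed = NULL) {
  if (!is_count(n_patients) || !is_count(images_per_patient) ||
      !is_count(image_size)) {
    abort_vitelm("counts must be positive integers", "invalid_config")
  }
  if (length(class_angle_means) != 2L) {
    abort_vitelm("`class_angle_means` must have two entries", "invalid_config")
  }
  if (!(min(class_angle_means) < angle_threshold &&
        max(class_angle_means) > angle_threshold)) {
    abort_vitelm("class angle means must straddle `angle_threshold`",
                 "invalid_config")
  }
  if (class_balance <= 0 || class_balance >= 1) {
    abort_vitelm("`class_balance` must be in (0, 1)", "invalid_config")
  }
  if (angle_sd < 0 || jitter_sd < 0 || noise_sd < 0) {
    abort_vitelm("spread parameters must be >= 0", "invalid_config")
  }
  structure(
    list(n_patients = as.integer(n_patients),
         images_per_patient = as.integer(images_per_patient),
         image_size = as.integer(image_size),
         angle_threshold = angle_threshold,
         class_angle_means = c(pes_planus = unname(min(class_angle_means)),
                               not_pes_planus = unname(max(class_angle_means))),
         angle_sd = angle_sd, jitter_sd = jitter_sd, noise_sd = noise_sd,
         class_balance = class_balance, seed = seed),
    class = "synthetic_config"
  )
}

#' Render one synthetic foot radiograph
#'
#' Draws, on a dark background, a bright elongated foot silhouette with a
#' short leg stub, and a brighter heel-to-midfoot band inclined at `angle`
#' degrees above horizontal (the synthetic analogue of the calcaneal line).
#' Gaussian pixel noise is added and the image clipped to `[0, 1]`.
#' Deterministic given `seed`.
#'
#' @param angle Arch-band angle in degrees, strictly inside `(0, 90)`.
#' @param config A [synthetic_config()] (only `image_size` and `noise_sd`
#'   are used).
#' @param seed Noise seed; `NULL` uses the current RNG stream.
#' @return `image_size x image_size` greyscale matrix in `[0, 1]`, rows
#'   indexed top-down.
#' @export
render_foot <- function(angle, config = synthetic_config(), seed = NULL) {
  if (!is.numeric(angle) || length(angle) != 1L || !is.finite(angle) ||
      angle <= 0 || angle >= 90) {
    abort_vitelm("`angle` must lie strictly inside (0, 90) degrees",
                 "invalid_input")
  }
  s <- config$image_size
  # Unit coordinates with y pointing up: row 1 is the top of the image.
  x <- (seq_len(s) - 0.5) / s
  y <- 1 - x
  X <- matrix(x, s, s, byrow = TRUE)
  Y <- matrix(y, s, s)
  img <- matrix(0.08, s, s)
  # Foot sole: elongated ellipse.
  sole <- ((X - 0.52) / 0.40)^2 + ((Y - 0.34) / 0.18)^2 <= 1
  img[sole] <- 0.55
  # Leg stub rising from the heel.
  leg <- X >= 0.14 & X <= 0.28 & Y >= 0.38 & Y <= 0.85
  img[leg] <- 0.45
  # Arch band: from the heel anchor toward the midfoot at `angle` degrees.
  theta <- angle * pi / 180
  hx <- 0.18; hy <- 0.30
  dx <- cos(theta); dy <- sin(theta)
  tpar <- (X - hx) * dx + (Y - hy) * dy     # along-band coordinate
  perp <- -(X - hx) * dy + (Y - hy) * dx    # across-band coordinate
  band <- tpar >= 0 & tpar <= 0.55 & abs(perp) <= 0.022
  img[band] <- 0.95
  if (config$noise_sd > 0) {
    img <- img + with_opt_seed(seed, matrix(rnorm(s * s, sd = config$noise_sd),
                                            s, s))
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a labelled synthetic radiograph dataset
#'
#' Draws one true arch angle per patient (from the class mean chosen by a
#' `class_balance` coin flip, with `angle_sd` spread, clamped to
#' `(1, 89)` degrees); the patient label is `pes_planus` exactly when that
#' angle is below `angle_threshold`. Each of the patient's images renders
#' the angle with a small per-image jitter, so all of a patient's images
#' share one label.
#'
#' @param config A [synthetic_config()].
#' @return Tibble with one row per image: `patient_id`, `image_id`, `label`,
#'   `angle` (patient's true angle), `render_angle` (jittered), and a
#'   `pixels` list-column of greyscale matrices.
#' @export
gen_dataset <- function(config = synthetic_config()) {
  with_opt_seed(config$seed %||% 1L, {
    n <- config$n_patients
    is_pp <- rbinom(n, 1L, config$class_balance) == 1L
    mu <- ifelse(is_pp, config$class_angle_means[["pes_planus"]],
                 config$class_angle_means[["not_pes_planus"]])
    angle <- pmin(pmax(rnorm(n, mu, config$angle_sd), 1), 89)
    label <- ifelse(angle < config$angle_threshold,
                    "pes_planus", "not_pes_planus")
    pid <- sprintf("P%03d", seq_len(n))
    rows <- vector("list", n * config$images_per_patient)
    i <- 0L
    for (p in seq_len(n)) {
      for (j in seq_len(config$images_per_patient)) {
        i <- i + 1L
        ra <- pmin(pmax(angle[p] + rnorm(1L, sd = config$jitter_sd), 1), 89)
        img_seed <- sample.int(2^30, 1L)
        rows[[i]] <- tibble(
          patient_id = pid[p], image_id = paste0(pid[p], "_", j),
          label = label[p], angle = angle[p], render_angle = ra,
          pixels = list(render_foot(ra, config, seed = img_seed))
        )
      }
    }
    list_rbind(rows)
  })
}

#' Generate two Gaussian feature clusters
#'
#' Unit-variance Gaussian features for two exactly balanced classes whose
#' means sit at `+/- separation / 2` along a random unit direction -- the
#' standard unit-test input for the ELM head, emulating extracted image
#' features.
#'
#' @param n Total sample count (even).
#' @param d Feature dimension.
#' @param separation Distance between the class means.
#' @param seed Generator seed.
#' @return Tibble with feature columns `f1 ... f<d>`, `label`, and unique
#'   per-row `patient_id`s.
#' @export
gen_feature_clusters <- function(n, d, separation, seed = NULL) {
  if (!is_count(n) || n %% 2 != 0) abort_vitelm("`n` must be even", "invalid_config")
  if (!is_count(d)) abort_vitelm("`d` must be >= 1", "invalid_config")
  with_opt_seed(seed %||% 1L, {
    u <- rnorm(d)
    u <- u / sqrt(sum(u^2))
    label <- sample(rep(DEFAULT_CLASSES, each = n / 2))
    shift <- ifelse(label == "pes_planus", separation / 2, -separation / 2)
    X <- matrix(rnorm(n * d), n, d) + outer(shift, u)
    colnames(X) <- paste0("f", seq_len(d))
    bind_cols(as_tibble(X),
              tibble(label = label, patient_id = sprintf("S%04d", seq_len(n))))
  })
}
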