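# Extreme Learning Machine head. The hidden layer (W, b) is random and
# frozen; only the output weights beta are fitted, either in closed form
# (Moore-Penrose pseudo-inverse / ridge) or by mini-batch Adam on a softmax
# cross-entropy (or linear-score MSE) objective with L2 regularisation and
# early stopping -- the "optimised ELM" variant.

OELM_SOLVERS <- c("adam", "pinv", "ridge")
OELM_ACTIVATIONS <- c("sigmoid", "tanh", "relu", "gelu")
OELM_LOSSES <- c("cross_entropy", "mse")
DEFAULT_CLASSES <- c("pes_planus", "not_pes_planus")

#' Configuration for the ELM head
#'
#' Training defaults follow the study protocol: mini-batches of 16, learning
#' rate 1e-4, a 250-epoch budget, early stopping with patience 10 on the
#' validation loss, cross-entropy loss.
#'
#' @param L Hidden-layer width. `L = 0` is the no-hidden-layer special case:
#'   the solver acts directly on the input features.
#' @param lambda L2 regularisation weight (>= 0).
#' @param solver `"adam"` (default), `"pinv"`, or `"ridge"`.
#' @param activation Hidden activation: sigmoid, tanh, relu or gelu.
#' @param loss `"cross_entropy"` (softmax cross-entropy, default) or `"mse"`
#'   (squared error of the linear scores against the one-hot targets, the
#'   classical ELM objective).
#' @param batch_size Mini-batch size for the Adam solver.
#' @param lr,beta1,beta2,epsilon Adam hyper-parameters.
#' @param max_epochs Epoch budget.
#' @param patience Early-stopping patience (consecutive epochs without
#'   validation-loss improvement); must not exceed `max_epochs`.
#' @param standardize Standardise features to train-set mean 0 / sd 1 before
#'   the hidden layer (the "input data are normalized" preprocessing step);
#'   the transform is stored in the fit and re-applied at prediction.
#' @param seed Seed for hidden-layer initialisation and batch shuffling.
#' @return An `oelm_config` list.
#' @export
oelm_config <- function(L = 1000L, lambda = 1e-4, solver = "adam",
                        activation = "sigmoid", loss = "cross_entropy",
                        batch_size = 16L, lr = 1e-4, beta1 = 0.9,
                        beta2 = 0.999, epsilon = 1e-8, max_epochs = 250L,
                        patience = 10L, standardize = TRUE, seed = NULL) {
  solver <- match.arg(solver, OELM_SOLVERS)
  activation <- match.arg(activation, OELM_ACTIVATIONS)
  loss <- match.arg(loss, OELM_LOSSES)
  if (!is.numeric(L) || length(L) != 1L || L < 0 || L != trunc(L)) {
    abort_vitelm("`L` must be a non-negative integer", "invalid_config")
  }
  if (lambda < 0) abort_vitelm("`lambda` must be >= 0", "invalid_config")
  if (!is_count(batch_size)) abort_vitelm("`batch_size` must be >= 1", "invalid_config")
  if (!is_count(max_epochs) || !is_count(patience) || patience > max_epochs) {
    abort_vitelm("need 1 <= patience <= max_epochs", "invalid_config")
  }
  if (lr <= 0) abort_vitelm("`lr` must be positive", "invalid_config")
  structure(
    list(L = as.integer(L), lambda = lambda, solver = solver,
         activation = activation, loss = loss,
         batch_size = as.integer(batch_size), lr = lr, beta1 = beta1,
         beta2 = beta2, epsilon = epsilon, max_epochs = as.integer(max_epochs),
         patience = as.integer(patience), standardize = isTRUE(standardize),
         seed = seed),
    class = "oelm_config"
  )
}

activation_fun <- function(name) {
  switch(name,
    sigmoid = function(x) 1 / (1 + exp(-x)),
    tanh = tanh,
    relu = function(x) pmax(x, 0),
    gelu = gelu,
    abort_vitelm(paste0("unknown activation `", name, "`"), "invalid_config")
  )
}

#' Initialise the frozen random hidden layer
#'
#' `W` (`input_dim x L`) and `b` (length `L`) are drawn uniformly from
#' `[-1, 1]` and never updated by any solver. `L = 0` yields an identity
#' layer whose output equals the input features.
#'
#' @param input_dim Feature dimension.
#' @param L Hidden width (`>= 0`).
#' @param activation Activation name (see [oelm_config()]).
#' @param seed Integer seed.
#' @return A `hidden_layer` list with fields `W`, `b`, `activation`,
#'   `input_dim`, `L`, `seed`.
#' @export
init_hidden <- function(input_dim, L, activation = "sigmoid", seed = 1L) {
  if (!is_count(input_dim)) abort_vitelm("`input_dim` must be >= 1", "invalid_config")
  if (!activation %in% OELM_ACTIVATIONS) {
    abort_vitelm(paste0("unknown activation `", activation, "`"),
                 "invalid_config")
  }
  if (L < 0 || L != trunc(L)) abort_vitelm("`L` must be >= 0", "invalid_config")
  if (L == 0) {
    layer <- list(W = NULL, b = NULL, activation = activation,
                  input_dim = as.integer(input_dim), L = 0L,
                  seed = as.integer(seed))
    return(structure(layer, class = "hidden_layer"))
  }
  with_opt_seed(seed, {
    structure(
      list(W = matrix(runif(input_dim * L, -1, 1), input_dim, L),
           b = runif(L, -1, 1), activation = activation,
           input_dim = as.integer(input_dim), L = as.integer(L),
           seed = as.integer(seed)),
      class = "hidden_layer"
    )
  })
}

#' Hidden-layer activations
#'
#' `H = g(X W + b)` applied element-wise; for the `L = 0` identity layer,
#' `H = X`.
#'
#' @param X Feature matrix (`n x input_dim`).
#' @param layer A [init_hidden()] layer.
#' @return `n x L` activation matrix (or `X` itself when `L = 0`).
#' @export
hidden_output <- function(X, layer) {
  X <- as.matrix(X)
  if (ncol(X) != layer$input_dim) {
    abort_vitelm("feature dimension does not match hidden layer",
                 "invalid_input")
  }
  if (layer$L == 0L) return(X)
  g <- activation_fun(layer$activation)
  g(sweep(X %*% layer$W, 2L, layer$b, "+"))
}

#' One-hot target matrix
#'
#' @param labels Character or factor labels.
#' @param classes Class order; defaults to `c("pes_planus", "not_pes_planus")`
#'   when the labels are drawn from those, otherwise the sorted unique labels.
#' @return `n x length(classes)` 0/1 matrix with unit row sums.
#' @export
label_matrix <- function(labels, classes = NULL) {
  labels <- as.character(labels)
  classes <- classes %||% default_classes(labels)
  bad <- setdiff(unique(labels), classes)
  if (length(bad) > 0) {
    abort_vitelm(paste0("unknown label(s): ", paste(bad, collapse = ", ")),
                 "invalid_input")
  }
  out <- matrix(0, length(labels), length(classes),
                dimnames = list(NULL, classes))
  out[cbind(seq_along(labels), match(labels, classes))] <- 1
  out
}

default_classes <- function(labels) {
  u <- unique(as.character(labels))
  if (all(u %in% DEFAULT_CLASSES)) DEFAULT_CLASSES else sort(u)
}

#' Minimum-norm least-squares output weights
#'
#' `beta = H^+ T` via the Moore-Penrose pseudo-inverse -- the classical ELM
#' solve.
#'
#' @param H Hidden activations (`n x L`).
#' @param T_mat One-hot target matrix (`n x n_classes`).
#' @return `L x n_classes` weight matrix.
#' @export
solve_pinv <- function(H, T_mat) {
  H <- as.matrix(H)
  if (length(H) == 0) abort_vitelm("`H` must be nonempty", "invalid_input")
  if (nrow(H) != nrow(T_mat)) {
    abort_vitelm("H and T must have equal row counts", "invalid_input")
  }
  ginv(H) %*% as.matrix(T_mat)
}

#' Ridge-regularised output weights
#'
#' Closed form `beta = (H'H + lambda I)^-1 H'T`.
#'
#' @inheritParams solve_pinv
#' @param lambda Regularisation weight (>= 0).
#' @return `L x n_classes` weight matrix.
#' @export
solve_ridge <- function(H, T_mat, lambda) {
  if (lambda < 0) abort_vitelm("`lambda` must be >= 0", "invalid_config")
  H <- as.matrix(H)
  if (length(H) == 0) abort_vitelm("`H` must be nonempty", "invalid_input")
  solve(crossprod(H) + lambda * diag(ncol(H)), crossprod(H, as.matrix(T_mat)))
}

#' Fresh Adam optimiser state
#'
#' @param dim `c(rows, cols)` of the parameter matrix.
#' @param lr,beta1,beta2,epsilon Adam hyper-parameters.
#' @return An `adam_state` list with zero moments and step counter 0.
#' @export
adam_state <- function(dim, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                       epsilon = 1e-8) {
  structure(
    list(m = matrix(0, dim[1], dim[2]), v = matrix(0, dim[1], dim[2]),
         t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, epsilon = epsilon),
    class = "adam_state"
  )
}

#' One Adam update
#'
#' Updates the exponential moment estimates, applies bias correction at step
#' `t + 1`, and moves `beta` against the corrected gradient:
#' `beta' = beta - lr * m_hat / (sqrt(v_hat) + epsilon)`.
#'
#' @param beta Parameter matrix.
#' @param gradient Gradient of the objective at `beta` (same shape).
#' @param state An [adam_state()].
#' @return List with elements `beta` and `state`.
#' @export
adam_step <- function(beta, gradient, state) {
  if (any(!is.finite(gradient))) {
    abort_vitelm("non-finite gradient", "numeric_error")
  }
  t <- state$t + 1L
  m <- state$beta1 * state$m + (1 - state$beta1) * gradient
  v <- state$beta2 * state$v + (1 - state$beta2) * gradient^2
  m_hat <- m / (1 - state$beta1^t)
  v_hat <- v / (1 - state$beta2^t)
  beta <- beta - state$lr * m_hat / (sqrt(v_hat) + state$epsilon)
  state$m <- m; state$v <- v; state$t <- t
  list(beta = beta, state = state)
}

# Early-stopping tracker: update(loss) returns TRUE once the loss has failed
# to improve for `patience` consecutive epochs; the best epoch is retained.
early_stopper <- function(patience) {
  best <- Inf; best_epoch <- 0L; since <- 0L; epoch <- 0L
  list(
    update = function(loss) {
      epoch <<- epoch + 1L
      if (loss < best) {
        best <<- loss; best_epoch <<- epoch; since <<- 0L
      } else {
        since <<- since + 1L
      }
      since >= patience
    },
    best_epoch = function() best_epoch,
    best_loss = function() best
  )
}

oelm_objective <- function(H, T_mat, beta, lambda, loss) {
  Z <- H %*% beta
  data_loss <- if (loss == "cross_entropy") {
    P <- softmax_rows(Z)
    -sum(T_mat * log(pmax(P, 1e-12))) / nrow(H)
  } else {
    mean((Z - T_mat)^2)
  }
  data_loss + lambda * sum(beta^2)
}

oelm_gradient <- function(H, T_mat, beta, lambda, loss) {
  Z <- H %*% beta
  g <- if (loss == "cross_entropy") {
    crossprod(H, softmax_rows(Z) - T_mat) / nrow(H)
  } else {
    2 * crossprod(H, Z - T_mat) / length(T_mat)
  }
  g + 2 * lambda * beta
}

#' Fit output weights by mini-batch Adam with early stopping
#'
#' Minimises the mean loss of `softmax(H beta)` (or the linear-score MSE)
#' plus `lambda * ||beta||^2` over `beta` only, in mini-batches of
#' `config$batch_size`. After each epoch the validation loss is logged;
#' training stops at `config$max_epochs` or once the validation loss has not
#' improved for `config$patience` consecutive epochs, and the weights from
#' the best-validation epoch are returned.
#'
#' @param X_train,y_train Training features (matrix or feature tibble) and
#'   labels.
#' @param X_val,y_val Validation features and labels used only for the
#'   early-stopping monitor.
#' @param layer A [init_hidden()] layer (never modified).
#' @param config An [oelm_config()].
#' @param classes Class order; both classes must be present in `y_train`.
#' @return List with `beta` (best-epoch weights), `log` (tibble: epoch,
#'   train_loss, val_loss, best flag), `best_epoch`, `epochs_run`.
#' @export
solve_adam <- function(X_train, y_train, X_val, y_val, layer,
                       config = oelm_config(), classes = NULL) {
  if (NROW(X_train) == 0 || NROW(X_val) == 0) {
    abort_vitelm("train and validation sets must be nonempty", "invalid_input")
  }
  classes <- classes %||% default_classes(y_train)
  if (!all(classes %in% as.character(y_train))) {
    abort_vitelm("every class must be present in the training labels",
                 "invalid_input")
  }
  H_tr <- hidden_output(as.matrix(X_train), layer)
  H_va <- hidden_output(as.matrix(X_val), layer)
  T_tr <- label_matrix(y_train, classes)
  T_va <- label_matrix(y_val, classes)
  n <- nrow(H_tr)
  beta <- matrix(0, ncol(H_tr), length(classes))
  best_beta <- beta
  state <- adam_state(dim(beta), lr = config$lr, beta1 = config$beta1,
                      beta2 = config$beta2, epsilon = config$epsilon)
  stopper <- early_stopper(config$patience)
  log_epoch <- integer(); log_train <- numeric(); log_val <- numeric()
  with_opt_seed(config$seed %||% 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      for (s in starts) {
        b_idx <- idx[s:min(s + config$batch_size - 1L, n)]
        g <- oelm_gradient(H_tr[b_idx, , drop = FALSE],
                           T_tr[b_idx, , drop = FALSE],
                           beta, config$lambda, config$loss)
        upd <- adam_step(beta, g, state)
        beta <- upd$beta; state <- upd$state
      }
      tr_loss <- oelm_objective(H_tr, T_tr, beta, config$lambda, config$loss)
      va_loss <- oelm_objective(H_va, T_va, beta, config$lambda, config$loss)
      log_epoch <- c(log_epoch, epoch)
      log_train <- c(log_train, tr_loss)
      log_val <- c(log_val, va_loss)
      stop_now <- stopper$update(va_loss)
      if (stopper$best_epoch() == epoch) best_beta <- beta
      if (stop_now) break
    }
  })
  log <- tibble(epoch = log_epoch, train_loss = log_train, val_loss = log_val,
                best = log_epoch == stopper$best_epoch())
  list(beta = best_beta, log = log, best_epoch = stopper$best_epoch(),
       epochs_run = length(log_epoch))
}

#' Fit the ELM head on a feature table
#'
#' Tidy front end tying the module together: initialises the frozen hidden
#' layer, one-hot encodes the labels, and fits the output weights with the
#' configured solver. The `"adam"` solver requires an explicit validation
#' set (as used by the cross-validation harness); `"pinv"` and `"ridge"` are
#' closed-form fits on the training set alone.
#'
#' @param train Tibble with feature columns `f1, f2, ...` and a `label`
#'   column.
#' @param validation Tibble of the same shape; required for the Adam solver.
#' @param config An [oelm_config()].
#' @param classes Class order; first class is the tie-break winner at
#'   prediction time. Defaults to `c("pes_planus", "not_pes_planus")` when
#'   applicable.
#' @param feature_cols Feature column names; auto-detected by default.
#' @return An object of class `oelm_fit` with the hidden layer, output
#'   weights `beta`, class order, config, and (for Adam) the training log.
#' @examples
#' d <- gen_feature_clusters(n = 80, d = 5, separation = 4, seed = 1)
#' fit <- oelm(d, config = oelm_config(L = 20, solver = "ridge", seed = 1))
#' predict(fit, d[1:3, ])
#' @export
oelm <- function(train, validation = NULL, config = oelm_config(),
                 classes = NULL, feature_cols = NULL) {
  feature_cols <- feature_cols %||% feature_cols_of(train)
  X <- feature_matrix(train, feature_cols)
  if (!"label" %in% names(train)) {
    abort_vitelm("`train` must contain a `label` column", "invalid_input")
  }
  y <- as.character(train$label)
  classes <- classes %||% default_classes(y)
  if (!all(classes %in% y)) {
    abort_vitelm("every class must be present in the training labels",
                 "invalid_input")
  }
  center <- NULL; scl <- NULL
  if (config$standardize) {
    center <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
    X <- scale(X, center = center, scale = scl)
  }
  layer <- init_hidden(ncol(X), config$L, config$activation,
                       seed = config$seed %||% 1L)
  log <- NULL; best_epoch <- NA_integer_; epochs_run <- NA_integer_
  if (config$solver == "adam") {
    if (is.null(validation)) {
      abort_vitelm("the adam solver needs an explicit `validation` set",
                   "invalid_config")
    }
    X_val <- feature_matrix(validation, feature_cols)
    if (config$standardize) X_val <- scale(X_val, center = center, scale = scl)
    res <- solve_adam(X, y, X_val,
                      as.character(validation$label), layer, config, classes)
    beta <- res$beta; log <- res$log
    best_epoch <- res$best_epoch; epochs_run <- res$epochs_run
  } else {
    H <- hidden_output(X, layer)
    T_mat <- label_matrix(y, classes)
    beta <- if (config$solver == "pinv") solve_pinv(H, T_mat)
            else solve_ridge(H, T_mat, config$lambda)
  }
  structure(
    list(layer = layer, beta = beta, classes = classes, config = config,
         feature_cols = feature_cols, center = center, scale = scl,
         log = log, best_epoch = best_epoch,
         epochs_run = epochs_run, n_train = nrow(X)),
    class = "oelm_fit"
  )
}

#' Predict classes and scores from a fitted ELM head
#'
#' Scores are `softmax(hidden_output(X) beta)`; each row sums to one. The
#' predicted label is the arg-max score with ties broken toward the first
#' class in the fit's class order.
#'
#' @param object An `oelm_fit`.
#' @param newdata Feature tibble or matrix.
#' @param ... Unused.
#' @return Tibble with `.pred_class` and one `.score_<class>` column per
#'   class.
#' @export
predict.oelm_fit <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata
       else feature_matrix(newdata, object$feature_cols)
  if (!is.null(object$center)) {
    X <- scale(X, center = object$center, scale = object$scale)
  }
  P <- softmax_rows(hidden_output(X, object$layer) %*% object$beta)
  lab <- object$classes[apply(P, 1L, which.max)]
  out <- tibble(.pred_class = lab)
  for (i in seq_along(object$classes)) {
    out[[paste0(".score_", object$classes[i])]] <- P[, i]
  }
  out
}

#' @export
print.oelm_fit <- function(x, ...) {
  cat(sprintf("<oelm_fit> solver %s, L = %d, lambda = %g, classes: %s\n",
              x$config$solver, x$layer$L, x$config$lambda,
              paste(x$classes, collapse = " vs ")))
  if (!is.null(x$log)) {
    cat(sprintf("  %d epochs run, best epoch %d (val loss %.5f)\n",
                x$epochs_run, x$best_epoch,
                x$log$val_loss[x$best_epoch]))
  }
  invisible(x)
}

#' Tidy the output weights of a fitted ELM head
#'
#' @param x An `oelm_fit`.
#' @param ... Unused.
#' @return Tibble with one row per (hidden unit, class) weight.
#' @export
tidy.oelm_fit <- function(x, ...) {
  tibble(
    hidden_unit = rep(seq_len(nrow(x$beta)), times = ncol(x$beta)),
    class = rep(x$classes, each = nrow(x$beta)),
    estimate = as.numeric(x$beta)
  )
}

#' One-row summary of a fitted ELM head
#'
#' @param x An `oelm_fit`.
#' @param ... Unused.
#' @return Tibble with fit size, solver, and (for Adam) training summary.
#' @export
glance.oelm_fit <- function(x, ...) {
  tibble(
    n_train = x$n_train, L = x$layer$L, solver = x$config$solver,
    lambda = x$config$lambda, epochs_run = x$epochs_run,
    best_epoch = x$best_epoch,
    best_val_loss = if (is.null(x$log)) NA_real_
                    else x$log$val_loss[x$best_epoch]
  )
}

#' Plot the training log of an Adam-solved ELM fit
#'
#' @param object An `oelm_fit` trained with the Adam solver.
#' @param ... Unused.
#' @return A ggplot of training and validation loss by epoch, with the
#'   best (restored) epoch marked.
#' @export
autoplot.oelm_fit <- function(object, ...) {
  if (is.null(object$log)) {
    abort_vitelm("no training log: fit used a closed-form solver",
                 "invalid_input")
  }
  df <- tidyr::pivot_longer(object$log, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL,
                  title = "ELM head training (Adam)",
                  subtitle = sprintf("best epoch %d", object$best_epoch)) +
    ggplot2::theme_minimal()
}
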