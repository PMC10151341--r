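#' Training configuration for the positioning classifier
#'
#' @param max_epochs Maximum number of training epochs.
#' @param batch_size Mini-batch size.
#' @param optimizer `"adam"` (the only implemented optimizer).
#' @param loss `"categorical_crossentropy"` (the only implemented loss).
#' @param backbone `"tiny_cnn"`, the bundled small network. Tokens naming
#'   ImageNet backbones (`"vgg16"`, `"xception"`, ...) are recognised but
#'   refused at run time because no pretrained weights ship with the
#'   package.
#' @param learning_rate Adam step size.
#' @param filters Number of 3 x 3 convolution filters in the tiny CNN.
#' @param pool Average-pooling window/stride.
#' @param input_size Square input side the backbone consumes; patches of a
#'   different size are resized bilinearly.
#' @param seed Seed for weight initialisation and batch shuffling.
#' @return A list of class `training_config`.
#' @export
training_config <- function(max_epochs = 50L, batch_size = 16L,
                            optimizer = "adam", loss = "categorical_crossentropy",
                            backbone = "tiny_cnn", learning_rate = 1e-3,
                            filters = 8L, pool = 4L, input_size = 64L,
                            seed = 1L) {
  if (!is_count(max_epochs)) abort("max_epochs must be >= 1", class = "mammoqc_config_error")
  if (!is_count(batch_size)) abort("batch_size must be >= 1", class = "mammoqc_config_error")
  if (!identical(optimizer, "adam")) {
    abort("only the 'adam' optimizer is implemented", class = "mammoqc_config_error")
  }
  if (!identical(loss, "categorical_crossentropy")) {
    abort("only 'categorical_crossentropy' loss is implemented", class = "mammoqc_config_error")
  }
  structure(
    list(max_epochs = as.integer(max_epochs), batch_size = as.integer(batch_size),
         optimizer = optimizer, loss = loss, backbone = backbone,
         learning_rate = learning_rate, filters = as.integer(filters),
         pool = as.integer(pool), input_size = as.integer(input_size),
         seed = as.integer(seed)),
    class = "training_config"
  )
}

#' Numerically stable softmax over three class scores
#'
#' Computes `exp(z_i - max(z)) / sum(exp(z_j - max(z)))`; the shift leaves
#' the result unchanged mathematically but avoids overflow.
#'
#' @param logits Numeric vector of length 3 (poor, average, excellent).
#' @return Named numeric vector `(p_poor, p_average, p_excellent)` summing
#'   to 1 within 1e-6.
#' @export
softmax3 <- function(logits) {
  if (length(logits) != 3L || !is.numeric(logits) || any(!is.finite(logits))) {
    abort("logits must be 3 finite numbers", class = "mammoqc_numeric_error")
  }
  z <- exp(logits - max(logits))
  p <- z / sum(z)
  names(p) <- c("p_poor", "p_average", "p_excellent")
  p
}

softmax_rows <- function(L) {
  z <- exp(L - apply(L, 1, max))
  z / rowSums(z)
}

tiny_geometry <- function(input_size, pool) {
  out <- input_size - 2L                       # valid 3x3 convolution
  pout <- out %/% pool                         # pooled grid side
  used <- pout * pool
  # conv positions in column-major order (row index fastest)
  i <- rep(seq_len(out), times = out)
  j <- rep(seq_len(out), each = out)
  grp <- ifelse(i <= used & j <= used,
                ((j - 1L) %/% pool) * pout + ((i - 1L) %/% pool) + 1L,
                NA_integer_)
  valid <- which(!is.na(grp))
  list(out = out, pout = pout, n_pos = out * out, n_grp = pout * pout,
       grp = grp, valid = valid, grp_valid = grp[valid], pool_area = pool^2)
}

im2col3 <- function(img) {
  n <- nrow(img)
  out <- n - 2L
  X <- matrix(0, out * out, 9L)
  k <- 0L
  for (dc in 0:2) for (dr in 0:2) {
    k <- k + 1L
    X[, k] <- as.numeric(img[dr + seq_len(out), dc + seq_len(out)])
  }
  X
}

prepare_patch <- function(p, input_size) {
  assert_image_matrix(p, "patch")
  if (nrow(p) != input_size || ncol(p) != input_size) {
    p <- resize_matrix(p, input_size, input_size, "bilinear")
  }
  p / 255
}

init_weights <- function(filters, n_feat) {
  list(W = matrix(rnorm(9 * filters, 0, sqrt(2 / 9)), 9, filters),
       b = rep(0, filters),
       V = matrix(rnorm(n_feat * 3, 0, sqrt(2 / n_feat)), n_feat, 3),
       c = rep(0, 3))
}

#' Instantiate an (untrained) positioning classifier
#'
#' Builds the tiny CNN — 3 x 3 convolution, ReLU, average pooling, dense
#' layer, softmax over the three quality classes — with seeded random
#' weights. [train_classifier()] starts from this state; an untrained model
#' already satisfies the probability contract (softmax output sums to 1).
#'
#' @param cfg A [training_config()].
#' @return A list of class `positioning_model`.
#' @export
positioning_model <- function(cfg = training_config()) {
  if (!identical(cfg$backbone, "tiny_cnn")) {
    abort(sprintf("backbone '%s' requires pretrained weights that do not ship with this package; use 'tiny_cnn'",
                  cfg$backbone), class = "mammoqc_config_error")
  }
  geom <- tiny_geometry(cfg$input_size, cfg$pool)
  w <- with_seed(cfg$seed, init_weights(cfg$filters, geom$n_grp * cfg$filters))
  structure(
    list(weights = w, cfg = cfg, geom = geom, classes = label_names,
         epochs_trained = 0L, updates_per_epoch = NA_integer_,
         history = tibble::tibble(epoch = integer(), loss = numeric(),
                                  accuracy = numeric())),
    class = "positioning_model"
  )
}

# forward pass over a stacked im2col batch; returns probabilities and the
# intermediates the backward pass needs
tiny_forward <- function(w, Xb, m, geom) {
  Z <- Xb %*% w$W
  Z <- sweep(Z, 2, w$b, "+")
  A <- pmax(Z, 0)
  groups <- rep((seq_len(m) - 1L) * geom$n_grp, each = length(geom$valid)) +
    rep(geom$grp_valid, times = m)
  rows <- rep((seq_len(m) - 1L) * geom$n_pos, each = length(geom$valid)) +
    rep(geom$valid, times = m)
  P <- rowsum(A[rows, , drop = FALSE], groups) / geom$pool_area
  f <- ncol(P)
  Pm <- matrix(aperm(array(P, c(geom$n_grp, m, f)), c(2, 1, 3)), m)
  L <- sweep(Pm %*% w$V, 2, w$c, "+")
  list(probs = softmax_rows(L), Z = Z, Pm = Pm, rows = rows, groups = groups)
}

adam_step <- function(state, grads, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    state$w[[nm]] <- state$w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

#' Train the positioning-quality classifier
#'
#' Minimizes categorical cross-entropy with the Adam optimizer over
#' mini-batches for at most `max_epochs` epochs (no early stopping). All
#' three classes must be present in the training labels. Training is
#' reproducible from `cfg$seed`.
#'
#' @param images List of numeric patch matrices (same shape; values on the
#'   0..255 scale), or a tibble with a `patch` list-column and a `label`
#'   column.
#' @param labels Positioning labels (codes 1/2/3 or names); ignored when
#'   `images` is a tibble carrying them.
#' @param cfg A [training_config()].
#' @return A fitted `positioning_model`; `$history` records the mean batch
#'   loss per epoch, `$train_accuracy` the final full-training-set accuracy,
#'   and `$updates_per_epoch` the number of gradient updates per epoch
#'   (`ceiling(n / batch_size)`).
#' @export
train_classifier <- function(images, labels = NULL, cfg = training_config()) {
  if (is.data.frame(images)) {
    labels <- labels %||% images$label
    images <- images$patch
  }
  if (!is.list(images) || length(images) == 0L) {
    abort("`images` must be a non-empty list of patch matrices", class = "mammoqc_input_error")
  }
  y <- label_code(labels)
  if (length(y) != length(images)) {
    abort("labels and images differ in length", class = "mammoqc_input_error")
  }
  if (length(unique(y)) < 3L) {
    abort("training data must contain at least one sample of every class",
          class = "mammoqc_training_error")
  }
  shapes <- vapply(images, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) {
    abort("all patches must share one shape", class = "mammoqc_input_error")
  }

  model <- positioning_model(cfg)
  geom <- model$geom
  n <- length(images)
  Xs <- lapply(images, function(p) im2col3(prepare_patch(p, cfg$input_size)))
  Y <- matrix(0, n, 3); Y[cbind(seq_len(n), y)] <- 1

  state <- list(w = model$weights,
                m = lapply(model$weights, function(x) x * 0),
                v = lapply(model$weights, function(x) x * 0))
  updates <- ceiling(n / cfg$batch_size)
  step <- 0L
  epoch_loss <- numeric(cfg$max_epochs)

  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      batch_loss <- numeric(updates)
      for (bi in seq_len(updates)) {
        B <- ord[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size, n)]
        m <- length(B)
        Xb <- do.call(rbind, Xs[B])
        fw <- tiny_forward(state$w, Xb, m, geom)
        batch_loss[bi] <- -mean(log(pmax(fw$probs[cbind(seq_len(m), y[B])], 1e-12)))
        dL <- (fw$probs - Y[B, , drop = FALSE]) / m
        dPm <- tcrossprod(dL, state$w$V)
        f <- cfg$filters
        dPmat <- matrix(aperm(array(dPm, c(m, geom$n_grp, f)), c(2, 1, 3)),
                        m * geom$n_grp, f)
        dA <- matrix(0, m * geom$n_pos, f)
        dA[fw$rows, ] <- dPmat[fw$groups, , drop = FALSE] / geom$pool_area
        dZ <- dA * (fw$Z > 0)
        grads <- list(W = crossprod(Xb, dZ), b = colSums(dZ),
                      V = crossprod(fw$Pm, dL), c = colSums(dL))
        step <- step + 1L
        state <- adam_step(state, grads, cfg$learning_rate, step)
      }
      epoch_loss[epoch] <- mean(batch_loss)
    }
  })

  model$weights <- state$w
  model$epochs_trained <- cfg$max_epochs
  model$updates_per_epoch <- as.integer(updates)
  # one full-set pass for the final training accuracy
  fw <- tiny_forward(state$w, do.call(rbind, Xs), n, geom)
  acc <- mean(max.col(fw$probs, ties.method = "first") == y)
  model$history <- tibble::tibble(epoch = seq_len(cfg$max_epochs),
                                  loss = epoch_loss)
  model$train_accuracy <- acc
  model
}

#' @export
print.positioning_model <- function(x, ...) {
  cat(sprintf("<positioning_model:%s> %d filters, input %dx%d, %d epoch(s) trained\n",
              x$cfg$backbone, x$cfg$filters, x$cfg$input_size, x$cfg$input_size,
              x$epochs_trained))
  if (nrow(x$history)) {
    cat(sprintf("  final loss %.4f, training accuracy %.3f\n",
                x$history$loss[nrow(x$history)], x$train_accuracy))
  }
  invisible(x)
}

#' Predict positioning quality for patches
#'
#' @param object A `positioning_model`.
#' @param newdata A single patch matrix or a list of patches (0..255 scale).
#' @param ... Unused.
#' @return A tibble with one row per patch: `p_poor`, `p_average`,
#'   `p_excellent` (softmax probabilities summing to 1), the predicted
#'   `label` code and `label_name`. Probability ties break toward the lower
#'   class code (the conservative grade).
#' @export
predict.positioning_model <- function(object, newdata, ...) {
  if (is.matrix(newdata)) newdata <- list(newdata)
  geom <- object$geom
  Xs <- lapply(newdata, function(p) im2col3(prepare_patch(p, object$cfg$input_size)))
  fw <- tiny_forward(object$weights, do.call(rbind, Xs), length(Xs), geom)
  pred <- max.col(fw$probs, ties.method = "first")
  tibble::tibble(p_poor = fw$probs[, 1], p_average = fw$probs[, 2],
                 p_excellent = fw$probs[, 3],
                 label = pred, label_name = label_names[pred])
}
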