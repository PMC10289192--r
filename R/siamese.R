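#' Model configuration for the Siamese regressor
#'
#' The shared embedding stack has 3-5 dense layers of 64 rectified-linear
#' units each, with dropout between layers and an l2 penalty of 1e-4 on every
#' layer; the regression head is a single linear node. Training uses
#' mini-batch SGD and early stopping on the validation Pearson correlation
#' with a patience of 3, 5 or 10 epochs.
#'
#' @param n_shared_layers Layers in the shared stack (3, 4 or 5).
#' @param layer_width Units per shared layer (default 64).
#' @param dropout Dropout rate between shared layers, in \[0.1, 0.3\].
#' @param l2_penalty l2 regularization value (default 1e-4).
#' @param patience Early-stopping patience in epochs (3, 5 or 10).
#' @param batch_size Pairs per SGD batch (128, 256 or 512).
#' @param lambda Mixing weight of the regression loss in the total loss
#'   (total = feature loss + lambda * regression loss; default 1).
#' @param learning_rate SGD learning rate (default 0.01; unspecified by the
#'   reference protocol, exposed here).
#' @param max_epochs Epoch cap (default 200).
#' @param seed Integer seed for weight initialization and batch shuffling, or
#'   `NULL` for an unseeded (restart-style) run.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_shared_layers = 3L, layer_width = 64L,
                         dropout = 0.2, l2_penalty = 1e-4,
                         patience = 5L, batch_size = 128L,
                         lambda = 1, learning_rate = 0.01,
                         max_epochs = 200L, seed = NULL) {
  if (!n_shared_layers %in% 3:5)
    stop("n_shared_layers must be 3, 4 or 5", call. = FALSE)
  if (dropout < 0.1 || dropout > 0.3)
    stop("dropout must be in [0.1, 0.3]", call. = FALSE)
  if (!patience %in% c(3L, 5L, 10L))
    stop("patience must be 3, 5 or 10", call. = FALSE)
  if (!batch_size %in% c(128L, 256L, 512L))
    stop("batch_size must be 128, 256 or 512", call. = FALSE)
  if (lambda <= 0 || learning_rate <= 0 || l2_penalty < 0)
    stop("lambda and learning_rate must be > 0, l2_penalty >= 0",
         call. = FALSE)
  structure(
    list(n_shared_layers = as.integer(n_shared_layers),
         layer_width = as.integer(layer_width), dropout = dropout,
         l2_penalty = l2_penalty, patience = as.integer(patience),
         batch_size = as.integer(batch_size), lambda = lambda,
         learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "model_config"
  )
}

#' Pairwise feature (metric) loss
#'
#' For a pair of embeddings and normalized labels the loss is
#' `weight * | ||emb_a - emb_b||_2 - |yhat_a - yhat_b| |`: the embedding
#' distance is pushed toward the (1-d Euclidean) distance of the normalized
#' labels. Vectorized over pairs when matrices are supplied.
#'
#' @param emb_a,emb_b Embedding vectors, or matrices with one pair per row.
#' @param yhat_a,yhat_b Normalized labels (scalars or vectors).
#' @param weight Pair weight(s), default 1.
#' @return Non-negative loss per pair.
#' @export
feature_loss <- function(emb_a, emb_b, yhat_a, yhat_b, weight = 1) {
  if (is.null(dim(emb_a))) emb_a <- matrix(emb_a, nrow = 1)
  if (is.null(dim(emb_b))) emb_b <- matrix(emb_b, nrow = 1)
  if (!all(dim(emb_a) == dim(emb_b)))
    stop("embedding dimension mismatch", call. = FALSE)
  d_emb <- sqrt(rowSums((emb_a - emb_b)^2))
  weight * abs(d_emb - abs(yhat_a - yhat_b))
}

#' Regression loss
#'
#' Weighted squared error `weight * (pred - y)^2` between the head output and
#' the raw label.
#'
#' @param pred Predicted value(s).
#' @param y True label(s).
#' @param weight Weight(s), default 1.
#' @return Non-negative loss per sample.
#' @export
regression_loss <- function(pred, y, weight = 1) {
  weight * (pred - y)^2
}

#' Build an (untrained) Siamese model
#'
#' Shared stack of `n_shared_layers` dense ReLU layers of `layer_width` units
#' plus a single-node linear head. Both branch inputs pass through the same
#' shared weights; the head reads the embedding.
#'
#' @param cfg A [model_config()].
#' @param input_dim Number of input features (>= 1).
#' @return An object of class `siamese_model` with fields `par` (weights),
#'   `cfg`, `input_dim`, `n_parameters`, and (after training) `history` and
#'   `best_epoch`.
#' @export
build_model <- function(cfg, input_dim) {
  stopifnot(inherits(cfg, "model_config"))
  if (input_dim < 1) stop("input_dim must be >= 1", call. = FALSE)
  par <- nn_init(input_dim, cfg$n_shared_layers, cfg$layer_width, cfg$seed)
  structure(
    list(par = par, cfg = cfg, input_dim = as.integer(input_dim),
         n_parameters = nn_param_count(par), history = NULL,
         best_epoch = NA_integer_, trained = FALSE),
    class = "siamese_model"
  )
}

#' @export
print.siamese_model <- function(x, ...) {
  cat("<siamese_model> ", x$cfg$n_shared_layers, "x", x$cfg$layer_width,
      " shared + 1-node head, input ", x$input_dim, ", ",
      x$n_parameters, " parameters",
      if (isTRUE(x$trained)) paste0(", trained (best epoch ", x$best_epoch,
                                    ")") else ", untrained",
      "\n", sep = "")
  invisible(x)
}

#' Train a Siamese model on within-participant pairs
#'
#' Minimizes `sum(feature_loss) + lambda * sum(regression_loss)` by
#' mini-batch SGD; the regression term is applied to both branch outputs, so
#' each pair contributes two squared-error terms. Pair weights multiply both
#' loss terms. After each epoch the validation Pearson correlation between
#' single-branch predictions and raw validation labels is computed; training
#' stops when it fails to improve for `patience` epochs and the best-epoch
#' weights are restored.
#'
#' @param model A `siamese_model` from [build_model()].
#' @param pairs A `pair_set`; its `idx_a`/`idx_b` index rows of `x_train`.
#' @param x_train Numeric matrix of training features (normalized), one row
#'   per record of the dataset the pairs were formed on.
#' @param val_x,val_y Validation feature matrix and raw labels.
#' @return The trained `siamese_model` with `history` (per-epoch validation
#'   Pearson r) and `best_epoch`.
#' @export
train_siamese <- function(model, pairs, x_train, val_x, val_y) {
  stopifnot(inherits(model, "siamese_model"), inherits(pairs, "pair_set"))
  cfg <- model$cfg
  if (ncol(x_train) != model$input_dim)
    stop("feature dimension mismatch: model expects ", model$input_dim,
         ", got ", ncol(x_train), call. = FALSE)
  if (nrow(pairs$pairs) == 0 || length(val_y) < 2)
    stop("need non-empty training pairs and >= 2 validation samples",
         call. = FALSE)
  run <- function() {
    par <- model$par
    pr <- pairs$pairs
    n_pairs <- nrow(pr)
    best_r <- -Inf
    best_par <- par
    best_epoch <- 0L
    history <- numeric(0)
    wait <- 0L
    eps <- 1e-8
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n_pairs)
      starts <- seq(1, n_pairs, by = cfg$batch_size)
      for (s in starts) {
        take <- ord[s:min(s + cfg$batch_size - 1, n_pairs)]
        nb <- length(take)
        xa <- x_train[pr$idx_a[take], , drop = FALSE]
        xb <- x_train[pr$idx_b[take], , drop = FALSE]
        w <- pr$weight[take]
        fa <- nn_forward(par, xa, cfg$dropout, training = TRUE)
        fb <- nn_forward(par, xb, cfg$dropout, training = TRUE)
        diff <- fa$emb - fb$emb
        d_emb_dist <- sqrt(rowSums(diff^2))
        t_lab <- abs(pr$yhat_a[take] - pr$yhat_b[take])
        sgn <- sign(d_emb_dist - t_lab)
        # mean over the batch of (lF + lambda * lR_both_branches)
        coef <- (w * sgn / pmax(d_emb_dist, eps)) / nb
        g_emb_a <- diff * coef
        g_pred_a <- 2 * cfg$lambda * w * (fa$pred - pr$y_a[take]) / nb
        g_pred_b <- 2 * cfg$lambda * w * (fb$pred - pr$y_b[take]) / nb
        ga <- nn_backward(par, fa, g_emb_a, g_pred_a)
        gb <- nn_backward(par, fb, -g_emb_a, g_pred_b)
        grads <- nn_add_grads(ga, gb)
        loss <- mean(w * abs(d_emb_dist - t_lab) +
                       cfg$lambda * w * ((fa$pred - pr$y_a[take])^2 +
                                           (fb$pred - pr$y_b[take])^2))
        if (!is.finite(loss)) {
          stop("non-finite training loss at epoch ", epoch,
               " (lr=", cfg$learning_rate, "); try a smaller learning rate",
               call. = FALSE)
        }
        par <- nn_sgd_step(par, grads, cfg$learning_rate, cfg$l2_penalty)
      }
      val_pred <- nn_forward(par, val_x)$pred
      r <- suppressWarnings(stats::cor(val_pred, val_y))
      if (!is.finite(r)) r <- 0
      history <- c(history, r)
      if (r > best_r) {
        best_r <- r
        best_par <- par
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    model$par <- best_par
    model$history <- history
    model$best_epoch <- best_epoch
    model$trained <- TRUE
    model
  }
  if (is.null(cfg$seed)) run() else withr::with_seed(cfg$seed + 1L, run())
}

#' Predict construct values with a trained model
#'
#' Single-branch inference: `g_V(f_W(x))`, dropout off, deterministic.
#'
#' @param model A `siamese_model`.
#' @param x Feature matrix (rows are samples).
#' @return Numeric vector of predictions.
#' @export
predict_model <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$input_dim)
    stop("feature dimension mismatch: model expects ", model$input_dim,
         ", got ", ncol(x), call. = FALSE)
  nn_forward(model$par, x)$pred
}

#' Extract embeddings `f_W(x)` from a trained model
#'
#' @param model A `siamese_model`.
#' @param x Feature matrix.
#' @return Matrix of embeddings, one row per sample, `layer_width` columns.
#' @export
embed_model <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$input_dim)
    stop("feature dimension mismatch: model expects ", model$input_dim,
         ", got ", ncol(x), call. = FALSE)
  nn_forward(model$par, x)$emb
}

#' Split target participants' data into fine-tuning and reduced test sets
#'
#' Per target participant, `floor(fraction * m)` of their `m` records are
#' selected uniformly at random (seeded) and moved into the training pool;
#' the remainder forms the reduced test set. The two parts are disjoint and
#' partition the input.
#'
#' @param test_participants A `wb_dataset` holding the test-fold
#'   participants' records.
#' @param fraction Fraction in \[0, 0.9\] of each participant's records to
#'   move to training.
#' @param seed Integer seed.
#' @return List with `fine_tune` and `reduced_test` (`wb_dataset`s).
#' @export
fine_tune_split <- function(test_participants, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 0.9)
    stop("fraction must be in [0, 0.9]", call. = FALSE)
  d <- test_participants
  if (fraction == 0) {
    ft <- d
    ft$data <- d$data[0, , drop = FALSE]
    return(list(fine_tune = ft, reduced_test = d))
  }
  rows_by_pid <- split(seq_len(nrow(d$data)), d$data$participant_id)
  sel <- withr::with_seed(as.integer(seed), {
    unlist(lapply(rows_by_pid, function(rows) {
      k <- floor(fraction * length(rows))
      if (k == 0) integer(0) else sample(rows, k)
    }), use.names = FALSE)
  })
  ft <- d
  rt <- d
  ft$data <- d$data[sel, , drop = FALSE]
  rt$data <- d$data[setdiff(seq_len(nrow(d$data)), sel), , drop = FALSE]
  rownames(ft$data) <- NULL
  rownames(rt$data) <- NULL
  list(fine_tune = ft, reduced_test = rt)
}
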