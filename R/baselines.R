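#' Train the feed-forward baseline regressor
#'
#' A plain dense regressor on the original (ambulatory) features: the same
#' layer count and width as the Siamese configuration, trained on
#' feature-to-label mean squared error with identical mini-batch SGD, l2,
#' dropout and early stopping on validation Pearson. Because the Siamese
#' branches share weights, the two architectures have exactly the same
#' trainable-parameter count, satisfying parameter parity by construction
#' (see [check_parameter_parity()]).
#'
#' @param x_train,y_train Training feature matrix and raw labels.
#' @param val_x,val_y Validation feature matrix and raw labels.
#' @param cfg A [model_config()].
#' @param weights Optional per-sample weights (default 1).
#' @return A trained `siamese_model` (the container is shared; only
#'   single-branch training differs).
#' @export
train_fnn_baseline <- function(x_train, y_train, val_x, val_y, cfg,
                               weights = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  keep <- !is.na(y_train)
  x_train <- x_train[keep, , drop = FALSE]
  y_train <- y_train[keep]
  if (length(y_train) == 0 || length(val_y) < 2)
    stop("need labeled training data and >= 2 validation samples",
         call. = FALSE)
  w <- if (is.null(weights)) rep(1, length(y_train)) else weights[keep]
  model <- build_model(cfg, ncol(x_train))
  run <- function() {
    par <- model$par
    n <- length(y_train)
    best_r <- -Inf
    best_par <- par
    best_epoch <- 0L
    history <- numeric(0)
    wait <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      for (s in seq(1, n, by = cfg$batch_size)) {
        take <- ord[s:min(s + cfg$batch_size - 1, n)]
        nb <- length(take)
        fw <- nn_forward(par, x_train[take, , drop = FALSE], cfg$dropout,
                         training = TRUE)
        resid <- fw$pred - y_train[take]
        loss <- mean(w[take] * resid^2)
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", epoch, call. = FALSE)
        g_pred <- 2 * w[take] * resid / nb
        grads <- nn_backward(par, fw, NULL, g_pred)
        par <- nn_sgd_step(par, grads, cfg$learning_rate, cfg$l2_penalty)
      }
      r <- suppressWarnings(stats::cor(nn_forward(par, val_x)$pred, val_y))
      if (!is.finite(r)) r <- 0
      history <- c(history, r)
      if (r > best_r) {
        best_r <- r; best_par <- par; best_epoch <- epoch; wait <- 0L
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

#' Check trainable-parameter parity between two models
#'
#' The baseline protocol requires the feed-forward baseline to have a similar
#' number of trainable parameters as the Siamese model (within `tol`,
#' default 5%).
#'
#' @param model_a,model_b `siamese_model`s (or anything with
#'   `n_parameters`).
#' @param tol Relative tolerance (default 0.05).
#' @return `TRUE` invisibly; error if parity is violated.
#' @export
check_parameter_parity <- function(model_a, model_b, tol = 0.05) {
  pa <- model_a$n_parameters
  pb <- model_b$n_parameters
  if (abs(pa - pb) / max(pa, pb) > tol)
    stop("parameter counts differ by more than ", tol * 100, "%: ",
         pa, " vs ", pb, call. = FALSE)
  invisible(TRUE)
}

#' Empirical Hilbert-Schmidt independence criterion (linear kernels)
#'
#' `HSIC(X, Y) = trace(Kx H Ky H) / (n - 1)^2` with `Kx = X X'`,
#' `Ky = Y Y'` and `H` the centering matrix. With linear kernels this equals
#' the squared Frobenius norm of the cross-covariance-like term and is
#' computed without materializing the n x n kernels.
#'
#' @param x,y Sample-by-feature matrices with equal row counts (vectors are
#'   treated as single columns).
#' @return Non-negative scalar; 0 iff the centered cross-products vanish.
#' @export
hsic <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(x)
  if (nrow(y) != n) stop("x and y need equal sample counts", call. = FALSE)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- scale(y, center = TRUE, scale = FALSE)
  sum(crossprod(xc, yc)^2) / (n - 1)^2
}

#' SMIDA configuration
#'
#' @param subspace_dim Dimension of the learned subspace.
#' @param mu Weight of the (to be minimized) dependence between the
#'   projection and the domain (participant) indicators.
#' @param gamma Weight of the (to be maximized) dependence between the
#'   projection and the available labels.
#' @param variance_weight Weight of the projected-variance term.
#' @param kernel Only `"linear"` is supported.
#' @param augment Append the domain indicators to the feature block before
#'   projecting (the standard formulation; default `TRUE`).
#' @return An object of class `smida_config`.
#' @export
smida_config <- function(subspace_dim = 30L, mu = 1, gamma = 1,
                         variance_weight = 1, kernel = "linear",
                         augment = TRUE) {
  if (!identical(kernel, "linear"))
    stop("only the linear kernel is supported", call. = FALSE)
  if (mu < 0 || gamma < 0 || variance_weight < 0)
    stop("weights must be >= 0", call. = FALSE)
  structure(list(subspace_dim = as.integer(subspace_dim), mu = mu,
                 gamma = gamma, variance_weight = variance_weight,
                 kernel = kernel, augment = isTRUE(augment)),
            class = "smida_config")
}

#' Fit a (semi-supervised) maximum-independence domain-adaptation projection
#'
#' Learns a linear projection of the (optionally domain-augmented) features
#' that maximizes `variance_weight * variance + gamma * HSIC(projection,
#' labels) - mu * HSIC(projection, domains)`, solved as a symmetric
#' eigenproblem; the top `subspace_dim` eigenvectors (orthonormal,
#' deterministic up to sign) form the projection. Semi-supervision: labels of
#' held-out samples are masked (`NA`) but their features still shape the
#' variance and domain terms.
#'
#' @param features Sample-by-feature matrix for ALL samples (train + test).
#' @param domains One-of-N domain (participant) indicator matrix, or a factor
#'   or character vector of domain ids.
#' @param labels Numeric labels with test entries `NA` (masked).
#' @param cfg A [smida_config()].
#' @return An object of class `smida_projection` with `w` (columns =
#'   orthonormal projection directions), `center`, `cfg`, `augment`,
#'   `n_domains`.
#' @export
fit_smida <- function(features, domains, labels, cfg = smida_config()) {
  stopifnot(inherits(cfg, "smida_config"))
  x <- as.matrix(features)
  n <- nrow(x)
  if (!is.matrix(domains)) {
    f <- factor(domains)
    domains <- stats::model.matrix(~ f - 1)
  }
  if (nrow(domains) != n || length(labels) != n)
    stop("features, domains and labels must have equal sample counts",
         call. = FALSE)
  xa <- if (cfg$augment) cbind(x, domains) else x
  center <- colMeans(xa)
  xc <- sweep(xa, 2, center)
  dc <- scale(domains, center = TRUE, scale = FALSE)
  # masked labels contribute nothing: center observed labels, zero elsewhere
  yv <- labels
  obs <- !is.na(yv)
  y0 <- numeric(n)
  if (any(obs)) y0[obs] <- yv[obs] - mean(yv[obs])
  # M = Xc' (variance_weight * I - mu * Dc Dc' + gamma * y0 y0') Xc, assembled
  # without n x n intermediates
  a <- crossprod(xc, dc)          # p x n_dom
  b <- crossprod(xc, y0)          # p x 1
  m <- cfg$variance_weight * crossprod(xc) -
    cfg$mu * tcrossprod(a) + cfg$gamma * tcrossprod(b)
  m <- (m + t(m)) / 2
  eig <- tryCatch(eigen(m, symmetric = TRUE), error = function(e) {
    warning("eigen solve failed (", conditionMessage(e),
            "); retrying with ridge regularization")
    eigen(m + diag(1e-8 * max(abs(m)), nrow(m)), symmetric = TRUE)
  })
  k <- min(cfg$subspace_dim, ncol(xa), n)
  structure(
    list(w = eig$vectors[, seq_len(k), drop = FALSE], center = center,
         eigenvalues = eig$values[seq_len(k)], cfg = cfg,
         augment = cfg$augment, n_domains = ncol(domains)),
    class = "smida_projection"
  )
}

#' Project samples with a fitted SMIDA projection
#'
#' @param projection A `smida_projection`.
#' @param features Sample-by-feature matrix (original feature space).
#' @param domains Domain indicators matching those used at fit time
#'   (required when the projection was fitted with `augment = TRUE`).
#' @return Projected matrix (samples x subspace_dim).
#' @export
smida_transform <- function(projection, features, domains = NULL) {
  x <- as.matrix(features)
  if (projection$augment) {
    if (is.null(domains))
      stop("projection was fitted with augmented domain indicators; ",
           "supply `domains`", call. = FALSE)
    if (!is.matrix(domains)) {
      f <- factor(domains)
      domains <- stats::model.matrix(~ f - 1)
    }
    x <- cbind(x, domains)
  }
  sweep(x, 2, projection$center) %*% projection$w
}

#' Linear-regression head on the SMIDA subspace
#'
#' Ordinary least squares fitted on the projected labeled (training) samples
#' and applied to the projected held-out samples. A singular design falls
#' back to ridge with a warning.
#'
#' @param projection A `smida_projection`.
#' @param features All samples' features (same matrix family used at fit).
#' @param domains Domain indicators for all samples.
#' @param labels Labels with held-out entries `NA`; the non-missing entries
#'   define the training set.
#' @return Numeric predictions for all samples (training rows included).
#' @export
smida_predict <- function(projection, features, domains, labels) {
  z <- smida_transform(projection, features, domains)
  obs <- !is.na(labels)
  if (sum(obs) < 2) stop("need >= 2 labeled samples", call. = FALSE)
  zt <- cbind(1, z[obs, , drop = FALSE])
  xtx <- crossprod(zt)
  coefs <- tryCatch(solve(xtx, crossprod(zt, labels[obs])),
                    error = function(e) {
    warning("singular design in SMIDA regression head; using ridge fallback")
    solve(xtx + diag(1e-6 * max(diag(xtx)), ncol(zt)),
          crossprod(zt, labels[obs]))
  })
  as.numeric(cbind(1, z) %*% coefs)
}
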