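## Pixel-wise classification harness. Spectra are classified one pixel at a
## time after min-max scaling to [-1, 1]; three learners mirror the evaluation
## protocol: an incrementally trained mini-batch k-means (k = 4, unsupervised),
## a one-vs-rest hinge-loss SVM trained by stochastic subgradient descent in
## batches of one hypercube, and a small 1D CNN (three convolutional layers,
## two fully connected layers and a softmax output) trained on 200-spectrum
## batches. All learners are deterministic given a seed.

#' Per-spectrum min-max scaling to [-1, 1]
#'
#' Affine map per row sending its minimum to -1 and maximum to 1. Constant
#' rows map to 0. Note this removes every per-row affine distortion: both
#' additive offsets and positive scalings of a spectrum leave its scaled form
#' unchanged.
#'
#' @param x Spectra matrix (pixels x channels) or a single spectrum.
#' @return Matrix of the same shape with rows in `[-1, 1]`.
#' @export
scale_rows_pm1 <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  lo <- apply(x, 1L, min)
  hi <- apply(x, 1L, max)
  rng <- hi - lo
  out <- 2 * (x - lo) / ifelse(rng > 0, rng, 1) - 1
  out[rng == 0, ] <- 0
  out
}

#' Fit a per-channel min-max scaler to [-1, 1]
#'
#' Learns per-channel minima/maxima from training spectra; [scale_channels()]
#' then maps each channel affinely so the training range spans `[-1, 1]`.
#' This is the channel-wise normalisation convention (sklearn's MinMaxScaler):
#' unlike [scale_rows_pm1()] it does NOT cancel per-pixel offsets or scalings,
#' so illumination errors survive it -- the regime in which background
#' corruption degrades classifiers. Channels with zero training range map
#' to 0.
#'
#' @param x Training spectra matrix, or a list of such matrices.
#' @return Object of class `channel_scaler` (list with `lo`, `hi`).
#' @export
fit_channel_scaler <- function(x) {
  if (is.list(x)) {
    lo <- do.call(pmin, lapply(x, function(m) apply(m, 2L, min)))
    hi <- do.call(pmax, lapply(x, function(m) apply(m, 2L, max)))
  } else {
    lo <- apply(x, 2L, min)
    hi <- apply(x, 2L, max)
  }
  structure(list(lo = lo, hi = hi), class = "channel_scaler")
}

#' Apply a fitted per-channel scaler
#'
#' @param scaler A `channel_scaler`.
#' @param x Spectra matrix on the same channel grid.
#' @return Scaled matrix (training range mapped to `[-1, 1]`; test values may
#'   exceed it).
#' @export
scale_channels <- function(scaler, x) {
  stopifnot(inherits(scaler, "channel_scaler"), ncol(x) == length(scaler$lo))
  rng <- scaler$hi - scaler$lo
  rng[rng == 0] <- 1
  out <- sweep(sweep(x, 2L, scaler$lo), 2L, rng, "/") * 2 - 1
  out[, scaler$hi == scaler$lo] <- 0
  out
}

## ---------------------------------------------------------------- k-means --

# k-means++ seeding on a spectra matrix (deterministic under the caller's RNG).
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  d2 <- rowSums((x - rep(centers[1L, ], each = n))^2)
  for (j in 2:k) {
    p <- d2 / sum(d2)
    i <- sample.int(n, 1L, prob = p)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums((x - rep(centers[j, ], each = n))^2))
  }
  centers
}

# Squared distances pixels x centroids via the expansion trick.
.dist2 <- function(x, centers) {
  cross <- x %*% t(centers)
  sweep(-2 * cross, 2L, rowSums(centers^2), "+") + rowSums(x^2)
}

#' Mini-batch k-means over a sequence of hypercube spectra
#'
#' Incremental k-means in batches of one hypercube: per epoch every cube is
#' assigned to the nearest centroid and centroids take the standard
#' mini-batch step (per-centroid learning rate `n_batch / n_seen`). Training
#' stops after `patience` epochs without inertia improvement (default 21) or
#' at `max_epochs`. The whole procedure is restarted from `n_init` k-means++
#' initialisations and the run with the lowest final inertia is kept.
#'
#' @param cubes List of spectra matrices (pixels x channels), already scaled.
#' @param k Number of clusters (default 4).
#' @param patience Early-stopping epochs without improvement (default 21).
#' @param max_epochs Hard epoch cap (default 100).
#' @param tol Minimum relative inertia improvement counted as progress.
#' @param n_init Number of k-means++ restarts (default 3, the lowest-inertia
#'   run wins).
#' @param seed Optional RNG seed (controls the k-means++ initialisations).
#' @return Object of class `mb_kmeans`: list with `centers`, `inertia`,
#'   `epochs_run`.
#' @export
fit_kmeans_mb <- function(cubes, k = 4, patience = 21, max_epochs = 100,
                          tol = 1e-6, n_init = 3, seed = NULL) {
  if (!is.list(cubes)) cubes <- list(cubes)
  if (!is.null(seed)) set.seed(seed)
  runs <- lapply(seq_len(n_init), function(i)
    .fit_kmeans_once(cubes, k, patience, max_epochs, tol))
  runs[[which.min(vapply(runs, `[[`, numeric(1), "inertia"))]]
}

.fit_kmeans_once <- function(cubes, k, patience, max_epochs, tol) {
  centers <- .kmeanspp_init(cubes[[1L]], k)
  counts <- rep(0, k)
  best <- Inf
  stale <- 0L
  epochs <- 0L
  for (ep in seq_len(max_epochs)) {
    epochs <- ep
    inertia <- 0
    for (x in cubes) {
      d2 <- .dist2(x, centers)
      assign <- max.col(-d2, ties.method = "first")
      inertia <- inertia + sum(d2[cbind(seq_len(nrow(x)), assign)])
      for (j in seq_len(k)) {
        idx <- assign == j
        nj <- sum(idx)
        if (nj == 0L) next
        counts[j] <- counts[j] + nj
        mu <- colMeans(x[idx, , drop = FALSE])
        centers[j, ] <- centers[j, ] + (nj / counts[j]) * (mu - centers[j, ])
      }
      # revive an empty cluster at the overall farthest point of this batch
      empty <- which(tabulate(assign, k) == 0L)
      if (length(empty)) {
        far <- order(d2[cbind(seq_len(nrow(x)), assign)], decreasing = TRUE)
        for (m in seq_along(empty)) {
          centers[empty[m], ] <- x[far[m], ]
          counts[empty[m]] <- 1
        }
      }
    }
    if (inertia < best * (1 - tol)) {
      best <- inertia
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  structure(list(centers = centers, inertia = best, epochs_run = epochs),
            class = "mb_kmeans")
}

#' @export
predict.mb_kmeans <- function(object, newdata, ...) {
  max.col(-.dist2(newdata, object$centers), ties.method = "first")
}

## -------------------------------------------------------------------- SVM --

#' Incremental one-vs-rest hinge-loss SVM
#'
#' Linear multi-class SVM trained by Pegasos-style stochastic subgradient
#' descent on the regularised hinge loss, consuming the training cubes
#' sequentially in mini-batches (incremental learning in batches of one
#' hypercube). One binary hinge classifier per class; prediction is the
#' arg-max margin.
#'
#' @param cubes List of spectra matrices (pixels x channels), already scaled.
#' @param labels List of integer class vectors (0-based), one per cube.
#' @param lambda L2 regularisation strength (default `1e-4`).
#' @param epochs Passes over the cube sequence (default 2).
#' @param batch Mini-batch size within a cube (default 256).
#' @param seed Optional RNG seed (row shuffling).
#' @return Object of class `svm_sgd`: list with `W` (channels x classes),
#'   `b`, `classes`.
#' @export
fit_svm_sgd <- function(cubes, labels, lambda = 1e-4, epochs = 2, batch = 256,
                        seed = NULL) {
  if (!is.list(cubes)) { cubes <- list(cubes); labels <- list(labels) }
  stopifnot(length(cubes) == length(labels))
  if (!is.null(seed)) set.seed(seed)
  classes <- sort(unique(unlist(lapply(labels, unique))))
  K <- length(classes)
  if (K < 2L) stop("need at least two classes", call. = FALSE)
  p <- ncol(cubes[[1L]])
  W <- matrix(0, p, K)
  b <- numeric(K)
  t <- 1
  for (ep in seq_len(epochs)) {
    for (ci in seq_along(cubes)) {
      x <- cubes[[ci]]
      y <- match(labels[[ci]], classes)
      ord <- sample.int(nrow(x))
      starts <- seq(1L, nrow(x), by = batch)
      for (s in starts) {
        idx <- ord[s:min(s + batch - 1L, nrow(x))]
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx]
        eta <- 1 / (lambda * (t + 1e3))
        scores <- xb %*% W + rep(b, each = nrow(xb))
        Y <- matrix(-1, nrow(xb), K)
        Y[cbind(seq_len(nrow(xb)), yb)] <- 1
        viol <- (Y * scores) < 1
        G <- (Y * viol) / nrow(xb)
        W <- (1 - eta * lambda) * W + eta * crossprod(xb, G)
        b <- b + eta * colSums(G)
        t <- t + 1
      }
    }
  }
  structure(list(W = W, b = b, classes = classes), class = "svm_sgd")
}

#' @export
predict.svm_sgd <- function(object, newdata, ...) {
  scores <- newdata %*% object$W + rep(object$b, each = nrow(newdata))
  object$classes[max.col(scores, ties.method = "first")]
}

## -------------------------------------------------------------------- CNN --

# Reference R implementations of the conv kernels (the compiled versions in
# src/conv1d.cpp are the ones used for training; these serve as slow,
# transparent equivalents).
.im2col <- function(A, K) {
  d <- dim(A)
  n <- d[1L]; L <- d[2L]; Cin <- d[3L]
  Lo <- L - K + 1L
  len <- n * Lo
  G <- matrix(0, len, K * Cin)               # (i,t) rows, (k,c) columns
  j <- 0L
  for (cc in seq_len(Cin)) {
    base <- (cc - 1L) * n * L
    for (k in seq_len(K)) {
      j <- j + 1L
      s <- base + (k - 1L) * n
      G[, j] <- A[(s + 1L):(s + len)]        # contiguous block copy
    }
  }
  G
}

# 1D convolution forward: A (batch, L, Cin), W (K, Cin, Cout), bias (Cout).
# Weight array W has linear layout (k, c) fastest, matching .im2col columns.
.conv1d_fwd_r <- function(A, W, bias) {
  dA <- dim(A)
  K <- dim(W)[1L]; Cout <- dim(W)[3L]
  Lo <- dA[2L] - K + 1L
  X2 <- .im2col(A, K)
  Wm <- W
  dim(Wm) <- c(K * dim(W)[2L], Cout)
  Z <- X2 %*% Wm + rep(bias, each = dA[1L] * Lo)
  dim(Z) <- c(dA[1L], Lo, Cout)
  Z
}

.conv1d_fwd <- function(A, W, bias) .cpp_conv1d_fwd(A, W, bias)

# Backward pass: gradients and (optionally) dA given pre-activation grad dZ.
# dA is computed as a full correlation with the flipped kernel (transposed
# convolution), again as one im2col gather plus one BLAS matmul.
.conv1d_bwd_r <- function(A, W, dZ, need_dA = TRUE) {
  dA_dims <- dim(A)
  K <- dim(W)[1L]; Cin <- dim(W)[2L]; Cout <- dim(W)[3L]
  Lo <- dim(dZ)[2L]
  n <- dA_dims[1L]
  dZm <- dZ
  dim(dZm) <- c(n * Lo, Cout)
  X2 <- .im2col(A, K)
  dW <- crossprod(X2, dZm)                   # (K*Cin, Cout)
  dim(dW) <- dim(W)
  dA <- NULL
  if (need_dA) {
    pad <- array(0, c(n, Lo + 2L * (K - 1L), Cout))
    pad[, K:(K + Lo - 1L), ] <- dZ
    G <- .im2col(pad, K)                     # (n*L, K*Cout), k' fastest
    Wt <- aperm(W[K:1, , , drop = FALSE], c(1L, 3L, 2L))
    dim(Wt) <- c(K * Cout, Cin)
    dA <- G %*% Wt
    dim(dA) <- dA_dims
  }
  list(dW = dW, db = colSums(dZm), dA = dA)
}

.conv1d_bwd <- function(A, W, dZ, need_dA = TRUE)
  .cpp_conv1d_bwd(A, W, dZ, need_dA)

.cnn_init <- function(n_channels, n_classes, conv_channels = c(8, 16, 32),
                      kernel = 7L, dense = c(64, 32)) {
  he <- function(fanin, ...) array(stats::rnorm(prod(c(...))) * sqrt(2 / fanin),
                                   dim = c(...))
  cin <- c(1L, conv_channels[-3L])
  L <- n_channels
  params <- list()
  for (i in 1:3) {
    params[[paste0("Wc", i)]] <- he(kernel * cin[i], kernel, cin[i],
                                    conv_channels[i])
    params[[paste0("bc", i)]] <- numeric(conv_channels[i])
    L <- L - kernel + 1L
  }
  flat <- L * conv_channels[3L]
  params$W4 <- he(flat, flat, dense[1L])
  params$b4 <- numeric(dense[1L])
  params$W5 <- he(dense[1L], dense[1L], dense[2L])
  params$b5 <- numeric(dense[2L])
  params$W6 <- he(dense[2L], dense[2L], n_classes)
  params$b6 <- numeric(n_classes)
  attr(params, "arch") <- list(kernel = kernel, conv = conv_channels,
                               dense = dense, flat = flat, L_out = L,
                               n_channels = n_channels, n_classes = n_classes)
  params
}

.relu <- function(x) {
  out <- .cpp_relu(x)
  attributes(out) <- attributes(x)
  out
}

# dZ = dA masked by Z > 0, keeping dims
.relu_bwd <- function(dA, Z) {
  out <- .cpp_relu_bwd(dA, Z)
  attributes(out) <- attributes(dA)
  out
}

# Forward pass; returns logits and (optionally) the activation cache.
.cnn_forward <- function(params, X, cache = FALSE) {
  n <- nrow(X)
  A0 <- array(X, c(n, ncol(X), 1L))
  Z1 <- .conv1d_fwd(A0, params$Wc1, params$bc1); A1 <- .relu(Z1)
  Z2 <- .conv1d_fwd(A1, params$Wc2, params$bc2); A2 <- .relu(Z2)
  Z3 <- .conv1d_fwd(A2, params$Wc3, params$bc3); A3 <- .relu(Z3)
  F3 <- A3; dim(F3) <- c(n, prod(dim(A3)[2:3]))
  Z4 <- F3 %*% params$W4 + rep(params$b4, each = n); A4 <- .relu(Z4)
  Z5 <- A4 %*% params$W5 + rep(params$b5, each = n); A5 <- .relu(Z5)
  logits <- A5 %*% params$W6 + rep(params$b6, each = n)
  if (!cache) return(list(logits = logits))
  list(logits = logits, A0 = A0, Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2,
       Z3 = Z3, A3 = A3, F3 = F3, Z4 = Z4, A4 = A4, Z5 = Z5, A5 = A5)
}

.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# One SGD step on a batch (classical momentum); returns updated params,
# velocity and the batch loss/accuracy.
.cnn_step <- function(params, X, y1, lr, vel = NULL, mu = 0.9) {
  n <- nrow(X)
  fw <- .cnn_forward(params, X, cache = TRUE)
  P <- .softmax(fw$logits)
  K <- ncol(P)
  Yh <- matrix(0, n, K)
  Yh[cbind(seq_len(n), y1)] <- 1
  loss <- -mean(log(pmax(P[cbind(seq_len(n), y1)], 1e-12)))
  acc <- mean(max.col(P, ties.method = "first") == y1)
  dZ6 <- (P - Yh) / n
  gW6 <- crossprod(fw$A5, dZ6); gb6 <- colSums(dZ6)
  dA5 <- tcrossprod(dZ6, params$W6); dZ5 <- .relu_bwd(dA5, fw$Z5)
  gW5 <- crossprod(fw$A4, dZ5); gb5 <- colSums(dZ5)
  dA4 <- tcrossprod(dZ5, params$W5); dZ4 <- .relu_bwd(dA4, fw$Z4)
  gW4 <- crossprod(fw$F3, dZ4); gb4 <- colSums(dZ4)
  dF3 <- tcrossprod(dZ4, params$W4)
  dA3 <- array(dF3, dim(fw$A3)); dZ3 <- .relu_bwd(dA3, fw$Z3)
  g3 <- .conv1d_bwd(fw$A2, params$Wc3, dZ3); dZ2 <- .relu_bwd(g3$dA, fw$Z2)
  g2 <- .conv1d_bwd(fw$A1, params$Wc2, dZ2); dZ1 <- .relu_bwd(g2$dA, fw$Z1)
  g1 <- .conv1d_bwd(fw$A0, params$Wc1, dZ1, need_dA = FALSE)
  grads <- list(Wc1 = g1$dW, bc1 = g1$db, Wc2 = g2$dW, bc2 = g2$db,
                Wc3 = g3$dW, bc3 = g3$db, W4 = gW4, b4 = gb4,
                W5 = gW5, b5 = gb5, W6 = gW6, b6 = gb6)
  if (is.null(vel)) vel <- lapply(grads, function(g) g * 0)
  for (nm in names(grads)) {
    vel[[nm]] <- mu * vel[[nm]] - lr * grads[[nm]]
    params[[nm]] <- params[[nm]] + vel[[nm]]
  }
  list(params = params, vel = vel, loss = loss, acc = acc)
}

#' Train the six-layer 1D CNN spectra classifier
#'
#' Architecture: three 1D convolutional layers (kernel 7, channels 8/16/32,
#' ReLU), two fully connected layers (64 and 32 units, ReLU) and a softmax
#' output - the smallest stack that separates four smooth spectra. Trained by
#' SGD with classical momentum 0.9 (learning rate 0.01) on shuffled
#' 200-spectrum batches with cross-entropy loss. Training stops early once an
#' entire epoch classifies at `stop_acc` accuracy, once `stop_batches`
#' consecutive batches classify perfectly, or after `max_epochs`.
#'
#' @param cubes List of spectra matrices (pixels x channels), already scaled.
#' @param labels List of integer class vectors (0-based), one per cube.
#' @param batch Batch size (default 200).
#' @param max_epochs Epoch cap (default 20).
#' @param lr SGD learning rate (default 0.01).
#' @param stop_acc Epoch training accuracy triggering early stop
#'   (default 0.9995).
#' @param stop_batches Consecutive perfectly classified batches triggering
#'   early stop (default 150).
#' @param cv_folds If > 1, additionally report `cv_folds`-fold
#'   cross-validation accuracies (each fold model trained on the remaining
#'   folds; expensive, off by default).
#' @param seed Optional RNG seed (weights and shuffling).
#' @return Object of class `cnn1d`: list with `params`, `classes`,
#'   `epochs_run`, `history` (per-epoch loss/accuracy) and optionally
#'   `cv_accuracy`.
#' @export
fit_cnn1d <- function(cubes, labels, batch = 200, max_epochs = 20, lr = 0.01,
                      stop_acc = 0.9995, stop_batches = 150, cv_folds = 0,
                      seed = NULL) {
  if (!is.list(cubes)) { cubes <- list(cubes); labels <- list(labels) }
  stopifnot(length(cubes) == length(labels))
  if (!is.null(seed)) set.seed(seed)
  classes <- sort(unique(unlist(lapply(labels, unique))))
  X <- do.call(rbind, cubes)
  y1 <- match(unlist(labels), classes)
  fit_one <- function(Xt, yt) {
    params <- .cnn_init(ncol(Xt), length(classes))
    vel <- NULL
    history <- NULL
    epochs <- 0L
    streak <- 0L
    converged <- FALSE
    for (ep in seq_len(max_epochs)) {
      epochs <- ep
      ord <- sample.int(nrow(Xt))
      starts <- seq(1L, nrow(Xt), by = batch)
      tot_loss <- 0; tot_acc <- 0; seen <- 0
      for (s in starts) {
        idx <- ord[s:min(s + batch - 1L, nrow(Xt))]
        st <- .cnn_step(params, Xt[idx, , drop = FALSE], yt[idx], lr, vel)
        params <- st$params
        vel <- st$vel
        tot_loss <- tot_loss + st$loss * length(idx)
        tot_acc <- tot_acc + st$acc * length(idx)
        seen <- seen + length(idx)
        streak <- if (st$acc == 1) streak + 1L else 0L
        if (streak >= stop_batches) { converged <- TRUE; break }
      }
      history <- rbind(history, c(epoch = ep, loss = tot_loss / seen,
                                  accuracy = tot_acc / seen))
      if (converged || tot_acc / seen >= stop_acc) break
    }
    list(params = params, epochs = epochs, history = as.data.frame(history))
  }
  fit <- fit_one(X, y1)
  out <- structure(list(params = fit$params, classes = classes,
                        epochs_run = fit$epochs, history = fit$history),
                   class = "cnn1d")
  if (cv_folds > 1) {
    fold <- sample(rep_len(seq_len(cv_folds), nrow(X)))
    out$cv_accuracy <- vapply(seq_len(cv_folds), function(f) {
      m <- fit_one(X[fold != f, , drop = FALSE], y1[fold != f])
      pred <- predict.cnn1d(structure(list(params = m$params,
                                           classes = classes),
                                      class = "cnn1d"),
                            X[fold == f, , drop = FALSE])
      mean(pred == classes[y1[fold == f]])
    }, numeric(1))
  }
  out
}

#' @export
predict.cnn1d <- function(object, newdata, chunk = 4096L, ...) {
  n <- nrow(newdata)
  pred <- integer(n)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    logits <- .cnn_forward(object$params,
                           newdata[idx, , drop = FALSE])$logits
    pred[idx] <- max.col(logits, ties.method = "first")
  }
  object$classes[pred]
}

## ------------------------------------------------------------- evaluation --

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .permutations(v[-i])) out <- c(out, list(c(v[i], rest)))
  out
}

#' Optimal cluster-to-class matching
#'
#' Maps unsupervised cluster ids to class labels by exhaustive search over
#' all one-to-one assignments (k! permutations, k <= 8), maximising pixel
#' accuracy.
#'
#' @param clusters Integer cluster ids (1-based).
#' @param labels True class labels.
#' @param k Number of clusters (default: max cluster id).
#' @return List with `mapping` (class label per cluster id), `accuracy`
#'   (percent) and `predicted` (mapped labels).
#' @export
match_clusters <- function(clusters, labels, k = max(clusters)) {
  if (k > 8L) stop("exhaustive matching is limited to k <= 8", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) < k) classes <- c(classes, rep(classes[1L],
                                                     k - length(classes)))
  conf <- matrix(0, k, length(classes))
  for (j in seq_along(classes))
    conf[, j] <- tabulate(clusters[labels == classes[j]], k)
  best <- -1
  best_perm <- seq_len(k)
  for (perm in .permutations(seq_len(min(k, length(classes))))) {
    hits <- sum(conf[cbind(seq_along(perm), perm)])
    if (hits > best) { best <- hits; best_perm <- perm }
  }
  mapping <- classes[best_perm]
  list(mapping = mapping, accuracy = 100 * best / length(labels),
       predicted = mapping[clusters])
}

#' Pixel accuracy of a trained classifier on labelled spectra
#'
#' Supervised models are scored directly; `mb_kmeans` clusters are first
#' mapped to classes by [match_clusters()].
#'
#' @param model A fitted `mb_kmeans`, `svm_sgd` or `cnn1d`.
#' @param x Spectra matrix (already scaled consistently with training).
#' @param labels True class labels per row.
#' @return List with `accuracy` (percent) and `predicted` labels.
#' @export
evaluate_classifier <- function(model, x, labels) {
  pred <- predict(model, x)
  if (inherits(model, "mb_kmeans")) {
    m <- match_clusters(pred, labels, k = nrow(model$centers))
    list(accuracy = m$accuracy, predicted = m$predicted)
  } else {
    list(accuracy = 100 * mean(pred == labels), predicted = pred)
  }
}
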