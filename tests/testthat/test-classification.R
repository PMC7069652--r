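test_that("per-spectrum scaling hits [-1,1] and cancels affine distortions", {
  expect_equal(as.vector(scale_rows_pm1(c(0, 5, 10))), c(-1, 0, 1))
  set.seed(21)
  x <- matrix(runif(50, 1, 3), 5, 10)
  s <- scale_rows_pm1(x)
  expect_equal(apply(s, 1, min), rep(-1, 5))
  expect_equal(apply(s, 1, max), rep(1, 5))
  # per-row additive offsets leave the output unchanged (the mechanism behind
  # supervised accuracy being immune to absorbance offsets)
  expect_equal(scale_rows_pm1(x + runif(5)), s)
  # per-row positive scalings cancel too
  expect_equal(scale_rows_pm1(x * runif(5, 0.1, 4)), s)
  # loop oracle
  oracle <- x
  for (i in 1:5) oracle[i, ] <- 2 * (x[i, ] - min(x[i, ])) /
      (max(x[i, ]) - min(x[i, ])) - 1
  expect_equal(s, oracle)
  # constant rows map to 0
  expect_true(all(scale_rows_pm1(matrix(3, 2, 4)) == 0))
})

test_that("the channel scaler preserves per-pixel corruption", {
  set.seed(22)
  x <- matrix(runif(60, 0.5, 2), 6, 10)
  sc <- fit_channel_scaler(x)
  s <- scale_channels(sc, x)
  expect_equal(apply(s, 2, min), rep(-1, 10))
  expect_equal(apply(s, 2, max), rep(1, 10))
  # per-pixel scaling is NOT removed by channel scaling
  s2 <- scale_channels(sc, x * runif(6, 0.1, 0.9))
  expect_false(isTRUE(all.equal(s, s2)))
  # list fitting pools ranges
  sc2 <- fit_channel_scaler(list(x, x * 2))
  expect_equal(sc2$hi, apply(x * 2, 2, max))
})

test_that("mini-batch k-means recovers well-separated clusters", {
  d <- blob_data()
  km <- fit_kmeans_mb(scale_rows_pm1(d$x), k = 4, seed = 1)
  pred <- predict(km, scale_rows_pm1(d$x))
  expect_length(unique(pred), 4)             # 4 non-empty clusters
  m <- match_clusters(pred, d$y)
  expect_equal(m$accuracy, 100)
  # independent route: stats::kmeans agrees on the partition
  ref <- stats::kmeans(scale_rows_pm1(d$x), 4, nstart = 5)
  agree <- match_clusters(pred, ref$cluster)
  expect_equal(agree$accuracy, 100)
  # determinism
  km2 <- fit_kmeans_mb(scale_rows_pm1(d$x), k = 4, seed = 1)
  expect_identical(km$centers, km2$centers)
})

test_that("cluster-class matching equals the exhaustive permutation oracle", {
  set.seed(23)
  for (rep in 1:5) {
    clusters <- sample(1:4, 300, replace = TRUE)
    labels <- sample(0:3, 300, replace = TRUE)
    m <- match_clusters(clusters, labels)
    # independent brute force over all 24 permutations
    perms <- list()
    for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b)))
      perms <- c(perms, list(c(a, b, cc, setdiff(1:4, c(a, b, cc)))))
    best <- -1
    for (p in perms) {
      mapped <- (0:3)[p][clusters]
      best <- max(best, mean(mapped == labels))
    }
    expect_equal(m$accuracy, 100 * best)
  }
  # permuted-but-pure clusters score 100 after matching
  y <- rep(0:3, each = 10)
  expect_equal(match_clusters(c(3, 4, 1, 2)[y + 1], y)$accuracy, 100)
})

test_that("the incremental SVM separates linearly separable data", {
  d <- blob_data(n_per = 80, sd = 0.4, seed = 2)
  xs <- scale_rows_pm1(d$x)
  svm <- fit_svm_sgd(xs, d$y, seed = 3)
  expect_equal(mean(predict(svm, xs) == d$y), 1)
  # 2-class 2-channel toy set against a brute-force max-margin search
  set.seed(24)
  x2 <- rbind(matrix(rnorm(60, sd = 0.2), 30, 2) + 2,
              matrix(rnorm(60, sd = 0.2), 30, 2) - 2)
  y2 <- rep(c(0, 1), each = 30)
  svm2 <- fit_svm_sgd(x2, y2, seed = 4, epochs = 10)
  # grid search over unit normals and intercepts for the widest margin
  thetas <- seq(0, pi, length.out = 181)
  best <- list(margin = -Inf)
  for (th in thetas) {
    w <- c(cos(th), sin(th))
    proj <- x2 %*% w
    lo <- max(proj[y2 == 0]); hi <- min(proj[y2 == 1])
    if (hi > lo && (hi - lo) / 2 > best$margin)
      best <- list(margin = (hi - lo) / 2, w = w, b = -(hi + lo) / 2)
    lo2 <- max(proj[y2 == 1]); hi2 <- min(proj[y2 == 0])
    if (hi2 > lo2 && (hi2 - lo2) / 2 > best$margin)
      best <- list(margin = (hi2 - lo2) / 2, w = -w, b = (hi2 + lo2) / 2)
  }
  expect_equal(as.integer(predict(svm2, x2)), y2)
  # away from the margin band the SGD solution and the max-margin oracle
  # classify identically
  grid <- as.matrix(expand.grid(seq(-3, 3, 0.5), seq(-3, 3, 0.5)))
  margin <- as.vector(grid %*% best$w + best$b)
  outside <- abs(margin) > best$margin
  oracle_pred <- as.integer(margin > 0)
  expect_equal(as.integer(predict(svm2, grid))[outside], oracle_pred[outside])
})

test_that("the CNN learns separable spectra and reports CV folds", {
  # smooth 4-class toy spectra
  set.seed(25)
  wlch <- 30
  base <- vapply(1:4, function(k) sin(seq(0, 3, length.out = wlch) + k) + 2,
                 numeric(wlch))
  x <- do.call(rbind, lapply(1:4, function(k)
    matrix(rep(base[, k], each = 50), 50) + matrix(rnorm(50 * wlch, sd = 0.05), 50)))
  y <- rep(0:3, each = 50)
  xs <- scale_rows_pm1(x)
  m <- fit_cnn1d(xs, y, batch = 50, max_epochs = 15, cv_folds = 3, seed = 5)
  expect_equal(mean(predict(m, xs) == y), 1)
  expect_length(m$cv_accuracy, 3)
  expect_true(all(m$cv_accuracy > 0.9))
  # deterministic under a fixed seed
  m2 <- fit_cnn1d(xs, y, batch = 50, max_epochs = 15, seed = 5)
  expect_identical(m$params$Wc1, m2$params$Wc1)
})

test_that("compiled conv kernels match the reference R implementation", {
  set.seed(26)
  A <- array(rnorm(4 * 20 * 3), c(4, 20, 3))
  W <- array(rnorm(7 * 3 * 5), c(7, 3, 5))
  b <- rnorm(5)
  Z <- hsibg:::.conv1d_fwd(A, W, b)
  expect_equal(Z, hsibg:::.conv1d_fwd_r(A, W, b))
  dZ <- array(rnorm(length(Z)), dim(Z))
  g <- hsibg:::.conv1d_bwd(A, W, dZ)
  gr <- hsibg:::.conv1d_bwd_r(A, W, dZ)
  expect_equal(g$dW, gr$dW)
  expect_equal(as.vector(g$db), gr$db)
  expect_equal(g$dA, gr$dA)
})

test_that("CNN gradients agree with finite differences", {
  set.seed(27)
  X <- matrix(rnorm(6 * 24), 6, 24)
  y <- c(1, 2, 3, 4, 1, 2)
  params <- hsibg:::.cnn_init(24, 4)
  loss_of <- function(p) {
    P <- hsibg:::.softmax(hsibg:::.cnn_forward(p, X)$logits)
    -mean(log(P[cbind(seq_along(y), y)]))
  }
  # recover analytic gradients from a zero-momentum step of known lr
  lr <- 1e-3
  st <- hsibg:::.cnn_step(params, X, y, lr, vel = NULL, mu = 0)
  for (nm in c("Wc2", "W5", "b6")) {
    g_analytic <- (params[[nm]] - st$params[[nm]]) / lr
    idx <- seq_len(min(4, length(g_analytic)))
    for (i in idx) {
      eps <- 1e-6
      p_up <- params; p_up[[nm]][i] <- p_up[[nm]][i] + eps
      p_dn <- params; p_dn[[nm]][i] <- p_dn[[nm]][i] - eps
      g_fd <- (loss_of(p_up) - loss_of(p_dn)) / (2 * eps)
      expect_equal(as.numeric(g_analytic[i]), g_fd, tolerance = 1e-4)
    }
  }
})

test_that("classifier evaluation scores pixels and maps clusters", {
  y <- rep(0:3, each = 5)
  model <- structure(list(centers = diag(4)), class = "mb_kmeans")
  x <- diag(4)[c(2, 3, 4, 1)[y + 1] , ]      # permuted pure clusters
  r <- evaluate_classifier(model, x, y)
  expect_equal(r$accuracy, 100)
})
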