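test_that("fit recovers exact sample moments and validates inputs", {
  X <- rbind(matrix(rep(c(1, 2, 2, 4, 3, 6), 2), ncol = 2, byrow = TRUE),
             matrix(rep(c(10, 1, 12, 3, 14, 5), 2), ncol = 2, byrow = TRUE))
  y <- rep(c(1, 0), each = 6)
  m <- gda_fit(X, y, "LDA", ridge = 0)
  expect_equal(unname(m$mu["w1", ]), colMeans(X[y == 1, ]), tolerance = 1e-15)
  expect_equal(unname(m$mu["w2", ]), colMeans(X[y == 0, ]), tolerance = 1e-15)
  expect_equal(m$pooled_cov,
               (5 * cov(X[y == 1, ]) + 5 * cov(X[y == 0, ])) / 10,
               tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(unname(m$priors), c(0.5, 0.5))
  expect_error(gda_fit(X, rep(1, 12), "NB"), "both classes")
  Xz <- X; Xz[, 2] <- 5
  expect_error(gda_fit(Xz, y, "NB", ridge = 0), "zero-variance feature")
  expect_error(predict(m, X[, 1, drop = FALSE]), "expects 2")
})

test_that("labels match literal-formula oracles for all four classifiers", {
  dat <- gaussian_classes(60, 80, c(0, 0, 0), c(1.5, -1, 0.5),
                          diag(3), 0.5 * diag(3) + 0.2, seed = 10)
  pts <- with_test_seed(11, matrix(rnorm(300, sd = 2), ncol = 3))
  for (variant in c("full", "printed")) {
    models <- fit_all_kinds(dat$X, dat$y, qda_variant = variant)
    oracle_fun <- list(NB = bf_nb_label, LDA = bf_lda_label,
                       QDA = bf_qda_label, MDA = bf_mda_label)
    for (k in names(models)) {
      got <- predict(models[[k]], pts)
      want <- vapply(seq_len(nrow(pts)), function(i)
        oracle_fun[[k]](models[[k]], pts[i, ]), integer(1))
      expect_identical(got, want)
    }
  }
})

test_that("ties and symmetric cases resolve to the negative class", {
  mu1 <- c(2, 0); mu2 <- c(-2, 0)
  dat <- gaussian_classes(50, 50, mu1, mu2, diag(2), diag(2), seed = 3)
  for (k in c("NB", "LDA", "QDA", "MDA")) {
    m <- gda_fit(dat$X, dat$y, k, priors = c(0.5, 0.5))
    # force exact symmetry so the midpoint is a true tie
    m$mu <- rbind(w1 = mu1, w2 = mu2)
    m$nb_sds <- rbind(w1 = c(1, 1), w2 = c(1, 1))
    if (!is.null(m$pooled_inv)) m$pooled_inv <- diag(2)
    if (!is.null(m$class_invs)) {
      m$class_invs <- list(w1 = diag(2), w2 = diag(2))
      m$logdet <- c(w1 = 0, w2 = 0)
    }
    mid <- matrix((mu1 + mu2) / 2, 1)
    expect_identical(predict(m, mid), 0L)
    expect_identical(predict(m, matrix(mu1, 1)), 1L)
  }
})

test_that("prior dominance: identical class parameters vote with the prior", {
  dat <- gaussian_classes(100, 100, c(0, 0), c(0, 0) + 1e-12, diag(2), diag(2),
                          seed = 5)
  m <- gda_fit(dat$X, dat$y, "NB", priors = c(0.3, 0.7))
  m$mu <- rbind(w1 = c(0, 0), w2 = c(0, 0))
  m$nb_sds <- rbind(w1 = c(1, 1), w2 = c(1, 1))
  pts <- with_test_seed(6, matrix(rnorm(100), ncol = 2))
  expect_true(all(predict(m, pts) == 0L))
})

test_that("MDA equals LDA under equal priors; full QDA collapses to LDA for equal covariances", {
  dat <- gaussian_classes(200, 300, c(1, 0, -1), c(-1, 0.5, 1),
                          0.8 * diag(3) + 0.1, 0.8 * diag(3) + 0.1, seed = 8)
  pts <- with_test_seed(9, matrix(rnorm(3000, sd = 2), ncol = 3))
  lda <- gda_fit(dat$X, dat$y, "LDA", priors = c(0.5, 0.5))
  mda <- gda_fit(dat$X, dat$y, "MDA", priors = c(0.5, 0.5))
  s_lda <- predict(lda, pts, type = "score")
  s_mda <- predict(mda, pts, type = "score")
  expect_lt(max(abs(s_mda - 2 * s_lda)), 1e-9)  # D(w2)-D(w1) = 2(g1-g2)
  expect_identical(predict(mda, pts), predict(lda, pts))
  qda <- gda_fit(dat$X, dat$y, "QDA", priors = c(0.5, 0.5))
  qda$class_invs <- list(w1 = lda$pooled_inv, w2 = lda$pooled_inv)
  ld <- determinant(lda$pooled_cov, logarithm = TRUE)$modulus
  qda$logdet <- c(w1 = ld, w2 = ld)
  s_qda <- predict(qda, pts, type = "score")
  expect_lt(max(abs(s_qda - s_lda)), 1e-9)
})

test_that("decisions are invariant under a common affine feature transform", {
  dat <- gaussian_classes(400, 600, c(0, 0), c(2.5, 1), diag(2),
                          matrix(c(1.2, 0.3, 0.3, 0.8), 2), seed = 12)
  pts <- with_test_seed(13, matrix(rnorm(2000, sd = 2), ncol = 2))
  A <- matrix(c(2, 0.5, -0.3, 1.4), 2)
  b <- c(3, -1)
  tx <- function(M) sweep(M %*% t(A), 2, -b)
  for (k in c("NB", "LDA", "QDA", "MDA")) {
    # NB is only affine-covariant for axis-aligned scaling
    Ak <- if (k == "NB") diag(c(2, 0.5)) else A
    txk <- function(M) sweep(M %*% t(Ak), 2, -b)
    m0 <- gda_fit(dat$X, dat$y, k, ridge = 0)
    m1 <- gda_fit(txk(dat$X), dat$y, k, ridge = 0)
    l0 <- predict(m0, pts)
    l1 <- predict(m1, txk(pts))
    expect_gte(mean(l0 == l1), 0.999)
  }
})

test_that("parameter recovery and accuracy on well-separated Gaussians", {
  d <- 3
  delta <- rep(6 / sqrt(d), d)  # Mahalanobis separation 6 under identity cov
  n <- 5000
  dat <- gaussian_classes(n, n, delta, rep(0, d), diag(d), diag(d), seed = 21)
  se <- 1 / sqrt(n)
  for (k in c("NB", "LDA", "QDA", "MDA")) {
    m <- gda_fit(dat$X, dat$y, k)
    expect_true(all(abs(m$mu["w1", ] - delta) < 3 * se))
    expect_true(all(abs(m$mu["w2", ] - 0) < 3 * se))
    acc <- mean(predict(m, dat$X) == dat$y)
    expect_gte(acc, 0.99)
  }
})

test_that("LDA/QDA labels agree with MASS on random data", {
  skip_if_not_installed("MASS")
  dat <- gaussian_classes(300, 500, c(0.5, -0.2, 1), c(-0.5, 0.4, 0),
                          diag(3), 1.3 * diag(3) - 0.1, seed = 30)
  pts <- with_test_seed(31, matrix(rnorm(900), ncol = 3))
  colnames(dat$X) <- colnames(pts) <- c("a", "b", "c")
  lda <- gda_fit(dat$X, dat$y, "LDA", ridge = 0)
  ref <- MASS::lda(dat$X, grouping = dat$y)
  want <- as.integer(as.character(predict(ref, pts)$class))
  expect_gte(mean(predict(lda, pts) == want), 0.999)
  qda <- gda_fit(dat$X, dat$y, "QDA", ridge = 0)
  refq <- MASS::qda(dat$X, grouping = dat$y)
  wantq <- as.integer(as.character(predict(refq, pts)$class))
  expect_gte(mean(predict(qda, pts) == wantq), 0.999)
})
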