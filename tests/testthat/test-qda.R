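test_that("fitted moments and priors match their closed forms", {
  fm <- as_feature_matrix(data.frame(
    Ax = c(0, 0, 2, 2),
    behaviour = rep(c("sound_standing", "sound_walking"), each = 2)))
  m <- fit_qda(fm, "Ax", shrinkage = 1e-6)
  expect_equal(m$mean$sound_standing[["Ax"]], 0)
  expect_equal(m$mean$sound_walking[["Ax"]], 2)
  expect_equal(unname(m$prior), c(0.5, 0.5))

  fm2 <- as_feature_matrix(data.frame(
    Ax = rnorm(100),
    behaviour = rep(c("sound_grazing", "sound_walking"), c(30, 70))))
  m2 <- fit_qda(fm2, "Ax")
  expect_equal(unname(m2$prior), c(0.3, 0.7))
  m2u <- fit_qda(fm2, "Ax", priors = "uniform")
  expect_equal(unname(m2u$prior), c(0.5, 0.5))
  expect_equal(sum(m2$prior), 1, tolerance = 1e-12)
})

test_that("fitted moments equal direct formula evaluation on random data", {
  fm <- gaussian_classes(n_per = 25, feats = c("Ax", "MV"), K = 3, seed = 30)
  lam <- 1e-6
  m <- fit_qda(fm, c("Ax", "MV"), shrinkage = lam)
  for (k in m$classes) {
    xi <- as.matrix(fm[fm$behaviour == k, c("Ax", "MV")])
    expect_equal(m$mean[[k]], colMeans(xi), tolerance = 1e-12)
    S <- cov(xi)
    expect_equal(m$cov[[k]], S + lam * (sum(diag(S)) / 2) * diag(2),
                 tolerance = 1e-12)
  }
})

test_that("zero-variance classes are handled via shrinkage, rejected without", {
  fm <- as_feature_matrix(data.frame(
    Ax = c(0, 0, 2, 2), MV = c(1, 1, 3, 3),
    behaviour = rep(c("sound_standing", "sound_walking"), each = 2)))
  m <- fit_qda(fm, c("Ax", "MV"), shrinkage = 1e-6)
  expect_true(all(vapply(m$cov, function(S) all(is.finite(chol(S))),
                         TRUE)))
  expect_error(fit_qda(fm, c("Ax", "MV"), shrinkage = 0), "singular")
  fm1 <- as_feature_matrix(data.frame(
    Ax = c(0, 1, 2), behaviour = c("sound_standing", "sound_standing",
                                   "sound_walking")))
  expect_error(fit_qda(fm1, "Ax"), "at least 2")
})

test_that("a point at a class mean is assigned that class", {
  fm <- gaussian_classes(n_per = 30, feats = c("Ax", "MV"), K = 3, seed = 31)
  m <- fit_qda(fm, c("Ax", "MV"), priors = "uniform")
  for (k in m$classes) {
    pr <- predict_qda(m, m$mean[[k]])
    expect_identical(pr$class, k)
    expect_gt(pr$posterior[1, k], 1 / 3)
  }
})

test_that("the symmetric 1-D two-class case splits posteriors evenly at zero", {
  s <- 1 / sqrt(2)   # two points at m +/- s have sample variance 1
  fm <- as_feature_matrix(data.frame(
    Ax = c(-1 - s, -1 + s, 1 - s, 1 + s),
    behaviour = rep(c("sound_standing", "sound_walking"), each = 2)))
  m <- fit_qda(fm, "Ax", shrinkage = 0)
  p0 <- predict_qda(m, 0)
  expect_equal(unname(p0$posterior[1, ]), c(0.5, 0.5), tolerance = 1e-12)
  expect_identical(p0$class, "sound_standing")  # tie -> first class in order
  expect_identical(predict_qda(m, 0.5)$class, "sound_walking")
})

test_that("predictions match brute-force Gaussian density evaluation", {
  fm <- gaussian_classes(n_per = 40, feats = c("Ax", "MV", "SMA"), K = 3,
                         sep = 1.5, seed = 32)
  m <- fit_qda(fm, c("Ax", "MV", "SMA"))
  set.seed(33)
  pts <- matrix(rnorm(50 * 3, mean = 3), 50, 3)
  pr <- predict_qda(m, pts)
  for (i in 1:50) {
    post <- oracle_qda_posterior(m, pts[i, ])
    expect_equal(unname(pr$posterior[i, ]), unname(post), tolerance = 1e-10)
    expect_identical(pr$class[i], names(post)[which.max(post)])
  }
  expect_equal(unname(rowSums(pr$posterior)), rep(1, 50), tolerance = 1e-12)
})

test_that("posteriors agree with an established QDA implementation", {
  skip_if_not_installed("MASS")
  fm <- gaussian_classes(n_per = 35, feats = c("Ax", "MV"), K = 3, sep = 2,
                         seed = 34)
  m <- fit_qda(fm, c("Ax", "MV"), shrinkage = 0)
  ref <- MASS::qda(fm[, c("Ax", "MV")], grouping = factor(fm$behaviour))
  set.seed(35)
  pts <- as.data.frame(matrix(rnorm(40 * 2, mean = 4), 40, 2))
  names(pts) <- c("Ax", "MV")
  ours <- predict_qda(m, pts)
  theirs <- predict(ref, pts)
  expect_identical(ours$class, as.character(theirs$class))
  expect_equal(unname(ours$posterior[, colnames(theirs$posterior)]),
               unname(theirs$posterior), tolerance = 1e-8)
})

test_that("forcing equal covariances gives linear-discriminant behaviour", {
  fm <- gaussian_classes(n_per = 40, feats = c("Ax", "MV"), K = 3, sep = 2,
                         seed = 36)
  m <- fit_qda(fm, c("Ax", "MV"), shrinkage = 0)
  pooled <- Reduce(`+`, m$cov) / length(m$cov)
  for (k in m$classes) {
    m$cov[[k]] <- pooled
    m$chol[[k]] <- chol(pooled)
  }
  set.seed(37)
  pts <- matrix(rnorm(60 * 2, mean = 4, sd = 2), 60, 2)
  pr <- predict_qda(m, pts)
  # linear-discriminant oracle: delta_k = v' W mu_k - mu_k' W mu_k / 2 + ln pi_k
  W <- solve(pooled)
  lin <- sapply(m$classes, function(k) {
    mu <- m$mean[[k]]
    pts %*% W %*% mu - 0.5 * as.numeric(t(mu) %*% W %*% mu) +
      log(m$prior[[k]])
  })
  expect_identical(pr$class, m$classes[apply(lin, 1, which.max)])
})

test_that("a common affine map of the features leaves labels unchanged", {
  feats <- c("Ax", "MV", "SMA")
  fm <- gaussian_classes(n_per = 40, feats = feats, K = 3, sep = 1.5,
                         seed = 38)
  set.seed(39)
  A <- matrix(rnorm(9), 3, 3) + 3 * diag(3)  # well-conditioned, invertible
  b <- rnorm(3)
  fm2 <- fm
  fm2[, feats] <- as.matrix(fm[, feats]) %*% t(A) + rep(b, each = nrow(fm))
  m1 <- fit_qda(fm, feats, shrinkage = 1e-10)
  m2 <- fit_qda(fm2, feats, shrinkage = 1e-10)
  set.seed(40)
  pts <- matrix(rnorm(50 * 3, mean = 3), 50, 3)
  pts2 <- pts %*% t(A) + rep(b, each = 50)
  expect_identical(predict_qda(m1, pts)$class, predict_qda(m2, pts2)$class)
})

test_that("dimension mismatches are rejected", {
  fm <- gaussian_classes(n_per = 10, feats = c("Ax", "MV"), K = 2, seed = 41)
  m <- fit_qda(fm, c("Ax", "MV"))
  expect_error(predict_qda(m, c(1, 2, 3)), "length 3")
  expect_error(predict_qda(m, matrix(1, 2, 3)), "3 columns")
  expect_error(fit_qda(fm, c("Ax", "Nope")), "lacks columns")
})
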