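# Brute-force normal-equations oracle for the RDA R2.
r2_oracle <- function(Y, X) {
  Yc <- scale(Y, scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  B <- solve(t(Xc) %*% Xc) %*% t(Xc) %*% Yc
  sum((Xc %*% B)^2) / sum(Yc^2)
}

test_that("rda R2 matches the normal-equations oracle and Ezekiel adjustment", {
  withr::with_seed(31, {
    Y <- matrix(stats::rnorm(10 * 5), 10, 5)
    X <- matrix(stats::rnorm(10 * 2), 10, 2, dimnames = list(NULL, c("x1", "x2")))
  })
  fit <- rda(Y, X, n_permutations = 99, seed = 1)
  expect_equal(fit$R2, r2_oracle(Y, X), tolerance = 1e-10)
  expect_equal(fit$adjR2, 1 - (1 - fit$R2) * 9 / 7, tolerance = 1e-14)
  # vegan agrees on both
  vfit <- vegan::rda(Y ~ X)
  expect_equal(fit$R2, vegan::RsquareAdj(vfit)$r.squared, tolerance = 1e-10)
  expect_equal(fit$adjR2, vegan::RsquareAdj(vfit)$adj.r.squared, tolerance = 1e-10)
  # saturated model: X spans all the variance of Y
  Xs <- prcomp(Y)$x  # all principal directions
  expect_equal(rda(Y, Xs[, 1:ncol(Xs)], n_permutations = 0)$R2, 1, tolerance = 1e-10)
  # X orthogonal to Y's variation: R2 ~ 0, adjR2 < 0
  withr::with_seed(32, {
    Z <- matrix(stats::rnorm(40 * 3), 40, 3)
    Yb <- matrix(stats::rnorm(40 * 4), 40, 4)
  })
  Yc <- scale(Yb, scale = FALSE)
  Zr <- qr.resid(qr(cbind(1, Yc)), scale(Z, scale = FALSE))  # orthogonalized
  fit2 <- rda(Yb, Zr, n_permutations = 0)
  expect_lt(fit2$R2, 1e-10)
  expect_lt(fit2$adjR2, 0)
  # rank-deficient X errors
  expect_error(rda(Y, cbind(X, x3 = X[, 1]), n_permutations = 0), "rank-deficient")
})

test_that("vif_filter matches the 1/(1-R2) definition and removes collinearity", {
  withr::with_seed(8, X <- matrix(stats::rnorm(30 * 4), 30, 4,
                                  dimnames = list(NULL, paste0("v", 1:4))))
  # orthogonalize -> all VIF ~ 1, nothing removed
  Q <- qr.Q(qr(scale(X, scale = FALSE)))
  colnames(Q) <- paste0("q", 1:4)
  res <- vif_filter(Q)
  expect_length(res$removed, 0)
  expect_true(all(abs(res$vif - 1) < 1e-10))
  # definition oracle via lm
  vifs <- vapply(seq_len(4), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  res2 <- vif_filter(X, threshold = Inf)
  expect_equal(unname(res2$vif), vifs, tolerance = 1e-8)
  # duplicated column: first of the pair removed
  Xd <- cbind(X, v1b = X[, 1])
  res3 <- vif_filter(Xd)
  expect_equal(res3$removed[1], "v1")
  expect_true(all(res3$vif <= 10))
})

test_that("forward selection finds the true predictor and stops on noise", {
  # One informative predictor among pure noise: the adjusted-R2 scope rule
  # (rule 2) legitimately returns an empty set in roughly half the
  # replicates (the single-variable adjR2 fluctuates around the global
  # adjR2; vegan::ordiR2step behaves identically), so the guarantee is
  # "never a noise variable first", not "always selected".
  noise_first <- 0; hits <- 0; nonempty <- 0
  for (s in 1:20) {
    withr::with_seed(400 + s, {
      x_true <- stats::rnorm(30)
      Y <- outer(x_true, c(1, -1, 1, -1)) + matrix(stats::rnorm(30 * 4), 30, 4)
      X <- cbind(true = x_true, matrix(stats::rnorm(30 * 5), 30, 5,
                 dimnames = list(NULL, paste0("noise", 1:5))))
    })
    sel <- forward_select(Y, X, n_permutations = 99, seed = s)
    if (length(sel$selected)) {
      nonempty <- nonempty + 1
      if (sel$selected[1] == "true") hits <- hits + 1 else noise_first <- noise_first + 1
    }
  }
  expect_equal(noise_first, 0)
  expect_equal(hits, nonempty)
  # With two complementary informative predictors the scope rule has
  # headroom and selection succeeds in >= 90% of replicates
  both_found <- 0
  for (s in 1:20) {
    withr::with_seed(500 + s, {
      x1 <- stats::rnorm(30); x2 <- stats::rnorm(30)
      Y <- outer(x1, c(1, -1, 1, -1)) + outer(x2, c(1, 1, -1, -1)) +
        matrix(stats::rnorm(30 * 4), 30, 4)
      X <- cbind(true1 = x1, true2 = x2,
                 matrix(stats::rnorm(30 * 4), 30, 4,
                        dimnames = list(NULL, paste0("noise", 1:4))))
    })
    sel <- forward_select(Y, X, n_permutations = 99, seed = s)
    if (length(sel$selected) >= 1 &&
        all(sel$selected %in% c("true1", "true2"))) both_found <- both_found + 1
  }
  expect_gte(both_found, 18)  # informative-only selections in >= 90%
  # pure-noise response: global pre-test usually refuses to select anything
  empties <- 0
  for (s in 1:20) {
    withr::with_seed(600 + s, {
      Y <- matrix(stats::rnorm(25 * 4), 25, 4)
      X <- matrix(stats::rnorm(25 * 4), 25, 4, dimnames = list(NULL, paste0("n", 1:4)))
    })
    sel <- forward_select(Y, X, n_permutations = 99, seed = s)
    if (!length(sel$selected)) empties <- empties + 1
  }
  expect_gte(empties, 14)  # ~95% expected; allow sampling slack
  # Blanchet rule 2: cumulative adjR2 never exceeds the global model's
  withr::with_seed(77, {
    x <- stats::rnorm(40)
    Y <- outer(x, c(1, 1, 1)) + matrix(stats::rnorm(120, 0, 0.1), 40, 3)
    X <- cbind(a = x, b = x + stats::rnorm(40, 0, 0.05),
               c = stats::rnorm(40))
  })
  sel <- forward_select(Y, X, n_permutations = 99, seed = 2)
  expect_true(all(sel$steps$adjR2_cum <= sel$global_adjR2 + 1e-12))
})

test_that("varpart2 fractions: identity, additivity, orthogonality, vegan oracle", {
  withr::with_seed(21, {
    Y <- matrix(stats::rnorm(30 * 6), 30, 6)
    X1 <- matrix(stats::rnorm(30 * 2), 30, 2)
    X2 <- matrix(stats::rnorm(30 * 2), 30, 2)
  })
  vp <- varpart2(Y, X1, X2, n_permutations = 49, seed = 1)
  f <- vp$fractions
  expect_equal(unname(sum(f)), 1, tolerance = 1e-10)
  # vegan::varpart computes the same adjusted fractions
  # (indfract rows: [a]=X1|X2, [b]=X2|X1, [c]=shared, [d]=residuals)
  vv <- vegan::varpart(Y, X1, X2)$part$indfract$Adj.R.squared
  expect_equal(unname(f[c("pure_env", "pure_spatial", "shared", "residual")]),
               vv, tolerance = 1e-10)
  # identical predictor sets: no unique fractions
  vp_same <- varpart2(Y, X1, X1 + 0, n_permutations = 0 + 9, seed = 1)
  expect_lt(abs(vp_same$fractions["pure_env"]), 1e-10)
  expect_lt(abs(vp_same$fractions["pure_spatial"]), 1e-10)
  # orthogonalized sets at n = 100: tiny shared fraction
  withr::with_seed(22, {
    Yb <- matrix(stats::rnorm(100 * 5), 100, 5)
    A <- matrix(stats::rnorm(100 * 3), 100, 3)
    B <- matrix(stats::rnorm(100 * 3), 100, 3)
  })
  Bo <- qr.resid(qr(cbind(1, A)), B)  # B orthogonal to A
  vp_o <- varpart2(Yb, A, Bo, n_permutations = 9, seed = 1)
  expect_lt(abs(vp_o$fractions["shared"]), 0.02)
  # invariance to invertible reparameterization of one set
  M <- matrix(c(2, 1, 0.5, -1), 2, 2)
  vp_re <- varpart2(Y, X1 %*% M, X2, n_permutations = 9, seed = 1)
  expect_equal(vp_re$fractions, vp$fractions, tolerance = 1e-10)
})

test_that("varpart2 recovers a known environmental variance share", {
  # communities driven by an env gradient + noise: a+b should approach the
  # generated share at n = 100, averaged over seeds
  shares <- vapply(1:10, function(s) {
    withr::with_seed(900 + s, {
      env <- stats::rnorm(100)
      spat <- stats::rnorm(100)
      signal <- outer(env, stats::rnorm(5))
      noise <- matrix(stats::rnorm(500), 100, 5)
      # scale so env explains ~50% of total variance
      Y <- signal / sqrt(sum(signal^2)) + noise / sqrt(sum(noise^2))
    })
    vp <- varpart2(Y, cbind(env), cbind(spat), n_permutations = 0 + 9, seed = s)
    unname(vp$fractions["pure_env"] + vp$fractions["shared"])
  }, numeric(1))
  expect_lt(abs(mean(shares) - 0.5), 0.1)
})
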