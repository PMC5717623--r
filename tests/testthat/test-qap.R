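test_that("qap_permute permutes rows and columns jointly", {
  set.seed(2)
  m <- random_dyad_matrix(5)
  expect_equal(unclass(qap_permute(m, 1:5)), unclass(m))
  # a two-node swap applied twice restores the matrix
  swap <- c(2L, 1L, 3L, 4L, 5L)
  expect_equal(unclass(qap_permute(qap_permute(m, swap), swap)), unclass(m))
  # any permutation preserves the off-diagonal value multiset
  for (rep in 1:10) {
    p <- sample(5)
    mp <- qap_permute(m, p)
    expect_equal(sort(unclass(mp)[row(mp) != col(mp)]),
                 sort(unclass(m)[row(m) != col(m)]))
  }
  # cell semantics: (i, j) -> (p[i], p[j])
  p <- c(3L, 1L, 2L, 5L, 4L)
  mp <- qap_permute(m, p)
  expect_equal(unname(mp[1, 2]), unname(unclass(m)[3, 1]))
  expect_error(qap_permute(m, c(1L, 1L, 2L, 3L, 4L)), "bijection")
  expect_error(qap_permute(m, c("N01", "N01", "N02", "N03", "N04")), "bijection")
})

test_that("MRQAP recovers an exact linear relationship with beta 1 and minimal p", {
  set.seed(31)
  x <- random_dyad_matrix(8)
  y <- x
  y[] <- 2 * unclass(x) + 5  # affine in x: standardized beta exactly 1
  res <- mrqap_dsp(y, list(x = x), n_perm = 199, seed = 1)
  expect_equal(unname(res$coefficients["x"]), 1, tolerance = 1e-10)
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
  expect_equal(unname(res$p_values["x"]), 1 / 200)
  expect_equal(res$n_dyads_used, 8 * 7)
})

test_that("MRQAP point estimates equal the normal-equations OLS solution", {
  set.seed(32)
  ids <- c("a", "b", "c", "d")
  x1 <- random_dyad_matrix(4, ids = ids)
  x2 <- random_dyad_matrix(4, ids = ids)
  y <- random_dyad_matrix(4, ids = ids)
  res <- mrqap_dsp(y, list(x1 = x1, x2 = x2), n_perm = 49, seed = 1)
  # independent oracle: z-score the off-diagonal vectors and solve X'X b = X'y
  off <- row(diag(4)) != col(diag(4))
  z <- function(v) (v - mean(v)) / sd(v)
  Y <- z(unclass(y)[off])
  X <- cbind(z(unclass(x1)[off]), z(unclass(x2)[off]))
  b <- solve(t(X) %*% X, t(X) %*% Y)[, 1]
  expect_equal(unname(res$coefficients), unname(b), tolerance = 1e-10)
  r2 <- 1 - sum((Y - X %*% b)^2) / sum(Y^2)
  expect_equal(res$r_squared, r2, tolerance = 1e-10)
})

test_that("MRQAP errors name collinear predictors and rejects tiny samples", {
  set.seed(33)
  x1 <- random_dyad_matrix(6)
  x2 <- x1
  x2[] <- 3 * unclass(x1)
  y <- random_dyad_matrix(6)
  expect_error(mrqap_dsp(y, list(alpha = x1, beta = x2), n_perm = 9, seed = 1),
               "'alpha' and 'beta' are collinear")
  small <- random_dyad_matrix(2)
  expect_error(mrqap_dsp(small, list(x = random_dyad_matrix(2)), n_perm = 9, seed = 1),
               "complete dyads")
})

test_that("MRQAP results are reproducible given the seed and drop missing dyads", {
  set.seed(34)
  x <- random_dyad_matrix(7)
  y <- random_dyad_matrix(7)
  y[2, 5] <- NA
  a <- mrqap_dsp(y, list(x = x), n_perm = 99, seed = 7)
  b <- mrqap_dsp(y, list(x = x), n_perm = 99, seed = 7)
  expect_identical(a$p_values, b$p_values)
  expect_identical(a$coefficients, b$coefficients)
  expect_equal(a$n_dyads_used, 7 * 6 - 1)
  expect_equal(a$seed, 7)
})

test_that("single-predictor MRQAP reduces to direct OLS QAP regression", {
  set.seed(35)
  x <- random_dyad_matrix(6)
  y <- random_dyad_matrix(6)
  res <- mrqap_dsp(y, list(x = x), n_perm = 19, seed = 1)
  off <- row(diag(6)) != col(diag(6))
  z <- function(v) (v - mean(v)) / sd(v)
  b <- sum(z(unclass(x)[off]) * z(unclass(y)[off])) / sum(z(unclass(x)[off])^2)
  expect_equal(unname(res$coefficients["x"]), b, tolerance = 1e-10)
})

test_that("node-level regression matches oracle OLS and finds a planted identity", {
  # outcome equal to a predictor -> standardized beta 1, minimal p
  set.seed(41)
  x <- rnorm(12)
  res <- node_level_regression(x, data.frame(x = x), n_perm = 199, seed = 1)
  expect_equal(unname(res$coefficients["x"]), 1, tolerance = 1e-10)
  expect_equal(unname(res$p_values["x"]), 1 / 200)
  # two-predictor fixture vs brute-force normal equations
  x1 <- rnorm(15); x2 <- rnorm(15)
  y <- 0.5 * x1 - 0.2 * x2 + rnorm(15)
  res2 <- node_level_regression(y, data.frame(x1 = x1, x2 = x2),
                                n_perm = 99, seed = 2)
  z <- function(v) (v - mean(v)) / sd(v)
  X <- cbind(z(x1), z(x2))
  b <- solve(t(X) %*% X, t(X) %*% z(y))[, 1]
  expect_equal(unname(res2$coefficients), unname(b), tolerance = 1e-10)
  expect_error(node_level_regression(rep(1, 10), data.frame(x = rnorm(10)),
                                     n_perm = 9, seed = 1),
               "constant")
})

test_that("null p-values are approximately uniform for both permutation tests", {
  # node-level: one null predictor, many replicates, KS against uniform
  set.seed(51)
  p_node <- replicate(200, {
    y <- rnorm(12)
    x <- rnorm(12)
    node_level_regression(y, data.frame(x = x), n_perm = 99,
                          seed = sample.int(1e6, 1))$p_values[["x"]]
  })
  ks <- suppressWarnings(ks.test(p_node, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(mean(p_node < 0.05), 0.12)
})
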