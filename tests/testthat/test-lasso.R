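small_training <- function() {
  fixture("small-training", function() {
    bundle <- dna_bundle(8, 300, seed = 7)
    ts <- build_training_set(bundle$alignment, bundle$model, eta = 60,
                             rng_seed = 11)
    list(bundle = bundle, ts = ts)
  })
}

test_that("training sets are reproducible and respect the identity y = rowsums(X)", {
  st <- small_training()
  ts <- st$ts
  expect_identical(ts$y, rowSums(ts$X))
  ts2 <- build_training_set(st$bundle$alignment, st$bundle$model, eta = 60,
                            rng_seed = 11)
  expect_identical(ts$X, ts2$X)
  ts3 <- build_training_set(st$bundle$alignment, st$bundle$model, eta = 2,
                            rng_seed = 12)
  expect_equal(nrow(ts3$X), 2)
  expect_error(build_training_set(st$bundle$alignment, st$bundle$model,
                                  eta = 1, rng_seed = 1), "eta")
})

test_that("standardization yields unit-norm columns and flags constants", {
  st <- small_training()
  std <- standardize_design(st$ts)
  nrm <- sqrt(colSums(std$X_std^2))
  keep <- setdiff(seq_along(nrm), std$dropped)
  expect_lt(max(abs(nrm[keep] - 1)), 1e-10)
  expect_lt(max(abs(colMeans(std$X_std))), 1e-10)
  # a constant column is flagged and held at zero along the whole path
  ts <- st$ts
  ts$X[, 5] <- 3.14
  ts$y <- rowSums(ts$X)
  std2 <- standardize_design(ts)
  expect_true(5 %in% std2$dropped)
  path <- fit_positive_lasso_path(std2$X_std, std2$y_centered,
                                  dropped = std2$dropped)
  expect_true(all(path$beta[5, ] == 0))
})

test_that("standardize/unstandardize round-trips a known linear model", {
  set.seed(123)
  n <- 120; m <- 15
  X <- matrix(rnorm(n * m, sd = 2), n, m)
  beta_true <- runif(m, 0.5, 2)      # all positive so the sign constraint binds nowhere
  b0_true <- 4.2
  y <- b0_true + as.vector(X %*% beta_true)
  std <- standardize_design(list(X = X, y = y))
  path <- fit_positive_lasso_path(std$X_std, std$y_centered,
                                  grid_ratio = 1e-10)
  # unstandardize the essentially-unpenalized solution at the grid minimum
  tail_path <- structure(list(lambda = path$lambda[100],
                              beta = path$beta[, 100, drop = FALSE],
                              nonzero = path$nonzero[100]),
                         class = "lasso_path")
  smp <- select_sample(tail_path, 1.0, std)
  expect_equal(sort(smp$sites), 1:m)
  w <- numeric(m); w[smp$sites] <- smp$weights
  expect_equal(w, beta_true, tolerance = 1e-4)
  expect_equal(smp$intercept, b0_true, tolerance = 1e-4)
  # fitted values reproduce the standardized model's
  pred <- smp$intercept + as.vector(X %*% w)
  expect_equal(pred, y, tolerance = 1e-5)
})

test_that("the lasso path obeys its contracts", {
  st <- small_training()
  std <- standardize_design(st$ts)
  path <- fit_positive_lasso_path(std$X_std, std$y_centered,
                                  dropped = std$dropped,
                                  trace_objective = TRUE)
  expect_equal(length(path$lambda), 100)
  expect_equal(path$lambda[1] * 1e-7, path$lambda[100], tolerance = 1e-9)
  # all-zero solution at the grid maximum
  expect_equal(path$nonzero[1], 0)
  expect_true(all(path$beta >= 0))
  # the active set grows as the penalty decreases until it saturates; with
  # fewer training trees than (highly correlated) sites the solution is not
  # unique and the count jitters, so the check is on the growth trend and the
  # saturation level rather than step-wise monotonicity
  g <- path$nonzero
  half <- seq_len(50)
  expect_gte(cor(half, g[half], method = "spearman"), 0.9)
  expect_gte(g[length(g)], 0.8 * max(g))
  # penalized objective is non-increasing across coordinate-descent sweeps
  for (tr in attr(path, "objective_trace"))
    if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-8))
})

test_that("a duplicated-column block absorbs the known coefficient mass", {
  set.seed(99)
  n <- 150
  base <- rnorm(n)
  X <- cbind(matrix(rep(base, 50), n, 50),     # 50 identical copies
             matrix(rnorm(n * 30), n, 30))
  beta_signal <- 3
  y <- beta_signal * base + rnorm(n, sd = 0.05)
  std <- standardize_design(list(X = X, y = y))
  path <- fit_positive_lasso_path(std$X_std, std$y_centered)
  # at the weakly penalized end the duplicate block carries the signal mass
  gi <- length(path$lambda)
  b <- path$beta[, gi] / std$col_norms
  block_weight <- sum(b[1:50])
  expect_gte(sum(path$beta[1:50, gi] > 0), 1)
  expect_lt(abs(block_weight - beta_signal) / beta_signal, 0.05)
  expect_lt(sum(b[51:80]), 0.05 * beta_signal)  # noise columns stay minor
})

test_that("the positive lasso agrees with glmnet under the sign constraint", {
  skip_if_not_installed("glmnet")
  # well-conditioned design: the solution is unique, so coefficients must match
  set.seed(42)
  n <- 80; m <- 60
  X <- matrix(rnorm(n * m), n, m)
  y <- as.vector(X %*% c(rep(2, 5), rep(0, 55))) + rnorm(n, sd = 0.1)
  std <- standardize_design(list(X = X, y = y))
  path <- fit_positive_lasso_path(std$X_std, std$y_centered)
  for (gi in c(30, 50, 70)) {
    fit <- glmnet::glmnet(std$X_std, std$y_centered,
                          lambda = path$lambda[gi] / (2 * n),
                          lower.limits = 0, standardize = FALSE,
                          intercept = FALSE, thresh = 1e-12)
    bg <- as.vector(stats::coef(fit))[-1]
    expect_equal(path$beta[, gi], bg, tolerance = 1e-2,
                 ignore_attr = TRUE)
    expect_equal(which(path$beta[, gi] > 1e-4), which(bg > 1e-4))
  }
  # near-duplicate per-site log-likelihood columns make coefficients
  # non-identifiable, so on phylogenetic training data the comparison is on
  # the attained penalized objective, not on individual coefficients
  st <- small_training()
  std2 <- standardize_design(st$ts)
  path2 <- fit_positive_lasso_path(std2$X_std, std2$y_centered,
                                   dropped = std2$dropped)
  n2 <- nrow(std2$X_std)
  objective <- function(beta, lam)
    sum((std2$y_centered - std2$X_std %*% beta)^2) + lam * sum(abs(beta))
  for (gi in c(30, 60)) {
    fit <- glmnet::glmnet(std2$X_std, std2$y_centered,
                          lambda = path2$lambda[gi] / (2 * n2),
                          lower.limits = 0, standardize = FALSE,
                          intercept = FALSE, thresh = 1e-12)
    bg <- as.vector(stats::coef(fit))[-1]
    o_mine <- objective(path2$beta[, gi], path2$lambda[gi])
    o_glmnet <- objective(bg, path2$lambda[gi])
    expect_lt(abs(o_mine - o_glmnet) / abs(o_glmnet), 0.01)
  }
})

test_that("sample selection takes the first crossing and reports the achieved fraction", {
  st <- small_training()
  std <- standardize_design(st$ts)
  path <- fit_positive_lasso_path(std$X_std, std$y_centered,
                                  dropped = std$dropped)
  zeta <- 0.05
  smp <- select_sample(path, zeta, std)
  gi <- match(smp$lambda, path$lambda)
  frac <- path$nonzero / nrow(path$beta)
  expect_gte(frac[gi], zeta)
  if (gi > 1) expect_lt(frac[gi - 1], zeta)
  expect_equal(smp$zeta_achieved, length(smp$sites) / smp$m)
  expect_true(all(smp$weights > 0))
  expect_identical(smp$sites, sort(smp$sites))
  # unreachable fraction errors out
  expect_error(select_sample(path, 0.999, std), "not reachable")
})

test_that("the all-sites limit reproduces the exact likelihood", {
  st <- small_training()
  ts <- st$ts
  aln <- st$bundle$alignment
  # identity sample: all sites, unit weights, zero intercept
  ident <- structure(list(sites = seq_len(n_sites(aln)),
                          weights = rep(1, n_sites(aln)),
                          intercept = 0, m = n_sites(aln)),
                     class = "lasso_sample")
  tr <- ts$trees[[1]]
  exact <- total_log_likelihood(tr, aln, st$bundle$model)
  expect_equal(approximate_log_likelihood(tr, ident, aln, st$bundle$model),
               exact, tolerance = 1e-9)
  expect_equal(approximate_log_likelihood(ts$X[1, ], ident), exact,
               tolerance = 1e-9)
  # with many more training trees than sites, the weakly penalized end of the
  # path converges to an exact interpolation (beta = 1 is feasible), so the
  # approximation reproduces the full log-likelihood on the training trees
  small_aln <- msa(aln$mat[, 1:40, drop = FALSE], aln$alphabet)
  ts2 <- build_training_set(small_aln, st$bundle$model, eta = 120,
                            rng_seed = 21)
  std <- standardize_design(ts2)
  path <- fit_positive_lasso_path(std$X_std, std$y_centered,
                                  dropped = std$dropped, grid_ratio = 1e-10,
                                  conv_tol = 1e-6)
  tail_path <- structure(list(lambda = path$lambda[100],
                              beta = path$beta[, 100, drop = FALSE],
                              nonzero = path$nonzero[100]),
                         class = "lasso_path")
  smp <- select_sample(tail_path, path$nonzero[100] / 40, std)
  errs <- vapply(seq_len(20), function(j)
    abs(approximate_log_likelihood(ts2$X[j, ], smp) - ts2$y[j]), 0)
  expect_lt(max(errs), 0.01)
})

test_that("the intercept shifts approximations without changing rankings", {
  st <- small_training()
  ts <- st$ts
  std <- standardize_design(ts)
  path <- fit_positive_lasso_path(std$X_std, std$y_centered,
                                  dropped = std$dropped)
  smp <- select_sample(path, 0.05, std)
  with_b0 <- vapply(1:15, function(j)
    approximate_log_likelihood(ts$X[j, ], smp), 0)
  no_b0 <- vapply(1:15, function(j)
    approximate_log_likelihood(ts$X[j, ], smp, use_intercept = FALSE), 0)
  expect_equal(with_b0 - no_b0, rep(smp$intercept, 15))
  expect_identical(order(with_b0), order(no_b0))
  bad <- smp; bad$sites[1] <- ncol(ts$X) + 5L
  expect_error(approximate_log_likelihood(ts$X[1, ], bad), "exceeds")
})

test_that("lasso samples serialize losslessly to JSON", {
  st <- small_training()
  std <- standardize_design(st$ts)
  path <- fit_positive_lasso_path(std$X_std, std$y_centered,
                                  dropped = std$dropped)
  smp <- select_sample(path, 0.05, std, meta = list(eta = 60, seed = 11))
  f <- withr::local_tempfile(fileext = ".json")
  write_lasso_sample(smp, f)
  back <- read_lasso_sample(f)
  expect_equal(back$sites, smp$sites)
  expect_equal(back$weights, smp$weights)
  expect_equal(back$intercept, smp$intercept)
  expect_equal(back$lambda, smp$lambda)
  expect_equal(back$zeta_achieved, smp$zeta_achieved)
})
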