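test_that("class posteriors implement Bayes rule over all classes", {
  d <- tiny_dina_data(n = 6)
  space <- latent_class_space(2, mixing = c(0.1, 0.2, 0.3, 0.4))
  post <- class_posteriors(d$x, d$q, d$params, space)
  expect_equal(rowSums(post), rep(1, 6))
  # brute-force Bayes rule
  for (i in 1:6) {
    w <- numeric(4)
    for (cc in 1:4) {
      eta <- brute_eta(space$profiles[cc, , drop = FALSE], d$q)
      p <- ifelse(eta == 1, 1 - d$params$slipping, d$params$guessing)
      w[cc] <- space$mixing[cc] *
        prod(ifelse(d$x[i, ] == 1, p, 1 - p))
    }
    expect_equal(unname(post[i, ]), w / sum(w), tolerance = 1e-12)
  }
})

test_that("posterior degenerates correctly in deterministic limits", {
  q <- qmatrix(rbind(c(1, 0), c(0, 1), c(1, 1)))
  space <- latent_class_space(2)
  # s = g = 0: a response pattern consistent with exactly one class
  post <- class_posteriors(matrix(c(1, 0, 0), 1), q,
                           list(slipping = rep(0, 3), guessing = rep(0, 3)),
                           space)
  hit <- which(apply(space$profiles, 1, function(a)
    identical(as.integer(a), c(1L, 0L))))
  expect_equal(unname(post[1, hit]), 1)
  # uninformative items (g = 1 - s) leave the prior untouched
  space2 <- latent_class_space(2, mixing = c(0.4, 0.3, 0.2, 0.1))
  post2 <- class_posteriors(matrix(c(1, 0, 1), 1), q,
                            list(slipping = rep(0.3, 3),
                                 guessing = rep(0.7, 3)), space2)
  expect_equal(unname(post2[1, ]), space2$mixing)
  # a response pattern impossible under every class is rejected loudly
  expect_error(
    class_posteriors(matrix(c(1, 1, 0), 1), q,
                     list(slipping = rep(0, 3), guessing = rep(0, 3)),
                     space),
    "zero total likelihood")
})

test_that("a non-identified design yields a loud singularity error", {
  # attribute 2 is measured by only two items: the DINA information is
  # structurally singular and the covariance must refuse, not guess
  q <- qmatrix(rbind(c(1, 0), c(0, 1), c(1, 1), c(1, 0)))
  set.seed(12)
  prof <- draw_attribute_profiles(400, 2, 0.3, seed = NULL)
  pars <- item_params(runif(4, 0.1, 0.3), runif(4, 0.1, 0.3))
  x <- simulate_responses(prof, q, pars, seed = NULL)
  fit <- em_fit(x, q)
  expect_error(parameter_covariance(fit), "singular")
})

test_that("marginal log-likelihood matches naive class summation", {
  d <- tiny_dina_data(n = 15)
  space <- latent_class_space(2, mixing = c(0.15, 0.35, 0.2, 0.3))
  expect_equal(marginal_loglik(d$x, d$q, d$params, space),
               naive_marginal_loglik(d$x, d$q, d$params$slipping,
                                     d$params$guessing, space$mixing,
                                     space$profiles),
               tolerance = 1e-10)
})

test_that("EM log-likelihood is nondecreasing and convergence is flagged", {
  d <- tiny_dina_data(n = 300, seed = 3)
  fit <- em_fit(d$x, d$q)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_true(all(fit$params$slipping >= 0.001 &
                    fit$params$slipping <= 0.5))
  expect_true(all(fit$params$guessing < 1 - fit$params$slipping))
  short <- em_fit(d$x, d$q, em_options(max_iter = 2))
  expect_false(short$converged)
})

test_that("EM matches a brute-force grid search on a 2-item 1-attribute toy", {
  q <- qmatrix(matrix(1, 2, 1))
  set.seed(14)
  alpha <- rbinom(300, 1, 0.6)
  p1 <- ifelse(alpha == 1, 0.8, 0.15)
  p2 <- ifelse(alpha == 1, 0.75, 0.25)
  x <- cbind(rbinom(300, 1, p1), rbinom(300, 1, p2))
  counts <- table(factor(x[, 1], 0:1), factor(x[, 2], 0:1))
  grid <- expand.grid(s1 = seq(0.05, 0.45, 0.05), g1 = seq(0.05, 0.45, 0.05),
                      s2 = seq(0.05, 0.45, 0.05), g2 = seq(0.05, 0.45, 0.05),
                      pi1 = seq(0.05, 0.95, 0.05))
  ll <- numeric(nrow(grid))
  for (x1 in 0:1) for (x2 in 0:1) {
    pm <- (1 - grid$s1)^x1 * grid$s1^(1 - x1) *
      (1 - grid$s2)^x2 * grid$s2^(1 - x2)
    pn <- grid$g1^x1 * (1 - grid$g1)^(1 - x1) *
      grid$g2^x2 * (1 - grid$g2)^(1 - x2)
    ll <- ll + counts[x1 + 1, x2 + 1] * log(grid$pi1 * pm +
                                              (1 - grid$pi1) * pn)
  }
  best <- grid[which.max(ll), ]
  fit <- em_fit(x, q, em_options(tol = 1e-6))
  # EM finds a likelihood at least as high as the best grid point
  expect_gte(fit$loglik, max(ll) - 1e-8)
  # and its solution sits within one grid step of the grid optimum
  expect_lt(abs(fit$params$slipping[1] - best$s1), 0.051)
  expect_lt(abs(fit$params$slipping[2] - best$s2), 0.051)
  expect_lt(abs(fit$params$guessing[1] - best$g1), 0.051)
  expect_lt(abs(fit$params$guessing[2] - best$g2), 0.051)
  expect_lt(abs(fit$space$mixing[2] - best$pi1), 0.051)
})

test_that("EM recovers generating parameters at N = 5000", {
  fx <- study_fixtures()
  prof <- draw_attribute_profiles(5000, 5, rho = 0.5, seed = 61)
  x <- simulate_responses(prof, fx$q, fx$params, seed = 62)
  fit <- em_fit(x, fx$q)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  rmse_s <- sqrt(mean((fit$params$slipping - fx$params$slipping)^2))
  rmse_g <- sqrt(mean((fit$params$guessing - fx$params$guessing)^2))
  expect_lt(rmse_s, 0.02)
  expect_lt(rmse_g, 0.02)
})

test_that("OPG covariance is symmetric and matches the Bernoulli closed
           form when classes are known", {
  set.seed(9)
  n1 <- 260; n0 <- 140
  x <- c(rbinom(n1, 1, 0.8), rbinom(n0, 1, 0.15))
  z <- rep(c(1, 0), c(n1, n0))                    # known mastery
  s_hat <- 1 - mean(x[z == 1]); g_hat <- mean(x[z == 0])
  fit <- structure(list(
    params = item_params(s_hat, g_hat),
    space = list(profiles = matrix(0:1, 2, 1), mixing = c(n0, n1) / (n0 + n1)),
    posteriors = cbind(1 - z, z),
    q = qmatrix(matrix(1, 1, 1)), x = matrix(x, ncol = 1)),
    class = "dina_fit")
  V <- parameter_covariance(fit)
  expect_equal(V, t(V))
  expect_equal(V["s1", "s1"], s_hat * (1 - s_hat) / n1, tolerance = 1e-10)
  expect_equal(V["g1", "g1"], g_hat * (1 - g_hat) / n0, tolerance = 1e-10)
})

test_that("standard errors shrink roughly as 1/sqrt(N)", {
  d1 <- tiny_dina_data(n = 600, seed = 5)
  set.seed(77)
  prof <- draw_attribute_profiles(2400, 2, 0.3, seed = NULL)
  x4 <- simulate_responses(prof, d1$q, d1$params, seed = NULL)
  se <- function(x, q) sqrt(diag(parameter_covariance(em_fit(x, q))))
  ratio <- median(se(d1$x, d1$q) / se(x4, d1$q))
  expect_equal(ratio, 2, tolerance = 0.25)
})

test_that("multigroup EM shares non-studied items and frees the studied one", {
  fx <- study_fixtures()
  q <- qmatrix(unclass(fx$q)[1:15, ])   # anchors plus two-attribute items
  pars <- item_params(fx$params$slipping[1:15], fx$params$guessing[1:15])
  set.seed(31)
  pr <- draw_attribute_profiles(800, 5, 0.5, seed = NULL)
  pf <- draw_attribute_profiles(800, 5, 0.5, seed = NULL)
  xr <- simulate_responses(pr, q, pars, seed = NULL)
  xf <- simulate_responses(pf, q, pars, seed = NULL)
  fit <- multigroup_em_fit(xr, xf, q, studied_item = 3)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  other <- setdiff(1:15, 3)
  expect_identical(fit$params_ref$slipping[other],
                   fit$params_foc$slipping[other])
  expect_identical(fit$params_ref$guessing[other],
                   fit$params_foc$guessing[other])
  # no DIF generated: group-specific estimates agree within sampling error
  # (the OPG SE of each group difference is about 0.04 here; bound ~ 3 SE)
  expect_lt(abs(fit$params_foc$slipping[3] - fit$params_ref$slipping[3]),
            0.12)
  expect_lt(abs(fit$params_foc$guessing[3] - fit$params_ref$guessing[3]),
            0.12)
  # and the studied item's estimates sit near the pooled single-group fit
  # (the multigroup model has group-specific mixing, so agreement is only
  # up to sampling error)
  pooled <- em_fit(rbind(xr, xf), q)
  expect_lt(abs(mean(c(fit$params_ref$slipping[3],
                       fit$params_foc$slipping[3])) -
                  pooled$params$slipping[3]), 0.03)
  expect_lt(abs(mean(c(fit$params_ref$guessing[3],
                       fit$params_foc$guessing[3])) -
                  pooled$params$guessing[3]), 0.03)
})
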