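# Independent oracle routines used across test files. These deliberately
# take the naive / brute-force path so they never share code with the
# implementation they check.

# eta by an explicit loop over required attributes
brute_eta <- function(profiles, q) {
  n <- nrow(profiles); J <- nrow(q)
  out <- matrix(0L, n, J)
  for (i in seq_len(n)) for (j in seq_len(J)) {
    ok <- TRUE
    for (k in seq_len(ncol(q)))
      if (q[j, k] == 1L && profiles[i, k] == 0L) ok <- FALSE
    out[i, j] <- as.integer(ok)
  }
  out
}

# marginal DINA log-likelihood by direct double summation over classes
naive_marginal_loglik <- function(x, q, s, g, mixing, profiles) {
  total <- 0
  for (i in seq_len(nrow(x))) {
    li <- 0
    for (cc in seq_len(nrow(profiles))) {
      pc <- 1
      for (j in seq_len(ncol(x))) {
        eta <- as.integer(all(profiles[cc, q[j, ] == 1L] == 1L))
        p <- if (eta == 1L) 1 - s[j] else g[j]
        pc <- pc * (if (x[i, j] == 1L) p else 1 - p)
      }
      li <- li + mixing[cc] * pc
    }
    total <- total + log(li)
  }
  total
}

# Mantel-Haenszel chi-square by direct summation over a list of 2x2
# tables, each c(a = ref correct, b = ref wrong, c = focal correct,
# d = focal wrong)
direct_mh <- function(tables, correct = TRUE) {
  num <- 0; den <- 0; sa <- 0
  for (tb in tables) {
    a <- tb[1]; b <- tb[2]; cc <- tb[3]; d <- tb[4]
    n1 <- a + b; n2 <- cc + d; m1 <- a + cc; m0 <- b + d; Tt <- n1 + n2
    sa <- sa + a
    num <- num + n1 * m1 / Tt
    den <- den + n1 * n2 * m1 * m0 / (Tt^2 * (Tt - 1))
  }
  (max(abs(sa - num) - if (correct) 0.5 else 0, 0))^2 / den
}

# binary logistic log-likelihood maximised numerically (oracle for the LR
# DIF statistic)
logistic_ml_loglik <- function(X, y) {
  negll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- optim(rep(0, ncol(X)), negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  -fit$value
}

# small random DINA dataset used by several tests; each attribute is
# measured by three or more items so the model is identified
tiny_dina_data <- function(n = 200, seed = 42) {
  q <- qmatrix(rbind(c(1, 0), c(0, 1), c(1, 1), c(1, 0), c(0, 1), c(1, 1)))
  set.seed(seed)
  prof <- draw_attribute_profiles(n, 2, rho = 0.3, seed = NULL)
  params <- item_params(runif(6, 0.1, 0.3), runif(6, 0.1, 0.3))
  x <- simulate_responses(prof, q, params, seed = NULL)
  list(q = q, profiles = prof, params = params, x = x)
}
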