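#' Ideal-response (eta) matrix of the DINA model
#'
#' The DINA model's "and" gate: examinee \eqn{i} has ideal response 1 on
#' item \eqn{j} iff they master every attribute the item requires,
#' \deqn{\eta_{ij} = \prod_k \alpha_{ik}^{q_{jk}}.}
#'
#' @param profiles N x K binary matrix of attribute mastery indicators
#'   (rows are examinees), e.g. from \code{\link{draw_attribute_profiles}}.
#' @param q a \code{\link{qmatrix}} with K columns.
#' @return N x J binary integer matrix of eta values.
#' @examples
#' q <- study_qmatrix()
#' a <- matrix(c(0, 0, 0, 1, 0), 1)
#' compute_eta(a, q)[1, 1]  # item 1 requires only attribute 4
#' @export
compute_eta <- function(profiles, q) {
  stopifnot(inherits(q, "qmatrix"))
  profiles <- as.matrix(profiles)
  if (ncol(profiles) != ncol(q))
    stop("attribute count mismatch: profiles have ", ncol(profiles),
         " columns but Q-matrix has ", ncol(q))
  if (length(profiles) && !all(profiles %in% c(0, 1)))
    stop("profiles must be binary")
  # eta = 1 iff mastered-required count reaches the item's requirement
  need <- rowSums(q)                       # length J
  have <- profiles %*% t(unclass(q))       # N x J, counts of mastered required
  eta <- matrix(0L, nrow(profiles), nrow(q))
  eta[sweep(have, 2L, need, ">=")] <- 1L
  colnames(eta) <- rownames(q)
  eta
}

#' DINA item response probability
#'
#' Probability of a correct response given the ideal response:
#' \eqn{P(X=1 \mid \eta) = (1-s)^{\eta} g^{1-\eta}}, i.e. \eqn{1-s} for
#' examinees mastering all required attributes and \eqn{g} otherwise.
#'
#' @param eta 0/1 ideal-response indicator (vectorised).
#' @param s slipping probability in [0,1] (vectorised); the boundary gives
#'   the deterministic limit where the response equals eta.
#' @param g guessing probability in [0,1] (vectorised).
#' @return Numeric vector of success probabilities.
#' @export
response_probability <- function(eta, s, g) {
  if (!all(eta %in% c(0, 1))) stop("eta must be binary")
  if (any(s < 0 | s > 1) || any(g < 0 | g > 1))
    stop("slipping and guessing parameters must lie in [0, 1]")
  ifelse(eta == 1, 1 - s, g)
}

#' Item parameter set (slipping and guessing)
#'
#' Bundles per-item slipping and guessing probabilities and enforces the
#' DINA monotonicity constraint \eqn{g_j < 1 - s_j} (mastery may not lower
#' the success probability).
#'
#' @param slipping,guessing numeric vectors of equal length J, each in (0,1).
#' @return A data.frame of class \code{"item_params"} with columns
#'   \code{item}, \code{slipping}, \code{guessing}.
#' @export
item_params <- function(slipping, guessing) {
  if (length(slipping) != length(guessing))
    stop("slipping and guessing must have equal length")
  if (any(slipping <= 0 | slipping >= 1) || any(guessing <= 0 | guessing >= 1))
    stop("parameters must lie strictly in (0, 1)")
  bad <- which(guessing >= 1 - slipping)
  if (length(bad))
    stop("monotonicity violated (g >= 1 - s) for item(s): ",
         paste(bad, collapse = ", "))
  structure(data.frame(item = seq_along(slipping), slipping = slipping,
                       guessing = guessing),
            class = c("item_params", "data.frame"))
}

#' Draw item parameters uniformly
#'
#' Slipping and guessing parameters are drawn independently from
#' U[lower, upper] per item; the study baseline uses U[0.1, 0.3]. With
#' \code{upper <= 0.5} the monotonicity constraint \eqn{g < 1-s} holds by
#' construction.
#'
#' @param j_items number of items.
#' @param lower,upper uniform bounds, \code{0 <= lower < upper <= 0.5}.
#' @param seed integer RNG seed.
#' @return An \code{\link{item_params}} object.
#' @export
draw_item_parameters <- function(j_items, lower = 0.1, upper = 0.3,
                                 seed = 1L) {
  if (lower < 0 || upper > 0.5 || lower >= upper)
    stop("require 0 <= lower < upper <= 0.5")
  local_seed(seed)
  s <- stats::runif(j_items, lower, upper)
  g <- stats::runif(j_items, lower, upper)
  item_params(s, g)
}

#' Draw correlated attribute mastery profiles
#'
#' Each examinee's K latent attribute propensities are multivariate
#' standard normal with equicorrelation \code{rho}; attribute k is mastered
#' iff the latent value is at or above \code{threshold} (default 0, giving
#' marginal mastery probability 0.5). Sampling uses the one-factor
#' representation \eqn{z_k = \sqrt{\rho}\, w + \sqrt{1-\rho}\, e_k}, valid
#' for \eqn{0 \le \rho < 1}.
#'
#' @param n number of examinees (0 allowed).
#' @param k number of attributes.
#' @param rho common pairwise latent correlation in [0, 1).
#' @param seed integer RNG seed.
#' @param threshold dichotomisation cut on the latent scale.
#' @return N x K binary integer matrix of mastery indicators, with
#'   attribute \code{"rho"} recording the generating correlation.
#' @export
draw_attribute_profiles <- function(n, k, rho, seed = 1L, threshold = 0) {
  if (k < 1L) stop("k must be >= 1")
  if (rho < 0 || rho >= 1)
    stop("rho must lie in [0, 1) for the equicorrelated latent model")
  if (n == 0L) {
    out <- matrix(integer(0), 0L, k)
  } else {
    local_seed(seed)
    w <- stats::rnorm(n)
    e <- matrix(stats::rnorm(n * k), n, k)
    z <- sqrt(rho) * w + sqrt(1 - rho) * e
    out <- matrix(0L, n, k)
    out[z >= threshold] <- 1L
  }
  attr(out, "rho") <- rho
  out
}

#' Simulate DINA item responses
#'
#' Generates an N x J binary response matrix: each response is Bernoulli
#' with success probability \eqn{(1-s_j)^{\eta_{ij}} g_j^{1-\eta_{ij}}},
#' independently across examinees and items.
#'
#' @param profiles N x K binary mastery matrix.
#' @param q a \code{\link{qmatrix}}.
#' @param params an \code{\link{item_params}} object with J rows.
#' @param seed integer RNG seed.
#' @return N x J binary integer matrix of responses.
#' @export
simulate_responses <- function(profiles, q, params, seed = 1L) {
  stopifnot(inherits(q, "qmatrix"))
  if (nrow(params) != nrow(q))
    stop("parameter set has ", nrow(params), " items but Q-matrix has ",
         nrow(q))
  eta <- compute_eta(profiles, q)
  p <- ifelse(eta == 1L,
              rep(1 - params$slipping, each = nrow(eta)),
              rep(params$guessing, each = nrow(eta)))
  local_seed(seed)
  x <- matrix(0L, nrow(eta), ncol(eta))
  x[matrix(stats::runif(length(p)), nrow(eta)) < p] <- 1L
  colnames(x) <- rownames(q)
  x
}

# Every stochastic entry point seeds explicitly; NULL continues the
# caller's stream (used internally when a parent already seeded).
local_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible()
}
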