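#' Latent attribute-class space
#'
#' Enumerates all 2^K binary attribute patterns together with a mixing
#' distribution over them; marginal maximum likelihood sums the DINA
#' likelihood over this space.
#'
#' @param k number of attributes.
#' @param mixing optional length-2^K simplex vector (default uniform).
#' @return List of class \code{"latent_class_space"} with \code{profiles}
#'   (2^K x K binary matrix, lexicographic order) and \code{mixing}.
#' @export
latent_class_space <- function(k, mixing = NULL) {
  profs <- as.matrix(expand.grid(rep(list(0:1), k), KEEP.OUT.ATTRS = FALSE))
  colnames(profs) <- paste0("A", seq_len(k))
  storage.mode(profs) <- "integer"
  if (is.null(mixing)) mixing <- rep(1 / nrow(profs), nrow(profs))
  if (length(mixing) != nrow(profs) || any(mixing < 0) ||
      abs(sum(mixing) - 1) > 1e-8)
    stop("mixing must be a nonnegative simplex vector of length 2^k")
  structure(list(profiles = profs, mixing = mixing),
            class = "latent_class_space")
}

# class-conditional success probabilities, C x J:
# p_cj = (1-s_j)^eta_cj * g_j^(1-eta_cj)
class_success_probs <- function(eta_classes, s, g) {
  C <- nrow(eta_classes)
  P <- matrix(rep(g, each = C), C)
  P[eta_classes == 1L] <- rep(1 - s, each = C)[eta_classes == 1L]
  P
}

# N x C matrix of log P(x_i | class c); tolerates boundary probabilities
# (0/1) by treating 0*log(0) as 0.
class_cond_loglik <- function(x, P) {
  lp <- log(P)
  lq <- log1p(-P)
  if (all(is.finite(lp)) && all(is.finite(lq)))
    return(x %*% t(lp - lq) + matrix(rowSums(lq), nrow(x), nrow(P),
                                     byrow = TRUE))
  out <- matrix(0, nrow(x), nrow(P))
  for (cc in seq_len(nrow(P))) {
    v <- x * rep(lp[cc, ], each = nrow(x)) +
      (1 - x) * rep(lq[cc, ], each = nrow(x))
    v[x == 1 & rep(lp[cc, ] == -Inf, each = nrow(x))] <- -Inf
    v[x == 0 & rep(lq[cc, ] == -Inf, each = nrow(x))] <- -Inf
    v[is.nan(v)] <- 0
    out[, cc] <- rowSums(v)
  }
  out
}

#' Posterior class membership probabilities
#'
#' Bayes rule over the latent class space: the posterior for examinee i and
#' class c is proportional to \eqn{\pi_c \prod_j P(x_{ij} \mid \eta_{jc})}.
#'
#' @param x N x J binary response matrix.
#' @param q a \code{\link{qmatrix}}.
#' @param params an \code{\link{item_params}} object, or any list/data.frame
#'   with \code{slipping} and \code{guessing} vectors (boundary values 0/1
#'   are tolerated here to allow deterministic limits).
#' @param space a \code{\link{latent_class_space}}.
#' @return N x 2^K matrix whose rows sum to one.
#' @export
class_posteriors <- function(x, q, params, space) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(q)) stop("response columns must match Q-matrix rows")
  etaC <- compute_eta(space$profiles, q)
  P <- class_success_probs(etaC, params$slipping, params$guessing)
  ll <- class_cond_loglik(x, P)
  w <- exp(sweep(ll, 2L, log(space$mixing), "+"))
  tot <- rowSums(w)
  if (any(tot == 0))
    stop("zero total likelihood for examinee(s) ",
         paste(utils::head(which(tot == 0), 5L), collapse = ", "),
         "; check for boundary parameters inconsistent with the data")
  w / tot
}

#' Marginal log-likelihood of a DINA parameter point
#'
#' Sums the class-conditional likelihood over the latent class space:
#' \eqn{\sum_i \log \sum_c \pi_c \prod_j P(x_{ij} \mid \eta_{jc})}.
#'
#' @inheritParams class_posteriors
#' @return Scalar log-likelihood.
#' @export
marginal_loglik <- function(x, q, params, space) {
  etaC <- compute_eta(space$profiles, q)
  P <- class_success_probs(etaC, params$slipping, params$guessing)
  ll <- class_cond_loglik(as.matrix(x), P)
  sum(log(rowSums(exp(sweep(ll, 2L, log(space$mixing), "+")))))
}

#' EM fit options
#'
#' @param tol convergence tolerance: maximum absolute change in any
#'   parameter (s, g, or mixing proportion) between iterations.
#' @param max_iter iteration cap; hitting it flags non-convergence.
#' @param bounds lower/upper clip for s and g during M-steps; the default
#'   \code{c(0.001, 0.5)} prevents boundary collapse and, jointly with
#'   the upper bound 0.5, preserves \eqn{g < 1 - s}.
#' @param init_sg starting value for every slipping and guessing parameter.
#' @return List of options for \code{\link{em_fit}} /
#'   \code{\link{multigroup_em_fit}}.
#' @export
em_options <- function(tol = 1e-4, max_iter = 1000L, bounds = c(0.001, 0.5),
                       init_sg = 0.2) {
  list(tol = tol, max_iter = max_iter, bounds = bounds, init_sg = init_sg)
}

clip <- function(x, b) pmin(pmax(x, b[1]), b[2])

#' Fit the DINA model by marginal maximum likelihood (EM)
#'
#' Treats the 2^K attribute classes as a finite mixture: the E-step
#' computes class posteriors under current parameters, the M-step updates
#' each item's slipping/guessing from expected correct counts split by the
#' class eta and the mixing proportions from posterior mass. The marginal
#' log-likelihood is nondecreasing across iterations (up to the parameter
#' clipping at the configured bounds).
#'
#' @param x N x J binary response matrix.
#' @param q a \code{\link{qmatrix}}.
#' @param options an \code{\link{em_options}} list.
#' @param init optional warm start: list with \code{slipping},
#'   \code{guessing}, \code{mixing}.
#' @return Object of class \code{"dina_fit"}: \code{params}
#'   (\code{\link{item_params}}), \code{space}
#'   (\code{\link{latent_class_space}} with fitted mixing), \code{loglik},
#'   \code{loglik_trace}, \code{converged}, \code{n_iter},
#'   \code{posteriors}.
#' @export
em_fit <- function(x, q, options = em_options(), init = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 examinees")
  if (ncol(x) != nrow(q)) stop("response columns must match Q-matrix rows")
  K <- ncol(q); J <- nrow(q); C <- 2L^K
  space <- latent_class_space(K)
  etaC <- compute_eta(space$profiles, q)       # C x J
  s <- rep(options$init_sg, J); g <- rep(options$init_sg, J)
  pi_c <- rep(1 / C, C)
  if (!is.null(init)) {
    s <- init$slipping; g <- init$guessing; pi_c <- init$mixing
  }
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    P <- class_success_probs(etaC, s, g)
    ll <- class_cond_loglik(x, P)
    w <- exp(sweep(ll, 2L, log(pi_c), "+"))
    tot <- rowSums(w)
    if (any(tot == 0)) stop("zero likelihood during EM; data degenerate")
    post <- w / tot
    loglik <- sum(log(tot))
    trace <- c(trace, loglik)
    # M-step
    Nc <- colSums(post)                        # class masses
    Rcj <- crossprod(post, x)                  # C x J expected correct
    N1 <- colSums(etaC * Nc); R1 <- colSums(etaC * Rcj)
    N0 <- sum(Nc) - N1;       R0 <- colSums(Rcj) - R1
    s_new <- clip(1 - R1 / pmax(N1, 1e-12), options$bounds)
    g_new <- clip(R0 / pmax(N0, 1e-12), options$bounds)
    pi_new <- Nc / sum(Nc)
    delta <- max(abs(s_new - s), abs(g_new - g), abs(pi_new - pi_c))
    s <- s_new; g <- g_new; pi_c <- pi_new
    if (delta < options$tol) { converged <- TRUE; break }
    if (it >= options$max_iter) break
  }
  space$mixing <- pi_c
  structure(list(params = item_params(s, g), space = space,
                 loglik = trace[length(trace)], loglik_trace = trace,
                 converged = converged, n_iter = it,
                 posteriors = post, q = q, x = x),
            class = "dina_fit")
}

#' @export
print.dina_fit <- function(x, ...) {
  cat("DINA EM fit:", ncol(x$x), "items,", nrow(x$x), "examinees,",
      ncol(x$posteriors), "latent classes\n")
  cat("log-likelihood", format(x$loglik), "after", x$n_iter, "iterations",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

# per-examinee score contributions for one group's item parameters:
# d loglik_i / d s_j = A_ij * (x==1 ? -1/(1-s) : 1/s)   with A = P(eta_j=1|x_i)
# d loglik_i / d g_j = (1-A_ij) * (x==1 ? 1/g : -1/(1-g))
item_scores <- function(x, post, etaC, s, g) {
  A <- post %*% etaC                            # N x J
  Ss <- A * (sweep(-x, 2L, 1 - s, "/") + sweep(1 - x, 2L, s, "/"))
  Sg <- (1 - A) * (sweep(x, 2L, g, "/") - sweep(1 - x, 2L, 1 - g, "/"))
  list(Ss = Ss, Sg = Sg)
}

# scores for free mixing proportions pi_2..pi_C (pi_1 = 1 - sum)
mixing_scores <- function(post, pi_c) {
  sweep(post[, -1L, drop = FALSE], 2L, pi_c[-1L], "/") - post[, 1L] / pi_c[1L]
}

#' Item-parameter covariance from outer products of gradients
#'
#' Estimates the covariance of the maximum-likelihood estimates as the
#' inverse of the empirical cross-product of per-examinee score vectors of
#' the marginal likelihood (OPG / BHHH information), evaluated at the
#' fitted values. The score vector stacks all slipping and guessing
#' parameters and the free mixing proportions; the returned matrix is the
#' item-parameter block of the full inverse (so mixing-estimation
#' uncertainty propagates into the item-parameter covariance).
#'
#' @param fit a \code{"dina_fit"} from \code{\link{em_fit}} or a
#'   \code{"dina_mg_fit"} from \code{\link{multigroup_em_fit}}.
#' @param full if \code{TRUE}, return the full covariance including mixing
#'   proportions.
#' @return Symmetric covariance matrix with labelled rows/columns
#'   (\code{s1..sJ, g1..gJ} for single group; shared plus group-specific
#'   studied-item parameters for multigroup fits).
#' @export
parameter_covariance <- function(fit, full = FALSE) {
  info <- opg_information(fit)
  rc <- tryCatch(solve(info$I), error = function(e)
    stop("singular OPG information (reciprocal condition number ",
         format(1 / kappa(info$I)), "); cannot form covariance"))
  V <- (rc + t(rc)) / 2
  dimnames(V) <- list(info$names, info$names)
  if (full) V else V[info$item_idx, info$item_idx, drop = FALSE]
}

opg_information <- function(fit) {
  if (inherits(fit, "dina_fit")) {
    etaC <- compute_eta(fit$space$profiles, fit$q)
    sc <- item_scores(fit$x, fit$posteriors, etaC,
                      fit$params$slipping, fit$params$guessing)
    Sp <- mixing_scores(fit$posteriors, fit$space$mixing)
    S <- cbind(sc$Ss, sc$Sg, Sp)
    J <- nrow(fit$q); C <- ncol(fit$posteriors)
    nms <- c(paste0("s", 1:J), paste0("g", 1:J), paste0("pi", 2:C))
    return(list(I = crossprod(S), names = nms, item_idx = seq_len(2 * J)))
  }
  if (inherits(fit, "dina_mg_fit")) return(opg_information_mg(fit))
  stop("unsupported fit object")
}
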