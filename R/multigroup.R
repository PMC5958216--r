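#' Two-group DINA fit with one studied item freed
#'
#' Joint marginal maximum-likelihood EM over a reference and a focal
#' group: all items except the studied one share slipping/guessing
#' parameters across groups, the studied item gets group-specific
#' parameters, and the latent-class mixing proportions are group-specific
#' throughout. This is the fitting scheme behind the Wald DIF test: the
#' null of invariance for the studied item is assessed from the
#' group-specific estimates and their joint covariance.
#'
#' @param x_ref,x_foc N x J binary response matrices for the reference and
#'   focal groups (same J).
#' @param q the analysis \code{\link{qmatrix}}, common to both groups.
#' @param studied_item item id whose parameters are group-specific;
#'   \code{NULL} fits the fully invariant model (all items shared), useful
#'   as a warm start.
#' @param options an \code{\link{em_options}} list.
#' @param init optional warm start: list with \code{slipping},
#'   \code{guessing} (shared baseline values), \code{mixing_ref},
#'   \code{mixing_foc}.
#' @return Object of class \code{"dina_mg_fit"}: \code{params_ref},
#'   \code{params_foc} (\code{\link{item_params}}; identical except at the
#'   studied item), \code{mixing_ref}, \code{mixing_foc}, \code{loglik},
#'   \code{loglik_trace}, \code{converged}, \code{n_iter},
#'   \code{studied_item}, plus the posteriors and inputs needed for
#'   covariance computation.
#' @export
multigroup_em_fit <- function(x_ref, x_foc, q, studied_item = NULL,
                              options = em_options(), init = NULL) {
  x_ref <- as.matrix(x_ref); x_foc <- as.matrix(x_foc)
  if (ncol(x_ref) != nrow(q) || ncol(x_foc) != nrow(q))
    stop("response columns must match Q-matrix rows in both groups")
  J <- nrow(q); K <- ncol(q); C <- 2L^K
  space <- latent_class_space(K)
  etaC <- compute_eta(space$profiles, q)
  j0 <- studied_item
  if (!is.null(j0) && (j0 < 1L || j0 > J)) stop("studied_item out of range")

  s_R <- rep(options$init_sg, J); g_R <- rep(options$init_sg, J)
  pi_R <- rep(1 / C, C); pi_F <- pi_R
  if (!is.null(init)) {
    s_R <- init$slipping; g_R <- init$guessing
    if (!is.null(init$mixing_ref)) pi_R <- init$mixing_ref
    if (!is.null(init$mixing_foc)) pi_F <- init$mixing_foc
  }
  s_F <- s_R; g_F <- g_R

  trace <- numeric(0); converged <- FALSE; it <- 0L
  repeat {
    it <- it + 1L
    P_R <- class_success_probs(etaC, s_R, g_R)
    P_F <- class_success_probs(etaC, s_F, g_F)
    w_R <- exp(sweep(class_cond_loglik(x_ref, P_R), 2L, log(pi_R), "+"))
    w_F <- exp(sweep(class_cond_loglik(x_foc, P_F), 2L, log(pi_F), "+"))
    tot_R <- rowSums(w_R); tot_F <- rowSums(w_F)
    if (any(tot_R == 0) || any(tot_F == 0))
      stop("zero likelihood during multigroup EM")
    post_R <- w_R / tot_R; post_F <- w_F / tot_F
    trace <- c(trace, sum(log(tot_R)) + sum(log(tot_F)))

    Nc_R <- colSums(post_R); Nc_F <- colSums(post_F)
    Rcj_R <- crossprod(post_R, x_ref); Rcj_F <- crossprod(post_F, x_foc)
    # pooled expected counts drive the shared items
    N1p <- colSums(etaC * (Nc_R + Nc_F))
    R1p <- colSums((Rcj_R + Rcj_F) * etaC)
    N0p <- sum(Nc_R) + sum(Nc_F) - N1p
    R0p <- colSums(Rcj_R + Rcj_F) - R1p
    s_new <- clip(1 - R1p / pmax(N1p, 1e-12), options$bounds)
    g_new <- clip(R0p / pmax(N0p, 1e-12), options$bounds)
    s_Rn <- s_new; g_Rn <- g_new; s_Fn <- s_new; g_Fn <- g_new
    if (!is.null(j0)) {   # group-specific update for the studied item
      for (grp in c("R", "F")) {
        Nc <- if (grp == "R") Nc_R else Nc_F
        Rcj <- if (grp == "R") Rcj_R else Rcj_F
        N1 <- sum(etaC[, j0] * Nc); R1 <- sum(Rcj[, j0] * etaC[, j0])
        N0 <- sum(Nc) - N1;         R0 <- sum(Rcj[, j0]) - R1
        sv <- clip(1 - R1 / max(N1, 1e-12), options$bounds)
        gv <- clip(R0 / max(N0, 1e-12), options$bounds)
        if (grp == "R") { s_Rn[j0] <- sv; g_Rn[j0] <- gv }
        else            { s_Fn[j0] <- sv; g_Fn[j0] <- gv }
      }
    }
    pi_Rn <- Nc_R / sum(Nc_R); pi_Fn <- Nc_F / sum(Nc_F)
    delta <- max(abs(s_Rn - s_R), abs(g_Rn - g_R), abs(s_Fn - s_F),
                 abs(g_Fn - g_F), abs(pi_Rn - pi_R), abs(pi_Fn - pi_F))
    s_R <- s_Rn; g_R <- g_Rn; s_F <- s_Fn; g_F <- g_Fn
    pi_R <- pi_Rn; pi_F <- pi_Fn
    if (delta < options$tol) { converged <- TRUE; break }
    if (it >= options$max_iter) break
  }
  structure(list(params_ref = item_params(s_R, g_R),
                 params_foc = item_params(s_F, g_F),
                 mixing_ref = pi_R, mixing_foc = pi_F,
                 studied_item = j0,
                 loglik = trace[length(trace)], loglik_trace = trace,
                 converged = converged, n_iter = it,
                 post_ref = post_R, post_foc = post_F,
                 x_ref = x_ref, x_foc = x_foc, q = q),
            class = "dina_mg_fit")
}

#' @export
print.dina_mg_fit <- function(x, ...) {
  cat("Two-group DINA EM fit,", ncol(x$x_ref), "items; studied item:",
      if (is.null(x$studied_item)) "none (fully invariant)" else
        x$studied_item, "\n")
  cat("log-likelihood", format(x$loglik), "after", x$n_iter, "iterations",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

# OPG information for the multigroup parameterisation. Parameter order:
# shared (s_j, g_j) for j != studied; studied (s_R, g_R, s_F, g_F);
# free mixing pi_ref[2..C], pi_foc[2..C].
opg_information_mg <- function(fit) {
  q <- fit$q; J <- nrow(q)
  space <- latent_class_space(ncol(q))
  etaC <- compute_eta(space$profiles, q)
  j0 <- fit$studied_item
  if (is.null(j0)) stop("covariance requires a studied item")
  sc_R <- item_scores(fit$x_ref, fit$post_ref, etaC,
                      fit$params_ref$slipping, fit$params_ref$guessing)
  sc_F <- item_scores(fit$x_foc, fit$post_foc, etaC,
                      fit$params_foc$slipping, fit$params_foc$guessing)
  n_R <- nrow(fit$x_ref); n_F <- nrow(fit$x_foc)
  other <- setdiff(seq_len(J), j0)
  C <- length(fit$mixing_ref)
  S <- rbind(
    cbind(sc_R$Ss[, other, drop = FALSE], sc_R$Sg[, other, drop = FALSE],
          sc_R$Ss[, j0], sc_R$Sg[, j0],
          matrix(0, n_R, 2L),
          mixing_scores(fit$post_ref, fit$mixing_ref),
          matrix(0, n_R, C - 1L)),
    cbind(sc_F$Ss[, other, drop = FALSE], sc_F$Sg[, other, drop = FALSE],
          matrix(0, n_F, 2L),
          sc_F$Ss[, j0], sc_F$Sg[, j0],
          matrix(0, n_F, C - 1L),
          mixing_scores(fit$post_foc, fit$mixing_foc)))
  nms <- c(paste0("s", other), paste0("g", other),
           "sR", "gR", "sF", "gF",
           paste0("piR", 2:C), paste0("piF", 2:C))
  item_idx <- seq_len(2L * (J - 1L) + 4L)
  list(I = crossprod(S), names = nms, item_idx = item_idx)
}
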