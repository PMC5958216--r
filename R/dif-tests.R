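#' @keywords internal
dif_result <- function(item, method, statistic, df, p_value, alpha,
                       valid = TRUE) {
  data.frame(item = item, method = method,
             statistic = statistic, df = df, p_value = p_value,
             flagged = if (valid) p_value < alpha else NA,
             valid = valid)
}

# Mantel-Haenszel chi-square for every item at once. Examinees are
# stratified by total score (0..J, studied item included); per stratum the
# 2x2 table is group x correct. Strata with fewer than 2 examinees or an
# empty group are dropped.
mh_all_items <- function(x_ref, x_foc, alpha = 0.05, correct = TRUE) {
  J <- ncol(x_ref)
  lev <- 0:J
  sc_ref <- factor(rowSums(x_ref), levels = lev)
  sc_foc <- factor(rowSums(x_foc), levels = lev)
  n1 <- as.vector(table(sc_ref))             # ref count per stratum
  n2 <- as.vector(table(sc_foc))
  a <- rowsum(x_ref, sc_ref)                 # (J+1) x J ref correct counts
  a <- a[match(lev, rownames(a)), , drop = FALSE]; a[is.na(a)] <- 0
  cf <- rowsum(x_foc, sc_foc)
  cf <- cf[match(lev, rownames(cf)), , drop = FALSE]; cf[is.na(cf)] <- 0
  Tk <- n1 + n2
  keep <- Tk >= 2 & n1 > 0 & n2 > 0
  m1 <- a + cf
  E <- n1 * m1 / Tk
  V <- n1 * n2 * m1 * (Tk - m1) / (Tk^2 * (Tk - 1))
  sumA <- colSums(a[keep, , drop = FALSE])
  sumE <- colSums(E[keep, , drop = FALSE])
  sumV <- colSums(V[keep, , drop = FALSE])
  if (!any(keep) || all(sumV == 0))
    stop("no usable score strata for the Mantel-Haenszel test")
  num <- abs(sumA - sumE) - if (correct) 0.5 else 0
  stat <- pmax(num, 0)^2 / sumV
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  valid <- sumV > 0
  out <- dif_result(seq_len(J), "MH", stat, 1L, p, alpha, valid = TRUE)
  out$flagged[!valid] <- NA; out$valid <- valid
  out
}

#' Mantel-Haenszel DIF test
#'
#' Stratifies the pooled sample by total test score (the studied item
#' included in the matching score), forms the per-stratum 2x2 table of
#' group by correct/incorrect for the studied item, and computes the
#' continuity-corrected Mantel-Haenszel chi-square (1 df). Score strata
#' with fewer than two examinees or with either group empty are dropped.
#' No purification loop is run.
#'
#' @param x_ref,x_foc binary response matrices for the two groups (same
#'   items).
#' @param item studied item id.
#' @param alpha significance level for flagging.
#' @param correct apply the 0.5 continuity correction (classical default).
#' @return One-row data.frame: \code{item}, \code{method},
#'   \code{statistic}, \code{df}, \code{p_value}, \code{flagged},
#'   \code{valid}.
#' @export
mantel_haenszel_test <- function(x_ref, x_foc, item, alpha = 0.05,
                                 correct = TRUE) {
  stopifnot(ncol(x_ref) == ncol(x_foc))
  mh_all_items(as.matrix(x_ref), as.matrix(x_foc), alpha, correct)[item, ]
}

# 2-df likelihood-ratio logistic DIF for one item.
lr_one_item <- function(y, score, grp, alpha) {
  X0 <- cbind(1, score)
  X1 <- cbind(X0, grp, grp * score)
  f0 <- suppressWarnings(stats::glm.fit(X0, y, family = stats::binomial()))
  f1 <- suppressWarnings(stats::glm.fit(X1, y, family = stats::binomial()))
  valid <- f0$converged && f1$converged && !any(is.na(f1$coefficients))
  stat <- max(f0$deviance - f1$deviance, 0)
  p <- stats::pchisq(stat, df = 2L, lower.tail = FALSE)
  list(stat = stat, p = p, valid = valid)
}

#' Logistic-regression DIF test
#'
#' Fits two nested logistic models for the studied item's response on the
#' pooled sample: the base model with intercept and total score, and the
#' augmented model adding group and group-by-score terms. The 2-df
#' likelihood-ratio statistic jointly tests uniform and nonuniform DIF.
#' The matching total score includes the studied item.
#'
#' @inheritParams mantel_haenszel_test
#' @return One-row data.frame as in \code{\link{mantel_haenszel_test}}
#'   with \code{method = "logistic"} and 2 df. Non-converged or separated
#'   fits are returned with \code{valid = FALSE} and \code{flagged = NA}.
#' @export
logistic_regression_test <- function(x_ref, x_foc, item, alpha = 0.05) {
  stopifnot(ncol(x_ref) == ncol(x_foc))
  x_ref <- as.matrix(x_ref); x_foc <- as.matrix(x_foc)
  y <- c(x_ref[, item], x_foc[, item])
  score <- c(rowSums(x_ref), rowSums(x_foc))
  grp <- rep(c(0, 1), c(nrow(x_ref), nrow(x_foc)))
  r <- lr_one_item(y, score, grp, alpha)
  dif_result(item, "logistic", r$stat, 2L, r$p, alpha, valid = r$valid)
}

#' Wald DIF test from a two-group DINA fit
#'
#' Fits the two-group DINA model with the studied item's slipping and
#' guessing parameters group-specific (\code{\link{multigroup_em_fit}}),
#' forms the difference vector \eqn{d = (g_F - g_R,\; s_F - s_R)}, and
#' computes \eqn{W = d' V^{-1} d} with \eqn{V} the covariance of \eqn{d}
#' extracted from the OPG covariance of the joint fit. The p-value is
#' chi-square with 2 df.
#'
#' @inheritParams mantel_haenszel_test
#' @param q the analysis \code{\link{qmatrix}} (always the original,
#'   unflipped matrix).
#' @param options an \code{\link{em_options}} list.
#' @param null_fit optional fully invariant \code{"dina_mg_fit"} (from
#'   \code{multigroup_em_fit} with \code{studied_item = NULL}) used as a
#'   warm start; pass it when testing many items on the same data.
#' @return One-row data.frame as in \code{\link{mantel_haenszel_test}}
#'   with \code{method = "wald"} and 2 df.
#' @export
wald_dif_test <- function(x_ref, x_foc, q, item, alpha = 0.05,
                          options = em_options(), null_fit = NULL) {
  init <- NULL
  if (!is.null(null_fit))
    init <- list(slipping = null_fit$params_ref$slipping,
                 guessing = null_fit$params_ref$guessing,
                 mixing_ref = null_fit$mixing_ref,
                 mixing_foc = null_fit$mixing_foc)
  fit <- multigroup_em_fit(x_ref, x_foc, q, studied_item = item,
                           options = options, init = init)
  V <- parameter_covariance(fit)
  d <- c(fit$params_foc$guessing[item] - fit$params_ref$guessing[item],
         fit$params_foc$slipping[item] - fit$params_ref$slipping[item])
  L <- matrix(0, 2L, ncol(V), dimnames = list(NULL, colnames(V)))
  L[1, "gF"] <- 1; L[1, "gR"] <- -1
  L[2, "sF"] <- 1; L[2, "sR"] <- -1
  Vd <- L %*% V %*% t(L)
  ok <- fit$converged
  W <- tryCatch(drop(t(d) %*% solve(Vd, d)), error = function(e) NA_real_)
  if (is.na(W) || W < 0) {
    return(dif_result(item, "wald", NA_real_, 2L, NA_real_, alpha,
                      valid = FALSE))
  }
  p <- stats::pchisq(W, df = 2L, lower.tail = FALSE)
  dif_result(item, "wald", W, 2L, p, alpha, valid = ok)
}

#' Run all DIF detection methods on every item
#'
#' Applies the Mantel-Haenszel, logistic-regression, and Wald tests to all
#' J items. The observed-score methods never read the Q-matrix; the Wald
#' test always conditions on the supplied analysis Q-matrix. Per-item
#' estimation failures are recorded (\code{valid = FALSE}), not fatal.
#'
#' @inheritParams wald_dif_test
#' @param methods subset of \code{c("MH", "logistic", "wald")}.
#' @return data.frame with one row per item x method.
#' @export
run_all_methods <- function(x_ref, x_foc, q = NULL, alpha = 0.05,
                            methods = c("MH", "logistic", "wald"),
                            options = em_options()) {
  x_ref <- as.matrix(x_ref); x_foc <- as.matrix(x_foc)
  J <- ncol(x_ref)
  out <- list()
  if ("MH" %in% methods)
    out$mh <- mh_all_items(x_ref, x_foc, alpha)
  if ("logistic" %in% methods) {
    score <- c(rowSums(x_ref), rowSums(x_foc))
    grp <- rep(c(0, 1), c(nrow(x_ref), nrow(x_foc)))
    out$lr <- do.call(rbind, lapply(seq_len(J), function(j) {
      r <- lr_one_item(c(x_ref[, j], x_foc[, j]), score, grp, alpha)
      dif_result(j, "logistic", r$stat, 2L, r$p, alpha, valid = r$valid)
    }))
  }
  if ("wald" %in% methods) {
    if (is.null(q)) stop("the Wald method requires the analysis Q-matrix")
    null_fit <- multigroup_em_fit(x_ref, x_foc, q, studied_item = NULL,
                                  options = options)
    out$wald <- do.call(rbind, lapply(seq_len(J), function(j)
      tryCatch(wald_dif_test(x_ref, x_foc, q, j, alpha, options, null_fit),
               error = function(e)
                 dif_result(j, "wald", NA_real_, 2L, NA_real_, alpha,
                            valid = FALSE))))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
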