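#' The study Q-matrix (31 items, 5 attributes)
#'
#' A fixed, versioned 31 x 5 binary loading structure with items measuring
#' between one and five attributes: ten single-attribute items (two anchors
#' per attribute, giving completeness for identifiability), eight
#' two-attribute, seven three-attribute, four four-attribute and two
#' five-attribute items. The low-complexity stratum (two or fewer
#' attributes) holds items 1-18, the high-complexity stratum (three or
#' more) items 19-31. The same matrix ships as
#' \code{inst/extdata/study_qmatrix.csv}.
#'
#' @return A \code{\link{qmatrix}}.
#' @export
study_qmatrix <- function() {
  rows <- list(
    # single-attribute anchors, two per attribute (items 1-10)
    4, 1, 2, 3, 5, 1, 2, 3, 4, 5,
    # two-attribute items (11-18)
    c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 5), c(1, 3), c(2, 4), c(3, 5),
    # three-attribute items (19-25)
    c(1, 2, 3), c(2, 3, 4), c(3, 4, 5), c(1, 4, 5), c(1, 2, 5), c(1, 3, 4),
    c(2, 4, 5),
    # four-attribute items (26-29)
    c(1, 2, 3, 4), c(2, 3, 4, 5), c(1, 3, 4, 5), c(1, 2, 4, 5),
    # five-attribute items (30-31)
    1:5, 1:5)
  m <- t(vapply(rows, function(r) as.integer(1:5 %in% r), integer(5)))
  qmatrix(m)
}

#' The frozen baseline item parameters
#'
#' One draw of slipping and guessing parameters from U[0.1, 0.3] for the 31
#' study items, fixed study-wide (seed 11364) so that every condition and
#' replication shares the same baseline test. The realized draw has mean
#' slipping 0.228 and mean guessing 0.182, with both parameters ranging
#' over roughly [0.10, 0.30]. Set \code{redraw_seed} to draw a fresh
#' baseline instead.
#'
#' @param redraw_seed optional integer; when given, a fresh U[0.1, 0.3]
#'   draw under this seed replaces the frozen fixture.
#' @return An \code{\link{item_params}} object with 31 rows.
#' @export
study_item_parameters <- function(redraw_seed = NULL) {
  draw_item_parameters(31L, 0.1, 0.3,
                       seed = if (is.null(redraw_seed)) 11364L else redraw_seed)
}

#' The frozen DIF item set
#'
#' Six items (about 20 percent of the test) carry DIF in every non-null
#' condition. The set is selected once via \code{\link{select_dif_items}}
#' (seed 20180511), stratified so that three items come from the
#' low-complexity stratum and three from the high-complexity stratum, and
#' is frozen study-wide so that per-item flag rates are comparable across
#' conditions and replications.
#'
#' @return Sorted integer vector of six item ids.
#' @export
study_dif_items <- function() {
  select_dif_items(study_qmatrix(), n_dif = 6L, seed = 20180511L)
}

#' Select DIF items, stratified by item complexity
#'
#' Draws \code{n_dif} item ids at random, split as evenly as possible
#' between the two complexity strata (two or fewer vs three or more
#' attributes) so both strata contribute DIF items to the power summaries.
#'
#' @param q a \code{\link{qmatrix}}.
#' @param n_dif number of DIF items.
#' @param seed integer RNG seed.
#' @return Sorted integer vector of item ids.
#' @export
select_dif_items <- function(q, n_dif = 6L, seed = 1L) {
  stopifnot(inherits(q, "qmatrix"))
  if (n_dif > nrow(q)) stop("n_dif exceeds item count")
  strat <- complexity_stratum(q)
  low <- which(strat == "2_or_fewer")
  high <- which(strat == "3_or_more")
  n_low <- ceiling(n_dif / 2)
  n_high <- n_dif - n_low
  if (n_low > length(low) || n_high > length(high))
    stop("not enough items in a complexity stratum for the requested split")
  local_seed(seed)
  sort(c(sample(low, n_low), sample(high, n_high)))
}

#' The 17-row DIF pattern table
#'
#' All study DIF patterns: for each size (moderate, delta 0.075; large,
#' delta 0.100) there are two uniform patterns (guessing and slipping
#' shifts sharing a sign) and six nonuniform patterns (opposite signs, or
#' one shift zero), giving 16 non-null patterns, plus the no-DIF baseline.
#' Deltas are focal minus reference.
#'
#' @return data.frame with columns \code{pattern_id}, \code{dif_type}
#'   (\code{uniform}/\code{nonuniform}/\code{none}), \code{dif_size}
#'   (\code{moderate}/\code{large}/\code{none}), \code{delta_g},
#'   \code{delta_s}.
#' @export
dif_condition_table <- function() {
  shapes <- rbind(
    c( 1,  1), c(-1, -1),                      # uniform
    c( 1, -1), c( 1, 0), c(-1, 1), c(-1, 0),   # nonuniform
    c( 0, -1), c( 0, 1))
  out <- do.call(rbind, lapply(c(moderate = 0.075, large = 0.100), function(d)
    data.frame(dif_type = rep(c("uniform", "nonuniform"), c(2L, 6L)),
               delta_g = shapes[, 1] * d, delta_s = shapes[, 2] * d)))
  out$dif_size <- rep(c("moderate", "large"), each = 8L)
  out <- rbind(out,
               data.frame(dif_type = "none", delta_g = 0, delta_s = 0,
                          dif_size = "none"))
  out$pattern_id <- c(sprintf("dif%02d", 1:16), "dif00")
  rownames(out) <- NULL
  out[, c("pattern_id", "dif_type", "dif_size", "delta_g", "delta_s")]
}

#' Apply a DIF pattern to the focal group's item parameters
#'
#' For the DIF items, the focal group's guessing and slipping parameters
#' are shifted by \code{delta_g} and \code{delta_s}; all other items keep
#' the reference values. The reference parameter set is never modified.
#'
#' @param params reference-group \code{\link{item_params}}.
#' @param dif_items integer vector of DIF item ids.
#' @param pattern one row of \code{\link{dif_condition_table}} (or any list
#'   with \code{delta_g}, \code{delta_s}).
#' @return Focal-group \code{\link{item_params}}.
#' @export
apply_dif <- function(params, dif_items, pattern) {
  s <- params$slipping
  g <- params$guessing
  s[dif_items] <- s[dif_items] + pattern$delta_s
  g[dif_items] <- g[dif_items] + pattern$delta_g
  if (any(s <= 0 | s >= 1) || any(g <= 0 | g >= 1))
    stop("DIF shift pushes a parameter outside (0, 1)")
  item_params(s, g)
}

#' Misspecification specification
#'
#' @param position where Q-entry flips may occur: \code{"random"} (any
#'   entry), \code{"low_complexity"} (entries of items measuring two or
#'   fewer attributes), \code{"high_complexity"} (three or more), or
#'   \code{"none"}.
#' @param impacted_group whose generating Q-matrix is flipped:
#'   \code{"both"}, \code{"focal_only"}, or \code{"none"}.
#' @param rate proportion of all Q entries flipped (study value 0.10).
#' @return A list of class \code{"misspec_spec"}.
#' @export
misspec_spec <- function(position = c("random", "low_complexity",
                                      "high_complexity", "none"),
                         impacted_group = c("both", "focal_only", "none"),
                         rate = 0.10) {
  position <- match.arg(position)
  impacted_group <- match.arg(impacted_group)
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  if ((position == "none") != (impacted_group == "none"))
    stop("position is 'none' iff impacted_group is 'none'")
  structure(list(position = position, impacted_group = impacted_group,
                 rate = rate), class = "misspec_spec")
}

# round-half-up; base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)

#' Flip Q-matrix entries at random (misspecification operator)
#'
#' Flips \code{round(rate * J * K)} entries (half-up rounding; 16 of the
#' study's 155 entries at rate 0.10), drawn uniformly without replacement
#' from the eligible pool: all entries for \code{position = "random"}, or
#' the entries of low/high-complexity items, complexity judged on the true
#' Q-matrix. Flip sets that would leave an item requiring no attribute are
#' redrawn. The input matrix is not modified.
#'
#' @param q the true \code{\link{qmatrix}}.
#' @param spec a \code{\link{misspec_spec}} with \code{position != "none"}.
#' @param seed integer RNG seed (\code{NULL} to continue the current
#'   stream).
#' @return A new \code{\link{qmatrix}} with the flipped entries.
#' @export
misspecify_qmatrix <- function(q, spec, seed = 1L) {
  stopifnot(inherits(q, "qmatrix"), inherits(spec, "misspec_spec"))
  if (spec$position == "none") stop("position must not be 'none'")
  n_flip <- round_half_up(spec$rate * length(q))
  strat <- complexity_stratum(q)
  rows_ok <- switch(spec$position,
    random = rep(TRUE, nrow(q)),
    low_complexity = strat == "2_or_fewer",
    high_complexity = strat == "3_or_more")
  pool <- which(matrix(rows_ok, nrow(q), ncol(q)))
  if (length(pool) < n_flip)
    stop("eligible entry pool (", length(pool),
         ") smaller than flip count (", n_flip, ")")
  local_seed(seed)
  for (attempt in 1:1000) {
    idx <- sample(pool, n_flip)
    m <- unclass(q)
    m[idx] <- 1L - m[idx]
    if (all(rowSums(m) > 0L))
      return(qmatrix(m, item_ids = rownames(q), attribute_ids = colnames(q)))
  }
  stop("could not find a flip set leaving no all-zero row")
}

#' The full factorial condition grid
#'
#' Crosses the 17 DIF patterns (16 non-null plus the baseline) with the 7
#' misspecification combinations (3 positions x 2 impacted groups, plus
#' none) and the 3 attribute-correlation levels (0.3, 0.5, 0.8): 357
#' conditions, each with a stable id. Construction is deterministic and
#' order-stable.
#'
#' @return data.frame with one row per condition: \code{condition_id},
#'   the DIF pattern columns, \code{position}, \code{impacted_group},
#'   \code{rate}, \code{rho}.
#' @export
build_condition_grid <- function() {
  dif <- dif_condition_table()
  mis <- rbind(
    data.frame(position = "none", impacted_group = "none", rate = 0),
    expand.grid(position = c("random", "low_complexity", "high_complexity"),
                impacted_group = c("both", "focal_only"),
                rate = 0.10, stringsAsFactors = FALSE))
  rho <- c(0.3, 0.5, 0.8)
  grid <- merge(merge(dif, mis, by = NULL), data.frame(rho = rho), by = NULL)
  # stable ordering: dif pattern, then misspec, then rho
  pos_code <- c(none = "N", random = "R", low_complexity = "L",
                high_complexity = "H")
  grp_code <- c(none = "n", both = "b", focal_only = "f")
  grid <- grid[order(grid$pattern_id, grid$position, grid$impacted_group,
                     grid$rho), ]
  grid$condition_id <- sprintf("%s_%s%s_rho%02.0f", grid$pattern_id,
                               pos_code[grid$position],
                               grp_code[grid$impacted_group], 100 * grid$rho)
  rownames(grid) <- NULL
  grid[, c("condition_id", "pattern_id", "dif_type", "dif_size", "delta_g",
           "delta_s", "position", "impacted_group", "rate", "rho")]
}
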