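#' Study fixtures bundle
#'
#' Collects the frozen design inputs shared by every condition: the study
#' Q-matrix, the baseline item parameters, and the DIF item set.
#'
#' @param q,params,dif_items overrides for the packaged fixtures.
#' @return List with \code{q}, \code{params}, \code{dif_items} and the
#'   derived complexity stratum.
#' @export
study_fixtures <- function(q = study_qmatrix(),
                           params = study_item_parameters(),
                           dif_items = study_dif_items()) {
  list(q = q, params = params, dif_items = dif_items,
       stratum = complexity_stratum(q))
}

#' Derived seed for one replication of one condition
#'
#' Deterministic hash of the condition id mixed with the replication index
#' and the study base seed, kept below 2^31 so any single replication can
#' be regenerated in isolation (and results are independent of execution
#' order or parallel scheduling).
#'
#' @param condition_id character condition identifier.
#' @param rep_index replication number (1-based).
#' @param base_seed study-level integer seed.
#' @return A positive integer seed.
#' @export
replication_seed <- function(condition_id, rep_index, base_seed = 1L) {
  M <- 2147483563
  h <- 0
  for (ch in utf8ToInt(as.character(condition_id))) h <- (h * 31 + ch) %% M
  as.integer(1 + (h + 104729 * as.numeric(rep_index) +
                    7919 * as.numeric(base_seed)) %% (M - 1))
}

as_condition <- function(condition) {
  if (is.data.frame(condition)) {
    stopifnot(nrow(condition) == 1L)
    condition <- as.list(condition)
  }
  condition
}

#' Run one replication of one study condition
#'
#' Draws reference and focal attribute profiles at the condition's
#' correlation, applies the condition's DIF pattern to the focal group's
#' item parameters, flips the generating Q-matrix for the impacted
#' group(s), simulates both groups' responses under the DINA model, and
#' runs the requested DIF methods conditioning on the original (analysis)
#' Q-matrix. Q-entry flips are redrawn each replication from the
#' replication's seed stream.
#'
#' @param condition one row of \code{\link{build_condition_grid}} (or an
#'   equivalent list).
#' @param rep_index replication number.
#' @param fixtures a \code{\link{study_fixtures}} bundle.
#' @param base_seed study-level seed fed to
#'   \code{\link{replication_seed}}.
#' @param n_per_group examinees per group (study value 1000).
#' @param alpha flagging level.
#' @param methods subset of \code{c("MH", "logistic", "wald")}.
#' @param options \code{\link{em_options}} for the Wald fits.
#' @return data.frame with one row per item x method: the test results of
#'   \code{\link{run_all_methods}} plus \code{condition_id},
#'   \code{replication}, \code{is_dif}, \code{stratum}.
#' @export
run_replication <- function(condition, rep_index, fixtures = study_fixtures(),
                            base_seed = 1L, n_per_group = 1000L,
                            alpha = 0.05,
                            methods = c("MH", "logistic", "wald"),
                            options = em_options()) {
  cond <- as_condition(condition)
  q <- fixtures$q
  set.seed(replication_seed(cond$condition_id, rep_index, base_seed))
  prof_ref <- draw_attribute_profiles(n_per_group, ncol(q), cond$rho,
                                      seed = NULL)
  prof_foc <- draw_attribute_profiles(n_per_group, ncol(q), cond$rho,
                                      seed = NULL)
  params_ref <- fixtures$params
  params_foc <- apply_dif(params_ref, fixtures$dif_items,
                          list(delta_g = cond$delta_g,
                               delta_s = cond$delta_s))
  q_gen_ref <- q; q_gen_foc <- q
  if (cond$impacted_group != "none") {
    spec <- misspec_spec(cond$position, cond$impacted_group, cond$rate)
    q_flip <- misspecify_qmatrix(q, spec, seed = NULL)
    q_gen_foc <- q_flip
    if (cond$impacted_group == "both") q_gen_ref <- q_flip
  }
  x_ref <- simulate_responses(prof_ref, q_gen_ref, params_ref, seed = NULL)
  x_foc <- simulate_responses(prof_foc, q_gen_foc, params_foc, seed = NULL)
  res <- run_all_methods(x_ref, x_foc, q = q, alpha = alpha,
                         methods = methods, options = options)
  res$condition_id <- cond$condition_id
  res$replication <- rep_index
  res$is_dif <- res$item %in% fixtures$dif_items &
    cond$dif_type != "none"
  res$stratum <- fixtures$stratum[res$item]
  res
}

#' Run a condition across replications and tabulate flag proportions
#'
#' @inheritParams run_replication
#' @param n_reps number of replications.
#' @return Object of class \code{"dif_result_table"}: a data.frame with
#'   one row per item x method carrying \code{prop_flagged} (mean flag
#'   rate over valid replications), \code{n_valid}, \code{is_dif},
#'   \code{stratum}; attributes record the condition, \code{n_reps}, and
#'   whether more than 20 percent of fits failed for any item/method
#'   (\code{unstable}).
#' @export
run_condition <- function(condition, n_reps, fixtures = study_fixtures(),
                          base_seed = 1L, n_per_group = 1000L, alpha = 0.05,
                          methods = c("MH", "logistic", "wald"),
                          options = em_options()) {
  stopifnot(n_reps >= 1L)
  cond <- as_condition(condition)
  recs <- do.call(rbind, lapply(seq_len(n_reps), function(r)
    run_replication(cond, r, fixtures, base_seed, n_per_group, alpha,
                    methods, options)))
  key <- interaction(recs$item, recs$method, drop = FALSE)
  agg <- do.call(rbind, lapply(split(recs, key), function(d)
    data.frame(item = d$item[1], method = d$method[1],
               prop_flagged = mean(d$flagged, na.rm = TRUE),
               n_valid = sum(!is.na(d$flagged)),
               is_dif = d$is_dif[1], stratum = d$stratum[1])))
  agg <- agg[order(agg$method, agg$item), ]
  rownames(agg) <- NULL
  agg$condition_id <- cond$condition_id
  structure(agg,
            class = c("dif_result_table", "data.frame"),
            condition = cond, n_reps = n_reps,
            unstable = any(agg$n_valid < 0.8 * n_reps))
}

result_tables_to_df <- function(tables) {
  if (inherits(tables, "dif_result_table")) tables <- list(tables)
  do.call(rbind, lapply(tables, function(tb) {
    cond <- attr(tb, "condition")
    df <- as.data.frame(tb)
    df$position <- cond$position
    df$impacted_group <- cond$impacted_group
    df$rho <- cond$rho
    df$dif_size <- cond$dif_size
    df$dif_type <- cond$dif_type
    df
  }))
}

#' Overall Type I error and power per condition
#'
#' The Type I error roll-up averages flag proportions over the non-DIF
#' items; power averages over the DIF items. Because all roll-ups are
#' means of per-item proportions, averaging items before or after
#' replications gives identical values.
#'
#' @param tables a \code{"dif_result_table"} or list of them (from
#'   \code{\link{run_condition}}).
#' @return data.frame: \code{condition_id}, \code{method},
#'   \code{type1_error}, \code{power} (power is \code{NA} for no-DIF
#'   conditions).
#' @export
aggregate_overall <- function(tables) {
  df <- result_tables_to_df(tables)
  out <- do.call(rbind, lapply(
    split(df, list(df$condition_id, df$method), drop = TRUE),
    function(d) data.frame(
      condition_id = d$condition_id[1], method = d$method[1],
      type1_error = mean(d$prop_flagged[!d$is_dif]),
      power = if (any(d$is_dif)) mean(d$prop_flagged[d$is_dif]) else NA_real_)))
  out <- out[order(out$condition_id, out$method), ]
  rownames(out) <- NULL
  out
}

#' Type I error and power by item-complexity stratum
#'
#' Reproduces the layout of the study's stratified tables: mean flag
#' proportions per method and complexity stratum (two or fewer vs three or
#' more attributes, judged on the true Q-matrix), indexed by the seven
#' misspecification group/position combinations. Conditions supplied are
#' averaged within each combination.
#'
#' @param tables a \code{"dif_result_table"} or list of them.
#' @return data.frame: \code{impacted_group}, \code{position},
#'   \code{method}, \code{stratum}, \code{type1_error}, \code{power},
#'   \code{n_conditions}.
#' @export
aggregate_by_complexity <- function(tables) {
  df <- result_tables_to_df(tables)
  if (!all(table(df$stratum) > 0)) stop("empty complexity stratum")
  grp <- list(df$impacted_group, df$position, df$method, df$stratum)
  out <- do.call(rbind, lapply(split(df, grp, drop = TRUE), function(d)
    data.frame(impacted_group = d$impacted_group[1],
               position = d$position[1], method = d$method[1],
               stratum = d$stratum[1],
               type1_error = mean(d$prop_flagged[!d$is_dif]),
               power = if (any(d$is_dif)) mean(d$prop_flagged[d$is_dif])
                       else NA_real_,
               n_conditions = length(unique(d$condition_id)))))
  out <- out[order(out$impacted_group, out$position, out$method,
                   out$stratum), ]
  rownames(out) <- NULL
  out
}

#' Run a configured study and write result CSVs
#'
#' Reads a YAML config with keys \code{conditions} (vector of condition
#' ids, or \code{"all"}), \code{reps}, \code{seed}, \code{alpha},
#' \code{n_per_group}, \code{methods}, \code{output}. Writes one
#' per-condition replication-record CSV (resumable: existing record files
#' are loaded, not recomputed), a per-condition summary
#' (\code{condition_summary.csv}), and a stratified summary
#' (\code{stratified_summary.csv}).
#'
#' @param config path to a YAML config file, or an equivalent named list.
#' @return Invisibly, the list of \code{"dif_result_table"} objects.
#' @export
cli_run <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- list(conditions = "all", reps = 100L, seed = 1L, alpha = 0.05,
                   n_per_group = 1000L,
                   methods = c("MH", "logistic", "wald"),
                   output = "dinadif-results")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  bad <- setdiff(names(cfg), names(defaults))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  grid <- build_condition_grid()
  if (!identical(cfg$conditions, "all")) {
    miss <- setdiff(cfg$conditions, grid$condition_id)
    if (length(miss)) stop("unknown condition id(s): ",
                           paste(miss, collapse = ", "))
    grid <- grid[grid$condition_id %in% cfg$conditions, ]
  }
  dir.create(cfg$output, showWarnings = FALSE, recursive = TRUE)
  fixtures <- study_fixtures()
  tables <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cond <- grid[i, ]
    f <- file.path(cfg$output, paste0("summary_", cond$condition_id, ".csv"))
    if (file.exists(f)) {
      agg <- utils::read.csv(f, comment.char = "#")
      tb <- structure(agg, class = c("dif_result_table", "data.frame"),
                      condition = as.list(cond), n_reps = cfg$reps,
                      unstable = NA)
    } else {
      message("condition ", cond$condition_id, " (", i, "/", nrow(grid), ")")
      tb <- run_condition(cond, cfg$reps, fixtures, base_seed = cfg$seed,
                          n_per_group = cfg$n_per_group, alpha = cfg$alpha,
                          methods = cfg$methods)
      write_with_provenance(as.data.frame(tb), f,
                            sprintf("condition=%s reps=%d seed=%d",
                                    cond$condition_id, cfg$reps, cfg$seed))
    }
    tables[[i]] <- tb
  }
  write_with_provenance(aggregate_overall(tables),
                        file.path(cfg$output, "condition_summary.csv"),
                        sprintf("seed=%d reps=%d", cfg$seed, cfg$reps))
  write_with_provenance(aggregate_by_complexity(tables),
                        file.path(cfg$output, "stratified_summary.csv"),
                        sprintf("seed=%d reps=%d", cfg$seed, cfg$reps))
  invisible(tables)
}
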