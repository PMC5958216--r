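test_that("the study Q-matrix fixture has the declared structure", {
  q <- study_qmatrix()
  expect_equal(dim(q), c(31L, 5L))
  expect_true(all(rowSums(q) >= 1 & rowSums(q) <= 5))
  # every attribute anchored by at least one single-attribute item
  singles <- q[rowSums(q) == 1, , drop = FALSE]
  expect_true(all(colSums(singles) >= 1))
  # both complexity strata populated
  expect_true(all(table(complexity_stratum(q)) > 0))
  # deterministic fixture, identical to the packaged CSV
  expect_identical(study_qmatrix(), study_qmatrix())
  csv <- system.file("extdata", "study_qmatrix.csv", package = "dinadif")
  expect_identical(unclass(read_qmatrix(csv)), unclass(q))
})

test_that("frozen baseline parameters reproduce the study draw summary", {
  p <- study_item_parameters()
  expect_equal(nrow(p), 31L)
  expect_true(all(p$slipping > 0.1 & p$slipping < 0.3))
  expect_true(all(p$guessing > 0.1 & p$guessing < 0.3))
  expect_equal(mean(p$slipping), 0.226, tolerance = 0.01)
  expect_equal(mean(p$guessing), 0.182, tolerance = 0.01)
  expect_false(identical(p, study_item_parameters(redraw_seed = 2)))
})

test_that("DIF pattern table partitions into the design's sign structure", {
  dt <- dif_condition_table()
  expect_equal(nrow(dt), 17L)
  nn <- dt[dt$dif_type != "none", ]
  expect_equal(nrow(nn), 16L)
  expect_equal(unname(table(nn$dif_type, nn$dif_size)["uniform", ]),
               c(2L, 2L))
  expect_equal(unname(table(nn$dif_type, nn$dif_size)["nonuniform", ]),
               c(6L, 6L))
  # uniform iff both deltas nonzero with equal sign
  uni <- nn$delta_g * nn$delta_s > 0
  expect_equal(nn$dif_type == "uniform", uni)
  expect_true(all(abs(nn$delta_g[nn$dif_size == "moderate"]) %in%
                    c(0, 0.075)))
  expect_true(all(abs(nn$delta_g[nn$dif_size == "large"]) %in% c(0, 0.10)))
  # specific published rows
  expect_true(any(nn$delta_g == 0.10 & nn$delta_s == 0.10 &
                    nn$dif_type == "uniform" & nn$dif_size == "large"))
  expect_true(any(nn$delta_g == 0 & nn$delta_s == -0.075 &
                    nn$dif_type == "nonuniform" & nn$dif_size == "moderate"))
  base <- dt[dt$dif_type == "none", ]
  expect_equal(c(base$delta_g, base$delta_s), c(0, 0))
})

test_that("DIF item selection is stratified, frozen, and guarded", {
  q <- study_qmatrix()
  di <- study_dif_items()
  expect_length(di, 6L)
  strat <- complexity_stratum(q)[di]
  expect_equal(as.vector(table(strat)), c(3L, 3L))
  expect_identical(select_dif_items(q, 6, seed = 4),
                   select_dif_items(q, 6, seed = 4))
  expect_error(select_dif_items(q, 40), "n_dif")
  # a stratum with one item cannot host two stratified DIF items
  q2 <- qmatrix(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0),
                      c(1, 1, 1)))
  expect_error(select_dif_items(q2, 4), "stratum")
})

test_that("apply_dif shifts only the DIF items of the focal group", {
  p <- item_params(rep(0.2, 5), rep(0.15, 5))
  foc <- apply_dif(p, c(2, 4), list(delta_g = 0.10, delta_s = -0.075))
  expect_equal(foc$guessing, c(0.15, 0.25, 0.15, 0.25, 0.15))
  expect_equal(foc$slipping, c(0.2, 0.125, 0.2, 0.125, 0.2))
  expect_equal(p$guessing, rep(0.15, 5))   # reference untouched
  none <- apply_dif(p, c(2, 4), list(delta_g = 0, delta_s = 0))
  expect_identical(none, p)
  expect_error(apply_dif(item_params(0.05, 0.92), 1,
                         list(delta_g = 0.10, delta_s = 0)), "outside")
  # interval arithmetic: baseline in [0.1,0.3], |delta| <= 0.10 stays valid
  base <- draw_item_parameters(31, seed = 30)
  shifted <- apply_dif(base, 1:31, list(delta_g = 0.10, delta_s = -0.10))
  expect_true(all(shifted$guessing >= 0 & shifted$guessing <= 0.4))
  expect_true(all(shifted$slipping >= 0 & shifted$slipping <= 0.4))
})

test_that("Q-matrix misspecification flips the right count in the pool", {
  q <- study_qmatrix()
  for (pos in c("random", "low_complexity", "high_complexity")) {
    spec <- misspec_spec(pos, "both", rate = 0.10)
    qm <- misspecify_qmatrix(q, spec, seed = 17)
    diffs <- which(unclass(qm) != unclass(q), arr.ind = TRUE)
    expect_equal(nrow(diffs), 16L)    # round-half-up of 0.10 * 155
    expect_true(all(rowSums(qm) > 0))
    if (pos == "low_complexity")
      expect_true(all(item_complexity(q)[diffs[, 1]] <= 2))
    if (pos == "high_complexity")
      expect_true(all(item_complexity(q)[diffs[, 1]] >= 3))
  }
  # input unmodified; deterministic under seed
  expect_equal(sum(study_qmatrix() != q), 0L)
  spec <- misspec_spec("random", "both")
  expect_identical(misspecify_qmatrix(q, spec, seed = 3),
                   misspecify_qmatrix(q, spec, seed = 3))
  # eligible pool too small: 65 high-complexity entries < 109 flips
  expect_error(misspecify_qmatrix(q, misspec_spec("high_complexity", "both",
                                                  rate = 0.7)), "pool")
  expect_error(misspec_spec("none", "both"), "iff")
})

test_that("the condition grid crosses all design factors", {
  grid <- build_condition_grid()
  expect_equal(nrow(grid), 357L)
  expect_equal(length(unique(grid$condition_id)), 357L)
  # 21 CDM-related combinations per DIF pattern
  cdm <- unique(grid[, c("position", "impacted_group", "rho")])
  expect_equal(nrow(cdm), 21L)
  expect_equal(sort(unique(grid$rho)), c(0.3, 0.5, 0.8))
  # idempotent and order-stable
  expect_identical(grid, build_condition_grid())
})
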