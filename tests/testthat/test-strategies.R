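test_that("the experiment design enumerates 19 unique configurations", {
  specs <- enumerate_model_configs()
  expect_length(specs, 19)
  fam <- vapply(specs, function(s) s$strategy, character(1))
  expect_equal(as.integer(table(fam)[c("NO_BIAS", "TAXIS",
                                       "CONSTANT_HEADING", "BIGRADIENT",
                                       "COMBINATION")]),
               c(1L, 3L, 6L, 3L, 6L))
  labels <- vapply(specs, function(s) s$label, character(1))
  expect_false(anyDuplicated(labels) > 0)
  # arity validation
  expect_error(strategy_spec("TAXIS", c("F", "I")), "1 cue")
  expect_error(strategy_spec("BIGRADIENT", c("F", "F")), "differ")
  expect_error(strategy_spec("CONSTANT_HEADING", "F"), "extreme")
})

test_that("taxis surface scales linearly from minimum 1 to maximum 0", {
  v <- matrix(c(40000, 45000, 50000, 55000, 60000, 42500), 2, 3)
  fg <- toy_grid(v)
  p <- taxis_surface(fg)$values
  expect_equal(p[v == 40000], 1)
  expect_equal(p[v == 60000], 0)
  expect_equal(p[v == 50000], 0.5)
  # antitone in the cue value
  o <- order(v)
  expect_true(all(diff(p[o]) <= 1e-12))
  # spring inversion
  expect_equal(taxis_surface(fg, towards = "max")$values, 1 - p)
  expect_error(taxis_surface(toy_grid(matrix(5, 2, 2))), "constant grid")
})

test_that("constant-heading surface peaks on the optimum-angle ray", {
  # extreme at the east edge, current at centre, target due east:
  # theta* = 0, probability 1 - |angle|/180
  nr <- 11; cs <- 1000
  v <- matrix(50000, nr, nr)
  v[6, 11] <- 40000            # unique minimum due east of the current cell
  fg <- toy_grid(v, cs = cs)
  cur <- c(5000, 5000); tgt <- c(9000, 5000)
  cal <- constant_heading_calibration(fg, cur, tgt, "min")
  expect_equal(cal$theta_star, 0, tolerance = 1e-9)
  s <- constant_heading_surface(fg, cur, tgt, "min", cal)
  g <- s$geometry
  # cells due east of current: angle 0 -> probability 1
  row_c <- 6; col_e <- 8
  expect_equal(s$values[row_c, col_e], 1)
  # cells due west: angle 180 -> probability 0
  expect_equal(s$values[row_c, 2], 0, tolerance = 1e-12)
  # 45-degree deviation -> 0.75
  expect_equal(s$values[row_c - 2, col_e], 0.75, tolerance = 1e-9)
  # brute-force check of every cell against the formula
  xs <- rep((0:(nr - 1)) * cs, each = nr)
  ys <- rep(((nr - 1):0) * cs, times = nr)
  a_ref <- atan2(0, 1)
  ang <- abs(atan2(ys - 5000, xs - 5000) - a_ref)
  ang <- pmin(ang, 2 * pi - ang) * 180 / pi
  ang[xs == 5000 & ys == 5000] <- 0
  expect_equal(as.vector(s$values), 1 - abs(ang - 0) / 180,
               tolerance = 1e-9)
  expect_error(constant_heading_calibration(fg, cur, cur, "min"),
               "target")
})

test_that("bi-gradient surface peaks at the target's cue pair", {
  Fv <- matrix(seq(40000, 60000, length.out = 16), 4, 4)
  Iv <- matrix(seq(80, 20, length.out = 16), 4, 4, byrow = TRUE)
  Fg <- toy_grid(Fv, "F"); Ig <- toy_grid(Iv, "I")
  tv <- c(F = Fv[2, 3], I = Iv[2, 3])
  s <- bigradient_surface(Fg, Ig, tv)
  expect_equal(s$values[2, 3], 1)
  # single-cue arithmetic: range 20000, deviation 15000 -> 0.25
  tv2 <- c(F = 45000, I = 50)
  pF <- 1 - abs(60000 - 45000) / 20000
  expect_equal(pF, 0.25)
  # product structure verified cellwise against the per-cue formula
  s2 <- bigradient_surface(Fg, Ig, tv2)
  pF_all <- pmax(1 - abs(Fv - 45000) / 20000, 0)
  pI_all <- pmax(1 - abs(Iv - 50) / 60, 0)
  expect_equal(s2$values, pF_all * pI_all, tolerance = 1e-12)
  # maximal where the weighted deviation is minimal (exhaustive scan)
  expect_equal(which.max(s2$values), which.max(pF_all * pI_all))
})

test_that("combination surface multiplies map and heading components", {
  nr <- 9
  Fv <- matrix(seq(60000, 40000, length.out = nr^2), nr, nr)
  Iv <- matrix(rep(seq(80, 40, length.out = nr), each = nr), nr, nr)
  Fg <- toy_grid(Fv, "F"); Ig <- toy_grid(Iv, "I")
  cur <- c(4000, 4000); tgt <- c(7000, 4000)
  tv <- c(F = 50000, I = 60)
  s <- combination_surface(Fg, Ig, cur, tgt, tv, "min")
  pm <- pmax(1 - abs(Fv - 50000) / 20000, 0)
  ph <- constant_heading_surface(Ig, cur, tgt, "min")$values
  expect_equal(s$values, pm * ph, tolerance = 1e-12)
  # annihilation and identity
  expect_true(all(s$values[pm == 0] == 0))
  expect_true(all(abs(s$values[pm == 1] - ph[pm == 1]) < 1e-12))
})

test_that("no-bias surface is uniform ones", {
  g <- toy_geometry(4, 6)
  s <- no_bias_surface(g)
  expect_equal(range(s$values), c(1, 1))
})

test_that("every strategy surface stays within [0, 1] on random stacks", {
  for (seed in 1:100) {
    st <- random_stack(seed, nr = 8)
    tgt <- c(st$geometry$origin_x + 2 * st$geometry$cell_size,
             st$geometry$origin_y - 5 * st$geometry$cell_size)
    cur <- c(st$geometry$origin_x + 5 * st$geometry$cell_size,
             st$geometry$origin_y - 2 * st$geometry$cell_size)
    ti <- list(target_values = c(F = value_at(st$F, tgt[1], tgt[2]),
                                 I = value_at(st$I, tgt[1], tgt[2]),
                                 H = value_at(st$H, tgt[1], tgt[2])))
    surfaces <- list(
      taxis_surface(st$F),
      taxis_surface(st$I),
      constant_heading_surface(st$H, cur, tgt, "max"),
      bigradient_surface(st$F, st$I, ti$target_values),
      combination_surface(st$I, st$F, cur, tgt, ti$target_values),
      no_bias_surface(st$geometry))
    for (s in surfaces) {
      expect_gte(min(s$values), 0)
      expect_lte(max(s$values), 1)
      expect_gt(max(s$values), 0)
    }
  }
})
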