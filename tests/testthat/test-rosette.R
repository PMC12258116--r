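test_that("geometry never creates or destroys cells", {
  # horizons keep chain displacement affordable for the fastest-growing c
  for (c in 2:8) {
    Tm <- rosette_horizon(c)
    ros <- simulate_rosette(rule_params(c = c, T = Tm))
    expect_equal(ros$counts$total, oracle_total_cells(c, Tm))
  }
})

test_that("the first daughter sits adjacent to the origin", {
  ros <- simulate_rosette(rule_params(c = 6, T = 1), snapshots = 1)
  cc <- cells_at(ros, 1)
  expect_equal(nrow(cc), 2)
  d1 <- cc[cc$label == 1, ]
  expect_equal(as.character(d1$state), "I")
  expect_equal(sqrt(d1$x^2 + d1$y^2), 1, tolerance = 1e-9)
})

test_that("occupancy is exclusive and the clonogenic cell holds the origin", {
  ros <- simulate_rosette(rule_params(c = 6, T = 14), snapshots = "all")
  for (t in 0:14) {
    cc <- cells_at(ros, t)
    keys <- paste(round(cc$x, 6), round(cc$y, 6))
    expect_false(any(duplicated(keys)))
    at_origin <- cc$label[abs(cc$x) < 1e-9 & abs(cc$y) < 1e-9]
    expect_equal(at_origin, 0L)
  }
})

test_that("the completed leaflet ring has full rotational symmetry", {
  # rotation by 360/c fixes only the origin, so exact multiset symmetry needs
  # the non-origin count divisible by c; growth visits that state at t = c,
  # when the ring of c immature daughters has just closed
  r6 <- simulate_rosette(rule_params(c = 6, T = 6))
  expect_equal(symmetry_order(cells_at(r6, 6)), 6L)
  r4 <- simulate_rosette(rule_params(c = 4, T = 4))
  expect_equal(symmetry_order(cells_at(r4, 4)), 4L)
  # a single off-origin neighbor has no nontrivial symmetry
  r1 <- simulate_rosette(rule_params(c = 6, T = 1))
  expect_equal(symmetry_order(cells_at(r1, 1)), 1L)
})

test_that("all 360/R branch directions populate and grow geometrically", {
  ros12 <- simulate_rosette(rule_params(c = 6, T = 12))
  bc <- branch_counts(ros12)
  expect_equal(nrow(bc), 6)
  expect_true(all(bc$n > 0))                   # six leaflets/branches formed
  expect_equal(sum(bc$n), 34 - 1 - 6)          # total minus clonogenic, ring

  # nothing beyond the first leaflet layer before t reaches c
  early <- simulate_rosette(rule_params(c = 6, T = 6))
  expect_true(all(branch_counts(early)$n == 0))

  # branch totals grow at the p-Fibonacci growth root
  s27 <- sum(branch_counts(simulate_rosette(rule_params(c = 6, T = 27)))$n)
  s28 <- sum(branch_counts(simulate_rosette(rule_params(c = 6, T = 28)))$n)
  expect_equal(s28 / s27, growth_root(6), tolerance = 0.01)
})

test_that("steady-state scheduling bounds the population", {
  st <- simulate_rosette(crypt_steady_params(T = 210))
  pop <- st$counts$total
  # zero linear trend over [3L, 6L] = [105, 210]
  window <- pop[106:211]
  tt <- 105:210
  slope <- stats::coef(stats::lm(window ~ tt))[2]
  expect_lt(abs(slope), 1e-8)
  expect_lt(max(window), 3000)                # bounded, crypt-scale
  cc <- cells_at(st, 210)
  states <- table(as.character(cc$state))
  expect_true(states["W"] > 0)                # outward stream of W cells
  expect_true(states["M"] > 0)                # persistent dividing region
  # W cells die near the edge: every death happened, none before age L
  dead <- st$cells[!st$cells$alive, ]
  expect_gt(nrow(dead), 0)
  expect_true(all(dead$death_time - dead$birth_time == st$params$L))
})

test_that("with n_wm0 = c only the clonogenic cell produces offspring", {
  p <- rule_params(c = 6, T = 30, n_wm0 = 6, L = 20, steady_state = TRUE)
  st <- simulate_rosette(p)
  expect_true(all(st$cells$parent[-1] == 0))
  # one birth per step; deaths start once daughters reach age L
  expect_equal(st$counts$total[1:20], 1:20 + 0)
})

test_that("lifespan limits structure size but not the dividing region", {
  radius <- function(cc) sqrt(cc$x^2 + cc$y^2)
  long <- simulate_rosette(rule_params(c = 6, T = 150, n_wm0 = 11, L = 35,
                                       steady_state = TRUE))
  short <- simulate_rosette(rule_params(c = 6, T = 150, n_wm0 = 11, L = 17,
                                        steady_state = TRUE))
  cl <- cells_at(long, 150); cs <- cells_at(short, 150)
  m_rad <- function(cc)
    max(radius(cc)[as.character(cc$state) %in% c("M", "CLONOGENIC")])
  expect_gt(max(radius(cl)) / max(radius(cs)), 1.3)  # overall extent shrinks
  expect_lt(abs(m_rad(cl) - m_rad(cs)) / m_rad(cl), 0.2)  # region persists
})

test_that("the cylindrical projection is modular and collision-free early on", {
  cc <- tibble::tibble(x = c(0, 1, 43), y = c(0, 2, 2))
  pr <- project_cylinder(cc, circumference = 42)
  expect_equal(pr$angle_rad[1], 0)
  expect_equal(pr$height, cc$y)
  expect_equal(pr$angle_rad[2], pr$angle_rad[3])  # x and x + 42 coincide

  st <- simulate_rosette(crypt_steady_params(T = 27))
  pr <- project_cylinder(cells_at(st, 27))
  keys <- paste(round(pr$angle_rad, 9), round(pr$height, 9))
  expect_false(any(duplicated(keys)))
})

test_that("rotation increments that do not divide 360 are rejected", {
  expect_error(simulate_rosette(rule_params(c = 6, T = 2, R = 70)),
               "divide 360")
})
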