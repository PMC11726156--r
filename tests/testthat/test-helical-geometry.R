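# helical_geometry: crossover, screw operators, stack expansion, fitting

test_that("crossover distance matches rise * 180 / |twist|", {
  # -1.42 deg / 4.76 A: the parameter set whose ribbon crossover is ~600 A
  expect_equal(crossover_distance(helical_params(-1.42, 4.76)),
               4.76 * 180 / 1.42, tolerance = 1e-12)
  expect_equal(crossover_distance(helical_params(-1.42, 4.76)), 603.3803,
               tolerance = 1e-4)
  # half-turn per subunit: one rise per crossover
  expect_equal(crossover_distance(helical_params(-180, 4.76)), 4.76)
  # frozen direct evaluation for the Type II parameter set
  expect_equal(crossover_distance(helical_params(-1.34, 4.76)), 639.40299,
               tolerance = 1e-5)
  expect_error(helical_params(0, 4.76), class = "fibril_value_error")
})

test_that("crossover is monotone decreasing in |twist| and linear in rise", {
  tw <- seq(0.5, 179.5, length.out = 40)
  cx <- vapply(tw, function(t) crossover_distance(helical_params(-t, 4.76)),
               numeric(1))
  expect_true(all(diff(cx) < 0))
  r <- seq(1, 10, length.out = 10)
  cx2 <- vapply(r, function(x) crossover_distance(helical_params(-1.42, x)),
                numeric(1))
  expect_equal(cx2, r * (180 / 1.42), tolerance = 1e-12)
})

test_that("screw operators satisfy group, inverse and axis properties", {
  ax <- screw_axis(origin = c(3, -2, 1), direction = c(0.2, 0.3, 0.93))
  hp <- helical_params(-1.42, 4.76)
  op <- screw_operator(hp, ax)
  # k-fold application equals the single operator with k * twist, k * rise
  k <- 5L
  opk <- Reduce(compose_transforms, rep(list(op), k))
  hp5 <- helical_params(k * hp$twist, k * hp$rise)
  op5 <- screw_operator(hp5, ax)
  pts <- matrix(rnorm(30, sd = 10), ncol = 3)
  expect_equal(apply_transform(opk, pts), apply_transform(op5, pts),
               tolerance = 1e-9)
  # operator then inverse is the identity
  ident <- compose_transforms(invert_transform(op), op)
  expect_equal(apply_transform(ident, pts), pts, tolerance = 1e-9)
  # a point on the axis moves exactly rise along the direction
  p_axis <- ax$origin + 2.5 * ax$direction
  moved <- apply_transform(op, p_axis)
  expect_equal(moved, p_axis + hp$rise * ax$direction, tolerance = 1e-9)
  # operators about the same axis commute
  op_b <- screw_operator(helical_params(10, 1.2), ax)
  expect_equal(apply_transform(compose_transforms(op, op_b), pts),
               apply_transform(compose_transforms(op_b, op), pts),
               tolerance = 1e-9)
})

test_that("expand_stack produces n rungs with correct spacing and rigidity", {
  pair <- make_fold_pair(seed = 2)
  r <- rung(template_atoms(pair$a))
  hp <- helical_params(-1.42, 4.76)
  # n = 1 leaves the rung unchanged
  m1 <- expand_stack(r, hp, 1)
  expect_equal(coords(m1$atoms), coords(r$atoms), tolerance = 1e-12)
  expect_error(expand_stack(r, hp, 0), class = "fibril_argument_error")
  m3 <- expand_stack(r, hp, 3)
  expect_identical(n_rungs(m3), 3L)
  expect_identical(sort(unique(m3$atoms$rung_index)), 0:2)
  # centroid spacing along the axis equals the rise
  cen_z <- vapply(0:2, function(i) {
    mean(m3$atoms$z[m3$atoms$rung_index == i])
  }, numeric(1))
  expect_equal(diff(cen_z), rep(4.76, 2), tolerance = 1e-9)
  # rigidity: intra-rung distances preserved across rungs
  d0 <- dist(coords(get_rung(m3, 0)$atoms))
  d2 <- dist(coords(get_rung(m3, 2)$atoms))
  expect_lt(max(abs(d0 - d2)), 1e-9)
})

test_that("expand_stack then fit_helical_params round-trips twist and rise", {
  for (seed in 1:8) {
    set.seed(seed)
    twist <- sample(c(-1, 1), 1) * runif(1, 0.3, 30)
    rise <- runif(1, 2, 8)
    pair <- make_fold_pair(seed = seed)
    m <- make_stack(pair$b, helical_params(twist, rise), 4)
    fit <- fit_helical_params(get_rung(m, 1), get_rung(m, 2))
    expect_equal(fit$params$twist, twist, tolerance = 1e-6)
    expect_equal(fit$params$rise, rise, tolerance = 1e-6)
    expect_lt(fit$rmsd, 1e-8)
    # fitted axis is the generator's z axis
    expect_equal(abs(sum(fit$axis$direction * c(0, 0, 1))), 1,
                 tolerance = 1e-6)
    expect_lt(sqrt(sum(fit$axis$origin[1:2]^2)), 1e-5)
  }
})

test_that("fit_helical_params recovers an off-origin, tilted generator", {
  pair <- make_fold_pair(seed = 9)
  ax <- screw_axis(origin = c(10, 5, -3), direction = c(1, 2, 9))
  hp <- helical_params(-1.34, 4.76)
  m <- expand_stack(rung(template_atoms(pair$a)), hp, 3, axis = ax)
  fit <- fit_helical_params(get_rung(m, 0), get_rung(m, 1))
  expect_equal(fit$params$twist, hp$twist, tolerance = 1e-6)
  expect_equal(fit$params$rise, hp$rise, tolerance = 1e-6)
  expect_equal(abs(sum(fit$axis$direction * ax$direction)), 1, tolerance = 1e-9)
  # fitted origin lies on the generator axis
  v <- fit$axis$origin - ax$origin
  expect_lt(sqrt(sum((v - sum(v * ax$direction) * ax$direction)^2)), 1e-6)
})

test_that("degenerate screws are rejected", {
  pair <- make_fold_pair(seed = 4)
  r <- get_rung(make_stack(pair$a, helical_params(-1.34, 4.76), 2), 0)
  expect_error(fit_helical_params(r, r),
               class = "fibril_degenerate_screw_error")
  r2 <- r
  expect_error(fit_helical_params(r, rung(r2$atoms, index = r2$index)),
               class = "fibril_degenerate_screw_error")
})
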