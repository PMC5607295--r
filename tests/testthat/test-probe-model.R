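test_that("probe channels expose normalized exit Stokes vectors", {
  p <- ideal_probe()
  expect_equal(p$channels$H1$exit_stokes, c(1, 1, 0))
  expect_equal(p$channels$V2$exit_stokes, c(1, -1, 0))
  expect_equal(p$channels$B1$exit_stokes, c(1, 0, -1), tolerance = 1e-15)
  # a partially polarised source still leaves fully polarised channel exits
  pp <- build_probe(list(source = list(dop = 0.15, axis_deg = 20)))
  for (ch in pp$channels) {
    expect_equal(ch$exit_stokes[1], 1)
    expect_equal(sqrt(sum(ch$exit_stokes[2:3]^2)), 1, tolerance = 1e-12)
  }
  expect_error(build_probe(list(bogus = 1)), "unknown probe config keys")
  expect_error(
    build_probe(list(channels = list(H1 = list(exit_stokes = c(0, 1, 0))))),
    "I > 0")
})

test_that("analyzer rows flip the sign of U", {
  p <- ideal_probe()
  expect_equal(analyzer_row(p, "H1"), 0.5 * c(1, 1, 0))
  expect_equal(analyzer_row(p, "V2"), 0.5 * c(1, -1, 0))
  expect_equal(analyzer_row(p, "B1"), 0.5 * c(1, 0, 1), tolerance = 1e-15)
  expect_error(analyzer_row(p, "X9"), "unknown channel")
})

test_that("pair intensities reproduce the hand-computed mirror and identity cases", {
  p <- ideal_probe()
  mirror3 <- diag(c(1, 1, -1))
  expect_equal(simulate_intensity(p$channels$H1, p$channels$H2, mirror3), 1)
  expect_equal(simulate_intensity(p$channels$H1, p$channels$V2, mirror3), 0)
  expect_equal(simulate_intensity(p$channels$B1, p$channels$B2, mirror3), 1)
  expect_error(simulate_intensity(p$channels$H1, p$channels$H2, mirror3,
                                  gain = -1), "gain")
  ms <- simulate_measurement_set(p, diag(3))
  expect_equal(unname(ms["H1H2"]), 1)
  expect_equal(unname(ms["H1V2"]), 0)
  expect_equal(unname(ms["H1B1"]), 0.5, tolerance = 1e-15)
})

test_that("intensities are linear in gain and sample matrix", {
  p <- ideal_probe()
  # physical samples keep every raw pair intensity non-negative, so the
  # zero-clamp never bites and linearity holds exactly
  s1 <- make_synthetic_tissue(50, 30, c(0.8, 0.9), diatten = 0.05)
  s2 <- make_synthetic_tissue(120, 100, c(0.6, 0.7), mode = "reflection")
  base <- simulate_measurement_set(p, s1)
  expect_equal(simulate_measurement_set(p, 3 * s1), 3 * base)
  expect_equal(simulate_measurement_set(p, s1 + s2),
               base + simulate_measurement_set(p, s2))
  gains <- stats::setNames(rep(2.5, 9), pair_labels())
  p2 <- build_probe(list(source = list(dop = 0), gains = gains))
  expect_equal(simulate_measurement_set(p2, s1), 2.5 * base)
})

test_that("noisy measurement sets are reproducible under a fixed seed", {
  p <- build_probe(list())
  nm <- noise_model(sigma_rel = 0.02, dark = 0.001)
  a <- simulate_measurement_set(p, diag(c(1, 1, -1)), noise = nm, seed = 33)
  b <- simulate_measurement_set(p, diag(c(1, 1, -1)), noise = nm, seed = 33)
  cc <- simulate_measurement_set(p, diag(c(1, 1, -1)), noise = nm, seed = 34)
  expect_identical(a, b)
  expect_false(identical(a, cc))
  expect_true(all(a >= 0))
})

test_that("the collection fibre drops out of the detected intensity", {
  # Full 4x4 chain (collection fibre . collection micro-polariser in the
  # reflected frame . sample) against the reduced analyzer-row form.
  p <- ideal_probe()
  set.seed(6)
  tab <- pair_scheme()
  for (i in 1:30) {
    row <- tab[sample(nrow(tab), 1), ]
    illum <- p$channels[[row$illum]]
    collect <- p$channels[[row$collect]]
    m4 <- matrix(stats::rnorm(16), 4, 4)
    s_in <- c(illum$exit_stokes, 0)
    fibre <- random_nondepolarising4()
    micro <- linear_polariser_mueller(180 - collect$polariser_angle)
    full <- (fibre %*% micro %*% m4 %*% s_in)[1]
    # analyzer-row reduction (no zero-clamp: this is a pure algebra check)
    reduced <- drop(analyzer_row(collect) %*% m4[1:3, 1:3] %*%
                      illum$exit_stokes)
    expect_equal(full, reduced, tolerance = 1e-12)
  }
})

test_that("per-fibre gains expand to per-pair products", {
  g6 <- c(H1 = 2, H2 = 3, V1 = 5, V2 = 7, B1 = 11, B2 = 13)
  p <- build_probe(list(source = list(dop = 0), gains = g6))
  expect_equal(unname(p$couplings["H1H2"]), 2 * 3)
  expect_equal(unname(p$couplings["V2B1"]), 7 * 11)
  expect_equal(unname(p$couplings["B1B2"]), 11 * 13)
  expect_error(build_probe(list(gains = c(H1H2 = 1))), "gains")
  expect_error(build_probe(list(gains = stats::setNames(c(-1, rep(1, 8)),
                                                        pair_labels()))),
               "positive")
})

test_that("footprint grows with working distance and respects the geometry", {
  geom <- ideal_probe()$geometry
  fp0 <- footprint(0, geom)
  expect_equal(fp0$spot_diameter_mm, 0.4)
  expect_equal(fp0$half_angle_deg, asin(0.39) * 180 / pi, tolerance = 1e-12)
  expect_equal(footprint(1, utils::modifyList(geom, list(pitch_um = 0))
                         )$pairwise_overlap_fraction[["H1H2"]], 1)
  d <- c(0, 0.5, 1, 2, 5)
  spots <- vapply(d, function(x) footprint(x, geom)$spot_diameter_mm,
                  numeric(1))
  expect_true(all(diff(spots) > 0))
  ovl <- vapply(d, function(x)
    footprint(x, geom)$pairwise_overlap_fraction[["H1H2"]], numeric(1))
  expect_true(all(diff(ovl) >= 0))
  expect_error(footprint(1, utils::modifyList(geom, list(na = 1.5))),
               "medium_ri")
  expect_error(footprint(-1, geom))
})

test_that("synthetic tissue fixtures compose as declared", {
  expect_matrix_equal(make_synthetic_tissue(0, 0, c(1, 1), 0), diag(3))
  expect_matrix_equal(
    make_synthetic_tissue(60, 90, mode = "reflection"),
    diag(c(1, 1, -0.5)))
  m <- make_synthetic_tissue(40, 30, c(0.7, 0.9), diatten = 0.1)
  expect_equal(attr(m, "truth")$delta, 40)
  expect_equal(diattenuation(m), 0.1, tolerance = 1e-12)
  expect_error(make_synthetic_tissue(depol_factors = c(1.2, 1)), "depol")
  expect_error(make_synthetic_tissue(diatten = 1), "diattenuation")
})
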