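
test_that("longitudinal velocity follows the elastic closed form", {
  expect_equal(longitudinal_velocity(1, 1, 0), 1)

  v1 <- longitudinal_velocity(5e9, 500, 0.25)
  v2 <- longitudinal_velocity(5e9, 1000, 0.25)
  expect_equal(v1 / v2, sqrt(2), tolerance = 1e-12)

  E <- 10e9; rho <- 600; sig <- 0.3
  expect_equal(longitudinal_velocity(E, rho, sig),
               sqrt((E / rho) * (1 - sig) / ((1 + sig) * (1 - 2 * sig))),
               tolerance = 1e-12)

  expect_error(longitudinal_velocity(1e9, 500, 0.5), "diverges")
  expect_error(longitudinal_velocity(-1, 500, 0.3), "positive")
})

test_that("velocity is monotone in density and stiffness", {
  rhos <- seq(300, 1200, by = 50)
  vs <- longitudinal_velocity(8e9, rhos, 0.3)
  expect_true(all(diff(vs) < 0))

  Es <- seq(1e9, 2e10, length.out = 20)
  vs <- longitudinal_velocity(Es, 600, 0.3)
  expect_true(all(diff(vs) > 0))
})

test_that("pulse-echo velocity is the round trip over the echo time", {
  expect_equal(velocity_from_echo(1, 2), 1)
  expect_equal(velocity_from_echo(0.5, 1) / velocity_from_echo(0.5, 2), 2)
  # consistency with the fastest immersion-sample velocity
  expect_equal(velocity_from_echo(0.02, 2 * 0.02 / 4706), 4706,
               tolerance = 1e-12)
  expect_error(velocity_from_echo(0, 1), "positive")
})

test_that("geometry helpers give textbook volumes and densities", {
  expect_equal(sample_volume("cylinder", c(6, 6)), pi * 9 * 6)
  expect_equal(sample_volume("cuboid", c(2, 4, 10)), 80)
  expect_equal(sample_volume("cylinder", c(10, 10)), pi * 25 * 10)
  expect_error(sample_volume("cylinder", c(6, 6, 6)), "diameter and height")

  expect_equal(round(bulk_density(102.60, sample_volume("cylinder", c(6, 6))), 2), 0.60)
  expect_equal(round(bulk_density(294.00, sample_volume("cylinder", c(10, 10))), 2), 0.37)
  expect_equal(bulk_density(42, 42), 1)
})

test_that("moisture formulas reproduce the reported spot values", {
  V6 <- sample_volume("cylinder", c(6, 6))
  expect_equal(volumetric_moisture(102.60, 102.60, 1, V6), 0)
  expect_equal(round(volumetric_moisture(173.60, 102.60, 1, V6), 2), 0.42)
  expect_equal(round(volumetric_moisture(115.80, 102.60, 1, V6), 2), 0.08)
  expect_error(volumetric_moisture(100, 102.60, 1, V6), "below")

  expect_equal(round(mass_moisture(173.60, 102.60), 2), 0.41)
  expect_equal(round(mass_moisture(106.60, 102.60), 2), 0.04)
  expect_equal(mass_moisture(50, 50), 0)
})

test_that("all derived immersion rows match the printed tables to 2 d.p.", {
  res <- immersion_analysis(table2_immersion())
  for (sid in rownames(ref_density)) {
    sub <- res$table[res$table$sample_id == sid, ]
    expect_equal(nrow(sub), 15L)
    # half a unit in the second decimal place (the printed resolution)
    expect_true(all(abs(sub$density_g_cm3 - ref_density[sid, ]) <= 0.0051),
                label = paste("density row", sid))
    expect_true(all(abs(sub$mass_mc - ref_mass_mc[sid, ]) <= 0.0051),
                label = paste("mass moisture row", sid))
    expect_true(all(abs(sub$vol_mc - ref_vol_mc[sid, ]) <= 0.0051),
                label = paste("volumetric moisture row", sid))
    # water uptake is monotone over the soak
    expect_true(!is.unsorted(sub$mass_mc))
    expect_true(!is.unsorted(sub$vol_mc))
  }
})

test_that("velocity-moisture quadratic fit agrees with the normal equations", {
  set.seed(71)
  theta <- seq(0, 0.4, length.out = 12)
  v <- 4500 - 9000 * theta + 4000 * theta^2 + rnorm(12, sd = 40)
  rec <- data.frame(sample_id = "s", shape = "cylinder", dim1_cm = 6,
                    dim2_cm = 6, dim3_cm = NA, timepoint_min = seq_len(12),
                    mass_g = 100 + theta * pi * 54, velocity_m_s = v)
  res <- immersion_analysis(rec)
  # same theta enters the package fit, so coefficients must match the
  # explicit least-squares solve on the package's own derived theta
  th <- res$table$vol_mc
  expect_equal(unname(res$fits$s$coefficients), unname(quad_fit_oracle(th, v)),
               tolerance = 1e-8)

  # exactly quadratic data fit perfectly
  rec$velocity_m_s <- 4500 - 9000 * th + 4000 * th^2
  expect_equal(immersion_analysis(rec)$fits$s$correlation, 1, tolerance = 1e-9)
})

test_that("samples with too few points are excluded with a warning", {
  rec <- table2_immersion()
  short <- rec[rec$sample_id != "cyl6" | rec$timepoint_min < 30, ]
  expect_warning(res <- immersion_analysis(short), "cyl6")
  expect_named(res$fits, c("cyl7", "cyl10"))

  lone <- rec[rec$sample_id == "cyl6" & rec$timepoint_min < 30, ]
  expect_warning(expect_error(immersion_analysis(lone), "no sample"))
})

test_that("beta rescales the volumetric moisture only", {
  res1 <- immersion_analysis(table2_immersion(), beta = 1)
  res2 <- immersion_analysis(table2_immersion(), beta = 0.998)
  expect_equal(res2$table$vol_mc, res1$table$vol_mc / 0.998)
  expect_equal(res2$table$mass_mc, res1$table$mass_mc)
})

test_that("track_correlation is the Pearson correlation of aligned pairs", {
  t <- 1:20
  picks <- data.frame(timestamp = t, onset_pu = 1.4 + 0.01 * sin(t))
  same <- data.frame(timestamp = t, soil = picks$onset_pu)
  expect_equal(track_correlation(picks, same), 1)
  neg <- data.frame(timestamp = t, soil = -picks$onset_pu)
  expect_equal(track_correlation(picks, neg), -1)

  set.seed(81)
  n <- 500
  x <- rnorm(n)
  y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(n)
  picks <- data.frame(timestamp = seq_len(n), onset_pu = x)
  cov <- data.frame(timestamp = seq_len(n), soil = y)
  r <- track_correlation(picks, cov)
  expect_equal(r, pearson_oracle(x, y), tolerance = 1e-12)
  expect_lt(abs(r - 0.9), 0.05)
})

test_that("track_correlation rejects unusable alignments", {
  picks <- data.frame(timestamp = 1:10, onset_pu = rnorm(10))
  cov <- data.frame(timestamp = 11:20, soil = rnorm(10))
  expect_error(track_correlation(picks, cov), "no aligned points")

  cov2 <- data.frame(timestamp = 1:10, soil = rnorm(10))
  expect_error(track_correlation(picks, cov2, window = c(1, 2)), "aligned")

  flat <- data.frame(timestamp = 1:10, soil = rep(5, 10))
  expect_error(track_correlation(picks, flat), "zero variance")

  # the window restricts which pairs enter the correlation
  y <- rnorm(10)
  cov3 <- data.frame(timestamp = 1:10, soil = c(picks$onset_pu[1:5], y[6:10]))
  expect_equal(track_correlation(picks, cov3, window = c(1, 5)), 1)
})
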