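# a stand with no random logs, into which tests inject known geometry
empty_stand <- function(seed = 1, ...) {
  generate_stand(stand_params(cwd_per_ha = 0, ...), seed = seed)
}

test_that("zero densities give an empty stand with all-zero truth", {
  st <- empty_stand(fwd_per_m = c(small = 0, medium = 0, large = 0),
                    duff_mean_in = 0, duff_amp_in = 0,
                    litter_mean_in = 0, litter_amp_in = 0)
  expect_equal(nrow(st$logs), 0)
  expect_equal(st$truth$cwd_volume_total_m3_ha, 0)
  expect_equal(st$truth$cwd_length_m_ha, 0)
  expect_equal(unname(st$truth$fwd_volume_m3_ha), c(0, 0, 0))
  sp <- sample_plot(st, c(10, 10), seed = 1)
  expect_equal(nrow(sp$cwd), 0)
  expect_equal(nrow(sp$pile), 0)
  expect_true(all(sp$fwd$SMALLCT == 0))
})

test_that("a fixed seed reproduces the stand and the samples", {
  a <- generate_stand(seed = 33)
  b <- generate_stand(seed = 33)
  expect_identical(a$logs, b$logs)
  expect_identical(a$truth, b$truth)
  expect_false(identical(generate_stand(seed = 34)$logs, a$logs))
  s1 <- sample_plot(a, c(40, 40), seed = 5)
  s2 <- sample_plot(b, c(40, 40), seed = 5)
  expect_identical(s1, s2)
})

test_that("nonpositive region is a config error", {
  expect_error(generate_stand(stand_params(region_w_m = -1)),
               "config error")
})

test_that("truth volume equals numeric quadrature over each frustum", {
  st <- generate_stand(stand_params(cwd_per_ha = 80, hollow_prob = 0.5),
                       seed = 12)
  num <- 0
  for (i in seq_len(nrow(st$logs))) {
    D <- st$logs$dlarge_cm[i] / 100
    d <- st$logs$dsmall_cm[i] / 100
    l <- st$logs$length_m[i]
    h <- st$logs$hollow_frac[i]
    f <- function(x) pi / 4 * (D + (d - D) * x / l)^2 * (1 - h^2)
    num <- num + stats::integrate(f, 0, l, rel.tol = 1e-10)$value
  }
  expect_equal(st$truth$cwd_volume_m3_ha, num / st$truth$area_ha,
               tolerance = 1e-6)
})

test_that("a log laid across a transect yields the interpolated diameter", {
  st <- empty_stand()
  cx <- 50; cy <- 60
  u <- c(sin(30 * pi / 180), cos(30 * pi / 180))   # transect 1, subplot 1
  v <- c(sin(120 * pi / 180), cos(120 * pi / 180)) # perpendicular log
  q <- c(cx, cy) + 3 * u   # crossing 3 m along the transect
  mid <- q + 1.0 * v       # crossing at t = -1 from the log midpoint
  st$logs <- data.frame(
    x = mid[1], y = mid[2], azimuth_deg = 120, dlarge_cm = 20,
    length_m = 4, spcd = 202L, decaycd = 2L, dsmall_cm = 12,
    hollow_frac = 0
  )
  sp <- sample_plot(st, c(cx, cy), seed = 1)
  expect_equal(nrow(sp$cwd), 1)
  expect_equal(sp$cwd$SUBP, 1L)
  expect_equal(sp$cwd$TRANSECT, 30L)
  # linear taper: frac along log = (t + l/2)/l = 0.25 from the large end
  expect_equal(sp$cwd$TRANSDIA, (20 + (12 - 20) * 0.25) / 2.54,
               tolerance = 1e-9)
})

test_that("a log parallel to and offset from all transects is not tallied", {
  st <- empty_stand()
  # parallel to the 30-degree transect, displaced sideways by 2 m
  u <- c(sin(30 * pi / 180), cos(30 * pi / 180))
  perp <- c(u[2], -u[1])
  mid <- c(50, 60) + 3 * u + 2 * perp
  st$logs <- data.frame(
    x = mid[1], y = mid[2], azimuth_deg = 30, dlarge_cm = 20,
    length_m = 4, spcd = 202L, decaycd = 2L, dsmall_cm = 20,
    hollow_frac = 0
  )
  sp <- sample_plot(st, c(50, 60), seed = 1)
  expect_equal(nrow(sp$cwd), 0)
})

test_that("cylindrical logs make the sampled diameter position-free", {
  st <- generate_stand(stand_params(cwd_per_ha = 300, taper_min = 1,
                                    taper_max = 1), seed = 8)
  expect_equal(st$logs$dsmall_cm, st$logs$dlarge_cm)
  ds <- make_dataset(st, n_plots = 8, seed = 8)
  # every tallied diameter must equal some cylinder's diameter exactly
  diam_cm <- ds$cwd$TRANSDIA * 2.54
  mind <- vapply(diam_cm, function(d) min(abs(st$logs$dlarge_cm - d)),
                 numeric(1))
  expect_gt(nrow(ds$cwd), 0)
  expect_lt(max(mind), 1e-9)
})

test_that("expected tally count follows the intersection law", {
  st <- generate_stand(stand_params(cwd_per_ha = 250), seed = 40)
  design <- plot_design()
  n <- 400
  mc <- run_monte_carlo(st, design, n_plots = n, seed = 41,
                        attributes = "cwd_length", return_values = TRUE)
  # E[count] = (2/pi) * L_m * sum(l)/A ; cwd_length = C * pi/(2L_ft) * count
  len_m_tot <- cwd_total_length_ft(design) * 0.3048
  area <- st$truth$area_ha * 1e4
  expect_count <- (2 / pi) * len_m_tot * sum(st$logs$length_m) / area
  counts <- mc$values[, "cwd_length"] /
    (paper_constant("cwd_length", "metric") * pi /
       (2 * cwd_total_length_ft(design)))
  z <- (mean(counts) - expect_count) / (sd(counts) / sqrt(n))
  expect_lt(abs(z), 3)
})

test_that("duff estimator recovers the depth-field mean", {
  st <- generate_stand(seed = 50)
  mc <- run_monte_carlo(st, n_plots = 400, seed = 51,
                        attributes = c("duff_volume", "litter_volume"))
  expect_true(all(abs(mc$table$z) < 3))
})

test_that("pile sampling validates and the pile estimator is unbiased", {
  st <- generate_stand(stand_params(cwd_per_ha = 0, piles_per_ha = 30),
                       seed = 60)
  expect_gt(nrow(st$piles), 0)
  ds <- make_dataset(st, n_plots = 5, seed = 60)
  expect_equal(nrow(validate_dataset(ds)), 0)
  mc <- run_monte_carlo(st, n_plots = 600, seed = 61,
                        attributes = "cwd_volume")
  expect_lt(abs(mc$table$z), 3)
})

test_that("single-plot Monte-Carlo flags an undefined SE", {
  st <- generate_stand(seed = 3)
  mc <- run_monte_carlo(st, n_plots = 1, seed = 3)
  expect_true(mc$se_undefined)
  expect_true(all(is.na(mc$table$mc_se)))
  expect_error(run_monte_carlo(st, n_plots = 0), "n_plots")
})

test_that("fast Monte-Carlo path equals the record-level estimators", {
  st <- generate_stand(stand_params(cwd_per_ha = 300, piles_per_ha = 10,
                                    hollow_prob = 0.3), seed = 70)
  design <- plot_design()
  set.seed(71)
  centers <- cbind(runif(12, 0, st$params$region_w_m),
                   runif(12, 0, st$params$region_h_m))
  sums <- dwmlis:::.plot_sums(st, centers, design)
  fast_vol <- dwmlis:::.sums_to_estimates(sums, design, "cwd_volume")
  fast_len <- dwmlis:::.sums_to_estimates(sums, design, "cwd_length")
  fast_cov <- dwmlis:::.sums_to_estimates(sums, design, "cwd_cover")
  fast_bio <- dwmlis:::.sums_to_estimates(sums, design, "cwd_biomass")
  for (i in seq_len(nrow(centers))) {
    sp <- sample_plot(st, centers[i, ], design, seed = i)
    expect_equal(fast_vol[i],
                 as.numeric(cwd_volume(sp$cwd, sp$pile, design,
                                       units = "metric")),
                 tolerance = 1e-9, label = paste("vol plot", i))
    expect_equal(fast_len[i],
                 as.numeric(cwd_length(sp$cwd, design, units = "metric")),
                 tolerance = 1e-9, label = paste("len plot", i))
    expect_equal(fast_cov[i],
                 as.numeric(cwd_cover(sp$cwd, sp$pile, design)),
                 tolerance = 1e-9, label = paste("cover plot", i))
    expect_equal(fast_bio[i],
                 as.numeric(cwd_mass(sp$cwd, sp$pile, design,
                                     st$ref_species, units = "metric")),
                 tolerance = 1e-9, label = paste("bio plot", i))
  }
})

test_that("emitted dataset reproduces the in-memory estimates", {
  dir <- withr::local_tempdir()
  st <- generate_stand(stand_params(cwd_per_ha = 300), seed = 80)
  ds_mem <- make_dataset(st, n_plots = 4, seed = 80)
  emit_dataset(st, design = plot_design(), seed = 80, out_dir = dir,
               n_plots = 4)
  ds_file <- read_tables(dir)
  e1 <- estimate_all(ds_mem, attributes = "cwd_volume")
  e2 <- estimate_all(ds_file, attributes = "cwd_volume")
  expect_equal(e2$VALUE, e1$VALUE, tolerance = 1e-12)
  expect_equal(nrow(validate_dataset(ds_file)), 0)
})
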