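design12 <- plot_design("national_2012")

test_that("hand-evaluated single-record values reproduce exactly", {
  # one solid 10-in piece on 192 ft of transect
  p <- make_pieces(10)
  expect_equal(as.numeric(cwd_volume(p, design = design12)),
               (43560 / 144) * pi^2 / 8 * 100 / 192, tolerance = 1e-9)
  # one pile, compacted height 3 ft over 6 ft of transect
  q <- make_piles(3, begin = 4, end = 10)
  expect_equal(as.numeric(cwd_volume(NULL, q, design12)),
               43560 * pi / 2 * 18 / 192, tolerance = 1e-9)
  # cover of one 12-in piece
  expect_equal(as.numeric(cwd_cover(make_pieces(12), design = design12)),
               100 * pi / (2 * 192), tolerance = 1e-9)
  # one tallied piece of length estimator
  expect_equal(as.numeric(cwd_length(p, design12)),
               43560 * pi / 384, tolerance = 1e-9)
  # mass of a 10-in piece at 20 lb/ft3 via a density-20 reference
  ref20 <- default_species_reference()
  ref20$WOOD_SPGR_GREENVOL_DRYWT <- 20 / 62.4
  ref20[paste0("CWD_DECAY_RATIO", 1:5)] <- 1
  expect_equal(as.numeric(cwd_mass(p, design = design12,
                                   density_ref = ref20)),
               0.15125 * pi^2 / 8 * 20 * 100 / 192, tolerance = 1e-9)
  # duff: 8 points at 2 in each
  pts <- make_points(rep(2, 8))
  expect_equal(as.numeric(dufflitter_volume(pts, "duff", design12)),
               3630 * 16 / 8, tolerance = 1e-9)
})

test_that("degenerate and empty inputs behave as the formulas dictate", {
  expect_equal(as.numeric(cwd_volume(NULL, NULL, design12)), 0)
  expect_equal(as.numeric(cwd_cover(NULL, NULL, design12)), 0)
  # fully hollow piece contributes nothing to volume
  p <- make_pieces(10, hollow = 10)
  expect_equal(as.numeric(cwd_volume(p, design = design12)), 0)
  # hollow beyond the piece is a domain error
  expect_error(cwd_volume(make_pieces(10, hollow = 12)), "hollow")
  expect_error(cwd_volume(NULL, make_piles(3, begin = 10, end = 4)),
               "negative pile")
  # a pile filling the whole 192 ft: cover exceeds 100% by construction
  q <- make_piles(rep(2, 8), begin = rep(0, 8), end = rep(24, 8),
                  subp = rep(1:4, each = 2),
                  transect = rep(c(30L, 150L), 4))
  expect_equal(as.numeric(cwd_cover(NULL, q, design12)), 100 * pi / 2,
               tolerance = 1e-9)
})

test_that("k pieces scale linearly and doubling L halves estimates", {
  one <- as.numeric(cwd_length(make_pieces(10), design12))
  three <- as.numeric(cwd_length(make_pieces(c(10, 11, 12)), design12))
  expect_equal(three, 3 * one, tolerance = 1e-12)
  p <- make_pieces(c(10, 14))
  full <- as.numeric(cwd_volume(p, design = design12))
  halfL <- as.numeric(cwd_volume(p, design = design12, L_ft = 384))
  expect_equal(halfL, full / 2, tolerance = 1e-12)
})

test_that("FWD volume matches the hand-evaluated class formula", {
  # n = 10 small pieces with QMD 0.15 in on 24 ft
  t1 <- make_tallies(c(10, 0, 0, 0), rep(0, 4), rep(0, 4))
  cond <- make_cond()  # group 200: small QMD 0.15
  got <- as.numeric(fwd_volume(t1, "small", design12, cond = cond))
  expect_equal(got, (43560 / 144) * pi^2 / (8 * 24) * 10 * 0.15^2,
               tolerance = 1e-9)
  # zero counts -> 0; quadrupling under doubled QMD
  t0 <- make_tallies(rep(0, 4), rep(0, 4), rep(0, 4))
  expect_equal(as.numeric(fwd_volume(t0, "small", design12, cond = cond)),
               0)
  ref2 <- default_forest_type_group_reference()
  ref2$FWD_SMALL_QMD <- ref2$FWD_SMALL_QMD * 2
  got2 <- as.numeric(fwd_volume(t1, "small", design12, qmd_ref = ref2,
                                cond = cond))
  expect_equal(got2, 4 * got, tolerance = 1e-12)
})

test_that("mass estimators compose volume with density", {
  cond <- make_cond()
  t1 <- make_tallies(c(10, 0, 0, 0), rep(0, 4), rep(0, 4))
  ref <- default_forest_type_group_reference()
  vol <- as.numeric(fwd_volume(t1, "small", design12, cond = cond))
  mass <- as.numeric(fwd_mass(t1, "small", design12, cond = cond))
  dens <- ref$FWD_DENSITY[ref$TYPGRPCD == 200]
  expect_equal(mass, vol * dens / 2000, tolerance = 1e-9)
  # density doubling doubles mass
  ref2 <- ref
  ref2$FWD_DENSITY <- ref2$FWD_DENSITY * 2
  expect_equal(as.numeric(fwd_mass(t1, "small", design12, ref2,
                                   cond = cond)), 2 * mass,
               tolerance = 1e-12)
  # carbon = biomass x carbon ratio for a single-species piece set
  p <- make_pieces(c(10, 12), decaycd = c(2L, 4L))
  sp <- default_species_reference()
  b <- as.numeric(cwd_mass(p, design = design12, output = "biomass"))
  c_ <- as.numeric(cwd_mass(p, design = design12, output = "carbon"))
  expect_equal(c_, b * sp$DWM_CARBON_RATIO[sp$SPCD == 202],
               tolerance = 1e-12)
  # missing density entry names the species
  bad <- make_pieces(10, spcd = 55555L)
  expect_error(cwd_mass(bad, design = design12), "55555")
})

test_that("duff/litter missing-point handling", {
  # missing depths leave the protocol denominator fixed
  pts <- make_points(c(2, 2, NA, NA, 2, 2, 2, 2), reason = 5L)
  got <- as.numeric(dufflitter_volume(pts, "duff", design12))
  expect_equal(got, 3630 * 12 / 8, tolerance = 1e-9)
  # the sampled-denominator option rescales
  got2 <- as.numeric(dufflitter_volume(pts, "duff", design12,
                                       denominator = "sampled"))
  expect_equal(got2, 3630 * 12 / 6, tolerance = 1e-9)
  # all points missing -> undefined NA, not zero
  allna <- make_points(rep(NA_real_, 8), litter = rep(NA_real_, 8),
                       reason = 5L)
  und <- dufflitter_volume(allna, "duff", design12)
  expect_true(is.na(as.numeric(und)))
  expect_true(attr(und, "undefined"))
  # domain excluding every point -> 0, and not flagged undefined
  z <- dufflitter_volume(make_points(rep(2, 8)), "duff", design12,
                         domain = dwm_domain(CONDID = 99))
  expect_equal(as.numeric(z), 0)
  expect_false(attr(z, "undefined"))
  # litter mass composes density
  pts2 <- make_points(rep(1, 8))
  cond <- make_cond()
  ref <- default_forest_type_group_reference()
  vol <- as.numeric(dufflitter_volume(pts2, "litter", design12))
  mass <- as.numeric(dufflitter_mass(pts2, "litter", design12,
                                     cond = cond))
  expect_equal(mass, vol * ref$LITTER_DENSITY[ref$TYPGRPCD == 200] / 2000,
               tolerance = 1e-9)
})

test_that("domain additivity holds exactly for every attribute", {
  rec <- random_plot_records(42)
  doms <- list(dwm_domain(DECAYCD = 1:2), dwm_domain(DECAYCD = 3:5))
  all_dom <- dwm_domain(DECAYCD = 1:5)
  ests <- function(dom) {
    c(cwd_volume = as.numeric(cwd_volume(rec$pieces, rec$piles, design12,
                                         dom)),
      cwd_mass = as.numeric(cwd_mass(rec$pieces, rec$piles, design12,
                                     domain = dom)),
      cwd_cover = as.numeric(cwd_cover(rec$pieces, rec$piles, design12,
                                       dom)),
      cwd_length = as.numeric(cwd_length(rec$pieces, design12, dom)))
  }
  parts <- ests(doms[[1]]) + ests(doms[[2]])
  expect_equal(parts, ests(all_dom), tolerance = 1e-12)
})

test_that("unit coherence: imperial x factor ~ metric on random fixtures", {
  for (seed in c(3, 17)) {
    rec <- random_plot_records(seed)
    imp <- as.numeric(cwd_volume(rec$pieces, rec$piles, design12,
                                 units = "imperial"))
    met <- as.numeric(cwd_volume(rec$pieces, rec$piles, design12,
                                 units = "metric"))
    if (met > 0) {
      expect_equal(imp * metric_conversion_factor("volume_per_area"), met,
                   tolerance = 5e-4)
    }
    impL <- as.numeric(cwd_length(rec$pieces, design12))
    metL <- as.numeric(cwd_length(rec$pieces, design12, units = "metric"))
    if (metL > 0) {
      expect_equal(impL * metric_conversion_factor("length_per_area"),
                   metL, tolerance = 5e-4)
    }
  }
})

test_that("monotonicity: adding a record never decreases an estimate", {
  rec <- random_plot_records(7)
  base_v <- as.numeric(cwd_volume(rec$pieces, rec$piles, design12))
  more <- rbind(rec$pieces, make_pieces(9))
  expect_gte(as.numeric(cwd_volume(more, rec$piles, design12)), base_v)
  more_piles <- rbind(rec$piles, make_piles(2, begin = 0, end = 5))
  expect_gte(as.numeric(cwd_volume(rec$pieces, more_piles, design12)),
             base_v)
  pts <- make_points(c(rep(1, 7), 0))
  pts2 <- pts; pts2$DUFFDEP[8] <- 3
  expect_gte(as.numeric(dufflitter_volume(pts2, "duff", design12)),
             as.numeric(dufflitter_volume(pts, "duff", design12)))
})

test_that("brute-force oracle equality on random small plots", {
  for (seed in 1:8) {
    rec <- random_plot_records(seed + 100)
    L <- 192
    expect_equal(
      as.numeric(cwd_volume(rec$pieces, rec$piles, design12)),
      oracle_cwd_volume(rec$pieces, rec$piles, L, 43560 / 144, 43560),
      tolerance = 1e-12, label = paste("volume seed", seed))
    expect_equal(
      as.numeric(cwd_cover(rec$pieces, rec$piles, design12)),
      oracle_cwd_cover(rec$pieces, rec$piles, L),
      tolerance = 1e-12, label = paste("cover seed", seed))
    expect_equal(
      as.numeric(cwd_mass(rec$pieces, rec$piles, design12)),
      oracle_cwd_mass(rec$pieces, rec$piles, L, 0.15125, 21.78,
                      default_species_reference()),
      tolerance = 1e-12, label = paste("mass seed", seed))
  }
})

test_that("estimate_plot composes the individual estimators", {
  stand <- generate_stand(stand_params(cwd_per_ha = 400, piles_per_ha = 15),
                          seed = 21)
  ds <- make_dataset(stand, n_plots = 3, seed = 21)
  cn <- ds$plot$CN[1]
  est <- estimate_plot(ds, cn)
  pieces <- ds$cwd[ds$cwd$PLT_CN == cn, ]
  piles <- ds$pile[ds$pile$PLT_CN == cn, ]
  expect_equal(est$VALUE[est$ATTRIBUTE == "cwd_volume"],
               as.numeric(cwd_volume(pieces, piles, ds$design)),
               tolerance = 1e-12)
  # disjoint-domain additivity across decay classes
  dsum <- 0
  for (k in 1:5) {
    ek <- estimate_plot(ds, cn, domains = list(dwm_domain(DECAYCD = k)),
                        attributes = "cwd_volume")
    dsum <- dsum + ek$VALUE
  }
  expect_equal(dsum, est$VALUE[est$ATTRIBUTE == "cwd_volume"],
               tolerance = 1e-12)
  # unknown plot errors; empty plot gives all zeros
  expect_error(estimate_plot(ds, "nope"), "not in dataset")
  empty_stand <- generate_stand(stand_params(cwd_per_ha = 0,
                                             fwd_per_m = c(small = 0,
                                                           medium = 0,
                                                           large = 0),
                                             duff_mean_in = 0,
                                             duff_amp_in = 0,
                                             litter_mean_in = 0,
                                             litter_amp_in = 0),
                                seed = 1)
  ds0 <- make_dataset(empty_stand, n_plots = 1, seed = 1)
  e0 <- estimate_plot(ds0, ds0$plot$CN[1])
  expect_true(all(e0$VALUE == 0))
})

test_that("QA plots are excluded from estimate_all by default", {
  stand <- generate_stand(stand_params(cwd_per_ha = 200), seed = 3)
  ds <- make_dataset(stand, n_plots = 3, seed = 3)
  ds$visit$QASTATCD[2] <- 2L  # blind remeasurement
  est <- estimate_all(ds, attributes = "cwd_volume")
  expect_false(ds$plot$CN[2] %in% est$PLT_CN)
  est_all <- estimate_all(ds, attributes = "cwd_volume",
                          include_qa = TRUE)
  expect_true(ds$plot$CN[2] %in% est_all$PLT_CN)
})
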