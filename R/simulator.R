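#' Synthetic stand parameters
#'
#' The stated world of the simulator: a rectangular, single-condition
#' temperate stand with a homogeneous Poisson population of downed logs
#' (uniform random azimuths — the condition under which line-intersect
#' sampling with fixed transect azimuths is design-unbiased), optional
#' circular residue piles, per-class fine-woody-debris crossing
#' intensities, and smooth periodic duff/litter depth surfaces whose
#' spatial mean is known exactly.
#'
#' Defaults describe a mesic conifer stand with a realistic downed-wood
#' load (~120 CWD logs/ha, large-end diameters lognormal around 20 cm,
#' lengths around 4--5 m, giving on the order of 15 m3/ha of CWD): see the
#' methods vignette for the rationale. Piles default to absent (they are
#' rare events in the field protocol).
#'
#' @param ... Overrides of the default fields.
#' @return Named list of parameters.
#' @export
stand_params <- function(...) {
  p <- list(
    region_w_m = 100, region_h_m = 120,
    cwd_per_ha = 120,            # expected downed logs per hectare
    dlarge_meanlog = log(20), dlarge_sdlog = 0.35,  # large-end diam, cm
    dmin_cm = 7.61,              # CWD threshold
    taper_min = 0.6, taper_max = 1.0,  # small end / large end ratio
    length_meanlog = log(4), length_sdlog = 0.5, length_min_m = 0.5,
    species = c(202L, 122L, 833L), species_probs = c(0.5, 0.3, 0.2),
    decay_probs = c(0.15, 0.25, 0.30, 0.20, 0.10),
    class5_dmin_cm = 12.7, class5_lmin_m = 1.52,
    hollow_prob = 0.10, hollow_frac_range = c(0.2, 0.6),
    piles_per_ha = 0,
    pile_radius_m = c(1.0, 2.5), pile_height_ft = c(2, 6),
    fwd_per_m = c(small = 2.0, medium = 1.0, large = 0.3),
    duff_mean_in = 1.5, duff_amp_in = 0.5,
    litter_mean_in = 1.0, litter_amp_in = 0.4,
    fortypcd = 201L, fortypgrpcd = 200L, condid = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown stand parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  p[names(over)] <- over
  p
}

.lb_ft3_to_kg_m3 <- function() {
  u <- unit_definitions()
  u$pound_in_kg / u$foot_in_m^3
}

# truncated lognormal >= lo (vectorized rejection)
.rlnorm_min <- function(n, meanlog, sdlog, lo) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  while (any(bad <- x < lo)) {
    x[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
  }
  x
}

# smooth periodic depth surface; exact spatial mean over the region = mean
.depth_field <- function(params, x, y, layer = c("duff", "litter")) {
  layer <- match.arg(layer)
  m <- if (layer == "duff") params$duff_mean_in else params$litter_mean_in
  a <- if (layer == "duff") params$duff_amp_in else params$litter_amp_in
  m + a * sin(2 * pi * x / params$region_w_m) *
    sin(2 * pi * y / params$region_h_m)
}

#' Generate a synthetic stand with known truth
#'
#' Draws the log and pile populations and attaches a closed-form truth
#' summary (per-hectare volume, biomass, carbon, length and cover; FWD
#' volume per class; duff/litter mean depth and volume), all in metric
#' units. Log volumes are conic frustums,
#' \eqn{v = (\pi \ell / 12)(D^2 + D d + d^2)}, reduced by \eqn{(1 - h^2)}
#' for a hollow fraction \eqn{h}. The pile truth is the transect pile
#' estimator's estimand, \eqn{(\pi/2) \sum PH \cdot A_{pile} / A}
#' (compacted height times plan area), since piles carry no piece-level
#' geometry. Decay-class-5 logs are generated to satisfy their stricter
#' tally thresholds (>= 12.7 cm over >= 1.52 m) so the tally filter never
#' truncates them.
#'
#' @param params [stand_params()].
#' @param seed Integer seed; the stand is reproducible given
#'   (params, seed).
#' @return Object of class `dwm_stand`: list with `logs`, `piles`,
#'   `params`, `ref_species`, `ref_forest_type_group`, `truth`, `seed`.
#' @export
generate_stand <- function(params = stand_params(), seed = 1L) {
  if (params$region_w_m <= 0 || params$region_h_m <= 0) {
    stop("config error: region dimensions must be positive", call. = FALSE)
  }
  area_m2 <- params$region_w_m * params$region_h_m
  area_ha <- area_m2 / 1e4
  ref_sp <- default_species_reference()
  ref_ft <- default_forest_type_group_reference()

  st <- .with_seed(seed, function() {
    n <- stats::rpois(1, params$cwd_per_ha * area_ha)
    logs <- data.frame(
      x = stats::runif(n, 0, params$region_w_m),
      y = stats::runif(n, 0, params$region_h_m),
      azimuth_deg = stats::runif(n, 0, 360),
      dlarge_cm = .rlnorm_min(n, params$dlarge_meanlog,
                              params$dlarge_sdlog, params$dmin_cm),
      length_m = pmax(params$length_min_m,
                      stats::rlnorm(n, params$length_meanlog,
                                    params$length_sdlog)),
      spcd = sample(params$species, n, TRUE, params$species_probs),
      decaycd = sample(1:5, n, TRUE, params$decay_probs)
    )
    logs$dsmall_cm <- pmax(params$dmin_cm,
                           logs$dlarge_cm *
                             stats::runif(n, params$taper_min,
                                          params$taper_max))
    is5 <- logs$decaycd == 5L
    logs$dlarge_cm[is5] <- pmax(logs$dlarge_cm[is5], params$class5_dmin_cm)
    logs$dsmall_cm[is5] <- pmax(logs$dsmall_cm[is5], params$class5_dmin_cm)
    logs$length_m[is5] <- pmax(logs$length_m[is5], params$class5_lmin_m)
    logs$hollow_frac <- ifelse(
      stats::runif(n) < params$hollow_prob,
      stats::runif(n, params$hollow_frac_range[1],
                   params$hollow_frac_range[2]),
      0
    )
    np <- stats::rpois(1, params$piles_per_ha * area_ha)
    piles <- data.frame(
      x = stats::runif(np, 0, params$region_w_m),
      y = stats::runif(np, 0, params$region_h_m),
      radius_m = stats::runif(np, params$pile_radius_m[1],
                              params$pile_radius_m[2]),
      height_ft = stats::runif(np, params$pile_height_ft[1],
                               params$pile_height_ft[2]),
      spcd = if (np) sample(params$species, np, TRUE,
                            params$species_probs) else integer(0),
      decaycd = if (np) sample(1:4, np, TRUE) else integer(0)
    )
    list(logs = logs, piles = piles)
  })
  logs <- st$logs
  piles <- st$piles

  kg_m3 <- .lb_ft3_to_kg_m3()
  u <- unit_definitions()
  Dm <- logs$dlarge_cm / 100
  dm <- logs$dsmall_cm / 100
  frustum <- pi * logs$length_m / 12 * (Dm^2 + Dm * dm + dm^2)
  net_vol <- frustum * (1 - logs$hollow_frac^2)
  dens_lb <- if (nrow(logs)) cwd_bulk_density(logs$spcd, logs$decaycd,
                                              ref_sp) else numeric(0)
  dens_c_lb <- if (nrow(logs)) cwd_bulk_density(logs$spcd, logs$decaycd,
                                                ref_sp, carbon = TRUE)
               else numeric(0)
  plan_area <- logs$length_m * (Dm + dm) / 2  # integral of d(x) dx

  pile_ph_m <- piles$height_ft * u$foot_in_m
  pile_area <- pi * piles$radius_m^2
  pile_vol <- pi / 2 * pile_ph_m * pile_area  # the pile estimand, m3
  pile_dens_lb <- if (nrow(piles)) cwd_bulk_density(piles$spcd,
                                                    piles$decaycd, ref_sp)
                  else numeric(0)
  pile_dens_c_lb <- if (nrow(piles)) cwd_bulk_density(piles$spcd,
                                                      piles$decaycd, ref_sp,
                                                      carbon = TRUE)
                    else numeric(0)

  # FWD truth: intensity-defined. The estimand of the count-based
  # estimator with exact constants: C pi^2/8 * lambda_per_ft * QMD_in^2.
  fi <- match(params$fortypgrpcd, ref_ft$TYPGRPCD)
  if (is.na(fi)) stop("config error: fortypgrpcd not in reference",
                      call. = FALSE)
  qmds <- c(small = ref_ft$FWD_SMALL_QMD[fi],
            medium = ref_ft$FWD_MEDIUM_QMD[fi],
            large = ref_ft$FWD_LARGE_QMD[fi])
  lam_ft <- params$fwd_per_m * u$foot_in_m  # pieces per ft of transect
  fwd_vol <- derive_metric_constant("fwd_volume") * pi^2 / 8 *
    lam_ft * qmds^2
  fwd_dens_kg <- ref_ft$FWD_DENSITY[fi] * kg_m3

  truth <- list(
    area_ha = area_ha,
    n_logs = nrow(logs),
    cwd_volume_m3_ha = sum(net_vol) / area_ha,
    pile_volume_m3_ha = sum(pile_vol) / area_ha,
    cwd_volume_total_m3_ha = (sum(net_vol) + sum(pile_vol)) / area_ha,
    cwd_biomass_Mg_ha = (sum(net_vol * dens_lb * kg_m3) +
                           sum(pile_vol * pile_dens_lb * kg_m3)) / 1000 /
                          area_ha,
    cwd_carbon_Mg_ha = (sum(net_vol * dens_c_lb * kg_m3) +
                          sum(pile_vol * pile_dens_c_lb * kg_m3)) / 1000 /
                         area_ha,
    cwd_length_m_ha = sum(logs$length_m) / area_ha,
    cwd_cover_pct = 100 * (sum(plan_area) + pi / 2 * sum(pile_area)) /
                      (area_ha * 1e4),
    fwd_volume_m3_ha = fwd_vol,
    fwd_biomass_Mg_ha = fwd_vol * fwd_dens_kg / 1000,
    duff_mean_in = params$duff_mean_in,
    litter_mean_in = params$litter_mean_in,
    duff_volume_m3_ha = derive_metric_constant("dufflitter_volume") *
      params$duff_mean_in,
    litter_volume_m3_ha = derive_metric_constant("dufflitter_volume") *
      params$litter_mean_in
  )

  out <- list(logs = logs, piles = piles, params = params,
              ref_species = ref_sp, ref_forest_type_group = ref_ft,
              truth = truth, seed = seed)
  class(out) <- "dwm_stand"
  out
}

#' @export
print.dwm_stand <- function(x, ...) {
  cat("Synthetic DWM stand:", nrow(x$logs), "logs,", nrow(x$piles),
      "piles over", x$truth$area_ha, "ha (seed", x$seed, ")\n")
  cat(sprintf("  truth: CWD %.2f m3/ha, %.2f Mg/ha, %.0f m/ha, cover %.2f%%\n",
              x$truth$cwd_volume_total_m3_ha, x$truth$cwd_biomass_Mg_ha,
              x$truth$cwd_length_m_ha, x$truth$cwd_cover_pct))
  invisible(x)
}

# wrap displacements into [-W/2, W/2) (toroidal region)
.wrap <- function(dx, w) dx - w * round(dx / w)

# transect origins and azimuths for plots centered at (cx, cy)
# returns data.frame: plot, subp, tr, ox, oy, az
.plot_transects <- function(design, cx, cy) {
  u <- unit_definitions()
  subp_az <- design$subplot_azimuths_deg
  n_sub <- design$n_subplots
  offs <- rbind(c(0, 0), design$subplot_offset_m * .az_unit(subp_az))
  offs <- offs[seq_len(n_sub), , drop = FALSE]
  tr_az <- design$transect_azimuths_deg
  np <- length(cx)
  grid <- expand.grid(tr = seq_along(tr_az), subp = seq_len(n_sub),
                      plot = seq_len(np))
  data.frame(
    plot = grid$plot,
    subp = grid$subp,
    tr = grid$tr,
    ox = cx[grid$plot] + offs[grid$subp, 1],
    oy = cy[grid$plot] + offs[grid$subp, 2],
    az = tr_az[grid$tr]
  )
}

# crossings of stand logs with transects; vectorized over transects x logs.
# returns data.frame(ti, li, s_m, diam_cm) for tallied crossings.
.log_crossings <- function(stand, ox, oy, az_deg, len_m) {
  logs <- stand$logs
  nl <- nrow(logs)
  nt <- length(ox)
  if (!nl || !nt) {
    return(data.frame(ti = integer(0), li = integer(0),
                      s_m = numeric(0), diam_cm = numeric(0)))
  }
  w <- stand$params$region_w_m
  h <- stand$params$region_h_m
  tu <- .az_unit(az_deg)            # nt x 2
  lu <- .az_unit(logs$azimuth_deg)  # nl x 2
  # matrices nt x nl
  dx <- .wrap(matrix(logs$x, nt, nl, byrow = TRUE) - ox, w)
  dy <- .wrap(matrix(logs$y, nt, nl, byrow = TRUE) - oy, h)
  uxm <- matrix(tu[, 1], nt, nl)
  uym <- matrix(tu[, 2], nt, nl)
  vxm <- matrix(lu[, 1], nt, nl, byrow = TRUE)
  vym <- matrix(lu[, 2], nt, nl, byrow = TRUE)
  det <- vxm * uym - uxm * vym
  par <- abs(det) < 1e-12
  det[par] <- 1  # avoid division by zero; masked below
  s <- (vxm * dy - dx * vym) / det
  tt <- (uxm * dy - uym * dx) / det
  lh <- matrix(logs$length_m / 2, nt, nl, byrow = TRUE)
  hit <- !par & s >= 0 & s <= len_m & tt >= -lh & tt <= lh
  idx <- which(hit, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(ti = integer(0), li = integer(0),
                      s_m = numeric(0), diam_cm = numeric(0)))
  }
  ti <- idx[, 1]; li <- idx[, 2]
  frac <- (tt[idx] + logs$length_m[li] / 2) / logs$length_m[li]
  diam <- logs$dlarge_cm[li] + (logs$dsmall_cm[li] - logs$dlarge_cm[li]) *
    frac
  keep <- diam >= stand$params$dmin_cm &
    (logs$decaycd[li] != 5L | diam >= stand$params$class5_dmin_cm)
  data.frame(ti = ti[keep], li = li[keep], s_m = s[idx][keep],
             diam_cm = diam[keep])
}

# pile chord crossings; returns data.frame(ti, pi, begin_m, end_m)
.pile_crossings <- function(stand, ox, oy, az_deg, len_m) {
  piles <- stand$piles
  np <- nrow(piles)
  nt <- length(ox)
  if (!np || !nt) {
    return(data.frame(ti = integer(0), pi = integer(0),
                      begin_m = numeric(0), end_m = numeric(0)))
  }
  w <- stand$params$region_w_m
  h <- stand$params$region_h_m
  tu <- .az_unit(az_deg)
  dx <- .wrap(matrix(piles$x, nt, np, byrow = TRUE) - ox, w)
  dy <- .wrap(matrix(piles$y, nt, np, byrow = TRUE) - oy, h)
  s0 <- dx * matrix(tu[, 1], nt, np) + dy * matrix(tu[, 2], nt, np)
  perp2 <- dx^2 + dy^2 - s0^2
  r2 <- matrix(piles$radius_m^2, nt, np, byrow = TRUE)
  hit <- perp2 < r2
  idx <- which(hit, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(ti = integer(0), pi = integer(0),
                      begin_m = numeric(0), end_m = numeric(0)))
  }
  half <- sqrt(r2[idx] - perp2[idx])
  a <- pmax(0, s0[idx] - half)
  b <- pmin(len_m, s0[idx] + half)
  keep <- b > a
  data.frame(ti = idx[keep, 1], pi = idx[keep, 2],
             begin_m = a[keep], end_m = b[keep])
}

#' Simulate the field measurement of one plot
#'
#' Lays the design's transects at `center`, tallies every log whose
#' centerline crosses a transect (diameter linearly interpolated at the
#' crossing point, recorded in inches), measures pile chords, draws FWD
#' counts from the class intensities over the FWD segments, and reads the
#' duff/litter depth surfaces at the transect ends. Output passes
#' [validate_dataset()] with zero violations.
#'
#' @param stand A [generate_stand()] result.
#' @param center Numeric `c(x, y)` in metres (toroidal wrap at the region
#'   edges).
#' @param design A [plot_design()].
#' @param seed Integer seed for the plot's stochastic components (FWD
#'   counts).
#' @param plt_cn Plot control number to stamp on the records.
#' @return List of data.frames: `cwd`, `pile`, `fwd`, `dufflitter`,
#'   `transect_segment`.
#' @export
sample_plot <- function(stand, center, design = plot_design(), seed = 1L,
                        plt_cn = "1") {
  u <- unit_definitions()
  p <- stand$params
  len_m <- design$cwd_transect_length_ft * u$foot_in_m
  tr <- .plot_transects(design, center[1], center[2])

  cr <- .log_crossings(stand, tr$ox, tr$oy, tr$az, len_m)
  cwd <- data.frame(
    PLT_CN = rep(plt_cn, nrow(cr)),
    SUBP = tr$subp[cr$ti],
    TRANSECT = as.integer(round(tr$az[cr$ti])),
    CWDID = seq_len(nrow(cr)),
    CONDID = rep(p$condid, nrow(cr)),
    SPCD = stand$logs$spcd[cr$li],
    DECAYCD = stand$logs$decaycd[cr$li],
    TRANSDIA = cr$diam_cm / 2.54,
    HOLLOW_DIA = stand$logs$hollow_frac[cr$li] * cr$diam_cm / 2.54,
    stringsAsFactors = FALSE
  )

  pc <- .pile_crossings(stand, tr$ox, tr$oy, tr$az, len_m)
  pile <- data.frame(
    PLT_CN = rep(plt_cn, nrow(pc)),
    SUBP = tr$subp[pc$ti],
    TRANSECT = as.integer(round(tr$az[pc$ti])),
    PILE = seq_len(nrow(pc)),
    CONDID = rep(p$condid, nrow(pc)),
    SPCD = stand$piles$spcd[pc$pi],
    DECAYCD = stand$piles$decaycd[pc$pi],
    COMP_HT = stand$piles$height_ft[pc$pi],
    HORIZ_BEGNDST = pc$begin_m / u$foot_in_m,
    HORIZ_ENDDIST = pc$end_m / u$foot_in_m,
    stringsAsFactors = FALSE
  )

  n_sub <- design$n_subplots
  fwd_counts <- .with_seed(seed, function() {
    sm_len <- design$fwd_sm_md_length_ft * u$foot_in_m
    lg_len <- design$fwd_large_length_ft * u$foot_in_m
    list(
      small = stats::rpois(n_sub, p$fwd_per_m[["small"]] * sm_len),
      medium = stats::rpois(n_sub, p$fwd_per_m[["medium"]] * sm_len),
      large = stats::rpois(n_sub, p$fwd_per_m[["large"]] * lg_len)
    )
  })
  fwd <- data.frame(
    PLT_CN = rep(plt_cn, n_sub),
    SUBP = seq_len(n_sub),
    CONDID = rep(p$condid, n_sub),
    SMALLCT = fwd_counts$small,
    MEDIUMCT = fwd_counts$medium,
    LARGECT = fwd_counts$large,
    TRANSECT = rep(as.integer(round(design$transect_azimuths_deg[1])),
                   n_sub),
    stringsAsFactors = FALSE
  )

  # depth points at the end of each transect, limited to the protocol's
  # points-per-subplot count
  npts <- design$dufflitter_points_per_subplot
  tr_pts <- tr[tr$tr <= npts, , drop = FALSE]
  ex <- tr_pts$ox + len_m * sin(tr_pts$az * pi / 180)
  ey <- tr_pts$oy + len_m * cos(tr_pts$az * pi / 180)
  dufflitter <- data.frame(
    PLT_CN = rep(plt_cn, nrow(tr_pts)),
    SUBP = tr_pts$subp,
    SMPLOCCD = tr_pts$tr,
    CONDID = rep(p$condid, nrow(tr_pts)),
    DUFFDEP = .depth_field(p, ex %% p$region_w_m, ey %% p$region_h_m,
                           "duff"),
    LITTDEP = .depth_field(p, ex %% p$region_w_m, ey %% p$region_h_m,
                           "litter"),
    stringsAsFactors = FALSE
  )

  transect_segment <- data.frame(
    PLT_CN = rep(plt_cn, nrow(tr)),
    SUBP = tr$subp,
    TRANSECT = as.integer(round(tr$az)),
    SEGMNT = rep(1L, nrow(tr)),
    CONDID = rep(p$condid, nrow(tr)),
    HORIZ_LENGTH = rep(design$cwd_transect_length_ft, nrow(tr)),
    HORIZ_BEGNDIST = rep(0, nrow(tr)),
    HORIZ_ENDDIST = rep(design$cwd_transect_length_ft, nrow(tr)),
    stringsAsFactors = FALSE
  )

  list(cwd = cwd, pile = pile, fwd = fwd, dufflitter = dufflitter,
       transect_segment = transect_segment)
}

#' Assemble a full inventory dataset from simulated plots
#'
#' Samples the stand at each plot center and builds the complete table set
#' (PLOT with synthetic coordinates, COND, DWM_VISIT, all measurement
#' tables, references) as a linked [dwm_dataset]. Per-plot random streams
#' are split from `seed`, so adding plot centers never perturbs earlier
#' plots.
#'
#' @param stand A [generate_stand()] result.
#' @param centers Two-column matrix (or data.frame) of plot centers in
#'   metres; default: `n_plots` uniform random centers.
#' @param design A [plot_design()].
#' @param seed Integer seed.
#' @param n_plots Number of random centers when `centers` is `NULL`.
#' @return A `dwm_dataset`.
#' @export
make_dataset <- function(stand, centers = NULL, design = plot_design(),
                         seed = 1L, n_plots = 10L) {
  p <- stand$params
  if (is.null(centers)) {
    centers <- .with_seed(.substream_seed(seed, 0L), function()
      cbind(stats::runif(n_plots, 0, p$region_w_m),
            stats::runif(n_plots, 0, p$region_h_m)))
  }
  centers <- as.matrix(centers)
  np <- nrow(centers)
  cns <- sprintf("P%04d", seq_len(np))
  recs <- lapply(seq_len(np), function(i) {
    sample_plot(stand, centers[i, ], design,
                seed = .substream_seed(seed, i), plt_cn = cns[i])
  })
  bindslot <- function(slot) do.call(rbind, lapply(recs, `[[`, slot))
  plot <- data.frame(
    CN = cns,
    LAT = 45 + centers[, 2] / 111000,
    LON = -93 + centers[, 1] / 78000,
    MEASYEAR = rep(2018L, np),
    INVYR = rep(2018L, np),
    stringsAsFactors = FALSE
  )
  cond <- data.frame(
    PLT_CN = cns, CONDID = rep(p$condid, np),
    FORTYPCD = rep(p$fortypcd, np),
    FORTYPGRPCD = rep(p$fortypgrpcd, np),
    STDAGE = rep(60, np), OWNCD = rep(11L, np), BALIVE = rep(120, np),
    stringsAsFactors = FALSE
  )
  visit <- data.frame(
    PLT_CN = cns, INVYR = rep(2018L, np), QASTATCD = rep(1L, np),
    SMPKNDCD = rep(1L, np), CWD_SAMPLE_METHOD = rep(1L, np),
    DWM_NBR_SUBP = rep(design$n_subplots, np),
    stringsAsFactors = FALSE
  )
  dwm_dataset(
    plot = plot, cond = cond, visit = visit,
    cwd = bindslot("cwd"), fwd = bindslot("fwd"),
    dufflitter = bindslot("dufflitter"), pile = bindslot("pile"),
    transect_segment = bindslot("transect_segment"),
    ref_species = stand$ref_species,
    ref_forest_type_group = stand$ref_forest_type_group,
    design = design
  )
}

#' Write a simulated dataset as the CSV table set
#'
#' [make_dataset()] followed by [write_tables()]; the files round-trip
#' through [read_tables()] into the same estimates.
#'
#' @inheritParams make_dataset
#' @param out_dir Output directory.
#' @return Named vector of written file paths, invisibly.
#' @export
emit_dataset <- function(stand, centers = NULL, design = plot_design(),
                         seed = 1L, out_dir, n_plots = 10L) {
  ds <- make_dataset(stand, centers, design, seed, n_plots)
  write_tables(ds, out_dir)
}

# per-plot sufficient statistics for the fast Monte-Carlo path
# returns data.frame per plot: sum_d2 (in^2, hollow-corrected), n_pieces,
# sum_di12 (DI/12, in->ft), sum_dens_d2, sum_densc_d2, sum_phpl (ft^2),
# sum_dens_phpl, sum_pl_ft, duff_sum_in, litter_sum_in
.plot_sums <- function(stand, centers, design) {
  u <- unit_definitions()
  p <- stand$params
  len_m <- design$cwd_transect_length_ft * u$foot_in_m
  np <- nrow(centers)
  tr <- .plot_transects(design, centers[, 1], centers[, 2])
  out <- data.frame(
    plot = seq_len(np), sum_d2 = 0, n_pieces = 0, sum_di12 = 0,
    sum_dens_d2 = 0, sum_densc_d2 = 0, sum_phpl = 0, sum_dens_phpl = 0,
    sum_pl_ft = 0, duff_sum_in = 0, litter_sum_in = 0
  )
  cr <- .log_crossings(stand, tr$ox, tr$oy, tr$az, len_m)
  if (nrow(cr)) {
    pl_of <- tr$plot[cr$ti]
    diam_in <- cr$diam_cm / 2.54
    hf <- stand$logs$hollow_frac[cr$li]
    d2 <- diam_in^2 * (1 - hf^2)
    dens <- cwd_bulk_density(stand$logs$spcd[cr$li],
                             stand$logs$decaycd[cr$li], stand$ref_species)
    densc <- cwd_bulk_density(stand$logs$spcd[cr$li],
                              stand$logs$decaycd[cr$li], stand$ref_species,
                              carbon = TRUE)
    agg <- function(x) {
      z <- rowsum(x, pl_of)
      ix <- as.integer(rownames(z))
      v <- numeric(np); v[ix] <- z[, 1]; v
    }
    out$sum_d2 <- agg(d2)
    out$n_pieces <- agg(rep(1, length(d2)))
    out$sum_di12 <- agg(diam_in / 12)
    out$sum_dens_d2 <- agg(dens * d2)
    out$sum_densc_d2 <- agg(densc * d2)
  }
  pc <- .pile_crossings(stand, tr$ox, tr$oy, tr$az, len_m)
  if (nrow(pc)) {
    pl_of <- tr$plot[pc$ti]
    pl_ft <- (pc$end_m - pc$begin_m) / u$foot_in_m
    ph_ft <- stand$piles$height_ft[pc$pi]
    dens <- cwd_bulk_density(stand$piles$spcd[pc$pi],
                             stand$piles$decaycd[pc$pi], stand$ref_species)
    agg <- function(x) {
      z <- rowsum(x, pl_of)
      ix <- as.integer(rownames(z))
      v <- numeric(np); v[ix] <- z[, 1]; v
    }
    out$sum_phpl <- agg(ph_ft * pl_ft)
    out$sum_dens_phpl <- agg(dens * ph_ft * pl_ft)
    out$sum_pl_ft <- agg(pl_ft)
  }
  npts <- design$dufflitter_points_per_subplot
  tr_pts <- tr[tr$tr <= npts, , drop = FALSE]
  ex <- (tr_pts$ox + len_m * sin(tr_pts$az * pi / 180)) %% p$region_w_m
  ey <- (tr_pts$oy + len_m * cos(tr_pts$az * pi / 180)) %% p$region_h_m
  dz <- rowsum(.depth_field(p, ex, ey, "duff"), tr_pts$plot)
  lz <- rowsum(.depth_field(p, ex, ey, "litter"), tr_pts$plot)
  out$duff_sum_in[as.integer(rownames(dz))] <- dz[, 1]
  out$litter_sum_in[as.integer(rownames(lz))] <- lz[, 1]
  out
}

# per-plot estimates (metric) from sufficient statistics, using the same
# published constants as the plot estimators
.sums_to_estimates <- function(sums, design, attribute) {
  L <- cwd_total_length_ft(design)
  npts <- dufflitter_n_points(design)
  c1v <- paper_constant("cwd_volume_piece", "metric")
  c2v <- paper_constant("cwd_volume_pile", "metric")
  c1m <- paper_constant("cwd_mass_piece", "metric")
  c2m <- paper_constant("cwd_mass_pile", "metric")
  switch(attribute,
    cwd_volume = (c1v * pi^2 / 8 * sums$sum_d2 +
                    c2v * pi / 2 * sums$sum_phpl) / L,
    cwd_biomass = (c1m * pi^2 / 8 * sums$sum_dens_d2 +
                     c2m * pi / 2 * sums$sum_dens_phpl) / L,
    cwd_carbon = (c1m * pi^2 / 8 * sums$sum_densc_d2 +
                    c2m * pi / 2 * 0) / L,
    cwd_length = paper_constant("cwd_length", "metric") * pi / (2 * L) *
      sums$n_pieces,
    cwd_cover = 100 * pi / (2 * L) * (sums$sum_di12 + sums$sum_pl_ft),
    duff_volume = paper_constant("dufflitter_volume", "metric") *
      sums$duff_sum_in / npts,
    litter_volume = paper_constant("dufflitter_volume", "metric") *
      sums$litter_sum_in / npts,
    stop("unsupported Monte-Carlo attribute: ", attribute, call. = FALSE)
  )
}

.mc_truth <- function(stand, attribute) {
  tr <- stand$truth
  switch(attribute,
    cwd_volume = tr$cwd_volume_total_m3_ha,
    cwd_biomass = tr$cwd_biomass_Mg_ha,
    cwd_carbon = tr$cwd_carbon_Mg_ha,
    cwd_length = tr$cwd_length_m_ha,
    cwd_cover = tr$cwd_cover_pct,
    duff_volume = tr$duff_volume_m3_ha,
    litter_volume = tr$litter_volume_m3_ha,
    stop("unsupported Monte-Carlo attribute: ", attribute, call. = FALSE)
  )
}

#' Monte-Carlo validation of the plot estimators
#'
#' Samples `n_plots` uniform random plot centers over the (toroidal)
#' region, computes the metric plot estimates for the requested
#' attributes, and reports the Monte-Carlo mean, its standard error, the
#' stand truth and the standardized error `z = (mean - truth) / SE`.
#' Line-intersect theory predicts design-unbiasedness when log azimuths
#' are uniform, so |z| should behave like a standard normal draw.
#'
#' Carbon from piles is not separated in the fast path, so `cwd_carbon` is
#' only supported for stands without piles.
#'
#' @param stand A [generate_stand()] result.
#' @param design A [plot_design()].
#' @param n_plots Number of independent plot locations (>= 1).
#' @param seed Integer seed.
#' @param attributes Subset of `cwd_volume`, `cwd_biomass`, `cwd_carbon`,
#'   `cwd_length`, `cwd_cover`, `duff_volume`, `litter_volume`.
#' @param return_values Also return the per-plot estimate matrix and the
#'   plot centers (for e.g. spatial post-stratification experiments).
#' @return Object of class `dwm_mc`: list with `table` (one row per
#'   attribute: `truth`, `mc_mean`, `mc_se`, `z`), `n_plots`, `seed`,
#'   `se_undefined` flag (TRUE when `n_plots` < 2), and optionally
#'   `values`.
#' @export
run_monte_carlo <- function(stand, design = plot_design(), n_plots = 1000L,
                            seed = 1L,
                            attributes = c("cwd_volume", "cwd_length"),
                            return_values = FALSE) {
  stopifnot(n_plots >= 1)
  if ("cwd_carbon" %in% attributes && nrow(stand$piles) > 0) {
    stop("cwd_carbon Monte-Carlo is not supported for stands with piles",
         call. = FALSE)
  }
  p <- stand$params
  centers <- .with_seed(.substream_seed(seed, 0L), function()
    cbind(stats::runif(n_plots, 0, p$region_w_m),
          stats::runif(n_plots, 0, p$region_h_m)))
  # chunk so the transect x log matrices stay modest
  ntr <- design$n_subplots * design$transects_per_subplot
  chunk <- max(1L, as.integer(2e6 / max(1, nrow(stand$logs)) / ntr))
  sums <- NULL
  for (i0 in seq(1L, n_plots, by = chunk)) {
    i1 <- min(n_plots, i0 + chunk - 1L)
    s <- .plot_sums(stand, centers[i0:i1, , drop = FALSE], design)
    s$plot <- s$plot + i0 - 1L
    sums <- if (is.null(sums)) s else rbind(sums, s)
  }
  vals <- sapply(attributes, function(a)
    .sums_to_estimates(sums, design, a))
  vals <- matrix(vals, nrow = n_plots,
                 dimnames = list(NULL, attributes))
  se_undef <- n_plots < 2
  tab <- do.call(rbind, lapply(attributes, function(a) {
    v <- vals[, a]
    m <- mean(v)
    se <- if (se_undef) NA_real_ else stats::sd(v) / sqrt(n_plots)
    tru <- .mc_truth(stand, a)
    data.frame(attribute = a, truth = tru, mc_mean = m, mc_se = se,
               z = if (se_undef || se == 0) NA_real_ else (m - tru) / se,
               n_plots = n_plots, stringsAsFactors = FALSE)
  }))
  out <- list(table = tab, n_plots = n_plots, seed = seed,
              se_undefined = se_undef)
  if (return_values) {
    out$values <- vals
    out$centers <- centers
  }
  class(out) <- "dwm_mc"
  out
}

#' @export
print.dwm_mc <- function(x, ...) {
  cat("Monte-Carlo validation over", x$n_plots, "plots (seed",
      x$seed, ")\n")
  if (x$se_undefined) {
    cat("  WARNING: SE undefined with a single plot\n")
  }
  print(x$table, row.names = FALSE)
  invisible(x)
}
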