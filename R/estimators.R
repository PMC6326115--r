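#' @name dwm_estimators
#' @title Plot-level transect estimators
#'
#' @description
#' The plot-level line-intersect estimators for downed dead wood. Writing
#' DI and DH for the piece and hollow diameters (in) at the transect
#' intersection, PH and PL for a pile's compacted height and occupied
#' transect length (ft), L for the plot's total transect length (ft), and
#' \eqn{\delta} for the 0/1 domain indicator:
#'
#' \deqn{volume: y = (1/L) [ C_1 (\pi^2/8) \sum (DI^2 - DH^2) \delta
#'   + C_2 (\pi/2) \sum PH \cdot PL \cdot \delta ]}
#' \deqn{mass:   y = (1/L) [ C_1 (\pi^2/8) \sum DENS (DI^2 - DH^2) \delta
#'   + C_2 (\pi/2) \sum DENS \cdot PH \cdot PL \cdot \delta ]}
#' \deqn{cover:  y = (100\pi/2L) [ \sum (DI/12) \delta + \sum PL \delta ]}
#' \deqn{length: y = C (\pi/2L) \sum \delta}
#' \deqn{FWD:    y = C (\pi^2/8L) \sum n \cdot QMD^2 \delta}
#' \deqn{duff/litter: y = C \sum y_{jm} \delta / (n_s n_{p,s})}
#'
#' Constants come from [paper_constant()]. L is the full protocol length
#' (192 ft under the 2012 design) regardless of condition mapping —
#' condition membership enters only through \eqn{\delta}; pass `L_ft`
#' (e.g. a [condition_transect_length()] sum) for the strict-conditional
#' alternative.
NULL

.unit_label <- function(context, units) {
  .paper_constants[[context]][[paste0(units, "_unit")]]
}

#' Construct a plot-estimate scalar
#' @param value Numeric estimate (per unit area).
#' @param attribute Attribute name, e.g. `"cwd_volume"`.
#' @param units `"imperial"` or `"metric"`.
#' @param unit_label Output unit string, e.g. `"ft3/acre"`.
#' @param domain A [dwm_domain()] or `NULL`.
#' @param undefined `TRUE` when the estimate is undefined (e.g. every
#'   depth point non-sampled); value is then `NA`.
#' @return Classed numeric scalar (`dwm_estimate`) carrying the metadata
#'   as attributes.
#' @export
dwm_estimate <- function(value, attribute, units, unit_label,
                         domain = NULL, undefined = FALSE) {
  structure(value,
            attribute = attribute, units = units, unit_label = unit_label,
            domain = if (is.null(domain)) "all" else format(domain),
            undefined = undefined, class = "dwm_estimate")
}

#' @export
print.dwm_estimate <- function(x, ...) {
  cat(sprintf("%s [%s, domain: %s] = %s %s\n",
              attr(x, "attribute"), attr(x, "units"), attr(x, "domain"),
              format(as.numeric(x)), attr(x, "unit_label")))
  invisible(x)
}

.check_pieces <- function(pieces) {
  if (is.null(pieces) || !nrow(pieces)) return(invisible(NULL))
  dh <- pieces$HOLLOW_DIA %||% rep(0, nrow(pieces))
  dh[is.na(dh)] <- 0
  if (any(dh > pieces$TRANSDIA + 1e-9)) {
    stop("hollow diameter exceeds piece diameter", call. = FALSE)
  }
  invisible(NULL)
}

.pile_pl <- function(piles) {
  if (is.null(piles) || !nrow(piles)) return(numeric(0))
  pl <- piles$HORIZ_ENDDIST - piles$HORIZ_BEGNDST
  if (any(pl < -1e-9)) stop("negative pile transect length", call. = FALSE)
  pmax(pl, 0)
}

#' Transect length actually sampled in a set of conditions, in feet
#'
#' Sums `HORIZ_LENGTH` over a plot's transect-segment records, optionally
#' restricted to given condition ids. Use as `L_ft` in the estimators for
#' the strict-conditional variant (off by default: the standard estimators
#' use the full protocol length).
#'
#' @param segments `DWM_TRANSECT_SEGMENT` rows for one plot.
#' @param condid Optional condition ids to keep.
#' @return Numeric scalar, feet.
#' @export
condition_transect_length <- function(segments, condid = NULL) {
  if (!is.null(condid)) segments <- segments[segments$CONDID %in% condid, ]
  sum(segments$HORIZ_LENGTH)
}

#' CWD volume per unit area for one plot
#'
#' @param pieces `DWM_COARSE_WOODY_DEBRIS` rows for one plot (may be
#'   empty/`NULL`).
#' @param piles `DWM_RESIDUAL_PILE` rows for the same plot (optional).
#' @param design A [plot_design()].
#' @param domain A [dwm_domain()] or `NULL` for all records.
#' @param units `"imperial"` (ft3/acre) or `"metric"` (m3/ha).
#' @param cond `COND` table, needed only for condition-level domain
#'   clauses.
#' @param L_ft Total transect length; defaults to the design's protocol
#'   length ([cwd_total_length_ft()]).
#' @return A [dwm_estimate()].
#' @export
cwd_volume <- function(pieces = NULL, piles = NULL, design = plot_design(),
                       domain = NULL, units = c("imperial", "metric"),
                       cond = NULL, L_ft = NULL) {
  units <- match.arg(units)
  L <- L_ft %||% cwd_total_length_ft(design)
  .check_pieces(pieces)
  piece_sum <- 0
  if (!is.null(pieces) && nrow(pieces)) {
    dh <- pieces$HOLLOW_DIA %||% rep(0, nrow(pieces))
    dh[is.na(dh)] <- 0
    delta <- domain_indicator(domain, pieces, cond)
    piece_sum <- sum((pieces$TRANSDIA^2 - dh^2) * delta)
  }
  pile_sum <- 0
  if (!is.null(piles) && nrow(piles)) {
    pl <- .pile_pl(piles)
    delta <- domain_indicator(domain, piles, cond)
    pile_sum <- sum(piles$COMP_HT * pl * delta)
  }
  c1 <- paper_constant("cwd_volume_piece", units)
  c2 <- paper_constant("cwd_volume_pile", units)
  val <- (c1 * pi^2 / 8 * piece_sum + c2 * pi / 2 * pile_sum) / L
  dwm_estimate(val, "cwd_volume", units,
               .unit_label("cwd_volume_piece", units), domain)
}

#' CWD biomass or carbon per unit area for one plot
#'
#' Each piece and pile is weighted by its bulk density
#' ([cwd_bulk_density()]: specific gravity x 62.4 lb/ft3 x decay-class
#' ratio, times the carbon ratio for carbon output).
#'
#' @inheritParams cwd_volume
#' @param density_ref Species reference table covering every (species,
#'   decay class) present.
#' @param output `"biomass"` or `"carbon"`.
#' @return A [dwm_estimate()] in short tons/acre or Mg/ha.
#' @export
cwd_mass <- function(pieces = NULL, piles = NULL, design = plot_design(),
                     density_ref = default_species_reference(),
                     output = c("biomass", "carbon"), domain = NULL,
                     units = c("imperial", "metric"), cond = NULL,
                     L_ft = NULL) {
  units <- match.arg(units)
  output <- match.arg(output)
  carbon <- output == "carbon"
  L <- L_ft %||% cwd_total_length_ft(design)
  .check_pieces(pieces)
  piece_sum <- 0
  if (!is.null(pieces) && nrow(pieces)) {
    dh <- pieces$HOLLOW_DIA %||% rep(0, nrow(pieces))
    dh[is.na(dh)] <- 0
    dens <- cwd_bulk_density(pieces$SPCD, pieces$DECAYCD, density_ref,
                             carbon = carbon)
    delta <- domain_indicator(domain, pieces, cond)
    piece_sum <- sum(dens * (pieces$TRANSDIA^2 - dh^2) * delta)
  }
  pile_sum <- 0
  if (!is.null(piles) && nrow(piles)) {
    pl <- .pile_pl(piles)
    dens <- cwd_bulk_density(piles$SPCD, piles$DECAYCD, density_ref,
                             carbon = carbon)
    delta <- domain_indicator(domain, piles, cond)
    pile_sum <- sum(dens * piles$COMP_HT * pl * delta)
  }
  c1 <- paper_constant("cwd_mass_piece", units)
  c2 <- paper_constant("cwd_mass_pile", units)
  val <- (c1 * pi^2 / 8 * piece_sum + c2 * pi / 2 * pile_sum) / L
  dwm_estimate(val, paste0("cwd_", output), units,
               .unit_label("cwd_mass_piece", units), domain)
}

#' Percent cover of CWD for one plot
#'
#' \eqn{(100\pi/2L)[\sum (DI/12)\delta + \sum PL\, \delta]} — DI in
#' inches converted to feet. By construction the estimate can exceed 100
#' (e.g. a pile occupying a whole transect contributes
#' \eqn{100\pi/2 \approx 157}); no cap is applied.
#'
#' @inheritParams cwd_volume
#' @return A [dwm_estimate()] in percent (same in both unit systems).
#' @export
cwd_cover <- function(pieces = NULL, piles = NULL, design = plot_design(),
                      domain = NULL, cond = NULL, L_ft = NULL) {
  L <- L_ft %||% cwd_total_length_ft(design)
  .check_pieces(pieces)
  piece_sum <- 0
  if (!is.null(pieces) && nrow(pieces)) {
    delta <- domain_indicator(domain, pieces, cond)
    piece_sum <- sum(pieces$TRANSDIA / 12 * delta)
  }
  pile_sum <- 0
  if (!is.null(piles) && nrow(piles)) {
    pl <- .pile_pl(piles)
    delta <- domain_indicator(domain, piles, cond)
    pile_sum <- sum(pl * delta)
  }
  val <- 100 * pi / (2 * L) * (piece_sum + pile_sum)
  dwm_estimate(val, "cwd_cover", "imperial", "%", domain)
}

#' Linear length of CWD pieces per unit area for one plot
#'
#' Counts tallied pieces only (piles are excluded from the length
#' estimator).
#'
#' @inheritParams cwd_volume
#' @return A [dwm_estimate()] in ft/acre or m/ha.
#' @export
cwd_length <- function(pieces = NULL, design = plot_design(),
                       domain = NULL, units = c("imperial", "metric"),
                       cond = NULL, L_ft = NULL) {
  units <- match.arg(units)
  L <- L_ft %||% cwd_total_length_ft(design)
  count <- 0
  if (!is.null(pieces) && nrow(pieces)) {
    count <- sum(domain_indicator(domain, pieces, cond))
  }
  val <- paper_constant("cwd_length", units) * pi / (2 * L) * count
  dwm_estimate(val, "cwd_length", units, .unit_label("cwd_length", units),
               domain)
}

.fwd_count_col <- c(small = "SMALLCT", medium = "MEDIUMCT",
                    large = "LARGECT")
.fwd_qmd_col <- c(small = "FWD_SMALL_QMD", medium = "FWD_MEDIUM_QMD",
                  large = "FWD_LARGE_QMD")

#' FWD volume per unit area for one plot and size class
#'
#' Converts per-subplot piece counts to volume through the class quadratic
#' mean diameter (QMD) taken from the forest-type-group reference of each
#' tally's condition.
#'
#' @param tallies `DWM_FINE_WOODY_DEBRIS` rows for one plot.
#' @param size_class `"small"`, `"medium"` or `"large"`.
#' @param design A [plot_design()].
#' @param qmd_ref Forest-type-group reference carrying the QMD columns.
#' @param cond `COND` table (required when tallies are present, to resolve
#'   the forest-type group).
#' @param domain,units,L_ft As in [cwd_volume()]; `L_ft` defaults to the
#'   class protocol total ([fwd_total_length_ft()]: 24 ft small/medium,
#'   40 ft large).
#' @return A [dwm_estimate()].
#' @export
fwd_volume <- function(tallies = NULL,
                       size_class = c("small", "medium", "large"),
                       design = plot_design(),
                       qmd_ref = default_forest_type_group_reference(),
                       cond = NULL, domain = NULL,
                       units = c("imperial", "metric"), L_ft = NULL) {
  size_class <- match.arg(size_class)
  units <- match.arg(units)
  L <- L_ft %||% fwd_total_length_ft(design, size_class)
  s <- 0
  if (!is.null(tallies) && nrow(tallies)) {
    if (is.null(cond)) {
      stop("COND table required to resolve FWD quadratic mean diameters",
           call. = FALSE)
    }
    n <- tallies[[.fwd_count_col[[size_class]]]]
    n[is.na(n)] <- 0L
    qmd <- .ftg_attr(tallies, cond, qmd_ref, .fwd_qmd_col[[size_class]])
    delta <- domain_indicator(domain, tallies, cond)
    s <- sum(n * qmd^2 * delta)
  }
  val <- paper_constant("fwd_volume", units) * pi^2 / (8 * L) * s
  dwm_estimate(val, paste0("fwd_volume_", size_class), units,
               .unit_label("fwd_volume", units), domain)
}

#' FWD biomass or carbon per unit area for one plot and size class
#'
#' The volume estimator weighted by the forest-type-group FWD bulk density
#' (times its carbon ratio for carbon), with the mass-unit constants.
#'
#' @inheritParams fwd_volume
#' @param density_ref Forest-type-group reference with `FWD_DENSITY` and
#'   `FWD_CARBON_RATIO`.
#' @param output `"biomass"` or `"carbon"`.
#' @return A [dwm_estimate()] in short tons/acre or Mg/ha.
#' @export
fwd_mass <- function(tallies = NULL,
                     size_class = c("small", "medium", "large"),
                     design = plot_design(),
                     density_ref = default_forest_type_group_reference(),
                     output = c("biomass", "carbon"), cond = NULL,
                     domain = NULL, units = c("imperial", "metric"),
                     L_ft = NULL) {
  size_class <- match.arg(size_class)
  units <- match.arg(units)
  output <- match.arg(output)
  L <- L_ft %||% fwd_total_length_ft(design, size_class)
  s <- 0
  if (!is.null(tallies) && nrow(tallies)) {
    if (is.null(cond)) {
      stop("COND table required to resolve FWD densities", call. = FALSE)
    }
    n <- tallies[[.fwd_count_col[[size_class]]]]
    n[is.na(n)] <- 0L
    qmd <- .ftg_attr(tallies, cond, density_ref, .fwd_qmd_col[[size_class]])
    dens <- .ftg_attr(tallies, cond, density_ref, "FWD_DENSITY")
    if (output == "carbon") {
      dens <- dens * .ftg_attr(tallies, cond, density_ref,
                               "FWD_CARBON_RATIO")
    }
    delta <- domain_indicator(domain, tallies, cond)
    s <- sum(n * qmd^2 * dens * delta)
  }
  val <- paper_constant("cwd_mass_piece", units) * pi^2 / (8 * L) * s
  dwm_estimate(val, paste0("fwd_", output, "_", size_class), units,
               .unit_label("cwd_mass_piece", units), domain)
}

.layer_depth_col <- c(duff = "DUFFDEP", litter = "LITTDEP")

#' Duff or litter volume per unit area for one plot
#'
#' Mean point depth scaled to volume per area:
#' \eqn{C \sum y_{jm}\delta / (n_s n_{p,s})}. Non-sampled points
#' (missing depth) are dropped from the numerator while the denominator
#' stays at the protocol point count (`denominator = "protocol"`, the
#' published form); `denominator = "sampled"` instead divides by the
#' number of sampled points — a documented deviation. If every in-domain
#' point is missing the estimate is undefined (`NA` with attribute
#' `undefined = TRUE`), not 0.
#'
#' @param points `DWM_DUFF_LITTER_FUEL` rows for one plot.
#' @param layer `"duff"` or `"litter"`.
#' @inheritParams cwd_volume
#' @param denominator `"protocol"` (fixed \eqn{n_s n_{p,s}}) or
#'   `"sampled"`.
#' @return A [dwm_estimate()].
#' @export
dufflitter_volume <- function(points = NULL, layer = c("duff", "litter"),
                              design = plot_design(), domain = NULL,
                              units = c("imperial", "metric"), cond = NULL,
                              denominator = c("protocol", "sampled")) {
  layer <- match.arg(layer)
  units <- match.arg(units)
  denominator <- match.arg(denominator)
  n_protocol <- dufflitter_n_points(design)
  undefined <- FALSE
  num <- 0
  denom <- n_protocol
  if (!is.null(points) && nrow(points)) {
    y <- points[[.layer_depth_col[[layer]]]]
    delta <- domain_indicator(domain, points, cond)
    sampled <- !is.na(y)
    if (denominator == "sampled") denom <- sum(sampled)
    if (any(delta > 0) && !any(sampled & delta > 0)) {
      undefined <- TRUE
    } else {
      num <- sum(y[sampled] * delta[sampled])
    }
    if (nrow(points) && !any(sampled)) undefined <- TRUE
  }
  # no point records at all: empty sums give 0 (undefined is reserved for
  # points that exist but were all obstructed)
  val <- if (undefined || denom == 0) {
    NA_real_
  } else {
    paper_constant("dufflitter_volume", units) * num / denom
  }
  dwm_estimate(val, paste0(layer, "_volume"), units,
               .unit_label("dufflitter_volume", units), domain,
               undefined = undefined)
}

#' Duff or litter biomass or carbon per unit area for one plot
#'
#' The volume estimator weighted by the layer's forest-type-group bulk
#' density (times the layer carbon ratio for carbon). The plot's group is
#' resolved through the points' conditions; with points in several groups
#' each point is weighted by its own condition's density.
#'
#' @inheritParams dufflitter_volume
#' @param density_ref Forest-type-group reference with
#'   `DUFF_DENSITY`/`LITTER_DENSITY` and the carbon ratios.
#' @param output `"biomass"` or `"carbon"`.
#' @return A [dwm_estimate()] in short tons/acre or Mg/ha.
#' @export
dufflitter_mass <- function(points = NULL, layer = c("duff", "litter"),
                            design = plot_design(),
                            density_ref =
                              default_forest_type_group_reference(),
                            output = c("biomass", "carbon"), domain = NULL,
                            units = c("imperial", "metric"), cond = NULL,
                            denominator = c("protocol", "sampled")) {
  layer <- match.arg(layer)
  units <- match.arg(units)
  output <- match.arg(output)
  denominator <- match.arg(denominator)
  n_protocol <- dufflitter_n_points(design)
  undefined <- FALSE
  num <- 0
  denom <- n_protocol
  if (!is.null(points) && nrow(points)) {
    if (is.null(cond)) {
      stop("COND table required to resolve duff/litter densities",
           call. = FALSE)
    }
    y <- points[[.layer_depth_col[[layer]]]]
    dens_col <- if (layer == "duff") "DUFF_DENSITY" else "LITTER_DENSITY"
    dens <- .ftg_attr(points, cond, density_ref, dens_col)
    if (output == "carbon") {
      cr_col <- if (layer == "duff") "DUFF_CARBON_RATIO" else
        "LITTER_CARBON_RATIO"
      dens <- dens * .ftg_attr(points, cond, density_ref, cr_col)
    }
    delta <- domain_indicator(domain, points, cond)
    sampled <- !is.na(y)
    if (denominator == "sampled") denom <- sum(sampled)
    if ((any(delta > 0) && !any(sampled & delta > 0)) ||
        (nrow(points) && !any(sampled))) {
      undefined <- TRUE
    } else {
      num <- sum(y[sampled] * dens[sampled] * delta[sampled])
    }
  }
  # depth (in) x density (lb/ft3): imperial tons/acre = C_vol / 2000;
  # metric applies the exact mass-per-area conversion
  c_imp <- paper_constant("dufflitter_volume", "imperial") /
    unit_definitions()$short_ton_in_lb
  cc <- if (units == "imperial") c_imp else
    c_imp * metric_conversion_factor("mass_per_area")
  val <- if (undefined || denom == 0) NA_real_ else cc * num / denom
  dwm_estimate(val, paste0(layer, "_", output), units,
               .unit_label("cwd_mass_piece", units), domain,
               undefined = undefined)
}

.plot_attributes <- c(
  "cwd_volume", "cwd_biomass", "cwd_carbon", "cwd_cover", "cwd_length",
  "fwd_volume_small", "fwd_volume_medium", "fwd_volume_large",
  "fwd_biomass_small", "fwd_biomass_medium", "fwd_biomass_large",
  "duff_volume", "duff_biomass", "litter_volume", "litter_biomass"
)

.estimate_row <- function(plt_cn, est) {
  data.frame(
    PLT_CN = plt_cn,
    DOMAIN = attr(est, "domain"),
    ATTRIBUTE = attr(est, "attribute"),
    UNITS = attr(est, "units"),
    UNIT_LABEL = attr(est, "unit_label"),
    VALUE = as.numeric(est),
    stringsAsFactors = FALSE
  )
}

#' All DDW attribute estimates for one plot
#'
#' Composes the individual estimators over every attribute, domain and
#' requested unit system.
#'
#' @param ds A `dwm_dataset`.
#' @param plt_cn Plot control number present in `ds$plot$CN`.
#' @param domains List of [dwm_domain()] objects (default: the all-records
#'   domain).
#' @param units `"imperial"`, `"metric"` or `"both"`.
#' @param attributes Attribute subset; default all of
#'   `cwd_volume`, `cwd_biomass`, `cwd_carbon`, `cwd_cover`, `cwd_length`,
#'   `fwd_volume_<class>`, `fwd_biomass_<class>`, `duff_volume`,
#'   `duff_biomass`, `litter_volume`, `litter_biomass`.
#' @return data.frame with one row per attribute x domain x unit system:
#'   columns `PLT_CN`, `DOMAIN`, `ATTRIBUTE`, `UNITS`, `UNIT_LABEL`,
#'   `VALUE`.
#' @export
estimate_plot <- function(ds, plt_cn, domains = list(dwm_domain()),
                          units = c("imperial", "metric", "both"),
                          attributes = .plot_attributes) {
  stopifnot(inherits(ds, "dwm_dataset"))
  units <- match.arg(units)
  if (!plt_cn %in% ds$plot$CN) {
    stop("plot not in dataset: ", plt_cn, call. = FALSE)
  }
  bad <- setdiff(attributes, .plot_attributes)
  if (length(bad)) {
    stop("unknown attribute(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  usys <- if (units == "both") c("imperial", "metric") else units
  pieces <- ds$cwd[ds$cwd$PLT_CN == plt_cn, , drop = FALSE]
  piles <- ds$pile[ds$pile$PLT_CN == plt_cn, , drop = FALSE]
  tallies <- ds$fwd[ds$fwd$PLT_CN == plt_cn, , drop = FALSE]
  points <- ds$dufflitter[ds$dufflitter$PLT_CN == plt_cn, , drop = FALSE]
  des <- ds$design
  co <- ds$cond
  sp_ref <- ds$ref_species
  ft_ref <- ds$ref_forest_type_group

  rows <- list()
  for (dom in domains) {
    for (u in usys) {
      for (a in attributes) {
        est <- switch(a,
          cwd_volume = cwd_volume(pieces, piles, des, dom, u, co),
          cwd_biomass = cwd_mass(pieces, piles, des, sp_ref, "biomass",
                                 dom, u, co),
          cwd_carbon = cwd_mass(pieces, piles, des, sp_ref, "carbon",
                                dom, u, co),
          cwd_cover = cwd_cover(pieces, piles, des, dom, co),
          cwd_length = cwd_length(pieces, des, dom, u, co),
          fwd_volume_small = fwd_volume(tallies, "small", des, ft_ref,
                                        co, dom, u),
          fwd_volume_medium = fwd_volume(tallies, "medium", des, ft_ref,
                                         co, dom, u),
          fwd_volume_large = fwd_volume(tallies, "large", des, ft_ref,
                                        co, dom, u),
          fwd_biomass_small = fwd_mass(tallies, "small", des, ft_ref,
                                       "biomass", co, dom, u),
          fwd_biomass_medium = fwd_mass(tallies, "medium", des, ft_ref,
                                        "biomass", co, dom, u),
          fwd_biomass_large = fwd_mass(tallies, "large", des, ft_ref,
                                       "biomass", co, dom, u),
          duff_volume = dufflitter_volume(points, "duff", des, dom, u, co),
          duff_biomass = dufflitter_mass(points, "duff", des, ft_ref,
                                         "biomass", dom, u, co),
          litter_volume = dufflitter_volume(points, "litter", des, dom,
                                            u, co),
          litter_biomass = dufflitter_mass(points, "litter", des, ft_ref,
                                           "biomass", dom, u, co)
        )
        rows[[length(rows) + 1L]] <- .estimate_row(plt_cn, est)
      }
    }
  }
  do.call(rbind, rows)
}

#' Estimates for every plot in a dataset
#'
#' Applies [estimate_plot()] to each plot. Plots flagged as quality-
#' assurance blind remeasurements (`DWM_VISIT$QASTATCD > 1`) are excluded
#' by default.
#'
#' @inheritParams estimate_plot
#' @param include_qa Keep QA remeasurement plots (default `FALSE`).
#' @return Long data.frame of estimates.
#' @export
estimate_all <- function(ds, domains = list(dwm_domain()),
                         units = c("imperial", "metric", "both"),
                         attributes = .plot_attributes,
                         include_qa = FALSE) {
  stopifnot(inherits(ds, "dwm_dataset"))
  units <- match.arg(units)
  cns <- ds$plot$CN
  if (!include_qa && nrow(ds$visit)) {
    qa <- ds$visit$PLT_CN[!is.na(ds$visit$QASTATCD) & ds$visit$QASTATCD > 1]
    cns <- setdiff(cns, qa)
  }
  out <- lapply(cns, function(cn)
    estimate_plot(ds, cn, domains, units, attributes))
  do.call(rbind, out)
}
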