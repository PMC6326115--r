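#' Synthetic species reference table
#'
#' A small stand-in for the national species reference: wood specific
#' gravity (green-volume / oven-dry-weight basis), decay-class density
#' reduction ratios (non-increasing from class 1 to 5) and a carbon ratio,
#' for a handful of common species codes. The values are realistic but
#' SYNTHETIC — they are not the published reference table, which ships with
#' the national database. Supply your own `REF_SPECIES` file for production
#' work.
#'
#' @return data.frame with columns `SPCD`, `COMMON_NAME`,
#'   `WOOD_SPGR_GREENVOL_DRYWT`, `CWD_DECAY_RATIO1`..`5`,
#'   `DWM_CARBON_RATIO`.
#' @export
default_species_reference <- function() {
  df <- data.frame(
    SPCD = c(202L, 122L, 106L, 833L, 316L, 999L),
    COMMON_NAME = c("Douglas-fir", "ponderosa pine", "common pinyon",
                    "northern red oak", "red maple", "unknown"),
    WOOD_SPGR_GREENVOL_DRYWT = c(0.45, 0.38, 0.50, 0.56, 0.49, 0.40),
    stringsAsFactors = FALSE
  )
  # decay reduction ratios, non-increasing with decay class
  df$CWD_DECAY_RATIO1 <- 1.00
  df$CWD_DECAY_RATIO2 <- 1.00
  df$CWD_DECAY_RATIO3 <- 0.85
  df$CWD_DECAY_RATIO4 <- 0.55
  df$CWD_DECAY_RATIO5 <- 0.35
  df$DWM_CARBON_RATIO <- 0.50
  df
}

#' Synthetic forest-type-group reference table
#'
#' Bulk densities (lb/ft3), carbon ratios and fine-woody-debris quadratic
#' mean diameters (QMD, inches) by forest-type group. The QMD values are
#' PLACEHOLDERS inside the size-class bounds (small 0--0.24 in, medium
#' 0.25--0.9 in, large 1.0--2.9 in): the production values come from an
#' external diameter study and are not published in the sources this
#' package was built from. Override with your own `REF_FOREST_TYPE_GROUP`
#' file when real values are available.
#'
#' @return data.frame keyed by `TYPGRPCD` with density, carbon-ratio and
#'   QMD columns.
#' @export
default_forest_type_group_reference <- function() {
  data.frame(
    TYPGRPCD = c(100L, 200L, 400L, 500L, 900L),
    GROUP_NAME = c("white/red/jack pine", "Douglas-fir", "oak/pine",
                   "oak/hickory", "maple/beech/birch"),
    DUFF_DENSITY = c(6.9, 7.5, 7.0, 6.2, 6.5),       # lb/ft3
    LITTER_DENSITY = c(2.8, 3.1, 2.9, 2.6, 2.7),     # lb/ft3
    FWD_DENSITY = c(27.0, 28.5, 29.0, 34.0, 30.5),   # lb/ft3
    DUFF_CARBON_RATIO = c(0.50, 0.50, 0.50, 0.50, 0.50),
    LITTER_CARBON_RATIO = c(0.45, 0.45, 0.45, 0.45, 0.45),
    FWD_CARBON_RATIO = c(0.50, 0.50, 0.50, 0.50, 0.50),
    FWD_SMALL_QMD = c(0.15, 0.15, 0.14, 0.13, 0.14),   # in, placeholder
    FWD_MEDIUM_QMD = c(0.62, 0.62, 0.60, 0.58, 0.60),  # in, placeholder
    FWD_LARGE_QMD = c(1.85, 1.85, 1.80, 1.75, 1.80),   # in, placeholder
    stringsAsFactors = FALSE
  )
}

# conventional density of water in the imperial system, lb/ft3
.water_density_lb_ft3 <- 62.4

#' Bulk density of CWD pieces/piles from the species reference
#'
#' DENS = specific gravity x 62.4 lb/ft3 x decay-class reduction ratio,
#' optionally times the carbon ratio (for carbon density).
#'
#' @param spcd Integer species codes.
#' @param decaycd Integer decay classes (1--5).
#' @param ref_species Species reference table (see
#'   [default_species_reference()]).
#' @param carbon If `TRUE`, return carbon density (applies
#'   `DWM_CARBON_RATIO`).
#' @return Numeric vector of densities in lb/ft3.
#' @export
cwd_bulk_density <- function(spcd, decaycd, ref_species, carbon = FALSE) {
  i <- match(spcd, ref_species$SPCD)
  if (anyNA(i)) {
    stop("reference error: species code(s) not in REF_SPECIES: ",
         paste(unique(spcd[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(decaycd) | decaycd < 1 | decaycd > 5)) {
    stop("reference error: decay class outside 1..5", call. = FALSE)
  }
  ratio_cols <- paste0("CWD_DECAY_RATIO", 1:5)
  ratios <- as.matrix(ref_species[ratio_cols])[cbind(i, decaycd)]
  dens <- ref_species$WOOD_SPGR_GREENVOL_DRYWT[i] *
    .water_density_lb_ft3 * ratios
  if (carbon) dens <- dens * ref_species$DWM_CARBON_RATIO[i]
  dens
}

# resolve a forest-type-group row index for each condition row
.ftg_index <- function(cond, ref_ftg) {
  grp <- cond$FORTYPGRPCD %||% cond$FORTYPCD
  grp[is.na(grp)] <- cond$FORTYPCD[is.na(grp)]
  i <- match(grp, ref_ftg$TYPGRPCD)
  if (anyNA(i)) {
    stop("reference error: forest-type group(s) not in ",
         "REF_FOREST_TYPE_GROUP: ",
         paste(unique(grp[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  i
}

# per-record forest-type-group attribute looked up through the COND table
.ftg_attr <- function(records, cond, ref_ftg, column) {
  ci <- match(paste(records$PLT_CN, records$CONDID),
              paste(cond$PLT_CN, cond$CONDID))
  if (anyNA(ci)) {
    stop("linkage error: record condition(s) not found in COND",
         call. = FALSE)
  }
  fi <- .ftg_index(cond[ci, , drop = FALSE], ref_ftg)
  ref_ftg[[column]][fi]
}
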