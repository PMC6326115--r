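#' @name dwm_schema
#' @title The DWM relational schema
#'
#' @description
#' The package mirrors the down woody material (DWM) tables of the national
#' forest inventory database: `PLOT`, `COND`, `DWM_VISIT`,
#' `DWM_COARSE_WOODY_DEBRIS`, `DWM_FINE_WOODY_DEBRIS`,
#' `DWM_DUFF_LITTER_FUEL`, `DWM_RESIDUAL_PILE`, `DWM_TRANSECT_SEGMENT`,
#' `REF_SPECIES` and `REF_FOREST_TYPE_GROUP`, with the production column
#' names (`PLT_CN`, `TRANSDIA`, `DECAYCD`, `SPCD`, `SMALLCT`, `COMP_HT`,
#' ...) so that real Datamart CSV exports load unchanged. All measurements
#' are stored in the database's imperial units: diameters and depths in
#' inches, transect distances and pile heights in feet. Files are
#' comma-separated UTF-8 with `.` decimal; an empty field is missing.
#'
#' Columns absent from the published table summary but required by the
#' estimators are added with conservative conventions: the CWD table's
#' `HOLLOW_DIA` (hollow diameter at the intersection, missing = 0 = solid),
#' and optional per-class FWD transect lengths `SM_MD_HORIZ_LENGTH` /
#' `LG_HORIZ_LENGTH` (default: the design's protocol lengths). The `COND`
#' table may carry `FORTYPGRPCD` (forest-type group); when absent,
#' `FORTYPCD` is matched directly against `REF_FOREST_TYPE_GROUP$TYPGRPCD`.
NULL

# Column specification per table: required columns, their types, and
# accepted optional columns. type: chr (identifier), int, num.
.dwm_tables <- list(
  PLOT = list(
    required = c(CN = "chr", LAT = "num", LON = "num",
                 MEASYEAR = "int", INVYR = "int"),
    optional = character(0)
  ),
  COND = list(
    required = c(PLT_CN = "chr", CONDID = "int", FORTYPCD = "int"),
    optional = c(STDAGE = "num", OWNCD = "int", BALIVE = "num",
                 DSTRBCD1 = "int", FORTYPGRPCD = "int")
  ),
  DWM_VISIT = list(
    required = c(PLT_CN = "chr", INVYR = "int", QASTATCD = "int",
                 SMPKNDCD = "int"),
    optional = c(CWD_SAMPLE_METHOD = "int", DWM_NBR_SUBP = "int")
  ),
  DWM_COARSE_WOODY_DEBRIS = list(
    required = c(PLT_CN = "chr", SUBP = "int", TRANSECT = "int",
                 CWDID = "int", CONDID = "int", SPCD = "int",
                 DECAYCD = "int", TRANSDIA = "num"),
    optional = c(HOLLOW_DIA = "num")
  ),
  DWM_FINE_WOODY_DEBRIS = list(
    required = c(PLT_CN = "chr", SUBP = "int", CONDID = "int",
                 SMALLCT = "int", MEDIUMCT = "int", LARGECT = "int"),
    optional = c(TRANSECT = "int", SM_MD_HORIZ_LENGTH = "num",
                 LG_HORIZ_LENGTH = "num")
  ),
  DWM_DUFF_LITTER_FUEL = list(
    required = c(PLT_CN = "chr", SUBP = "int", SMPLOCCD = "int",
                 CONDID = "int", DUFFDEP = "num", LITTDEP = "num"),
    optional = c(FUELDEP = "num", NONSAMPLE_REASN_CD = "int")
  ),
  DWM_RESIDUAL_PILE = list(
    required = c(PLT_CN = "chr", SUBP = "int", TRANSECT = "int",
                 PILE = "int", CONDID = "int", SPCD = "int",
                 DECAYCD = "int", COMP_HT = "num",
                 HORIZ_BEGNDST = "num", HORIZ_ENDDIST = "num"),
    optional = character(0)
  ),
  DWM_TRANSECT_SEGMENT = list(
    required = c(PLT_CN = "chr", SUBP = "int", TRANSECT = "int",
                 SEGMNT = "int", CONDID = "int", HORIZ_LENGTH = "num",
                 HORIZ_BEGNDIST = "num", HORIZ_ENDDIST = "num"),
    optional = character(0)
  ),
  REF_SPECIES = list(
    required = c(SPCD = "int", WOOD_SPGR_GREENVOL_DRYWT = "num",
                 CWD_DECAY_RATIO1 = "num", CWD_DECAY_RATIO2 = "num",
                 CWD_DECAY_RATIO3 = "num", CWD_DECAY_RATIO4 = "num",
                 CWD_DECAY_RATIO5 = "num", DWM_CARBON_RATIO = "num"),
    optional = c(COMMON_NAME = "chr")
  ),
  REF_FOREST_TYPE_GROUP = list(
    required = c(TYPGRPCD = "int", DUFF_DENSITY = "num",
                 LITTER_DENSITY = "num", FWD_DENSITY = "num",
                 DUFF_CARBON_RATIO = "num", LITTER_CARBON_RATIO = "num",
                 FWD_CARBON_RATIO = "num", FWD_SMALL_QMD = "num",
                 FWD_MEDIUM_QMD = "num", FWD_LARGE_QMD = "num"),
    optional = c(FWD_DECAY_RATIO = "num", GROUP_NAME = "chr")
  )
)

# slot name inside a dwm_dataset for each file/table name
.dwm_table_slots <- c(
  PLOT = "plot", COND = "cond", DWM_VISIT = "visit",
  DWM_COARSE_WOODY_DEBRIS = "cwd", DWM_FINE_WOODY_DEBRIS = "fwd",
  DWM_DUFF_LITTER_FUEL = "dufflitter", DWM_RESIDUAL_PILE = "pile",
  DWM_TRANSECT_SEGMENT = "transect_segment", REF_SPECIES = "ref_species",
  REF_FOREST_TYPE_GROUP = "ref_forest_type_group"
)

.blank_col <- function(type, n = 0L) {
  switch(type,
    chr = character(n),
    int = integer(n),
    num = numeric(n)
  )
}

#' Empty typed table of the DWM schema
#'
#' @param table A table name, e.g. `"DWM_COARSE_WOODY_DEBRIS"`.
#' @return A zero-row data.frame with the table's required columns, typed.
#' @export
empty_table <- function(table) {
  spec <- .dwm_tables[[table]]
  if (is.null(spec)) stop("unknown DWM table: ", table, call. = FALSE)
  as.data.frame(lapply(spec$required, .blank_col),
                stringsAsFactors = FALSE)
}

.coerce_table <- function(df, table) {
  spec <- .dwm_tables[[table]]
  types <- c(spec$required, spec$optional)
  for (nm in intersect(names(df), names(types))) {
    df[[nm]] <- switch(types[[nm]],
      chr = as.character(df[[nm]]),
      int = {
        v <- df[[nm]]
        if (is.character(v)) v[!nzchar(trimws(v))] <- NA
        as.integer(v)
      },
      num = {
        v <- df[[nm]]
        if (is.character(v)) v[!nzchar(trimws(v))] <- NA
        as.numeric(v)
      }
    )
  }
  df
}

.check_columns <- function(df, table) {
  need <- names(.dwm_tables[[table]]$required)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("schema error: table ", table, " is missing required column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Assemble a DWM inventory dataset
#'
#' Bundles the schema tables into one linked object. Unsupplied tables
#' become empty typed tables. Cross-table keys are checked: every child
#' record's `PLT_CN` must exist in `PLOT$CN` and (for measurement tables)
#' its `(PLT_CN, CONDID)` in `COND`.
#'
#' @param plot,cond,visit,cwd,fwd,dufflitter,pile,transect_segment
#'   data.frames in the schema of the corresponding table (see
#'   [dwm_schema]).
#' @param ref_species,ref_forest_type_group Reference tables; default to
#'   the built-in synthetic references ([default_species_reference()],
#'   [default_forest_type_group_reference()]).
#' @param design A [plot_design()].
#' @return An object of class `dwm_dataset`.
#' @export
dwm_dataset <- function(plot, cond, visit = NULL, cwd = NULL, fwd = NULL,
                        dufflitter = NULL, pile = NULL,
                        transect_segment = NULL, ref_species = NULL,
                        ref_forest_type_group = NULL,
                        design = plot_design()) {
  tabs <- list(
    plot = plot, cond = cond, visit = visit, cwd = cwd, fwd = fwd,
    dufflitter = dufflitter, pile = pile,
    transect_segment = transect_segment,
    ref_species = ref_species %||% default_species_reference(),
    ref_forest_type_group =
      ref_forest_type_group %||% default_forest_type_group_reference()
  )
  for (tbl in names(.dwm_table_slots)) {
    slot <- .dwm_table_slots[[tbl]]
    if (is.null(tabs[[slot]])) tabs[[slot]] <- empty_table(tbl)
    .check_columns(tabs[[slot]], tbl)
    tabs[[slot]] <- .coerce_table(tabs[[slot]], tbl)
  }
  ds <- c(tabs, list(design = design))
  class(ds) <- "dwm_dataset"
  .check_linkage(ds)
  ds
}

.check_linkage <- function(ds) {
  cns <- ds$plot$CN
  if (anyDuplicated(cns)) {
    stop("linkage error: duplicated plot CN: ",
         paste(unique(cns[duplicated(cns)]), collapse = ", "),
         call. = FALSE)
  }
  child_slots <- c("cond", "visit", "cwd", "fwd", "dufflitter", "pile",
                   "transect_segment")
  for (slot in child_slots) {
    df <- ds[[slot]]
    if (!nrow(df)) next
    bad <- setdiff(unique(df$PLT_CN), cns)
    if (length(bad)) {
      stop("linkage error: ", slot, " rows reference unknown PLT_CN: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  condkey <- paste(ds$cond$PLT_CN, ds$cond$CONDID)
  for (slot in c("cwd", "fwd", "dufflitter", "pile", "transect_segment")) {
    df <- ds[[slot]]
    if (!nrow(df)) next
    k <- paste(df$PLT_CN, df$CONDID)
    bad <- setdiff(unique(k), condkey)
    if (length(bad)) {
      stop("linkage error: ", slot,
           " rows reference unknown (PLT_CN, CONDID): ",
           paste(bad, collapse = "; "), call. = FALSE)
    }
  }
  invisible(ds)
}

#' @export
print.dwm_dataset <- function(x, ...) {
  cat("DWM inventory dataset:", nrow(x$plot), "plots,",
      nrow(x$cond), "conditions,", nrow(x$cwd), "CWD pieces,",
      nrow(x$pile), "piles,", nrow(x$fwd), "FWD tallies,",
      nrow(x$dufflitter), "duff/litter points\n")
  cat("  design:", x$design$name, "\n")
  invisible(x)
}

#' Read a DWM table set from delimited files
#'
#' Reads the CSV tables of a DWM export (or of [emit_dataset()] output),
#' checks required columns, coerces types, and links the tables into a
#' [dwm_dataset]. Unknown extra columns are preserved but ignored by the
#' estimators.
#'
#' @param paths Named character vector or list mapping table names
#'   (`PLOT`, `COND`, `DWM_COARSE_WOODY_DEBRIS`, ...) to file paths;
#'   alternatively a single directory containing files named
#'   `<TABLE>.csv`. `PLOT` and `COND` are required; others optional.
#' @param design A [plot_design()].
#' @return A `dwm_dataset`.
#' @export
read_tables <- function(paths, design = plot_design()) {
  if (is.character(paths) && length(paths) == 1 && dir.exists(paths)) {
    fls <- file.path(paths, paste0(names(.dwm_table_slots), ".csv"))
    names(fls) <- names(.dwm_table_slots)
    paths <- fls[file.exists(fls)]
  }
  paths <- as.list(paths)
  unknown <- setdiff(names(paths), names(.dwm_table_slots))
  if (length(unknown)) {
    stop("unknown table name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (tbl in c("PLOT", "COND")) {
    if (is.null(paths[[tbl]])) {
      stop("schema error: required table ", tbl, " not supplied",
           call. = FALSE)
    }
  }
  tabs <- list()
  for (tbl in names(paths)) {
    p <- paths[[tbl]]
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
    df <- utils::read.csv(p, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
    .check_columns(df, tbl)
    tabs[[.dwm_table_slots[[tbl]]]] <- df
  }
  dwm_dataset(
    plot = tabs$plot, cond = tabs$cond, visit = tabs$visit,
    cwd = tabs$cwd, fwd = tabs$fwd, dufflitter = tabs$dufflitter,
    pile = tabs$pile, transect_segment = tabs$transect_segment,
    ref_species = tabs$ref_species,
    ref_forest_type_group = tabs$ref_forest_type_group,
    design = design
  )
}

#' Write a DWM dataset to delimited files
#'
#' Inverse of [read_tables()]: writes each table as `<TABLE>.csv` under
#' `dir`. `read_tables(dir)` reproduces the dataset.
#'
#' @param ds A `dwm_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_tables <- function(ds, dir) {
  stopifnot(inherits(ds, "dwm_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- character(0)
  for (tbl in names(.dwm_table_slots)) {
    slot <- .dwm_table_slots[[tbl]]
    p <- file.path(dir, paste0(tbl, ".csv"))
    utils::write.csv(ds[[slot]], p, row.names = FALSE, na = "")
    out[tbl] <- p
  }
  invisible(out)
}

.violation <- function(table, plt_cn, record, rule, message) {
  data.frame(table = table, plt_cn = as.character(plt_cn),
             record = as.character(record), rule = rule,
             message = message, stringsAsFactors = FALSE)
}

#' Validate a DWM dataset against the schema invariants
#'
#' Checks the enumerated record-level rules and returns every violation as
#' data (never an error). Rules: CWD transect diameter below the 7.61 cm
#' (3.0 in) threshold; hollow diameter exceeding piece diameter; decay
#' class outside 1--5; negative FWD counts; pile end before begin,
#' non-positive compacted height, or pile length beyond the design transect
#' length; overlapping transect segments or segment sums beyond the design
#' length; duff/litter depth missing without a non-sampled reason code;
#' latitude/longitude out of range; non-positive condition ids.
#'
#' @param ds A `dwm_dataset`.
#' @return A data.frame with columns `table`, `plt_cn`, `record`, `rule`,
#'   `message`; zero rows iff the dataset is clean.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "dwm_dataset"))
  v <- list()
  add <- function(x) v[[length(v) + 1L]] <<- x
  des <- ds$design

  p <- ds$plot
  bad <- which(!is.na(p$LAT) & (p$LAT < -90 | p$LAT > 90))
  for (i in bad) add(.violation("PLOT", p$CN[i], p$CN[i], "lat_range",
                                sprintf("latitude %g out of [-90, 90]",
                                        p$LAT[i])))
  bad <- which(!is.na(p$LON) & (p$LON < -180 | p$LON > 180))
  for (i in bad) add(.violation("PLOT", p$CN[i], p$CN[i], "lon_range",
                                sprintf("longitude %g out of [-180, 180]",
                                        p$LON[i])))

  co <- ds$cond
  bad <- which(!is.na(co$CONDID) & co$CONDID < 1)
  for (i in bad) add(.violation("COND", co$PLT_CN[i], co$CONDID[i],
                                "condid_positive",
                                "condition id must be >= 1"))

  w <- ds$cwd
  if (nrow(w)) {
    dh <- w$HOLLOW_DIA %||% rep(NA_real_, nrow(w))
    dh[is.na(dh)] <- 0
    bad <- which(!is.na(w$TRANSDIA) & w$TRANSDIA < 3.0)
    for (i in bad) add(.violation(
      "DWM_COARSE_WOODY_DEBRIS", w$PLT_CN[i], w$CWDID[i], "cwd_min_diameter",
      sprintf("transect diameter %.2f in below 7.61 cm CWD threshold",
              w$TRANSDIA[i])))
    bad <- which(dh > w$TRANSDIA)
    for (i in bad) add(.violation(
      "DWM_COARSE_WOODY_DEBRIS", w$PLT_CN[i], w$CWDID[i], "hollow_gt_piece",
      sprintf("hollow diameter %.2f exceeds piece diameter %.2f",
              dh[i], w$TRANSDIA[i])))
    bad <- which(is.na(w$DECAYCD) | w$DECAYCD < 1 | w$DECAYCD > 5)
    for (i in bad) add(.violation(
      "DWM_COARSE_WOODY_DEBRIS", w$PLT_CN[i], w$CWDID[i], "decay_class",
      "decay class outside 1..5"))
  }

  f <- ds$fwd
  if (nrow(f)) {
    for (colnm in c("SMALLCT", "MEDIUMCT", "LARGECT")) {
      bad <- which(!is.na(f[[colnm]]) & f[[colnm]] < 0)
      for (i in bad) add(.violation(
        "DWM_FINE_WOODY_DEBRIS", f$PLT_CN[i], f$SUBP[i], "fwd_count_negative",
        paste0(colnm, " is negative")))
    }
  }

  pl <- ds$pile
  if (nrow(pl)) {
    bad <- which(pl$HORIZ_ENDDIST < pl$HORIZ_BEGNDST)
    for (i in bad) add(.violation(
      "DWM_RESIDUAL_PILE", pl$PLT_CN[i], pl$PILE[i], "pile_distances",
      "pile end distance before begin distance"))
    bad <- which(!is.na(pl$COMP_HT) & pl$COMP_HT <= 0)
    for (i in bad) add(.violation(
      "DWM_RESIDUAL_PILE", pl$PLT_CN[i], pl$PILE[i], "pile_height",
      "compacted height must be positive"))
    plen <- pl$HORIZ_ENDDIST - pl$HORIZ_BEGNDST
    bad <- which(plen > des$cwd_transect_length_ft + 1e-9)
    for (i in bad) add(.violation(
      "DWM_RESIDUAL_PILE", pl$PLT_CN[i], pl$PILE[i], "pile_length",
      sprintf("pile occupies %.1f ft, beyond the %g ft transect",
              plen[i], des$cwd_transect_length_ft)))
    bad <- which(is.na(pl$DECAYCD) | pl$DECAYCD < 1 | pl$DECAYCD > 5)
    for (i in bad) add(.violation(
      "DWM_RESIDUAL_PILE", pl$PLT_CN[i], pl$PILE[i], "decay_class",
      "decay class outside 1..5"))
  }

  dl <- ds$dufflitter
  if (nrow(dl)) {
    reason <- dl$NONSAMPLE_REASN_CD %||% rep(NA_integer_, nrow(dl))
    bad <- which((is.na(dl$DUFFDEP) | is.na(dl$LITTDEP)) & is.na(reason))
    for (i in bad) add(.violation(
      "DWM_DUFF_LITTER_FUEL", dl$PLT_CN[i], dl$SMPLOCCD[i],
      "missing_depth_no_reason",
      "missing depth without a non-sampled reason code"))
    for (colnm in c("DUFFDEP", "LITTDEP")) {
      bad <- which(!is.na(dl[[colnm]]) & dl[[colnm]] < 0)
      for (i in bad) add(.violation(
        "DWM_DUFF_LITTER_FUEL", dl$PLT_CN[i], dl$SMPLOCCD[i],
        "negative_depth", paste0(colnm, " is negative")))
    }
  }

  ts <- ds$transect_segment
  if (nrow(ts)) {
    bad <- which(ts$HORIZ_LENGTH <= 0 |
                   abs((ts$HORIZ_ENDDIST - ts$HORIZ_BEGNDIST) -
                         ts$HORIZ_LENGTH) > 1e-6)
    for (i in bad) add(.violation(
      "DWM_TRANSECT_SEGMENT", ts$PLT_CN[i], ts$SEGMNT[i], "segment_length",
      "horizontal length must equal end - begin and be positive"))
    key <- paste(ts$PLT_CN, ts$SUBP, ts$TRANSECT)
    for (k in unique(key)) {
      idx <- which(key == k)
      if (length(idx) < 1) next
      o <- idx[order(ts$HORIZ_BEGNDIST[idx])]
      b <- ts$HORIZ_BEGNDIST[o]; e <- ts$HORIZ_ENDDIST[o]
      if (length(o) > 1 && any(b[-1] < e[-length(e)] - 1e-9)) {
        add(.violation("DWM_TRANSECT_SEGMENT", ts$PLT_CN[o[1]], k,
                       "segments_overlap",
                       "transect segments overlap"))
      }
      if (sum(e - b) > des$cwd_transect_length_ft + 1e-9) {
        add(.violation("DWM_TRANSECT_SEGMENT", ts$PLT_CN[o[1]], k,
                       "segments_exceed_design",
                       "segments sum beyond the design transect length"))
      }
    }
  }

  if (length(v)) do.call(rbind, v) else
    .violation("x", "x", "x", "x", "x")[0, ]
}

#' Write plot estimates to a delimited file
#'
#' Writes a long estimate table (as produced by [estimate_plot()] or
#' [estimate_all()], modeled on the condition-level DWM calculation table)
#' to CSV. Values round-trip exactly at the stored decimal precision:
#' [read_estimates()] reproduces them bit-for-bit.
#'
#' @param estimates data.frame with columns `PLT_CN`, `DOMAIN`,
#'   `ATTRIBUTE`, `UNITS`, `UNIT_LABEL`, `VALUE`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  need <- c("PLT_CN", "DOMAIN", "ATTRIBUTE", "UNITS", "UNIT_LABEL", "VALUE")
  miss <- setdiff(need, names(estimates))
  if (length(miss)) {
    stop("estimate table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  est <- estimates
  # full double precision so read-back is bit-exact
  est$VALUE <- vapply(est$VALUE, function(x)
    if (is.na(x)) "" else sprintf("%.17g", x), character(1))
  utils::write.csv(est, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a plot-estimate file written by [write_estimates()]
#' @param path File path.
#' @return data.frame of estimates.
#' @export
read_estimates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  df$PLT_CN <- as.character(df$PLT_CN)
  df$VALUE <- as.numeric(df$VALUE)
  df
}
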