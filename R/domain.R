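#' Estimation domains
#'
#' A domain restricts an estimator to records satisfying a predicate — the
#' 0/1 indicator of the plot-level estimators. Clauses are conjunctive
#' set-membership tests on record-level columns (`DECAYCD`, `SPCD`,
#' `CONDID`, ...) or condition-level columns resolved through the `COND`
#' table (`FORTYPCD`, `OWNCD`, `STDAGE`, ...).
#'
#' @param ... Named value sets, e.g. `dwm_domain(DECAYCD = 1:4,
#'   SPCD = 202)`. No clauses = the all-records domain.
#' @param name Optional label; defaults to a serialized form like
#'   `"DECAYCD in 1,2,3,4 & SPCD in 202"` (or `"all"`).
#' @return An object of class `dwm_domain`.
#' @examples
#' d <- dwm_domain(DECAYCD = 1:4)
#' parse_domain("DECAYCD in 1,2,3,4")
#' @export
dwm_domain <- function(..., name = NULL) {
  clauses <- list(...)
  if (length(clauses) && (is.null(names(clauses)) ||
                          any(!nzchar(names(clauses))))) {
    stop("domain clauses must be named by field", call. = FALSE)
  }
  d <- list(clauses = clauses,
            name = name %||% .format_domain_clauses(clauses))
  class(d) <- "dwm_domain"
  d
}

.format_domain_clauses <- function(clauses) {
  if (!length(clauses)) return("all")
  paste(vapply(names(clauses), function(f) {
    paste0(f, " in ", paste(clauses[[f]], collapse = ","))
  }, character(1)), collapse = " & ")
}

#' @export
format.dwm_domain <- function(x, ...) x$name

#' @export
print.dwm_domain <- function(x, ...) {
  cat("DWM domain:", format(x), "\n")
  invisible(x)
}

#' Parse a domain expression
#'
#' Grammar: `FIELD in v1,v2,...` clauses joined with `&`. `all` (or the
#' empty string) is the unrestricted domain. Inverse of
#' `format(dwm_domain(...))`.
#'
#' @param expr Character scalar.
#' @return A [dwm_domain()].
#' @export
parse_domain <- function(expr) {
  expr <- trimws(expr)
  if (!nzchar(expr) || identical(tolower(expr), "all")) return(dwm_domain())
  parts <- strsplit(expr, "&", fixed = TRUE)[[1]]
  clauses <- list()
  for (p in parts) {
    m <- regmatches(p, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s+in\\s+(.+)$",
                               p))[[1]]
    if (length(m) != 3) {
      stop("cannot parse domain clause: '", trimws(p),
           "' (expected 'FIELD in v1,v2,...')", call. = FALSE)
    }
    vals <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(vals))
    clauses[[m[2]]] <- if (anyNA(nums)) vals else nums
  }
  do.call(dwm_domain, clauses)
}

.known_schema_columns <- function() {
  unique(unlist(lapply(.dwm_tables, function(t)
    c(names(t$required), names(t$optional)))))
}

#' Evaluate the 0/1 domain indicator for records
#'
#' @param domain A [dwm_domain()] (or `NULL` for all records).
#' @param records data.frame of records (pieces, piles, tallies, points).
#' @param cond Optional `COND` table for condition-level clauses; records
#'   must then carry `PLT_CN` and `CONDID`.
#' @return Numeric vector of 0/1, one per record row. A record whose
#'   clause field is `NA` gets indicator 0, as does a record whose table
#'   does not carry the field at all (e.g. a decay-class clause applied to
#'   FWD tallies — decay is not recorded for FWD); a field unknown to the
#'   whole schema is an error.
#' @export
domain_indicator <- function(domain, records, cond = NULL) {
  n <- nrow(records)
  delta <- rep(1, n)
  if (is.null(domain) || !length(domain$clauses)) return(delta)
  stopifnot(inherits(domain, "dwm_domain"))
  for (field in names(domain$clauses)) {
    vals <- domain$clauses[[field]]
    if (field %in% names(records)) {
      x <- records[[field]]
    } else if (!is.null(cond) && field %in% names(cond)) {
      ci <- match(paste(records$PLT_CN, records$CONDID),
                  paste(cond$PLT_CN, cond$CONDID))
      x <- cond[[field]][ci]
    } else if (field %in% .known_schema_columns()) {
      # a legitimate schema column this record type does not carry (e.g.
      # DECAYCD on FWD tallies, which record no decay class): such records
      # can never satisfy the clause
      x <- rep(NA, n)
    } else {
      stop("domain field not found in records or COND: ", field,
           call. = FALSE)
    }
    hit <- !is.na(x) & (x %in% vals)
    delta <- delta * as.numeric(hit)
  }
  delta
}
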