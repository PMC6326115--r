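# Record builders -----------------------------------------------------------

make_pieces <- function(transdia, hollow = 0, spcd = 202L, decaycd = 2L,
                        subp = 1L, transect = 30L, condid = 1L,
                        plt_cn = "1") {
  n <- length(transdia)
  data.frame(
    PLT_CN = rep_len(plt_cn, n), SUBP = rep_len(subp, n),
    TRANSECT = rep_len(transect, n), CWDID = seq_len(n),
    CONDID = rep_len(condid, n), SPCD = rep_len(spcd, n),
    DECAYCD = rep_len(decaycd, n), TRANSDIA = transdia,
    HOLLOW_DIA = rep_len(hollow, n), stringsAsFactors = FALSE
  )
}

make_piles <- function(comp_ht, begin, end, spcd = 202L, decaycd = 2L,
                       subp = 1L, transect = 30L, condid = 1L,
                       plt_cn = "1") {
  n <- length(comp_ht)
  data.frame(
    PLT_CN = rep_len(plt_cn, n), SUBP = rep_len(subp, n),
    TRANSECT = rep_len(transect, n), PILE = seq_len(n),
    CONDID = rep_len(condid, n), SPCD = rep_len(spcd, n),
    DECAYCD = rep_len(decaycd, n), COMP_HT = comp_ht,
    HORIZ_BEGNDST = begin, HORIZ_ENDDIST = end, stringsAsFactors = FALSE
  )
}

make_tallies <- function(small, medium, large, subp = seq_along(small),
                         condid = 1L, plt_cn = "1") {
  n <- length(small)
  data.frame(
    PLT_CN = rep_len(plt_cn, n), SUBP = subp,
    CONDID = rep_len(condid, n), SMALLCT = small, MEDIUMCT = medium,
    LARGECT = large, stringsAsFactors = FALSE
  )
}

make_points <- function(duff, litter = duff, subp = NULL, condid = 1L,
                        plt_cn = "1", reason = NA_integer_) {
  n <- length(duff)
  data.frame(
    PLT_CN = rep_len(plt_cn, n),
    SUBP = subp %||% rep(1:4, length.out = n),
    SMPLOCCD = rep(1:2, length.out = n), CONDID = rep_len(condid, n),
    DUFFDEP = duff, LITTDEP = litter,
    NONSAMPLE_REASN_CD = rep_len(reason, n), stringsAsFactors = FALSE
  )
}

make_cond <- function(plt_cn = "1", condid = 1L, fortypcd = 201L,
                      fortypgrpcd = 200L) {
  data.frame(PLT_CN = plt_cn, CONDID = condid, FORTYPCD = fortypcd,
             FORTYPGRPCD = fortypgrpcd, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random small plot for oracle comparisons ----------------------------------

random_plot_records <- function(seed) {
  set.seed(seed)
  ref <- default_species_reference()
  npiece <- sample(0:6, 1)
  di <- round(runif(npiece, 3, 25), 1)
  pieces <- make_pieces(
    transdia = di,
    hollow = ifelse(runif(npiece) < 0.3, round(di * runif(npiece, 0, 0.6), 1), 0),
    spcd = sample(ref$SPCD, max(npiece, 1), TRUE)[seq_len(npiece)],
    decaycd = sample(1:5, max(npiece, 1), TRUE)[seq_len(npiece)],
    subp = sample(1:4, max(npiece, 1), TRUE)[seq_len(npiece)],
    transect = sample(c(30L, 150L), max(npiece, 1), TRUE)[seq_len(npiece)]
  )
  npile <- sample(0:2, 1)
  b <- round(runif(npile, 0, 15), 1)
  piles <- make_piles(
    comp_ht = round(runif(npile, 0.5, 6), 1), begin = b,
    end = b + round(runif(npile, 0.5, 8), 1),
    spcd = sample(ref$SPCD, max(npile, 1), TRUE)[seq_len(npile)],
    decaycd = sample(1:4, max(npile, 1), TRUE)[seq_len(npile)],
    subp = sample(1:4, max(npile, 1), TRUE)[seq_len(npile)]
  )
  tallies <- make_tallies(sample(0:40, 4, TRUE), sample(0:20, 4, TRUE),
                          sample(0:8, 4, TRUE))
  duff <- round(runif(8, 0, 4), 1)
  duff[runif(8) < 0.15] <- NA
  points <- make_points(duff, litter = round(runif(8, 0, 3), 1),
                        reason = 5L)
  list(pieces = pieces, piles = piles, tallies = tallies, points = points,
       cond = make_cond())
}

# Independent brute-force oracles: literal nested sums over subplot j,
# transect m and record t, written directly from the estimator formulas.
# They share nothing with the package's vectorized implementations.

oracle_cwd_volume <- function(pieces, piles, L, c1, c2, delta_p = NULL,
                              delta_q = NULL) {
  if (is.null(delta_p)) delta_p <- rep(1, nrow(pieces))
  if (is.null(delta_q)) delta_q <- rep(1, nrow(piles))
  tot <- 0
  for (j in 1:4) for (m in c(30L, 150L)) {
    s1 <- 0
    for (t in seq_len(nrow(pieces))) {
      if (pieces$SUBP[t] == j && pieces$TRANSECT[t] == m) {
        s1 <- s1 + (pieces$TRANSDIA[t]^2 - pieces$HOLLOW_DIA[t]^2) *
          delta_p[t]
      }
    }
    s2 <- 0
    for (t in seq_len(nrow(piles))) {
      if (piles$SUBP[t] == j && piles$TRANSECT[t] == m) {
        s2 <- s2 + piles$COMP_HT[t] *
          (piles$HORIZ_ENDDIST[t] - piles$HORIZ_BEGNDST[t]) * delta_q[t]
      }
    }
    tot <- tot + c1 * pi^2 / 8 * s1 + c2 * pi / 2 * s2
  }
  tot / L
}

oracle_cwd_mass <- function(pieces, piles, L, c1, c2, ref,
                            carbon = FALSE) {
  dens_of <- function(spcd, dk) {
    i <- which(ref$SPCD == spcd)
    d <- ref$WOOD_SPGR_GREENVOL_DRYWT[i] * 62.4 *
      ref[[paste0("CWD_DECAY_RATIO", dk)]][i]
    if (carbon) d <- d * ref$DWM_CARBON_RATIO[i]
    d
  }
  tot <- 0
  for (j in 1:4) for (m in c(30L, 150L)) {
    s1 <- 0
    for (t in seq_len(nrow(pieces))) {
      if (pieces$SUBP[t] == j && pieces$TRANSECT[t] == m) {
        s1 <- s1 + dens_of(pieces$SPCD[t], pieces$DECAYCD[t]) *
          (pieces$TRANSDIA[t]^2 - pieces$HOLLOW_DIA[t]^2)
      }
    }
    s2 <- 0
    for (t in seq_len(nrow(piles))) {
      if (piles$SUBP[t] == j && piles$TRANSECT[t] == m) {
        s2 <- s2 + dens_of(piles$SPCD[t], piles$DECAYCD[t]) *
          piles$COMP_HT[t] *
          (piles$HORIZ_ENDDIST[t] - piles$HORIZ_BEGNDST[t])
      }
    }
    tot <- tot + c1 * pi^2 / 8 * s1 + c2 * pi / 2 * s2
  }
  tot / L
}

oracle_cwd_cover <- function(pieces, piles, L) {
  tot <- 0
  for (j in 1:4) for (m in c(30L, 150L)) {
    for (t in seq_len(nrow(pieces))) {
      if (pieces$SUBP[t] == j && pieces$TRANSECT[t] == m) {
        tot <- tot + pieces$TRANSDIA[t] / 12
      }
    }
    for (t in seq_len(nrow(piles))) {
      if (piles$SUBP[t] == j && piles$TRANSECT[t] == m) {
        tot <- tot + piles$HORIZ_ENDDIST[t] - piles$HORIZ_BEGNDST[t]
      }
    }
  }
  100 * pi / (2 * L) * tot
}

oracle_cwd_length <- function(pieces, L, cc) {
  k <- 0
  for (j in 1:4) for (m in c(30L, 150L)) {
    for (t in seq_len(nrow(pieces))) {
      if (pieces$SUBP[t] == j && pieces$TRANSECT[t] == m) k <- k + 1
    }
  }
  cc * pi / (2 * L) * k
}

oracle_fwd_volume <- function(tallies, count_col, qmd, L, cc) {
  tot <- 0
  for (j in 1:4) {
    for (t in seq_len(nrow(tallies))) {
      if (tallies$SUBP[t] == j) {
        tot <- tot + tallies[[count_col]][t] * qmd^2
      }
    }
  }
  cc * pi^2 / (8 * L) * tot
}

oracle_dufflitter_volume <- function(points, depth_col, cc, n_pts) {
  tot <- 0
  for (t in seq_len(nrow(points))) {
    y <- points[[depth_col]][t]
    if (!is.na(y)) tot <- tot + y
  }
  cc * tot / n_pts
}
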