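`%||%` <- function(a, b) if (is.null(a)) b else a

# degrees -> unit vector (east, north); azimuth measured clockwise from north
.az_unit <- function(az_deg) {
  a <- az_deg * pi / 180
  cbind(ex = sin(a), ny = cos(a))
}

# tiny FNV-1a hash of a string, for run-config fingerprints in logs
.fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# derive a stream seed below 2^31 from a base seed and an index
.substream_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483629)
}

# evaluate fn with a local RNG state seeded by `seed`, restoring on exit
.with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}
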