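# Internal helpers: seeded substreams, connectivity, normalized radius map.

# Evaluate expr under a deterministic RNG stream derived from (seed, stream),
# restoring the caller's RNG state afterwards.  One global integer seed thus
# feeds independent named streams, so e.g. changing noise draws never perturbs
# territory placement.
.withStream <- function(seed, stream, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  streams <- c(mask = 101L, perturb = 103L, territory = 107L, noise = 109L,
               trace = 211L, calcium = 223L, deg = 307L, misc = 401L)
  if (!stream %in% names(streams)) stop("unknown RNG stream: ", stream)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  sub <- (as.double(seed) * 48271 + 7919 * as.double(streams[[stream]])) %% 2147483647
  set.seed(as.integer(sub), kind = "Mersenne-Twister")
  expr
}

# Number of 4-connected foreground components of a logical matrix.
.nComponents4 <- function(mask) {
  if (!any(mask)) return(0L)
  max(EBImage::bwlabel(mask * 1))
}

# Normalized radius map: for each foreground pixel, r = 1 - D/Dmax where D is
# the exact Euclidean distance to the nearest background pixel (image border
# counts as background).  The deepest pixel has r = 0; boundary pixels
# approach 1.  Background is NA.
.normalizedRadiusMap <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- as.numeric(mask)
  d <- EBImage::distmap(pad, metric = "euclidean")
  d <- d[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
  dmax <- max(d)
  r <- 1 - d / dmax
  r[!mask] <- NA_real_
  r
}

.isCount <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
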