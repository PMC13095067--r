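# Independent brute-force oracles, deliberately written without reusing any
# package internals: direct nearest-background search for the normalized
# radius, direct decile splits for equal-area bins, and a random-mask
# generator for oracle-equivalence sweeps.

# Euclidean distance of every foreground pixel to the nearest background
# pixel (image border counts as background), by exhaustive search.
bruteNormalizedRadius <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  bg <- which(!pad, arr.ind = TRUE)
  d <- matrix(NA_real_, nr, nc)
  for (idx in which(mask)) {
    i <- ((idx - 1L) %% nr) + 1L
    j <- ((idx - 1L) %/% nr) + 1L
    d[i, j] <- sqrt(min((bg[, 1] - (i + 1L))^2 + (bg[, 2] - (j + 1L))^2))
  }
  1 - d / max(d, na.rm = TRUE)
}

# Direct bin assignment from a radius map, following the same contract as
# the package but computed element by element.
bruteBins <- function(rmap, mask, n = 10L, mode = "equal_width") {
  bins <- matrix(0L, nrow(mask), ncol(mask))
  rf <- rmap[mask]
  if (mode == "equal_width") {
    for (idx in which(mask)) {
      b <- floor(rmap[idx] * n) + 1
      bins[idx] <- as.integer(min(b, n))
    }
  } else {
    rs <- sort(rf)
    thr <- rs[ceiling(seq_len(n - 1L) * length(rs) / n)]
    for (idx in which(mask)) {
      bins[idx] <- as.integer(1L + sum(thr < rmap[idx]))
    }
  }
  bins
}

# Random connected blob mask inside a maxdim x maxdim image: threshold a
# smoothed random field and keep the largest 4-connected component.
randomBlobMask <- function(seed, maxdim = 64L) {
  set.seed(seed)
  nr <- sample(24:maxdim, 1); nc <- sample(24:maxdim, 1)
  f <- matrix(rnorm(nr * nc), nr, nc)
  k <- outer(dnorm(-4:4, sd = 2), dnorm(-4:4, sd = 2))
  sm <- as.matrix(EBImage::filter2(f, k / sum(k)))
  m <- sm > quantile(sm, 0.55)
  m[c(1, nr), ] <- FALSE; m[, c(1, nc)] <- FALSE
  lab <- EBImage::bwlabel(m * 1)
  if (max(lab) == 0) return(randomBlobMask(seed + 1000, maxdim))
  biggest <- which.max(tabulate(lab[lab > 0]))
  keep <- matrix(lab == biggest, nr, nc)
  if (sum(keep) < 60) return(randomBlobMask(seed + 1000, maxdim))
  keep
}

asMask <- function(m, px = 0.2, id = "n", group = "g", probe = "p") {
  new("NuclearMask", mask = m, pixelSize = px, nucleusID = id,
      groupLabel = group, probeID = probe)
}

# Rasterized disk mask of radius r.
diskMask <- function(r, px = 0.2) {
  n <- 2L * r + 11L; c0 <- (n + 1) / 2
  g1 <- matrix(seq_len(n), n, n)
  g2 <- t(g1)
  asMask(matrix((g1 - c0)^2 + (g2 - c0)^2 <= r^2, n, n), px = px)
}

# Build a BeatTrace directly from a sample vector.
asTrace <- function(x, fr = 63, pacing = 1, modality = "displacement") {
  new("BeatTrace", samples = x, frameRate = fr, pacingRate = pacing,
      modality = modality)
}

# Small pipeline config for end-to-end tests.
smallRunConfig <- function(seed = 1L) {
  cfg <- defaultRunConfig(seed = seed, nPerGroup = 3L, tracesPerGroup = 2L)
  cfg$trace$duration <- 6
  cfg$deg$genes_per_chromosome <- 60L
  cfg$deg$n_tables <- 1L
  cfg
}
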