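# Shared fixture builders and independent oracles. Oracles deliberately use
# the dumbest possible formulation (full prefix re-summation per voxel, full
# 3-D kernel convolution) so they share no code path with the package.

PITCH <- c(8.1, 2.3, 2.2)

column_volume <- function(values, kind = "angio", pitch = PITCH) {
  oct_volume(array(values, c(length(values), 1L, 1L)), pitch, kind = kind)
}

random_volume <- function(seed, d = c(16L, 8L, 8L), kind = "angio",
                          pitch = PITCH, scale = 1) {
  set.seed(seed)
  oct_volume(array(stats::runif(prod(d)) * scale, d), pitch, kind = kind)
}

## A small phantom that runs in milliseconds but keeps the default geometry's
## character: vessel mid-depth, tail room below it.
small_phantom_spec <- function(...) {
  defaults <- list(shape = c(96L, 24L, 24L),
                   vessels = list(vessel_spec(center_mm = c(0.4, 0.026),
                                              radius_mm = 0.015,
                                              axis = "x", delta_r = 0.002)))
  dots <- list(...)
  args <- c(dots, defaults[setdiff(names(defaults), names(dots))])
  do.call(phantom_spec, args)
}

## --- naive per-voxel oracles: re-sum the full prefix at every layer -------

naive_tartes <- function(A, S, w1) {
  a <- as.array(unclass(A)); s <- as.array(unclass(S))
  out <- a
  for (y in seq_len(dim(a)[2])) for (x in seq_len(dim(a)[3])) {
    for (n in seq_len(dim(a)[1])[-1]) {
      prefix <- out[seq_len(n - 1L), y, x]
      v <- a[n, y, x] - w1 * s[n, y, x] * sqrt(sum(prefix^2))
      out[n, y, x] <- max(v, 0)
    }
  }
  out
}

naive_msa <- function(A, w2) {
  a <- as.array(unclass(A))
  out <- a
  for (y in seq_len(dim(a)[2])) for (x in seq_len(dim(a)[3])) {
    baseline <- w2 * mean(a[, y, x])
    out[, y, x] <- pmax(a[, y, x] - baseline, 0)
  }
  out
}

naive_sdef <- function(A, w3) {
  a <- as.array(unclass(A))
  out <- a
  for (y in seq_len(dim(a)[2])) for (x in seq_len(dim(a)[3])) {
    for (n in seq_len(dim(a)[1])[-1]) {
      out[n, y, x] <- a[n, y, x] * exp(-w3 * sum(out[seq_len(n - 1L), y, x]))
    }
  }
  out
}

## Full (non-separable) 3-D Gaussian convolution with reflected padding.
brute_gaussian <- function(v, sigma) {
  a <- as.array(unclass(v))
  d <- dim(a)
  r <- ceiling(4 * sigma)
  g1 <- function(s, rr) { k <- exp(-0.5 * ((-rr):rr / s)^2); k / sum(k) }
  kz <- g1(sigma[1], r[1]); ky <- g1(sigma[2], r[2]); kx <- g1(sigma[3], r[3])
  kern <- outer(outer(kz, ky), kx)   # (2rz+1, 2ry+1, 2rx+1)
  refl <- function(i, n) {
    j <- (i - 1L) %% (2L * n)
    ifelse(j >= n, 2L * n - 1L - j, j) + 1L
  }
  out <- array(0, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    zi <- refl(z + (-r[1]):r[1], d[1])
    yi <- refl(y + (-r[2]):r[2], d[2])
    xi <- refl(x + (-r[3]):r[3], d[3])
    out[z, y, x] <- sum(kern * a[zi, yi, xi])
  }
  out
}

## Bare array of a volume: everything but dim stripped, for comparisons.
vals <- function(v) {
  a <- unclass(v)
  attributes(a) <- list(dim = dim(a))
  a
}

rewrap_scale <- function(v, f) {
  oct_volume(unclass(v) * f, attr(v, "pitch_um")[c("z", "x", "y")],
             kind = attr(v, "kind"))
}

max_rel_err <- function(got, want, floor = 1e-300) {
  max(abs(got - want) / pmax(abs(want), floor))
}
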