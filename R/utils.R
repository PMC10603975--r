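# Internal helpers: seeded RNG scoping, deterministic sub-seeds,
# center crop/pad, range clipping, config hashing.

# Derive a per-item seed from a master seed and an index. Kept strictly
# below 2^31 - 1 so it is always a valid R integer seed.
subSeed <- function(seed, index) {
  m <- 2147483629
  s <- (as.double(seed) %% m) * 48271 + as.double(index) * 9973 + 1
  as.integer(s %% m)
}

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never disturbs user-level reproducibility.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Center-crop or zero-pad a 2-D or 3-D array to target spatial size.
centerCropPad <- function(x, th, tw) {
  d <- dim(x)
  h <- d[1]; w <- d[2]
  if (h == th && w == tw) return(x)
  # crop
  if (h > th) {
    off <- (h - th) %/% 2
    x <- if (length(d) == 2) x[off + seq_len(th), , drop = FALSE] else
      x[off + seq_len(th), , , drop = FALSE]
  }
  if (w > tw) {
    off <- (w - tw) %/% 2
    x <- if (length(d) == 2) x[, off + seq_len(tw), drop = FALSE] else
      x[, off + seq_len(tw), , drop = FALSE]
  }
  d <- dim(x)
  if (d[1] < th || d[2] < tw) {
    nd <- d; nd[1] <- th; nd[2] <- tw
    y <- array(0, nd)
    ro <- (th - d[1]) %/% 2
    co <- (tw - d[2]) %/% 2
    if (length(d) == 2) y[ro + seq_len(d[1]), co + seq_len(d[2])] <- x
    else y[ro + seq_len(d[1]), co + seq_len(d[2]), ] <- x
    x <- y
  }
  x
}

# Adjoint of centerCropPad: map a gradient at the target size back to the
# source size (pad where cropped, crop where padded).
centerCropPadAdjoint <- function(g, sh, sw) {
  centerCropPad(g, sh, sw)
}

# Stable md5 hash of any serializable R object (via its YAML rendering).
configHash <- function(obj) {
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(obj), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
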