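# Internal helpers shared across modules.

# Deterministic child-seed derivation: mixes a master seed with a stage tag
# and an index so that pipeline stages draw from independent streams while
# the whole run stays reproducible from one integer.  Arithmetic is kept
# below 2^53 so it is exact in doubles; the result is a valid 32-bit seed.
derive_seed <- function(seed, tag, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- (seed %% 2147483646) + 1
  for (ch in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  h <- (h + (index %% 1e6) * 2654435761) %% 2147483647
  # three multiplicative-congruential rounds decorrelate nearby indices
  # (R's Mersenne-Twister warm-up correlates for adjacent seed values)
  for (k in 1:3) h <- (h * 48271) %% 2147483647
  as.integer((h %% 2147483645) + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Lognormal multipliers with unit mean and fractional coefficient of
# variation cv (cv = 0 returns exactly 1).
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

# Bilinear interpolation of a (axial x lateral) matrix at arbitrary
# physical coordinates.  Points outside the grid are clamped to the edge.
bilinear_sample <- function(img, axial_mm, lateral_mm, ax, lat) {
  nz <- nrow(img); nx <- ncol(img)
  dz <- axial_mm[2] - axial_mm[1]
  dx <- if (nx > 1) lateral_mm[2] - lateral_mm[1] else 1
  i <- (ax - axial_mm[1]) / dz
  j <- (lat - lateral_mm[1]) / dx
  i <- pmin(pmax(i, 0), nz - 1)
  j <- pmin(pmax(j, 0), nx - 1)
  i0 <- pmin(floor(i), nz - 2); i0[nz == 1] <- 0
  j0 <- pmin(floor(j), max(nx - 2, 0))
  fi <- i - i0; fj <- j - j0
  i0 <- i0 + 1; j0 <- j0 + 1 # 1-based
  i1 <- pmin(i0 + 1, nz); j1 <- pmin(j0 + 1, nx)
  img[cbind(i0, j0)] * (1 - fi) * (1 - fj) +
    img[cbind(i1, j0)] * fi * (1 - fj) +
    img[cbind(i0, j1)] * (1 - fi) * fj +
    img[cbind(i1, j1)] * fi * fj
}

# Even-odd point-in-polygon test, vectorized over points.  A bounding
# box prefilter skips points that cannot be inside; max_vertices caps
# the polygon resolution (boundaries are resampled to >= 256 vertices
# for diameter accuracy, far more than membership tests need).
points_in_polygon <- function(px, py, vx, vy, max_vertices = 72L) {
  n <- length(vx)
  if (n > max_vertices) {
    keep <- unique(round(seq(1, n, length.out = max_vertices)))
    vx <- vx[keep]; vy <- vy[keep]
    n <- length(vx)
  }
  inside <- logical(length(px))
  box <- which(px >= min(vx) & px <= max(vx) &
                 py >= min(vy) & py <= max(vy))
  if (!length(box)) return(inside)
  bx <- px[box]; by <- py[box]
  ins <- logical(length(box))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    crosses <- ((yi > by) != (yj > by)) &
      (bx < (xj - xi) * (by - yi) / (yj - yi) + xi)
    ins <- xor(ins, crosses)
    j <- i
  }
  inside[box] <- ins
  inside
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_perimeter <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
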