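# Internal numerical helpers: seed splitting, separable Gaussian smoothing,
# Otsu thresholding, 3D connected components, local maxima.

# Deterministic child seeds derived from one top-level seed. Kept below
# 2^31 - 1 so they are valid R integer seeds.
split_seed <- function(seed, stage, k = 0L) {
  stage_num <- sum(utf8ToInt(as.character(stage)))
  (as.double(seed) %% 2147483629 * 48271 +
    stage_num * 69621 + as.double(k) * 16807) %% 2147483629
}

gauss_kernel_1d <- function(sigma, half = ceiling(3 * sigma)) {
  w <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  w / sum(w)
}

# Smooth along dim 1 of a matrix with edge replication.
smooth_dim1 <- function(m, w) {
  n <- nrow(m)
  h <- (length(w) - 1L) %/% 2L
  out <- matrix(0, n, ncol(m))
  base <- seq_len(n)
  for (k in -h:h) {
    idx <- pmin(pmax(base + k, 1L), n)
    out <- out + w[k + h + 1L] * m[idx, , drop = FALSE]
  }
  out
}

# Separable 3D Gaussian smoothing.
smooth3d <- function(a, sigma = 1) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  w <- gauss_kernel_1d(sigma)
  a <- array(smooth_dim1(matrix(a, d[1]), w), d)
  a <- aperm(a, c(2L, 1L, 3L))
  a <- array(smooth_dim1(matrix(a, d[2]), w), d[c(2L, 1L, 3L)])
  a <- aperm(a, c(2L, 1L, 3L))
  a <- aperm(a, c(3L, 1L, 2L))
  a <- array(smooth_dim1(matrix(a, d[3]), w), d[c(3L, 1L, 2L)])
  aperm(a, c(2L, 3L, 1L))
}

# Otsu threshold (maximize between-class variance) on a numeric vector.
otsu_threshold <- function(v, nbins = 256L) {
  rng <- range(v)
  if (diff(rng) <= 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(pmin(findInterval(v, breaks, all.inside = TRUE), nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  denom <- omega * (1 - omega)
  sigma_b2 <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  mids[which.max(sigma_b2)]
}

neighbor_offsets_26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# 3D connected-component labeling, 26-connectivity, BFS frontier expansion.
label_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  unvisited <- array(FALSE, d)
  unvisited[fg] <- TRUE
  offs <- neighbor_offsets_26()
  n_off <- nrow(offs)
  cur <- 0L
  for (s in fg) {
    if (!unvisited[s]) next
    cur <- cur + 1L
    lab[s] <- cur
    unvisited[s] <- FALSE
    frontier <- s
    while (length(frontier)) {
      fc <- arrayInd(frontier, d)
      nf <- nrow(fc)
      nx <- rep(fc[, 1], each = n_off) + rep(offs[, 1], times = nf)
      ny <- rep(fc[, 2], each = n_off) + rep(offs[, 2], times = nf)
      nz <- rep(fc[, 3], each = n_off) + rep(offs[, 3], times = nf)
      ok <- nx >= 1L & nx <= d[1] & ny >= 1L & ny <= d[2] & nz >= 1L & nz <= d[3]
      nl <- unique((nz[ok] - 1L) * d[1] * d[2] + (ny[ok] - 1L) * d[1] + nx[ok])
      nl <- nl[unvisited[nl]]
      if (length(nl)) {
        lab[nl] <- cur
        unvisited[nl] <- FALSE
      }
      frontier <- nl
    }
  }
  lab
}

# Local maxima of `a` restricted to linear indices `idx`: voxels whose value
# is >= all 26 neighbors, then greedily thinned to a minimum separation.
local_maxima_3d <- function(a, idx, min_sep) {
  d <- dim(a)
  offs <- neighbor_offsets_26()
  co <- arrayInd(idx, d)
  is_max <- rep(TRUE, length(idx))
  for (j in seq_len(nrow(offs))) {
    nx <- pmin(pmax(co[, 1] + offs[j, 1], 1L), d[1])
    ny <- pmin(pmax(co[, 2] + offs[j, 2], 1L), d[2])
    nz <- pmin(pmax(co[, 3] + offs[j, 3], 1L), d[3])
    nb <- (nz - 1L) * d[1] * d[2] + (ny - 1L) * d[1] + nx
    is_max <- is_max & a[idx] >= a[nb]
  }
  cand <- idx[is_max]
  if (length(cand) <= 1L) return(cand)
  cand <- cand[order(a[cand], decreasing = TRUE)]
  cc <- arrayInd(cand, d)
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    if (!any(keep)) {
      keep[i] <- TRUE
      next
    }
    dmin <- min(sqrt(rowSums((cc[keep, , drop = FALSE] -
      matrix(cc[i, ], sum(keep), 3, byrow = TRUE))^2)))
    if (dmin >= min_sep) keep[i] <- TRUE
  }
  cand[keep]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
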