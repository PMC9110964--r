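# shared fixture builders and independent oracles

unit_geometry <- function(d, spacing = c(1, 1, 1)) {
  list(dim = as.integer(d), spacing = spacing, origin = c(0, 0, 0),
       direction = diag(3))
}

make_volume <- function(values, d = dim(values), spacing = c(1, 1, 1),
                        domain = "hounsfield", phase = "native") {
  ct_volume(array(values, dim = d), spacing = spacing, phase = phase,
            intensity_domain = domain)
}

make_mask <- function(bits, d = dim(bits), spacing = c(1, 1, 1),
                      label = "test") {
  binary_mask(array(bits, dim = d), unit_geometry(d, spacing), label = label)
}

# coordinate arrays (0-based) for a grid
grid_coords <- function(d) {
  list(x = array(rep(0:(d[1] - 1), times = d[2] * d[3]), dim = d),
       y = array(rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]), dim = d),
       z = array(rep(0:(d[3] - 1), each = d[1] * d[2]), dim = d))
}

voxel_sphere_mask <- function(r = 10, pad = 5, spacing = c(1, 1, 1)) {
  n <- 2L * (r + pad) + 1L
  g <- grid_coords(c(n, n, n))
  ctr <- r + pad
  make_mask((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= r^2,
            spacing = spacing, label = "sphere")
}

# ---- independent brute-force morphology oracle -------------------------
# Direct 3D window definitions computed by R array shifting; no shared code
# with the package's separable C++ passes. Out-of-grid voxels are
# background, matching the stated contract.

shift_bits <- function(a, o) {
  d <- dim(a)
  out <- array(FALSE, dim = d)
  src_lo <- pmax(1 + o, 1); src_hi <- pmin(d + o, d)
  if (any(src_lo > src_hi)) return(out)
  dst_lo <- src_lo - o; dst_hi <- src_hi - o
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    a[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  out
}

window_offsets <- function(lo, hi)
  as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))

erode_oracle <- function(a, lo, hi) {
  offs <- window_offsets(lo, hi)
  out <- array(TRUE, dim = dim(a))
  for (i in seq_len(nrow(offs))) out <- out & shift_bits(a, offs[i, ])
  out
}

dilate_oracle <- function(a, lo, hi) {
  offs <- window_offsets(lo, hi)
  out <- array(FALSE, dim = dim(a))
  for (i in seq_len(nrow(offs))) out <- out | shift_bits(a, offs[i, ])
  out
}

cube_windows <- function(dim_) {
  a <- (dim_ - 1L) %/% 2L
  b <- dim_ - 1L - a
  list(lo = rep(-a, 3), hi = rep(b, 3), rlo = rep(-b, 3), rhi = rep(a, 3))
}

opening_oracle <- function(a, dim_) {
  w <- cube_windows(dim_)
  dilate_oracle(erode_oracle(a, w$lo, w$hi), w$rlo, w$rhi)
}

closing_oracle <- function(a, dim_) {
  w <- cube_windows(dim_)
  erode_oracle(dilate_oracle(a, w$lo, w$hi), w$rlo, w$rhi)
}

particle_removal_oracle <- function(a, dim_) closing_oracle(opening_oracle(a, dim_), dim_)

dilation_oracle_cube <- function(a, dim_) {
  w <- cube_windows(dim_)
  dilate_oracle(a, w$lo, w$hi)
}

# brute-force median filter with replicated borders
median_oracle <- function(vals, radius) {
  d <- dim(vals)
  out <- array(0, dim = d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    ii <- pmin(pmax((i - radius):(i + radius), 1), d[1])
    jj <- pmin(pmax((j - radius):(j + radius), 1), d[2])
    kk <- pmin(pmax((k - radius):(k + radius), 1), d[3])
    out[i, j, k] <- median(vals[ii, jj, kk])
  }
  out
}

# 26-connected component count by flood fill (diagnostic oracle)
count_components <- function(bits) {
  d <- dim(bits)
  lab <- array(0L, dim = d)
  offs <- window_offsets(c(-1, -1, -1), c(1, 1, 1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  ncomp <- 0L
  idx_all <- which(bits)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    lab[start] <- ncomp
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      k <- (cur - 1L) %/% (d[1] * d[2])
      rem <- (cur - 1L) %% (d[1] * d[2])
      j <- rem %/% d[1]; i <- rem %% d[1]
      for (m in seq_len(nrow(offs))) {
        ni <- i + offs[m, 1]; nj <- j + offs[m, 2]; nk <- k + offs[m, 3]
        if (ni < 0 || nj < 0 || nk < 0 || ni >= d[1] || nj >= d[2] ||
            nk >= d[3]) next
        nidx <- 1L + ni + d[1] * (nj + d[2] * nk)
        if (bits[nidx] && lab[nidx] == 0L) {
          lab[nidx] <- ncomp
          queue <- c(queue, nidx)
        }
      }
    }
  }
  ncomp
}
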