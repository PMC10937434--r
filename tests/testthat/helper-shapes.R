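# Shared mask builders for geometry and feature tests.

mkGrid <- function(d, spacing = c(1, 1, 1)) {
  ax <- list(x = (seq_len(d[1]) - 1) * spacing[1],
             y = (seq_len(d[2]) - 1) * spacing[2],
             z = (seq_len(d[3]) - 1) * spacing[3])
  list(X = array(ax$x, d),
       Y = array(rep(ax$y, each = d[1]), d),
       Z = array(rep(ax$z, each = d[1] * d[2]), d))
}

mkSphere <- function(r, spacing = c(1, 1, 1), pad = 6) {
  d <- ceiling(2 * (r + pad) / spacing)
  g <- mkGrid(d, spacing)
  cen <- (d - 1) * spacing / 2
  (g$X - cen[1])^2 + (g$Y - cen[2])^2 + (g$Z - cen[3])^2 <= r^2
}

mkBox <- function(sides, spacing = c(1, 1, 1), pad = 4) {
  d <- as.integer(sides / spacing) + 2 * pad
  m <- array(FALSE, d)
  lo <- rep(pad + 1, 3)
  hi <- pad + as.integer(sides / spacing)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}

singleVoxel <- function(d, at) {
  m <- array(FALSE, d)
  m[at[1], at[2], at[3]] <- TRUE
  m
}

wadell <- function(V, A) pi^(1 / 3) * (6 * V)^(2 / 3) / A
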