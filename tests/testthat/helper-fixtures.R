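# Shared fixtures, built once per test run.

.fix <- new.env()

# Substrate with no cells: free diffusion everywhere.
empty_substrate <- function(voxel = c(400, 400, 400)) {
  cs <- myowalk:::new_cross_section_set(list(), integer(0), 100, 100)
  build_substrate(tissue_block(cs, Lz = 100), voxel = voxel)
}

# One square cell [0.5, 1.5]^2 in a 2 x 2 box, extruded over Lz = 10.
# Walls at x,y in {0.5, 1.5}; caps at z = 0 and 10 (mod 10).
square_cell_substrate <- function(icd_depth = 2, ha_rate = 0,
                                  half_shift = FALSE, Lz = 10) {
  poly <- matrix(c(0.5, 0.5, 1.5, 0.5, 1.5, 1.5, 0.5, 1.5), 4, 2,
                 byrow = TRUE)
  cs <- myowalk:::new_cross_section_set(list(poly), 1L, 2, 2)
  build_substrate(tissue_block(cs, Lz = Lz, icd_depth = icd_depth),
                  voxel = c(100, 100, 100), ha_rate = ha_rate,
                  half_shift = half_shift)
}

# Histology-like packing, memoised per (n_cells, ecv).
packed_cross_sections <- function(n_cells = 30, ecv = NULL, seed = 2) {
  key <- paste0("cs_", n_cells, "_", seed, "_", ecv %||% "raw")
  if (is.null(.fix[[key]])) {
    cs <- generate_cross_sections(n_cells, 18, seed = seed)
    if (!is.null(ecv)) cs <- morph_ecv(cs, ecv)
    .fix[[key]] <- cs
  }
  .fix[[key]]
}

packed_substrate <- function(n_cells = 30, ecv = 0.2469, ha_rate = 10,
                             half_shift = TRUE, voxel = c(2800, 2800, 8000)) {
  build_substrate(tissue_block(packed_cross_sections(n_cells, ecv)),
                  voxel = voxel, ha_rate = ha_rate, half_shift = half_shift)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Analytic standard error of |mean of unit phasors| for approximately
# Gaussian phase dispersion (free diffusion): SE = (1 - S^2) / sqrt(2 n).
phasor_se <- function(S, n) (1 - S^2) / sqrt(2 * n)

# Random SPD tensor with eigenvalues in [lo, hi].
random_spd <- function(seed, lo = 0.3, hi = 2.5) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3)
  Q <- qr.Q(qr(A))
  lam <- runif(3, lo, hi)
  Q %*% diag(lam) %*% t(Q)
}

# Synthesize noiseless mono-exponential signals on a scheme.
synth_signals <- function(D, scheme) {
  m <- scheme$measurements
  q <- vapply(seq_len(nrow(m)), function(i) {
    e <- c(m$gx[i], m$gy[i], m$gz[i])
    as.numeric(t(e) %*% D %*% e)
  }, numeric(1))
  dplyr::mutate(m, S_over_S0 = exp(-m$b * q))
}
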