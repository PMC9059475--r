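# digital solid sphere of radius r voxels, centred in a cube with margin
digital_sphere <- function(r, margin = 6) {
  n <- 2 * r + 2 * margin + 1
  cc <- (n + 1) / 2
  ax <- (1:n) - cc
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  array(d2 <= r^2, dim = c(n, n, n))
}

# digital solid cylinder along z, radius r voxels, length nz
digital_cylinder <- function(r, nz, margin = 6) {
  n <- 2 * r + 2 * margin + 1
  cc <- (n + 1) / 2
  ax <- (1:n) - cc
  disc <- outer(ax^2, ax^2, "+") <= r^2
  array(rep(disc, nz), dim = c(n, n, nz))
}

# plate of thickness t voxels spanning the xy extent
digital_plate <- function(t, nxy = 60, margin = 20) {
  nz <- t + 2 * margin
  a <- array(FALSE, dim = c(nxy, nxy, nz))
  a[, , (margin + 1):(margin + t)] <- TRUE
  a
}

# three-axis rod lattice block (no jitter): rods of diameter t_vox at pitch
# s_vox along the edges of cubic cells, cropped to an n^3 block
rod_lattice_block <- function(n, s_vox, t_vox) {
  ax <- (0:(n - 1))
  near <- function(u) (u - round(u / s_vox) * s_vox)^2
  m2 <- outer(near(ax), near(ax), "+") <= (t_vox / 2)^2
  out <- array(FALSE, dim = c(n, n, n))
  for (k in seq_len(n)) {
    out[, , k] <- m2 |
      matrix(rep(m2[, k], n), n, n) |
      matrix(rep(m2[, k], each = n), n, n)
  }
  out
}

# small annulus tube fe model + Euler-Bernoulli reference pieces
make_test_tube <- function(ro = 0.45, ri = 0.3, len = 13, spacing = 60,
                           E = 10000) {
  ph <- make_prism_phantom("annulus", list(ro = ro, ri = ri), length = len,
                           spacing = spacing)
  model <- assign_materials(ph$volume, material_map(cortical_E = E))
  mid <- dim(ph$volume$labels)[3] %/% 2
  sec <- section_properties(ph$volume$labels[, , mid] == 1, spacing)
  list(phantom = ph, model = model, section = sec, E = E)
}
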