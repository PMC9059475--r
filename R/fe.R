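#' Tissue material map for finite-element models
#'
#' Per-label isotropic elasticity. Units: MPa (N/mm^2). Defaults follow the
#' study's model: bone Poisson's ratio 0.3; marrow treated as a nearly
#' incompressible soft solid, E = 20 MPa, nu = 0.499.
#'
#' @param cortical_E,trabecular_E moduli, MPa (e.g. nanoindentation group
#'   means converted from GPa).
#' @param marrow_E marrow modulus, MPa.
#' @param bone_nu,marrow_nu Poisson's ratios.
#' @return Named list, one \code{c(E, nu)} per label.
#' @export
material_map <- function(cortical_E, trabecular_E = cortical_E,
                         marrow_E = 20, bone_nu = 0.3, marrow_nu = 0.499) {
  m <- list(`1` = c(E = cortical_E, nu = bone_nu),
            `2` = c(E = trabecular_E, nu = bone_nu),
            `3` = c(E = marrow_E, nu = marrow_nu))
  for (v in m) {
    if (v[["E"]] <= 0) param_error("all moduli must be > 0")
    if (v[["nu"]] < 0 || v[["nu"]] >= 0.5)
      param_error("all Poisson ratios must be in [0, 0.5)")
  }
  m
}

# 24x24 stiffness of a trilinear hexahedron of side h with B-bar (mean
# dilatation) integration; selective treatment of the volumetric part avoids
# locking at nu near 0.5. Local node l has offsets (l&1, l>>1&1, l>>2&1).
hex_stiffness <- function(E, nu, h) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu

  gp <- c(-1, 1) / sqrt(3)
  signs <- as.matrix(expand.grid(sx = c(-1, 1), sy = c(-1, 1),
                                 sz = c(-1, 1)))[, 1:3]
  # local node order: x fastest -> offsets match bit order (x, y, z)
  bmat <- function(xi, eta, zeta) {
    B <- matrix(0, 6, 24)
    for (l in 0:7) {
      s <- c(ifelse(bitwAnd(l, 1L) > 0, 1, -1),
             ifelse(bitwAnd(l, 2L) > 0, 1, -1),
             ifelse(bitwAnd(l, 4L) > 0, 1, -1))
      # dN/dx_i on the physical element (side h), natural coords in [-1, 1]
      dn <- c(s[1] * (1 + s[2] * eta) * (1 + s[3] * zeta),
              s[2] * (1 + s[1] * xi) * (1 + s[3] * zeta),
              s[3] * (1 + s[1] * xi) * (1 + s[2] * eta)) / 8 * (2 / h)
      c0 <- 3 * l
      B[1, c0 + 1] <- dn[1]
      B[2, c0 + 2] <- dn[2]
      B[3, c0 + 3] <- dn[3]
      B[4, c0 + 1] <- dn[2]; B[4, c0 + 2] <- dn[1]
      B[5, c0 + 2] <- dn[3]; B[5, c0 + 3] <- dn[2]
      B[6, c0 + 1] <- dn[3]; B[6, c0 + 3] <- dn[1]
    }
    B
  }
  dil <- function(B) {
    # volumetric operator: replicate the column mean of the 3 normal rows
    v <- colMeans(B[1:3, , drop = FALSE])
    Bv <- matrix(0, 6, 24)
    Bv[1, ] <- v; Bv[2, ] <- v; Bv[3, ] <- v
    Bv
  }
  Bbar_dil <- dil(bmat(0, 0, 0))   # element-mean dilatation (= centre value)
  K <- matrix(0, 24, 24)
  w <- (h / 2)^3                   # Gauss weight x |J|
  for (a in gp) for (b in gp) for (c in gp) {
    B <- bmat(a, b, c)
    Bb <- B - dil(B) + Bbar_dil
    K <- K + t(Bb) %*% D %*% Bb * w
  }
  (K + t(K)) / 2
}

#' Build a voxel-hexahedral FE model from a labeled volume
#'
#' Every voxel whose label appears in the material map becomes an 8-node
#' hexahedral element carrying its label's isotropic elasticity; background
#' voxels are excluded. The mesh must form a single face-connected component
#' (floating voxels would make the stiffness matrix singular).
#'
#' @param volume a \code{voxel_volume}.
#' @param materials a \code{\link{material_map}} (labels as names, MPa).
#' @param include_marrow include marrow voxels (label 3) as soft elements.
#' @return An \code{fe_model}: element-node incidence, node coordinates (mm),
#'   per-element material, element size.
#' @export
assign_materials <- function(volume, materials, include_marrow = TRUE) {
  lab <- volume$labels
  present <- setdiff(sort(unique(as.vector(lab))), LBL_BACKGROUND)
  if (!include_marrow) present <- setdiff(present, LBL_MARROW)
  missing <- setdiff(as.character(present), names(materials))
  if (length(missing) > 0)
    stop(errorCondition(
      paste("labels without material assignment:",
            paste(missing, collapse = ", ")),
      class = c("osteomech_config_error", "osteomech_error")))
  solid <- lab %in% present & lab != LBL_BACKGROUND
  dim(solid) <- dim(lab)
  if (!include_marrow) solid <- solid & lab != LBL_MARROW
  d <- dim(lab)
  vox <- which(solid)
  if (length(vox) == 0L) data_error("no solid voxels")
  k <- (vox - 1L) %/% (d[1] * d[2])
  r <- (vox - 1L) %% (d[1] * d[2])
  j <- r %/% d[1]
  i <- r %% d[1]

  check_connected(i, j, k, d)

  # global corner ids on the (nx+1)(ny+1)(nz+1) node grid, x fastest
  nnx <- d[1] + 1L; nny <- d[2] + 1L
  corner <- function(di, dj, dk)
    (i + di) + nnx * ((j + dj) + nny * (k + dk))
  cid <- cbind(corner(0L, 0L, 0L), corner(1L, 0L, 0L),
               corner(0L, 1L, 0L), corner(1L, 1L, 0L),
               corner(0L, 0L, 1L), corner(1L, 0L, 1L),
               corner(0L, 1L, 1L), corner(1L, 1L, 1L))
  nodes <- sort(unique(as.vector(cid)))
  elem_nodes <- matrix(match(cid, nodes) - 1L, ncol = 8)  # 0-based compact

  nk <- nodes %/% (nnx * nny)
  nr <- nodes %% (nnx * nny)
  nj <- nr %/% nnx
  ni <- nr %% nnx
  h <- spacing_mm(volume)
  coords <- cbind(x = volume$origin[1] + (ni - 0.5) * h,
                  y = volume$origin[2] + (nj - 0.5) * h,
                  z = volume$origin[3] + (nk - 0.5) * h)

  lab_e <- lab[vox]
  mat_names <- as.character(sort(unique(lab_e)))
  mat_id <- match(as.character(lab_e), mat_names) - 1L
  mats <- materials[mat_names]
  structure(list(elem_nodes = elem_nodes, coords = coords, mat_id = mat_id,
                 materials = mats, h = h, n_nodes = length(nodes),
                 labels_per_element = lab_e),
            class = "fe_model")
}

# BFS over 6-connected voxels; errors if more than one component
check_connected <- function(i, j, k, d) {
  lin <- i + d[1] * (j + d[2] * k)
  solid <- logical(d[1] * d[2] * d[3])
  solid[lin + 1L] <- TRUE
  seen <- logical(length(solid))
  frontier <- lin[1] + 1L
  seen[frontier] <- TRUE
  nvis <- 1L
  offs <- c(-1L, 1L, -d[1], d[1], -d[1] * d[2], d[1] * d[2])
  while (length(frontier) > 0) {
    cand <- as.vector(outer(frontier, offs, "+"))
    src_i <- rep((frontier - 1L) %% d[1], times = 6L)
    src_j <- rep(((frontier - 1L) %/% d[1]) %% d[2], times = 6L)
    ok <- cand >= 1L & cand <= length(solid)
    # reject x/y wrap-around across array edges
    di <- abs((cand - 1L) %% d[1] - src_i)
    dj <- abs(((cand - 1L) %/% d[1]) %% d[2] - src_j)
    ok <- ok & di <= 1L & dj <= 1L
    nb <- unique(cand[ok])
    nb <- nb[solid[nb] & !seen[nb]]
    seen[nb] <- TRUE
    nvis <- nvis + length(nb)
    frontier <- nb
  }
  if (nvis < length(lin))
    stop(errorCondition(
      sprintf("mesh is not a single connected component (%d of %d voxels reached)",
              nvis, length(lin)),
      class = c("osteomech_solver_error", "osteomech_error")))
  invisible(TRUE)
}

#' Solve elastic three-point bending on a voxel FE model
#'
#' Simply supported beam along z with a concentrated midspan load: vertical
#' (y) displacement is fixed on two transverse bottom node lines at
#' midspan +/- span/2; one support line is additionally fixed axially and one
#' of its nodes laterally, removing all six rigid-body modes. The load is
#' distributed over the one-voxel-wide transverse top node line at midspan
#' (a true point load would be singular). Small-strain isotropic elasticity
#' with B-bar hexahedra; direct sparse Cholesky solve.
#'
#' @param model an \code{fe_model}.
#' @param span support span, mm.
#' @param load total downward load, N (default the 5 N protocol load).
#' @return An \code{fe_solution}: nodal displacements (mm), element strains
#'   and stresses, von Mises fields, midspan deflection (mm), strain energy
#'   (N mm), reaction balance, and the inputs.
#' @export
fe_bending_solve <- function(model, span, load = 5) {
  co <- model$coords
  zs <- sort(unique(co[, "z"]))
  z_mid <- (min(zs) + max(zs)) / 2
  pick_plane <- function(zt) zs[which.min(abs(zs - zt))]
  z_a <- pick_plane(z_mid - span / 2)
  z_b <- pick_plane(z_mid + span / 2)
  z_m <- pick_plane(z_mid)
  if (z_a == z_b) param_error("span too small for the mesh")

  at_plane <- function(zp) which(abs(co[, "z"] - zp) < 1e-9)
  bottom_line <- function(idx) {
    ymin <- min(co[idx, "y"])
    idx[co[idx, "y"] < ymin + 1e-9]
  }
  top_line <- function(idx) {
    ymax <- max(co[idx, "y"])
    idx[co[idx, "y"] > ymax - 1e-9]
  }
  sup_a <- bottom_line(at_plane(z_a))
  sup_b <- bottom_line(at_plane(z_b))
  load_nodes <- top_line(at_plane(z_m))

  ndof <- 3L * model$n_nodes
  fixed <- c(3L * (sup_a - 1L) + 2L,          # uy at both supports
             3L * (sup_b - 1L) + 2L,
             3L * (sup_a - 1L) + 3L)          # uz at support A
  cx <- sup_a[which.min(abs(co[sup_a, "x"] - mean(range(co[sup_a, "x"]))))]
  fixed <- unique(c(fixed, 3L * (cx - 1L) + 1L))   # ux at one node
  f <- numeric(ndof)
  f[3L * (load_nodes - 1L) + 2L] <- -load / length(load_nodes)

  kmats <- lapply(model$materials, function(m)
    hex_stiffness(m[["E"]], m[["nu"]], model$h))
  tr <- .fe_triplets(model$elem_nodes, model$mat_id, unname(kmats))
  K <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(ndof, ndof), symmetric = TRUE)
  free <- setdiff(seq_len(ndof), fixed)
  Kff <- Matrix::forceSymmetric(K[free, free], uplo = "U")
  ch <- Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE, super = TRUE)
  u <- numeric(ndof)
  u[free] <- as.numeric(Matrix::solve(ch, f[free]))

  resid <- as.numeric(K %*% u - f)
  reactions <- resid[fixed]
  fy_idx <- fixed[fixed %% 3 == 2]
  reaction_balance <- sum(resid[fy_idx]) - load  # should be ~0

  eps <- .fe_strains(model$elem_nodes, u, model$h)
  lam_e <- mu_e <- numeric(nrow(eps))
  for (m in seq_along(model$materials)) {
    pm <- model$materials[[m]]
    sel <- model$mat_id == m - 1L
    lam_e[sel] <- pm[["E"]] * pm[["nu"]] /
      ((1 + pm[["nu"]]) * (1 - 2 * pm[["nu"]]))
    mu_e[sel] <- pm[["E"]] / (2 * (1 + pm[["nu"]]))
  }
  tr3 <- eps[, 1] + eps[, 2] + eps[, 3]
  stress <- cbind(lam_e * tr3 + 2 * mu_e * eps[, 1],
                  lam_e * tr3 + 2 * mu_e * eps[, 2],
                  lam_e * tr3 + 2 * mu_e * eps[, 3],
                  mu_e * eps[, 4], mu_e * eps[, 5], mu_e * eps[, 6])
  colnames(stress) <- c("sxx", "syy", "szz", "sxy", "syz", "szx")
  colnames(eps) <- c("exx", "eyy", "ezz", "gxy", "gyz", "gzx")

  mid_nodes <- at_plane(z_m)
  midspan_deflection <- -mean(u[3L * (mid_nodes - 1L) + 2L])

  # elements touching the load or support node lines carry constraint/load
  # concentrations; field summaries can exclude them
  special <- c(load_nodes, sup_a, sup_b)
  boundary_elem <- rowSums(matrix((model$elem_nodes + 1L) %in% special,
                                  nrow(model$elem_nodes))) > 0

  structure(list(
    u = matrix(u, ncol = 3, byrow = TRUE,
               dimnames = list(NULL, c("ux", "uy", "uz"))),
    strain = eps, stress = stress,
    von_mises_stress = von_mises_stress(stress),
    von_mises_strain = von_mises_strain(eps),
    midspan_deflection = midspan_deflection,
    boundary_element = boundary_elem,
    strain_energy = 0.5 * sum(u * f),
    reaction_balance = reaction_balance,
    load = load, span = z_b - z_a, model = model),
    class = "fe_solution")
}

#' Von Mises equivalent stress
#'
#' \code{sqrt(0.5 * ((s1-s2)^2 + (s2-s3)^2 + (s3-s1)^2))} in terms of
#' principal stresses; computed componentwise from the stress tensor.
#'
#' @param stress matrix with columns sxx, syy, szz, sxy, syz, szx (MPa).
#' @return Vector of von Mises stresses, MPa.
#' @export
von_mises_stress <- function(stress) {
  s <- stress
  sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                (s[, 3] - s[, 1])^2) +
         3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
}

#' Von Mises equivalent strain
#'
#' \code{sqrt(2/3 * e:e)} on the deviatoric strain tensor (engineering shear
#' components are halved to tensor shears first).
#'
#' @param strain matrix with columns exx, eyy, ezz, gxy, gyz, gzx.
#' @return Vector of equivalent strains.
#' @export
von_mises_strain <- function(strain) {
  e <- strain
  tr3 <- (e[, 1] + e[, 2] + e[, 3]) / 3
  d1 <- e[, 1] - tr3; d2 <- e[, 2] - tr3; d3 <- e[, 3] - tr3
  t4 <- e[, 4] / 2; t5 <- e[, 5] / 2; t6 <- e[, 6] / 2
  sqrt((2 / 3) * (d1^2 + d2^2 + d3^2 + 2 * (t4^2 + t5^2 + t6^2)))
}

#' Compare two FE bending solutions
#'
#' Percent differences of matched summary statistics: peak and 95th-percentile
#' von Mises stress and strain, and midspan deflection. Solutions must share
#' the same applied load.
#'
#' @param sol_a,sol_b \code{fe_solution} objects (e.g. KO vs WT).
#' @param bone_only restrict the stress/strain summaries to bone elements
#'   (labels 1-2), excluding marrow.
#' @param exclude_boundary drop elements on the load/support node lines
#'   (constraint concentrations) from the field summaries.
#' @return \code{data.frame} of summary values and percent differences
#'   (a relative to b).
#' @export
compare_groups <- function(sol_a, sol_b, bone_only = TRUE,
                           exclude_boundary = TRUE) {
  if (abs(sol_a$load - sol_b$load) > 1e-9)
    stop(errorCondition("solutions have different applied loads",
                        class = c("osteomech_comparison_error",
                                  "osteomech_error")))
  summarize <- function(sol) {
    keep <- if (bone_only)
      sol$model$labels_per_element %in% c(LBL_CORTICAL, LBL_TRABECULAR)
    else rep(TRUE, length(sol$von_mises_stress))
    if (exclude_boundary) keep <- keep & !sol$boundary_element
    c(peak_vm_stress = max(sol$von_mises_stress[keep]),
      p95_vm_stress = unname(quantile(sol$von_mises_stress[keep], 0.95)),
      peak_vm_strain = max(sol$von_mises_strain[keep]),
      p95_vm_strain = unname(quantile(sol$von_mises_strain[keep], 0.95)),
      midspan_deflection = sol$midspan_deflection)
  }
  a <- summarize(sol_a); b <- summarize(sol_b)
  data.frame(quantity = names(a), value_a = unname(a), value_b = unname(b),
             percent_difference = 100 * (unname(a) - unname(b)) / unname(b))
}
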