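# In-code fixtures and independent oracles shared across test files.

# three-atom alanine fixture (N, CA, C), chain A, residue 1
alanine_atoms <- function() {
  tibble::tibble(
    serial = 1:3, name = c("N", "CA", "C"), element = c("N", "C", "C"),
    alt_loc = "", res_name = "ALA", chain_id = "A", res_seq = 1L, i_code = "",
    x = c(0.000, 1.458, 2.009), y = c(0.000, 0.000, 1.420),
    z = c(0.000, 0.000, 0.000), occupancy = 1, b_factor = c(20, 30, 25),
    is_hetero = FALSE
  )
}

write_alanine_pdb <- function(path) {
  write_structure(as_structure(alanine_atoms()), path, format = "pdb")
  path
}

# n-residue poly-ALA chain of CA atoms along x, 3.8 A spacing
ca_chain <- function(n = 10, chain_id = "A", b = 30) {
  as_structure(tibble::tibble(
    serial = seq_len(n), name = "CA", element = "C", res_name = "ALA",
    chain_id = chain_id, res_seq = seq_len(n),
    x = 3.8 * (seq_len(n) - 1), y = 0, z = 0,
    occupancy = 1, b_factor = rep(b, length.out = n)
  ))
}

# independent dihedral oracle: angle between plane normals + sign test
dihedral_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(
    a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Lee-Richards style z-slice SASA integrator (independent of Shrake-Rupley):
# per atom, slice its expanded sphere into dz-thick disks; each disk is a
# circle whose exposed arc fraction is found by subtracting the angular
# intervals occluded by neighbouring spheres; area = sum(arc length * dz).
sasa_slice_oracle <- function(structure, probe = 1.4, dz = 0.2) {
  r <- conformeter:::element_vdw_radius(structure$element) + probe
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  n <- nrow(xyz)
  total <- 0
  for (i in seq_len(n)) {
    zs <- seq(xyz[i, 3] - r[i] + dz / 2, xyz[i, 3] + r[i] - dz / 2, by = dz)
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r[i] + max(r))^2 & d2 > 1e-12)
    nb <- nb[sqrt(d2[nb]) < r[i] + r[nb]]
    for (z in zs) {
      ri_z2 <- r[i]^2 - (z - xyz[i, 3])^2
      if (ri_z2 <= 0) next
      ri_z <- sqrt(ri_z2)
      ivals <- list()
      buried_all <- FALSE
      for (j in nb) {
        rj_z2 <- r[j]^2 - (z - xyz[j, 3])^2
        if (rj_z2 <= 0) next
        rj_z <- sqrt(rj_z2)
        dx <- xyz[j, 1] - xyz[i, 1]; dy <- xyz[j, 2] - xyz[i, 2]
        dd <- sqrt(dx^2 + dy^2)
        if (dd >= ri_z + rj_z) next
        if (dd + ri_z <= rj_z) { buried_all <- TRUE; break }
        if (dd + rj_z <= ri_z) next
        alpha <- acos(pmin(1, pmax(-1, (dd^2 + ri_z2 - rj_z2) / (2 * dd * ri_z))))
        mid <- atan2(dy, dx)
        ivals[[length(ivals) + 1]] <- c(mid - alpha, mid + alpha)
      }
      if (buried_all) next
      exposed <- 2 * pi - union_length(ivals)
      # lateral surface of the sphere band: r[i] * dz per unit angle
      total <- total + exposed * r[i] * dz
    }
  }
  unname(total)
}

# total length of a union of angular intervals on the circle
union_length <- function(ivals) {
  if (length(ivals) == 0) return(0)
  segs <- list()
  for (iv in ivals) {
    a <- iv[1] %% (2 * pi); b <- a + (iv[2] - iv[1])
    if (b <= 2 * pi) {
      segs[[length(segs) + 1]] <- c(a, b)
    } else {
      segs[[length(segs) + 1]] <- c(a, 2 * pi)
      segs[[length(segs) + 1]] <- c(0, b - 2 * pi)
    }
  }
  m <- do.call(rbind, segs)
  m <- m[order(m[, 1]), , drop = FALSE]
  tot <- 0; cur_a <- m[1, 1]; cur_b <- m[1, 2]
  for (k in seq_len(nrow(m))[-1]) {
    if (m[k, 1] <= cur_b) {
      cur_b <- max(cur_b, m[k, 2])
    } else {
      tot <- tot + cur_b - cur_a
      cur_a <- m[k, 1]; cur_b <- m[k, 2]
    }
  }
  tot + cur_b - cur_a
}

# SVD-free rigid-superposition oracle: multi-start Nelder-Mead over Euler
# angles; translation handled by centroids
rmsd_euler_oracle <- function(fixed, mobile, n_starts = 64) {
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  F0 <- sweep(fixed, 2, cf); M0 <- sweep(mobile, 2, cm)
  rotmat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) mean(rowSums((t(rotmat(ang) %*% t(M0)) - F0)^2))
  set.seed(4242)
  starts <- matrix(runif(3 * n_starts, -pi, pi), ncol = 3)
  best <- Inf
  for (s in seq_len(n_starts)) {
    o <- optim(starts[s, ], obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000))
    if (o$value < best) best <- o$value
  }
  sqrt(best)
}

rigid_transform <- function(structure, axis = c(0, 0, 1), angle_deg = 30,
                            shift = c(1, 2, 3)) {
  R <- conformeter:::rotation_matrix_axis_angle(axis, angle_deg)
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  new <- t(R %*% t(xyz)) + matrix(shift, nrow(xyz), 3, byrow = TRUE)
  structure$x <- new[, 1]; structure$y <- new[, 2]; structure$z <- new[, 3]
  structure
}
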