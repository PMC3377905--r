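# Independent oracles used to cross-check the package's geometry code.
# Nothing here calls kabsch_superpose() or the package's interface scan.

rot_z <- function(a) {
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}
rot_y <- function(a) {
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3,
         byrow = TRUE)
}
euler_rotation <- function(a, b, c) rot_z(a) %*% rot_y(b) %*% rot_z(c)

# RMSD for a given rotation with the (closed-form) optimal translation,
# i.e. centroids aligned.
rmsd_given_rotation <- function(moving, fixed, rot) {
  p <- sweep(moving, 2, colMeans(moving))
  q <- sweep(fixed, 2, colMeans(fixed))
  sqrt(mean(rowSums((p %*% t(rot) - q)^2)))
}

# Brute-force minimum RMSD over a Euler-angle grid, then Nelder-Mead
# refinement from the best grid point.  Independent of the SVD path.
brute_force_min_rmsd <- function(moving, fixed, step_deg = 15) {
  st <- step_deg * pi / 180
  grid_a <- seq(0, 2 * pi - st / 2, by = st)
  grid_b <- seq(0, pi, by = st)
  best <- Inf
  best_ang <- c(0, 0, 0)
  for (a in grid_a) for (b in grid_b) for (cc in grid_a) {
    r <- rmsd_given_rotation(moving, fixed, euler_rotation(a, b, cc))
    if (r < best) {
      best <- r
      best_ang <- c(a, b, cc)
    }
  }
  refined <- stats::optim(
    best_ang,
    function(ang) rmsd_given_rotation(moving, fixed,
                                      euler_rotation(ang[1], ang[2], ang[3])),
    method = "Nelder-Mead",
    control = list(reltol = 1e-14, maxit = 5000))
  list(grid = best, refined = refined$value)
}

# O(n^2) double-loop interface scan: residues of either chain with any
# heavy atom within `cutoff` of any heavy atom of the partner.
brute_force_interface <- function(structure, chain_x, chain_y, cutoff = 10) {
  at <- tibble::as_tibble(structure)
  ax <- at[at$chain == chain_x, ]
  ay <- at[at$chain == chain_y, ]
  res <- list()
  for (i in seq_len(nrow(ax))) {
    for (j in seq_len(nrow(ay))) {
      d <- sqrt((ax$x[i] - ay$x[j])^2 + (ax$y[i] - ay$y[j])^2 +
                  (ax$z[i] - ay$z[j])^2)
      if (d <= cutoff) {
        res[[length(res) + 1]] <- data.frame(
          chain = c(ax$chain[i], ay$chain[j]),
          resno = c(ax$resno[i], ay$resno[j]),
          ins = c(ax$ins[i], ay$ins[j]))
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(chain = character(), resno = integer(),
                      ins = character()))
  }
  unique(do.call(rbind, res))
}

# Residue-residue contact list (any heavy atom within cutoff), as keys.
brute_force_contacts <- function(structure, chain_x, chain_y, cutoff = 5) {
  at <- tibble::as_tibble(structure)
  ax <- at[at$chain == chain_x, ]
  ay <- at[at$chain == chain_y, ]
  keys <- character()
  for (i in seq_len(nrow(ax))) {
    for (j in seq_len(nrow(ay))) {
      d <- sqrt((ax$x[i] - ay$x[j])^2 + (ax$y[i] - ay$y[j])^2 +
                  (ax$z[i] - ay$z[j])^2)
      if (d <= cutoff) {
        keys <- c(keys, paste(ax$resno[i], ax$ins[i],
                              ay$resno[j], ay$ins[j]))
      }
    }
  }
  unique(keys)
}

# Superposed RMSD through bio3d (independent code path; fit.xyz keeps full
# precision where bio3d::rmsd would round to 3 decimals).
bio3d_fit_rmsd <- function(moving, fixed) {
  xf <- as.vector(t(fixed))
  xm <- as.vector(t(moving))
  fitted <- bio3d::fit.xyz(xf, xm, fixed.inds = seq_along(xf),
                           mobile.inds = seq_along(xm))
  sqrt(mean((fitted - xf)^2) * 3)
}
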