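# Independent oracles: a dense direct FE solver written from scratch (its own
# element integration at a different Gauss order, base-R assembly and solve)
# and the closed-form expectation of the correct classification rate implied
# by the generator's parameters.

# 24x24 stiffness of a cube element, 3x3x3 Gauss (exact for trilinear), with
# the package's local node order: corners x-fastest, then y, then z
oracle_hex_ke <- function(h, E, nu) {
  sgn <- as.matrix(expand.grid(sx = c(-1, 1), sy = c(-1, 1), sz = c(-1, 1)))
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  gp <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  gw <- c(5, 8, 5) / 9
  Ke <- matrix(0, 24, 24)
  for (a in 1:3) for (b in 1:3) for (c in 1:3) {
    xi <- gp[a]; eta <- gp[b]; ze <- gp[c]
    B <- matrix(0, 6, 24)
    for (i in 1:8) {
      s <- sgn[i, ]
      dNx <- s[1] * (1 + s[2] * eta) * (1 + s[3] * ze) / 8 * 2 / h
      dNy <- s[2] * (1 + s[1] * xi) * (1 + s[3] * ze) / 8 * 2 / h
      dNz <- s[3] * (1 + s[1] * xi) * (1 + s[2] * eta) / 8 * 2 / h
      col <- 3 * (i - 1)
      B[1, col + 1] <- dNx
      B[2, col + 2] <- dNy
      B[3, col + 3] <- dNz
      B[4, col + 1] <- dNy; B[4, col + 2] <- dNx
      B[5, col + 2] <- dNz; B[5, col + 3] <- dNy
      B[6, col + 1] <- dNz; B[6, col + 3] <- dNx
    }
    Ke <- Ke + gw[a] * gw[b] * gw[c] * t(B) %*% D %*% B * (h / 2)^3
  }
  Ke
}

# dense assembly + base::solve of the same boundary-value problem that
# solve_compression poses (high-friction variant); returns the full nodal
# displacement vector in (node, xyz) order
oracle_dense_solve <- function(mesh, applied_strain = 0.01) {
  h <- mesh$voxel_size
  nu <- mesh$law$nu
  ndof <- 3L * mesh$n_nodes
  K <- matrix(0, ndof, ndof)
  Ke1 <- oracle_hex_ke(h, 1, nu)
  for (e in seq_along(mesh$elements)) {
    dofs <- as.vector(t(outer(mesh$elem_nodes[e, ], 0:2,
                              function(n, c) 3L * n + c))) + 1L
    K[dofs, dofs] <- K[dofs, dofs] + mesh$E[e] * Ke1
  }
  height <- (mesh$z_layers[2] - mesh$z_layers[1] + 1L) * h
  fixed <- logical(ndof)
  u <- numeric(ndof)
  bd <- rep(3L * mesh$bottom_nodes, each = 3L) + (0:2) + 1L
  fixed[bd] <- TRUE
  td <- rep(3L * mesh$top_nodes, each = 3L) + (0:2) + 1L
  fixed[td] <- TRUE
  u[3L * mesh$top_nodes + 2L + 1L] <- -applied_strain * height
  free <- !fixed
  u[free] <- solve(K[free, free], -K[free, fixed] %*% u[fixed])
  u
}

# Expected CCR of the surface-event analysis under the generator's stochastic
# rule, by exact enumeration of the candidate sites: ratio of the expected
# number of correctly predicted events to the expected number of events.
oracle_expected_ccr <- function(clean, strain, rule, thresholds,
                                bone_threshold = 320) {
  d <- dim(clean)
  Tr <- thresholds[["Tr"]]; Tf <- thresholds[["Tf"]]
  shf <- function(a, ax, s, fill) {
    out <- array(fill, d)
    n <- d[ax]
    src <- dst <- lapply(d, seq_len)
    if (s > 0) { dst[[ax]] <- (s + 1):n; src[[ax]] <- 1:(n - s) }
    else { dst[[ax]] <- 1:(n + s); src[[ax]] <- (1 - s):n }
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      a[src[[1]], src[[2]], src[[3]]]
    out
  }
  bone <- clean >= bone_threshold
  interior <- bone
  for (ax in 1:3) for (s in c(-1L, 1L))
    interior <- interior & shf(bone, ax, s, fill = TRUE)  # out-of-grid = bone
  surf <- bone & !interior
  adj_bone <- array(FALSE, d)
  for (ax in 1:3) for (s in c(-1L, 1L))
    adj_bone <- adj_bone | shf(bone, ax, s, fill = FALSE)
  bg <- !bone & adj_bone

  p_act <- function(complies)
    ifelse(complies, rule$event_rate * rule$obedience,
           rule$event_rate * (1 - rule$obedience))
  # formation probability of every background candidate, on the full grid
  pf <- array(0, d)
  pf[bg] <- p_act(strain[bg] > rule$formation_threshold)
  # donor strain of a formed voxel: lowest-linear-index adjacent bone voxel
  strides <- c(1L, d[1], d[1] * d[2])
  bg_idx <- which(bg)
  b0 <- bg_idx - 1L
  bx <- b0 %% d[1]; by <- (b0 %/% d[1]) %% d[2]; bz <- b0 %/% (d[1] * d[2])
  donor <- rep(NA_integer_, length(bg_idx))
  offs <- list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
               c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
  for (off in offs) {
    jx <- bx + off[1]; jy <- by + off[2]; jz <- bz + off[3]
    inb <- jx >= 0L & jx < d[1] & jy >= 0L & jy < d[2] & jz >= 0L & jz < d[3]
    nb <- jx + strides[2] * jy + strides[3] * jz + 1L
    ok <- inb
    ok[inb] <- bone[nb[inb]]
    donor <- pmin(donor, ifelse(ok, nb, NA_integer_), na.rm = TRUE)
  }
  pred <- function(s) ifelse(s < Tr, "resorbed",
                             ifelse(s > Tf, "formed", "quiescent"))
  # resorption term
  surf_idx <- which(surf)
  pr <- p_act(strain[surf_idx] < rule$resorption_threshold)
  corr_r <- sum(pr * (pred(strain[surf_idx]) == "resorbed"))
  # formation term (events predicted from the donor's strain)
  pfv <- pf[bg_idx]
  corr_f <- sum(pfv * (pred(strain[donor]) == "formed"))
  # quiescence term: not resorbed and no adjacent candidate formed
  log_keep <- array(0, d)
  lk <- array(0, d)
  lk[bg] <- log1p(-pf[bg])
  for (off in offs) {
    # neighbour's log(1 - pf) accumulated onto each voxel
    log_keep <- log_keep + shf(lk, which(off != 0L),
                               -off[which(off != 0L)], fill = 0)
  }
  pq <- (1 - pr) * exp(log_keep[surf_idx])
  corr_q <- sum(pq * (pred(strain[surf_idx]) == "quiescent"))
  (corr_r + corr_f + corr_q) / (sum(pr) + sum(pfv) + sum(pq))
}
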