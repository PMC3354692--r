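# Independent brute-force oracles used across the test files. These follow
# the definitions directly (loops, dense algebra, exhaustive search) and are
# deliberately slower and structurally different from the package code paths
# they check.

rand_stack <- function(shape, p = 0.5, seed = 1, pixel_size = 36,
                       slice_increment = 36) {
  set.seed(seed)
  image_stack(array(rbinom(prod(shape), 1, p), shape),
              pixel_size, slice_increment)
}

# elementwise AND of arbitrary slice index pairs, voxel length d
oracle_pair_model <- function(stack, pairs_first, pairs_second) {
  s <- stack$slices
  n <- length(pairs_first)
  out <- array(0L, c(dim(s)[1], dim(s)[2], n))
  for (k in seq_len(n)) {
    out[, , k] <- s[, , pairs_first[k]] * s[, , pairs_second[k]]
  }
  out
}

# cuberrille majority coarsening by explicit triple loop
oracle_coarsen_h <- function(occ, f) {
  d <- dim(occ)
  nb <- ceiling(d / f)
  out <- array(0L, nb)
  for (i in seq_len(nb[1])) for (j in seq_len(nb[2])) for (k in seq_len(nb[3])) {
    xs <- ((i - 1) * f + 1):min(i * f, d[1])
    ys <- ((j - 1) * f + 1):min(j * f, d[2])
    zs <- ((k - 1) * f + 1):min(k * f, d[3])
    fill <- sum(occ[xs, ys, zs])
    out[i, j, k] <- as.integer(fill / f^3 > 0.5)
  }
  out
}

# 6-neighbour flood fill component labels over occupied cells (nel x 3 index)
oracle_components <- function(eidx, gd) {
  nel <- nrow(eidx)
  key <- function(ijk) paste(ijk, collapse = ",")
  id <- new.env()
  for (t in seq_len(nel)) assign(key(eidx[t, ]), t, envir = id)
  comp <- integer(nel)
  cur <- 0L
  for (t in seq_len(nel)) {
    if (comp[t] != 0L) next
    cur <- cur + 1L
    queue <- t
    comp[t] <- cur
    while (length(queue)) {
      e <- queue[1]; queue <- queue[-1]
      for (step in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                        c(0, 0, 1), c(0, 0, -1))) {
        nb <- eidx[e, ] + step
        if (any(nb < 1) || any(nb > gd)) next
        other <- mget(key(nb), envir = id, ifnotfound = list(NULL))[[1]]
        if (!is.null(other) && comp[other] == 0L) {
          comp[other] <- cur
          queue <- c(queue, other)
        }
      }
    }
  }
  comp
}

# dense direct solve of the compression problem, base-R linear algebra only
oracle_dense_solve <- function(mesh, mat, strain) {
  Ke <- element_stiffness(mat, mesh$h)
  nn <- nrow(mesh$nodes)
  K <- matrix(0, 3 * nn, 3 * nn)
  for (e in seq_len(nrow(mesh$elems))) {
    dofs <- as.vector(rbind(3 * (mesh$elems[e, ] - 1) + 1,
                            3 * (mesh$elems[e, ] - 1) + 2,
                            3 * (mesh$elems[e, ] - 1) + 3))
    K[dofs, dofs] <- K[dofs, dofs] + Ke
  }
  nodes_mm <- mesh$nodes / 1000
  z <- nodes_mm[, 3]
  ztol <- mesh$h / 1000 * 1e-6
  fixed <- which(abs(z - min(z)) < ztol)
  driven <- which(abs(z - max(z)) < ztol)
  H <- max(z) - min(z)
  presc <- c(3 * (fixed - 1) + 3, 3 * (driven - 1) + 3)
  vals <- c(rep(0, length(fixed)), rep(-strain * H, length(driven)))
  # identical pin rule to the package solver (same constrained subspace)
  fx <- nodes_mm[fixed, 1]; fy <- nodes_mm[fixed, 2]
  ordA <- order(fx, fy)
  A <- fixed[ordA[1]]
  sameY <- fixed[abs(fy - nodes_mm[A, 2]) < ztol & fixed != A]
  B <- if (length(sameY) > 0)
    sameY[which.max(abs(nodes_mm[sameY, 1] - nodes_mm[A, 1]))]
  else fixed[fixed != A][1]
  pins <- c(3 * (A - 1) + 1, 3 * (A - 1) + 2)
  if (!is.na(B) && length(B) == 1L) pins <- c(pins, 3 * (B - 1) + 2)
  presc <- c(presc, pins)
  vals <- c(vals, rep(0, length(pins)))
  u <- numeric(3 * nn)
  u[presc] <- vals
  free <- setdiff(seq_len(3 * nn), presc)
  u[free] <- solve(K[free, free], -K[free, presc, drop = FALSE] %*% vals)
  r <- K %*% u
  list(u = u, force_n = abs(sum(r[3 * (driven - 1) + 3])))
}

# stiffness by independent numerical integration: finite-difference shape
# gradients and 4x4x4 Gauss-Legendre quadrature
oracle_element_stiffness <- function(mat, h) {
  h_mm <- h / 1000
  e_mpa <- mat$e_tissue_gpa * 1000
  nu <- mat$nu
  lam <- e_mpa * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- e_mpa / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam; diag(D)[1:3] <- lam + 2 * mu; diag(D)[4:6] <- mu
  shp <- function(xi, eta, zeta) {
    s <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
               c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
    (1 + s[, 1] * xi) * (1 + s[, 2] * eta) * (1 + s[, 3] * zeta) / 8
  }
  num_grad <- function(xi, eta, zeta, eps = 1e-6) {
    cbind((shp(xi + eps, eta, zeta) - shp(xi - eps, eta, zeta)) / (2 * eps),
          (shp(xi, eta + eps, zeta) - shp(xi, eta - eps, zeta)) / (2 * eps),
          (shp(xi, eta, zeta + eps) - shp(xi, eta, zeta - eps)) / (2 * eps))
  }
  gl <- statmod_gauss4()
  K <- matrix(0, 24, 24)
  half <- h_mm / 2
  for (a in 1:4) for (b in 1:4) for (c in 1:4) {
    dN <- num_grad(gl$x[a], gl$x[b], gl$x[c]) / half
    B <- matrix(0, 6, 24)
    for (i in 1:8) {
      c0 <- 3 * (i - 1)
      B[1, c0 + 1] <- dN[i, 1]; B[2, c0 + 2] <- dN[i, 2]
      B[3, c0 + 3] <- dN[i, 3]
      B[4, c0 + 1] <- dN[i, 2]; B[4, c0 + 2] <- dN[i, 1]
      B[5, c0 + 2] <- dN[i, 3]; B[5, c0 + 3] <- dN[i, 2]
      B[6, c0 + 1] <- dN[i, 3]; B[6, c0 + 3] <- dN[i, 1]
    }
    K <- K + t(B) %*% D %*% B * half^3 * gl$w[a] * gl$w[b] * gl$w[c]
  }
  K
}

statmod_gauss4 <- function() {
  a <- sqrt(3 / 7 - 2 / 7 * sqrt(6 / 5))
  b <- sqrt(3 / 7 + 2 / 7 * sqrt(6 / 5))
  wa <- (18 + sqrt(30)) / 36
  wb <- (18 - sqrt(30)) / 36
  list(x = c(-b, -a, a, b), w = c(wb, wa, wa, wb))
}

# local thickness by exhaustive search over all candidate sphere centres
oracle_local_thickness <- function(model, boundary = "background") {
  occ <- model$occupancy == 1L
  d <- dim(occ)
  if (length(boundary) == 1L) boundary <- rep(boundary, 3L)
  hf <- c(model$dx, model$dy, model$dz) / 2
  fd <- 2L * d + 1L
  B <- array(FALSE, fd)
  idx <- which(occ, arr.ind = TRUE)
  for (t in seq_len(nrow(idx))) {
    B[(2 * idx[t, 1] - 1):(2 * idx[t, 1] + 1),
      (2 * idx[t, 2] - 1):(2 * idx[t, 2] + 1),
      (2 * idx[t, 3] - 1):(2 * idx[t, 3] + 1)] <- TRUE
  }
  pad <- ifelse(boundary == "background", 1L, 0L)
  P <- array(FALSE, fd + 2L * pad)
  P[pad[1] + seq_len(fd[1]), pad[2] + seq_len(fd[2]),
    pad[3] + seq_len(fd[3])] <- B
  pd <- dim(P)
  bg <- which(!P, arr.ind = TRUE)
  bone_nodes <- which(P, arr.ind = TRUE)
  # exact nearest-background-node distance per bone node
  # fine node at (unpadded) index t sits at position (t - 1) * hf
  coords <- function(ind, off) sweep(ind, 2, off + 1, `-`)
  bgc <- sweep(coords(bg, pad), 2, hf, `*`)
  r <- numeric(nrow(bone_nodes))
  bc <- sweep(coords(bone_nodes, pad), 2, hf, `*`)
  for (t in seq_len(nrow(bone_nodes))) {
    dv <- sweep(bgc, 2, bc[t, ], `-`)
    r[t] <- sqrt(min(rowSums(dv^2))) - min(hf)
  }
  th <- array(0, d)
  centers <- which(occ, arr.ind = TRUE)
  for (v in seq_len(nrow(centers))) {
    pc <- (2 * centers[v, ] - 1) * hf  # voxel centre, fine index 2i
    best <- 0
    for (t in seq_len(nrow(bone_nodes))) {
      if (r[t] <= best / 2) next
      if (sum((bc[t, ] - pc)^2) <= r[t]^2 + 1e-9) best <- 2 * r[t]
    }
    th[centers[v, 1], centers[v, 2], centers[v, 3]] <- best
  }
  th
}

# closed-form simple linear regression via normal equations
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  a <- sxy / sxx
  b <- mean(y) - a * mean(x)
  pred <- a * x + b
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum((y - pred)^2) / sst
  list(a = a, b = b, r2 = r2)
}
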