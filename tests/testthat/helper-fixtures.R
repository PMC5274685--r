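# shared fixtures and independent oracles for the test suite

default_tx <- function(...) transducer_spec(...)

# small, fast phantom: short standoff keeps traces short
fast_phantom <- function(...) {
  cartilage_phantom_spec(standoff_mean = 2, ...)
}

# digital solid shapes for morphometry tests (voxel centres at i - 0.5)
digital_sphere <- function(n, radius, center = rep(n / 2, 3)) {
  cx <- seq_len(n) - 0.5
  arr <- array(FALSE, dim = c(n, n, n))
  for (k in seq_len(n)) {
    arr[, , k] <- outer((cx - center[1])^2, (cx - center[2])^2, "+") +
      (cx[k] - center[3])^2 <= radius^2
  }
  arr
}

digital_cylinder_z <- function(nxy, nz, radius) {
  cx <- seq_len(nxy) - 0.5
  disc <- outer((cx - nxy / 2)^2, (cx - nxy / 2)^2, "+") <= radius^2
  array(rep(disc, nz), dim = c(nxy, nxy, nz))
}

digital_slab_z <- function(n, z_from, z_to) {
  arr <- array(FALSE, dim = c(n, n, n))
  arr[, , z_from:z_to] <- TRUE
  arr
}

# rectangular rod along x with cross-section wy x wz, spanning full x
digital_box_rod_x <- function(n, wy, wz) {
  arr <- array(FALSE, dim = c(n, n, n))
  y0 <- floor((n - wy) / 2) + 1
  z0 <- floor((n - wz) / 2) + 1
  arr[, y0:(y0 + wy - 1), z0:(z0 + wz - 1)] <- TRUE
  arr
}

# --- independent oracles ---------------------------------------------------

# Mann-Whitney: U by direct pairwise counting, p by enumerating all group
# assignments of the pooled values (independent of the rank-sum route)
oracle_mw <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(x, y)
  cols <- utils::combn(n, n1)
  us <- apply(cols, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  p <- min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
  list(U = u_obs, p_value = p)
}

# Euler characteristic by explicit set enumeration of the cubical complex
# (vertices/edges/faces keyed by coordinates; independent of the shifted
# array-OR implementation)
oracle_euler <- function(a) {
  d <- dim(a)
  verts <- new.env(parent = emptyenv())
  edges <- new.env(parent = emptyenv())
  faces <- new.env(parent = emptyenv())
  put <- function(env, ...) assign(paste(..., sep = ","), TRUE, envir = env)
  n_cells <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!a[i, j, k]) next
    n_cells <- n_cells + 1L
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      put(verts, "v", i + di, j + dj, k + dk)
    }
    for (dj in 0:1) for (dk in 0:1) put(edges, "ex", i, j + dj, k + dk)
    for (di in 0:1) for (dk in 0:1) put(edges, "ey", i + di, j, k + dk)
    for (di in 0:1) for (dj in 0:1) put(edges, "ez", i + di, j + dj, k)
    put(faces, "fx", i, j, k); put(faces, "fx", i + 1, j, k)
    put(faces, "fy", i, j, k); put(faces, "fy", i, j + 1, k)
    put(faces, "fz", i, j, k); put(faces, "fz", i, j, k + 1)
  }
  length(ls(verts)) - length(ls(edges)) + length(ls(faces)) - n_cells
}
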