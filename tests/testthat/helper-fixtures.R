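# shared fixtures, built in code

# regular triangulated plate in the z = 0 plane, normals +z
flat_plate <- function(half = 10, n = 11) {
  g <- expand.grid(x = seq(-half, half, length.out = n),
                   y = seq(-half, half, length.out = n))
  v <- cbind(g$x, g$y, 0)
  id <- function(i, j) (j - 1) * n + i
  f <- NULL
  for (j in 1:(n - 1)) for (i in 1:(n - 1))
    f <- rbind(f, c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
               c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  surface_mesh(v, f)
}

# independent absolute-orientation oracle: Horn's quaternion eigenvector
# method (a different algorithm than the package's SVD route)
horn_quaternion_oracle <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  M <- crossprod(Pc, Qc)
  S <- M; A <- S - t(S)
  delta <- c(A[2, 3], A[3, 1], A[1, 2])
  N <- rbind(c(sum(diag(S)), delta),
             cbind(delta, S + t(S) - sum(diag(S)) * diag(3)))
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- rbind(
    c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2))
  list(R = R, t = as.numeric(qc - R %*% pc))
}

# brute-force binary closing with a box structuring element on a padded grid
closing_oracle <- function(arr, kernel) {
  r <- (kernel - 1L) %/% 2L
  d <- dim(arr)
  pd <- d + 2L * (r + r)  # generous padding
  pad <- array(0L, pd)
  pad[2 * r[1] + seq_len(d[1]) - r[1], 2 * r[2] + seq_len(d[2]) - r[2],
      2 * r[3] + seq_len(d[3]) - r[3]] <- arr
  offs <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  shift_or <- function(a, acc_fun, init) {
    acc <- array(init, dim(a))
    for (s in seq_len(nrow(offs))) {
      sh <- array(0L, dim(a))
      xs <- seq_len(dim(a)[1]) + offs$dx[s]
      ys <- seq_len(dim(a)[2]) + offs$dy[s]
      zs <- seq_len(dim(a)[3]) + offs$dz[s]
      ok_x <- xs >= 1 & xs <= dim(a)[1]
      ok_y <- ys >= 1 & ys <= dim(a)[2]
      ok_z <- zs >= 1 & zs <= dim(a)[3]
      sh[ok_x, ok_y, ok_z] <- a[xs[ok_x], ys[ok_y], zs[ok_z]]
      acc <- acc_fun(acc, sh)
    }
    acc
  }
  dil <- shift_or(pad, function(a, b) pmax(a, b), 0L)
  ero <- shift_or(dil, function(a, b) pmin(a, b), 1L)
  ero[2 * r[1] + seq_len(d[1]) - r[1], 2 * r[2] + seq_len(d[2]) - r[2],
      2 * r[3] + seq_len(d[3]) - r[3]]
}

# small deterministic phantom for trial-level tests (cheapest case)
test_phantom <- function(seed = 3L, case = "AR3DP0003") {
  tab <- phantom_case_table()
  row <- tab[tab$case_id == case, ]
  row$seed <- seed
  generate_phantom(spec_from_case_row(row))
}

all_phantoms <- function(seeds = 1:6) {
  tab <- phantom_case_table(seeds = seeds)
  lapply(seq_len(nrow(tab)), function(i) generate_phantom(spec_from_case_row(tab[i, ])))
}
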