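# shared generators and comparison helpers for the suite

# random small bipartite cloud for oracle comparisons
random_small_cloud <- function(p, q, box = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- p + q
  topobind:::new_atom_table(
    c(sprintf("P%d", seq_len(p)), sprintf("L%d", seq_len(q))),
    "C",
    runif(n, 0, box), runif(n, 0, box), runif(n, 0, box),
    rep(c("protein", "ligand"), c(p, q))
  )
}

# random rigid motion: rotation from QR of a Gaussian matrix, plus shift
apply_rigid_motion <- function(atoms, seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- rnorm(3, sd = 10)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}

# displace every atom by an independent random vector of norm <= delta
# (the premise of the 2*delta Lipschitz bound on cross-edge lengths)
perturb_atoms <- function(atoms, delta, seed = 1) {
  set.seed(seed)
  n <- nrow(atoms)
  dir <- matrix(rnorm(3 * n), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  r <- runif(n, 0, delta)
  atoms$x <- atoms$x + dir[, 1] * r
  atoms$y <- atoms$y + dir[, 2] * r
  atoms$z <- atoms$z + dir[, 3] * r
  atoms
}

# multiset comparison of critical values per dimension
expect_cv_equal <- function(cv, expected, tol = 1e-9) {
  for (d in 0:1) {
    expect_equal(
      sort(cv$value[cv$dimension == d]),
      sort(expected$value[expected$dimension == d]),
      tolerance = tol
    )
  }
}

# oracle critical values in the same (dimension, value) form as persistence():
# finite 0D deaths + 1D births (all 1D classes are essential under d_op)
oracle_cv <- function(cloud) {
  pairs <- persistence_oracle(opposition_distance_matrix(cloud))
  d0 <- pairs[pairs$dimension == 0 & is.finite(pairs$death), , drop = FALSE]
  d1 <- pairs[pairs$dimension == 1, , drop = FALSE]
  tibble::tibble(
    dimension = rep(c(0L, 1L), c(nrow(d0), nrow(d1))),
    value = c(d0$death, d1$birth)
  )
}

# independent ensemble-prediction oracle: recursive traversal of the
# exported JSON, base + rate * sum of tree leaves
traverse_exported <- function(json, newdata) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  one_tree <- function(tr, row) {
    id <- 1
    repeat {
      k <- which(tr$node == id)
      if (tr$is_leaf[k]) {
        return(tr$value[k])
      }
      id <- if (row[[tr$feature[k]]] <= tr$threshold[k]) tr$left[k] else tr$right[k]
    }
  }
  vapply(seq_len(nrow(newdata)), function(i) {
    obj$base_prediction + obj$learning_rate *
      sum(vapply(obj$trees, one_tree, numeric(1), row = newdata[i, , drop = FALSE]))
  }, numeric(1))
}
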