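#' Opposition distance between two atoms
#'
#' Euclidean distance if one atom is a protein atom and the other a ligand
#' atom; `Inf` if both sit on the same side of the bipartition. Symmetric
#' by construction. Under this distance the Vietoris-Rips complex never
#' contains a triangle (no three atoms have pairwise-finite distances), so
#' its persistent homology lives entirely in the cross-distance graph.
#'
#' @param a,b one-row atom tables (or rows of one) with columns
#'   `x`, `y`, `z`, `affiliation`.
#' @return distance in Angstrom, possibly `Inf`.
#' @export
opposition_distance <- function(a, b) {
  if (a$affiliation[1] == b$affiliation[1]) {
    return(Inf)
  }
  sqrt((a$x[1] - b$x[1])^2 + (a$y[1] - b$y[1])^2 + (a$z[1] - b$z[1])^2)
}

#' All finite opposition-distance edges of a point cloud
#'
#' Enumerates every protein-ligand atom pair with its Euclidean distance,
#' sorted ascending by (weight, protein id, ligand id). Same-side pairs are
#' infinite under the opposition distance and are never materialized. This
#' sorted edge list is the preprocessing step on which both the persistence
#' sweep and the radius truncation rest.
#'
#' @param cloud atom table (any mix of protein and ligand rows).
#' @return tibble with columns `protein_id`, `ligand_id`, `weight`
#'   (Angstrom), p*q rows.
#' @export
cross_edges <- function(cloud) {
  p <- cloud[cloud$affiliation == "protein", , drop = FALSE]
  q <- cloud[cloud$affiliation == "ligand", , drop = FALSE]
  if (nrow(p) == 0 || nrow(q) == 0) {
    return(tibble(protein_id = character(), ligand_id = character(), weight = numeric()))
  }
  pm <- as.matrix(p[, c("x", "y", "z")])
  qm <- as.matrix(q[, c("x", "y", "z")])
  d2 <- outer(rowSums(pm^2), rowSums(qm^2), "+") - 2 * tcrossprod(pm, qm)
  w <- sqrt(pmax(d2, 0))
  out <- tibble(
    protein_id = rep(p$id, times = nrow(q)),
    ligand_id = rep(q$id, each = nrow(p)),
    weight = as.numeric(w)
  )
  out[order(out$weight, out$protein_id, out$ligand_id), ]
}

#' Critical values of the opposition-distance filtration
#'
#' Single ascending sweep over the cross edges with a union-find structure:
#' an edge that merges two distinct connected components is the death of a
#' 0-dimensional class (recorded as `dimension = 0`), and an edge that
#' closes a cycle within one component is the birth of a 1-dimensional
#' class (`dimension = 1`). With p protein and q ligand points (both > 0)
#' this yields exactly p+q-1 deaths and p*q-(p+q-1) births; the essential
#' 0D class (the component surviving to infinity) carries no finite
#' critical value and is not reported. The equivalence of this sweep with
#' full Vietoris-Rips persistence under the opposition distance is asserted
#' against [persistence_oracle()] in the test suite rather than assumed.
#'
#' @param cloud atom table.
#' @return tibble with columns `dimension` (0 or 1), `value` (Angstrom),
#'   and the critical edge's `protein_id` and `ligand_id` (the merging edge
#'   for dimension 0, the cycle-closing edge for dimension 1), sorted by
#'   (dimension, value).
#' @examples
#' persistence(make_square(2)) # deaths {2,2,2}, one 1D birth at 2
#' @export
persistence <- function(cloud) {
  core <- persist_core(cloud)
  out <- tibble(
    dimension = core$dimension, value = core$value,
    protein_id = core$protein_id, ligand_id = core$ligand_id
  )
  out[order(out$dimension, out$value, out$protein_id, out$ligand_id), ]
}

# tibble-free core of the union-find sweep (hot path for ipc_stack)
persist_core <- function(cloud) {
  is_p <- cloud$affiliation == "protein"
  np <- sum(is_p)
  nq <- sum(!is_p)
  empty <- list(
    dimension = integer(), value = numeric(),
    protein_id = character(), ligand_id = character()
  )
  if (np == 0 || nq == 0) {
    return(empty)
  }
  pm <- cbind(cloud$x[is_p], cloud$y[is_p], cloud$z[is_p])
  qm <- cbind(cloud$x[!is_p], cloud$y[!is_p], cloud$z[!is_p])
  d2 <- outer(rowSums(pm^2), rowSums(qm^2), "+") - 2 * tcrossprod(pm, qm)
  w <- sqrt(pmax(as.numeric(d2), 0))
  pid <- rep(cloud$id[is_p], times = nq)
  qid <- rep(cloud$id[!is_p], each = np)
  ord <- order(w, pid, qid, method = "radix")
  w <- w[ord]
  pidx <- rep.int(seq_len(np), nq)[ord]
  qidx <- (np + rep(seq_len(nq), each = np))[ord]

  parent <- seq_len(np + nq)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]] # path halving
      i <- parent[i]
    }
    i
  }
  dim0 <- logical(length(w))
  for (k in seq_along(w)) {
    ra <- find(pidx[k])
    rb <- find(qidx[k])
    if (ra != rb) {
      parent[ra] <- rb
      dim0[k] <- TRUE
    }
  }
  list(
    dimension = ifelse(dim0, 0L, 1L), value = w,
    protein_id = pid[ord], ligand_id = qid[ord]
  )
}

#' Brute-force Vietoris-Rips persistence from a distance matrix
#'
#' Independent reference implementation: builds every simplex of dimension
#' at most 2 whose pairwise distances are finite, filters by simplex
#' diameter, and runs standard boundary-matrix reduction over Z/2. Used to
#' validate [persistence()]; deliberately limited to small inputs.
#'
#' @param distance_matrix symmetric matrix of extended reals (`Inf`
#'   allowed); the diagonal is ignored.
#' @param max_points refuse matrices larger than this (reduction is
#'   exponential-ish by design).
#' @return tibble with columns `dimension` (0 or 1), `birth`, `death`
#'   (`Inf` for essential classes), sorted by (dimension, birth, death).
#' @export
persistence_oracle <- function(distance_matrix, max_points = 14) {
  n <- nrow(distance_matrix)
  stopifnot(n == ncol(distance_matrix))
  if (n > max_points) {
    abort(sprintf("oracle refuses matrices larger than %d points", max_points))
  }
  D <- distance_matrix

  # simplex inventory: vertices, finite edges, triangles with finite sides
  simp <- list()
  for (i in seq_len(n)) simp[[length(simp) + 1]] <- list(dim = 0L, v = i, filt = 0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (is.finite(D[i, j])) {
          simp[[length(simp) + 1]] <- list(dim = 1L, v = c(i, j), filt = D[i, j])
        }
      }
    }
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) {
      for (j in (i + 1):(n - 1)) {
        for (k in (j + 1):n) {
          sides <- c(D[i, j], D[i, k], D[j, k])
          if (all(is.finite(sides))) {
            simp[[length(simp) + 1]] <- list(dim = 2L, v = c(i, j, k), filt = max(sides))
          }
        }
      }
    }
  }
  filt <- vapply(simp, `[[`, numeric(1), "filt")
  dims <- vapply(simp, `[[`, integer(1), "dim")
  ord <- order(filt, dims)
  simp <- simp[ord]
  filt <- filt[ord]
  dims <- dims[ord]
  key <- vapply(simp, function(s) paste(sort(s$v), collapse = ","), character(1))
  idx_of <- setNames(seq_along(simp), key)

  m <- length(simp)
  cols <- vector("list", m) # boundary columns as sorted integer sets (Z/2)
  for (j in seq_len(m)) {
    s <- simp[[j]]
    if (s$dim == 0L) {
      cols[[j]] <- integer(0)
    } else {
      facets <- utils::combn(sort(s$v), s$dim, simplify = FALSE)
      cols[[j]] <- sort(unname(idx_of[vapply(
        facets, paste, character(1),
        collapse = ","
      )]))
    }
  }

  low_of <- integer(m) # low index -> column that has it as pivot
  pairs <- list()
  positive <- logical(m)
  for (j in seq_len(m)) {
    col <- cols[[j]]
    while (length(col) > 0 && low_of[max(col)] != 0L) {
      col <- sort(c(
        setdiff(col, cols[[low_of[max(col)]]]),
        setdiff(cols[[low_of[max(col)]]], col)
      )) # symmetric difference = Z/2 addition
    }
    if (length(col) == 0) {
      positive[j] <- TRUE
    } else {
      lo <- max(col)
      low_of[lo] <- j
      cols[[j]] <- col
      pairs[[length(pairs) + 1]] <- list(
        dimension = dims[lo], birth = filt[lo], death = filt[j]
      )
      positive[lo] <- FALSE # paired: no longer essential
    }
  }
  is_paired_birth <- logical(m)
  is_paired_birth[which(low_of != 0L)] <- TRUE
  ess <- which(positive & !is_paired_birth & dims <= 1L)
  out <- dplyr::bind_rows(
    purrr::map_dfr(pairs, as_tibble),
    tibble(dimension = dims[ess], birth = filt[ess], death = Inf)
  )
  out <- out[out$dimension <= 1L & out$death > out$birth, , drop = FALSE]
  out[order(out$dimension, out$birth, out$death), ]
}

#' Opposition-distance matrix of a point cloud
#'
#' Convenience for feeding [persistence_oracle()]: the full symmetric
#' matrix of pairwise opposition distances (Euclidean across the
#' bipartition, `Inf` within a side), protein atoms first.
#'
#' @param cloud atom table.
#' @return square numeric matrix with `Inf` off the bipartition.
#' @export
opposition_distance_matrix <- function(cloud) {
  cloud <- dplyr::arrange(cloud, dplyr::desc(.data$affiliation == "protein"))
  xyz <- as.matrix(cloud[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  same <- outer(cloud$affiliation, cloud$affiliation, "==")
  d[same] <- Inf
  diag(d) <- 0
  dimnames(d) <- list(cloud$id, cloud$id)
  d
}
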