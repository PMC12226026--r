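#' Bin grid for discretizing persistence contours
#'
#' Half-open, fixed-width bins `[start + k*width, start + (k+1)*width)`.
#' The default grid spans [0, 15) Angstrom in 0.5 Angstrom bins: wide
#' enough to contain every fingerprint bin (max upper edge 10.5) and the
#' 15 Angstrom protein-atom cutoff of the binder screen.
#'
#' @param start left edge of the first bin (Angstrom).
#' @param width bin width (Angstrom), > 0.
#' @param count number of bins, >= 1.
#' @return a list of class `bin_grid` with elements `start`, `width`,
#'   `count` and the derived `breaks` vector (length count+1).
#' @export
bin_grid <- function(start = 0, width = 0.5, count = 30) {
  stopifnot(width > 0, count >= 1)
  structure(
    list(
      start = start, width = width, count = as.integer(count),
      breaks = start + width * (0:count)
    ),
    class = "bin_grid"
  )
}

#' Build an internuclear persistence contour
#'
#' An IPC is the function obtained by summing unit-mass Gaussians of fixed
#' standard deviation centered at each critical value of one
#' (element pair, dimension) channel: deaths of 0-dimensional classes or
#' births of 1-dimensional ones. An empty critical set gives the zero
#' function.
#'
#' @param cv critical-value table from [persistence()] (columns
#'   `dimension`, `value`), or a bare numeric vector of critical values.
#' @param dimension 0 or 1; which channel to select (ignored when `cv` is
#'   a bare numeric vector).
#' @param sigma Gaussian standard deviation, Angstrom (> 0); default 0.1.
#' @param subset optional element-pair provenance, carried along.
#' @return object of class `ipc`: list with `values`, `sigma`,
#'   `dimension`, `subset`. Evaluate it with [ipc_eval()], integrate with
#'   [ipc_density()].
#' @examples
#' gamma <- build_ipc(persistence(make_square(9.75)), dimension = 1)
#' ipc_eval(gamma, 9.75) # single unit Gaussian peak: 1/(0.1*sqrt(2*pi))
#' @export
build_ipc <- function(cv, dimension = 0, sigma = 0.1, subset = NULL) {
  stopifnot(sigma > 0, dimension %in% c(0, 1))
  vals <- if (is.numeric(cv)) as.numeric(cv) else cv$value[cv$dimension == dimension]
  stopifnot(all(is.finite(vals)))
  structure(
    list(
      values = vals, sigma = sigma, dimension = as.integer(dimension),
      subset = subset
    ),
    class = "ipc"
  )
}

#' Evaluate an IPC at points
#'
#' @param ipc object from [build_ipc()].
#' @param x numeric vector of radii (Angstrom).
#' @return numeric vector: sum over critical values c of the Gaussian
#'   density N(x; c, sigma).
#' @export
ipc_eval <- function(ipc, x) {
  vapply(x, function(xi) sum(dnorm(xi, mean = ipc$values, sd = ipc$sigma)), numeric(1))
}

#' Integral of an IPC over an interval (IPC density)
#'
#' Closed form via the Gaussian CDF — no quadrature:
#' sum over critical values c of Phi((hi-c)/sigma) - Phi((lo-c)/sigma).
#' Each critical value contributes at most unit mass.
#'
#' @param ipc object from [build_ipc()].
#' @param lo,hi interval bounds, `lo < hi` (Angstrom).
#' @return non-negative scalar.
#' @export
ipc_density <- function(ipc, lo, hi) {
  stopifnot(lo < hi)
  if (length(ipc$values) == 0) {
    return(0)
  }
  sum(pnorm(hi, mean = ipc$values, sd = ipc$sigma) -
    pnorm(lo, mean = ipc$values, sd = ipc$sigma))
}

#' Discretize an IPC over a bin grid
#'
#' @param ipc object from [build_ipc()].
#' @param grid a [bin_grid()].
#' @return tibble with one row per bin: `bin`, `lo`, `hi`, `density`, plus
#'   provenance columns `dimension` and (when known) `protein_element`,
#'   `ligand_element`.
#' @export
discretize <- function(ipc, grid = bin_grid()) {
  lo <- grid$breaks[-(grid$count + 1)]
  hi <- grid$breaks[-1]
  dens <- if (length(ipc$values) == 0) {
    rep(0, grid$count)
  } else {
    # vectorized over bins and critical values
    cdf <- function(b) colSums(pnorm(
      matrix(b, nrow = length(ipc$values), ncol = grid$count, byrow = TRUE),
      mean = ipc$values, sd = ipc$sigma
    ))
    cdf(hi) - cdf(lo)
  }
  out <- tibble(bin = seq_len(grid$count), lo = lo, hi = hi, density = dens)
  out$dimension <- ipc$dimension
  if (!is.null(ipc$subset)) {
    out$protein_element <- ipc$subset[["protein_element"]]
    out$ligand_element <- ipc$subset[["ligand_element"]]
  }
  out
}

#' Gaussian mass falling outside a grid (closed form)
#'
#' @param ipc object from [build_ipc()].
#' @param grid a [bin_grid()].
#' @return scalar tail mass; grid sum + tail = number of critical values.
#' @export
ipc_tail_mass <- function(ipc, grid = bin_grid()) {
  if (length(ipc$values) == 0) {
    return(0)
  }
  a <- grid$breaks[1]
  b <- grid$breaks[grid$count + 1]
  sum(pnorm(a, ipc$values, ipc$sigma) + (1 - pnorm(b, ipc$values, ipc$sigma)))
}

canonical_feature_name <- function(pe, le, dim, lo, hi) {
  sprintf("%s_%s_%d_%g_%g", pe, le, dim, lo, hi)
}

#' Full discretized-IPC stack of a complex
#'
#' For every element-pair subset: extract the point cloud, run the
#' opposition-distance persistence sweep, and discretize the 0D and 1D
#' IPCs over the grid. With the default 36 subsets this yields 72
#' discretized IPCs (36 pairs), in a fixed order: subsets in
#' [element_pair_subsets()] order, dimension 0 before 1, bins ascending.
#' Empty point clouds contribute zero vectors, so the stack always has the
#' same shape.
#'
#' @param atoms atom table of the complex.
#' @param subsets tibble of element pairs (default the 36 standard ones).
#' @param grid a [bin_grid()].
#' @param sigma Gaussian standard deviation, Angstrom.
#' @return tibble in long form with columns `protein_element`,
#'   `ligand_element`, `dimension`, `bin`, `lo`, `hi`, `density` and
#'   canonical `feature` names `"<pelem>_<lelem>_<dim>_<lo>_<hi>"`.
#' @export
ipc_stack <- function(atoms, subsets = element_pair_subsets(),
                      grid = bin_grid(), sigma = 0.1) {
  check_atom_table(atoms)
  lo <- grid$breaks[-(grid$count + 1)]
  hi <- grid$breaks[-1]
  nb <- grid$count
  bins <- function(vals) {
    if (length(vals) == 0) {
      return(rep(0, nb))
    }
    cdf <- function(b) colSums(pnorm(
      matrix(b, nrow = length(vals), ncol = nb, byrow = TRUE),
      mean = vals, sd = sigma
    ))
    cdf(hi) - cdf(lo)
  }
  ns <- nrow(subsets)
  dens <- vector("list", 2L * ns)
  is_p <- atoms$affiliation == "protein"
  for (s in seq_len(ns)) {
    keep <- (is_p & atoms$element == subsets$protein_element[s]) |
      (!is_p & atoms$element == subsets$ligand_element[s])
    cv <- persist_core(atoms[keep, , drop = FALSE])
    dens[[2L * s - 1L]] <- bins(cv$value[cv$dimension == 0L])
    dens[[2L * s]] <- bins(cv$value[cv$dimension == 1L])
  }
  pe <- rep(subsets$protein_element, each = 2L * nb)
  le <- rep(subsets$ligand_element, each = 2L * nb)
  dm <- rep(rep(c(0L, 1L), each = nb), times = ns)
  out <- tibble(
    protein_element = pe, ligand_element = le, dimension = dm,
    bin = rep(seq_len(nb), times = 2L * ns),
    lo = rep(lo, times = 2L * ns), hi = rep(hi, times = 2L * ns),
    density = unlist(dens, use.names = FALSE)
  )
  out$feature <- canonical_feature_name(
    out$protein_element, out$ligand_element, out$dimension, out$lo, out$hi
  )
  out
}

#' Flatten one or more IPC stacks to a wide feature row
#'
#' @param stack long tibble from [ipc_stack()].
#' @param id complex identifier for the output row.
#' @return one-row tibble: `complex_id` followed by one named density
#'   column per stack entry, in stack order.
#' @export
stack_row <- function(stack, id = "complex") {
  wide <- setNames(as.list(stack$density), stack$feature)
  dplyr::bind_cols(tibble(complex_id = id), as_tibble(wide))
}
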