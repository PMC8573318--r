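#' Cardiac geometry objects
#'
#' A `cardiac_geometry` bundles everything the forward model needs to know
#' about the discrete myocardium: node coordinates (mm), a symmetric
#' k-nearest-neighbour adjacency, a weighted graph Laplacian whose rows sum
#' to zero, a set of pacing nodes that receive the stimulus current, and an
#' AHA 17-segment label per node (0 marks non-LV tissue; the synthetic
#' fixture is all-LV so labels are 1..17).
#'
#' @name cardiac_geometry
#' @keywords internal
NULL

new_cardiac_geometry <- function(node_coords, adjacency, laplacian,
                                 pacing_nodes, segment_labels) {
  geom <- list(
    node_coords = node_coords,
    adjacency = adjacency,
    laplacian = laplacian,
    pacing_nodes = as.integer(pacing_nodes),
    segment_labels = as.integer(segment_labels)
  )
  class(geom) <- "cardiac_geometry"
  geom
}

#' Number of nodes in a geometry
#' @param geom a `cardiac_geometry`
#' @return integer node count
#' @export
n_nodes <- function(geom) nrow(geom$node_coords)

#' @export
print.cardiac_geometry <- function(x, ...) {
  cat(sprintf(
    "cardiac_geometry: %d nodes, %d edges, %d pacing node(s), %d labelled segments\n",
    n_nodes(x), sum(x$adjacency > 0) / 2, length(x$pacing_nodes),
    length(unique(x$segment_labels[x$segment_labels > 0]))))
  invisible(x)
}

#' Validate geometry invariants
#'
#' Checks symmetry of the neighbour graph, zero row sums of the Laplacian,
#' non-empty pacing set and reachability of every node from the pacing set.
#'
#' @param geom a `cardiac_geometry`
#' @return `geom`, invisibly; signals an error on violation
#' @export
validate_geometry <- function(geom) {
  stopifnot(inherits(geom, "cardiac_geometry"))
  A <- geom$adjacency
  if (!isTRUE(all.equal(A, t(A), tolerance = 1e-12)))
    stop("neighbor graph must be symmetric")
  if (max(abs(rowSums(geom$laplacian))) > 1e-8)
    stop("laplacian rows must sum to zero")
  if (length(geom$pacing_nodes) < 1L)
    stop("pacing_nodes must be non-empty")
  if (any(geom$pacing_nodes < 1L | geom$pacing_nodes > n_nodes(geom)))
    stop("pacing node index out of range")
  reach <- graph_reachable(A, geom$pacing_nodes)
  if (!all(reach))
    stop(sprintf("%d node(s) unreachable from the pacing set", sum(!reach)))
  invisible(geom)
}

# breadth-first reachability over a (weighted) adjacency matrix
graph_reachable <- function(A, from) {
  n <- nrow(A)
  seen <- rep(FALSE, n)
  frontier <- unique(as.integer(from))
  seen[frontier] <- TRUE
  while (length(frontier)) {
    nb <- which(rowSums(A[, frontier, drop = FALSE] > 0) > 0)
    frontier <- nb[!seen[nb]]
    seen[frontier] <- TRUE
  }
  seen
}

#' Build a symmetric k-nearest-neighbour adjacency with Gaussian edge weights
#'
#' Edges connect each node to its `k` nearest neighbours (union
#' symmetrization). Weights are exp(-d^2 / l^2) with `l` the mean k-NN
#' distance, so that a typical edge carries weight ~ exp(-1).
#'
#' @param coords N x 3 coordinate matrix
#' @param k neighbours per node
#' @return list with `adjacency` (weighted, symmetric) and `laplacian`
#'   (L = W - diag(rowSums(W)), rows sum to zero, negative semidefinite)
#' @export
knn_graph <- function(coords, k = 6L) {
  n <- nrow(coords)
  if (k >= n) stop("k must be smaller than the node count")
  D <- as.matrix(stats::dist(coords))
  A <- matrix(0, n, n)
  knn_d <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ])
    nb <- ord[ord != i][seq_len(k)]
    A[i, nb] <- 1
    knn_d[i] <- mean(D[i, nb])
  }
  A <- pmax(A, t(A))                      # union symmetrization
  l <- mean(knn_d)
  W <- A * exp(-(D / l)^2)
  L <- W
  diag(L) <- diag(L) - rowSums(W)
  list(adjacency = W, laplacian = L)
}

#' Largest Laplacian eigenvalue (magnitude), by power iteration
#'
#' Used for the explicit-Euler diffusion stability bound
#' dt < 2 / (d_iso * lambda_max).
#'
#' @param L graph Laplacian
#' @param iters power iterations
#' @return scalar estimate of max |eigenvalue| of -L
#' @export
laplacian_lambda_max <- function(L, iters = 60L) {
  n <- nrow(L)
  x <- rep(1 / sqrt(n), n) + sin(seq_len(n))  # deterministic, non-degenerate
  x <- x / sqrt(sum(x^2))
  for (i in seq_len(iters)) {
    y <- -L %*% x
    nrm <- sqrt(sum(y^2))
    if (nrm < 1e-14) return(0)
    x <- as.numeric(y / nrm)
  }
  as.numeric(abs(crossprod(x, -L %*% x)))
}

#' Assign AHA 17-segment labels to an LV-like node cloud
#'
#' Approximate labelling by construction: the long axis (z, apex at minimum z)
#' is split into basal / mid / apical thirds plus an apical-cap tip; basal and
#' mid rings are split into circumferential sextants (segments 1-6 and 7-12),
#' the apical ring into quadrants (13-16), and the tip is segment 17.
#'
#' @param coords N x 3 coordinates, long axis along z, apex at min z
#' @return integer vector of labels in 1..17
#' @export
aha_segment_labels <- function(coords) {
  z <- coords[, 3]
  zr <- (z - min(z)) / (max(z) - min(z))    # 0 at apex, 1 at base
  ang <- atan2(coords[, 2], coords[, 1])    # (-pi, pi]
  sector <- function(a, nsec) {
    s <- floor((a + pi) / (2 * pi) * nsec) + 1
    pmin(pmax(s, 1), nsec)
  }
  lab <- integer(length(z))
  tip   <- zr < 0.08
  apical <- !tip & zr < 1 / 3
  mid    <- zr >= 1 / 3 & zr < 2 / 3
  basal  <- zr >= 2 / 3
  lab[basal]  <- sector(ang[basal], 6L)
  lab[mid]    <- 6L + sector(ang[mid], 6L)
  lab[apical] <- 12L + sector(ang[apical], 4L)
  lab[tip]    <- 17L
  lab
}

#' Generate the synthetic LV-like fixture geometry
#'
#' Nodes are placed on a half-ellipsoid shell (a prolate LV surrogate): the
#' long axis runs along z with the apex at the bottom, node placement follows
#' a deterministic spiral with seed-controlled jitter and a small radial
#' thickness. A k-NN graph, graph Laplacian, AHA labels and an apical pacing
#' set are attached.
#'
#' @param n_nodes_target number of nodes (>= 50)
#' @param k neighbours per node for the graph
#' @param long_axis half-length of the long axis (mm)
#' @param short_axis equatorial radius (mm)
#' @param wall_thickness radial jitter emulating wall thickness (mm)
#' @param n_pacing number of apical pacing nodes
#' @param seed RNG seed for jitter
#' @return a validated `cardiac_geometry`
#' @export
fixture_geometry <- function(n_nodes_target = 300L, k = 6L,
                             long_axis = 60, short_axis = 30,
                             wall_thickness = 3, n_pacing = 12L, seed = 1L) {
  if (n_nodes_target < 50L) stop("node count must be >= 50")
  rng <- local_rng(seed)
  n <- as.integer(n_nodes_target)
  # Fibonacci spiral on the lower half ellipsoid: u in (0, 1], u=0 is apex
  i <- seq_len(n)
  u <- (i - 0.5) / n
  phi <- 2 * pi * ((i * 0.6180339887498949) %% 1)
  polar <- pi / 2 * u                       # 0 at apex, pi/2 at base ring
  radial <- 1 + (rng$runif(n) - 0.5) * (wall_thickness / short_axis)
  x <- short_axis * radial * sin(polar) * cos(phi)
  y <- short_axis * radial * sin(polar) * sin(phi)
  z <- -long_axis * radial * cos(polar)
  coords <- cbind(x = x, y = y, z = z + long_axis)  # apex near z = -la -> shift
  g <- knn_graph(coords, k = k)
  labels <- aha_segment_labels(coords)
  pacing <- order(coords[, 3])[seq_len(n_pacing)]   # most apical nodes
  geom <- new_cardiac_geometry(coords, g$adjacency, g$laplacian, pacing, labels)
  validate_geometry(geom)
}

# Scoped RNG helper: draws do not disturb the caller's RNG state.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  draw <- function(fn) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fn()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(
    runif = function(n, min = 0, max = 1) draw(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) draw(function() stats::rnorm(n, mean, sd)),
    sample_int = function(n, size, replace = FALSE)
      draw(function() sample.int(n, size, replace = replace))
  )
}

#' Write / read a geometry as plain-text files
#'
#' The geometry is stored as a directory holding `nodes.csv` (x,y,z),
#' `edges.csv` (i,j,weight for i < j), `segments.csv` and `pacing.csv`.
#'
#' @param geom a `cardiac_geometry`
#' @param path directory to create/read
#' @return `read_geometry` returns a `cardiac_geometry`; `write_geometry`
#'   returns `path` invisibly
#' @export
write_geometry <- function(geom, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(x = geom$node_coords[, 1],
                              y = geom$node_coords[, 2],
                              z = geom$node_coords[, 3]),
                   file.path(path, "nodes.csv"), row.names = FALSE)
  idx <- which(upper.tri(geom$adjacency) & geom$adjacency > 0, arr.ind = TRUE)
  utils::write.csv(data.frame(i = idx[, 1], j = idx[, 2],
                              weight = geom$adjacency[idx]),
                   file.path(path, "edges.csv"), row.names = FALSE)
  utils::write.csv(data.frame(segment = geom$segment_labels),
                   file.path(path, "segments.csv"), row.names = FALSE)
  utils::write.csv(data.frame(node = geom$pacing_nodes),
                   file.path(path, "pacing.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  nodes <- as.matrix(utils::read.csv(file.path(path, "nodes.csv")))
  edges <- utils::read.csv(file.path(path, "edges.csv"))
  n <- nrow(nodes)
  W <- matrix(0, n, n)
  W[cbind(edges$i, edges$j)] <- edges$weight
  W <- pmax(W, t(W))
  L <- W
  diag(L) <- diag(L) - rowSums(W)
  segs <- utils::read.csv(file.path(path, "segments.csv"))$segment
  pac <- utils::read.csv(file.path(path, "pacing.csv"))$node
  validate_geometry(new_cardiac_geometry(nodes, W, L, pac, segs))
}
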