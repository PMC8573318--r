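#' Random region growing of injured tissue
#'
#' Grows a connected injured region one node at a time: at each step the
#' five exterior nodes nearest (Euclidean distance to the closest member)
#' to the current region form the candidate set, and one is drawn uniformly.
#' Ties in distance are broken by node index. The candidate set is
#' restricted to exterior nodes adjacent (in the neighbour graph) to the
#' region so growth respects connectivity.
#'
#' @param geom a `cardiac_geometry`
#' @param seed_node starting node index
#' @param target_size desired region size (1 <= target_size <= n nodes)
#' @param knn candidate-set size (default 5)
#' @param rng_seed RNG seed
#' @return integer vector of member node indices (length `target_size`)
#' @export
region_grow <- function(geom, seed_node, target_size, knn = 5L, rng_seed = 1L) {
  n <- n_nodes(geom)
  stopifnot(seed_node >= 1L, seed_node <= n, knn >= 1L,
            target_size >= 1L, target_size <= n)
  rng <- local_rng(rng_seed)
  coords <- geom$node_coords
  adj <- geom$adjacency > 0
  member <- rep(FALSE, n)
  member[seed_node] <- TRUE
  # distance from each exterior node to the region (min over members),
  # maintained incrementally as nodes join
  dist_to_region <- sqrt(rowSums(sweep(coords, 2, coords[seed_node, ])^2))
  frontier <- adj[, seed_node]
  size <- 1L
  while (size < target_size) {
    cand <- which(frontier & !member)
    if (!length(cand))
      stop(sprintf("region growth stuck at size %d: component exhausted", size))
    ord <- order(dist_to_region[cand], cand)   # ties broken by node index
    cand <- cand[ord[seq_len(min(knn, length(cand)))]]
    pick <- cand[rng$sample_int(length(cand), 1L)]
    member[pick] <- TRUE
    size <- size + 1L
    d_new <- sqrt(rowSums(sweep(coords, 2, coords[pick, ])^2))
    dist_to_region <- pmin(dist_to_region, d_new)
    frontier <- frontier | adj[, pick]
  }
  which(member)
}

#' Binary training excitability field
#'
#' theta = 0.5 on the injured set, 0.15 elsewhere, plus independent
#' uniform noise on [0, 0.001]. The noise amplitude cannot move a node
#' across classes; injured nodes may exceed the nominal 0.5 prior bound by
#' at most 0.001, which the simulator tolerates.
#'
#' @param geom a `cardiac_geometry`
#' @param injured integer vector of injured node indices (may be empty)
#' @param rng_seed RNG seed for the noise
#' @return numeric excitability field of length n_nodes(geom)
#' @export
make_training_field <- function(geom, injured, rng_seed = 1L) {
  n <- n_nodes(geom)
  if (length(injured) && any(injured < 1L | injured > n))
    stop("injured index out of range")
  rng <- local_rng(rng_seed)
  theta <- rep(0.15, n)
  theta[injured] <- 0.5
  theta + rng$runif(n, 0, 0.001)
}

#' AHA-segment test excitability field
#'
#' theta = `severity` on nodes whose AHA label is in `segments`, 0.15
#' elsewhere, plus uniform [0, 0.001] noise. Severities
#' follow the graded protocol 0.40 / 0.45 / 0.50; training fields only ever
#' use 0.5, so severities below 0.5 probe generalization of the generative
#' model to unseen abnormal values.
#'
#' @param geom a `cardiac_geometry`
#' @param segments AHA segment ids (subset of 1..17), non-empty
#' @param severity abnormal excitability, one of 0.40, 0.45, 0.50
#' @param rng_seed RNG seed for the noise
#' @return numeric excitability field
#' @export
make_aha_test_case <- function(geom, segments, severity, rng_seed = 1L) {
  if (!length(segments) || any(!segments %in% 1:17))
    stop("segments must be a non-empty subset of 1..17")
  if (!severity %in% c(0.40, 0.45, 0.50))
    stop("severity must be one of 0.40, 0.45, 0.50")
  rng <- local_rng(rng_seed)
  theta <- rep(0.15, n_nodes(geom))
  theta[geom$segment_labels %in% segments] <- severity
  theta + rng$runif(length(theta), 0, 0.001)
}

#' Generate a training corpus by random region growing
#'
#' Draws `n_fields` binary injured/healthy fields. Per field, the seed node
#' is uniform over nodes and the region size uniform over
#' `round(size_range * n_nodes)`. All per-field seeds derive from
#' `master_seed`, making the corpus bit-reproducible.
#'
#' @param geom a `cardiac_geometry`
#' @param n_fields corpus size (default 10000)
#' @param size_range region size range as a fraction of node count
#' @param knn candidate-set size for growth
#' @param master_seed master RNG seed
#' @return a `training_corpus`: `fields` (n_fields x n_nodes matrix) and
#'   `provenance` data frame (seed_node, target_size, rng_seed per field)
#' @export
make_corpus <- function(geom, n_fields = 10000L, size_range = c(0.02, 0.40),
                        knn = 5L, master_seed = 1L) {
  stopifnot(n_fields >= 1L, size_range[1] > 0, size_range[2] <= 1)
  n <- n_nodes(geom)
  rng <- local_rng(master_seed)
  seed_nodes <- rng$sample_int(n, n_fields, replace = TRUE)
  lo <- max(1L, as.integer(round(size_range[1] * n)))
  hi <- max(lo, as.integer(round(size_range[2] * n)))
  sizes <- lo + rng$sample_int(hi - lo + 1L, n_fields, replace = TRUE) - 1L
  sub_seeds <- rng$sample_int(.Machine$integer.max - 1L, n_fields, replace = TRUE)
  fields <- matrix(0, n_fields, n)
  prov <- data.frame(seed_node = seed_nodes, target_size = sizes,
                     rng_seed = sub_seeds)
  for (i in seq_len(n_fields)) {
    reg <- region_grow(geom, seed_nodes[i], sizes[i], knn = knn,
                       rng_seed = sub_seeds[i])
    fields[i, ] <- make_training_field(geom, reg, rng_seed = sub_seeds[i])
  }
  corpus <- list(fields = fields, provenance = prov)
  class(corpus) <- "training_corpus"
  corpus
}

#' @export
print.training_corpus <- function(x, ...) {
  cat(sprintf("training_corpus: %d fields x %d nodes, region sizes %d..%d\n",
              nrow(x$fields), ncol(x$fields),
              min(x$provenance$target_size), max(x$provenance$target_size)))
  invisible(x)
}

#' Write / read a corpus as CSV + JSON
#' @param corpus a `training_corpus`
#' @param path directory
#' @return `path` invisibly; `read_corpus` returns a `training_corpus`
#' @export
write_corpus <- function(corpus, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(corpus$fields, file.path(path, "theta.csv"),
                   row.names = FALSE)
  jsonlite::write_json(corpus$provenance, file.path(path, "provenance.json"),
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  fields <- as.matrix(utils::read.csv(file.path(path, "theta.csv")))
  dimnames(fields) <- NULL
  prov <- as.data.frame(jsonlite::read_json(file.path(path, "provenance.json"),
                                            simplifyVector = TRUE))
  corpus <- list(fields = fields, provenance = prov)
  class(corpus) <- "training_corpus"
  corpus
}
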