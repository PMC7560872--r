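#' Mean k-nearest-neighbour distance of one sample
#'
#' `kNN(i, k)` = mean of the distances from sample `i` to its `k` nearest
#' other samples. Ties at the k-th neighbour are broken by lower sample
#' index, so exactly `k` neighbours enter the mean and the result is
#' deterministic.
#'
#' @param D symmetric distance matrix.
#' @param i sample index.
#' @param k neighbourhood size, `1 <= k <= n - 1`.
#' @return scalar mean distance.
#' @export
knn_distance <- function(D, i, k) {
  n <- nrow(D)
  if (k < 1 || k > n - 1) stop("k must be in [1, n - 1], got ", k)
  d <- D[i, -i]
  idx <- seq_len(n)[-i]
  ord <- order(d, idx)
  mean(d[ord[seq_len(k)]])
}

#' Default kNN neighbourhood size
#'
#' 10% of the number of samples, rounded to the nearest integer (at least
#' 1) — the convention used throughout for density estimation.
#'
#' @param n_samples number of samples.
#' @return integer k.
#' @export
default_k <- function(n_samples) max(1L, as.integer(round(0.10 * n_samples)))

#' Per-vertex density of a Mapper graph
#'
#' For a vertex V holding n samples, the inverse density is
#' \deqn{D_{inv}(V) = \sum_{i \in V} kNN(i, k) / n^2,} and the density is
#' `D(V) = 1 / D_inv(V)`. The n^2 denominator compensates for differing
#' vertex sizes. kNN distances are computed over the full sample set. A
#' vertex whose members are all mutual duplicates has `D_inv = 0`; its
#' density is recorded as `Inf` and flagged.
#'
#' @param g a `mapper_graph`.
#' @param D distance matrix over all samples.
#' @param k neighbourhood size; default `default_k(nrow(D))`.
#' @return data frame with one row per vertex: `vertex`, `n`, `d_inv`,
#'   `density`, `degenerate`.
#' @export
vertex_density <- function(g, D, k = default_k(nrow(D))) {
  stopifnot(inherits(g, "mapper_graph"))
  n_all <- nrow(D)
  if (k < 1 || k > n_all - 1) stop("k must be in [1, n - 1], got ", k)
  knn <- vapply(seq_len(n_all), function(i) knn_distance(D, i, k), numeric(1))
  rows <- lapply(seq_along(g$vertices), function(vi) {
    members <- g$vertices[[vi]]$members
    n <- length(members)
    d_inv <- sum(knn[members]) / n^2
    data.frame(vertex = g$vertices[[vi]]$id, n = n, d_inv = d_inv,
               density = if (d_inv > 0) 1 / d_inv else Inf,
               degenerate = d_inv == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$degenerate))
    warning(sum(out$degenerate),
            " vertex/vertices with zero inverse density (duplicate samples);",
            " density set to Inf")
  out
}

# adjacency list over mapper vertices (undirected)
.adjacency <- function(g) {
  nv <- length(g$vertices)
  adj <- vector("list", nv)
  if (nrow(g$edges))
    for (r in seq_len(nrow(g$edges))) {
      u <- g$edges[r, 1]; v <- g$edges[r, 2]
      adj[[u]] <- c(adj[[u]], v)
      adj[[v]] <- c(adj[[v]], u)
    }
  adj
}

#' Local density maxima of a Mapper graph
#'
#' A vertex is a local maximum iff its density is at least that of every
#' neighbour, and any neighbours it ties with are themselves maxima
#' (equivalently: its equal-density plateau has no member with a
#' higher-density neighbour). Isolated vertices are maxima.
#'
#' @param g a `mapper_graph`.
#' @param dens data frame from [vertex_density()] (or any vector-like with
#'   densities in vertex order).
#' @return integer vector of maximal vertex indices.
#' @export
find_local_maxima <- function(g, dens) {
  d <- if (is.data.frame(dens)) dens$density else as.numeric(dens)
  nv <- length(g$vertices)
  stopifnot(length(d) == nv)
  adj <- .adjacency(g)
  # "weak" candidates: no strictly higher neighbour
  ok <- vapply(seq_len(nv), function(v)
    length(adj[[v]]) == 0L || all(d[adj[[v]]] <= d[v]), logical(1))
  # plateaus: components of the subgraph of equal-density edges
  plateau <- seq_len(nv)
  repeat {
    changed <- FALSE
    for (v in seq_len(nv)) for (u in adj[[v]]) {
      if (d[u] == d[v] && plateau[u] != plateau[v]) {
        lab <- min(plateau[u], plateau[v])
        plateau[plateau == plateau[u] | plateau == plateau[v]] <- lab
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  is_max <- vapply(seq_len(nv), function(v)
    all(ok[plateau == plateau[v]]), logical(1))
  which(is_max)
}

#' Orient the Mapper graph along the density gradient
#'
#' Each undirected edge becomes an arc from the lower-density endpoint to
#' the higher-density one; equal-density edges become a pair of opposite
#' arcs, preserving plateau connectivity.
#'
#' @inheritParams find_local_maxima
#' @return 2-column integer matrix of arcs (from, to).
#' @export
orient_graph <- function(g, dens) {
  d <- if (is.data.frame(dens)) dens$density else as.numeric(dens)
  if (nrow(g$edges) == 0) return(matrix(integer(0), ncol = 2))
  arcs <- list()
  for (r in seq_len(nrow(g$edges))) {
    u <- g$edges[r, 1]; v <- g$edges[r, 2]
    if (d[u] < d[v]) arcs[[length(arcs) + 1L]] <- c(u, v)
    else if (d[v] < d[u]) arcs[[length(arcs) + 1L]] <- c(v, u)
    else { arcs[[length(arcs) + 1L]] <- c(u, v)
           arcs[[length(arcs) + 1L]] <- c(v, u) }
  }
  do.call(rbind, arcs)
}

#' Assign Mapper vertices to metastable states
#'
#' Maxima connected through maxima-only paths in the undirected graph are
#' merged into one state. Every other vertex is assigned to the state whose
#' maxima set it can reach by a uniquely shortest directed (density-
#' ascending) path: the hop-count distance from the vertex to the nearest
#' maximum of each state is compared, and the vertex joins the strictly
#' closest state. Vertices equidistant to two or more states, or unable to
#' reach any maximum, are labelled `"unassigned"` (unstable regions).
#'
#' @param g a `mapper_graph`.
#' @param arcs directed arcs from [orient_graph()].
#' @param maxima integer vertex indices from [find_local_maxima()].
#' @return An object of class `state_partition`: list with `state_of`
#'   (character per vertex: `"1"`, `"2"`, ... or `"unassigned"`), `maxima`,
#'   `n_states`, `dist_to_state` (vertex x state hop counts).
#' @export
assign_states <- function(g, arcs, maxima) {
  nv <- length(g$vertices)
  if (length(maxima) == 0L) stop("no maxima supplied")
  # merge maxima connected through maxima-only undirected paths
  madj <- .adjacency(g)
  state_of_max <- stats::setNames(seq_along(maxima), maxima)
  lab <- seq_along(maxima)
  is_max <- logical(nv); is_max[maxima] <- TRUE
  repeat {
    changed <- FALSE
    for (mi in seq_along(maxima)) {
      v <- maxima[mi]
      for (u in madj[[v]]) if (is_max[u]) {
        ui <- match(u, maxima)
        if (lab[ui] != lab[mi]) {
          l <- min(lab[ui], lab[mi])
          lab[lab == lab[ui] | lab == lab[mi]] <- l
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  states <- match(lab, sort(unique(lab)))  # consecutive 1..S
  n_states <- max(states)
  # reverse-BFS from each state's maxima set: hop distance vertex -> state
  radj <- vector("list", nv)  # reversed arcs: to -> from
  if (!is.null(arcs) && nrow(arcs))
    for (r in seq_len(nrow(arcs)))
      radj[[arcs[r, 2]]] <- c(radj[[arcs[r, 2]]], arcs[r, 1])
  dist_to_state <- matrix(Inf, nv, n_states)
  for (s in seq_len(n_states)) {
    src <- maxima[states == s]
    dist <- rep(Inf, nv); dist[src] <- 0
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in radj[[v]]) if (dist[u] > dist[v] + 1) {
        dist[u] <- dist[v] + 1
        queue <- c(queue, u)
      }
    }
    dist_to_state[, s] <- dist
  }
  state_of <- rep("unassigned", nv)
  state_of[maxima] <- as.character(states)
  for (v in seq_len(nv)) {
    if (is_max[v]) next
    dmin <- min(dist_to_state[v, ])
    if (!is.finite(dmin)) next
    winners <- which(dist_to_state[v, ] == dmin)
    if (length(winners) == 1L) state_of[v] <- as.character(winners)
  }
  structure(list(state_of = state_of,
                 maxima = maxima,
                 n_states = n_states,
                 dist_to_state = dist_to_state),
            class = "state_partition")
}

#' @export
print.state_partition <- function(x, ...) {
  cat("state_partition: ", x$n_states, " state(s), ",
      sum(x$state_of == "unassigned"), " unassigned vertex/vertices of ",
      length(x$state_of), "\n", sep = "")
  invisible(x)
}

#' Full density-based state assignment
#'
#' Convenience wrapper: density, maxima, orientation, assignment.
#'
#' @inheritParams vertex_density
#' @return list with `density` (data frame), `maxima`, `arcs`, `partition`.
#' @export
partition_states <- function(g, D, k = default_k(nrow(D))) {
  dens <- vertex_density(g, D, k)
  maxima <- find_local_maxima(g, dens)
  arcs <- orient_graph(g, dens)
  part <- assign_states(g, arcs, maxima)
  list(density = dens, maxima = maxima, arcs = arcs, partition = part)
}

#' Per-sample state label sets
#'
#' A sample inherits the union of the state labels of every vertex that
#' contains it (samples in overlapping bins may belong to several vertices
#' and hence several states); `"unassigned"` counts as one distinct label.
#'
#' @param g a `mapper_graph`.
#' @param part a `state_partition`.
#' @return named list: for each covered sample (by ID if available, else
#'   index), the character vector of its state labels.
#' @export
sample_states <- function(g, part) {
  stopifnot(inherits(part, "state_partition"))
  out <- list()
  for (vi in seq_along(g$vertices)) {
    lab <- part$state_of[vi]
    for (s in g$vertices[[vi]]$members) {
      key <- if (!is.null(g$sample_ids)) g$sample_ids[s] else as.character(s)
      out[[key]] <- union(out[[key]], lab)
    }
  }
  lapply(out, function(x) sort(x))
}

#' Majority state per sample
#'
#' The single most frequent state label among the vertices containing each
#' sample ("unassigned" loses ties to real states; remaining ties go to the
#' lexicographically smallest label). Useful for benchmarking recovered
#' states against ground truth.
#'
#' @inheritParams sample_states
#' @return named character vector of one label per covered sample.
#' @export
sample_majority_state <- function(g, part) {
  votes <- list()
  for (vi in seq_along(g$vertices)) {
    lab <- part$state_of[vi]
    for (s in g$vertices[[vi]]$members) {
      key <- if (!is.null(g$sample_ids)) g$sample_ids[s] else as.character(s)
      votes[[key]] <- c(votes[[key]], lab)
    }
  }
  vapply(votes, function(v) {
    tab <- table(v)
    real <- tab[names(tab) != "unassigned"]
    if (length(real)) names(real)[which.max(real)]
    else "unassigned"
  }, character(1))
}

#' Write the state partition as TSV
#'
#' Vertex-level table (`vertex_id`, `n`, `density`, `is_maximum`, `state`)
#' and optionally a sample-level table (`sample_id`, semicolon-joined
#' `states`).
#'
#' @param g a `mapper_graph`.
#' @param dens data frame from [vertex_density()].
#' @param part a `state_partition`.
#' @param path output TSV for the vertex table.
#' @param sample_path optional output TSV for the sample table.
#' @return `path`, invisibly.
#' @export
write_state_partition <- function(g, dens, part, path, sample_path = NULL) {
  is_max <- seq_along(g$vertices) %in% part$maxima
  df <- data.frame(vertex_id = dens$vertex, n = dens$n,
                   density = dens$density, is_maximum = is_max,
                   state = part$state_of, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_path)) {
    ss <- sample_states(g, part)
    sdf <- data.frame(sample_id = names(ss),
                      states = vapply(ss, paste, character(1),
                                      collapse = ";"),
                      stringsAsFactors = FALSE)
    utils::write.table(sdf, sample_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
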