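#' Mapper hyperparameters
#'
#' Bundles the cover and clustering hyperparameters of the Mapper graph:
#' the number of overlapping intervals per filter dimension, the percent
#' overlap between consecutive intervals, and the number of equal-width
#' histogram bins used by the local-clustering cutoff. Typical published
#' settings for microbiome phase spaces range from (15, 15) intervals at 70%
#' overlap to (30, 30) at 50%, with 10 histogram bins.
#'
#' @param n_intervals integer vector of length 1 or 2: intervals per filter
#'   dimension (recycled to 2).
#' @param overlap_pct percent overlap between consecutive intervals, in
#'   (0, 100).
#' @param n_hist_bins histogram bins for the local-clustering cutoff
#'   (>= 2; default 10).
#' @param seed integer seed used only for graph layout.
#' @return An object of class `mapper_config`.
#' @export
mapper_config <- function(n_intervals = c(10, 10), overlap_pct = 50,
                          n_hist_bins = 10, seed = 1L) {
  n_intervals <- as.integer(rep_len(n_intervals, 2L))
  if (any(n_intervals < 1)) stop("n_intervals must be >= 1")
  if (!(overlap_pct > 0 && overlap_pct < 100))
    stop("overlap_pct must be in (0, 100)")
  if (n_hist_bins < 2) stop("n_hist_bins must be >= 2")
  structure(list(n_intervals = n_intervals,
                 overlap_pct = as.numeric(overlap_pct),
                 n_hist_bins = as.integer(n_hist_bins),
                 seed = as.integer(seed)),
            class = "mapper_config")
}

#' @export
print.mapper_config <- function(x, ...) {
  cat("mapper_config: intervals (", x$n_intervals[1], ", ", x$n_intervals[2],
      "), overlap ", x$overlap_pct, "%, ", x$n_hist_bins,
      " histogram bins\n", sep = "")
  invisible(x)
}

#' Principal coordinate (classical MDS) filter
#'
#' Embeds a distance matrix by double-centering \eqn{-d^2/2},
#' eigendecomposing, and scaling the top eigenvectors by the square roots of
#' their (positive) eigenvalues. Components are sorted by descending
#' eigenvalue; negative eigenvalues (possible for non-Euclidean metrics such
#' as sqrt-JSD) are discarded. Sign convention: within each component the
#' largest-magnitude loading is made positive, so the embedding is
#' deterministic.
#'
#' @param D symmetric distance matrix.
#' @param n_components number of coordinates requested (default 2).
#' @return numeric matrix (samples x components) with sample IDs as
#'   rownames and an `eigenvalues` attribute. If fewer positive eigenvalues
#'   exist than requested, the available ones are returned with a warning.
#' @export
pcoa_filter <- function(D, n_components = 2L) {
  validate_distance_matrix(D)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 samples for PCoA")
  # Gower centering: B = (I - 11'/n) A (I - 11'/n), A = -d^2/2
  A <- -0.5 * D^2
  B <- A - outer(rowMeans(A), rep(1, n)) - outer(rep(1, n), colMeans(A)) +
    mean(A)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(e$values > max(e$values) * 1e-12 & e$values > 0)
  keep <- utils::head(pos, n_components)
  if (length(keep) < n_components)
    warning("only ", length(keep), " positive eigenvalue(s) available; ",
            "returning ", length(keep), " component(s)")
  X <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), nrow = length(keep))
  for (j in seq_len(ncol(X))) {
    i <- which.max(abs(X[, j]))
    if (X[i, j] < 0) X[, j] <- -X[, j]
  }
  rownames(X) <- rownames(D)
  colnames(X) <- paste0("PCo", seq_len(ncol(X)))
  attr(X, "eigenvalues") <- e$values[keep]
  X
}

#' Rank transform of filter values
#'
#' Ordinal ranks 1..n with ties broken by input order, giving a
#' deterministic, uniformly spread filter.
#'
#' @param values numeric vector of finite filter values.
#' @return integer ranks, same length.
#' @export
rank_transform <- function(values) {
  if (any(!is.finite(values))) stop("filter values must be finite")
  rank(values, ties.method = "first")
}

#' Build the overlapping 2D cover over filter values
#'
#' Per dimension, `n_intervals` closed intervals of equal length L span the
#' observed rank range, with consecutive starts spaced
#' `L * (1 - overlap_pct/100)`; the last interval is clamped to end at the
#' maximum. 2D bins are the Cartesian product; a sample joins every bin whose
#' two intervals both contain its rank pair. Empty bins are dropped.
#'
#' @param f numeric matrix (samples x 2) of filter values (typically ranks).
#' @param config a [mapper_config()].
#' @return list of bins; each bin has `id`, `members` (integer sample
#'   indices) and `intervals` (2x2 matrix of \[lo, hi\] per dimension).
#' @export
make_cover <- function(f, config) {
  stopifnot(inherits(config, "mapper_config"))
  f <- as.matrix(f)
  if (ncol(f) != 2) stop("expected 2 filter dimensions")
  ivals <- lapply(1:2, function(dim)
    .cover_intervals(range(f[, dim]), config$n_intervals[dim],
                     config$overlap_pct))
  bins <- list()
  for (i in seq_len(nrow(ivals[[1]]))) {
    in1 <- f[, 1] >= ivals[[1]][i, 1] & f[, 1] <= ivals[[1]][i, 2]
    for (j in seq_len(nrow(ivals[[2]]))) {
      members <- which(in1 &
                       f[, 2] >= ivals[[2]][j, 1] &
                       f[, 2] <= ivals[[2]][j, 2])
      if (length(members) == 0L) next
      bins[[length(bins) + 1L]] <- list(
        id = sprintf("bin_%d_%d", i, j),
        members = members,
        intervals = rbind(ivals[[1]][i, ], ivals[[2]][j, ]))
    }
  }
  bins
}

# Equal-length closed intervals over `rng`: n intervals of length
# L = span / (1 + (n-1)(1-g)), starts spaced L(1-g); last clamped to max.
.cover_intervals <- function(rng, n, overlap_pct) {
  span <- diff(rng)
  if (n == 1L || span == 0) return(matrix(rng, nrow = n, ncol = 2,
                                          byrow = TRUE))
  g <- overlap_pct / 100
  L <- span / (1 + (n - 1) * (1 - g))
  starts <- rng[1] + (seq_len(n) - 1) * L * (1 - g)
  ends <- pmin(starts + L, rng[2])
  ends[n] <- rng[2]
  cbind(starts, ends, deparse.level = 0)
}

#' Cluster the samples of one cover bin
#'
#' Single-linkage hierarchical clustering on the within-bin distance
#' sub-matrix. The dendrogram merge heights are histogrammed into
#' `n_hist_bins` equal-width bins spanning \[0, max within-bin pairwise
#' distance\]; the cutoff is the lower edge of the first empty histogram bin
#' that follows a non-empty one (the "separation of length scales" gap). If
#' no such gap exists the bin is a single cluster. Bins with fewer than 3
#' members form one cluster.
#'
#' @param bin_members integer sample indices of the bin.
#' @param D full distance matrix.
#' @param n_hist_bins number of histogram bins (default 10).
#' @return list of integer vectors (disjoint clusters, covering the bin).
#' @export
local_cluster <- function(bin_members, D, n_hist_bins = 10L) {
  m <- length(bin_members)
  if (m == 0L) stop("empty bin")
  if (m < 3L) return(list(bin_members))
  sub <- D[bin_members, bin_members, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(sub), method = "single")
  cutoff <- .first_gap_cutoff(hc$height, max(sub), n_hist_bins)
  if (is.na(cutoff)) return(list(bin_members))
  grp <- stats::cutree(hc, h = cutoff)
  unname(split(bin_members, grp))
}

# First-empty-histogram-bin cutoff over merge heights. Returns NA when no
# empty bin follows a non-empty one (no separation of scales).
.first_gap_cutoff <- function(heights, dmax, n_hist_bins) {
  if (dmax <= 0) return(NA_real_)
  edges <- seq(0, dmax, length.out = n_hist_bins + 1L)
  counts <- graphics::hist(heights, breaks = edges, plot = FALSE)$counts
  seen <- FALSE
  for (b in seq_along(counts)) {
    if (counts[b] > 0) seen <- TRUE
    else if (seen) return(edges[b])
  }
  NA_real_
}

#' Build the nerve graph from per-bin clusters
#'
#' One vertex per local cluster; an edge joins two vertices iff they share
#' at least one sample.
#'
#' @param clusters_per_bin list of lists: for each bin, its clusters (integer
#'   sample-index vectors) and the bin id. Accepts either the output shape
#'   `list(list(id=, clusters=))` or a flat list of clusters (then bin ids
#'   are synthesized).
#' @param sample_ids optional character vector mapping indices to IDs.
#' @return An object of class `mapper_graph`: list with `vertices` (list of
#'   `{id, members, bin}`), `edges` (2-column integer matrix of vertex
#'   indices), `n_samples`, `sample_ids`.
#' @export
build_nerve <- function(clusters_per_bin, sample_ids = NULL) {
  vertices <- list()
  for (b in clusters_per_bin) {
    if (is.list(b) && !is.null(b$clusters)) {
      cl <- b$clusters; bid <- b$id
    } else {
      cl <- list(b); bid <- sprintf("bin_%d", length(vertices) + 1L)
    }
    for (members in cl) {
      if (length(members) == 0L) next
      vertices[[length(vertices) + 1L]] <-
        list(id = sprintf("v%d", length(vertices) + 1L),
             members = sort(unique(as.integer(members))),
             bin = bid)
    }
  }
  nv <- length(vertices)
  # sparse intersection test: index vertices by member sample
  by_sample <- list()
  for (v in seq_len(nv))
    for (s in vertices[[v]]$members)
      by_sample[[as.character(s)]] <- c(by_sample[[as.character(s)]], v)
  pairs <- unique(do.call(rbind, lapply(by_sample, function(vs) {
    if (length(vs) < 2) return(NULL)
    t(utils::combn(sort(vs), 2))
  })))
  if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 2)
  all_samples <- sort(unique(unlist(lapply(vertices, `[[`, "members"))))
  structure(list(vertices = vertices,
                 edges = pairs,
                 n_samples = length(all_samples),
                 sample_ids = sample_ids),
            class = "mapper_graph")
}

#' @export
print.mapper_graph <- function(x, ...) {
  cat("mapper_graph: ", length(x$vertices), " vertices, ",
      nrow(x$edges), " edges, ", x$n_samples, " samples covered\n", sep = "")
  invisible(x)
}

#' Run the full Mapper construction
#'
#' PCoA filter on the distance matrix, rank transform of the first two
#' principal coordinates, overlapping 2D cover, per-bin single-linkage
#' clustering with the first-empty-histogram-bin cutoff, and the nerve
#' graph. Deterministic given `D` and `config`.
#'
#' @param D symmetric distance matrix with sample IDs.
#' @param config a [mapper_config()].
#' @return A `mapper_graph` (see [build_nerve()]); carries the config and
#'   filter values as attributes.
#' @export
run_mapper <- function(D, config = mapper_config()) {
  validate_distance_matrix(D)
  X <- pcoa_filter(D, 2L)
  if (ncol(X) < 2)  # degenerate geometry: duplicate the single coordinate
    X <- cbind(X, X[, 1])
  f <- cbind(rank_transform(X[, 1]), rank_transform(X[, 2]))
  bins <- make_cover(f, config)
  clusters_per_bin <- lapply(bins, function(b)
    list(id = b$id,
         clusters = local_cluster(b$members, D, config$n_hist_bins)))
  g <- build_nerve(clusters_per_bin, sample_ids = rownames(D))
  attr(g, "config") <- config
  attr(g, "filter") <- f
  g
}

#' Hyperparameter heuristic report
#'
#' Checks the published rule of thumb for Mapper hyperparameters: the
#' largest vertex should hold no more than ~10% of the data points, and the
#' number of singleton connected components should be minimized (reported,
#' not thresholded).
#'
#' @param g a `mapper_graph`.
#' @param n_samples total number of data points in the data set.
#' @return list with `largest_vertex_fraction`, `n_singleton_components`,
#'   `pass`.
#' @export
check_hyperparameters <- function(g, n_samples) {
  stopifnot(inherits(g, "mapper_graph"))
  sizes <- vapply(g$vertices, function(v) length(v$members), integer(1))
  largest <- if (length(sizes)) max(sizes) else 0L
  comp <- .components(g)
  singleton <- if (length(comp))
    sum(vapply(split(seq_along(comp), comp), length, integer(1)) == 1L)
  else 0L
  list(largest_vertex_fraction = largest / n_samples,
       n_singleton_components = singleton,
       pass = largest <= ceiling(0.10 * n_samples))
}

# connected-component labels over vertices (undirected)
.components <- function(g) {
  nv <- length(g$vertices)
  if (nv == 0L) return(integer(0))
  ig <- mapper_to_igraph(g, directed = FALSE)
  igraph::components(ig)$membership
}

#' Convert a mapper_graph to an igraph object
#'
#' @param g a `mapper_graph`.
#' @param directed if `TRUE`, `arcs` must be supplied.
#' @param arcs 2-column matrix of directed arcs (from, to) when
#'   `directed = TRUE`.
#' @return an `igraph` graph whose vertex names are the mapper vertex ids.
#' @export
mapper_to_igraph <- function(g, directed = FALSE, arcs = NULL) {
  nv <- length(g$vertices)
  ids <- vapply(g$vertices, `[[`, character(1), "id")
  if (directed) {
    el <- if (is.null(arcs) || nrow(arcs) == 0) matrix(character(0), ncol = 2)
          else cbind(ids[arcs[, 1]], ids[arcs[, 2]])
  } else {
    el <- if (nrow(g$edges) == 0) matrix(character(0), ncol = 2)
          else cbind(ids[g$edges[, 1]], ids[g$edges[, 2]])
  }
  ig <- igraph::graph_from_edgelist(el, directed = directed)
  missing <- setdiff(ids, igraph::V(ig)$name)
  if (length(missing)) ig <- igraph::add_vertices(ig, length(missing),
                                                  name = missing)
  igraph::permute(ig, match(igraph::V(ig)$name, ids))
}

#' Export a Mapper graph to GraphML or JSON
#'
#' Vertex attributes: semicolon-joined member sample IDs, member count, bin
#' id, plus optional density/state columns. Graph attributes record the
#' Mapper configuration.
#'
#' @param g a `mapper_graph`.
#' @param path output file; format chosen by extension (`.graphml` /
#'   `.json`).
#' @param density optional numeric per-vertex density.
#' @param states optional per-vertex state labels (character).
#' @return `path`, invisibly.
#' @export
export_mapper_graph <- function(g, path, density = NULL, states = NULL) {
  ids <- vapply(g$vertices, `[[`, character(1), "id")
  members_chr <- vapply(g$vertices, function(v) {
    s <- if (!is.null(g$sample_ids)) g$sample_ids[v$members] else v$members
    paste(s, collapse = ";")
  }, character(1))
  sizes <- vapply(g$vertices, function(v) length(v$members), integer(1))
  bins <- vapply(g$vertices, `[[`, character(1), "bin")
  cfg <- attr(g, "config")
  if (grepl("\\.json$", path)) {
    obj <- list(
      config = if (is.null(cfg)) NULL else unclass(cfg),
      vertices = data.frame(id = ids, members = members_chr, size = sizes,
                            bin = bins, stringsAsFactors = FALSE),
      edges = if (nrow(g$edges)) data.frame(from = ids[g$edges[, 1]],
                                            to = ids[g$edges[, 2]])
              else data.frame(from = character(0), to = character(0)))
    if (!is.null(density)) obj$vertices$density <- density
    if (!is.null(states)) obj$vertices$state <- states
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    ig <- mapper_to_igraph(g)
    igraph::V(ig)$members <- members_chr
    igraph::V(ig)$size <- sizes
    igraph::V(ig)$bin <- bins
    if (!is.null(density)) igraph::V(ig)$density <- density
    if (!is.null(states)) igraph::V(ig)$state <- as.character(states)
    if (!is.null(cfg)) {
      ig <- igraph::set_graph_attr(ig, "n_intervals",
                                   paste(cfg$n_intervals, collapse = ","))
      ig <- igraph::set_graph_attr(ig, "overlap_pct", cfg$overlap_pct)
      ig <- igraph::set_graph_attr(ig, "n_hist_bins", cfg$n_hist_bins)
    }
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}
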