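# Independent oracles and fixture builders. These deliberately use naive,
# scalar implementations so they stay independent of the package's code
# paths.

# scalar Jensen-Shannon distance via explicit KL divergences (base 2)
oracle_js <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log2(a[i] / b[i])
    s
  }
  sqrt(0.5 * kl(p, m) + 0.5 * kl(q, m))
}

# random composition of length d (Dirichlet(1,...,1))
random_composition <- function(d) {
  x <- stats::rexp(d)
  x / sum(x)
}

# random abundance table (counts), n samples x d taxa
random_table <- function(n, d, max_count = 100) {
  m <- matrix(stats::runif(n * d, 0, max_count), n, d)
  abundance_table(m)
}

# Euclidean distance matrix for points given as rows of a matrix
euclid_dmat <- function(X) {
  X <- as.matrix(X)
  d <- as.matrix(stats::dist(X))
  dimnames(d) <- list(paste0("p", seq_len(nrow(X))),
                      paste0("p", seq_len(nrow(X))))
  d
}

# build a mapper_graph by hand from a list of member vectors and an
# explicit edge list (vertex index pairs); edges default to the nerve.
manual_graph <- function(members, edges = NULL, n_samples = NULL) {
  vertices <- lapply(seq_along(members), function(i)
    list(id = sprintf("v%d", i), members = sort(unique(members[[i]])),
         bin = "manual"))
  if (is.null(edges)) {
    edges <- list()
    for (i in seq_along(members)) for (j in seq_along(members))
      if (i < j && length(intersect(members[[i]], members[[j]])))
        edges[[length(edges) + 1L]] <- c(i, j)
    edges <- if (length(edges)) do.call(rbind, edges)
             else matrix(integer(0), ncol = 2)
  } else edges <- matrix(as.integer(edges), ncol = 2, byrow = TRUE)
  structure(list(vertices = vertices, edges = edges,
                 n_samples = if (is.null(n_samples))
                   length(unique(unlist(members))) else n_samples,
                 sample_ids = NULL),
            class = "mapper_graph")
}

# chain graph over nv vertices (v1 - v2 - ... - vnv), one private sample
# per vertex
chain_graph <- function(nv) {
  manual_graph(as.list(seq_len(nv)),
               edges = unlist(lapply(seq_len(nv - 1),
                                     function(i) c(i, i + 1))))
}

# brute-force nerve edges: all-pairs intersection test
oracle_nerve_edges <- function(members) {
  out <- list()
  for (i in seq_along(members)) for (j in seq_along(members))
    if (i < j && length(intersect(members[[i]], members[[j]])) > 0)
      out[[length(out) + 1L]] <- c(i, j)
  if (length(out)) do.call(rbind, out) else matrix(integer(0), ncol = 2)
}

# brute-force kNN distance: sort all other distances, lowest-index ties
oracle_knn <- function(D, i, k) {
  others <- setdiff(seq_len(nrow(D)), i)
  ord <- others[order(D[i, others], others)]
  mean(D[i, ord[seq_len(k)]])
}

# all-pairs directed BFS distances (hop counts) from arcs matrix
oracle_directed_dist <- function(nv, arcs) {
  d <- matrix(Inf, nv, nv)
  diag(d) <- 0
  adj <- vector("list", nv)
  if (!is.null(arcs) && nrow(arcs))
    for (r in seq_len(nrow(arcs)))
      adj[[arcs[r, 1]]] <- c(adj[[arcs[r, 1]]], arcs[r, 2])
  for (s in seq_len(nv)) {
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) if (d[s, u] > d[s, v] + 1) {
        d[s, u] <- d[s, v] + 1
        queue <- c(queue, u)
      }
    }
  }
  d
}

# oracle state assignment: merge maxima connected through maxima-only
# undirected paths, then argmin of directed hop distance with tie/unreach
# detection
oracle_assign <- function(g, arcs, maxima, densities) {
  nv <- length(g$vertices)
  is_max <- seq_len(nv) %in% maxima
  # union maxima through undirected edges between maxima
  lab <- seq_along(maxima)
  repeat {
    changed <- FALSE
    if (nrow(g$edges)) for (r in seq_len(nrow(g$edges))) {
      u <- g$edges[r, 1]; v <- g$edges[r, 2]
      if (is_max[u] && is_max[v]) {
        iu <- match(u, maxima); iv <- match(v, maxima)
        if (lab[iu] != lab[iv]) {
          l <- min(lab[iu], lab[iv])
          lab[lab %in% c(lab[iu], lab[iv])] <- l
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  states <- match(lab, sort(unique(lab)))
  dd <- oracle_directed_dist(nv, arcs)
  out <- rep("unassigned", nv)
  out[maxima] <- as.character(states)
  for (v in seq_len(nv)) {
    if (is_max[v]) next
    ds <- vapply(seq_len(max(states)), function(s)
      min(dd[v, maxima[states == s]]), numeric(1))
    if (all(!is.finite(ds))) next
    w <- which(ds == min(ds))
    if (length(w) == 1L) out[v] <- as.character(w)
  }
  out
}

# random connected-ish mapper graph with random densities, for property
# tests of maxima/orientation/assignment
random_density_graph <- function(nv, p_edge = 0.15, tie_prob = 0.2) {
  edges <- list()
  for (i in seq_len(nv)) for (j in seq_len(nv))
    if (i < j && stats::runif(1) < p_edge)
      edges[[length(edges) + 1L]] <- c(i, j)
  g <- manual_graph(as.list(seq_len(nv)),
                    edges = if (length(edges)) unlist(edges) else NULL)
  # densities from a small value pool so ties happen (continuous when
  # tie_prob = 0)
  dens <- if (tie_prob <= 0) stats::runif(nv) else {
    pool <- stats::runif(max(2, ceiling(nv * (1 - tie_prob))))
    sample(pool, nv, replace = TRUE)
  }
  list(g = g, dens = dens)
}

# analytic tau-step return probability of a symmetric two-state chain
two_state_return <- function(q, tau) 0.5 + 0.5 * (2 * q - 1)^tau
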