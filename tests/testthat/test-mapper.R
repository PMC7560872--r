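test_that("pcoa_filter reproduces Euclidean-realizable distances", {
  # collinear points at 0, 1, 3 on a line
  D <- euclid_dmat(matrix(c(0, 1, 3), ncol = 1))
  expect_warning(X <- pcoa_filter(D, 2), "positive eigenvalue")
  emb <- as.matrix(dist(X))
  expect_equal(unname(emb), unname(D), tolerance = 1e-9)
  # 2D configuration: both components recoverable, cmdscale as oracle
  set.seed(23)
  P <- matrix(rnorm(12), 6, 2)
  D2 <- euclid_dmat(P)
  X2 <- pcoa_filter(D2, 2)
  expect_equal(unname(as.matrix(dist(X2))), unname(D2), tolerance = 1e-9)
  ref <- stats::cmdscale(D2, k = 2)
  expect_equal(abs(unname(X2)), abs(unname(ref)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # duplicates embed identically
  D3 <- euclid_dmat(rbind(c(0, 0), c(0, 0), c(1, 0), c(0, 2)))
  X3 <- pcoa_filter(D3, 2)
  expect_equal(X3[1, ], X3[2, ], ignore_attr = TRUE)
  expect_error(pcoa_filter(euclid_dmat(matrix(c(0, 1), ncol = 1))),
               "at least 3")
})

test_that("pcoa_filter on non-Euclidean input keeps the positive part", {
  set.seed(29)
  t <- to_relative_abundance(random_table(12, 6))
  D <- pairwise_distances(t)
  X <- pcoa_filter(D, 2)
  # oracle: independent eigendecomposition of the Gower-centered matrix
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% (-0.5 * D^2) %*% J
  ev <- eigen((B + t(B)) / 2, symmetric = TRUE)
  expect_equal(unname(attr(X, "eigenvalues")), ev$values[1:2],
               tolerance = 1e-9)
  expect_equal(abs(unname(X)),
               abs(ev$vectors[, 1:2] %*% diag(sqrt(ev$values[1:2]))),
               tolerance = 1e-9, ignore_attr = TRUE)
  # deterministic sign: largest-magnitude loading positive
  for (j in 1:2) expect_gt(X[which.max(abs(X[, j])), j], 0)
})

test_that("rank_transform gives ordinal ranks with input-order ties", {
  expect_equal(rank_transform(c(0.5, -1.2, 3.3)), c(2, 1, 3))
  expect_equal(rank_transform(rep(1, 5)), 1:5)
  expect_equal(rank_transform(1:7), 1:7)
  expect_error(rank_transform(c(1, NA)), "finite")
})

test_that("make_cover builds the documented interval geometry", {
  cfg <- mapper_config(c(2, 1), overlap_pct = 50)
  f <- cbind(1:10, rep(1, 10))
  bins <- make_cover(f, cfg)
  # span 9, L = 9 / (1 + 1*0.5) = 6, starts spaced 3: [1,7], [4,10]
  iv <- t(sapply(bins, function(b) b$intervals[1, ]))
  expect_equal(unname(iv), rbind(c(1, 7), c(4, 10)))
  expect_equal(bins[[1]]$members, 1:7)
  expect_equal(bins[[2]]$members, 4:10)
  # union covers everything
  expect_setequal(unlist(lapply(bins, `[[`, "members")), 1:10)

  # 1x1 cover: single bin with all samples
  b1 <- make_cover(f, mapper_config(c(1, 1), 50))
  expect_length(b1, 1)
  expect_equal(b1[[1]]$members, 1:10)
})

test_that("cover property and bin-multiplicity bound hold on random filters", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    f <- cbind(rank_transform(runif(n)), rank_transform(runif(n)))
    cfg <- mapper_config(sample(2:6, 2, replace = TRUE),
                         overlap_pct = runif(1, 10, 45))
    bins <- make_cover(f, cfg)
    counts <- integer(n)
    for (b in bins) counts[b$members] <- counts[b$members] + 1L
    expect_true(all(counts >= 1))       # cover
    expect_true(all(counts <= 4))       # < 50% overlap in both dims
  }
})

test_that("increasing overlap never removes a co-membership", {
  set.seed(37)
  n <- 40
  f <- cbind(rank_transform(runif(n)), rank_transform(runif(n)))
  co <- function(bins) {
    m <- matrix(FALSE, n, n)
    for (b in bins) m[b$members, b$members] <- TRUE
    m
  }
  lo <- co(make_cover(f, mapper_config(c(4, 4), 25)))
  hi <- co(make_cover(f, mapper_config(c(4, 4), 60)))
  expect_true(all(hi[lo]))
})

test_that("local_cluster separates scales via the first-empty-bin cutoff", {
  # two tight groups, far apart: merge heights {<=0.1, 5}
  X <- c(0, 0.05, 0.1, 5, 5.05, 5.1)
  D <- euclid_dmat(matrix(X, ncol = 1))
  cl <- local_cluster(1:6, D, 10)
  expect_length(cl, 2)
  expect_setequal(cl[[which(vapply(cl, function(x) 1 %in% x,
                                   logical(1)))]], 1:3)
  # oracle: dendrogram inspection — cutoff must lie between 0.1 and 5
  hc <- stats::hclust(stats::as.dist(D), method = "single")
  expect_true(all(hc$height[hc$height > 0.2] >= 4.9))

  # all pairwise distances equal: no gap, one cluster
  De <- matrix(1, 4, 4); diag(De) <- 0
  dimnames(De) <- list(paste0("s", 1:4), paste0("s", 1:4))
  expect_length(local_cluster(1:4, De, 10), 1)

  # singleton and pair bins
  expect_equal(local_cluster(3L, D, 10), list(3L))
  expect_length(local_cluster(c(1L, 6L), D, 10), 1)
})

test_that("build_nerve matches the quadratic intersection oracle", {
  g <- build_nerve(list(list(id = "b1", clusters = list(c(1, 2))),
                        list(id = "b2", clusters = list(c(2, 3)))))
  expect_length(g$vertices, 2)
  expect_equal(unname(g$edges), matrix(c(1L, 2L), ncol = 2))
  g2 <- build_nerve(list(list(id = "b1", clusters = list(c(1, 2))),
                         list(id = "b2", clusters = list(c(3, 4)))))
  expect_equal(nrow(g2$edges), 0)
  set.seed(41)
  for (i in 1:10) {
    members <- replicate(sample(5:15, 1),
                         sample(50, sample(1:6, 1)), simplify = FALSE)
    g3 <- build_nerve(lapply(seq_along(members), function(j)
      list(id = paste0("b", j), clusters = members[j])))
    got <- g3$edges[order(g3$edges[, 1], g3$edges[, 2]), , drop = FALSE]
    want <- oracle_nerve_edges(members)
    want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(want))
    # no self loops / duplicates
    expect_true(all(got[, 1] < got[, 2]))
    expect_equal(anyDuplicated(got), 0)
  }
})

test_that("run_mapper is deterministic and permutation-equivariant", {
  set.seed(43)
  sim <- simulate_markov_community(n_timepoints = 60, seed = 9)
  t <- to_relative_abundance(sim$table)
  D <- pairwise_distances(t)
  cfg <- mapper_config(c(5, 5), 40)
  g1 <- run_mapper(D, cfg)
  g2 <- run_mapper(D, cfg)
  mem <- function(g) lapply(g$vertices, `[[`, "members")
  expect_identical(mem(g1), mem(g2))
  expect_identical(g1$edges, g2$edges)
  # every sample covered
  expect_setequal(unlist(mem(g1)), seq_len(nrow(D)))
  # permutation: same vertex member *sets* (as sample IDs), same edge count
  perm <- sample(nrow(D))
  Dp <- D[perm, perm]
  gp <- run_mapper(Dp, cfg)
  ids1 <- sort(vapply(g1$vertices, function(v)
    paste(sort(rownames(D)[v$members]), collapse = ";"), character(1)))
  ids2 <- sort(vapply(gp$vertices, function(v)
    paste(sort(rownames(Dp)[v$members]), collapse = ";"), character(1)))
  expect_identical(ids1, ids2)
  expect_equal(nrow(gp$edges), nrow(g1$edges))
})

test_that("run_mapper on a tiny 1x1 cover reduces to one local clustering", {
  m <- rbind(a = c(.9, .1), b = c(.85, .15), c = c(.1, .9), d = c(.15, .85),
             e = c(.5, .5))
  t <- abundance_table(m / rowSums(m))
  D <- pairwise_distances(to_relative_abundance(t))
  g <- run_mapper(D, mapper_config(c(1, 1), 50))
  expect_equal(sort(unlist(lapply(g$vertices, `[[`, "members"))), 1:5)
  expect_identical(lapply(g$vertices, `[[`, "members"),
                   local_cluster(1:5, D, 10))
})

test_that("check_hyperparameters applies the ~10% largest-vertex rule", {
  g <- manual_graph(list(1:2, 3:4, c(4, 5)), n_samples = 20)
  chk <- check_hyperparameters(g, 20)
  expect_equal(chk$largest_vertex_fraction, 0.1)
  expect_true(chk$pass)
  g2 <- manual_graph(list(1:5, 6:7), n_samples = 20)
  chk2 <- check_hyperparameters(g2, 20)
  expect_equal(chk2$largest_vertex_fraction, 0.25)
  expect_false(chk2$pass)
  g3 <- manual_graph(list(1, 2, 3), n_samples = 3)
  expect_equal(check_hyperparameters(g3, 3)$n_singleton_components, 3)
})

test_that("mapper graphs export to GraphML and JSON", {
  g <- manual_graph(list(1:2, 2:3))
  f1 <- withr::local_tempfile(fileext = ".graphml")
  f2 <- withr::local_tempfile(fileext = ".json")
  export_mapper_graph(g, f1, density = c(1, 2), states = c("1", "1"))
  export_mapper_graph(g, f2, density = c(1, 2), states = c("1", "1"))
  ig <- igraph::read_graph(f1, format = "graphml")
  expect_equal(igraph::vcount(ig), 2)
  expect_equal(igraph::ecount(ig), 1)
  expect_equal(igraph::V(ig)$density, c(1, 2))
  js <- jsonlite::read_json(f2)
  expect_length(js$vertices, 2)
})
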