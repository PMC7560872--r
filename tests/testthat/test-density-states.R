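test_that("knn_distance matches enumeration, handles ties and duplicates", {
  D <- euclid_dmat(matrix(c(0, 1, 3), ncol = 1))
  expect_equal(knn_distance(D, 1, 2), 2)     # (1 + 3) / 2
  expect_equal(knn_distance(D, 1, 1), 1)
  Dd <- euclid_dmat(matrix(c(0, 0, 5), ncol = 1))
  expect_equal(knn_distance(Dd, 1, 1), 0)    # duplicated point
  expect_error(knn_distance(D, 1, 3), "k must be")
  expect_error(knn_distance(D, 1, 0), "k must be")
  set.seed(47)
  for (i in 1:30) {
    n <- sample(5:20, 1)
    D2 <- euclid_dmat(matrix(rnorm(n * 2), n, 2))
    i0 <- sample(n, 1); k <- sample(n - 1, 1)
    expect_equal(knn_distance(D2, i0, k), oracle_knn(D2, i0, k),
                 tolerance = 1e-12)
  }
})

test_that("vertex_density follows the n^2-normalized kNN estimator", {
  # three points 0, 1, 3; k = 1: knn = (1, 1, 2)
  D <- euclid_dmat(matrix(c(0, 1, 3), ncol = 1))
  g <- manual_graph(list(1L, c(2L, 3L)))
  vd <- vertex_density(g, D, k = 1)
  expect_equal(vd$d_inv, c(1 / 1, (1 + 2) / 4))
  expect_equal(vd$density, 1 / vd$d_inv)
  # single-member vertex with kNN = 2 (point at 0 with k = 2)
  g1 <- manual_graph(list(1L))
  vd1 <- vertex_density(g1, D, k = 2)
  expect_equal(vd1$d_inv, 2)
  expect_equal(vd1$density, 0.5)
  # doubling all distances halves density
  vd2 <- vertex_density(g, 2 * D, k = 1)
  expect_equal(vd2$density, vd$density / 2, tolerance = 1e-12)
  # duplicate-only vertex: density Inf with a warning
  Dd <- euclid_dmat(matrix(c(0, 0, 5), ncol = 1))
  gd <- manual_graph(list(c(1L, 2L), 3L))
  expect_warning(vdd <- vertex_density(gd, Dd, k = 1), "Inf")
  expect_true(is.infinite(vdd$density[1]) && vdd$degenerate[1])
})

test_that("find_local_maxima handles chains, plateaus and isolates", {
  g <- chain_graph(3)
  expect_equal(find_local_maxima(g, c(1, 3, 2)), 2L)
  expect_equal(find_local_maxima(g, c(3, 3, 1)), c(1L, 2L))
  # tie with a non-maximal plateau member: not maxima
  g4 <- chain_graph(4)
  expect_equal(find_local_maxima(g4, c(2, 2, 3, 1)), 3L)
  gi <- manual_graph(list(1L))
  expect_equal(find_local_maxima(gi, 5), 1L)
})

test_that("orient_graph points arcs up the density gradient", {
  g <- chain_graph(3)
  arcs <- orient_graph(g, c(1, 2, 2))
  expect_true(any(arcs[, 1] == 1 & arcs[, 2] == 2))
  # equal edge becomes two arcs
  expect_equal(nrow(arcs), 3)
  set.seed(53)
  for (i in 1:20) {
    rg <- random_density_graph(sample(5:15, 1))
    a <- orient_graph(rg$g, rg$dens)
    ties <- sum(apply(rg$g$edges, 1, function(e)
      rg$dens[e[1]] == rg$dens[e[2]]))
    expect_equal(if (is.null(a)) 0 else nrow(a),
                 nrow(rg$g$edges) + ties)
  }
})

test_that("assign_states reproduces the hand-worked chain cases", {
  # chain D = (1,2,3,2,1): single maximum, one state for all
  g5 <- chain_graph(5)
  d5 <- c(1, 2, 3, 2, 1)
  p5 <- assign_states(g5, orient_graph(g5, d5), find_local_maxima(g5, d5))
  expect_equal(p5$n_states, 1)
  expect_equal(p5$state_of, rep("1", 5))

  # chain D = (3,1,3): middle vertex equidistant -> unassigned
  g3 <- chain_graph(3)
  d3 <- c(3, 1, 3)
  p3 <- assign_states(g3, orient_graph(g3, d3), find_local_maxima(g3, d3))
  expect_equal(p3$n_states, 2)
  expect_equal(p3$state_of[2], "unassigned")
  expect_setequal(p3$state_of[c(1, 3)], c("1", "2"))

  # chain D = (3,2,1,2,3): ends maxima, center equidistant
  gc <- chain_graph(5)
  dc <- c(3, 2, 1, 2, 3)
  pc <- assign_states(gc, orient_graph(gc, dc), find_local_maxima(gc, dc))
  expect_equal(pc$state_of, c("1", "1", "unassigned", "2", "2"))

  # tied maxima merge into one state
  gt <- chain_graph(3)
  dt <- c(3, 3, 1)
  pt <- assign_states(gt, orient_graph(gt, dt), find_local_maxima(gt, dt))
  expect_equal(pt$n_states, 1)
  expect_equal(pt$state_of, c("1", "1", "1"))
})

test_that("assign_states agrees with the directed-BFS oracle on random graphs", {
  set.seed(59)
  for (i in 1:120) {
    rg <- random_density_graph(sample(4:30, 1))
    maxima <- find_local_maxima(rg$g, rg$dens)
    arcs <- orient_graph(rg$g, rg$dens)
    part <- assign_states(rg$g, arcs, maxima)
    expect_identical(part$state_of,
                     oracle_assign(rg$g, arcs, maxima, rg$dens))
    # partition sanity: every vertex has exactly one label
    expect_length(part$state_of, length(rg$g$vertices))
  }
})

test_that("the partition depends only on the density ranking", {
  set.seed(61)
  for (i in 1:20) {
    rg <- random_density_graph(sample(5:20, 1))
    f <- function(d) exp(3 * d) + 1  # strictly increasing
    m1 <- find_local_maxima(rg$g, rg$dens)
    m2 <- find_local_maxima(rg$g, f(rg$dens))
    expect_identical(m1, m2)
    p1 <- assign_states(rg$g, orient_graph(rg$g, rg$dens), m1)
    p2 <- assign_states(rg$g, orient_graph(rg$g, f(rg$dens)), m2)
    expect_identical(p1$state_of, p2$state_of)
  }
})

test_that("single-maximum graphs drain every reachable vertex to one state", {
  set.seed(67)
  tries <- 0
  for (i in 1:200) {
    rg <- random_density_graph(sample(5:15, 1), p_edge = 0.5,
                               tie_prob = 0)
    maxima <- find_local_maxima(rg$g, rg$dens)
    if (length(maxima) != 1) next
    tries <- tries + 1
    part <- assign_states(rg$g, orient_graph(rg$g, rg$dens), maxima)
    reach <- is.finite(part$dist_to_state[, 1])
    expect_true(all(part$state_of[reach] == "1"))
    expect_true(all(part$state_of[!reach] == "unassigned"))
    if (tries >= 20) break
  }
  expect_gte(tries, 5)
})

test_that("sample_states unions vertex labels; majority state is sensible", {
  g <- manual_graph(list(c(1, 2), c(2, 3), 4))
  part <- structure(list(state_of = c("1", "2", "unassigned"),
                         maxima = c(1L, 2L), n_states = 2,
                         dist_to_state = NULL),
                    class = "state_partition")
  ss <- sample_states(g, part)
  expect_equal(ss[["1"]], "1")
  expect_equal(ss[["2"]], c("1", "2"))
  expect_equal(ss[["4"]], "unassigned")
  maj <- sample_majority_state(g, part)
  expect_equal(unname(maj["4"]), "unassigned")
  expect_equal(unname(maj["1"]), "1")
})

test_that("state partition TSV export round-trips vertex fields", {
  D <- euclid_dmat(matrix(c(0, 1, 3, 10), ncol = 1))
  g <- manual_graph(list(c(1, 2), c(2, 3), 4L))
  ps <- partition_states(g, D, k = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  fs <- withr::local_tempfile(fileext = ".tsv")
  write_state_partition(g, ps$density, ps$partition, f, sample_path = fs)
  df <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(df), 3)
  expect_equal(df$density, ps$density$density)
  expect_equal(sum(df$is_maximum), length(ps$maxima))
  sdf <- read.table(fs, header = TRUE, sep = "\t",
                    colClasses = "character")
  expect_equal(nrow(sdf), 4)
})
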