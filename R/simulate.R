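#' Simulate an antagonistic two-species toy ecosystem
#'
#' A minimal bistable community: two focal taxa X and Y suppress each other,
#' so the system settles near one of two compositional modes (X-dominant or
#' Y-dominant) with small fluctuations, and balanced configurations occur
#' only transiently. Realized as a discrete-time double-well diffusion on a
#' latent dominance variable z in (-1, 1),
#' \deqn{z_{t+1} = z_t + a\, z_t (1 - z_t^2)\, \Delta t + \sigma\, \epsilon_t,}
#' whose wells at z = +/-1 correspond to the two modes; each sample is an
#' independent short run from a uniform start. X and Y receive fractions
#' `(1 + z)/2` and `(1 - z)/2` of the focal mass; bystander taxa carry
#' multiplicative log-normal noise; rows are normalized to compositions.
#' With `antagonism = 0` the latent variable merely diffuses and no
#' bimodality arises (null control).
#'
#' @param n_samples number of samples (time points) to draw.
#' @param antagonism strength a of the mutual suppression (default 4; 0
#'   disables it).
#' @param noise diffusion scale sigma of the latent dynamics (default 0.25).
#' @param n_bystanders number of non-focal taxa (default 3).
#' @param bystander_mass total relative mass of the bystanders (default
#'   0.2).
#' @param burn_in latent-dynamics steps per sample (default 50).
#' @param seed integer seed.
#' @return list with `table` (an [abundance_table()], rows normalized) and
#'   `truth` (character: `"X"` or `"Y"`, the mode each sample is nearest).
#' @export
simulate_antagonistic <- function(n_samples = 200L, antagonism = 4,
                                  noise = 0.25, n_bystanders = 3L,
                                  bystander_mass = 0.2, burn_in = 50L,
                                  seed = 1L) {
  set.seed(seed)
  dt <- 0.1
  z <- vapply(seq_len(n_samples), function(i) {
    zi <- stats::runif(1, -1, 1)
    for (s in seq_len(burn_in)) {
      zi <- zi + antagonism * zi * (1 - zi^2) * dt +
        noise * sqrt(dt) * stats::rnorm(1)
      zi <- max(min(zi, 1.5), -1.5)
    }
    zi
  }, numeric(1))
  focal <- 1 - bystander_mass
  x <- focal * (1 + pmax(pmin(z, 1), -1)) / 2
  y <- focal - x
  byst <- matrix(stats::rlnorm(n_samples * n_bystanders, sdlog = 0.2),
                 n_samples, n_bystanders)
  byst <- byst / rowSums(byst) * bystander_mass
  m <- cbind(X = x, Y = y, byst)
  colnames(m) <- c("X", "Y", paste0("B", seq_len(n_bystanders)))
  rownames(m) <- sprintf("s%03d", seq_len(n_samples))
  m <- m / rowSums(m)
  meta <- data.frame(sample_id = rownames(m), subject = "toy",
                     time = seq_len(n_samples), stringsAsFactors = FALSE)
  list(table = abundance_table(m, meta),
       truth = ifelse(z >= 0, "X", "Y"))
}

#' Default well-separated state mean compositions
#'
#' S mean compositions over `n_taxa` taxa, each concentrating `mass` of the
#' abundance on its own block of taxa and spreading the rest uniformly.
#' With the defaults the pairwise Jensen-Shannon distances exceed 0.5.
#'
#' @param S number of states.
#' @param n_taxa number of taxa (>= S).
#' @param mass block mass per state (default 0.8).
#' @return S x n_taxa matrix of compositions (rows sum to 1).
#' @export
default_state_means <- function(S = 3L, n_taxa = 9L, mass = 0.8) {
  if (n_taxa < S) stop("need n_taxa >= S")
  block <- floor(n_taxa / S)
  means <- matrix((1 - mass) / (n_taxa - block), S, n_taxa)
  for (s in seq_len(S)) {
    idx <- ((s - 1) * block + 1):(s * block)
    means[s, idx] <- mass / block
  }
  means / rowSums(means)
}

#' Minimum pairwise JS separation of state means
#'
#' @param means S x n_taxa matrix of compositions.
#' @return smallest pairwise [js_distance()] between rows.
#' @export
state_separation <- function(means) {
  S <- nrow(means)
  if (S < 2) return(Inf)
  min(apply(utils::combn(S, 2), 2, function(p)
    js_distance(means[p[1], ], means[p[2], ])))
}

# one Dirichlet draw with mean `mean` and concentration `conc`
.rdirichlet <- function(mean, conc) {
  g <- stats::rgamma(length(mean), shape = mean * conc, rate = 1)
  if (sum(g) == 0) g[which.max(mean)] <- 1
  g / sum(g)
}

#' Simulate Markov-switching multi-state community time series
#'
#' Per subject, a discrete-time Markov chain over S community states; at
#' each time point the composition is drawn from the current state's
#' Dirichlet distribution (mean = the state's characteristic composition,
#' concentration controlling within-state tightness). This is the ground-
#' truth world for pipeline-recovery tests: states are well separated in JS
#' distance and visited with known dynamics.
#'
#' @param S number of states (default 3).
#' @param n_taxa number of taxa (default 9).
#' @param means optional S x n_taxa matrix of state mean compositions;
#'   default [default_state_means()].
#' @param concentration Dirichlet concentration (default 50).
#' @param transition S x S row-stochastic transition matrix; default: stay
#'   probability 0.9, uniform otherwise.
#' @param n_subjects number of independent chains (default 1).
#' @param n_timepoints time points per subject (default 300).
#' @param min_separation required minimum pairwise JS distance between
#'   state means (default 0.5); violation is an error.
#' @param seed integer seed.
#' @return list with `table` (normalized [abundance_table()]; metadata
#'   carries subject and integer time), `truth` (integer state per sample),
#'   `means`, `transition`.
#' @export
simulate_markov_community <- function(S = 3L, n_taxa = 9L, means = NULL,
                                      concentration = 50,
                                      transition = NULL,
                                      n_subjects = 1L, n_timepoints = 300L,
                                      min_separation = 0.5, seed = 1L) {
  if (is.null(means)) means <- default_state_means(S, n_taxa)
  stopifnot(nrow(means) == S, ncol(means) == n_taxa)
  if (any(concentration <= 0)) stop("concentration must be positive")
  if (is.null(transition)) {
    transition <- matrix(if (S > 1) 0.1 / (S - 1) else 0, S, S)
    diag(transition) <- if (S > 1) 0.9 else 1
  }
  stopifnot(nrow(transition) == S, ncol(transition) == S)
  if (any(abs(rowSums(transition) - 1) > 1e-9))
    stop("transition rows must sum to 1")
  sep <- state_separation(means)
  if (sep < min_separation)
    stop("state means separated by ", format(sep),
         " < required ", min_separation)
  set.seed(seed)
  vals <- list(); truth <- integer(0)
  subj <- character(0); tim <- integer(0)
  for (u in seq_len(n_subjects)) {
    state <- sample.int(S, 1)
    for (t in seq_len(n_timepoints)) {
      truth <- c(truth, state)
      vals[[length(vals) + 1L]] <- .rdirichlet(means[state, ], concentration)
      subj <- c(subj, sprintf("subj%d", u))
      tim <- c(tim, t)
      state <- sample.int(S, 1, prob = transition[state, ])
    }
  }
  m <- do.call(rbind, vals)
  colnames(m) <- paste0("taxon", seq_len(n_taxa))
  rownames(m) <- sprintf("s%04d", seq_along(truth))
  meta <- data.frame(sample_id = rownames(m), subject = subj, time = tim,
                     stringsAsFactors = FALSE)
  list(table = abundance_table(m, meta), truth = truth,
       means = means, transition = transition)
}

#' Write a simulated data set to TSV files
#'
#' Writes the abundance table (samples as rows), the metadata table and the
#' ground-truth labels as three tab-separated files.
#'
#' @param sim output of [simulate_antagonistic()] or
#'   [simulate_markov_community()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of the three paths, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ab <- file.path(dir, paste0(prefix, "_abundance.tsv"))
  mt <- file.path(dir, paste0(prefix, "_metadata.tsv"))
  tr <- file.path(dir, paste0(prefix, "_truth.tsv"))
  v <- sim$table$values
  utils::write.table(data.frame(sample_id = rownames(v), v,
                                check.names = FALSE),
                     ab, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$table$meta, mt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = sim$table$samples,
                                truth = sim$truth),
                     tr, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(ab, mt, tr))
}

#' Adjusted Rand index between two labelings
#'
#' Standard chance-corrected agreement between two partitions of the same
#' items; 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
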