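#' Rarefaction plan
#'
#' Specification of the rarefaction robustness test: random subsets of the
#' samples at the given fractions, a fixed number of replicates each, Mapper
#' re-run with the unchanged base hyperparameters. The published protocol
#' uses fractions 0.9, 0.5, 0.1 with 10 replicates.
#'
#' @param fractions numeric vector of retention fractions in (0, 1].
#' @param replicates replicates per fraction (>= 1; default 10).
#' @param config base [mapper_config()] reused for every subset.
#' @param seed master seed; each (fraction, replicate) draws from its own
#'   derived stream.
#' @return An object of class `rarefaction_plan`.
#' @export
rarefaction_plan <- function(fractions = c(0.9, 0.5, 0.1), replicates = 10L,
                             config = mapper_config(), seed = 1L) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must be in (0, 1]")
  if (replicates < 1) stop("replicates must be >= 1")
  structure(list(fractions = as.numeric(fractions),
                 replicates = as.integer(replicates),
                 config = config, seed = as.integer(seed)),
            class = "rarefaction_plan")
}

# round-half-away-from-zero
.round_half_away <- function(x) floor(x + 0.5)

# derived per-stream seed kept below 2^31
.derive_seed <- function(master, fraction_idx, replicate) {
  (as.integer(master) * 7919L + fraction_idx * 104729L +
     replicate * 1299709L) %% 2147483647L
}

#' Draw one rarefied sample subset
#'
#' Uniform sampling without replacement of `round(fraction * n)` sample IDs
#' (round half away from zero). Reproducible given the seed.
#'
#' @param samples character vector of sample IDs.
#' @param fraction retention fraction in (0, 1].
#' @param seed integer seed for this draw.
#' @return character vector of retained IDs (original order preserved).
#' @export
rarefy <- function(samples, fraction, seed) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n <- length(samples)
  m <- .round_half_away(fraction * n)
  if (m < 3) stop("rarefied subset would have ", m, " samples (< 3)")
  if (m >= n) return(samples)
  # draw from a private RNG stream, restoring the caller's state
  old <- .Random.seed_exists()
  set.seed(seed)
  idx <- sort(sample.int(n, m))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  samples[idx]
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

#' Group edge densities of a Mapper graph
#'
#' Each vertex is labelled by its dominant feature class (the most frequent
#' metadata value among its member samples; numeric features should be
#' binned first). The edge density between groups A and B is the number of
#' observed A-B edges divided by the number of possible A-B vertex pairs;
#' within-group density divides by `choose(|A|, 2)`.
#'
#' @param g a `mapper_graph`.
#' @param feature_by_sample named vector: feature class per sample ID.
#' @return list with `vertex_group`, `dominant_fraction` (per vertex),
#'   `within_density`, `between_density` (pooled over group pairs), and the
#'   full `density_matrix` (groups x groups).
#' @export
group_edge_densities <- function(g, feature_by_sample) {
  ids <- g$sample_ids
  grp <- character(length(g$vertices))
  domfrac <- numeric(length(g$vertices))
  for (vi in seq_along(g$vertices)) {
    mem <- g$vertices[[vi]]$members
    keys <- if (!is.null(ids)) ids[mem] else as.character(mem)
    tab <- table(feature_by_sample[keys])
    grp[vi] <- names(tab)[which.max(tab)]
    domfrac[vi] <- max(tab) / sum(tab)
  }
  groups <- sort(unique(grp))
  ng <- length(groups)
  obs <- matrix(0, ng, ng, dimnames = list(groups, groups))
  if (nrow(g$edges))
    for (r in seq_len(nrow(g$edges))) {
      a <- grp[g$edges[r, 1]]; b <- grp[g$edges[r, 2]]
      obs[a, b] <- obs[a, b] + 1
      if (a != b) obs[b, a] <- obs[b, a] + 1
    }
  sizes <- table(factor(grp, levels = groups))
  poss <- outer(as.numeric(sizes), as.numeric(sizes))
  diag(poss) <- as.numeric(sizes) * (as.numeric(sizes) - 1) / 2
  dens <- ifelse(poss > 0, obs / poss, NA_real_)
  dimnames(dens) <- list(groups, groups)
  w_obs <- sum(diag(obs)); w_poss <- sum(diag(poss))
  b_obs <- (sum(obs) - sum(diag(obs))) / 2
  b_poss <- (sum(poss) - sum(diag(poss))) / 2
  list(vertex_group = grp,
       dominant_fraction = domfrac,
       within_density = if (w_poss > 0) w_obs / w_poss else NA_real_,
       between_density = if (b_poss > 0) b_obs / b_poss else NA_real_,
       density_matrix = dens)
}

#' Bin a numeric feature into quartiles
#'
#' Depth-like numeric metadata are grouped into quartile bins for the
#' robustness summary.
#'
#' @param x numeric vector.
#' @return character vector of bin labels; bin edges attached as an
#'   attribute.
#' @export
bin_numeric_feature <- function(x) {
  edges <- unique(stats::quantile(x, probs = seq(0, 1, 0.25)))
  if (length(edges) < 2) return(structure(rep("bin1", length(x)),
                                          edges = edges))
  lab <- cut(x, breaks = edges, include.lowest = TRUE,
             labels = paste0("Q", seq_len(length(edges) - 1)))
  structure(as.character(lab), edges = edges)
}

#' Rarefaction robustness run
#'
#' For every (fraction, replicate) pair of the plan: draw a random sample
#' subset, subset the precomputed distance matrix (distances are per-pair,
#' so no recomputation is needed), re-run Mapper with the unchanged base
#' hyperparameters, and summarize vertex feature homogeneity and
#' within/between-group edge densities for the chosen metadata feature.
#' Density estimation and state assignment are deliberately not re-run:
#' the test targets the robustness of the graph structure.
#'
#' @param t a normalized [abundance_table()].
#' @param plan a [rarefaction_plan()].
#' @param feature name of a metadata column to group vertices by; numeric
#'   features are quartile-binned.
#' @param D optional precomputed distance matrix (JS by default).
#' @return An object of class `robustness_summary`: a data frame with one
#'   row per (fraction, replicate): `fraction`, `replicate`, `n_samples`,
#'   `n_vertices`, `n_edges`, `mean_dominant_fraction`, `within_density`,
#'   `between_density`.
#' @export
robustness_run <- function(t, plan, feature, D = NULL) {
  stopifnot(inherits(t, "abundance_table"),
            inherits(plan, "rarefaction_plan"))
  if (!feature %in% names(t$meta))
    stop("feature '", feature, "' not in metadata")
  fv <- t$meta[[feature]]
  if (is.numeric(fv) && length(unique(fv)) > 8) fv <- bin_numeric_feature(fv)
  feature_by_sample <- stats::setNames(as.character(fv), t$meta$sample_id)
  if (is.null(D)) D <- pairwise_distances(t, metric = "js")
  rows <- list()
  for (fi in seq_along(plan$fractions)) {
    fr <- plan$fractions[fi]
    for (rep_i in seq_len(plan$replicates)) {
      seed <- .derive_seed(plan$seed, fi, rep_i)
      keep <- rarefy(t$samples, fr, seed)
      Dsub <- D[keep, keep, drop = FALSE]
      g <- run_mapper(Dsub, plan$config)
      ed <- group_edge_densities(g, feature_by_sample)
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = fr, replicate = rep_i, n_samples = length(keep),
        n_vertices = length(g$vertices), n_edges = nrow(g$edges),
        mean_dominant_fraction = mean(ed$dominant_fraction),
        within_density = ed$within_density,
        between_density = ed$between_density)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("robustness_summary", class(out))
  out
}

#' Write a robustness summary as TSV
#'
#' @param summary a [robustness_run()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_robustness_summary <- function(summary, path) {
  utils::write.table(as.data.frame(summary), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
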