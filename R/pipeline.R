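#' Pipeline configuration
#'
#' Everything needed for a full run: input paths, metric, Mapper and density
#' hyperparameters, output directory and seed. Round-trips losslessly
#' through a `key = value` text file (see [read_pipeline_config()]).
#'
#' @param abundance path to the abundance TSV/CSV.
#' @param metadata path to the metadata TSV (`NULL` for a stub).
#' @param out_dir output directory.
#' @param metric `"js"` or `"aitchison"`.
#' @param format `"tsv"` or `"csv"`.
#' @param orientation `"samples_as_rows"` or `"taxa_as_rows"`.
#' @param mapper a [mapper_config()].
#' @param k density neighbourhood size; `NULL` = 10% of samples.
#' @param seed integer seed (layout and rarefaction streams).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(abundance, metadata = NULL, out_dir = ".",
                            metric = c("js", "aitchison"),
                            format = c("tsv", "csv"),
                            orientation = c("samples_as_rows",
                                            "taxa_as_rows"),
                            mapper = mapper_config(), k = NULL, seed = 1L) {
  structure(list(abundance = abundance, metadata = metadata,
                 out_dir = out_dir, metric = match.arg(metric),
                 format = match.arg(format),
                 orientation = match.arg(orientation),
                 mapper = mapper, k = k, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' Plain `key = value` text mirroring the Mapper hyperparameter table:
#' `n_intervals_1`, `n_intervals_2`, `overlap_pct`, `n_hist_bins`, plus the
#' pipeline fields (`abundance`, `metadata`, `out_dir`, `metric`, `format`,
#' `orientation`, `k`, `seed`).
#'
#' @param path config file path.
#' @return [read_pipeline_config()] returns a `pipeline_config`;
#'   [write_pipeline_config()] returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=")
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  conf <- stats::setNames(as.list(vals), keys)
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  pipeline_config(
    abundance = conf$abundance,
    metadata = if (identical(conf$metadata, "") ||
                   is.null(conf$metadata)) NULL else conf$metadata,
    out_dir = if (is.null(conf$out_dir)) "." else conf$out_dir,
    metric = if (is.null(conf$metric)) "js" else conf$metric,
    format = if (is.null(conf$format)) "tsv" else conf$format,
    orientation = if (is.null(conf$orientation)) "samples_as_rows"
                  else conf$orientation,
    mapper = mapper_config(
      n_intervals = c(num(conf$n_intervals_1, 10), num(conf$n_intervals_2,
                                                       10)),
      overlap_pct = num(conf$overlap_pct, 50),
      n_hist_bins = num(conf$n_hist_bins, 10),
      seed = num(conf$seed, 1)),
    k = if (is.null(conf$k) || conf$k == "") NULL else as.integer(conf$k),
    seed = as.integer(num(conf$seed, 1)))
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lines <- c(
    paste("abundance =", config$abundance),
    paste("metadata =", if (is.null(config$metadata)) "" else
      config$metadata),
    paste("out_dir =", config$out_dir),
    paste("metric =", config$metric),
    paste("format =", config$format),
    paste("orientation =", config$orientation),
    paste("n_intervals_1 =", config$mapper$n_intervals[1]),
    paste("n_intervals_2 =", config$mapper$n_intervals[2]),
    paste("overlap_pct =", config$mapper$overlap_pct),
    paste("n_hist_bins =", config$mapper$n_hist_bins),
    paste("k =", if (is.null(config$k)) "" else config$k),
    paste("seed =", config$seed))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full pipeline and write its artifacts
#'
#' distance -> Mapper -> density -> states. Writes, under `out_dir`:
#' `distances.tsv` (square distance matrix), `mapper.graphml` (graph with
#' density and state attributes), `states.tsv` (vertex-level partition),
#' `sample_states.tsv` (per-sample label sets) and `manifest.json`
#' (config, seed, package and R versions, hyperparameter heuristic report).
#' Deterministic given inputs, config and seed (layout excluded).
#'
#' @param config a [pipeline_config()].
#' @return list with the in-memory results: `table`, `D`, `graph`,
#'   `density`, `partition`, `sample_states`, `check`, `artifacts` (named
#'   paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(config$abundance))
    stop("[input] abundance file not found: ", config$abundance)
  meta <- if (!is.null(config$metadata)) {
    if (!file.exists(config$metadata))
      stop("[input] metadata file not found: ", config$metadata)
    read_sample_metadata(config$metadata)
  } else NULL
  t <- read_abundance_table(config$abundance, format = config$format,
                            orientation = config$orientation, meta = meta)
  t <- to_relative_abundance(t)
  D <- tryCatch(pairwise_distances(t, metric = config$metric),
                error = function(e) stop("[distance] ",
                                         conditionMessage(e), call. = FALSE))
  g <- tryCatch(run_mapper(D, config$mapper),
                error = function(e) stop("[mapper] ", conditionMessage(e),
                                         call. = FALSE))
  k <- if (is.null(config$k)) default_k(nrow(D)) else config$k
  ps <- tryCatch(partition_states(g, D, k),
                 error = function(e) stop("[states] ", conditionMessage(e),
                                          call. = FALSE))
  ss <- sample_states(g, ps$partition)
  chk <- check_hyperparameters(g, nrow(D))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    distances = file.path(config$out_dir, "distances.tsv"),
    graph = file.path(config$out_dir, "mapper.graphml"),
    states = file.path(config$out_dir, "states.tsv"),
    sample_states = file.path(config$out_dir, "sample_states.tsv"),
    manifest = file.path(config$out_dir, "manifest.json"))
  write_distance_matrix(D, paths["distances"])
  export_mapper_graph(g, paths["graph"], density = ps$density$density,
                      states = ps$partition$state_of)
  write_state_partition(g, ps$density, ps$partition, paths["states"],
                        sample_path = paths["sample_states"])
  manifest <- list(
    config = list(abundance = config$abundance,
                  metadata = config$metadata, metric = config$metric,
                  n_intervals = config$mapper$n_intervals,
                  overlap_pct = config$mapper$overlap_pct,
                  n_hist_bins = config$mapper$n_hist_bins,
                  k = k, seed = config$seed),
    hyperparameter_check = chk,
    n_samples = nrow(D),
    versions = list(package = as.character(utils::packageVersion(
      "mapperstates")), R = R.version.string))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  list(table = t, D = D, graph = g, density = ps$density,
       maxima = ps$maxima, partition = ps$partition, sample_states = ss,
       check = chk, artifacts = paths)
}

#' Correlation analysis over pipeline outputs
#'
#' Builds the membership series for one subject (optionally windowed) and
#' computes the temporal correlation function for one state, writing a TSV
#' and optionally a plot.
#'
#' @param sample_states named list from [sample_states()] (or the
#'   `sample_states.tsv` artifact read back).
#' @param meta metadata data frame.
#' @param subject subject ID.
#' @param state state label.
#' @param window optional `(t_min, t_max)`.
#' @param out_tsv,out_plot optional output paths.
#' @param bandwidth optional smoothing bandwidth for the plot.
#' @return the `correlation_series`, invisibly.
#' @export
correlate_states <- function(sample_states, meta, subject, state,
                             window = NULL, out_tsv = NULL,
                             out_plot = NULL, bandwidth = NULL) {
  if (!subject %in% meta$subject)
    stop("unknown subject '", subject, "'; valid: ",
         paste(unique(meta$subject), collapse = ", "))
  s <- membership_series(sample_states, meta, subject, window)
  all_states <- sort(unique(unlist(s$labels)))
  if (!as.character(state) %in% all_states)
    stop("state '", state, "' not visited; valid: ",
         paste(all_states, collapse = ", "))
  cs <- temporal_correlation(s, state)
  if (!is.null(out_tsv)) write_correlation(cs, out_tsv)
  if (!is.null(out_plot)) {
    grDevices::png(out_plot, width = 700, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(cs, bandwidth = bandwidth)
  }
  invisible(cs)
}

#' Read a sample_states.tsv artifact back into a label-set list
#'
#' @param path the `sample_states.tsv` written by [run_pipeline()].
#' @return named list of character label vectors.
#' @export
read_sample_states <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  stats::setNames(strsplit(df$states, ";", fixed = TRUE), df$sample_id)
}

#' Plot a Mapper graph
#'
#' Seed-controlled Fruchterman-Reingold layout; vertex area encodes member
#' count; optional vertex colouring by state or any per-vertex value.
#' Layout is presentation-only: conclusions should rest on connectivity.
#'
#' @param x a `mapper_graph`.
#' @param color optional per-vertex labels (character) or numeric values.
#' @param seed layout seed.
#' @param ... further arguments to `igraph::plot.igraph`.
#' @return `x`, invisibly.
#' @export
plot.mapper_graph <- function(x, color = NULL, seed = 1L, ...) {
  ig <- mapper_to_igraph(x)
  sizes <- vapply(x$vertices, function(v) length(v$members), integer(1))
  set.seed(seed)
  lay <- igraph::layout_with_fr(ig)
  cols <- if (is.null(color)) "steelblue" else {
    f <- as.factor(color)
    pal <- grDevices::hcl.colors(max(3, nlevels(f)), "Dark 3")
    pal[as.integer(f)]
  }
  igraph::plot.igraph(ig, layout = lay,
                      vertex.size = 5 + 10 * sqrt(sizes / max(sizes)),
                      vertex.color = cols, vertex.label = NA, ...)
  invisible(x)
}

#' Command-line entry point
#'
#' Subcommands: `run`, `correlate`, `rarefy`, `simulate`, `check-params`.
#' Arguments are `--key value` pairs; `run` takes `--config <file>`
#' (see [read_pipeline_config()]) plus optional overrides. Designed to be
#' called from an `Rscript` wrapper:
#' `Rscript -e 'mapperstates::mapper_cli()' run --config conf.txt`.
#'
#' @param args character vector of arguments (default: the command line).
#' @return exit status 0 invisibly; errors raise conditions (nonzero exit
#'   under Rscript).
#' @export
mapper_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: mapper_cli <run|correlate|rarefy|simulate|check-params> ",
         "[--key value ...]")
  cmd <- args[1]
  opts <- .parse_opts(args[-1])
  getopt <- function(name, default = NULL) {
    if (!is.null(opts[[name]])) opts[[name]] else default
  }
  switch(cmd,
    run = {
      config <- read_pipeline_config(getopt("config",
        stop("run requires --config")))
      if (!is.null(opts$out_dir)) config$out_dir <- opts$out_dir
      res <- run_pipeline(config)
      message("wrote: ", paste(res$artifacts, collapse = ", "))
      message("largest vertex fraction: ",
              format(res$check$largest_vertex_fraction),
              "; singleton components: ",
              res$check$n_singleton_components)
    },
    correlate = {
      ss <- read_sample_states(getopt("states",
        stop("correlate requires --states")))
      meta <- read_sample_metadata(getopt("metadata",
        stop("correlate requires --metadata")))
      window <- if (!is.null(opts$window))
        as.numeric(strsplit(opts$window, ",")[[1]]) else NULL
      correlate_states(ss, meta, getopt("subject"), getopt("state"),
                       window = window,
                       out_tsv = getopt("out", "correlation.tsv"),
                       out_plot = getopt("plot"),
                       bandwidth = if (!is.null(opts$bandwidth))
                         as.numeric(opts$bandwidth) else NULL)
    },
    rarefy = {
      config <- read_pipeline_config(getopt("config",
        stop("rarefy requires --config")))
      meta <- if (!is.null(config$metadata))
        read_sample_metadata(config$metadata) else NULL
      t <- read_abundance_table(config$abundance, format = config$format,
                                orientation = config$orientation,
                                meta = meta)
      t <- to_relative_abundance(t)
      plan <- rarefaction_plan(
        fractions = as.numeric(strsplit(getopt("fractions", "0.9,0.5,0.1"),
                                        ",")[[1]]),
        replicates = as.integer(getopt("replicates", "10")),
        config = config$mapper, seed = config$seed)
      summ <- robustness_run(t, plan, getopt("feature", "subject"))
      write_robustness_summary(summ, getopt("out", "robustness.tsv"))
    },
    simulate = {
      kind <- getopt("kind", "markov")
      seed <- as.integer(getopt("seed", "1"))
      sim <- if (kind == "antagonistic")
        simulate_antagonistic(n_samples = as.integer(getopt("n", "200")),
                              seed = seed)
      else
        simulate_markov_community(
          S = as.integer(getopt("states", "3")),
          n_timepoints = as.integer(getopt("n", "300")), seed = seed)
      write_simulation(sim, getopt("out", "."), prefix = kind)
    },
    `check-params` = {
      config <- read_pipeline_config(getopt("config",
        stop("check-params requires --config")))
      res <- run_pipeline(config)
      cat(jsonlite::toJSON(res$check, auto_unbox = TRUE, pretty = TRUE),
          "\n")
    },
    stop("unknown subcommand '", cmd, "'"))
  invisible(0L)
}

.parse_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      key <- sub("^--", "", args[i])
      if (i + 1 <= length(args) && !startsWith(args[i + 1], "--")) {
        opts[[key]] <- args[i + 1]; i <- i + 2
      } else { opts[[key]] <- TRUE; i <- i + 1 }
    } else i <- i + 1
  }
  opts
}
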