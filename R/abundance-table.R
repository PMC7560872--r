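#' Construct an abundance table
#'
#' The central data container: a sample-by-taxon matrix of non-negative
#' abundances (counts or relative abundances) together with per-sample
#' metadata. Rows are samples, columns are taxa/OTUs/ecotypes.
#'
#' @param values numeric matrix, samples in rows, taxa in columns. Row and
#'   column names are used as sample and taxon IDs; unnamed dimensions get
#'   `sample1..n` / `taxon1..m`.
#' @param meta data frame with one row per sample and at least columns
#'   `sample_id`, `subject` and `time`. If `NULL`, a stub with
#'   `subject = "all"` and `time = 1..n` is created.
#' @return An object of class `abundance_table`: a list with elements
#'   `values` (matrix), `samples`, `taxa` and `meta` (data frame keyed by
#'   `sample_id`).
#' @examples
#' m <- matrix(c(2, 2, 1, 3), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("taxA", "taxB")))
#' abundance_table(m)
#' @export
abundance_table <- function(values, meta = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- paste0("sample", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("taxon", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("abundance values must be finite")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative abundance at sample '", rownames(values)[bad[1]],
         "', taxon '", colnames(values)[bad[2]], "'")
  }
  zero <- rowSums(values) == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " all-zero sample(s): ",
            paste(rownames(values)[zero], collapse = ", "))
    values <- values[!zero, , drop = FALSE]
  }
  if (nrow(values) == 0L) stop("no samples left after dropping zero rows")
  if (is.null(meta)) {
    meta <- data.frame(sample_id = rownames(values),
                       subject = "all",
                       time = seq_len(nrow(values)),
                       stringsAsFactors = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("sample_id", "subject", "time")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("metadata lacks required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample IDs in metadata")
  absent <- setdiff(rownames(values), meta$sample_id)
  if (length(absent))
    stop("metadata missing for sample(s): ", paste(absent, collapse = ", "))
  meta <- meta[match(rownames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  meta$time <- as.numeric(meta$time)
  structure(list(values = values,
                 samples = rownames(values),
                 taxa = colnames(values),
                 meta = meta),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table: ", length(x$samples), " samples x ",
      length(x$taxa), " taxa\n", sep = "")
  cat("  subjects: ", paste(unique(x$meta$subject), collapse = ", "), "\n",
      sep = "")
  rs <- rowSums(x$values)
  cat("  row sums in [", format(min(rs)), ", ", format(max(rs)), "]\n",
      sep = "")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Read an abundance table from a delimited text file
#'
#' Reads a TSV/CSV table with a header row and first column of IDs. The
#' on-disk orientation is declared by `orientation`; the returned table is
#' always samples-as-rows. All-zero samples are dropped with a warning.
#'
#' @param path path to the file.
#' @param format `"tsv"` or `"csv"`.
#' @param orientation `"samples_as_rows"` (default) or `"taxa_as_rows"`.
#' @param meta optional metadata data frame (see [abundance_table()]); if
#'   `NULL` a stub is created.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path,
                                 format = c("tsv", "csv"),
                                 orientation = c("samples_as_rows",
                                                 "taxa_as_rows"),
                                 meta = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (format == "tsv") "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df, 2, as.numeric))),
                 arr.ind = TRUE)
    line <- if (length(bad)) bad[1, 1] + 1L else NA_integer_
    stop("non-numeric cell in ", path, " near line ", line)
  }
  if (orientation == "taxa_as_rows") m <- t(m)
  abundance_table(m, meta = meta)
}

#' Read a sample metadata table
#'
#' TSV with mandatory columns `sample_id`, `subject`, `time`; extra columns
#' (phenotype, depth, ...) are carried through as labels.
#'
#' @param path path to a tab-separated file.
#' @return data frame.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "subject", "time")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("metadata file lacks column(s): ", paste(miss, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  meta$time <- as.numeric(meta$time)
  meta
}

#' Normalize an abundance table to relative abundances
#'
#' Divides each sample (row) by its total, so rows are compositions summing
#' to one. Idempotent; zero cells stay zero.
#'
#' @param t an [abundance_table()].
#' @return An [abundance_table()] whose rows sum to 1.
#' @export
to_relative_abundance <- function(t) {
  stopifnot(inherits(t, "abundance_table"))
  rs <- rowSums(t$values)
  if (any(rs <= 0))
    stop("zero-sum sample(s): ",
         paste(t$samples[rs <= 0], collapse = ", "))
  t$values <- t$values / rs
  t
}

#' Drop taxa absent from every sample
#'
#' Taxa with zero total abundance carry no distance information and are
#' removed before phase-space construction.
#'
#' @param t an [abundance_table()].
#' @return An [abundance_table()] without all-zero taxa.
#' @export
drop_empty_taxa <- function(t) {
  stopifnot(inherits(t, "abundance_table"))
  keep <- colSums(t$values) > 0
  t$values <- t$values[, keep, drop = FALSE]
  t$taxa <- colnames(t$values)
  t
}
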