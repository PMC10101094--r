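#' Construct a validated sample-by-genus abundance table
#'
#' The abundance table is the universal currency of the package: a numeric
#' matrix with samples as rows and genera as columns, carrying either raw
#' counts or relative abundances (rows summing to one).
#'
#' @param values Numeric matrix, samples in rows, genera in columns. Must
#'   have unique, non-empty row and column names.
#' @param is_relative Logical; `TRUE` if each row is a relative-abundance
#'   vector summing to one.
#' @return An object of class `abundance_table`: a list with elements
#'   `values` (the matrix), `sample_ids`, `taxon_ids` and `is_relative`.
#' @export
abundance_table <- function(values, is_relative = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x taxa)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry sample ids as rownames and taxon ids as colnames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    stop("duplicate taxon ids: ", paste(dup, collapse = ", "))
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative abundance at sample '%s', taxon '%s'",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]))
  }
  if (isTRUE(is_relative)) {
    rs <- rowSums(values)
    if (any(abs(rs - 1) > 1e-9)) {
      bad <- rownames(values)[abs(rs - 1) > 1e-9]
      stop("is_relative = TRUE but rows do not sum to 1: ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  structure(
    list(values = values,
         sample_ids = rownames(values),
         taxon_ids = colnames(values),
         is_relative = isTRUE(is_relative)),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d genera (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_relative) "relative" else "counts"))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Read an abundance table from TSV
#'
#' Expects a header row whose first column is `sample_id` and remaining
#' columns are genus names, with a numeric body. If the file is transposed
#' (genera in rows, a `sample_id` entry heading the columns is absent but the
#' first header cell is `sample_id`-less), orientation is auto-detected from
#' the position of the `sample_id` header and the matrix is transposed so
#' rows are always samples.
#'
#' @param path Path to a UTF-8, tab-separated file.
#' @param is_relative Declare the body as relative abundances.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, is_relative = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("abundance TSV needs a sample_id column plus at least one genus")
  first <- names(df)[1]
  if (!identical(first, "sample_id")) {
    # transposed layout: first column holds taxon ids, header holds sample ids
    taxa <- as.character(df[[1]])
    body <- df[, -1, drop = FALSE]
    m <- t(as.matrix(body))
    colnames(m) <- taxa
    rownames(m) <- names(body)
  } else {
    ids <- as.character(df[[1]])
    body <- df[, -1, drop = FALSE]
    m <- as.matrix(body)
    rownames(m) <- ids
  }
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)
    if (length(bad)) {
      stop(sprintf("malformed numeric cell at row '%s', column '%s' in %s",
                   rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], path))
    }
  }
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf("malformed numeric cell at row '%s', column '%s' in %s",
                 rownames(m)[idx[1, 1]], colnames(m)[idx[1, 2]], path))
  }
  abundance_table(m, is_relative = is_relative)
}

#' Write an abundance table to TSV
#'
#' Inverse of [read_abundance_table()]: first column `sample_id`, one column
#' per genus.
#'
#' @param x An `abundance_table`.
#' @param path Output path.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(inherits(x, "abundance_table"))
  df <- data.frame(sample_id = x$sample_ids, x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata from TSV
#'
#' Validates the presence of `sample_id`, uniqueness, and coordinate ranges.
#' City characteristics used downstream (city, surface_type, latitude,
#' longitude, elevation, population, population_density, coastal_proximity,
#' region, continent, avg_june_temp, koppen_climate) are kept as-is; extra
#' columns pass through.
#'
#' @param path Path to a tab-separated metadata file with a `sample_id`
#'   column.
#' @return A data.frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  md <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_metadata(md)
}

#' @keywords internal
validate_sample_metadata <- function(md) {
  if (!"sample_id" %in% names(md)) stop("metadata must contain a sample_id column")
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample ids in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  }
  if ("latitude" %in% names(md) &&
      any(md$latitude < -90 | md$latitude > 90, na.rm = TRUE)) {
    stop("latitude outside [-90, 90]")
  }
  if ("longitude" %in% names(md) &&
      any(md$longitude < -180 | md$longitude > 180, na.rm = TRUE)) {
    stop("longitude outside [-180, 180]")
  }
  md
}

#' Drop genera lacking a phylum-level assignment
#'
#' Reads not assigned at the phylum level are removed before any analysis;
#' the marker is a configurable regular expression matched against taxon ids.
#'
#' @param x An `abundance_table`.
#' @param pattern Regular expression identifying unassigned taxa
#'   (case-insensitive). The default matches common "unassigned" /
#'   "unclassified" labelling conventions.
#' @return The table without matching columns; errors if nothing remains.
#' @export
remove_unassigned <- function(x, pattern = "unassigned|unclassified|no_phylum") {
  stopifnot(inherits(x, "abundance_table"))
  drop <- grepl(pattern, x$taxon_ids, ignore.case = TRUE)
  if (all(drop)) stop("removing unassigned taxa would empty the table")
  if (!any(drop)) return(x)
  abundance_table(x$values[, !drop, drop = FALSE], is_relative = FALSE)
}

#' Convert counts to relative abundances
#'
#' Each row is divided by its sum. Idempotent on already-relative tables.
#'
#' @param x An `abundance_table` with strictly positive row sums.
#' @return A relative `abundance_table`.
#' @export
to_relative <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  rs <- rowSums(x$values)
  if (any(rs <= 0)) {
    stop("zero-sum samples: ",
         paste(x$sample_ids[rs <= 0], collapse = ", "))
  }
  abundance_table(x$values / rs, is_relative = TRUE)
}

#' Aggregate finer-rank columns to genus level
#'
#' Columns whose ids share the same leading genus token (text before the
#' first whitespace, semicolon or pipe) are summed.
#'
#' @param x An `abundance_table`.
#' @return An `abundance_table` with one column per genus token.
#' @export
aggregate_genus <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  genus <- sub("[[:space:];|].*$", "", x$taxon_ids)
  if (!anyDuplicated(genus)) {
    colnames(x$values) <- genus
    return(abundance_table(x$values, is_relative = x$is_relative))
  }
  agg <- t(rowsum(t(x$values), group = genus))
  agg <- agg[, unique(genus), drop = FALSE]
  abundance_table(agg, is_relative = x$is_relative)
}

#' Subset table and metadata by a metadata predicate
#'
#' @param x An `abundance_table`.
#' @param metadata Metadata data.frame with `sample_id`.
#' @param predicate Either a function of the metadata data.frame returning a
#'   logical vector, or a logical vector of length `nrow(metadata)`.
#' @return A list with elements `table` and `metadata`, aligned in the same
#'   sample order.
#' @export
filter_samples <- function(x, metadata, predicate) {
  stopifnot(inherits(x, "abundance_table"))
  validate_sample_metadata(metadata)
  keep <- if (is.function(predicate)) predicate(metadata) else predicate
  if (!is.logical(keep) || length(keep) != nrow(metadata)) {
    stop("predicate must yield one logical per metadata row")
  }
  keep[is.na(keep)] <- FALSE
  md <- metadata[keep, , drop = FALSE]
  ids <- intersect(md$sample_id, x$sample_ids)
  if (length(ids) == 0) stop("no samples match the predicate")
  md <- md[match(ids, md$sample_id), , drop = FALSE]
  rownames(md) <- NULL
  tab <- abundance_table(x$values[ids, , drop = FALSE], is_relative = x$is_relative)
  list(table = tab, metadata = md)
}

#' Write a result data.frame as TSV
#'
#' @param df A data.frame.
#' @param path Output path.
#' @export
write_result_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
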