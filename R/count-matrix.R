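#' SAR11 ecotype vocabulary
#'
#' Controlled vocabulary of ecotype labels used throughout the package.
#' `"other"` marks non-SAR11 amplicons.
#'
#' @export
ECOTYPE_LEVELS <- c("Ia.1", "Ia.3", "Ia.4", "Ib", "Ib.2", "I", "II", "IIa",
                    "IIa.A", "IIa.B", "IIb", "IIIa", "IV", "other")

#' Construct a dated ASV count matrix
#'
#' The pipeline's raw input: a samples x ASVs matrix of non-negative integer
#' amplicon counts, with one calendar date per sample.
#'
#' @param counts numeric matrix, samples as rows, ASVs as columns; must be
#'   non-negative integers. Row names are sample ids, column names ASV ids.
#' @param dates `Date` vector (or ISO-8601 strings), one per sample.
#' @param sample_ids,asv_ids optional identifiers overriding the dimnames.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix), `dates` (`Date`), `sample_ids`, `asv_ids`.
#' @export
count_matrix <- function(counts, dates, sample_ids = NULL, asv_ids = NULL) {
  counts <- as.matrix(counts)
  sample_ids <- sample_ids %||% rownames(counts) %||%
    paste0("S", seq_len(nrow(counts)))
  asv_ids <- asv_ids %||% colnames(counts) %||%
    paste0("ASV", seq_len(ncol(counts)))
  dates <- as.Date(dates)
  dimnames(counts) <- list(sample_ids, asv_ids)
  obj <- structure(list(counts = counts, dates = dates,
                        sample_ids = sample_ids, asv_ids = asv_ids),
                   class = "count_matrix")
  validate_count_matrix(obj)
}

validate_count_matrix <- function(x) {
  counts <- x$counts
  if (anyNA(counts)) stop("counts contain missing values")
  bad <- which(counts < 0 | abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "counts must be non-negative integers; first offending cell: sample '%s', ASV '%s' (value %g)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      counts[bad[1, 1], bad[1, 2]]))
  }
  storage.mode(x$counts) <- "integer"
  if (anyDuplicated(x$sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(x$sample_ids[duplicated(x$sample_ids)]), collapse = ", "))
  if (anyDuplicated(x$asv_ids))
    stop("duplicate ASV ids: ",
         paste(unique(x$asv_ids[duplicated(x$asv_ids)]), collapse = ", "))
  if (length(x$dates) != nrow(counts))
    stop("need exactly one date per sample")
  if (anyNA(x$dates)) stop("dates contain NA or failed to parse")
  x
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d samples x %d ASVs, %s to %s, %s reads\n",
              nrow(x$counts), ncol(x$counts), min(x$dates), max(x$dates),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' Subset a count matrix by sample and/or ASV
#' @param x a `count_matrix`.
#' @param samples,asvs index vectors (logical, integer or character).
#' @export
subset_count_matrix <- function(x, samples = NULL, asvs = NULL) {
  si <- samples %||% seq_len(nrow(x$counts))
  ai <- asvs %||% seq_len(ncol(x$counts))
  if (is.character(si)) si <- match(si, x$sample_ids)
  if (is.character(ai)) ai <- match(ai, x$asv_ids)
  count_matrix(x$counts[si, ai, drop = FALSE], x$dates[if (is.logical(si)) which(si) else si])
}

#' Read a dated ASV count table
#'
#' Supported formats: delimited text (`tsv`/`csv`) with samples as rows and a
#' `date` column (or dates supplied separately), and BIOM JSON (dense or
#' sparse; requires the biomformat package).
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"csv"`, `"biom-json"`.
#' @param dates optional `Date` vector overriding/providing per-sample dates
#'   (matched to the file's sample order).
#' @param orientation `"samples_rows"` (default) or `"asvs_rows"` for the
#'   delimited formats.
#' @return a [count_matrix()].
#' @export
read_count_table <- function(path, format = c("tsv", "csv", "biom-json"),
                             dates = NULL,
                             orientation = c("samples_rows", "asvs_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "biom-json") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))  # biom is obs x samples
    if (is.null(dates)) {
      sm <- biomformat::sample_metadata(b)
      if (is.null(sm) || !"date" %in% colnames(sm))
        stop("BIOM file has no 'date' sample metadata; pass `dates`")
      dates <- as.Date(sm[rownames(m), "date"])
    }
    cm <- count_matrix(m, dates)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    rownames(df) <- df[[1]]
    df[[1]] <- NULL
    if ("date" %in% colnames(df)) {
      if (is.null(dates)) dates <- as.Date(df[["date"]])
      df[["date"]] <- NULL
    }
    m <- as.matrix(df)
    if (orientation == "asvs_rows") m <- t(m)
    if (is.null(dates))
      stop("no 'date' column in file and no `dates` supplied")
    cm <- count_matrix(m, dates)
  }
  message(sprintf("read %d samples x %d ASVs (%s total reads) from %s",
                  nrow(cm$counts), ncol(cm$counts),
                  format(sum(as.numeric(cm$counts)), big.mark = ","),
                  basename(path)))
  cm
}

#' Write a count matrix to delimited text
#'
#' Writes samples as rows with a leading sample-id column and a `date`
#' column, so that [read_count_table()] round-trips exactly.
#'
#' @param cm a `count_matrix`.
#' @param path output path.
#' @param format `"tsv"` or `"csv"`.
#' @export
write_count_table <- function(cm, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  df <- data.frame(sample_id = cm$sample_ids,
                   date = as.character(cm$dates),
                   cm$counts, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ASV -> ecotype taxonomy map
#'
#' Two-column delimited file (`asv_id`, `ecotype`). Labels outside the
#' controlled vocabulary are mapped to `"other"` with a warning.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return named character vector: `asv_id -> ecotype`.
#' @export
read_taxonomy <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  taxonomy_map(stats::setNames(df[[2]], df[[1]]))
}

#' Validate / normalise a taxonomy map
#' @param tax named character vector, `asv_id -> ecotype label`.
#' @export
taxonomy_map <- function(tax) {
  tax <- vapply(tax, as.character, character(1))
  unknown <- setdiff(unique(tax), ECOTYPE_LEVELS)
  if (length(unknown) > 0) {
    warning("unknown ecotype labels mapped to 'other': ",
            paste(unknown, collapse = ", "))
    tax[tax %in% unknown] <- "other"
  }
  tax
}

#' Write a taxonomy map
#' @param tax named character vector.
#' @param path output path.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(data.frame(asv_id = names(tax), ecotype = unname(tax)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an environmental metadata table
#'
#' CSV with a `date` column and one column per variable; missing values
#' permitted. Returns a data frame with a `Date` `date` column first.
#'
#' @param path file path.
#' @export
read_env_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"date" %in% colnames(df)) stop("env table needs a 'date' column")
  df$date <- as.Date(df$date)
  if (anyDuplicated(colnames(df))) stop("duplicate variable names in env table")
  df[order(df$date), c("date", setdiff(colnames(df), "date"))]
}

#' Write an environmental metadata table
#' @param env data frame with a `date` column.
#' @param path output path.
#' @export
write_env_table <- function(env, path) {
  utils::write.csv(env, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
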