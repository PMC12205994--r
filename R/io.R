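# Readers and writers for the external formats the pipeline touches:
# expression matrices (plain TSV or GEO series-matrix dialect), per-sample
# clinical tables, and GMT gene-signature files. No statistics live here.

#' Read a probe-by-sample expression matrix
#'
#' Reads nonnegative expression intensities into a numeric matrix with probe
#' identifiers as row names and sample identifiers as column names. Two
#' dialects are supported: `plain_tsv` (header row `probe_id` followed by
#' sample IDs) and `series_matrix`, the GEO series-matrix flavour, in which
#' only the block between the `series_matrix_table_begin` and
#' `series_matrix_table_end` marker lines is parsed (sample metadata lines are
#' ignored; clinical annotation enters through [read_clinical_table()]).
#' Quoted identifiers are unquoted on load. Identifiers are case-sensitive and
#' never remapped.
#'
#' @param path Path to the file. UTF-8; both LF and CRLF line endings accepted.
#' @param dialect `"plain_tsv"` or `"series_matrix"`.
#' @param missing Policy for missing cells: `"error"` (default; summarized
#'   matrices are expected to be complete) rejects the file, `"drop_probe"`
#'   removes every probe with at least one missing value.
#' @return A numeric matrix, probes in rows, samples in columns, column order
#'   as in the file.
#' @seealso [write_expression_matrix()] for the exact-precision inverse.
#' @export
read_expression_matrix <- function(path,
                                   dialect = c("plain_tsv", "series_matrix"),
                                   missing = c("error", "drop_probe")) {
  dialect <- match.arg(dialect)
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (dialect == "series_matrix") {
    beg <- grep("series_matrix_table_begin", lines, fixed = TRUE)
    end <- grep("series_matrix_table_end", lines, fixed = TRUE)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
      stop("series-matrix table markers not found in ", path)
    lines <- lines[(beg + 1L):(end - 1L)]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("no expression rows in ", path)

  # sentinel keeps trailing empty fields that strsplit would drop
  fields <- strsplit(paste0(lines, "\x01"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) {
    f[length(f)] <- sub("\x01$", "", f[length(f)])
    f
  })
  unquote <- function(x) gsub('^"|"$', "", x)
  header <- unquote(fields[[1L]])
  sample_ids <- header[-1L]
  if (length(sample_ids) == 0L) stop("no sample columns in ", path)
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stop("duplicate sample ID: ", dup[1L])

  ncells <- lengths(fields[-1L])
  if (any(ncells != length(header)))
    stop("row ", which(ncells != length(header))[1L] + 1L,
         " does not have ", length(header), " fields")
  body <- matrix(unquote(unlist(fields[-1L], use.names = FALSE)),
                 ncol = length(header), byrow = TRUE)
  probe_ids <- body[, 1L]
  dup <- probe_ids[duplicated(probe_ids)]
  if (length(dup)) stop("duplicate probe ID: ", dup[1L])

  raw <- body[, -1L, drop = FALSE]
  was_blank <- raw == "" | toupper(raw) %in% c("NA", "NULL")
  values <- suppressWarnings(as.numeric(raw))
  bad <- is.na(values) & !was_blank
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("non-numeric value in row ", ((i - 1L) %% nrow(body)) + 1L)
  }
  values <- matrix(values, nrow = nrow(body),
                   dimnames = list(probe_ids, sample_ids))
  if (anyNA(values)) {
    if (missing == "error") {
      idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
      stop("missing value at probe ", probe_ids[idx[1L]],
           ", sample ", sample_ids[idx[2L]],
           " (use missing = \"drop_probe\" to discard such probes)")
    }
    drop <- rowSums(is.na(values)) > 0L
    message("dropping ", sum(drop), " probe(s) with missing values")
    values <- values[!drop, , drop = FALSE]
    if (nrow(values) == 0L) stop("all probes dropped by missing-value policy")
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop("negative value at probe ", rownames(values)[neg[1L, 1L]],
         ", sample ", colnames(values)[neg[1L, 2L]])
  }
  values
}

#' Write an expression matrix as plain TSV
#'
#' Serializes with 17 significant digits so that a write/read round trip
#' through [read_expression_matrix()] reproduces the values bit for bit.
#'
#' @param x Numeric matrix with probe row names and sample column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  fmt <- formatC(x, format = "g", digits = 17)
  rows <- apply(fmt, 1L, paste, collapse = "\t")
  lines <- c(paste(c("probe_id", colnames(x)), collapse = "\t"),
             paste(rownames(x), rows, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

.clinical_columns <- c(
  "sample_id", "ihc_score", "faint_staining_flag", "fish_ratio",
  "fish_status", "hr_status", "time_rfs", "event_rfs",
  "time_dmfs", "event_dmfs", "time_os", "event_os"
)

.parse_flag <- function(x) {
  out <- rep(NA, length(x))
  out[toupper(x) %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[toupper(x) %in% c("FALSE", "F", "0", "NO")] <- FALSE
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) stop("row ", which(bad)[1L], ": unparsable flag '",
                     x[bad][1L], "'")
  out
}

#' Read a per-sample clinical table
#'
#' Tab-separated with a header of canonical column names: `sample_id`,
#' `ihc_score` (0-3), `faint_staining_flag` (IHC-0 with faint or incomplete
#' membrane staining in at most 10% of cells, the HER2-ultralow pattern),
#' `fish_ratio`, `fish_status`, `hr_status` (`positive`/`negative`), and the
#' survival endpoints `time_rfs`/`event_rfs`, `time_dmfs`/`event_dmfs`,
#' `time_os`/`event_os` (times in months, events 1 = event / 0 = censored).
#' Unknown columns are ignored; empty cells become `NA`, never zero. An event
#' recorded without its time, an IHC score outside 0-3, or a negative time is
#' a row-level error.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with one row per sample and the canonical columns
#'   (missing ones filled with `NA`).
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"), colClasses = "character")
  if (!"sample_id" %in% names(df)) stop("clinical table lacks sample_id column")
  out <- data.frame(sample_id = as.character(df$sample_id),
                    stringsAsFactors = FALSE)
  dup <- out$sample_id[duplicated(out$sample_id)]
  if (length(dup)) stop("duplicate sample_id: ", dup[1L])

  num <- function(col) {
    if (!col %in% names(df)) return(rep(NA_real_, nrow(df)))
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- !is.na(df[[col]]) & is.na(v)
    if (any(bad)) stop("row ", which(bad)[1L], ": non-numeric ", col)
    v
  }
  chr <- function(col, allowed) {
    if (!col %in% names(df)) return(rep(NA_character_, nrow(df)))
    v <- tolower(df[[col]])
    bad <- !is.na(v) & !v %in% allowed
    if (any(bad)) stop("row ", which(bad)[1L], ": ", col, " must be one of ",
                       paste(allowed, collapse = "/"))
    v
  }
  out$ihc_score <- num("ihc_score")
  bad <- !is.na(out$ihc_score) & !out$ihc_score %in% 0:3
  if (any(bad)) stop("row ", which(bad)[1L], ": ihc_score outside {0,1,2,3}")
  out$faint_staining_flag <-
    if ("faint_staining_flag" %in% names(df)) .parse_flag(df$faint_staining_flag)
    else rep(NA, nrow(df))
  out$fish_ratio <- num("fish_ratio")
  bad <- !is.na(out$fish_ratio) & out$fish_ratio <= 0
  if (any(bad)) stop("row ", which(bad)[1L], ": fish_ratio must be positive")
  out$fish_status <- chr("fish_status", c("positive", "negative"))
  out$hr_status <- chr("hr_status", c("positive", "negative"))
  for (ep in c("rfs", "dmfs", "os")) {
    tm <- num(paste0("time_", ep))
    ev <- num(paste0("event_", ep))
    bad <- !is.na(tm) & tm < 0
    if (any(bad)) stop("row ", which(bad)[1L], ": negative time_", ep)
    bad <- !is.na(ev) & !ev %in% c(0, 1)
    if (any(bad)) stop("row ", which(bad)[1L], ": event_", ep,
                       " must be 0 or 1")
    bad <- !is.na(ev) & is.na(tm)
    if (any(bad)) stop("row ", which(bad)[1L], ": event_", ep,
                       " recorded without time_", ep)
    out[[paste0("time_", ep)]] <- tm
    out[[paste0("event_", ep)]] <- ev
  }
  out[.clinical_columns]
}

#' Write a clinical table as TSV
#'
#' Inverse of [read_clinical_table()]; `NA` cells are written empty.
#'
#' @param clinical Data frame with (a subset of) the canonical clinical columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  cols <- intersect(.clinical_columns, names(clinical))
  df <- clinical[cols]
  df[] <- lapply(df, function(v) {
    s <- as.character(v)
    s[is.na(v)] <- ""
    s
  })
  lines <- c(paste(cols, collapse = "\t"),
             do.call(paste, c(unname(df), sep = "\t")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' Standard MSigDB-convention GMT: one signature per line, tab-separated as
#' name, description, then the gene identifiers. The description is discarded
#' and duplicate genes within a line are deduplicated preserving first
#' occurrence.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (signature name -> genes), in
#'   file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) stop("GMT line ", which(short)[1L],
                       " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, character(1L), 1L)
  dup <- nm[duplicated(nm)]
  if (length(dup)) stop("duplicate signature name: ", dup[1L])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  sets
}

#' Write gene signatures to a GMT file
#'
#' @param signatures Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-signature descriptions
#'   (recycled `"na"` when omitted).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path, descriptions = NULL) {
  stopifnot(is.list(signatures), !is.null(names(signatures)))
  if (is.null(descriptions)) descriptions <- rep("na", length(signatures))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(signatures), descriptions, signatures)
  writeLines(unlist(lines), path, useBytes = TRUE)
  invisible(path)
}
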