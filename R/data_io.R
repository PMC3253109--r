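# Canonical column names of the long-format Ct table.
CT_COLUMNS <- c("gene", "sample", "type", "serial", "ct")

# Stage output sheets, named after the workflow's result tables.
STAGE_SHEETS <- c("Efficiency", "M_value", "Pairwise_V", "Exp_ratio")

#' Construct a Ct table from a data frame
#'
#' A `ct_table` is the sole input of the workflow: a long-format table of raw
#' threshold-cycle (Ct) measurements with one row per individual PCR
#' reaction.  Five columns are required: `gene`, `sample`, `type` (treatment
#' group label), `serial` (a positive integer: the dilution level for
#' standard reactions, a technical-replicate index for unknowns) and `ct`.
#' Each record additionally carries a `role` marker distinguishing
#' serial-dilution *standard* reactions (used for efficiency estimation)
#' from *unknown* reactions (used for all downstream quantification).
#'
#' @param df data frame with (at least) the five canonical columns; an
#'   optional `role` column with values `"standard"`/`"unknown"`.
#' @param standard_type character vector of `type` labels that mark standard
#'   (dilution-series) reactions when no explicit `role` column is present.
#'   Default `"standard"`.
#' @return A `ct_table`: a data frame with columns `gene`, `sample`, `type`,
#'   `serial`, `ct`, `role`.  Unparseable or instrument-flagged Ct values
#'   ("Undetermined", "N/A", empty) become `NA` and are excluded from all
#'   computations downstream.
#' @export
as_ct_table <- function(df, standard_type = "standard") {
  stopifnot(is.data.frame(df))
  names(df) <- tolower(names(df))
  missing_cols <- setdiff(CT_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    gene   = trimws(as.character(df$gene)),
    sample = trimws(as.character(df$sample)),
    type   = trimws(as.character(df$type)),
    serial = suppressWarnings(as.integer(df$serial)),
    ct     = parse_ct(df$ct),
    stringsAsFactors = FALSE
  )
  if ("role" %in% names(df)) {
    role <- tolower(trimws(as.character(df$role)))
    bad <- !role %in% c("standard", "unknown")
    if (any(bad)) {
      stop("invalid role value(s): ",
           paste(unique(role[bad]), collapse = ", "), call. = FALSE)
    }
    out$role <- role
  } else {
    out$role <- ifelse(out$type %in% standard_type, "standard", "unknown")
  }
  n_missing <- sum(is.na(out$ct))
  if (n_missing > 0L) {
    warning(n_missing, " record(s) with missing/unparseable Ct are excluded",
            " from all computations", call. = FALSE)
  }
  class(out) <- c("ct_table", "data.frame")
  out
}

# Instrument exports flag failed reactions as "Undetermined"/"N/A"; these are
# parsed to NA rather than aborting the load.
parse_ct <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  miss <- is.na(x) | x == "" |
    tolower(x) %in% c("na", "n/a", "undetermined", "undet", "nan")
  out <- suppressWarnings(as.numeric(x))
  out[miss] <- NA_real_
  if (any(is.na(out) & !miss)) {
    bad <- which(is.na(out) & !miss)
    stop("unparseable Ct value(s) at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "", call. = FALSE)
  }
  out
}

#' Read a raw Ct table from a delimited file
#'
#' Reads a long-format Ct table from CSV or TSV (or, if the `readxl` package
#' is installed, from the first sheet of an xlsx workbook).  Column matching
#' is case-insensitive on the five canonical names `gene`, `sample`, `type`,
#' `serial`, `ct`; a `column_map` can rename non-standard headers.
#' Technical replicates are *not* collapsed at load time: collapsing by
#' arithmetic mean of Ct happens at the start of each analytical stage.
#'
#' @param path path to the input file.
#' @param format `"auto"` (default: by file extension), `"csv"`, `"tsv"` or
#'   `"xlsx"`.
#' @param column_map optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(ct = "Cq")`.
#' @param standard_type passed to [as_ct_table()].
#' @return a [as_ct_table()] `ct_table`, records in file order.
#' @export
read_ct_table <- function(path, format = c("auto", "csv", "tsv", "xlsx"),
                          column_map = NULL, standard_type = "standard") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", xlsx = "xlsx", "tsv")
  }
  if (format == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the 'readxl' package; ",
           "export the sheet as CSV/TSV instead", call. = FALSE)
    }
    df <- as.data.frame(readxl::read_excel(path))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                            stringsAsFactors = FALSE, check.names = FALSE,
                            colClasses = "character")
  }
  names(df) <- tolower(names(df))
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- tolower(column_map[[canon]])
      if (!src %in% names(df)) {
        stop("column_map: column '", column_map[[canon]],
             "' not present in file", call. = FALSE)
      }
      names(df)[names(df) == src] <- tolower(canon)
    }
  }
  as_ct_table(df, standard_type = standard_type)
}

#' Validate a Ct table
#'
#' Checks every record against the input-data invariants and returns a
#' report rather than throwing: Ct must be finite and positive (or flagged
#' missing), identifiers must be non-empty after whitespace trimming,
#' `serial` must be a positive integer, `(gene, sample, serial)` triples
#' must be unique within a role, and every gene carrying standard reactions
#' must cover at least three distinct dilution levels (the standard-curve
#' regression needs three points).
#'
#' @param table a `ct_table`.
#' @return a `ct_validation` object: list with data frames `errors` and
#'   `warnings`, each with columns `row`, `rule`, `message`.  `errors` is
#'   empty if and only if the table satisfies all invariants.
#' @export
validate_ct_table <- function(table) {
  stopifnot(inherits(table, "ct_table"))
  err <- list(); wrn <- list()
  add <- function(store, row, rule, message) {
    c(store, list(data.frame(row = row, rule = rule, message = message,
                             stringsAsFactors = FALSE)))
  }

  bad_ct <- which(!is.na(table$ct) & (!is.finite(table$ct) | table$ct <= 0))
  for (i in bad_ct) {
    err <- add(err, i, "ct_positive",
               sprintf("Ct must be finite and > 0 (got %g)", table$ct[i]))
  }
  n_missing <- sum(is.na(table$ct))
  if (n_missing > 0L) {
    wrn <- add(wrn, NA_integer_, "ct_missing",
               sprintf("%d record(s) with missing Ct are excluded", n_missing))
  }
  for (col in c("gene", "sample", "type")) {
    empty <- which(is.na(table[[col]]) | trimws(table[[col]]) == "")
    for (i in empty) {
      err <- add(err, i, paste0(col, "_nonempty"),
                 sprintf("%s must be non-empty", col))
    }
  }
  bad_serial <- which(is.na(table$serial) | table$serial < 1L)
  for (i in bad_serial) {
    err <- add(err, i, "serial_positive", "serial must be an integer >= 1")
  }

  key <- paste(table$role, table$gene, table$sample, table$serial, sep = "\r")
  dup <- which(duplicated(key))
  for (i in dup) {
    err <- add(err, i, "unique_triple",
               sprintf("duplicate (gene, sample, serial) = (%s, %s, %s)",
                       table$gene[i], table$sample[i], table$serial[i]))
  }

  # empty-named records are already reported above; keep them out of the
  # per-gene dilution-depth check so each defect yields exactly one error
  std <- table[table$role == "standard" & !is.na(table$ct) &
                 !is.na(table$gene) & trimws(table$gene) != "", ,
               drop = FALSE]
  if (nrow(std) > 0L) {
    levels_per_gene <- tapply(std$serial, std$gene,
                              function(x) length(unique(x)))
    shallow <- names(levels_per_gene)[levels_per_gene < 3L]
    for (g in shallow) {
      err <- add(err, NA_integer_, "standard_min_levels",
                 sprintf("gene '%s' has < 3 distinct dilution levels", g))
    }
  }

  empty_report <- data.frame(row = integer(), rule = character(),
                             message = character(), stringsAsFactors = FALSE)
  out <- list(
    errors = if (length(err)) do.call(rbind, err) else empty_report,
    warnings = if (length(wrn)) do.call(rbind, wrn) else empty_report
  )
  class(out) <- "ct_validation"
  out
}

#' @export
print.ct_validation <- function(x, ...) {
  cat("Ct table validation:", nrow(x$errors), "error(s),",
      nrow(x$warnings), "warning(s)\n")
  if (nrow(x$errors)) print(x$errors)
  if (nrow(x$warnings)) print(x$warnings)
  invisible(x)
}

# Collapse technical replication by arithmetic mean of Ct, applied at the
# start of each analytical stage:
#   standards -> one mean Ct per (gene, dilution level [serial]);
#   unknowns  -> one mean Ct per (gene, sample), pooling replicate serials.
# Missing Ct values are dropped before averaging.
collapse_ct <- function(table) {
  stopifnot(inherits(table, "ct_table"))
  tab <- table[!is.na(table$ct), , drop = FALSE]
  std <- tab[tab$role == "standard", , drop = FALSE]
  unk <- tab[tab$role == "unknown", , drop = FALSE]
  std_out <- if (nrow(std)) {
    agg <- stats::aggregate(ct ~ gene + serial, data = std, FUN = mean)
    agg[order(agg$gene, agg$serial), , drop = FALSE]
  } else {
    data.frame(gene = character(), serial = integer(), ct = numeric())
  }
  unk_out <- if (nrow(unk)) {
    type_of <- unk$type[!duplicated(unk$sample)]
    names(type_of) <- unk$sample[!duplicated(unk$sample)]
    agg <- stats::aggregate(ct ~ gene + sample, data = unk, FUN = mean)
    agg$type <- unname(type_of[agg$sample])
    agg[order(agg$gene, agg$sample), c("gene", "sample", "type", "ct")]
  } else {
    data.frame(gene = character(), sample = character(),
               type = character(), ct = numeric())
  }
  list(standard = std_out, unknown = unk_out)
}

#' Write a stage output sheet
#'
#' Each analytical stage exports one result table named after its sheet:
#' `Efficiency`, `M_value`, `Pairwise_V` or `Exp_ratio`.  The default output
#' is a TSV file `<sheet>.tsv` in `dir`; re-running a stage overwrites that
#' file only, leaving the other sheets untouched.
#'
#' @param rows non-empty data frame of stage results.
#' @param dir output directory (created if absent).
#' @param sheet one of `"Efficiency"`, `"M_value"`, `"Pairwise_V"`,
#'   `"Exp_ratio"`, or any other name for auxiliary exports.
#' @return the path written, invisibly.
#' @export
write_stage_output <- function(rows, dir, sheet) {
  stopifnot(is.data.frame(rows))
  if (nrow(rows) == 0L) stop("refusing to write an empty result table",
                             call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(sheet, ".tsv"))
  df <- as.data.frame(rows)
  num <- vapply(df, is.numeric, logical(1L))
  # Full double precision so a write/read round trip is exact to < 1e-12.
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a stage output sheet
#'
#' @param dir directory holding stage outputs.
#' @param sheet sheet name (file `<sheet>.tsv`).
#' @return data frame with numeric columns restored.
#' @export
read_stage_output <- function(dir, sheet) {
  path <- file.path(dir, paste0(sheet, ".tsv"))
  if (!file.exists(path)) stop("no such stage output: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  df
}

#' Write a Ct table to a delimited file
#'
#' Round-trip companion of [read_ct_table()]: `read_ct_table(write_ct_table(x))`
#' reproduces `x` field for field.
#'
#' @param table a `ct_table`.
#' @param path output path; extension picks the delimiter (`.csv` vs TSV).
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(table, path) {
  stopifnot(inherits(table, "ct_table"))
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- as.data.frame(table)
  df$ct <- sprintf("%.17g", df$ct)
  df$ct[df$ct == "nan" | is.na(table$ct)] <- "NA"
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
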