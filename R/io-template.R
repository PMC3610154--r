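# Experiment template, long-CSV and mapping-table I/O.
#
# The template dialect is a single plain-text CSV workbook:
#   #omicnet-template,1
#   #meta,<key>,<value>            (one line per meta field)
#   condition,,,<cond per column...>
#   time,,,<time value per column...>
#   time_unit,,,<unit per column...>
#   replicate,,,<replicate index per column...>
#   <substance>,<kind>,<unit>,<value per column...>
# Columns A-C of substance rows are name / kind / unit; the four header rows
# define the sample axis of every measurement column.  Blank cells are
# absent measurements, never zeros.  An .xlsx workbook with sheets "meta"
# (key/value) and "data" (same layout, no # lines) is accepted when the
# readxl package is installed.

csv_quote <- function(x) {
  x <- as.character(x)
  need <- grepl("[\",\n]", x)
  x[need] <- paste0("\"", gsub("\"", "\"\"", x[need]), "\"")
  x
}
csv_line <- function(...) paste(csv_quote(c(...)), collapse = ",")

num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read an experiment data template
#'
#' Parses the structured template dialect (see the package vignette) into an
#' \code{\link{experiment}}.  Missing cells become absent measurements;
#' non-numeric measurement cells are skipped with a warning; duplicate
#' substance rows are an error.
#'
#' @param path a \code{.csv} template (or \code{.xlsx} with sheets
#'   \code{meta} and \code{data} when readxl is available).
#' @return an \code{omic_experiment}.
#' @export
read_template <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) return(read_template_xlsx(path))
  lines <- readLines(path, warn = FALSE)
  metalines <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  meta <- list()
  for (ml in metalines) {
    parts <- strsplit(sub("^#", "", ml), ",")[[1]]
    if (length(parts) >= 3 && parts[1] == "meta")
      meta[[parts[2]]] <- paste(parts[-(1:2)], collapse = ",")
  }
  if (length(body) < 5) stop2("template parse error: needs 4 header rows plus data")
  cells <- utils::read.csv(text = paste(body, collapse = "\n"), header = FALSE,
                           colClasses = "character", check.names = FALSE)
  build_experiment_from_cells(as.matrix(cells), meta)
}

build_experiment_from_cells <- function(cells, meta) {
  hdr_names <- c("condition", "time", "time_unit", "replicate")
  if (!identical(cells[1:4, 1], hdr_names))
    stop2("template parse error: first column of rows 1-4 must be ",
          paste(hdr_names, collapse = "/"))
  ncols <- ncol(cells)
  if (ncols < 4) stop2("template parse error: no measurement columns")
  samp_cols <- 4:ncols
  samples <- data.frame(
    condition = as.character(cells[1, samp_cols]),
    time = num_or_na(cells[2, samp_cols]),
    time_unit = as.character(cells[3, samp_cols]),
    replicate = as.integer(num_or_na(cells[4, samp_cols])),
    stringsAsFactors = FALSE)
  if (anyNA(samples$replicate)) stop2("template parse error: non-integer replicate row")
  samples$time[is.na(samples$time)] <- 0
  sub_rows <- 5:nrow(cells)
  subs <- data.frame(name = trimws(cells[sub_rows, 1]),
                     kind = trimws(cells[sub_rows, 2]),
                     unit = as.character(cells[sub_rows, 3]),
                     stringsAsFactors = FALSE)
  if (anyDuplicated(subs$name))
    stop2("duplicate substance rows: ",
          paste(unique(subs$name[duplicated(subs$name)]), collapse = ", "))
  raw <- cells[sub_rows, samp_cols, drop = FALSE]
  vals <- matrix(NA_real_, nrow(subs), length(samp_cols))
  skipped <- 0L
  for (i in seq_len(nrow(raw))) for (j in seq_len(ncol(raw))) {
    cell <- trimws(raw[i, j])
    if (!nzchar(cell)) next
    v <- num_or_na(cell)
    if (is.na(v)) skipped <- skipped + 1L else vals[i, j] <- v
  }
  if (skipped > 0)
    warn2(skipped, " non-numeric measurement cell(s) skipped")
  experiment(subs, samples, vals, meta)
}

read_template_xlsx <- function(path) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop2("reading .xlsx templates requires the readxl package")
  meta_df <- as.data.frame(readxl::read_excel(path, sheet = "meta",
                                              col_names = FALSE, col_types = "text"))
  meta <- list()
  for (i in seq_len(nrow(meta_df)))
    if (!is.na(meta_df[i, 1])) meta[[meta_df[i, 1]]] <- meta_df[i, 2]
  cells <- as.matrix(as.data.frame(readxl::read_excel(path, sheet = "data",
                                                      col_names = FALSE,
                                                      col_types = "text")))
  cells[is.na(cells)] <- ""
  build_experiment_from_cells(cells, meta)
}

#' Write an experiment data template
#'
#' Inverse of \code{\link{read_template}} for the CSV dialect:
#' \code{read_template(write_template(e))} reproduces \code{e}.
#' @param e an \code{omic_experiment}. @param path output \code{.csv} path.
#' @export
write_template <- function(e, path) {
  stopifnot(exp_is(e))
  lines <- c("#omicnet-template,1",
             vapply(names(e$meta), function(k)
               paste0("#", csv_line("meta", k, e$meta[[k]])), character(1)))
  hdr <- function(name, vals) csv_line(name, "", "", vals)
  lines <- c(lines,
             hdr("condition", e$samples$condition),
             hdr("time", e$samples$time),
             hdr("time_unit", e$samples$time_unit),
             hdr("replicate", e$samples$replicate))
  for (i in seq_len(nrow(e$substances))) {
    v <- e$values[i, ]
    cells <- ifelse(is.na(v), "", sprintf("%.17g", v))
    lines <- c(lines, csv_line(e$substances$name[i], e$substances$kind[i],
                               e$substances$unit[i], cells))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read long-format CSV measurements
#'
#' Folds a long table (one measurement per row) into an
#' \code{\link{experiment}}.  \code{columns} maps the required roles
#' \code{substance} and \code{value} — and optionally \code{condition},
#' \code{time}, \code{time_unit}, \code{replicate}, \code{kind},
#' \code{unit} — to CSV column names.  Roles without a column get defaults
#' (single condition, time 0, replicate index by order of appearance,
#' kind "other"), standing in for the meta-data a structured template
#' would carry.
#'
#' @param path CSV file with a header row.
#' @param columns named list/character vector role -> column name.
#' @param meta experiment-level meta-data list.
#' @export
read_csv_long <- function(path, columns = list(substance = "substance",
                                               value = "value"),
                          meta = list()) {
  if (!file.exists(path)) stop2("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  columns <- as.list(columns)
  for (role in c("substance", "value"))
    if (is.null(columns[[role]])) stop2("columns must map the '", role, "' role")
  for (role in names(columns)) {
    cn <- columns[[role]]
    if (!(cn %in% names(df)))
      stop2("configured column '", cn, "' (role ", role, ") not in CSV header")
  }
  pick <- function(role, default) {
    cn <- columns[[role]]
    if (is.null(cn)) rep(default, nrow(df)) else df[[cn]]
  }
  sub <- as.character(df[[columns$substance]])
  cond <- as.character(pick("condition", "C1"))
  tim <- num_or_na(pick("time", 0)); tim[is.na(tim)] <- 0
  tun <- as.character(pick("time_unit", ""))
  val <- num_or_na(df[[columns$value]])
  kind <- as.character(pick("kind", "other"))
  unit <- as.character(pick("unit", ""))
  rep_col <- columns[["replicate"]]
  if (is.null(rep_col)) {
    key <- paste(sub, cond, tim, sep = "\r")
    repl <- stats::ave(seq_along(key), key, FUN = seq_along)
  } else repl <- as.integer(num_or_na(df[[rep_col]]))
  subs <- unique(data.frame(name = sub, kind = kind, unit = unit,
                            stringsAsFactors = FALSE))
  if (anyDuplicated(subs$name))
    stop2("substance '", subs$name[duplicated(subs$name)][1],
          "' declared with conflicting kind/unit")
  samples <- unique(data.frame(condition = cond, time = tim, time_unit = tun,
                               replicate = repl, stringsAsFactors = FALSE))
  vals <- matrix(NA_real_, nrow(subs), nrow(samples))
  si <- match(sub, subs$name)
  skey <- paste(cond, tim, repl, sep = "\r")
  qkey <- paste(samples$condition, samples$time, samples$replicate, sep = "\r")
  sj <- match(skey, qkey)
  for (r in seq_along(val)) {
    if (!is.na(vals[si[r], sj[r]]))
      stop2("duplicate measurement row for (", sub[r], ", ", cond[r],
            ", t=", tim[r], ", rep ", repl[r], ")")
    vals[si[r], sj[r]] <- val[r]
  }
  experiment(subs, samples, vals, meta)
}

#' Read a mapping table
#'
#' A mapping table is a simple two-plus-column file listing existing element
#' names in the first column and alternative identifiers in the subsequent
#' columns; it drives \code{\link{enrich_identifiers}}.
#'
#' @param path CSV file, no header, >= 2 columns.
#' @return object of class \code{omic_mapping_table}: list of
#'   \code{primary} (character) and \code{synonyms} (list of character).
#' @export
read_mapping_table <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2) stop2("mapping table has no synonym columns")
  primary <- trimws(df[[1]])
  keep <- nzchar(primary)
  df <- df[keep, , drop = FALSE]; primary <- primary[keep]
  if (anyDuplicated(primary))
    stop2("duplicate primary name in mapping table: ",
          paste(unique(primary[duplicated(primary)]), collapse = ", "))
  synonyms <- lapply(seq_len(nrow(df)), function(i) {
    s <- trimws(unlist(df[i, -1], use.names = FALSE))
    unique(s[nzchar(s)])
  })
  structure(list(primary = primary, synonyms = synonyms),
            class = "omic_mapping_table")
}

#' @export
print.omic_mapping_table <- function(x, ...) {
  cat(sprintf("<omic_mapping_table: %d entries, %d synonyms>\n",
              length(x$primary), sum(lengths(x$synonyms))))
  invisible(x)
}

#' Serialize an experiment to and from JSON
#'
#' Internal interchange format used by the command-line workflow.
#' @param e experiment. @param path file path.
#' @export
write_experiment_json <- function(e, path) {
  stopifnot(exp_is(e))
  obj <- list(meta = e$meta, substances = e$substances, samples = e$samples,
              values = apply(e$values, 1, function(r) r, simplify = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_experiment_json
#' @export
read_experiment_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- if (is.matrix(obj$values)) obj$values
          else do.call(rbind, lapply(obj$values, as.numeric))
  storage.mode(vals) <- "double"
  experiment(obj$substances, obj$samples, vals, as.list(obj$meta))
}
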