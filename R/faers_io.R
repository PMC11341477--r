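# FAERS quarterly ASCII dialect: `$`-delimited, one header line, columns
# resolved by header name (layouts changed across years, so never by
# position). Empty fields, literal "NULL" and whitespace-only fields all map
# to NA ("absent").

.faers_schemas <- list(
  DEMO = list(
    required = c("primaryid", "caseid"),
    optional = c("fda_dt", "event_dt", "sex", "age", "age_cod", "wt",
                 "wt_cod", "reporter_country")
  ),
  DRUG = list(
    required = c("primaryid", "drug_seq", "drugname"),
    optional = c("role_cod", "prod_ai")
  ),
  REAC = list(
    required = c("primaryid", "pt"),
    optional = character()
  ),
  THER = list(
    required = c("primaryid", "dsg_drug_seq"),
    optional = c("start_dt")
  )
)

#' Column layout of the supported FAERS tables
#'
#' @param schema one of \code{"DEMO"}, \code{"DRUG"}, \code{"REAC"},
#'   \code{"THER"}.
#' @return character vector of the schema's column names (required then
#'   optional).
#' @export
faers_schema_columns <- function(schema) {
  schema <- match.arg(toupper(schema), names(.faers_schemas))
  s <- .faers_schemas[[schema]]
  c(s$required, s$optional)
}

.blank_to_na <- function(x) {
  x <- trimws(x)
  x[x == "" | toupper(x) == "NULL"] <- NA_character_
  x
}

#' Read one FAERS quarterly ASCII table
#'
#' Reads a \code{$}-delimited FAERS table (DEMO, DRUG, REAC or THER). The
#' first line must be a header naming at least the schema's required columns
#' (case-insensitive); unknown columns are ignored and field order is taken
#' from the header, never from position. Empty fields, \code{"NULL"} and
#' whitespace-only fields become \code{NA}.
#'
#' @param path path to the table file.
#' @param schema table kind: \code{"DEMO"}, \code{"DRUG"}, \code{"REAC"} or
#'   \code{"THER"}. Defaults to a guess from the file name prefix.
#' @return data.frame with the schema's columns (all character); missing
#'   optional columns are filled with \code{NA}.
#' @export
read_faers_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(schema)) {
    guess <- toupper(substr(basename(path), 1L, 4L))
    if (!guess %in% names(.faers_schemas))
      stop("cannot guess schema from file name '", basename(path),
           "'; pass schema explicitly")
    schema <- guess
  }
  schema <- match.arg(toupper(schema), names(.faers_schemas))
  spec <- .faers_schemas[[schema]]

  lines <- tryCatch(
    readLines(path, encoding = "UTF-8", warn = FALSE),
    error = function(e) {
      readLines(path, encoding = "latin1", warn = FALSE)
    }
  )
  if (length(lines) == 0L) stop("empty file (no header line): ", path)

  header <- tolower(trimws(strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]]))
  missing_req <- setdiff(spec$required, header)
  if (length(missing_req) > 0L)
    stop("table '", basename(path), "' (schema ", schema,
         ") is missing required column(s): ",
         paste(missing_req, collapse = ", "))

  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  cols <- c(spec$required, spec$optional)
  if (length(body) == 0L) {
    out <- as.data.frame(
      stats::setNames(rep(list(character(0)), length(cols)), cols),
      stringsAsFactors = FALSE)
    return(out)
  }

  parts <- strsplit(body, "$", fixed = TRUE)
  nfield <- lengths(parts)
  # trailing empty fields are dropped by strsplit; tolerate short rows but
  # flag rows that overflow the header
  bad <- which(nfield > length(header))
  if (length(bad) > 0L)
    stop("unparseable line ", bad[1L] + 1L, " in '", basename(path),
         "': ", nfield[bad[1L]], " fields for ", length(header),
         " header columns")
  mat <- matrix(NA_character_, nrow = length(body), ncol = length(header))
  for (j in seq_along(header)) {
    has <- nfield >= j
    mat[has, j] <- vapply(parts[has], `[[`, character(1), j)
  }
  out <- stats::setNames(
    lapply(cols, function(cn) {
      j <- match(cn, header)
      if (is.na(j)) rep(NA_character_, length(body))
      else .blank_to_na(mat[, j])
    }), cols)
  out <- as.data.frame(out, stringsAsFactors = FALSE)

  if (anyNA(out$primaryid))
    stop("unparseable line ", which(is.na(out$primaryid))[1L] + 1L,
         " in '", basename(path), "': empty primaryid")
  if (schema == "DEMO" && anyNA(out$caseid))
    stop("unparseable line ", which(is.na(out$caseid))[1L] + 1L,
         " in '", basename(path), "': empty caseid")
  if (schema == "REAC" && anyNA(out$pt))
    stop("unparseable line ", which(is.na(out$pt))[1L] + 1L,
         " in '", basename(path), "': empty pt")
  out
}

#' Write a table in the FAERS ASCII dialect
#'
#' Inverse of \code{\link{read_faers_table}}: writes a \code{$}-delimited
#' file with one header line; \code{NA} fields become empty strings.
#'
#' @param records data.frame with (at least) the schema's columns.
#' @param path output file path.
#' @param schema table kind, as in \code{\link{read_faers_table}}.
#' @return \code{path}, invisibly.
#' @export
write_faers_table <- function(records, path, schema) {
  schema <- match.arg(toupper(schema), names(.faers_schemas))
  cols <- faers_schema_columns(schema)
  stopifnot(all(cols %in% names(records)))
  m <- as.matrix(
    as.data.frame(lapply(records[cols], as.character),
                  stringsAsFactors = FALSE))
  m[is.na(m)] <- ""
  lines <- c(paste(cols, collapse = "$"),
             if (nrow(m) > 0L) apply(m, 1L, paste, collapse = "$"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a FAERS quarter directory
#'
#' Reads the four supported tables from a directory containing files named
#' like \code{DEMO23Q1.txt}, \code{DRUG23Q1.txt}, ... (any suffix after the
#' four-letter schema prefix) and joins them into case-level records.
#'
#' @param dir directory containing the quarter's ASCII files.
#' @return a \code{faers_cases} object, see \code{\link{join_cases}}.
#' @export
read_faers_quarter <- function(dir) {
  if (!dir.exists(dir)) stop("quarter directory does not exist: ", dir)
  tabs <- lapply(names(.faers_schemas), function(schema) {
    hits <- list.files(dir, pattern = paste0("^", schema, ".*\\.(txt|TXT)$"),
                       full.names = TRUE, ignore.case = TRUE)
    hits <- hits[toupper(substr(basename(hits), 1, 4)) == schema]
    if (length(hits) == 0L) {
      if (schema %in% c("DEMO", "REAC"))
        stop("no ", schema, " table found in ", dir)
      return(NULL)
    }
    do.call(rbind, lapply(sort(hits), read_faers_table, schema = schema))
  })
  names(tabs) <- names(.faers_schemas)
  empty <- function(schema) {
    cols <- faers_schema_columns(schema)
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                  cols), stringsAsFactors = FALSE)
  }
  if (is.null(tabs$DRUG)) tabs$DRUG <- empty("DRUG")
  if (is.null(tabs$THER)) tabs$THER <- empty("THER")
  join_cases(tabs$DEMO, tabs$DRUG, tabs$REAC, tabs$THER)
}

#' Join FAERS tables into case-level records
#'
#' Attaches DRUG, REAC and THER rows to their DEMO row by \code{primaryid}.
#' Child rows whose \code{primaryid} has no DEMO row are orphans: they are
#' counted and dropped, never attached.
#'
#' @param demo,drug,reac,ther data.frames as returned by
#'   \code{\link{read_faers_table}}.
#' @return An object of class \code{faers_cases}: a list with the four
#'   tables (children filtered to known \code{primaryid}s) and an
#'   \code{orphans} count per child table.
#' @export
join_cases <- function(demo, drug, reac, ther) {
  keep_known <- function(tab) {
    known <- tab$primaryid %in% demo$primaryid
    list(kept = tab[known, , drop = FALSE], orphans = sum(!known))
  }
  d <- keep_known(drug); r <- keep_known(reac); t <- keep_known(ther)
  structure(
    list(demo = demo, drug = d$kept, reac = r$kept, ther = t$kept,
         orphans = c(drug = d$orphans, reac = r$orphans, ther = t$orphans)),
    class = "faers_cases")
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("FAERS case set: ", nrow(x$demo), " reports (",
      length(unique(x$demo$caseid)), " unique cases), ",
      nrow(x$drug), " drug rows, ", nrow(x$reac), " reaction rows, ",
      nrow(x$ther), " therapy rows\n", sep = "")
  if (any(x$orphans > 0L))
    cat("orphan child rows dropped:",
        paste(names(x$orphans), x$orphans, collapse = ", "), "\n")
  invisible(x)
}

#' Number of reports in a case set
#' @param x a \code{faers_cases} object.
#' @param ... unused.
#' @export
nreports <- function(x, ...) UseMethod("nreports")

#' @export
nreports.faers_cases <- function(x, ...) nrow(x$demo)

# subset a faers_cases object to a set of primaryids
.subset_cases <- function(cases, primaryids) {
  structure(
    list(demo = cases$demo[cases$demo$primaryid %in% primaryids, ,
                           drop = FALSE],
         drug = cases$drug[cases$drug$primaryid %in% primaryids, ,
                           drop = FALSE],
         reac = cases$reac[cases$reac$primaryid %in% primaryids, ,
                           drop = FALSE],
         ther = cases$ther[cases$ther$primaryid %in% primaryids, ,
                           drop = FALSE],
         orphans = cases$orphans),
    class = "faers_cases")
}
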