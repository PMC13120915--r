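#' @name io_tables
#' @title Tabular input/output for the flavatlas pipeline
#'
#' @description
#' Readers and writers for every table the pipeline touches. All files are
#' UTF-8 text. Interaction tables are whitespace- or tab-separated (the
#' STRING/STITCH convention); all other tables are tab-separated by default
#' with a comma-separated fallback via `sep = ","`. A header line is
#' detected automatically by recognised column names and may be omitted.
#' Readers validate every row and never silently drop one: malformed rows
#' abort with an error naming each offending line number.
NULL

# known header tokens used for automatic header detection
.fa_header_tokens <- c(
  "protein1", "protein2", "chemical", "protein", "combined_score",
  "node_a", "node_b", "score", "drug_id", "atc_code", "atc_level2_code",
  "food_id", "food", "flavonoid", "flavonoid_id", "mg_per_100g", "value",
  "evidence_count", "supported", "lc50", "lc50_um", "censored", "level"
)

# Split non-blank lines of a text table, keeping original line numbers.
# sep: "whitespace" (any run of blanks/tabs), "\t" or ",".
fa_parse_lines <- function(path, sep) {
  if (!file.exists(path)) fa_stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  pattern <- switch(sep,
    whitespace = "[ \t]+",
    "\t" = "\t",
    "," = ",",
    fa_stop("unsupported separator: ", sep)
  )
  fields <- strsplit(trimws(lines[idx]), pattern)
  list(fields = fields, line_no = idx, n_lines = length(idx))
}

fa_is_header <- function(fields) {
  any(tolower(trimws(fields)) %in% .fa_header_tokens)
}

# parse strictly integer-valued text; NA if malformed
fa_as_int <- function(x) {
  ok <- grepl("^[+-]?[0-9]+$", x)
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer(x[ok])
  out
}

fa_as_num <- function(x) {
  suppressWarnings(as.numeric(x))
}

fa_report_bad <- function(bad_line_no, what) {
  if (length(bad_line_no) == 0L) return(invisible(NULL))
  fa_stop(length(bad_line_no), " malformed row(s): ", what,
          " at line(s) ", paste(bad_line_no, collapse = ", "))
}

#' Read a STRING- or STITCH-dialect interaction link table
#'
#' Parses whitespace- or tab-separated triples
#' (`protein1 protein2 combined_score` for `string_links`,
#' `chemical protein combined_score` for `stitch_links`) into a normalised
#' record table. Scores must be integers on the 0-1000 combined-confidence
#' scale. Self-loops are permitted at read time (they are removed during
#' network construction). Identifiers may optionally have a fixed prefix
#' stripped (STITCH chemical ids sometimes carry species/stereo prefixes).
#'
#' @param path path to the link table.
#' @param dialect `"string_links"` or `"stitch_links"`; controls only the
#'   documented column semantics, the returned columns are always
#'   `node_a`, `node_b`, `combined_score`.
#' @param strip_prefix character prefix removed from the start of every
#'   identifier in the first column (default `""`, i.e. none).
#' @param sep `"whitespace"` (default), `"\t"` or `","`.
#' @return data.frame with columns `node_a`, `node_b` (character) and
#'   `combined_score` (integer in \[0, 1000\]).
#' @examples
#' f <- tempfile()
#' writeLines(c("protein1 protein2 combined_score",
#'              "p1 p2 800", "p2 p3 150"), f)
#' read_interaction_table(f, "string_links")
#' @export
read_interaction_table <- function(path,
                                   dialect = c("string_links", "stitch_links"),
                                   strip_prefix = "",
                                   sep = "whitespace") {
  dialect <- match.arg(dialect)
  parsed <- fa_parse_lines(path, sep)
  fields <- parsed$fields
  line_no <- parsed$line_no
  if (length(fields) > 0L && fa_is_header(fields[[1L]])) {
    fields <- fields[-1L]
    line_no <- line_no[-1L]
  }
  if (length(fields) == 0L) {
    return(data.frame(node_a = character(), node_b = character(),
                      combined_score = integer(), stringsAsFactors = FALSE))
  }
  nf <- lengths(fields)
  fa_report_bad(line_no[nf < 3L], "fewer than 3 columns")
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  s <- fa_as_int(vapply(fields, `[[`, "", 3L))
  fa_report_bad(line_no[is.na(s)], "non-integer combined_score")
  fa_report_bad(line_no[s < 0L | s > 1000L],
                "combined_score outside [0, 1000]")
  if (nzchar(strip_prefix)) {
    strip1 <- function(v) {
      hit <- startsWith(v, strip_prefix)
      v[hit] <- substring(v[hit], nchar(strip_prefix) + 1L)
      v
    }
    a <- strip1(a)
    if (dialect == "string_links") b <- strip1(b)
  }
  data.frame(node_a = a, node_b = b, combined_score = s,
             stringsAsFactors = FALSE)
}

#' Read a drug-to-ATC Level 2 mapping table
#'
#' Two columns, `drug_id` and an ATC Level-2 code (one letter from the 14
#' anatomical/therapeutic domains followed by two digits, e.g. `L01`).
#' Each Level-2 row also yields its implied Level-1 record (the letter
#' prefix); duplicate records are collapsed.
#'
#' @param path path to the mapping table.
#' @param sep field separator, `"\t"` (default) or `","`.
#' @return data.frame with columns `drug_id`, `atc_code`, `atc_level`
#'   (integer 1 or 2), one row per distinct (drug, code) pair.
#' @export
read_atc_table <- function(path, sep = "\t") {
  parsed <- fa_parse_lines(path, sep)
  fields <- parsed$fields
  line_no <- parsed$line_no
  if (length(fields) > 0L && fa_is_header(fields[[1L]])) {
    fields <- fields[-1L]
    line_no <- line_no[-1L]
  }
  if (length(fields) == 0L) {
    return(data.frame(drug_id = character(), atc_code = character(),
                      atc_level = integer(), stringsAsFactors = FALSE))
  }
  nf <- lengths(fields)
  fa_report_bad(line_no[nf < 2L], "fewer than 2 columns")
  drug <- vapply(fields, `[[`, "", 1L)
  code <- toupper(vapply(fields, `[[`, "", 2L))
  bad <- !grepl("^[A-Z][0-9]{2}$", code)
  fa_report_bad(line_no[bad], "ATC code not letter+2 digits")
  out <- rbind(
    data.frame(drug_id = drug, atc_code = code, atc_level = 2L,
               stringsAsFactors = FALSE),
    data.frame(drug_id = drug, atc_code = substr(code, 1L, 1L),
               atc_level = 1L, stringsAsFactors = FALSE)
  )
  out <- unique(out)
  out <- out[order(out$drug_id, out$atc_level, out$atc_code), ]
  rownames(out) <- NULL
  out
}

#' Read a long-format food flavonoid composition table
#'
#' Three columns: `food_id`, `flavonoid_id`, concentration in mg per 100 g.
#' Every returned food has an entry for every flavonoid in
#' `flavonoid_universe`; pairs absent from the file are explicit zeros
#' (the USDA table is sparse, but downstream rank correlation needs the
#' full content vector).
#'
#' @param path path to the composition table.
#' @param flavonoid_universe character vector of flavonoid identifiers
#'   defining the content-vector dimension.
#' @param strict if `TRUE` (default) a flavonoid outside the universe is an
#'   error; if `FALSE` such rows are dropped with a warning.
#' @param sep field separator, `"\t"` (default) or `","`.
#' @return numeric matrix, foods in rows (rownames = food ids), flavonoids
#'   in columns in the order of `flavonoid_universe`; all values >= 0.
#' @export
read_food_composition <- function(path, flavonoid_universe, strict = TRUE,
                                  sep = "\t") {
  if (length(flavonoid_universe) == 0L) {
    fa_stop("flavonoid_universe must be non-empty")
  }
  parsed <- fa_parse_lines(path, sep)
  fields <- parsed$fields
  line_no <- parsed$line_no
  if (length(fields) > 0L && fa_is_header(fields[[1L]])) {
    fields <- fields[-1L]
    line_no <- line_no[-1L]
  }
  if (length(fields) == 0L) {
    return(matrix(numeric(), nrow = 0L, ncol = length(flavonoid_universe),
                  dimnames = list(NULL, flavonoid_universe)))
  }
  nf <- lengths(fields)
  fa_report_bad(line_no[nf < 3L], "fewer than 3 columns")
  food <- vapply(fields, `[[`, "", 1L)
  flav <- vapply(fields, `[[`, "", 2L)
  val <- fa_as_num(vapply(fields, `[[`, "", 3L))
  fa_report_bad(line_no[is.na(val)], "non-numeric concentration")
  fa_report_bad(line_no[val < 0], "negative concentration")
  unknown <- !(flav %in% flavonoid_universe)
  if (any(unknown)) {
    if (strict) {
      fa_report_bad(line_no[unknown], "flavonoid outside the universe")
    }
    warning(sum(unknown), " row(s) with flavonoids outside the universe ",
            "dropped", call. = FALSE)
    food <- food[!unknown]; flav <- flav[!unknown]; val <- val[!unknown]
  }
  foods <- unique(food)
  m <- matrix(0, nrow = length(foods), ncol = length(flavonoid_universe),
              dimnames = list(foods, flavonoid_universe))
  m[cbind(match(food, foods), match(flav, flavonoid_universe))] <- val
  m
}

#' Read a food-ATC epidemiological evidence table
#'
#' Four columns: `food_id`, `atc_code`, `evidence_count` (non-negative
#' integer), `supported` (logical). `supported = TRUE` requires
#' `evidence_count >= 1`.
#'
#' @param path path to the evidence table.
#' @param sep field separator, `"\t"` (default) or `","`.
#' @return data.frame with columns `food_id`, `atc_code`, `evidence_count`,
#'   `supported`.
#' @export
read_evidence_table <- function(path, sep = "\t") {
  parsed <- fa_parse_lines(path, sep)
  fields <- parsed$fields
  line_no <- parsed$line_no
  if (length(fields) > 0L && fa_is_header(fields[[1L]])) {
    fields <- fields[-1L]
    line_no <- line_no[-1L]
  }
  if (length(fields) == 0L) {
    return(data.frame(food_id = character(), atc_code = character(),
                      evidence_count = integer(), supported = logical(),
                      stringsAsFactors = FALSE))
  }
  nf <- lengths(fields)
  fa_report_bad(line_no[nf < 4L], "fewer than 4 columns")
  food <- vapply(fields, `[[`, "", 1L)
  atc <- toupper(vapply(fields, `[[`, "", 2L))
  cnt <- fa_as_int(vapply(fields, `[[`, "", 3L))
  fa_report_bad(line_no[is.na(cnt) | cnt < 0L],
                "evidence_count not a non-negative integer")
  supp_raw <- toupper(vapply(fields, `[[`, "", 4L))
  supp <- supp_raw %in% c("TRUE", "T", "1", "YES")
  bad_supp <- !(supp_raw %in% c("TRUE", "T", "1", "YES",
                                "FALSE", "F", "0", "NO"))
  fa_report_bad(line_no[bad_supp], "supported not interpretable as logical")
  fa_report_bad(line_no[supp & cnt < 1L],
                "supported row with evidence_count < 1")
  data.frame(food_id = food, atc_code = atc, evidence_count = cnt,
             supported = supp, stringsAsFactors = FALSE)
}

#' Read a flavonoid bioassay (LC50) table
#'
#' Three columns: `flavonoid_id`, `lc50_uM` (positive real, micromolar),
#' `censored` (logical; `TRUE` means the LC50 is a lower bound, encoding
#' ">bound" outcomes where cytotoxicity was not reached in the tested
#' range).
#'
#' @param path path to the assay table.
#' @param sep field separator, `"\t"` (default) or `","`.
#' @return data.frame with columns `flavonoid_id`, `lc50`, `censored`.
#' @export
read_bioassay_table <- function(path, sep = "\t") {
  parsed <- fa_parse_lines(path, sep)
  fields <- parsed$fields
  line_no <- parsed$line_no
  if (length(fields) > 0L && fa_is_header(fields[[1L]])) {
    fields <- fields[-1L]
    line_no <- line_no[-1L]
  }
  if (length(fields) == 0L) {
    return(data.frame(flavonoid_id = character(), lc50 = numeric(),
                      censored = logical(), stringsAsFactors = FALSE))
  }
  nf <- lengths(fields)
  fa_report_bad(line_no[nf < 3L], "fewer than 3 columns")
  flav <- vapply(fields, `[[`, "", 1L)
  lc50 <- fa_as_num(vapply(fields, `[[`, "", 2L))
  fa_report_bad(line_no[is.na(lc50) | lc50 <= 0], "lc50 not a positive real")
  cens_raw <- toupper(vapply(fields, `[[`, "", 3L))
  cens <- cens_raw %in% c("TRUE", "T", "1", "YES")
  bad_cens <- !(cens_raw %in% c("TRUE", "T", "1", "YES",
                                "FALSE", "F", "0", "NO"))
  fa_report_bad(line_no[bad_cens], "censored not interpretable as logical")
  data.frame(flavonoid_id = flav, lc50 = lc50, censored = cens,
             stringsAsFactors = FALSE)
}

#' Write a result table as TSV
#'
#' Writes any homogeneous result data.frame as a tab-separated file with a
#' header row giving the fixed column order. Reals are serialized with 15
#' significant digits so that derived quantities (e.g. -log10 p) are
#' recomputable from the text. An empty input yields a header-only file.
#' The output round-trips through [read_results_table()].
#'
#' @param records a data.frame of one result type.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_results_table <- function(records, path) {
  if (!is.data.frame(records)) fa_stop("records must be a data.frame")
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = 15, format = "g")
    }
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) fa_stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Read a table written by [write_results_table()]
#'
#' @param path path to the TSV file.
#' @return data.frame with types inferred by `read.table`.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) fa_stop("file not found: ", path)
  read.table(path, sep = "\t", header = TRUE, quote = "",
             stringsAsFactors = FALSE, comment.char = "",
             encoding = "UTF-8")
}
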