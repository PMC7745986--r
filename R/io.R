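#' @title Count matrices and NanoString file I/O
#' @description Probes-by-samples matrices of non-negative integer
#'   barcode counts, read either from single-sample RCC files or from
#'   delimited count tables.
#' @name nanostring_io
NULL

# validate a probes x samples count matrix
.validate_counts <- function(counts, what = "count matrix") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop(what, " must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop(what, " must have probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate probe names in ", what)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample identifiers in ", what)
  }
  if (anyNA(counts)) stop("missing values in ", what)
  if (any(counts < 0)) stop("negative counts in ", what)
  if (any(counts != round(counts))) {
    stop("non-integer counts in ", what,
         "; barcode counts are discrete and fractional values are refused")
  }
  invisible(counts)
}

.rcc_class_map <- c(endogenous = "endogenous", housekeeping = "housekeeping",
                    negative = "negative", positive = "positive")

#' Read a single-sample RCC file
#'
#' Parses the bracketed-section raw-count format written per lane by the
#' nCounter instrument. Section names are matched case-insensitively,
#' both LF and CRLF line endings are accepted, and unknown sections are
#' ignored. Probe classes are inferred from the `CodeClass` column
#' (`Endogenous` \eqn{\to} `endogenous`, etc.).
#'
#' @param path Path to an RCC file.
#' @return A list with elements `counts` (one-column integer matrix,
#'   probes x 1), `panel` (the [probe_panel] inferred from `CodeClass`),
#'   `sample_id`, and `lane_attributes` (named character vector passed
#'   through from the Lane Attributes section).
#' @seealso [read_count_table()], [write_rcc()]
#' @export
read_rcc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  sec_open <- grepl("^<[^/][^>]*>$", lines)
  sec_close <- grepl("^</[^>]*>$", lines)
  sections <- list()
  open_name <- NULL
  start <- NULL
  for (i in seq_along(lines)) {
    if (sec_open[i]) {
      open_name <- tolower(gsub("[<>]", "", lines[i]))
      start <- i + 1L
    } else if (sec_close[i] && !is.null(open_name)) {
      nm <- tolower(gsub("[</>]", "", lines[i]))
      if (identical(nm, open_name)) {
        sections[[open_name]] <- if (start <= i - 1L) lines[start:(i - 1L)] else character()
        open_name <- NULL
      }
    }
  }
  code_key <- grep("code.?summary", names(sections), value = TRUE)
  if (!length(code_key)) {
    stop("RCC format error: no code-summary section in ", path)
  }
  body <- sections[[code_key[1]]]
  body <- body[nzchar(body)]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("CodeClass", "Name", "Count")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("RCC format error: code summary lacks column(s) ",
         paste(miss, collapse = ", "), " in ", path)
  }
  cnt <- suppressWarnings(as.numeric(tab$Count))
  if (anyNA(cnt) || any(cnt != round(cnt)) || any(cnt < 0)) {
    stop("RCC format error: Count column must be non-negative integers in ",
         path)
  }
  cls <- .rcc_class_map[tolower(tab$CodeClass)]
  if (anyNA(cls)) {
    stop("RCC format error: unknown CodeClass value(s): ",
         paste(unique(tab$CodeClass[is.na(cls)]), collapse = ", "))
  }
  lane <- .parse_attr_section(sections, "lane.?attributes")
  samp <- .parse_attr_section(sections, "sample.?attributes")
  sample_id <- if (!is.na(samp["ID"]) && nzchar(samp["ID"])) {
    unname(samp["ID"])
  } else {
    sub("\\.rcc$", "", basename(path), ignore.case = TRUE)
  }
  counts <- matrix(as.integer(cnt), ncol = 1,
                   dimnames = list(tab$Name, sample_id))
  .validate_counts(counts, paste0("RCC counts (", path, ")"))
  list(counts = counts,
       panel = probe_panel(tab$Name, unname(cls)),
       sample_id = sample_id,
       lane_attributes = lane)
}

.parse_attr_section <- function(sections, pattern) {
  key <- grep(pattern, names(sections), value = TRUE)
  if (!length(key)) return(stats::setNames(character(), character()))
  body <- sections[[key[1]]]
  body <- body[nzchar(body)]
  kv <- strsplit(body, ",", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = ","), ""),
                  vapply(kv, `[`, "", 1))
}

#' Write a single-sample RCC file
#'
#' Emits the minimal bracketed-section format that [read_rcc()] consumes;
#' used to exercise the pipeline on simulated cohorts.
#'
#' @param counts Named non-negative integer vector (one sample), or a
#'   one-column count matrix.
#' @param panel A [probe_panel] covering the probes in `counts`.
#' @param path Output file path.
#' @param sample_id Sample identifier written to the Sample Attributes
#'   section; defaults to the column name or the file stem.
#' @param lane_attributes Optional named character vector passed through
#'   to the Lane Attributes section.
#' @return `path`, invisibly.
#' @export
write_rcc <- function(counts, panel, path, sample_id = NULL,
                      lane_attributes = c(ID = "1")) {
  if (is.matrix(counts)) {
    if (ncol(counts) != 1) stop("write_rcc() takes a single sample")
    if (is.null(sample_id)) sample_id <- colnames(counts)
    counts <- stats::setNames(counts[, 1], rownames(counts))
  }
  if (is.null(sample_id)) sample_id <- sub("\\.rcc$", "", basename(path))
  idx <- match(names(counts), panel$probe)
  if (anyNA(idx)) {
    stop("probes absent from panel: ",
         paste(names(counts)[is.na(idx)], collapse = ", "))
  }
  cls <- c(endogenous = "Endogenous", housekeeping = "Housekeeping",
           negative = "Negative", positive = "Positive")[panel$class[idx]]
  out <- c(
    "<Header>", "FileVersion,1.7", "SoftwareVersion,4.0.0.3", "</Header>",
    "<Sample_Attributes>", paste0("ID,", sample_id), "</Sample_Attributes>",
    "<Lane_Attributes>",
    paste0(names(lane_attributes), ",", lane_attributes),
    "</Lane_Attributes>",
    "<Code_Summary>", "CodeClass,Name,Accession,Count",
    sprintf("%s,%s,NA,%d", cls, names(counts), as.integer(counts)),
    "</Code_Summary>")
  writeLines(out, path)
  invisible(path)
}

#' Read a probes-by-samples count table
#'
#' Tab- (or comma-, for `.csv`) separated text with probe names in the
#' first column and one column per sample. When a panel is supplied the
#' rows are reordered to panel order; probes present in the table but not
#' in the panel raise a warning and are dropped (recorded in the
#' `"unmatched"` attribute), as are panel probes missing from the table
#' (attribute `"missing"`).
#'
#' @param path File path.
#' @param panel Optional [probe_panel].
#' @return Integer matrix, probes x samples.
#' @export
read_count_table <- function(path, panel = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 2) stop("count table needs a probe column plus >=1 sample")
  probes <- as.character(df[[1]])
  if (anyDuplicated(probes)) {
    stop("duplicate probe row(s): ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- probes
  .validate_counts(m, paste0("count table (", path, ")"))
  storage.mode(m) <- "integer"
  if (!is.null(panel)) {
    unmatched <- setdiff(probes, panel$probe)
    missing <- setdiff(panel$probe, probes)
    if (length(unmatched)) {
      warning("probe(s) absent from panel dropped: ",
              paste(unmatched, collapse = ", "))
    }
    if (length(missing)) {
      warning("panel probe(s) absent from table: ",
              paste(missing, collapse = ", "))
    }
    m <- m[intersect(panel$probe, probes), , drop = FALSE]
    attr(m, "unmatched") <- unmatched
    attr(m, "missing") <- missing
  }
  m
}

#' @rdname read_count_table
#' @param counts Probes x samples integer matrix.
#' @export
write_count_table <- function(counts, path) {
  .validate_counts(counts)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(probe = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with a mandatory `sample_id` column; recognised optional
#' columns (`cohort`, `race`, `sex`, `smoking`, `stage`, `true_subtype`)
#' are passed through, and `true_subtype` is checked against the
#' basal/luminal vocabulary.
#'
#' @param path File path.
#' @return A `data.frame`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("metadata must have a 'sample_id' column")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if ("true_subtype" %in% names(df)) {
    bad <- setdiff(unique(df$true_subtype), c("basal", "luminal", NA))
    if (length(bad)) {
      stop("true_subtype values outside {basal, luminal}: ",
           paste(bad, collapse = ", "))
    }
  }
  df
}
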