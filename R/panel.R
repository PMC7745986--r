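#' Probe panel definitions
#'
#' A probe panel maps every probe on a codeset to its class
#' (`endogenous`, `housekeeping`, `negative`, `positive`) and, for
#' endogenous probes of a two-subtype signature, to the subtype whose
#' tumours express it highly (`basal`, `luminal`, or `none`).
#'
#' @param probe Character vector of unique probe names.
#' @param class Character vector of probe classes, one per probe; each
#'   must be one of `"endogenous"`, `"housekeeping"`, `"negative"`,
#'   `"positive"`.
#' @param subtype_node Character vector (recycled if length 1) giving the
#'   subtype node of each probe: `"basal"`, `"luminal"` or `"none"`.
#' @return A `data.frame` of class `probe_panel` with columns `probe`,
#'   `class`, `subtype_node`.
#' @examples
#' probe_panel(c("KRT5", "AMMECR1L", "NEG_A"),
#'             c("endogenous", "housekeeping", "negative"),
#'             c("basal", "none", "none"))
#' @export
probe_panel <- function(probe, class, subtype_node = "none") {
  probe <- as.character(probe)
  class <- as.character(class)
  subtype_node <- rep_len(as.character(subtype_node), length(probe))
  if (length(class) != length(probe)) {
    stop("'probe' and 'class' must have the same length")
  }
  if (anyDuplicated(probe)) {
    stop("duplicate probe names: ",
         paste(unique(probe[duplicated(probe)]), collapse = ", "))
  }
  bad <- setdiff(unique(class), .probe_classes)
  if (length(bad)) {
    stop("unknown probe class(es): ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(unique(subtype_node), c("basal", "luminal", "none"))
  if (length(bad)) {
    stop("unknown subtype_node value(s): ", paste(bad, collapse = ", "))
  }
  structure(
    data.frame(probe = probe, class = class, subtype_node = subtype_node,
               stringsAsFactors = FALSE),
    class = c("probe_panel", "data.frame")
  )
}

.probe_classes <- c("endogenous", "housekeeping", "negative", "positive")

#' @export
print.probe_panel <- function(x, ...) {
  cat(sprintf("probe_panel: %d probes (%s)\n", nrow(x),
              paste(sprintf("%d %s", table(factor(x$class, .probe_classes)),
                            .probe_classes), collapse = ", ")))
  invisible(x)
}

# probes of given class(es), in panel order
.panel_probes <- function(panel, classes) {
  panel$probe[panel$class %in% classes]
}

.check_panel_usable <- function(panel) {
  if (!sum(panel$class == "negative")) {
    stop("panel has no negative-control probes; background thresholding ",
         "requires at least one")
  }
  if (!sum(panel$class == "housekeeping")) {
    stop("panel has no housekeeping probes; normalization requires at ",
         "least one")
  }
  invisible(panel)
}

#' Synthetic 47-gene basal/luminal panel
#'
#' The default panel shipped with the package. It mirrors the geometry of
#' a 47-gene basal/luminal bladder-cancer codeset — 20 basal-high and 20
#' luminal-high endogenous probes plus 7 subtype-neutral probes, the four
#' housekeeping genes *AMMECR1L*, *SRPRA*, *XRCC6* and *EIF2B4*, and 8
#' negative-control probes. The endogenous probe names (`BSL01` ...,
#' `LUM01` ..., `NTR01` ...) are synthetic stand-ins, not the published
#' gene symbols; only the housekeeping names are real.
#'
#' @param n_basal,n_luminal,n_neutral Number of endogenous probes in each
#'   block.
#' @param n_housekeeping Number of housekeeping probes. When 4 (default)
#'   the real housekeeping gene names are used.
#' @param n_negative Number of negative-control probes.
#' @return A [probe_panel].
#' @examples
#' p <- synthetic_base47_panel()
#' table(p$class)
#' @export
synthetic_base47_panel <- function(n_basal = 20, n_luminal = 20,
                                   n_neutral = 7, n_housekeeping = 4,
                                   n_negative = 8) {
  hk <- if (n_housekeeping == 4) {
    c("AMMECR1L", "SRPRA", "XRCC6", "EIF2B4")
  } else {
    sprintf("HK%02d", seq_len(n_housekeeping))
  }
  probe_panel(
    probe = c(sprintf("BSL%02d", seq_len(n_basal)),
              sprintf("LUM%02d", seq_len(n_luminal)),
              sprintf("NTR%02d", seq_len(n_neutral)),
              hk,
              sprintf("NEG_%s", LETTERS[seq_len(n_negative)])),
    class = rep(c("endogenous", "housekeeping", "negative"),
                c(n_basal + n_luminal + n_neutral, n_housekeeping,
                  n_negative)),
    subtype_node = rep(c("basal", "luminal", "none"),
                       c(n_basal, n_luminal,
                         n_neutral + n_housekeeping + n_negative))
  )
}

#' Read / write a probe panel as TSV
#'
#' Tab-separated with columns `probe`, `class`, `subtype_node` (the last
#' optional on read, defaulting to `"none"`).
#'
#' @param path File path.
#' @return `read_panel` returns a [probe_panel]; `write_panel` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("probe", "class")
  if (!all(need %in% names(df))) {
    stop("panel file must have columns 'probe' and 'class': ", path)
  }
  probe_panel(df$probe, df$class,
              if ("subtype_node" %in% names(df)) df$subtype_node else "none")
}

#' @rdname read_panel
#' @param panel A [probe_panel].
#' @export
write_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
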