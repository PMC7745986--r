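#' Geometric mean with a read floor
#'
#' `exp(mean(log(pmax(v, floor))))`. The default floor of 1 read means
#' zero counts contribute as 1, the convention used before every
#' geometric mean in the nCounter normalization chain.
#'
#' @param values Non-empty numeric vector, values >= 0.
#' @param floor Read floor applied before the log, >= 0.
#' @return The geometric mean of the floored values.
#' @examples
#' geometric_mean(c(2, 8))          # 4
#' geometric_mean(c(0, 4))          # 2: the zero is floored to 1
#' @export
geometric_mean <- function(values, floor = 1) {
  if (!length(values)) stop("geometric_mean(): empty input")
  if (!is.numeric(values) || anyNA(values)) {
    stop("geometric_mean(): values must be numeric and non-missing")
  }
  if (floor < 0) stop("geometric_mean(): floor must be >= 0")
  v <- pmax(values, floor)
  if (any(v == 0)) return(0)
  exp(mean(log(v)))
}

#' Negative-control background thresholding
#'
#' Per sample, the background \eqn{B_s} is the geometric mean of the
#' negative-control probe counts (floored at 1 read). Every housekeeping
#' and endogenous count strictly below \eqn{B_s} is set to 0; counts
#' equal to or above the background are untouched. Negative (and
#' positive) control rows are never modified, so the operation is
#' idempotent.
#'
#' @param counts Probes x samples count matrix (or a single named
#'   column).
#' @param panel A [probe_panel] with at least one negative probe.
#' @return List with `counts` (thresholded matrix, same shape) and
#'   `background` (named per-sample \eqn{B_s}).
#' @export
background_threshold <- function(counts, panel) {
  counts <- .as_count_matrix(counts)
  if (!sum(panel$class == "negative")) {
    stop("panel has no negative-control probes")
  }
  neg <- intersect(.panel_probes(panel, "negative"), rownames(counts))
  if (!length(neg)) {
    stop("no negative-control probes present in the count matrix")
  }
  B <- apply(counts[neg, , drop = FALSE], 2, geometric_mean, floor = 1)
  target <- intersect(.panel_probes(panel, c("endogenous", "housekeeping")),
                      rownames(counts))
  m <- counts[target, , drop = FALSE]
  m[sweep(m, 2, B, `<`)] <- if (is.integer(m)) 0L else 0
  counts[target, ] <- m
  list(counts = counts, background = B)
}

#' Housekeeping quality-control filter
#'
#' A sample is excluded iff any housekeeping probe count is 0 after
#' background thresholding, i.e. the housekeeping gene fell below the
#' sample's negative-control background — counts from such a lane are
#' unreliable. Excluded samples stay in the QC report; they are only
#' dropped from the matrix.
#'
#' @param counts Thresholded probes x samples matrix (see
#'   [background_threshold()]).
#' @param panel A [probe_panel].
#' @param background Optional named per-sample background vector, carried
#'   into the report.
#' @return List with `counts` (retained samples) and `qc` (data.frame:
#'   `sample`, `background`, `excluded`, `reason`).
#' @export
qc_filter <- function(counts, panel, background = NULL) {
  counts <- .as_count_matrix(counts)
  hk <- intersect(.panel_probes(panel, "housekeeping"), rownames(counts))
  if (!length(hk)) stop("no housekeeping probes present in the count matrix")
  hkm <- counts[hk, , drop = FALSE]
  failed <- apply(hkm == 0, 2, any)
  reason <- vapply(seq_len(ncol(hkm)), function(j) {
    bad <- hk[hkm[, j] == 0]
    if (length(bad)) {
      paste0("housekeeping below background: ", paste(bad, collapse = ","))
    } else ""
  }, "")
  qc <- data.frame(
    sample = colnames(counts),
    background = if (is.null(background)) NA_real_ else
      unname(background[colnames(counts)]),
    excluded = unname(failed),
    reason = reason,
    stringsAsFactors = FALSE)
  if (all(failed)) {
    stop("all samples failed housekeeping QC:\n",
         paste(sprintf("  %s: %s", qc$sample, qc$reason), collapse = "\n"))
  }
  list(counts = counts[, !failed, drop = FALSE], qc = qc)
}

#' Housekeeping geometric-mean scaling
#'
#' Per retained sample, the normalization factor is
#' \eqn{F_s = 100 / H_s} with \eqn{H_s} the geometric mean of the
#' (thresholded) housekeeping counts; every endogenous value is
#' multiplied by \eqn{F_s}. After scaling, the housekeeping geometric
#' mean equals 100 in every sample. Because \eqn{F_s} is a pure
#' per-sample quantity the result for one sample never depends on which
#' other samples are present.
#'
#' @param counts Thresholded, QC-passed probes x samples matrix.
#' @param panel A [probe_panel].
#' @return List with `expr` (endogenous x samples normalized values),
#'   `housekeeping` (scaled housekeeping rows, for audit),
#'   `hk_geomean` (\eqn{H_s}) and `factor` (\eqn{F_s}).
#' @export
housekeeping_normalize <- function(counts, panel) {
  counts <- .as_count_matrix(counts)
  hk <- intersect(.panel_probes(panel, "housekeeping"), rownames(counts))
  endo <- intersect(.panel_probes(panel, "endogenous"), rownames(counts))
  if (!length(hk)) stop("no housekeeping probes present in the count matrix")
  H <- apply(counts[hk, , drop = FALSE], 2, geometric_mean, floor = 1)
  if (any(H == 0)) {
    stop("housekeeping geometric mean of 0 in sample(s) ",
         paste(colnames(counts)[H == 0], collapse = ", "),
         "; run qc_filter() first")
  }
  f <- 100 / H
  list(expr = sweep(counts[endo, , drop = FALSE], 2, f, `*`),
       housekeeping = sweep(counts[hk, , drop = FALSE], 2, f, `*`),
       hk_geomean = H, factor = f)
}

#' Log transform of normalized expression
#'
#' `x -> log_base(x + pseudocount)`. With the defaults (base 2,
#' pseudocount 1) zeros — which arise only from background thresholding —
#' map to 0.
#'
#' @param x Non-negative numeric matrix or vector.
#' @param base Logarithm base: 2, `exp(1)` or 10.
#' @param pseudocount Added before the log; must be positive whenever
#'   zeros are present.
#' @return Transformed object of the same shape.
#' @export
log_transform <- function(x, base = 2, pseudocount = 1) {
  if (any(x < 0)) stop("log_transform(): negative values")
  if (any(x + pseudocount <= 0)) {
    stop("log_transform(): pseudocount ", pseudocount,
         " leaves non-positive values")
  }
  log(x + pseudocount) / log(base)
}

#' Per-gene median centering
#'
#' Subtracts each gene's across-sample median, the preprocessing applied
#' to log2 RNA-seq expression before classification. Idempotent.
#'
#' @param x Genes x samples numeric matrix.
#' @return Matrix of the same shape with per-gene median 0.
#' @export
median_center <- function(x) {
  if (!is.matrix(x) || !ncol(x)) stop("median_center(): need >= 1 sample")
  sweep(x, 1, apply(x, 1, stats::median))
}

#' Full nCounter normalization chain
#'
#' Runs, in order: negative-control background thresholding
#' ([background_threshold()]), housekeeping QC exclusion ([qc_filter()]),
#' housekeeping geometric-mean scaling to 100
#' ([housekeeping_normalize()]) and the log transform
#' ([log_transform()]). Every step is strictly per-sample: reordering,
#' adding or removing other samples never changes a sample's output.
#'
#' @param counts Probes x samples non-negative integer matrix covering
#'   the panel's negative and housekeeping probes.
#' @param panel A [probe_panel].
#' @param log_base,pseudocount Passed to [log_transform()].
#' @return An object of class `ns_normalized`: list with `expr` (linear
#'   normalized endogenous matrix), `logexpr` (log layer),
#'   `housekeeping` (scaled housekeeping rows), `qc` (per-sample report:
#'   `sample`, `background`, `hk_geomean`, `factor`, `excluded`,
#'   `reason`) and `params`.
#' @examples
#' sim <- simulate_cohort(simulation_config(n_samples = 4, seed = 7))
#' nm <- normalize_counts(sim$counts, sim$panel)
#' round(apply(nm$housekeeping, 2, geometric_mean), 6)  # all 100
#' @export
normalize_counts <- function(counts, panel, log_base = 2, pseudocount = 1) {
  counts <- .as_count_matrix(counts)
  .validate_counts(counts)
  .check_panel_usable(panel)
  th <- background_threshold(counts, panel)
  qf <- qc_filter(th$counts, panel, th$background)
  hn <- housekeeping_normalize(qf$counts, panel)
  qc <- qf$qc
  qc$hk_geomean <- NA_real_
  qc$factor <- NA_real_
  keep <- match(colnames(qf$counts), qc$sample)
  qc$hk_geomean[keep] <- unname(hn$hk_geomean)
  qc$factor[keep] <- unname(hn$factor)
  qc <- qc[, c("sample", "background", "hk_geomean", "factor",
               "excluded", "reason")]
  structure(list(
    expr = hn$expr,
    logexpr = log_transform(hn$expr, base = log_base,
                            pseudocount = pseudocount),
    housekeeping = hn$housekeeping,
    qc = qc,
    params = list(log_base = log_base, pseudocount = pseudocount)),
    class = "ns_normalized")
}

#' @export
print.ns_normalized <- function(x, ...) {
  cat(sprintf(
    "ns_normalized: %d endogenous probes x %d samples (%d excluded)\n",
    nrow(x$expr), ncol(x$expr), sum(x$qc$excluded)))
  invisible(x)
}

# accept a named vector as a one-sample matrix
.as_count_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  if (is.numeric(counts) && !is.null(names(counts))) {
    return(matrix(counts, ncol = 1,
                  dimnames = list(names(counts), "sample1")))
  }
  stop("counts must be a probes x samples matrix or a named vector")
}
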