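#' Train a nearest-shrunken-centroid (PAM) classifier
#'
#' Implements the classical nearest-shrunken-centroid model. With class
#' centroids \eqn{\bar x_{kj}}, overall centroid \eqn{\bar x_j}, pooled
#' within-class standard deviation \eqn{s_j} (divisor \eqn{n - K}),
#' fudge factor \eqn{s_0 = \mathrm{median}_j(s_j)} and
#' \eqn{m_k = \sqrt{1/n_k - 1/n}}, the standardized class difference
#' \eqn{d_{kj} = (\bar x_{kj} - \bar x_j) / (m_k (s_j + s_0))} is
#' soft-thresholded by \eqn{\Delta} and the shrunken centroid is
#' \eqn{\bar x'_{kj} = \bar x_j + m_k (s_j + s_0) d'_{kj}}. At
#' \eqn{\Delta = 0} the shrunken centroids are the class means; as
#' \eqn{\Delta \to \infty} they collapse to the overall centroid.
#'
#' The default \eqn{\Delta = 0} keeps every gene: a fixed diagnostic
#' signature is an input here, not something to be re-selected. Use
#' [choose_delta()] when shrinkage-based gene elimination is wanted.
#'
#' @param x Genes x samples numeric matrix of log expression, with gene
#'   rownames and sample colnames.
#' @param labels Per-sample class labels (character or factor); every
#'   class needs >= 2 samples.
#' @param delta Shrinkage amount \eqn{\Delta \ge 0}.
#' @param priors `"empirical"` (class frequencies, the pamr default) or
#'   `"uniform"`, or a named numeric vector summing to 1.
#' @return An object of class `pam_model`; see Details for the fields.
#'   Serializable with [write_pam_model()].
#' @details Model fields: `classes`, `genes`, `overall` (\eqn{\bar x_j}),
#'   `centroids` (unshrunken \eqn{\bar x_{kj}}), `shrunken`
#'   (\eqn{\bar x'_{kj}}), `sj`, `s0`, `delta`, `mk`, `priors`,
#'   `n_per_class`, and `provenance`.
#' @examples
#' x <- matrix(c(0, 0, 2, 0, 4, 2, 6, 2), nrow = 2,
#'             dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
#' m <- train_pam(x, c("A", "A", "B", "B"))
#' m$s0  # sqrt(2)/2
#' @export
train_pam <- function(x, labels, delta = 0,
                      priors = c("empirical", "uniform")) {
  base <- .pam_base(x, labels, priors)
  .pam_shrink(base, delta)
}

# sufficient statistics shared by all delta values
.pam_base <- function(x, labels, priors = c("empirical", "uniform")) {
  if (!is.matrix(x) || is.null(rownames(x))) {
    stop("x must be a genes x samples matrix with gene rownames")
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(x)) {
    stop("length(labels) must equal ncol(x)")
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("labels must cover >= 2 classes")
  nk <- table(factor(labels, classes))
  if (any(nk < 2)) {
    stop("class(es) with < 2 samples: ",
         paste(classes[nk < 2], collapse = ", "))
  }
  n <- ncol(x)
  K <- length(classes)
  centroids <- vapply(classes, function(k) {
    rowMeans(x[, labels == k, drop = FALSE])
  }, numeric(nrow(x)))
  overall <- rowMeans(x)
  ss <- rowSums(vapply(classes, function(k) {
    xc <- x[, labels == k, drop = FALSE] - centroids[, k]
    rowSums(xc^2)
  }, numeric(nrow(x))))
  sj <- sqrt(ss / (n - K))
  s0 <- stats::median(sj)
  if (s0 == 0) {
    # perfectly separated (or constant) training data: every within-class
    # deviation is zero for at least half the genes; keep the discriminant
    # finite with a tiny positive fudge relative to the overall spread
    spread <- stats::sd(as.vector(x))
    if (!is.finite(spread) || spread == 0) {
      stop("training matrix is constant; cannot fit a classifier")
    }
    s0 <- 1e-6 * spread
    warning("zero median within-class deviation; using s0 = ",
            signif(s0, 3))
  }
  if (is.numeric(priors)) {
    if (is.null(names(priors)) || !setequal(names(priors), classes)) {
      stop("numeric priors must be named with the class labels")
    }
    pk <- priors[classes]
    if (abs(sum(pk) - 1) > 1e-8 || any(pk <= 0)) {
      stop("priors must be positive and sum to 1")
    }
  } else {
    priors <- match.arg(priors)
    pk <- if (priors == "uniform") {
      stats::setNames(rep(1 / K, K), classes)
    } else {
      stats::setNames(as.numeric(nk) / n, classes)
    }
  }
  mk <- stats::setNames(sqrt(1 / as.numeric(nk) - 1 / n), classes)
  list(classes = classes, genes = rownames(x), centroids = centroids,
       overall = overall, sj = sj, s0 = s0, mk = mk, priors = pk,
       n_per_class = stats::setNames(as.integer(nk), classes), n = n)
}

.pam_shrink <- function(base, delta) {
  if (delta < 0) stop("delta must be >= 0")
  denom <- outer(base$sj + base$s0, base$mk) # genes x K
  dkj <- (base$centroids - base$overall) / denom
  dshr <- sign(dkj) * pmax(abs(dkj) - delta, 0)
  structure(list(
    classes = base$classes, genes = base$genes,
    overall = base$overall, centroids = base$centroids,
    shrunken = base$overall + denom * dshr,
    sj = base$sj, s0 = base$s0, delta = delta,
    mk = base$mk, priors = base$priors,
    n_per_class = base$n_per_class,
    provenance = list(package = "nanosubtype",
                      version = as.character(utils::packageVersion("nanosubtype")),
                      n = base$n)),
    class = "pam_model")
}

#' @export
print.pam_model <- function(x, ...) {
  active <- sum(rowSums(x$shrunken != x$overall) > 0)
  cat(sprintf(
    "pam_model: %d genes (%d unshrunk), classes %s, delta = %g, s0 = %.4g\n",
    length(x$genes), active, paste(x$classes, collapse = "/"), x$delta,
    x$s0))
  invisible(x)
}

# K x m discriminant matrix: delta_k(x) = sum_j (x_j - c_kj)^2/(s_j+s0)^2
#                                          - 2 log pi_k
.pam_discriminant <- function(model, x) {
  scale <- model$sj + model$s0
  xs <- x / scale
  d <- vapply(model$classes, function(k) {
    colSums((xs - model$shrunken[, k] / scale)^2)
  }, numeric(ncol(x)))
  d <- matrix(d, ncol = length(model$classes),
              dimnames = list(colnames(x), model$classes))
  t(d) - 2 * log(model$priors)
}

.softmax_rows <- function(d) {
  # posteriors exp(-d/2)/sum; invariant to adding a constant to all d_k
  e <- exp(-(sweep(d, 2, apply(d, 2, min))) / 2)
  sweep(e, 2, colSums(e), `/`)
}

# deterministic label from a column of discriminants:
# argmin; on an exact tie flag it, prefer larger prior, then the
# lexicographically last class (basal/luminal tie at uniform priors ->
# "luminal")
.pam_label <- function(dcol, priors) {
  cand <- names(dcol)[dcol == min(dcol)]
  tie <- length(cand) > 1
  if (tie) {
    cand <- cand[priors[cand] == max(priors[cand])]
    cand <- sort(cand)[length(cand)]
  }
  list(label = cand, tie = tie)
}

#' Classify samples with a trained PAM model
#'
#' For each sample, the discriminant
#' \eqn{\delta_k(x) = \sum_j (x_j - \bar x'_{kj})^2 / (s_j + s_0)^2 -
#' 2 \log \pi_k} is evaluated; the call is the class minimising
#' \eqn{\delta_k}, posteriors are the softmax of \eqn{-\delta_k / 2},
#' and the Pearson correlation of the sample with each shrunken centroid
#' is reported. For a basal/luminal model the basal score
#' \eqn{(1 + r_{basal} - r_{luminal}) / 2}, clipped to \eqn{[0, 1]},
#' gives a scaled distance from 0 (luminal) to 1 (basal).
#'
#' Classification is a pure function of the model and the one sample:
#' no cohort statistic enters, so single-sample and batch calls agree.
#'
#' @param object A `pam_model`.
#' @param newdata Genes x samples matrix (or a named vector for one
#'   sample) of log expression covering the model's gene list.
#' @param impute_missing If `TRUE`, genes absent from `newdata` are
#'   filled from the overall centroid with a warning instead of raising
#'   an error.
#' @param ... Unused.
#' @return A `data.frame` of class `subtype_calls`: one row per sample
#'   with `sample`, `label`, one `delta_*`, `p_*` and `r_*` column per
#'   class, `basal_score` (NA unless the classes are basal/luminal),
#'   `tie` and `flag` (degenerate-correlation indicator).
#' @export
predict.pam_model <- function(object, newdata, impute_missing = FALSE, ...) {
  if (!is.matrix(newdata)) {
    if (is.numeric(newdata) && !is.null(names(newdata))) {
      newdata <- matrix(newdata, ncol = 1,
                        dimnames = list(names(newdata), "sample1"))
    } else {
      stop("newdata must be a genes x samples matrix or a named vector")
    }
  }
  miss <- setdiff(object$genes, rownames(newdata))
  if (length(miss)) {
    if (!impute_missing) {
      stop("gene(s) missing from input: ", paste(miss, collapse = ", "),
           " (set impute_missing = TRUE to fill from the overall centroid)")
    }
    warning("imputing ", length(miss),
            " missing gene(s) from the overall centroid: ",
            paste(miss, collapse = ", "))
    fill <- matrix(object$overall[miss], nrow = length(miss),
                   ncol = ncol(newdata),
                   dimnames = list(miss, colnames(newdata)))
    newdata <- rbind(newdata, fill)
  }
  x <- newdata[object$genes, , drop = FALSE]
  d <- .pam_discriminant(object, x)
  post <- .softmax_rows(d)
  cent_sd <- apply(object$shrunken, 2, stats::sd)
  m <- ncol(x)
  r <- matrix(0, nrow = length(object$classes), ncol = m,
              dimnames = dimnames(d))
  flag <- logical(m)
  for (j in seq_len(m)) {
    if (stats::sd(x[, j]) == 0) {
      flag[j] <- TRUE
      next
    }
    for (k in object$classes) {
      if (cent_sd[k] == 0) {
        flag[j] <- TRUE
      } else {
        r[k, j] <- stats::cor(x[, j], object$shrunken[, k])
      }
    }
  }
  if (any(flag)) {
    warning("zero-variance profile(s); centroid correlation set to 0 for ",
            "flagged sample(s)")
  }
  lab <- lapply(seq_len(m), function(j) .pam_label(d[, j], object$priors))
  out <- data.frame(
    sample = if (is.null(colnames(x))) paste0("sample", seq_len(m)) else
      colnames(x),
    label = vapply(lab, `[[`, "", "label"),
    stringsAsFactors = FALSE)
  for (k in object$classes) out[[paste0("delta_", k)]] <- d[k, ]
  for (k in object$classes) out[[paste0("p_", k)]] <- post[k, ]
  for (k in object$classes) out[[paste0("r_", k)]] <- r[k, ]
  out$basal_score <- if (setequal(object$classes, c("basal", "luminal"))) {
    pmin(pmax((1 + r["basal", ] - r["luminal", ]) / 2, 0), 1)
  } else {
    NA_real_
  }
  out$tie <- vapply(lab, `[[`, NA, "tie")
  out$flag <- flag
  rownames(out) <- NULL
  class(out) <- c("subtype_calls", "data.frame")
  out
}

#' Cross-validated choice of the shrinkage amount
#'
#' Stratified K-fold cross-validation of the misclassification error over
#' a grid of \eqn{\Delta} values; returns the largest \eqn{\Delta}
#' attaining the minimum error (the most parsimonious classifier among
#' the best). Folds are stratified within class; the fold count is
#' capped at the smallest class size so no training fold can lose a
#' class.
#'
#' @inheritParams train_pam
#' @param folds Number of folds (>= 2).
#' @param grid Non-empty vector of \eqn{\Delta} values; `NULL` builds a
#'   30-point grid from 0 to the largest standardized class difference.
#' @param seed Optional integer seed for the fold assignment.
#' @return List with `delta` (the chosen \eqn{\Delta^*}) and `cv`
#'   (data.frame `delta`, `errors`, `error_rate` in percent).
#' @export
choose_delta <- function(x, labels, folds = 10, grid = NULL, seed = NULL,
                         priors = c("empirical", "uniform")) {
  if (!is.null(grid) && !length(grid)) stop("grid must be non-empty")
  if (folds < 2) stop("folds must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  nk <- table(factor(labels, classes))
  folds <- max(2, min(folds, min(nk)))
  fold_id <- integer(length(labels))
  for (k in classes) {
    idx <- which(labels == k)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  if (is.null(grid)) {
    base <- .pam_base(x, labels, priors)
    dmax <- max(abs((base$centroids - base$overall) /
                      outer(base$sj + base$s0, base$mk)))
    grid <- seq(0, dmax, length.out = 30)
  }
  errors <- numeric(length(grid))
  for (f in seq_len(folds)) {
    train <- fold_id != f
    base <- .pam_base(x[, train, drop = FALSE], labels[train], priors)
    xt <- x[, !train, drop = FALSE]
    for (g in seq_along(grid)) {
      model <- .pam_shrink(base, grid[g])
      d <- .pam_discriminant(model, xt)
      pred <- vapply(seq_len(ncol(xt)), function(j) {
        .pam_label(d[, j], model$priors)$label
      }, "")
      errors[g] <- errors[g] + sum(pred != labels[!train])
    }
  }
  cv <- data.frame(delta = grid, errors = errors,
                   error_rate = 100 * errors / length(labels))
  best <- max(grid[errors == min(errors)])
  list(delta = best, cv = cv)
}

#' Misclassification error of a call set
#'
#' @param calls Predicted labels — a character/factor vector or a
#'   `subtype_calls` data.frame.
#' @param truth Reference labels, same length.
#' @return List of class `classification_error` with `errors`, `n`,
#'   `rate` (percent, exact) and `printed` (integer percent,
#'   round-half-away-from-zero, as results are quoted).
#' @examples
#' classification_error(rep(c("basal", "luminal"), c(7, 45)),
#'                      rep("luminal", 52))  # 7/52 = 13%
#' @export
classification_error <- function(calls, truth) {
  if (inherits(calls, "subtype_calls")) calls <- calls$label
  if (inherits(truth, "subtype_calls")) truth <- truth$label
  calls <- as.character(calls)
  truth <- as.character(truth)
  if (!length(calls)) stop("empty call vector")
  if (length(calls) != length(truth)) {
    stop("calls and truth differ in length (", length(calls), " vs ",
         length(truth), ")")
  }
  errors <- sum(calls != truth)
  rate <- 100 * errors / length(calls)
  structure(list(errors = errors, n = length(calls), rate = rate,
                 printed = round_half_away(rate)),
            class = "classification_error")
}

#' @export
print.classification_error <- function(x, ...) {
  cat(sprintf("%d/%d misclassified (%s%%)\n", x$errors, x$n,
              format(x$printed)))
  invisible(x)
}

#' Round half away from zero
#'
#' The rounding used when quoting percentages (so 46.15 prints as 46 and
#' 61.90 as 62), as opposed to R's round-half-to-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Serialize / restore a PAM model as JSON
#'
#' Full-precision JSON with a schema version; a write/read round trip
#' reproduces predictions bit-exactly.
#'
#' @param model A `pam_model`.
#' @param path File path.
#' @return `write_pam_model` returns `path` invisibly; `read_pam_model`
#'   returns the `pam_model`.
#' @export
write_pam_model <- function(model, path) {
  stopifnot(inherits(model, "pam_model"))
  obj <- list(
    schema = "nanosubtype-pam-model/1",
    classes = model$classes, genes = model$genes,
    overall = unname(model$overall),
    centroids = unname(model$centroids),
    shrunken = unname(model$shrunken),
    sj = unname(model$sj), s0 = model$s0, delta = model$delta,
    mk = unname(model$mk), priors = unname(model$priors),
    n_per_class = unname(model$n_per_class),
    provenance = model$provenance)
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pam_model
#' @export
read_pam_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "nanosubtype-pam-model/1")) {
    stop("not a nanosubtype PAM model file: ", path)
  }
  classes <- obj$classes
  genes <- obj$genes
  dn <- list(genes, classes)
  structure(list(
    classes = classes, genes = genes,
    overall = stats::setNames(obj$overall, genes),
    centroids = matrix(unlist(obj$centroids), nrow = length(genes),
                       dimnames = dn),
    shrunken = matrix(unlist(obj$shrunken), nrow = length(genes),
                      dimnames = dn),
    sj = stats::setNames(obj$sj, genes), s0 = obj$s0, delta = obj$delta,
    mk = stats::setNames(obj$mk, classes),
    priors = stats::setNames(obj$priors, classes),
    n_per_class = stats::setNames(as.integer(obj$n_per_class), classes),
    provenance = obj$provenance),
    class = "pam_model")
}

#' Write a subtype call table as TSV
#'
#' @param calls A `subtype_calls` data.frame from [predict.pam_model()].
#' @param path File path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
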