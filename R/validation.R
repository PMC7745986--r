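#' Monte Carlo cross-validation of a PAM classifier
#'
#' Repeatedly draws a simple random train subset (no stratification —
#' draws missing a class are rejected, redrawn and counted), trains a
#' nearest-shrunken-centroid model on it and records the
#' misclassification error on the complement. The error estimate is the
#' mean per-iteration test error; the pooled confusion matrix is
#' row-normalized to percentages per true class.
#'
#' @inheritParams train_pam
#' @param train_frac Fraction of samples assigned to training, in (0,1);
#'   the classical split is 2/3 train / 1/3 test.
#' @param iterations Number of random splits (the reference protocol uses
#'   10,000; smaller values trade precision for time, SE shrinking as
#'   \eqn{1/\sqrt{iterations}}).
#' @param seed Integer seed; the whole result is a deterministic function
#'   of it.
#' @return Object of class `monte_carlo_cv`: `estimate` (percent error),
#'   `error_rates` (per iteration), `confusion` (counts) and
#'   `confusion_pct` (row percentages), `iterations`, `train_frac`,
#'   `delta`, `rejections`, `seed`.
#' @export
monte_carlo_cv <- function(x, labels, train_frac = 2 / 3,
                           iterations = 10000, delta = 0,
                           priors = c("empirical", "uniform"),
                           seed = NULL) {
  if (train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must be in (0, 1)")
  }
  if (iterations < 1) stop("iterations must be >= 1")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("labels must cover >= 2 classes")
  n <- ncol(x)
  if (n < 6) stop("need n >= 6 samples")
  ntrain <- round(train_frac * n)
  if (!is.null(seed)) set.seed(seed)
  err <- numeric(iterations)
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(truth = classes, predicted = classes))
  rejections <- 0L
  for (it in seq_len(iterations)) {
    repeat {
      idx <- sample.int(n, ntrain)
      tl <- labels[idx]
      # training also needs >= 2 per class for the pooled variance
      if (all(vapply(classes, function(k) sum(tl == k) >= 2, NA)) &&
          length(idx) < n) {
        break
      }
      rejections <- rejections + 1L
    }
    base <- .pam_base(x[, idx, drop = FALSE], tl, priors)
    model <- .pam_shrink(base, delta)
    test <- setdiff(seq_len(n), idx)
    d <- .pam_discriminant(model, x[, test, drop = FALSE])
    pred <- vapply(seq_along(test), function(j) {
      .pam_label(d[, j], model$priors)$label
    }, "")
    tt <- labels[test]
    err[it] <- 100 * sum(pred != tt) / length(test)
    for (j in seq_along(test)) {
      conf[tt[j], pred[j]] <- conf[tt[j], pred[j]] + 1L
    }
  }
  structure(list(
    estimate = mean(err), error_rates = err,
    confusion = conf,
    confusion_pct = 100 * conf / pmax(rowSums(conf), 1),
    iterations = iterations, train_frac = train_frac, delta = delta,
    rejections = rejections, seed = seed),
    class = "monte_carlo_cv")
}

#' @export
print.monte_carlo_cv <- function(x, ...) {
  cat(sprintf(
    "monte_carlo_cv: %.2f%% error over %d iterations (train %.0f%%)\n",
    x$estimate, x$iterations, 100 * x$train_frac))
  print(round(x$confusion_pct, 1))
  invisible(x)
}

#' McNemar test of paired-classifier concordance
#'
#' Compares two classifiers evaluated on the same samples against a
#' common truth through the discordant counts `b` (A correct, B wrong)
#' and `c` (A wrong, B correct). For `b + c < 25` the exact two-sided
#' binomial p-value `min(1, 2 P(Bin(b+c, 1/2) <= min(b, c)))` is used;
#' otherwise the continuity-corrected chi-square
#' \eqn{(|b-c|-1)^2/(b+c)} on 1 df.
#'
#' @param calls_a,calls_b Predicted label vectors (or `subtype_calls`).
#' @param truth Reference labels.
#' @return List of class `mcnemar_test`: `b`, `c`, `statistic`, `p`,
#'   `method` (`"exact"` or `"chi-square"`), `degenerate` (`TRUE` when
#'   `b + c == 0`, in which case `p = 1`).
#' @export
mcnemar_test <- function(calls_a, calls_b, truth) {
  if (inherits(calls_a, "subtype_calls")) calls_a <- calls_a$label
  if (inherits(calls_b, "subtype_calls")) calls_b <- calls_b$label
  if (inherits(truth, "subtype_calls")) truth <- truth$label
  if (length(calls_a) != length(truth) || length(calls_b) != length(truth)) {
    stop("calls_a, calls_b and truth must be aligned vectors")
  }
  a_ok <- calls_a == truth
  b_ok <- calls_b == truth
  b <- sum(a_ok & !b_ok)
  cc <- sum(!a_ok & b_ok)
  nd <- b + cc
  if (nd == 0) {
    return(structure(list(b = b, c = cc, statistic = 0, p = 1,
                          method = "exact", degenerate = TRUE),
                     class = "mcnemar_test"))
  }
  statistic <- (abs(b - cc) - 1)^2 / nd
  if (nd < 25) {
    p <- min(1, 2 * stats::pbinom(min(b, cc), nd, 0.5))
    method <- "exact"
  } else {
    p <- stats::pchisq(statistic, df = 1, lower.tail = FALSE)
    method <- "chi-square"
  }
  structure(list(b = b, c = cc, statistic = statistic, p = p,
                 method = method, degenerate = FALSE),
            class = "mcnemar_test")
}

#' @export
print.mcnemar_test <- function(x, ...) {
  cat(sprintf("McNemar (%s): b = %d, c = %d, statistic = %.3g, p = %.4g%s\n",
              x$method, x$b, x$c, x$statistic, x$p,
              if (x$degenerate) " [degenerate: no discordant pairs]" else ""))
  invisible(x)
}

#' Per-gene coefficient of variation across replicates
#'
#' CoV = sample standard deviation (divisor n-1) over mean, the
#' repeatability metric quoted for technical replicates. Genes with
#' non-positive mean get `NA` and are flagged.
#'
#' @param x Genes x replicates numeric matrix (>= 2 replicates).
#' @return List with `cov` (named per-gene vector), `median_cov`,
#'   `max_cov` and `flagged` (genes with undefined CoV).
#' @export
coefficient_of_variance <- function(x) {
  if (!is.matrix(x) || ncol(x) < 2) stop("need >= 2 replicates")
  means <- rowMeans(x)
  sds <- apply(x, 1, stats::sd)
  cov <- ifelse(means > 0, sds / means, NA_real_)
  names(cov) <- rownames(x)
  flagged <- rownames(x)[means <= 0]
  if (length(flagged)) {
    warning("CoV undefined for gene(s) with non-positive mean: ",
            paste(flagged, collapse = ", "))
  }
  list(cov = cov, median_cov = stats::median(cov, na.rm = TRUE),
       max_cov = max(cov, na.rm = TRUE), flagged = flagged)
}

#' Pearson correlation with a t-based p-value
#'
#' Product-moment correlation with the two-sided p-value from
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on \eqn{n - 2} df. Zero variance in
#' either vector yields `r = NA` with `flagged = TRUE`.
#'
#' @param x,y Numeric vectors, length >= 3, finite.
#' @return List with `r`, `p`, `n`, `flagged`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  n <- length(x)
  if (n < 3) stop("need length >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values")
  }
  dx <- x - mean(x)
  dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n, flagged = TRUE))
  }
  r <- max(-1, min(1, sum(dx * dy) / den))
  p <- if (abs(r) == 1) {
    0
  } else {
    2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
  }
  list(r = r, p = p, n = n, flagged = FALSE)
}

#' Contingency-table association test
#'
#' `method = "fisher"` runs the two-sided exact test on a 2x2 table
#' (p-value by summing hypergeometric probabilities no larger than the
#' observed table's); `method = "chi2"` the Pearson chi-square on an
#' r x c table without continuity correction.
#'
#' @param table Non-negative integer matrix.
#' @param method `"fisher"` or `"chi2"`.
#' @return List with `method`, `p`, and either `odds_ratio` (sample
#'   cross-product ratio, fisher) or `statistic` + `df` (chi2).
#' @examples
#' enrichment_test(matrix(c(13, 19, 8, 36), 2), "fisher")
#' @export
enrichment_test <- function(table, method = c("fisher", "chi2")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (any(table < 0)) stop("negative cell count")
  if (any(table != round(table))) stop("non-integer cell count")
  if (method == "fisher") {
    if (!all(dim(table) == 2)) stop("fisher requires a 2x2 table")
    ft <- stats::fisher.test(table)
    or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
    list(method = "fisher", p = ft$p.value, odds_ratio = or)
  } else {
    ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    list(method = "chi2", p = ct$p.value,
         statistic = unname(ct$statistic), df = unname(ct$parameter))
  }
}

#' Subtype proportion with printed-style rounding
#'
#' @param count Number of samples in the category.
#' @param total Row total, > 0.
#' @return List with `rate` (exact percent) and `printed` (integer
#'   percent, round-half-away-from-zero).
#' @examples
#' subtype_proportion(13, 21)  # 61.9%, prints 62
#' @export
subtype_proportion <- function(count, total) {
  if (total <= 0) stop("total must be > 0")
  if (count < 0 || count > total) stop("count must be in [0, total]")
  rate <- 100 * count / total
  list(count = count, total = total, rate = rate,
       printed = round_half_away(rate))
}

#' Average-linkage clustering under centered-correlation distance
#'
#' Orders genes or samples the way the expression heatmaps are ordered:
#' distance is 1 minus the centered Pearson correlation between item
#' profiles, agglomeration is unweighted average linkage (UPGMA), and the
#' leaf order is the deterministic [stats::hclust()] order.
#'
#' @param x Genes x samples numeric matrix.
#' @param axis `"rows"` (cluster genes) or `"columns"` (cluster samples).
#' @return List with `order` (leaf indices), `labels` (leaf names in
#'   order) and `hclust` (the dendrogram object).
#' @export
cluster_order <- function(x, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  m <- if (axis == "rows") x else t(x)
  if (nrow(m) < 2) stop("need >= 2 items to cluster")
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant profile(s); centered-correlation distance undefined ",
         "for: ", paste(rownames(m)[sds == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(t(m)))
  hc <- stats::hclust(d, method = "average")
  list(order = hc$order, labels = rownames(m)[hc$order], hclust = hc)
}
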