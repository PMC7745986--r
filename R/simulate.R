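#' Configuration of the synthetic NanoString cohort simulator
#'
#' Describes a two-subtype cohort profiled on a 47-gene style codeset:
#' endogenous genes split into basal-high, luminal-high and neutral
#' blocks with a symmetric subtype shift of \eqn{\pm \delta/2} log2
#' units, stable housekeeping genes, negative-control background, a
#' per-lane scale factor and Poisson counting noise, plus a correlated
#' paired log-expression layer standing in for a second platform
#' (RNA-seq).
#'
#' Defaults state a cohort a bench scientist would call realistic for an
#' FFPE validation study: n = 60 samples, balanced subtypes, 20/20/7
#' endogenous blocks, 4 housekeeping and 8 negative probes, per-gene
#' baselines between 2^6 and 2^10 counts, housekeeping around 2^9, a
#' subtype effect of 2 log2 units against 1 log2 unit of biological
#' noise, lane factors within +/-25%, mean background of 10 counts, and
#' cross-platform correlation 0.9.
#'
#' @param n_samples Cohort size.
#' @param basal_fraction Probability a sample is basal, in (0, 1).
#' @param n_basal,n_luminal,n_neutral Endogenous block sizes.
#' @param n_housekeeping,n_negative Control probe counts.
#' @param baseline_log2 Optional per-endogenous-gene baseline log2
#'   expression; `NULL` draws once from Uniform(6, 10) under the seed.
#' @param hk_log2 Housekeeping baseline log2 expression.
#' @param effect_size Subtype shift \eqn{\delta \ge 0} (log2 units,
#'   applied +/- delta/2 by block and subtype).
#' @param bio_sd Biological noise SD \eqn{\sigma_b \ge 0} (log2 units).
#' @param scale_range Length-2 positive range of per-sample lane scale
#'   factors (drawn log-uniformly).
#' @param background_mean Poisson mean \eqn{\lambda} of negative-control
#'   counts.
#' @param tech_sd Technical replicate noise SD \eqn{\sigma_t \ge 0}
#'   (log2 units), used by [simulate_technical_replicates()].
#' @param rho Per-gene correlation in \eqn{[-1, 1]} between the true
#'   log2 expression and the paired platform layer.
#' @param race_black_prob Marginal probability of the `black` metadata
#'   category.
#' @param race_basal_or Odds ratio linking race to the basal subtype;
#'   the default 1 makes metadata independent of subtype (a true null
#'   for enrichment tests).
#' @param seed Integer seed; all outputs are deterministic given it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 60, basal_fraction = 0.5,
                              n_basal = 20, n_luminal = 20, n_neutral = 7,
                              n_housekeeping = 4, n_negative = 8,
                              baseline_log2 = NULL, hk_log2 = 9,
                              effect_size = 2, bio_sd = 1,
                              scale_range = c(0.8, 1.25),
                              background_mean = 10, tech_sd = 0.1,
                              rho = 0.9, race_black_prob = 0.3,
                              race_basal_or = 1, seed = 1) {
  cfg <- list(n_samples = n_samples, basal_fraction = basal_fraction,
              n_basal = n_basal, n_luminal = n_luminal,
              n_neutral = n_neutral, n_housekeeping = n_housekeeping,
              n_negative = n_negative, baseline_log2 = baseline_log2,
              hk_log2 = hk_log2, effect_size = effect_size,
              bio_sd = bio_sd, scale_range = scale_range,
              background_mean = background_mean, tech_sd = tech_sd,
              rho = rho, race_black_prob = race_black_prob,
              race_basal_or = race_basal_or, seed = seed)
  bad <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(n_samples >= 4, "n_samples must be >= 4")
  chk(basal_fraction > 0 && basal_fraction < 1,
      "basal_fraction must be in (0, 1)")
  chk(n_basal >= 1 && n_luminal >= 1, "need >= 1 gene per subtype block")
  chk(n_neutral >= 0, "n_neutral must be >= 0")
  chk(n_housekeeping >= 1, "need >= 1 housekeeping probe")
  chk(n_negative >= 1, "need >= 1 negative probe")
  chk(is.null(baseline_log2) ||
        length(baseline_log2) == n_basal + n_luminal + n_neutral,
      "baseline_log2 must have one value per endogenous gene")
  chk(effect_size >= 0, "effect_size must be >= 0")
  chk(bio_sd >= 0, "bio_sd must be >= 0")
  chk(tech_sd >= 0, "tech_sd must be >= 0")
  chk(length(scale_range) == 2 && all(scale_range > 0) &&
        scale_range[1] <= scale_range[2],
      "scale_range must be a positive, ordered length-2 range")
  chk(background_mean >= 0, "background_mean must be >= 0")
  chk(rho >= -1 && rho <= 1, "rho must be in [-1, 1]")
  chk(race_black_prob > 0 && race_black_prob < 1,
      "race_black_prob must be in (0, 1)")
  chk(race_basal_or > 0, "race_basal_or must be > 0")
  chk(length(seed) == 1 && is.finite(seed), "seed must be a single number")
  if (length(bad)) {
    stop("invalid simulation config:\n  ", paste(bad, collapse = "\n  "))
  }
  structure(cfg, class = "simulation_config")
}

.panel_from_config <- function(config) {
  synthetic_base47_panel(config$n_basal, config$n_luminal,
                         config$n_neutral, config$n_housekeeping,
                         config$n_negative)
}

#' Simulate a NanoString-like cohort with known ground truth
#'
#' Per sample, the subtype is drawn by `basal_fraction`; each endogenous
#' gene's true log2 expression is its baseline plus the block shift
#' (\eqn{+\delta/2} when the gene's block matches the subtype,
#' \eqn{-\delta/2} for the opposing block, 0 for neutral genes) plus
#' Normal(0, `bio_sd`) noise. Counts are Poisson on the lane-scaled
#' linear expression; housekeeping counts are Poisson around the stable
#' housekeeping baseline; negative-control counts are Poisson
#' (`background_mean`). The paired platform layer mixes the
#' standardized true expression with independent noise so that each
#' gene's expected correlation across platforms is `rho`.
#'
#' @param config A [simulation_config].
#' @return List with `counts` (full probes x samples integer matrix, in
#'   panel order), `panel`, `paired` (endogenous x samples log-expression
#'   layer of the second platform), `truth` (named subtype vector),
#'   `metadata` (data.frame) and `config`.
#' @examples
#' sim <- simulate_cohort(simulation_config(n_samples = 8, seed = 42))
#' dim(sim$counts)
#' table(sim$truth)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  panel <- .panel_from_config(config)
  n <- config$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  subtype <- ifelse(stats::runif(n) < config$basal_fraction,
                    "basal", "luminal")
  names(subtype) <- samples

  endo <- .panel_probes(panel, "endogenous")
  hk <- .panel_probes(panel, "housekeeping")
  neg <- .panel_probes(panel, "negative")
  g <- length(endo)
  node <- panel$subtype_node[match(endo, panel$probe)]

  baseline <- if (is.null(config$baseline_log2)) {
    stats::runif(g, 6, 10)
  } else {
    config$baseline_log2
  }
  # block shift sign: +1 where gene block matches the sample subtype
  sign_mat <- outer(node, subtype, function(nd, st) {
    ifelse(nd == "none", 0, ifelse(nd == st, 1, -1))
  })
  true_log2 <- baseline + sign_mat * (config$effect_size / 2) +
    matrix(stats::rnorm(g * n, 0, config$bio_sd), g, n)
  dimnames(true_log2) <- list(endo, samples)

  scale_f <- exp(stats::runif(n, log(config$scale_range[1]),
                              log(config$scale_range[2])))
  endo_counts <- matrix(
    stats::rpois(g * n, t(t(2^true_log2) * scale_f)), g, n,
    dimnames = list(endo, samples))
  hk_counts <- matrix(
    stats::rpois(length(hk) * n,
                 rep(scale_f * 2^config$hk_log2, each = length(hk))),
    length(hk), n, dimnames = list(hk, samples))
  neg_counts <- matrix(
    stats::rpois(length(neg) * n, config$background_mean),
    length(neg), n, dimnames = list(neg, samples))
  counts <- rbind(endo_counts, hk_counts, neg_counts)[panel$probe, ,
                                                      drop = FALSE]
  storage.mode(counts) <- "integer"

  z <- t(apply(true_log2, 1, function(v) {
    s <- stats::sd(v)
    if (s == 0) v - mean(v) else (v - mean(v)) / s
  }))
  paired <- config$rho * z +
    sqrt(1 - config$rho^2) * matrix(stats::rnorm(g * n), g, n)
  dimnames(paired) <- list(endo, samples)

  p_black <- config$race_black_prob
  odds <- p_black / (1 - p_black)
  p_by_subtype <- ifelse(subtype == "basal",
                         odds * config$race_basal_or /
                           (1 + odds * config$race_basal_or),
                         p_black)
  metadata <- data.frame(
    sample_id = samples,
    cohort = "synthetic",
    race = ifelse(stats::runif(n) < p_by_subtype, "black", "white"),
    sex = sample(c("male", "female"), n, replace = TRUE),
    smoking = sample(c("ever", "never"), n, replace = TRUE,
                     prob = c(0.7, 0.3)),
    stage = sample(c("T2", "T3", "T4"), n, replace = TRUE,
                   prob = c(0.5, 0.4, 0.1)),
    true_subtype = unname(subtype),
    stringsAsFactors = FALSE)

  list(counts = counts, panel = panel, paired = paired, truth = subtype,
       metadata = metadata, config = config)
}

#' Simulate technical replicates of one sample
#'
#' Replicate counts are Poisson around `2^(log2(base) + Normal(0,
#' sigma_t))` per probe: pure counting noise at `sigma_t = 0`, plus
#' log-normal lane-to-lane wobble otherwise.
#'
#' @param base Named non-negative numeric vector of expected per-probe
#'   counts (e.g. one column of a simulated cohort); values below 1 are
#'   floored to 1 before the log.
#' @param sigma_t Technical noise SD in log2 units.
#' @param k Number of replicates (>= 2).
#' @param seed Optional integer seed.
#' @return Probes x k integer matrix (columns `rep1` ... `repk`).
#' @export
simulate_technical_replicates <- function(base, sigma_t = 0.1, k = 2,
                                          seed = NULL) {
  if (k < 2) stop("need k >= 2 replicates")
  if (sigma_t < 0) stop("sigma_t must be >= 0")
  if (is.matrix(base)) {
    if (ncol(base) != 1) stop("base must be a single sample")
    base <- stats::setNames(base[, 1], rownames(base))
  }
  if (!is.null(seed)) set.seed(seed)
  mu <- log2(pmax(base, 1))
  g <- length(mu)
  out <- matrix(
    stats::rpois(g * k, 2^(mu + stats::rnorm(g * k, 0, sigma_t))),
    g, k, dimnames = list(names(base), paste0("rep", seq_len(k))))
  storage.mode(out) <- "integer"
  out
}

#' Two-platform label-transfer fixture
#'
#' Reproduces, in silico, the workflow in which a cohort is profiled in
#' parallel on an established platform (A, here the simulated paired
#' log-expression layer, median-centered) and on NanoString (B): a PAM
#' model trained on platform A supplies the "true" transfer calls, and
#' the platform-B counts are returned for de novo retraining against
#' those calls. Mirroring the real setting — where the platform-A
#' classifier predates the cohort — the A model is trained on an
#' independently simulated cohort of the same design, so its calls on
#' this cohort are genuine out-of-sample predictions.
#'
#' @param config A [simulation_config]; `rho` controls how much
#'   platform A knows about the truth (`rho = 0` is degenerate — the
#'   transfer labels carry no signal — and raises a warning).
#' @return List with `platform_a` (median-centered log matrix),
#'   `calls_a` (named transfer labels), `model_a`, `counts_b` (the
#'   NanoString count matrix), `panel`, `truth` and `config`.
#' @export
make_label_transfer_fixture <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$rho < 0) stop("rho must be >= 0 for label transfer")
  if (config$rho == 0) {
    warning("rho = 0: platform A carries no subtype signal; ",
            "transferred labels are noise")
  }
  # independent training cohort for the platform-A classifier
  train_cfg <- config
  train_cfg$seed <- (config$seed + 1000003) %% 2^31
  sim_train <- simulate_cohort(train_cfg)
  model_a <- train_pam(median_center(sim_train$paired), sim_train$truth,
                       delta = 0)
  sim <- simulate_cohort(config)
  a <- median_center(sim$paired)
  calls_a <- stats::setNames(predict(model_a, a)$label, colnames(a))
  list(platform_a = a, calls_a = calls_a, model_a = model_a,
       counts_b = sim$counts, panel = sim$panel, truth = sim$truth,
       config = config)
}
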