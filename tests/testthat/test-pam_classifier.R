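# hand-checkable 2-gene, 4-sample instance used throughout:
# class A = {(0,0), (2,0)}, class B = {(4,2), (6,2)}
two_gene_instance <- function() {
  list(x = matrix(c(0, 0, 2, 0, 4, 2, 6, 2), nrow = 2,
                  dimnames = list(c("g1", "g2"), paste0("s", 1:4))),
       labels = c("A", "A", "B", "B"))
}

test_that("train_pam reproduces the hand-computed sufficient statistics", {
  inst <- two_gene_instance()
  m <- train_pam(inst$x, inst$labels)
  expect_equal(unname(m$centroids), cbind(c(1, 0), c(5, 2)))
  expect_equal(unname(m$overall), c(3, 1))
  expect_equal(unname(m$sj), c(sqrt(2), 0))
  expect_equal(m$s0, sqrt(2) / 2)   # median of (sqrt(2), 0): midpoint
  expect_equal(unname(m$mk), rep(sqrt(1 / 2 - 1 / 4), 2))
  # delta = 0: shrunken centroids are the class means
  expect_equal(m$shrunken, m$centroids)
})

test_that("full shrinkage collapses centroids to the overall mean", {
  inst <- two_gene_instance()
  base <- nanosubtype:::.pam_base(inst$x, inst$labels, "empirical")
  dmax <- max(abs((base$centroids - base$overall) /
                    outer(base$sj + base$s0, base$mk)))
  m <- train_pam(inst$x, inst$labels, delta = dmax + 1)
  expect_equal(m$shrunken, cbind(A = m$overall, B = m$overall))
})

test_that("soft thresholding is monotone in delta", {
  set.seed(4)
  inst <- random_nsc_instance()
  deltas <- seq(0, 2, by = 0.25)
  prev <- NULL
  for (d in deltas) {
    m <- train_pam(inst$x, inst$labels, delta = d)
    dev <- abs(m$shrunken - m$overall)
    if (!is.null(prev)) expect_true(all(dev <= prev + 1e-12))
    prev <- dev
  }
})

test_that("predict matches the hand-derived discriminant values", {
  inst <- two_gene_instance()
  m <- train_pam(inst$x, inst$labels, priors = "uniform")
  call <- predict(m, c(g1 = 2, g2 = 1))
  # delta_k includes -2 log pi_k = 2 log 2 under uniform priors
  expect_equal(call$delta_A - 2 * log(2), 20 / 9, tolerance = 1e-9)
  expect_equal(call$delta_B - 2 * log(2), 4, tolerance = 1e-9)
  expect_identical(call$label, "A")
  expect_false(call$tie)
})

test_that("a centroid classifies as itself with r = 1", {
  set.seed(7)
  lx <- sim_logexpr(simulation_config(n_samples = 20, seed = 7))
  m <- train_pam(lx$x, lx$truth, priors = "uniform")
  call <- predict(m, m$shrunken[, "basal"])
  expect_identical(call$label, "basal")
  expect_equal(call$r_basal, 1)
  expect_equal(call$delta_basal, -2 * log(0.5))
  expect_equal(call$basal_score,
               min(1, (1 + 1 - call$r_luminal) / 2))
})

test_that("exact symmetry raises the tie flag and resolves to luminal", {
  # both class centroids coincide at (1,1,1): every point is an exact tie
  x <- matrix(c(0, 0, 0, 2, 2, 2, -2, -2, -2, 4, 4, 4), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  labels <- c("basal", "basal", "luminal", "luminal")
  m <- train_pam(x, labels, priors = "uniform")
  mid <- (m$shrunken[, "basal"] + m$shrunken[, "luminal"]) / 2
  # the coincident centroids are constant vectors, so the correlation is
  # degenerate: r is forced to 0 with the flag raised
  expect_warning(call <- predict(m, mid), "zero-variance")
  expect_true(call$tie)
  expect_true(call$flag)
  expect_identical(call$label, "luminal")
  expect_equal(call$p_basal, 0.5)
  expect_equal(call$p_luminal, 0.5)
  expect_equal(call$basal_score, 0.5)
})

test_that("unequal priors break an exact tie toward the larger prior", {
  pick <- nanosubtype:::.pam_label(c(basal = 2, luminal = 2),
                                   c(basal = 0.4, luminal = 0.6))
  expect_true(pick$tie)
  expect_identical(pick$label, "luminal")
  pick <- nanosubtype:::.pam_label(c(basal = 2, luminal = 2),
                                   c(basal = 0.6, luminal = 0.4))
  expect_identical(pick$label, "basal")
})

test_that("train/predict agree with the brute-force oracle", {
  set.seed(2024)
  for (i in seq_len(40)) {
    inst <- random_nsc_instance()
    uniform <- i %% 2 == 0
    m <- train_pam(inst$x, inst$labels, delta = inst$delta,
                   priors = if (uniform) "uniform" else "empirical")
    o <- naive_nsc_train(inst$x, inst$labels, inst$delta,
                         uniform_priors = uniform)
    expect_equal(unname(m$shrunken), unname(o$shrunken),
                 tolerance = 1e-9)
    expect_equal(unname(m$sj), o$sj, tolerance = 1e-9)
    expect_equal(m$s0, o$s0, tolerance = 1e-9)
    xnew <- rnorm(nrow(inst$x))
    names(xnew) <- rownames(inst$x)
    call <- predict(m, xnew)
    d_o <- naive_nsc_discriminant(o, xnew)
    expect_equal(call$delta_A, unname(d_o["A"]), tolerance = 1e-9)
    expect_equal(call$delta_B, unname(d_o["B"]), tolerance = 1e-9)
    if (d_o["A"] != d_o["B"]) {
      expect_identical(call$label, names(which.min(d_o)))
    } else {
      # full shrinkage can make the classes exactly equidistant: the
      # documented tie rule applies (flag + lexicographically last class
      # at equal priors)
      expect_true(call$tie)
    }
  }
})

test_that("delta = 0, equal priors, s0 = 0, unit s_j reduces to nearest
           class mean in Euclidean distance", {
  set.seed(88)
  for (i in 1:20) {
    g <- sample(2:5, 1)
    cents <- matrix(rnorm(2 * g), g, 2,
                    dimnames = list(paste0("g", 1:g), c("A", "B")))
    model <- structure(list(
      classes = c("A", "B"), genes = rownames(cents),
      overall = rowMeans(cents), centroids = cents, shrunken = cents,
      sj = rep(1, g), s0 = 0, delta = 0,
      mk = c(A = 0.5, B = 0.5),
      priors = c(A = 0.5, B = 0.5),
      n_per_class = c(A = 2L, B = 2L),
      provenance = list()), class = "pam_model")
    x <- rnorm(g)
    names(x) <- rownames(cents)
    call <- predict(model, x)
    eu <- c(A = sum((x - cents[, 1])^2), B = sum((x - cents[, 2])^2))
    expect_identical(call$label, names(which.min(eu)))
  }
})

test_that("posteriors are invariant to a constant shift of all deltas", {
  d <- matrix(c(3, 7, 1.5, 2), 2, dimnames = list(c("A", "B"), NULL))
  expect_equal(nanosubtype:::.softmax_rows(d),
               nanosubtype:::.softmax_rows(d + 42))
  expect_equal(colSums(nanosubtype:::.softmax_rows(d)), c(1, 1))
})

test_that("predict is pure: repeats and gene permutations agree", {
  lx <- sim_logexpr(simulation_config(n_samples = 16, seed = 13))
  m <- train_pam(lx$x, lx$truth)
  c1 <- predict(m, lx$x)
  c2 <- predict(m, lx$x)
  expect_identical(c1, c2)
  set.seed(5)
  perm <- sample(nrow(lx$x))
  c3 <- predict(m, lx$x[perm, ])
  # permuting gene order only changes floating-point summation order
  expect_equal(c1, c3)
  expect_identical(c1$label, c3$label)
})

test_that("missing genes are refused by default, imputable on request", {
  lx <- sim_logexpr(simulation_config(n_samples = 16, seed = 13))
  m <- train_pam(lx$x, lx$truth)
  crop <- lx$x[-match("BSL01", rownames(lx$x)), , drop = FALSE]
  expect_error(predict(m, crop), "BSL01")
  expect_warning(calls <- predict(m, crop, impute_missing = TRUE),
                 "BSL01")
  expect_identical(nrow(calls), ncol(crop))
})

test_that("training contract errors", {
  inst <- two_gene_instance()
  expect_error(train_pam(inst$x, c("A", "A", "A", "B")), "< 2 samples")
  expect_error(train_pam(inst$x, rep("A", 4)), ">= 2 classes")
  expect_error(train_pam(inst$x, inst$labels, delta = -1), "delta")
  expect_error(train_pam(unname(inst$x), inst$labels), "rownames")
  # constant gene is absorbed by s0, not a division by zero
  x <- rbind(inst$x, g3 = rep(1, 4), g4 = c(0, 2, 0, 2))
  m <- train_pam(x, inst$labels)
  expect_gt(m$s0, 0)
  expect_true(all(is.finite(m$shrunken)))
})

test_that("choose_delta finds separable data and honours the grid", {
  lx <- sim_logexpr(simulation_config(n_samples = 24, effect_size = 4,
                                      bio_sd = 0.3, seed = 31))
  cd <- choose_delta(lx$x, lx$truth, folds = 4, seed = 1)
  expect_equal(cd$cv$error_rate[cd$cv$delta == 0], 0)
  one <- choose_delta(lx$x, lx$truth, folds = 4, grid = 0.7, seed = 1)
  expect_identical(one$delta, 0.7)
  expect_error(choose_delta(lx$x, lx$truth, grid = numeric()), "grid")
})

test_that("choose_delta on permuted labels sits at chance", {
  lx <- sim_logexpr(simulation_config(n_samples = 40, seed = 17))
  set.seed(170)
  shuffled <- sample(lx$truth)
  cd <- choose_delta(lx$x, shuffled, folds = 5, seed = 2)
  # binomial band: 50% +/- 3 * 100 * sqrt(0.25 / n)
  band <- 3 * 100 * sqrt(0.25 / length(shuffled))
  expect_true(abs(min(cd$cv$error_rate) - 50) < band + 15)
  expect_true(min(cd$cv$error_rate) > 10)
})

test_that("classification_error computes and prints rates", {
  ce <- classification_error(rep(c("x", "y"), c(7, 45)), rep("y", 52))
  expect_identical(ce$errors, 7L)
  expect_equal(ce$rate, 100 * 7 / 52)
  expect_equal(ce$printed, 13)
  expect_equal(classification_error(rep("a", 10), rep("a", 10))$rate, 0)
  expect_error(classification_error("a", c("a", "b")), "length")
  expect_error(classification_error(character(), character()), "empty")
})

test_that("model JSON round trip reproduces predictions bit-exactly", {
  lx <- sim_logexpr(simulation_config(n_samples = 18, seed = 23))
  m <- train_pam(lx$x, lx$truth, delta = 0.3)
  f <- tempfile(fileext = ".json")
  write_pam_model(m, f)
  m2 <- read_pam_model(f)
  expect_identical(predict(m, lx$x), predict(m2, lx$x))
  expect_identical(m2$delta, 0.3)
})
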