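test_that("the one-variable F-to-enter equals the one-way ANOVA F", {
  set.seed(30)
  for (g in 2:3) {
    y <- factor(rep(letters[1:g], each = 12))
    x <- rnorm(length(y)) + as.integer(y)
    sel <- stepwise_select(matrix(x, dimnames = list(NULL, "x")), y,
                           f_enter = 0, f_remove = -1)
    f_anova <- summary(aov(x ~ y))[[1]]$`F value`[1]
    expect_equal(sel$trace$F[1], f_anova, tolerance = 1e-10)
    lam <- wilks_lambda(matrix(x), y)
    expect_equal(lam, 1 / (1 + f_anova * (g - 1) / (length(y) - g)),
                 tolerance = 1e-10)
  }
})

test_that("a single perfectly separating variable is selected among noise", {
  set.seed(31)
  y <- factor(rep(c("a", "b", "c"), each = 20))
  X <- cbind(sep = as.integer(y) * 10 + rnorm(60, 0, 0.1),
             n1 = rnorm(60), n2 = rnorm(60), n3 = rnorm(60))
  sel <- stepwise_select(X, y)
  expect_true("sep" %in% sel$selected)
  expect_equal(sel$selected[1], "sep")
})

test_that("the stepwise path matches an exhaustive Wilks-lambda oracle", {
  set.seed(32)
  n <- 45
  y <- factor(rep(c("a", "b", "c"), each = n / 3))
  X <- cbind(v1 = rnorm(n) + 2 * (y == "a"),
             v2 = rnorm(n) + 1.5 * (y == "b"),
             v3 = rnorm(n, sd = 2),
             v4 = rnorm(n) + 0.5 * (y == "c"))
  f_enter <- 3.84; f_remove <- 2.71
  # oracle: literal exhaustive re-evaluation of every entry/removal candidate
  g <- 3
  lam_of <- function(set) if (length(set) == 0) 1
    else wilks_lambda(X[, set, drop = FALSE], y)
  in_set <- character(0)
  repeat {
    changed <- FALSE
    outs <- setdiff(colnames(X), in_set)
    if (length(outs)) {
      Fs <- sapply(outs, function(v) {
        p1 <- length(in_set) + 1
        ((n - g - p1 + 1) / (g - 1)) *
          (lam_of(in_set) / lam_of(c(in_set, v)) - 1)
      })
      if (max(Fs) >= f_enter) {
        in_set <- c(in_set, outs[which.max(Fs)]); changed <- TRUE
      }
    }
    repeat {
      if (length(in_set) < 2) break
      Fr <- sapply(in_set, function(v) {
        p <- length(in_set)
        ((n - g - p + 1) / (g - 1)) *
          (lam_of(setdiff(in_set, v)) / lam_of(in_set) - 1)
      })
      if (min(Fr) < f_remove) {
        in_set <- setdiff(in_set, in_set[which.min(Fr)]); changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  sel <- stepwise_select(X, y, f_enter = f_enter, f_remove = f_remove)
  expect_equal(sel$selected, in_set)
})

test_that("two spherical classes split along the perpendicular bisector of the means", {
  set.seed(33)
  X <- rbind(matrix(rnorm(100), 50, 2) + 5, matrix(rnorm(100), 50, 2) - 5)
  colnames(X) <- c("x1", "x2")
  y <- factor(rep(c("hi", "lo"), each = 50))
  fit <- fit_lda(X, y)
  mid <- (colMeans(X[1:50, ]) + colMeans(X[51:100, ])) / 2
  dirn <- colMeans(X[1:50, ]) - colMeans(X[51:100, ])
  probe <- rbind(mid + 0.5 * dirn, mid - 0.5 * dirn)
  colnames(probe) <- colnames(X)
  expect_equal(predict(fit, probe)$class, c("hi", "lo"))
  # near the bisector the class scores are nearly equal
  sc <- predict(fit, rbind(mid))$scores
  expect_lt(abs(sc[1] - sc[2]), 0.5)
})

test_that("classification matches brute-force Bayes and MASS::lda", {
  fx <- lda_fixture(seed = 34, sep = 1.2)
  fit <- fit_lda(fx$X, fx$y)
  set.seed(35)
  Xnew <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, colnames(fx$X)))
  got <- predict(fit, Xnew)$class
  expect_equal(got, bayes_oracle(fx$X, fx$y, Xnew))
  mass <- MASS::lda(fx$X, fx$y, prior = rep(1 / 3, 3))
  expect_equal(got, as.character(predict(mass, Xnew)$class))
})

test_that("classification is invariant to affine rescaling of a variable", {
  fx <- lda_fixture(seed = 36, sep = 1)
  fit <- fit_lda(fx$X, fx$y)
  Xr <- fx$X
  Xr[, 2] <- 100 * Xr[, 2] - 7
  fit_r <- fit_lda(Xr, fx$y)
  expect_equal(predict(fit_r, Xr)$class, predict(fit, fx$X)$class)
})

test_that("LOO confusion matches a naive refit oracle and MASS cross-validation", {
  fx <- lda_fixture(seed = 37, n_per = 15, sep = 0.8)
  loo <- loo_confusion(fx$X, fx$y)
  mass_cv <- MASS::lda(fx$X, fx$y, prior = rep(1 / 3, 3), CV = TRUE)
  expect_equal(loo$predicted, as.character(mass_cv$class))
  expect_equal(unname(rowSums(loo$confusion)), rep(100, 3))
  # resubstitution accuracy is never below LOO accuracy
  fit <- fit_lda(fx$X, fx$y)
  resub <- mean(predict(fit, fx$X)$class == as.character(fx$y))
  expect_gte(resub, mean(loo$predicted == as.character(fx$y)))
  # perfectly separated classes -> identity confusion
  fx2 <- lda_fixture(seed = 38, n_per = 10, sep = 50)
  expect_equal(unname(diag(loo_confusion(fx2$X, fx2$y)$confusion)),
               rep(100, 3))
})

test_that("wild cards at a class mean are fully allocated to that class", {
  fx <- lda_fixture(seed = 39, sep = 3)
  fit <- fit_lda(fx$X, fx$y)
  reg <- tiny_registry()
  # put mimic specimens exactly at the class-b mean, at a schmidti site
  Xm <- matrix(rep(fit$means["b", ], 5), 5, 4, byrow = TRUE,
               dimnames = list(NULL, colnames(fx$X)))
  expect_error(wildcard_allocate(fit, Xm, rep(9, 5), reg),
               "absent from registry")
  alloc <- wildcard_allocate(fit, Xm, rep(2, 5), reg)
  expect_equal(alloc$per_site$b, 100)
  expect_equal(unname(rowSums(alloc$per_site[, c("a", "b", "c")])), 100)
})

test_that("the full discriminant stage separates generated species and allocates mimics home", {
  gen <- generate_dataset(synthetic_config(seed = 40, lambda = 1))
  da <- discriminant_analysis(gen$specimens)
  expect_gte(length(da$selection$selected), 1)
  expect_true(all(diag(da$loo$confusion) >= 90))
  expect_true(all(da$allocation$correct >= 90))
  expect_equal(unname(rowSums(da$allocation$per_category[, model_taxa()])),
               rep(100, 3), tolerance = 0.1)
})
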