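test_that("Euclidean distance has its closed-form values and metric properties", {
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_error(euclidean_distance(1:3, 1:4), "equal length")
  set.seed(17)
  for (i in 1:20) {
    a <- rnorm(4); b <- rnorm(4); c_ <- rnorm(4)
    expect_equal(euclidean_distance(a, b), euclidean_distance(b, a))
    expect_lte(euclidean_distance(a, c_),
               euclidean_distance(a, b) + euclidean_distance(b, c_) + 1e-12)
  }
})

test_that("per-site syntopic and allotopic means match hand enumeration on a 3-site fixture", {
  # nest coordinates chosen so that the per-foreign-site mean-of-means
  # differs from a pooled mean over all foreign pairs (sites 2 and 3 have
  # different nest counts)
  ns <- data.frame(
    site_id = c(1, 1, 1, 2, 2, 3, 3, 3, 3),
    group   = c("mimic", "model", "model",
                "mimic", "model",
                "mimic", "model", "model", "model"),
    nest_id = paste0("n", 1:9),
    PC1 = c(0, 1, 3, 10, 14, -5, -6, -7, -10))
  reg <- tiny_registry()
  ds <- site_distance_table(ns, reg)
  # site 1: mimic at 0 vs models {1,3} -> 2; allotopic: site2 models {14}->14,
  # site3 models {-6,-7,-10} -> mean(6,7,10)=23/3; allo = (14 + 23/3)/2
  expect_equal(ds$per_site$syntopic[1], 2)
  expect_equal(ds$per_site$allotopic[1], (14 + 23 / 3) / 2)
  # site 2: mimic at 10 vs model 14 -> 4; allo sites: 1 -> mean(9,7)=8,
  # 3 -> mean(16,17,20)=53/3
  expect_equal(ds$per_site$syntopic[2], 4)
  expect_equal(ds$per_site$allotopic[2], (8 + 53 / 3) / 2)
  # pooled-over-pairs definition would give a different site-2 value
  pooled <- mean(c(9, 7, 16, 17, 20))
  expect_false(isTRUE(all.equal(ds$per_site$allotopic[2], pooled)))
  # site 3: mimic -5 vs models {-6,-7,-10} -> mean(1,2,5)=8/3
  expect_equal(ds$per_site$syntopic[3], 8 / 3)
  expect_equal(unname(ds$grand["syntopic_mean"]), mean(c(2, 4, 8 / 3)))
})

test_that("degenerate inputs: identical nest means give zero everywhere", {
  ns <- data.frame(site_id = rep(1:3, each = 2),
                   group = rep(c("mimic", "model"), 3),
                   nest_id = paste0("n", 1:6), PC1 = 5, PC2 = -2)
  ds <- site_distance_table(ns, tiny_registry())
  expect_equal(ds$per_site$syntopic, rep(0, 3))
  expect_equal(ds$per_site$allotopic, rep(0, 3))
  expect_equal(ds$test$t, 0)
  expect_equal(ds$test$p, 0.5)
})

test_that("a site missing one genus is reported by name", {
  ns <- data.frame(site_id = c(1, 1, 2), group = c("mimic", "model", "model"),
                   nest_id = c("a", "b", "c"), PC1 = 1:3)
  expect_error(site_distance_table(ns, tiny_registry()),
               "site 2 lacks nests of one genus")
})

test_that("size differences aggregate |delta CS| like the color table", {
  nm <- data.frame(site_id = c(1, 1, 1, 2, 2, 3, 3),
                   group = c("mimic", "mimic", "model",
                             "mimic", "model", "mimic", "model"),
                   nest_id = paste0("n", 1:7),
                   CS = c(990, 1010, 1000, 1000, 1020, 950, 950))
  ds <- size_difference_table(nm, tiny_registry())
  expect_equal(ds$per_site$syntopic[1], 10)   # |990-1000|, |1010-1000|
  expect_equal(ds$per_site$syntopic[2], 20)
  expect_equal(ds$per_site$syntopic[3], 0)
  expect_equal(ds$per_site$allotopic[1], mean(c(mean(c(30, 10)),
                                                mean(c(40, 60)))))
})

test_that("the paired one-sided t-test matches the closed-form t distribution", {
  r <- paired_one_sided_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$t, 0)
  expect_equal(r$p, 0.5)
  set.seed(23)
  syn <- c(4, 5, 6, 7)
  allo <- syn + 1 + rnorm(4, 0, 0.01)
  r2 <- paired_one_sided_t(syn, allo)
  d <- syn - allo
  t_oracle <- mean(d) / (sd(d) / 2)
  expect_equal(r2$t, t_oracle, tolerance = 1e-12)
  expect_equal(r2$df, 3)
  expect_equal(r2$p, pt(t_oracle, df = 3), tolerance = 1e-12)
  expect_lt(r2$p, 0.01)
  expect_error(paired_one_sided_t(c(1, 2, 3), c(2, 3, 4)),
               "zero variance")
  expect_error(paired_one_sided_t(1:3, 1:4), "length mismatch")
})

test_that("permuting mimic site labels removes the syntopy signal in expectation", {
  gen <- generate_dataset(synthetic_config(seed = 55, lambda = 0.9))
  nm <- nest_means(gen$specimens)
  red <- reduce_cumulative(as.matrix(nm[, sqrt_channel_names()]), 0.8)
  ns <- cbind(nm[, c("site_id", "group", "nest_id")],
              as.data.frame(red$scores))
  real <- site_distance_table(ns, default_site_registry())
  expect_lt(real$grand[["syntopic_mean"]], real$grand[["allotopic_mean"]])
  # permute whole mimic sites: relabel each mimic site by a random derangement
  set.seed(56)
  sites <- sort(unique(ns$site_id))
  repeat {
    perm <- sample(sites)
    if (all(perm != sites)) break
  }
  ns_perm <- ns
  mim <- ns_perm$group == "mimic"
  ns_perm$site_id[mim] <- perm[match(ns_perm$site_id[mim], sites)]
  broken <- site_distance_table(ns_perm, default_site_registry())
  gap_real <- real$grand[["allotopic_mean"]] - real$grand[["syntopic_mean"]]
  gap_broken <- broken$grand[["allotopic_mean"]] -
    broken$grand[["syntopic_mean"]]
  expect_lt(abs(gap_broken), 0.25 * gap_real)
})
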