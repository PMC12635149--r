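test_that("mesosoma card color is the unweighted mean of its three regions", {
  ch <- matrix(100, 1, 18, dimnames = list(NULL, channel_names()))
  ch[, c("R_pr", "G_pr", "B_pr")] <- c(100, 50, 50)
  ch[, c("R_me", "G_me", "B_me")] <- c(100, 50, 50)
  ch[, c("R_pp", "G_pp", "B_pp")] <- c(100, 50, 50)
  df <- rbind(make_specimens(1, "model", "n1", "a", ch),
              make_specimens(1, "mimic", "m1", "b", ch))
  cards <- suppressWarnings(site_color_cards(df, tiny_registry()))
  m <- cards[cards$group == "model", ]
  expect_equal(c(m$R_mesosoma, m$G_mesosoma, m$B_mesosoma), c(100, 50, 50))

  ch2 <- ch
  ch2[, "R_pr"] <- 90; ch2[, "R_me"] <- 100; ch2[, "R_pp"] <- 110
  df2 <- make_specimens(1, "model", "n1", "a", ch2)
  cards2 <- suppressWarnings(site_color_cards(df2, tiny_registry()))
  expect_equal(cards2$R_mesosoma[1], 100)
})

test_that("card colors stay inside the convex hull of specimen values", {
  gen <- generate_dataset(synthetic_config(seed = 44, nests_model = 2,
                                           nests_mimic = 2, workers_model = 5,
                                           workers_mimic = 5))
  cards <- site_color_cards(gen$specimens)
  for (i in seq_len(nrow(cards))) {
    sel <- gen$specimens$site_id == cards$site_id[i] &
      gen$specimens$group == cards$group[i]
    v <- as.matrix(gen$specimens[sel, channel_names()])
    expect_gte(cards$R_head[i], min(v[, "R_he"]))
    expect_lte(cards$R_head[i], max(v[, "R_he"]))
    expect_gte(cards$B_gaster[i], min(v[, "B_ga"]))
    expect_lte(cards$B_gaster[i], max(v[, "B_ga"]))
  }
})

test_that("with perfect mimicry, model and mimic cards agree per site", {
  gen <- generate_dataset(synthetic_config(seed = 45, lambda = 1,
                                           workers_model = 20,
                                           workers_mimic = 20))
  cards <- site_color_cards(gen$specimens)
  for (s in unique(cards$site_id)) {
    a <- cards[cards$site_id == s & cards$group == "model",
               -(1:3)]
    b <- cards[cards$site_id == s & cards$group == "mimic", -(1:3)]
    # site/nest layers (sd 0.3 sqrt units) dominate the sampling error
    expect_lt(max(abs(a - b)), 30)
  }
})

test_that("confidence ellipses follow the chi-squared geometry", {
  set.seed(46)
  xy <- matrix(rnorm(40000), 20000, 2)
  e <- confidence_ellipse(xy)
  expect_equal(unname(e$radii), rep(sqrt(qchisq(0.95, 2)), 2),
               tolerance = 0.03)
  # known covariance: axes from its eigendecomposition
  S <- matrix(c(4, 1.5, 1.5, 1), 2)
  xy2 <- matrix(rnorm(200000), 100000, 2) %*% chol(S)
  e2 <- confidence_ellipse(xy2)
  ev <- eigen(S)$values
  expect_equal(unname(e2$radii), sqrt(ev * qchisq(0.95, 2)),
               tolerance = 0.05)
  # empirical coverage ~95%
  d2 <- mahalanobis(xy2, e2$center, e2$cov)
  expect_equal(mean(d2 <= qchisq(0.95, 2)), 0.95, tolerance = 0.02)
  expect_error(confidence_ellipse(xy[1:2, ]), "at least 3")
})

test_that("pca_scatter returns points, per-group ellipses and loadings", {
  gen <- generate_dataset(synthetic_config(seed = 47, nests_model = 2,
                                           nests_mimic = 2, workers_model = 4,
                                           workers_mimic = 4))
  sq <- sqrt(as.matrix(gen$specimens[, channel_names()]))
  colnames(sq) <- sqrt_channel_names()
  ps <- pca_scatter(sq, gen$specimens$taxon, level = "individual")
  expect_equal(nrow(ps$points), nrow(sq))
  expect_equal(sort(unique(ps$ellipses$group)),
               sort(unique(gen$specimens$taxon)))
  ps2 <- pca_scatter(sq, gen$specimens$taxon, level = "site",
                     site_labels = gen$specimens$site_id)
  expect_equal(nrow(ps2$points), 36)  # 18 sites x 2 groups
  expect_equal(ncol(ps2$loadings), 2)
  expect_warning(
    pca_scatter(sq[1:7, ], c("a", "a", "a", "a", "a", "b", "b"),
                level = "individual"),
    "< 3 points")
})

test_that("summary tables report sample means and (n-1) SDs per group", {
  ch <- matrix(100, 2, 18, dimnames = list(NULL, channel_names()))
  ch[, "R_he"] <- c(10, 14)
  df <- make_specimens(c(1, 1), "model", "n1", c("a", "b"), ch)
  df$taxon <- "scutellaris"
  tab <- summary_table(df)
  expect_equal(tab$R_he_mean, 12)
  expect_equal(tab$R_he_sd, sd(c(10, 14)))
  expect_equal(round(tab$R_he_sd, 2), 2.83)
  single <- make_specimens(2, "mimic", "m1", "only")
  single$taxon <- "schmidti-syntopic"
  tab1 <- summary_table(single)
  expect_equal(tab1$CS_sd, 0)
  expect_equal(tab1$n, 1)
})

test_that("color cards render to a parseable SVG strip", {
  gen <- generate_dataset(synthetic_config(seed = 48, nests_model = 1,
                                           nests_mimic = 1, workers_model = 2,
                                           workers_mimic = 2))
  cards <- site_color_cards(gen$specimens)
  path <- withr::local_tempfile(fileext = ".svg")
  write_color_cards_svg(cards, path)
  svg <- readLines(path)
  expect_match(svg[1], "<svg")
  # model gasters are triangles, mimic gasters circles
  expect_equal(sum(grepl("<polygon", svg)), 18)
  expect_equal(sum(grepl("<circle", svg)), 18)
  expect_true(requireNamespace("xml2", quietly = TRUE))
  expect_silent(xml2::read_xml(paste(svg, collapse = "\n")))
})
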