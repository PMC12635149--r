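#' Per-site mean color cards
#'
#' Reconstructs the displayed mean coloration of each genus at each site on
#' the raw RGB scale (unlike the sqrt-scale statistics): per site and genus,
#' the raw channel means for head, mesosoma, petiole and gaster, where the
#' mesosoma is the unweighted mean of the pronotum, mesonotum and propodeum
#' channels.
#'
#' @param records validated specimen data.frame (raw RGB).
#' @param registry site registry.
#' @return data.frame (`site_id`, `group`, `n`, then `R_head`, `G_head`,
#'   `B_head`, `R_mesosoma`, ..., `B_gaster`).
#' @export
site_color_cards <- function(records, registry = default_site_registry()) {
  parts <- list(head = "he", mesosoma = c("pr", "me", "pp"),
                petiole = "pe", gaster = "ga")
  out <- list()
  for (sid in sort(unique(registry$site_id))) {
    for (g in c("model", "mimic")) {
      sel <- records$site_id == sid & records$group == g
      if (!any(sel)) {
        warning("site ", sid, ": no ", g, " records; card skipped")
        next
      }
      row <- data.frame(site_id = sid, group = g, n = sum(sel))
      for (pn in names(parts)) {
        for (ch in c("R", "G", "B")) {
          cols <- paste(ch, parts[[pn]], sep = "_")
          row[[paste(ch, pn, sep = "_")]] <-
            mean(colMeans(records[sel, cols, drop = FALSE]))
        }
      }
      out[[paste(sid, g)]] <- row
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Render color cards as an SVG strip
#'
#' One stylized ant glyph per site and genus: head, mesosoma and petiole as
#' ellipses filled with the card's mean colors; the gaster drawn as a
#' triangle for models and as a circle for mimics.
#'
#' @param cards data.frame from [site_color_cards()].
#' @param path output SVG path.
#' @export
write_color_cards_svg <- function(cards, path) {
  rgb_hex <- function(row, part)
    grDevices::rgb(row[[paste0("R_", part)]], row[[paste0("G_", part)]],
                   row[[paste0("B_", part)]], maxColorValue = 255)
  cw <- 60; chh <- 150
  sites <- sort(unique(cards$site_id))
  w <- cw * length(sites); h <- chh * 2
  ln <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                  w, h))
  for (i in seq_along(sites)) {
    for (gi in 1:2) {
      g <- c("model", "mimic")[gi]
      row <- cards[cards$site_id == sites[i] & cards$group == g, ]
      if (nrow(row) == 0) next
      x <- (i - 1) * cw + cw / 2
      y0 <- (gi - 1) * chh
      ln <- c(ln,
        sprintf('<text x="%g" y="%g" font-size="10" text-anchor="middle">%s %s</text>',
                x, y0 + 12, sites[i], substr(g, 1, 2)),
        sprintf('<ellipse cx="%g" cy="%g" rx="14" ry="11" fill="%s"/>',
                x, y0 + 32, rgb_hex(row, "head")),
        sprintf('<ellipse cx="%g" cy="%g" rx="11" ry="20" fill="%s"/>',
                x, y0 + 64, rgb_hex(row, "mesosoma")),
        sprintf('<ellipse cx="%g" cy="%g" rx="5" ry="5" fill="%s"/>',
                x, y0 + 90, rgb_hex(row, "petiole")))
      if (g == "model") {
        ln <- c(ln, sprintf('<polygon points="%g,%g %g,%g %g,%g" fill="%s"/>',
                            x - 13, y0 + 100, x + 13, y0 + 100, x, y0 + 132,
                            rgb_hex(row, "gaster")))
      } else {
        ln <- c(ln, sprintf('<circle cx="%g" cy="%g" r="14" fill="%s"/>',
                            x, y0 + 114, rgb_hex(row, "gaster")))
      }
    }
  }
  writeLines(c(ln, "</svg>"), path)
  invisible(path)
}

#' 95% confidence ellipse of a 2-D point cloud
#'
#' Gaussian ellipse: center at the mean, axes from the eigendecomposition of
#' the 2x2 covariance scaled by the chi-squared(2) quantile at `level`.
#'
#' @param xy two-column matrix of points (>= 3 rows).
#' @param level coverage level.
#' @return list: `center`, `radii` (semi-axes), `angle` (radians, major
#'   axis), `cov`.
#' @export
confidence_ellipse <- function(xy, level = 0.95) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3) stop("need at least 3 points for an ellipse")
  ctr <- colMeans(xy)
  S <- stats::cov(xy)
  e <- eigen(S, symmetric = TRUE)
  q <- stats::qchisq(level, df = 2)
  list(center = ctr, radii = sqrt(pmax(e$values, 0) * q),
       angle = atan2(e$vectors[2, 1], e$vectors[1, 1]), cov = S)
}

#' Plot-ready PCA scatter with group confidence ellipses
#'
#' Projects observations onto the first two components and computes a 95%
#' confidence ellipse per group; at site level, rows are site means. Also
#' returns the loadings of the two plotted components for biplot vectors.
#'
#' @param x numeric matrix on the reduced character set (sqrt scale).
#' @param labels group label per row (species or mimic category).
#' @param level `"individual"` (rows as-is) or `"site"` (`site_labels`
#'   required; rows averaged per site x group first).
#' @param site_labels site per row, required for `level = "site"`.
#' @param conf ellipse coverage level.
#' @return list: `points` data.frame (PC1, PC2, group, and site at site
#'   level), `ellipses` (one row per group with >= 3 points: center, radii,
#'   angle), `loadings` (variables x 2), `explained` (first two fractions).
#' @export
pca_scatter <- function(x, labels, level = c("individual", "site"),
                        site_labels = NULL, conf = 0.95) {
  level <- match.arg(level)
  x <- as.matrix(x)
  if (level == "site") {
    if (is.null(site_labels)) stop("site_labels required at site level")
    key <- paste(site_labels, labels, sep = "\r")
    first <- !duplicated(key)
    x <- rowsum(x, key)[unique(key), , drop = FALSE] /
      as.vector(table(key)[unique(key)])
    site_out <- site_labels[first]
    labels <- labels[first]
  }
  m <- pca_fit(x)
  sc <- pca_scores(m, x, k = 2)
  pts <- data.frame(PC1 = sc[, 1], PC2 = sc[, 2], group = labels,
                    stringsAsFactors = FALSE)
  if (level == "site") pts$site <- site_out
  ell <- list()
  for (g in unique(labels)) {
    sel <- labels == g
    if (sum(sel) < 3) {
      warning("group '", g, "' has < 3 points; no ellipse")
      next
    }
    e <- confidence_ellipse(sc[sel, , drop = FALSE], level = conf)
    ell[[g]] <- data.frame(group = g, center1 = e$center[1],
                           center2 = e$center[2], radius1 = e$radii[1],
                           radius2 = e$radii[2], angle = e$angle)
  }
  list(points = pts,
       ellipses = if (length(ell)) do.call(rbind, c(ell, list(make.row.names = FALSE)))
         else NULL,
       loadings = m$loadings[, 1:2, drop = FALSE],
       explained = m$explained[1:2])
}

#' Group summary table: means and SDs of raw traits
#'
#' Per species / mimic category: mean and sample (n-1) SD of the 18 raw
#' channel variables and cephalic size, with group sizes.
#'
#' @param records validated specimen data.frame with `taxon`.
#' @return data.frame: `taxon`, `n`, then `<var>_mean` and `<var>_sd` for
#'   each channel and `CS`.
#' @export
summary_table <- function(records) {
  records$CS <- cephalic_size(records$CL, records$CW)
  vars <- c(channel_names(), "CS")
  out <- lapply(split(records, records$taxon), function(d) {
    row <- data.frame(taxon = d$taxon[1], n = nrow(d),
                      stringsAsFactors = FALSE)
    for (v in vars) {
      row[[paste0(v, "_mean")]] <- mean(d[[v]])
      row[[paste0(v, "_sd")]] <- if (nrow(d) > 1) stats::sd(d[[v]]) else 0
    }
    row
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
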