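#' Euclidean distance between two trait vectors
#'
#' @param a,b numeric vectors of equal length (e.g. nest-mean PC scores).
#' @return `sqrt(sum((a - b)^2))`.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  sqrt(sum((a - b)^2))
}

#' @noRd
#' Core syntopy/allotopy aggregation shared by the color-distance and
#' size-difference tables. `coords`: numeric matrix of nest coordinates;
#' rows aligned with `site_id`/`group`. The per-site allotopic value is the
#' unweighted mean of the 17 per-foreign-site means (not a pooled mean over
#' all foreign nest pairs).
syntopy_allotopy_table <- function(coords, site_id, group, registry) {
  coords <- as.matrix(coords)
  sites <- sort(unique(registry$site_id))
  used <- sort(unique(site_id))
  sites <- sites[sites %in% used]
  for (s in sites) {
    if (!any(site_id == s & group == "mimic") ||
        !any(site_id == s & group == "model"))
      stop("site ", s, " lacks nests of one genus")
  }
  mean_cross <- function(A, B) {
    # mean pairwise Euclidean distance between rows of A and rows of B
    tot <- 0
    for (i in seq_len(nrow(A)))
      tot <- tot + sum(sqrt(colSums((t(B) - A[i, ])^2)))
    tot / (nrow(A) * nrow(B))
  }
  syn <- allo <- numeric(length(sites))
  for (i in seq_along(sites)) {
    s <- sites[i]
    Ms <- coords[site_id == s & group == "mimic", , drop = FALSE]
    syn[i] <- mean_cross(Ms, coords[site_id == s & group == "model", ,
                                    drop = FALSE])
    foreign <- setdiff(sites, s)
    per_site <- vapply(foreign, function(t2) {
      mean_cross(Ms, coords[site_id == t2 & group == "model", , drop = FALSE])
    }, 0)
    allo[i] <- mean(per_site)
  }
  per_site <- data.frame(
    site_id = sites,
    model_taxon = registry$model_taxon[match(sites, registry$site_id)],
    syntopic = syn, allotopic = allo, gap = allo - syn,
    stringsAsFactors = FALSE)
  test <- paired_one_sided_t(syn, allo)
  structure(list(
    per_site = per_site,
    grand = c(syntopic_mean = mean(syn), syntopic_sd = stats::sd(syn),
              allotopic_mean = mean(allo), allotopic_sd = stats::sd(allo)),
    test = test), class = "distance_summary")
}

#' Syntopic vs allotopic model-mimic color distances
#'
#' For each site s, the syntopic value is the mean Euclidean distance over all
#' (mimic nest at s, model nest at s) pairs in the reduced nest-mean PC
#' space; the allotopic value is the unweighted mean over the foreign sites
#' t != s of the per-site mean distance from s's mimic nests to t's model
#' nests. Grand means weight all sites equally. A one-sided paired t-test
#' asks whether syntopic distances are smaller than allotopic ones.
#'
#' @param nest_scores data.frame with `site_id`, `group`, `nest_id` plus the
#'   reduced PC score columns (from [reduce_cumulative()] on pooled nest
#'   means, threshold 0.80).
#' @param registry site registry.
#' @return `distance_summary`: `per_site` table (site, syntopic, allotopic,
#'   gap), `grand` means +- SD, and the paired `test`.
#' @export
site_distance_table <- function(nest_scores, registry) {
  score_cols <- setdiff(names(nest_scores),
                        c("site_id", "group", "taxon", "nest_id",
                          "CS", "n_specimens"))
  coords <- as.matrix(nest_scores[, score_cols, drop = FALSE])
  syntopy_allotopy_table(coords, nest_scores$site_id, nest_scores$group,
                         registry)
}

#' Syntopic vs allotopic model-mimic cephalic-size differences
#'
#' Identical aggregation to [site_distance_table()], with the absolute
#' nest-mean cephalic-size difference |delta CS| (micrometers) in place of
#' the color distance.
#'
#' @param nest_mean_table nest means as from [nest_means()] (`CS` column).
#' @param registry site registry.
#' @return `distance_summary` on the micrometer scale.
#' @export
size_difference_table <- function(nest_mean_table, registry) {
  syntopy_allotopy_table(matrix(nest_mean_table$CS, ncol = 1),
                         nest_mean_table$site_id, nest_mean_table$group,
                         registry)
}

#' One-sided paired t-test for syntopy < allotopy
#'
#' Paired t on d = syntopic - allotopic with alternative mean(d) < 0 and
#' df = n - 1. The degenerate all-zero-difference case returns t = 0,
#' p = 0.5; any other zero-variance difference vector is an error.
#'
#' @param syntopic,allotopic per-site values, paired by site, length n >= 2.
#' @return list with `t`, `df`, `p`, `mean_difference`.
#' @export
paired_one_sided_t <- function(syntopic, allotopic) {
  if (length(syntopic) != length(allotopic)) stop("length mismatch")
  n <- length(syntopic)
  if (n < 2) stop("need at least 2 paired sites")
  d <- syntopic - allotopic
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, df = n - 1, p = 0.5, mean_difference = 0))
    stop("zero variance of paired differences: t statistic undefined")
  }
  tt <- stats::t.test(syntopic, allotopic, paired = TRUE,
                      alternative = "less")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_difference = unname(tt$estimate))
}

#' Full nest-mean similarity analysis
#'
#' Convenience wrapper running the complete syntopy/allotopy statistic from a
#' validated specimen table: nest means, pooled PC reduction at the
#' cumulative-variance threshold, color-distance and size-difference tables.
#'
#' @param records specimen data.frame (raw RGB).
#' @param registry site registry.
#' @param threshold cumulative explained-variance threshold for the nest-mean
#'   PC reduction.
#' @return list with `color` and `size` `distance_summary` objects, the nest
#'   means and the `reduction` (scores, k, model).
#' @export
mimicry_distance_analysis <- function(records,
                                      registry = default_site_registry(),
                                      threshold = 0.8) {
  nm <- nest_means(records)
  red <- reduce_cumulative(as.matrix(nm[, sqrt_channel_names()]), threshold)
  scores <- as.data.frame(red$scores)
  names(scores) <- paste0("PC", seq_len(red$k))
  nest_scores <- cbind(nm[, c("site_id", "group", "nest_id")], scores)
  list(color = site_distance_table(nest_scores, registry),
       size = size_difference_table(nm, registry),
       nest_means = nm, reduction = red)
}

#' Write a distance summary as a per-site CSV
#'
#' Columns: site, syntopic mean, allotopic mean, difference; one trailing
#' summary row with the grand means.
#'
#' @param summary a `distance_summary`.
#' @param path output CSV path.
#' @export
write_distance_summary <- function(summary, path) {
  ps <- summary$per_site
  out <- data.frame(site = as.character(ps$site_id),
                    model_taxon = ps$model_taxon,
                    syntopic = ps$syntopic, allotopic = ps$allotopic,
                    difference = ps$gap, stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(
    site = "mean", model_taxon = "",
    syntopic = summary$grand[["syntopic_mean"]],
    allotopic = summary$grand[["allotopic_mean"]],
    difference = summary$grand[["allotopic_mean"]] -
      summary$grand[["syntopic_mean"]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
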