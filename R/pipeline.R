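#' Run configuration for the pipeline
#'
#' Bundles the paths and tuning parameters of a reproducible run. Defaults
#' follow the analysis conventions: cumulative-variance threshold 0.80 for
#' the nest-mean reduction, global alpha 0.05, stepwise F thresholds
#' 3.84 / 2.71, equal class priors.
#'
#' @param out_dir output directory (created if missing).
#' @param input specimen CSV path (`NULL` to simulate instead).
#' @param registry_path site registry CSV (`NULL` for the built-in 18-site
#'   design).
#' @param synthetic_config_path flat key=value generator config (`NULL` for
#'   defaults with `seed`).
#' @param seed RNG seed for simulation.
#' @param pc_threshold cumulative explained-variance threshold in (0, 1].
#' @param alpha global alpha in (0, 1).
#' @param f_enter,f_remove stepwise F thresholds.
#' @param priors LDA class priors (`NULL` = equal).
#' @return validated `run_config` list.
#' @export
run_config <- function(out_dir, input = NULL, registry_path = NULL,
                       synthetic_config_path = NULL, seed = 1L,
                       pc_threshold = 0.8, alpha = 0.05,
                       f_enter = 3.84, f_remove = 2.71, priors = NULL) {
  if (pc_threshold <= 0 || pc_threshold > 1)
    stop("pc_threshold must be in (0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (f_enter < 0 || f_remove < 0) stop("F thresholds must be non-negative")
  structure(list(out_dir = out_dir, input = input,
                 registry_path = registry_path,
                 synthetic_config_path = synthetic_config_path,
                 seed = as.integer(seed), pc_threshold = pc_threshold,
                 alpha = alpha, f_enter = f_enter, f_remove = f_remove,
                 priors = priors),
            class = "run_config")
}

#' @noRd
pipeline_log <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), "  ", ...)
  message(msg)
  cat(msg, "\n", file = log_path, append = TRUE)
}

#' Run pipeline stages
#'
#' Subcommands map 1:1 to the analysis stages: `simulate` writes a synthetic
#' specimen table (plus latent truth), `traits` runs the per-body-part PC1
#' and cephalic-size mixed-model comparisons, `distances` the
#' syntopy/allotopy distance statistic, `lda` the stepwise discriminant
#' calibration, cross-validation and wild-card allocation, `report` the
#' summary tables, color cards and PCA scatters, and `all` the whole
#' pipeline. Every run writes a manifest (config echo, seed, package version,
#' input checksums) and a log under `out_dir`.
#'
#' @param subcommand one of `"simulate"`, `"traits"`, `"distances"`, `"lda"`,
#'   `"report"`, `"all"`.
#' @param config a `run_config`.
#' @return invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "traits",
                                        "distances", "lda", "report"),
                         config) {
  subcommand <- match.arg(subcommand)
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  registry <- if (is.null(config$registry_path)) default_site_registry()
              else read_registry(config$registry_path)
  artifacts <- list(log = log_path)
  pth <- function(f) file.path(config$out_dir, f)

  need_sim <- subcommand == "simulate" ||
    (is.null(config$input) && subcommand != "simulate")
  if (need_sim) {
    scfg <- if (is.null(config$synthetic_config_path))
      synthetic_config(seed = config$seed)
    else read_synthetic_config(config$synthetic_config_path)
    pipeline_log(log_path, "simulate: seed ", scfg$seed)
    gen <- generate_dataset(scfg)
    write_specimens(gen$specimens, pth("specimens.csv"))
    write_latent_truth(gen$truth, pth("latent_truth.json"))
    utils::write.csv(scfg$registry, pth("registry.csv"), row.names = FALSE,
                     quote = FALSE)
    registry <- scfg$registry
    records <- gen$specimens
    artifacts$specimens <- pth("specimens.csv")
    artifacts$latent_truth <- pth("latent_truth.json")
    input_path <- pth("specimens.csv")
  } else {
    input_path <- config$input
    pipeline_log(log_path, "reading ", input_path)
    records <- read_specimens(input_path, registry)
  }

  stages <- if (subcommand == "all") c("traits", "distances", "lda", "report")
            else subcommand
  sq <- sqrt_transform(as.matrix(records[, channel_names()]))
  colnames(sq) <- sqrt_channel_names()

  if ("traits" %in% stages) {
    pipeline_log(log_path, "traits: PC1 per body part + CS mixed models")
    for (g in c("model", "mimic")) {
      if (length(unique(records$taxon[records$group == g])) < 3)
        stop("traits: 3 ", g, " groups are required for the ",
             "pairwise-letter display (found ",
             length(unique(records$taxon[records$group == g])), ")")
    }
    rows <- list()
    for (part in body_parts()) {
      cols <- paste0("sqrt", c("R", "G", "B"), "_", part)
      pc1 <- pc1_scores(sq[, cols])
      for (g in c("model", "mimic")) {
        sel <- records$group == g
        fit <- fit_lmm(pc1$scores[sel], records$taxon[sel],
                       records$site_id[sel], records$nest_id[sel])
        ct <- pairwise_contrasts(fit, alpha = config$alpha)
        ct <- cbind(trait = paste0("PC1_", part), genus = g, ct,
                    pc1_explained = pc1$explained)
        rows[[paste(part, g)]] <- ct
      }
    }
    cs <- cephalic_size(records$CL, records$CW)
    for (g in c("model", "mimic")) {
      sel <- records$group == g
      fit <- fit_lmm(cs[sel], records$taxon[sel], records$site_id[sel],
                     records$nest_id[sel])
      ct <- pairwise_contrasts(fit, alpha = config$alpha)
      rows[[paste("CS", g)]] <- cbind(trait = "CS", genus = g, ct,
                                      pc1_explained = NA)
    }
    res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    utils::write.csv(res, pth("trait_contrasts.csv"), row.names = FALSE)
    artifacts$trait_contrasts <- pth("trait_contrasts.csv")
  }

  if ("distances" %in% stages) {
    pipeline_log(log_path, "distances: syntopy vs allotopy")
    mda <- mimicry_distance_analysis(records, registry,
                                     threshold = config$pc_threshold)
    write_distance_summary(mda$color, pth("color_distances.csv"))
    write_distance_summary(mda$size, pth("size_differences.csv"))
    pipeline_log(log_path, sprintf(
      "  color %.2f/%.2f p=%.3g; size %.1f/%.1f p=%.3g (syn/allo)",
      mda$color$grand[["syntopic_mean"]], mda$color$grand[["allotopic_mean"]],
      mda$color$test$p,
      mda$size$grand[["syntopic_mean"]], mda$size$grand[["allotopic_mean"]],
      mda$size$test$p))
    artifacts$color_distances <- pth("color_distances.csv")
    artifacts$size_differences <- pth("size_differences.csv")
  }

  da <- NULL
  if (any(c("lda", "report") %in% stages)) {
    pipeline_log(log_path, "lda: stepwise selection + calibration")
    da <- discriminant_analysis(records, registry,
                                f_enter = config$f_enter,
                                f_remove = config$f_remove,
                                prior = config$priors)
  }
  if ("lda" %in% stages) {
    utils::write.csv(da$selection$trace, pth("stepwise_trace.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(class = rownames(da$loo$confusion),
                                n = da$model$n_per_class,
                                da$loo$confusion),
                     pth("loo_confusion.csv"), row.names = FALSE)
    utils::write.csv(rbind(
      stats::setNames(da$allocation$per_site,
                      c("row", names(da$allocation$per_site)[-1])),
      stats::setNames(da$allocation$per_category,
                      c("row", names(da$allocation$per_category)[-1]))),
      pth("wildcard_allocation.csv"), row.names = FALSE)
    pipeline_log(log_path, "  selected: ",
                 paste(da$selection$selected, collapse = ", "))
    artifacts$loo_confusion <- pth("loo_confusion.csv")
    artifacts$wildcard_allocation <- pth("wildcard_allocation.csv")
    artifacts$stepwise_trace <- pth("stepwise_trace.csv")
  }

  if ("report" %in% stages) {
    pipeline_log(log_path, "report: summaries, color cards, PCA scatters")
    utils::write.csv(summary_table(records), pth("group_summaries.csv"),
                     row.names = FALSE)
    cards <- site_color_cards(records, registry)
    utils::write.csv(cards, pth("site_color_cards.csv"), row.names = FALSE)
    write_color_cards_svg(cards, pth("site_color_cards.svg"))
    vars <- da$selection$selected
    for (lv in c("individual", "site")) {
      ps <- pca_scatter(sq[, vars, drop = FALSE], records$taxon, level = lv,
                        site_labels = records$site_id)
      utils::write.csv(ps$points, pth(paste0("pca_", lv, "_points.csv")),
                       row.names = FALSE)
      if (!is.null(ps$ellipses))
        utils::write.csv(ps$ellipses, pth(paste0("pca_", lv, "_ellipses.csv")),
                         row.names = FALSE)
      if (lv == "site")
        utils::write.csv(data.frame(variable = rownames(ps$loadings),
                                    ps$loadings),
                         pth("pca_site_loadings.csv"), row.names = FALSE)
    }
    artifacts$group_summaries <- pth("group_summaries.csv")
    artifacts$site_color_cards <- pth("site_color_cards.svg")
  }

  manifest <- list(
    subcommand = subcommand,
    config = unclass(config),
    package_version = as.character(utils::packageVersion("antmimic")),
    input = input_path,
    input_md5 = unname(tools::md5sum(input_path)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  artifacts$manifest <- pth("manifest.json")
  pipeline_log(log_path, "done: ", subcommand)
  invisible(artifacts)
}
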