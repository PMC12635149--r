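#' Stylized color and size archetypes for the three model species and the
#' mimic baseline
#'
#' Encodes the qualitative regional color patterns: *scutellaris* is blackish
#' with a reddish head; *schmidti* has a reddish head, mesosoma and petiole
#' with a dark gaster; *ionia* is homogeneously brownish-blackish. The mimic
#' baseline has a reddish head, an intermediate mesosoma and a dark gaster.
#' Channel means are stored on the sqrt scale (the generator's noise scale);
#' cephalic-size means are the species means in micrometers.
#'
#' The mimic baseline is the point nearest to its stylized coloration that is
#' exactly equidistant (sqrt-scale Euclidean) from the three model
#' archetypes. This makes the mimicry-accuracy dial `lambda` the only source
#' of syntopic color convergence: at `lambda = 0` the syntopy statistic is
#' under a true null (site labels carry no information about mimic color), so
#' the statistic is falsifiable against the generator.
#'
#' @return named list (`scutellaris`, `schmidti`, `ionia`, `mimic`), each a
#'   list with `color` (18 named sqrt-scale channel means) and `cs`
#'   (micrometers).
#' @export
default_archetypes <- function() {
  part_rgb <- function(he, meso, pe, ga) {
    raw <- c(he, meso, meso, meso, pe, ga)
    v <- sqrt(unlist(raw))
    stats::setNames(v, sqrt_channel_names())
  }
  equidistant_projection <- function(b0, anchors) {
    # nearest point to b0 with equal Euclidean distance to all anchors
    a1 <- anchors[[1]]
    A <- t(vapply(anchors[-1], function(ak) 2 * (ak - a1), a1))
    rhs <- vapply(anchors[-1], function(ak) sum(ak^2) - sum(a1^2), 0)
    as.vector(b0 - t(A) %*% solve(A %*% t(A), A %*% b0 - rhs))
  }
  out <- list(
    scutellaris = list(
      color = part_rgb(he = c(150, 60, 50), meso = c(45, 35, 33),
                       pe = c(45, 35, 33), ga = c(40, 32, 30)),
      cs = 1079),
    schmidti = list(
      color = part_rgb(he = c(150, 62, 52), meso = c(135, 62, 50),
                       pe = c(130, 60, 50), ga = c(40, 32, 30)),
      cs = 990),
    ionia = list(
      color = part_rgb(he = c(52, 41, 37), meso = c(55, 42, 38),
                       pe = c(54, 42, 38), ga = c(50, 40, 36)),
      cs = 996),
    mimic = list(
      color = part_rgb(he = c(120, 60, 50), meso = c(85, 52, 45),
                       pe = c(80, 50, 45), ga = c(45, 35, 33)),
      cs = 1030)
  )
  b <- equidistant_projection(out$mimic$color,
                              lapply(out[model_taxa()], `[[`, "color"))
  out$mimic$color <- stats::setNames(b, sqrt_channel_names())
  out
}

#' Configuration for the hierarchical specimen generator
#'
#' The generator emulates the study design: 18 sites each hosting one model
#' species and its syntopic mimic population, with Gaussian site, nest and
#' individual variance layers on the sqrt-channel scale (and micrometer scale
#' for size). The mimic's color archetype at a site is a convex blend of the
#' mimic baseline toward the syntopic model's archetype, controlled by the
#' mimicry accuracy `lambda` (and `lambda_size` for cephalic size); syntopic
#' convergence in generated data comes only from these blends, because model
#' and mimic receive independent site effects.
#'
#' @param seed RNG seed (mandatory; the whole table is reproducible from it).
#' @param lambda color mimicry accuracy in \[0, 1\].
#' @param lambda_size size mimicry accuracy in \[0, 1\].
#' @param sigma_site,sigma_nest,sigma_ind Gaussian SDs of the site, nest and
#'   individual layers, sqrt-channel scale.
#' @param sigma_site_cs,sigma_nest_cs,sigma_ind_cs size analogues,
#'   micrometers.
#' @param nests_model,nests_mimic nests per site per genus.
#' @param workers_model,workers_mimic specimens per nest.
#' @param registry site registry (site -> model taxon).
#' @param archetypes archetype list as from [default_archetypes()].
#' @return validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed,
                             lambda = 0.9, lambda_size = 0.5,
                             sigma_site = 0.3, sigma_nest = 0.3,
                             sigma_ind = 0.5,
                             sigma_site_cs = 30, sigma_nest_cs = 25,
                             sigma_ind_cs = 45,
                             nests_model = 4, nests_mimic = 5,
                             workers_model = 8, workers_mimic = 10,
                             registry = default_site_registry(),
                             archetypes = default_archetypes()) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  cfg <- list(seed = as.integer(seed), lambda = lambda,
              lambda_size = lambda_size,
              sigma_site = sigma_site, sigma_nest = sigma_nest,
              sigma_ind = sigma_ind,
              sigma_site_cs = sigma_site_cs, sigma_nest_cs = sigma_nest_cs,
              sigma_ind_cs = sigma_ind_cs,
              nests_model = nests_model, nests_mimic = nests_mimic,
              workers_model = workers_model, workers_mimic = workers_mimic,
              registry = registry, archetypes = archetypes)
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
}

#' @noRd
validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (lambda < 0 || lambda > 1 || lambda_size < 0 || lambda_size > 1)
      stop("lambda and lambda_size must lie in [0, 1]")
    if (any(c(sigma_site, sigma_nest, sigma_ind,
              sigma_site_cs, sigma_nest_cs, sigma_ind_cs) < 0))
      stop("variance-layer SDs must be non-negative")
    if (nests_model < 1 || nests_mimic < 1 ||
        workers_model < 1 || workers_mimic < 1)
      stop("at least one nest and one specimen per nest are required")
  })
  validate_registry(cfg$registry)
  for (a in cfg$archetypes)
    if (any(a$color < 0) || any(a$color > sqrt(255)))
      stop("archetype sqrt-channels must lie in [0, sqrt(255)]")
  cfg
}

#' Read a flat key=value generator configuration file
#'
#' Lines of the form `key = value`; unknown keys error; `seed` is mandatory.
#' Only scalar parameters can be set this way (registry and archetypes keep
#' their defaults).
#'
#' @param path config file path.
#' @return a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  ln <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(ln, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[[`, "", 2L)))
  known <- setdiff(names(formals(synthetic_config)),
                   c("registry", "archetypes"))
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(synthetic_config, as.list(stats::setNames(vals, keys)))
}

#' Generate a synthetic specimen table
#'
#' Each sqrt-scale trait value is archetype + site effect + nest effect +
#' individual effect, all Gaussian; sqrt values are clamped to
#' \[0, sqrt(255)\] and squared to give stored RGB intensities. Cephalic size
#' is generated analogously on the micrometer scale, then split into CL and CW
#' with a symmetric within-head deviation so that CS = (CL + CW)/2 equals the
#' generated size exactly. RGB is rounded to 2 decimals and CL/CW to 1, the
#' precision at which tables round-trip through CSV.
#'
#' @param config a `synthetic_config`.
#' @return list with `specimens` (schema data.frame, `taxon` derived) and
#'   `truth`: the latent archetypes per site, site/nest effects and the config
#'   echo, for parameter-recovery tests.
#' @export
generate_dataset <- function(config) {
  cfg <- validate_synthetic_config(config)
  set.seed(cfg$seed)
  arch <- cfg$archetypes
  reg <- cfg$registry
  nch <- length(sqrt_channel_names())
  rows <- list()
  truth_sites <- list()
  for (i in seq_len(nrow(reg))) {
    sid <- reg$site_id[i]
    mt <- reg$model_taxon[i]
    mimic_color <- (1 - cfg$lambda) * arch$mimic$color +
      cfg$lambda * arch[[mt]]$color
    mimic_cs <- (1 - cfg$lambda_size) * arch$mimic$cs +
      cfg$lambda_size * arch[[mt]]$cs
    for (g in c("model", "mimic")) {
      base_color <- if (g == "model") arch[[mt]]$color else mimic_color
      base_cs <- if (g == "model") arch[[mt]]$cs else mimic_cs
      n_nests <- if (g == "model") cfg$nests_model else cfg$nests_mimic
      n_w <- if (g == "model") cfg$workers_model else cfg$workers_mimic
      site_eff <- stats::rnorm(nch, 0, cfg$sigma_site)
      site_eff_cs <- stats::rnorm(1, 0, cfg$sigma_site_cs)
      nest_rows <- list()
      nest_eff_mat <- matrix(NA_real_, n_nests, nch)
      nest_eff_cs <- numeric(n_nests)
      for (k in seq_len(n_nests)) {
        nest_eff <- stats::rnorm(nch, 0, cfg$sigma_nest)
        ne_cs <- stats::rnorm(1, 0, cfg$sigma_nest_cs)
        nest_eff_mat[k, ] <- nest_eff
        nest_eff_cs[k] <- ne_cs
        ind <- matrix(stats::rnorm(n_w * nch, 0, cfg$sigma_ind), n_w, nch)
        sq <- sweep(ind, 2, base_color + site_eff + nest_eff, `+`)
        sq <- pmin(pmax(sq, 0), sqrt(255))
        rgb <- round(sq^2, 2)
        colnames(rgb) <- channel_names()
        cs <- base_cs + site_eff_cs + ne_cs +
          stats::rnorm(n_w, 0, cfg$sigma_ind_cs)
        half_diff <- stats::rnorm(n_w, 0, 15)
        cl <- round(cs + half_diff, 1)
        cw <- round(cs - half_diff, 1)
        nest_rows[[k]] <- data.frame(
          site_id = sid, group = g,
          nest_id = sprintf("%s%02d_%s%d", substr(g, 1, 2), sid, "n", k),
          specimen_id = sprintf("s%d_%s_n%d_w%02d", sid, g, k, seq_len(n_w)),
          rgb, CL = cl, CW = cw, stringsAsFactors = FALSE)
      }
      truth_sites[[paste(sid, g, sep = ".")]] <- list(
        site_id = sid, group = g, taxon = mt,
        archetype_color = as.vector(base_color), archetype_cs = base_cs,
        site_effect = site_eff, site_effect_cs = site_eff_cs,
        nest_effects = nest_eff_mat, nest_effects_cs = nest_eff_cs)
      rows[[paste(sid, g)]] <- do.call(rbind, nest_rows)
    }
  }
  specimens <- do.call(rbind, rows)
  rownames(specimens) <- NULL
  specimens <- assign_taxon(specimens, reg)
  validate_specimens(specimens, reg)
  list(specimens = specimens,
       truth = list(config = cfg[setdiff(names(cfg),
                                         c("registry", "archetypes"))],
                    archetypes = arch, sites = truth_sites))
}

#' Write the generator's latent truth as JSON
#'
#' @param truth the `truth` element returned by [generate_dataset()].
#' @param path output path.
#' @export
write_latent_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
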