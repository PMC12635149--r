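#' Body parts and channel naming
#'
#' Measurements cover six body parts, each with mean R, G and B channel
#' intensities: head (`he`), pronotum (`pr`), mesonotum (`me`), propodeum
#' (`pp`), petiole (`pe`) and gaster (`ga`).
#'
#' @return `body_parts()` returns the six part codes; `channel_names()` the 18
#'   raw channel column names (`R_he`, `G_he`, ..., `B_ga`);
#'   `sqrt_channel_names()` the corresponding square-root-scale names
#'   (`sqrtR_he`, ...).
#' @export
body_parts <- function() c("he", "pr", "me", "pp", "pe", "ga")

#' @rdname body_parts
#' @export
channel_names <- function() {
  as.vector(t(outer(body_parts(), c("R", "G", "B"),
                    function(p, ch) paste(ch, p, sep = "_"))))
}

#' @rdname body_parts
#' @export
sqrt_channel_names <- function() paste0("sqrt", channel_names())

#' Model taxa recognized by the pipeline
#'
#' The three model species, in their fixed class order. The order is also the
#' tie-break order for discriminant classification.
#'
#' @return character vector of taxon codes.
#' @export
model_taxa <- function() c("scutellaris", "schmidti", "ionia")

#' Site registry: which model species occurs at each site
#'
#' A site registry maps every collection site to the single model species
#' occurring there; the mimic category at a site is derived from it
#' (e.g. site 6 -> "scutellaris-syntopic"). `default_site_registry()` returns
#' the 18-site study design: sites 1-3 and 5-8 carry *Crematogaster
#' scutellaris*, 4 and 9-13 *Cr. schmidti*, and 14-18 *Cr. ionia* s.l.
#'
#' @return data.frame with columns `site_id` (integer) and `model_taxon`
#'   (one of [model_taxa()]), optionally `lat`/`lon`.
#' @export
default_site_registry <- function() {
  taxon <- character(18)
  taxon[c(1:3, 5:8)] <- "scutellaris"
  taxon[c(4, 9:13)] <- "schmidti"
  taxon[14:18] <- "ionia"
  data.frame(site_id = 1:18, model_taxon = taxon, stringsAsFactors = FALSE)
}

#' Read a site registry CSV
#'
#' @param path CSV with columns `site_id`, `model_taxon` and optional
#'   `lat`, `lon`.
#' @return validated registry data.frame.
#' @export
read_registry <- function(path) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_registry(reg)
  reg
}

#' @noRd
validate_registry <- function(registry) {
  if (!all(c("site_id", "model_taxon") %in% names(registry)))
    stop("registry must have columns 'site_id' and 'model_taxon'")
  if (anyDuplicated(registry$site_id))
    stop("registry: duplicated site_id; exactly one model taxon per site")
  bad <- setdiff(unique(registry$model_taxon), model_taxa())
  if (length(bad))
    stop("registry: unknown model taxon: ", paste(bad, collapse = ", "))
  invisible(registry)
}

#' Mimic category label for a site
#'
#' Pure function of the registry: the mimic category at a site is named after
#' the syntopic model species ("scutellaris-syntopic", ...).
#'
#' @param site_id integer site identifiers.
#' @param registry a site registry.
#' @return character vector of category labels.
#' @export
mimic_category <- function(site_id, registry) {
  idx <- match(site_id, registry$site_id)
  if (anyNA(idx))
    stop("unknown site_id not in registry: ",
         paste(unique(site_id[is.na(idx)]), collapse = ", "))
  paste0(registry$model_taxon[idx], "-syntopic")
}

specimen_columns <- function() {
  c("site_id", "group", "nest_id", "specimen_id", channel_names(), "CL", "CW")
}

#' Validate a specimen table
#'
#' Checks the schema invariants: all 18 channel values in \[0, 255\], `CL` and
#' `CW` strictly positive, no missing values, `group` in {model, mimic}, and
#' (site_id, nest_id, specimen_id) unique. Errors name the offending row and
#' column.
#'
#' @param df specimen data.frame (raw-RGB scale).
#' @param registry site registry used to check `site_id` membership.
#' @return the input, invisibly, if valid.
#' @export
validate_specimens <- function(df, registry = default_site_registry()) {
  need <- specimen_columns()
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("specimen table missing column(s): ", paste(miss, collapse = ", "))
  for (col in need) {
    if (anyNA(df[[col]]) || any(df[[col]] == "", na.rm = TRUE))
      stop("missing value in column '", col, "' at row ",
           which(is.na(df[[col]]) | df[[col]] == "")[1])
  }
  if (!all(df$group %in% c("model", "mimic")))
    stop("column 'group' must be 'model' or 'mimic' (row ",
         which(!df$group %in% c("model", "mimic"))[1], ")")
  unknown <- setdiff(unique(df$site_id), registry$site_id)
  if (length(unknown))
    stop("site_id not in registry: ", paste(unknown, collapse = ", "))
  for (col in channel_names()) {
    v <- df[[col]]
    if (!is.numeric(v))
      stop("column '", col, "' must be numeric")
    bad <- which(v < 0 | v > 255)
    if (length(bad))
      stop("channel value out of [0,255]: row ", bad[1], ", column '", col,
           "' (value ", v[bad[1]], ")")
  }
  for (col in c("CL", "CW")) {
    bad <- which(!is.numeric(df[[col]]) | df[[col]] <= 0)
    if (length(bad))
      stop("non-positive ", col, " at row ", bad[1])
  }
  key <- paste(df$site_id, df$nest_id, df$specimen_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (site_id, nest_id, specimen_id) at row ",
         which(duplicated(key))[1])
  invisible(df)
}

#' Read a specimen CSV
#'
#' Reads the specimen table (one row per worker: site, group, nest, specimen,
#' 18 RGB channel means, cephalic length and width in micrometers), validates
#' it, and derives the `taxon` column from the registry: model rows get the
#' site's model species, mimic rows their syntopy category. Taxon is never
#' stored in the file, preventing label/registry drift.
#'
#' @param path CSV path.
#' @param registry site registry.
#' @return validated data.frame with derived `taxon` column.
#' @export
read_specimens <- function(path, registry = default_site_registry()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(nest_id = "character",
                                       specimen_id = "character"))
  validate_specimens(df, registry)
  assign_taxon(df, registry)
}

#' @noRd
assign_taxon <- function(df, registry) {
  idx <- match(df$site_id, registry$site_id)
  df$taxon <- ifelse(df$group == "model",
                     registry$model_taxon[idx],
                     paste0(registry$model_taxon[idx], "-syntopic"))
  df
}

#' Write a specimen CSV
#'
#' Writes the schema columns only (derived `taxon` is dropped). Values
#' round-trip exactly through [read_specimens()].
#'
#' @param df specimen data.frame.
#' @param path output CSV path.
#' @export
write_specimens <- function(df, path) {
  utils::write.csv(df[, specimen_columns()], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Cephalic size
#'
#' The standard ant body-size proxy: the arithmetic mean of cephalic length
#' and cephalic width.
#'
#' @param CL cephalic length, micrometers, > 0.
#' @param CW cephalic width, micrometers, > 0.
#' @return `(CL + CW) / 2`, micrometers.
#' @export
cephalic_size <- function(CL, CW) {
  if (any(CL <= 0) || any(CW <= 0))
    stop("CL and CW must be strictly positive")
  (CL + CW) / 2
}

#' Per-nest trait means
#'
#' Aggregates specimens to one row per (site, group, nest). Channel means are
#' taken on the square-root scale (the analysis scale); cephalic size is
#' averaged on the raw micrometer scale.
#'
#' @param records specimen data.frame (raw RGB); `taxon` column optional.
#' @param channels_are_sqrt set `TRUE` if the channel columns already hold
#'   sqrt-scale values (then they are averaged as-is).
#' @return data.frame with columns `site_id`, `group`, `taxon` (if present),
#'   `nest_id`, the 18 `sqrt*` channel means, `CS` and `n_specimens`.
#' @export
nest_means <- function(records, channels_are_sqrt = FALSE) {
  out_cols <- c("site_id", "group", intersect("taxon", names(records)),
                "nest_id")
  if (nrow(records) == 0) {
    empty <- records[0, out_cols, drop = FALSE]
    for (nm in sqrt_channel_names()) empty[[nm]] <- numeric(0)
    empty$CS <- numeric(0)
    empty$n_specimens <- integer(0)
    return(empty)
  }
  ch <- as.matrix(records[, channel_names()])
  if (!channels_are_sqrt) ch <- sqrt_transform(ch)
  cs <- cephalic_size(records$CL, records$CW)
  key <- interaction(records$site_id, records$group, records$nest_id,
                     drop = TRUE, lex.order = TRUE)
  first <- !duplicated(key)
  out <- records[first, out_cols, drop = FALSE]
  m <- rowsum(ch, key) / as.vector(table(key))
  ord <- match(key[first], rownames(m))
  m <- m[ord, , drop = FALSE]
  colnames(m) <- sqrt_channel_names()
  out <- cbind(out, as.data.frame(m))
  out$CS <- as.vector(rowsum(cs, key) / as.vector(table(key)))[ord]
  out$n_specimens <- as.vector(table(key))[ord]
  rownames(out) <- NULL
  out
}
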