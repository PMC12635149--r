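#' Square-root transform of channel intensities
#'
#' RGB channel means are right-skewed on the raw 0-255 scale; all analyses run
#' on the square-root scale.
#'
#' @param value numeric vector/matrix of channel intensities in \[0, 255\].
#' @return `sqrt(value)`, in \[0, sqrt(255)\].
#' @export
sqrt_transform <- function(value) {
  if (any(value < 0)) stop("channel intensity must be non-negative")
  sqrt(value)
}

#' Principal components of a covariance matrix
#'
#' Covariance-mode PCA (all channel variables share one physical scale):
#' eigendecomposition of the sample (n-1) covariance matrix of centered data.
#' Each component's sign is fixed so its mean loading is positive, making
#' scores reproducible (for color data, a larger PC1 score means a lighter /
#' redder surface).
#'
#' @param x numeric matrix, observations in rows.
#' @return object of class `pc_model`: list with `center`, `loadings`
#'   (columns = components, orthonormal), `eigenvalues` (non-increasing),
#'   `explained` (fractions summing to 1), `variables`.
#' @export
pca_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 observations")
  ctr <- colMeans(x)
  s <- stats::cov(x)
  e <- eigen(s, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  if (sum(ev) <= .Machine$double.eps * ncol(x))
    stop("zero total variance: principal directions undefined")
  load <- e$vectors
  for (j in seq_len(ncol(load))) {
    sgn <- sign(mean(load[, j]))
    if (sgn == 0) sgn <- sign(load[which(load[, j] != 0)[1], j])
    if (!is.na(sgn) && sgn < 0) load[, j] <- -load[, j]
  }
  vars <- colnames(x)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(x)))
  dimnames(load) <- list(vars, paste0("PC", seq_len(ncol(load))))
  structure(list(center = stats::setNames(ctr, vars), loadings = load,
                 eigenvalues = ev, explained = ev / sum(ev),
                 variables = vars),
            class = "pc_model")
}

#' Project observations onto principal components
#'
#' @param model a `pc_model`.
#' @param x matrix with the model's variables in columns.
#' @param k number of leading components (default all).
#' @return score matrix, n x k.
#' @export
pca_scores <- function(model, x, k = length(model$eigenvalues)) {
  x <- as.matrix(x)
  if (!is.null(colnames(x))) x <- x[, model$variables, drop = FALSE]
  sweep(x, 2, model$center) %*% model$loadings[, seq_len(k), drop = FALSE]
}

#' PC1 of one body part's three channels
#'
#' Reduces the three sqrt-scale channels of one body part to their first
#' principal component, the per-part lightness/redness axis.
#'
#' @param x numeric matrix, n >= 3 specimens x 3 sqrt-channels.
#' @return list with `scores` (length n), `explained` (PC1's share of total
#'   variance) and the fitted `model`.
#' @export
pc1_scores <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 specimens")
  if (anyNA(x)) stop("missing values not permitted")
  m <- pca_fit(x)
  list(scores = as.vector(pca_scores(m, x, k = 1)),
       explained = m$explained[1], model = m)
}

#' Reduce to components explaining a cumulative variance threshold
#'
#' Retains the smallest number k of leading components whose cumulative
#' explained-variance fraction reaches `threshold` (default 0.80, the
#' convention used for the nest-mean distance analysis).
#'
#' @param x numeric matrix, m observations x p variables.
#' @param threshold fraction in (0, 1].
#' @return list with `scores` (m x k), `k`, `explained` (per retained
#'   component) and `model`.
#' @export
reduce_cumulative <- function(x, threshold = 0.8) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  x <- as.matrix(x)
  m <- pca_fit(x)
  k <- which(cumsum(m$explained) >= threshold - 1e-12)[1]
  if (is.na(k)) k <- length(m$explained)
  list(scores = pca_scores(m, x, k = k), k = k,
       explained = m$explained[seq_len(k)], model = m)
}

#' Serialize / restore a PC model as plain text
#'
#' Writes variable names, centering means, eigenvalues and loadings in a
#' simple tab-separated text format.
#'
#' @param model a `pc_model`.
#' @param path output path.
#' @export
write_pc_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("variables\t", paste(model$variables, collapse = "\t")),
             con)
  writeLines(paste0("center\t",
                    paste(format(model$center, digits = 17), collapse = "\t")),
             con)
  writeLines(paste0("eigenvalues\t",
                    paste(format(model$eigenvalues, digits = 17),
                          collapse = "\t")), con)
  for (j in seq_len(ncol(model$loadings)))
    writeLines(paste0("loading.", j, "\t",
                      paste(format(model$loadings[, j], digits = 17),
                            collapse = "\t")), con)
  invisible(path)
}

#' @rdname write_pc_model
#' @export
read_pc_model <- function(path) {
  ln <- strsplit(readLines(path), "\t", fixed = TRUE)
  key <- vapply(ln, `[[`, "", 1L)
  vars <- ln[[which(key == "variables")]][-1]
  ctr <- as.numeric(ln[[which(key == "center")]][-1])
  ev <- as.numeric(ln[[which(key == "eigenvalues")]][-1])
  li <- grep("^loading\\.", key)
  load <- vapply(ln[li], function(v) as.numeric(v[-1]), numeric(length(vars)))
  dimnames(load) <- list(vars, paste0("PC", seq_along(li)))
  structure(list(center = stats::setNames(ctr, vars), loadings = load,
                 eigenvalues = ev, explained = ev / sum(ev),
                 variables = vars),
            class = "pc_model")
}
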