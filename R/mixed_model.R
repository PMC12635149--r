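#' Nested random-effects mixed model for one trait
#'
#' Fits the Gaussian linear mixed model
#' `y = mu + beta_group + u_site + v_nest(site) + e` by REML, with nests
#' nested within sites as random intercepts and group (species or mimic
#' category) as the fixed effect. The fixed part is parameterized as cell
#' means (no intercept), so the coefficients are the estimated group means.
#'
#' @param trait numeric per-specimen trait values (a PC1 score, CS, ...).
#' @param groups group label per specimen (>= 2 distinct).
#' @param sites site label per specimen.
#' @param nests nest label per specimen; each nest must belong to one site.
#' @return object of class `lmm_fit`: group means `beta` with covariance
#'   `vcov_beta`, variance components `varcomp` (site, nest, residual),
#'   `REMLcrit`, sizes, `converged` flag and the underlying `merMod`.
#' @export
fit_lmm <- function(trait, groups, sites, nests) {
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  d <- data.frame(y = trait, group = factor(groups),
                  site = factor(sites), nest = factor(nests))
  if (anyNA(d)) stop("missing values not permitted")
  site_per_nest <- tapply(as.character(d$site), d$nest,
                          function(s) length(unique(s)))
  if (any(site_per_nest > 1))
    stop("nest(s) span multiple sites: ",
         paste(names(site_per_nest)[site_per_nest > 1], collapse = ", "))
  nests_per_site <- tapply(as.character(d$nest), d$site,
                           function(n) length(unique(n)))
  if (max(nests_per_site) == 1)
    warning("only one nest per site: site and nest variance components ",
            "are not separately identifiable")
  fit <- lme4::lmer(y ~ 0 + group + (1 | site) + (1 | site:nest), data = d,
                    REML = TRUE,
                    control = lme4::lmerControl(
                      optimizer = "bobyqa",
                      check.conv.singular = "ignore"))
  msgs <- fit@optinfo$conv$lme4$messages
  failed <- !is.null(msgs) &&
    any(grepl("failed to converge", msgs, ignore.case = TRUE))
  if (failed) {
    # retry from a different optimizer before giving up
    fit2 <- stats::update(fit,
                          control = lme4::lmerControl(
                            optimizer = "Nelder_Mead",
                            check.conv.singular = "ignore"))
    msgs2 <- fit2@optinfo$conv$lme4$messages
    if (is.null(msgs2) ||
        !any(grepl("failed to converge", msgs2, ignore.case = TRUE))) {
      fit <- fit2
      failed <- FALSE
    } else {
      # near-flat REML surfaces trip the gradient check spuriously; accept
      # gradients just above lme4's tolerance, error otherwise
      grad <- max(abs(fit@optinfo$derivs$gradient))
      if (is.finite(grad) && grad < 0.01) {
        warning("convergence check marginal (max|grad| = ",
                signif(grad, 3), "); estimates retained")
        failed <- FALSE
      }
    }
  }
  if (failed)
    stop("mixed model failed to converge: ",
         paste(fit@optinfo$conv$lme4$messages, collapse = "; "))
  converged <- TRUE
  vc <- as.data.frame(lme4::VarCorr(fit))
  getvc <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else 0
  }
  beta <- lme4::fixef(fit)
  names(beta) <- sub("^group", "", names(beta))
  vb <- as.matrix(stats::vcov(fit))
  dimnames(vb) <- list(names(beta), names(beta))
  structure(list(beta = beta, vcov_beta = vb,
                 varcomp = c(site = getvc("site"),
                             nest = getvc("site:nest"),
                             residual = getvc("Residual")),
                 REMLcrit = lme4::REMLcrit(fit),
                 n_obs = nrow(d),
                 n_sites = nlevels(d$site),
                 n_nests = length(unique(paste(d$site, d$nest))),
                 converged = converged,
                 boundary = lme4::isSingular(fit),
                 model = fit),
            class = "lmm_fit")
}

#' Holm step-down multiple-testing decisions
#'
#' Step-down Holm: order the p-values ascending and reject while
#' `p_(i) <= alpha / (m - i + 1)`; decisions are mapped back to input order.
#' Controls the family-wise error rate at the global `alpha`.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @param alpha global alpha level.
#' @return list with `reject` (logical, input order) and `adjusted`
#'   (Holm-adjusted p-values).
#' @export
holm_correct <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0)
    return(list(reject = logical(0), adjusted = numeric(0)))
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "holm")
  list(reject = adj <= alpha, adjusted = adj)
}

#' Holm-corrected pairwise group contrasts
#'
#' Wald tests of fixed-effect differences using the REML covariance of the
#' group-mean estimates (z reference distribution, two-sided), with the
#' family corrected by the Holm step-down method at the global alpha.
#'
#' @param fit an `lmm_fit`.
#' @param pairs 2-column character matrix of group pairs; default all pairs.
#' @param alpha global alpha for the Holm decisions.
#' @return data.frame: `group1`, `group2`, `estimate`, `se`, `statistic`,
#'   `p_value`, `p_holm`, `significant`.
#' @export
pairwise_contrasts <- function(fit, pairs = NULL, alpha = 0.05) {
  gs <- names(fit$beta)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(gs, 2))
  } else {
    pairs <- matrix(as.character(pairs), ncol = 2)
    bad <- setdiff(unique(as.vector(pairs)), gs)
    if (length(bad))
      stop("group(s) not in fitted model: ", paste(bad, collapse = ", "))
  }
  est <- fit$beta[pairs[, 1]] - fit$beta[pairs[, 2]]
  se <- sqrt(fit$vcov_beta[cbind(pairs[, 1], pairs[, 1])] +
             fit$vcov_beta[cbind(pairs[, 2], pairs[, 2])] -
             2 * fit$vcov_beta[cbind(pairs[, 1], pairs[, 2])])
  z <- ifelse(se > 0, est / se, 0)
  p <- ifelse(se > 0, 2 * stats::pnorm(-abs(z)), 1)
  hc <- holm_correct(p, alpha)
  data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
             estimate = unname(est), se = unname(se),
             statistic = unname(z), p_value = unname(p),
             p_holm = hc$adjusted, significant = hc$reject,
             stringsAsFactors = FALSE)
}

#' Compact letter display from pairwise significance decisions
#'
#' Insert-and-absorb algorithm: groups sharing a letter are not significantly
#' different. Used for the boxplot annotations of trait comparisons.
#'
#' @param contrasts data.frame from [pairwise_contrasts()].
#' @param groups group names in display order (default: order encountered).
#' @return named character vector of letter strings per group.
#' @export
contrast_letters <- function(contrasts, groups = NULL) {
  if (is.null(groups))
    groups <- unique(c(contrasts$group1, contrasts$group2))
  sets <- list(groups)  # start: one letter containing everyone
  for (i in seq_len(nrow(contrasts))) {
    if (!contrasts$significant[i]) next
    a <- contrasts$group1[i]; b <- contrasts$group2[i]
    new_sets <- list()
    for (s in sets) {
      if (all(c(a, b) %in% s)) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb subsets
    keep <- rep(TRUE, length(new_sets))
    for (j in seq_along(new_sets)) for (k in seq_along(new_sets)) {
      if (j != k && keep[j] && keep[k] &&
          all(new_sets[[j]] %in% new_sets[[k]])) keep[j] <- FALSE
    }
    sets <- new_sets[keep]
  }
  letters_out <- stats::setNames(rep("", length(groups)), groups)
  for (j in seq_along(sets))
    for (g in sets[[j]])
      letters_out[g] <- paste0(letters_out[g], letters[j])
  letters_out
}
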