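#' Wilks' lambda of a variable set
#'
#' Ratio of the within-group to the total generalized variance,
#' det(W)/det(T), computed from the within- and total sums-of-squares
#' cross-product matrices. Smaller values mean stronger group separation.
#'
#' @param X numeric matrix, observations x variables.
#' @param y group labels.
#' @return Wilks' lambda in \[0, 1\] (1 for an empty variable set).
#' @export
wilks_lambda <- function(X, y) {
  X <- as.matrix(X)
  if (ncol(X) == 0) return(1)
  y <- factor(y)
  Xc_tot <- sweep(X, 2, colMeans(X))
  T_ <- crossprod(Xc_tot)
  W <- matrix(0, ncol(X), ncol(X))
  for (g in levels(y)) {
    Xg <- X[y == g, , drop = FALSE]
    W <- W + crossprod(sweep(Xg, 2, colMeans(Xg)))
  }
  dT <- det(T_)
  if (dT <= 0) stop("singular total SSCP: variables linearly dependent")
  det(W) / dT
}

#' @noRd
#' Partial F statistics of the stepwise procedure. With p variables entered
#' and Wilks' lambda `lambda_p`, the F-to-enter of a candidate giving
#' `lambda_p1` is ((n - g - p) / (g - 1)) * (lambda_p / lambda_p1 - 1);
#' F-to-remove of an entered variable uses the same form one step down.
partial_F <- function(lambda_small, lambda_large, n, g, p_after) {
  ((n - g - p_after + 1) / (g - 1)) * (lambda_small / lambda_large - 1)
}

#' Stepwise variable selection by Wilks' lambda minimization
#'
#' Iterative forward/backward stepping: at each step the candidate with the
#' largest F-to-enter joins the set if F >= `f_enter`; afterwards any entered
#' variable whose F-to-remove falls below `f_remove` leaves. The defaults
#' (3.84 / 2.71) are the conventional F thresholds of stepwise discriminant
#' analysis. Candidates whose entry would make the within-group SSCP
#' numerically singular are skipped with a warning.
#'
#' @param X numeric matrix (specimens x candidate variables, sqrt scale).
#' @param y class labels (>= 3 classes for the study design, >= 2 accepted).
#' @param f_enter,f_remove F thresholds for entry and removal.
#' @param tol reciprocal-condition tolerance below which a candidate set is
#'   treated as singular.
#' @return list with `selected` (variable names, entry order), `trace`
#'   (data.frame: step, action, variable, wilks, F).
#' @export
stepwise_select <- function(X, y, f_enter = 3.84, f_remove = 2.71,
                            tol = 1e-10) {
  X <- as.matrix(X)
  y <- factor(y)
  n <- nrow(X); g <- nlevels(y)
  if (g < 2) stop("need at least 2 classes")
  vars <- colnames(X)
  if (is.null(vars)) vars <- colnames(X) <- paste0("V", seq_len(ncol(X)))
  in_set <- character(0)
  lambda_cur <- 1
  trace <- list()
  step <- 0
  usable <- function(set) {
    # guard against singular within-group SSCP on the candidate set
    Xs <- X[, set, drop = FALSE]
    W <- matrix(0, length(set), length(set))
    for (cl in levels(y)) {
      Xg <- Xs[y == cl, , drop = FALSE]
      W <- W + crossprod(sweep(Xg, 2, colMeans(Xg)))
    }
    rcond(W) > tol
  }
  repeat {
    changed <- FALSE
    # entry
    out_set <- setdiff(vars, in_set)
    if (length(out_set) && n - g - length(in_set) > 0) {
      cand <- lapply(out_set, function(v) {
        set <- c(in_set, v)
        if (!usable(set)) {
          warning("skipping '", v, "': singular within-group covariance")
          return(NULL)
        }
        lam <- wilks_lambda(X[, set, drop = FALSE], y)
        list(v = v, lambda = lam,
             F = partial_F(lambda_cur, lam, n, g, length(set)))
      })
      cand <- Filter(Negate(is.null), cand)
      if (length(cand)) {
        Fs <- vapply(cand, `[[`, 0, "F")
        best <- cand[[which.max(Fs)]]
        if (best$F >= f_enter) {
          in_set <- c(in_set, best$v)
          lambda_cur <- best$lambda
          step <- step + 1
          trace[[length(trace) + 1]] <- data.frame(
            step = step, action = "enter", variable = best$v,
            wilks = best$lambda, F = best$F, stringsAsFactors = FALSE)
          changed <- TRUE
        }
      }
    }
    # removal (repeat until stable)
    repeat {
      if (length(in_set) < 2) break
      rem <- lapply(in_set, function(v) {
        set <- setdiff(in_set, v)
        lam <- wilks_lambda(X[, set, drop = FALSE], y)
        list(v = v, lambda = lam,
             F = partial_F(lam, lambda_cur, n, g, length(in_set)))
      })
      Fs <- vapply(rem, `[[`, 0, "F")
      worst <- rem[[which.min(Fs)]]
      if (worst$F < f_remove) {
        in_set <- setdiff(in_set, worst$v)
        lambda_cur <- worst$lambda
        step <- step + 1
        trace[[length(trace) + 1]] <- data.frame(
          step = step, action = "remove", variable = worst$v,
          wilks = worst$lambda, F = worst$F, stringsAsFactors = FALSE)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  list(selected = in_set,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(step = integer(0), action = character(0),
                    variable = character(0), wilks = numeric(0),
                    F = numeric(0)))
}

#' Linear discriminant classification model
#'
#' Gaussian equal-covariance Bayes classifier in classification-function
#' form: per class k, score_k(x) = x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 +
#' log(prior_k), with S the pooled within-class covariance (divisor n - g).
#' Classification is argmax of the class scores; ties break by class order.
#'
#' @param X numeric matrix on the selected variables.
#' @param y class labels; factor level order fixes the tie-break order.
#' @param prior class prior probabilities (default equal; must sum to 1).
#' @return object of class `discriminant_model`: `variables`, `classes`,
#'   `means`, `pooled_cov`, `coef` (classification-function coefficients),
#'   `const`, `prior`, `n_per_class`.
#' @export
fit_lda <- function(X, y, prior = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  g <- nlevels(y)
  if (g < 2) stop("need at least 2 classes")
  if (is.null(prior)) prior <- rep(1 / g, g)
  if (abs(sum(prior) - 1) > 1e-8) stop("priors must sum to 1")
  n <- nrow(X)
  M <- t(vapply(levels(y), function(cl) colMeans(X[y == cl, , drop = FALSE]),
                numeric(ncol(X))))
  W <- matrix(0, ncol(X), ncol(X))
  for (cl in levels(y)) {
    Xg <- X[y == cl, , drop = FALSE]
    W <- W + crossprod(sweep(Xg, 2, colMeans(Xg)))
  }
  S <- W / (n - g)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch))
    stop("singular pooled within-class covariance; reduce the variable set")
  Sinv_Mt <- backsolve(ch, forwardsolve(t(ch), t(M)))
  coef <- Sinv_Mt                      # p x g
  const <- -0.5 * colSums(t(M) * Sinv_Mt) + log(prior)
  vars <- colnames(X)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(X)))
  dimnames(coef) <- list(vars, levels(y))
  structure(list(variables = vars, classes = levels(y), means = M,
                 pooled_cov = S, coef = coef,
                 const = stats::setNames(const, levels(y)),
                 prior = stats::setNames(prior, levels(y)),
                 n_per_class = as.vector(table(y))),
            class = "discriminant_model")
}

#' Classify specimens with a discriminant model
#'
#' @param object a `discriminant_model`.
#' @param newdata matrix or data.frame containing the model's variables.
#' @param ... unused.
#' @return list with `class` (predicted labels, tie-break by class order) and
#'   `scores` (n x classes classification-function values).
#' @export
predict.discriminant_model <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$variables, drop = FALSE])
  sc <- X %*% object$coef
  sc <- sweep(sc, 2, object$const, `+`)
  cls <- object$classes[apply(sc, 1, which.max)]  # which.max: first = order
  list(class = cls, scores = sc)
}

#' Leave-one-out cross-validated confusion matrix
#'
#' For each specimen the class statistics (means and pooled covariance) are
#' re-estimated without it and the specimen is classified; the selected
#' variable set stays fixed throughout, matching the cross-validation
#' behavior of stepwise discriminant workflows. Percentages are
#' row-normalized.
#'
#' @param X numeric matrix on the selected variables.
#' @param y class labels.
#' @param prior class priors (default equal).
#' @return list with `confusion` (row-percent matrix, true x predicted),
#'   `counts`, `predicted` labels, `accuracy` per class (diagonal).
#' @export
loo_confusion <- function(X, y, prior = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  if (any(table(y) < 2)) stop("every class needs >= 2 members for LOO")
  pred <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    fit_i <- fit_lda(X[-i, , drop = FALSE], y[-i], prior = prior)
    pred[i] <- predict(fit_i, X[i, , drop = FALSE])$class
  }
  counts <- table(true = y, predicted = factor(pred, levels = levels(y)))
  conf <- 100 * prop.table(counts, 1)
  list(confusion = as.matrix(conf), counts = as.matrix(counts),
       predicted = pred,
       accuracy = stats::setNames(diag(as.matrix(conf)), levels(y)))
}

#' Wild-card allocation of mimic specimens
#'
#' Classifies mimic individuals against the calibration model (fitted on
#' model-species data only; wild cards never influence it) and tabulates the
#' percentage allocated to each model species per site and per mimic
#' category. "Correct" means allocation to the syntopic model species.
#'
#' @param model `discriminant_model` calibrated on model-species data.
#' @param X_mimic matrix of mimic specimens on the model's variables.
#' @param sites site_id per mimic specimen.
#' @param registry site registry.
#' @return object of class `allocation_table`: `per_site` data.frame (site,
#'   syntopic model, n, one percentage column per model class),
#'   `per_category` totals by mimic category, `correct` percentage per
#'   category, `predicted`.
#' @export
wildcard_allocate <- function(model, X_mimic, sites, registry) {
  idx <- match(sites, registry$site_id)
  if (anyNA(idx))
    stop("mimic site(s) absent from registry: ",
         paste(unique(sites[is.na(idx)]), collapse = ", "))
  pred <- predict(model, X_mimic)$class
  syntopic <- registry$model_taxon[idx]
  pct_rows <- function(split_by, syn_by) {
    lv <- sort(unique(split_by))
    do.call(rbind, lapply(lv, function(s) {
      sel <- split_by == s
      tab <- table(factor(pred[sel], levels = model$classes))
      row <- as.data.frame(t(100 * as.vector(tab) / sum(sel)))
      names(row) <- model$classes
      cbind(data.frame(key = s, syntopic_model = unique(syn_by[sel])[1],
                       n = sum(sel), stringsAsFactors = FALSE), row)
    }))
  }
  per_site <- pct_rows(sites, syntopic)
  names(per_site)[1] <- "site_id"
  per_cat <- pct_rows(paste0(syntopic, "-syntopic"), syntopic)
  names(per_cat)[1] <- "category"
  correct <- stats::setNames(
    vapply(seq_len(nrow(per_cat)), function(i) {
      sm <- per_cat$syntopic_model[i]
      if (sm %in% model$classes) per_cat[i, sm] else NA_real_
    }, 0),
    per_cat$category)
  structure(list(per_site = per_site, per_category = per_cat,
                 correct = correct, predicted = pred),
            class = "allocation_table")
}

#' Run the full discriminant stage on a specimen table
#'
#' Stepwise selection and calibration on the model-species specimens only
#' (sqrt-scale channels), leave-one-out confusion for the models, wild-card
#' allocation for the mimics.
#'
#' @param records validated specimen data.frame with `taxon` column.
#' @param registry site registry.
#' @param f_enter,f_remove stepwise F thresholds.
#' @param prior class priors (default equal).
#' @return list with `selection`, `model`, `loo`, `allocation`.
#' @export
discriminant_analysis <- function(records, registry = default_site_registry(),
                                  f_enter = 3.84, f_remove = 2.71,
                                  prior = NULL) {
  sq <- sqrt_transform(as.matrix(records[, channel_names()]))
  colnames(sq) <- sqrt_channel_names()
  is_model <- records$group == "model"
  y <- factor(records$taxon[is_model],
              levels = intersect(model_taxa(), records$taxon[is_model]))
  sel <- stepwise_select(sq[is_model, , drop = FALSE], y,
                         f_enter = f_enter, f_remove = f_remove)
  if (length(sel$selected) == 0)
    stop("stepwise selection retained no variables")
  Xs <- sq[is_model, sel$selected, drop = FALSE]
  model <- fit_lda(Xs, y, prior = prior)
  loo <- loo_confusion(Xs, y, prior = prior)
  alloc <- wildcard_allocate(model,
                             sq[!is_model, sel$selected, drop = FALSE],
                             records$site_id[!is_model], registry)
  list(selection = sel, model = model, loo = loo, allocation = alloc)
}
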