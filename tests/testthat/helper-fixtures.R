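# Small in-code fixtures shared across test files.

# Minimal valid specimen data.frame; channel values default to 100.
make_specimens <- function(site_id, group, nest_id, specimen_id = NULL,
                           channels = NULL, CL = 1000, CW = 1000) {
  n <- length(site_id)
  if (is.null(specimen_id)) specimen_id <- paste0("sp", seq_len(n))
  df <- data.frame(site_id = site_id, group = group, nest_id = nest_id,
                   specimen_id = specimen_id, stringsAsFactors = FALSE)
  if (is.null(channels)) channels <- matrix(100, n, 18)
  channels <- as.matrix(channels)
  colnames(channels) <- channel_names()
  df <- cbind(df, as.data.frame(channels))
  df$CL <- rep(CL, length.out = n)
  df$CW <- rep(CW, length.out = n)
  df
}

# Registry with a site per model taxon (3 sites).
tiny_registry <- function() {
  data.frame(site_id = 1:3,
             model_taxon = c("scutellaris", "schmidti", "ionia"),
             stringsAsFactors = FALSE)
}

# Independent textbook Holm step-down (oracle).
holm_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) reject[ord[i]] <- TRUE else break
  }
  reject
}

# Brute-force Gaussian equal-covariance Bayes classifier (oracle).
bayes_oracle <- function(X_train, y_train, X_new, prior = NULL) {
  y_train <- factor(y_train)
  g <- nlevels(y_train)
  if (is.null(prior)) prior <- rep(1 / g, g)
  n <- nrow(X_train)
  W <- matrix(0, ncol(X_train), ncol(X_train))
  mus <- list()
  for (cl in levels(y_train)) {
    Xg <- X_train[y_train == cl, , drop = FALSE]
    mus[[cl]] <- colMeans(Xg)
    W <- W + crossprod(sweep(Xg, 2, colMeans(Xg)))
  }
  S <- W / (n - g)
  Sinv <- solve(S)
  ll <- sapply(seq_len(g), function(k) {
    mu <- mus[[k]]
    apply(X_new, 1, function(x)
      -0.5 * t(x - mu) %*% Sinv %*% (x - mu) + log(prior[k]))
  })
  levels(y_train)[apply(matrix(ll, nrow = nrow(X_new)), 1, which.max)]
}

# Restricted log-likelihood of the nested Gaussian mixed model (oracle).
reml_loglik <- function(y, X, Zs, Zn, vs, vn, ve) {
  V <- vs * tcrossprod(Zs) + vn * tcrossprod(Zn) + ve * diag(length(y))
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  b <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  -0.5 * (determinant(V)$modulus[1] + determinant(XtVX)$modulus[1] +
            as.numeric(t(r) %*% Vi %*% r))
}

# Well-separated 3-class training fixture for discriminant tests.
lda_fixture <- function(seed = 42, n_per = 30, p = 4, sep = 4) {
  set.seed(seed)
  centers <- matrix(rnorm(3 * p), 3, p) * sep
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(n_per * p), n_per, p), 2, centers[k, ], `+`)))
  colnames(X) <- paste0("V", 1:p)
  list(X = X, y = factor(rep(c("a", "b", "c"), each = n_per)),
       centers = centers)
}
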