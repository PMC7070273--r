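# Age-regression models and evaluation protocol.
#
# The protocol: a stratified split of the 200 samples into 125 training
# (25 per class) and 75 testing (15 per class), then PLSR (NIPALS), an
# extreme learning machine with 27 hidden nodes, and epsilon-SVR with an
# RBF kernel (LIBSVM via e1071) at c = 1024, g = 0.0313. Performance is
# reported as squared Pearson correlation (R^2) and mean squared error on
# both partitions.

#' Model hyperparameters
#'
#' Defaults follow the published regression protocol: ELM with n = 27
#' hidden nodes, LIBSVM with c = 1024 and g = 0.0313 (epsilon 0.1, the
#' LIBSVM convention, as no value is published). PLSR components default to
#' `min(10, rank)` chosen at fit time.
#'
#' @param plsr_components latent components for PLSR (`NULL` = min(10, rank)).
#' @param elm_hidden_nodes hidden-layer width of the ELM.
#' @param elm_activation `"sigmoid"`, `"tanh"` or `"relu"`.
#' @param svr_C,svr_gamma,svr_epsilon RBF-SVR cost, kernel width and tube
#'   half-width.
#' @return An object of class `model_params`.
#' @export
model_params <- function(plsr_components = NULL, elm_hidden_nodes = 27,
                         elm_activation = "sigmoid", svr_C = 1024,
                         svr_gamma = 0.0313, svr_epsilon = 0.1) {
  stopifnot(elm_hidden_nodes >= 1, svr_C > 0, svr_gamma > 0, svr_epsilon > 0)
  structure(
    list(plsr_components = plsr_components,
         elm_hidden_nodes = as.integer(elm_hidden_nodes),
         elm_activation = elm_activation,
         svr_C = svr_C, svr_gamma = svr_gamma, svr_epsilon = svr_epsilon),
    class = "model_params"
  )
}

#' Stratified train/test split
#'
#' Draws, per age class, `n_train` training and `n_test` testing samples
#' without replacement (seeded shuffle). The defaults reproduce the
#' 125-train / 75-test protocol on the 200-sample design.
#'
#' @param table a labelled [feature_table()].
#' @param n_train,n_test per-class counts (defaults 25 and 15).
#' @param seed integer RNG seed.
#' @return List with `train` and `test` [feature_table()]s (disjoint).
#' @export
stratified_split <- function(table, n_train = 25, n_test = 15, seed = 1) {
  if (is.null(table$age_years)) stopf("feature table has no age labels")
  classes <- sort(unique(table$age_years))
  with_seed(seed, {
    tr_idx <- integer(0)
    te_idx <- integer(0)
    for (cl in classes) {
      idx <- which(table$age_years == cl)
      if (length(idx) < n_train + n_test) {
        stopf("class %g has %d samples, need %d", cl, length(idx),
              n_train + n_test)
      }
      idx <- sample(idx)
      tr_idx <- c(tr_idx, idx[seq_len(n_train)])
      if (n_test > 0) {
        te_idx <- c(te_idx, idx[n_train + seq_len(n_test)])
      }
    }
    list(train = ft_subset(table, sort(tr_idx)),
         test = if (n_test > 0) ft_subset(table, sort(te_idx))
                else ft_subset(table, integer(0)))
  })
}

## ---- PLSR (NIPALS, univariate response) -----------------------------------

#' Partial least squares regression (NIPALS)
#'
#' PLS1 with NIPALS deflation: at each step the weight vector is the
#' covariance direction `X'y` (normalized), scores/loadings are extracted
#' and both X and y are deflated. Prediction is linear in X via the
#' regression vector `B = W (P'W)^{-1} q`. At full rank PLSR coincides with
#' ordinary least squares.
#'
#' @param x numeric matrix (n x p) or [feature_table()].
#' @param y numeric response (wine age in years).
#' @param n_components number of latent components (defaults to
#'   `min(10, rank(X))`).
#' @return An object of class `plsr_model`.
#' @export
plsr_fit <- function(x, y, n_components = NULL) {
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  if (stats::var(y) == 0) stopf("response has zero variance")
  mu_x <- colMeans(x)
  mu_y <- mean(y)
  xc <- sweep(x, 2, mu_x)
  yc <- y - mu_y
  rank_x <- qr(xc)$rank
  if (is.null(n_components)) n_components <- min(10, rank_x)
  if (n_components > rank_x) {
    stopf("n_components (%d) exceeds the rank of X (%d)", n_components, rank_x)
  }
  p <- ncol(x)
  w_mat <- matrix(0, p, n_components)
  p_mat <- matrix(0, p, n_components)
  q_vec <- numeric(n_components)
  h <- 0
  for (a in seq_len(n_components)) {
    w <- crossprod(xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break                 # y fully deflated
    w <- w / nw
    t_sc <- xc %*% w
    tt <- sum(t_sc^2)
    p_ld <- crossprod(xc, t_sc) / tt
    q_ld <- sum(yc * t_sc) / tt
    xc <- xc - t_sc %*% t(p_ld)
    yc <- yc - q_ld * t_sc
    h <- a
    w_mat[, a] <- w
    p_mat[, a] <- p_ld
    q_vec[a] <- q_ld
  }
  w_mat <- w_mat[, seq_len(h), drop = FALSE]
  p_mat <- p_mat[, seq_len(h), drop = FALSE]
  q_vec <- q_vec[seq_len(h)]
  b <- w_mat %*% solve(crossprod(p_mat, w_mat), q_vec)
  structure(
    list(coefficients = drop(b), x_mean = mu_x, y_mean = mu_y,
         n_components = h, weights = w_mat, loadings = p_mat,
         y_loadings = q_vec),
    class = "plsr_model"
  )
}

#' @rdname plsr_fit
#' @param model a fitted `plsr_model`.
#' @param newdata matrix or [feature_table()] with the training columns.
#' @export
plsr_predict <- function(model, newdata) {
  x <- as_feature_matrix(newdata)
  drop(sweep(x, 2, model$x_mean) %*% model$coefficients) + model$y_mean
}

## ---- Extreme learning machine ---------------------------------------------

elm_activations <- list(
  sigmoid = function(x) 1 / (1 + exp(-x)),
  tanh = tanh,
  relu = function(x) pmax(x, 0)
)

#' Extreme learning machine regression
#'
#' Single-hidden-layer network with fixed random input weights: weights and
#' biases are drawn from a seeded uniform(-1, 1), the hidden matrix is
#' `H = g(XW + b)`, and the output weights are the minimum-norm least
#' squares solution `pinv(H) y`.
#'
#' @param x numeric matrix (n x p) or [feature_table()].
#' @param y numeric response.
#' @param n_hidden hidden nodes (default 27).
#' @param activation `"sigmoid"`, `"tanh"` or `"relu"`.
#' @param seed integer RNG seed for the input weights.
#' @return An object of class `elm_model`.
#' @export
elm_fit <- function(x, y, n_hidden = 27, activation = "sigmoid", seed = 1) {
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  if (n_hidden < 1) stopf("n_hidden must be >= 1")
  act <- elm_activations[[activation]]
  if (is.null(act)) {
    stopf("unknown activation '%s'; use %s", activation,
          paste(names(elm_activations), collapse = ", "))
  }
  p <- ncol(x)
  with_seed(seed, {
    w <- matrix(stats::runif(p * n_hidden, -1, 1), p, n_hidden)
    b <- stats::runif(n_hidden, -1, 1)
    h <- act(x %*% w + rep(b, each = nrow(x)))
    beta <- drop(pinv(h) %*% y)
    structure(
      list(input_weights = w, biases = b, output_weights = beta,
           activation = activation, hidden = h),
      class = "elm_model"
    )
  })
}

#' @rdname elm_fit
#' @param model a fitted `elm_model`.
#' @param newdata matrix or [feature_table()].
#' @export
elm_predict <- function(model, newdata) {
  x <- as_feature_matrix(newdata)
  act <- elm_activations[[model$activation]]
  h <- act(x %*% model$input_weights + rep(model$biases, each = nrow(x)))
  drop(h %*% model$output_weights)
}

## ---- RBF support vector regression ----------------------------------------

#' Epsilon-SVR with RBF kernel
#'
#' Support vector regression with kernel `k(x, z) = exp(-gamma ||x - z||^2)`
#' solved by LIBSVM (package e1071). The default cost and kernel width are
#' the published protocol values (c = 1024, g = 0.0313).
#'
#' @param x numeric matrix or [feature_table()].
#' @param y numeric response.
#' @param C cost parameter.
#' @param gamma RBF kernel width.
#' @param epsilon tube half-width of the epsilon-insensitive loss.
#' @param tolerance termination tolerance of the dual optimizer.
#' @return An object of class `svr_model` carrying the support-vector
#'   expansion (`sv_index`, `dual_coefs`, `intercept`).
#' @export
svr_fit <- function(x, y, C = 1024, gamma = 0.0313, epsilon = 0.1,
                    tolerance = 0.001) {
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  if (C <= 0 || gamma <= 0) stopf("C and gamma must be positive")
  fit <- e1071::svm(x = x, y = y, type = "eps-regression", kernel = "radial",
                    cost = C, gamma = gamma, epsilon = epsilon,
                    tolerance = tolerance, scale = FALSE)
  structure(
    list(fit = fit, C = C, gamma = gamma, epsilon = epsilon,
         x_train = x, y_train = y,
         sv_index = fit$index, dual_coefs = drop(fit$coefs),
         intercept = -fit$rho),
    class = "svr_model"
  )
}

#' @rdname svr_fit
#' @param model a fitted `svr_model`.
#' @param newdata matrix or [feature_table()].
#' @export
svr_predict <- function(model, newdata) {
  x <- as_feature_matrix(newdata)
  unname(stats::predict(model$fit, x))
}

#' Dual objective value of a fitted SVR model
#'
#' Evaluates the epsilon-SVR dual objective
#' `-(1/2) b'Kb - epsilon sum(|b|) + y'b` at the fitted dual coefficients
#' `b = alpha - alpha*`; useful for cross-checking the optimizer against an
#' independent QP solver.
#'
#' @param model a fitted `svr_model`.
#' @return Numeric scalar.
#' @export
svr_dual_objective <- function(model) {
  n <- nrow(model$x_train)
  beta <- numeric(n)
  beta[model$sv_index] <- model$dual_coefs
  k <- rbf_kernel(model$x_train, model$x_train, model$gamma)
  -0.5 * drop(t(beta) %*% k %*% beta) - model$epsilon * sum(abs(beta)) +
    sum(model$y_train * beta)
}

rbf_kernel <- function(a, b, gamma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

## ---- Evaluation ------------------------------------------------------------

#' Evaluate predictions: squared correlation and mean squared error
#'
#' `r2` is the squared Pearson correlation between observed and predicted
#' values (the LIBSVM convention); `r2_determination` additionally reports
#' the coefficient of determination `1 - SS_res / SS_tot`. A constant
#' prediction vector has undefined correlation and is reported as `r2 = 0`
#' with a warning.
#'
#' @param y_true,y_hat numeric vectors of equal length >= 2.
#' @return List with `r2`, `mse`, `r2_determination`.
#' @export
evaluate_predictions <- function(y_true, y_hat) {
  if (length(y_true) != length(y_hat)) stopf("length mismatch")
  if (length(y_true) < 2) stopf("need at least 2 observations")
  mse <- mean((y_true - y_hat)^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  r2_det <- 1 - sum((y_true - y_hat)^2) / ss_tot
  if (stats::sd(y_hat) == 0 || stats::sd(y_true) == 0) {
    warning("constant predictions: squared correlation undefined, reported as 0",
            call. = FALSE)
    r2 <- 0
  } else {
    r2 <- stats::cor(y_true, y_hat)^2
  }
  list(r2 = r2, mse = mse, r2_determination = r2_det)
}

#' Fit and evaluate all three regression models on one split
#'
#' @param train,test labelled [feature_table()]s from [stratified_split()].
#' @param params a [model_params()].
#' @param elm_seed seed for the ELM's random input weights.
#' @return Data frame with columns `model`, `split`, `r2`, `mse`.
#' @export
evaluate_models <- function(train, test, params = model_params(),
                            elm_seed = 1) {
  y_tr <- train$age_years
  y_te <- test$age_years
  models <- list(
    plsr = {
      m <- plsr_fit(train, y_tr, n_components = params$plsr_components)
      list(train = plsr_predict(m, train), test = plsr_predict(m, test))
    },
    elm = {
      m <- elm_fit(train, y_tr, n_hidden = params$elm_hidden_nodes,
                   activation = params$elm_activation, seed = elm_seed)
      list(train = elm_predict(m, train), test = elm_predict(m, test))
    },
    svr = {
      m <- svr_fit(train, y_tr, C = params$svr_C, gamma = params$svr_gamma,
                   epsilon = params$svr_epsilon)
      list(train = svr_predict(m, train), test = svr_predict(m, test))
    }
  )
  rows <- list()
  for (nm in names(models)) {
    for (split in c("train", "test")) {
      y <- if (split == "train") y_tr else y_te
      ev <- evaluate_predictions(y, models[[nm]][[split]])
      rows[[length(rows) + 1L]] <- data.frame(
        model = nm, split = split, r2 = ev$r2, mse = ev$mse)
    }
  }
  do.call(rbind, rows)
}
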