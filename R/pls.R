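# PLS1 (single-response partial least squares) via NIPALS, used to regress
# time from baseline on the standardized item scores. Predictors are centered
# but not variance-scaled: items already share the 0-1 range, and the raw
# coefficients are what become the composite weights.

#' Fit a single-response PLS regression (PLS1, NIPALS)
#'
#' Regresses the response on the predictor columns through `A` latent
#' components. For each component the weight vector is proportional to the
#' covariance of the deflated predictors with the deflated response, so with
#' `A = 1` the item ordering equals the ordering of absolute covariance with
#' the response; with `A = p` (full rank) the coefficients equal ordinary least
#' squares.
#'
#' @param X Numeric matrix (n x p) of unit scores, complete (no NA). Column
#'   names identify items.
#' @param t Numeric response of length n (time from baseline, months).
#' @param A Number of latent components, `1 <= A <= p`; reduced with a warning
#'   when the predictors run out of rank.
#' @return An object of class `pls1_fit` with elements `W` (p x A weights, unit
#'   norm per column), `P` (p x A loadings), `q` (A response loadings),
#'   `score_ss` (A score sums of squares t'a t'a), `coefficients` (p, on the
#'   unit-score scale), `x_means`, `t_mean`, `constant_items`.
#' @export
fit_pls1 <- function(X, t, A = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(is.numeric(X), is.numeric(t), nrow(X) == length(t))
  if (anyNA(X) || anyNA(t)) stop("fit_pls1 requires complete data", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  A <- as.integer(A)
  if (A < 1L || n <= A) stop("need n > A >= 1", call. = FALSE)
  if (A > p) stop("A cannot exceed the number of predictors", call. = FALSE)
  x_means <- colMeans(X)
  t_mean <- mean(t)
  constant <- apply(X, 2L, function(col) max(col) - min(col) == 0)
  if (any(constant)) {
    warning("constant predictor column(s) carry zero weight: ",
            paste(colnames(X)[constant], collapse = ", "), call. = FALSE)
  }
  Xc <- sweep(X, 2L, x_means)
  tc <- t - t_mean
  W <- P <- matrix(0, p, A, dimnames = list(colnames(X), NULL))
  q <- score_ss <- numeric(A)
  a_used <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xc, tc)  # p x 1, covariance direction
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    s <- Xc %*% w           # scores
    ss <- sum(s^2)
    if (ss < 1e-12) break
    pa <- crossprod(Xc, s) / ss
    qa <- sum(tc * s) / ss
    Xc <- Xc - s %*% t(pa)
    tc <- tc - qa * s
    W[, a] <- w; P[, a] <- pa; q[a] <- qa; score_ss[a] <- ss
    a_used <- a
  }
  if (a_used < A) {
    warning("predictor rank exhausted: using ", a_used,
            " component(s) instead of ", A, call. = FALSE)
    if (a_used == 0L) stop("no usable PLS component (response uncorrelated ",
                           "with all predictors)", call. = FALSE)
    W <- W[, seq_len(a_used), drop = FALSE]
    P <- P[, seq_len(a_used), drop = FALSE]
    q <- q[seq_len(a_used)]
    score_ss <- score_ss[seq_len(a_used)]
    A <- a_used
  }
  beta <- drop(W %*% solve(crossprod(P, W), q))
  names(beta) <- colnames(X)
  structure(list(A = A, W = W, P = P, q = q, score_ss = score_ss,
                 coefficients = beta, x_means = x_means, t_mean = t_mean,
                 constant_items = colnames(X)[constant], n = n, p = p),
            class = "pls1_fit")
}

#' @export
print.pls1_fit <- function(x, ...) {
  cat(sprintf("<pls1_fit: %d component(s), %d predictors, n = %d>\n",
              x$A, x$p, x$n))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict the response from a PLS1 fit
#'
#' @param object A [fit_pls1()] result.
#' @param newdata Matrix or data frame with the fitted predictor columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.pls1_fit <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)
  if (!is.null(colnames(Xn))) {
    Xn <- Xn[, names(object$coefficients), drop = FALSE]
  }
  drop(sweep(Xn, 2L, object$x_means) %*% object$coefficients) + object$t_mean
}

#' Choose the number of PLS components by cross-validated PRESS
#'
#' Computes the cross-validated predicted residual sum of squares for
#' `A = 1..A_max` and returns the smallest `A` whose PRESS is within 5% of the
#' minimum (parsimony rule). Leave-one-out folds are used up to `n = 200`
#' rows; beyond that, 20 deterministic interleaved folds keep the search cheap
#' with no practical loss at such sample sizes.
#'
#' @param X,t As in [fit_pls1()].
#' @param A_max Largest number of components to consider (capped at `p` and
#'   `n - 2`).
#' @param folds `"loo"`, an integer fold count, or `NULL` for the size-based
#'   default.
#' @return Integer `A`, with the PRESS profile attached as attribute `press`.
#' @export
select_components <- function(X, t, A_max = 3L, folds = NULL) {
  X <- as.matrix(X); n <- nrow(X); p <- ncol(X)
  A_max <- min(as.integer(A_max), p, n - 2L)
  if (A_max < 1L) {
    warning("too few rows for cross-validation; using A = 1", call. = FALSE)
    return(structure(1L, press = NA_real_))
  }
  if (A_max == 1L) return(structure(1L, press = NA_real_))
  if (is.null(folds)) folds <- if (n <= 200L) "loo" else 20L
  idx <- if (identical(folds, "loo")) seq_len(n) else {
    (seq_len(n) - 1L) %% min(as.integer(folds), n) + 1L
  }
  press <- numeric(A_max)
  for (f in unique(idx)) {
    test <- idx == f
    fit_max <- tryCatch(
      suppressWarnings(fit_pls1(X[!test, , drop = FALSE], t[!test], A_max)),
      error = function(e) NULL)
    if (is.null(fit_max)) next
    # reuse the deflation sequence: coefficients for A <= A_max are nested
    for (a in seq_len(A_max)) {
      a_eff <- min(a, fit_max$A)
      Wa <- fit_max$W[, seq_len(a_eff), drop = FALSE]
      Pa <- fit_max$P[, seq_len(a_eff), drop = FALSE]
      qa <- fit_max$q[seq_len(a_eff)]
      beta <- drop(Wa %*% solve(crossprod(Pa, Wa), qa))
      pred <- drop(sweep(X[test, , drop = FALSE], 2L, fit_max$x_means) %*% beta) +
        fit_max$t_mean
      press[a] <- press[a] + sum((t[test] - pred)^2)
    }
  }
  best <- min(press)
  A <- which(press <= 1.05 * best)[1L]
  structure(as.integer(A), press = press)
}

#' Variable Importance in Projection (VIP) scores
#'
#' For predictor j,
#' \deqn{VIP_j = \sqrt{p \sum_a SS_a w_{aj}^2 / \sum_a SS_a},}
#' where `SS_a = q_a^2 t_a' t_a` is the response variance explained by
#' component a and the weight vectors have unit norm. The squared VIPs always
#' sum to p, so 1 is the "average importance" reference and the conventional
#' retention cutoffs (0.5 here) sit below it.
#'
#' @param fit A [fit_pls1()] result.
#' @return Named numeric vector of VIP scores (one per predictor).
#' @export
compute_vip <- function(fit) {
  stopifnot(inherits(fit, "pls1_fit"))
  ss <- fit$q^2 * fit$score_ss
  if (sum(ss) < 1e-300) {
    stop("VIP undefined: fit explains no response variance", call. = FALSE)
  }
  w2 <- fit$W^2  # columns already unit norm
  vip <- sqrt(fit$p * drop(w2 %*% ss) / sum(ss))
  names(vip) <- rownames(fit$W)
  vip
}
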