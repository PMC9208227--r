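# Internal helpers: reproducible RNG scoping, derived stage seeds, the beta
# fit used by the permutation machinery, and small linear-algebra utilities.

#' Evaluate an expression with a locally-set RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package internals do
#' not disturb user-level random streams.
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a per-stage seed from a master seed
#'
#' Deterministic mixing of the master seed with the stage name so pipeline
#' stages can be rerun in isolation with reproducible streams. Kept strictly
#' below 2^31 - 1.
#' @param seed master integer seed
#' @param stage character stage name
#' @return integer seed
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 131 + v) %% 1000003
  s0 <- (abs(seed) %% 65011 + 1) * 32749
  as.integer((s0 + h) %% 2147483629 + 1)
}

#' Package log messages (suppressible via suppressMessages)
#' @noRd
tq_log <- function(...) message("[tumorQTL] ", sprintf(...))

#' Center columns and scale to unit sum of squares
#' @noRd
col_unit <- function(X) {
  X <- as.matrix(X)
  Xc <- sweep(X, 2, colMeans(X))
  ss <- sqrt(colSums(Xc^2))
  if (any(ss == 0)) stop("zero-variance column encountered where variation is required")
  sweep(Xc, 2, ss, "/")
}

#' Convert squared correlation to a two-sided simple-regression p-value
#' @noRd
r2_to_p <- function(r2, n) {
  r2 <- pmin(r2, 1 - 1e-14)
  stats::pf(r2 * (n - 2) / (1 - r2), 1, n - 2, lower.tail = FALSE)
}

#' Maximum-likelihood fit of a Beta distribution
#'
#' Method-of-moments start, damped Newton refinement on the log-likelihood.
#' Falls back to the moment estimates with a warning when Newton fails.
#' @param x values in (0,1)
#' @return list(shape1, shape2, converged)
#' @noRd
beta_mle <- function(x) {
  x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  m <- mean(x)
  v <- stats::var(x)
  if (!is.finite(v) || v <= 0) {
    return(list(shape1 = 1, shape2 = 1, converged = FALSE))
  }
  c0 <- m * (1 - m) / v - 1
  if (c0 <= 0) c0 <- 1e-3
  s <- c(m * c0, (1 - m) * c0)
  mom <- s
  lx <- mean(log(x))
  ly <- mean(log1p(-x))
  converged <- FALSE
  for (i in seq_len(200)) {
    g <- c(digamma(sum(s)) - digamma(s[1]) + lx,
           digamma(sum(s)) - digamma(s[2]) + ly)
    H <- matrix(trigamma(sum(s)), 2, 2)
    diag(H) <- diag(H) - trigamma(s)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    s_new <- s - step
    damp <- 1
    while (any(s_new <= 0) && damp > 1e-4) {
      damp <- damp / 2
      s_new <- s - damp * step
    }
    if (any(s_new <= 0)) break
    if (max(abs(s_new - s) / pmax(1, abs(s))) < 1e-10) {
      s <- s_new
      converged <- TRUE
      break
    }
    s <- s_new
  }
  if (!converged) {
    warning("beta MLE did not converge; using method-of-moments estimates")
    s <- mom
  }
  list(shape1 = s[1], shape2 = s[2], converged = converged)
}

#' Adaptive permutation calibration with beta approximation
#'
#' Shared engine for the cis and interaction gene-level passes. Draws
#' permutation minima from `perm_fun`, stops early after `n_min` permutations
#' once at least `exceed_stop` permuted minima fall at or below the observed
#' minimum, fits a Beta distribution to the permuted minima, and reports both
#' the empirical and beta-approximated gene-level p-value.
#'
#' @param obs_p observed minimum nominal p across cis variants
#' @param perm_fun function(b) returning b permuted minimum p-values
#' @param n_min,n_max adaptive permutation bounds
#' @param exceed_stop early-stop exceedance count
#' @return list(empirical_p, beta_shape1, beta_shape2, adjusted_p, n_perm)
#' @noRd
perm_calibrate <- function(obs_p, perm_fun, n_min = 1000L, n_max = 10000L,
                           exceed_stop = 30L, block = 500L) {
  stopifnot(n_min <= n_max, n_min >= 10)
  perm_min <- numeric(0)
  target <- n_min
  repeat {
    while (length(perm_min) < target) {
      b <- min(block, target - length(perm_min))
      perm_min <- c(perm_min, perm_fun(b))
    }
    if (target >= n_max || sum(perm_min <= obs_p) >= exceed_stop) break
    target <- n_max
  }
  n_used <- length(perm_min)
  emp <- (1 + sum(perm_min <= obs_p)) / (1 + n_used)
  fit <- beta_mle(perm_min)
  adj <- stats::pbeta(obs_p, fit$shape1, fit$shape2)
  adj <- min(max(adj, .Machine$double.xmin), 1)
  list(empirical_p = emp, beta_shape1 = fit$shape1, beta_shape2 = fit$shape2,
       adjusted_p = adj, n_perm = n_used)
}

#' Coefficient t-tests for a least-squares fit
#'
#' @param X design matrix (with intercept), y response
#' @param cols columns to test (indices into X)
#' @return data.frame(estimate, se, t, p) for the requested columns
#' @noRd
lm_coef_tests <- function(X, y, cols) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("rank-deficient design in coefficient test")
  beta <- qr.coef(qr_x, y)
  res <- qr.resid(qr_x, y)
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tt <- beta / se
  p <- 2 * stats::pt(-abs(tt), df)
  data.frame(estimate = beta[cols], se = se[cols], t = tt[cols], p = p[cols],
             row.names = colnames(X)[cols])
}

#' Drop constant columns from a matrix, with a log note
#' @noRd
drop_constant_cols <- function(X, what = "design") {
  if (is.null(X) || ncol(X) == 0) return(X)
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    tq_log("dropping constant %s column(s): %s", what,
           paste(colnames(X)[!keep], collapse = ", "))
  }
  X[, keep, drop = FALSE]
}
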