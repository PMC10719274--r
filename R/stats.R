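#' Regress covariates out of a variable
#'
#' Ordinary-least-squares residuals of `values` on an intercept plus the
#' covariate columns. With `covariates = NULL` only the intercept is
#' removed (centering), which leaves ranks unchanged.
#'
#' @param values numeric vector.
#' @param covariates data.frame/matrix of numeric covariates (or NULL).
#' @return residual vector, orthogonal to the intercept and every covariate.
#' @export
residualize <- function(values, covariates = NULL) {
  if (any(is.na(values))) stop("values contain missing entries")
  n <- length(values)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    C <- as.matrix(covariates)
    if (nrow(C) != n) stop("covariate rows must match values length")
    if (any(is.na(C))) stop("covariates contain missing entries")
    if (!is.numeric(C)) stop("covariates must be numeric")
    X <- cbind(`(Intercept)` = 1, C)
  }
  if (n <= ncol(X)) stop("need more observations than covariates + intercept")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  as.numeric(qr.resid(qrX, values))
}

#' Covariate-adjusted Spearman rank correlation
#'
#' Residualizes both variables on the covariates (OLS, raw values), then
#' computes Spearman's rho between the residual ranks (average ranks for
#' ties). Two-sided p-value from the t approximation with n - 2 degrees of
#' freedom, or an exact-style permutation p on request.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame of covariates or NULL for plain Spearman.
#' @param method "t" (default) or "permutation".
#' @param n_perm permutation count when method = "permutation".
#' @param seed optional seed for the permutation stream.
#' @param names optional c(x_name, y_name) used in the result.
#' @return list of class `ddtopo_cor`: `variable_x`, `variable_y`, `rho`,
#'   `p_value`, `n`, `covariates`, `method`.
#' @export
spearman_partial <- function(x, y, covariates = NULL,
                             method = c("t", "permutation"),
                             n_perm = 10000, seed = NULL,
                             names = c("x", "y")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  # with no covariates rank the raw values: centering would perturb exact
  # ties by floating-point noise and silently break average-rank handling
  no_cov <- is.null(covariates) || NCOL(covariates) == 0
  rx <- if (no_cov) x else residualize(x, covariates)
  ry <- if (no_cov) y else residualize(y, covariates)
  tol_x <- 1e-10 * max(1, max(abs(x)))
  tol_y <- 1e-10 * max(1, max(abs(y)))
  if (stats::sd(rx) < tol_x || stats::sd(ry) < tol_y) {
    stop("degenerate after residualization: zero-variance residuals")
  }
  kx <- rank(rx)
  ky <- rank(ry)
  rho <- stats::cor(kx, ky)
  if (method == "t") {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
  } else {
    if (!is.null(seed)) set.seed(seed)
    perm <- vapply(seq_len(n_perm),
                   function(i) stats::cor(kx, sample(ky)), numeric(1))
    p <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
  }
  structure(list(variable_x = names[1], variable_y = names[2],
                 rho = rho, p_value = p, n = n,
                 covariates = if (is.null(covariates)) character(0)
                              else colnames(as.data.frame(covariates)),
                 method = method),
            class = "ddtopo_cor")
}

#' @export
print.ddtopo_cor <- function(x, ...) {
  cat(sprintf("Spearman (partial) %s ~ %s: rho = %.3f, p = %.4g, n = %d\n",
              x$variable_x, x$variable_y, x$rho, x$p_value, x$n))
  if (length(x$covariates)) {
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run the behavioral/topology association battery
#'
#' For every pair of a behavioral score and a topological measure, computes
#' the covariate-adjusted Spearman correlation. Global metrics are judged at
#' the nominal alpha (default 0.05); nodal metrics at the node-count
#' adjusted threshold 1 / n_nodes. The top decile of nodal associations by
#' |rho| is flagged for supplementary reporting.
#'
#' @param cohort data.frame with one row per included subject; must contain
#'   the behavioral, metric and covariate columns named below.
#' @param behavioral character vector of behavioral score columns
#'   (e.g. "log10_k", "bis_motor").
#' @param global_metrics character vector of global metric columns.
#' @param nodal_metrics character vector of nodal metric columns (optional).
#' @param covariates character vector of covariate columns.
#' @param n_nodes node count defining the nodal threshold 1 / n_nodes.
#' @param global_alpha nominal global threshold (default 0.05).
#' @return data.frame sorted by p-value: `x`, `y`, `family`, `rho`, `p`,
#'   `n`, `threshold`, `significant`, `top_decile`.
#' @export
run_association_battery <- function(cohort, behavioral,
                                    global_metrics,
                                    nodal_metrics = character(0),
                                    covariates = c("age", "sex",
                                                   "education_years"),
                                    n_nodes = 90,
                                    global_alpha = 0.05) {
  all_vars <- c(behavioral, global_metrics, nodal_metrics, covariates)
  missing_cols <- setdiff(all_vars, names(cohort))
  if (length(missing_cols) > 0) {
    stop("unknown variable(s) in battery: ",
         paste(missing_cols, collapse = ", "))
  }
  cov_df <- if (length(covariates)) cohort[, covariates, drop = FALSE]
            else NULL
  nodal_threshold <- 1 / n_nodes

  one <- function(xv, yv, fam) {
    thr <- if (fam == "global") global_alpha else nodal_threshold
    r <- tryCatch(
      spearman_partial(cohort[[xv]], cohort[[yv]], cov_df,
                       names = c(xv, yv)),
      error = function(e) {
        if (!grepl("degenerate", conditionMessage(e))) stop(e)
        list(rho = NA_real_, p_value = NA_real_, n = nrow(cohort))
      })
    data.frame(x = xv, y = yv, family = fam, rho = r$rho, p = r$p_value,
               n = r$n, threshold = thr,
               significant = !is.na(r$p_value) && r$p_value < thr,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (b in behavioral) {
    for (m in global_metrics) rows[[length(rows) + 1]] <- one(b, m, "global")
    for (m in nodal_metrics) rows[[length(rows) + 1]] <- one(b, m, "nodal")
  }
  out <- do.call(rbind, rows)
  out$top_decile <- FALSE
  nod <- out$family == "nodal" & !is.na(out$rho)
  if (any(nod)) {
    cut <- stats::quantile(abs(out$rho[nod]), 0.9, type = 7)
    out$top_decile[nod] <- abs(out$rho[nod]) >= cut
  }
  out[order(out$p, out$x, out$y), , drop = FALSE]
}
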