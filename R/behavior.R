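#' Hyperbolic subjective value
#'
#' Subjective value of a reward of a given amount delivered after a delay,
#' under the hyperbolic discounting model SV = A / (1 + k D), where k is the
#' per-day discount rate. Larger k means steeper devaluation of delayed
#' rewards.
#'
#' @param amount reward amount (currency units), > 0.
#' @param delay delay to receipt in days, >= 0.
#' @param k per-day discount rate, >= 0.
#' @return subjective value, same units as `amount`. Vectorized.
#' @examples
#' subjective_value(10000, 0, 0.0164)    # undiscounted
#' subjective_value(20000, 100, 0.01)    # kD = 1 halves the value
#' @export
subjective_value <- function(amount, delay, k) {
  if (any(amount <= 0)) stop("amount must be positive")
  if (any(delay < 0)) stop("delay must be nonnegative")
  if (any(k < 0)) stop("discount rate k must be nonnegative")
  amount / (1 + k * delay)
}

#' Probability of choosing the delayed option
#'
#' Softmax (logistic) choice rule on the subjective-value difference:
#' P(delayed) = logistic(beta * (SV_delayed - SV_immediate)). The immediate
#' option is undelayed, so its subjective value equals its face amount.
#'
#' @param immediate_amount amount of the immediate option.
#' @param delayed_amount amount of the delayed option.
#' @param delay_days delay of the delayed option, days.
#' @param k per-day discount rate.
#' @param beta choice sensitivity (inverse temperature), >= 0; beta = 0 gives
#'   indifference (P = 0.5) regardless of the values.
#' @return probability of choosing the delayed option, in (0, 1). Vectorized.
#' @export
choice_probability <- function(immediate_amount, delayed_amount, delay_days,
                               k, beta) {
  if (any(beta < 0)) stop("beta must be nonnegative")
  sv_del <- subjective_value(delayed_amount, delay_days, k)
  sv_imm <- subjective_value(immediate_amount, 0, k)
  stats::plogis(beta * (sv_del - sv_imm))
}

#' Flag degenerate (single-option) responders
#'
#' A subject who chose the same option on every trial carries no information
#' about the discount rate and is excluded from fitting, mirroring the
#' standard exclusion rule for extreme decision preferences.
#'
#' @param trials data.frame with at least a `choice` column (1 = delayed).
#' @return list with `excluded` (logical) and `reason`
#'   ("always-delayed", "always-immediate", or NA).
#' @export
detect_degenerate <- function(trials) {
  ch <- if (is.data.frame(trials)) trials$choice else trials
  if (length(ch) < 1) stop("empty choice dataset")
  if (!all(ch %in% c(0, 1))) stop("choice must be 0/1")
  if (all(ch == 1)) return(list(excluded = TRUE, reason = "always-delayed"))
  if (all(ch == 0)) return(list(excluded = TRUE, reason = "always-immediate"))
  list(excluded = FALSE, reason = NA_character_)
}

# internal: negative Bernoulli log-likelihood on (log10 k, log10 beta)
.dd_nll <- function(par, imm, del, delay, choice) {
  k <- 10^par[1]
  beta <- 10^par[2]
  dsv <- del / (1 + k * delay) - imm
  x <- beta * dsv
  -sum(ifelse(choice == 1,
              stats::plogis(x, log.p = TRUE),
              stats::plogis(-x, log.p = TRUE)))
}

#' Fit the hyperbolic discounting model to one subject's choices
#'
#' Maximum-likelihood fit of (k, beta) for the Bernoulli model in which each
#' choice of the delayed option has probability
#' logistic(beta * (SV_delayed - SV_immediate)) with SV = A / (1 + k D).
#' The likelihood is maximized over (log10 k, log10 beta) with box
#' constraints, using L-BFGS-B launched from the best-scoring points of a
#' log-spaced multi-start grid (the surface can be multimodal for extreme
#' preference patterns).
#'
#' @param trials data.frame with columns `immediate_amount`,
#'   `delayed_amount`, `delay_days`, `choice` (1 = delayed chosen).
#' @param k_bounds,beta_bounds box constraints on k (per day) and beta.
#' @param k_starts,beta_starts multi-start grids (original scale).
#' @param n_refine number of best grid starts refined with L-BFGS-B.
#' @return list with `k`, `log_k` (log10 of k), `beta`, `log_likelihood`
#'   (nats, <= 0), `converged`, `at_bound`, `excluded` (always FALSE here;
#'   degenerate data are refused), `reason`.
#' @seealso [detect_degenerate()] which must be applied first.
#' @export
fit_discounting <- function(trials,
                            k_bounds = c(1e-6, 10),
                            beta_bounds = c(1e-6, 1e3),
                            k_starts = 10^seq(-4, 0, length.out = 8),
                            beta_starts = 10^seq(-3.5, -0.5, length.out = 4),
                            n_refine = 6) {
  need <- c("immediate_amount", "delayed_amount", "delay_days", "choice")
  if (!all(need %in% names(trials))) {
    stop("trials must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(trials) < 10) stop("need at least 10 trials to fit")
  deg <- detect_degenerate(trials)
  if (deg$excluded) {
    stop("degenerate preference (", deg$reason, "): refuse to fit")
  }
  imm <- trials$immediate_amount
  del <- trials$delayed_amount
  delay <- trials$delay_days
  choice <- trials$choice

  lower <- log10(c(k_bounds[1], beta_bounds[1]))
  upper <- log10(c(k_bounds[2], beta_bounds[2]))
  grid <- expand.grid(lk = log10(k_starts), lb = log10(beta_starts))
  grid$nll <- vapply(seq_len(nrow(grid)), function(i) {
    .dd_nll(c(grid$lk[i], grid$lb[i]), imm, del, delay, choice)
  }, numeric(1))
  ord <- order(grid$nll)[seq_len(min(n_refine, nrow(grid)))]

  best <- NULL
  any_conv <- FALSE
  for (i in ord) {
    fit <- tryCatch(
      stats::optim(c(grid$lk[i], grid$lb[i]), .dd_nll,
                   imm = imm, del = del, delay = delay, choice = choice,
                   method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      any_conv <- fit$convergence == 0
    }
  }
  if (is.null(best)) {
    return(list(k = NA_real_, log_k = NA_real_, beta = NA_real_,
                log_likelihood = NA_real_, converged = FALSE,
                at_bound = FALSE, excluded = FALSE,
                reason = "optimizer-failure"))
  }
  k_hat <- 10^best$par[1]
  beta_hat <- 10^best$par[2]
  tol <- 1e-6
  at_bound <- (best$par[1] <= lower[1] + tol || best$par[1] >= upper[1] - tol ||
               best$par[2] <= lower[2] + tol || best$par[2] >= upper[2] - tol)
  list(k = k_hat, log_k = log10(k_hat), beta = beta_hat,
       log_likelihood = -best$value, converged = any_conv,
       at_bound = at_bound, excluded = FALSE, reason = NA_character_)
}

#' Fit discounting for a whole cohort of subjects
#'
#' Applies the exclusion rule and [fit_discounting()] per subject.
#'
#' @param choices long data.frame with columns `subject_id`,
#'   `immediate_amount`, `delayed_amount`, `delay_days`, `choice`.
#' @param ... passed to [fit_discounting()].
#' @return data.frame with one row per subject: `subject_id`, `k`,
#'   `log10_k`, `beta`, `log_lik`, `converged`, `excluded`, `reason`.
#' @export
fit_dd_cohort <- function(choices, ...) {
  ids <- unique(choices$subject_id)
  rows <- lapply(ids, function(id) {
    tr <- choices[choices$subject_id == id, , drop = FALSE]
    deg <- detect_degenerate(tr)
    if (deg$excluded) {
      return(data.frame(subject_id = id, k = NA_real_, log10_k = NA_real_,
                        beta = NA_real_, log_lik = NA_real_,
                        converged = FALSE, excluded = TRUE,
                        reason = deg$reason, stringsAsFactors = FALSE))
    }
    f <- fit_discounting(tr, ...)
    data.frame(subject_id = id, k = f$k, log10_k = f$log_k, beta = f$beta,
               log_lik = f$log_likelihood, converged = f$converged,
               excluded = FALSE, reason = NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' BIS-11 item-to-subscale scoring key
#'
#' The standard published 30-item key: three subscales (attentional, motor,
#' non-planning) partitioning the items, with 11 reverse-keyed items scored
#' as 5 - response before summation.
#'
#' @param path optional path to an alternative key CSV with columns
#'   `item`, `subscale`, `reverse`.
#' @return data.frame with columns `item` (1..30), `subscale`, `reverse`.
#' @export
bis11_key <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "bis11_key.csv", package = "ddtopo")
  }
  key <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("item", "subscale", "reverse") %in% names(key))) {
    stop("key must have columns item, subscale, reverse")
  }
  if (!setequal(key$item, 1:30)) stop("key must cover items 1..30 exactly once")
  if (!all(key$subscale %in% c("attentional", "motor", "non_planning"))) {
    stop("unknown subscale in key")
  }
  key$reverse <- as.logical(key$reverse)
  key
}

#' Score a BIS-11 questionnaire
#'
#' Reverses the reverse-keyed items (5 - response), then sums per subscale
#' and in total. Higher scores mean greater impulsivity; totals range 30-120.
#'
#' @param items integer vector of 30 raw responses in 1..4, in item order.
#' @param key scoring key as returned by [bis11_key()].
#' @return list with `items`, `attentional`, `motor`, `non_planning`, `total`.
#' @export
score_bis <- function(items, key = bis11_key()) {
  if (length(items) != 30) stop("expected exactly 30 items, got ", length(items))
  bad <- which(is.na(items) | !(items %in% 1:4))
  if (length(bad) > 0) {
    stop("BIS item ", bad[1], " is missing or out of range 1..4")
  }
  key <- key[order(key$item), , drop = FALSE]
  scored <- ifelse(key$reverse, 5L - as.integer(items), as.integer(items))
  sums <- tapply(scored, key$subscale, sum)
  out <- list(items = as.integer(items),
              attentional = unname(sums[["attentional"]]),
              motor = unname(sums[["motor"]]),
              non_planning = unname(sums[["non_planning"]]),
              total = sum(scored))
  stopifnot(out$total == out$attentional + out$motor + out$non_planning)
  out
}

#' Score BIS-11 for a cohort table
#'
#' @param bis data.frame with `subject_id` and columns `item01`..`item30`.
#' @param key scoring key as returned by [bis11_key()].
#' @return data.frame: `subject_id`, `bis_attentional`, `bis_motor`,
#'   `bis_nonplanning`, `bis_total`.
#' @export
score_bis_cohort <- function(bis, key = bis11_key()) {
  cols <- sprintf("item%02d", 1:30)
  if (!all(cols %in% names(bis))) {
    stop("BIS table missing column(s): ",
         paste(setdiff(cols, names(bis)), collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(bis)), function(i) {
    s <- score_bis(as.integer(bis[i, cols]), key = key)
    data.frame(subject_id = bis$subject_id[i],
               bis_attentional = s$attentional, bis_motor = s$motor,
               bis_nonplanning = s$non_planning, bis_total = s$total,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
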