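# Twin-structured linear mixed model for the longitudinal marker:
# y_ijk = beta0 + beta1 t + b_ij0 (+ b_ij1 t) + u_i + eps_ijk,
# with subject-level random effects b, a pair-shared intercept u and
# independent residuals. Fitting is delegated to lme4 (ML); the pair
# covariance, empirical-Bayes BLUPs and predictions are explicit linear
# algebra so they remain available for arbitrary parameter values and
# for the risk-set refits.

lmm_structures <- c("intercept_slope", "intercept", "pair_only")

subject_Z <- function(times, structure) {
  switch(structure,
         intercept_slope = cbind(1, times),
         intercept = matrix(1, length(times), 1),
         pair_only = matrix(0, length(times), 0))
}

#' Marginal covariance of one pair's stacked marker observations
#'
#' `Cov = Z Sigma_b Z' (block-diagonal per subject) + sigma_u2 * J (ones
#' across the whole pair) + sigma_e2 * I`, where `Z = [1, t]` (or `[1]`
#' without a random slope). Rows are ordered twin 1's times then twin
#' 2's.
#'
#' @param t1,t2 observation times of the two twins (`t2` may be `NULL`
#'   for a singleton risk set).
#' @param params list with `Sigma_b` (matrix, possibly 0 x 0),
#'   `sigma_u2`, `sigma_e2`.
#' @param structure one of `"intercept_slope"`, `"intercept"`,
#'   `"pair_only"`.
#' @return symmetric positive semi-definite covariance matrix.
#' @export
pair_marginal_cov <- function(t1, t2 = NULL, params,
                              structure = "intercept") {
  Sb <- params$Sigma_b
  if (length(Sb) && any(eigen(Sb, symmetric = TRUE,
                              only.values = TRUE)$values < -1e-10))
    stop("Sigma_b must be positive semi-definite")
  ts <- list(t1, t2)
  ts <- ts[!vapply(ts, is.null, TRUE)]
  n <- sum(lengths(ts))
  V <- matrix(params$sigma_u2, n, n)
  off <- 0
  for (tt in ts) {
    Z <- subject_Z(tt, structure)
    idx <- off + seq_along(tt)
    if (ncol(Z)) V[idx, idx] <- V[idx, idx] + Z %*% Sb %*% t(Z)
    off <- off + length(tt)
  }
  V + params$sigma_e2 * diag(n)
}

#' Fit the twin linear mixed model
#'
#' Maximum-likelihood fit (lme4, `REML = FALSE`) of the marker model with
#' the requested random-effect structure. The exact Gaussian marginal
#' likelihood being maximized is the one induced by
#' [pair_marginal_cov] with independent pairs.
#'
#' @param long long-format data.frame with columns `pair_id`, `twin_id`,
#'   `time`, `y`.
#' @param structure `"intercept"` (subject random intercept + pair
#'   intercept; the simulation-study structure), `"intercept_slope"`
#'   (adds a correlated subject random slope) or `"pair_only"` (pair
#'   intercept only, for degenerate risk sets).
#' @param reml use REML instead of ML (default ML, keeping the
#'   downstream two-stage likelihood interpretation coherent).
#' @return object of class `lmm_fit`: `params` (beta0, beta1, Sigma_b,
#'   sigma_u2, sigma_e2), `structure`, `blups` (see [compute_blups]),
#'   `loglik`, `converged`, plus the fitting data.
#' @export
fit_lmm <- function(long, structure = "intercept", reml = FALSE) {
  structure <- match.arg(structure, lmm_structures)
  if (length(unique(long$pair_id)) < 2) stop("need at least 2 pairs")
  d <- data.frame(y = long$y, time = long$time,
                  pair = factor(long$pair_id),
                  sid = factor(paste(long$pair_id, long$twin_id)))
  if (structure == "intercept_slope" &&
      max(table(d$sid)) < 2)
    stop("random slope is non-identifiable: no subject has repeated measures")
  form <- switch(structure,
    intercept_slope = y ~ time + (1 + time | sid) + (1 | pair),
    intercept       = y ~ time + (1 | sid) + (1 | pair),
    pair_only       = y ~ time + (1 | pair))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            calc.derivs = FALSE)
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = d, REML = reml, control = ctrl)))
  vc <- lme4::VarCorr(fit)
  Sb <- switch(structure,
    intercept_slope = {
      m <- as.matrix(Matrix::bdiag(vc$sid))
      dimnames(m) <- NULL
      m
    },
    intercept = matrix(as.numeric(vc$sid), 1, 1),
    pair_only = matrix(0, 0, 0))
  fe <- lme4::fixef(fit)
  params <- list(beta0 = unname(fe[1]), beta1 = unname(fe["time"]),
                 Sigma_b = Sb,
                 sigma_u2 = as.numeric(vc$pair),
                 sigma_e2 = sigma(fit)^2)
  out <- list(params = params, structure = structure,
              loglik = as.numeric(logLik(fit)),
              converged = length(fit@optinfo$conv$lme4$messages) == 0,
              data = long, lmer = fit)
  out$blups <- compute_blups(params, long, structure)
  class(out) <- "lmm_fit"
  out
}

#' Empirical-Bayes random-effect predictions (BLUPs)
#'
#' For each pair, the posterior mean of its random effects under the
#' fitted Gaussian model: `blup = D Z' V^-1 (y - X beta)` with `D` the
#' joint covariance of (b_1, b_2, u), `Z` the pair design and `V` the
#' marginal covariance from [pair_marginal_cov].
#'
#' @param params,structure as in [fit_lmm] (pass `fit$params`,
#'   `fit$structure`).
#' @param long the observations to condition on.
#' @return list with data.frames `subjects` (`pair_id`, `twin_id`, `b0`,
#'   `b1`) and `pairs` (`pair_id`, `u`).
#' @export
compute_blups <- function(params, long, structure = "intercept") {
  structure <- match.arg(structure, lmm_structures)
  q <- switch(structure, intercept_slope = 2, intercept = 1, pair_only = 0)
  pids <- unique(long$pair_id)
  idx_by_pair <- split(seq_len(nrow(long)),
                       factor(long$pair_id, levels = pids))
  s_pid <- s_tid <- s_b0 <- s_b1 <- p_u <- list()
  for (pi in seq_along(pids)) {
    ii <- idx_by_pair[[pi]]
    ii <- ii[order(long$twin_id[ii], long$time[ii])]
    tid <- long$twin_id[ii]
    twins <- unique(tid)
    tlist <- lapply(twins, function(j) long$time[ii][tid == j])
    V <- pair_marginal_cov(tlist[[1]],
                           if (length(tlist) > 1) tlist[[2]] else NULL,
                           params, structure)
    r <- long$y[ii] - params$beta0 - params$beta1 * long$time[ii]
    # joint random-effect design and covariance: (b_twin1, b_twin2, u)
    n <- nrow(V)
    Z <- matrix(0, n, q * length(twins) + 1)
    off <- 0
    for (jj in seq_along(twins)) {
      if (q) Z[off + seq_along(tlist[[jj]]), (jj - 1) * q + seq_len(q)] <-
          subject_Z(tlist[[jj]], structure)
      off <- off + length(tlist[[jj]])
    }
    Z[, q * length(twins) + 1] <- 1
    Dblocks <- c(rep(list(params$Sigma_b), if (q) length(twins) else 0),
                 list(matrix(params$sigma_u2, 1, 1)))
    D <- as.matrix(Matrix::bdiag(Dblocks))
    sol <- tryCatch(solve(V, r), error = function(e)
      stop("singular pair covariance for pair ", pids[pi]))
    blup <- drop(D %*% crossprod(Z, sol))
    s_pid[[pi]] <- rep.int(pids[pi], length(twins))
    s_tid[[pi]] <- twins
    s_b0[[pi]] <- if (q >= 1) blup[q * (seq_along(twins) - 1) + 1] else
      numeric(length(twins))
    s_b1[[pi]] <- if (q >= 2) blup[q * (seq_along(twins) - 1) + 2] else
      numeric(length(twins))
    p_u[[pi]] <- blup[q * length(twins) + 1]
  }
  list(subjects = data.frame(pair_id = unlist(s_pid),
                             twin_id = unlist(s_tid),
                             b0 = unlist(s_b0), b1 = unlist(s_b1)),
       pairs = data.frame(pair_id = pids, u = unlist(p_u)))
}

#' Predict the marker trajectory for one subject
#'
#' `include_pair_effect = TRUE` gives the calibration prediction
#' \eqn{\hat M_{ij}(t) = \hat\beta_0 + \hat\beta_1 t + \hat b_{ij0} +
#' \hat b_{ij1} t + \hat u_i}; `FALSE` gives the subject profile
#' \eqn{\hat G_{ij}(t)} without the pair effect, as plugged into the
#' two-stage joint model (where \eqn{u_i} stays a random variable).
#' Subjects absent from the fitting data receive population predictions
#' (all BLUPs zero).
#'
#' @param fit an `lmm_fit`.
#' @param pair_id,twin_id subject identifier.
#' @param times prediction times.
#' @param include_pair_effect add the pair-effect BLUP.
#' @return predicted marker values.
#' @export
predict_marker <- function(fit, pair_id, twin_id, times,
                           include_pair_effect = TRUE) {
  co <- subject_lines(fit, data.frame(pair_id = pair_id,
                                      twin_id = twin_id),
                      include_pair_effect)
  co$g0 + co$g1 * times
}

# Per-subject intercept/slope of the fitted marker line, vectorised over
# a data.frame of (pair_id, twin_id) keys. Unseen subjects fall back to
# the population line.
subject_lines <- function(fit, keys, include_pair_effect = TRUE) {
  p <- fit$params; bl <- fit$blups
  sk <- paste(keys$pair_id, keys$twin_id)
  sb <- paste(bl$subjects$pair_id, bl$subjects$twin_id)
  m <- match(sk, sb)
  b0 <- ifelse(is.na(m), 0, bl$subjects$b0[m])
  b1 <- ifelse(is.na(m), 0, bl$subjects$b1[m])
  u <- if (include_pair_effect) {
    mu <- match(keys$pair_id, bl$pairs$pair_id)
    ifelse(is.na(mu), 0, bl$pairs$u[mu])
  } else 0
  list(g0 = p$beta0 + b0 + u, g1 = p$beta1 + b1)
}

#' Refit the marker model on the risk set at a given age
#'
#' Implements the first stage of risk-set regression calibration: the
#' mixed model is refitted using only subjects at risk at `risk_time`
#' (entered, event-free and uncensored) and only their marker
#' observations taken at or before `risk_time` (no look-ahead). If the
#' restricted data cannot identify the requested structure, the random
#' slope is dropped first, then the subject intercept; if fewer than
#' `min_pairs` pairs remain, `NULL` is returned so the caller can reuse
#' the nearest earlier refit.
#'
#' @param long longitudinal data (`pair_id`, `twin_id`, `time`, `y`).
#' @param survival survival records (`pair_id`, `twin_id`, `entry_age`,
#'   `exit_age`).
#' @param risk_time the age defining the risk set.
#' @param structure requested structure, degraded as needed.
#' @param min_pairs smallest usable risk set (in pairs).
#' @return an `lmm_fit` with attributes `risk_time` and
#'   `structure_used`, or `NULL` when the risk set is too small.
#' @export
rrc_refit <- function(long, survival, risk_time, structure = "intercept",
                      min_pairs = 10) {
  at_risk <- survival[survival$entry_age <= risk_time &
                      survival$exit_age > risk_time, ]
  if (!nrow(at_risk))
    stop("empty risk set at time ", risk_time)
  key <- paste(long$pair_id, long$twin_id)
  rkey <- paste(at_risk$pair_id, at_risk$twin_id)
  sub <- long[key %in% rkey & long$time <= risk_time, ]
  if (length(unique(sub$pair_id)) < min_pairs) return(NULL)
  structure <- match.arg(structure, lmm_structures)
  if (structure == "intercept_slope" &&
      max(table(paste(sub$pair_id, sub$twin_id))) < 2)
    structure <- "intercept"
  fit <- tryCatch(fit_lmm(sub, structure), error = function(e) NULL)
  if (is.null(fit) && structure != "pair_only")
    fit <- tryCatch(fit_lmm(sub, "pair_only"), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  attr(fit, "risk_time") <- risk_time
  attr(fit, "structure_used") <- fit$structure
  fit
}
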