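# Two-stage joint longitudinal-survival likelihood. Stage 1: the
# all-data twin mixed model supplies fixed effects and subject-level
# BLUPs, defining each subject's profile G_ij(t) = g0 + g1 t WITHOUT the
# pair effect. Stage 2 maximizes, over (alpha, theta, lambda, rho,
# sigma_u2, sigma_e2), the likelihood that integrates the pair-shared
# effect u numerically (Gauss-Hermite) and the gamma frailty in closed
# form: given u, the subject's marker is G_ij(t) + u, the survival
# factor is the delayed-entry-corrected frailty integral, and the
# longitudinal factor is the Gaussian density of the residuals y -
# G_ij(t_k) - u with variance sigma_e2.

.gh_cache <- new.env(parent = emptyenv())
gh_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]]))
    .gh_cache[[key]] <- pracma::gaussHermite(n)
  .gh_cache[[key]]
}

# Precompute everything that does not depend on stage-2 parameters:
# per-subject profile lines, survival outcomes, Gauss-Legendre node
# positions for the two hazard integrals (entry..exit and 0..entry),
# per-pair residual sets.
jm_prepare <- function(dataset, stage1, n_gl = 30) {
  sv <- dataset$survival
  lines <- subject_lines(stage1, sv, include_pair_effect = FALSE)
  gl <- gl_nodes(n_gl)
  mk_nodes <- function(a, b) {
    half <- (b - a) / 2
    list(s = outer(half, gl$x) + (b + a) / 2, half = half)
  }
  obsw <- mk_nodes(sv$entry_age, sv$exit_age)
  entw <- mk_nodes(rep(0, nrow(sv)), sv$entry_age)
  cl <- match(sv$pair_id, unique(sv$pair_id))
  lg <- dataset$longitudinal
  lkey <- paste(lg$pair_id, lg$twin_id)
  skey <- paste(sv$pair_id, sv$twin_id)
  m <- match(lkey, skey)
  resid0 <- lg$y - (lines$g0[m] + lines$g1[m] * lg$time)
  lcl <- cl[m]
  n_cl <- max(cl)
  list(sv = sv, g0 = lines$g0, g1 = lines$g1, cl = cl, n_cl = n_cl,
       glw = gl$w, obsw = obsw, entw = entw,
       d = drop(rowsum(sv$event, cl)),
       resid = resid0, lcl = lcl,
       n_obs = drop(rowsum(rep(1, length(lcl)), lcl)),
       sum_r = drop(rowsum(resid0, lcl)),
       sum_r2 = drop(rowsum(resid0^2, lcl)))
}

# Core evaluation on the working scale. Returns total loglik.
jm_loglik_pre <- function(alpha, theta, lambda, rho, sigma_u2, sigma_e2,
                          pre, nodes = 20) {
  sv <- pre$sv
  # per-subject event terms and hazard integrals at u = 0
  lam_rho <- lambda * rho
  f_obs <- pre$obsw$s^(rho - 1) *
    exp(alpha * (pre$g0 + pre$g1 * pre$obsw$s))
  A_sub <- lam_rho * pre$obsw$half * drop(f_obs %*% pre$glw)
  f_ent <- pre$entw$s^(rho - 1) *
    exp(alpha * (pre$g0 + pre$g1 * pre$entw$s))
  B_sub <- lam_rho * pre$entw$half * drop(f_ent %*% pre$glw)
  B_sub[sv$entry_age == 0] <- 0
  A <- drop(rowsum(A_sub, pre$cl))
  B <- drop(rowsum(B_sub, pre$cl))
  ev <- sv$event == 1
  ev_term <- numeric(nrow(sv))
  ev_term[ev] <- log(lam_rho) + (rho - 1) * log(sv$exit_age[ev]) +
    alpha * (pre$g0[ev] + pre$g1[ev] * sv$exit_age[ev])
  E <- drop(rowsum(ev_term, pre$cl))
  d <- pre$d
  # longitudinal residual pieces: sum over pair of (r - u)^2 =
  # sum_r2 - 2 u sum_r + n u^2
  const_M <- -0.5 * pre$n_obs * log(2 * pi * sigma_e2)
  if (sigma_u2 <= 1e-10) {
    llS <- E + gamma_cluster_term(A, B, d, theta)
    llM <- const_M - pre$sum_r2 / (2 * sigma_e2)
    return(sum(llS + llM))
  }
  gh <- gh_nodes(nodes)
  # adaptive centering: the longitudinal factor localizes u around its
  # per-pair Gaussian posterior (prior N(0, sigma_u2) times the
  # residual likelihood), which can be far narrower than the prior;
  # nodes are placed on that posterior and the exact integrand is
  # re-weighted, so the rule stays a proper quadrature of the full
  # likelihood
  post_var <- 1 / (1 / sigma_u2 + pre$n_obs / sigma_e2)
  post_mean <- post_var * pre$sum_r / sigma_e2
  s <- sqrt(post_var)
  llmat <- matrix(0, pre$n_cl, nodes)
  for (qi in seq_len(nodes)) {
    u <- post_mean + sqrt(2) * s * gh$x[qi]
    eau <- exp(alpha * u)
    llS <- E + d * (alpha * u) +
      gamma_cluster_term(A * eau, B * eau, d, theta)
    llM <- const_M -
      (pre$sum_r2 - 2 * u * pre$sum_r + pre$n_obs * u^2) / (2 * sigma_e2)
    lprior <- -0.5 * log(2 * pi * sigma_u2) - u^2 / (2 * sigma_u2)
    llmat[, qi] <- llS + llM + lprior + log(gh$w[qi]) + gh$x[qi]^2 +
      0.5 * log(2) + log(s)
  }
  mx <- apply(llmat, 1, max)
  sum(mx + log(rowSums(exp(llmat - mx))))
}

#' Two-stage joint-model log-likelihood
#'
#' Evaluates the stage-2 likelihood at the given parameters: for each
#' pair, a Gauss-Hermite sum over the pair effect `u` of the product of
#' (i) the closed-form gamma-frailty survival integral with marker
#' trajectory \eqn{\hat G_{ij}(t) + u}, cumulative hazards taken from
#' entry to exit with the entry-conditioning term of the updated frailty
#' distribution, and (ii) the Gaussian density of the longitudinal
#' residuals \eqn{y - \hat G_{ij}(t_k) - u} with variance
#' \eqn{\sigma_\varepsilon^2}. At \eqn{\sigma_u^2 \le 10^{-10}} the
#' integral collapses analytically to the `u = 0` integrand.
#'
#' @param params list with `alpha`, `theta`, `lambda`, `rho`,
#'   `sigma_u2`, `sigma_e2`.
#' @param dataset a `twin_data` object.
#' @param stage1 the all-data `lmm_fit` supplying fixed effects and
#'   subject BLUPs (pair effect excluded internally).
#' @param nodes Gauss-Hermite node count (>= 5).
#' @return total log-likelihood.
#' @export
jm_loglik <- function(params, dataset, stage1, nodes = 20) {
  if (nodes < 5) stop("'nodes' must be >= 5")
  pre <- jm_prepare(dataset, stage1)
  jm_loglik_pre(params$alpha, params$theta, params$lambda, params$rho,
                params$sigma_u2, params$sigma_e2, pre, nodes)
}

#' Fit the two-stage joint model
#'
#' Maximizes [jm_loglik] over \eqn{(\alpha, \theta, \lambda, \rho,
#' \sigma_u^2, \sigma_\varepsilon^2)} with positive parameters on the
#' log scale; stage-1 fixed effects and subject BLUPs stay frozen, so
#' their sampling error is not propagated into the standard errors
#' (a documented limitation of the two-stage construction). Standard
#' errors come from the inverse finite-difference Hessian; a
#' non-positive-definite Hessian leaves `se = NA` with `converged =
#' FALSE` rather than an error, since a noticeable share of replicates
#' is expected to lack a usable Hessian.
#'
#' @param dataset a `twin_data` object.
#' @param stage1 all-data `lmm_fit` (e.g. the ORC first stage).
#' @param init optional list of starting values (fields as in
#'   [jm_loglik] `params`); defaults use the stage-1 variance
#'   components, \eqn{\alpha = 0}, \eqn{\rho = 1}, \eqn{\lambda} =
#'   events / exposure, \eqn{\theta = 0.5}.
#' @param nodes Gauss-Hermite node count.
#' @param se compute standard errors.
#' @param control passed to [stats::nlminb].
#' @return object of class `jm_fit` with `estimates`, `se`, `loglik`,
#'   `converged`, `quadrature_nodes`.
#' @export
fit_jm <- function(dataset, stage1, init = NULL, nodes = 20, se = TRUE,
                   control = list(iter.max = 500)) {
  if (nodes < 5) stop("'nodes' must be >= 5")
  if (sum(dataset$survival$event) == 0)
    stop("no events: survival parameters are non-identifiable")
  pre <- jm_prepare(dataset, stage1)
  sv <- dataset$survival
  if (is.null(init)) {
    expo <- sum(sv$exit_age - sv$entry_age)
    init <- list(alpha = 0, theta = 0.5,
                 lambda = sum(sv$event) / expo, rho = 1,
                 sigma_u2 = max(stage1$params$sigma_u2, 1e-4),
                 sigma_e2 = max(stage1$params$sigma_e2, 1e-4))
  }
  par0 <- c(init$alpha, log(max(init$theta, 1e-4)), log(init$lambda),
            log(init$rho), log(max(init$sigma_u2, 1e-6)),
            log(max(init$sigma_e2, 1e-6)))
  neg <- function(p)
    -jm_loglik_pre(p[1], exp(p[2]), exp(p[3]), exp(p[4]), exp(p[5]),
                   exp(p[6]), pre, nodes)
  lower <- c(-Inf, log(1e-8), -Inf, -Inf, log(1e-9), log(1e-8))
  opt <- nlminb(par0, neg, lower = lower, control = control)
  est <- opt$par
  natural <- list(alpha = est[1], theta = exp(est[2]),
                  lambda = exp(est[3]), rho = exp(est[4]),
                  sigma_u2 = exp(est[5]), sigma_e2 = exp(est[6]))
  fit <- list(estimates = natural, se = NULL, loglik = -opt$objective,
              converged = opt$convergence == 0,
              quadrature_nodes = nodes, n_clusters = pre$n_cl,
              n_events = sum(sv$event), opt = opt)
  if (se) {
    H <- tryCatch(pracma::hessian(neg, est, h = 1e-5),
                  error = function(e) NULL)
    se_work <- rep(NA_real_, 6)
    ok <- FALSE
    if (!is.null(H)) {
      evv <- tryCatch(eigen(H, symmetric = TRUE,
                            only.values = TRUE)$values,
                      error = function(e) NA)
      if (all(is.finite(evv)) && all(evv > 0)) {
        se_work <- sqrt(diag(solve(H)))
        ok <- TRUE
      }
    }
    se_nat <- se_work
    se_nat[2:6] <- se_work[2:6] * unlist(natural[2:6])
    names(se_nat) <- c("alpha", "theta", "lambda", "rho", "sigma_u2",
                       "sigma_e2")
    fit$se <- se_nat
    fit$se_work <- setNames(se_work, names(se_nat))
    fit$converged <- fit$converged && ok
  }
  class(fit) <- "jm_fit"
  fit
}

#' @export
print.jm_fit <- function(x, ...) {
  cat("Two-stage joint model fit (", x$n_clusters, " pairs, ",
      x$n_events, " events, ", x$quadrature_nodes, " GH nodes)\n",
      sep = "")
  est <- unlist(x$estimates)
  se <- if (is.null(x$se)) rep(NA_real_, length(est)) else x$se
  print(data.frame(estimate = est, se = se))
  cat("logLik:", format(x$loglik), " converged:", x$converged, "\n")
  invisible(x)
}
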