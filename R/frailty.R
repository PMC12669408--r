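# Shared gamma-frailty Weibull proportional-hazards likelihood with
# piecewise-constant time-varying covariates, corrected for delayed entry
# through the updated gamma frailty distribution: conditional on both
# pair members surviving past their entry ages, a Gamma(1/theta, 1/theta)
# frailty remains gamma with rate 1/theta + B, where B is the summed
# entry-age cumulative hazard of the pair.

#' Weibull cumulative baseline hazard
#'
#' \eqn{H_0(t) = \lambda t^\rho} for baseline hazard
#' \eqn{h_0(t) = \lambda \rho t^{\rho - 1}}.
#'
#' @param t nonnegative time(s).
#' @param lambda,rho scale and shape, both > 0.
#' @return \eqn{\lambda t^\rho}.
#' @export
weibull_cumhaz <- function(t, lambda, rho) {
  if (any(t < 0)) stop("'t' must be >= 0")
  stopifnot(lambda > 0, rho > 0)
  lambda * t^rho
}

#' Frailty model parameters
#'
#' Bundle of the survival-model parameters: marker effect `alpha`, fixed
#' covariate effects `gamma` (possibly empty), frailty variance `theta`
#' and Weibull baseline `lambda` (scale), `rho` (shape).
#'
#' @param alpha marker effect.
#' @param gamma numeric vector of fixed covariate effects.
#' @param theta frailty variance, >= 0.
#' @param lambda,rho Weibull baseline scale/shape, > 0.
#' @return list of class `frailty_params`.
#' @export
frailty_params <- function(alpha = 0, gamma = numeric(0), theta = 0.5,
                           lambda = 0.001, rho = 2) {
  if (theta < 0) stop("'theta' must be >= 0")
  stopifnot(lambda > 0, rho > 0)
  structure(list(alpha = alpha, gamma = gamma, theta = theta,
                 lambda = lambda, rho = rho), class = "frailty_params")
}

# Columns holding fixed covariates in a start-stop table.
x_cols <- function(tab) grep("^x", names(tab), value = TRUE)

validate_startstop <- function(tab) {
  need <- c("pair_id", "twin_id", "start", "stop", "status", "z")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("start-stop table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(tab$stop <= tab$start))
    stop("rows with stop <= start: ",
         paste(head(which(tab$stop <= tab$start)), collapse = ", "))
  sid <- paste(tab$pair_id, tab$twin_id)
  o <- order(sid, tab$start)
  same <- sid[o][-1] == sid[o][-length(o)]
  gap <- abs(tab$start[o][-1] - tab$stop[o][-length(o)]) > 1e-8
  if (any(same & gap))
    stop("non-contiguous intervals for subject ",
         sid[o][-1][which(same & gap)[1]])
  if (any(tab$status[o][-length(o)][same] == 1))
    stop("event before final interval for subject ",
         sid[o][-length(o)][same][which(tab$status[o][-length(o)][same] ==
                                          1)[1]])
  invisible(tab)
}

#' Per-subject cumulative hazards under a piecewise-constant marker
#'
#' For the start-stop rows of one subject, returns the cumulative hazard
#' accumulated over the observed window,
#' \eqn{A = \sum_k [H_0(\texttt{stop}_k) - H_0(\texttt{start}_k)]
#' e^{\gamma x + \alpha z_k}}, and the entry-age mass
#' \eqn{B = H_0(\texttt{entry}) e^{\gamma x + \alpha z_0}} evaluated at
#' the marker value in force at entry, which drives the updated frailty
#' distribution under delayed entry.
#'
#' @param rows start-stop rows of a single subject (columns start, stop,
#'   z, status, optional covariate columns `x*`).
#' @param params a [frailty_params].
#' @return list with elements `A_obs` and `A_entry`.
#' @export
subject_cumhaz <- function(rows, params) {
  o <- order(rows$start)
  rows <- rows[o, ]
  if (any(abs(rows$start[-1] - rows$stop[-nrow(rows)]) > 1e-8))
    stop("intervals must be contiguous")
  xc <- x_cols(rows)
  lpx <- if (length(xc))
    as.matrix(rows[, xc, drop = FALSE]) %*% params$gamma else 0
  lp <- drop(lpx) + params$alpha * rows$z
  H0 <- function(t) weibull_cumhaz(t, params$lambda, params$rho)
  A_obs <- sum((H0(rows$stop) - H0(rows$start)) * exp(lp))
  A_entry <- H0(rows$start[1]) * exp(lp[1])
  list(A_obs = A_obs, A_entry = A_entry)
}

# Stable log of the gamma-frailty cluster integral:
#   sum_{k<d} log(R+k) + R log(R+B) - (R+d) log(R+A+B),  R = 1/theta,
# written so that it degrades gracefully to the no-frailty limit
# (-A after adding back nothing) as theta -> 0.
gamma_cluster_term <- function(A, B, d, theta) {
  if (theta <= 1e-8) return(-A)
  R <- 1 / theta
  t1 <- if (any(d > 0)) {
    out <- numeric(length(A))
    for (k in 0:(max(d) - 1))
      out <- out - ifelse(d > k, log1p((A + B - k) / (R + k)), 0)
    out
  } else 0
  t1 - R * log1p(A / (R + B))
}

#' Marginal log-likelihood contribution of one twin pair
#'
#' Integrates the conditional (given-frailty) likelihood of a pair's
#' start-stop data against the gamma frailty distribution in closed form.
#' With `truncation_adjust = TRUE` the integration uses the updated
#' frailty distribution Gamma\eqn{(1/\theta,\ 1/\theta + B)} that
#' conditions on both members surviving to their entry ages (B is the
#' pair's summed entry cumulative hazard); with `FALSE` (the "naive"
#' analysis) the population Gamma\eqn{(1/\theta, 1/\theta)} is used,
#' i.e. B = 0. At \eqn{\theta = 0} the expression reduces analytically
#' to the independent Weibull proportional-hazards log-likelihood.
#'
#' @param rows start-stop rows covering exactly one pair.
#' @param params a [frailty_params].
#' @param truncation_adjust use the updated frailty distribution.
#' @return the pair's log-likelihood contribution.
#' @export
cluster_marginal_loglik <- function(rows, params, truncation_adjust = TRUE) {
  sid <- paste(rows$pair_id, rows$twin_id)
  per <- lapply(split(rows, sid), subject_cumhaz, params = params)
  A <- sum(vapply(per, `[[`, 0, "A_obs"))
  B <- if (truncation_adjust)
    sum(vapply(per, `[[`, 0, "A_entry")) else 0
  d <- sum(rows$status)
  ev <- rows[rows$status == 1, , drop = FALSE]
  ev_ll <- 0
  if (nrow(ev)) {
    xc <- x_cols(ev)
    lpx <- if (length(xc))
      drop(as.matrix(ev[, xc, drop = FALSE]) %*% params$gamma) else 0
    ev_ll <- sum(log(params$lambda * params$rho) +
                 (params$rho - 1) * log(ev$stop) +
                 lpx + params$alpha * ev$z)
  }
  ev_ll + gamma_cluster_term(A, B, d, params$theta)
}

# Precompute index structures so that repeated likelihood evaluations are
# vectorised across the whole table.
prep_startstop <- function(tab) {
  validate_startstop(tab)
  sid <- paste(tab$pair_id, tab$twin_id)
  o <- order(tab$pair_id, tab$twin_id, tab$start)
  tab <- tab[o, ]
  sid <- sid[o]
  first <- !duplicated(sid)
  cl <- match(tab$pair_id, unique(tab$pair_id))
  xc <- x_cols(tab)
  list(tab = tab, cl = cl, n_cl = max(cl), first = first,
       cl_first = cl[first],
       xmat = if (length(xc)) as.matrix(tab[, xc, drop = FALSE]) else NULL,
       d = drop(rowsum(tab$status, cl)))
}

# Working-scale parameter vector: (alpha, gamma..., log lambda, log rho,
# log theta).
frailty_loglik_work <- function(par, pre, truncation_adjust) {
  p <- length(par)
  ng <- if (is.null(pre$xmat)) 0 else ncol(pre$xmat)
  alpha <- par[1]
  gamma <- if (ng) par[1 + seq_len(ng)] else numeric(0)
  lambda <- exp(par[ng + 2]); rho <- exp(par[ng + 3])
  theta <- exp(par[ng + 4])
  tab <- pre$tab
  lpx <- if (ng) drop(pre$xmat %*% gamma) else 0
  lp <- lpx + alpha * tab$z
  elp <- exp(lp)
  A <- drop(rowsum((lambda * (tab$stop^rho - tab$start^rho)) * elp, pre$cl))
  B <- if (truncation_adjust) {
    bsub <- (lambda * tab$start[pre$first]^rho) * elp[pre$first]
    drop(rowsum(bsub, pre$cl_first))
  } else numeric(pre$n_cl)
  evi <- tab$status == 1
  ev_ll <- sum(log(lambda * rho) + (rho - 1) * log(tab$stop[evi]) +
               lp[evi])
  ev_ll + sum(gamma_cluster_term(A, B, pre$d, theta))
}

#' Fit the shared gamma-frailty Weibull model
#'
#' Maximizes the sum of pair-level marginal log-likelihoods
#' ([cluster_marginal_loglik]) over \eqn{(\alpha, \gamma, \lambda, \rho,
#' \theta)}. Positive parameters are optimized on the log scale;
#' standard errors come from the inverse of a central finite-difference
#' Hessian at the optimum, transported back to the natural scale by the
#' delta method. A non-positive-definite Hessian yields `converged =
#' FALSE` with `se` set to `NA` (the fit itself is still returned).
#'
#' @param table start-stop table (columns pair_id, twin_id, start, stop,
#'   status, z, optional covariates `x*`); complete pairs.
#' @param init optional [frailty_params] starting value; default starts
#'   at \eqn{\alpha = \gamma = 0}, \eqn{\rho = 1}, \eqn{\lambda =}
#'   events / total exposure, \eqn{\theta = 0.5}.
#' @param truncation_adjust condition the frailty on survival to entry
#'   (the delayed-entry correction); `FALSE` reproduces the naive
#'   analysis.
#' @param se compute standard errors (skippable for speed in
#'   replication loops where only point estimates are aggregated).
#' @param control passed to [stats::nlminb].
#' @return object of class `frailty_fit`: `estimates`
#'   ([frailty_params]), `se`, `loglik`, `converged`, `n_clusters`,
#'   `n_events`.
#' @export
fit_frailty <- function(table, init = NULL, truncation_adjust = TRUE,
                        se = TRUE, control = list(iter.max = 500)) {
  zero <- table$stop == table$start
  if (any(zero)) {
    warning(sum(zero), " zero-length interval(s) dropped")
    table <- table[!zero, , drop = FALSE]
  }
  pre <- prep_startstop(table)
  ng <- if (is.null(pre$xmat)) 0 else ncol(pre$xmat)
  if (is.null(init)) {
    expo <- sum(pre$tab$stop - pre$tab$start)
    init <- frailty_params(alpha = 0, gamma = rep(0, ng),
                           lambda = sum(pre$tab$status) / expo, rho = 1,
                           theta = 0.5)
  }
  par0 <- c(init$alpha, init$gamma, log(init$lambda), log(init$rho),
            log(max(init$theta, 1e-4)))
  neg <- function(p) -frailty_loglik_work(p, pre, truncation_adjust)
  lower <- c(rep(-Inf, 1 + ng), -Inf, -Inf, log(1e-8))
  opt <- nlminb(par0, neg, lower = lower, control = control)
  est <- opt$par
  natural <- frailty_params(alpha = est[1],
                            gamma = if (ng) est[1 + seq_len(ng)] else numeric(0),
                            lambda = exp(est[ng + 2]), rho = exp(est[ng + 3]),
                            theta = exp(est[ng + 4]))
  fit <- list(estimates = natural, se = NULL, loglik = -opt$objective,
              converged = opt$convergence == 0,
              n_clusters = pre$n_cl, n_events = sum(pre$tab$status),
              opt = opt)
  if (se) {
    H <- pracma::hessian(neg, est, h = 1e-5)
    se_work <- rep(NA_real_, length(est))
    ok <- FALSE
    ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) NA)
    if (all(is.finite(ev)) && all(ev > 0)) {
      se_work <- sqrt(diag(solve(H)))
      ok <- TRUE
    }
    # delta method: log-scale parameters back to natural scale
    se_nat <- se_work
    se_nat[ng + 2] <- se_work[ng + 2] * natural$lambda
    se_nat[ng + 3] <- se_work[ng + 3] * natural$rho
    se_nat[ng + 4] <- se_work[ng + 4] * natural$theta
    names(se_nat) <- c("alpha", if (ng) paste0("gamma", seq_len(ng)),
                       "lambda", "rho", "theta")
    fit$se <- se_nat
    fit$se_work <- setNames(se_work, names(se_nat))
    fit$converged <- fit$converged && ok
  }
  class(fit) <- "frailty_fit"
  fit
}

#' @export
print.frailty_fit <- function(x, ...) {
  e <- x$estimates
  cat("Shared gamma-frailty Weibull fit (",
      x$n_clusters, " pairs, ", x$n_events, " events)\n", sep = "")
  est <- c(alpha = e$alpha,
           if (length(e$gamma)) setNames(e$gamma,
                                         paste0("gamma", seq_along(e$gamma))),
           lambda = e$lambda, rho = e$rho, theta = e$theta)
  se <- if (is.null(x$se)) rep(NA_real_, length(est)) else x$se
  print(data.frame(estimate = est, se = se))
  cat("logLik:", format(x$loglik), " converged:", x$converged, "\n")
  invisible(x)
}
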