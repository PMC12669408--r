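# Monte-Carlo study harness: replicate the simulate -> fit pipeline for
# a set of estimators on the SAME datasets and aggregate relative bias,
# SD, MCSE, MSE and Wald coverage per estimator and parameter.

#' Monte-Carlo scenario specification
#'
#' @param sim a [sim_config] (its `seed` is overridden per replicate).
#' @param methods subset of `c("naive", "locf", "orc", "rrc", "jm")`.
#' @param n_reps number of replicates.
#' @param base_seed master seed; replicate r uses a seed derived
#'   deterministically from it, so results do not depend on execution
#'   order.
#' @param grid_L dense-grid size for the calibration estimators.
#' @param lmm_structure first-stage mixed-model structure.
#' @param jm_nodes Gauss-Hermite nodes for the joint model.
#' @param se compute standard errors per replicate (needed for
#'   coverage; can be switched off when only bias is studied).
#' @return list of class `mc_scenario`.
#' @export
mc_scenario <- function(sim = sim_config(), methods = c("naive", "locf"),
                        n_reps = 10, base_seed = 1L, grid_L = 100,
                        lmm_structure = "intercept", jm_nodes = 20,
                        se = TRUE) {
  methods <- match.arg(methods, c("naive", "locf", "orc", "rrc", "jm"),
                       several.ok = TRUE)
  stopifnot(n_reps >= 1)
  structure(list(sim = sim, methods = methods, n_reps = as.integer(n_reps),
                 base_seed = as.integer(base_seed), grid_L = grid_L,
                 lmm_structure = lmm_structure, jm_nodes = jm_nodes,
                 se = se),
            class = "mc_scenario")
}

# Fit every requested method on one dataset; returns a named list of
# (est, se, converged) per method. Failures are caught and recorded.
fit_all_methods <- function(dataset, spec) {
  res <- list()
  grab <- function(expr) tryCatch(expr, error = function(e) e)
  if (any(c("naive", "locf") %in% spec$methods)) {
    tab <- grab(build_locf_startstop(dataset))
    for (m in intersect(c("naive", "locf"), spec$methods)) {
      res[[m]] <- if (inherits(tab, "error")) tab else
        grab(fit_frailty(tab, truncation_adjust = (m == "locf"),
                         se = spec$se))
    }
  }
  need_lmm <- any(c("orc", "rrc", "jm") %in% spec$methods)
  if (need_lmm) {
    lmm <- grab(fit_lmm(dataset$longitudinal, spec$lmm_structure))
    grid <- dense_grid(dataset, spec$grid_L)
    if ("orc" %in% spec$methods)
      res$orc <- if (inherits(lmm, "error")) lmm else
        grab(fit_frailty(build_calibrated_startstop(dataset, lmm, grid,
                                                    "orc"),
                         se = spec$se))
    if ("rrc" %in% spec$methods)
      res$rrc <- if (inherits(lmm, "error")) lmm else
        grab({
          rf <- rrc_refits(dataset, spec$lmm_structure)
          fit_frailty(build_calibrated_startstop(dataset, lmm, grid,
                                                 "rrc", rf),
                      se = spec$se)
        })
    if ("jm" %in% spec$methods)
      res$jm <- if (inherits(lmm, "error")) lmm else
        grab(fit_jm(dataset, lmm, nodes = spec$jm_nodes, se = spec$se))
  }
  res
}

#' Run a Monte-Carlo scenario
#'
#' For each replicate, simulates a dataset with a replicate-specific
#' derived seed and fits every requested estimator on that same
#' dataset; per-replicate estimates, standard errors and convergence
#' flags are collected and aggregated with [mc_aggregate]. Replicates
#' whose fit fails or does not converge are excluded from the moment
#' summaries and reported as failures; replicates that converge but
#' lack standard errors still contribute to bias yet not to coverage.
#'
#' @param spec an [mc_scenario].
#' @param verbose print a progress line per replicate.
#' @return object of class `mc_result`: `summary` (data.frame per
#'   method x parameter), `inc_G`, `events`, `failures`, `raw`.
#' @export
run_scenario <- function(spec, verbose = FALSE) {
  pars <- c("alpha", "theta", "lambda", "rho")
  truth <- c(alpha = spec$sim$alpha, theta = spec$sim$theta,
             lambda = spec$sim$weibull_scale, rho = spec$sim$weibull_shape)
  R <- spec$n_reps
  est <- se <- lapply(spec$methods, function(m)
    matrix(NA_real_, R, length(pars), dimnames = list(NULL, pars)))
  names(est) <- names(se) <- spec$methods
  conv <- matrix(FALSE, R, length(spec$methods),
                 dimnames = list(NULL, spec$methods))
  inc_G <- events <- numeric(R)
  for (r in seq_len(R)) {
    cfg <- spec$sim
    cfg$seed <- as.integer(derive_seed(spec$base_seed, r, 3L))
    dat <- simulate_dataset(cfg)
    inc_G[r] <- length(unique(dat$survival$pair_id))
    events[r] <- sum(dat$survival$event)
    fits <- fit_all_methods(dat, spec)
    for (m in spec$methods) {
      f <- fits[[m]]
      if (inherits(f, "error") || is.null(f)) next
      e <- f$estimates
      est[[m]][r, ] <- c(e$alpha, e$theta, e$lambda, e$rho)
      if (!is.null(f$se)) se[[m]][r, ] <- f$se[pars]
      conv[r, m] <- isTRUE(f$converged) ||
        (!is.null(f$opt) && f$opt$convergence == 0)
    }
    if (verbose)
      message(sprintf("rep %d/%d: G=%d events=%d", r, R, inc_G[r],
                      events[r]))
  }
  summ <- do.call(rbind, lapply(spec$methods, function(m) {
    ok <- conv[, m] & !is.na(est[[m]][, 1])
    agg <- mc_aggregate(est[[m]][ok, , drop = FALSE],
                        se[[m]][ok, , drop = FALSE], truth,
                        log_scale = c(FALSE, TRUE, TRUE, TRUE))
    cbind(method = m, agg)
  }))
  structure(list(summary = summ, inc_G = mean(inc_G),
                 events = mean(events),
                 failures = colSums(!conv),
                 n_reps = R, truth = truth, spec = spec,
                 raw = list(est = est, se = se, conv = conv)),
            class = "mc_result")
}

#' Aggregate replicate estimates into study metrics
#'
#' @param est replicate x parameter matrix of point estimates.
#' @param se matching matrix of standard errors (may be all `NA`).
#' @param truth named true values.
#' @param log_scale logical per parameter: build the Wald interval on
#'   the log scale (delta method), as is natural for variance and
#'   baseline parameters.
#' @param level confidence level.
#' @return data.frame with columns parameter, reBias, SD, MCSE, MSE,
#'   CP, n_used, n_se.
#' @export
mc_aggregate <- function(est, se = NULL, truth,
                         log_scale = rep(FALSE, length(truth)),
                         level = 0.95) {
  pars <- names(truth)
  zq <- qnorm(1 - (1 - level) / 2)
  out <- lapply(seq_along(pars), function(j) {
    x <- est[, j]
    x <- x[!is.na(x)]
    R <- length(x)
    if (!R)
      return(data.frame(parameter = pars[j], reBias = NA, SD = NA,
                        MCSE = NA, MSE = NA, CP = NA, n_used = 0,
                        n_se = 0))
    sdx <- if (R > 1) sd(x) else NA_real_
    cp <- NA_real_; nse <- 0L
    if (!is.null(se) && nrow(se)) {
      s <- se[, j]
      okse <- !is.na(est[, j]) & !is.na(s) & s > 0
      nse <- sum(okse)
      if (nse) {
        e <- est[okse, j]; s <- se[okse, j]
        cover <- if (log_scale[j]) {
          lo <- log(e) - zq * s / e; hi <- log(e) + zq * s / e
          lo <= log(truth[j]) & log(truth[j]) <= hi
        } else {
          abs(e - truth[j]) <= zq * s
        }
        cp <- mean(cover)
      }
    }
    data.frame(parameter = pars[j],
               reBias = (mean(x) - truth[j]) / truth[j],
               SD = sdx, MCSE = sdx / sqrt(R),
               MSE = mean((x - truth[j])^2), CP = cp,
               n_used = R, n_se = nse)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @importFrom stats sd
#' @export
print.mc_result <- function(x, digits = 3, ...) {
  cat("Monte-Carlo study:", x$n_reps, "replicates, mean Inc.G =",
      round(x$inc_G, 1), ", mean events =", round(x$events, 1), "\n")
  if (any(x$failures > 0)) {
    cat("non-converged replicates:",
        paste(names(x$failures), x$failures, sep = "=", collapse = ", "),
        "\n")
  }
  df <- x$summary
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Format a Monte-Carlo result as a publication-style table
#'
#' One row per parameter with `Inc.G`, `Events` and, per method, the
#' relative bias and SD columns, each with its Monte-Carlo standard
#' error in parentheses — the layout of the simulation bias tables.
#'
#' @param result an `mc_result`.
#' @param params parameters to tabulate.
#' @param digits rounding.
#' @return data.frame of character columns (also printable as
#'   markdown via `knitr::kable`).
#' @export
summarize_mc <- function(result, params = c("alpha", "theta"),
                         digits = 3) {
  s <- result$summary
  fmt <- function(v, m) sprintf(paste0("%.", digits, "f (%.", digits,
                                       "f)"), v, m)
  rows <- lapply(params, function(p) {
    row <- data.frame(Par. = p, Inc.G = round(result$inc_G, 1),
                      Events = round(result$events, 1))
    for (m in unique(s$method)) {
      ss <- s[s$method == m & s$parameter == p, ]
      mcse_sd <- ss$SD / sqrt(2 * (ss$n_used - 1))
      row[[paste0(m, ".reBias")]] <-
        fmt(ss$reBias, ss$MCSE / result$truth[p])
      row[[paste0(m, ".SD")]] <- fmt(ss$SD, mcse_sd)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
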