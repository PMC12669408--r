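# Shared fixtures, built in code.

# A start-stop table for one pair: two subjects, `k` intervals each,
# random marker values and entry ages; at most one event per subject.
random_pair_table <- function(pair_id = 1, k = 3, entry_max = 2,
                              horizon = 6) {
  rows <- lapply(1:2, function(j) {
    entry <- runif(1, 0, entry_max)
    cuts <- sort(c(entry, entry + cumsum(runif(k, 0.2, horizon / k))))
    data.frame(pair_id = pair_id, twin_id = j,
               start = cuts[-length(cuts)], stop = cuts[-1],
               status = c(rep(0L, k - 1), rbinom(1, 1, 0.6)),
               z = rnorm(k, 1, 0.5))
  })
  do.call(rbind, rows)
}

# Independent Gauss-Laguerre oracle for the pair marginal likelihood:
# integrates the conditional likelihood against the updated gamma
# frailty density Gamma(1/theta, 1/theta + B) over v, using the plain
# e^{-v}-weight rule (no closed-form shortcuts).
laguerre_cluster_loglik <- function(rows, params, truncation_adjust = TRUE,
                                    n = 64) {
  per <- lapply(split(rows, paste(rows$pair_id, rows$twin_id)),
                subject_cumhaz, params = params)
  A <- sum(vapply(per, `[[`, 0, "A_obs"))
  B <- if (truncation_adjust) sum(vapply(per, `[[`, 0, "A_entry")) else 0
  d <- sum(rows$status)
  ev <- rows[rows$status == 1, , drop = FALSE]
  ev_ll <- if (nrow(ev))
    sum(log(params$lambda * params$rho) +
        (params$rho - 1) * log(ev$stop) + params$alpha * ev$z) else 0
  shape <- 1 / params$theta
  rate <- shape + B
  # generalized Gauss-Laguerre with weight x^(shape+d-1) e^(-x): the
  # remaining factor is a pure exponential, integrated to near machine
  # precision at 64 nodes
  gl <- pracma::gaussLaguerre(n, shape + d - 1)
  ev_ll + shape * log(rate) - lgamma(shape) +
    log(sum(gl$w * exp(-gl$x * (A + rate - 1))))
}

# Trapezoid cumulative hazard oracle on a fine grid.
trapezoid_cumhaz <- function(t, c0, c1, alpha, v, lambda, rho,
                             n = 1e5) {
  s <- seq(0, t, length.out = n + 1)
  f <- lambda * rho * s^(rho - 1) * v * exp(alpha * (c0 + c1 * s))
  sum((f[-1] + f[-length(f)]) / 2 * diff(s))
}

# Small two-pair longitudinal set with known random effects.
toy_long <- function() {
  data.frame(pair_id = rep(1:2, each = 4),
             twin_id = rep(c(1, 1, 2, 2), 2),
             time = rep(c(0, 2), 4),
             y = c(1.2, 1.3, 0.9, 0.95, 1.05, 1.1, 1.0, 1.06))
}
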