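# Twin-pair data simulator: shared gamma frailty survival times with a
# linearly drifting marker in the hazard, uniform right censoring, delayed
# entry (left truncation), grid-based marker observation and Gaussian
# measurement error.

#' Simulation configuration
#'
#' Assembles and validates the parameters of the twin-pair generating
#' model. Defaults are the base scenario of the accompanying simulation
#' study: marker trajectory \eqn{M_{ij}(t) = \beta_0 + \beta_1 t + b_{ij} +
#' u_i} with subject random intercept \eqn{b_{ij} \sim N(0, \sigma_b^2)}
#' and pair-shared effect \eqn{u_i \sim N(0, \sigma_u^2)}; conditional
#' hazard \eqn{h_{ij}(t) = \lambda \rho t^{\rho-1} v_i
#' \exp\{\alpha M_{ij}(t)\}} with pair frailty \eqn{v_i \sim}
#' Gamma(mean 1, variance \eqn{\theta}); right censoring
#' \eqn{C \sim U[0, \texttt{censor\_upper}]}; entry age 0 with probability
#' \eqn{1 - \texttt{delay\_prob}}, else \eqn{U(0, \texttt{delay\_upper})};
#' marker observed as \eqn{y = M(t_k) + \varepsilon},
#' \eqn{\varepsilon \sim N(0, \sigma_\varepsilon^2)}.
#'
#' @param n_pairs number of pairs G simulated before truncation.
#' @param alpha marker effect on the log hazard.
#' @param beta0,beta1 fixed intercept and slope of the marker trajectory.
#' @param sigma_b,sigma_u,sigma_e SDs of the subject intercept, pair
#'   effect and measurement error (all >= 0).
#' @param theta frailty variance (>= 0; 0 means no frailty).
#' @param weibull_shape,weibull_scale Weibull baseline hazard
#'   \eqn{h_0(t) = \lambda \rho t^{\rho-1}}: shape \eqn{\rho} and scale
#'   \eqn{\lambda}, both > 0.
#' @param censor_upper upper bound of the uniform censoring window.
#' @param delay_prob probability that entry is delayed.
#' @param delay_upper upper bound of the uniform delayed-entry window.
#' @param grid observation-grid scheme: `list(type = "dense", gap = g)`
#'   for calendar-age measurements at 0, g, 2g, ... or
#'   `list(type = "sparse", max_k = K)` for a per-subject uniform number
#'   of 1..K irregular measurement times.
#' @param horizon search horizon for the event-time inversion; survival
#'   past the horizon is treated as censored-by-design.
#' @param seed master seed; per-pair substreams are derived from it so
#'   that enlarging `n_pairs` leaves earlier pairs unchanged.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 2000, alpha = 1, beta0 = 1, beta1 = 0.01,
                       sigma_b = 0.1, sigma_u = 0.1, sigma_e = 0,
                       theta = 0.5, weibull_shape = 2, weibull_scale = 0.001,
                       censor_upper = 15, delay_prob = 0.5, delay_upper = 5,
                       grid = list(type = "dense", gap = 2),
                       horizon = 200, seed = 1L) {
  cfg <- list(n_pairs = as.integer(n_pairs), alpha = alpha, beta0 = beta0,
              beta1 = beta1, sigma_b = sigma_b, sigma_u = sigma_u,
              sigma_e = sigma_e, theta = theta,
              weibull_shape = weibull_shape, weibull_scale = weibull_scale,
              censor_upper = censor_upper, delay_prob = delay_prob,
              delay_upper = delay_upper, grid = grid, horizon = horizon,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_pairs >= 1)
  num <- c("sigma_b", "sigma_u", "sigma_e", "theta")
  for (nm in num)
    if (cfg[[nm]] < 0) stop(sprintf("'%s' must be >= 0", nm))
  if (cfg$weibull_shape <= 0 || cfg$weibull_scale <= 0)
    stop("Weibull shape and scale must be > 0")
  if (cfg$delay_prob < 0 || cfg$delay_prob > 1)
    stop("'delay_prob' must lie in [0, 1]")
  if (cfg$delay_upper < 0) stop("'delay_upper' must be >= 0")
  if (cfg$censor_upper <= 0) stop("'censor_upper' must be > 0")
  if (cfg$horizon <= 0) stop("'horizon' must be > 0")
  g <- cfg$grid
  if (is.null(g$type) || !g$type %in% c("dense", "sparse"))
    stop("grid$type must be 'dense' or 'sparse'")
  if (g$type == "dense" && (is.null(g$gap) || g$gap <= 0))
    stop("dense grid requires gap > 0")
  if (g$type == "sparse" && (is.null(g$max_k) || g$max_k < 1))
    stop("sparse grid requires max_k >= 1")
  invisible(cfg)
}

# Deterministic derived seeds: pair i, stream s (1 = latent draws,
# 2 = observation grid + noise). Kept below 2^31 - 1; arithmetic stays
# within double precision.
derive_seed <- function(seed, i, stream = 1L) {
  ((seed %% 1000003) * 1103515245 + i * 12345 + stream * 7919) %% 2147483647
}

# Gauss-Legendre nodes, cached per node count.
.gl_cache <- new.env(parent = emptyenv())
gl_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]]))
    .gl_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  .gl_cache[[key]]
}

# Cumulative hazard H(t2) - H(t1) for hazard
# lambda*rho*s^(rho-1)*v*exp(alpha*(c0 + c1*s)), vectorised over subjects.
# The exponent is linear in s, so fixed-node Gauss-Legendre is accurate.
cumhaz_lin <- function(t1, t2, c0, c1, alpha, lambda, rho, v = 1,
                       n_nodes = 30) {
  gl <- gl_nodes(n_nodes)
  half <- (t2 - t1) / 2
  mid <- (t2 + t1) / 2
  s <- outer(half, gl$x) + mid          # n x q
  f <- s^(rho - 1) * exp((alpha * c1) * s)
  lambda * rho * v * exp(alpha * c0) * half * drop(f %*% gl$w)
}

#' Invert the cumulative hazard to obtain an event time
#'
#' Solves \eqn{H(t) = -\log w} for \eqn{t}, where
#' \eqn{H(t) = \int_0^t \lambda\rho s^{\rho-1} v
#' \exp\{\alpha(c_0 + c_1 s)\}\,ds} is the cumulative hazard of a subject
#' whose marker follows the line \eqn{c_0 + c_1 s} (inverse-transform
#' sampling with a time-varying covariate). Monotone bisection on
#' \eqn{[0, \texttt{horizon}]}; the integral uses Gauss-Legendre
#' quadrature, exact for the smooth linear-exponent integrand to
#' high order.
#'
#' @param w uniform(0,1) draw(s); the solved time satisfies
#'   \eqn{S(t) = w}.
#' @param c0,c1 intercept and slope of the marker line.
#' @param alpha marker effect.
#' @param v frailty value(s), > 0.
#' @param lambda,rho Weibull baseline scale and shape.
#' @param horizon upper search bound; `Inf` is returned when the total
#'   hazard over the horizon is below \eqn{-\log w} (survival beyond the
#'   horizon).
#' @return event time(s); `Inf` for beyond-horizon survival.
#' @export
solve_event_time <- function(w, c0, c1, alpha, v, lambda, rho,
                             horizon = 200) {
  stopifnot(all(w > 0), all(w < 1), all(v > 0), horizon > 0)
  n <- max(length(w), length(c0), length(c1), length(v))
  w <- rep_len(w, n); c0 <- rep_len(c0, n); c1 <- rep_len(c1, n)
  v <- rep_len(v, n)
  target <- -log(w)
  H_end <- cumhaz_lin(0, rep(horizon, n), c0, c1, alpha, lambda, rho, v)
  beyond <- H_end < target
  lo <- numeric(n)
  hi <- rep(horizon, n)
  for (it in seq_len(48L)) {
    mid <- (lo + hi) / 2
    Hm <- cumhaz_lin(0, mid, c0, c1, alpha, lambda, rho, v)
    up <- Hm < target
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  t <- (lo + hi) / 2
  t[beyond] <- Inf
  if (any(!beyond & !is.finite(t)))
    stop("event-time bisection failed to converge; inputs: ",
         paste(utils::head(which(!beyond & !is.finite(t))), collapse = ", "))
  t
}

#' Draw entry (left-truncation) ages
#'
#' Each subject enters at age 0 with probability `1 - delay_prob`,
#' otherwise at an age drawn uniformly on `(0, delay_upper)`.
#'
#' @param n number of draws.
#' @param delay_prob probability of delayed entry.
#' @param delay_upper upper bound of the delay window.
#' @return numeric vector of entry ages.
#' @export
draw_entry_time <- function(n, delay_prob = 0.5, delay_upper = 5) {
  delayed <- runif(n) < delay_prob
  t0raw <- runif(n, 0, delay_upper)
  ifelse(delayed, t0raw, 0)
}

#' Generate marker observation times for one subject
#'
#' Dense scheme: calendar ages `0, gap, 2*gap, ...` intersected with
#' `[entry, exit)`, with the entry age prepended when it is not itself a
#' grid point (every subject carries a marker value at entry, needed by
#' the delayed-entry frailty update). Sparse scheme: a uniform number
#' `K in {1, ..., max_k}` of times, the first at entry, the remaining
#' `K - 1` uniform on `(entry, exit)` and sorted.
#'
#' @param scheme `list(type = "dense", gap = )` or
#'   `list(type = "sparse", max_k = )`.
#' @param entry_age,exit_age observation window; `exit_age > entry_age`.
#' @return strictly increasing times starting at `entry_age`, all
#'   `< exit_age` (dense) or `<= exit_age` (sparse).
#' @export
generate_observation_grid <- function(scheme, entry_age, exit_age) {
  if (exit_age <= entry_age) return(entry_age)
  if (scheme$type == "dense") {
    gap <- scheme$gap
    k <- seq.int(ceiling(entry_age / gap), floor(exit_age / gap))
    t <- k[k >= 0] * gap
    t <- t[t >= entry_age & t < exit_age]
    if (!length(t) || t[1] > entry_age) t <- c(entry_age, t)
    t
  } else {
    K <- sample.int(scheme$max_k, 1L)
    if (K == 1L) return(entry_age)
    extra <- sort(runif(K - 1L, entry_age, exit_age))
    c(entry_age, extra)
  }
}

#' Simulate a twin-pair dataset
#'
#' Generates `n_pairs` pairs from the shared-frailty joint model of
#' [sim_config]: pair frailty, pair effect and subject intercepts are
#' drawn, event times are obtained by inverse-transform sampling
#' ([solve_event_time]), exit age is the minimum of event and censoring
#' times, entry ages are drawn, subjects whose exit does not exceed their
#' entry are excluded (left truncation; a subject censored before entry
#' is never enrolled), and only pairs with both members retained are
#' kept. Marker observations on the configured grid receive Gaussian
#' measurement error.
#'
#' Randomness is consumed through per-pair substreams derived from
#' `config$seed`, so the same seed reproduces the dataset byte for byte
#' and increasing `n_pairs` appends new pairs without altering existing
#' ones.
#'
#' @param config a [sim_config].
#' @param keep_latent also return the latent per-subject quantities
#'   (frailty, random effects, uncensored event time, censoring time,
#'   inclusion flag) for diagnostic use.
#' @return an object of class `twin_data`: list with data.frames
#'   `survival` (pair_id, twin_id, entry_age, exit_age, event) and
#'   `longitudinal` (pair_id, twin_id, time, y), the generating `truth`,
#'   and optionally `latent`.
#' @export
simulate_dataset <- function(config, keep_latent = FALSE) {
  validate_sim_config(config)
  G <- config$n_pairs
  # phase 1: latent draws, fixed order within each pair substream
  v <- numeric(G); u <- numeric(G)
  b <- matrix(0, G, 2); w <- matrix(0, G, 2)
  C <- matrix(0, G, 2); t0 <- matrix(0, G, 2)
  for (i in seq_len(G)) {
    set.seed(derive_seed(config$seed, i, 1L))
    v[i] <- if (config$theta > 0)
      rgamma(1, shape = 1 / config$theta, rate = 1 / config$theta) else 1
    u[i] <- rnorm(1, 0, config$sigma_u)
    b[i, ] <- rnorm(2, 0, config$sigma_b)
    w[i, ] <- runif(2)
    C[i, ] <- runif(2, 0, config$censor_upper)
    t0[i, ] <- draw_entry_time(2, config$delay_prob, config$delay_upper)
  }
  # phase 2: event times (vectorised bisection), truncation filter
  c0 <- config$beta0 + as.vector(t(b)) + rep(u, each = 2)
  Tlat <- solve_event_time(as.vector(t(w)), c0, config$beta1, config$alpha,
                           rep(v, each = 2), config$weibull_scale,
                           config$weibull_shape, config$horizon)
  Cv <- as.vector(t(C)); t0v <- as.vector(t(t0))
  exit <- pmin(Tlat, Cv)
  event <- as.integer(Tlat <= Cv)
  # beyond-horizon survivors are alive at the horizon, then censored by C
  exit[!is.finite(Tlat)] <- Cv[!is.finite(Tlat)]
  event[!is.finite(Tlat)] <- 0L
  included <- exit > t0v
  pair_ok <- included[c(TRUE, FALSE)] & included[c(FALSE, TRUE)]
  # phase 3: marker observations for retained pairs (own substream)
  keep <- which(pair_ok)
  lt <- ly <- lp <- lj <- vector("list", 2 * length(keep))
  for (ki in seq_along(keep)) {
    i <- keep[ki]
    set.seed(derive_seed(config$seed, i, 2L))
    for (j in 1:2) {
      idx <- 2 * (i - 1) + j
      tk <- generate_observation_grid(config$grid, t0v[idx], exit[idx])
      eps <- rnorm(length(tk), 0, config$sigma_e)
      slot <- 2 * (ki - 1) + j
      lt[[slot]] <- tk
      ly[[slot]] <- config$beta0 + config$beta1 * tk + b[i, j] + u[i] + eps
      lp[[slot]] <- rep.int(i, length(tk))
      lj[[slot]] <- rep.int(j, length(tk))
    }
  }
  sidx <- as.vector(rbind(2 * (keep - 1) + 1, 2 * keep))
  out <- list(survival = data.frame(pair_id = rep(keep, each = 2),
                                    twin_id = rep.int(1:2, length(keep)),
                                    entry_age = t0v[sidx],
                                    exit_age = exit[sidx],
                                    event = event[sidx]),
              longitudinal = data.frame(pair_id = unlist(lp),
                                        twin_id = unlist(lj),
                                        time = unlist(lt),
                                        y = unlist(ly)),
              truth = config)
  rownames(out$survival) <- rownames(out$longitudinal) <- NULL
  if (keep_latent)
    out$latent <- data.frame(pair_id = rep(seq_len(G), each = 2),
                             twin_id = rep(1:2, G), v = rep(v, each = 2),
                             u = rep(u, each = 2), b = as.vector(t(b)),
                             w = as.vector(t(w)),
                             T_latent = Tlat, censor = Cv, entry = t0v,
                             included = included,
                             pair_retained = rep(pair_ok, each = 2))
  class(out) <- "twin_data"
  out
}

#' @export
print.twin_data <- function(x, ...) {
  np <- length(unique(x$survival$pair_id))
  cat("twin_data:", np, "complete pairs,",
      nrow(x$survival), "subjects,",
      sum(x$survival$event), "events,",
      nrow(x$longitudinal), "marker observations\n")
  invisible(x)
}
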