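# Builders turning a twin dataset into counting-process (start-stop)
# tables with a piecewise-constant marker column, the common input of
# all frailty-likelihood fits.

#' LOCF start-stop table
#'
#' One row per inter-observation interval, carrying the last observed
#' marker value forward, plus a final row ending at the exit age; the
#' event indicator sits on the final row only. Every subject must have
#' an observation at its entry age (the simulator and readers guarantee
#' this), so the first row starts at entry and the entry marker value is
#' available for the delayed-entry frailty update.
#'
#' @param dataset a `twin_data` object.
#' @return data.frame with columns `pair_id`, `twin_id`, `start`,
#'   `stop`, `status`, `z`.
#' @export
build_locf_startstop <- function(dataset) {
  sv <- dataset$survival; lg <- dataset$longitudinal
  skey <- paste(sv$pair_id, sv$twin_id)
  lkey <- paste(lg$pair_id, lg$twin_id)
  missing_obs <- setdiff(skey, lkey)
  if (length(missing_obs))
    stop("subject(s) without marker observations: ",
         paste(head(missing_obs), collapse = ", "))
  lrows <- split(seq_len(nrow(lg)), factor(lkey, levels = unique(skey)))
  ls <- lp <- lw <- lz <- lst <- le <- vector("list", nrow(sv))
  for (i in seq_len(nrow(sv))) {
    rows <- lrows[[i]]
    rows <- rows[order(lg$time[rows])]
    tt <- lg$time[rows]
    if (abs(tt[1] - sv$entry_age[i]) > 1e-8)
      stop("first observation of subject ", skey[i],
           " is not at the entry age")
    br <- c(tt, sv$exit_age[i])
    keep <- diff(br) > 0
    nr <- sum(keep)
    ls[[i]] <- br[-length(br)][keep]
    le[[i]] <- br[-1][keep]
    lz[[i]] <- lg$y[rows][keep]
    lst[[i]] <- c(rep.int(0L, nr - 1), sv$event[i])
    lp[[i]] <- rep.int(sv$pair_id[i], nr)
    lw[[i]] <- rep.int(sv$twin_id[i], nr)
  }
  data.frame(pair_id = unlist(lp), twin_id = unlist(lw),
             start = unlist(ls), stop = unlist(le),
             status = unlist(lst), z = unlist(lz))
}

#' Dense calibration grid
#'
#' Equally spaced ages spanning the observed range (minimum entry to
#' maximum exit), used as the common prediction grid of the calibration
#' estimators; each subject's own entry and exit are inserted at table
#' construction time.
#'
#' @param dataset a `twin_data` object.
#' @param L number of grid points.
#' @return ascending numeric vector.
#' @export
dense_grid <- function(dataset, L = 100) {
  seq(min(dataset$survival$entry_age), max(dataset$survival$exit_age),
      length.out = L)
}

#' Calibrated start-stop table (ORC / RRC)
#'
#' Replaces the observed marker by mixed-model predictions on a dense
#' age grid: for subject (i, j) the grid points in `[entry, exit)` (with
#' entry inserted) define rows `[t_l, t_{l+1})` whose `z` is the
#' predicted marker at `t_l`, pair effect included; the final row ends
#' at exit and carries the event status. ORC predicts from the single
#' all-data fit; RRC predicts grid point `t_l` from the risk-set refit
#' at the latest refit time `<= t_l` (earliest refit before the first
#' one).
#'
#' @param dataset a `twin_data` object.
#' @param fit the all-data `lmm_fit` (ORC) -- also used by RRC as the
#'   fallback when no refit precedes a grid point.
#' @param grid ascending prediction ages; default [dense_grid].
#' @param method `"orc"` or `"rrc"`.
#' @param rrc_fits for `"rrc"`: the list returned by [rrc_refits].
#' @return start-stop data.frame as in [build_locf_startstop].
#' @export
build_calibrated_startstop <- function(dataset, fit, grid = NULL,
                                       method = c("orc", "rrc"),
                                       rrc_fits = NULL) {
  method <- match.arg(method)
  if (is.null(grid)) grid <- dense_grid(dataset)
  if (method == "rrc" && is.null(rrc_fits))
    stop("method 'rrc' needs the refits from rrc_refits()")
  sv <- dataset$survival
  rt <- if (method == "rrc") vapply(rrc_fits, attr, 0, "risk_time")
  out <- vector("list", nrow(sv))
  for (i in seq_len(nrow(sv))) {
    entry <- sv$entry_age[i]; exit <- sv$exit_age[i]
    pts <- grid[grid > entry & grid < exit]
    pts <- c(entry, pts)
    if (!length(pts))
      stop("no grid point covers subject ",
           paste(sv$pair_id[i], sv$twin_id[i]))
    z <- if (method == "orc") {
      predict_marker(fit, sv$pair_id[i], sv$twin_id[i], pts, TRUE)
    } else {
      idx <- findInterval(pts, rt)   # latest refit time <= t_l
      idx[idx == 0] <- 1L
      vapply(seq_along(pts), function(l)
        predict_marker(rrc_fits[[idx[l]]], sv$pair_id[i], sv$twin_id[i],
                       pts[l], TRUE), 0)
    }
    br <- c(pts, exit)
    nr <- length(pts)
    out[[i]] <- data.frame(pair_id = sv$pair_id[i],
                           twin_id = sv$twin_id[i],
                           start = br[-length(br)], stop = br[-1],
                           status = c(rep(0L, nr - 1), sv$event[i]),
                           z = z)
  }
  do.call(rbind, out)
}

#' Risk-set refits for RRC
#'
#' Fits the marker mixed model on the risk set at each unique event age
#' ([rrc_refit]); times whose risk set is too small or degenerate reuse
#' the nearest earlier refit, so the returned list always has one usable
#' fit per refit time.
#'
#' @param dataset a `twin_data` object.
#' @param structure mixed-model structure passed to [rrc_refit].
#' @param times refit ages; default the sorted unique event ages.
#' @param min_pairs smallest usable risk set.
#' @return list of `lmm_fit`s, each with attribute `risk_time`; an
#'   attribute `reused` records which times fell back to an earlier fit.
#' @export
rrc_refits <- function(dataset, structure = "intercept", times = NULL,
                       min_pairs = 10) {
  sv <- dataset$survival
  if (is.null(times))
    times <- sort(unique(sv$exit_age[sv$event == 1]))
  if (!length(times)) stop("no event times to refit at")
  fits <- vector("list", length(times))
  reused <- logical(length(times))
  for (k in seq_along(times)) {
    f <- rrc_refit(dataset$longitudinal, sv, times[k], structure,
                   min_pairs)
    if (is.null(f)) {
      prev <- if (k > 1) fits[[k - 1]] else NULL
      if (is.null(prev))
        f <- fit_lmm(dataset$longitudinal, structure)  # global fallback
      else f <- prev
      reused[k] <- TRUE
      attr(f, "risk_time") <- times[k]
    }
    fits[[k]] <- f
  }
  attr(fits, "reused") <- reused
  fits
}
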