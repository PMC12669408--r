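# CSV readers/writers and YAML scenario configuration. Dialect: comma
# separator, dot decimal, mandatory header. Ages are real-valued; no
# calendar handling.

#' Write a twin dataset to CSV
#'
#' Writes `survival.csv` (`pair_id,twin_id,entry_age,exit_age,event`)
#' and `longitudinal.csv` (`pair_id,twin_id,time,y`) into `dir`.
#'
#' @param dataset a `twin_data` object.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_twin_data <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(dataset$survival, file.path(dir, "survival.csv"),
            row.names = FALSE)
  write.csv(dataset$longitudinal, file.path(dir, "longitudinal.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a twin dataset from CSV
#'
#' Reads the two-file dialect of [write_twin_data] and validates it:
#' required columns, `exit_age > entry_age`, strictly increasing
#' observation times starting at the entry age. Pairs with a missing
#' member are dropped with a warning (analyses assume complete pairs).
#'
#' @param dir directory containing `survival.csv` and
#'   `longitudinal.csv`, or `survival` / `longitudinal` given directly.
#' @param survival,longitudinal optional explicit file paths.
#' @return a `twin_data` object.
#' @export
read_twin_data <- function(dir = NULL, survival = NULL,
                           longitudinal = NULL) {
  if (!is.null(dir)) {
    survival <- file.path(dir, "survival.csv")
    longitudinal <- file.path(dir, "longitudinal.csv")
  }
  sv <- read.csv(survival)
  lg <- read.csv(longitudinal)
  need_sv <- c("pair_id", "twin_id", "entry_age", "exit_age", "event")
  if (length(miss <- setdiff(need_sv, names(sv))))
    stop("survival file lacks column(s): ", paste(miss, collapse = ", "))
  need_lg <- c("pair_id", "twin_id", "time", "y")
  if (length(miss <- setdiff(need_lg, names(lg))))
    stop("longitudinal file lacks column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(sv$exit_age <= sv$entry_age)
  if (length(bad))
    stop("survival row(s) with exit_age <= entry_age: ",
         paste(head(bad), collapse = ", "))
  # complete pairs only
  cnt <- table(sv$pair_id)
  singles <- names(cnt)[cnt != 2]
  if (length(singles)) {
    warning(length(singles),
            " pair(s) without both members dropped: ",
            paste(head(singles), collapse = ", "))
    sv <- sv[!sv$pair_id %in% singles, ]
    lg <- lg[!lg$pair_id %in% singles, ]
  }
  # per-subject observation checks
  skey <- paste(sv$pair_id, sv$twin_id)
  lkey <- paste(lg$pair_id, lg$twin_id)
  for (i in seq_len(nrow(sv))) {
    rows <- which(lkey == skey[i])
    tt <- lg$time[rows][order(lg$time[rows])]
    if (!length(tt))
      stop("no marker observations for subject ", skey[i])
    if (any(diff(tt) <= 0))
      stop("non-increasing observation times for subject ", skey[i],
           " (longitudinal rows ",
           paste(head(rows), collapse = ", "), ")")
    if (tt[1] < sv$entry_age[i] - 1e-8 || tt[length(tt)] > sv$exit_age[i])
      stop("observation time outside [entry, exit] for subject ",
           skey[i])
  }
  structure(list(survival = sv, longitudinal = lg, truth = NULL),
            class = "twin_data")
}

#' Write / read a start-stop table
#'
#' CSV dialect `pair_id,twin_id,start,stop,status,z[,x...]`.
#'
#' @param table start-stop data.frame.
#' @param path file path.
#' @return `write_startstop`: the path, invisibly; `read_startstop`:
#'   the validated table.
#' @export
write_startstop <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_startstop
#' @export
read_startstop <- function(path) {
  tab <- read.csv(path)
  validate_startstop(tab)
  tab
}

sim_keys <- c("n_pairs", "alpha", "beta0", "beta1", "sigma_b", "sigma_u",
              "sigma_e", "theta", "weibull_shape", "weibull_scale",
              "censor_upper", "delay_prob", "delay_upper", "grid",
              "horizon", "seed")
scenario_keys <- c("sim", "methods", "n_reps", "base_seed", "grid_L",
                   "lmm_structure", "jm_nodes", "se")

#' Read a scenario configuration from YAML
#'
#' Parses a YAML file with an optional `sim:` block (keys of
#' [sim_config]) and top-level harness keys (`methods`, `n_reps`,
#' `base_seed`, `grid_L`, `lmm_structure`, `jm_nodes`, `se`). Unknown
#' keys are rejected; omitted keys take the package defaults, and the
#' effective configuration is returned so a run can be reproduced
#' exactly.
#'
#' @param path YAML file.
#' @return an [mc_scenario].
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (length(unk <- setdiff(names(raw), scenario_keys)))
    stop("unknown configuration key(s): ", paste(unk, collapse = ", "))
  simraw <- raw$sim
  if (length(unk <- setdiff(names(simraw), sim_keys)))
    stop("unknown sim key(s): ", paste(unk, collapse = ", "))
  sim <- do.call(sim_config, simraw)
  args <- raw[setdiff(names(raw), "sim")]
  args$sim <- sim
  do.call(mc_scenario, args)
}
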