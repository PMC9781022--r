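#' Write a trajectory in COLVAR-dialect text
#'
#' Whitespace-separated text with a `#! FIELDS time cv bias` header line
#' and one row per recorded step -- the plain-text time-series dialect used
#' by biased-MD post-processing tools.
#'
#' @param trajectory a [simulate_langevin()] result (or any object with
#'   `times`, `cv`, `bias`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_colvar <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time cv bias", con)
  writeLines(sprintf("%.12g %.12g %.12g", trajectory$times, trajectory$cv,
                     trajectory$bias), con)
  invisible(path)
}

#' Read a COLVAR-dialect file
#'
#' Parses the `#! FIELDS ...` header and the whitespace-separated columns.
#' Repeated headers (restarts) are tolerated: rows are merged keeping
#' monotone time, dropping any rewound segment prefix. A file without a
#' `bias` column is read as unbiased (bias 0) with a warning. The `time`
#' column and a CV column (named `cv`, or `cv_alias`) are required.
#'
#' @param path input file.
#' @param cv_alias optional alternative name of the CV column.
#' @param escaped logical carried onto the returned trajectory; files
#'   written by the fixture generator represent escaped runs (default
#'   `TRUE`).
#' @return An object of class `trajectory` (with `dt` inferred from the
#'   time column and `escape_step` set to the row count).
#' @export
read_colvar <- function(path, cv_alias = NULL, escaped = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr_idx <- grep("^#!\\s*FIELDS", lines)
  if (length(hdr_idx) == 0L)
    stop("format error: no '#! FIELDS' header in ", path, call. = FALSE)
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", lines[hdr_idx[1]]),
                     "\\s+")[[1]]
  cv_name <- if (!is.null(cv_alias)) cv_alias else "cv"
  if (!"time" %in% fields)
    stop("format error: missing required column 'time'", call. = FALSE)
  if (!cv_name %in% fields)
    stop("format error: missing required CV column '", cv_name,
         "' (use cv_alias for a differently named column)", call. = FALSE)
  has_bias <- "bias" %in% fields
  if (!has_bias)
    warning("no 'bias' column; reading as an unbiased run (bias = 0)")
  data_idx <- setdiff(seq_along(lines), grep("^#", lines))
  data_idx <- data_idx[nzchar(trimws(lines[data_idx]))]
  if (length(data_idx) == 0L)
    stop("format error: no data rows in ", path, call. = FALSE)
  # segment boundaries at repeated headers
  seg_of <- findInterval(data_idx, hdr_idx)
  parse_rows <- function(idx) {
    m <- do.call(rbind, lapply(strsplit(trimws(lines[idx]), "\\s+"),
                               as.numeric))
    if (ncol(m) != length(fields))
      stop("format error: row width does not match header", call. = FALSE)
    colnames(m) <- fields
    m
  }
  segs <- lapply(split(data_idx, seg_of), parse_rows)
  for (m in segs)
    if (is.unsorted(m[, "time"], strictly = TRUE))
      stop("format error: non-monotone time within a segment", call. = FALSE)
  merged <- segs[[1]]
  if (length(segs) > 1L) {
    for (m in segs[-1]) {
      m <- m[m[, "time"] > merged[nrow(merged), "time"], , drop = FALSE]
      merged <- rbind(merged, m)
    }
  }
  times <- merged[, "time"]
  if (is.unsorted(times, strictly = TRUE))
    stop("format error: non-monotone time after restart merge",
         call. = FALSE)
  dt <- if (length(times) > 1L) stats::median(diff(times)) else times[1]
  structure(list(times = unname(times), cv = unname(merged[, cv_name]),
                 bias = if (has_bias) unname(merged[, "bias"])
                        else numeric(length(times)),
                 seed = NA_integer_, escaped = escaped,
                 escape_step = length(times),
                 escape_position = unname(merged[nrow(merged), cv_name]),
                 n_steps = length(times), dt = dt, kT = 1,
                 method = if (has_bias) "biased" else "unbiased"),
            class = "trajectory")
}

#' Analyze a set of COLVAR files
#'
#' Reads one COLVAR-dialect file per run, rescales each to physical time,
#' and fits the release kinetics.
#'
#' @param paths character vector of files, or a single directory (all
#'   `*.colvar` files in it are used, sorted).
#' @param kT thermal energy used in the rescaling.
#' @param n_boot parametric-bootstrap replicates for the KS p-value
#'   (0 = off).
#' @param cv_alias forwarded to [read_colvar()].
#' @return A [fit_release_kinetics()] object with the per-event table in
#'   `$events`.
#' @export
analyze_colvar <- function(paths, kT = 1, n_boot = 0L, cv_alias = NULL) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "\\.colvar$",
                             full.names = TRUE))
  if (length(paths) == 0L) stop("no COLVAR files found", call. = FALSE)
  rows <- lapply(paths, function(p) {
    tr <- read_colvar(p, cv_alias = cv_alias)
    tr$kT <- kT
    # file convention: apparent run time = last recorded time + dt
    tr$escape_step <- length(tr$times)
    tr$dt <- if (length(tr$times) > 1L)
      (tr$times[length(tr$times)] + stats::median(diff(tr$times))) /
        length(tr$times)
    else tr$times[1]
    ev <- rescale_time(tr, kT = kT)
    data.frame(file = basename(p), t_md = ev$t_md,
               acceleration = ev$acceleration,
               physical_time = ev$physical_time, method = ev$method)
  })
  events <- do.call(rbind, rows)
  fit_release_kinetics(events, kT = kT, n_boot = n_boot,
                       method = "colvar_files")
}

# --- unit helpers -----------------------------------------------------------

.R_kcal <- 1.98720425864083e-3   # gas constant, kcal / (mol K)

#' Unit conversions for physically worded reporting
#'
#' The package works in reduced units (kT = 1, D0 = 1, dimensionless
#' lengths). These helpers convert energies between kcal/mol and kT at a
#' given temperature (default the physiological 310 K, where
#' kT ~ 0.616 kcal/mol) for reporting and for configs written in physical
#' units.
#'
#' @param temperature temperature in kelvin.
#' @param x energy value(s) to convert.
#' @return `kT_in_kcal_mol`: the value of kT in kcal/mol;
#'   `kcal_mol_to_kT` / `kT_to_kcal_mol`: converted energies.
#' @export
kT_in_kcal_mol <- function(temperature = 310) .R_kcal * temperature

#' @rdname kT_in_kcal_mol
#' @export
kcal_mol_to_kT <- function(x, temperature = 310) x / kT_in_kcal_mol(temperature)

#' @rdname kT_in_kcal_mol
#' @export
kT_to_kcal_mol <- function(x, temperature = 310) x * kT_in_kcal_mol(temperature)

# --- YAML configuration -----------------------------------------------------

.config_keys <- list(
  top = c("units", "scenario", "method", "engine", "output"),
  scenario = c("label", "overrides"),
  method = c("name", "e_cut", "gamma", "pace", "excluded", "n_components",
             "n_boot", "sigma"),
  engine = c("dt", "max_steps", "kT", "D0", "seed", "n_runs",
             "record_stride", "temperature"),
  output = c("dir", "stride"))

#' Read a run configuration
#'
#' YAML file with `scenario`, `method`, `engine` and `output` blocks.
#' Unknown keys are rejected. With `units: physical`, energies are given in
#' kcal/mol and converted to kT at `engine$temperature` (default 310 K) at
#' the config boundary; the default method cutoff in physical mode is
#' 7 kcal/mol and the default excluded region 8.5 length units, the
#' conventional flooding settings for a layered-host release problem.
#'
#' @param path YAML file.
#' @return A named list (class `run_config`) with all energies in kT.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  reject_unknown <- function(block, name) {
    extra <- setdiff(names(block), .config_keys[[name]])
    if (length(extra))
      stop("unknown key(s) in ", name, " block: ",
           paste(extra, collapse = ", "), call. = FALSE)
  }
  reject_unknown(cfg, "top")
  for (b in intersect(names(cfg), c("scenario", "method", "engine",
                                    "output")))
    reject_unknown(cfg[[b]], b)
  units <- if (is.null(cfg$units)) "reduced" else cfg$units
  if (!units %in% c("reduced", "physical"))
    stop("units must be 'reduced' or 'physical'", call. = FALSE)
  temperature <- cfg$engine$temperature
  if (is.null(temperature)) temperature <- 310
  if (units == "physical") {
    if (is.null(cfg$method$e_cut)) cfg$method$e_cut <- 7      # kcal/mol
    if (is.null(cfg$method$excluded)) cfg$method$excluded <- 8.5
    cfg$method$e_cut <- kcal_mol_to_kT(cfg$method$e_cut, temperature)
    if (!is.null(cfg$engine$kT))
      cfg$engine$kT <- kcal_mol_to_kT(cfg$engine$kT, temperature)
  }
  cfg$units <- units
  class(cfg) <- "run_config"
  cfg
}

#' Serialize a scenario to a YAML block
#'
#' Writes the scenario as its label plus the parameter table of its
#' surface and escape problem, sufficient to rebuild it with
#' [read_scenario_yaml()].
#'
#' @param scenario a [scenario_spec()].
#' @param path output file.
#' @return `path` invisibly, or the rebuilt scenario.
#' @export
write_scenario_yaml <- function(scenario, path) {
  obj <- list(label = scenario$label,
              surface = c(list(name = scenario$surface$name),
                          scenario$surface$params),
              start_position = scenario$start_position,
              absorbing_threshold = scenario$absorbing_threshold,
              kT = scenario$kT, D0 = scenario$D0,
              two_exit = scenario$two_exit,
              bound_region = scenario$bound_region)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  o <- yaml::read_yaml(path)
  surf <- switch(o$surface$name,
    double_well = make_double_well(o$surface$barrier_height,
                                   o$surface$well_separation),
    double_well_shifted = shift_surface(
      make_double_well(o$surface$barrier_height, o$surface$well_separation),
      o$surface$shift),
    interlayer_surrogate = make_interlayer_surrogate(
      o$surface$corrugation_depth, o$surface$corrugation_period,
      o$surface$edge_position, o$surface$solvation_drop,
      o$surface$edge_width),
    single_well = make_single_well(o$surface$depth, o$surface$width),
    stop("unknown surface name: ", o$surface$name, call. = FALSE))
  scenario_spec(surf, start_position = o$start_position,
                absorbing_threshold = o$absorbing_threshold,
                kT = o$kT, D0 = o$D0, label = o$label,
                two_exit = isTRUE(o$two_exit),
                bound_region = unlist(o$bound_region))
}
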