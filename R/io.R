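# configuration and tabular I/O

.config_schema <- list(
  geometry = c("n_subunits", "c_radius", "a_radius", "angle_aE162",
               "angle_aR176", "angle_aE223", "window_half_width",
               "edge_smooth"),
  energetics = c("B", "debye_length", "dist_floor", "eps_mem", "g_theta0",
                 "g_sigma", "reservoir_weight", "pKa_aE223", "pKa_aE162",
                 "background_amplitude", "background_n_fold",
                 "background_phase", "A_GLU", "r0_GLU", "pKa_GLU", "A_ASP",
                 "r0_ASP", "pKa_ASP"),
  environment = c("pH_IMS", "pH_matrix", "delta_psi",
                  "psi_fraction_at_ring", "mv_per_kT"),
  mutations = c("pattern"),
  run = c("rounds", "md_steps_per_round", "frames_per_round", "dt",
          "D_rot", "seed", "replicates", "profile")
)

#' Load and validate a simulation configuration file
#'
#' Reads a JSON or YAML configuration with sections `geometry`,
#' `energetics`, `environment`, `mutations` and `run`; every default of the
#' model is overridable and unknown keys are rejected.  An empty file gives
#' the full default configuration (6000 rounds of 1e5 MD steps, pH 7/8,
#' 150 mV, wild type).
#'
#' @param path Path to a `.json`, `.yaml`/`.yml` file.
#' @return List of class `fo_config` with the filled sections plus `model`
#'   (an [fo_model()]) and `sim` (an [fo_sim_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) list() else
      jsonlite::fromJSON(txt, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  } else stop("unsupported config format (use .json or .yaml): ", path)
  if (!is.list(raw)) stop("config must be a mapping of sections")
  validate_config(raw)
}

#' Validate a configuration list
#'
#' @param raw Nested list with any subset of the config sections.
#' @return As [load_config()].
#' @export
validate_config <- function(raw = list()) {
  bad_sections <- setdiff(names(raw), names(.config_schema))
  if (length(bad_sections))
    stop("schema error: unknown section(s): ",
         paste(bad_sections, collapse = ", "))
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), .config_schema[[sec]])
    if (length(bad))
      stop("schema error in [", sec, "]: unknown key(s): ",
           paste(bad, collapse = ", "))
  }
  gg <- raw$geometry
  geometry <- fo_geometry(
    n_subunits = gg$n_subunits %||% 10L,
    c_radius = gg$c_radius %||% 2.5, a_radius = gg$a_radius %||% 3.3,
    angle_aE162 = gg$angle_aE162 %||% -36,
    angle_aR176 = gg$angle_aR176 %||% 0,
    angle_aE223 = gg$angle_aE223 %||% 36,
    window_half_width = gg$window_half_width %||% 72,
    edge_smooth = gg$edge_smooth %||% 2)
  ee <- raw$energetics
  energetics <- fo_energetics(
    B = ee$B %||% 2.0, debye_length = ee$debye_length %||% 1.0,
    dist_floor = ee$dist_floor %||% 0.3, eps_mem = ee$eps_mem %||% 8.0,
    g_theta0 = ee$g_theta0 %||% 0, g_sigma = ee$g_sigma %||% 30,
    reservoir_weight = ee$reservoir_weight %||% 1.0,
    pKa_aE223 = ee$pKa_aE223 %||% 8.0, pKa_aE162 = ee$pKa_aE162 %||% 8.0,
    background_amplitude = ee$background_amplitude %||% 0,
    background_n_fold = ee$background_n_fold %||% 10L,
    background_phase = ee$background_phase %||% 0)
  glu <- fo_site_params("GLU", A = ee$A_GLU, r0 = ee$r0_GLU,
                        pKa = ee$pKa_GLU)
  asp <- fo_site_params("ASP", A = ee$A_ASP, r0 = ee$r0_ASP,
                        pKa = ee$pKa_ASP)
  vv <- raw$environment
  env <- fo_env(pH_IMS = vv$pH_IMS %||% 7.0,
                pH_matrix = vv$pH_matrix %||% 8.0,
                delta_psi = vv$delta_psi %||% 150,
                psi_fraction_at_ring = vv$psi_fraction_at_ring %||% 0.5,
                mv_per_kT = vv$mv_per_kT %||% 25.693)
  mutant <- raw$mutations$pattern %||% ""
  rr <- raw$run
  sim <- fo_sim_config(rounds = rr$rounds,
                       md_steps_per_round = rr$md_steps_per_round,
                       frames_per_round = rr$frames_per_round %||% 10L,
                       dt = rr$dt, D_rot = rr$D_rot %||% 1.4e-8,
                       seed = rr$seed %||% 1L, mutant = mutant,
                       profile = rr$profile %||% "paper")
  model <- fo_model(mutant, geometry = geometry, env = env,
                    energetics = energetics, glu = glu, asp = asp)
  structure(list(geometry = geometry, energetics = energetics,
                 environment = env, mutations = list(pattern = mutant),
                 run = sim, replicates = rr$replicates %||% 1L,
                 model = model, sim = sim, raw = raw),
            class = "fo_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_csv_meta <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  write.csv(df, con, row.names = FALSE)
}

.read_csv_meta <- function(path, colClasses = NA) {
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (l in lines[is_meta]) {
    m <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- m[3]
  }
  body <- lines[!is_meta]
  if (length(body) < 1L) stop("no tabular content in ", path)
  nfield <- count.fields(textConnection(body), sep = ",",
                         quote = "\"")
  if (any(nfield != nfield[1])) {
    bad <- which(nfield != nfield[1])[1]
    stop("malformed row in ", path, " at line ",
         which(!is_meta)[bad], ": expected ", nfield[1], " fields, found ",
         nfield[bad])
  }
  df <- read.csv(textConnection(body), stringsAsFactors = FALSE,
                 colClasses = colClasses)
  list(meta = meta, df = df)
}

#' Write / read a trajectory and its event log
#'
#' CSV with a `#`-prefixed metadata header; occupancy is stored as a
#' 12-character 0/1 string (site order `a`..`j`, `aE223`, `aE162`).  The
#' reader validates the columns and reports malformed rows with their line
#' numbers; `write_trajectory()` followed by [read_trajectory()] is the
#' identity on all fields.
#'
#' @param trajectory An `fo_trajectory`.
#' @param path Output CSV path for the frames.
#' @param events_path Output CSV for the events (default: `path` with
#'   `_events` suffix).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path,
                             events_path = .events_path(path)) {
  cfg <- trajectory$config
  meta <- list(package = "protonmotor",
               version = as.character(packageVersion("protonmotor")),
               mutant = cfg$mutant, seed = trajectory$seed,
               rounds = cfg$rounds,
               md_steps_per_round = cfg$md_steps_per_round,
               frames_per_round = cfg$frames_per_round,
               dt = cfg$dt, D_rot = cfg$D_rot, profile = cfg$profile)
  .write_csv_meta(trajectory$frames, path, meta)
  .write_csv_meta(trajectory$events, events_path, meta["seed"])
  invisible(path)
}

.events_path <- function(path) sub("(\\.[^.]+)?$", "_events\\1", path)

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, events_path = .events_path(path)) {
  fr <- .read_csv_meta(path, colClasses = c(occupancy = "character"))
  need <- c("frame", "md_step", "phi_deg_cum", "occupancy", "n_ims_in",
            "n_matrix_out")
  miss <- setdiff(need, names(fr$df))
  if (length(miss))
    stop("format error in ", path, ": missing column(s): ",
         paste(miss, collapse = ", "))
  occ <- as.character(fr$df$occupancy)
  badocc <- which(nchar(occ) != 12L | grepl("[^01]", occ))
  if (length(badocc))
    stop("format error in ", path, ": occupancy strings must be 12 x 0/1 ",
         "(first bad data row: ", badocc[1], ")")
  fr$df$occupancy <- occ
  ev <- if (file.exists(events_path)) .read_csv_meta(events_path)$df else
    .decorate_events(list(md_step = numeric(0), kind = integer(0),
                          subunit = integer(0), direction = integer(0),
                          outcome = integer(0), delta_energy = numeric(0)))
  m <- fr$meta
  cfg <- fo_sim_config(
    rounds = as.integer(m$rounds %||% 1),
    md_steps_per_round = as.integer(m$md_steps_per_round %||%
                                      max(fr$df$md_step, 1)),
    frames_per_round = as.integer(m$frames_per_round %||%
                                    max(nrow(fr$df), 1L)),
    dt = as.numeric(m$dt %||% 1), D_rot = as.numeric(m$D_rot %||% 1.4e-8),
    seed = as.integer(m$seed %||% 0), mutant = m$mutant %||% "",
    profile = m$profile %||% "paper")
  structure(list(frames = fr$df, events = ev, config = cfg,
                 model = fo_model(cfg$mutant),
                 seed = as.integer(m$seed %||% 0)),
            class = "fo_trajectory")
}

#' Run manifest
#'
#' Reproducibility record of a simulate/analyze invocation: configuration
#' echo, seeds, package version, timestamp and md5 checksums of the listed
#' files.
#'
#' @param config Any list-like configuration echo.
#' @param seeds Integer vector of seeds used.
#' @param files Character vector of input/output files to checksum.
#' @param path Optional JSON output path.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(config, seeds, files = character(0), path = NULL) {
  files <- files[file.exists(files)]
  man <- list(
    package = "protonmotor",
    version = as.character(packageVersion("protonmotor")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = as.integer(seeds),
    config = config,
    checksums = as.list(tools::md5sum(files))
  )
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, force = TRUE)
    return(invisible(man))
  }
  man
}
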