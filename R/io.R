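# CSV dialect for traces: comma separator, "." decimal, fixed header prefix
# t_ms,P_kPa,V_ml,Pao_kPa,phase (extra columns such as flows follow after).
# Unit-suffixed headers are validated on read and never silently rescaled.

trace_core_cols <- c("t_ms", "P_kPa", "V_ml", "Pao_kPa", "phase")

#' Write a pressure-volume trace as CSV
#'
#' @param trace An `lv_trace` tibble (or any data frame with the core
#'   columns `t_ms`, `P_kPa`, `V_ml`, `Pao_kPa`, `phase`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pv_trace <- function(trace, path) {
  if (!all(trace_core_cols %in% names(trace)))
    abort(sprintf("trace must have columns %s",
                  paste(trace_core_cols, collapse = ",")))
  extra <- setdiff(names(trace), trace_core_cols)
  cols <- c(trace_core_cols, extra)
  fmt <- function(x) {
    if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
  }
  body <- do.call(paste, c(purrr::map(cols, function(cc) fmt(trace[[cc]])),
                           sep = ","))
  writeLines(c(paste(cols, collapse = ","), body), path)
  invisible(path)
}

#' Read a pressure-volume trace from CSV
#'
#' Validates the unit-suffixed header (failing fast on a unit mismatch,
#' never rescaling), rejects malformed numeric fields with their line
#' number, and reports the last complete row when the file is truncated
#' mid-record.
#'
#' @param path CSV file path.
#' @return An `lv_trace` tibble.
#' @export
read_pv_trace <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) abort("trace file has no data rows")
  hdr <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(hdr) < 5 || !identical(hdr[1:5], trace_core_cols))
    abort(sprintf(
      "unexpected trace header '%s': expected it to start with '%s' (units are part of the contract)",
      lines[1], paste(trace_core_cols, collapse = ",")))
  n_col <- length(hdr)
  rows <- strsplit(lines[-1], ",", fixed = TRUE)
  n_fields <- lengths(rows)
  bad <- which(n_fields != n_col)
  if (length(bad)) {
    first_bad <- bad[1]
    abort(sprintf(
      "truncated or malformed record at line %d; last complete row is %d",
      first_bad + 1, first_bad - 1))
  }
  mat <- do.call(rbind, rows)
  out <- purrr::imap(setNames(seq_along(hdr), hdr), function(j, nm) {
    col <- mat[, j]
    if (nm == "phase") {
      factor(col, levels = c("filling", "isovolumic_contraction", "ejection",
                             "isovolumic_relaxation"))
    } else {
      x <- suppressWarnings(as.numeric(col))
      if (anyNA(x)) {
        abort(sprintf("non-numeric value in column '%s' at line %d", nm,
                      which(is.na(x))[1] + 1))
      }
      x
    }
  })
  tr <- as_tibble(out)
  class(tr) <- c("lv_trace", class(tr))
  tr
}

#' Write / read model parameters as JSON
#'
#' Round-trips parameter objects losslessly (doubles serialized at full
#' precision); the object class is recorded in a `type` field.
#'
#' @param params A `cell_params`, `circ_params`, `lo_params` object or a
#'   plain named list.
#' @param path JSON file path.
#' @return `path` invisibly ([write_params()]); the restored object
#'   ([read_params()]).
#' @export
write_params <- function(params, path) {
  payload <- unclass(params)
  payload$type <- paste(class(params), collapse = "/")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  type <- x$type
  x$type <- NULL
  if (identical(type, "list") || is.null(type)) return(x)
  cls <- strsplit(type, "/", fixed = TRUE)[[1]][1]
  switch(cls,
         cell_params = do.call(cell_params, x),
         circ_params = do.call(circ_params, x),
         lo_params = do.call(lo_params, x),
         structure(x, class = cls))
}

# deterministic 32-bit FNV-1a hash of a serialized R object, hex string.
# The multiply is split into 16-bit halves so every intermediate stays exact
# in doubles (R has no native 64-bit integers).
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    lo <- h %% 2^16
    hi <- (h - lo) / 2^16
    h <- xor_low_byte(lo, hi, b)
    lo <- h %% 2^16
    hi <- (h - lo) / 2^16
    h <- (lo * prime + ((hi * prime) %% 2^16) * 2^16) %% 2^32
  }
  lo <- h %% 2^16
  hi <- (h - lo) / 2^16
  sprintf("%04x%04x", as.integer(hi), as.integer(lo))
}

xor_low_byte <- function(lo, hi, b) {
  low8 <- lo %% 256
  hi * 2^16 + (lo - low8) + bitwXor(as.integer(low8), b)
}

#' Run configuration
#'
#' Bundles the parameter blocks and solver settings of a reproducible run.
#' Every block is validated on construction; the seed flows to all random
#' components (reference noise, training, sampling, cross-validation).
#'
#' @param cell A [cell_params()] object.
#' @param lo An [lo_params()] object.
#' @param circulation Named list of [circ_params()] objects (the active
#'   training conditions).
#' @param multi_element Optional [multi_config()].
#' @param solver A [solver_settings()] object.
#' @param passive_pressures Pressure grid (kPa) for the inflation protocol.
#' @param generator Reference generator mode: `"single_element"`,
#'   `"parallel"` or `"series"`.
#' @param noise_sd Optional additive Gaussian noise (sd, same units as the
#'   perturbed column) applied to the written reference bundle only.
#' @param seed Integer master seed.
#' @return A list of class `lv_config`.
#' @export
lv_config <- function(cell = cell_params(), lo = lo_params_normal(),
                      circulation = list(A1 = circ_preset("A1"),
                                         A2 = circ_preset("A2"),
                                         A3 = circ_preset("A3")),
                      multi_element = NULL,
                      solver = solver_settings(),
                      passive_pressures = seq(-0.5, 4, by = 0.25),
                      generator = c("single_element", "parallel", "series"),
                      noise_sd = 0, seed = 1L) {
  generator <- match.arg(generator)
  stopifnot(inherits(cell, "cell_params"), inherits(lo, "lo_params"),
            inherits(solver, "solver_settings"))
  if (!length(circulation) || !all(purrr::map_lgl(circulation, inherits,
                                                  "circ_params")))
    abort("circulation must be a non-empty list of circ_params")
  if (generator != "single_element") {
    if (is.null(multi_element)) {
      multi_element <- multi_config(mode = generator, base = lo, cell = cell)
    }
    stopifnot(inherits(multi_element, "multi_config"))
    if (multi_element$mode != generator)
      abort("multi_element mode disagrees with the generator mode")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  structure(list(cell = cell, lo = lo, circulation = circulation,
                 multi_element = multi_element, solver = solver,
                 passive_pressures = passive_pressures,
                 generator = generator, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "lv_config")
}

#' Generate a pseudo-high-fidelity reference bundle
#'
#' Simulates the configured generator (single-element oracle, or a parallel
#' or series multi-element model standing in for high-resolution
#' simulations) under the passive inflation protocol and each active
#' circulation, and writes the bundle: `passive.csv` (p, V), one
#' `active_<name>.csv` per circulation, and `metadata.json` sufficient to
#' regenerate the bundle bit-identically. Optional Gaussian noise is applied
#' to the written traces only, never inside simulations. Metadata also
#' records the volume-stretch linearity (R^2 of V against the reference
#' unit's mean stretch pooled across the active conditions), the
#' single-unit transform rationale.
#'
#' @param cfg An [lv_config()] object.
#' @param dir Output directory (created if missing).
#' @return A list of class `reference_bundle` with `passive`, `actives`,
#'   `circs`, `metadata`, `dir`.
#' @export
make_reference_bundle <- function(cfg, dir = tempfile("refbundle")) {
  stopifnot(inherits(cfg, "lv_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- cfg$generator
  if (gen == "single_element") {
    passive <- passive_inflation(cfg$lo, cfg$passive_pressures)
    actives <- purrr::map(cfg$circulation, function(hp)
      simulate_beats(cfg$lo, cfg$cell, hp, cfg$solver))
  } else {
    passive <- passive_inflation(cfg$multi_element, cfg$passive_pressures)
    actives <- purrr::map(cfg$circulation, function(hp)
      simulate_multi(cfg$multi_element, hp, cfg$solver))
  }
  conv <- purrr::map_lgl(actives, function(tr) isTRUE(attr(tr, "converged")))
  if (!all(conv))
    abort("reference generator did not reach steady state under all conditions")
  # linearity of volume vs mean unit stretch across active conditions
  vv <- unlist(purrr::map(actives, "V_ml"))
  ll <- unlist(purrr::map(actives, "lambda"))
  r2_lin <- summary(stats::lm(vv ~ ll))$r.squared
  if (cfg$noise_sd > 0) {
    actives <- withr::with_seed(cfg$seed, purrr::map(actives, function(tr) {
      tr$P_kPa <- tr$P_kPa + rnorm(nrow(tr), 0, cfg$noise_sd)
      tr$V_ml <- tr$V_ml + rnorm(nrow(tr), 0, cfg$noise_sd)
      tr
    }))
    passive$V_ml <- withr::with_seed(cfg$seed + 1L,
      passive$V_ml + rnorm(nrow(passive), 0, cfg$noise_sd))
  }
  pfile <- file.path(dir, "passive.csv")
  writeLines(c("p_kPa,V_ml",
               paste(sprintf("%.17g", passive$p_kPa),
                     sprintf("%.17g", passive$V_ml), sep = ",")), pfile)
  afiles <- purrr::imap(actives, function(tr, nm) {
    f <- file.path(dir, paste0("active_", nm, ".csv"))
    write_pv_trace(tr, f)
    f
  })
  me <- cfg$multi_element
  metadata <- list(
    generator = gen,
    n_sub = if (is.null(me)) 1L else me$n_sub,
    mu1_range = if (is.null(me)) NULL else me$mu1_range,
    w_range = if (is.null(me)) NULL else me$w_range,
    weight_beta = if (is.null(me)) NULL else isTRUE(me$weight_beta),
    noise_sd = cfg$noise_sd,
    seed = cfg$seed,
    stretch_volume_r_squared = r2_lin,
    circulations = purrr::map(cfg$circulation, unclass),
    passive_pressures = cfg$passive_pressures,
    config_hash = config_hash(cfg),
    package_version = as.character(packageVersion("lvreduce")))
  jsonlite::write_json(metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(passive = passive, actives = actives,
                 circs = cfg$circulation, metadata = metadata, dir = dir),
            class = "reference_bundle")
}

#' Read a reference bundle from disk
#'
#' @param dir Directory written by [make_reference_bundle()].
#' @return A `reference_bundle` list.
#' @export
read_reference_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  plines <- readLines(file.path(dir, "passive.csv"))
  if (plines[1] != "p_kPa,V_ml")
    abort("unexpected passive-curve header: expected 'p_kPa,V_ml'")
  pm <- do.call(rbind, strsplit(plines[-1], ",", fixed = TRUE))
  passive <- tibble(p_kPa = as.numeric(pm[, 1]), V_ml = as.numeric(pm[, 2]))
  afiles <- sort(list.files(dir, pattern = "^active_.*\\.csv$",
                            full.names = TRUE))
  actives <- purrr::map(afiles, read_pv_trace)
  names(actives) <- sub("^active_(.*)\\.csv$", "\\1", basename(afiles))
  circs <- purrr::map(meta$circulations, function(cc)
    circ_params(Pat0 = cc$Pat0, atrium_mode = cc$atrium_mode, Cat = cc$Cat,
                Rmv = cc$Rmv, R1 = cc$R1, R2 = cc$R2, R3 = cc$R3,
                Cwk = cc$Cwk))
  structure(list(passive = passive, actives = actives[names(circs)],
                 circs = circs, metadata = meta, dir = dir),
            class = "reference_bundle")
}

#' Write a reproducibility manifest
#'
#' Records the configuration hash, master seed and package version so a run
#' can be regenerated exactly.
#'
#' @param dir Output directory.
#' @param cfg An [lv_config()] object.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, cfg) {
  stopifnot(inherits(cfg, "lv_config"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(config_hash = config_hash(cfg), seed = cfg$seed,
         package_version = as.character(packageVersion("lvreduce"))),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' Scalar overrides of the default configuration blocks; unknown fields are
#' rejected by the block constructors.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return An [lv_config()] object.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(raw$cell)) args$cell <- do.call(cell_params, raw$cell)
  if (!is.null(raw$lo)) args$lo <- do.call(lo_params, raw$lo)
  if (!is.null(raw$circulation))
    args$circulation <- purrr::map(raw$circulation, function(cc)
      do.call(circ_params, cc))
  if (!is.null(raw$solver)) args$solver <- do.call(solver_settings, raw$solver)
  if (!is.null(raw$multi_element)) {
    me <- raw$multi_element
    me$base <- if (is.null(args$lo)) lo_params_normal() else args$lo
    me$cell <- if (is.null(args$cell)) cell_params() else args$cell
    args$multi_element <- do.call(multi_config, me)
  }
  for (f in c("passive_pressures", "generator", "noise_sd", "seed"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  do.call(lv_config, args)
}
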