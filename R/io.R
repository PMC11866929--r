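#' Write an RDF histogram to a plain-text file
#'
#' Two whitespace-separated columns (bin center, intensity) preceded by
#' comment lines carrying the grid metadata, so the file round-trips
#' identically through [read_rdf_file()].
#'
#' @param hist an [rdf_histogram()].
#' @param path output file path.
#' @param mode optional weighting-mode tag stored in the header.
#' @return `path`, invisibly.
#' @export
write_rdf_file <- function(hist, path, mode = "identical") {
  g <- hist$grid
  lines <- c(
    "# RDF (rdfbias)",
    sprintf("# B=%d delta=%.17g r_lo=%.17g mode=%s", g$b, g$delta, g$r_lo,
            mode),
    "# r g",
    sprintf("%.17g %.17g", grid_centers(g), hist$values))
  writeLines(lines, path)
  invisible(path)
}

#' Read an RDF histogram from a plain-text file
#'
#' Accepts the format written by [write_rdf_file()] (and any two-column
#' text table with `#` comments).  The bin spacing must be uniform to
#' 1e-9 relative; malformed rows are reported with their line number.
#'
#' @param path input file path.
#' @param grid optional [rdf_grid()] the file must match (hard error on
#'   mismatch, e.g. when a run config prescribes the binning).
#' @return an [rdf_histogram()]; attribute `mode` carries the header tag
#'   if present.
#' @export
read_rdf_file <- function(path, grid = NULL) {
  if (!file.exists(path)) stop("RDF file not found: ", path)
  raw <- readLines(path)
  if (length(raw) == 0) stop("empty RDF file: ", path)
  is_comment <- grepl("^\\s*#", raw) | grepl("^\\s*$", raw)
  data_idx <- which(!is_comment)
  if (length(data_idx) < 2)
    stop("RDF file has fewer than two data rows: ", path)
  parse_row <- function(i) {
    parts <- strsplit(trimws(raw[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) < 2 || anyNA(vals[1:2]))
      stop("malformed row at line ", i, " of ", path, ": '", raw[i], "'")
    vals[1:2]
  }
  tab <- t(vapply(data_idx, parse_row, numeric(2)))
  r <- tab[, 1]
  g <- tab[, 2]
  dr <- diff(r)
  delta <- stats::median(dr)
  if (any(abs(dr - delta) > 1e-9 * delta))
    stop("non-uniform bin spacing in ", path,
         " (max deviation ", signif(max(abs(dr - delta)), 3), ")")
  r_lo <- r[1] - delta / 2
  if (abs(r_lo) < 1e-12 * delta) r_lo <- 0
  file_grid <- rdf_grid(delta = delta, b = length(r), r_lo = r_lo)

  # header metadata, if present, must agree with the columns
  meta <- grep("^#\\s*B=", raw, value = TRUE)
  mode <- NA_character_
  if (length(meta) >= 1) {
    kv <- regmatches(meta[1],
                     gregexpr("[A-Za-z_]+=[^ ]+", meta[1]))[[1]]
    kv <- strsplit(kv, "=")
    keys <- vapply(kv, `[`, "", 1)
    vals <- vapply(kv, `[`, "", 2)
    hmeta <- setNames(vals, keys)
    if ("mode" %in% keys) mode <- hmeta[["mode"]]
    num <- function(k) as.numeric(hmeta[[k]])
    if (all(c("B", "delta", "r_lo") %in% keys)) {
      hgrid <- rdf_grid(delta = num("delta"), b = num("B"),
                        r_lo = num("r_lo"))
      if (!grids_equal(hgrid, file_grid, tol = 1e-6))
        stop("RDF header grid metadata disagrees with the data columns in ",
             path)
      file_grid <- hgrid  # header carries full precision; exact round trip
    }
  }
  if (!is.null(grid) && !grids_equal(grid, file_grid, tol = 1e-6))
    stop("RDF file grid (B=", file_grid$b, ", delta=", file_grid$delta,
         ", r_lo=", file_grid$r_lo, ") does not match the configured grid")
  h <- rdf_histogram(file_grid, g)
  attr(h, "mode") <- mode
  h
}

#' Write frames as extended XYZ
#'
#' One block per frame: atom count, a comment line with
#' `Lattice="ax 0 0 0 by 0 0 0 cz" Properties=species:S:1:pos:R:3
#' Time=...`, then one `species x y z` row per atom.  Unwrapped
#' trajectories are tagged `Unwrapped=T` so displacement analysis can
#' verify its input.
#'
#' @param frames an [md_frame()] or list of frames.
#' @param path output path.
#' @param unwrapped logical tag written to the header.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, unwrapped = FALSE) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$positions)
    lat <- sprintf('Lattice="%.17g 0 0 0 %.17g 0 0 0 %.17g"',
                   fr$box[1], fr$box[2], fr$box[3])
    hdr <- sprintf('%s Properties=species:S:1:pos:R:3 Time=%.17g%s', lat,
                   fr$time, if (unwrapped) " Unwrapped=T" else "")
    writeLines(as.character(n), con)
    writeLines(hdr, con)
    writeLines(sprintf("%s %.17g %.17g %.17g", fr$species,
                       fr$positions[, 1], fr$positions[, 2],
                       fr$positions[, 3]), con)
  }
  invisible(path)
}

#' Read extended-XYZ frames
#'
#' @param path input path (one or more concatenated frames).
#' @return list of [md_frame()]s; each carries attribute `unwrapped`
#'   (TRUE when the writer tagged the coordinates as unwrapped, in which
#'   case they are not re-wrapped on reading).
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  raw <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(raw)) {
    if (grepl("^\\s*$", raw[i])) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(raw[i])))
    if (is.na(n) || n < 1)
      stop("bad atom count at line ", i, " of ", path)
    if (i + 1 + n > length(raw))
      stop("truncated frame starting at line ", i, " of ", path)
    hdr <- raw[i + 1]
    lat <- regmatches(hdr, regexpr('Lattice="[^"]+"', hdr))
    if (length(lat) == 0)
      stop("missing Lattice=... in frame header at line ", i + 1, " of ",
           path)
    lv <- as.numeric(strsplit(sub('Lattice="([^"]+)"', "\\1", lat),
                              "\\s+")[[1]])
    if (length(lv) != 9 || anyNA(lv))
      stop("malformed Lattice at line ", i + 1, " of ", path)
    if (any(abs(lv[-c(1, 5, 9)]) > 1e-12))
      stop("only orthorhombic lattices are supported (line ", i + 1, ")")
    box <- lv[c(1, 5, 9)]
    tm <- regmatches(hdr, regexpr("Time=[-0-9.eE+]+", hdr))
    tm <- if (length(tm)) as.numeric(sub("Time=", "", tm)) else 0
    unwrapped <- grepl("Unwrapped=T", hdr, fixed = TRUE)
    rows <- strsplit(trimws(raw[(i + 2):(i + 1 + n)]), "\\s+")
    bad <- which(vapply(rows, length, 0L) < 4)
    if (length(bad))
      stop("malformed atom row at line ", i + 1 + bad[1], " of ", path)
    species <- vapply(rows, `[`, "", 1)
    pos <- t(vapply(rows, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(pos)) stop("non-numeric coordinates in frame at line ", i)
    fr <- md_frame(pos, box, species, time = tm, wrap = !unwrapped)
    attr(fr, "unwrapped") <- unwrapped
    frames[[length(frames) + 1]] <- fr
    i <- i + 2 + n
  }
  if (length(frames) == 0) stop("no frames found in ", path)
  frames
}

run_config_schema <- list(
  engine = c("species", "epsilon", "sigma", "cutoff", "mass", "dt",
             "temperature", "damp", "pressure", "ptau", "shift"),
  system = c("lattice", "cells", "density", "species"),
  bias = c("target_file", "gamma", "sample_every", "window", "equilibrate",
           "kappa_mode", "kappa_factor", "grid"),
  bias_grid = c("delta", "b", "r_lo"),
  weighting = c("mode", "factors"),
  output = c("dir", "prefix", "traj_every", "trace_every"),
  top = c("engine", "system", "bias", "weighting", "output", "seed",
          "n_steps"))

#' Read and validate a YAML run configuration
#'
#' Strict reader for the structured config used by the command-line
#' interface: unknown keys anywhere are rejected.  Recognised keys are
#' `engine.{species,epsilon,sigma,cutoff,mass,dt,temperature,damp,
#' pressure,ptau,shift}`, `system.{lattice,cells,density,species}`,
#' `bias.{target_file,gamma,sample_every,window,equilibrate,kappa_mode,
#' kappa_factor,grid.{delta,b,r_lo}}`, `weighting.{mode,factors.<species>}`,
#' `output.{dir,prefix,traj_every,trace_every}`, `seed` and `n_steps`.
#'
#' @param path YAML file path.
#' @return validated nested list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  reject_unknown <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop("unknown config key(s) in ", where, ": ",
           paste(extra, collapse = ", "))
  }
  reject_unknown(cfg, run_config_schema$top, "top level")
  if (!is.null(cfg$engine))
    reject_unknown(cfg$engine, run_config_schema$engine, "engine")
  if (!is.null(cfg$system))
    reject_unknown(cfg$system, run_config_schema$system, "system")
  if (!is.null(cfg$bias)) {
    reject_unknown(cfg$bias, run_config_schema$bias, "bias")
    if (!is.null(cfg$bias$grid))
      reject_unknown(cfg$bias$grid, run_config_schema$bias_grid,
                     "bias.grid")
  }
  if (!is.null(cfg$weighting))
    reject_unknown(cfg$weighting, run_config_schema$weighting, "weighting")
  if (!is.null(cfg$output))
    reject_unknown(cfg$output, run_config_schema$output, "output")
  structure(cfg, class = "run_config")
}

# materialise R objects from a validated config
config_from_run_config <- function(cfg) {
  e <- cfg$engine
  species <- e$species %||% cfg$system$species %||% "A"
  engine_config(
    species = species,
    epsilon = unlist_matrix(e$epsilon, length(species)) %||% 1,
    sigma = unlist_matrix(e$sigma, length(species)) %||% 1,
    cutoff = unlist_matrix(e$cutoff, length(species)) %||% 2.5,
    mass = e$mass %||% 1, dt = e$dt %||% 0.005,
    temperature = e$temperature %||% 1, damp = e$damp,
    pressure = e$pressure, ptau = e$ptau %||% 1,
    shift = e$shift %||% "energy")
}

unlist_matrix <- function(x, s) {
  if (is.null(x)) return(NULL)
  v <- unlist(x)
  if (length(v) == 1) return(as.numeric(v))
  matrix(as.numeric(v), s, s)
}

weighting_from_run_config <- function(cfg, species) {
  w <- cfg$weighting
  if (is.null(w) || is.null(w$mode) || w$mode == "identical")
    return(species_weighting())
  counts <- table(factor(species, levels = unique(species)))
  conc <- setNames(as.numeric(counts) / length(species), names(counts))
  if (w$mode == "frequency")
    return(species_weighting("frequency", names(conc),
                             concentrations = conc))
  f <- if (!is.null(w$factors)) unlist(w$factors)
       else atomic_scattering_factors(names(conc))
  xray_pair_weights(conc, f)
}

schedule_from_run_config <- function(cfg) {
  b <- cfg$bias
  if (is.null(b)) stop("config has no bias section")
  bias_schedule(gamma = b$gamma %||% 1,
                sample_every = b$sample_every %||% 10,
                window = b$window %||% 100,
                equilibrate = b$equilibrate %||% 0,
                kappa_mode = b$kappa_mode %||% "none",
                kappa_factor = b$kappa_factor %||% 1)
}

grid_from_run_config <- function(cfg) {
  g <- cfg$bias$grid
  if (is.null(g)) stop("config has no bias.grid section")
  rdf_grid(delta = g$delta, b = g$b, r_lo = g$r_lo %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
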