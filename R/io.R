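# Readers and writers: multi-page TIFF stacks with plain-text metadata
# sidecars, lookup tables, run configuration, and CSV outputs.
#
# TIFF pages are stored normalised to [0, 1] (quantised to 32-bit); the
# affine scale (scale_lo / scale_hi) lives in the sidecar and is applied on
# read, so round trips reproduce the stored values exactly. Sidecars are
# human-readable YAML key/value files rather than embedded TIFF tags.

write_tiff_scaled <- function(frames, path) {
  lo <- min(vapply(frames, min, numeric(1)))
  hi <- max(vapply(frames, max, numeric(1)))
  if (hi <= lo) hi <- lo + 1
  q <- 2^32 - 1
  pages <- lapply(frames, function(f) round((f - lo) / (hi - lo) * q) / q)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  c(lo = lo, hi = hi)
}

read_tiff_scaled <- function(path, lo, hi) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) p * (hi - lo) + lo)
}

default_sidecar <- function(path) paste0(path, ".yml")

#' Write a frame stack to a multi-page TIFF with sidecar metadata
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF path.
#' @param sidecar Metadata file path (default `path` + `.yml`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, sidecar = default_sidecar(path)) {
  stopifnot(inherits(stack, "warp_frame_stack"))
  sc <- write_tiff_scaled(stack$frames, path)
  meta <- c(list(kind = "frame_stack",
                 n_frames = length(stack$frames),
                 pixel_size_um = stack$pixel_size,
                 scale_lo = unname(sc["lo"]), scale_hi = unname(sc["hi"]),
                 wavelengths_nm = stack$wavelengths,
                 timestamps_s = stack$timestamps),
            stack$meta)
  yaml::write_yaml(meta, sidecar)
  invisible(path)
}

required_stack_keys <- c("kind", "pixel_size_um", "scale_lo", "scale_hi",
                         "wavelengths_nm", "timestamps_s")

#' Read a frame stack written by [write_stack()]
#'
#' Validates that the sidecar carries all required keys and that the
#' wavelength labels alternate strictly (a broken sequence reports the
#' offending frame).
#'
#' @param path TIFF path.
#' @param sidecar Metadata file path.
#' @return A [frame_stack()].
#' @export
read_stack <- function(path, sidecar = default_sidecar(path)) {
  if (!file.exists(sidecar))
    stop("missing metadata sidecar '", sidecar, "'; required keys: ",
         paste(required_stack_keys, collapse = ", "))
  meta <- yaml::read_yaml(sidecar)
  miss <- setdiff(required_stack_keys, names(meta))
  if (length(miss))
    stop("sidecar is missing required keys: ", paste(miss, collapse = ", "))
  frames <- read_tiff_scaled(path, meta$scale_lo, meta$scale_hi)
  extra <- meta[setdiff(names(meta),
                        c(required_stack_keys, "n_frames"))]
  frame_stack(frames, as.numeric(meta$wavelengths_nm),
              as.numeric(meta$timestamps_s), meta$pixel_size_um,
              meta = extra)
}

#' Write displacement maps as a multi-page float TIFF
#'
#' Values are stored in nm (scaled; the affine scale is recorded in the
#' sidecar together with pixel size and frame times). Per-pixel quality
#' flags are written alongside as a second TIFF when `flags = TRUE`.
#'
#' @param maps A [displacement_map()] or list of them.
#' @param path Output TIFF path.
#' @param sidecar Metadata file path.
#' @param times Optional frame times (s).
#' @param flags Also write a `<path>.flags.tif` stack of quality flags.
#' @return `path`, invisibly.
#' @export
write_displacement_stack <- function(maps, path,
                                     sidecar = default_sidecar(path),
                                     times = NULL, flags = FALSE) {
  if (inherits(maps, "displacement_map")) maps <- list(maps)
  stopifnot(all(vapply(maps, inherits, TRUE, "displacement_map")))
  sc <- write_tiff_scaled(lapply(maps, `[[`, "values"), path)
  meta <- list(kind = "displacement_stack", units = "nm",
               n_frames = length(maps),
               pixel_size_um = maps[[1]]$pixel_size,
               scale_lo = unname(sc["lo"]), scale_hi = unname(sc["hi"]))
  if (!is.null(times)) meta$timestamps_s <- times
  yaml::write_yaml(meta, sidecar)
  if (flags)
    write_tiff_scaled(lapply(maps, function(m) m$flags / 2),
                      paste0(path, ".flags.tif"))
  invisible(path)
}

#' Read a displacement stack written by [write_displacement_stack()]
#'
#' @param path TIFF path.
#' @param sidecar Metadata file path.
#' @return A list of [displacement_map()]s with a `times` attribute.
#' @export
read_displacement_stack <- function(path, sidecar = default_sidecar(path)) {
  if (!file.exists(sidecar)) stop("missing metadata sidecar '", sidecar, "'")
  meta <- yaml::read_yaml(sidecar)
  pages <- read_tiff_scaled(path, meta$scale_lo, meta$scale_hi)
  maps <- lapply(pages, displacement_map, pixel_size = meta$pixel_size_um)
  attr(maps, "times") <- if (!is.null(meta$timestamps_s))
    as.numeric(meta$timestamps_s)
  maps
}

#' Assemble a run configuration
#'
#' All pipeline parameters in one serialisable object: wavelengths,
#' refractive index, pixel size, frame rate, rest thickness, substrate
#' stiffness, flat reference region, filter bands, output directory, seed
#' and log level. A single seed drives every source of randomness in a run.
#'
#' @param lambda1,lambda2 Illumination wavelengths (nm).
#' @param refractive_index Cavity medium index.
#' @param pixel_size_um Pixel pitch (um).
#' @param frame_rate_hz Acquisition rate (Hz).
#' @param d0_nm Rest cavity thickness (nm).
#' @param stiffness_pa Substrate apparent stiffness (Pa).
#' @param flat_region Flat reference region `c(row0, col0, row1, col1)`.
#' @param band_um Spatial band-pass wavelengths `c(low, high)` (um).
#' @param highpass_hz Temporal high-pass cutoff (Hz).
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param log_level One of `"quiet"`, `"info"`, `"debug"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(lambda1 = 628, lambda2 = 633, refractive_index = 1.40,
                       pixel_size_um = 0.3, frame_rate_hz = 100,
                       d0_nm = 8000, stiffness_pa = 5000,
                       flat_region = NULL, band_um = c(0.5, 5),
                       highpass_hz = 0.2, out_dir = ".", seed = 1L,
                       log_level = "info") {
  cfg <- list(lambda1 = lambda1, lambda2 = lambda2,
              refractive_index = refractive_index,
              pixel_size_um = pixel_size_um, frame_rate_hz = frame_rate_hz,
              d0_nm = d0_nm, stiffness_pa = stiffness_pa,
              flat_region = flat_region, band_um = band_um,
              highpass_hz = highpass_hz, out_dir = out_dir,
              seed = as.integer(seed), log_level = log_level)
  num <- c("lambda1", "lambda2", "refractive_index", "pixel_size_um",
           "frame_rate_hz", "d0_nm", "stiffness_pa")
  for (k in num) if (cfg[[k]] <= 0) stop("'", k, "' must be positive")
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path File path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Hash of a run configuration
#'
#' MD5 digest of the serialised configuration, recorded in every output
#' header so results can be traced to the exact parameter set.
#'
#' @param cfg A [run_config()].
#' @return Hex digest string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Write pipeline outputs with provenance headers
#'
#' Writes displacement stacks (TIFF + sidecar), traces and tables (CSV with
#' a comment header recording the package version and config hash) and a
#' run log listing every parameter, into `cfg$out_dir`.
#'
#' @param cfg A [run_config()].
#' @param maps Optional list of [displacement_map()]s.
#' @param traces Optional named list of [time_trace()]s.
#' @param tables Optional named list of data frames.
#' @return Character vector of files written, invisibly.
#' @export
write_outputs <- function(cfg, maps = NULL, traces = NULL, tables = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(cfg$out_dir)) stop("cannot create '", cfg$out_dir, "'")
  hash <- config_hash(cfg)
  ver <- as.character(utils::packageVersion("warpmic"))
  header <- c(sprintf("# warpmic %s", ver),
              sprintf("# config_hash: %s", hash))
  written <- character(0)
  write_csv_hdr <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.csv(df, con, row.names = FALSE)
    path
  }
  if (!is.null(maps)) {
    p <- file.path(cfg$out_dir, "displacement.tif")
    write_displacement_stack(maps, p)
    written <- c(written, p)
  }
  for (nm in names(traces)) {
    tr <- traces[[nm]]
    p <- write_csv_hdr(data.frame(time_s = tr$t, value = tr$values,
                                  unit = tr$unit),
                       file.path(cfg$out_dir, paste0(nm, ".csv")))
    written <- c(written, p)
  }
  for (nm in names(tables)) {
    p <- write_csv_hdr(tables[[nm]],
                       file.path(cfg$out_dir, paste0(nm, ".csv")))
    written <- c(written, p)
  }
  log_path <- file.path(cfg$out_dir, "run.log")
  flat <- vapply(unclass(cfg), function(x)
    paste(format(x), collapse = " "), character(1))
  writeLines(c(header, sprintf("%s: %s", names(flat), flat)), log_path)
  invisible(c(written, log_path))
}
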