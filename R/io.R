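#' Write an image stack as a multi-page grayscale TIFF
#'
#' Frames are stored as 32-bit float TIFF pages, scaled into `[0, 1]`
#' by the stack maximum; the scale factor and the acquisition metadata
#' (pixel size, frame schedule, free-form keys) go into a flat
#' `key: value` sidecar file at `<path>.meta`.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @param bits 16 or 32 bits per sample (default 32, stored as float).
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path, bits = 32) {
  stopifnot(inherits(stack, "image_stack"))
  if (!bits %in% c(16L, 32L)) stopf("bits must be 16 or 32")
  scale <- max(stack$frames, 1e-12)
  pages <- lapply(seq_len(dim(stack$frames)[1]),
                  function(k) stack$frames[k, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)

  meta <- c(list(pixel_size = stack$pixel_size, intensity_scale = scale),
            if (!is.null(stack$schedule))
              stack$schedule[c("n_pre", "t_bleach", "n_post", "dt")],
            lapply(stack$metadata, function(v) paste(v, collapse = ",")))
  writeLines(sprintf("%s: %s", names(meta), vapply(meta, format, "")),
             paste0(path, ".meta"))
  invisible(path)
}

#' Read a multi-page grayscale TIFF as an image stack
#'
#' @param path TIFF path; a `<path>.meta` sidecar written by
#'   [write_stack()] is merged when present.
#' @param pixel_size um/px, used when no sidecar is found.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2, logical(1))))
    stopf("%s is not single-channel grayscale (RGB or multi-sample pages)", path)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("%s has inconsistent page shapes", path)

  meta <- read_sidecar(paste0(path, ".meta"))
  scale <- as.numeric(meta$intensity_scale %||% 1)
  ps <- as.numeric(meta$pixel_size %||% pixel_size %||%
                     stopf("pixel_size not in sidecar; supply it explicitly"))
  schedule <- if (all(c("n_pre", "t_bleach", "n_post", "dt") %in% names(meta)))
    frame_schedule(as.numeric(meta$n_pre), as.numeric(meta$t_bleach),
                   as.numeric(meta$n_post), as.numeric(meta$dt)) else NULL

  frames <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (k in seq_along(pages)) frames[k, , ] <- pages[[k]] * scale

  extra <- meta[setdiff(names(meta),
                        c("pixel_size", "intensity_scale",
                          "n_pre", "t_bleach", "n_post", "dt"))]
  if (!is.null(extra$center_um))
    extra$center_um <- as.numeric(strsplit(extra$center_um, ",")[[1]])
  if (!is.null(extra$spot_radius_um))
    extra$spot_radius_um <- as.numeric(extra$spot_radius_um)
  if (!is.null(extra$membrane_radius_um))
    extra$membrane_radius_um <- as.numeric(extra$membrane_radius_um)
  image_stack(frames, ps, schedule, metadata = extra)
}

read_sidecar <- function(path) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  read_sidecar_lines(lines, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a FRAP trace as CSV
#'
#' Columns `frame,time_s,intensity,phase` with phase in
#' `{pre, bleach, post}` (this package writes `pre` and `post` only;
#' the bleach pulse is not imaged).
#'
#' @param trace a [frap_trace()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  df <- data.frame(frame = seq_along(trace$times), time_s = trace$times,
                   intensity = trace$intensities, phase = trace$phase)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a FRAP trace from CSV
#'
#' Expects the header `frame,time_s,intensity,phase`; extra columns
#' are ignored with a warning, `bleach` rows are dropped (the pulse is
#' not part of the analyzed trace), and the frame schedule is
#' reconstructed from the times and phases.
#'
#' @param path CSV path.
#' @param w bleach-spot radius (um) for the trace geometry.
#' @param area observed membrane disc area (um^2); `Inf` when unknown.
#' @param condition,vesicle_id optional labels.
#' @return A [frap_trace()].
#' @export
read_trace_csv <- function(path, w = 2, area = Inf,
                           condition = NA_character_,
                           vesicle_id = NA_character_) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("frame", "time_s", "intensity", "phase")
  if (!all(needed %in% names(df)))
    stopf("%s: missing column(s) %s", path,
          paste(setdiff(needed, names(df)), collapse = ", "))
  extra <- setdiff(names(df), needed)
  if (length(extra))
    warnf("%s: ignoring extra column(s) %s", path, paste(extra, collapse = ", "))
  if (any(diff(df$time_s) <= 0)) stopf("%s: time_s must be strictly increasing", path)
  if (!all(df$phase %in% c("pre", "bleach", "post")))
    stopf("%s: phase must be one of pre, bleach, post", path)

  df <- df[df$phase != "bleach", , drop = FALSE]
  n_pre <- sum(df$phase == "pre")
  n_post <- sum(df$phase == "post")
  if (n_pre < 8)
    stopf("%s: %d pre-bleach frames; the analysis requires >= 8", path, n_pre)
  if (n_post < 8)
    stopf("%s: %d recovery frames; the analysis requires >= 8", path, n_post)
  post_t <- df$time_s[df$phase == "post"]
  dt <- median(diff(post_t))
  t_bleach <- max(0, -max(df$time_s[df$phase == "pre"]))
  sched <- frame_schedule(n_pre, t_bleach, n_post, dt)
  frap_trace(df$time_s, df$intensity, sched,
             spot_geometry(w, area, t_bleach),
             phase = df$phase, condition = condition, vesicle_id = vesicle_id)
}

#' Read a flat key:value run configuration file
#'
#' One `key: value` pair per line; `#` starts a comment.  Known keys
#' are typed and validated with messages naming the offending key;
#' unknown keys raise an error.
#'
#' @param path configuration file path.
#' @return A named list of typed values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  raw <- read_sidecar_lines(lines, path)

  spec <- list(
    pixel_size = "num", n_pre = "int", t_bleach = "num", n_post = "int",
    dt = "num", w = "num", D_true = "num", beta = "num", M_true = "num",
    F_pre = "num", sigma_noise = "num", reservoir_radius = "num",
    curve_model = "chr", seed = "int", n = "int", n_per_condition = "int",
    conditions = "chr_list", area_ratio_min = "num", pulse_ratio_max = "num",
    mobile_min = "num", movement_max_displacement = "num",
    brightness_per_unit = "num", n_per_group = "int", system = "chr")
  unknown <- setdiff(names(raw), names(spec))
  if (length(unknown))
    stopf("unknown configuration key '%s' in %s", unknown[1], path)
  out <- list()
  for (key in names(raw)) {
    val <- trimws(raw[[key]])
    out[[key]] <- switch(spec[[key]],
      num = {
        v <- suppressWarnings(as.numeric(val))
        if (is.na(v)) stopf("key '%s' must be numeric, got '%s'", key, val)
        v
      },
      int = {
        v <- suppressWarnings(as.integer(val))
        if (is.na(v)) stopf("key '%s' must be an integer, got '%s'", key, val)
        v
      },
      chr = val,
      chr_list = trimws(strsplit(val, ",")[[1]]))
  }
  out
}

read_sidecar_lines <- function(lines, path) {
  kv <- regmatches(lines, regexec("^([^:]+):[[:space:]]*(.*)$", lines))
  bad <- lines[vapply(kv, length, 0L) != 3]
  if (length(bad)) stopf("malformed line in %s: '%s'", path, trimws(bad[1]))
  setNames(lapply(kv, `[`, 3), trimws(vapply(kv, `[`, "", 2)))
}
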