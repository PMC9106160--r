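# Minimal C3D support: the Intel (processor type 84), floating-point storage
# subset of the standard, which covers files exported by common mocap
# pipelines. Points are stored in metres; analog channels carry per-belt
# vertical force. Integer-scaled storage, DEC/MIPS byte orders and
# multi-section parameter exotica are out of scope and rejected with a
# format error.

C3D_BLOCK <- 512L
C3D_PROC_INTEL <- 84L

#' Read a C3D motion-capture file
#'
#' Parses the header, parameter and data sections of a C3D file (Intel byte
#' order, floating-point storage) into a [marker_trial()] and, when analog
#' channels are present, a [force_trial()]. Analog channels named
#' `Fz_<side>` (any case) populate the force trial's sides; other channels
#' are kept under their own names.
#'
#' @param path file path.
#' @param axis_map lab-frame convention for the returned marker trial, see
#'   [marker_trial()]. The C3D standard does not fix the lab frame, so
#'   confirm this against the recording system.
#' @param require_tibia error unless at least one tibia marker pair
#'   (LTIB/LTIBI or RTIB/RTIBI) is present (default `TRUE`).
#' @return list with elements `markers` (a [marker_trial()]) and `force`
#'   (a [force_trial()] or `NULL` when the file has no analog channels).
#' @export
read_c3d <- function(path, axis_map = list(vertical = "Z", forward = "Y"),
                     require_tibia = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 2L * C3D_BLOCK || raw[2L] != as.raw(0x50)) {
    stop("format error: not a C3D file (missing 0x50 magic byte)",
         call. = FALSE)
  }
  rd_u8 <- function(i) as.integer(raw[i])
  rd_i8 <- function(i) {
    v <- as.integer(raw[i]); ifelse(v > 127L, v - 256L, v)
  }
  rd_i16 <- function(i) readBin(raw[i:(i + 1L)], "integer", size = 2L,
                                endian = "little")
  rd_f32 <- function(i, n = 1L) readBin(raw[i:(i + 4L * n - 1L)], "double",
                                        n = n, size = 4L, endian = "little")
  param_block <- rd_u8(1L)
  n_points <- rd_i16(3L)
  analog_per_frame <- rd_i16(5L)          # channels x subsamples
  first_frame <- rd_i16(7L)
  last_frame <- rd_i16(9L)
  point_scale <- rd_f32(13L)
  data_block <- rd_i16(17L)
  analog_sub <- rd_i16(19L)               # subsamples per 3D frame
  point_rate <- rd_f32(21L)
  if (point_scale >= 0) {
    stop("format error: integer-scaled C3D data is not supported ",
         "(POINT:SCALE >= 0)", call. = FALSE)
  }
  p0 <- (param_block - 1L) * C3D_BLOCK
  proc <- rd_u8(p0 + 4L)
  if (proc != C3D_PROC_INTEL) {
    stop("format error: unsupported processor type ", proc,
         " (only Intel/84 is supported)", call. = FALSE)
  }
  params <- parse_c3d_params(raw, p0, rd_i8, rd_i16, rd_f32)
  n_frames <- last_frame - first_frame + 1L
  n_chan <- if (analog_sub > 0L) analog_per_frame %/% analog_sub else 0L
  stride <- 4L * n_points + analog_sub * n_chan
  d0 <- (data_block - 1L) * C3D_BLOCK + 1L
  dat <- readBin(raw[d0:length(raw)], "double", n = stride * n_frames,
                 size = 4L, endian = "little")
  if (length(dat) < stride * n_frames) {
    stop("format error: truncated C3D data section", call. = FALSE)
  }
  dm <- matrix(dat, nrow = stride)
  labels <- c3d_param(params, "POINT", "LABELS")
  if (is.null(labels) || length(labels) < n_points) {
    labels <- c(labels, sprintf("P%03d", seq_len(n_points)))[seq_len(n_points)]
  }
  labels <- trimws(labels[seq_len(n_points)])
  markers <- lapply(seq_len(n_points), function(m) {
    t(dm[(m - 1L) * 4L + 1:3, , drop = FALSE])
  })
  names(markers) <- labels
  trial_id <- sub("\\.c3d$", "", basename(path), ignore.case = TRUE)
  if (isTRUE(require_tibia)) {
    tib <- c("LTIB", "LTIBI", "RTIB", "RTIBI")
    if (!any(tib %in% labels)) {
      stop("no tibia markers (LTIB/LTIBI/RTIB/RTIBI) in C3D file; ",
           "available labels: ", paste(labels, collapse = ", "),
           call. = FALSE)
    }
  }
  mk <- marker_trial(markers, fs = point_rate, trial_id = trial_id,
                     axis_map = axis_map)
  force <- NULL
  if (n_chan > 0L) {
    alab <- trimws(c3d_param(params, "ANALOG", "LABELS") %||%
                     sprintf("A%02d", seq_len(n_chan)))[seq_len(n_chan)]
    arate <- c3d_param(params, "ANALOG", "RATE") %||%
      (point_rate * analog_sub)
    series <- lapply(seq_len(n_chan), function(cc) {
      rows <- 4L * n_points + (0:(analog_sub - 1L)) * n_chan + cc
      as.vector(dm[rows, , drop = FALSE])
    })
    names(series) <- sub("^Fz_", "", alab)
    force <- force_trial(series, fs = as.numeric(arate[1L]),
                         trial_id = trial_id)
  }
  list(markers = mk, force = force)
}

# Walk the parameter section entries into params[[GROUP]][[NAME]].
#' @noRd
parse_c3d_params <- function(raw, p0, rd_i8, rd_i16, rd_f32) {
  pos <- p0 + 5L
  groups <- list()   # id -> name
  entries <- list()  # list of (group_id, name, value)
  repeat {
    if (pos + 1L > length(raw)) break
    nname <- abs(rd_i8(pos))
    id <- rd_i8(pos + 1L)
    if (nname == 0L) break
    name <- rawToChar(raw[(pos + 2L):(pos + 1L + nname)])
    opos <- pos + 2L + nname
    offset <- rd_i16(opos)
    nxt <- opos + offset
    if (id < 0L) {
      groups[[as.character(-id)]] <- name
    } else {
      tpos <- opos + 2L
      etype <- rd_i8(tpos)
      ndims <- rd_i8(tpos + 1L)
      dims <- if (ndims > 0L) {
        vapply((tpos + 2L):(tpos + 1L + ndims), function(i)
          as.integer(raw[i]), integer(1))
      } else integer(0)
      nelem <- prod(c(dims, 1L))
      dpos <- tpos + 2L + ndims
      value <- switch(as.character(etype),
        "-1" = {
          ch <- rawToChar(raw[dpos:(dpos + nelem - 1L)])
          if (length(dims) == 2L) {
            substring(ch, (0:(dims[2L] - 1L)) * dims[1L] + 1L,
                      (1:dims[2L]) * dims[1L])
          } else ch
        },
        "1" = as.integer(raw[dpos:(dpos + nelem - 1L)]),
        "2" = vapply(seq_len(nelem), function(k)
          rd_i16(dpos + 2L * (k - 1L)), integer(1)),
        "4" = rd_f32(dpos, nelem),
        stop("format error: unknown parameter element type ", etype,
             call. = FALSE))
      entries[[length(entries) + 1L]] <- list(gid = id, name = name,
                                              value = value)
    }
    if (offset == 0L) break
    pos <- nxt
  }
  params <- list()
  for (e in entries) {
    gname <- groups[[as.character(e$gid)]] %||% as.character(e$gid)
    params[[gname]][[e$name]] <- e$value
  }
  params
}

#' @noRd
c3d_param <- function(params, group, name) {
  params[[group]][[name]]
}

#' Write marker (and optionally force) data to a C3D file
#'
#' Emits the Intel, floating-point C3D subset read back by [read_c3d()]:
#' one point per marker at the marker rate, and one analog channel per force
#' series (labelled `Fz_<side>`) at the force rate, which must be an integer
#' multiple of the marker rate.
#'
#' @param trial a [marker_trial()].
#' @param path output file path.
#' @param force optional [force_trial()] to embed as analog channels.
#' @return `path`, invisibly.
#' @export
write_c3d <- function(trial, path, force = NULL) {
  stopifnot(inherits(trial, "marker_trial"))
  n_points <- length(trial$markers)
  n_frames <- trial$n_samples
  if (n_frames > 32767L) {
    stop("C3D writer supports at most 32767 frames", call. = FALSE)
  }
  labels <- names(trial$markers)
  analog_sub <- 0L
  n_chan <- 0L
  alabels <- character(0)
  if (!is.null(force)) {
    stopifnot(inherits(force, "force_trial"))
    ratio <- force$fs / trial$fs
    if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1) {
      stop("force rate must be an integer multiple of the marker rate",
           call. = FALSE)
    }
    analog_sub <- as.integer(round(ratio))
    n_chan <- length(force$fz)
    alabels <- paste0("Fz_", names(force$fz))
    if (any(vapply(force$fz, length, integer(1)) != n_frames * analog_sub)) {
      stop("force series length must equal n_frames * (fs_force/fs_markers)",
           call. = FALSE)
    }
  }
  w_i16 <- function(con, v) writeBin(as.integer(v), con, size = 2L,
                                     endian = "little")
  w_f32 <- function(con, v) writeBin(as.double(v), con, size = 4L,
                                     endian = "little")
  params <- c3d_param_section(labels, alabels, n_points, n_frames,
                              trial$fs, if (n_chan) force$fs else 0,
                              analog_sub)
  param_blocks <- length(params) %/% C3D_BLOCK
  data_block <- 2L + param_blocks
  params <- patch_data_start(params, data_block)
  con <- file(path, "wb")
  on.exit(close(con))
  # --- header block
  writeBin(as.raw(c(2L, 0x50)), con)
  w_i16(con, n_points)
  w_i16(con, n_chan * analog_sub)
  w_i16(con, 1L)
  w_i16(con, n_frames)
  w_i16(con, 0L)                       # max gap
  w_f32(con, -1)                       # point scale: float storage
  w_i16(con, data_block)
  w_i16(con, analog_sub)
  w_f32(con, trial$fs)
  writeBin(raw(C3D_BLOCK - 24L), con)
  # --- parameter section
  writeBin(params, con)
  # --- data section
  stride <- 4L * n_points + analog_sub * n_chan
  dm <- matrix(0, nrow = stride, ncol = n_frames)
  for (m in seq_len(n_points)) {
    dm[(m - 1L) * 4L + 1:3, ] <- t(trial$markers[[m]])
  }
  if (n_chan > 0L) {
    for (cc in seq_len(n_chan)) {
      rows <- 4L * n_points + (0:(analog_sub - 1L)) * n_chan + cc
      dm[rows, ] <- matrix(force$fz[[cc]], nrow = analog_sub)
    }
  }
  w_f32(con, as.vector(dm))
  pad <- (-(stride * n_frames * 4L)) %% C3D_BLOCK
  if (pad > 0L) writeBin(raw(pad), con)
  invisible(path)
}

# Build the raw parameter section (POINT and ANALOG groups), padded to whole
# blocks. DATA_START is written as 0 and patched once the section size is
# known.
#' @noRd
c3d_param_section <- function(labels, alabels, n_points, n_frames,
                              point_rate, analog_rate, analog_sub) {
  out <- list()
  emit <- function(x) out[[length(out) + 1L]] <<- x
  r_i8 <- function(v) as.raw(bitwAnd(as.integer(v), 0xFFL))
  r_i16 <- function(v) writeBin(as.integer(v), raw(), size = 2L,
                                endian = "little")
  r_f32 <- function(v) writeBin(as.double(v), raw(), size = 4L,
                                endian = "little")
  group <- function(id, name) {
    nm <- charToRaw(name)
    emit(r_i8(length(nm))); emit(r_i8(-id)); emit(nm)
    emit(r_i16(3L)); emit(r_i8(0L))  # offset to next entry, empty desc
  }
  param <- function(gid, name, etype, dims, data_raw) {
    nm <- charToRaw(name)
    body_len <- 2L + length(dims) + length(data_raw) + 1L
    emit(r_i8(length(nm))); emit(r_i8(gid)); emit(nm)
    emit(r_i16(2L + body_len))
    emit(r_i8(etype)); emit(r_i8(length(dims)))
    for (d in dims) emit(r_i8(d))
    emit(data_raw)
    emit(r_i8(0L))  # empty description
  }
  char_matrix <- function(strs, width = NULL) {
    width <- width %||% max(nchar(strs), 1L)
    padded <- formatC(strs, width = -width)
    list(dims = c(width, length(strs)),
         raw = charToRaw(paste(padded, collapse = "")))
  }
  group(1L, "POINT")
  param(1L, "USED", 2L, integer(0) + 0L, r_i16(n_points))
  param(1L, "FRAMES", 2L, integer(0), r_i16(n_frames))
  param(1L, "RATE", 4L, integer(0), r_f32(point_rate))
  param(1L, "SCALE", 4L, integer(0), r_f32(-1))
  param(1L, "DATA_START", 2L, integer(0), r_i16(0L))  # patched later
  lm <- char_matrix(labels)
  param(1L, "LABELS", -1L, lm$dims, lm$raw)
  um <- char_matrix("m", 4L)
  param(1L, "UNITS", -1L, um$dims[1L], um$raw)
  group(2L, "ANALOG")
  param(2L, "USED", 2L, integer(0), r_i16(length(alabels)))
  param(2L, "RATE", 4L, integer(0), r_f32(analog_rate))
  param(2L, "GEN_SCALE", 4L, integer(0), r_f32(1))
  if (length(alabels) > 0L) {
    am <- char_matrix(alabels)
    param(2L, "LABELS", -1L, am$dims, am$raw)
    param(2L, "SCALE", 4L, length(alabels),
          r_f32(rep(1, length(alabels))))
    param(2L, "OFFSET", 2L, length(alabels),
          r_i16(rep(0L, length(alabels))))
  }
  # terminator entry (zero name length, zero offset)
  emit(as.raw(c(0L, 0L))); emit(r_i16(0L))
  body <- do.call(c, out)
  n_blocks <- as.integer(ceiling((4L + length(body)) / C3D_BLOCK))
  head <- as.raw(c(1L, 0x50, n_blocks, 84L))
  sec <- c(head, body)
  c(sec, raw(n_blocks * C3D_BLOCK - length(sec)))
}

# DATA_START was emitted as int16 0 right after its type/dims bytes; locate
# the parameter by name and overwrite its payload.
#' @noRd
patch_data_start <- function(params, data_block) {
  pat <- charToRaw("DATA_START")
  n <- length(params)
  hit <- NULL
  for (i in seq_len(n - length(pat))) {
    if (all(params[i:(i + length(pat) - 1L)] == pat)) { hit <- i; break }
  }
  if (is.null(hit)) stop("internal error: DATA_START not found")
  # layout after the name: int16 offset, int8 type, int8 ndims, int16 value
  vpos <- hit + length(pat) + 4L
  params[vpos:(vpos + 1L)] <- writeBin(as.integer(data_block), raw(),
                                       size = 2L, endian = "little")
  params
}

#' Export a synthetic trial to a C3D file
#'
#' Convenience wrapper over [write_c3d()] embedding the synthetic force as
#' analog channels.
#'
#' @param trial a `synthetic_trial` from [generate_trial()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_trial_c3d <- function(trial, path) {
  stopifnot(inherits(trial, "synthetic_trial"))
  write_c3d(trial$markers, path, force = trial$force)
}
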