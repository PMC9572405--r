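#' Write a trajectory as extended XYZ
#'
#' Dialect: first line bead count; comment line of `key=value` pairs
#' (`time`, optionally `piston_x`, `config_hash`); then one
#' `element x y z [vx vy vz]` row per bead. Coordinates are written with
#' 17 significant digits so a write/read round trip is bitwise lossless.
#'
#' @param traj a `trajectory` (or a single N x 3 matrix).
#' @param path output file.
#' @param element element tag written per bead.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path, element = "C") {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.17g", x)
  if (!inherits(traj, "trajectory")) {
    traj <- new_trajectory(array(traj, c(1, nrow(traj), 3)), 0, NULL,
                           sim_config(N = nrow(traj)), NULL, 0L)
  }
  has_v <- !is.null(traj$velocities)
  for (i in seq_len(n_frames(traj))) {
    f <- get_frame(traj, i)
    hdr <- sprintf("time=%s", fmt(traj$times[i]))
    if (!is.null(traj$piston_x))
      hdr <- paste0(hdr, sprintf(" piston_x=%s", fmt(traj$piston_x[i])))
    hdr <- paste0(hdr, " config_hash=", traj$config_hash)
    writeLines(c(as.character(nrow(f)), hdr), con)
    if (has_v) {
      v <- matrix(traj$velocities[i, , ], ncol = 3)
      writeLines(sprintf("%s %s %s %s %s %s %s", element,
                         fmt(f[, 1]), fmt(f[, 2]), fmt(f[, 3]),
                         fmt(v[, 1]), fmt(v[, 2]), fmt(v[, 3])), con)
    } else {
      writeLines(sprintf("%s %s %s %s", element,
                         fmt(f[, 1]), fmt(f[, 2]), fmt(f[, 3])), con)
    }
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Accepts the dialect written by [write_xyz()] and foreign XYZ files
#' without velocities or comment keys (flagged via the returned metadata).
#' Malformed input raises an error naming the offending frame and line.
#'
#' @param path file to read.
#' @param config optional [sim_config()] to attach.
#' @return a `trajectory`; attribute `has_velocities` reports whether
#'   velocity columns were present.
#' @export
read_xyz <- function(path, config = NULL) {
  lines <- readLines(path)
  i <- 1L; frame_no <- 0L
  frames <- list(); vels <- list(); times <- numeric(); piston <- numeric()
  hash <- NA_character_; has_v <- NA
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame_no <- frame_no + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop(sprintf("parse error at line %d (frame %d): expected bead count", i, frame_no))
    if (i + 1L + n > length(lines))
      stop(sprintf("truncated file: frame %d needs %d atom lines after line %d", frame_no, n, i + 1L))
    cmt <- lines[i + 1L]
    kv <- regmatches(cmt, gregexpr("[A-Za-z_]+=[^ ]+", cmt))[[1]]
    keys <- sub("=.*", "", kv); vals <- sub("^[^=]*=", "", kv)
    tm <- if ("time" %in% keys) as.numeric(vals[keys == "time"]) else frame_no - 1
    if ("piston_x" %in% keys) piston <- c(piston, as.numeric(vals[keys == "piston_x"]))
    if ("config_hash" %in% keys) hash <- vals[keys == "config_hash"]
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "[ \t]+")
    nf <- lengths(rows)
    if (any(nf != 4 & nf != 7) || length(unique(nf)) != 1)
      stop(sprintf("parse error in frame %d near line %d: expected 'el x y z [vx vy vz]'",
                   frame_no, i + 1L + which(nf != nf[1] | (nf != 4 & nf != 7))[1]))
    num <- suppressWarnings(
      vapply(rows, function(r) as.numeric(r[-1]), numeric(nf[1] - 1)))
    if (any(is.na(num)))
      stop(sprintf("parse error in frame %d: non-numeric coordinate", frame_no))
    frames[[frame_no]] <- t(num[1:3, , drop = FALSE])
    fv <- nf[1] == 7
    if (is.na(has_v)) has_v <- fv
    if (fv) vels[[frame_no]] <- t(num[4:6, , drop = FALSE])
    times <- c(times, tm)
    i <- i + 2L + n
  }
  if (frame_no == 0L) stop("no frames in file")
  N <- nrow(frames[[1]])
  arr <- array(0, c(frame_no, N, 3))
  for (k in seq_len(frame_no)) arr[k, , ] <- frames[[k]]
  varr <- NULL
  if (isTRUE(has_v) && length(vels) == frame_no) {
    varr <- array(0, c(frame_no, N, 3))
    for (k in seq_len(frame_no)) varr[k, , ] <- vels[[k]]
  }
  if (is.null(config)) config <- sim_config(N = N)
  tr <- new_trajectory(arr, times,
                       if (length(piston) == frame_no) piston else NULL,
                       config, NULL, 0L, velocities = varr)
  if (!is.na(hash)) tr$config_hash <- hash
  attr(tr, "has_velocities") <- isTRUE(has_v)
  tr
}

#' Run manifest
#'
#' Records everything needed to regenerate a result: config hash, per-
#' repeat seeds, tool version and per-stage output paths.
#'
#' @param config a [sim_config()].
#' @param seeds integer vector of per-repeat seeds.
#' @param outputs named character vector of output paths.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(config, seeds, outputs = character()) {
  structure(list(config_hash = config_hash(config), seeds = as.integer(seeds),
                 version = as.character(utils::packageVersion("helixknot")),
                 outputs = outputs, created = format(Sys.time(), tz = "UTC")),
            class = "run_manifest")
}
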