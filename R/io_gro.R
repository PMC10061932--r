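#' Read a GROMACS GRO coordinate file
#'
#' Parses the fixed-column GRO dialect (positions in nm). Velocities, if
#' present, are ignored. Only orthorhombic boxes are supported; a box line
#' with nonzero off-diagonal components raises an error.
#'
#' @param path path to a `.gro` file.
#' @return list with elements `topology` (see [as_topology()]) and `frame`
#'   (a frame: list with `time` ns, `box` nm, `xyz` N x 3 matrix in nm).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("GRO file too short: ", path)
  res <- parse_gro_block(lines, 1L, path)
  list(topology = res$topology, frame = res$frame)
}

#' Read a multi-frame GRO trajectory
#'
#' Concatenated GRO frames are read into a trajectory. The topology is taken
#' from the first frame; all frames must have the same atom count. Frame
#' times are parsed from `t=` in the title line when present, otherwise
#' numbered 0, 1, 2, ... ns.
#'
#' @param path path to a concatenated multi-frame `.gro` file.
#' @return list with `topology` and `trajectory` (class `md_trajectory`:
#'   list with `times`, `frames` = list of frames).
#' @export
read_gro_frames <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list()
  topo <- NULL
  while (pos <= length(lines) && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
  while (pos + 2L <= length(lines)) {
    res <- parse_gro_block(lines, pos, path)
    if (is.null(topo)) {
      topo <- res$topology
    } else if (nrow(topo) != nrow(res$topology)) {
      stop("frame starting at line ", pos, " has a different atom count")
    }
    frames[[length(frames) + 1L]] <- res$frame
    pos <- res$next_line
    while (pos <= length(lines) && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
  }
  if (!length(frames)) stop("no frames found in ", path)
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (anyNA(times)) times <- seq_along(frames) - 1
  for (i in seq_along(frames)) frames[[i]]$time <- times[i]
  list(topology = topo,
       trajectory = structure(list(times = times, frames = frames),
                              class = "md_trajectory"))
}

parse_gro_block <- function(lines, start, path) {
  title <- lines[start]
  n <- suppressWarnings(as.integer(trimws(lines[start + 1L])))
  if (is.na(n) || n < 1L) {
    stop("malformed atom-count line ", start + 1L, " in ", path, ": '",
         lines[start + 1L], "'")
  }
  if (start + 1L + n + 1L > length(lines)) {
    stop("header count (", n, ") at line ", start + 1L,
         " exceeds atoms listed in ", path)
  }
  at <- lines[(start + 2L):(start + 1L + n)]
  bad <- which(nchar(at) < 44L)
  if (length(bad)) {
    stop("malformed atom line ", start + 1L + bad[1], " in ", path)
  }
  resid <- as.integer(substr(at, 1L, 5L))
  resname <- trimws(substr(at, 6L, 10L))
  atom_name <- trimws(substr(at, 11L, 15L))
  xyz <- cbind(as.numeric(substr(at, 21L, 28L)),
               as.numeric(substr(at, 29L, 36L)),
               as.numeric(substr(at, 37L, 44L)))
  if (anyNA(resid) || anyNA(xyz)) {
    stop("unparsable atom record in ", path, " near line ", start + 2L,
         " (header count may not match listed atoms)")
  }
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[start + 1L + n + 1L]), "\\s+")[[1]]))
  if (length(boxv) < 3L || anyNA(boxv[1:3])) {
    stop("malformed box line in ", path,
         " (header count may not match listed atoms)")
  }
  if (length(boxv) > 3L && any(abs(boxv[-(1:3)]) > 1e-9)) {
    stop("non-orthorhombic box unsupported in ", path)
  }
  time <- NA_real_
  tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
  if (length(tm)) time <- as.numeric(sub("t=\\s*", "", tm))
  topo <- as_topology(data.frame(
    atom_id = seq_len(n),
    mol_id = cumsum(c(TRUE, resid[-1] != resid[-n] | resname[-1] != resname[-n])),
    resid = resid, resname = resname, atom_name = atom_name,
    stringsAsFactors = FALSE
  ))
  frame <- structure(list(time = time, box = boxv[1:3], xyz = xyz),
                     class = "md_frame")
  if (any(frame$box <= 0)) stop("non-positive box edge in ", path)
  list(topology = topo, frame = frame, next_line = start + n + 3L)
}

#' Write a frame to GRO format
#'
#' @param topology a `topology` object.
#' @param frame a frame as returned by [read_gro()].
#' @param path output path; with `append = TRUE` frames can be concatenated
#'   into a multi-frame trajectory.
#' @param append append instead of overwrite.
#' @export
write_gro <- function(topology, frame, path, append = FALSE) {
  n <- nrow(topology)
  stopifnot(nrow(frame$xyz) == n)
  t_ns <- if (is.null(frame$time) || is.na(frame$time)) 0 else frame$time
  hdr <- c(sprintf("synthetic monolayer t= %.4f", t_ns), sprintf("%5d", n))
  body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  topology$resid %% 100000L,
                  substr(topology$resname, 1L, 5L),
                  substr(topology$atom_name, 1L, 5L),
                  topology$atom_id %% 100000L,
                  frame$xyz[, 1], frame$xyz[, 2], frame$xyz[, 3])
  box <- sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2], frame$box[3])
  con <- file(path, open = if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c(hdr, body, box), con)
  invisible(path)
}
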