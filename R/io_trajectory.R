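# Trajectory container and structure/trajectory readers.
#
# Coordinates are held in nm internally; PDB/DCD inputs (angstrom) are
# converted on read. A bundle carries per-frame coordinates, per-frame box
# dimensions, and a topology table (atom names, residues, partial charges).

#' Construct a trajectory bundle
#'
#' @param frames List of `n_atoms x 3` coordinate matrices in nm, one per frame.
#' @param box Numeric `n_frames x 3` matrix (or length-3 vector recycled) of
#'   box dimensions in nm.
#' @param topology Tibble with one row per atom: columns `name`, `resname`,
#'   `resid`, and optionally `charge` (e; default 0).
#' @param time Optional per-frame times in ps.
#' @return A `traj_bundle` object.
#' @export
traj_bundle <- function(frames, box, topology, time = NULL) {
  if (!is.list(frames) || length(frames) == 0) abort("`frames` must be a non-empty list")
  n_atoms <- unique(vapply(frames, nrow, integer(1)))
  if (length(n_atoms) != 1) abort("all frames must have the same atom count")
  if (is.null(dim(box))) box <- matrix(box, nrow = length(frames), ncol = 3, byrow = TRUE)
  if (nrow(box) != length(frames)) abort("`box` must have one row per frame")
  if (any(box[, 3] <= 0)) abort("box z-dimension must be > 0")
  topology <- as_tibble(topology)
  if (nrow(topology) != n_atoms) abort("topology rows must match atom count")
  if (!"charge" %in% names(topology)) topology$charge <- 0
  structure(
    list(frames = frames, box = box, topology = topology,
         time = time %||% seq_along(frames) - 1),
    class = "traj_bundle"
  )
}

#' @export
print.traj_bundle <- function(x, ...) {
  cat(sprintf("<traj_bundle> %d frames x %d atoms | box z %.3f nm (frame 1)\n",
              length(x$frames), nrow(x$topology), x$box[1, 3]))
  invisible(x)
}

n_frames <- function(bundle) length(bundle$frames)

#' Select atom indices from a bundle topology
#'
#' @param bundle A [traj_bundle()].
#' @param name,resname Character vectors matched exactly against the topology
#'   (either may be NULL to skip that filter).
#' @param allow_empty Return an empty selection instead of erroring.
#' @return Integer atom indices.
#' @export
select_atoms <- function(bundle, name = NULL, resname = NULL, allow_empty = FALSE) {
  keep <- rep(TRUE, nrow(bundle$topology))
  if (!is.null(name)) keep <- keep & bundle$topology$name %in% name
  if (!is.null(resname)) keep <- keep & bundle$topology$resname %in% resname
  idx <- which(keep)
  if (length(idx) == 0 && !allow_empty) {
    abort("selection resolved to zero atoms")
  }
  idx
}

# ---- GRO dialect ------------------------------------------------------------

parse_gro_frames <- function(lines) {
  frames <- list(); boxes <- list(); times <- c(); topo <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1])))
    if (is.na(nat)) abort(sprintf("GRO parse error at line %d: bad atom count", i + 1))
    if (i + 1 + nat + 1 > length(lines)) abort("GRO parse error: truncated frame")
    atom_lines <- lines[(i + 2):(i + 1 + nat)]
    coords <- matrix(NA_real_, nrow = nat, ncol = 3)
    coords[, 1] <- as.numeric(substr(atom_lines, 21, 28))
    coords[, 2] <- as.numeric(substr(atom_lines, 29, 36))
    coords[, 3] <- as.numeric(substr(atom_lines, 37, 44))
    if (anyNA(coords)) abort("GRO parse error: non-numeric coordinates")
    if (is.null(topo)) {
      topo <- tibble(
        resid = as.integer(substr(atom_lines, 1, 5)),
        resname = trimws(substr(atom_lines, 6, 10)),
        name = trimws(substr(atom_lines, 11, 15))
      )
    }
    box_vals <- as.numeric(strsplit(trimws(lines[i + 2 + nat]), "\\s+")[[1]])
    t_match <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    times <- c(times, if (length(t_match)) as.numeric(sub("t=\\s*", "", t_match)) else length(frames))
    frames[[length(frames) + 1]] <- coords
    boxes[[length(boxes) + 1]] <- box_vals[1:3]
    i <- i + nat + 3L
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  list(frames = frames, box = do.call(rbind, boxes), topology = topo, time = times)
}

read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parse_gro_frames(lines)
}

#' Write a bundle as a (multi-frame) GRO file
#'
#' @param bundle A [traj_bundle()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(bundle, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  topo <- bundle$topology
  for (f in seq_len(n_frames(bundle))) {
    writeLines(sprintf("memperm toy system, t= %.4f", bundle$time[f]), con)
    writeLines(sprintf("%5d", nrow(topo)), con)
    xyz <- bundle$frames[[f]]
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       topo$resid %% 100000, substr(topo$resname, 1, 5),
                       substr(topo$name, 1, 5), seq_len(nrow(topo)) %% 100000,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", bundle$box[f, 1], bundle$box[f, 2],
                       bundle$box[f, 3]), con)
  }
  invisible(path)
}

#' Write a bundle topology (with charges) as CSV
#'
#' @param bundle A [traj_bundle()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(bundle, path) {
  readr::write_csv(bundle$topology, path)
  invisible(path)
}

# ---- generic reader ---------------------------------------------------------

#' Read a structure plus trajectory into a bundle
#'
#' Supported structure formats: GRO (nm, parsed directly) and PDB (angstrom,
#' via bio3d, converted to nm). Supported trajectories: multi-frame GRO files
#' and DCD (via bio3d). With `traj = NULL` the structure's own frame(s) are the
#' trajectory.
#'
#' @param coords Path to the structure file (.gro or .pdb).
#' @param traj Optional path to a trajectory (.gro multi-frame or .dcd).
#' @param topology Optional topology: a tibble or a CSV path with per-atom
#'   `name`, `resname`, `resid`, `charge` columns; replaces the topology
#'   derived from the structure (atom count must match).
#' @return A [traj_bundle()].
#' @export
read_trajectory <- function(coords, traj = NULL, topology = NULL) {
  if (!file.exists(coords)) abort(sprintf("structure file not found: %s", coords))
  ext <- tolower(tools::file_ext(coords))
  if (ext == "gro") {
    parsed <- read_gro(coords)
  } else if (ext == "pdb") {
    pdb <- bio3d::read.pdb(coords)
    xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE) / 10  # A -> nm
    box <- if (!is.null(pdb$cryst1) && length(pdb$cryst1$abc) == 3) {
      pdb$cryst1$abc / 10
    } else {
      apply(xyz, 2, function(v) diff(range(v))) + 1
    }
    parsed <- list(
      frames = list(xyz), box = matrix(box, nrow = 1),
      topology = tibble(resid = pdb$atom$resno, resname = pdb$atom$resid,
                        name = pdb$atom$elety),
      time = 0
    )
  } else {
    abort(sprintf("unsupported structure format: .%s (use .gro or .pdb)", ext))
  }

  if (!is.null(traj)) {
    text <- tolower(tools::file_ext(traj))
    if (text == "gro") {
      tparsed <- read_gro(traj)
      if (nrow(tparsed$topology) != nrow(parsed$topology)) {
        abort("atom-count mismatch between structure and trajectory")
      }
      parsed$frames <- tparsed$frames
      parsed$box <- tparsed$box
      parsed$time <- tparsed$time
    } else if (text == "dcd") {
      xyz <- bio3d::read.dcd(traj, verbose = FALSE)
      if (ncol(xyz) != 3 * nrow(parsed$topology)) {
        abort("atom-count mismatch between structure and trajectory")
      }
      parsed$frames <- lapply(seq_len(nrow(xyz)), function(i) {
        matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10
      })
      parsed$box <- matrix(rep(parsed$box[1, ], nrow(xyz)), ncol = 3, byrow = TRUE)
      parsed$time <- seq_len(nrow(xyz)) - 1
    } else {
      abort(sprintf("unsupported trajectory format: .%s (use .gro or .dcd)", text))
    }
  }

  topo <- parsed$topology
  topo$charge <- 0
  if (!is.null(topology)) {
    user_topo <- if (is.character(topology)) {
      readr::read_csv(topology, show_col_types = FALSE, progress = FALSE)
    } else {
      as_tibble(topology)
    }
    if (nrow(user_topo) != nrow(topo)) {
      abort("atom-count mismatch between structure and supplied topology")
    }
    topo <- as_tibble(user_topo)
    if (!"charge" %in% names(topo)) topo$charge <- 0
  }
  traj_bundle(parsed$frames, parsed$box, topo, time = parsed$time)
}

#' Tidy a bundle into a long tibble
#'
#' @param x A [traj_bundle()].
#' @param ... Unused.
#' @return A tibble with one row per atom per frame (`frame`, `time`, `atom`,
#'   `name`, `resname`, `resid`, `x`, `y`, `z`).
#' @method tidy traj_bundle
#' @export
tidy.traj_bundle <- function(x, ...) {
  purrr::map_dfr(seq_len(n_frames(x)), function(f) {
    xyz <- x$frames[[f]]
    tibble(frame = f, time = x$time[f], atom = seq_len(nrow(xyz)),
           name = x$topology$name, resname = x$topology$resname,
           resid = x$topology$resid,
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
}
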