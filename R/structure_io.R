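# Structure and trajectory I/O on standard PDB files. Parsing is delegated
# to bio3d; a record-level validation pass runs first so that malformed
# ATOM/HETATM records are reported with their line number rather than
# surfacing as an opaque downstream failure.

new_structure <- function(atoms, xyz, label = "structure") {
  stopifnot(is.data.frame(atoms), is.matrix(xyz), ncol(xyz) == 3,
            nrow(atoms) == nrow(xyz))
  if (nrow(atoms) == 0) stop_vhh("a structure must contain at least one atom")
  if (any(!is.finite(xyz))) stop_vhh("non-finite coordinates in structure")
  # sequential residue indices follow file order of (chain, resno, insert)
  key <- paste(atoms$chain, atoms$resno, atoms$insert %||% "", sep = "|")
  atoms$res_index <- match(key, unique(key))
  dup <- duplicated(paste(atoms$res_index, atoms$elety))
  if (any(dup)) {
    stop_vhh("duplicate atom name(s) within a residue: ",
             paste(unique(atoms$elety[dup]), collapse = ", "))
  }
  structure(
    list(atoms = atoms, xyz = xyz, label = label),
    class = "vhh_structure"
  )
}

#' @export
print.vhh_structure <- function(x, ...) {
  cat(sprintf("<vhh_structure> %s: %d residues, %d atoms\n",
              x$label, n_residues(x), nrow(x$atoms)))
  invisible(x)
}

#' Number of residues in a structure
#' @param structure A `vhh_structure`.
#' @return Integer residue count.
#' @export
n_residues <- function(structure) {
  stopifnot(inherits(structure, "vhh_structure"))
  max(structure$atoms$res_index)
}

#' Per-residue summary table of a structure
#'
#' One row per residue: internal sequential index, three-letter code,
#' chain and the author-assigned PDB residue number (preserved for
#' reporting).
#'
#' @param structure A `vhh_structure`.
#' @return A data frame with columns `res_index`, `resid`, `chain`, `resno`.
#' @export
residue_table <- function(structure) {
  a <- structure$atoms
  first <- !duplicated(a$res_index)
  data.frame(res_index = a$res_index[first], resid = a$resid[first],
             chain = a$chain[first], resno = a$resno[first],
             row.names = NULL, stringsAsFactors = FALSE)
}

validate_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  if (length(idx) == 0) stop_vhh("no ATOM/HETATM records in '", path, "'")
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop_vhh("malformed ATOM/HETATM record at line ", i, " of '", path,
               "': record too short for coordinate fields")
    }
    coords <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (any(is.na(coords))) {
      stop_vhh("malformed ATOM/HETATM record at line ", i, " of '", path,
               "': unreadable coordinate field")
    }
  }
  invisible(TRUE)
}

#' Read a single conformation from a PDB file
#'
#' Parses all ATOM/HETATM records of the chosen model. Residues are indexed
#' sequentially in file order; the author-assigned residue numbers are kept
#' alongside for reporting. Only the first alternate location of an atom is
#' retained.
#'
#' @param path Path to a PDB file.
#' @param model Model number to extract (1-based position among MODEL
#'   records; default first).
#' @param label Free-text identifier; defaults to the file name.
#' @return A `vhh_structure`.
#' @export
read_structure <- function(path, model = 1, label = NULL) {
  if (!file.exists(path)) stop_vhh("file not found: '", path, "'")
  if (!is_count(model)) stop_vhh("'model' must be a positive integer")
  validate_pdb_records(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE, verbose = FALSE)
  n_models <- nrow(pdb$xyz)
  if (model > n_models) {
    stop_vhh("model ", model, " not present in '", path, "'; available models: 1",
             if (n_models > 1) paste0("-", n_models) else "")
  }
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  atoms <- pdb$atom[, c("type", "eleno", "elety", "resid", "chain", "resno",
                        "insert", "elesy")]
  atoms$chain[is.na(atoms$chain)] <- " "
  atoms$insert[is.na(atoms$insert)] <- ""
  miss <- is.na(atoms$elesy) | atoms$elesy == ""
  atoms$elesy[miss] <- guess_element(atoms$elety[miss])
  new_structure(atoms, xyz, label = label %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a structure as a PDB file
#'
#' @param structure A `vhh_structure`.
#' @param path Output file path.
#' @param b Optional per-atom B-factor column values (recycled if length 1).
#' @return Invisibly, `path`.
#' @export
write_structure <- function(structure, path, b = 0) {
  stopifnot(inherits(structure, "vhh_structure"))
  a <- structure$atoms
  bio3d::write.pdb(
    file = path, xyz = as.vector(t(structure$xyz)),
    type = a$type %||% "ATOM", eleno = a$eleno, elety = a$elety,
    resid = a$resid, chain = ifelse(a$chain == " ", "", a$chain),
    resno = a$resno, insert = a$insert,
    o = rep(1, nrow(a)), b = rep_len(b, nrow(a)), elesy = a$elesy
  )
  invisible(path)
}

new_trajectory <- function(topology, frames, times, label = topology$label) {
  stopifnot(inherits(topology, "vhh_structure"), is.list(frames))
  if (length(frames) != length(times)) {
    stop_vhh("trajectory must have one time per frame")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop_vhh("frame times must be strictly increasing")
  }
  n_atoms <- nrow(topology$atoms)
  ok <- vapply(frames, function(f) is.matrix(f) && all(dim(f) == c(n_atoms, 3)),
               logical(1))
  if (!all(ok)) {
    stop_vhh("frame ", which(!ok)[1], " does not match the topology atom count")
  }
  structure(list(topology = topology, frames = frames, times = as.numeric(times),
                 label = label),
            class = "vhh_trajectory")
}

#' @export
print.vhh_trajectory <- function(x, ...) {
  cat(sprintf("<vhh_trajectory> %s: %d frames x %d atoms, t = %g..%g ps\n",
              x$label, n_frames(x), nrow(x$topology$atoms),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `vhh_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "vhh_trajectory"))
  length(traj$frames)
}

#' Materialize one trajectory frame as a structure
#' @param traj A `vhh_trajectory`.
#' @param frame Frame number (1-based).
#' @return A `vhh_structure` with the frame's coordinates.
#' @export
frame_structure <- function(traj, frame) {
  stopifnot(inherits(traj, "vhh_trajectory"), is_count(frame))
  if (frame > n_frames(traj)) stop_vhh("frame ", frame, " out of range")
  out <- traj$topology
  out$xyz <- traj$frames[[frame]]
  out$label <- sprintf("%s_frame%d", traj$label, frame)
  out
}

#' Read a trajectory from one multi-model PDB file or an ordered file list
#'
#' All frames must share the atom count and atom ordering of the first
#' frame. An optional time window is applied first, then every `stride`-th
#' remaining frame is kept.
#'
#' @param paths One multi-model PDB path, or a character vector of
#'   single-model PDB paths in frame order.
#' @param stride Keep every `stride`-th frame (default 1 = all).
#' @param window Optional `c(t0, t1)` in ps; frames with `t0 <= t <= t1`
#'   are kept.
#' @param dt Frame spacing in ps used when `times` is not given.
#' @param times Optional explicit frame times in ps (length = total frames).
#' @param label Trajectory identifier.
#' @return A `vhh_trajectory`.
#' @export
read_trajectory <- function(paths, stride = 1, window = NULL, dt = 1,
                            times = NULL, label = NULL) {
  if (!is_count(stride)) stop_vhh("'stride' must be a positive integer")
  if (length(paths) == 1) {
    validate_pdb_records(paths)
    pdb <- bio3d::read.pdb(paths, multi = TRUE, rm.alt = TRUE, verbose = FALSE)
    topo <- read_structure(paths, model = 1, label = label)
    frames <- lapply(seq_len(nrow(pdb$xyz)), function(i) {
      matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
    })
  } else {
    structures <- lapply(paths, read_structure)
    topo <- structures[[1]]
    ref <- topo$atoms
    for (k in seq_along(structures)[-1]) {
      a <- structures[[k]]$atoms
      if (nrow(a) != nrow(ref)) {
        stop_vhh("atom count mismatch in frame ", k, " ('", paths[k], "'): ",
                 nrow(a), " vs ", nrow(ref), " atoms")
      }
      if (!identical(a$elety, ref$elety) || !identical(a$resno, ref$resno) ||
          !identical(a$resid, ref$resid)) {
        stop_vhh("atom ordering differs from frame 1 in frame ", k,
                 " ('", paths[k], "')")
      }
    }
    frames <- lapply(structures, function(s) s$xyz)
  }
  if (!is.null(label)) topo$label <- label
  times <- times %||% ((seq_along(frames) - 1) * dt)
  if (length(times) != length(frames)) {
    stop_vhh("'times' must have one entry per frame")
  }
  keep <- seq_along(frames)
  if (!is.null(window)) {
    stopifnot(length(window) == 2)
    keep <- keep[times[keep] >= window[1] & times[keep] <= window[2]]
    if (length(keep) == 0) stop_vhh("time window selects no frames")
  }
  keep <- keep[seq(1, length(keep), by = stride)]
  new_trajectory(topo, frames[keep], times[keep],
                 label = topo$label)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj A `vhh_trajectory`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "vhh_trajectory"))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (i in seq_len(n_frames(traj))) {
    write_structure(frame_structure(traj, i), tmp)
    body <- readLines(tmp, warn = FALSE)
    body <- body[!grepl("^END", body)]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(body, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atom indices by role, residue set, or both
#'
#' @param structure A `vhh_structure`.
#' @param what One of `"calpha"`, `"backbone"` (N, CA, C, O), `"heavy"`
#'   (non-hydrogen) or `"all"`.
#' @param residues Optional integer vector of sequential residue indices;
#'   the selection is intersected with the atoms of these residues.
#' @return Sorted unique atom indices (1-based). Empty selections are an
#'   error, never silently empty.
#' @export
select_atoms <- function(structure,
                         what = c("calpha", "backbone", "heavy", "all"),
                         residues = NULL) {
  stopifnot(inherits(structure, "vhh_structure"))
  what <- match.arg(what)
  a <- structure$atoms
  idx <- switch(what,
    calpha   = which(a$elety == "CA"),
    backbone = which(a$elety %in% c("N", "CA", "C", "O")),
    heavy    = which(toupper(a$elesy) != "H"),
    all      = seq_len(nrow(a))
  )
  if (!is.null(residues)) {
    residues <- unique(as.integer(residues))
    bad <- residues[residues < 1 | residues > n_residues(structure)]
    if (length(bad) > 0) {
      stop_vhh("residue indices out of range: ", paste(bad, collapse = ", "))
    }
    idx <- idx[a$res_index[idx] %in% residues]
  }
  idx <- sort(unique(idx))
  if (length(idx) == 0) {
    stop_vhh("atom selection '", what, "' is empty for this structure")
  }
  idx
}
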