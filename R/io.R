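#' Write a toy structure and its reference pair to disk
#'
#' Writes `<prefix>_of.pdb` and `<prefix>_if.pdb` (C-alpha-only PDB, one
#' atom per residue named CA; chain A = bundle 1, chain B = bundle 2, loop
#' particles carry the chain of the bundle they bridge, the ion is a HETATM
#' on chain X) plus a JSON sidecar `<prefix>_tags.json` holding the role
#' tags, helix/bundle map, rocking axis and angle, and full-precision
#' coordinates (PDB fields are fixed at 3 decimals; the sidecar preserves
#' the coordinates losslessly for round-tripping).
#'
#' @param structure a `toy_structure`.
#' @param refs the matching `reference_pair`.
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
write_structure <- function(structure, refs, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  a <- structure$atoms
  chain <- ifelse(!is.na(a$bundle_id) & a$bundle_id == 2L, "B", "A")
  # loop particles: chain of the bundle whose helices they bridge (by index
  # order they follow the bundle blocks; nearest helix atom decides)
  loops <- which(is.na(a$bundle_id))
  if (length(loops)) {
    hel_atoms <- which(!is.na(a$bundle_id))
    for (i in loops) {
      d <- sqrt(rowSums(sweep(structure$coords[hel_atoms, , drop = FALSE], 2,
                              structure$coords[i, ])^2))
      chain[i] <- chain[hel_atoms[which.min(d)]]
    }
  }
  write_one <- function(xyz, path, with_ion) {
    n <- nrow(xyz)
    type <- rep("ATOM", n); elety <- rep("CA", n); resid <- rep("ALA", n)
    ch <- chain; resno <- a$residue_id; eleno <- seq_len(n)
    if (with_ion) {
      xyz <- rbind(xyz, structure$ion$position)
      type <- c(type, "HETATM"); elety <- c(elety, "NA")
      resid <- c(resid, "NA"); ch <- c(ch, "X")
      resno <- c(resno, max(a$residue_id) + 1L); eleno <- c(eleno, n + 1L)
    }
    bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)), type = type,
                     resno = resno, resid = resid, eleno = eleno,
                     elety = elety, chain = ch)
  }
  p_of <- paste0(prefix, "_of.pdb")
  p_if <- paste0(prefix, "_if.pdb")
  p_tags <- paste0(prefix, "_tags.json")
  write_one(refs$of_coords, p_of, structure$ion$present)
  write_one(refs$if_coords, p_if, FALSE)
  side <- list(
    atoms = structure$atoms,
    chain = chain,
    of_coords = refs$of_coords, if_coords = refs$if_coords,
    ion = structure$ion,
    rocking = list(axis = refs$axis, angle_deg = refs$angle_deg),
    meta = structure$meta[setdiff(names(structure$meta), "helices")],
    helices = structure$meta$helices
  )
  jsonlite::write_json(side, p_tags, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(c(p_of, p_if, p_tags))
}

#' Read a toy structure and reference pair written by [write_structure()]
#'
#' Coordinates are taken from the full-precision sidecar; the PDB files are
#' parsed and validated against it (atom counts, CA naming, chain layout,
#' coordinates to PDB precision). A missing sidecar or any mismatch is an
#' error naming the offending record.
#'
#' @param prefix the path prefix used when writing.
#' @return list with `structure` and `refs`.
#' @export
read_structure <- function(prefix) {
  p_of <- paste0(prefix, "_of.pdb")
  p_if <- paste0(prefix, "_if.pdb")
  p_tags <- paste0(prefix, "_tags.json")
  if (!file.exists(p_tags))
    stop(sprintf("tag sidecar '%s' is missing", p_tags))
  if (!file.exists(p_of) || !file.exists(p_if))
    stop("structure PDB file(s) missing")
  side <- jsonlite::read_json(p_tags, simplifyVector = TRUE)
  atoms <- as.data.frame(side$atoms)
  atoms$helix_id <- as.integer(atoms$helix_id)
  atoms$bundle_id <- as.integer(atoms$bundle_id)
  n <- nrow(atoms)
  of_coords <- matrix(as.numeric(unlist(side$of_coords)), ncol = 3)
  if_coords <- matrix(as.numeric(unlist(side$if_coords)), ncol = 3)
  check_pdb <- function(path, xyz_ref, expect_ion) {
    pdb <- bio3d::read.pdb(path)
    at <- pdb$atom
    prot <- at[at$type == "ATOM", ]
    if (nrow(prot) != n)
      stop(sprintf("%s: expected %d ATOM records, found %d", path, n, nrow(prot)))
    bad <- which(prot$elety != "CA")
    if (length(bad))
      stop(sprintf("%s: ATOM record %d is not a CA atom", path, bad[1]))
    pxyz <- as.matrix(prot[, c("x", "y", "z")])
    dmax <- max(abs(pxyz - xyz_ref))
    if (dmax > 1.5e-3) {
      worst <- which.max(apply(abs(pxyz - xyz_ref), 1, max))
      stop(sprintf("%s: ATOM record %d disagrees with the sidecar coordinates", path, worst))
    }
    if (expect_ion) {
      het <- at[at$type == "HETATM", ]
      if (nrow(het) != 1L || het$chain[1] != "X")
        stop(sprintf("%s: expected one HETATM ion on chain X", path))
    }
    invisible(TRUE)
  }
  ion <- list(present = isTRUE(side$ion$present),
              position = as.numeric(unlist(side$ion$position)))
  check_pdb(p_of, of_coords, ion$present)
  check_pdb(p_if, if_coords, FALSE)
  meta <- side$meta
  meta$site_helices <- stats::setNames(as.integer(unlist(meta$site_helices)),
                                       c("moving", "fixed"))
  meta$substrate_pairs <- lapply(meta$substrate_pairs, as.integer)
  meta$helices <- as.data.frame(side$helices)
  structure_out <- structure(list(atoms = atoms, coords = of_coords,
                                  ion = ion, meta = meta),
                             class = "toy_structure")
  refs <- structure(list(of_coords = of_coords, if_coords = if_coords,
                         axis = as.numeric(unlist(side$rocking$axis)),
                         angle_deg = as.numeric(side$rocking$angle_deg)),
                    class = "reference_pair")
  list(structure = structure_out, refs = refs)
}

#' Write a trajectory as multi-frame XYZ plus a JSON sidecar
#'
#' `<prefix>.xyz` holds one standard XYZ block per frame (count line, a
#' comment line with the frame index and step, then `CA x y z` records, the
#' ion as `ION`); `<prefix>.json` records dt, stride, seed, ion flag, frame
#' steps and provenance.
#'
#' @param traj a `cg_trajectory`.
#' @param prefix output path prefix.
#' @return invisibly, the two paths.
#' @export
write_trajectory <- function(traj, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  p_xyz <- paste0(prefix, ".xyz")
  p_json <- paste0(prefix, ".json")
  con <- file(p_xyz, "w")
  on.exit(close(con))
  frames <- traj_frames(traj)
  n <- nrow(frames[[1]])
  labels <- rep("CA", n)
  if (traj$ion_present) labels[n] <- "ION"
  for (i in seq_along(frames)) {
    writeLines(c(sprintf("%d", n),
                 sprintf("frame %d step %d time %.6f", i, traj$frame_steps[i],
                         traj$frame_steps[i] * traj$dt)), con)
    writeLines(sprintf("%s %.9f %.9f %.9f", labels,
                       frames[[i]][, 1], frames[[i]][, 2], frames[[i]][, 3]), con)
  }
  meta <- list(dt = traj$dt, stride = traj$stride, seed = traj$seed,
               ion_present = traj$ion_present, frame_steps = traj$frame_steps,
               provenance = traj$provenance)
  jsonlite::write_json(meta, p_json, digits = NA, auto_unbox = TRUE)
  invisible(c(p_xyz, p_json))
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param prefix the path prefix used when writing.
#' @return a `cg_trajectory`.
#' @export
read_trajectory <- function(prefix) {
  p_xyz <- paste0(prefix, ".xyz")
  p_json <- paste0(prefix, ".json")
  if (!file.exists(p_json))
    stop(sprintf("trajectory sidecar '%s' is missing", p_json))
  meta <- jsonlite::read_json(p_json, simplifyVector = TRUE)
  lines <- readLines(p_xyz)
  frames <- list()
  pos <- 1L
  while (pos <= length(lines)) {
    n <- suppressWarnings(as.integer(lines[pos]))
    if (is.na(n)) stop(sprintf("malformed XYZ count line at line %d", pos))
    block <- lines[(pos + 2L):(pos + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + n
  }
  as_trajectory(frames, dt = meta$dt, stride = meta$stride, seed = meta$seed,
                ion_present = meta$ion_present,
                frame_steps = meta$frame_steps,
                provenance = as.list(meta$provenance))
}
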