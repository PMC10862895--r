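# Topology and trajectory containers. Coordinates are in Angstrom throughout.

#' Build a topology
#'
#' @param atoms data.frame with columns `atom_id` (unique integers),
#'   `atom_name`, `element`, `residue_id`, `residue_name`, `chain`.
#' @param bonds optional two-column integer matrix of bonded `atom_id` pairs.
#'   When absent, the hydrogen-bond detector infers each hydrogen's donor as
#'   the nearest N/O/S heavy atom within 1.2 Angstrom.
#' @param nucleotide_protons named list mapping proton labels (e.g. `"a"` to
#'   `"d"`) to the atom id(s) carrying them; a label may map to several
#'   equivalent atoms (the `"d"` methylene pair). All must be hydrogens.
#' @return an object of class `topology`.
#' @export
topology <- function(atoms, bonds = NULL, nucleotide_protons = list()) {
  need <- c("atom_id", "atom_name", "element", "residue_id", "residue_name",
            "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    ss_validation_error("atoms",
                        paste("missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(atoms$atom_id))
    ss_validation_error("atoms", "atom_id values must be unique")
  if (!is.null(bonds)) {
    bonds <- as.matrix(bonds)
    if (ncol(bonds) != 2L)
      ss_validation_error("bonds", "must be a two-column matrix")
    if (!all(bonds %in% atoms$atom_id))
      ss_validation_error("bonds", "refer to unknown atom ids")
  }
  if (length(nucleotide_protons)) {
    if (is.null(names(nucleotide_protons)))
      ss_validation_error("nucleotide_protons", "must be a named list")
    ids <- unlist(nucleotide_protons, use.names = FALSE)
    bad <- setdiff(ids, atoms$atom_id)
    if (length(bad))
      ss_validation_error("nucleotide_protons",
                          paste("unknown atom ids:", paste(bad, collapse = ", ")))
    elems <- atoms$element[match(ids, atoms$atom_id)]
    if (any(elems != "H"))
      ss_validation_error("nucleotide_protons", "labeled atoms must be hydrogens")
  }
  structure(list(atoms = atoms, bonds = bonds,
                 nucleotide_protons = nucleotide_protons),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d atoms, %d residues, %d labeled nucleotide protons\n",
              nrow(x$atoms), length(unique(x$atoms$residue_id)),
              length(x$nucleotide_protons)))
  invisible(x)
}

#' Build a trajectory
#'
#' @param topology a [topology()].
#' @param frames a numeric array `n_frames x n_atoms x 3` of Angstrom
#'   coordinates, atom order matching `topology$atoms`.
#' @param frame_interval frame spacing in ps (metadata only).
#' @param replica_id replica index (metadata only).
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(topology, frames, frame_interval = 1, replica_id = 1L) {
  if (!inherits(topology, "topology"))
    ss_validation_error("topology", "must be a topology")
  if (length(dim(frames)) != 3L || dim(frames)[2] != nrow(topology$atoms) ||
      dim(frames)[3] != 3L)
    ss_validation_error("frames",
                        "must be an n_frames x n_atoms x 3 array matching the topology")
  if (dim(frames)[1] < 1L)
    ss_validation_error("frames", "need at least one frame")
  structure(list(topology = topology, frames = frames,
                 frame_interval = frame_interval,
                 replica_id = as.integer(replica_id)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> replica %d: %d frames x %d atoms\n",
              x$replica_id, dim(x$frames)[1], dim(x$frames)[2]))
  invisible(x)
}

n_frames <- function(traj) dim(traj$frames)[1]

# One frame as an n_atoms x 3 matrix.
frame_coords <- function(traj, i) {
  matrix(traj$frames[i, , ], ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}
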