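# Minimal multi-model PDB reader/writer. PDB is a fixed-column format; only
# the records a coordinate trajectory needs (MODEL/ATOM/HETATM/ENDMDL/END)
# are handled. No pre-installed R package in this stack reads multi-model
# PDB, hence the in-package implementation; it is round-trip tested.

#' Write a trajectory as a multi-model PDB file
#'
#' Each frame becomes one `MODEL`/`ENDMDL` block of `ATOM` records with the
#' element column populated; coordinates in Angstrom with 3 decimals (the PDB
#' fixed-column precision, so a read-back round-trips only to 1e-3).
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  if (!inherits(traj, "trajectory"))
    ss_validation_error("traj", "must be a trajectory")
  at <- traj$topology$atoms
  name4 <- ifelse(nchar(at$atom_name) < 4L,
                  sprintf(" %-3s", at$atom_name),
                  substr(at$atom_name, 1, 4))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    writeLines(sprintf("MODEL %8d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$atom_id %% 100000L, name4, substr(at$residue_name, 1, 3),
      substr(at$chain, 1, 1), at$residue_id %% 10000L,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Parses `MODEL`/`ATOM`/`HETATM`/`ENDMDL` records by fixed columns. Every
#' model must contain the same atoms in the same order; frames with missing
#' atoms are rejected rather than imputed.
#'
#' @param path PDB file path.
#' @param nucleotide_protons optional named list of proton labels to atom ids,
#'   attached to the resulting topology (PDB itself cannot carry the labels).
#' @param frame_interval frame spacing in ps (metadata).
#' @param replica_id replica index (metadata).
#' @return a [trajectory()].
#' @export
read_trajectory_pdb <- function(path, nucleotide_protons = list(),
                                frame_interval = 1, replica_id = 1L) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_id <- cumsum(startsWith(lines, "MODEL"))
  if (!any(is_atom)) ss_input_error("no ATOM records found")
  if (max(model_id) == 0L) model_id <- rep(1L, length(lines))  # single model
  al <- lines[is_atom]
  mid <- model_id[is_atom]
  parse_num <- function(from, to) as.numeric(substr(al, from, to))
  atoms_all <- data.frame(
    atom_id = as.integer(substr(al, 7, 11)),
    atom_name = trimws(substr(al, 13, 16)),
    residue_name = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    residue_id = as.integer(substr(al, 23, 26)),
    x = parse_num(31, 38), y = parse_num(39, 46), z = parse_num(47, 54),
    element = trimws(substr(al, 77, 78)),
    stringsAsFactors = FALSE)
  first <- atoms_all[mid == mid[1], ]
  n_at <- nrow(first)
  counts <- table(mid)
  if (any(counts != n_at))
    ss_input_error(sprintf(
      "models differ in atom count (expected %d): frames with missing atoms are rejected",
      n_at))
  nf <- length(counts)
  key_all <- paste(atoms_all$atom_id, atoms_all$atom_name)
  if (!all(key_all == rep(key_all[seq_len(n_at)], nf)))
    ss_input_error("models differ in atom identity/order")
  frames <- array(NA_real_, dim = c(nf, n_at, 3))
  frames[, , 1] <- matrix(atoms_all$x, nrow = nf, byrow = TRUE)
  frames[, , 2] <- matrix(atoms_all$y, nrow = nf, byrow = TRUE)
  frames[, , 3] <- matrix(atoms_all$z, nrow = nf, byrow = TRUE)
  topo <- topology(first[, c("atom_id", "atom_name", "element", "residue_id",
                             "residue_name", "chain")],
                   nucleotide_protons = nucleotide_protons)
  trajectory(topo, frames, frame_interval = frame_interval,
             replica_id = replica_id)
}
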