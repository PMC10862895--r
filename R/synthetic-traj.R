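# Toy-trajectory generator: builds replica coordinate trajectories in which
# hydrogen-bond occupancies and nucleotide-proton closest-residue fractions
# are realized by construction, so the trajectory analyses can be tested
# against scheduled ground truth. Geometry is schematic, not physical: every
# scheduled interaction lives in its own spatial zone, far from all others,
# so schedules do not interfere.
#
# Layout (Angstrom):
#   - labeled nucleotide proton j sits at (200*j, 0, 0): protons are 200 apart
#     so one residue marker can never be near two protons at once;
#   - protein residue i has its home base at (0, 500 + 100*i, 0) carrying a
#     donor N, its bonded H, an acceptor O and a side marker proton HS;
#   - a scheduled H-bond moves the acceptor residue's O onto the donor's N-H
#     axis at 2.0 A (bonded frames) or 4.0 A (broken frames), i.e. safely
#     inside/outside the 2.4 A / 120 deg detection cutoffs;
#   - a scheduled proximity event moves the residue's HS to 3.0 A from the
#     proton (inside the 6 A radius); at home it is ~500 A away.

#' Specification for toy replica trajectories
#'
#' @param topology a [topology()] containing the scheduled donors, acceptors
#'   and labeled nucleotide protons — normally built with [toy_topology()].
#' @param hbond_schedule named numeric vector of target occupancy fractions in
#'   \[0, 1\]; names are `"donorRes-acceptorRes"` residue-id pairs, e.g.
#'   `"205-230"`.
#' @param proximity_schedule named numeric vector of target closest-residue
#'   fractions; names are `"label:residue"` pairs, e.g. `"a:52"`. A label that
#'   maps to several equivalent atoms applies to each atom; individual atoms
#'   can be addressed as `"label#i:residue"` (e.g. `"d#2:50"`). Per proton
#'   atom, fractions must sum to <= 1; the remainder is the
#'   "no protein proton within radius" share.
#' @param jitter_sd per-coordinate Gaussian jitter in Angstrom (drives RMSF).
#' @param n_frames frames per replica.
#' @param n_replicas number of independent replicas (default 100, the usual
#'   replica-ensemble size).
#' @param assignment `"deterministic"` (default): targets are realized by
#'   exact frame counting, `round(f * n_frames)` frames per class, removing
#'   sampling error; `"bernoulli"`: each frame draws its class independently,
#'   giving binomial replica-to-replica variability.
#' @param seed integer RNG seed.
#' @return an object of class `toy_traj_spec`.
#' @export
toy_trajectory_spec <- function(topology, hbond_schedule = numeric(),
                                proximity_schedule = numeric(),
                                jitter_sd = 0, n_frames = 100L,
                                n_replicas = 100L,
                                assignment = c("deterministic", "bernoulli"),
                                seed = 1L) {
  if (!inherits(topology, "topology"))
    ss_validation_error("topology", "must be a topology")
  assignment <- match.arg(assignment)
  stopifnot_scalar_number(jitter_sd, "jitter_sd", nonnegative = TRUE)
  if (n_frames < 1) ss_validation_error("n_frames", "must be >= 1")
  if (n_replicas < 1) ss_validation_error("n_replicas", "must be >= 1")
  if (length(hbond_schedule) &&
      (any(hbond_schedule < 0) || any(hbond_schedule > 1)))
    ss_validation_error("hbond_schedule", "occupancies must lie in [0, 1]")
  if (length(proximity_schedule) &&
      (any(proximity_schedule < 0) || any(proximity_schedule > 1)))
    ss_validation_error("proximity_schedule", "fractions must lie in [0, 1]")
  structure(list(topology = topology, hbond_schedule = hbond_schedule,
                 proximity_schedule = proximity_schedule,
                 jitter_sd = jitter_sd, n_frames = as.integer(n_frames),
                 n_replicas = as.integer(n_replicas), assignment = assignment,
                 seed = as.integer(seed)),
            class = "toy_traj_spec")
}

#' Build a toy topology for scheduled trajectories
#'
#' One pseudo-nucleotide residue (`GDP`, chain `X`, residue 1000) carrying the
#' labeled protons, and one schematic protein residue per requested id, each
#' with a donor nitrogen `N`, its hydrogen `H`, an acceptor oxygen `O` and one
#' side marker proton `HS<k>` per labeled nucleotide proton atom (so a residue
#' can be scheduled against several protons without its markers competing).
#'
#' @param residue_ids integer ids of the protein residues.
#' @param residue_names optional names (default `"GLY"`).
#' @param proton_labels labels for the nucleotide protons; label `"d"` gets
#'   two equivalent atoms, all others one.
#' @return a [topology()] whose attribute `"rest"` holds the rest-state
#'   coordinate matrix used by [generate_toy_trajectories()].
#' @export
toy_topology <- function(residue_ids, residue_names = NULL,
                         proton_labels = c("a", "b", "c", "d")) {
  if (is.null(residue_names)) residue_names <- rep("GLY", length(residue_ids))
  rows <- list(); coords <- list(); prot_map <- list()
  next_id <- 1L
  add_atom <- function(name, element, res_id, res_name, chain, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      atom_id = next_id, atom_name = name, element = element,
      residue_id = res_id, residue_name = res_name, chain = chain,
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- xyz
    next_id <<- next_id + 1L
    next_id - 1L
  }
  for (j in seq_along(proton_labels)) {
    lab <- proton_labels[j]
    n_equiv <- if (lab == "d") 2L else 1L
    ids <- integer(n_equiv)
    for (e in seq_len(n_equiv)) {
      # equivalent atoms 80 A apart: independent proximity zones
      pos <- c(200 * j + 80 * (e - 1L), 0, 0)
      ids[e] <- add_atom(paste0("H", toupper(lab), if (n_equiv > 1L) e else ""),
                         "H", 1000L, "GDP", "X", pos)
    }
    prot_map[[lab]] <- ids
  }
  n_proton_atoms <- length(unlist(prot_map))
  for (i in seq_along(residue_ids)) {
    base <- c(0, 500 + 100 * i, 0)
    rid <- residue_ids[i]; rname <- residue_names[i]
    add_atom("N", "N", rid, rname, "A", base)
    add_atom("H", "H", rid, rname, "A", base + c(1, 0, 0))
    add_atom("O", "O", rid, rname, "A", base + c(10, 0, 0))
    for (k in seq_len(n_proton_atoms))
      add_atom(paste0("HS", k), "H", rid, rname, "A", base + c(0, 10 + 2 * k, 0))
  }
  topo <- topology(do.call(rbind, rows), nucleotide_protons = prot_map)
  attr(topo, "rest") <- do.call(rbind, coords)
  topo
}

# Resolve "label" / "label#i" schedule keys to proton atom ids.
resolve_proton_key <- function(key, topo) {
  parts <- strsplit(key, "#", fixed = TRUE)[[1]]
  lab <- parts[1]
  ids <- topo$nucleotide_protons[[lab]]
  if (is.null(ids))
    ss_validation_error("proximity_schedule",
                        sprintf("unknown proton label '%s'", lab))
  if (length(parts) == 2L) {
    i <- as.integer(parts[2])
    if (is.na(i) || i < 1L || i > length(ids))
      ss_validation_error("proximity_schedule",
                          sprintf("bad equivalent-atom index in '%s'", key))
    ids <- ids[i]
  }
  ids
}

# Frame-index assignment for one schedule (named fractions -> list of index
# vectors). Deterministic: consecutive blocks of round(f*n) frames.
# Bernoulli: one categorical draw per frame.
assign_frames <- function(fractions, n, assignment) {
  if (!length(fractions)) return(list())
  if (sum(fractions) > 1 + 1e-9)
    ss_construction_error(sprintf(
      "unsatisfiable schedule: fractions sum to %.3f > 1 for {%s}",
      sum(fractions), paste(names(fractions), collapse = ", ")))
  if (assignment == "deterministic") {
    counts <- round(fractions * n)
    if (sum(counts) > n)
      ss_construction_error(
        "unsatisfiable schedule: rounded frame counts exceed n_frames")
    start <- cumsum(c(0, counts[-length(counts)]))
    out <- lapply(seq_along(counts), function(i)
      if (counts[i] > 0) seq.int(start[i] + 1L, start[i] + counts[i])
      else integer())
  } else {
    draw <- sample.int(length(fractions) + 1L, n, replace = TRUE,
                       prob = c(fractions, max(0, 1 - sum(fractions))))
    out <- lapply(seq_along(fractions), function(i) which(draw == i))
  }
  names(out) <- names(fractions)
  out
}

#' Generate toy replica trajectories with scheduled interactions
#'
#' Constructs `n_replicas` trajectories in which each scheduled hydrogen bond
#' satisfies the geometric criterion (H...A at 2.0 Angstrom, angle 180 deg) in
#' exactly its target fraction of frames (H...A at 4.0 Angstrom otherwise),
#' and each scheduled proton–residue pair is the closest protein proton within
#' the radius in its target fraction of frames. Gaussian jitter is then added
#' to every coordinate. Identical spec and seed give identical output.
#'
#' Under the default deterministic assignment the realized frame counts equal
#' `round(f * n_frames)` exactly in every replica; `"bernoulli"` assignment
#' draws each frame's class independently instead, so realized fractions vary
#' binomially between replicas.
#'
#' @param spec a [toy_trajectory_spec()].
#' @return a list of [trajectory()] objects.
#' @export
generate_toy_trajectories <- function(spec) {
  if (!inherits(spec, "toy_traj_spec"))
    ss_validation_error("spec", "must be a toy_traj_spec")
  topo <- spec$topology
  rest <- attr(topo, "rest")
  if (is.null(rest))
    ss_construction_error("topology lacks rest coordinates; use toy_topology()")
  at <- topo$atoms
  n <- spec$n_frames
  idx_of <- function(id) match(id, at$atom_id)
  res_atom <- function(rid, name) {
    i <- which(at$residue_id == rid & at$atom_name == name)
    if (!length(i))
      ss_construction_error(sprintf("residue %s has no atom '%s'", rid, name))
    i[1]
  }

  # ---- parse hbond schedule: each acceptor residue may serve one pair ----
  hb <- spec$hbond_schedule
  hb_pairs <- NULL
  if (length(hb)) {
    parts <- strsplit(names(hb), "-", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      ss_validation_error("hbond_schedule",
                          "names must be 'donorRes-acceptorRes'")
    hb_pairs <- data.frame(donor = as.integer(vapply(parts, `[`, "", 1)),
                           acceptor = as.integer(vapply(parts, `[`, "", 2)),
                           frac = as.numeric(hb))
    dup <- hb_pairs$acceptor[duplicated(hb_pairs$acceptor)]
    if (length(dup))
      ss_construction_error(sprintf(
        "conflicting H-bond schedule: acceptor residue(s) %s appear in more than one pair",
        paste(unique(dup), collapse = ", ")))
  }

  # ---- parse proximity schedule, grouped per proton atom ----
  px <- spec$proximity_schedule
  px_by_atom <- list()   # atom_id (as char) -> named fractions (residue ids)
  if (length(px)) {
    keys <- strsplit(names(px), ":", fixed = TRUE)
    if (any(lengths(keys) != 2L))
      ss_validation_error("proximity_schedule", "names must be 'label:residue'")
    for (i in seq_along(px)) {
      atom_ids <- resolve_proton_key(keys[[i]][1], topo)
      rid <- keys[[i]][2]
      for (aid in atom_ids) {
        k <- as.character(aid)
        px_by_atom[[k]] <- c(px_by_atom[[k]],
                             stats::setNames(px[[i]], rid))
      }
    }
    for (k in names(px_by_atom))
      if (anyDuplicated(names(px_by_atom[[k]])))
        ss_construction_error(sprintf(
          "conflicting proximity schedule for proton atom %s: duplicate residue targets",
          k))
  }

  set.seed(spec$seed)
  lapply(seq_len(spec$n_replicas), function(rep_i) {
    frames <- array(rep(rest, each = n), dim = c(n, nrow(at), 3))

    # hydrogen bonds: move the acceptor residue's O along the donor N-H axis.
    # Pairs are independent events (each owns its acceptor O), so each is
    # frame-assigned on its own.
    if (!is.null(hb_pairs)) {
      hb_idx <- lapply(seq_len(nrow(hb_pairs)), function(p)
        assign_frames(stats::setNames(hb_pairs$frac[p], "on"),
                      n, spec$assignment)[[1]])
      for (p in seq_len(nrow(hb_pairs))) {
        iN <- res_atom(hb_pairs$donor[p], "N")
        iH <- res_atom(hb_pairs$donor[p], "H")
        iO <- res_atom(hb_pairs$acceptor[p], "O")
        axis <- rest[iH, ] - rest[iN, ]
        axis <- axis / sqrt(sum(axis^2))
        bonded <- hb_idx[[p]]
        pos_on <- rest[iH, ] + 2.0 * axis
        pos_off <- rest[iH, ] + 4.0 * axis
        for (d in 1:3) {
          frames[, iO, d] <- pos_off[d]
          if (length(bonded)) frames[bonded, iO, d] <- pos_on[d]
        }
      }
    }

    # proximity: move the residue's marker proton dedicated to this
    # nucleotide-proton atom next to the proton in the assigned frames.
    # Unsatisfiable schedules (per-proton fractions summing past 1) error
    # out in assign_frames.
    if (length(px_by_atom)) {
      proton_atom_ids <- unlist(topo$nucleotide_protons, use.names = FALSE)
      for (k in names(px_by_atom)) {
        fr <- px_by_atom[[k]]
        blocks <- assign_frames(fr, n, spec$assignment)
        p_idx <- idx_of(as.integer(k))
        marker <- paste0("HS", match(as.integer(k), proton_atom_ids))
        for (b in seq_along(blocks)) {
          fset <- blocks[[b]]
          iHS <- res_atom(as.integer(names(fr)[b]), marker)
          if (length(fset)) {
            for (d in 1:3)
              frames[fset, iHS, d] <- rest[p_idx, d] + c(3, 0, 0)[d]
          }
        }
      }
    }

    if (spec$jitter_sd > 0)
      frames <- frames + stats::rnorm(length(frames), sd = spec$jitter_sd)
    trajectory(topo, frames, replica_id = rep_i)
  })
}
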