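# Trajectory post-processing: geometric hydrogen-bond detection, inter-switch
# occupancy matrices with persistence thresholds, per-residue backbone RMSF,
# and nucleotide-proton closest-residue proximity profiles.

#' Hydrogen-bond geometric criteria
#'
#' A donor–hydrogen...acceptor triplet qualifies when the H...A distance is
#' below `max_ha_distance` and the D–H...A angle (180 deg = linear) exceeds
#' `min_dha_angle`.
#'
#' @param max_ha_distance Angstrom, default 2.4.
#' @param min_dha_angle degrees in (0, 180], default 120.
#' @return an object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_ha_distance = 2.4, min_dha_angle = 120) {
  stopifnot_scalar_number(max_ha_distance, "max_ha_distance", positive = TRUE)
  if (min_dha_angle <= 0 || min_dha_angle > 180)
    ss_validation_error("min_dha_angle", "must lie in (0, 180]")
  structure(list(max_ha_distance = max_ha_distance,
                 min_dha_angle = min_dha_angle),
            class = "hbond_criteria")
}

#' Named switch-region residue ranges
#'
#' @param regions named list of integer residue-id vectors (use `seq`) — the
#'   default covers the three switch regions of the stimulatory Galpha subunit
#'   in 1AZT chain-B author numbering (Switch I 197–207, II 225–235,
#'   III 252–268); these annotations are editable configuration, not a fixed
#'   truth.
#' @return an object of class `region_map`.
#' @export
region_map <- function(regions = list(switch1 = 197:207, switch2 = 225:235,
                                      switch3 = 252:268)) {
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    ss_config_error("regions must be a named list")
  if (any(lengths(regions) == 0L))
    ss_config_error("empty region in region map")
  all_ids <- unlist(regions, use.names = FALSE)
  if (anyDuplicated(all_ids))
    ss_config_error("region residue ranges must be disjoint")
  structure(regions, class = "region_map")
}

# Donor heavy atom index for each hydrogen: bonded heavy atom if bonds are
# present, else nearest N/O/S within 1.2 A. NA when no donor (non-polar or
# free hydrogen).
donor_of_hydrogens <- function(xyz, topo, h_idx) {
  at <- topo$atoms
  heavy <- which(at$element %in% c("N", "O", "S"))
  if (!is.null(topo$bonds)) {
    vapply(h_idx, function(i) {
      id <- at$atom_id[i]
      partners <- c(topo$bonds[topo$bonds[, 1] == id, 2],
                    topo$bonds[topo$bonds[, 2] == id, 1])
      j <- match(partners, at$atom_id)
      j <- j[j %in% heavy]
      if (length(j)) j[1] else NA_integer_
    }, integer(1))
  } else {
    vapply(h_idx, function(i) {
      if (!length(heavy)) return(NA_integer_)
      d <- dist_to(xyz[i, ], xyz[heavy, , drop = FALSE])
      j <- heavy[which.min(d)]
      if (min(d) <= 1.2) j else NA_integer_
    }, integer(1))
  }
}

#' Detect hydrogen bonds in one frame
#'
#' Geometric detection on explicit-hydrogen coordinates. For each hydrogen,
#' the donor is its covalently bonded N/O/S heavy atom (from the topology's
#' bond list when present, otherwise the nearest N/O/S within 1.2 Angstrom);
#' acceptors are any N or O that is neither the donor itself nor bonded to
#' the hydrogen. A triplet is reported when H...A distance <
#' `criteria$max_ha_distance` and D–H...A angle > `criteria$min_dha_angle`.
#'
#' @param frame `n_atoms x 3` coordinate matrix in Angstrom (or a
#'   [trajectory()] plus `frame_index`).
#' @param topo the [topology()].
#' @param criteria an [hbond_criteria()].
#' @return a data.frame with columns `donor`, `hydrogen`, `acceptor` (atom
#'   ids), `distance`, `angle`; zero rows when nothing qualifies.
#' @export
detect_hbonds_frame <- function(frame, topo, criteria = hbond_criteria()) {
  if (inherits(frame, "trajectory"))
    ss_validation_error("frame", "pass a coordinate matrix, not a trajectory")
  at <- topo$atoms
  h_idx <- which(at$element == "H")
  if (!length(h_idx))
    ss_config_error("no hydrogens in topology: explicit-H input required")
  donors <- donor_of_hydrogens(frame, topo, h_idx)
  keep <- !is.na(donors)
  h_idx <- h_idx[keep]; donors <- donors[keep]
  acc_all <- which(at$element %in% c("N", "O"))
  out <- list()
  for (k in seq_along(h_idx)) {
    iH <- h_idx[k]; iD <- donors[k]
    acc <- setdiff(acc_all, iD)
    if (!is.null(topo$bonds)) {
      idH <- at$atom_id[iH]
      bonded <- c(topo$bonds[topo$bonds[, 1] == idH, 2],
                  topo$bonds[topo$bonds[, 2] == idH, 1])
      acc <- setdiff(acc, match(bonded, at$atom_id))
    }
    if (!length(acc)) next
    dHA <- dist_to(frame[iH, ], frame[acc, , drop = FALSE])
    cand <- which(dHA < criteria$max_ha_distance)
    if (!length(cand)) next
    u <- frame[iD, ] - frame[iH, ]
    nu <- sqrt(sum(u^2))
    for (c_i in cand) {
      iA <- acc[c_i]
      v <- frame[iA, ] - frame[iH, ]
      cosang <- sum(u * v) / (nu * sqrt(sum(v^2)))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang > criteria$min_dha_angle)
        out[[length(out) + 1L]] <- data.frame(
          donor = at$atom_id[iD], hydrogen = at$atom_id[iH],
          acceptor = at$atom_id[iA], distance = dHA[c_i], angle = ang)
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric()))
  do.call(rbind, out)
}

#' Inter-region hydrogen-bond occupancy matrix
#'
#' For every residue pair whose members fall in two *different* named regions,
#' the fraction of frames with at least one qualifying hydrogen bond between
#' any atoms of the two residues, in either donor/acceptor direction.
#' Intra-region pairs are excluded. Pairs never observed bonded are omitted
#' (occupancy zero).
#'
#' @param traj a [trajectory()].
#' @param regions a [region_map()].
#' @param criteria an [hbond_criteria()].
#' @return an object of class `occupancy_matrix`: a data.frame with columns
#'   `donor_res`, `acceptor_res`, `region_pair`, `occupancy`, with attribute
#'   `n_frames`. Direction is canonicalized to `donor_res < acceptor_res`.
#' @export
hbond_occupancy <- function(traj, regions = region_map(),
                            criteria = hbond_criteria()) {
  if (!inherits(regions, "region_map"))
    ss_config_error("regions must be a region_map")
  at <- traj$topology$atoms
  region_of <- rep(NA_character_, max(at$residue_id))
  for (nm in names(regions)) region_of[regions[[nm]]] <- nm
  nf <- n_frames(traj)
  counts <- new.env(parent = emptyenv())
  for (f in seq_len(nf)) {
    hb <- detect_hbonds_frame(frame_coords(traj, f), traj$topology, criteria)
    if (!nrow(hb)) next
    rd <- at$residue_id[match(hb$donor, at$atom_id)]
    ra <- at$residue_id[match(hb$acceptor, at$atom_id)]
    reg_d <- region_of[rd]; reg_a <- region_of[ra]
    ok <- !is.na(reg_d) & !is.na(reg_a) & reg_d != reg_a & rd != ra
    if (!any(ok)) next
    lo <- pmin(rd[ok], ra[ok]); hi <- pmax(rd[ok], ra[ok])
    keys <- unique(paste(lo, hi, sep = "-"))
    for (key in keys)
      assign(key, (if (exists(key, counts)) get(key, counts) else 0L) + 1L,
             counts)
  }
  keys <- ls(counts)
  if (length(keys)) {
    parts <- strsplit(keys, "-", fixed = TRUE)
    lo <- as.integer(vapply(parts, `[`, "", 1))
    hi <- as.integer(vapply(parts, `[`, "", 2))
    df <- data.frame(
      donor_res = lo, acceptor_res = hi,
      region_pair = paste(region_of[lo], region_of[hi], sep = ":"),
      occupancy = vapply(keys, get, numeric(1), envir = counts) / nf)
    df <- df[order(df$donor_res, df$acceptor_res), ]
    rownames(df) <- NULL
  } else {
    df <- data.frame(donor_res = integer(), acceptor_res = integer(),
                     region_pair = character(), occupancy = numeric())
  }
  structure(df, class = c("occupancy_matrix", "data.frame"), n_frames = nf)
}

#' Apply persistence thresholds to an occupancy matrix
#'
#' Adds one logical column per threshold (`ge_<t>`: occupancy >= t) and a
#' `levels_passed` count — the colour-intensity level of a persistence plot.
#' The mask is monotone by construction: passing a higher threshold implies
#' passing every lower one.
#'
#' @param matrix an [hbond_occupancy()] result.
#' @param thresholds ascending occupancy cutoffs in (0, 1]; the default
#'   `c(0.1, 0.25, 0.5, 0.75)` is a documented configuration choice.
#' @return the matrix with mask columns and `levels_passed` appended;
#'   attribute `thresholds` records the cutoffs.
#' @export
persistence_mask <- function(matrix, thresholds = c(0.1, 0.25, 0.5, 0.75)) {
  if (any(thresholds <= 0) || any(thresholds > 1))
    ss_validation_error("thresholds", "must lie in (0, 1]")
  if (is.unsorted(thresholds, strictly = TRUE))
    ss_validation_error("thresholds", "must be sorted strictly ascending")
  out <- matrix
  for (t in thresholds)
    out[[sprintf("ge_%g", t)]] <- matrix$occupancy >= t
  out$levels_passed <- rowSums(outer(matrix$occupancy, thresholds, `>=`))
  attr(out, "thresholds") <- thresholds
  out
}

# Kabsch rotation R minimizing ||P R - Q|| for centred P, Q (n x 3).
kabsch_rotation <- function(P, Q) {
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Per-residue backbone RMSF
#'
#' Per atom, \eqn{RMSF_i = \sqrt{\langle \|x_i(t) - \langle x_i\rangle\|^2
#' \rangle_t}} — the deviation about the atom's trajectory-average position;
#' per residue, the mean over the selected backbone atoms. Superposition is
#' off by default (restrained-boundary simulations share a lab frame); with
#' `superpose = TRUE` every frame is least-squares aligned (Kabsch, on the
#' selection) to the average structure first.
#'
#' @param traj a [trajectory()].
#' @param selection backbone atom names (default `c("N", "CA", "C", "O")`).
#'   Atom names not present are simply not selected; an empty selection is an
#'   error.
#' @param superpose align frames to the mean structure before computing.
#' @return an object of class `rmsf_profile`: data.frame with `residue_id`,
#'   `rmsf` (Angstrom); attribute `selection`.
#' @export
compute_rmsf <- function(traj, selection = c("N", "CA", "C", "O"),
                         superpose = FALSE) {
  at <- traj$topology$atoms
  sel <- which(at$atom_name %in% selection)
  if (!length(sel))
    ss_config_error("backbone selection matches no atoms")
  nf <- n_frames(traj)
  if (nf == 1L)
    warning("single frame: RMSF is identically zero")
  coords <- traj$frames[, sel, , drop = FALSE]
  if (superpose && nf > 1L) {
    ref <- matrix(coords[1, , ], ncol = 3)
    ref_c <- scale(ref, scale = FALSE)
    for (pass in 1:2) {
      for (f in seq_len(nf)) {
        P <- matrix(coords[f, , ], ncol = 3)
        cen <- colMeans(P)
        Pc <- sweep(P, 2, cen)
        R <- kabsch_rotation(Pc, ref_c)
        coords[f, , ] <- Pc %*% R
      }
      ref_c <- apply(coords, c(2, 3), mean)  # realign to the mean structure
      ref_c <- sweep(ref_c, 2, colMeans(ref_c))
    }
  }
  mean_pos <- apply(coords, c(2, 3), mean)
  dev2 <- sweep(coords, c(2, 3), mean_pos)^2
  atom_rmsf <- sqrt(apply(dev2, 2, sum) / nf)
  res <- at$residue_id[sel]
  prof <- stats::aggregate(atom_rmsf, by = list(residue_id = res), FUN = mean)
  names(prof)[2] <- "rmsf"
  structure(prof[order(prof$residue_id), ],
            class = c("rmsf_profile", "data.frame"), selection = selection)
}

#' Nucleotide-proton closest-residue proximity profile
#'
#' Per frame and per labeled nucleotide proton: find the nearest *protein*
#' hydrogen within `radius`; the frame is attributed to that hydrogen's
#' residue (ties broken by lowest atom id). Frames with no protein hydrogen
#' within the radius accrue to the `none_in_radius` bucket, so per proton the
#' frequencies always sum to 1. Labels mapping to several equivalent atoms
#' (the `'d'` pair) are computed per atom independently and then averaged
#' arithmetically.
#'
#' @param traj a [trajectory()] whose topology labels nucleotide protons.
#' @param radius Angstrom; strict `< radius` (default 6).
#' @param mode `"closest"` (default) attributes each frame to the single
#'   nearest in-radius residue; `"within"` counts, for each residue, the
#'   fraction of frames with *any* of its protons in the radius (a residence
#'   measure; the `none_in_radius` entry is then the fraction of frames with
#'   no residue in radius and frequencies need not sum to 1).
#' @return an object of class `proximity_profile`: a list per proton label,
#'   each a named numeric vector of frequencies over residue ids plus
#'   `none_in_radius`; attributes `radius`, `mode`.
#' @export
proton_proximity_profile <- function(traj, radius = 6,
                                     mode = c("closest", "within")) {
  mode <- match.arg(mode)
  topo <- traj$topology
  if (!length(topo$nucleotide_protons))
    ss_config_error("topology has no labeled nucleotide protons")
  at <- topo$atoms
  nuc_res <- at$residue_id[match(unlist(topo$nucleotide_protons),
                                 at$atom_id)][1]
  prot_h <- which(at$element == "H" & at$residue_id != nuc_res)
  nf <- n_frames(traj)
  profile_for_atom <- function(aid) {
    i_p <- match(aid, at$atom_id)
    tallies <- new.env(parent = emptyenv())
    none <- 0L
    for (f in seq_len(nf)) {
      xyz <- frame_coords(traj, f)
      d <- dist_to(xyz[i_p, ], xyz[prot_h, , drop = FALSE])
      inr <- which(d < radius)
      if (!length(inr)) { none <- none + 1L; next }
      if (mode == "closest") {
        best <- inr[order(d[inr], at$atom_id[prot_h[inr]])][1]
        key <- as.character(at$residue_id[prot_h[best]])
        assign(key, (if (exists(key, tallies)) get(key, tallies) else 0L) + 1L,
               tallies)
      } else {
        for (key in unique(as.character(at$residue_id[prot_h[inr]])))
          assign(key, (if (exists(key, tallies)) get(key, tallies) else 0L) + 1L,
                 tallies)
      }
    }
    keys <- ls(tallies)
    freqs <- stats::setNames(
      vapply(keys, get, numeric(1), envir = tallies) / nf, keys)
    c(freqs[order(as.integer(keys))], none_in_radius = none / nf)
  }
  out <- lapply(topo$nucleotide_protons, function(ids) {
    profs <- lapply(ids, profile_for_atom)
    if (length(profs) == 1L) return(profs[[1]])
    keys <- unique(unlist(lapply(profs, names)))
    avg <- vapply(keys, function(k)
      mean(vapply(profs, function(p) if (k %in% names(p)) p[[k]] else 0,
                  numeric(1))), numeric(1))
    nk <- setdiff(keys, "none_in_radius")
    c(avg[nk][order(as.integer(nk))],
      none_in_radius = unname(avg["none_in_radius"]))
  })
  structure(out, class = "proximity_profile", radius = radius, mode = mode)
}

#' @export
print.proximity_profile <- function(x, ...) {
  cat(sprintf("<proximity_profile> radius %g A, mode '%s'\n",
              attr(x, "radius"), attr(x, "mode")))
  for (lab in names(x)) {
    v <- x[[lab]]
    cat(sprintf("  %s: %s\n", lab,
                paste(sprintf("%s=%.3f", names(v), v), collapse = ", ")))
  }
  invisible(x)
}

#' Aggregate per-replica values into mean and s.e.m.
#'
#' Accepts a list of per-replica scalars, or a list of equally keyed named
#' vectors (e.g. one proximity vector per replica). The standard error of the
#' mean, `sd / sqrt(n)` with the sample (n-1) standard deviation, is the
#' conventional variability indicator across independent replica simulations.
#'
#' @param values list of numeric scalars or of named numeric vectors.
#' @return an object of class `replica_aggregate`: data.frame with `key`,
#'   `mean`, `sem`, `label` (`"mean±sem"` rendering via [format_mean_sem()],
#'   as a percentage when all values lie in \[0, 1\]); attribute `n_replicas`.
#' @examples
#' aggregate_replicas(list(96, 98))  # 97 ± 1
#' @export
aggregate_replicas <- function(values) {
  if (length(values) < 2L)
    ss_aggregation_error("need >= 2 replicas for an s.e.m.")
  if (all(vapply(values, function(v) is.null(names(v)) && length(v) == 1L,
                 logical(1)))) {
    values <- lapply(values, function(v) c(value = as.numeric(v)))
  }
  keys <- names(values[[1]])
  for (i in seq_along(values)) {
    miss <- setdiff(keys, names(values[[i]]))
    extra <- setdiff(names(values[[i]]), keys)
    if (length(miss) || length(extra))
      ss_aggregation_error(sprintf(
        "replica %d keys mismatch (missing: %s; extra: %s)", i,
        paste(miss, collapse = ","), paste(extra, collapse = ",")))
  }
  n <- length(values)
  m <- do.call(rbind, lapply(values, function(v) v[keys]))
  mu <- colMeans(m)
  sem <- apply(m, 2, stats::sd) / sqrt(n)
  as_pct <- all(m >= 0 & m <= 1)
  structure(data.frame(key = keys, mean = unname(mu), sem = unname(sem),
                       label = vapply(seq_along(keys), function(i)
                         format_mean_sem(mu[i], sem[i], percent = as_pct),
                         character(1)),
                       stringsAsFactors = FALSE),
            class = c("replica_aggregate", "data.frame"), n_replicas = n)
}
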