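# Independent oracles and fixture builders. These deliberately avoid the
# package's fitting/detection code paths: grid searches, closed forms and
# exhaustive enumeration only.

# Two-stage exhaustive grid search minimizing SSE of the Boltzmann sigmoid
# with Top/Bottom fixed at 1/0. Coarse pass over V50 in [t_min, t_max] x
# slope in [0.1, 20], then V50 refined to 0.01 degC around the best cell.
oracle_melt_grid <- function(x, y) {
  sse_grid <- function(v50s, slopes) {
    best <- c(Inf, NA, NA)
    for (s in slopes) {
      # vectorized over v50 for one slope
      sse <- vapply(v50s, function(v) sum((y - 1 / (1 + exp((v - x) / s)))^2),
                    numeric(1))
      i <- which.min(sse)
      if (sse[i] < best[1]) best <- c(sse[i], v50s[i], s)
    }
    best
  }
  coarse <- sse_grid(seq(min(x), max(x), by = 0.1), seq(0.1, 20, by = 0.1))
  fine <- sse_grid(seq(coarse[2] - 0.2, coarse[2] + 0.2, by = 0.01),
                   seq(max(0.1, coarse[3] - 0.2), coarse[3] + 0.2, by = 0.01))
  list(v50 = fine[2], slope = fine[3], sse = fine[1])
}

# 1-D search on k with Y0/Plateau solved as a linear least-squares subproblem.
oracle_kinetics_k <- function(x, y, k_range = c(1e-4, 2)) {
  sse_of_k <- function(k) {
    f <- 1 - exp(-k * x)
    fit <- stats::lm.fit(cbind(1, f), y)
    sum(fit$residuals^2)
  }
  stats::optimize(sse_of_k, k_range, tol = 1e-10)$minimum
}

# Exhaustive hydrogen-bond enumeration: every (hydrogen, acceptor) pair is
# examined with the donor taken as the nearest N/O/S heavy atom within 1.2 A
# (full distance matrix, no pruning).
oracle_hbonds <- function(xyz, atoms, max_ha = 2.4, min_angle = 120) {
  D <- as.matrix(stats::dist(xyz))
  heavy <- which(atoms$element %in% c("N", "O", "S"))
  acceptors <- which(atoms$element %in% c("N", "O"))
  out <- list()
  for (h in which(atoms$element == "H")) {
    if (!length(heavy)) next
    dh <- D[h, heavy]
    d_i <- heavy[which.min(dh)]
    if (min(dh) > 1.2) next
    for (a in acceptors) {
      if (a == d_i) next
      if (D[h, a] >= max_ha) next
      u <- xyz[d_i, ] - xyz[h, ]
      v <- xyz[a, ] - xyz[h, ]
      ang <- acos(max(-1, min(1, sum(u * v) /
                                sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      if (ang > min_angle)
        out[[length(out) + 1L]] <- c(donor = atoms$atom_id[d_i],
                                     hydrogen = atoms$atom_id[h],
                                     acceptor = atoms$atom_id[a])
    }
  }
  if (!length(out))
    return(matrix(integer(), ncol = 3,
                  dimnames = list(NULL, c("donor", "hydrogen", "acceptor"))))
  do.call(rbind, out)
}

# Random packed frame: heavy atoms uniform in a box, each hydrogen bonded at
# 1.0 A to a random heavy atom, so donors and near-contacts actually occur.
random_frame <- function(n_atoms = 50, box = 8, seed = 1) {
  set.seed(seed)
  n_h <- floor(n_atoms * 0.4)
  n_heavy <- n_atoms - n_h
  elements <- c(sample(c("C", "N", "O", "S"), n_heavy, replace = TRUE,
                       prob = c(0.4, 0.25, 0.25, 0.1)),
                rep("H", n_h))
  xyz <- matrix(stats::runif(n_heavy * 3, 0, box), ncol = 3)
  hosts <- sample.int(n_heavy, n_h, replace = TRUE)
  dirs <- matrix(stats::rnorm(n_h * 3), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  xyz <- rbind(xyz, xyz[hosts, , drop = FALSE] + dirs)
  atoms <- data.frame(atom_id = seq_len(n_atoms),
                      atom_name = elements, element = elements,
                      residue_id = seq_len(n_atoms),
                      residue_name = "UNK", chain = "A",
                      stringsAsFactors = FALSE)
  list(xyz = xyz, atoms = atoms)
}

hbond_key_set <- function(df) {
  if (!nrow(df)) return(character())
  sort(paste(df[, "donor"], df[, "hydrogen"], df[, "acceptor"]))
}

# Standard small toy system reused across trajectory tests.
toy_system <- function(residues = c(52L, 173L, 201L, 205L, 230L),
                       labels = c("a", "b", "d")) {
  toy_topology(residues, proton_labels = labels)
}
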