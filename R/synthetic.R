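# Seeded synthetic-data generators for the three solution experiments the
# pipeline analyses: CD thermal melts, tryptophan-fluorescence exchange
# kinetics, and STD-NMR integral tables. These are forward models of the same
# equations the fitting modules invert, so round-trip tests can assert
# parameter recovery.

#' Specification for synthetic CD melting curves
#'
#' Forward model of the Boltzmann sigmoid
#' \deqn{Y = Bottom + (Top - Bottom) / (1 + \exp((V_{50} - X)/Slope))}
#' evaluated on a linear temperature grid (default 25–89 °C in 1 °C steps,
#' matching a 1 °C/min single-wavelength melt) with iid Gaussian noise.
#'
#' @param tm_true true midpoint temperature V50 in °C.
#' @param slope_true true slope parameter in °C (> 0: unfolding transition,
#'   signal ordered folded -> unfolded).
#' @param top,bottom sigmoid asymptotes (defaults 1 and 0, the conventional
#'   normalized folded-fraction scale).
#' @param t_start,t_stop,t_step temperature grid in °C.
#' @param noise_sd Gaussian noise standard deviation as an absolute value on
#'   the signal scale (so with top=1, bottom=0 it is a fraction of amplitude).
#' @param replicates number of replicate curves, differing only by noise.
#' @param seed integer RNG seed.
#' @param variant,nucleotide metadata carried onto the generated curves.
#' @return an object of class `melt_gen_spec`.
#' @seealso [generate_melting_curves()], [fit_melting_curve()]
#' @export
melt_gen_spec <- function(tm_true, slope_true, top = 1, bottom = 0,
                          t_start = 25, t_stop = 89, t_step = 1,
                          noise_sd = 0.02, replicates = 1L, seed = 1L,
                          variant = "WT", nucleotide = "GDP") {
  stopifnot_scalar_number(tm_true, "tm_true")
  stopifnot_scalar_number(slope_true, "slope_true", positive = TRUE)
  stopifnot_scalar_number(t_step, "t_step", positive = TRUE)
  stopifnot_scalar_number(noise_sd, "noise_sd", nonnegative = TRUE)
  if (!is.numeric(replicates) || length(replicates) != 1L || replicates < 1)
    ss_validation_error("replicates", "must be >= 1")
  if (!(t_start < tm_true && tm_true < t_stop))
    ss_validation_error("tm_true", "must satisfy t_start < tm_true < t_stop")
  structure(list(tm_true = tm_true, slope_true = slope_true, top = top,
                 bottom = bottom, t_start = t_start, t_stop = t_stop,
                 t_step = t_step, noise_sd = noise_sd,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 variant = variant, nucleotide = nucleotide),
            class = "melt_gen_spec")
}

boltzmann_sigmoid <- function(x, v50, slope, top = 1, bottom = 0) {
  bottom + (top - bottom) / (1 + exp((v50 - x) / slope))
}

#' Generate synthetic melting curves
#'
#' Evaluates the Boltzmann sigmoid on the spec's temperature grid and adds iid
#' Gaussian noise; replicates differ only by noise. Identical spec and seed
#' give identical output.
#'
#' @param spec a [melt_gen_spec()].
#' @return a list of [melting_curve()] objects, one per replicate.
#' @export
generate_melting_curves <- function(spec) {
  if (!inherits(spec, "melt_gen_spec"))
    ss_validation_error("spec", "must be a melt_gen_spec")
  temps <- seq(spec$t_start, spec$t_stop, by = spec$t_step)
  clean <- boltzmann_sigmoid(temps, spec$tm_true, spec$slope_true,
                             spec$top, spec$bottom)
  set.seed(spec$seed)
  lapply(seq_len(spec$replicates), function(r) {
    y <- clean + stats::rnorm(length(temps), sd = spec$noise_sd)
    melting_curve(temps, y, variant = spec$variant,
                  nucleotide = spec$nucleotide, replicate = r)
  })
}

#' Specification for a synthetic fluorescence exchange trace
#'
#' Forward model of the one-phase association
#' \deqn{Y = Y_0 + (Plateau - Y_0)(1 - e^{-kx})}
#' sampled on a regular time grid (default every 12 s for 200 min, the usual
#' acquisition schedule) with iid Gaussian noise. `plateau` may be below `y0`:
#' some variants show a fluorescence decrease on exchange.
#'
#' @param y0 intensity at time zero (a.u.).
#' @param plateau intensity at infinite time (a.u.).
#' @param k_true true rate constant in reciprocal minutes.
#' @param t_step sampling interval in seconds (default 12).
#' @param t_total total acquisition in minutes (default 200).
#' @param noise_sd Gaussian noise sd in intensity units.
#' @param seed integer RNG seed.
#' @param variant,nucleotide metadata.
#' @return an object of class `kinetic_gen_spec`.
#' @export
kinetic_gen_spec <- function(y0, plateau, k_true, t_step = 12, t_total = 200,
                             noise_sd = 0, seed = 1L, variant = "WT",
                             nucleotide = "GTPgS") {
  stopifnot_scalar_number(y0, "y0")
  stopifnot_scalar_number(plateau, "plateau")
  stopifnot_scalar_number(k_true, "k_true", positive = TRUE)
  stopifnot_scalar_number(t_step, "t_step", positive = TRUE)
  stopifnot_scalar_number(t_total, "t_total", positive = TRUE)
  stopifnot_scalar_number(noise_sd, "noise_sd", nonnegative = TRUE)
  structure(list(y0 = y0, plateau = plateau, k_true = k_true, t_step = t_step,
                 t_total = t_total, noise_sd = noise_sd,
                 seed = as.integer(seed), variant = variant,
                 nucleotide = nucleotide),
            class = "kinetic_gen_spec")
}

one_phase_association <- function(x, y0, plateau, k) {
  y0 + (plateau - y0) * (1 - exp(-k * x))
}

#' Generate a synthetic kinetic trace
#'
#' @param spec a [kinetic_gen_spec()]. Time axis is emitted in minutes so that
#'   `k_true` (1/min) round-trips through [fit_one_phase_association()] in the
#'   same unit.
#' @return a [kinetic_trace()].
#' @export
generate_kinetic_trace <- function(spec) {
  if (!inherits(spec, "kinetic_gen_spec"))
    ss_validation_error("spec", "must be a kinetic_gen_spec")
  t_min <- seq(0, spec$t_total, by = spec$t_step / 60)
  clean <- one_phase_association(t_min, spec$y0, spec$plateau, spec$k_true)
  set.seed(spec$seed)
  y <- clean + stats::rnorm(length(t_min), sd = spec$noise_sd)
  kinetic_trace(t_min, y, variant = spec$variant,
                nucleotide = spec$nucleotide, time_unit = "min")
}

#' Specification for a synthetic STD-NMR integral table
#'
#' Forward model for the amplification-factor pipeline: each proton has a true
#' per-proton saturation-transfer weight `w` so that
#' `Isat = I0 * (1 - w) + noise`, with noise sd `I0 * w / snr` — i.e. `snr` is
#' the signal-to-noise ratio of the *difference*-spectrum signal `I0 - Isat`,
#' the same quantity whose reciprocal scales the amplification-factor error
#' downstream. With ligand 50-fold in excess over protein (the default, 2 mM
#' ligand vs 40 uM protein) the noiseless amplification factor is `w * 50`.
#'
#' @param epitope_weights named numeric vector, proton label -> transfer
#'   fraction in \[0, 1\].
#' @param i0 named numeric vector of reference integrals (recycled from a
#'   scalar), all > 0.
#' @param snr named numeric vector of difference-spectrum signal-to-noise
#'   ratios (recycled from a scalar), all > 0.
#' @param ligand_conc,protein_conc concentrations in uM (defaults 2000 and 40).
#' @param seed integer RNG seed.
#' @param noise if `FALSE`, noise is suppressed regardless of snr.
#' @param variant,nucleotide metadata.
#' @return an object of class `std_gen_spec`.
#' @export
std_gen_spec <- function(epitope_weights, i0 = 1, snr = 50,
                         ligand_conc = 2000, protein_conc = 40, seed = 1L,
                         noise = TRUE, variant = "WT", nucleotide = "GDP") {
  if (is.null(names(epitope_weights)) || any(!nzchar(names(epitope_weights))))
    ss_validation_error("epitope_weights", "must be a named vector")
  if (any(epitope_weights < 0 | epitope_weights > 1))
    ss_validation_error("epitope_weights", "weights must lie in [0, 1]")
  labels <- names(epitope_weights)
  recycle <- function(x, field) {
    if (length(x) == 1L) x <- stats::setNames(rep(x, length(labels)), labels)
    if (is.null(names(x))) names(x) <- labels
    if (any(x[labels] <= 0) || anyNA(x[labels]))
      ss_validation_error(field, "must be > 0 for every proton label")
    x[labels]
  }
  stopifnot_scalar_number(ligand_conc, "ligand_conc", positive = TRUE)
  stopifnot_scalar_number(protein_conc, "protein_conc", positive = TRUE)
  structure(list(epitope_weights = epitope_weights,
                 i0 = recycle(i0, "i0"), snr = recycle(snr, "snr"),
                 ligand_conc = ligand_conc, protein_conc = protein_conc,
                 seed = as.integer(seed), noise = isTRUE(noise),
                 variant = variant, nucleotide = nucleotide),
            class = "std_gen_spec")
}

#' Generate a synthetic STD-NMR integral table
#'
#' @param spec a [std_gen_spec()].
#' @return a data.frame of STD integral records with columns `proton`, `i0`,
#'   `isat`, `snr_diff`, `usable`, `variant`, `nucleotide`, `ligand_uM`,
#'   `protein_uM` — the same tabular layout [compute_std_af()] consumes.
#' @export
generate_std_table <- function(spec) {
  if (!inherits(spec, "std_gen_spec"))
    ss_validation_error("spec", "must be a std_gen_spec")
  labels <- names(spec$epitope_weights)
  set.seed(spec$seed)
  noise <- if (spec$noise)
    stats::rnorm(length(labels),
                 sd = spec$i0 * spec$epitope_weights / spec$snr)
  else rep(0, length(labels))
  isat <- spec$i0 * (1 - spec$epitope_weights) + noise
  data.frame(proton = labels,
             i0 = unname(spec$i0),
             isat = unname(isat),
             snr_diff = unname(spec$snr),
             usable = TRUE,
             variant = spec$variant,
             nucleotide = spec$nucleotide,
             ligand_uM = spec$ligand_conc,
             protein_uM = spec$protein_conc,
             stringsAsFactors = FALSE)
}
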