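# STD-NMR amplification-factor analysis: converts background-corrected peak
# integrals into amplification factors with SNR-propagated errors, normalizes
# the per-proton profile to a reference proton, and bins the resulting
# epitope fingerprint.

#' An STD-NMR integral record
#'
#' @param proton_label proton label, conventionally one of `"a"`–`"d"`.
#' @param i0 integral of the signal in the reference (off-resonance) spectrum;
#'   must be > 0.
#' @param isat integral in the saturated spectrum. (`i0 - isat` is the
#'   difference-spectrum integral.)
#' @param snr_diff signal-to-noise ratio of the signal in the difference
#'   spectrum; must be > 0 when the record is usable.
#' @param usable `FALSE` when the signal overlaps residual protein background
#'   and must be excluded from analysis.
#' @return an object of class `std_record`.
#' @export
std_record <- function(proton_label, i0, isat, snr_diff, usable = TRUE) {
  stopifnot_scalar_number(i0, "i0", positive = TRUE)
  stopifnot_scalar_number(isat, "isat")
  if (usable) stopifnot_scalar_number(snr_diff, "snr_diff", positive = TRUE)
  structure(list(proton_label = proton_label, i0 = i0, isat = isat,
                 snr_diff = snr_diff, usable = isTRUE(usable)),
            class = "std_record")
}

#' Sample context for an STD experiment
#'
#' @param ligand_conc,protein_conc concentrations in uM, both > 0. The ratio
#'   `[L]/[P]` is the molar excess entering the amplification factor (the
#'   conventional setup is 50-fold: 2 mM ligand, 40 uM protein).
#' @param nucleotide `"GDP"` or `"GppNHp"`.
#' @param variant variant name.
#' @return an object of class `sample_context`.
#' @export
sample_context <- function(ligand_conc = 2000, protein_conc = 40,
                           nucleotide = "GDP", variant = "WT") {
  stopifnot_scalar_number(ligand_conc, "ligand_conc", positive = TRUE)
  stopifnot_scalar_number(protein_conc, "protein_conc", positive = TRUE)
  structure(list(ligand_conc = ligand_conc, protein_conc = protein_conc,
                 nucleotide = nucleotide, variant = variant),
            class = "sample_context")
}

#' Compute the STD amplification factor for one signal
#'
#' \deqn{A_{STD} = \frac{I_0 - I_{sat}}{I_0} \cdot \frac{[L]}{[P]}}
#' with error \eqn{\sigma = A_{STD} / SNR_{diff}}. The amplification factor
#' converts the STD intensity, which tracks the fraction of bound ligand, to a
#' quantity referenced to the fraction of bound protein.
#'
#' `isat > i0` (a subtraction artifact) yields a negative `a_std`, preserved
#' with a warning rather than clipped. Unusable records are skipped: the
#' return is `NULL` with a message.
#'
#' @param rec an [std_record()].
#' @param ctx a [sample_context()].
#' @return an object of class `std_af` with `a_std`, `sigma` (always >= 0),
#'   `proton_label`, `usable`; or `NULL` for unusable records.
#' @examples
#' compute_std_af(std_record("a", i0 = 2, isat = 1, snr_diff = 50),
#'                sample_context(2000, 40))   # a_std 25, sigma 0.5
#' @export
compute_std_af <- function(rec, ctx) {
  if (!inherits(rec, "std_record"))
    ss_validation_error("rec", "must be an std_record")
  if (!inherits(ctx, "sample_context"))
    ss_validation_error("ctx", "must be a sample_context")
  if (!rec$usable) {
    message(sprintf("skipping unusable proton '%s' (protein background overlap)",
                    rec$proton_label))
    return(NULL)
  }
  a_std <- (rec$i0 - rec$isat) / rec$i0 * (ctx$ligand_conc / ctx$protein_conc)
  if (a_std < 0)
    warning(sprintf("proton '%s': isat > i0 (subtraction artifact), a_std = %.4g",
                    rec$proton_label, a_std))
  sigma <- abs(a_std) / rec$snr_diff
  structure(list(a_std = a_std, sigma = sigma,
                 proton_label = rec$proton_label, usable = TRUE),
            class = "std_af")
}

#' Normalize an amplification-factor profile to a reference proton
#'
#' Each usable proton's ratio to the reference is
#' `r_p = a_std(p) / a_std(ref)`, with errors propagated in quadrature of
#' relative errors:
#' \deqn{\sigma_r = r \sqrt{(\sigma_p/A_p)^2 + (\sigma_{ref}/A_{ref})^2}.}
#' The reference proton is reported with ratio exactly 1, error 0 and category
#' `"reference"`. Excluded (unusable) protons appear with category
#' `"excluded"` and no ratio.
#'
#' @param afs a list of [compute_std_af()] results (`NULL`s allowed and
#'   treated as excluded), or a list of `std_af` objects.
#' @param reference reference proton label (default `"a"`, whose local
#'   environment is the least perturbed across variants).
#' @param excluded optional character vector of proton labels to report as
#'   excluded (e.g. background-overlapped protons).
#' @param ref_tol half-width of the reference-equivalent band passed to
#'   [bin_fingerprint_value()].
#' @return an object of class `std_fingerprint`: a data.frame with columns
#'   `proton`, `ratio`, `sigma`, `category`, plus attributes
#'   `reference_label`.
#' @export
normalize_fingerprint <- function(afs, reference = "a", excluded = character(),
                                  ref_tol = 0.02) {
  afs <- Filter(Negate(is.null), afs)
  labels <- vapply(afs, function(a) a$proton_label, character(1))
  ref <- afs[match(reference, labels)][[1]]
  if (is.na(match(reference, labels)) || is.null(ref))
    ss_normalization_error(sprintf("reference proton '%s' absent", reference))
  if (!is.finite(ref$a_std) || ref$a_std <= 0)
    ss_normalization_error(sprintf(
      "reference proton '%s' has a_std <= 0; fingerprint undefined", reference))
  rows <- lapply(afs, function(a) {
    if (a$proton_label == reference)
      return(data.frame(proton = reference, ratio = 1, sigma = 0,
                        category = "reference", stringsAsFactors = FALSE))
    r <- a$a_std / ref$a_std
    sig <- if (a$a_std == 0) ref$sigma / ref$a_std * abs(r) else
      abs(r) * sqrt((a$sigma / a$a_std)^2 + (ref$sigma / ref$a_std)^2)
    data.frame(proton = a$proton_label, ratio = r, sigma = sig,
               category = bin_fingerprint_value(r, ref_tol = ref_tol),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (length(excluded))
    out <- rbind(out, data.frame(proton = excluded, ratio = NA_real_,
                                 sigma = NA_real_, category = "excluded",
                                 stringsAsFactors = FALSE))
  structure(out, class = c("std_fingerprint", "data.frame"),
            reference_label = reference)
}

#' Bin a normalized fingerprint ratio
#'
#' Categories follow the conventional epitope-map colouring: `weak` below 50%
#' of the reference, `weak_moderate` from 50% up to (but excluding) the
#' reference band, `reference_equivalent` within `ref_tol` of 100%, `moderate`
#' above the band up to 150%, `strong` above 150%. Negative ratios (subtraction
#' artifacts) are flagged `artifact`.
#'
#' @param ratio finite numeric scalar, the normalized amplification factor.
#' @param ref_tol half-width of the reference-equivalent band (default 0.02,
#'   i.e. 98–102%).
#' @return a category string.
#' @examples
#' bin_fingerprint_value(0.49)  # "weak"
#' bin_fingerprint_value(1.25)  # "moderate"
#' bin_fingerprint_value(1.00)  # "reference_equivalent"
#' @export
bin_fingerprint_value <- function(ratio, ref_tol = 0.02) {
  if (!is.finite(ratio)) ss_validation_error("ratio", "must be finite")
  if (ratio < 0) return("artifact")
  if (abs(ratio - 1) <= ref_tol) return("reference_equivalent")
  if (ratio < 0.5) return("weak")
  if (ratio < 1) return("weak_moderate")
  if (ratio <= 1.5) return("moderate")
  "strong"
}

#' Select the saturation time from a build-up series
#'
#' Returns the smallest saturation time whose signal is within `frac` of the
#' maximum observed signal — the usual "gain has plateaued" selection rule
#' (typically picking 2.0 s on a 0.5–3.0 s series). If only the final time
#' qualifies, it is returned with a warning.
#'
#' @param signal_vs_time named numeric vector, names are saturation times in
#'   seconds, values the observed integrals.
#' @param frac plateau tolerance as a fraction of the maximum (default 0.05).
#' @return selected saturation time in seconds.
#' @export
select_saturation_time <- function(signal_vs_time, frac = 0.05) {
  if (length(signal_vs_time) < 2L)
    ss_input_error("need >= 2 saturation time points")
  times <- as.numeric(names(signal_vs_time))
  if (anyNA(times))
    ss_validation_error("signal_vs_time", "names must be numeric times")
  o <- order(times)
  times <- times[o]; sig <- as.numeric(signal_vs_time)[o]
  if (any(diff(sig) < 0))
    warning("signal is not monotone in saturation time")
  ok <- sig >= (1 - frac) * max(sig)
  t_sel <- times[which(ok)[1]]
  if (t_sel == times[length(times)] && length(times) > 1L &&
      !any(ok[-length(ok)]))
    warning("signal still rising: selected the final saturation time")
  t_sel
}

#' Run the STD pipeline on a tabular input
#'
#' Convenience wrapper taking the tabular layout written by
#' [generate_std_table()] (or read from CSV with columns `proton`, `i0`,
#' `isat`, `snr_diff`, `usable`, `ligand_uM`, `protein_uM`, `variant`,
#' `nucleotide`) and returning the normalized fingerprint.
#'
#' @param table a data.frame, one row per proton for a single sample.
#' @param reference reference proton label.
#' @param ref_tol reference-equivalent tolerance.
#' @return an [normalize_fingerprint()] result.
#' @export
std_fingerprint_from_table <- function(table, reference = "a",
                                       ref_tol = 0.02) {
  ctx <- sample_context(table$ligand_uM[1], table$protein_uM[1],
                        nucleotide = as.character(table$nucleotide[1]),
                        variant = as.character(table$variant[1]))
  afs <- lapply(seq_len(nrow(table)), function(i) {
    rec <- std_record(as.character(table$proton[i]), table$i0[i],
                      table$isat[i], table$snr_diff[i],
                      usable = isTRUE(table$usable[i]))
    if (!rec$usable) return(NULL)
    compute_std_af(rec, ctx)
  })
  excluded <- as.character(table$proton[!as.logical(table$usable)])
  normalize_fingerprint(afs, reference = reference, excluded = excluded,
                        ref_tol = ref_tol)
}
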