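#' @title Phase normalization to the CA1 stratum pyramidale reference
#' @description Converts firing phases reported against any hippocampal or
#'   entorhinal layer, in either peak-at-0 or trough-at-0 convention, into
#'   the common reference in which the CA1 stratum pyramidale theta peak is
#'   0 degrees. Offsets are shipped as a versioned data file because they
#'   are estimated mean phase shifts, replaceable as better estimates
#'   appear.
#' @name phase_normalization
NULL

PHASE_VARIABLES <- c("theta_phase", "gamma_phase", "epsilon_phase")
# Only theta phases have an established layer-to-layer phase equivalence;
# gamma/epsilon phases pass through normalization unchanged.
OFFSET_CORRECTED_VARIABLES <- "theta_phase"

#' Layer-to-CA1-SP theta phase offsets
#'
#' Reads the shipped offset table (degrees to add to a phase reported at a
#' given layer to refer it to the CA1-SP theta peak): DG cell layer -160,
#' hilus -170, CA3a -30, CA3b -80, CA3c -180, CA2 -10, CA1 SLM -180,
#' CA1 SR -60, CA1 SP 0, EC layer I -180 and EC layers II-VI 0. Layers with
#' no established offset (DG molecular layer, CA1 SO) are deliberately
#' absent: records citing them are rejected rather than guessed at.
#'
#' @param path CSV with columns `layer`, `offset_deg` (defaults to the
#'   table shipped with the package).
#' @return named numeric vector of offsets in degrees.
#' @export
default_layer_offsets <- function(path = system.file("extdata",
                                                     "layer_offsets.csv",
                                                     package = "hippophen")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("layer", "offset_deg") %in% names(df)))
  offsets <- stats::setNames(as.numeric(df$offset_deg), df$layer)
  if (any(abs(offsets) >= 360)) stopf("offsets must lie in (-360, 360)")
  if (!identical(unname(offsets[["CA1-SP"]]), 0))
    stopf("CA1-SP offset must be exactly 0")
  offsets
}

#' Normalize a reported phase to the CA1-SP peak reference
#'
#' result = wrap360(reported + offset(site) + 180 if trough convention).
#'
#' @param reported_deg reported phase(s), degrees.
#' @param site layer label at which the phase was reported.
#' @param convention `"peak0"` (0 degrees at the local theta peak) or
#'   `"trough0"` (0 degrees at the local trough).
#' @param offsets named offset vector, as from [default_layer_offsets()].
#' @return normalized phase(s) in `[0, 360)`.
#' @export
normalize_phase <- function(reported_deg, site,
                            convention = c("peak0", "trough0"),
                            offsets = default_layer_offsets()) {
  convention <- match.arg(convention)
  if (!site %in% names(offsets))
    stopf("unknown site '%s' (valid: %s)", site,
          paste(names(offsets), collapse = ", "))
  wrap360(reported_deg + offsets[[site]] +
            if (convention == "trough0") 180 else 0)
}

#' Weighted circular mean and mean vector length of digitized points
#'
#' Aggregates points digitized from published polar plots or phase
#' histograms: each point is a phase with a weight (histogram count, or 1
#' for polar scatter). Uses the same circular-mean / resultant-length
#' formulas as [circular_mean_mvl()].
#'
#' @param phase_deg phases in degrees.
#' @param weight non-negative weights, recycled to length of `phase_deg`.
#' @return list with `mu_deg` (weighted circular mean, `[0, 360)`) and
#'   `r` (weighted mean vector length).
#' @export
aggregate_digitized <- function(phase_deg, weight = 1) {
  weight <- rep_len(weight, length(phase_deg))
  if (length(phase_deg) < 3) stopf("need at least 3 digitized points")
  if (any(weight < 0)) stopf("weights must be >= 0")
  if (sum(weight) == 0) stopf("all weights are zero")
  rad <- deg2rad(phase_deg)
  c_bar <- sum(weight * cos(rad)) / sum(weight)
  s_bar <- sum(weight * sin(rad)) / sum(weight)
  list(mu_deg = wrap360(rad2deg(atan2(s_bar, c_bar))),
       r = sqrt(c_bar^2 + s_bar^2))
}

#' Normalize phase variables in an evidence table
#'
#' Rewrites theta-phase records to the CA1-SP peak-at-0 convention and
#' passes every other variable through untouched. Provenance columns
#' record the offset and convention flip applied to each row. Phase rows
#' whose site has no established offset, or which lack a site or
#' convention, are removed and returned in the `rejected` attribute with a
#' reason.
#'
#' @param records evidence data.frame (see [generate_evidence_table()] for
#'   the schema).
#' @param offsets named offset vector.
#' @return the normalized records, with attribute `rejected` (data.frame
#'   of dropped rows plus a `reason` column).
#' @export
normalize_evidence <- function(records, offsets = default_layer_offsets()) {
  rec <- records
  rec$applied_offset_deg <- NA_real_
  rec$applied_flip_deg <- NA_real_
  is_corrected <- rec$variable %in% OFFSET_CORRECTED_VARIABLES
  reason <- rep(NA_character_, nrow(rec))
  idx <- which(is_corrected)
  for (i in idx) {
    site <- rec$lfp_site[i]
    conv <- rec$phase_convention[i]
    if (is.na(site) || !nzchar(site)) {
      reason[i] <- "missing lfp_site"
    } else if (is.na(conv) || !conv %in% c("peak0", "trough0")) {
      reason[i] <- "missing or invalid phase_convention"
    } else if (!site %in% names(offsets)) {
      reason[i] <- sprintf("no established offset for site '%s'", site)
    } else {
      flip <- if (conv == "trough0") 180 else 0
      rec$value[i] <- wrap360(rec$value[i] + offsets[[site]] + flip)
      rec$applied_offset_deg[i] <- offsets[[site]]
      rec$applied_flip_deg[i] <- flip
      rec$phase_convention[i] <- "peak0"
      rec$lfp_site[i] <- "CA1-SP"
    }
  }
  # non-theta phase variables (gamma/epsilon): no layer equivalence, no
  # correction applied, flagged in provenance as untouched
  rejected <- rec[!is.na(reason), , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!is.na(reason)]
  out <- rec[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}
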