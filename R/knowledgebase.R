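#' @title Neuron-type knowledge base
#' @description Aggregates normalized evidence records into per-type
#'   "pieces of knowledge" (circular mean +/- circular SD for phases,
#'   arithmetic mean +/- SD otherwise), selects one summary per
#'   (type, variable) by metadata preference, and produces
#'   evidence/knowledge count breakdowns.
#' @name knowledgebase
NULL

#' Circular standard deviation from a resultant length
#'
#' sqrt(-2 ln r), expressed in degrees.
#'
#' @param r mean vector length in `[0, 1]`.
#' @return circular SD, degrees.
#' @export
circular_sd_deg <- function(r) {
  r <- pmin(1, pmax(.Machine$double.eps, r))
  rad2deg(sqrt(-2 * log(r)))
}

#' Aggregate normalized evidence into neuron-type summaries
#'
#' One summary per (neuron type, variable, metadata stratum): circular
#' mean and circular SD for phase variables, arithmetic mean and SD for
#' everything else, with the contributing record count and citation keys.
#' Missing metadata values form their own `"unknown"` stratum.
#'
#' @param records normalized evidence (see [normalize_evidence()]); phase
#'   records must share a single convention.
#' @param group_by metadata columns defining the strata.
#' @return data.frame of summaries (class `neuron_type_summary`).
#' @export
aggregate_evidence <- function(records, group_by = c("state", "method")) {
  if (!nrow(records))
    return(structure(data.frame(), class = c("neuron_type_summary", "data.frame")))
  rec <- records
  for (g in group_by) {
    rec[[g]][is.na(rec[[g]]) | !nzchar(rec[[g]])] <- "unknown"
  }
  key <- if (length(group_by))
    interaction(rec$neuron_type, rec$variable,
                do.call(interaction, rec[group_by]), drop = TRUE)
  else interaction(rec$neuron_type, rec$variable, drop = TRUE)
  out <- lapply(split(rec, key), function(grp) {
    is_phase <- grp$variable[1] %in% PHASE_VARIABLES
    if (is_phase) {
      agg <- aggregate_digitized_safe(grp$value)
      value <- agg$mu_deg; disp <- circular_sd_deg(agg$r)
      if (nrow(grp) == 1) disp <- 0
    } else {
      value <- mean(grp$value)
      disp <- if (nrow(grp) > 1) stats::sd(grp$value) else 0
    }
    keep <- intersect(c("neuron_type", "type_name", "variable", group_by),
                      names(grp))
    cbind(grp[1, keep, drop = FALSE],
          data.frame(value = value, dispersion = disp, n = nrow(grp),
                     citation_keys = paste(sort(grp$citation_key),
                                           collapse = ";")))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("neuron_type_summary", "data.frame")
  out
}

# Circular mean without the >= 3 points precondition used for digitized
# plots; single records pass through unchanged.
aggregate_digitized_safe <- function(phase_deg) {
  rad <- deg2rad(phase_deg)
  c_bar <- mean(cos(rad)); s_bar <- mean(sin(rad))
  list(mu_deg = wrap360(rad2deg(atan2(s_bar, c_bar))),
       r = sqrt(c_bar^2 + s_bar^2))
}

#' Default metadata preference order
#'
#' Drug-free states are preferred over anesthesia, and morphologically
#' validated single-cell methods over extracellular ones; unknown values
#' rank last.
#'
#' @return list with character vectors `state` and `method`, most
#'   preferred first.
#' @export
metadata_priority <- function() {
  list(state = c("awake-freely-moving", "awake-head-fixed", "sleep",
                 "anesthesia", "unknown"),
       method = c("juxtacellular", "sharp", "whole-cell", "optotag",
                  "silicon-probe", "tetrode", "unknown"))
}

#' Select one summary per (type, variable) by metadata preference
#'
#' Strata are ranked by the ordered preferences (earlier metadata keys
#' dominate later ones); ties are broken by larger n, then by citation-key
#' order, so the choice is deterministic.
#'
#' @param summaries data.frame from [aggregate_evidence()].
#' @param priority list of ordered preference vectors, as from
#'   [metadata_priority()].
#' @return data.frame with one row per (neuron type, variable).
#' @export
select_preferred <- function(summaries, priority = metadata_priority()) {
  if (!nrow(summaries)) return(summaries)
  rank_of <- function(values, ordered) {
    r <- match(values, ordered)
    r[is.na(r)] <- length(ordered) + 1L
    r
  }
  ranks <- rep(0, nrow(summaries))
  for (key in names(priority)) {
    if (!key %in% names(summaries)) next
    ranks <- ranks * (length(priority[[key]]) + 2L) +
      rank_of(summaries[[key]], priority[[key]])
  }
  ord <- order(summaries$neuron_type, summaries$variable, ranks,
               -summaries$n, summaries$citation_keys)
  s <- summaries[ord, , drop = FALSE]
  first <- !duplicated(s[, c("neuron_type", "variable")])
  out <- s[first, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evidence and knowledge counts per metadata axis
#'
#' For each value of each requested axis, counts the evidence rows and the
#' distinct (neuron type, variable) knowledge cells they support, plus the
#' proportion of total evidence.
#'
#' @param records evidence data.frame.
#' @param axes metadata column names.
#' @return named list of data.frames, one per axis, each with columns
#'   `value`, `evidence`, `knowledge`, `proportion`.
#' @export
evidence_breakdown <- function(records, axes = c("state", "method")) {
  bad <- setdiff(axes, names(records))
  if (length(bad)) stopf("unknown axis key(s): %s", paste(bad, collapse = ", "))
  total <- nrow(records)
  out <- lapply(axes, function(ax) {
    vals <- records[[ax]]
    vals[is.na(vals) | !nzchar(vals)] <- "unknown"
    tab <- lapply(split(records, vals), function(grp)
      data.frame(evidence = nrow(grp),
                 knowledge = nrow(unique(grp[, c("neuron_type", "variable")])),
                 proportion = nrow(grp) / total))
    df <- do.call(rbind, tab)
    cbind(value = rownames(df), df, row.names = NULL)
  })
  stats::setNames(out, axes)
}
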