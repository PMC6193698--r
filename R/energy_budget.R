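#' Energy conversion coefficients for the scope-for-growth budget
#'
#' Converts physiological rates to a common energy currency (J/h):
#' an oxycaloric coefficient for respiration, an ammonia-N coefficient for
#' excretion, and an energy density for absorbed organic matter. Defaults are
#' the standard values of the mussel scope-for-growth literature; all three
#' can be overridden, and absolute SFG values scale with them.
#'
#' @param q_O2 J per ml O2 respired (default 20.33).
#' @param q_NH4 J per microgram NH4-N excreted (default 0.02483).
#' @param q_POM J per mg organic matter absorbed (default 17.9).
#' @return An object of class `energy_coefficients`.
#' @export
energy_coefficients <- function(q_O2 = 20.33, q_NH4 = 0.02483, q_POM = 17.9) {
  stopifnot(q_O2 > 0, q_NH4 > 0, q_POM > 0)
  structure(list(q_O2 = q_O2, q_NH4 = q_NH4, q_POM = q_POM),
            class = "energy_coefficients")
}

#' Clearance rate from flow-through particle depletion
#'
#' CR = flow x (c_in - c_out) / c_in: the volume of water fully cleared of
#' particles per hour, from the drop in particle concentration between the
#' inflow and outflow of a flow-through chamber.
#'
#' Records where the outflow concentration exceeds the inflow (physically
#' impossible depletion, typically counter noise) are set to CR = 0 and
#' flagged with a warning rather than dropped.
#'
#' @param flow Water flow through the chamber, l/h (> 0).
#' @param c_in,c_out Particle concentrations at inflow and outflow
#'   (same units, `c_in` > 0).
#' @return Numeric clearance rates (l/h) in \[0, flow\], with attribute
#'   `flagged`: logical, `TRUE` where `c_out > c_in` was clamped.
#' @export
clearance_rate <- function(flow, c_in, c_out) {
  stopifnot(is.numeric(flow), is.numeric(c_in), is.numeric(c_out))
  if (any(flow <= 0, na.rm = TRUE)) stop("'flow' must be positive")
  if (any(c_in <= 0, na.rm = TRUE)) stop("'c_in' must be positive")
  if (any(c_out < 0, na.rm = TRUE)) stop("'c_out' must be non-negative")
  flagged <- !is.na(c_out) & !is.na(c_in) & c_out > c_in
  if (any(flagged))
    warning(sum(flagged), " record(s) with c_out > c_in; CR set to 0")
  cr <- flow * (c_in - c_out) / c_in
  cr[flagged] <- 0
  structure(cr, flagged = flagged)
}

#' Organic ingestion rate
#'
#' OIR = CR x POM (mg organic matter ingested per hour).
#'
#' @param CR Clearance rate, l/h (>= 0).
#' @param POM Particulate organic matter of the diet, mg/l (>= 0).
#' @return OIR in mg/h. Missing inputs propagate.
#' @export
organic_ingestion_rate <- function(CR, POM) {
  if (any(CR < 0, na.rm = TRUE)) stop("'CR' must be non-negative")
  if (any(POM < 0, na.rm = TRUE)) stop("'POM' must be non-negative")
  CR * POM
}

#' Conover absorption efficiency
#'
#' The ash-ratio estimate of the fraction of ingested organics absorbed,
#' AE = (F - E) / ((1 - E) F), from the organic fraction of the food (F)
#' and of the feces (E). AE can be negative when the feces are more organic
#' than the food; such values are retained (truncating them would bias group
#' means) and should be flagged downstream.
#'
#' @param F_food Organic fraction of the ingested food, in (0, 1).
#' @param E_feces Organic fraction of the feces, in \[0, 1).
#' @return Dimensionless absorption efficiency.
#' @export
conover_ae <- function(F_food, E_feces) {
  ok_f <- is.na(F_food) | (F_food > 0 & F_food < 1)
  ok_e <- is.na(E_feces) | (E_feces >= 0 & E_feces < 1)
  if (!all(ok_f)) stop("'F_food' must lie in (0, 1)")
  if (!all(ok_e)) stop("'E_feces' must lie in [0, 1)")
  (F_food - E_feces) / ((1 - E_feces) * F_food)
}

#' Absorption rate
#'
#' AR = AE x OIR (mg organic matter absorbed per hour).
#'
#' @param AE Absorption efficiency (dimensionless).
#' @param OIR Organic ingestion rate, mg/h (>= 0).
#' @return AR in mg/h. Missing inputs propagate.
#' @export
absorption_rate <- function(AE, OIR) {
  if (any(OIR < 0, na.rm = TRUE)) stop("'OIR' must be non-negative")
  AE * OIR
}

#' Metabolic cost in energy units
#'
#' M = q_O2 x VO2 + q_NH4 x VNH4 (J/h), combining respiration and ammonia
#' excretion. A missing rate propagates to a missing M; no imputation.
#'
#' @param VO2 Respiration rate, ml O2/h (>= 0).
#' @param VNH4 Ammonia excretion rate, ug NH4-N/h (>= 0).
#' @param coeff An [energy_coefficients()] object.
#' @return M in J/h.
#' @export
metabolic_cost <- function(VO2, VNH4, coeff = energy_coefficients()) {
  if (any(VO2 < 0, na.rm = TRUE)) stop("'VO2' must be non-negative")
  if (any(VNH4 < 0, na.rm = TRUE)) stop("'VNH4' must be non-negative")
  coeff$q_O2 * VO2 + coeff$q_NH4 * VNH4
}

#' Scope for growth
#'
#' SFG = q_POM x AR - M (J/h): the energy balance left for somatic and
#' gametogenic growth once metabolic requirements are met. Negative values
#' (maintenance ration not met) are meaningful and retained.
#'
#' @param AR Absorption rate, mg/h.
#' @param M Metabolic cost, J/h (>= 0).
#' @param coeff An [energy_coefficients()] object (supplies q_POM).
#' @return SFG in J/h.
#' @export
scope_for_growth <- function(AR, M, coeff = energy_coefficients()) {
  if (any(M < 0, na.rm = TRUE)) stop("'M' must be non-negative")
  coeff$q_POM * AR - M
}

#' Derive all physiological rates and the energy balance per record
#'
#' Joins each measurement record to its tank's diet at the nearest sampling
#' time (within `window` days), then computes OIR, AR, M and SFG with missing
#' inputs propagating to missing outputs. Unmatched records are never dropped:
#' they appear in the join report and carry `no_diet_match` in `qc_flags`.
#'
#' @param records Data frame of measurements with columns `individual_id`,
#'   `tank_id`, `t` (days), `L`, `TFW`, `CR`, `AE`, `VO2`, `VNH4`.
#' @param diet Data frame with columns `tank_id`, `t`, `TPM`, `PIM`, `POM`.
#' @param coeff An [energy_coefficients()] object.
#' @param window Maximum |t difference| in days for the diet join (default 3).
#' @return The input records with added columns `POM`, `OIR`, `AR`, `M`,
#'   `SFG`, `qc_flags`, and attribute `join_report` (data frame of unmatched
#'   records, empty when all matched). Row count and order are preserved.
#' @export
derive_all <- function(records, diet, coeff = energy_coefficients(),
                       window = 3) {
  req <- c("individual_id", "tank_id", "t", "CR", "AE", "VO2", "VNH4")
  if (!all(req %in% names(records)))
    stop("records must contain columns: ", paste(req, collapse = ", "))
  if (nrow(records) == 0L) {
    out <- records
    out$POM <- out$OIR <- out$AR <- out$M <- out$SFG <- numeric(0)
    out$qc_flags <- character(0)
    attr(out, "join_report") <- data.frame(row = integer(0),
                                           individual_id = character(0),
                                           tank_id = character(0),
                                           t = numeric(0),
                                           reason = character(0))
    return(out)
  }
  out <- records
  n <- nrow(out)
  POM <- rep(NA_real_, n)
  unmatched <- logical(n)
  for (i in seq_len(n)) {
    d <- diet[diet$tank_id == out$tank_id[i], , drop = FALSE]
    if (nrow(d) > 0L) {
      dt <- abs(d$t - out$t[i])
      j <- which.min(dt)
      if (dt[j] <= window) POM[i] <- d$POM[j] else unmatched[i] <- TRUE
    } else unmatched[i] <- TRUE
  }
  out$POM <- POM
  out$OIR <- organic_ingestion_rate(out$CR, POM)
  out$AR <- absorption_rate(out$AE, out$OIR)
  out$M <- metabolic_cost(out$VO2, out$VNH4, coeff)
  out$SFG <- scope_for_growth(out$AR, out$M, coeff)
  flags <- character(n)
  flags[unmatched] <- "no_diet_match"
  neg_ae <- !is.na(out$AE) & out$AE < 0
  flags[neg_ae] <- paste0(ifelse(nchar(flags[neg_ae]) > 0,
                                 paste0(flags[neg_ae], ";"), ""),
                          "negative_AE")
  out$qc_flags <- flags
  attr(out, "join_report") <- data.frame(
    row = which(unmatched),
    individual_id = out$individual_id[unmatched],
    tank_id = out$tank_id[unmatched],
    t = out$t[unmatched],
    reason = rep("no diet record within join window", sum(unmatched)),
    stringsAsFactors = FALSE
  )
  out
}
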