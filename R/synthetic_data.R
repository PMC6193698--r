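#' Configuration for the synthetic mussel cohort generator
#'
#' Encodes the study design the generator emulates: 48 individuals split over
#' 3 tanks, 6 monthly samplings, even initial sizes (shell length about
#' 20-21 mm, total fresh weight 0.66 g with sd 0.089), per-tank diet with POM
#' between 0.673 and 0.734 mg/l, and a latent individual "quality" factor that
#' gives eventual fast growers correlated feeding/digestion advantages and
#' lower metabolic costs. Between-individual dispersion of the rates inflates
#' across samplings by `dispersion_growth` per step, and size increments are
#' driven by each individual's accumulated positive scope for growth.
#'
#' Baseline rate magnitudes are order-of-magnitude placeholders: the generator
#' targets the statistical structure of such an experiment, not calibrated
#' physiology.
#'
#' @param n_individuals Number of monitored individuals (default 48).
#' @param n_tanks Number of tanks, individuals split as evenly as possible
#'   (default 3).
#' @param samplings Sampling times in days (default 0, 30, ..., 150).
#' @param L0_mean,L0_sd Initial shell length distribution, mm (rounded to
#'   0.1 mm, the caliper precision).
#' @param TFW0_mean,TFW0_sd Initial total fresh weight distribution, g.
#' @param POM_range Uniform range for per-tank, per-sampling POM, mg/l.
#' @param organic_fraction_range Uniform range for the diet organic content
#'   POM/TPM (determines TPM and PIM).
#' @param quality_sd Sd of the latent individual quality factor q.
#' @param loadings Named vector: per-variable multiplicative loading on q for
#'   CR, AE, VO2, VNH4 (positive = high-quality individuals have larger
#'   values).
#' @param baselines Named vector of baseline rates: CR (l/h), AE (fraction),
#'   VO2 (ml O2/h), VNH4 (ug NH4-N/h).
#' @param noise_sd Measurement/process noise sd per variable (named vector
#'   over CR, AE, VO2, VNH4, TFW, or a single number recycled to all).
#' @param dispersion_growth Factor by which the between-individual component
#'   of each rate inflates per sampling step (> 1 gives increasing
#'   dispersion).
#' @param growth_gain Conversion from accumulated positive SFG (J) to fresh
#'   weight gain (g/J).
#' @param growth_noise_sd Process noise sd on each monthly weight increment,
#'   g.
#' @param coeff [energy_coefficients()] used internally to convert rates to
#'   SFG.
#' @param seed Integer seed (mandatory: the cohort is a pure function of the
#'   config).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 48L, n_tanks = 3L,
                          samplings = seq(0, 150, by = 30),
                          L0_mean = 20.5, L0_sd = 0.5,
                          TFW0_mean = 0.66, TFW0_sd = 0.089,
                          POM_range = c(0.673, 0.734),
                          organic_fraction_range = c(0.72, 0.75),
                          quality_sd = 1,
                          loadings = c(CR = 0.15, AE = 0.08,
                                       VO2 = -0.05, VNH4 = -0.05),
                          baselines = c(CR = 2, AE = 0.6,
                                        VO2 = 0.35, VNH4 = 8),
                          noise_sd = c(CR = 0.15, AE = 0.04, VO2 = 0.04,
                                       VNH4 = 1, TFW = 0.01),
                          dispersion_growth = 1.15,
                          growth_gain = 7e-5,
                          growth_noise_sd = 0.03,
                          coeff = energy_coefficients(),
                          seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (length(noise_sd) == 1L && is.null(names(noise_sd)))
    noise_sd <- stats::setNames(rep(noise_sd, 5),
                                c("CR", "AE", "VO2", "VNH4", "TFW"))
  stopifnot(n_individuals >= 2L, n_tanks >= 1L,
            all(diff(samplings) > 0), length(samplings) >= 2L,
            L0_sd >= 0, TFW0_sd >= 0, quality_sd >= 0,
            all(noise_sd >= 0), dispersion_growth > 0, growth_gain >= 0,
            growth_noise_sd >= 0,
            all(c("CR", "AE", "VO2", "VNH4") %in% names(loadings)),
            all(c("CR", "AE", "VO2", "VNH4") %in% names(baselines)),
            all(c("CR", "AE", "VO2", "VNH4", "TFW") %in% names(noise_sd)))
  if (L0_mean - 4 * L0_sd <= 0 || TFW0_mean - 4 * TFW0_sd <= 0)
    stop("config implies non-positive initial sizes")
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic longitudinal mussel cohort
#'
#' Draws a latent quality q_i ~ N(0, quality_sd^2) per individual, then per
#' sampling k (dispersion factor d_k = dispersion_growth^(k-1)) generates
#' CR_i = baseline_CR (1 + lambda_CR q_i d_k) + noise, and similarly AE
#' (clamped to \[0, 1\]), VO2 and VNH4 (clamped at 0). The generator computes
#' each individual's SFG from the recorded rates and the tank diet with the
#' package's own budget arithmetic, and grows total fresh weight by
#' growth_gain x max(SFG, 0) x hours between samplings (plus process noise);
#' shell length follows allometrically (L proportional to TFW^(1/3)). Energy
#' identities therefore hold by construction, and size dispersion grows over
#' time because quality differences persist.
#'
#' @param cfg A [cohort_config()].
#' @return List of class `cohort`: `measurements` (one row per individual per
#'   sampling: individual_id, tank_id, t, L, TFW, CR, AE, VO2, VNH4), `diet`
#'   (tank_id, t, TPM, PIM, POM), `truth` (individual_id, tank_id, quality,
#'   true_group, sfg_final: the generator's internal SFG at the last
#'   sampling), and `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  ts <- cfg$samplings
  nk <- length(ts)
  ids <- sprintf("M%02d", seq_len(n))
  tanks <- paste0("T", rep_len(seq_len(cfg$n_tanks), n))
  q <- stats::rnorm(n, 0, cfg$quality_sd)

  diet <- expand.grid(tank_id = paste0("T", seq_len(cfg$n_tanks)), t = ts,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  diet$POM <- stats::runif(nrow(diet), cfg$POM_range[1], cfg$POM_range[2])
  oc <- stats::runif(nrow(diet), cfg$organic_fraction_range[1],
                     cfg$organic_fraction_range[2])
  diet$TPM <- diet$POM / oc
  diet$PIM <- diet$TPM - diet$POM
  diet <- diet[, c("tank_id", "t", "TPM", "PIM", "POM")]

  L0 <- round(stats::rnorm(n, cfg$L0_mean, cfg$L0_sd), 1)
  TFW0 <- stats::rnorm(n, cfg$TFW0_mean, cfg$TFW0_sd)
  if (any(L0 <= 0) || any(TFW0 <= 0))
    stop("config generated non-positive initial sizes")

  b <- cfg$baselines; lam <- cfg$loadings; ns <- cfg$noise_sd
  rows <- vector("list", nk)
  tfw_true <- TFW0
  sfg_prev <- rep(NA_real_, n)
  for (k in seq_len(nk)) {
    d_k <- cfg$dispersion_growth^(k - 1)
    if (k > 1L) {
      hours <- (ts[k] - ts[k - 1]) * 24
      inc <- cfg$growth_gain * pmax(sfg_prev, 0) * hours +
        stats::rnorm(n, 0, cfg$growth_noise_sd)
      tfw_true <- pmax(tfw_true + inc, 0.05)
    }
    CR <- pmax(b[["CR"]] * (1 + lam[["CR"]] * q * d_k) +
                 stats::rnorm(n, 0, ns[["CR"]]), 0)
    AE <- pmin(pmax(b[["AE"]] * (1 + lam[["AE"]] * q * d_k) +
                      stats::rnorm(n, 0, ns[["AE"]]), 0), 1)
    VO2 <- pmax(b[["VO2"]] * (1 + lam[["VO2"]] * q * d_k) +
                  stats::rnorm(n, 0, ns[["VO2"]]), 0)
    VNH4 <- pmax(b[["VNH4"]] * (1 + lam[["VNH4"]] * q * d_k) +
                   stats::rnorm(n, 0, ns[["VNH4"]]), 0)
    pom_k <- diet$POM[match(paste(tanks, ts[k]),
                            paste(diet$tank_id, diet$t))]
    ar <- absorption_rate(AE, organic_ingestion_rate(CR, pom_k))
    m <- metabolic_cost(VO2, VNH4, cfg$coeff)
    sfg_prev <- scope_for_growth(ar, m, cfg$coeff)
    TFW_obs <- round(tfw_true + stats::rnorm(n, 0, ns[["TFW"]]), 3)
    L_obs <- round(L0 * (pmax(tfw_true, 1e-6) / TFW0)^(1 / 3), 1)
    rows[[k]] <- data.frame(
      individual_id = ids, tank_id = tanks, t = ts[k],
      L = L_obs, TFW = pmax(TFW_obs, 0.001),
      CR = CR, AE = AE, VO2 = VO2, VNH4 = VNH4,
      stringsAsFactors = FALSE)
  }
  measurements <- do.call(rbind, rows)
  measurements <- measurements[order(measurements$individual_id,
                                     measurements$t), ]
  rownames(measurements) <- NULL
  truth <- data.frame(individual_id = ids, tank_id = tanks, quality = q,
                      true_group = ifelse(q > 0, "fast", "slow"),
                      sfg_final = sfg_prev, stringsAsFactors = FALSE)
  structure(list(measurements = measurements, diet = diet, truth = truth,
                 config = cfg),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individuals x %d samplings (%d tanks), seed %d\n",
              x$config$n_individuals, length(x$config$samplings),
              x$config$n_tanks, x$config$seed))
  invisible(x)
}

#' Plant outlying individuals into a cohort
#'
#' Shifts the named individuals' trajectories of a variable by a stated number
#' of pooled standard deviations (the sd of that variable over all records),
#' producing known extreme curves for testing outlier detection. All other
#' cells are left bit-identical.
#'
#' @param cohort A [generate_cohort()] result.
#' @param spec Data frame with columns `individual_id`, `variable`,
#'   `shift_sd`.
#' @return The modified cohort, with attribute `planted_outliers` = `spec`.
#' @export
plant_outliers <- function(cohort, spec) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(spec) || nrow(spec) == 0L) {
    attr(cohort, "planted_outliers") <-
      data.frame(individual_id = character(0), variable = character(0),
                 shift_sd = numeric(0))
    return(cohort)
  }
  stopifnot(all(c("individual_id", "variable", "shift_sd") %in% names(spec)))
  m <- cohort$measurements
  for (r in seq_len(nrow(spec))) {
    id <- as.character(spec$individual_id[r])
    v <- as.character(spec$variable[r])
    if (!id %in% m$individual_id) stop("unknown individual id: ", id)
    if (!v %in% names(m)) stop("unknown variable: ", v)
    pooled_sd <- stats::sd(m[[v]], na.rm = TRUE)
    sel <- m$individual_id == id
    m[[v]][sel] <- m[[v]][sel] + spec$shift_sd[r] * pooled_sd
  }
  cohort$measurements <- m
  attr(cohort, "planted_outliers") <- spec
  cohort
}

#' Introduce missing values into a cohort
#'
#' Independently sets each physiological rate cell (CR, AE, VO2, VNH4) missing
#' with probability `missing_rate`, and size cells (L, TFW) at interior
#' samplings only — the first and last size measurements are never removed,
#' so initial selection and final classification stay possible. Rates above
#' 0.3 are refused: downstream smoothing needs at least 3 points per curve.
#'
#' @param cohort A [generate_cohort()] result.
#' @param missing_rate Probability a cell goes missing, in \[0, 0.3).
#' @param seed Integer seed.
#' @param degrade_sizes Also degrade interior L/TFW cells (default TRUE).
#' @return The degraded cohort.
#' @export
degrade <- function(cohort, missing_rate, seed, degrade_sizes = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  if (missing_rate < 0 || missing_rate >= 0.3)
    stop("'missing_rate' must lie in [0, 0.3)")
  if (missing_rate == 0) return(cohort)
  set.seed(seed)
  m <- cohort$measurements
  for (v in c("CR", "AE", "VO2", "VNH4"))
    m[[v]][stats::runif(nrow(m)) < missing_rate] <- NA_real_
  if (degrade_sizes) {
    interior <- m$t > min(m$t) & m$t < max(m$t)
    for (v in c("L", "TFW")) {
      hit <- interior & stats::runif(nrow(m)) < missing_rate
      m[[v]][hit] <- NA_real_
    }
  }
  cohort$measurements <- m
  cohort
}
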