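#' Read a measurements CSV
#'
#' Expects columns `individual_id`, `tank_id`, `date_or_day`, `L_mm`, `TFW_g`,
#' `CR_l_h`, `AE`, `VO2_ml_h`, `VNH4_ug_h` (empty cells = missing).
#' `date_or_day` may be ISO-8601 dates or integer day offsets; dates are
#' converted to days since the earliest date in the file.
#'
#' @param path CSV path.
#' @return Data frame with internal column names (`t`, `L`, `TFW`, `CR`, `AE`,
#'   `VO2`, `VNH4`).
#' @export
read_measurements <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("individual_id", "tank_id", "date_or_day", "L_mm", "TFW_g",
           "CR_l_h", "AE", "VO2_ml_h", "VNH4_ug_h")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0)
    stop("measurements CSV missing column(s): ", paste(miss, collapse = ", "))
  data.frame(
    individual_id = as.character(raw$individual_id),
    tank_id = as.character(raw$tank_id),
    t = to_days(raw$date_or_day),
    L = as.numeric(raw$L_mm), TFW = as.numeric(raw$TFW_g),
    CR = as.numeric(raw$CR_l_h), AE = as.numeric(raw$AE),
    VO2 = as.numeric(raw$VO2_ml_h), VNH4 = as.numeric(raw$VNH4_ug_h),
    stringsAsFactors = FALSE)
}

#' Read a diet CSV
#'
#' Expects columns `tank_id`, `date_or_day`, `TPM_mg_l`, `PIM_mg_l`,
#' `POM_mg_l`. The identity TPM = PIM + POM is checked to numeric tolerance.
#'
#' @param path CSV path.
#' @return Data frame with columns `tank_id`, `t`, `TPM`, `PIM`, `POM`.
#' @export
read_diet <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("tank_id", "date_or_day", "TPM_mg_l", "PIM_mg_l", "POM_mg_l")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0)
    stop("diet CSV missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(
    tank_id = as.character(raw$tank_id), t = to_days(raw$date_or_day),
    TPM = as.numeric(raw$TPM_mg_l), PIM = as.numeric(raw$PIM_mg_l),
    POM = as.numeric(raw$POM_mg_l), stringsAsFactors = FALSE)
  bad <- abs(out$TPM - out$PIM - out$POM) > 1e-6 * pmax(out$TPM, 1)
  if (any(bad, na.rm = TRUE))
    warning(sum(bad, na.rm = TRUE),
            " diet row(s) violate TPM = PIM + POM beyond tolerance")
  out
}

to_days <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  xs <- as.character(x)
  if (all(grepl("^\\s*-?\\d+(\\.\\d+)?\\s*$", xs[!is.na(xs)])))
    return(as.numeric(xs))
  d <- as.Date(xs)
  if (any(is.na(d) & !is.na(xs)))
    stop("'date_or_day' must be ISO-8601 dates or numeric day offsets")
  as.numeric(d - min(d, na.rm = TRUE))
}

#' Write a cohort's measurement and diet tables as CSV
#'
#' Emits the same CSV dialects [read_measurements()] and [read_diet()]
#' consume, plus the ground-truth table (which no analysis stage reads).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- cohort$measurements
  mm <- data.frame(individual_id = m$individual_id, tank_id = m$tank_id,
                   date_or_day = m$t, L_mm = m$L, TFW_g = m$TFW,
                   CR_l_h = m$CR, AE = m$AE, VO2_ml_h = m$VO2,
                   VNH4_ug_h = m$VNH4)
  d <- cohort$diet
  dd <- data.frame(tank_id = d$tank_id, date_or_day = d$t, TPM_mg_l = d$TPM,
                   PIM_mg_l = d$PIM, POM_mg_l = d$POM)
  paths <- file.path(dir, c("measurements.csv", "diet.csv", "ground_truth.csv"))
  utils::write.csv(mm, paths[1], row.names = FALSE, na = "")
  utils::write.csv(dd, paths[2], row.names = FALSE, na = "")
  utils::write.csv(cohort$truth, paths[3], row.names = FALSE, na = "")
  invisible(paths)
}

#' Validate measurement and diet tables
#'
#' Schema, unit-sanity, duplicate (id, t) and time-monotonicity checks. Every
#' violation is reported with the offending row number; an empty report means
#' the inputs are clean.
#'
#' @param measurements Measurement data frame (internal column names, see
#'   [read_measurements()]).
#' @param diet Diet data frame (see [read_diet()]); optional.
#' @return Data frame with columns `table`, `row`, `check`, `message`.
#' @export
validate_inputs <- function(measurements, diet = NULL) {
  viol <- list()
  add <- function(tab, row, check, msg)
    viol[[length(viol) + 1]] <<- data.frame(table = tab, row = row,
                                            check = check, message = msg,
                                            stringsAsFactors = FALSE)
  m <- measurements
  rng <- list(L = c(1, 200), TFW = c(0.001, 500), CR = c(0, 50),
              AE = c(-1, 1), VO2 = c(0, 50), VNH4 = c(0, 1e4), t = c(0, Inf))
  for (v in names(rng)) {
    if (!v %in% names(m)) { add("measurements", NA, "schema",
                                paste("missing column", v)); next }
    bad <- which(!is.na(m[[v]]) &
                   (m[[v]] < rng[[v]][1] | m[[v]] > rng[[v]][2]))
    for (r in bad)
      add("measurements", r, "range",
          sprintf("%s = %g outside [%g, %g]", v, m[[v]][r],
                  rng[[v]][1], rng[[v]][2]))
  }
  key <- paste(m$individual_id, m$t)
  dup <- which(duplicated(key))
  for (r in dup)
    add("measurements", r, "duplicate",
        sprintf("duplicated (individual_id, t) = (%s, %g)",
                m$individual_id[r], m$t[r]))
  for (id in unique(m$individual_id)) {
    tt <- m$t[m$individual_id == id]
    if (is.unsorted(tt, strictly = FALSE) && is.unsorted(sort(tt)))
      add("measurements", NA, "time_order",
          paste("non-monotonic times for", id))
  }
  if (!is.null(diet)) {
    bad <- which(!is.na(diet$TPM) &
                   abs(diet$TPM - diet$PIM - diet$POM) >
                   1e-6 * pmax(diet$TPM, 1))
    for (r in bad)
      add("diet", r, "identity", "TPM != PIM + POM beyond tolerance")
    neg <- which(diet$TPM < 0 | diet$PIM < 0 | diet$POM < 0)
    for (r in neg) add("diet", r, "range", "negative particulate matter")
  }
  if (length(viol) == 0)
    return(data.frame(table = character(0), row = integer(0),
                      check = character(0), message = character(0)))
  do.call(rbind, viol)
}

#' Run the full growth-variability analysis pipeline
#'
#' Fixed stage order: load or simulate the cohort; validate; derive the energy
#' budget; smooth every variable into functional samples; detect and exclude
#' depth outliers (on the size curves); cross-sectional tests per variable
#' (rank ANOVA + Tukey HSD across samplings, dispersion test); even-start
#' subsample; median-split group comparison with functional ANOVA. Every
#' stage draws its seed deterministically from the master seed, so the whole
#' run is a pure function of (inputs, config, seed).
#'
#' @param out_dir Output directory; created if needed.
#' @param seed Master integer seed.
#' @param cohort A `cohort` object, or `NULL` to read from `measurements_csv`
#'   / `diet_csv`, or `NULL` with `synthetic = TRUE` to simulate.
#' @param measurements_csv,diet_csv Input CSV paths (used when `cohort` is
#'   `NULL` and `synthetic` is `FALSE`).
#' @param synthetic Simulate the cohort from `config` (default TRUE when no
#'   inputs are given).
#' @param config A [cohort_config()] for synthetic runs; default config with
#'   the master seed if `NULL`.
#' @param coeff [energy_coefficients()].
#' @param grid_size Common grid size (default 101).
#' @param outlier_vars Variables scanned for outliers (default L and TFW).
#' @param trim,B_outlier,alpha_cut Outlier-detection parameters (see
#'   [trimmed_mode_outliers()]).
#' @param n_perm Permutations for dispersion tests (default 999).
#' @param B_fanova Functional-ANOVA resamples (default 500).
#' @param even_start_target,even_start_tol Even-start selection on initial
#'   shell length (defaults 21 mm +/- 0.5).
#' @param criteria Median-split criteria (default `c("L", "TFW")`).
#' @param write_curves Also serialize each variable's functional sample
#'   (wide CSV + JSON sidecar) under `out_dir/functional_samples/`.
#' @return Invisibly, a list with every stage result (`cohort`, `validation`,
#'   `derived`, `functional_samples`, `outliers`, `cross_sectional`,
#'   `even_start_ids`, `group_report`, `manifest`). Artifacts are written to
#'   `out_dir`.
#' @export
run_pipeline <- function(out_dir, seed,
                         cohort = NULL, measurements_csv = NULL,
                         diet_csv = NULL, synthetic = is.null(measurements_csv),
                         config = NULL, coeff = energy_coefficients(),
                         grid_size = 101L,
                         outlier_vars = c("L", "TFW"), trim = 0.1,
                         B_outlier = 200L, alpha_cut = 0.01,
                         n_perm = 999L, B_fanova = 500L,
                         even_start_target = 21, even_start_tol = 0.5,
                         criteria = c("L", "TFW"), write_curves = FALSE) {
  if (missing(seed)) stop("'seed' is required")
  if (!is.null(measurements_csv) && synthetic)
    stop("give either input CSVs or a synthetic config, not both")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  stage <- "load"
  result <- list()
  tryCatch({
    logf("stage load: assembling cohort")
    if (is.null(cohort)) {
      if (synthetic) {
        if (is.null(config))
          config <- cohort_config(seed = derive_seed(seed, "simulate"))
        cohort <- generate_cohort(config)
      } else {
        if (is.null(measurements_csv) || is.null(diet_csv))
          stop("both measurements_csv and diet_csv are required")
        cohort <- structure(list(measurements = read_measurements(measurements_csv),
                                 diet = read_diet(diet_csv),
                                 truth = NULL, config = NULL),
                            class = "cohort")
      }
    }
    result$cohort <- cohort

    stage <- "validate"
    logf("stage validate")
    result$validation <- validate_inputs(cohort$measurements, cohort$diet)
    utils::write.csv(result$validation,
                     file.path(out_dir, "validation_report.csv"),
                     row.names = FALSE)
    if (nrow(result$validation) > 0)
      logf("validate: ", nrow(result$validation), " violation(s) reported")

    stage <- "derive"
    logf("stage derive: energy budget")
    derived <- derive_all(cohort$measurements, cohort$diet, coeff)
    result$derived <- derived
    enr <- derived
    names(enr)[match(c("OIR", "AR", "M", "SFG"), names(enr))] <-
      c("OIR_mg_h", "AR_mg_h", "M_J_h", "SFG_J_h")
    utils::write.csv(enr, file.path(out_dir, "enriched_measurements.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(attr(derived, "join_report"),
                     file.path(out_dir, "join_report.csv"), row.names = FALSE)

    stage <- "smooth"
    logf("stage smooth: functional samples")
    all_vars <- c("L", "TFW", "SFG", "CR", "OIR", "AE", "AR", "VO2", "VNH4")
    fss <- list()
    for (v in all_vars) {
      long <- derived[, c("individual_id", "t")]
      long$y <- derived[[v]]
      fss[[v]] <- tryCatch(
        suppressWarnings(build_functional_sample(long, "y", grid_size)),
        error = function(e) NULL)
      if (!is.null(fss[[v]])) fss[[v]]$variable <- v
    }
    result$functional_samples <- fss
    if (write_curves) {
      fdir <- file.path(out_dir, "functional_samples")
      dir.create(fdir, showWarnings = FALSE)
      for (v in names(fss)) if (!is.null(fss[[v]]))
        write_functional_sample(fss[[v]], file.path(fdir, v))
    }

    stage <- "outliers"
    logf("stage outliers: trimmed-mode depth scan on ",
         paste(outlier_vars, collapse = ", "))
    out_rows <- list(); out_ids <- character(0)
    for (v in outlier_vars) {
      if (is.null(fss[[v]])) next
      dr <- trimmed_mode_outliers(fss[[v]], trim = trim, B = B_outlier,
                                  alpha_cut = alpha_cut,
                                  seed = derive_seed(seed, paste0("outliers_", v)))
      out_ids <- union(out_ids, dr$outlier_ids)
      out_rows[[v]] <- data.frame(
        variable = v,
        individual_id = names(dr$depths),
        depth = unname(dr$depths), cutoff = dr$cutoff,
        flagged = names(dr$depths) %in% dr$outlier_ids,
        stringsAsFactors = FALSE)
    }
    outlier_report <- do.call(rbind, c(out_rows, make.row.names = FALSE))
    utils::write.csv(outlier_report, file.path(out_dir, "outlier_report.csv"),
                     row.names = FALSE)
    result$outliers <- list(ids = out_ids, report = outlier_report)
    logf("outliers: ", length(out_ids), " individual(s) excluded hereafter")
    clean <- derived[!derived$individual_id %in% out_ids, ]

    stage <- "cross_sectional"
    logf("stage cross_sectional: rank ANOVA, Tukey HSD, dispersion tests")
    cs_rows <- list()
    for (v in all_vars) {
      vals <- clean[[v]]; samp <- factor(clean$t)
      ok <- !is.na(vals)
      if (sum(ok) < 10L || length(unique(samp[ok])) < 2L) next
      kw <- kruskal_wallis(vals[ok], as.character(samp[ok]))
      s_disp <- derive_seed(seed, paste0("dispersion_", v))
      dt <- dispersion_test(vals[ok], samp[ok], n_perm = n_perm,
                            seed = s_disp)
      cs_rows[[v]] <- data.frame(
        variable = v,
        method = c("kruskal_wallis", "dispersion_test"),
        statistic = c(kw$statistic, dt$statistic),
        p_value = c(kw$p_value, dt$p_value),
        n_perm = c(NA_integer_, as.integer(n_perm)),
        seed = c(NA_integer_, s_disp),
        stringsAsFactors = FALSE)
    }
    cross_sectional <- do.call(rbind, c(cs_rows, make.row.names = FALSE))
    utils::write.csv(cross_sectional,
                     file.path(out_dir, "cross_sectional_tests.csv"),
                     row.names = FALSE)
    result$cross_sectional <- cross_sectional

    stage <- "groups"
    logf("stage groups: even-start subsample and median-split comparison")
    even_ids <- select_even_start(clean, "L", even_start_target,
                                  even_start_tol)
    result$even_start_ids <- even_ids
    report <- compare_groups_report(clean, criteria = criteria,
                                    ids = even_ids, grid_size = grid_size,
                                    B = B_fanova,
                                    seed = derive_seed(seed, "groups"))
    utils::write.csv(report$table, file.path(out_dir, "group_report.csv"),
                     row.names = FALSE)
    result$group_report <- report

    stage <- "manifest"
    manifest <- list(
      package = "growfda",
      version = as.character(utils::packageVersion("growfda")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      master_seed = seed,
      stage_seeds = list(
        simulate = derive_seed(seed, "simulate"),
        outliers = stats::setNames(
          lapply(outlier_vars, function(v)
            derive_seed(seed, paste0("outliers_", v))), outlier_vars),
        groups = derive_seed(seed, "groups")),
      parameters = list(grid_size = grid_size, trim = trim,
                        B_outlier = B_outlier, alpha_cut = alpha_cut,
                        n_perm = n_perm, B_fanova = B_fanova,
                        even_start_target = even_start_target,
                        even_start_tol = even_start_tol,
                        criteria = criteria,
                        coefficients = unclass(coeff)),
      n_individuals = length(unique(cohort$measurements$individual_id)),
      excluded_outliers = out_ids,
      even_start_n = length(even_ids))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    result$manifest <- manifest
    logf("pipeline complete: artifacts in ", out_dir)
  }, error = function(e) {
    logf("FAILED at stage '", stage, "': ", conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Serialize a functional sample
#'
#' Writes a wide CSV (id, then one column per grid point) and a JSON sidecar
#' holding the grid, per-curve bandwidths and metadata.
#'
#' @param fs A [functional_sample()].
#' @param stem Output path without extension.
#' @return Invisibly, the two paths.
#' @export
write_functional_sample <- function(fs, stem) {
  stopifnot(inherits(fs, "functional_sample"))
  wide <- data.frame(individual_id = fs$ids, fs$curves, check.names = FALSE)
  names(wide)[-1] <- sprintf("t%.6g", fs$grid)
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  utils::write.csv(wide, csv, row.names = FALSE)
  jsonlite::write_json(
    list(variable = fs$variable, grid = fs$grid, bandwidths = fs$bandwidths,
         ids = fs$ids, skipped = fs$skipped),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' Read back a serialized functional sample
#'
#' @param stem Path stem used by [write_functional_sample()].
#' @return A [functional_sample()].
#' @export
read_functional_sample <- function(stem) {
  wide <- utils::read.csv(paste0(stem, ".csv"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  bw <- meta$bandwidths
  if (length(bw) == 0L) bw <- NULL
  functional_sample(as.numeric(meta$grid),
                    as.matrix(wide[, -1, drop = FALSE]),
                    ids = as.character(wide$individual_id),
                    bandwidths = bw,
                    variable = ifelse(is.null(meta$variable), NA_character_,
                                      meta$variable))
}
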