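# Non-compartmental pharmacokinetic analysis of IV-bolus concentration-time
# profiles: terminal-slope estimation, linear-up/log-down AUC and AUMC with
# tail extrapolation, and the derived clearance / MRT / Vss, plus the
# replicate-based assay-precision statistic.

#' Construct a pharmacokinetic profile
#'
#' @param time_h Strictly increasing sampling times (h).
#' @param conc_ng_ml Concentrations (ng/mL), non-negative.
#' @param below_lloq Logical flags for samples below the lower limit of
#'   quantitation.
#' @param dose_mg_per_kg Administered dose.
#' @param route Administration route; only `"iv_bolus"` is supported.
#' @param matrix_type `"plasma"` or `"brain"`.
#' @return A data.frame of class `pk_profile` with attributes
#'   `dose_mg_per_kg`, `route`, `matrix_type`.
#' @export
pk_profile <- function(time_h, conc_ng_ml, below_lloq = FALSE,
                       dose_mg_per_kg = NA_real_, route = "iv_bolus",
                       matrix_type = c("plasma", "brain")) {
  matrix_type <- match.arg(matrix_type)
  route <- match.arg(route, "iv_bolus")
  if (any(diff(time_h) <= 0)) abort_arg("`time_h` must be strictly increasing")
  if (any(conc_ng_ml < 0)) abort_arg("concentrations must be >= 0")
  df <- data.frame(time_h = as.numeric(time_h),
                   conc_ng_ml = as.numeric(conc_ng_ml),
                   below_lloq = rep_len(as.logical(below_lloq),
                                        length(time_h)))
  structure(df, dose_mg_per_kg = dose_mg_per_kg, route = route,
            matrix_type = matrix_type,
            class = c("pk_profile", "data.frame"))
}

#' Read a PK profile from CSV
#' @param path CSV with columns `time_h`, `concentration_ng_ml`, and
#'   optionally `lloq_flag`.
#' @param dose_mg_per_kg,route,matrix_type Passed to [pk_profile()].
#' @return A `pk_profile`.
#' @export
read_pk_profile <- function(path, dose_mg_per_kg = NA_real_,
                            route = "iv_bolus", matrix_type = "plasma") {
  df <- utils::read.csv(path)
  check_columns(df, c("time_h", "concentration_ng_ml"), "PK CSV")
  lloq <- if ("lloq_flag" %in% names(df)) as.logical(df$lloq_flag) else FALSE
  pk_profile(df$time_h, df$concentration_ng_ml, lloq,
             dose_mg_per_kg = dose_mg_per_kg, route = route,
             matrix_type = matrix_type)
}

# Quantifiable samples under the LLOQ rule: below-LLOQ samples are dropped
# everywhere (before Cmax they are pre-distribution artifacts; after Cmax
# they carry no usable magnitude). Zero concentrations are unquantifiable.
quantifiable <- function(profile) {
  keep <- !profile$below_lloq & profile$conc_ng_ml > 0
  profile[keep, , drop = FALSE]
}

#' Fit the terminal elimination rate constant
#'
#' Ordinary least squares of log concentration on time over candidate
#' terminal windows: the last `n` quantifiable points after (and excluding)
#' Cmax, for `n` from `min_points` up to all post-Cmax points. The window
#' maximizing the adjusted R-squared is selected (ties within 1e-4 go to the
#' longer window, the convention of standard NCA software). `lambda_z` is the
#' negative slope and must be positive.
#'
#' @param profile A `pk_profile` (or data.frame with `time_h`, `conc_ng_ml`,
#'   `below_lloq`).
#' @param min_points Minimum window size (default 3).
#' @return A list with `lambda_z` (1/h), `t_half` (h), `points_used`, `r2`,
#'   `adj_r2`, and `window` (the times used).
#' @export
fit_lambda_z <- function(profile, min_points = 3L) {
  min_points <- check_count(min_points, "min_points", min = 2L)
  q <- quantifiable(profile)
  imax <- which.max(q$conc_ng_ml)
  post <- q[seq_len(nrow(q)) > imax, , drop = FALSE]   # Cmax itself excluded
  if (nrow(post) < min_points) {
    abort_arg(sprintf("need >= %d quantifiable points after Cmax", min_points))
  }
  best <- NULL
  for (n in min_points:nrow(post)) {
    w <- post[(nrow(post) - n + 1L):nrow(post), , drop = FALSE]
    x <- w$time_h
    y <- log(w$conc_ng_ml)
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- fit$coefficients[2L]
    if (!is.finite(slope) || slope >= 0) next   # no decline: rejected window
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
    if (!is.finite(r2)) next
    adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
    if (is.null(best) || adj > best$adj_r2 + 1e-4 ||
        (abs(adj - best$adj_r2) <= 1e-4 && n > best$points_used)) {
      best <- list(lambda_z = -unname(slope), t_half = log(2) / -unname(slope),
                   points_used = n, r2 = r2, adj_r2 = adj, window = x)
    }
  }
  if (is.null(best)) {
    abort_arg("no terminal window with a positive elimination rate")
  }
  best
}

#' Areas and moments under a concentration-time curve
#'
#' AUC by the linear-up/log-down trapezoid rule (linear when concentration
#' rises or is flat, logarithmic when it falls), with AUMC computed segment
#' by segment under the same rule. The tail beyond the last quantifiable
#' sample is extrapolated as `Clast / lambda_z` for AUC and
#' `tlast * Clast / lambda_z + Clast / lambda_z^2` for AUMC.
#'
#' @param profile A `pk_profile`.
#' @param lambda_z Terminal rate constant (> 0), e.g. from [fit_lambda_z()].
#' @param method `"linlog"` (default) or `"linear"` trapezoids.
#' @return A list with `auc_0_last`, `auc_0_inf`, `aumc_0_last`,
#'   `aumc_0_inf` and `extrapolated_fraction`.
#' @export
auc_moments <- function(profile, lambda_z, method = c("linlog", "linear")) {
  method <- match.arg(method)
  if (!is.finite(lambda_z) || lambda_z <= 0) {
    abort_arg("`lambda_z` must be > 0")
  }
  q <- quantifiable(profile)
  if (nrow(q) < 2L) abort_arg("need >= 2 quantifiable samples")
  t <- q$time_h
  C <- q$conc_ng_ml
  auc <- aumc <- 0
  for (i in seq_len(nrow(q) - 1L)) {
    dt <- t[i + 1L] - t[i]
    c1 <- C[i]; c2 <- C[i + 1L]
    if (method == "linlog" && c2 < c1 && c2 > 0) {
      k <- log(c1 / c2) / dt
      auc <- auc + (c1 - c2) / k
      aumc <- aumc + (t[i] * c1 - t[i + 1L] * c2) / k + (c1 - c2) / k^2
    } else {
      auc <- auc + (c1 + c2) / 2 * dt
      aumc <- aumc + (t[i] * c1 + t[i + 1L] * c2) / 2 * dt
    }
  }
  c_last <- C[length(C)]
  t_last <- t[length(t)]
  if (c_last <= 0) {
    warning("Clast = 0; extrapolated tail set to 0", call. = FALSE)
    tail_auc <- tail_aumc <- 0
  } else {
    tail_auc <- c_last / lambda_z
    tail_aumc <- t_last * c_last / lambda_z + c_last / lambda_z^2
  }
  list(auc_0_last = auc, auc_0_inf = auc + tail_auc,
       aumc_0_last = aumc, aumc_0_inf = aumc + tail_aumc,
       extrapolated_fraction = tail_auc / (auc + tail_auc))
}

#' Non-compartmental analysis of an IV-bolus profile
#'
#' Produces the standard NCA battery: Cmax/Tmax from the observed maximum,
#' the terminal slope and half-life from [fit_lambda_z()], AUC/AUMC from
#' [auc_moments()], clearance `CL = dose / AUC(0-inf)` (reported in
#' mL/min/kg), mean residence time `MRT = AUMC / AUC` (h), and the
#' steady-state volume of distribution `Vss = CL * MRT` (reported in L/kg) —
#' the moment method appropriate for bolus intravenous dosing.
#'
#' @param profile A `pk_profile` with a dose attribute, or supply `dose_mg_per_kg`.
#' @param dose_mg_per_kg Dose override (mg/kg).
#' @param min_points,method Passed to the slope fit and AUC rule.
#' @return An object of class `nca_result`: list with `cmax`, `tmax`,
#'   `lambda_z`, `t_half`, `auc_0_last`, `auc_0_inf`, `aumc_0_inf`,
#'   `extrapolated_fraction`, `cl_ml_min_kg`, `mrt_h`, `vss_l_kg`,
#'   `lambda_z_points`, `lambda_z_r2`, `estimable`, `reason`.
#' @export
nca_summary <- function(profile, dose_mg_per_kg = NULL, min_points = 3L,
                        method = "linlog") {
  dose <- if (!is.null(dose_mg_per_kg)) dose_mg_per_kg
          else attr(profile, "dose_mg_per_kg")
  if (is.null(dose) || !is.finite(dose) || dose <= 0) {
    abort_arg("a positive `dose_mg_per_kg` is required")
  }
  not_estimable <- function(reason) {
    structure(list(cmax = NA_real_, tmax = NA_real_, lambda_z = NA_real_,
                   t_half = NA_real_, auc_0_last = NA_real_,
                   auc_0_inf = NA_real_, aumc_0_inf = NA_real_,
                   extrapolated_fraction = NA_real_, cl_ml_min_kg = NA_real_,
                   mrt_h = NA_real_, vss_l_kg = NA_real_,
                   lambda_z_points = NA_integer_, lambda_z_r2 = NA_real_,
                   dose_mg_per_kg = dose, estimable = FALSE, reason = reason),
              class = "nca_result")
  }
  q <- quantifiable(profile)
  if (nrow(q) < 3L) return(not_estimable("fewer than 3 quantifiable samples"))
  imax <- which.max(q$conc_ng_ml)
  cmax <- q$conc_ng_ml[imax]
  tmax <- q$time_h[imax]
  lz <- tryCatch(fit_lambda_z(profile, min_points = min_points),
                 error = function(e) NULL)
  if (is.null(lz)) return(not_estimable("terminal slope not estimable"))
  am <- auc_moments(profile, lz$lambda_z, method = method)
  # dose mg/kg -> ng/kg; AUC ng*h/mL => CL in mL/h/kg, then per minute
  cl_ml_h_kg <- dose * 1e6 / am$auc_0_inf
  mrt <- am$aumc_0_inf / am$auc_0_inf
  vss_l_kg <- cl_ml_h_kg * mrt / 1000
  structure(list(cmax = cmax, tmax = tmax, lambda_z = lz$lambda_z,
                 t_half = lz$t_half, auc_0_last = am$auc_0_last,
                 auc_0_inf = am$auc_0_inf, aumc_0_inf = am$aumc_0_inf,
                 extrapolated_fraction = am$extrapolated_fraction,
                 cl_ml_min_kg = cl_ml_h_kg / 60, mrt_h = mrt,
                 vss_l_kg = vss_l_kg, lambda_z_points = lz$points_used,
                 lambda_z_r2 = lz$r2, dose_mg_per_kg = dose,
                 estimable = TRUE, reason = NA_character_),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat("Non-compartmental analysis (IV bolus,", x$dose_mg_per_kg, "mg/kg)\n")
  if (!x$estimable) {
    cat("  not estimable:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  Cmax %.3g ng/mL at %.3g h\n", x$cmax, x$tmax))
  cat(sprintf("  lambda_z %.4g 1/h (t1/2 %.3g h, %d points, r2 %.4f)\n",
              x$lambda_z, x$t_half, x$lambda_z_points, x$lambda_z_r2))
  cat(sprintf("  AUC(0-inf) %.4g ng*h/mL (%.1f%% extrapolated)\n",
              x$auc_0_inf, 100 * x$extrapolated_fraction))
  cat(sprintf("  CL %.3g mL/min/kg   MRT %.3g h   Vss %.3g L/kg\n",
              x$cl_ml_min_kg, x$mrt_h, x$vss_l_kg))
  invisible(x)
}

#' Replicate-based assay precision statistic
#'
#' For duplicate standard-curve measurements, `D = 100 * (x1 - x2) / mean`
#' per pair and `S = sqrt(sum(D^2) / (2N - 1))` over the `N` pairs — a
#' percent-scale pooled measure of replicate scatter.
#'
#' @param x1,x2 Numeric vectors of paired replicate concentrations; pair
#'   means must be positive.
#' @return A list with `S` and the per-pair `D` values.
#' @examples
#' assay_precision(c(110, 105), c(90, 95))
#' @export
assay_precision <- function(x1, x2) {
  stopifnot(length(x1) == length(x2), length(x1) >= 1L)
  m <- (x1 + x2) / 2
  if (any(m <= 0)) abort_arg("every replicate pair must have a positive mean")
  D <- 100 * (x1 - x2) / m
  list(S = sqrt(sum(D^2) / (2 * length(D) - 1)), D = D)
}
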