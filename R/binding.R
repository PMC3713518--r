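#' @include AllClasses.R AllGenerics.R
NULL

#' Bound complex concentration and observed signal fraction (1:N model)
#'
#' Ligand-depletion binding of a ligand L to fiber sites each made of N
#' monomers. With S = F_T/N + L_T + Kd, the bound complex concentration is
#' the smaller root of the binding quadratic,
#' [FNL] = (S - sqrt(S^2 - 4 (F_T/N) L_T)) / 2,
#' and the observed fractional NMR signal decrease is
#' f_obs = f_max [FNL] / L_T.
#'
#' @param fiberTotal total fiber monomer concentration F_T (micromolar);
#'   may be a vector.
#' @param ligandTotal total ligand concentration L_T (micromolar).
#' @param kd apparent dissociation constant (micromolar).
#' @param fMax maximum fractional signal decrease at saturation.
#' @param n monomers per binding site (default 3).
#' @return list with components \code{complex} ([FNL], micromolar) and
#'   \code{fObs} (dimensionless), each the length of \code{fiberTotal}.
#' @examples
#' # stoichiometric limit: kd -> 0 with excess sites gives f_obs = f_max
#' boundFraction(300, 100, kd = 1e-9, fMax = 0.5, n = 3)$fObs
#' @export
boundFraction <- function(fiberTotal, ligandTotal, kd, fMax = 1, n = 3) {
  if (any(fiberTotal < 0) || ligandTotal < 0 || kd < 0 || n < 1) {
    stop("input error: concentrations and kd must be >= 0, n >= 1",
         call. = FALSE)
  }
  fn <- fiberTotal / n
  s <- fn + ligandTotal + kd
  disc <- s^2 - 4 * fn * ligandTotal
  disc[disc < 0] <- 0
  complex <- (s - sqrt(disc)) / 2
  complex <- pmin(complex, pmin(fn, ligandTotal))
  if (ligandTotal == 0) {
    stop("division guard: f_obs undefined at ligandTotal = 0", call. = FALSE)
  }
  list(complex = complex, fObs = fMax * complex / ligandTotal)
}

#' Simulate an NMR fiber-into-ligand titration
#'
#' Generates fractional peak-area decreases from the 1:N depletion model at
#' the given fiber-monomer grid, optionally with additive Gaussian noise
#' (clipped to [0, 1]).
#'
#' @param kd apparent dissociation constant, micromolar.
#' @param fMax maximum fractional signal decrease.
#' @param n monomers per site.
#' @param ligandTotal ligand concentration, micromolar.
#' @param fiberGrid strictly increasing fiber monomer concentrations,
#'   micromolar.
#' @param noiseSd Gaussian noise standard deviation (default 0 =
#'   noiseless).
#' @param seed integer seed used when noiseSd > 0.
#' @return a \linkS4class{TitrationSeries}.
#' @export
simulateTitration <- function(kd, fMax, n = 3, ligandTotal,
                              fiberGrid, noiseSd = 0, seed = 1L) {
  if (any(diff(fiberGrid) <= 0)) {
    stop("input error: fiberGrid must be strictly increasing", call. = FALSE)
  }
  f <- boundFraction(fiberGrid, ligandTotal, kd, fMax, n)$fObs
  if (noiseSd > 0) {
    set.seed(as.integer(seed))
    f <- f + stats::rnorm(length(f), 0, noiseSd)
  }
  f <- pmin(1, pmax(0, f))
  new("TitrationSeries", ligandTotal = ligandTotal, fiberTotals = fiberGrid,
      fractionalDecreases = f)
}

#' Build a TitrationSeries from observed data
#'
#' Accepts either fractional decreases directly or raw peak areas together
#' with the free-ligand area (the zero-fiber reference), in which case
#' fractional decreases are computed as (A_L - A) / A_L.
#'
#' @param ligandTotal ligand concentration, micromolar.
#' @param fiberTotals fiber monomer concentrations, micromolar.
#' @param fractionalDecreases observed Delta A / A_L values.
#' @param peakAreas raw integrated peak areas (alternative input).
#' @param freeArea peak area at zero fiber (required with peakAreas).
#' @return a \linkS4class{TitrationSeries}.
#' @export
titrationSeries <- function(ligandTotal, fiberTotals,
                            fractionalDecreases = NULL, peakAreas = NULL,
                            freeArea = NULL) {
  if (is.null(fractionalDecreases)) {
    if (is.null(peakAreas) || is.null(freeArea)) {
      stop("input error: provide fractionalDecreases, or peakAreas with freeArea",
           call. = FALSE)
    }
    fractionalDecreases <- (freeArea - peakAreas) / freeArea
  }
  new("TitrationSeries", ligandTotal = ligandTotal,
      fiberTotals = fiberTotals, fractionalDecreases = fractionalDecreases)
}

#' Fit the apparent Kd and f_max of a titration
#'
#' Ordinary least squares fit of the 1:N depletion model (see
#' \code{\link{boundFraction}}) to fractional peak-area decreases, with N
#' fixed. Initialization: kd = median fiber site concentration, f_max = the
#' largest observed decrease; bounds kd > 0, 0 <= f_max <= 1 are enforced
#' by the optimizer. Deterministic given the data.
#'
#' @param series a \linkS4class{TitrationSeries}.
#' @param n monomers per binding site, fixed during the fit (default 3).
#' @return a \linkS4class{BindingFit}.
#' @export
fitKd <- function(series, n = 3) {
  fr <- series@fractionalDecreases
  ft <- series@fiberTotals
  lt <- series@ligandTotal
  if (length(fr) < 3) stop("input error: need >= 3 titration points",
                           call. = FALSE)
  if (!any(ft > 0)) stop("input error: need at least one point with fiber present",
                         call. = FALSE)
  if (max(fr) - min(fr) < 1e-9) {
    stop("fit failure: series not identifiable (constant response; ",
         "all points saturated or all zero)", call. = FALSE)
  }
  model <- function(kd, fmax) boundFraction(ft, lt, kd, fmax, n)$fObs
  # Profiled grid start: the model is linear in f_max, so for each trial kd
  # the best f_max has a closed form; the (kd, f_max) pair with least SSE
  # seeds the nonlinear refinement. (A naive midpoint start can leave the
  # two gradient columns nearly collinear and abort the fit.)
  kd_grid <- 10^seq(-3, 5, by = 0.2)
  best <- NULL
  for (kd_try in kd_grid) {
    g <- boundFraction(ft, lt, kd_try, 1, n)$fObs
    denom <- sum(g^2)
    if (denom < 1e-12) next
    fm <- min(1, max(0, sum(fr * g) / denom))
    sse <- sum((fr - fm * g)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(kd = kd_try, fmax = fm, sse = sse)
    }
  }
  start <- list(kd = if (is.null(best)) max(stats::median(ft) / n, 1e-3)
                     else best$kd,
                fmax = if (is.null(best)) max(fr) else max(best$fmax, 1e-3))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fr ~ model(kd, fmax),
      start = start,
      lower = c(kd = 1e-9, fmax = 0),
      upper = c(kd = Inf, fmax = 1),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)),
    error = function(e) stop("fit failure: ", conditionMessage(e),
                             call. = FALSE))
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(kd = NA_real_, fmax = NA_real_))
  new("BindingFit", kd = unname(co[["kd"]]), fMax = unname(co[["fmax"]]),
      n = n,
      standardErrors = c(kd = unname(se[[1]]), fMax = unname(se[[2]])),
      residuals = as.numeric(stats::residuals(fit)), series = series)
}

#' Rescue percentage of a viability measurement
#'
#' Normalizes cell viability so that the buffer-treated control (PBS) is
#' 100 percent and the fiber-alone condition is 0 percent:
#' 100 (v_treated - v_fiber) / (v_pbs - v_fiber). Values below 0 (added
#' harm) or above 100 are possible and preserved.
#'
#' @param vTreated viability under compound + fiber treatment (may be a
#'   vector).
#' @param vFiberAlone viability with fiber alone.
#' @param vPbs viability of the buffer control (default 1.0, i.e. values
#'   already PBS-scaled).
#' @return rescue percentage(s).
#' @examples
#' rescuePercentage(0.93, 0.40)  # 88.3
#' @export
rescuePercentage <- function(vTreated, vFiberAlone, vPbs = 1.0) {
  if (vPbs <= vFiberAlone) {
    stop("input error: vPbs must exceed vFiberAlone", call. = FALSE)
  }
  100 * (vTreated - vFiberAlone) / (vPbs - vFiberAlone)
}

#' Two-sample t test from summary statistics
#'
#' Standard two-sample t statistic from group means, standard deviations
#' and sizes, pooled-variance or Welch, one- or two-tailed.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @param variant "pooled" (classic Student) or "welch".
#' @param tails 1 or 2.
#' @return list with components t, df and p.
#' @export
groupTTest <- function(mean1, sd1, n1, mean2, sd2, n2,
                       variant = c("pooled", "welch"), tails = 2) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop("input error: group sizes must be >= 2",
                             call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("input error: sds must be >= 0", call. = FALSE)
  if (!tails %in% c(1, 2)) stop("input error: tails must be 1 or 2",
                                call. = FALSE)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    df <- (sd1^2 / n1 + sd2^2 / n2)^2 /
      ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  }
  if (se == 0) {
    t <- 0
    p <- 1
  } else {
    t <- (mean1 - mean2) / se
    p <- tails * stats::pt(-abs(t), df)
  }
  list(t = t, df = df, p = min(p, 1))
}

#' Read a titration series from CSV
#'
#' Expected columns: \code{fiber_uM} and either \code{fractional_decrease}
#' or \code{peak_area}; ligand concentration is read from a
#' \code{ligand_uM} column (constant) unless given explicitly.
#'
#' @param path CSV file path.
#' @param ligandTotal ligand concentration override, micromolar.
#' @return a \linkS4class{TitrationSeries}.
#' @export
readTitrationCsv <- function(path, ligandTotal = NULL) {
  if (!file.exists(path)) stop("input error: file not found: ", path,
                               call. = FALSE)
  d <- utils::read.csv(path)
  if (is.null(ligandTotal)) {
    if (!"ligand_uM" %in% names(d)) {
      stop("input error: no ligand_uM column and no ligandTotal given",
           call. = FALSE)
    }
    ligandTotal <- d$ligand_uM[1]
  }
  if ("fractional_decrease" %in% names(d)) {
    titrationSeries(ligandTotal, d$fiber_uM,
                    fractionalDecreases = d$fractional_decrease)
  } else if ("peak_area" %in% names(d)) {
    i0 <- which(d$fiber_uM == 0)
    if (!length(i0)) stop("input error: peak_area input needs a fiber_uM = 0 row",
                          call. = FALSE)
    titrationSeries(ligandTotal, d$fiber_uM[-i0],
                    peakAreas = d$peak_area[-i0],
                    freeArea = d$peak_area[i0[1]])
  } else {
    stop("input error: need a fractional_decrease or peak_area column",
         call. = FALSE)
  }
}
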