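# Two-state unfolding thermodynamics: chemical (linear extrapolation
# method) and thermal (Gibbs-Helmholtz) fits, Myers chain-length
# correlations and cross-homolog ddG correlation partitioning.

#' Two-state signal model for chemical denaturation
#'
#' `y(c) = (aN + bN c + (aU + bU c) K(c)) / (1 + K(c))` with
#' `K(c) = exp(-(dG0 - m c)/(R T))`, R = 1.9872e-3 kcal/mol/K. At
#' `c = dG0/m` the unfolded fraction is exactly 0.5.
#'
#' @param x denaturant molarity (M).
#' @param dG0 unfolding free energy at zero denaturant (kcal/mol).
#' @param m denaturant m-value (kcal/mol/M).
#' @param aN,bN,aU,bU native / unfolded baseline intercepts and slopes.
#' @param temperatureK temperature in K.
#' @return Predicted signal.
#' @export
chemicalUnfoldingSignal <- function(x, dG0, m, aN, bN, aU, bU,
                                    temperatureK = 293.15) {
  K <- exp(-(dG0 - m * x) / (.R_KCAL * temperatureK))
  (aN + bN * x + (aU + bU * x) * K) / (1 + K)
}

#' Gibbs-Helmholtz stability curve
#'
#' `dG(T) = dHm (1 - T/Tm) + dCp ((T - Tm) - T log(T/Tm))`; zero at
#' `T = Tm` by construction.
#'
#' @param temperatureK temperature(s) in K.
#' @param Tm melting temperature (K).
#' @param dHm van 't Hoff enthalpy at Tm (kcal/mol).
#' @param dCp heat-capacity change (kcal/mol/K).
#' @return dG in kcal/mol.
#' @export
gibbsHelmholtz <- function(temperatureK, Tm, dHm, dCp) {
  dHm * (1 - temperatureK / Tm) +
    dCp * ((temperatureK - Tm) - temperatureK * log(temperatureK / Tm))
}

#' Two-state signal model for thermal denaturation
#'
#' @inheritParams gibbsHelmholtz
#' @param x temperatures (K).
#' @param aN,bN,aU,bU linear baselines in temperature.
#' @return Predicted signal.
#' @export
thermalUnfoldingSignal <- function(x, Tm, dHm, dCp, aN, bN, aU, bU) {
  K <- exp(-gibbsHelmholtz(x, Tm, dHm, dCp) / (.R_KCAL * x))
  (aN + bN * x + (aU + bU * x) * K) / (1 + K)
}

.check_curve <- function(x, y, minPoints = 8L) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < minPoints)
    stop("need at least ", minPoints, " points to fit, got ", length(x))
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in the curve")
}

# baseline-based starting values; mid = x where apparent fraction = 0.5
.plateau_starts <- function(x, y) {
  n <- length(x)
  nb <- max(3L, n %/% 5L)
  fitN <- lm(y ~ x, data = data.frame(x = x[1:nb], y = y[1:nb]))
  fitU <- lm(y ~ x, data = data.frame(x = x[(n - nb + 1):n],
                                      y = y[(n - nb + 1):n]))
  yN <- unname(predict(fitN, data.frame(x = x)))
  yU <- unname(predict(fitU, data.frame(x = x)))
  fapp <- (y - yN) / (yU - yN)
  list(aN = unname(coef(fitN)[1]), bN = unname(coef(fitN)[2]),
       aU = unname(coef(fitU)[1]), bU = unname(coef(fitU)[2]),
       fapp = fapp)
}

#' Fit the two-state linear-extrapolation model to a chemical
#' denaturation curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) with six free
#' parameters: `dG0`, `m` and sloped native/unfolded baselines. Starting
#' values are data-driven: plateau linear fits for the baselines, the
#' midpoint from the apparent unfolded fraction crossing 0.5, and `m`
#' from the width of the transition. Parameter standard errors come from
#' the fit covariance; `Cm = dG0 / m` is derived.
#'
#' @param x denaturant molarity, strictly increasing, at least 8 points
#'   with points on both plateaus.
#' @param y observed signal (e.g. tryptophan fluorescence).
#' @param temperatureK isothermal temperature of the experiment (K),
#'   default 293.15 (20 C).
#' @return A [ChemicalUnfoldingFit-class].
#' @examples
#' sim <- simulateUnfolding("chemical",
#'   params = list(dG0 = 4.3, m = 1.55), nPoints = 30, noiseSd = 0,
#'   seed = 1)
#' fitChemicalUnfolding(sim$curve$x, sim$curve$y)
#' @export
fitChemicalUnfolding <- function(x, y, temperatureK = 293.15) {
  .check_curve(x, y)
  st <- .plateau_starts(x, y)
  fapp <- st$fapp
  amplitude <- abs((st$aU + st$bU * mean(x)) - (st$aN + st$bN * mean(x)))
  if (!is.finite(amplitude) || amplitude < 1e-3 * diff(range(y)) ||
      diff(range(y)) == 0)
    stop("no unfolding transition detected in the curve")
  crosses <- which(diff(sign(fapp - 0.5)) != 0)
  if (!length(crosses) || max(fapp, na.rm = TRUE) < 0.75 ||
      min(fapp, na.rm = TRUE) > 0.25)
    stop("no unfolding transition detected in the curve")
  i <- crosses[1]
  Cm0 <- x[i] + (0.5 - fapp[i]) * (x[i + 1] - x[i]) / (fapp[i + 1] - fapp[i])
  if (!is.finite(Cm0))
    stop("no unfolding transition detected in the curve")
  inTrans <- range(x[fapp > 0.2 & fapp < 0.8])
  width <- max(diff(inTrans), diff(range(x)) / 20)
  m0 <- 4.4 * .R_KCAL * temperatureK / width  # logistic 20-80% width
  start <- list(dG0 = m0 * Cm0, m = m0, aN = st$aN, bN = st$bN,
                aU = st$aU, bU = st$bU)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ chemicalUnfoldingSignal(x, dG0, m, aN, bN, aU, bU, temperatureK),
      data = data.frame(x = x, y = y), start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("chemical unfolding fit failed to converge: ",
           conditionMessage(e), "\nstarting values: ",
           paste(names(start), round(unlist(start), 3), sep = "=",
                 collapse = ", "), call. = FALSE))

  co <- coef(fit)
  sm <- summary(fit)
  new("ChemicalUnfoldingFit",
      coefficients = co, se = sm$coefficients[, "Std. Error"],
      cov = vcov(fit), Cm = unname(co["dG0"] / co["m"]),
      temperatureK = temperatureK,
      rss = sum(resid(fit)^2),
      data = data.frame(x = x, y = y, fitted = fitted(fit),
                        residual = resid(fit)))
}

#' Fit the two-state Gibbs-Helmholtz model to a thermal denaturation
#' curve
#'
#' `dCp` is a fixed input (not fitted), following standard practice when
#' a single ramp cannot constrain it; a sensitivity analysis across a
#' `dCp` grid can be run by refitting. Returns the stability
#' extrapolated to a reference temperature via the stability curve.
#'
#' @param x temperatures in K, strictly increasing, spanning the
#'   transition.
#' @param y observed signal (e.g. far-UV CD at 220 nm).
#' @param dCp fixed heat-capacity change, kcal/mol/K; must be positive.
#' @param TrefK reference temperature for the extrapolated dG (default
#'   293.15 K).
#' @return A [ThermalUnfoldingFit-class].
#' @examples
#' sim <- simulateUnfolding("thermal",
#'   params = list(Tm = 330, dHm = 60, dCp = 1.6), nPoints = 40,
#'   noiseSd = 0, seed = 1)
#' fitThermalUnfolding(sim$curve$x, sim$curve$y, dCp = 1.6)
#' @export
fitThermalUnfolding <- function(x, y, dCp, TrefK = 293.15) {
  .check_curve(x, y)
  if (!is.numeric(dCp) || dCp <= 0) stop("dCp must be positive")
  st <- .plateau_starts(x, y)
  fapp <- st$fapp
  amplitude <- abs((st$aU + st$bU * mean(x)) - (st$aN + st$bN * mean(x)))
  if (!is.finite(amplitude) || amplitude < 1e-3 * diff(range(y)) ||
      diff(range(y)) == 0)
    stop("no unfolding transition detected in the curve")
  crosses <- which(diff(sign(fapp - 0.5)) != 0)
  if (!length(crosses))
    stop("no unfolding transition detected in the curve")
  i <- crosses[1]
  Tm0 <- x[i] + (0.5 - fapp[i]) * (x[i + 1] - x[i]) / (fapp[i + 1] - fapp[i])
  if (!is.finite(Tm0))
    stop("no unfolding transition detected in the curve")
  inTrans <- range(x[fapp > 0.2 & fapp < 0.8])
  width <- max(diff(inTrans), diff(range(x)) / 20)
  dHm0 <- 4.4 * .R_KCAL * Tm0^2 / width
  start <- list(Tm = Tm0, dHm = dHm0, aN = st$aN, bN = st$bN,
                aU = st$aU, bU = st$bU)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ thermalUnfoldingSignal(x, Tm, dHm, dCp, aN, bN, aU, bU),
      data = data.frame(x = x, y = y), start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("thermal unfolding fit failed to converge: ",
           conditionMessage(e), call. = FALSE))

  co <- coef(fit)
  sm <- summary(fit)
  new("ThermalUnfoldingFit",
      coefficients = co, se = sm$coefficients[, "Std. Error"],
      cov = vcov(fit), dCp = dCp,
      dGTref = gibbsHelmholtz(TrefK, co[["Tm"]], co[["dHm"]], dCp),
      TrefK = TrefK, rss = sum(resid(fit)^2),
      data = data.frame(x = x, y = y, fitted = fitted(fit),
                        residual = resid(fit)))
}

#' Myers chain-length correlations for unfolding energetics
#'
#' Empirical linear relations between chain length, the change in
#' solvent-accessible surface area on unfolding, the urea m-value and the
#' heat-capacity change (Myers, Pace & Scholtz 1995):
#' `dASA = -907 + 93 n` (A^2), `m = (374 + 0.11 dASA)/1000`
#' (kcal/mol/M), `dCp = (-251 + 0.19 dASA)/1000` (kcal/mol/K).
#'
#' @param nResidues chain length; at least 20.
#' @return Named numeric: `deltaASA`, `m_urea`, `dCp`.
#' @examples
#' myersPredict(116)
#' @export
myersPredict <- function(nResidues) {
  if (!is.numeric(nResidues) || any(nResidues < 20))
    stop("nResidues must be numeric and at least 20")
  dASA <- -907 + 93 * nResidues
  c(deltaASA = dASA,
    m_urea = (374 + 0.11 * dASA) / 1000,
    dCp = (-251 + 0.19 * dASA) / 1000)
}

#' Cross-homolog correlation of alanine-scanning ddG values
#'
#' Pearson correlation and least-squares line of the per-position ddG
#' values of one homolog against the other, overall and partitioned by
#' conservation class (conserved / non-conserved / disease-linked), as
#' used to compare mutational effects on the energetics of two frataxin
#' variants.
#'
#' @param table data.frame with columns `position_a`, `position_b`,
#'   `ddg_a`, `ddg_b` (kcal/mol) and `class` (one of `conserved`,
#'   `non_conserved`, `disease`).
#' @param classes classes to report; `"all"` pools every row.
#' @return data.frame: class, n, pearson_r, slope, intercept. `pearson_r`
#'   is `NA` (with a message) for degenerate variance.
#' @export
ddgCorrelation <- function(table,
                           classes = c("all", "conserved", "non_conserved",
                                       "disease")) {
  need <- c("ddg_a", "ddg_b", "class")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  known <- c("conserved", "non_conserved", "disease")
  bad <- setdiff(unique(table$class), known)
  if (length(bad))
    stop("unknown conservation class(es): ", paste(bad, collapse = ", "))
  out <- lapply(classes, function(cl) {
    rows <- if (cl == "all") table else table[table$class == cl, ]
    if (nrow(rows) < 3L)
      stop("fewer than 3 rows for class '", cl, "'")
    if (var(rows$ddg_a) == 0 || var(rows$ddg_b) == 0) {
      message("degenerate variance for class '", cl, "'; r undefined")
      return(data.frame(class = cl, n = nrow(rows), pearson_r = NA_real_,
                        slope = NA_real_, intercept = NA_real_))
    }
    fit <- lm(ddg_b ~ ddg_a, data = rows)
    data.frame(class = cl, n = nrow(rows),
               pearson_r = cor(rows$ddg_a, rows$ddg_b),
               slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]))
  })
  do.call(rbind, out)
}

#' Read an alanine-scanning ddG table from CSV
#'
#' Expected header: `position_a, position_b, ddg_a, ddg_b, class`.
#'
#' @param file CSV path.
#' @return data.frame validated for [ddgCorrelation()].
#' @export
readDdgTable <- function(file) {
  if (!file.exists(file)) stop("ddG table not found: ", file)
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("position_a", "position_b", "ddg_a", "ddg_b", "class")
  if (!all(need %in% names(df)))
    stop("ddG table must have header: ", paste(need, collapse = ", "))
  df
}
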