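#' Default kinetic parameter table for the methionine cycle
#'
#' The rate laws encode the canonical regulatory motifs of methionine-cycle
#' models: SAM product inhibition of MATI/MATII, cooperative SAM activation of
#' MATIII, a Hill (n = 2) GNMT with SAH inhibition, a generic SAM-dependent
#' transmethylation flux (DNMT) with SAH inhibition, reversible mass-action
#' AHCY, SAM+SAH-activated CBS, and betaine/folate-saturable BHMT and MTR.
#' Values are package defaults chosen to give physiologically plausible
#' steady states (Met and SAM tens of uM, SAH ~1-2 uM) under a 100 uM/h
#' methionine input; they are not fitted to any published data set.
#' @keywords internal
.defaultEnzymeTable <- function() {
  list(
    MATI   = list(present = TRUE,  vmax = 400, km = 41,  ki = 50),
    MATII  = list(present = FALSE, vmax = 300, km = 4,   ki = 60),
    MATIII = list(present = TRUE,  vmax = 300, km = 300, alpha = 7, ka = 360),
    GNMT   = list(present = TRUE,  vmax = 600, km = 100, ki = 18),
    DNMT   = list(present = TRUE,  vmax = 150, km = 50,  ki = 20),
    AHCY   = list(present = TRUE,  af = 100,  ar = 1),
    CBS    = list(present = TRUE,  k = 30,    ka = 90),
    MTR    = list(present = TRUE,  vmax = 80,  kmh = 1,  kmf = 25),
    BHMT   = list(present = TRUE,  vmax = 180, kmh = 12, kmb = 100)
  )
}

.defaultPools <- function() c(fivemthf = 5.2, betaine = 50, adenosine = 1)

#' Construct an enzyme profile for the methionine-cycle model
#'
#' Builds an [EnzymeProfile-class] from one of two cell-type presets.
#' \code{"hepatic"} carries the liver complement (MATI and MATIII present,
#' BHMT present, MATII absent); \code{"follicular"} mirrors ovarian
#' somatic/embryonic cells (MATII only; MATI, MATIII and BHMT absent) in
#' which homocysteine remethylation relies entirely on folate/B12-dependent
#' MTR. Kinetic constants are shared between presets so that the presets
#' differ only in enzyme presence.
#'
#' @param cellType "hepatic" or "follicular".
#' @param enzymes optional named list of per-enzyme overrides, merged over the
#'   default table (e.g. \code{list(DNMT = list(vmax = 100))}).
#' @param pools optional named numeric overrides for fivemthf, betaine,
#'   adenosine (uM).
#' @return An [EnzymeProfile-class].
#' @examples
#' hep <- enzymeProfile("hepatic")
#' fol <- enzymeProfile("follicular")
#' @export
enzymeProfile <- function(cellType = c("hepatic", "follicular"),
                          enzymes = list(), pools = numeric()) {
  cellType <- match.arg(cellType)
  tab <- .defaultEnzymeTable()
  if (cellType == "follicular") {
    tab$MATI$present <- FALSE
    tab$MATIII$present <- FALSE
    tab$BHMT$present <- FALSE
    tab$MATII$present <- TRUE
  }
  for (e in names(enzymes)) {
    if (!e %in% .ENZYMES) stop("unknown enzyme: ", e)
    tab[[e]][names(enzymes[[e]])] <- enzymes[[e]]
  }
  pl <- .defaultPools()
  if (length(pools)) pl[names(pools)] <- pools
  new("EnzymeProfile", enzymes = tab, pools = pl, cellType = cellType)
}

#' Remove enzymes from a profile
#'
#' @param profile an [EnzymeProfile-class].
#' @param enzymes character vector of enzyme names to mark absent.
#' @return The modified profile. Marking an enzyme absent forces its flux to
#'   zero identically, equivalent to setting its vmax to 0.
#' @export
knockoutEnzymes <- function(profile, enzymes) {
  bad <- setdiff(enzymes, .ENZYMES)
  if (length(bad)) stop("unknown enzyme(s): ", paste(bad, collapse = ", "))
  for (e in enzymes) profile@enzymes[[e]]$present <- FALSE
  validObject(profile)
  profile
}

#' @describeIn enzymeProfile Read a profile from a YAML parameter file (one
#'   section per enzyme plus a \code{pools} section and optional
#'   \code{cellType}).
#' @param path file path.
#' @export
readEnzymeProfile <- function(path) {
  y <- yaml::read_yaml(path)
  cellType <- if (is.null(y$cellType)) "hepatic" else y$cellType
  pools <- if (is.null(y$pools)) numeric() else unlist(y$pools)
  enz <- y[intersect(names(y), .ENZYMES)]
  enz <- lapply(enz, function(p) { p$present <- isTRUE(p$present); p })
  enzymeProfile(cellType, enzymes = enz, pools = pools)
}

#' @describeIn enzymeProfile Write a profile to a YAML parameter file.
#' @param profile an [EnzymeProfile-class].
#' @export
writeEnzymeProfile <- function(profile, path) {
  y <- profile@enzymes
  y$pools <- as.list(profile@pools)
  y$cellType <- profile@cellType
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Input-protocol constructors
#'
#' @param baseline baseline methionine influx (uM/h).
#' @param stepTo post-step influx (uM/h). @param stepTime step time (h).
#' @param relAmplitude relative forcing amplitude, in [0, 1).
#' @param period forcing period (h).
#' @return An [InputProtocol-class].
#' @export
constantInput <- function(baseline) {
  new("InputProtocol", kind = "constant", baseline = baseline, stepTo = 0,
      stepTime = 0, relAmplitude = 0, period = 1)
}

#' @rdname constantInput
#' @export
stepInput <- function(baseline, stepTo, stepTime) {
  new("InputProtocol", kind = "step", baseline = baseline, stepTo = stepTo,
      stepTime = stepTime, relAmplitude = 0, period = 1)
}

#' @rdname constantInput
#' @export
sinusoidInput <- function(baseline, relAmplitude, period) {
  new("InputProtocol", kind = "sinusoid", baseline = baseline, stepTo = 0,
      stepTime = 0, relAmplitude = relAmplitude, period = period)
}

#' Evaluate the methionine influx at time t
#' @param input an [InputProtocol-class]. @param t time (h), vectorised.
#' @return influx (uM/h).
#' @export
inputRate <- function(input, t) {
  switch(input@kind,
    constant = rep(input@baseline, length(t)),
    step = ifelse(t < input@stepTime, input@baseline, input@stepTo),
    sinusoid = input@baseline *
      (1 + input@relAmplitude * sin(2 * pi * t / input@period)))
}

#' Construct a methionine-cycle state vector
#' @param met,sam,sah,hcy concentrations (uM), all >= 0.
#' @return named numeric of length 4.
#' @export
metCycleState <- function(met, sam, sah, hcy) {
  s <- c(met = met, sam = sam, sah = sah, hcy = hcy)
  if (any(!is.finite(s)) || any(s < 0))
    stop("concentrations must be finite and >= 0")
  s
}

# Internal flux kernel. Tolerates the tiny negative excursions a stiff
# integrator can produce (clamped at 0 below 1e-9 in magnitude).
.fluxKernel <- function(state, profile) {
  s <- pmax(unname(state), 0)
  met <- s[1]; sam <- s[2]; sah <- s[3]; hcy <- s[4]
  e <- profile@enzymes
  pl <- profile@pools
  pres <- vapply(e, function(p) as.numeric(p$present), numeric(1))
  v <- c(
    MATI   = e$MATI$vmax   * met / (e$MATI$km + met)   * e$MATI$ki / (e$MATI$ki + sam),
    MATII  = e$MATII$vmax  * met / (e$MATII$km + met)  * e$MATII$ki / (e$MATII$ki + sam),
    MATIII = e$MATIII$vmax * met / (e$MATIII$km + met) *
             (1 + e$MATIII$alpha * sam^2 / (e$MATIII$ka^2 + sam^2)),
    GNMT   = e$GNMT$vmax * sam^2 / (e$GNMT$km^2 + sam^2) *
             e$GNMT$ki / (e$GNMT$ki + sah),
    DNMT   = e$DNMT$vmax * sam / (e$DNMT$km + sam) * e$DNMT$ki / (e$DNMT$ki + sah),
    AHCY   = e$AHCY$af * sah - e$AHCY$ar * hcy * unname(pl["adenosine"]),
    CBS    = e$CBS$k * hcy * (sam + sah)^2 / (e$CBS$ka^2 + (sam + sah)^2),
    MTR    = e$MTR$vmax * hcy / (e$MTR$kmh + hcy) *
             unname(pl["fivemthf"]) / (e$MTR$kmf + unname(pl["fivemthf"])),
    BHMT   = e$BHMT$vmax * hcy / (e$BHMT$kmh + hcy) *
             unname(pl["betaine"]) / (e$BHMT$kmb + unname(pl["betaine"]))
  )
  v * pres[.ENZYMES]
}

#' Reaction fluxes of the methionine cycle at a given state
#'
#' Evaluates all nine reaction rates at a state under the fixed rate laws
#' (see [enzymeProfile()] for the regulatory motifs). An enzyme with
#' \code{present = FALSE} or \code{vmax = 0} contributes exactly 0. AHCY is
#' reported as the net (forward minus reverse) hydrolysis rate.
#'
#' @param state named numeric from [metCycleState()] (uM); negative values
#'   are a domain error.
#' @param profile an [EnzymeProfile-class].
#' @return named numeric of rates (uM/h) for MATI, MATII, MATIII, GNMT,
#'   DNMT, AHCY, CBS, MTR, BHMT.
#' @export
reactionFluxes <- function(state, profile) {
  if (length(state) != 4 || any(!is.finite(state)))
    stop("state must be 4 finite concentrations")
  if (any(state < 0))
    stop("negative concentration in state: ",
         paste(names(state)[state < 0], collapse = ", "))
  .fluxKernel(state, profile)
}

#' Time derivative of the methionine-cycle state
#'
#' Stoichiometry: methionine is fed by the input and by remethylation (MTR,
#' BHMT) and consumed by the three MAT isoforms; SAM by MAT minus the two
#' transmethylation fluxes (GNMT, DNMT); SAH by transmethylation minus AHCY;
#' homocysteine by AHCY minus remethylation and transsulfuration (CBS).
#'
#' @param state named numeric (uM). @param t time (h).
#' @param profile an [EnzymeProfile-class]. @param input an [InputProtocol-class].
#' @return named numeric d(state)/dt (uM/h).
#' @export
metCycleRHS <- function(state, t, profile, input) {
  v <- .fluxKernel(state, profile)
  vin <- inputRate(input, t)
  c(met = vin + v[["MTR"]] + v[["BHMT"]] -
          v[["MATI"]] - v[["MATII"]] - v[["MATIII"]],
    sam = v[["MATI"]] + v[["MATII"]] + v[["MATIII"]] - v[["GNMT"]] - v[["DNMT"]],
    sah = v[["GNMT"]] + v[["DNMT"]] - v[["AHCY"]],
    hcy = v[["AHCY"]] - v[["MTR"]] - v[["BHMT"]] - v[["CBS"]])
}

#' Simulate the methionine cycle
#'
#' Stiff-capable integration (deSolve::lsoda, rtol 1e-8, atol 1e-10) of the
#' cycle under a forcing protocol.
#'
#' @param profile an [EnzymeProfile-class]. @param input an [InputProtocol-class].
#' @param init initial state from [metCycleState()].
#' @param tEnd end time (h), > 0. @param dtReport reporting interval (h).
#' @return A [MetCycleTrajectory-class] with states and per-reaction fluxes
#'   at every reported time.
#' @export
simulateMetCycle <- function(profile, input, init, tEnd, dtReport = 0.01) {
  stopifnot(tEnd > 0, dtReport > 0)
  validObject(profile); validObject(input)
  if (any(init < 0)) stop("initial state must be non-negative")
  times <- seq(0, tEnd, by = dtReport)
  deriv <- function(t, y, parms) list(unname(metCycleRHS(y, t, profile, input)))
  out <- deSolve::lsoda(unname(init), times, deriv, parms = NULL,
                        rtol = 1e-8, atol = 1e-10, maxsteps = 50000)
  if (nrow(out) < length(times) || any(!is.finite(out)))
    stop("integration failed at t = ", max(out[is.finite(out[, 1]), 1]), " h")
  states <- out[, 2:5, drop = FALSE]
  colnames(states) <- .METABOLITES
  fluxes <- t(apply(states, 1, .fluxKernel, profile = profile))
  colnames(fluxes) <- .ENZYMES
  new("MetCycleTrajectory", times = out[, 1], states = states,
      fluxes = fluxes, profile = profile, input = input)
}

#' Steady state of the methionine cycle under constant input
#'
#' Finds a state where all four derivatives vanish, by Newton-type root
#' finding (pracma::fsolve) seeded from a long integration. Fails loudly if
#' the residual cannot be driven below \code{tol}.
#'
#' @param profile an [EnzymeProfile-class].
#' @param constantInputRate methionine influx (uM/h).
#' @param tol max-norm tolerance on the residual (uM/h).
#' @param tSettle settling horizon for the seeding integration (h).
#' @return named numeric steady state (uM).
#' @export
steadyState <- function(profile, constantInputRate, tol = 1e-10,
                        tSettle = 2000) {
  input <- constantInput(constantInputRate)
  if (constantInputRate > 0) {
    e <- profile@enzymes
    if (!e$MTR$present && !e$BHMT$present && !e$CBS$present)
      stop("non-physiological: no homocysteine removal route ",
           "(MTR, BHMT and CBS all absent) with positive input")
  }
  init <- metCycleState(10, 10, 1, 1)
  traj <- simulateMetCycle(profile, input, init, tEnd = tSettle, dtReport = tSettle / 200)
  seed <- pmax(traj@states[nrow(traj@states), ], 0)
  f <- function(x) unname(metCycleRHS(x, 0, profile, input))
  res <- tryCatch(pracma::fsolve(f, unname(seed), tol = .Machine$double.eps),
                  error = function(e) NULL)
  cand <- if (!is.null(res)) pmax(res$x, 0) else seed
  if (max(abs(f(cand))) > tol) {
    # polish with a damped Newton pass on the numerical Jacobian
    x <- cand
    for (i in seq_len(50)) {
      fx <- f(x)
      if (max(abs(fx)) <= tol) break
      J <- pracma::jacobian(f, x)
      step <- tryCatch(solve(J, fx), error = function(e) NULL)
      if (is.null(step)) break
      x <- pmax(x - step, 0)
    }
    cand <- x
  }
  if (max(abs(f(cand))) > tol)
    stop("steady state not found: residual ", signif(max(abs(f(cand))), 3),
         " uM/h exceeds tolerance ", tol)
  stats::setNames(cand, .METABOLITES)
}

#' Volatility of SAM-mediated transmethylation under periodic forcing
#'
#' Simulates the cycle from its constant-input steady state under sinusoidal
#' methionine forcing, discards \code{nTransient} periods, and summarises the
#' chosen flux over the following \code{nAnalysis} periods as a relative
#' amplitude, (max - min) / mean.
#'
#' @param profile an [EnzymeProfile-class].
#' @param input a sinusoid [InputProtocol-class].
#' @param nTransient,nAnalysis whole forcing periods to discard / analyse.
#' @param fluxName which reaction to summarise (default "DNMT", the generic
#'   SAM-dependent transmethylation flux).
#' @return list with \code{fluxName}, \code{meanFlux} (uM/h) and
#'   \code{relAmplitude} (dimensionless).
#' @export
transmethylationVolatility <- function(profile, input, nTransient = 5,
                                       nAnalysis = 3, fluxName = "DNMT") {
  if (input@kind != "sinusoid") stop("input must be a sinusoid protocol")
  stopifnot(nTransient >= 1, nAnalysis >= 1, fluxName %in% .ENZYMES)
  ss <- steadyState(profile, input@baseline)
  tEnd <- (nTransient + nAnalysis) * input@period
  traj <- simulateMetCycle(profile, input, ss, tEnd,
                           dtReport = input@period / 200)
  keep <- traj@times >= nTransient * input@period
  v <- traj@fluxes[keep, fluxName]
  m <- mean(v)
  list(fluxName = fluxName, meanFlux = m,
       relAmplitude = if (m > 0) (max(v) - min(v)) / m else 0)
}

#' Enzyme-knockout experiment: volatility and remethylation partition
#'
#' Compares a baseline profile with the same profile after removing the given
#' enzymes: transmethylation volatility under the supplied sinusoid forcing
#' (baseline vs knockout) and, at the constant-input steady state, the
#' fraction of homocysteine remethylation carried by the folate/B12-dependent
#' methionine synthase, V_MTR / (V_MTR + V_BHMT).
#'
#' @param profile baseline [EnzymeProfile-class].
#' @param enzymes character vector of enzymes to remove (may be empty).
#' @param input a sinusoid [InputProtocol-class].
#' @return list with elements \code{baseline} and \code{knockout}, each a
#'   list of \code{volatility} (see [transmethylationVolatility()]),
#'   \code{steadyState}, \code{fluxes}, \code{mtrFraction}.
#' @export
knockoutExperiment <- function(profile, enzymes, input) {
  ko <- knockoutEnzymes(profile, enzymes)
  one <- function(p) {
    ss <- steadyState(p, input@baseline)
    v <- .fluxKernel(ss, p)
    remeth <- v[["MTR"]] + v[["BHMT"]]
    list(volatility = transmethylationVolatility(p, input),
         steadyState = ss, fluxes = v,
         mtrFraction = if (remeth > 0) v[["MTR"]] / remeth else NA_real_)
  }
  list(baseline = one(profile), knockout = one(ko))
}

#' Export a trajectory as a data frame (and optionally TSV)
#'
#' @param traj a [MetCycleTrajectory-class].
#' @param path optional TSV output path (columns: time, met, sam, sah, hcy,
#'   then one column per reaction flux).
#' @return data.frame (invisibly if \code{path} given).
#' @export
trajectoryFrame <- function(traj, path = NULL) {
  df <- data.frame(time = traj@times, traj@states, traj@fluxes,
                   check.names = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' @export
setMethod("show", "EnzymeProfile", function(object) {
  pres <- vapply(object@enzymes, function(p) isTRUE(p$present), logical(1))
  cat("EnzymeProfile (", object@cellType, ")\n", sep = "")
  cat("  present:", paste(names(pres)[pres], collapse = ", "), "\n")
  if (any(!pres)) cat("  absent: ", paste(names(pres)[!pres], collapse = ", "), "\n")
  cat("  pools (uM):", paste(names(object@pools), signif(object@pools, 3),
                             sep = "=", collapse = ", "), "\n")
})

#' @export
setMethod("show", "MetCycleTrajectory", function(object) {
  cat("MetCycleTrajectory:", length(object@times), "time points over",
      signif(max(object@times), 4), "h\n")
  cat("  final state (uM):",
      paste(colnames(object@states),
            signif(object@states[nrow(object@states), ], 4),
            sep = "=", collapse = ", "), "\n")
})
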