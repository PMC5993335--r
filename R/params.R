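#' Simulation parameter set
#'
#' Builds and validates the full parameter set of the model. Defaults are the
#' reference values used throughout: a 135 nm filament of 2.7 nm subunits,
#' fimbrin-like crosslinkers (extensional stiffness 0.1 pN/nm, torsional
#' stiffness 10 pN nm/rad, rest length 10 nm), slip-bond kinetics
#' (`kf` = 1/s, `kb0` = 10/s, critical energy 10 kBT), a 500 nm cubic box and
#' a 7000-subunit actin budget.
#'
#' Internally all quantities are in pN, nm, s. Two fields are given in the
#' customary external units and converted/stored alongside:
#' `eta` is supplied in Pa s (stored converted as `eta` in pN s/nm^2, with the
#' original kept as `eta_Pas`), and `Ec` is supplied in units of `kBT`
#' (`Ec_abs` holds the value in pN nm).
#'
#' @param L filament length (nm); must be an integer multiple of `delta`.
#' @param b filament diameter (nm).
#' @param delta axial rise per subunit (nm).
#' @param kappa_ext crosslinker extensional stiffness (pN/nm).
#' @param kappa_tor crosslinker torsional stiffness (pN nm / rad).
#' @param l0 crosslinker rest length (nm).
#' @param kf crosslink formation rate constant per subunit pair (1/s).
#' @param kb0 strain-free crosslink breakage rate constant (1/s).
#' @param Ec critical energy of the slip bond, in units of `kBT`.
#' @param rc reaction distance for crosslink formation (nm).
#' @param fst magnitude of the steric repulsion force (pN).
#' @param kBT thermal energy (pN nm).
#' @param N_actin total actin subunit budget (count).
#' @param eta viscosity of the medium (Pa s).
#' @param dt simulation time step (s).
#' @param box_size edge of the cubic simulation box (nm).
#' @param g_max maximum fraction of occupied subunits per filament.
#' @param seed integer RNG seed recorded with the parameter set.
#' @param check_dt if `TRUE` (default), reject time steps larger than 1/100 of
#'   the fastest spring relaxation time (see [stability_timestep()]).
#' @return an object of class `cn_params` (a named list).
#' @examples
#' p <- cn_params()
#' p$N_mon            # 50 subunits for the 135 nm reference filament
#' stability_timestep(p)
#' @export
cn_params <- function(L = 135, b = 6, delta = 2.7, kappa_ext = 0.1,
                      kappa_tor = 10, l0 = 10, kf = 1, kb0 = 10, Ec = 10,
                      rc = 20, fst = 100, kBT = 4.1, N_actin = 7000,
                      eta = 10, dt = 1e-5, box_size = 500, g_max = 0.25,
                      seed = 1L, check_dt = TRUE) {
  p <- list(L = L, b = b, delta = delta, kappa_ext = kappa_ext,
            kappa_tor = kappa_tor, l0 = l0, kf = kf, kb0 = kb0, Ec = Ec,
            rc = rc, fst = fst, kBT = kBT, N_actin = N_actin,
            eta_Pas = eta, eta = eta * 1e-6, dt = dt, box_size = box_size,
            g_max = g_max, seed = as.integer(seed))
  p$Ec_abs <- p$Ec * p$kBT
  p$N_mon <- as.integer(round(L / delta))
  class(p) <- "cn_params"
  validate_params(p, check_dt = check_dt)
  p
}

validate_params <- function(p, check_dt = TRUE) {
  pos <- c("L", "b", "delta", "kappa_ext", "kappa_tor", "l0", "kf", "kb0",
           "Ec", "rc", "fst", "kBT", "N_actin", "eta", "dt", "box_size")
  for (key in pos) {
    v <- p[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("parameter '", key, "' must be a finite non-negative number")
  }
  strictly <- c("L", "b", "delta", "eta", "dt", "box_size")
  for (key in strictly) {
    if (p[[key]] <= 0) stop("parameter '", key, "' must be strictly positive")
  }
  if (p$g_max <= 0 || p$g_max > 1)
    stop("parameter 'g_max' must be in (0, 1]")
  if (abs(p$L - p$N_mon * p$delta) > 1e-6 * p$delta)
    stop("parameter 'L' must be an integer multiple of the subunit rise 'delta'")
  if (p$N_mon < 2L)
    stop("filaments must have at least 2 subunits (L >= 2*delta)")
  if (log(p$L / p$b) <= 0.66)
    stop("slender-body friction requires log(L/b) > 0.66")
  if (check_dt && p$kappa_ext > 0 && p$kappa_tor > 0) {
    tau <- stability_timestep(p)
    if (p$dt > tau / 100)
      stop(sprintf(paste0("time step dt = %g s exceeds tau/100 = %g s ",
                          "(spring relaxation time tau = %g s); reduce dt ",
                          "or construct with check_dt = FALSE"),
                   p$dt, tau / 100, tau))
  }
  invisible(p)
}

#' Spring relaxation time for the time-step criterion
#'
#' The fastest relaxation time of the crosslinker springs against filament
#' drag, `tau = min(xi_par_t/kappa_ext, xi_perp_t/kappa_ext,
#' xi_par_r/kappa_tor, xi_perp_r/kappa_tor)`. A run is only stable when the
#' time step is at least 100 times smaller than `tau`.
#'
#' @param p a [cn_params()] object.
#' @return the relaxation time in seconds.
#' @examples
#' stability_timestep(cn_params())  # ~0.015 s for the reference values
#' @export
stability_timestep <- function(p) {
  stopifnot(inherits(p, "cn_params"))
  fr <- friction_coefficients(p$L, p$b, p$eta)
  min(fr$xi_par_t / p$kappa_ext, fr$xi_perp_t / p$kappa_ext,
      fr$xi_par_r / p$kappa_tor, fr$xi_perp_r / p$kappa_tor)
}

#' Maximum number of simultaneously attached crosslinkers
#'
#' The per-filament occupancy cap `g_max` bounds the total number of attached
#' crosslinkers by `floor(N_actin * g_max / 2)` (two subunits per
#' crosslinker): 875 for the reference budget of 7000 subunits at 25%
#' occupancy.
#'
#' @param p a [cn_params()] object.
#' @return integer upper bound on the attached crosslinker count.
#' @export
max_crosslinkers <- function(p) {
  stopifnot(inherits(p, "cn_params"))
  as.integer(floor(p$N_actin * p$g_max / 2))
}

#' @export
print.cn_params <- function(x, ...) {
  cat("<cn_params>\n")
  cat(sprintf("  filament: L = %g nm (%d subunits of %g nm), b = %g nm\n",
              x$L, x$N_mon, x$delta, x$b))
  cat(sprintf("  crosslinker: kappa_ext = %g pN/nm, kappa_tor = %g pN nm/rad, l0 = %g nm\n",
              x$kappa_ext, x$kappa_tor, x$l0))
  cat(sprintf("  kinetics: kf = %g /s, kb0 = %g /s, Ec = %g kBT, rc = %g nm\n",
              x$kf, x$kb0, x$Ec, x$rc))
  cat(sprintf("  medium: eta = %g Pa s, kBT = %g pN nm, box = %g nm\n",
              x$eta_Pas, x$kBT, x$box_size))
  cat(sprintf("  budget: N_actin = %d subunits, g_max = %g, dt = %g s, seed = %d\n",
              as.integer(x$N_actin), x$g_max, x$dt, x$seed))
  invisible(x)
}

# keys accepted in config files, in the external units of the config format
config_keys <- c("L", "b", "delta", "kappa_ext", "kappa_tor", "l0", "kf",
                 "kb0", "Ec", "rc", "fst", "kBT", "N_actin", "eta", "dt",
                 "box_size", "g_max", "seed")

#' Read or write a parameter configuration file
#'
#' Configurations are flat YAML key-value files using the external units
#' (`eta` in Pa s, `Ec` in kBT). Keys absent from the file take the reference
#' defaults of [cn_params()]; unknown keys are rejected. An empty file yields
#' the full reference parameter set.
#'
#' @param path file path.
#' @param check_dt passed to [cn_params()].
#' @return `load_config()` returns a `cn_params` object; `write_config()`
#'   returns `path` invisibly.
#' @export
load_config <- function(path, check_dt = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  bad <- names(raw)[!vapply(raw, function(v)
    is.numeric(v) && length(v) == 1L, logical(1))]
  if (length(bad))
    stop("configuration key(s) not single numbers: ", paste(bad, collapse = ", "))
  do.call(cn_params, c(raw, list(check_dt = check_dt)))
}

#' @rdname load_config
#' @param p a [cn_params()] object to serialize.
#' @export
write_config <- function(p, path) {
  stopifnot(inherits(p, "cn_params"))
  out <- list(L = p$L, b = p$b, delta = p$delta, kappa_ext = p$kappa_ext,
              kappa_tor = p$kappa_tor, l0 = p$l0, kf = p$kf, kb0 = p$kb0,
              Ec = p$Ec, rc = p$rc, fst = p$fst, kBT = p$kBT,
              N_actin = p$N_actin, eta = p$eta_Pas, dt = p$dt,
              box_size = p$box_size, g_max = p$g_max, seed = p$seed)
  yaml::write_yaml(out, path)
  invisible(path)
}
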