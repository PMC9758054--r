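#' Elastic parameters for ssDNA and dsDNA stretching
#'
#' Container for the polymer-elasticity constants used to convert between
#' force, extension and base pairs unzipped. Single-stranded DNA is modeled as
#' an extensible freely jointed chain (FJC); double-stranded DNA as an
#' extensible worm-like chain (WLC, Marko-Siggia interpolation).
#'
#' @param ss_contour_nm ssDNA contour length per nucleotide (nm/nt).
#' @param ss_kuhn_nm ssDNA Kuhn length (nm).
#' @param ss_stretch_pN ssDNA stretch modulus (pN); \code{Inf} for an
#'   inextensible chain.
#' @param ds_contour_nm dsDNA contour length per base pair (nm/bp).
#' @param ds_persistence_nm dsDNA persistence length (nm).
#' @param ds_stretch_pN dsDNA stretch modulus (pN).
#' @param temperature_K temperature (K); sets the thermal energy
#'   \eqn{kT} in pN nm.
#' @return An object of class \code{"elastic_params"}.
#' @export
elastic_params <- function(ss_contour_nm = 0.56, ss_kuhn_nm = 1.5,
                           ss_stretch_pN = 800,
                           ds_contour_nm = 0.338, ds_persistence_nm = 43,
                           ds_stretch_pN = 1200, temperature_K = 298.15) {
  vals <- c(ss_contour_nm, ss_kuhn_nm, ss_stretch_pN, ds_contour_nm,
            ds_persistence_nm, ds_stretch_pN, temperature_K)
  if (any(!is.finite(vals) & vals != Inf) || any(vals <= 0))
    stop("all elastic parameters must be strictly positive")
  structure(list(ss_contour_nm = ss_contour_nm, ss_kuhn_nm = ss_kuhn_nm,
                 ss_stretch_pN = ss_stretch_pN, ds_contour_nm = ds_contour_nm,
                 ds_persistence_nm = ds_persistence_nm,
                 ds_stretch_pN = ds_stretch_pN,
                 temperature_K = temperature_K,
                 kT_pNnm = 0.0138065 * temperature_K),
            class = "elastic_params")
}

#' @export
print.elastic_params <- function(x, ...) {
  cat("Elastic parameters (kT =", format(x$kT_pNnm, digits = 4), "pN nm)\n")
  cat(sprintf("  ssDNA FJC: contour %.3g nm/nt, Kuhn %.3g nm, S %.4g pN\n",
              x$ss_contour_nm, x$ss_kuhn_nm, x$ss_stretch_pN))
  cat(sprintf("  dsDNA WLC: contour %.3g nm/bp, Lp %.3g nm, S %.4g pN\n",
              x$ds_contour_nm, x$ds_persistence_nm, x$ds_stretch_pN))
  invisible(x)
}

#' ssDNA extension per nucleotide at a given force
#'
#' Extensible freely jointed chain:
#' \deqn{x(f) = L_c \left[\coth(fb/kT) - kT/(fb)\right](1 + f/S)}
#' with Kuhn length \eqn{b} and stretch modulus \eqn{S}.
#'
#' @param force force in pN (vectorized, must be >= 0).
#' @param p an \code{\link{elastic_params}} object.
#' @return extension per nucleotide in nm/nt.
#' @export
ssdna_extension <- function(force, p = elastic_params()) {
  stopifnot(inherits(p, "elastic_params"))
  if (any(force < 0)) stop("force must be nonnegative")
  u <- force * p$ss_kuhn_nm / p$kT_pNnm
  lang <- ifelse(u < 1e-4, u / 3 - u^3 / 45,          # series near zero force
                 1 / tanh(u) - 1 / u)
  p$ss_contour_nm * lang * (1 + force / p$ss_stretch_pN)
}

#' dsDNA extension per base pair at a given force
#'
#' Extensible worm-like chain via the Marko-Siggia interpolation with an
#' enthalpic stretch term: with \eqn{u = x/L - f/S}, the force satisfies
#' \deqn{f L_p / kT = \frac{1}{4(1-u)^2} - \frac14 + u,}
#' solved for \eqn{u} by root finding.
#'
#' @inheritParams ssdna_extension
#' @return extension per base pair in nm/bp.
#' @export
dsdna_extension <- function(force, p = elastic_params()) {
  stopifnot(inherits(p, "elastic_params"))
  if (any(force < 0)) stop("force must be nonnegative")
  rhs <- force * p$ds_persistence_nm / p$kT_pNnm
  u <- vapply(rhs, function(r) {
    if (r == 0) return(0)
    stats::uniroot(function(v) 1 / (4 * (1 - v)^2) - 0.25 + v - r,
                   interval = c(0, 1 - 1e-9), tol = 1e-12)$root
  }, numeric(1))
  p$ds_contour_nm * (u + force / p$ds_stretch_pN)
}

# Stretching free energy helpers: Helmholtz free energy of holding a chain at
# the extension it adopts under force f, per monomer, obtained by Legendre
# transform A(x(f)) = f x(f) - int_0^f x(f') df'. The integral term is
# precomputed on a force grid by cumulative trapezoid and interpolated.
.force_grid <- function(fmax = 45, n = 1500) {
  # denser at low force where curvature is largest
  c(seq(0, 2, length.out = 200)[-200], seq(2, fmax, length.out = n))
}

.cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (y[-1] + y[-length(y)]) / 2))
}

# returns list of interpolation functions on [0, fmax]:
#   xss(f), xds(f): per-monomer extensions; wss(f), wds(f): int_0^f x df'
# cached per parameter set (the WLC table needs ~2000 root solves)
.elastic_cache <- new.env(parent = emptyenv())

.elastic_tables <- function(p, fmax = 45) {
  key <- paste(format(c(unlist(p[c("ss_contour_nm", "ss_kuhn_nm",
                                   "ss_stretch_pN", "ds_contour_nm",
                                   "ds_persistence_nm", "ds_stretch_pN",
                                   "temperature_K")]), fmax), digits = 12),
               collapse = "|")
  hit <- .elastic_cache[[key]]
  if (!is.null(hit)) return(hit)
  f <- .force_grid(fmax)
  xss <- ssdna_extension(f, p)
  xds <- dsdna_extension(f, p)
  tab <- list(f = f,
              xss = stats::approxfun(f, xss, rule = 2),
              xds = stats::approxfun(f, xds, rule = 2),
              wss = stats::approxfun(f, .cumtrapz(f, xss), rule = 2),
              wds = stats::approxfun(f, .cumtrapz(f, xds), rule = 2))
  .elastic_cache[[key]] <- tab
  tab
}
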