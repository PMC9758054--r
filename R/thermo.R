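#' Nearest-neighbor thermodynamic parameters for DNA base pairing
#'
#' Bundles the unified nearest-neighbor (NN) dinucleotide enthalpies and
#' entropies at 1 M NaCl together with the experimental temperature, monovalent
#' salt concentration and a per-step salt-correction coefficient. The pairing
#' free energy of each NN step at the configured conditions is
#' \deqn{\Delta G = \Delta H - T \Delta S - m \ln[\mathrm{Na}^+],}
#' with \eqn{\Delta G < 0} for a stable (stabilizing) step. Opening a base pair
#' therefore costs \eqn{-\Delta G > 0}.
#'
#' @param temperature_K temperature in kelvin. Default 298.15 K (25 C), the
#'   effective temperature of the trapping assay after local laser heating.
#' @param salt_M monovalent salt concentration in mol/L. Default 0.1 M,
#'   matching a typical transcription buffer (100 mM KCl).
#' @param salt_coef_kcal salt correction in kcal/mol per NN step per ln(M);
#'   subtracted as \eqn{m\ln[\mathrm{Na}^+]} so that duplexes are destabilized
#'   below 1 M. Default 0.114.
#' @param init_penalty_kcal duplex initiation penalty in kcal/mol. Only
#'   relevant to full-duplex energies, not to the per-bp unzipping landscape;
#'   kept for completeness. Default 1.96.
#' @param nn_dH,nn_dS optional replacement NN tables: named numeric vectors over
#'   the 10 unique dinucleotide steps (names like \code{"AA"}, \code{"CG"}),
#'   enthalpy in kcal/mol and entropy in cal/(mol K).
#'
#' @return An object of class \code{"thermo_params"}.
#' @export
thermo_params <- function(temperature_K = 298.15, salt_M = 0.1,
                          salt_coef_kcal = 0.114, init_penalty_kcal = 1.96,
                          nn_dH = NULL, nn_dS = NULL) {
  stopifnot(temperature_K > 0, salt_M > 0)
  if (is.null(nn_dH)) nn_dH <- .nn_unified$dH
  if (is.null(nn_dS)) nn_dS <- .nn_unified$dS
  need <- names(.nn_unified$dH)
  if (!all(need %in% names(nn_dH)) || !all(need %in% names(nn_dS)))
    stop("nn tables must cover all 10 unique nearest-neighbor steps")
  structure(list(temperature_K = temperature_K, salt_M = salt_M,
                 salt_coef_kcal = salt_coef_kcal,
                 init_penalty_kcal = init_penalty_kcal,
                 nn_dH = nn_dH[need], nn_dS = nn_dS[need]),
            class = "thermo_params")
}

# Unified NN parameters (10 unique steps, 1 M NaCl): dH kcal/mol, dS cal/(mol K)
.nn_unified <- list(
  dH = c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
         CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0),
  dS = c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
         CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
)

# map all 16 steps onto the 10 unique ones (reverse-complement symmetry)
.nn_canonical <- c(AA = "AA", TT = "AA", AT = "AT", TA = "TA",
                   CA = "CA", TG = "CA", GT = "GT", AC = "GT",
                   CT = "CT", AG = "CT", GA = "GA", TC = "GA",
                   CG = "CG", GC = "GC", GG = "GG", CC = "GG")

# gas constant, kcal/(mol K)
.R_kcal <- 0.0019872

#' @export
print.thermo_params <- function(x, ...) {
  cat("Nearest-neighbor thermodynamic parameters\n")
  cat(sprintf("  T = %.2f K, [Na+] = %g M, salt coef = %g kcal/mol/ln(M)\n",
              x$temperature_K, x$salt_M, x$salt_coef_kcal))
  g <- x$nn_dH - x$temperature_K * x$nn_dS / 1000 -
    x$salt_coef_kcal * log(x$salt_M)
  cat(sprintf("  step dG range at conditions: %.2f to %.2f kcal/mol\n",
              min(g), max(g)))
  invisible(x)
}

#' Per-base-pair opening free energies along a sequence
#'
#' Converts a DNA sequence into the free-energy cost of opening each base pair
#' at the unzipping fork, in units of kT. Nearest-neighbor step energies are
#' evaluated at the configured temperature and salt, negated (opening costs the
#' pairing free energy) and averaged onto base-pair positions: interior base
#' pairs take the mean of their two flanking steps, terminal base pairs take
#' their single flanking step.
#'
#' @param seq a single DNA string (A/C/G/T, case-insensitive), length >= 2.
#' @param thermo a \code{\link{thermo_params}} object.
#' @return numeric vector, one positive opening energy (kT) per base pair.
#' @examples
#' junction_energies("ACGTACGT", thermo_params())
#' @export
junction_energies <- function(seq, thermo = thermo_params()) {
  stopifnot(inherits(thermo, "thermo_params"))
  seq <- toupper(as.character(seq)[1L])
  n <- nchar(seq)
  if (n < 2L) stop("sequence must have at least 2 bases")
  bases <- strsplit(seq, "")[[1L]]
  bad <- which(!bases %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop(sprintf("non-ACGT character '%s' at position %d", bases[bad[1L]],
                 bad[1L]))
  steps <- paste0(bases[-n], bases[-1L])
  key <- .nn_canonical[steps]
  dG <- thermo$nn_dH[key] - thermo$temperature_K * thermo$nn_dS[key] / 1000 -
    thermo$salt_coef_kcal * log(thermo$salt_M)
  open_kcal <- -unname(dG)                       # cost of opening each step
  kT_kcal <- .R_kcal * thermo$temperature_K
  step_kT <- open_kcal / kT_kcal
  # average step energies onto bp positions
  per_bp <- numeric(n)
  per_bp[1L] <- step_kT[1L]
  per_bp[n] <- step_kT[n - 1L]
  if (n > 2L)
    per_bp[2:(n - 1L)] <- (step_kT[-(n - 1L)] + step_kT[-1L]) / 2
  per_bp
}
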