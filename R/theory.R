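#' Equilibrium unzipping theory curve for a construct
#'
#' Computes the expected force and mean fork position versus controlled total
#' extension for mechanical unzipping of naked DNA, from the sequence-dependent
#' nearest-neighbor opening energies and the elasticity of the dsDNA arms and
#' the released ssDNA.
#'
#' At each total extension \eqn{z}, every fork position \eqn{j} defines a
#' mechanical state whose force \eqn{f_j} solves
#' \deqn{z = L_{arm} x_{ds}(f) + 2 j\, x_{ss}(f)}
#' and whose free energy is the opening cost of the first \eqn{j} base pairs
#' plus the Helmholtz stretching free energy of arms and ssDNA at that
#' extension. Reported force and fork position are Boltzmann averages over
#' \eqn{j}; this equilibrium weighting reproduces the sequence-dependent
#' sawtooth around the 12-17 pN unzipping plateau and the thermal "breathing"
#' softening ahead of weakly paired regions.
#'
#' @param construct an \code{\link{unzip_construct}}.
#' @param thermo a \code{\link{thermo_params}}.
#' @param elastic an \code{\link{elastic_params}}.
#' @param schedule numeric vector of total extensions (nm) to evaluate;
#'   \code{NULL} chooses a grid from arms-only to fully unzipped.
#' @param n_points grid size of the default schedule; the default samples the
#'   sawtooth rips finely enough that interpolating the curve introduces
#'   errors well below the measurement noise.
#' @param energies optional replacement per-bp opening energies (kT), e.g. a
#'   perturbed landscape with protein signatures; default is
#'   \code{junction_energies(construct$sequence, thermo)}.
#' @param fmax maximum force (pN) of the elastic tables.
#' @param weight_cutoff Boltzmann weights below this fraction of the maximum
#'   are truncated to zero.
#' @return An object of class \code{"unzip_theory"}: a data.frame with columns
#'   \code{extension_nm}, \code{force_pN}, \code{bp_unzipped}.
#' @export
unzip_theory <- function(construct, thermo = thermo_params(),
                         elastic = elastic_params(), schedule = NULL,
                         n_points = 2500, energies = NULL, fmax = 45,
                         weight_cutoff = 1e-12) {
  stopifnot(inherits(construct, "unzip_construct"))
  dg <- if (is.null(energies)) junction_energies(construct$sequence, thermo)
        else energies
  n <- construct$length
  if (length(dg) != n) stop("energies must have one value per base pair")
  G <- c(0, cumsum(dg))                      # opening energy of states j=0..n
  kT <- elastic$kT_pNnm
  tab <- .elastic_tables(elastic, fmax)
  arm <- construct$arm_bp

  if (is.null(schedule)) {
    fstar <- .plateau_force(mean(dg), elastic)
    f_lo <- max(3, fstar - 4)
    f_hi <- min(fmax - 2, fstar + 5)
    schedule <- seq(arm * tab$xds(f_lo),
                    arm * tab$xds(f_hi) + 2 * n * tab$xss(f_hi),
                    length.out = n_points)
  }
  z <- as.numeric(schedule)
  st <- .state_matrices(G, arm, elastic, z, fmax)
  fmat <- st$fmat
  emat <- st$emat
  emin <- apply(emat, 2, min)
  if (any(!is.finite(emin)))
    stop("no mechanical state available at some schedule extensions")
  w <- exp(-sweep(emat, 2, emin))
  w[w < weight_cutoff] <- 0
  w[is.na(w)] <- 0
  wsum <- colSums(w)
  fmat[is.na(fmat)] <- 0
  force <- colSums(w * fmat) / wsum
  bp <- colSums(w * (0:n)) / wsum
  out <- data.frame(extension_nm = z, force_pN = force, bp_unzipped = bp)
  structure(out, class = c("unzip_theory", "data.frame"),
            arm_bp = arm, segment_length = n, elastic = elastic)
}

# State force and free-energy matrices over (fork position j = 0..n) x
# (schedule extension): f[j, z] solves z = arm x_ds(f) + 2 j x_ss(f);
# E[j, z] (kT) = cumulative opening energy + stretching Helmholtz energy.
.state_matrices <- function(G, arm, elastic, z, fmax = 45) {
  n <- length(G) - 1L
  kT <- elastic$kT_pNnm
  tab <- .elastic_tables(elastic, fmax)
  zmax_ok <- arm * tab$xds(fmax) + 2 * n * tab$xss(fmax)
  if (any(z > zmax_ok))
    stop("schedule extension beyond fully-unzipped contour at fmax")
  fgrid <- tab$f
  xss_g <- tab$xss(fgrid)
  xds_g <- tab$xds(fgrid)
  nz <- length(z)
  fmat <- matrix(NA_real_, n + 1L, nz)
  emat <- matrix(Inf, n + 1L, nz)
  for (j in 0:n) {
    zj <- arm * xds_g + 2 * j * xss_g        # monotone in f
    fj <- stats::approx(zj, fgrid, xout = z, rule = 1)$y
    low <- is.na(fj) & z <= zj[1L]
    fj[low] <- fgrid[1L]
    ok <- !is.na(fj)
    a <- fj[ok] * z[ok] - (arm * tab$wds(fj[ok]) + 2 * j * tab$wss(fj[ok]))
    fmat[j + 1L, ok] <- fj[ok]
    emat[j + 1L, ok] <- G[j + 1L] + a / kT
  }
  list(fmat = fmat, emat = emat)
}

# Equilibrium curve with protein clamps rendered as yielding constraints:
# the fork cannot pass a clamp position until the force of the stalled branch
# (fork pinned at the clamp) reaches the clamp's yield force, at which point
# the protein is displaced and the constraint lifts. Bubbles and sequence
# effects enter through the opening energies dg. Used by the synthetic trace
# renderer.
.constrained_curve <- function(dg, arm, elastic, z, clamps = NULL,
                               fmax = 45, weight_cutoff = 1e-12) {
  G <- c(0, cumsum(dg))
  st <- .state_matrices(G, arm, elastic, z, fmax)
  n <- length(dg)
  nz <- length(z)
  if (!is.null(clamps) && nrow(clamps)) {
    clamps <- clamps[order(clamps$pos), , drop = FALSE]
  }
  k <- 1L
  m <- if (is.null(clamps)) 0L else nrow(clamps)
  force <- bp <- numeric(nz)
  for (iz in seq_len(nz)) {
    while (k <= m) {
      fstall <- st$fmat[round(clamps$pos[k]) + 1L, iz]
      if (is.na(fstall) || fstall >= clamps$yield[k]) k <- k + 1L else break
    }
    jmax <- if (k <= m) round(clamps$pos[k]) else n
    rows <- seq_len(jmax + 1L)
    e <- st$emat[rows, iz]
    w <- exp(-(e - min(e)))
    w[w < weight_cutoff] <- 0
    fv <- st$fmat[rows, iz]
    fv[is.na(fv)] <- 0
    wsum <- sum(w)
    force[iz] <- sum(w * fv) / wsum
    bp[iz] <- sum(w * (rows - 1L)) / wsum
  }
  data.frame(extension_nm = z, force_pN = force, bp_unzipped = bp)
}

# two-state work-balance plateau force for a uniform opening energy g (kT):
# g * kT = 2 * int_0^f x_ss(f') df'
.plateau_force <- function(g_kT, elastic, fmax = 45) {
  tab <- .elastic_tables(elastic, fmax)
  stats::uniroot(function(f) 2 * tab$wss(f) - g_kT * elastic$kT_pNnm,
                 interval = c(0.01, fmax), tol = 1e-9)$root
}

#' Baseline force as a function of base pairs unzipped
#'
#' Interpolates an unzipping theory curve to give the expected (naked DNA)
#' force at a fork position, for baseline subtraction and peak calling.
#'
#' @param theory an \code{\link{unzip_theory}} object.
#' @return a function \code{f(bp)} returning force in pN.
#' @export
baseline_force <- function(theory) {
  stopifnot(inherits(theory, "unzip_theory"))
  stats::approxfun(theory$bp_unzipped, theory$force_pN, rule = 2,
                   ties = mean)
}

#' @export
print.unzip_theory <- function(x, ...) {
  cat(sprintf(
    "Unzipping theory curve: %d points, segment %d bp, arms %d bp\n",
    nrow(x), attr(x, "segment_length"), attr(x, "arm_bp")))
  cat(sprintf("  force range %.1f-%.1f pN\n", min(x$force_pN),
              max(x$force_pN)))
  invisible(x)
}

#' @export
plot.unzip_theory <- function(x, xaxis = c("bp", "extension"), ...) {
  xaxis <- match.arg(xaxis)
  if (xaxis == "bp")
    graphics::plot(x$bp_unzipped, x$force_pN, type = "l",
                   xlab = "base pairs unzipped", ylab = "force (pN)", ...)
  else
    graphics::plot(x$extension_nm, x$force_pN, type = "l",
                   xlab = "extension (nm)", ylab = "force (pN)", ...)
  invisible(x)
}

#' Write a theory curve to a tab-separated file
#'
#' @param theory an \code{\link{unzip_theory}}.
#' @param path output path.
#' @return invisibly, the theory object.
#' @export
write_theory <- function(theory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# columns: extension_nm force_pN bp_unzipped", con)
  utils::write.table(as.data.frame(theory), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(theory)
}
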