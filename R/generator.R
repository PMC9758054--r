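#' Pre- and post-chase trace category labels
#'
#' Category vocabulary of the outcome analysis. Before the chase a trace shows
#' the motor stalled at A20 and/or a bound dCas (or neither); after the chase
#' the seven outcomes distinguish motors still upstream, collisions, dCas
#' removal with a stalled motor, motors downstream, naked DNA and dCas alone.
#'
#' @name categories
#' @export
PRE_CATEGORIES <- c("A20_dCas", "A20_only", "dCas_only", "Nak")

#' @rdname categories
#' @export
POST_CATEGORIES <- c("TEC_up_dCas", "TEC_up_only", "Coll", "dCas_rem",
                     "TEC_dn", "Nak", "dCas_only")

#' Configuration of the synthetic chamber generator
#'
#' Defines the probabilistic outcome tree the generator draws from: initial
#' occupancy fractions, nuisance (non-collision) dissociation probabilities,
#' collision competence, and the collision outcome split between read-through,
#' removal-then-stall and blocked. A collision-competent motor on a template
#' whose dCas is absent (or was lost spontaneously) runs freely and ends as
#' naked DNA or as a downstream motor peak, split by \code{p_runoff}.
#'
#' @param motor \code{"RNAP"} or \code{"Mfd"}.
#' @param f_initial named probabilities of the four pre-chase states
#'   \code{A20_dCas}, \code{A20_only}, \code{dCas_only}, \code{Nak};
#'   must sum to 1. Defaults reflect the >90 percent co-occupancy of the
#'   assay.
#' @param p_motor_diss,p_dcas_diss probabilities of the motor / the dCas
#'   dissociating through a non-collision mechanism over the chase interval.
#' @param p_coll_comp probability that a surviving motor reaches the dCas
#'   site (collision competence).
#' @param p_read_through,p_removal_stall collision outcome probabilities; the
#'   blocked probability is \code{1 - p_read_through - p_removal_stall}.
#'   For Mfd, removal-then-stall is not observed; use
#'   \code{p_removal_stall = 0}.
#' @param p_runoff probability that a motor running on a dCas-free template
#'   leaves the template end (naked DNA) rather than remaining as a
#'   downstream peak. The efficiency estimator is insensitive to this value.
#' @param n_control,n_chase traces per chamber in the control (pre-chase) and
#'   chase phases.
#' @param n_chambers number of sample chambers.
#' @param chase_s chase duration in seconds (metadata; 135 s for RNAP,
#'   480 s for Mfd).
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @return An object of class \code{"generator_config"}.
#' @export
generator_config <- function(motor = c("RNAP", "Mfd"),
                             f_initial = c(A20_dCas = 0.90, A20_only = 0.04,
                                           dCas_only = 0.04, Nak = 0.02),
                             p_motor_diss = 0.05, p_dcas_diss = 0.05,
                             p_coll_comp = 0.85, p_read_through = 0.43,
                             p_removal_stall = 0.10, p_runoff = 0.5,
                             n_control = 40, n_chase = 60, n_chambers = 6,
                             chase_s = NULL, seed = NULL) {
  motor <- match.arg(motor)
  if (is.null(chase_s)) chase_s <- if (motor == "RNAP") 135 else 480
  f_initial <- f_initial[PRE_CATEGORIES]
  if (anyNA(f_initial))
    stop("f_initial must name all four pre-chase states")
  probs <- c(f_initial, p_motor_diss, p_dcas_diss, p_coll_comp,
             p_read_through, p_removal_stall, p_runoff)
  if (any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (abs(sum(f_initial) - 1) > 1e-9)
    stop("f_initial must sum to 1")
  p_block <- 1 - p_read_through - p_removal_stall
  if (p_block < -1e-9)
    stop("p_read_through + p_removal_stall must not exceed 1")
  stopifnot(n_control >= 1, n_chase >= 1, n_chambers >= 1)
  structure(list(motor = motor, f_initial = f_initial,
                 p_motor_diss = p_motor_diss, p_dcas_diss = p_dcas_diss,
                 p_coll_comp = p_coll_comp, p_read_through = p_read_through,
                 p_removal_stall = p_removal_stall,
                 p_block = max(p_block, 0), p_runoff = p_runoff,
                 n_control = n_control, n_chase = n_chase,
                 n_chambers = n_chambers, chase_s = chase_s, seed = seed),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("Generator config: motor %s, %d chambers x (%d control + %d chase), chase %g s\n",
              x$motor, x$n_chambers, x$n_control, x$n_chase, x$chase_s))
  cat(sprintf("  truth: P_coll_comp %.3f, P_read_through %.3f, P_removal %.3f\n",
              x$p_coll_comp, x$p_read_through,
              x$p_read_through + x$p_removal_stall))
  cat(sprintf("  nuisance: p_motor_diss %.3f, p_dcas_diss %.3f\n",
              x$p_motor_diss, x$p_dcas_diss))
  invisible(x)
}

#' Exact expected category fractions under a generator configuration
#'
#' Closed-form leaf probabilities of the generative outcome tree: the expected
#' pre-chase (4) and post-chase (7) category fractions. This is the algebraic
#' twin of \code{\link{sample_outcomes}} and the quantity on which the
#' efficiency estimator is an exact inverse.
#'
#' @param cfg a \code{\link{generator_config}}.
#' @return list with named numeric vectors \code{pre} and \code{post}, each
#'   summing to 1.
#' @export
expected_fractions <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  a <- cfg$f_initial[["A20_dCas"]]; b <- cfg$f_initial[["A20_only"]]
  cc <- cfg$f_initial[["dCas_only"]]; d <- cfg$f_initial[["Nak"]]
  pmd <- cfg$p_motor_diss; pdd <- cfg$p_dcas_diss; pcc <- cfg$p_coll_comp
  prt <- cfg$p_read_through; prs <- cfg$p_removal_stall; pb <- cfg$p_block
  pr <- cfg$p_runoff
  surv <- 1 - pmd
  rt_flux <- a * surv * pcc * (1 - pdd) * prt        # true read-through
  free_flux <- a * surv * pcc * pdd + b * surv * pcc  # free-running motors
  post <- c(
    TEC_up_dCas = a * surv * (1 - pcc) * (1 - pdd),
    TEC_up_only = a * surv * (1 - pcc) * pdd + b * surv * (1 - pcc),
    Coll        = a * surv * pcc * (1 - pdd) * pb,
    dCas_rem    = a * surv * pcc * (1 - pdd) * prs,
    TEC_dn      = (1 - pr) * (rt_flux + free_flux),
    Nak         = a * pmd * pdd + b * pmd + cc * pdd + d +
                  pr * (rt_flux + free_flux),
    dCas_only   = a * pmd * (1 - pdd) + cc * (1 - pdd)
  )
  list(pre = cfg$f_initial, post = post[POST_CATEGORIES])
}

#' Sample per-chamber labelled trace outcomes from the generative tree
#'
#' Draws, for each chamber, \code{n_control} pre-chase control traces from the
#' initial occupancy fractions and \code{n_chase} chase traces by walking the
#' outcome tree trace by trace: initial state, non-collision motor and dCas
#' dissociation, collision competence, collision outcome, and runoff.
#'
#' @param cfg a \code{\link{generator_config}}. If \code{cfg$seed} is set the
#'   RNG is seeded for bitwise-reproducible tables.
#' @return data.frame with columns \code{chamber}, \code{trace}, \code{phase}
#'   (\code{control}/\code{chase}) and \code{category}.
#' @export
sample_outcomes <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  out <- vector("list", cfg$n_chambers)
  for (ch in seq_len(cfg$n_chambers)) {
    pre <- sample(PRE_CATEGORIES, cfg$n_control, replace = TRUE,
                  prob = cfg$f_initial)
    post <- .walk_tree(cfg, cfg$n_chase)
    out[[ch]] <- data.frame(
      chamber = ch,
      trace = seq_len(cfg$n_control + cfg$n_chase),
      phase = rep(c("control", "chase"), c(cfg$n_control, cfg$n_chase)),
      category = c(pre, post), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# one chase trace at a time through the outcome tree, vectorized over traces
.walk_tree <- function(cfg, n) {
  init <- sample(PRE_CATEGORIES, n, replace = TRUE, prob = cfg$f_initial)
  motor <- init %in% c("A20_dCas", "A20_only")
  dcas <- init %in% c("A20_dCas", "dCas_only")
  mdiss <- motor & stats::runif(n) < cfg$p_motor_diss
  dlost <- dcas & stats::runif(n) < cfg$p_dcas_diss     # spontaneous loss
  compet <- motor & !mdiss & stats::runif(n) < cfg$p_coll_comp
  runoff <- stats::runif(n) < cfg$p_runoff
  collide <- compet & dcas & !dlost
  outcome <- sample(c("rt", "rs", "block"), n, replace = TRUE,
                    prob = c(cfg$p_read_through, cfg$p_removal_stall,
                             cfg$p_block))
  lab <- character(n)
  dcas_now <- dcas & !dlost
  # motor never left or never started
  upstream <- motor & !mdiss & !compet
  lab[upstream & dcas_now] <- "TEC_up_dCas"
  lab[upstream & !dcas_now] <- "TEC_up_only"
  # collision outcomes
  lab[collide & outcome == "block"] <- "Coll"
  lab[collide & outcome == "rs"] <- "dCas_rem"
  through <- (collide & outcome == "rt") | (compet & !dcas_now)
  lab[through & runoff] <- "Nak"
  lab[through & !runoff] <- "TEC_dn"
  # no active motor
  idle <- !motor | mdiss
  lab[idle & dcas_now] <- "dCas_only"
  lab[idle & !dcas_now] <- "Nak"
  lab
}

#' Tally category counts per chamber
#'
#' @param outcomes a data.frame as returned by \code{\link{sample_outcomes}}
#'   (or by classification of real traces): columns \code{chamber},
#'   \code{phase}, \code{category}.
#' @return data.frame with one row per chamber: \code{chamber},
#'   \code{n_pre}, \code{n_post} and count columns \code{pre_*} and
#'   \code{post_*} over the category vocabulary.
#' @export
count_categories <- function(outcomes) {
  stopifnot(all(c("chamber", "phase", "category") %in% names(outcomes)))
  chambers <- sort(unique(outcomes$chamber))
  rows <- lapply(chambers, function(ch) {
    oc <- outcomes[outcomes$chamber == ch, ]
    pre <- table(factor(oc$category[oc$phase == "control"],
                        levels = PRE_CATEGORIES))
    post <- table(factor(oc$category[oc$phase == "chase"],
                         levels = POST_CATEGORIES))
    cbind(data.frame(chamber = ch, n_pre = sum(pre), n_post = sum(post)),
          as.data.frame(rbind(stats::setNames(
            as.integer(pre), paste0("pre_", PRE_CATEGORIES)))),
          as.data.frame(rbind(stats::setNames(
            as.integer(post), paste0("post_", POST_CATEGORIES)))))
  })
  do.call(rbind, rows)
}

#' Force-signature model for rendered traces
#'
#' Parameters of the protein signatures embedded in synthetic traces. Clamp
#' rises and R-loop bubble dips are rendered physically: a clamp adds an
#' opening-energy barrier sized so that the fork stalls until the force
#' exceeds the local baseline by about \code{clamp_rise_pN}; the bubble
#' replaces the sequence opening energies with the residual corresponding to
#' a force about \code{dip_pN} below the plateau. The equilibrium Boltzmann
#' weighting then produces the thermal breathing look-ahead of the dip
#' without an explicit offset.
#'
#' @param clamp_rise_pN clamp rise amplitude above baseline (pN).
#' @param clamp_width_bp clamped footprint width (bp).
#' @param dip_pN bubble dip amplitude below baseline (pN).
#' @param breathing_bp nominal look-ahead of the dip onset (bp), used by
#'   classification when assessing dip onset, not by rendering.
#' @param noise_sd_pN Gaussian force noise standard deviation (pN).
#' @param p_single_rise dCas12a dual-conformation mixture weight: probability
#'   of the single-rise conformation (only used when
#'   \code{dual_conformation = TRUE} in \code{\link{render_trace}}).
#' @param clamp_offset_bp dCas clamp offset upstream of the PAM for
#'   PAM-proximal-first unzipping (bp).
#' @param coll_offset_bp stalled-motor peak offset upstream of the PAM for
#'   PAM-proximal collisions (bp).
#' @param coll_gap_bp stalled-motor gap upstream of the dCas footprint for
#'   PAM-distal collisions (bp).
#' @param invasion_bp depth of motor invasion into the R-loop window rendered
#'   for removal-then-stall traces (bp).
#' @return An object of class \code{"signature_model"}.
#' @export
signature_model <- function(clamp_rise_pN = 6, clamp_width_bp = 4,
                            dip_pN = 3, breathing_bp = 3, noise_sd_pN = 0.4,
                            p_single_rise = 0.43, clamp_offset_bp = 6,
                            coll_offset_bp = 30, coll_gap_bp = 15,
                            invasion_bp = 5) {
  stopifnot(clamp_rise_pN > 0, dip_pN > 0, clamp_width_bp >= 1,
            noise_sd_pN >= 0, p_single_rise >= 0, p_single_rise <= 1,
            clamp_offset_bp >= 0, coll_offset_bp >= 0, coll_gap_bp >= 0,
            invasion_bp >= 0)
  structure(list(clamp_rise_pN = clamp_rise_pN,
                 clamp_width_bp = clamp_width_bp, dip_pN = dip_pN,
                 breathing_bp = breathing_bp, noise_sd_pN = noise_sd_pN,
                 p_single_rise = p_single_rise,
                 clamp_offset_bp = clamp_offset_bp,
                 coll_offset_bp = coll_offset_bp, coll_gap_bp = coll_gap_bp,
                 invasion_bp = invasion_bp),
            class = "signature_model")
}

# resolve ground-truth signature positions for a category on a construct;
# returns list(motor_pos = bp or NA, dcas = TRUE/FALSE)
.category_layout <- function(category, construct, sig) {
  a20 <- motor_site(construct)
  site <- dcas_site_ref(construct)
  rl <- rloop_window(construct)
  pam <- .ann(construct, "PAM")
  seglen <- construct$length
  proximal <- construct$direction == "PAM_proximal_first"
  coll_pos <- if (proximal) pam$start - sig$coll_offset_bp
              else rl[1] - sig$coll_gap_bp
  edge <- if (proximal) pam$start else rl[1]
  motor_pos <- switch(category,
    A20_dCas = , A20_only = a20,
    TEC_up_dCas = , TEC_up_only = {
      hi <- min(site, seglen) - 80
      if (hi <= a20 + 1) stop("construct too short to place an upstream motor")
      round(stats::runif(1, a20, hi))
    },
    Coll = coll_pos,
    dCas_rem = edge + sig$invasion_bp,
    TEC_dn = round(stats::runif(1, max(site, rl[2]) + 40, seglen - 15)),
    NA_real_)
  dcas <- category %in% c("A20_dCas", "dCas_only", "TEC_up_dCas", "Coll")
  list(motor_pos = if (is.null(motor_pos)) NA_real_ else motor_pos,
       dcas = dcas)
}

#' Render a synthetic force-extension trace for an outcome category
#'
#' Builds a full synthetic optical-trap unzipping trace for a labelled
#' outcome: the naked-DNA equilibrium baseline perturbed by the protein
#' signatures the category implies (motor clamp rise, dCas clamp rise, R-loop
#' bubble dip for PAM-distal-first constructs), plus Gaussian force noise.
#' Signatures are embedded by modifying the per-bp opening-energy landscape
#' and recomputing the equilibrium curve, so conversion of the rendered
#' (force, extension) record back to base pairs unzipped is self-consistent.
#'
#' @param category a pre- or post-chase category label.
#' @param construct an \code{\link{unzip_construct}}.
#' @param sig a \code{\link{signature_model}}.
#' @param thermo,elastic parameter objects.
#' @param schedule extension schedule (nm); \code{NULL} uses a uniform
#'   0.5 nm grid over the naked-DNA default range (500 nm/s at 1 kHz).
#' @param loading \code{"constant_velocity"} (500 nm/s) or
#'   \code{"force_ramp"} (8 pN/s); sets the time stamps.
#' @param seed optional integer seed for the motor placement and noise.
#' @param dual_conformation render the dCas12a two-conformation mixture
#'   (a second rise at the distal end of the hybrid with probability
#'   \code{1 - p_single_rise}).
#' @return An \code{\link{unzip_trace}} whose \code{"truth"} attribute records
#'   the generating category and signature positions.
#' @export
render_trace <- function(category, construct, sig = signature_model(),
                         thermo = thermo_params(),
                         elastic = elastic_params(), schedule = NULL,
                         loading = c("constant_velocity", "force_ramp"),
                         seed = NULL, dual_conformation = FALSE) {
  loading <- match.arg(loading)
  stopifnot(category %in% c(PRE_CATEGORIES, POST_CATEGORIES))
  if (!is.null(seed)) set.seed(seed)
  lay <- .category_layout(category, construct, sig)
  dg <- junction_energies(construct$sequence, thermo)
  tab <- .elastic_tables(elastic)
  kT <- elastic$kT_pNnm
  fstar <- .plateau_force(mean(dg), elastic)
  # residual opening energy inside the R-loop bubble, sized so the fork
  # traverses it at about dip_pN below the plateau
  bubble_g <- 2 * tab$wss(max(fstar - sig$dip_pN, 0.5)) / kT
  seglen <- construct$length
  dg0 <- dg                                  # naked landscape, for baselines
  clamps <- data.frame(pos = numeric(0), yield = numeric(0))
  add_clamp <- function(pos) {
    pos <- round(pos)
    if (pos < 1 || pos > seglen - 2)
      stop("signature extends beyond the segment")
    # yield when the stalled force exceeds the local naked baseline (the
    # plateau force of the surrounding sequence) by the rise amplitude
    win <- max(1, pos - 10):min(seglen, pos + 10)
    local_f <- .plateau_force(mean(dg0[win]), elastic)
    rbind(clamps, data.frame(pos = pos,
                             yield = local_f + sig$clamp_rise_pN))
  }
  truth <- list(category = category, motor_pos = lay$motor_pos,
                dcas_present = lay$dcas, dcas_clamp_pos = NA_real_)
  if (!is.na(lay$motor_pos)) clamps <- add_clamp(lay$motor_pos)
  if (lay$dcas) {
    clamp <- dcas_clamp_pos(construct, sig$clamp_offset_bp)
    rl <- rloop_window(construct)
    # unpaired R-loop bubble, widened upstream by the breathing look-ahead
    bub <- seq.int(max(1, rl[1] - sig$breathing_bp + 1), rl[2])
    dg[bub] <- pmin(dg[bub], bubble_g)
    if (construct$direction == "PAM_distal_first" && dual_conformation &&
        stats::runif(1) >= sig$p_single_rise)
      clamps <- add_clamp(rl[1] + 1)        # distal-end second rise
    clamps <- add_clamp(clamp)
    truth$dcas_clamp_pos <- clamp
  }
  if (is.null(schedule)) {
    # same range construction as the naked default schedule, extended above
    # the clamp yield force so every signature is traversed; 0.5 nm steps
    # correspond to 500 nm/s sampled at 1 kHz
    f_lo <- max(3, fstar - 4)
    f_hi <- min(42, fstar + sig$clamp_rise_pN + 3)
    schedule <- seq(construct$arm_bp * tab$xds(f_lo),
                    construct$arm_bp * tab$xds(f_hi) +
                      2 * seglen * tab$xss(f_hi), by = 0.5)
  }
  th <- .constrained_curve(dg, construct$arm_bp, elastic, schedule,
                           clamps = clamps)
  force <- th$force_pN + stats::rnorm(length(schedule), 0, sig$noise_sd_pN)
  time <- if (loading == "constant_velocity")
    (schedule - schedule[1]) / 500
  else
    cummax(force) / 8 + seq_along(force) * 1e-9
  tr <- unzip_trace(time = time, force = force, extension = schedule,
                    rate_hz = 1000, loading = loading)
  attr(tr, "truth") <- truth
  tr
}
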