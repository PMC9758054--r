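#' Per-chamber category counts or fractions
#'
#' Holds one chamber's pre-chase (4) and post-chase (7) category composition.
#' Accepts raw counts (fractions are derived) or fractions directly (for
#' algebraic work); each phase must sum to its total (counts) or to 1
#' (fractions).
#'
#' @param pre named numeric vector over \code{A20_dCas}, \code{A20_only},
#'   \code{dCas_only}, \code{Nak}.
#' @param post named numeric vector over \code{TEC_up_dCas},
#'   \code{TEC_up_only}, \code{Coll}, \code{dCas_rem}, \code{TEC_dn},
#'   \code{Nak}, \code{dCas_only}.
#' @param counts logical: are \code{pre}/\code{post} raw counts
#'   (default TRUE) or fractions?
#' @return An object of class \code{"chamber_counts"} with elements
#'   \code{pre}, \code{post} (fractions), \code{n_pre}, \code{n_post}.
#' @export
chamber_counts <- function(pre, post, counts = TRUE) {
  pre <- pre[PRE_CATEGORIES]
  post <- post[POST_CATEGORIES]
  if (anyNA(pre) || anyNA(post))
    stop("pre and post must name all categories")
  if (any(pre < 0) || any(post < 0)) stop("negative counts")
  if (counts) {
    n_pre <- sum(pre); n_post <- sum(post)
    if (n_pre == 0 || n_post == 0) stop("each phase needs at least one trace")
    pre <- pre / n_pre; post <- post / n_post
  } else {
    n_pre <- NA_integer_; n_post <- NA_integer_
    if (abs(sum(pre) - 1) > 1e-9 || abs(sum(post) - 1) > 1e-9)
      stop("fractions must sum to 1 in each phase")
  }
  structure(list(pre = pre, post = post, n_pre = n_pre, n_post = n_post),
            class = "chamber_counts")
}

#' Nuisance dissociation probabilities
#'
#' Probabilities that the motor (RNAP or Mfd) and the dCas dissociate through
#' a non-collision mechanism over the chase interval, measured in separate
#' dissociation controls and supplied here as fixed inputs.
#'
#' @param p_motor_diss,p_dcas_diss probabilities in [0, 1).
#' @return An object of class \code{"nuisance_params"}.
#' @export
nuisance_params <- function(p_motor_diss = 0, p_dcas_diss = 0) {
  stopifnot(p_motor_diss >= 0, p_motor_diss < 1,
            p_dcas_diss >= 0, p_dcas_diss < 1)
  structure(list(p_motor_diss = p_motor_diss, p_dcas_diss = p_dcas_diss),
            class = "nuisance_params")
}

#' Collision competence probability
#'
#' The probability that a motor that survived non-collision dissociation
#' escaped the stall site and reached the bound dCas:
#' \deqn{P_{cc} = 1 - \frac{F_{TECup,dCas,f} + F_{TECuponly,f}}
#'   {(F_{A20,dCas,i} + F_{A20only,i})(1 - p_{motor,diss})}.}
#'
#' @param c a \code{\link{chamber_counts}}.
#' @param nu a \code{\link{nuisance_params}}.
#' @return numeric probability; \code{NA} with a \code{"reason"} attribute
#'   when the denominator is zero.
#' @export
collision_competence <- function(c, nu = nuisance_params()) {
  stopifnot(inherits(c, "chamber_counts"), inherits(nu, "nuisance_params"))
  den <- (c$pre[["A20_dCas"]] + c$pre[["A20_only"]]) * (1 - nu$p_motor_diss)
  if (den <= 0)
    return(structure(NA_real_, reason = "no initial motor occupancy"))
  1 - (c$post[["TEC_up_dCas"]] + c$post[["TEC_up_only"]]) / den
}

# shared numerator of the read-through / removal equations
.efficiency_core <- function(c, nu, p_cc, include_removed) {
  pre <- c$pre; post <- c$post
  pmd <- nu$p_motor_diss; pdd <- nu$p_dcas_diss
  reached <- p_cc * (1 - pmd) + pmd       # motor gone from A20 either way
  num <- post[["Nak"]] + post[["TEC_dn"]] -
    pre[["Nak"]] -
    pre[["A20_dCas"]] * reached * pdd -
    pre[["A20_only"]] * reached -
    pre[["dCas_only"]] * pdd
  if (include_removed) num <- num + post[["dCas_rem"]]
  den <- pre[["A20_dCas"]] * p_cc * (1 - pmd) * (1 - pdd)
  if (den <= 0)
    return(structure(NA_real_, reason = "zero denominator"))
  unname(num / den)
}

#' Read-through probability
#'
#' The probability that a collision-competent motor that met a bound dCas
#' removed it and translocated past the binding site. Starting from the
#' post-chase naked-DNA and downstream-motor fractions, all other pathways
#' feeding those observations (initially naked templates, motors on
#' dCas-free templates, spontaneous dCas loss) are subtracted, and the
#' remainder is normalized by the fraction of templates on which a true
#' collision could occur.
#'
#' @inheritParams collision_competence
#' @param p_cc collision competence probability (from
#'   \code{\link{collision_competence}} or known).
#' @return numeric; \code{NA} with a reason attribute on a zero denominator.
#'   Values outside [0, 1] (possible under sampling noise) are returned
#'   as-is for flagging by the caller, never clipped.
#' @export
read_through <- function(c, nu = nuisance_params(), p_cc) {
  stopifnot(inherits(c, "chamber_counts"), inherits(nu, "nuisance_params"))
  .efficiency_core(c, nu, p_cc, include_removed = FALSE)
}

#' Removal probability
#'
#' As \code{\link{read_through}}, additionally counting motors that removed
#' the dCas but then stalled near the binding site
#' (the \code{dCas_rem} fraction).
#'
#' @inheritParams read_through
#' @return numeric; see \code{\link{read_through}}.
#' @export
removal <- function(c, nu = nuisance_params(), p_cc) {
  stopifnot(inherits(c, "chamber_counts"), inherits(nu, "nuisance_params"))
  .efficiency_core(c, nu, p_cc, include_removed = TRUE)
}

#' Fit roadblock read-through and removal efficiencies from chamber counts
#'
#' The central estimator: applies the conditional-probability equations for
#' collision competence, read-through and removal to each chamber's category
#' fractions and aggregates across chambers (unweighted mean and s.e.m.).
#' Chambers with undefined estimates (zero denominators) are excluded from
#' the aggregate and counted; estimates outside [0, 1] (possible under
#' sampling noise) are flagged but enter the aggregate unclipped, matching
#' the per-chamber-dot presentation of the assay.
#'
#' @param data per-chamber input: either a data.frame as produced by
#'   \code{\link{count_categories}} (columns \code{pre_*}, \code{post_*}) or
#'   a list of \code{\link{chamber_counts}}.
#' @param nuisance a \code{\link{nuisance_params}}.
#' @param motor \code{"RNAP"} or \code{"Mfd"}. For Mfd the same equations
#'   apply with the Mfd dissociation probability as the motor nuisance;
#'   removal-then-stall is not expected and removal coincides with
#'   move-through when \code{dCas_rem} is empty.
#' @return An object of class \code{"roadblock_model"} with components
#'   \code{chambers} (per-chamber estimate table), \code{aggregate}
#'   (mean, sem, n per quantity), \code{nuisance}, \code{motor},
#'   \code{n_invalid}.
#' @examples
#' cfg <- generator_config(seed = 42)
#' counts <- count_categories(sample_outcomes(cfg))
#' fit <- roadblock_model(counts, nuisance_params(0.05, 0.05))
#' coef(fit)
#' @export
roadblock_model <- function(data, nuisance = nuisance_params(),
                            motor = c("RNAP", "Mfd")) {
  motor <- match.arg(motor)
  chambers <- .as_chamber_list(data)
  rows <- lapply(seq_along(chambers), function(i) {
    cc <- chambers[[i]]
    p_cc <- collision_competence(cc, nuisance)
    p_rt <- if (is.na(p_cc)) NA_real_ else read_through(cc, nuisance, p_cc)
    p_rm <- if (is.na(p_cc)) NA_real_ else removal(cc, nuisance, p_cc)
    data.frame(chamber = names(chambers)[i], p_coll_comp = as.numeric(p_cc),
               p_read_through = as.numeric(p_rt),
               p_removal = as.numeric(p_rm),
               valid = !is.na(p_cc) && !is.na(p_rt),
               out_of_range = !is.na(p_rt) &&
                 (p_rt < 0 || p_rt > 1 || p_rm < 0 || p_rm > 1),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  agg <- .aggregate_chambers(tab)
  structure(list(chambers = tab, aggregate = agg, nuisance = nuisance,
                 motor = motor, n_invalid = sum(!tab$valid),
                 counts = chambers),
            class = "roadblock_model")
}

.as_chamber_list <- function(data) {
  if (is.data.frame(data)) {
    pre_cols <- paste0("pre_", PRE_CATEGORIES)
    post_cols <- paste0("post_", POST_CATEGORIES)
    miss <- setdiff(c(pre_cols, post_cols), names(data))
    if (length(miss))
      stop("counts table missing column: ", paste(miss, collapse = ", "))
    ids <- if ("chamber" %in% names(data)) as.character(data$chamber)
           else as.character(seq_len(nrow(data)))
    out <- lapply(seq_len(nrow(data)), function(i) {
      chamber_counts(
        stats::setNames(as.numeric(data[i, pre_cols]), PRE_CATEGORIES),
        stats::setNames(as.numeric(data[i, post_cols]), POST_CATEGORIES))
    })
    names(out) <- ids
    out
  } else if (is.list(data) && all(vapply(data, inherits, TRUE,
                                         "chamber_counts"))) {
    if (is.null(names(data))) names(data) <- as.character(seq_along(data))
    data
  } else stop("data must be a counts data.frame or a list of chamber_counts")
}

.aggregate_chambers <- function(tab) {
  ok <- tab[tab$valid, , drop = FALSE]
  qty <- c("p_coll_comp", "p_read_through", "p_removal")
  agg <- lapply(qty, function(q) {
    v <- ok[[q]]
    n <- sum(!is.na(v))
    if (n == 0)
      return(data.frame(quantity = q, mean = NA_real_, sem = NA_real_, n = 0))
    data.frame(quantity = q, mean = mean(v, na.rm = TRUE),
               sem = if (n >= 2) stats::sd(v, na.rm = TRUE) / sqrt(n)
                     else NA_real_,
               n = n)
  })
  do.call(rbind, agg)
}

#' @export
print.roadblock_model <- function(x, ...) {
  cat(sprintf("Roadblock efficiency model (%s), %d chambers (%d invalid)\n",
              x$motor, nrow(x$chambers), x$n_invalid))
  a <- x$aggregate
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-15s %.4f +/- %s (s.e.m., n = %d)\n", a$quantity[i],
                a$mean[i],
                ifelse(is.na(a$sem[i]), "NA", sprintf("%.4f", a$sem[i])),
                a$n[i]))
  invisible(x)
}

#' @export
summary.roadblock_model <- function(object, ...) {
  structure(list(chambers = object$chambers, aggregate = object$aggregate,
                 motor = object$motor, nuisance = object$nuisance,
                 n_invalid = object$n_invalid),
            class = "summary.roadblock_model")
}

#' @export
print.summary.roadblock_model <- function(x, ...) {
  cat(sprintf("Roadblock efficiency model (%s)\n\nPer-chamber estimates:\n",
              x$motor))
  print(x$chambers, row.names = FALSE, digits = 4)
  cat(sprintf("\nNuisance: p_motor_diss = %g, p_dcas_diss = %g\n",
              x$nuisance$p_motor_diss, x$nuisance$p_dcas_diss))
  cat("\nAggregate (mean +/- s.e.m. across chambers):\n")
  print(x$aggregate, row.names = FALSE, digits = 4)
  if (x$n_invalid) cat(sprintf("\n%d chamber(s) excluded (undefined)\n",
                               x$n_invalid))
  invisible(x)
}

#' @export
coef.roadblock_model <- function(object, ...) {
  stats::setNames(object$aggregate$mean, object$aggregate$quantity)
}

#' @export
residuals.roadblock_model <- function(object, ...) {
  ok <- object$chambers[object$chambers$valid, , drop = FALSE]
  m <- coef(object)
  cbind(p_coll_comp = ok$p_coll_comp - m[["p_coll_comp"]],
        p_read_through = ok$p_read_through - m[["p_read_through"]],
        p_removal = ok$p_removal - m[["p_removal"]])
}

#' Predict expected post-chase category fractions from a fitted model
#'
#' Runs the generative outcome tree forward with the fitted efficiencies:
#' given pre-chase occupancy fractions, returns the expected post-chase
#' category fractions. The removal-minus-read-through difference is assigned
#' to the removal-then-stall pathway.
#'
#' @param object a \code{\link{roadblock_model}}.
#' @param prechase named pre-chase fractions (default: mean of the fitted
#'   chambers' pre-chase fractions).
#' @param p_runoff runoff split of read-through motors (does not affect the
#'   sum \code{Nak + TEC_dn}).
#' @param ... unused.
#' @return named numeric vector of expected post-chase fractions.
#' @export
predict.roadblock_model <- function(object, prechase = NULL, p_runoff = 0.5,
                                    ...) {
  est <- coef(object)
  if (is.null(prechase)) {
    pres <- vapply(object$counts, function(c) c$pre, numeric(4))
    prechase <- rowMeans(pres)
  }
  prt <- min(max(est[["p_read_through"]], 0), 1)
  prm <- min(max(est[["p_removal"]], 0), 1)
  cfg <- generator_config(
    motor = object$motor, f_initial = prechase[PRE_CATEGORIES],
    p_motor_diss = object$nuisance$p_motor_diss,
    p_dcas_diss = object$nuisance$p_dcas_diss,
    p_coll_comp = min(max(est[["p_coll_comp"]], 0), 1),
    p_read_through = prt, p_removal_stall = max(prm - prt, 0),
    p_runoff = p_runoff)
  expected_fractions(cfg)$post
}

#' Simulate chamber outcome tables from a fitted model
#'
#' Draws synthetic chambers from the generative tree parameterized at the
#' fitted efficiencies, mirroring the fitted chamber sizes.
#'
#' @param object a \code{\link{roadblock_model}}.
#' @param nsim number of simulated data sets.
#' @param seed optional integer seed.
#' @param n_control,n_chase traces per chamber (defaults: the fitted
#'   chambers' sizes where known, else 40/60).
#' @param ... unused.
#' @return a list of \code{nsim} outcome data.frames (see
#'   \code{\link{sample_outcomes}}).
#' @export
simulate.roadblock_model <- function(object, nsim = 1, seed = NULL,
                                     n_control = NULL, n_chase = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  est <- coef(object)
  pres <- vapply(object$counts, function(c) c$pre, numeric(4))
  n_pre <- vapply(object$counts, function(c) c$n_pre, numeric(1))
  n_post <- vapply(object$counts, function(c) c$n_post, numeric(1))
  if (is.null(n_control))
    n_control <- if (all(is.finite(n_pre))) round(mean(n_pre)) else 40
  if (is.null(n_chase))
    n_chase <- if (all(is.finite(n_post))) round(mean(n_post)) else 60
  prt <- min(max(est[["p_read_through"]], 0), 1)
  prm <- min(max(est[["p_removal"]], 0), 1)
  cfg <- generator_config(
    motor = object$motor, f_initial = rowMeans(pres)[PRE_CATEGORIES],
    p_motor_diss = object$nuisance$p_motor_diss,
    p_dcas_diss = object$nuisance$p_dcas_diss,
    p_coll_comp = min(max(est[["p_coll_comp"]], 0), 1),
    p_read_through = prt,
    p_removal_stall = max(min(prm - prt, 1 - prt), 0),
    n_control = n_control, n_chase = n_chase,
    n_chambers = length(object$counts))
  lapply(seq_len(nsim), function(i) sample_outcomes(cfg))
}

#' @export
plot.roadblock_model <- function(x, quantity = "p_read_through", ...) {
  ok <- x$chambers[x$chambers$valid, , drop = FALSE]
  v <- ok[[quantity]]
  a <- x$aggregate[x$aggregate$quantity == quantity, ]
  graphics::plot(jitter(rep(1, length(v)), amount = 0.05), v,
                 xlim = c(0.5, 1.5), ylim = range(c(v, 0, 1)), xaxt = "n",
                 xlab = "", ylab = quantity, pch = 16, ...)
  graphics::segments(0.85, a$mean, 1.15, a$mean, lwd = 2)
  if (!is.na(a$sem))
    graphics::arrows(1, a$mean - a$sem, 1, a$mean + a$sem, angle = 90,
                     code = 3, length = 0.05)
  invisible(x)
}
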