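#' Classifier configuration
#'
#' Parameters of the category decision rules: the collision-competence
#' distance cutoff (60 bp upstream of the dCas target site for RNAP, 70 bp
#' for Mfd, matching the motor footprints), the tolerance for matching a call
#' to an annotated site, and the footprint window used to assess removal
#' overlap. The boundary convention is that a motor peak strictly more than
#' \code{cutoff_bp} upstream of the target site has not collided; a distance
#' less than or equal to the cutoff counts as collided.
#'
#' @param motor \code{"RNAP"} or \code{"Mfd"}.
#' @param cutoff_bp collision-competence cutoff (bp); default 60 for RNAP,
#'   70 for Mfd.
#' @param site_tol_bp tolerance for matching a rise call to an annotated site.
#' @param footprint_bp dCas footprint window half-width for removal-overlap
#'   assessment.
#' @return An object of class \code{"classifier_config"}.
#' @export
classifier_config <- function(motor = c("RNAP", "Mfd"), cutoff_bp = NULL,
                              site_tol_bp = 15, footprint_bp = 25) {
  motor <- match.arg(motor)
  if (is.null(cutoff_bp)) cutoff_bp <- if (motor == "RNAP") 60 else 70
  stopifnot(cutoff_bp > 0, site_tol_bp > 0, footprint_bp > 0)
  structure(list(motor = motor, cutoff_bp = cutoff_bp,
                 site_tol_bp = site_tol_bp, footprint_bp = footprint_bp),
            class = "classifier_config")
}

# Partition rise calls into dCas evidence and motor calls.
# dCas presence on PAM-proximal-first constructs: a rise within site_tol of
# the expected clamp position (the sharp rise ~6 bp from the PAM). On
# PAM-distal-first constructs a lone rise inside the footprint could equally
# be a motor that invaded after removing the dCas, so the clamp rise must be
# corroborated: either by the R-loop bubble dip over the hybrid window (the
# fork approached the intact complex quasi-statically), or by a separate
# motor rise upstream of the footprint (a collision: the fork rips through
# the stalled motor and lands on the still-bound dCas, skipping the dip).
.match_calls <- function(calls, construct, cfg) {
  rises <- calls[calls$sign == "rise", , drop = FALSE]
  dips <- calls[calls$sign == "dip", , drop = FALSE]
  clamp <- dcas_clamp_pos(construct)
  rl <- rloop_window(construct)
  near_clamp <- abs(rises$position_bp - clamp) <= cfg$site_tol_bp
  if (construct$direction == "PAM_distal_first") {
    has_dip <- any(dips$position_bp >= rl[1] - cfg$site_tol_bp &
                     dips$position_bp <= rl[2] + cfg$site_tol_bp)
    other_rise <- any(rises$position_bp[!near_clamp] < rl[1] + 1)
    dcas_present <- any(near_clamp) && (has_dip || other_rise)
  } else {
    dcas_present <- any(near_clamp)
  }
  dcas_idx <- if (dcas_present) which(near_clamp) else integer(0)
  dcas_pos <- if (length(dcas_idx))
    rises$position_bp[dcas_idx[which.max(rises$amplitude_pN[dcas_idx])]]
  else NA_real_
  motor_rises <- if (length(dcas_idx)) rises[-dcas_idx, , drop = FALSE]
                 else rises
  motor_pos <- if (nrow(motor_rises))
    motor_rises$position_bp[which.max(motor_rises$amplitude_pN)]
  else NA_real_
  list(dcas_present = dcas_present, dcas_pos = dcas_pos,
       motor_pos = motor_pos, n_motor = nrow(motor_rises))
}

#' Classify a pre-chase (control) trace
#'
#' Maps a trace's interaction calls to one of the four pre-chase categories:
#' motor at A20 and dCas bound (\code{A20_dCas}), motor only
#' (\code{A20_only}), dCas only (\code{dCas_only}) or naked DNA (\code{Nak}).
#' Motor presence requires a rise within the site tolerance of the A20
#' position.
#'
#' @param calls a call table from \code{\link{call_interactions}}.
#' @param construct an \code{\link{unzip_construct}}.
#' @param cfg a \code{\link{classifier_config}}.
#' @return list with \code{label}, \code{motor_pos}, \code{dcas_pos},
#'   \code{flag} (\code{NA} or \code{"ambiguous"}).
#' @export
classify_prechase <- function(calls, construct, cfg = classifier_config()) {
  m <- .match_calls(calls, construct, cfg)
  a20 <- motor_site(construct)
  motor <- !is.na(m$motor_pos) && abs(m$motor_pos - a20) <= cfg$site_tol_bp
  label <- if (motor && m$dcas_present) "A20_dCas"
  else if (motor) "A20_only"
  else if (m$dcas_present) "dCas_only"
  else "Nak"
  list(label = label, phase = "control",
       motor_pos = if (motor) m$motor_pos else NA_real_,
       dcas_pos = m$dcas_pos, flag = NA_character_)
}

#' Classify a post-chase trace
#'
#' Maps interaction calls to one of the seven post-chase categories. Decision
#' order: dCas presence from the clamp-site call (with the dip requirement on
#' PAM-distal-first constructs); then the motor call position relative to the
#' dCas target site: strictly more than \code{cutoff_bp} upstream gives
#' \code{TEC_up_dCas}/\code{TEC_up_only}; within the cutoff gives \code{Coll}
#' (dCas present) or \code{dCas_rem} (dCas absent: the motor removed the dCas
#' but stalled, its peak typically overlapping the expected footprint);
#' downstream of the site without dCas gives \code{TEC_dn}; no motor gives
#' \code{dCas_only} or \code{Nak}. A motor downstream of the site with a dCas
#' still present is contradictory and flagged ambiguous.
#'
#' @inheritParams classify_prechase
#' @return list with \code{label}, \code{motor_pos}, \code{dcas_pos},
#'   \code{upstream_bp} (distance of the motor peak upstream of the target
#'   site) and \code{flag}.
#' @export
classify_postchase <- function(calls, construct, cfg = classifier_config()) {
  m <- .match_calls(calls, construct, cfg)
  site <- dcas_site_ref(construct)
  flag <- NA_character_
  if (is.na(m$motor_pos)) {
    label <- if (m$dcas_present) "dCas_only" else "Nak"
    dist <- NA_real_
  } else {
    dist <- site - m$motor_pos            # >0: motor upstream of the site
    if (dist > cfg$cutoff_bp) {
      label <- if (m$dcas_present) "TEC_up_dCas" else "TEC_up_only"
    } else if (dist >= 0) {
      label <- if (m$dcas_present) "Coll" else "dCas_rem"
    } else {
      if (m$dcas_present) {
        label <- "Coll"
        flag <- "ambiguous"               # motor past a still-bound dCas
      } else {
        # just past the site: stalled motor overlapping the footprint
        label <- if (-dist <= cfg$footprint_bp) "dCas_rem" else "TEC_dn"
      }
    }
  }
  list(label = label, phase = "chase", motor_pos = m$motor_pos,
       dcas_pos = m$dcas_pos, upstream_bp = dist, flag = flag)
}

#' Classify a batch of traces
#'
#' Applies \code{\link{classify_prechase}} or \code{\link{classify_postchase}}
#' to a list of call tables and assembles the per-trace classification table.
#' Every trace receives exactly one label or an explicit flag.
#'
#' @param calls_list list of call tables.
#' @param phases character vector (\code{"control"}/\code{"chase"}), one per
#'   trace.
#' @param construct an \code{\link{unzip_construct}}.
#' @param cfg a \code{\link{classifier_config}}.
#' @param chamber optional chamber ids, one per trace.
#' @return data.frame with columns \code{chamber}, \code{trace}, \code{phase},
#'   \code{category}, \code{motor_pos_bp}, \code{dcas_pos_bp}, \code{flag}.
#' @export
classify_traces <- function(calls_list, phases, construct,
                            cfg = classifier_config(), chamber = NULL) {
  n <- length(calls_list)
  stopifnot(length(phases) == n)
  if (is.null(chamber)) chamber <- rep(1L, n)
  rows <- lapply(seq_len(n), function(i) {
    r <- if (phases[i] == "control")
      classify_prechase(calls_list[[i]], construct, cfg)
    else classify_postchase(calls_list[[i]], construct, cfg)
    data.frame(chamber = chamber[i], trace = i, phase = phases[i],
               category = r$label, motor_pos_bp = r$motor_pos,
               dcas_pos_bp = r$dcas_pos, flag = r$flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Invasion statistics of motor peaks relative to the dCas R-loop
#'
#' Summarizes motor force-peak positions of collision (\code{Coll}) and
#' removal-then-stall (\code{dCas_rem}) traces relative to the R-loop edge
#' facing the motor: the invasion depth is the signed overlap of the motor
#' peak into the annotated R-loop window (positive = inside the window).
#' Reports 25th/75th percentiles, standard deviation and n per condition.
#'
#' @param classified a classification table from \code{\link{classify_traces}}
#'   (or equivalent) with columns \code{category}, \code{motor_pos_bp} and
#'   optionally \code{condition}.
#' @param construct an \code{\link{unzip_construct}}.
#' @return data.frame, one row per condition x category with columns
#'   \code{condition}, \code{category}, \code{n}, \code{p25}, \code{median},
#'   \code{p75}, \code{sd} of the invasion depth (bp). Empty conditions are
#'   omitted.
#' @export
invasion_statistics <- function(classified, construct) {
  keep <- classified$category %in% c("Coll", "dCas_rem") &
    !is.na(classified$motor_pos_bp)
  cl <- classified[keep, , drop = FALSE]
  if (!nrow(cl))
    return(data.frame(condition = character(0), category = character(0),
                      n = integer(0), p25 = numeric(0), median = numeric(0),
                      p75 = numeric(0), sd = numeric(0)))
  rl <- rloop_window(construct)
  pam <- .ann(construct, "PAM")
  edge <- if (construct$direction == "PAM_proximal_first") rl[2] else rl[1]
  inv <- if (construct$direction == "PAM_proximal_first")
    edge - cl$motor_pos_bp else cl$motor_pos_bp - edge
  cond <- if ("condition" %in% names(cl)) cl$condition else "all"
  agg <- split(inv, list(cond, cl$category), drop = TRUE)
  rows <- lapply(names(agg), function(k) {
    v <- agg[[k]]
    parts <- strsplit(k, ".", fixed = TRUE)[[1L]]
    data.frame(condition = parts[1L], category = parts[2L], n = length(v),
               p25 = unname(stats::quantile(v, 0.25, type = 7)),
               median = unname(stats::median(v)),
               p75 = unname(stats::quantile(v, 0.75, type = 7)),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
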