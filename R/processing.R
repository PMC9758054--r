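#' Convert a force-extension trace to base pairs unzipped
#'
#' Inverts the series elasticity of the construct at each sample: with the
#' dsDNA arms at extension \eqn{L_{arm} x_{ds}(f)}, the number of base pairs
#' unzipped is
#' \deqn{j = \frac{z - L_{arm} x_{ds}(f)}{2\, x_{ss}(f)}.}
#' Samples below the force floor are masked (the ssDNA extension model is
#' degenerate near zero force); negative \eqn{j} is clipped at 0 and flagged.
#'
#' @param trace an \code{\link{unzip_trace}}.
#' @param elastic an \code{\link{elastic_params}}.
#' @param construct an \code{\link{unzip_construct}}.
#' @param force_floor_pN samples below this force are masked, not converted.
#' @param smooth_samples boxcar width (samples) applied to the force before
#'   conversion. Conversion amplifies force noise several-fold in bp, with a
#'   systematic bias where the theory curve is steep; averaging first (as
#'   instrument pipelines do when decimating) suppresses both.
#' @return An object of class \code{"processed_trace"}: data.frame with
#'   columns \code{bp_unzipped}, \code{force_pN}; masked samples are dropped.
#'   Attributes: \code{n_masked}, \code{n_clipped}, \code{aligned} (FALSE),
#'   \code{offset_bp}, \code{scale}.
#' @export
bp_from_force_extension <- function(trace, elastic = elastic_params(),
                                    construct, force_floor_pN = 3,
                                    smooth_samples = 5) {
  stopifnot(inherits(trace, "unzip_trace"),
            inherits(construct, "unzip_construct"))
  f <- trace$force_pN
  if (smooth_samples > 1 && nrow(trace) >= smooth_samples) {
    fs <- as.numeric(stats::filter(f, rep(1 / smooth_samples,
                                          smooth_samples), sides = 2))
    fs[is.na(fs)] <- f[is.na(fs)]
    f <- fs
  }
  if (any(f > 65))
    warning("forces above 65 pN are outside the elastic model validity")
  keep <- f >= force_floor_pN
  tab <- .elastic_tables(elastic)
  fk <- f[keep]
  j <- (trace$extension_nm[keep] - construct$arm_bp * tab$xds(fk)) /
    (2 * tab$xss(fk))
  clipped <- j < 0
  j[clipped] <- 0
  structure(data.frame(bp_unzipped = j, force_pN = fk,
                       extension_nm = trace$extension_nm[keep]),
            class = c("processed_trace", "data.frame"),
            n_masked = sum(!keep), n_clipped = sum(clipped),
            aligned = FALSE, offset_bp = NA_real_, scale = NA_real_,
            residual_pN = NA_real_, alignment_failed = NA)
}

#' @export
print.processed_trace <- function(x, ...) {
  cat(sprintf("Processed trace: %d samples, bp %.1f-%.1f\n", nrow(x),
              min(x$bp_unzipped), max(x$bp_unzipped)))
  if (isTRUE(attr(x, "aligned")))
    cat(sprintf("  aligned: offset %.2f bp, scale %.3f, residual %.2f pN RMS%s\n",
                attr(x, "offset_bp"), attr(x, "scale"),
                attr(x, "residual_pN"),
                if (isTRUE(attr(x, "alignment_failed"))) " [FAILED]" else ""))
  invisible(x)
}

#' Align a processed trace to the unzipping theory curve
#'
#' Finds the base-pair offset and stretch scale that minimize a robust
#' (trimmed) mean squared force residual between the trace and the naked-DNA
#' theory baseline, by grid search over \code{offset_range} and
#' \code{scale_range}. Trimming keeps protein peaks from biasing the fit. A
#' trace whose best trimmed RMS residual exceeds \code{fail_rms_pN} is flagged
#' as alignment-failed (excluded downstream).
#'
#' @param pt a \code{"processed_trace"} from
#'   \code{\link{bp_from_force_extension}}.
#' @param theory an \code{\link{unzip_theory}} for the same construct.
#' @param offset_range,offset_step offset search grid (bp).
#' @param scale_range,scale_step scale search grid (dimensionless).
#' @param trim fraction of the largest squared residuals discarded.
#' @param fail_rms_pN trimmed RMS residual (pN) above which alignment fails.
#' @param scale_ridge ridge penalty weight on \code{(scale - 1)^2} added to
#'   the objective; breaks noise-level ties toward the identity scale, since
#'   a spurious scale of even 1.01 displaces distal positions by several bp.
#' @return the aligned \code{"processed_trace"}: \code{bp_unzipped} has been
#'   mapped through the fitted offset/scale; attributes \code{offset_bp},
#'   \code{scale}, \code{residual_pN} and \code{alignment_failed} are set.
#' @export
align_to_theory <- function(pt, theory, offset_range = c(-20, 20),
                            offset_step = 0.25, scale_range = c(0.95, 1.05),
                            scale_step = 0.005, trim = 0.10,
                            fail_rms_pN = 1.2, scale_ridge = 300) {
  stopifnot(inherits(pt, "processed_trace"), inherits(theory, "unzip_theory"))
  bl <- baseline_force(theory)
  bp <- pt$bp_unzipped
  f <- pt$force_pN
  span <- range(theory$bp_unzipped)
  if (sum(bp >= span[1] & bp <= span[2]) < 100)
    stop("trace and theory overlap by fewer than 100 bp of samples")
  keepn <- function(r2) {
    k <- max(1L, floor(length(r2) * (1 - trim)))
    sort.int(r2, partial = k)[seq_len(k)]
  }
  search <- function(offsets, scales, best) {
    for (s in scales) {
      sb <- s * bp
      for (o in offsets) {
        r2 <- (f - bl(sb + o))^2
        obj <- mean(keepn(r2)) + scale_ridge * (s - 1)^2
        if (obj < best$obj) best <- list(obj = obj, offset = o, scale = s)
      }
    }
    best
  }
  # coarse grid, then local refinement around the coarse optimum
  best <- search(seq(offset_range[1], offset_range[2], by = 1),
                 seq(scale_range[1], scale_range[2], by = 2 * scale_step),
                 list(obj = Inf, offset = NA_real_, scale = NA_real_))
  best <- search(
    seq(max(offset_range[1], best$offset - 1),
        min(offset_range[2], best$offset + 1), by = offset_step),
    seq(max(scale_range[1], best$scale - 2 * scale_step),
        min(scale_range[2], best$scale + 2 * scale_step), by = scale_step),
    best)
  # continuous polish of the offset: residual misalignment of even a
  # fraction of a bp leaves threshold-crossing deviations at steep
  # sawtooth rips
  sb <- best$scale * bp
  op <- stats::optimize(function(o) mean(keepn((f - bl(sb + o))^2)),
                        c(best$offset - offset_step,
                          best$offset + offset_step), tol = 1e-3)
  if (op$objective + scale_ridge * (best$scale - 1)^2 < best$obj) {
    best$offset <- op$minimum
    best$obj <- op$objective + scale_ridge * (best$scale - 1)^2
  }
  rms <- sqrt(mean(keepn((f - bl(best$scale * bp + best$offset))^2)))
  out <- pt
  out$bp_unzipped <- best$scale * bp + best$offset
  attr(out, "aligned") <- TRUE
  attr(out, "offset_bp") <- best$offset
  attr(out, "scale") <- best$scale
  attr(out, "residual_pN") <- rms
  attr(out, "alignment_failed") <- rms > fail_rms_pN
  out
}

#' Call interaction signatures (force rises and dips) against the baseline
#'
#' Scans the aligned record, in loading order, for maximal runs of samples
#' whose deviation from the naked-DNA baseline exceeds the rise threshold
#' (bound protein) or falls below the dip threshold (unpaired bubble).
#' Run extent is measured in the fork-progress coordinate (the naked-theory
#' fork position at the sample's extension), so a stalled fork, which climbs
#' in force at nearly constant bp, still accumulates width; runs separated by
#' gaps shorter than the minimum width are merged, and runs narrower than the
#' minimum width are discarded. Each call reports the bp position of maximum
#' absolute deviation, the signed maximum deviation, the run width and the
#' bp at which the run starts and ends.
#'
#' @param pt an aligned \code{"processed_trace"}.
#' @param theory an \code{\link{unzip_theory}}.
#' @param rise_pN rise threshold above baseline (pN).
#' @param dip_pN dip threshold below baseline (pN, positive number).
#' @param min_width_bp minimum run width (bp of fork progress).
#' @return data.frame of calls sorted by position: \code{position_bp},
#'   \code{sign} (\code{"rise"}/\code{"dip"}), \code{amplitude_pN} (signed),
#'   \code{width_bp}, \code{start_bp}, \code{end_bp}. Zero rows when nothing
#'   deviates.
#' @export
call_interactions <- function(pt, theory, rise_pN = 2, dip_pN = 1.5,
                              min_width_bp = 3) {
  stopifnot(inherits(pt, "processed_trace"))
  if (!isTRUE(attr(pt, "aligned")))
    stop("trace must be aligned before calling interactions")
  bl <- baseline_force(theory)
  ord <- order(pt$extension_nm)
  bp <- pt$bp_unzipped[ord]
  dev <- pt$force_pN[ord] - bl(bp)
  # light boxcar smoothing so sample noise does not fragment threshold runs
  if (length(dev) >= 5) {
    sm <- as.numeric(stats::filter(dev, rep(1 / 5, 5), sides = 2))
    sm[is.na(sm)] <- dev[is.na(sm)]
    dev <- sm
  }
  # fork-progress coordinate: where the naked fork would be at this extension
  prog <- stats::approx(theory$extension_nm, theory$bp_unzipped,
                        xout = pt$extension_nm[ord], rule = 2,
                        ties = mean)$y
  # positions are read off a lightly median-filtered bp series: conversion
  # noise in bp grows with fork position and is several-fold larger than the
  # force noise would suggest
  bp_s <- if (length(bp) >= 7) stats::runmed(bp, 7) else bp
  # exclude samples whose fork position is at the template end, where both
  # trace and baseline stiffen sharply as the template is exhausted and
  # deviations are edge artifacts
  keep <- bp_s <= max(theory$bp_unzipped) - 6
  calls <- rbind(
    .call_runs(bp_s[keep], prog[keep], dev[keep], dev[keep] > rise_pN,
               "rise", min_width_bp),
    .call_runs(bp_s[keep], prog[keep], -dev[keep], -dev[keep] > dip_pN,
               "dip", min_width_bp))
  if (nrow(calls)) calls <- calls[order(calls$position_bp), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

.call_runs <- function(bp, prog, mag, hit, sign, min_width_bp) {
  empty <- data.frame(position_bp = numeric(0), sign = character(0),
                      amplitude_pN = numeric(0), width_bp = numeric(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      stringsAsFactors = FALSE)
  hit[is.na(hit)] <- FALSE
  if (!any(hit)) return(empty)
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by less than the minimum width of fork progress
  if (nrow(runs) > 1L) {
    merged <- runs[1L, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- prog[runs$start[i]] - prog[merged$end[nrow(merged)]]
      if (gap < min_width_bp)
        merged$end[nrow(merged)] <- runs$end[i]
      else
        merged <- rbind(merged, runs[i, ])
    }
    runs <- merged
  }
  width <- prog[runs$end] - prog[runs$start] +
    stats::median(diff(prog))                 # inclusive of one sample step
  keep <- width >= min_width_bp
  runs <- runs[keep, , drop = FALSE]
  width <- width[keep]
  if (!nrow(runs)) return(empty)
  pos <- amp <- numeric(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    idx <- runs$start[i]:runs$end[i]
    mx <- max(mag[idx])
    # position = median bp over the samples near the run maximum, where the
    # fork sits hard against the obstruction: averages out the conversion
    # noise (which grows with fork position) and avoids both the softened
    # approach and the relaxation tail after a protein yields
    pos[i] <- stats::median(bp[idx][mag[idx] >= 0.9 * mx])
    amp[i] <- if (sign == "rise") mx else -mx
  }
  # run start/end are reported in the fork-progress coordinate: where the
  # naked fork stood when the deviation began/ended (a dip that "starts"
  # before a bubble reflects the fork sensing it downstream)
  data.frame(position_bp = pos, sign = sign, amplitude_pN = amp,
             width_bp = width, start_bp = prog[runs$start],
             end_bp = prog[runs$end], stringsAsFactors = FALSE)
}

#' Correct call positions for nascent-transcript tether shortening
#'
#' After transcription, the nascent transcript can partially anneal to the
#' exposed ssDNA, shortening the tether and shifting apparent positions of
#' later peaks upstream. A shortening event is detected as a backward jump in
#' bp at near-constant force; calls downstream of the event are shifted
#' forward by the measured shortening.
#'
#' @param pt an aligned \code{"processed_trace"}.
#' @param calls a call table from \code{\link{call_interactions}}.
#' @param min_jump_bp minimum backward jump regarded as a shortening event.
#'   The working threshold additionally adapts to the trace's conversion
#'   noise, so noisy traces cannot fire spurious corrections.
#' @param max_dforce_pN maximum force change across the jump.
#' @param window flanking-window length (samples) used to confirm that the
#'   backward shift is sustained.
#' @return the corrected call table; attribute \code{"shortening_bp"} records
#'   the total shift applied (0 when no event was detected).
#' @export
correct_transcript_annealing <- function(pt, calls, min_jump_bp = 2,
                                         max_dforce_pN = 0.75, window = 8) {
  stopifnot(inherits(pt, "processed_trace"))
  n <- nrow(pt)
  total <- 0
  if (n > 3 * window && nrow(calls)) {
    bp <- pt$bp_unzipped
    f <- pt$force_pN
    d <- diff(bp)
    step <- stats::median(d)
    # candidate = single-sample backward jump well beyond the conversion
    # noise; confirmed by a sustained, drift-corrected level shift between
    # the medians of the flanking windows at near-constant force
    thr <- max(min_jump_bp, 6 * stats::mad(d))
    cand <- which(d < -thr)
    cand <- cand[cand > window & cand < n - window - 1]
    last <- -Inf
    for (i in cand) {
      if (i - last <= window) next         # one event per cluster
      last <- i
      before <- stats::median(bp[(i - window):i])
      after <- stats::median(bp[(i + 1):(i + 1 + window)])
      dfo <- abs(stats::median(f[(i + 1):(i + 1 + window)]) -
                   stats::median(f[(i - window):i]))
      jump <- before + (window + 1) * step - after
      if (jump > min_jump_bp / 2 && dfo < max_dforce_pN) {
        hit <- calls$position_bp > before
        calls$position_bp[hit] <- calls$position_bp[hit] + jump
        if (any(hit)) total <- total + jump
      }
    }
  }
  attr(calls, "shortening_bp") <- total
  calls
}

#' Process a raw trace end to end
#'
#' Convenience wrapper: decimate (if needed), convert to bp, align to theory
#' and call interactions with annealing correction.
#'
#' @param trace an \code{\link{unzip_trace}}.
#' @param construct,theory,elastic model inputs.
#' @param target_hz decimation target (Hz); \code{NULL} keeps the raw rate.
#' @param ... passed to \code{\link{call_interactions}}.
#' @return list with elements \code{processed} (aligned trace) and
#'   \code{calls} (corrected call table).
#' @export
process_trace <- function(trace, construct, theory,
                          elastic = elastic_params(), target_hz = NULL, ...) {
  if (!is.null(target_hz) && target_hz < attr(trace, "rate_hz"))
    trace <- decimate(trace, target_hz)
  pt <- bp_from_force_extension(trace, elastic, construct)
  pt <- align_to_theory(pt, theory)
  calls <- call_interactions(pt, theory, ...)
  calls <- correct_transcript_annealing(pt, calls)
  # both the trace and the baseline stiffen sharply where the template is
  # exhausted; deviations called within a few bp of either end are edge
  # artifacts, not protein interactions
  calls <- calls[calls$position_bp >= 2 &
                   calls$position_bp <= construct$length - 6, , drop = FALSE]
  list(processed = pt, calls = calls)
}
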