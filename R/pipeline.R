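#' Write / read outcome and classification tables
#'
#' Tab-separated exchange of per-trace category tables with the seed and
#' schema recorded in header comments.
#'
#' @param outcomes data.frame with columns \code{chamber}, \code{trace},
#'   \code{phase}, \code{category} (extra columns are preserved).
#' @param path file path.
#' @param seed optional integer recorded in the header.
#' @return \code{write_outcomes}: invisibly the table; \code{read_outcomes}:
#'   the data.frame.
#' @export
write_outcomes <- function(outcomes, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# schema: outcomes v1",
               sprintf("# seed: %s", if (is.null(seed)) "NA" else seed)),
             con)
  utils::write.table(outcomes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(outcomes)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chamber", "trace", "phase", "category")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("outcomes file missing column: ", miss[1L])
  bad <- which(!d$phase %in% c("control", "chase"))
  if (length(bad))
    stop(sprintf("malformed phase at data line %d", bad[1L]))
  bad <- which(!d$category %in% c(PRE_CATEGORIES, POST_CATEGORIES))
  if (length(bad))
    stop(sprintf("unknown category at data line %d", bad[1L]))
  d
}

#' Write a peak-call table
#'
#' @param calls call table (from \code{\link{call_interactions}}), optionally
#'   with a \code{trace_id} column.
#' @param path file path.
#' @return invisibly, the table.
#' @export
write_calls <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# schema: calls v1; units: position_bp=bp amplitude_pN=pN",
             con)
  utils::write.table(calls, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(calls)
}

#' Run the synthetic analysis pipeline end to end
#'
#' Simulate chambers from a generator configuration, optionally render and
#' re-analyze full traces (process, classify), estimate efficiencies, and
#' write all stage artifacts to a directory. With \code{render = FALSE} the
#' classification stage is skipped and the estimator consumes the sampled
#' outcome labels directly (outcome-level run); with \code{render = TRUE}
#' every sampled trace is rendered, processed and classified, and the
#' confusion matrix of recovered versus generating categories is reported.
#'
#' @param cfg a \code{\link{generator_config}}.
#' @param construct an \code{\link{unzip_construct}} (required when
#'   \code{render = TRUE}).
#' @param nuisance a \code{\link{nuisance_params}} used by the estimator;
#'   defaults to the generator's true nuisance probabilities.
#' @param out_dir output directory for stage artifacts; \code{NULL} writes
#'   nothing.
#' @param render render and re-analyze full traces?
#' @param sig,thermo,elastic,classifier model parameter objects for the
#'   rendering path.
#' @return list with \code{outcomes}, \code{counts}, \code{fit} (a
#'   \code{\link{roadblock_model}}), and when rendering, \code{classified}
#'   and \code{confusion}.
#' @export
run_pipeline <- function(cfg, construct = NULL,
                         nuisance = NULL, out_dir = NULL, render = FALSE,
                         sig = signature_model(), thermo = thermo_params(),
                         elastic = elastic_params(), classifier = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(nuisance))
    nuisance <- nuisance_params(cfg$p_motor_diss, cfg$p_dcas_diss)
  if (is.null(classifier)) classifier <- classifier_config(cfg$motor)
  outcomes <- sample_outcomes(cfg)
  result <- list(outcomes = outcomes)
  if (render) {
    stopifnot(inherits(construct, "unzip_construct"))
    theory <- unzip_theory(construct, thermo, elastic)
    rows <- vector("list", nrow(outcomes))
    for (i in seq_len(nrow(outcomes))) {
      tr <- render_trace(outcomes$category[i], construct, sig, thermo,
                         elastic)
      an <- process_trace(tr, construct, theory, elastic)
      cl <- if (outcomes$phase[i] == "control")
        classify_prechase(an$calls, construct, classifier)
      else classify_postchase(an$calls, construct, classifier)
      rows[[i]] <- data.frame(
        chamber = outcomes$chamber[i], trace = outcomes$trace[i],
        phase = outcomes$phase[i], category = cl$label,
        generated = outcomes$category[i],
        motor_pos_bp = cl$motor_pos, dcas_pos_bp = cl$dcas_pos,
        flag = cl$flag, stringsAsFactors = FALSE)
    }
    classified <- do.call(rbind, rows)
    result$classified <- classified
    result$confusion <- table(generated = classified$generated,
                              recovered = classified$category)
    counts <- count_categories(classified)
  } else {
    counts <- count_categories(outcomes)
  }
  result$counts <- counts
  result$fit <- roadblock_model(counts, nuisance, motor = cfg$motor)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_outcomes(outcomes, file.path(out_dir, "outcomes.tsv"),
                   seed = cfg$seed)
    utils::write.table(counts, file.path(out_dir, "counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .write_report(result$fit, file.path(out_dir, "report.tsv"), cfg)
    if (render)
      utils::write.table(result$classified,
                         file.path(out_dir, "classified.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  result
}

.write_report <- function(fit, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# schema: report v1",
               sprintf("# motor: %s", fit$motor),
               sprintf("# seed: %s", if (is.null(cfg$seed)) "NA"
                       else cfg$seed)), con)
  utils::write.table(format(fit$aggregate, digits = 10), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(fit)
}
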