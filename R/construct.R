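#' Unzipping construct: sequence, arms and annotated protein sites
#'
#' Describes the DNA template of an unzipping experiment in the coordinate
#' frame used by all downstream analysis: the "unzip coordinate", 0-based and
#' half-open, increasing in the direction of fork progression. The segment
#' sequence is the strand read in the unzip direction; dsDNA arms of total
#' contour \code{arm_bp} precede the segment. Annotations mark the promoter,
#' the stall position of the motor (A20), the dCas protospacer and PAM, and
#' the template end.
#'
#' @param sequence DNA string of the unzipping segment, read in the unzip
#'   direction (A/C/G/T).
#' @param arm_bp total dsDNA arm contour in base pairs.
#' @param direction \code{"PAM_proximal_first"} if the fork reaches the PAM
#'   before the protospacer, \code{"PAM_distal_first"} otherwise.
#' @param annotations data.frame with columns \code{name}, \code{start},
#'   \code{end}, \code{kind}; 0-based half-open intervals in the unzip
#'   coordinate. Recognized kinds: \code{promoter}, \code{A20},
#'   \code{protospacer}, \code{PAM}, \code{template_end}.
#' @return An object of class \code{"unzip_construct"}.
#' @export
unzip_construct <- function(sequence, arm_bp, direction = c(
  "PAM_distal_first", "PAM_proximal_first"), annotations) {
  direction <- match.arg(direction)
  sequence <- toupper(as.character(sequence)[1L])
  bases <- strsplit(sequence, "")[[1L]]
  bad <- which(!bases %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop(sprintf("non-ACGT character at position %d", bad[1L]))
  stopifnot(is.data.frame(annotations),
            all(c("name", "start", "end", "kind") %in% names(annotations)),
            arm_bp > 0)
  n <- nchar(sequence)
  if (any(annotations$start < 0) || any(annotations$end > n) ||
      any(annotations$end <= annotations$start))
    stop("annotations must lie within [0, segment length) with end > start")
  ps <- annotations[annotations$kind == "protospacer", , drop = FALSE]
  pam <- annotations[annotations$kind == "PAM", , drop = FALSE]
  if (nrow(ps) == 1L && nrow(pam) == 1L) {
    adjacent <- pam$end == ps$start || ps$end == pam$start
    if (!adjacent) stop("PAM and protospacer must be adjacent")
    pam_first <- pam$start < ps$start
    if (pam_first != (direction == "PAM_proximal_first"))
      stop("PAM/protospacer order inconsistent with direction label")
  }
  structure(list(sequence = sequence, arm_bp = arm_bp, direction = direction,
                 annotations = annotations, length = n),
            class = "unzip_construct")
}

#' @export
print.unzip_construct <- function(x, ...) {
  cat(sprintf("Unzipping construct: %d bp segment, %d bp arms, %s\n",
              x$length, x$arm_bp, x$direction))
  print(x$annotations, row.names = FALSE)
  invisible(x)
}

# annotation lookup helpers ---------------------------------------------------

.ann <- function(construct, kind) {
  a <- construct$annotations
  a[a$kind == kind, , drop = FALSE]
}

# motor stall site (A20) position in the unzip coordinate
motor_site <- function(construct) {
  a <- .ann(construct, "A20")
  if (nrow(a) != 1L) stop("construct must annotate exactly one A20 site")
  a$start
}

# dCas target-site reference point: the PAM-proximal edge of the protospacer
dcas_site_ref <- function(construct) {
  ps <- .ann(construct, "protospacer")
  pam <- .ann(construct, "PAM")
  if (nrow(ps) != 1L || nrow(pam) != 1L)
    stop("construct must annotate one protospacer and one PAM")
  if (pam$start < ps$start) ps$start else ps$end
}

# gRNA-DNA hybrid (R-loop) window = the protospacer interval
rloop_window <- function(construct) {
  ps <- .ann(construct, "protospacer")
  c(ps$start, ps$end)
}

# expected dCas clamp-rise position given the unzip direction:
# PAM-proximal-first: a sharp rise ~clamp_offset bp before the fork reaches the
# PAM; PAM-distal-first: a rise within the hybrid region.
dcas_clamp_pos <- function(construct, clamp_offset = 6) {
  pam <- .ann(construct, "PAM")
  ps <- .ann(construct, "protospacer")
  if (construct$direction == "PAM_proximal_first")
    pam$start - clamp_offset
  else
    ps$start + round(0.6 * (ps$end - ps$start))
}

# construct i/o ---------------------------------------------------------------

#' Read an unzipping construct from FASTA plus an annotation table
#'
#' @param fasta path to a FASTA file whose first record is the segment
#'   sequence in the unzip direction.
#' @param annotations path to a tab-separated file with columns
#'   \code{name}, \code{start}, \code{end}, \code{kind} (0-based half-open).
#' @param arm_bp total dsDNA arm contour (bp).
#' @param direction unzip direction label; see \code{\link{unzip_construct}}.
#' @return an \code{\link{unzip_construct}}.
#' @export
read_construct <- function(fasta, annotations, arm_bp,
                           direction = "PAM_distal_first") {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) < 1L) stop("FASTA contains no sequences: ", fasta)
  ann <- utils::read.delim(annotations, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("name", "start", "end", "kind")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation file missing column: ", paste(miss, collapse = ", "))
  unzip_construct(as.character(seqs[[1L]]), arm_bp = arm_bp,
                  direction = direction, annotations = ann[need])
}

#' Write an unzipping construct to FASTA plus an annotation table
#'
#' @param construct an \code{\link{unzip_construct}}.
#' @param fasta,annotations output paths.
#' @return invisibly, the construct.
#' @export
write_construct <- function(construct, fasta, annotations) {
  stopifnot(inherits(construct, "unzip_construct"))
  writeLines(c(sprintf(">segment arm_bp=%d direction=%s", construct$arm_bp,
                       construct$direction),
               construct$sequence), fasta)
  con <- file(annotations, "w")
  on.exit(close(con))
  writeLines("# unzip coordinate, 0-based half-open", con)
  utils::write.table(construct$annotations, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(construct)
}
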