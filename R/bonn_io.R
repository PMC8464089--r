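bonn_label_map <- c(Z = "A", O = "B", N = "C", F = "D", S = "E",
                    A = "A", B = "B", C = "C", D = "D", E = "E")

#' Write segments in the Bonn on-disk convention
#'
#' One directory per class label, one plain-text file per segment, one
#' integer (rounded sample value) per line — the layout of the Bonn EEG
#' benchmark, so a synthetic corpus and the real corpus are
#' interchangeable to the rest of the pipeline.
#'
#' @param segments List of labeled [eeg_segment]s.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_bonn_corpus <- function(segments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  counter <- list()
  for (seg in segments) {
    lab <- attr(seg, "label")
    if (is.na(lab)) stop("write_bonn_corpus: unlabeled segment")
    cdir <- file.path(dir, lab)
    dir.create(cdir, showWarnings = FALSE)
    counter[[lab]] <- (counter[[lab]] %||% 0L) + 1L
    id <- attr(seg, "source_id")
    fname <- if (nzchar(id)) paste0(id, ".txt")
             else sprintf("%s%03d.txt", lab, counter[[lab]])
    path <- file.path(cdir, fname)
    writeLines(format(round(seg_samples(seg)), scientific = FALSE,
                      trim = TRUE), path)
    written <- c(written, path)
  }
  invisible(written)
}

#' Load a Bonn-format corpus directory
#'
#' Reads every plain-text segment file (one numeric sample per line) from
#' the class subdirectories of `dir`.  Both Bonn folder conventions are
#' accepted: `Z/O/N/F/S` are mapped to labels `A/B/C/D/E`; folders already
#' named `A`..`E` (or anything else) keep their name as the label.
#' Directories and files are traversed in lexicographic order so the
#' segment list is deterministic.
#'
#' @param dir Corpus directory containing one subdirectory per class.
#' @param sampling_rate Sampling rate assigned to every segment (default
#'   173.61 Hz, the Bonn rate).
#' @return List of labeled [eeg_segment]s.
#' @export
load_bonn <- function(dir, sampling_rate = 173.61) {
  if (!dir.exists(dir)) stop("load_bonn: no such directory: ", dir)
  classes <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  if (!length(classes)) stop("load_bonn: no class subdirectories in ", dir)
  segments <- list()
  for (cl in classes) {
    label <- unname(bonn_label_map[cl])
    if (is.na(label)) label <- cl
    files <- sort(list.files(file.path(dir, cl), full.names = TRUE))
    if (!length(files))
      stop("load_bonn: class folder ", cl, " is empty")
    for (f in files) {
      lines <- readLines(f, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      vals <- suppressWarnings(as.numeric(lines))
      if (anyNA(vals)) {
        bad <- which(is.na(vals))[1L]
        stop("load_bonn: non-numeric value in ", f, " at line ", bad,
             ": '", lines[bad], "'")
      }
      segments[[length(segments) + 1L]] <-
        eeg_segment(vals, sampling_rate = sampling_rate, label = label,
                    source_id = sub("\\.[^.]*$", "", basename(f)))
    }
  }
  segments
}
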