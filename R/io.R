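#' Convert a session design to a long events table
#'
#' One row per audiovisual exposure trial and auditory post-test trial, in
#' the tab-separated events dialect: columns `onset`, `duration`,
#' `trial_type` (`"exposure"`/`"posttest"`), `block_index`, `run`,
#' `condition`, `exposure_text`, `sound_token` (`NA` for exposure trials).
#'
#' @param design a `session_design`.
#' @return Data frame sorted by onset.
#' @export
design_to_events <- function(design) {
  stopifnot(inherits(design, "session_design"))
  ex <- design$exposures
  pt <- design$posttests
  ev <- rbind(
    data.frame(onset = ex$onset, duration = ex$duration,
               trial_type = "exposure", block_index = ex$block,
               run = ex$run, condition = ex$condition,
               exposure_text = ex$exposure_text,
               sound_token = NA_integer_),
    data.frame(onset = pt$onset, duration = pt$duration,
               trial_type = "posttest", block_index = pt$block,
               run = pt$run, condition = pt$condition,
               exposure_text = pt$exposure_text,
               sound_token = pt$sound_token)
  )
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Write an events or trial table as tab-separated text
#'
#' Serializes a `session_design` (via [design_to_events()]), a
#' `trial_table`, or a plain events data frame to a TSV file with `n/a`
#' for missing values.
#'
#' @param x object to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(x, path) {
  if (inherits(x, "session_design")) x <- design_to_events(x)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "n/a")
  invisible(path)
}

#' Read a tab-separated events or trial table
#'
#' Parses the events dialect written by [write_events()]. The header must
#' contain `onset`; behavioral tables (`type = "behavior"`) must also
#' contain `response` and `subject`. Non-monotone onsets (within subject
#' when a `subject` column exists) raise a warning; row order is
#' preserved.
#'
#' @param path input file path.
#' @param type `"auto"` (behavioral when a `response` column is present),
#'   `"design"`, or `"behavior"`.
#' @return Data frame (class `trial_table` for behavioral tables).
#' @export
read_events <- function(path, type = c("auto", "design", "behavior")) {
  type <- match.arg(type)
  tab <- read.delim(path, sep = "\t", na.strings = "n/a",
                    stringsAsFactors = FALSE)
  if (!"onset" %in% names(tab)) {
    stop("parse error: required column missing: onset")
  }
  if (type == "behavior" || (type == "auto" && "response" %in% names(tab))) {
    for (col in c("response", "subject")) {
      if (!col %in% names(tab)) {
        stop("schema error: behavioral table lacks required column: ", col)
      }
    }
    class(tab) <- c("trial_table", "data.frame")
  } else if (type == "behavior") {
    stop("schema error: behavioral table lacks required column: response")
  }
  groups <- if ("subject" %in% names(tab)) split(tab$onset, tab$subject) else
    list(tab$onset)
  if (any(vapply(groups, function(o) any(diff(o) < 0), logical(1)))) {
    warning("onset column is non-monotone; row order preserved")
  }
  tab
}

#' Write a vertex map as a NIfTI volume
#'
#' The 2-D lattice is unrolled into a volume with a singleton third axis
#' (`nrow x ncol x 1`); values are stored as 32-bit float with the vertex
#' spacing as pixel dimension.
#'
#' @param values numeric vector over all vertices.
#' @param geometry an `roi_geometry`.
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_vertex_map <- function(values, geometry, path) {
  stopifnot(inherits(geometry, "roi_geometry"))
  if (length(values) != geometry$n_vertices) {
    stop("geometry error: values length does not match the grid")
  }
  arr <- array(values, dim = c(geometry$nrow, geometry$ncol, 1L))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(geometry$spacing_mm, geometry$spacing_mm, 1)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a vertex map from a NIfTI volume
#'
#' @param path input NIfTI path.
#' @param geometry the expected `roi_geometry`; a shape mismatch is a
#'   geometry error.
#' @return Numeric vector over vertices.
#' @export
read_vertex_map <- function(path, geometry) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) < 2 || d[1] != geometry$nrow || d[2] != geometry$ncol ||
      (length(d) >= 3 && prod(d[-(1:2)]) != 1)) {
    stop("geometry error: volume shape (", paste(d, collapse = "x"),
         ") does not match the ", geometry$nrow, "x", geometry$ncol,
         " grid")
  }
  as.vector(img)
}

#' Write a BOLD dataset as a 4-D NIfTI volume
#'
#' Stores the vertex x time matrix as `nrow x ncol x 1 x time` float data
#' with the TR in the temporal pixel dimension.
#'
#' @param data a `bold_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bold <- function(data, path) {
  stopifnot(inherits(data, "bold_dataset"))
  g <- data$geometry
  arr <- array(data$data, dim = c(g$nrow, g$ncol, 1L, ncol(data$data)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(g$spacing_mm, g$spacing_mm, 1, data$tr)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a BOLD volume back into a vertex x time matrix
#'
#' @param path input NIfTI path.
#' @param geometry the expected `roi_geometry`.
#' @return Vertex x time matrix with attribute `tr`.
#' @export
read_bold <- function(path, geometry) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4 || d[1] != geometry$nrow || d[2] != geometry$ncol ||
      d[3] != 1) {
    stop("geometry error: volume shape (", paste(d, collapse = "x"),
         ") does not match the ", geometry$nrow, "x", geometry$ncol,
         " grid")
  }
  m <- matrix(as.vector(img), nrow = geometry$n_vertices)
  attr(m, "tr") <- RNifti::pixdim(img)[4]
  m
}

#' Serialize a model fit as a delimited coefficient table
#'
#' @param fit a `model_fit`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_model_fit <- function(fit, path) {
  stopifnot(inherits(fit, "model_fit"))
  write.table(fit$coefficients, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
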