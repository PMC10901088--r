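# Leadfield containers, on-disk input/output, and the SVD-derived
# tangential/radial target coordinate frame.

#' Construct a leadfield object
#'
#' A leadfield is the channels-by-3 gain matrix mapping the three orthogonal
#' dipole components of a source at one fixed brain location to the sensor
#' array.  EEG-role leadfields must have full column rank 3 (EEG sees all
#' orientations); MEG-role leadfields need rank at least 2 (MEG is blind to
#' the near-radial direction, so its third singular value may vanish).
#'
#' @param matrix numeric matrix with one row per channel and exactly 3
#'   columns, in arbitrary but consistent gain units.
#' @param modality `"EEG"` or `"MEG"`; decides the rank requirement.
#' @param label free-text label (e.g. a target name); purely descriptive.
#' @return an object of class `leadfield` with fields `matrix`, `modality`,
#'   `n_channels` and `label`.
#' @examples
#' L <- leadfield(rbind(diag(3), diag(3)), "EEG")
#' L$n_channels
#' @export
leadfield <- function(matrix, modality = c("EEG", "MEG"), label = "unlabeled") {
  modality <- match.arg(modality)
  m <- base::as.matrix(matrix)
  storage.mode(m) <- "double"
  if (ncol(m) != 3L)
    stop("not a channels x 3 leadfield: got ", nrow(m), " x ", ncol(m))
  if (!all(is.finite(m)))
    stop("leadfield contains non-finite entries")
  min_ch <- if (modality == "EEG") 3L else 2L
  if (nrow(m) < min_ch)
    stop("leadfield has ", nrow(m), " channels; ", modality,
         " use requires at least ", min_ch)
  need_rank <- if (modality == "EEG") 3L else 2L
  if (matrix_rank(m) < need_rank)
    stop(modality, " leadfield must have rank >= ", need_rank)
  structure(
    list(matrix = m, modality = modality, n_channels = nrow(m), label = label),
    class = "leadfield"
  )
}

#' @export
print.leadfield <- function(x, ...) {
  s <- svd(x$matrix, nu = 0, nv = 0)$d
  cat(sprintf("<leadfield '%s'> %s, %d channels, singular values %s\n",
              x$label, x$modality, x$n_channels,
              paste(signif(s, 4), collapse = " ")))
  invisible(x)
}

#' Read a leadfield matrix from a file
#'
#' Reads a channels-by-3 gain matrix from delimited text (whitespace- or
#' comma-separated, `#` comment lines allowed, no header required) or from a
#' JSON array-of-rows file.  The matrix is taken exactly as stored, with no
#' rescaling; the file path is recorded in the label.
#'
#' @param path path to the file.
#' @param modality `"EEG"` or `"MEG"` (sets the rank requirement).
#' @param format_hint optional, one of `"text"` or `"json"`; when missing the
#'   format is auto-detected from the extension and content.
#' @return a [leadfield].
#' @seealso [write_leadfield()], [load_leadfield_manifest()]
#' @export
load_leadfield <- function(path, modality = c("EEG", "MEG"), format_hint = NULL) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("leadfield file not found: ", path)
  fmt <- format_hint
  if (is.null(fmt)) {
    ext <- tolower(tools::file_ext(path))
    fmt <- if (ext == "json") "json" else "text"
  }
  fmt <- match.arg(fmt, c("text", "json"))
  m <- switch(fmt,
    json = {
      v <- jsonlite::fromJSON(path)
      base::as.matrix(v)
    },
    text = read_delimited_matrix(path)
  )
  if (is.null(dim(m)) || ncol(m) != 3L)
    stop("not a channels x 3 leadfield: ", path)
  leadfield(m, modality = modality, label = path)
}

# Delimited text reader: '#' comments, whitespace or comma separated.
read_delimited_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("no data rows in ", path)
  sep <- if (grepl(",", lines[[1L]])) "," else ""
  m <- base::as.matrix(utils::read.table(text = lines, sep = sep,
                                         header = FALSE,
                                         colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' Write a leadfield to delimited text
#'
#' Full-precision (17 significant digits) whitespace-delimited text, one
#' channel per row, so that [load_leadfield()] round-trips the matrix
#' bit-exactly.
#'
#' @param lf a [leadfield] or bare numeric matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_leadfield <- function(lf, path) {
  m <- if (inherits(lf, "leadfield")) lf$matrix else base::as.matrix(lf)
  rows <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c("# channels x 3 leadfield", rows), path)
  invisible(path)
}

#' Read a target manifest naming the leadfield files of one target
#'
#' The manifest is a flat JSON object with fields `eeg` and `meg` (file
#' paths, resolved relative to the manifest's directory) and an optional
#' `label`.
#'
#' @param path path to the manifest JSON.
#' @return list with elements `eeg` and `meg` (both [leadfield]s) and
#'   `label`.
#' @export
load_leadfield_manifest <- function(path) {
  man <- jsonlite::fromJSON(path)
  if (is.null(man$eeg) || is.null(man$meg))
    stop("manifest must name 'eeg' and 'meg' leadfield paths")
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  label <- man$label %||% "manifest"
  list(
    eeg = load_leadfield(resolve(man$eeg), "EEG"),
    meg = load_leadfield(resolve(man$meg), "MEG"),
    label = label
  )
}

#' Derive the tangential/radial target coordinate frame from an MEG leadfield
#'
#' Computes the singular value decomposition `LM = U S V'` of the MEG target
#' leadfield.  The right singular vectors (`vt1`, `vt2`, `vr`) form the
#' target-specific coordinate system: `vt1`, `vt2` span the tangential plane
#' the MEG is sensitive to, and `vr` is the (near-)radial direction it is
#' blind to.  The reduced MEG leadfield restricted to the tangential plane is
#' `LMred = (s1 u1, s2 u2)`, i.e. column i equals `LM vt_i`.
#'
#' Singular values are sorted decreasingly and the sign of each right
#' singular vector is fixed so its largest-magnitude entry is positive (the
#' left vector is flipped jointly, preserving the decomposition).
#'
#' @param meg_leadfield a [leadfield] of rank at least 2 (the frame source).
#' @param source_leadfield_for_condition leadfield whose condition number
#'   (largest over smallest singular value) is recorded; defaults to
#'   `meg_leadfield`, pass the EEG leadfield to get the EEG condition number.
#' @return an object of class `target_frame` with fields `vt1`, `vt2`, `vr`,
#'   `singular_values`, `left_vectors` (channels x 3), `condition_number`,
#'   `reduced_meg` (channels x 2), `degenerate` (`TRUE` when s1 and s2
#'   coincide within relative 1e-12) and `label`.
#' @examples
#' L <- generate_synthetic_leadfield(12, c(3, 2, 1), seed = 1, modality = "MEG")
#' fr <- make_target_frame(L)
#' fr$singular_values
#' @export
make_target_frame <- function(meg_leadfield, source_leadfield_for_condition = meg_leadfield) {
  lf <- if (inherits(meg_leadfield, "leadfield")) meg_leadfield
        else leadfield(meg_leadfield, "MEG")
  m <- lf$matrix
  if (!all(is.finite(m))) stop("non-finite leadfield")
  sv <- svd(m, nu = 3L, nv = 3L)
  s <- sv$d                      # LAPACK returns decreasing order
  if (s[2L] <= max(dim(m)) * .Machine$double.eps * s[1L])
    stop("leadfield is rank-deficient below 2; no tangential plane")
  U <- sv$u
  V <- sv$v
  for (i in 1:3) {               # sign convention on the right vectors
    j <- which.max(abs(V[, i]))
    if (V[j, i] < 0) {
      V[, i] <- -V[, i]
      U[, i] <- -U[, i]
    }
  }
  cm <- if (inherits(source_leadfield_for_condition, "leadfield"))
    source_leadfield_for_condition$matrix else base::as.matrix(source_leadfield_for_condition)
  cs <- svd(cm, nu = 0, nv = 0)$d
  condition_number <- max(cs) / min(cs)
  degenerate <- (s[1L] - s[2L]) <= 1e-12 * s[1L]
  structure(
    list(
      vt1 = V[, 1L], vt2 = V[, 2L], vr = V[, 3L],
      singular_values = s,
      left_vectors = U,
      condition_number = condition_number,
      reduced_meg = cbind(s[1L] * U[, 1L], s[2L] * U[, 2L]),
      degenerate = degenerate,
      label = lf$label
    ),
    class = "target_frame"
  )
}

#' @export
print.target_frame <- function(x, ...) {
  cat(sprintf(
    "<target_frame '%s'> singular values %s, condition number %.4g%s\n",
    x$label, paste(signif(x$singular_values, 4), collapse = " "),
    x$condition_number, if (x$degenerate) " (degenerate s1 = s2)" else ""))
  invisible(x)
}

# Tangential (2-vector) and radial (scalar) coordinates of a 3-vector in a
# target frame.
tangential_component <- function(frame, v) {
  c(sum(frame$vt1 * v), sum(frame$vt2 * v))
}

radial_component <- function(frame, v) {
  sum(frame$vr * v)
}
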