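#' Skeletal dimension vocabulary
#'
#' The fixed, ordered vocabulary of the 13 skeletal dimensions used throughout
#' the package: skull, neck and tail length; humerus, ulna/radius and wing
#' metacarpal (metacarpal IV) length; the four wing-finger phalanges WP1--WP4;
#' femur and tibia length; and wingspan.  All are lengths in millimetres.
#'
#' @return Character vector of the 13 dimension names, in canonical order.
#' @export
#' @examples
#' dimension_vocabulary()
dimension_vocabulary <- function() {
  c("skull", "neck", "tail",
    "humerus", "ulna_radius", "mcIV",
    "wp1", "wp2", "wp3", "wp4",
    "femur", "tibia", "wingspan")
}

# The seven forelimb elements whose summed length defines wingspan.
FORELIMB_ELEMENTS <- c("humerus", "ulna_radius", "mcIV",
                       "wp1", "wp2", "wp3", "wp4")

# Wingspan = 2.1 x summed forelimb skeletal length.
WINGSPAN_FACTOR <- 2.1

#' Construct a specimen measurement table
#'
#' A specimen table holds one row per fossil specimen and one column per
#' skeletal dimension (in millimetres); cells may be `NA` where an element is
#' not preserved.  The taxon name is carried as metadata and never inferred
#' from a file name.
#'
#' @param specimen_id Character vector of unique specimen identifiers.
#' @param measurements Data frame (or matrix) of measurements in mm, columns
#'   named from [dimension_vocabulary()].  Missing cells are `NA`; present
#'   cells must be strictly positive (zero is not a valid length and is never
#'   used to mean "missing").
#' @param taxon Single taxon name carried as metadata.
#' @return An object of class `specimen_table`: a data frame with a
#'   `specimen_id` column followed by measurement columns in vocabulary order,
#'   and a `taxon` attribute.
#' @export
#' @examples
#' specimen_table(c("a", "b"),
#'                data.frame(humerus = c(30, NA), femur = c(25, 27)),
#'                taxon = "Demo")
specimen_table <- function(specimen_id, measurements, taxon) {
  stopifnot(is.character(taxon), length(taxon) == 1L)
  specimen_id <- as.character(specimen_id)
  if (anyDuplicated(specimen_id))
    stop("duplicate specimen_id: ",
         paste(unique(specimen_id[duplicated(specimen_id)]), collapse = ", "))
  measurements <- as.data.frame(measurements)
  vocab <- dimension_vocabulary()
  unknown <- setdiff(names(measurements), vocab)
  if (length(unknown))
    stop("unknown dimension column(s): ", paste(unknown, collapse = ", "),
         "; the vocabulary is: ", paste(vocab, collapse = ", "))
  if (nrow(measurements) != length(specimen_id))
    stop("measurements must have one row per specimen_id")
  for (nm in names(measurements)) {
    v <- measurements[[nm]]
    if (!is.numeric(v))
      stop("column '", nm, "' is not numeric")
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad))
      stop("non-positive measurement in column '", nm, "', row ", bad[1L])
  }
  # canonical column order
  keep <- vocab[vocab %in% names(measurements)]
  out <- cbind(data.frame(specimen_id = specimen_id,
                          stringsAsFactors = FALSE),
               measurements[keep])
  rownames(out) <- NULL
  structure(out, taxon = taxon, class = c("specimen_table", "data.frame"))
}

#' @export
print.specimen_table <- function(x, ...) {
  cat("Specimen table: ", attr(x, "taxon"), "\n", sep = "")
  meas <- as.matrix(x[, -1, drop = FALSE])
  cat(nrow(x), " specimens, ", ncol(meas), " dimensions, ",
      sum(is.na(meas)), " missing cells\n", sep = "")
  NextMethod()
  invisible(x)
}

#' Taxon name of a specimen table
#' @param x A `specimen_table`.
#' @return The taxon name (character scalar).
#' @export
taxon_name <- function(x) attr(x, "taxon")

#' Read a specimen measurement table from CSV
#'
#' Reads a UTF-8 CSV with a header row; one column must be `specimen_id`
#' (if absent, row numbers are used), the remaining columns must be drawn from
#' [dimension_vocabulary()].  Empty cells and the sentinel `NA` both mean
#' "element absent"; present cells must be positive decimal numbers
#' (millimetres, `.` decimal separator).
#'
#' @param file Path or connection to a CSV file.
#' @param taxon Taxon name to attach (metadata; never inferred from the file
#'   name).
#' @return A [specimen_table].
#' @seealso [write_specimen_table()]
#' @export
read_specimen_table <- function(file, taxon) {
  raw <- utils::read.csv(file, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if ("specimen_id" %in% names(raw)) {
    ids <- raw[["specimen_id"]]
    raw <- raw[setdiff(names(raw), "specimen_id")]
  } else {
    ids <- as.character(seq_len(nrow(raw)))
  }
  vocab <- dimension_vocabulary()
  unknown <- setdiff(names(raw), vocab)
  if (length(unknown))
    stop("unknown column(s) ", paste(unknown, collapse = ", "),
         " in ", deparse(substitute(file)),
         "; the vocabulary is: ", paste(vocab, collapse = ", "))
  meas <- raw
  for (nm in names(raw)) {
    v <- trimws(raw[[nm]])
    v[v %in% c("", "NA")] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop("cannot parse cell as number: row ", bad[1L], ", column '", nm, "'")
    bad <- which(!is.na(num) & num <= 0)
    if (length(bad))
      stop("non-positive measurement: row ", bad[1L], ", column '", nm, "'")
    meas[[nm]] <- num
  }
  specimen_table(ids, meas, taxon = taxon)
}

#' Write a specimen measurement table to CSV
#'
#' Columns are emitted in the fixed vocabulary order with missing cells left
#' empty, so that `read_specimen_table(write_specimen_table(x, f), taxon)`
#' round-trips the table.
#'
#' @param x A [specimen_table].
#' @param file Path to write to.
#' @return `file`, invisibly.
#' @export
write_specimen_table <- function(x, file) {
  stopifnot(inherits(x, "specimen_table"))
  utils::write.csv(x, file, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(file)
}

#' Wingspan from forelimb skeletal elements
#'
#' Wingspan is 2.1 times the combined length of humerus, ulna/radius,
#' metacarpal IV and wing phalanges 1--4.  All seven elements must be
#' present; under the combined-phalanx convention a single `wp34` entry may
#' stand in for `wp3` and `wp4`.
#'
#' @param measurements Named numeric vector or one-row data frame of
#'   measurements in mm.
#' @return Wingspan in millimetres.
#' @export
#' @examples
#' m <- c(humerus = 100, ulna_radius = 100, mcIV = 100,
#'        wp1 = 100, wp2 = 100, wp3 = 100, wp4 = 100)
#' compute_wingspan(m)  # 2.1 * 700 = 1470 mm
compute_wingspan <- function(measurements) {
  if (is.data.frame(measurements)) {
    stopifnot(nrow(measurements) == 1L)
    measurements <- unlist(measurements[intersect(names(measurements),
                                                  dimension_vocabulary())])
  }
  elements <- FORELIMB_ELEMENTS
  if ("wp34" %in% names(measurements) &&
      !all(c("wp3", "wp4") %in% names(measurements)))
    elements <- c("humerus", "ulna_radius", "mcIV", "wp1", "wp2", "wp34")
  v <- measurements[elements]
  if (anyNA(v) || length(v) != length(elements))
    stop("incomplete forelimb: missing ",
         paste(elements[is.na(v) | !(elements %in% names(measurements))],
               collapse = ", "))
  WINGSPAN_FACTOR * sum(v)
}

#' Wingspans of all complete specimens in a table
#'
#' Applies [compute_wingspan()] to every row with a complete forelimb;
#' incomplete rows yield `NA` (incomplete preservation prevents calculation of
#' wingspan).
#'
#' @param x A [specimen_table].
#' @param units `"mm"` (internal unit) or `"m"` (pipeline boundary unit).
#' @return Named numeric vector (one entry per specimen).
#' @export
table_wingspans <- function(x, units = c("mm", "m")) {
  units <- match.arg(units)
  stopifnot(inherits(x, "specimen_table"))
  have <- intersect(FORELIMB_ELEMENTS, names(x))
  out <- rep(NA_real_, nrow(x))
  if (length(have) == 7L) {
    m <- as.matrix(x[, FORELIMB_ELEMENTS])
    ok <- stats::complete.cases(m)
    out[ok] <- WINGSPAN_FACTOR * rowSums(m[ok, , drop = FALSE])
  }
  names(out) <- x$specimen_id
  if (units == "m") out / 1000 else out
}

#' Keep only specimens complete in the required dimensions
#'
#' @param x A [specimen_table].
#' @param required Character vector of dimension names that must be present
#'   (non-`NA`).  An empty set keeps the table unchanged.
#' @return The filtered [specimen_table]; row order is preserved and the
#'   operation is idempotent.
#' @export
filter_complete <- function(x, required = character()) {
  stopifnot(inherits(x, "specimen_table"))
  required <- as.character(required)
  unknown <- setdiff(required, dimension_vocabulary())
  if (length(unknown))
    stop("unknown dimension(s) in 'required': ",
         paste(unknown, collapse = ", "))
  if (!length(required)) return(x)
  missing_cols <- setdiff(required, names(x))
  keep <- if (length(missing_cols)) {
    rep(FALSE, nrow(x))            # a wholly absent column is absent in every row
  } else {
    stats::complete.cases(x[, required, drop = FALSE])
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, taxon = attr(x, "taxon"),
            class = c("specimen_table", "data.frame"))
}
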