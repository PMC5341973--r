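#' Screen dataset container
#'
#' A `screen_dataset` bundles the long-format well table of a viability
#' screen with per-culture annotations and the fixed-ratio combination
#' designs tested. One row of `wells` is one well: treatment compounds and
#' doses (uM), replicate index, raw fluorescence and a vehicle-control
#' flag. Single-drug wells carry the compound in `compound_a` with
#' `compound_b` empty and `dose_b_uM = 0`; control (DMSO) wells have both
#' doses zero and `is_control = TRUE`.
#'
#' @param wells data.frame with columns `culture_id, plate_id, well_id,
#'   compound_a, dose_a_uM, compound_b, dose_b_uM, replicate, raw_signal,
#'   is_control`.
#' @param cultures optional data.frame of annotations with columns
#'   `culture_id, subtype, age, sex, survival_days`; subtype is one of
#'   CL, MS, NL, PN or unknown.
#' @param designs optional named list of [combination_design()] objects.
#' @return An object of class `screen_dataset`.
#' @export
screen_dataset <- function(wells, cultures = NULL, designs = NULL) {
  wells <- validate_wells(wells)
  if (!is.null(cultures)) {
    stopifnot(is.data.frame(cultures), "culture_id" %in% names(cultures))
    missing_ann <- setdiff(unique(wells$culture_id[!wells$is_control]),
                           cultures$culture_id)
    if (length(missing_ann))
      stop("cultures without annotation: ",
           paste(missing_ann, collapse = ", "))
  }
  if (!is.null(designs)) {
    stopifnot(is.list(designs))
    for (d in designs) stopifnot(inherits(d, "combination_design"))
  }
  structure(list(wells = wells, cultures = cultures, designs = designs),
            class = "screen_dataset")
}

screen_columns <- c("culture_id", "plate_id", "well_id", "compound_a",
                    "dose_a_uM", "compound_b", "dose_b_uM", "replicate",
                    "raw_signal", "is_control")

validate_wells <- function(wells) {
  stopifnot(is.data.frame(wells))
  miss <- setdiff(screen_columns, names(wells))
  if (length(miss))
    stop("screen table is missing required column(s): ",
         paste(miss, collapse = ", "))
  wells <- wells[, screen_columns]
  for (col in c("compound_a", "compound_b")) {
    wells[[col]] <- as.character(wells[[col]])
    wells[[col]][is.na(wells[[col]])] <- ""
  }
  wells$is_control <- as.logical(wells$is_control)
  for (col in c("dose_a_uM", "dose_b_uM", "raw_signal")) {
    v <- wells[[col]]
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad))
      stop(sprintf("column '%s' must be finite and >= 0; first bad row: %d",
                   col, bad[1]))
  }
  ctl_bad <- which(wells$is_control &
                   (wells$dose_a_uM != 0 | wells$dose_b_uM != 0))
  if (length(ctl_bad))
    stop("control wells must have zero doses; first bad row: ", ctl_bad[1])
  key <- with(wells, paste(culture_id, plate_id, compound_a, dose_a_uM,
                           compound_b, dose_b_uM, replicate, is_control,
                           well_id, sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (culture, treatment, dose, replicate, well) key at row ",
         which(duplicated(key))[1])
  wells
}

#' Fixed-ratio combination design
#'
#' A combination is tested as a serial dilution in which the second
#' compound's dose is always `ratio` times the first (anchor) compound's
#' dose: at anchor dose `d_a` the pair is dosed at `(d_a, ratio * d_a)`.
#'
#' @param compound_a,compound_b compound names; `compound_a` is the anchor.
#' @param ratio dose of b per unit dose of a, strictly positive.
#' @param anchor_doses strictly increasing positive anchor doses (uM).
#' @return An object of class `combination_design`.
#' @export
combination_design <- function(compound_a, compound_b, ratio, anchor_doses) {
  stopifnot(nzchar(compound_a), nzchar(compound_b))
  if (!is.finite(ratio) || ratio <= 0) stop("ratio must be > 0")
  if (any(anchor_doses <= 0) || is.unsorted(anchor_doses, strictly = TRUE))
    stop("anchor_doses must be strictly increasing and > 0")
  structure(list(compound_a = compound_a, compound_b = compound_b,
                 ratio = ratio, anchor_doses = anchor_doses,
                 n_doses = length(anchor_doses)),
            class = "combination_design")
}

pair_label <- function(design)
  paste(design$compound_a, design$compound_b, sep = "+")

#' Read / write a screen well table
#'
#' Tables are plain CSV (or TSV) in the long layout documented in
#' [screen_dataset()]; row order is preserved and doses are read as uM.
#'
#' @param path file path; a `.tsv` extension selects tab separation.
#' @param cultures optional annotation data.frame or path to a CSV/TSV with
#'   culture annotations.
#' @param designs optional named list of [combination_design()]s.
#' @return `read_screen` returns a `screen_dataset`; `write_screen` writes
#'   `dataset$wells` and returns `path` invisibly.
#' @export
read_screen <- function(path, cultures = NULL, designs = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  wells <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             colClasses = NA, na.strings = c("NA"))
  if (is.character(cultures)) {
    csep <- if (grepl("\\.tsv$", cultures, ignore.case = TRUE)) "\t" else ","
    cultures <- utils::read.table(cultures, header = TRUE, sep = csep,
                                  stringsAsFactors = FALSE)
  }
  screen_dataset(wells, cultures = cultures, designs = designs)
}

#' @rdname read_screen
#' @param dataset a `screen_dataset`.
#' @export
write_screen <- function(dataset, path) {
  stopifnot(inherits(dataset, "screen_dataset"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(dataset$wells, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Normalize raw signals to viability ratios
#'
#' Computes the viability ratio `W = raw_signal / mean(control raw_signal)`
#' within each control scope. The screen normalizes against DMSO vehicle
#' wells on the same plate by default; per-culture pooling is available.
#' Control wells receive their own ratios, so the mean control ratio is
#' exactly 1 in every scope.
#'
#' @param dataset a [screen_dataset()].
#' @param control_scope `"plate"` (default) or `"culture"`.
#' @return The well table with an added numeric column `W`.
#' @export
normalize_viability <- function(dataset,
                                control_scope = c("plate", "culture")) {
  stopifnot(inherits(dataset, "screen_dataset"))
  control_scope <- match.arg(control_scope)
  wells <- dataset$wells
  scope <- if (control_scope == "plate") wells$plate_id else wells$culture_id
  w <- rep(NA_real_, nrow(wells))
  for (s in unique(scope)) {
    in_s <- scope == s
    ctl <- in_s & wells$is_control
    if (!any(ctl))
      stop(sprintf("no control wells in %s scope '%s'", control_scope, s))
    m <- mean(wells$raw_signal[ctl])
    if (m == 0) stop(sprintf("control mean is zero in scope '%s'", s))
    w[in_s] <- wells$raw_signal[in_s] / m
  }
  wells$W <- w
  wells
}
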