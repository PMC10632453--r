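#' Read a participant table
#'
#' Reads the package's CSV dialect: one record per participant with
#' required columns `participant_id`, `study_id`, `arm`, `age_years` and
#' one `cp_<month>` column per timepoint (nmol/L; `cp_0` = baseline at
#' treatment initiation), comma-delimited with a header, missing values
#' as empty cells. Rows violating the invariants (non-positive age,
#' negative C-peptide, missing baseline, unknown arm) are rejected with
#' row-numbered diagnostics rather than silently dropped; unknown extra
#' columns are kept and noted.
#'
#' @param path CSV file path.
#' @param quiet Suppress the diagnostic messages (default `FALSE`).
#' @return A validated participant data frame; rejected rows are attached
#'   as `attr(, "rejected")` (with a `reason` column).
#' @export
read_participants <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  required <- c("participant_id", "study_id", "arm", "age_years")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  cp_cols <- grep("^cp_", names(raw), value = TRUE)
  if (!"cp_0" %in% cp_cols)
    stop("missing required baseline column cp_0", call. = FALSE)
  extra <- setdiff(names(raw), c(required, cp_cols))
  if (length(extra) && !quiet)
    message("ignoring ", length(extra), " extra column(s): ",
            paste(extra, collapse = ", "))
  for (cc in c("age_years", cp_cols)) {
    bad <- !is.na(raw[[cc]]) & is.na(suppressWarnings(as.numeric(raw[[cc]])))
    if (any(bad))
      stop("non-numeric value in column ", cc, " at data row(s) ",
           paste(which(bad), collapse = ", "), call. = FALSE)
    raw[[cc]] <- as.numeric(raw[[cc]])
  }
  raw$arm <- tolower(trimws(raw$arm))
  reason <- rep(NA_character_, nrow(raw))
  flag <- function(cond, why) ifelse(cond & is.na(reason), why, reason)
  reason <- flag(is.na(raw$cp_0), "missing baseline cp_0")
  reason <- flag(!raw$arm %in% c("active", "control"),
                 "arm not active/control")
  reason <- flag(is.na(raw$age_years) | raw$age_years <= 0,
                 "non-positive or missing age")
  for (cc in cp_cols)
    reason <- flag(!is.na(raw[[cc]]) & raw[[cc]] < 0,
                   paste("negative", cc))
  ok <- is.na(reason)
  if (any(!ok) && !quiet)
    message("rejected ", sum(!ok), " row(s): ",
            paste(sprintf("row %d (%s)", which(!ok), reason[!ok]),
                  collapse = "; "))
  out <- raw[ok, , drop = FALSE]
  rownames(out) <- NULL
  rejected <- raw[!ok, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!ok]
  attr(out, "rejected") <- rejected
  out
}

#' Write a participant table
#'
#' Full-precision round-trip companion to [read_participants()]: numeric
#' columns are written with `format(digits = 17)` so that write-then-read
#' preserves every value bit-for-bit.
#'
#' @param data Participant data frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(data, path) {
  out <- data
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v)
    ifelse(is.na(v), "", format(v, digits = 17, trim = TRUE,
                                scientific = FALSE)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Path to the bundled published QR model file
#'
#' @return Path to the JSON file shipping the published model, loadable
#'   with [read_qr_model()].
#' @export
published_qr_model_path <- function() {
  system.file("extdata", "published_qr_model.json", package = "qrmetric",
              mustWork = TRUE)
}
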