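#' @keywords internal
"_PACKAGE"

# Controlled vocabularies used across the pipeline. Order matters: age groups
# and FOV categories are ordinal, and factor levels follow these vectors.
AGE_GROUPS <- c("4-6y", "7-11y", "12-14y", ">=15y")
FOV_CATEGORIES <- c("small", "medium", "large")
OPERATION_MODES <- c("standard", "HR")
INDICATIONS <- c(
  "endodontics", "orthodontic planning", "pedodontics", "implant placement",
  "surgical planning and follow-up", "second opinion radiodiagnosis",
  "medically compromised patient care"
)

#' Controlled vocabularies
#'
#' Accessors for the fixed vocabularies the pipeline classifies into: the four
#' age groups, the three field-of-view size categories, the two normalized
#' operation modes, and the seven clinical indications.
#'
#' @return A character vector, in classification order.
#' @export
age_groups <- function() AGE_GROUPS

#' @rdname age_groups
#' @export
fov_categories <- function() FOV_CATEGORIES

#' @rdname age_groups
#' @export
operation_modes <- function() OPERATION_MODES

#' @rdname age_groups
#' @export
clinical_indications <- function() INDICATIONS

#' Display rounding to 3 significant figures
#'
#' Dose and DAP values are carried at full precision internally; reports
#' display them at 3 significant figures. Values of 100 or more therefore
#' print with no decimals (300), values below 10 with two (4.66).
#'
#' @param x numeric vector.
#' @return Numeric vector rounded to 3 significant figures.
#' @export
display_3sf <- function(x) signif(x, 3)

# largest-remainder apportionment of n into counts proportional to p
largest_remainder <- function(n, p) {
  stopifnot(n >= 0, all(p >= 0), abs(sum(p) - 1) < 1e-8)
  raw <- round(n * p, 9)  # shield floor() from float error when n*p is integral
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    take <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[take] <- counts[take] + 1L
  }
  as.integer(counts)
}

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_numeric_col <- function(df, col, path, lines) {
  raw <- df[[col]]
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(val) & !is.na(raw) & trimws(raw) != "")
  if (length(bad) > 0) {
    stop_("unparseable numeric value '%s' in column '%s' of %s (line %d)",
          raw[bad[1]], col, path, lines[bad[1]])
  }
  val
}
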