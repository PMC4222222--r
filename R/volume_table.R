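#' Construct a per-subject volume table
#'
#' A volume table is the package's central data container: one row per
#' subject, an `icv` column (intracranial volume, cc), one numeric column
#' per named brain region (cc, `NA` allowed), and optional `sex`, `age`
#' and `group` annotations.  It is an ordinary `data.frame` carrying the
#' class `"volume_table"` and a `"regions"` attribute naming the region
#' columns, so all data-frame idioms keep working.
#'
#' @param subject_id character vector of unique subject labels.
#' @param icv numeric vector of intracranial volumes in cc; strictly
#'   positive and finite.
#' @param regions a data frame (or named list of numeric vectors) of
#'   regional volumes in cc; values must be `NA` or strictly positive
#'   and finite.
#' @param sex optional factor/character with levels `male`/`female`.
#' @param age optional numeric, years.
#' @param group optional character/factor of group labels.
#' @return A `volume_table` object.
#' @examples
#' vt <- volume_table(c("s1", "s2", "s3"), icv = c(1500, 1600, 1700),
#'                    regions = data.frame(caudate = c(3.2, 3.5, 3.6)))
#' region_names(vt)
#' @export
volume_table <- function(subject_id, icv, regions, sex = NULL, age = NULL,
                         group = NULL) {
  regions <- as.data.frame(regions, optional = TRUE)
  if (ncol(regions) < 1L)
    stop("at least one region column is required", call. = FALSE)
  df <- data.frame(subject_id = as.character(subject_id), icv = as.numeric(icv),
                   stringsAsFactors = FALSE)
  if (!is.null(sex)) df$sex <- as.character(sex)
  if (!is.null(age)) df$age <- as.numeric(age)
  if (!is.null(group)) df$group <- as.character(group)
  if (nrow(regions) != nrow(df))
    stop("regions must have one row per subject", call. = FALSE)
  df <- cbind(df, regions)
  attr(df, "regions") <- names(regions)
  class(df) <- c("volume_table", "data.frame")
  validate_volume_table(df)
}

#' Validate a volume table
#'
#' Checks the container invariants: unique subject ids, strictly positive
#' finite ICV, region volumes `NA` or strictly positive and finite, and at
#' least one region column.
#'
#' @param x a `volume_table` (or data frame with a `"regions"` attribute).
#' @return `x`, invisibly usable, after validation; errors otherwise.
#' @export
validate_volume_table <- function(x) {
  stopifnot(is.data.frame(x))
  regs <- attr(x, "regions")
  if (is.null(regs) || length(regs) == 0L)
    stop("volume table has no region columns", call. = FALSE)
  if (!all(regs %in% names(x)))
    stop("region attribute names columns absent from the table", call. = FALSE)
  if (anyDuplicated(x$subject_id))
    stop("duplicate subject ids: ",
         paste(unique(x$subject_id[duplicated(x$subject_id)]), collapse = ", "),
         call. = FALSE)
  if (!is.numeric(x$icv) || !all(is.finite(x$icv)) || any(x$icv <= 0))
    stop("icv values must all be finite and strictly positive", call. = FALSE)
  for (r in regs) {
    v <- x[[r]]
    if (!is.numeric(v))
      stop("region column '", r, "' is not numeric", call. = FALSE)
    bad <- !is.na(v) & (!is.finite(v) | v <= 0)
    if (any(bad))
      stop("region '", r, "' has nonpositive or non-finite volumes",
           call. = FALSE)
  }
  x
}

#' Region columns of a volume table
#' @param x a `volume_table`.
#' @return Character vector of region column names.
#' @export
region_names <- function(x) attr(x, "regions")

#' @export
print.volume_table <- function(x, ...) {
  regs <- region_names(x)
  cat(sprintf("Volume table: %d subjects, %d regions\n", nrow(x), length(regs)))
  cat("ICV (cc): ", sprintf("%.1f-%.1f (mean %.1f)\n",
      min(x$icv), max(x$icv), mean(x$icv)))
  cat("Regions:", paste(utils::head(regs, 8), collapse = ", "),
      if (length(regs) > 8) sprintf("... (%d more)", length(regs) - 8L) else "",
      "\n")
  NextMethod()
}

#' @export
`[.volume_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    regs <- intersect(attr(x, "regions"), names(out))
    if (all(c("subject_id", "icv") %in% names(out)) && length(regs)) {
      attr(out, "regions") <- regs
      class(out) <- c("volume_table", "data.frame")
    } else {
      class(out) <- "data.frame"
      attr(out, "regions") <- NULL
    }
  }
  out
}

# Paired, usable (finite positive) observations for one region.
region_pairs <- function(table, region) {
  v <- table[[region]]
  keep <- !is.na(v) & is.finite(v) & v > 0
  list(icv = table$icv[keep], voi = v[keep],
       subject_id = table$subject_id[keep], n = sum(keep))
}
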