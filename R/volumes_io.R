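#' Read a per-subject volume table from CSV or TSV
#'
#' Expects a header row with a subject-id column, an ICV column and at
#' least one region column.  Column matching is case-insensitive; the ICV
#' column may be called `icv`, `eTIV` or `EstimatedTotalIntraCranialVol`.
#' Rows whose ICV is missing, non-numeric or nonpositive are dropped and
#' reported; nonpositive region values are set to `NA` per region (regions
#' are fitted independently, so a bad value in one region does not cost
#' the subject's other regions).
#'
#' @param path path to a delimited text file.
#' @param sep field separator; `NULL` (default) infers `","` vs tab from
#'   the file extension (`.tsv`/`.txt` means tab).
#' @param unit `"cc"` (default) or `"mm3"`; with `"mm3"` all volumes,
#'   including ICV, are divided by 1000 on input.
#' @param id_col,icv_col column names; `NULL` means auto-detect.
#' @param region_cols names of the region columns; `NULL` (default) takes
#'   every numeric column that is not id/ICV/sex/age/group.
#' @param quiet suppress the row-rejection report.
#' @return A [volume_table()].
#' @export
read_volumes_table <- function(path, sep = NULL, unit = c("cc", "mm3"),
                               id_col = NULL, icv_col = NULL,
                               region_cols = NULL, quiet = FALSE) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  nm <- names(raw)
  pick <- function(candidates) {
    hit <- nm[tolower(nm) %in% tolower(candidates)]
    if (length(hit)) hit[1] else NULL
  }
  if (is.null(id_col))
    id_col <- pick(c("subject_id", "subject", "id", "sid"))
  if (is.null(id_col)) stop("no subject-id column found", call. = FALSE)
  if (is.null(icv_col))
    icv_col <- pick(c("icv", "etiv", "estimatedtotalintracranialvol",
                      "intracranialvol"))
  if (is.null(icv_col))
    stop("no ICV column found (looked for icv/eTIV/EstimatedTotalIntraCranialVol)",
         call. = FALSE)
  aux <- c(pick("sex"), pick("age"), pick("group"))
  if (is.null(region_cols)) {
    cand <- setdiff(nm, c(id_col, icv_col, aux))
    region_cols <- cand[vapply(raw[cand], is.numeric, logical(1))]
  }
  if (length(region_cols) < 1L)
    stop("no region columns found", call. = FALSE)

  scale <- if (unit == "mm3") 1e-3 else 1
  icv <- suppressWarnings(as.numeric(raw[[icv_col]])) * scale
  ok <- is.finite(icv) & icv > 0
  if (any(!ok) && !quiet)
    message(sum(!ok), " row(s) dropped for missing/nonpositive ICV: ",
            paste(utils::head(as.character(raw[[id_col]])[!ok], 5),
                  collapse = ", "))
  raw <- raw[ok, , drop = FALSE]
  icv <- icv[ok]
  if (nrow(raw) < 3L)
    stop("fewer than 3 usable rows; at least 3 subjects are required",
         call. = FALSE)
  regions <- as.data.frame(lapply(raw[region_cols], function(v) {
    v <- suppressWarnings(as.numeric(v)) * scale
    bad <- !is.na(v) & (!is.finite(v) | v <= 0)
    v[bad] <- NA_real_
    v
  }), optional = TRUE)
  nbad <- sum(vapply(region_cols, function(r) {
    v0 <- suppressWarnings(as.numeric(raw[[r]]))
    sum(!is.na(v0) & (!is.finite(v0) | v0 <= 0))
  }, numeric(1)))
  if (nbad > 0 && !quiet)
    message(nbad, " nonpositive region value(s) set to NA")
  names(regions) <- region_cols
  volume_table(subject_id = raw[[id_col]], icv = icv, regions = regions,
               sex = if (!is.null(pick("sex"))) raw[[pick("sex")]],
               age = if (!is.null(pick("age"))) raw[[pick("age")]],
               group = if (!is.null(pick("group"))) raw[[pick("group")]])
}

#' Write a volume table to CSV
#'
#' Full double precision is preserved (values are written with
#' `format(..., digits = 17)`), so read -> write -> read round trips
#' exactly.
#'
#' @param table a [volume_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volumes_table <- function(table, path) {
  validate_volume_table(table)
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one subject's volumes from a FreeSurfer stats file
#'
#' Parses the plain-text `aseg.stats` / `aparc.stats` dialect: comment
#' lines start with `#`, a `# ColHeaders` line names the columns of the
#' whitespace-delimited body, and ICV (when present) comes from the
#' `# Measure EstimatedTotalIntraCranialVol` header line.  Volumes are
#' taken from `Volume_mm3` (aseg) or `GrayVol` (aparc) and converted from
#' mm^3 to cc.
#'
#' Structure names are normalized to lower case with `-`/spaces replaced
#' by `_`.  With `hemi_sum = TRUE` (default) `Left-`/`Right-` (and
#' `lh_`/`rh_`) prefixes are stripped and hemispheric volumes for the same
#' structure are summed — including summation into a value that is already
#' present for that subject in `table` (e.g. the other hemisphere's aparc
#' file read earlier).  With `hemi_sum = FALSE` the prefixed names are kept
#' as distinct regions.
#'
#' @param path stats file path.
#' @param table an existing [volume_table()] to append to, or `NULL`.
#' @param subject_id label for the subject this file describes.
#' @param measure volume column to read; `NULL` picks `Volume_mm3` if
#'   present, else `GrayVol`.
#' @param hemi_sum sum left/right hemispheres into one region (default).
#' @return A `volume_table` including the new subject.  If `table` already
#'   carries this subject's ICV (e.g. from CSV) and the stats file lacks
#'   the ICV measure line, the existing ICV is kept and regions are merged.
#' @export
read_freesurfer_stats <- function(path, table = NULL, subject_id,
                                  measure = NULL, hemi_sum = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#\\s*ColHeaders", lines, value = TRUE)
  if (length(hdr) != 1L)
    stop("not a FreeSurfer stats file: no '# ColHeaders' line in ", path,
         call. = FALSE)
  cols <- strsplit(sub("^#\\s*ColHeaders\\s+", "", hdr), "\\s+")[[1]]
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(trimws(body), "\\s+")
  if (any(lengths(fields) != length(cols)))
    stop("stats body does not match ColHeaders in ", path, call. = FALSE)
  mat <- do.call(rbind, fields)
  colnames(mat) <- cols
  if (is.null(measure))
    measure <- if ("Volume_mm3" %in% cols) "Volume_mm3" else "GrayVol"
  if (!measure %in% cols)
    stop("measure column '", measure, "' absent from ", path, call. = FALSE)
  if (!"StructName" %in% cols)
    stop("no StructName column in ", path, call. = FALSE)

  vols_cc <- as.numeric(mat[, measure]) / 1000
  struct <- mat[, "StructName"]
  norm <- tolower(gsub("[- ]", "_", struct))
  if (hemi_sum)
    norm <- sub("^(left_|right_|lh_|rh_)", "", norm)
  vols <- tapply(vols_cc, norm, sum)          # sums hemispheres if collapsed

  icv_line <- grep("^#\\s*Measure\\s+EstimatedTotalIntraCranialVol",
                   lines, value = TRUE)
  icv_cc <- NA_real_
  if (length(icv_line)) {
    parts <- strsplit(icv_line[1], ",")[[1]]
    nums <- suppressWarnings(as.numeric(trimws(parts)))
    icv_cc <- nums[which(is.finite(nums))[1]] / 1000
  }

  new_regions <- as.list(vols)
  if (is.null(table)) {
    if (!is.finite(icv_cc))
      stop("stats file has no ICV measure and no table was supplied",
           call. = FALSE)
    return(volume_table(subject_id, icv_cc,
                        as.data.frame(new_regions, optional = TRUE)))
  }
  validate_volume_table(table)
  df <- as.data.frame(table)
  regs <- union(region_names(table), names(new_regions))
  i <- match(subject_id, df$subject_id)
  if (is.na(i)) {                              # new subject row
    if (!is.finite(icv_cc))
      stop("subject '", subject_id, "' not in table and stats file has no ICV",
           call. = FALSE)
    row <- df[NA_integer_, , drop = FALSE][1, , drop = FALSE]
    row$subject_id <- subject_id
    row$icv <- icv_cc
    df <- rbind(df, row)
    i <- nrow(df)
  } else if (is.finite(icv_cc)) {
    df$icv[i] <- icv_cc                        # stats-file ICV wins when given
  }                                            # else: keep table's ICV
  for (r in names(new_regions)) {
    if (!r %in% names(df)) df[[r]] <- NA_real_
    cur <- df[[r]][i]
    df[[r]][i] <- if (hemi_sum && !is.na(cur)) cur + new_regions[[r]]
                  else new_regions[[r]]
  }
  attr(df, "regions") <- regs
  class(df) <- c("volume_table", "data.frame")
  validate_volume_table(df)
}

#' Write a table of power-law fits to CSV
#'
#' One row per region with the display columns `beta`, `se`, `ci_lower`,
#' `ci_upper` rounded to 2 decimals (the conventional presentation for
#' scaling-exponent tables) and full-precision duplicates in `*_full`
#' columns.  Unconverged fits keep their row, flagged by `converged`.
#'
#' @param fits a `power_law_fits` collection from [fit_all_regions()], or
#'   a list of [fit_power_law()] results.
#' @param path output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_fit_table <- function(fits, path) {
  df <- as.data.frame(fits)
  if (nrow(df) < 1L) stop("no fits to write", call. = FALSE)
  out <- data.frame(
    region = df$region, n = df$n,
    beta = round(df$beta, 2), se = round(df$se, 2),
    ci_lower = round(df$ci_lower, 2), ci_upper = round(df$ci_upper, 2),
    nonproportional_flag = df$nonproportional,
    alpha = df$alpha, sigma2 = df$sigma2, converged = df$converged,
    beta_full = df$beta, se_full = df$se,
    ci_lower_full = df$ci_lower, ci_upper_full = df$ci_upper,
    stringsAsFactors = FALSE)
  num <- vapply(out, is.numeric, logical(1))
  fmt <- out
  fmt[num] <- lapply(which(num), function(j) {
    d <- if (names(out)[j] %in% c("beta", "se", "ci_lower", "ci_upper")) 2 else 17
    format(out[[j]], digits = d, nsmall = if (d == 2) 2 else 0,
           trim = TRUE, scientific = FALSE)
  })
  utils::write.table(fmt, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Write corrected volumes to CSV
#'
#' Long format: `subject_id, region, method, corrected_value, parameters`,
#' where `parameters` is a compact `key=value` provenance string
#' sufficient to reproduce the correction.
#'
#' @param corrected a `corrected_table` from [correct_volumes()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_corrected_table <- function(corrected, path) {
  stopifnot(inherits(corrected, "corrected_table"))
  df <- as.data.frame(corrected)
  pars <- attr(corrected, "parameters")
  df$parameters <- vapply(df$region, function(r) {
    p <- pars[[r]]
    vals <- vapply(p, function(z)
      if (is.numeric(z)) sprintf("%.10g", z) else as.character(z), character(1))
    paste(sprintf("%s=%s", names(p), vals), collapse = ";")
  }, character(1))
  df$corrected_value <- format(df$corrected_value, digits = 17, trim = TRUE,
                               scientific = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
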