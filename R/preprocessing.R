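# Deterministic assembly of one analysis row per subject from raw dated form
# records: choose the analysis biopsy (the one closest in time to a liver
# panel), attach the nearest biomarker measurement within one year (365
# days; farther records are treated as missing), collapse fibrosis
# sub-stages 1a/1b/1c to stage 1, drop the qualitative lesion-location
# field, and derive the AST/ALT and waist/hip ratios. Ties are broken toward
# the earlier record; date arithmetic is in whole days.

#' Collapse fibrosis sub-stages
#'
#' Maps raw fibrosis codes `0, 1a, 1b, 1c, 2, 3, 4` (plain `1` also
#' accepted) to the integer stage `0-4`; the three sub-stages of stage 1 are
#' summarized as 1. Order preserving and surjective onto `0:4`.
#'
#' @param raw character or numeric vector of raw fibrosis codes.
#' @return Integer vector of stages 0-4 (`NA` preserved).
#' @export
collapseFibrosis <- function(raw) {
  x <- trimws(as.character(raw))
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x)
  map <- c("0" = 0L, "1" = 1L, "1a" = 1L, "1b" = 1L, "1c" = 1L,
           "2" = 2L, "3" = 3L, "4" = 4L)
  bad <- ok & !(x %in% names(map))
  if (any(bad))
    stop(sprintf("unknown fibrosis code(s): %s",
                 paste(unique(x[bad]), collapse = ", ")))
  out[ok] <- map[x[ok]]
  out
}

#' Select the analysis biopsy per subject
#'
#' When a subject has several biopsies, the specimen with the smallest time
#' difference to the closest liver-panel measurement is chosen; equidistant
#' candidates resolve to the earlier biopsy. Subjects without any liver-panel
#' record fall back to their earliest biopsy (counted in the `fallback`
#' attribute). Subjects without a biopsy are absent from the result
#' (disregarded).
#'
#' @param biopsies data.frame with `subject_id`, `biopsy_date` and score
#'   columns.
#' @param liverPanel data.frame with `subject_id`, `panel_date`.
#' @return The selected biopsy rows, one per subject, ordered by subject id;
#'   attribute `fallback` lists subjects scored without a panel record.
#' @export
selectBiopsy <- function(biopsies, liverPanel) {
  biopsies <- as.data.frame(biopsies)
  biopsies$biopsy_date <- as.Date(biopsies$biopsy_date)
  lp <- as.data.frame(liverPanel)
  lp$panel_date <- as.Date(lp$panel_date)
  ids <- unique(as.character(biopsies$subject_id))
  fallback <- character(0)
  rows <- integer(0)
  for (id in ids) {
    bi <- which(as.character(biopsies$subject_id) == id)
    bdates <- biopsies$biopsy_date[bi]
    pdates <- lp$panel_date[as.character(lp$subject_id) == id]
    if (!length(pdates)) {
      fallback <- c(fallback, id)
      pick <- bi[order(bdates)[1L]]
    } else {
      dist <- vapply(bdates, function(d)
        min(abs(as.integer(d - pdates))), 0L)
      # smallest panel distance, ties toward the earlier biopsy
      ord <- order(dist, bdates)
      pick <- bi[ord[1L]]
    }
    rows <- c(rows, pick)
  }
  out <- biopsies[rows, , drop = FALSE]
  out <- out[order(as.character(out$subject_id)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fallback") <- fallback
  out
}

#' Attach the nearest biomarker values within the one-year window
#'
#' For each subject and biomarker, the measurement nearest in time to the
#' subject's analysis biopsy is used, provided the temporal distance does not
#' exceed the window (365 days); otherwise the value is missing. Equidistant
#' records resolve to the earlier one.
#'
#' @param chosen data.frame from [selectBiopsy()] (`subject_id`,
#'   `biopsy_date`).
#' @param biomarkers long data.frame with `subject_id`, `date`, `name`,
#'   `value`.
#' @param window window half-width in days.
#' @return Wide data.frame, one row per subject in `chosen`, one column per
#'   biomarker name (character values; `NA` when out of window or absent).
#' @export
attachBiomarkers <- function(chosen, biomarkers, window = 365L) {
  chosen <- as.data.frame(chosen)
  chosen$biopsy_date <- as.Date(chosen$biopsy_date)
  bm <- as.data.frame(biomarkers)
  bm$date <- as.Date(bm$date)
  ids <- as.character(chosen$subject_id)
  nms <- sort(unique(as.character(bm$name)))
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (nm in nms) out[[nm]] <- NA_character_
  bm <- bm[order(as.character(bm$subject_id), bm$date), , drop = FALSE]
  bySubj <- split(bm, as.character(bm$subject_id))
  for (i in seq_along(ids)) {
    sub <- bySubj[[ids[i]]]
    if (is.null(sub)) next
    bd <- chosen$biopsy_date[i]
    for (nm in unique(as.character(sub$name))) {
      rec <- sub[as.character(sub$name) == nm, , drop = FALSE]
      dist <- abs(as.integer(rec$date - bd))
      ord <- order(dist, rec$date)
      if (dist[ord[1L]] <= window)
        out[[nm]][i] <- as.character(rec$value[ord[1L]])
    }
  }
  out
}

#' Derive ratio covariates
#'
#' Adds `ast_alt` (AST/ALT) and `waist_hip` (waist/hip circumference) to a
#' covariate row set; a ratio is missing whenever either component is.
#'
#' @param row data.frame containing (any of) `ast`, `alt`,
#'   `waist_circumference`, `hip_circumference` as numeric columns.
#' @return The data.frame with the derived columns appended.
#' @export
deriveCovariates <- function(row) {
  row <- as.data.frame(row)
  if (all(c("ast", "alt") %in% names(row)))
    row$ast_alt <- as.numeric(row$ast) / as.numeric(row$alt)
  if (all(c("waist_circumference", "hip_circumference") %in% names(row)))
    row$waist_hip <- as.numeric(row$waist_circumference) /
      as.numeric(row$hip_circumference)
  row
}

#' Assemble analysis rows from raw records
#'
#' Full preprocessing pipeline: biopsy selection, item extraction with
#' fibrosis collapsing and removal of the lesion-location field, liver-panel
#' and biomarker attachment within the one-year window, type coercion, and
#' derivation of the ratio covariates. Deterministic and idempotent: the
#' output depends only on the record content, not on row order.
#'
#' @param biopsies data.frame of dated biopsy records (one row per biopsy)
#'   with the 13 item columns (fibrosis possibly as `1a/1b/1c`) and
#'   optionally `lesion_location`.
#' @param liverPanel data.frame with `subject_id`, `panel_date` and
#'   liver-panel value columns.
#' @param biomarkers long data.frame with `subject_id`, `date`, `name`,
#'   `value`.
#' @param window biomarker attachment window in days.
#' @param numericCovariates names of biomarkers to coerce to numeric;
#'   defaults to everything that parses as numeric throughout.
#' @return List with `responses` (integer matrix, subjects x 13) and
#'   `covariates` (data.frame), rows aligned, plus `fallback` subject ids.
#' @export
preprocessRecords <- function(biopsies, liverPanel, biomarkers,
                              window = 365L, numericCovariates = NULL) {
  chosen <- selectBiopsy(biopsies, liverPanel)
  itemNms <- itemCatalog()$name
  resp <- matrix(NA_integer_, nrow(chosen), length(itemNms),
                 dimnames = list(as.character(chosen$subject_id), itemNms))
  for (nm in itemNms) {
    if (!nm %in% names(chosen)) next
    resp[, nm] <- if (nm == "fibrosis") collapseFibrosis(chosen[[nm]])
                  else as.integer(as.character(chosen[[nm]]))
  }

  # liver-panel values attach by the same nearest-within-window rule
  lp <- as.data.frame(liverPanel)
  valueCols <- setdiff(names(lp), c("subject_id", "panel_date"))
  lpLong <- do.call(rbind, lapply(valueCols, function(v) {
    keep <- !is.na(lp[[v]])
    data.frame(subject_id = as.character(lp$subject_id[keep]),
               date = as.Date(lp$panel_date[keep]), name = v,
               value = as.character(lp[[v]][keep]), stringsAsFactors = FALSE)
  }))
  allRecords <- rbind(lpLong,
                      as.data.frame(biomarkers)[, c("subject_id", "date",
                                                    "name", "value")])
  covs <- attachBiomarkers(chosen, allRecords, window = window)
  covs$subject_id <- NULL
  rownames(covs) <- as.character(chosen$subject_id)

  if (is.null(numericCovariates)) {
    numericCovariates <- names(covs)[vapply(names(covs), function(nm) {
      v <- covs[[nm]][!is.na(covs[[nm]])]
      length(v) > 0L && !any(is.na(suppressWarnings(as.numeric(v))))
    }, TRUE)]
  }
  for (nm in intersect(numericCovariates, names(covs)))
    covs[[nm]] <- as.numeric(covs[[nm]])
  covs <- deriveCovariates(covs)
  list(responses = resp, covariates = covs,
       fallback = attr(chosen, "fallback"))
}
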