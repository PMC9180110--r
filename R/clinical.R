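#' Eye-mapped clinical correlations
#'
#' Correlates per-subject ROI diffusion measures with clinical covariates
#' under the anatomical eye mapping: prechiasmatic ROIs (optic nerve) pair
#' with the ipsilateral eye; ROIs within or posterior to the chiasm
#' (chiasm, optic tract), where fibres of both eyes mix, pair with eyes
#' grouped as first- or second-affected. For postchiasmatic ROIs the RNFL
#' covariate additionally uses the mean of the two contributing lateral
#' quadrants (right temporal plus left nasal for the right side, mirrored
#' on the left). Pearson's r with two-sided uncorrected p-values; entries
#' are flagged at the exploratory threshold p < 0.05.
#'
#' @param roi_values data.frame with columns `subject`, `roi` (one of
#'   `optic_nerve`, `optic_tract`, `chiasm`), `side` (`left`, `right`, or
#'   `NA` for the bilateral chiasm), `variable`, `value` — one row per
#'   subject/ROI/variable.
#' @param clinical data.frame as produced by [simulate_clinical()]:
#'   `subject`, `eye`, `va_logmar`, `rnfl_um`, `rnfl_temporal_um`,
#'   `rnfl_nasal_um`, `duration_days`, `affected_order`.
#' @param alpha exploratory flagging threshold (default 0.05, uncorrected).
#' @return a `correlation_table` data.frame: variable, roi, side,
#'   covariate, eye_mapping, n, r, p, flagged, reason.
#' @export
clinical_correlate <- function(roi_values, clinical, alpha = 0.05) {
  need <- c("subject", "roi", "side", "variable", "value")
  if (!all(need %in% names(roi_values)))
    stop("roi_values needs columns: ", paste(need, collapse = ", "))
  rows <- list()
  add <- function(variable, roi, side, covariate, mapping, value, covar) {
    ok <- is.finite(value) & is.finite(covar)
    n <- sum(ok)
    if (n < 3) {
      rows[[length(rows) + 1L]] <<- data.frame(
        variable = variable, roi = roi, side = side, covariate = covariate,
        eye_mapping = mapping, n = n, r = NA_real_, p = NA_real_,
        flagged = FALSE, reason = "insufficient pairs",
        stringsAsFactors = FALSE)
      return(invisible())
    }
    ct <- stats::cor.test(value[ok], covar[ok], method = "pearson")
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, roi = roi, side = side, covariate = covariate,
      eye_mapping = mapping, n = n, r = unname(ct$estimate),
      p = ct$p.value, flagged = ct$p.value < alpha, reason = "",
      stringsAsFactors = FALSE)
  }

  eye_tab <- function(eye) clinical[clinical$eye == eye, , drop = FALSE]
  order_tab <- function(ord)
    clinical[clinical$affected_order == ord, , drop = FALSE]
  # contributing lateral quadrants for a postchiasmatic side
  quadrant_rnfl <- function(side, subjects) {
    temporal_eye <- side                 # ipsilateral temporal quadrant
    nasal_eye <- setdiff(c("left", "right"), side)
    te <- eye_tab(temporal_eye); na <- eye_tab(nasal_eye)
    (te$rnfl_temporal_um[match(subjects, te$subject)] +
        na$rnfl_nasal_um[match(subjects, na$subject)]) / 2
  }

  combos <- unique(roi_values[, c("variable", "roi", "side")])
  for (i in seq_len(nrow(combos))) {
    v <- combos$variable[i]; roi <- combos$roi[i]; side <- combos$side[i]
    sel <- roi_values$variable == v & roi_values$roi == roi &
      (roi_values$side %in% side | (is.na(side) & is.na(roi_values$side)))
    vals <- roi_values[sel, , drop = FALSE]
    vals <- stats::aggregate(value ~ subject, data = vals, FUN = mean)
    subj <- vals$subject
    if (roi == "optic_nerve") {
      et <- eye_tab(side)
      m <- match(subj, et$subject)
      add(v, roi, side, "va_logmar", paste0("ipsilateral_", side),
          vals$value, et$va_logmar[m])
      add(v, roi, side, "rnfl_um", paste0("ipsilateral_", side),
          vals$value, et$rnfl_um[m])
      add(v, roi, side, "duration_days", paste0("ipsilateral_", side),
          vals$value, et$duration_days[m])
    } else {
      for (ord in c("first", "second")) {
        ot <- order_tab(ord)
        m <- match(subj, ot$subject)
        mapping <- paste0(ord, "_affected")
        add(v, roi, side, "va_logmar", mapping, vals$value, ot$va_logmar[m])
        add(v, roi, side, "rnfl_um", mapping, vals$value, ot$rnfl_um[m])
        add(v, roi, side, "duration_days", mapping, vals$value,
            ot$duration_days[m])
      }
      if (!is.na(side))
        add(v, roi, side, "rnfl_quadrants", paste0("quadrants_", side),
            vals$value, quadrant_rnfl(side, subj))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Write a correlation table as TSV
#' @param x a `correlation_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correlations <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
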