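#' @title Four-way confidence grouping of peptide identifications
#' @name classify
#' @description Crosses charge-dependent Sequest Xcorr acceptance (the
#'   Washburn criteria) with agreement between predicted and experimental
#'   retention times.  Each peptide-spectrum match lands in exactly one of
#'   four groups: CORRECT (both criteria met), INCORRECT (both failed),
#'   POTENTIAL_FALSE_POSITIVE (score accepted, retention time discordant)
#'   or POTENTIAL_FALSE_NEGATIVE (score rejected, retention time
#'   concordant).
NULL

CONFIDENCE_GROUPS <- c("CORRECT", "INCORRECT",
                       "POTENTIAL_FALSE_POSITIVE", "POTENTIAL_FALSE_NEGATIVE")

#' Classification thresholds
#'
#' Defaults follow the Washburn filtering criteria as stated in the source
#' study, with its wording fixing boundary strictness: Xcorr strictly
#' greater than 1.9 (charge 1+) and 2.2 (2+), at least 3.75 (3+); Delta-Cn
#' strictly above 0.08; and a retention-time agreement cutoff of |delta tR|
#' strictly below 5 minutes.
#'
#' @param xcorr_min_by_charge Named numeric vector of per-charge Xcorr
#'   thresholds (names "1", "2", "3").
#' @param delta_cn_min Minimum Delta-Cn (applied only when a record carries
#'   a Delta-Cn value).
#' @param delta_tr_max Retention-time cutoff in minutes.
#' @return An object of class `qsrr_thresholds`.
#' @export
classification_thresholds <- function(xcorr_min_by_charge = c("1" = 1.9,
                                                              "2" = 2.2,
                                                              "3" = 3.75),
                                      delta_cn_min = 0.08,
                                      delta_tr_max = 5.0) {
  if (!all(c("1", "2", "3") %in% names(xcorr_min_by_charge))) {
    stop("xcorr thresholds must be named for charges 1, 2 and 3",
         call. = FALSE)
  }
  if (any(xcorr_min_by_charge <= 0) || delta_cn_min <= 0 || delta_tr_max <= 0) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  structure(list(xcorr_min_by_charge = xcorr_min_by_charge,
                 delta_cn_min = delta_cn_min,
                 delta_tr_max = delta_tr_max),
            class = "qsrr_thresholds")
}

#' Does an identification pass the Xcorr (Washburn) criteria?
#'
#' Strict inequality for charges 1 and 2 ("higher than" / "over"),
#' greater-or-equal for charge 3 ("at least").  When `delta_cn` is supplied
#' it must additionally exceed `delta_cn_min`; the bundled tables do not
#' print Delta-Cn (the study states all spectra exceeded 0.08), so the
#' argument is optional.
#'
#' @param charge Charge state; must be 1, 2 or 3 (vectorised).
#' @param xcorr Sequest cross-correlation score (non-negative).
#' @param delta_cn Optional Delta-Cn score gap (NA = not recorded).
#' @param th A `qsrr_thresholds` object.
#' @return Logical vector.
#' @examples
#' xcorr_pass(2, 4.72)   # TRUE
#' xcorr_pass(3, 3.41)   # FALSE: below the 3.75 charge-3 threshold
#' xcorr_pass(1, 1.9)    # FALSE: boundary is strict for charge 1
#' @export
xcorr_pass <- function(charge, xcorr, delta_cn = NA_real_,
                       th = classification_thresholds()) {
  n <- max(length(charge), length(xcorr), length(delta_cn))
  charge <- rep_len(as.integer(charge), n)
  xcorr <- rep_len(xcorr, n)
  delta_cn <- rep_len(delta_cn, n)
  bad <- !charge %in% c(1L, 2L, 3L)
  if (any(bad)) {
    stop("unsupported charge state ",
         paste(unique(charge[bad]), collapse = ", "),
         " (thresholds defined for charges 1, 2, 3)", call. = FALSE)
  }
  if (any(is.finite(xcorr) & xcorr < 0)) {
    stop("xcorr must be non-negative", call. = FALSE)
  }
  cut <- th$xcorr_min_by_charge[as.character(charge)]
  score_ok <- ifelse(charge == 3L, xcorr >= cut, xcorr > cut)
  cn_ok <- is.na(delta_cn) | delta_cn > th$delta_cn_min
  unname(score_ok & cn_ok)
}

#' Classify one identification into a confidence group
#'
#' @param charge,xcorr,delta_cn Score inputs, see [xcorr_pass()].
#' @param delta_t_r Signed or absolute retention-time difference (min);
#'   compared by magnitude.
#' @param th A `qsrr_thresholds` object.
#' @return One of `"CORRECT"`, `"INCORRECT"`,
#'   `"POTENTIAL_FALSE_POSITIVE"`, `"POTENTIAL_FALSE_NEGATIVE"`
#'   (vectorised).
#' @examples
#' classify_record(2, 3.25, delta_t_r = 0.10)   # CORRECT
#' classify_record(1, 0.54, delta_t_r = 80.55)  # INCORRECT
#' classify_record(3, 6.97, delta_t_r = -10.05) # POTENTIAL_FALSE_POSITIVE
#' classify_record(1, 0.92, delta_t_r = 1.90)   # POTENTIAL_FALSE_NEGATIVE
#' @export
classify_record <- function(charge, xcorr, delta_cn = NA_real_, delta_t_r,
                            th = classification_thresholds()) {
  if (missing(delta_t_r) || any(!is.finite(delta_t_r))) {
    stop("delta_t_r is required for classification", call. = FALSE)
  }
  pass <- xcorr_pass(charge, xcorr, delta_cn, th)
  n <- max(length(pass), length(delta_t_r))
  pass <- rep_len(pass, n)
  rt_ok <- rep_len(abs(delta_t_r) < th$delta_tr_max, n)
  ifelse(pass,
         ifelse(rt_ok, "CORRECT", "POTENTIAL_FALSE_POSITIVE"),
         ifelse(rt_ok, "POTENTIAL_FALSE_NEGATIVE", "INCORRECT"))
}

#' Classify a peptide table
#'
#' Requires columns `charge`, `xcorr` and either `delta_t_r` or both
#' `t_r_exp` and `t_r_pred` (from which the difference is computed).  An
#' optional `delta_cn` column participates in the score criterion.
#'
#' @param tab Data frame of identification records.
#' @param th A `qsrr_thresholds` object.
#' @return The table with a `group` column (stage `"classified"`), plus an
#'   attribute `group_summary`: a data frame with one row per group giving
#'   `n`, `min_abs_delta` and `max_abs_delta`.  Input row order is
#'   preserved.
#' @export
classify_table <- function(tab, th = classification_thresholds()) {
  stopifnot(is.data.frame(tab))
  if (!"delta_t_r" %in% names(tab)) {
    if (!all(c("t_r_exp", "t_r_pred") %in% names(tab))) {
      stop("table needs delta_t_r, or t_r_exp and t_r_pred", call. = FALSE)
    }
    tab$delta_t_r <- tab$t_r_exp - tab$t_r_pred
  }
  need <- c("charge", "xcorr")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dcn <- if ("delta_cn" %in% names(tab)) tab$delta_cn else NA_real_
  if (nrow(tab) == 0L) {
    tab$group <- character(0)
  } else {
    tab$group <- tryCatch(
      classify_record(tab$charge, tab$xcorr, dcn, tab$delta_t_r, th),
      error = function(e) {
        stop("classification failed: ", conditionMessage(e), call. = FALSE)
      })
  }
  summ <- do.call(rbind, lapply(CONFIDENCE_GROUPS, function(g) {
    d <- abs(tab$delta_t_r[tab$group == g])
    data.frame(group = g, n = length(d),
               min_abs_delta = if (length(d)) min(d) else NA_real_,
               max_abs_delta = if (length(d)) max(d) else NA_real_)
  }))
  attr(tab, "group_summary") <- summ
  table_stage(tab) <- "classified"
  tab
}

#' Per-sample comparative report of confidence groups
#'
#' Tabulates group membership per sample and per protein label across one or
#' more classified tables.  The report states counts only; any biological
#' inference from differing group occupancy between samples is left to the
#' reader.
#'
#' @param ... Classified tables (from [classify_table()]), named by sample;
#'   alternatively a single named list of such tables.
#' @return A list of class `qsrr_strain_report` with elements `by_protein`
#'   (sample x protein label x group counts) and `by_group` (sample x group
#'   counts).
#' @export
strain_report <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) && !is.data.frame(tabs[[1]])) {
    tabs <- tabs[[1]]
  }
  if (length(tabs) == 0L) stop("need at least one sample", call. = FALSE)
  if (is.null(names(tabs)) || any(!nzchar(names(tabs)))) {
    names(tabs) <- paste0("sample", seq_along(tabs))
  }
  rows <- lapply(names(tabs), function(nm) {
    t <- tabs[[nm]]
    stopifnot("group" %in% names(t))
    lab <- if ("protein" %in% names(t)) t$protein else "(unlabelled)"
    data.frame(sample = nm, protein = lab, group = t$group,
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  long$group <- factor(long$group, levels = CONFIDENCE_GROUPS)
  by_protein <- as.data.frame(table(sample = long$sample,
                                    protein = long$protein,
                                    group = long$group),
                              responseName = "n")
  by_protein <- by_protein[by_protein$n > 0, ]
  by_protein <- by_protein[order(by_protein$sample, by_protein$protein), ]
  rownames(by_protein) <- NULL
  by_group <- as.data.frame(table(sample = long$sample, group = long$group),
                            responseName = "n")
  structure(list(by_protein = by_protein, by_group = by_group),
            class = "qsrr_strain_report")
}

#' @export
print.qsrr_strain_report <- function(x, ...) {
  cat("Confidence-group counts per sample:\n")
  wide <- stats::reshape(x$by_group, idvar = "sample", timevar = "group",
                         direction = "wide")
  names(wide) <- sub("^n\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Human-readable block report of a classified table
#'
#' Formats a classified table as four blocks (one per confidence group, in
#' canonical order), mirroring the block layout of the study's printed
#' identification tables.  Empty groups are reported as empty rather than
#' omitted.
#'
#' @param tab A classified table.
#' @param label Sample label printed in the header.
#' @return Character vector of report lines.
#' @export
classification_report <- function(tab, label = "sample") {
  stopifnot("group" %in% names(tab))
  lines <- sprintf("== %s: %d peptide identification(s) ==", label, nrow(tab))
  for (g in CONFIDENCE_GROUPS) {
    sub <- tab[tab$group == g, , drop = FALSE]
    if (nrow(sub) == 0L) {
      lines <- c(lines, sprintf("-- %s (none) --", g))
      next
    }
    rng <- range(abs(sub$delta_t_r))
    lines <- c(lines,
               sprintf("-- %s (n = %d, |delta tR| %.2f-%.2f min) --",
                       g, nrow(sub), rng[1], rng[2]),
               sprintf("%s\t%s\tz=%d\tXcorr=%.2f\tdeltaTR=%.2f",
                       if ("protein" %in% names(sub)) sub$protein else "",
                       sub$peptide_sequence, as.integer(sub$charge),
                       sub$xcorr, sub$delta_t_r))
  }
  lines
}
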