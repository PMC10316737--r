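#' Test-retest scenarios
#'
#' A scenario names the set of repeated measurements over which per-probe
#' stability is computed: a session (`NoStress`, `Stress`, or both for the
#' cross-session baseline comparison), an ordered set of timepoints, and the
#' nominal interval between first and last draw. All scenarios use two
#' timepoints except `NoStressT1-2-3-4`, which uses four; `CrossSessionT1`
#' pairs the first draw of each session, taken one week apart, and the two
#' sessions play the role of the two "timepoints".
#'
#' @param name Scenario name.
#' @param session `"NoStress"`, `"Stress"` or `"both"`.
#' @param timepoints Character vector of timepoint labels.
#' @param interval_minutes Nominal minutes between first and last draw.
#' @return Object of class `"scenario"` with fields `name`, `session`,
#'   `timepoints`, `nt` and `interval_minutes`.
#' @export
scenario <- function(name, session, timepoints, interval_minutes) {
  stopifnot(length(timepoints) >= 1,
            session %in% c("NoStress", "Stress", "both"))
  nt <- if (session == "both") 2L * length(timepoints) else length(timepoints)
  if (nt < 2) stop("a scenario needs at least two repeated measurements")
  structure(
    list(name = name, session = session,
         timepoints = as.character(timepoints), nt = nt,
         interval_minutes = interval_minutes),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario %s: session=%s, timepoints=%s, nt=%d, %g min>\n",
              x$name, x$session, paste(x$timepoints, collapse = ","),
              x$nt, x$interval_minutes))
  invisible(x)
}

#' Catalog of the ten standard test-retest scenarios
#'
#' Four two-timepoint scenarios per session (T1-2: 75 min, T1-3: 135 min,
#' T1-4: 285 min, T3-4: 150 min), the four-timepoint `NoStressT1-2-3-4`,
#' and `CrossSessionT1` (session baselines one week apart).
#'
#' @param names Optional subset of scenario names to return.
#' @return Named list of `scenario` objects.
#' @export
scenario_catalog <- function(names = NULL) {
  two_pt <- list(
    `T1-2` = list(tp = c("T1", "T2"), min = 75),
    `T1-3` = list(tp = c("T1", "T3"), min = 135),
    `T1-4` = list(tp = c("T1", "T4"), min = 285),
    `T3-4` = list(tp = c("T3", "T4"), min = 150)
  )
  out <- list()
  for (sess in c("NoStress", "Stress")) {
    for (nm in names(two_pt)) {
      sc <- scenario(paste0(sess, nm), sess, two_pt[[nm]]$tp, two_pt[[nm]]$min)
      out[[sc$name]] <- sc
    }
  }
  out[["NoStressT1-2-3-4"]] <-
    scenario("NoStressT1-2-3-4", "NoStress", c("T1", "T2", "T3", "T4"), 285)
  out[["CrossSessionT1"]] <- scenario("CrossSessionT1", "both", "T1", 10080)
  if (!is.null(names)) {
    miss <- setdiff(names, base::names(out))
    if (length(miss)) stop("unknown scenario(s): ", paste(miss, collapse = ", "))
    out <- out[names]
  }
  out
}

#' Select the samples belonging to a scenario
#'
#' @param sheet Sample sheet.
#' @param sc A `scenario` object (or catalog name).
#' @return The sample-sheet subset for the scenario, with an added `time`
#'   factor holding the repeated-measurement level (timepoint, or session for
#'   `CrossSessionT1`).
#' @export
scenario_samples <- function(sheet, sc) {
  if (is.character(sc)) sc <- scenario_catalog(sc)[[1]]
  keep <- sheet$timepoint %in% sc$timepoints
  if (sc$session != "both") keep <- keep & sheet$session == sc$session
  sub <- sheet[keep, , drop = FALSE]
  sub$time <- if (sc$session == "both") {
    factor(sub$session)
  } else {
    factor(sub$timepoint, levels = sc$timepoints)
  }
  sub
}
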