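## Packaged clinical fixture tables: per-patient stability and dosimetry
## values transcribed from the published tables of a cross-over
## premedication study (8 patients; 6 evaluable tumor lesions in 4
## patients), plus the printed summary statistics used for agreement
## flags. Ambiguities of the typeset source are noted in the CSV headers
## and carried through, never corrected.

fixturePath <- function(name)
  system.file("extdata", name, package = "LuDosim", mustWork = TRUE)

#' Load the packaged clinical fixture tables
#'
#' Returns the transcribed per-patient tables of the cross-over
#' premedication study: in-vivo stability (percent intact peptide at
#' 5/15/30/60 min p.i., both arms, with non-evaluable entries flagged)
#' and dosimetry (per-lesion tumor doses, per-patient organ doses in
#' Gy/GBq, and per-lesion tumor-to-organ dose ratios), plus the summary
#' statistics exactly as printed (for agreement checks).
#'
#' @return A list with data.frames \code{stability} (patient, arm,
#'   time_min, percent_intact, evaluable, note), \code{doses} (patient,
#'   lesion, arm, endpoint, value) and \code{printed} (table, endpoint,
#'   arm, time_min, statistic, printed).
#' @examples
#' fx <- clinicalFixtures()
#' subset(fx$doses, endpoint == "tumor_dose" & arm == "without")$value
#' @export
clinicalFixtures <- function() {
  stab <- utils::read.csv(fixturePath("stability_patients.csv"),
                          comment.char = "#", stringsAsFactors = FALSE)
  stab$evaluable <- as.logical(stab$evaluable)
  doses <- utils::read.csv(fixturePath("dose_patients.csv"),
                           comment.char = "#", stringsAsFactors = FALSE)
  printed <- utils::read.csv(fixturePath("printed_summaries.csv"),
                             comment.char = "#", stringsAsFactors = FALSE)
  list(stability = stab, doses = doses, printed = printed)
}

## wide (without, with) value matrix for one dose endpoint, paired by
## patient/lesion unit
pairedEndpoint <- function(doses, endpoint) {
  d <- doses[doses$endpoint == endpoint, ]
  unit <- paste(d$patient, d$lesion, sep = ":")
  units <- unique(unit)
  data.frame(
    unit = units,
    without = vapply(units, function(u)
      d$value[unit == u & d$arm == "without"][1], 0),
    with = vapply(units, function(u)
      d$value[unit == u & d$arm == "with"][1], 0),
    row.names = NULL)
}
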