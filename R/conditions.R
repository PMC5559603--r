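# Condition layout: untreated monocytes (baseline) plus three microbial
# ligands -- LPS (TLR4), 5'-ppp-dsRNA (RIG-I), MDP (NOD2) -- profiled at
# 90 min and 6 h after stimulation.

.conditions <- c("baseline", "LPS90", "LPS6h", "RNA90", "RNA6h", "MDP90", "MDP6h")
.treatments <- c("LPS", "RNA", "MDP")
.timepoints <- c("90", "6h")

#' Condition, treatment and time-point vocabulary
#'
#' The seven experimental conditions are the untreated baseline plus three
#' treatments (`LPS`, `RNA`, `MDP`) at two time points (`90` minutes, `6h`).
#'
#' @return `reqtl_conditions()` returns the seven condition names, baseline
#'   first; `reqtl_treatments()` the three treatment names;
#'   `reqtl_timepoints()` the two time-point labels.
#' @examples
#' reqtl_conditions()
#' @export
reqtl_conditions <- function() .conditions

#' @rdname reqtl_conditions
#' @export
reqtl_treatments <- function() .treatments

#' @rdname reqtl_conditions
#' @export
reqtl_timepoints <- function() .timepoints

#' @rdname reqtl_conditions
#' @export
stimulated_conditions <- function() .conditions[-1]

#' Decompose or build condition names
#'
#' @param condition Condition name(s), e.g. `"LPS90"`.
#' @param treatment,timepoint Treatment (`"LPS"`, `"RNA"`, `"MDP"`) and
#'   time point (`"90"`, `"6h"`).
#' @return `condition_treatment()` / `condition_timepoint()` return the
#'   treatment / time-point component (`NA` for baseline);
#'   `condition_name()` pastes the two together.
#' @export
condition_treatment <- function(condition) {
  out <- rep(NA_character_, length(condition))
  for (t in .treatments) out[startsWith(condition, t)] <- t
  out
}

#' @rdname condition_treatment
#' @export
condition_timepoint <- function(condition) {
  out <- rep(NA_character_, length(condition))
  out[endsWith(condition, "6h")] <- "6h"
  out[endsWith(condition, "90")] <- "90"
  out[condition == "baseline"] <- NA_character_
  out
}

#' @rdname condition_treatment
#' @export
condition_name <- function(treatment, timepoint) {
  stopifnot(treatment %in% .treatments, timepoint %in% .timepoints)
  paste0(treatment, timepoint)
}

.check_condition <- function(condition) {
  bad <- setdiff(condition, .conditions)
  if (length(bad))
    stop("unknown condition(s): ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(condition)
}
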