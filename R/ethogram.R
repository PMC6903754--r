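# Ethogram registry: the catalogue of codable behaviors and the state
# (category) each belongs to. The default instance is the 19-behavior
# ethogram used for dyadic mouse interactions: three aggressive and three
# subordinate behaviors (jointly "agonistic"), four investigative, three
# social, two repetitive, three activity behaviors, and idling.

.DT_STATES <- c("Aggressive", "Subordinate", "Investigative", "Social",
                "Repetitive", "Activity", "Inactivity")

#' Normalize a behavior label
#'
#' Labels are lower-cased and hyphens/spaces collapsed to underscores so
#' that CSV dialects ("Sniff-Head", "sniff head") map to one canonical
#' label.
#' @param x character vector of labels
#' @return character vector of canonical labels
#' @export
normalize_label <- function(x) {
  gsub("[ -]+", "_", tolower(trimws(as.character(x))))
}

#' Construct an ethogram
#'
#' @param behaviors character vector of behavior labels
#' @param states character vector (same length) of state labels, each one
#'   of Aggressive, Subordinate, Investigative, Social, Repetitive,
#'   Activity, Inactivity
#' @return named character vector (names = behaviors, values = states)
#'   with class `"ethogram"`
#' @export
ethogram <- function(behaviors, states) {
  behaviors <- normalize_label(behaviors)
  if (length(behaviors) != length(states)) {
    dt_error("behaviors and states must have equal length", "dt_format_error")
  }
  if (anyDuplicated(behaviors)) {
    dt_error("duplicate behavior labels in ethogram", "dt_format_error")
  }
  bad <- setdiff(unique(states), .DT_STATES)
  if (length(bad)) {
    dt_error(paste0("unknown state label(s): ", paste(bad, collapse = ", ")),
             "dt_format_error")
  }
  out <- stats::setNames(as.character(states), behaviors)
  class(out) <- "ethogram"
  out
}

#' The default 19-behavior ethogram
#'
#' Lunge, bite and tail rattle are Aggressive; flee, freeze and
#' subordinate posture are Subordinate; the four sniffing behaviors are
#' Investigative; pursue, allogroom and side-by-side contact are Social;
#' digging and self-grooming are Repetitive; active moving, rearing and
#' jumping are Activity; idle is Inactivity.
#' @return an [ethogram()] object
#' @export
default_ethogram <- function() {
  ethogram(
    behaviors = c("lunge", "bite", "tail_rattle",
                  "flee", "freeze", "subordinate_posture",
                  "sniff_head", "sniff_body", "sniff_anogenital", "sniff_follow",
                  "pursue", "allogroom", "side_by_side",
                  "digging", "self_grooming",
                  "active_moving", "rearing", "jumping",
                  "idle"),
    states = c(rep("Aggressive", 3), rep("Subordinate", 3),
               rep("Investigative", 4), rep("Social", 3),
               rep("Repetitive", 2), rep("Activity", 3),
               "Inactivity")
  )
}

#' Behaviors belonging to given states
#' @param eth an ethogram
#' @param states character vector of state labels
#' @return character vector of behavior labels
#' @export
behaviors_of_state <- function(eth, states) {
  names(eth)[unclass(eth) %in% states]
}

#' Agonistic behaviors (Aggressive plus Subordinate states)
#' @param eth an ethogram
#' @export
agonistic_behaviors <- function(eth) {
  behaviors_of_state(eth, c("Aggressive", "Subordinate"))
}

#' @export
print.ethogram <- function(x, ...) {
  cat("<ethogram> ", length(x), " behaviors\n", sep = "")
  for (s in intersect(.DT_STATES, unique(unclass(x)))) {
    cat("  ", s, ": ", paste(behaviors_of_state(x, s), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
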