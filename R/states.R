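#' Disease-state combinations
#'
#' A nuclear family in which one parent carries a dominant variant presents in
#' one of three mutually exclusive states: unaffected (`U`, no affected
#' member), sporadic (`S`, exactly one affected member), or familial (`F`, two
#' or more affected members). The affected state (`A`) pools sporadic and
#' familial. Penetrance estimation models a subset of these states; the subset
#' must be one of `{F,S}`, `{F,U}`, `{S,U}`, `{F,S,U}` or `{A,U}` — the
#' affected state cannot be combined with the familial or sporadic states
#' because it is defined as their union.
#'
#' @param states Character vector of state letters among `"F"`, `"S"`, `"U"`,
#'   `"A"` (any order; a single string such as `"FSU"` is also accepted).
#' @param rate_state The designated state `X` whose rate is modelled. Defaults
#'   to `"F"` when the familial state is modelled, otherwise `"S"` when
#'   sporadic is modelled, otherwise `"A"`: when familial data are absent the
#'   sporadic rate is the informative quantity.
#'
#' @return A character vector of class `"state_combination"` in canonical
#'   order (F, S, U, A) with a `rate_state` attribute.
#' @examples
#' state_combination(c("F", "S"))
#' state_combination("SU") # models the sporadic rate
#' @export
state_combination <- function(states, rate_state = NULL) {
  if (is.character(states) && length(states) == 1L && nchar(states) > 1L)
    states <- strsplit(states, "")[[1]]
  states <- toupper(as.character(states))
  bad <- setdiff(states, c("F", "S", "U", "A"))
  if (length(bad))
    stop("unknown disease state(s): ", paste(bad, collapse = ", "))
  states <- intersect(c("F", "S", "A", "U"), unique(states))
  valid <- list(c("F", "S"), c("F", "U"), c("S", "U"),
                c("F", "S", "U"), c("A", "U"))
  if (!any(vapply(valid, identical, logical(1), y = states)))
    stop("invalid state combination {", paste(states, collapse = ","),
         "}: must be one of {F,S}, {F,U}, {S,U}, {F,S,U}, {A,U}")
  if (is.null(rate_state)) {
    rate_state <- if ("F" %in% states) "F" else if ("S" %in% states) "S" else "A"
  } else {
    rate_state <- toupper(rate_state)
    if (!rate_state %in% states)
      stop("rate_state '", rate_state, "' is not among the modelled states")
  }
  structure(states, rate_state = rate_state, class = "state_combination")
}

#' @export
print.state_combination <- function(x, ...) {
  cat("States modelled: {", paste(unclass(x), collapse = ", "),
      "}; rate computed for state ", attr(x, "rate_state"), "\n", sep = "")
  invisible(x)
}

# Coerce character input to a validated combination, preserving an existing one.
as_state_combination <- function(states, rate_state = NULL) {
  if (inherits(states, "state_combination")) {
    if (!is.null(rate_state) && !identical(rate_state, attr(states, "rate_state")))
      return(state_combination(unclass(states), rate_state))
    return(states)
  }
  state_combination(states, rate_state)
}

rate_state_of <- function(combo) attr(combo, "rate_state")
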