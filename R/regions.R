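# Stable regions and interfaces over a collective variable plus an
# electronic-state membership set: the state-aware extension that makes
# forward flux sampling applicable to nonadiabatic dynamics.

cv_weights <- function(cv) {
  if (is.numeric(cv)) {
    stopifnot(length(cv) == 3L)
    return(as.numeric(cv))
  }
  switch(cv,
         "x"   = c(1, 0, 0),
         "y"   = c(0, 1, 0),
         "z"   = c(0, 0, 1),
         "x-y" = c(1, -1, 0),
         abort(paste0("unknown collective variable `", cv,
                      "`; use \"x\", \"y\", \"z\", \"x-y\" or a weight 3-vector")))
}

#' Define a stable region over a collective variable and electronic states
#'
#' A snapshot belongs to the region when its collective variable (a linear
#' combination of the Cartesian coordinates) satisfies the comparator and
#' its active adiabatic state is in `states`.  Electronic-state membership
#' is what distinguishes these regions from ordinary ground-state forward
#' flux sampling regions.
#'
#' @param cv `"x"`, `"x-y"`, ... or a numeric weight 3-vector.
#' @param op `"<"`, `"<="`, `">"`, or `">="`.
#' @param threshold Collective-variable threshold.
#' @param states Integer vector of allowed adiabatic states (1-based).
#' @return A `fh_region` object.
#' @export
#' @examples
#' A <- region_spec("x", "<", -0.5, states = 1)
#' B <- region_spec("x", ">",  0.5, states = 1)
region_spec <- function(cv, op, threshold, states = 1L) {
  stopifnot(op %in% c("<", "<=", ">", ">="), is.numeric(threshold),
            all(states >= 1))
  structure(list(w = cv_weights(cv), cv = cv,
                 dir = if (op %in% c("<", "<=")) -1L else 1L,
                 level = threshold, op = op,
                 states = as.integer(states)),
            class = "fh_region")
}

#' @export
print.fh_region <- function(x, ...) {
  cvlab <- if (is.character(x$cv)) x$cv else paste(x$w, collapse = ",")
  cat("<fh_region> ", cvlab, " ", x$op, " ", x$level,
      "  states {", paste(x$states, collapse = ","), "}\n", sep = "")
  invisible(x)
}

state_mask <- function(states) sum(2L^(unique(as.integer(states)) - 1L))

region_event <- function(region, type, every = 1L) {
  c(region$w, region$level, region$dir, state_mask(region$states),
    type, every)
}

cv_of <- function(w, snapshots) {
  w[1] * snapshots$x + w[2] * snapshots$y + w[3] * snapshots$z
}

#' Region membership of trajectory snapshots
#'
#' @param region A `fh_region`.
#' @param snapshots Data frame with columns x, y, z, active_state.
#' @return Logical vector.
#' @export
region_contains <- function(region, snapshots) {
  cv <- cv_of(region$w, snapshots)
  side <- region$dir * (cv - region$level) >= 0
  side & snapshots$active_state %in% region$states
}

#' Define an ordered set of interfaces between two regions
#'
#' Interface levels must run monotonically from the boundary of A
#' (`levels[1]`, identified with lambda_0) to the boundary of B (the last
#' level, lambda_{n+1}).  `direction` is +1 when the collective variable
#' increases from A to B and -1 when it decreases.  Each interface carries a
#' set of allowed electronic states; a crossing only counts when the
#' post-crossing snapshot's active state is allowed.
#'
#' @param cv Collective variable (as in [region_spec()]).
#' @param levels Numeric vector of interface positions, A-boundary first.
#' @param direction +1 or -1; inferred from `levels` when omitted.
#' @param states Allowed states: a vector applied to every interface, or a
#'   list with one vector per interface.
#' @return A `fh_interfaces` object.
#' @export
#' @examples
#' interface_set("x", c(-0.5, -0.3, -0.1, 0.1, 0.3, 0.5), states = c(1, 2))
interface_set <- function(cv, levels, direction = NULL, states = NULL) {
  stopifnot(length(levels) >= 2L)
  d <- diff(levels)
  if (all(d > 0)) inferred <- 1L
  else if (all(d < 0)) inferred <- -1L
  else abort("interface levels must be strictly monotone from A to B")
  direction <- direction %||% inferred
  if (direction != inferred)
    abort("`direction` contradicts the ordering of `levels`")
  n <- length(levels)
  if (is.null(states)) states <- list(1L)[rep(1, n)]
  if (!is.list(states)) states <- rep(list(as.integer(states)), n)
  if (length(states) != n)
    abort("`states` must have one entry per interface")
  structure(list(w = cv_weights(cv), cv = cv, levels = levels,
                 direction = as.integer(direction), states = states),
            class = "fh_interfaces")
}

#' @export
print.fh_interfaces <- function(x, ...) {
  cat("<fh_interfaces> ", length(x$levels), " levels on ",
      if (is.character(x$cv)) x$cv else "custom cv",
      " (", if (x$direction > 0) "increasing" else "decreasing",
      " toward B)\n", sep = "")
  cat("  ", paste(signif(x$levels, 4), collapse = " -> "), "\n", sep = "")
  invisible(x)
}

interface_event <- function(interfaces, i, type) {
  c(interfaces$w, interfaces$levels[i], interfaces$direction,
    state_mask(interfaces$states[[i]]), type, 1L)
}

#' Detect outward interface crossings between consecutive snapshots
#'
#' A crossing is counted when the collective variable moves from the A-side
#' to the B-side of the interface level between two consecutive snapshots
#' and the later snapshot's active state is in the interface's allowed set.
#' Detection is discrete (no interpolation of the crossing time), matching
#' the step-based counting of the flux estimators.
#'
#' @param snapshots Data frame of consecutive snapshots (columns x, y, z,
#'   active_state).
#' @param interfaces A `fh_interfaces` object.
#' @param index Which interface to test (default 1, the A boundary).
#' @return Logical vector, one entry per snapshot pair (length nrow - 1).
#' @export
crossing_detect <- function(snapshots, interfaces, index = 1L) {
  cv <- cv_of(interfaces$w, snapshots)
  lev <- interfaces$levels[index]
  dir <- interfaces$direction
  n <- length(cv)
  if (n < 2L) return(logical(0))
  was <- dir * (cv[-n] - lev) < 0
  now <- dir * (cv[-1] - lev) >= 0
  ok <- snapshots$active_state[-1] %in% interfaces$states[[index]]
  was & now & ok
}
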