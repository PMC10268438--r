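#' @title One-to-one time reallocations
#' @name reallocation
#' @description
#' The geometric substrate of the isotemporal-substitution model:
#' transferring a fixed number of minutes from one behaviour to another
#' while all remaining behaviours (and the 24-h total) stay fixed.
NULL

#' Reallocate time between two behaviours
#'
#' Decreases `from` and increases `to` by exactly `minutes`/60 hours;
#' other parts and the total are untouched (no re-closure is needed, the
#' transfer is exact by construction). A reallocation that exhausts or
#' exceeds the source part is an error, not a clamp.
#'
#' @param base named composition in hours (e.g. the cohort's mean baseline
#'   composition).
#' @param from,to distinct part names.
#' @param minutes duration to transfer, minutes/day, in (0, 1440).
#' @return composition with the same names, same total.
#' @export
reallocate <- function(base, from, to, minutes) {
  base <- as.numeric_parts(base)
  if (is.null(names(base))) stop("base composition must be named")
  if (!from %in% names(base) || !to %in% names(base))
    stop("unknown part in reallocation")
  if (from == to) stop("from and to must differ")
  if (!is.finite(minutes) || minutes <= 0 || minutes >= 1440)
    stop("minutes must be in (0, 1440)")
  h <- minutes / 60
  if (base[[from]] <= h)
    stop(sprintf("reallocating %g min exhausts '%s' (%.3g h available)",
                 minutes, from, base[[from]]))
  base[from] <- base[[from]] - h
  base[to] <- base[[to]] + h
  base
}

#' Grid of reallocated compositions
#'
#' All ordered behaviour pairs crossed with each duration, starting from
#' `base`. Combinations that would exhaust the source part are skipped
#' with a warning (never clamped, which would silently change the
#' estimand).
#'
#' @param base named composition in hours.
#' @param durations vector of reallocation durations in minutes/day
#'   (default `c(10, 30, 60)`).
#' @return data.frame with columns `from`, `to`, `minutes` and one column
#'   per part holding the reallocated composition.
#' @export
substitution_grid <- function(base, durations = c(10, 30, 60)) {
  base <- as.numeric_parts(base)
  parts <- names(base)
  rows <- list()
  for (m in durations) {
    for (from in parts) for (to in setdiff(parts, from)) {
      if (base[[from]] <= m / 60) {
        warning(sprintf("skipping infeasible reallocation %s -> %s, %g min",
                        from, to, m), call. = FALSE)
        next
      }
      comp <- reallocate(base, from, to, m)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(from = from, to = to, minutes = m),
        as.data.frame(as.list(comp))
      )
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}
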