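#' Bench grid of endotracheal tube and bronchoscope combinations
#'
#' The tube-bronchoscope combinations characterised on the bench: cuffed
#' endotracheal tubes of 6.0-9.0 mm inner diameter in 0.5 mm increments,
#' combined with single-use bronchoscopes in three sizes (measured shaft
#' diameters 3.8, 5.0 and 5.9 mm). Combinations whose remaining lumen was too
#' narrow to be used (6.5 mm tube + large scope; 6.0 mm tube + medium or
#' large scope) are omitted. `d_eff_printed` is the published effective
#' diameter rounded to one decimal; note that the printed medium-scope values
#' sit 0.05-0.06 mm above `sqrt(d_tube^2 - 5.0^2)`, consistent with a shaft
#' closer to 4.9 mm for that instrument.
#'
#' @param scoped_only If `TRUE` (default) return only combinations with a
#'   bronchoscope inserted; if `FALSE`, also include the seven unobstructed
#'   tubes.
#' @return A data.frame with columns `d_tube` (mm), `d_scope` (mm, `NA` when
#'   unobstructed), `scope_size` (`"none"`, `"small"`, `"medium"`,
#'   `"large"`), `d_eff` (mm, from [effective_diameter()]) and
#'   `d_eff_printed` (mm, one decimal).
#' @export
ett_scope_combinations <- function(scoped_only = TRUE) {
  tubes <- seq(6.0, 9.0, by = 0.5)
  scopes <- c(small = 3.8, medium = 5.0, large = 5.9)
  printed <- rbind(  # rows: ETT 6.0 .. 9.0; cols: small, medium, large
    c(4.6,  NA,  NA),
    c(5.3, 4.3,  NA),
    c(5.9, 5.0, 3.8),
    c(6.5, 5.7, 4.6),
    c(7.0, 6.3, 5.4),
    c(7.6, 6.9, 6.1),
    c(8.2, 7.5, 6.8))
  rows <- list()
  if (!scoped_only) {
    rows[[1L]] <- data.frame(d_tube = tubes, d_scope = NA_real_,
                             scope_size = "none", d_eff = tubes,
                             d_eff_printed = tubes)
  }
  for (j in seq_along(scopes)) {
    keep <- !is.na(printed[, j])
    dt <- tubes[keep]
    rows[[length(rows) + 1L]] <- data.frame(
      d_tube = dt,
      d_scope = scopes[[j]],
      scope_size = names(scopes)[j],
      d_eff = vapply(dt, effective_diameter, numeric(1), d_scope = scopes[[j]]),
      d_eff_printed = printed[keep, j])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
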