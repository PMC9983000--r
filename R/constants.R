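# Physical constants (CODATA 2018, exact by SI redefinition for e).
# All internal computation is SI; m/z crosses interfaces in thomson
# (Da per elementary charge).
.e_charge <- 1.602176634e-19   # elementary charge, C
.u_mass   <- 1.66053906660e-27 # unified atomic mass, kg

#' Physical constants used by the simulator
#'
#' Returns the pinned values of the elementary charge and the unified atomic
#' mass constant used throughout the package, so that downstream code can
#' reproduce any internal conversion exactly.
#'
#' @return Named list with `e` (C) and `u` (kg).
#' @export
#' @examples
#' ms_constants()$e
ms_constants <- function() {
  list(e = .e_charge, u = .u_mass)
}
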