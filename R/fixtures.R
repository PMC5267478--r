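#' Shipped dynamical fixtures
#'
#' Reference parameter vectors frozen into the package after a seeded
#' randomized search (see [make_fixtures()]) and validation against both
#' the circuit-breaking and the multi-start Newton steady-state routes:
#' \describe{
#'   \item{`bistable`}{bistable at rest; a transient input can switch the
#'     system permanently to the upper ppERK state.}
#'   \item{`quasi_bistable`}{monostable at rest with a saddle-node
#'     bifurcation at small positive input; its NGF trajectory lingers
#'     near the vanished upper state long after the signal has decayed.}
#'   \item{`monostable`}{fast-relaxing response that tracks the input
#'     (trajectory class 3).}
#' }
#'
#' @param name fixture name.
#' @return An [mapk_params] vector.
#' @examples
#' theta_b <- mapk_fixture("bistable")
#' find_steady_states(theta_b, u = 0)$classification
#' @export
mapk_fixture <- function(name = c("quasi_bistable", "bistable",
                                  "monostable")) {
  name <- match.arg(name)
  path <- system.file("extdata", "fixtures.json", package = "mapkqb",
                      mustWork = TRUE)
  fx <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(fx[[name]]))
    stop("fixture '", name, "' not found in ", path)
  mapk_params(unlist(fx[[name]]$params))
}

#' Provenance metadata of the shipped fixtures
#'
#' @return list with the search seed, search size, and per-fixture
#'   validation summaries recorded when the fixtures were frozen.
#' @export
mapk_fixture_metadata <- function() {
  path <- system.file("extdata", "fixtures.json", package = "mapkqb",
                      mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
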