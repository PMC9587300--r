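# Bundled letter-shaped waypoint plans for navigation experiments.

#' Bundled letter waypoint plans
#'
#' Returns one of the shipped schematic letter plans ("A", "R", "S", "M",
#' "U"): an ordered polyline of target points of roughly 50 um extent, as
#' used in the user-defined trajectory experiments.
#'
#' @param label letter label.
#' @return a [waypoint_plan()].
#' @export
#' @examples
#' plan <- make_waypoint_plan("A")
#' nrow(plan$points)
make_waypoint_plan <- function(label) {
  path <- system.file("extdata", "waypoint_plans.json",
                      package = "mucoswim", mustWork = TRUE)
  plans <- jsonlite::read_json(path, simplifyVector = TRUE)$plans
  if (!label %in% names(plans)) {
    stop("unknown waypoint plan '", label, "'; bundled plans: ",
         paste(names(plans), collapse = ", "))
  }
  waypoint_plan(plans[[label]], label = label)
}

#' Names of the bundled waypoint plans
#'
#' @return character vector of plan labels.
#' @export
waypoint_plan_labels <- function() {
  path <- system.file("extdata", "waypoint_plans.json",
                      package = "mucoswim", mustWork = TRUE)
  names(jsonlite::read_json(path)$plans)
}

#' Read a waypoint plan from JSON
#'
#' Expects a JSON object with a `points` array of `[x_um, y_um]` pairs and
#' an optional `label`.
#'
#' @param path JSON file path.
#' @return a [waypoint_plan()].
#' @export
read_waypoint_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  waypoint_plan(obj$points, label = obj$label %||% "")
}

#' Write a waypoint plan to JSON
#'
#' @param plan a [waypoint_plan()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_waypoint_plan <- function(plan, path) {
  stopifnot(inherits(plan, "waypoint_plan"))
  jsonlite::write_json(
    list(label = plan$label,
         points = unname(split(plan$points, row(plan$points)[, 1]))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
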