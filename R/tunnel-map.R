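#' Built-in catalytic-tunnel region map
#'
#' Returns the curated partition of the lyase catalytic tunnel into named
#' surfaces (roof/floor/wall segments `R1`, `R2`, `oLW`, `iLW`, `F1`,
#' `F2`, `oRW`, `iRW` at the entry face; rings `i` and `ii` at the exit
#' face) and the three substrate-interacting site sets (entry: 6
#' residues, tunnel: 7, exit: 11, totalling the 24 substrate-interacting
#' residues) plus the catalytic set. The map is shipped as YAML data
#' under `inst/extdata/` so a disagreement can be fixed by configuration
#' rather than code.
#'
#' @return A `region_map` object: list with `surfaces` (named list of
#'   residue-id vectors), `sites` (entry/tunnel/exit/catalytic) and
#'   `interacting24` (ordered union of entry, tunnel and exit sets).
#' @examples
#' rm <- default_region_map()
#' length(rm$interacting24)
#' @export
default_region_map <- function() {
  path <- system.file("extdata", "tunnel_regions.yaml",
                      package = "tunnelflex", mustWork = TRUE)
  .build_region_map(yaml::read_yaml(path))
}

#' Load a region map with user overrides
#'
#' Reads a YAML mapping of region names to residue-id lists and merges it
#' over the built-in map: any surface or site named in the config
#' replaces the default set of the same name. Invariants (site
#' disjointness, residue-id format) are re-validated after the merge.
#'
#' @param config Path to a YAML file, or YAML text, or an already-parsed
#'   list with optional elements `surfaces` and `sites`. An empty config
#'   returns [default_region_map()].
#' @return A `region_map` object.
#' @examples
#' load_region_map("sites:\n  entry: [Q52, K56, D63, R218, H221, R312]")
#' @export
load_region_map <- function(config = NULL) {
  base <- .region_map_raw()
  if (is.null(config)) return(.build_region_map(base))
  if (is.character(config)) {
    config <- if (length(config) == 1L && file.exists(config)) {
      yaml::read_yaml(config)
    } else {
      yaml::yaml.load(paste(config, collapse = "\n"))
    }
  }
  if (is.null(config)) return(.build_region_map(base))
  stopifnot(is.list(config))
  for (part in c("surfaces", "sites")) {
    for (nm in names(config[[part]])) {
      base[[part]][[nm]] <- unlist(config[[part]][[nm]], use.names = FALSE)
    }
  }
  .build_region_map(base)
}

.region_map_raw <- function() {
  path <- system.file("extdata", "tunnel_regions.yaml",
                      package = "tunnelflex", mustWork = TRUE)
  yaml::read_yaml(path)
}

.build_region_map <- function(raw) {
  surfaces <- lapply(raw$surfaces, unlist, use.names = FALSE)
  sites <- lapply(raw$sites, unlist, use.names = FALSE)
  all_ids <- unique(c(unlist(surfaces), unlist(sites)))
  bad <- all_ids[!grepl("^[A-Z][0-9]+$", all_ids)]
  if (length(bad)) {
    stop("unrecognized residue id(s): ", paste(bad, collapse = ", "),
         " (expected one-letter code + number, e.g. Y38)")
  }
  three <- sites[c("entry", "tunnel", "exit")]
  if (any(vapply(three, is.null, logical(1)))) {
    stop("region map must define entry, tunnel and exit sites")
  }
  tab <- table(unlist(three))
  if (any(tab > 1L)) {
    stop("residue(s) assigned to more than one site: ",
         paste(names(tab)[tab > 1L], collapse = ", "))
  }
  map <- structure(
    list(surfaces = surfaces, sites = sites,
         interacting24 = unname(unlist(three))),
    class = "region_map"
  )
  map
}

#' Residue number encoded in a region-map id
#'
#' `"Y38"` gives `38L`. Vectorized.
#'
#' @param ids Character vector of residue ids.
#' @return Integer vector of author residue numbers.
#' @export
region_resno <- function(ids) {
  as.integer(sub("^[A-Z]", "", ids))
}

#' Surface label(s) of a residue in a region map
#'
#' @param map A `region_map`.
#' @param id Residue id such as `"R312"`.
#' @return Character vector of surface names containing the residue
#'   (may be empty).
#' @export
surface_of <- function(map, id) {
  stopifnot(inherits(map, "region_map"))
  names(map$surfaces)[vapply(map$surfaces, function(s) id %in% s,
                             logical(1))]
}

#' Site label of a residue in a region map
#'
#' @param map A `region_map`.
#' @param id Residue id such as `"Y38"`.
#' @return `"entry"`, `"tunnel"`, `"exit"` or `NA` if unassigned.
#' @export
site_of <- function(map, id) {
  stopifnot(inherits(map, "region_map"))
  for (s in c("entry", "tunnel", "exit")) {
    if (id %in% map$sites[[s]]) return(s)
  }
  NA_character_
}

#' @export
print.region_map <- function(x, ...) {
  cat("region_map: ", length(x$interacting24),
      " substrate-interacting residues (",
      paste(vapply(x$sites[c("entry", "tunnel", "exit")], length,
                   integer(1)), collapse = "/"),
      " entry/tunnel/exit), ", length(x$surfaces), " surfaces\n", sep = "")
  invisible(x)
}
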