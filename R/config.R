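#' Read a protocol / phantom configuration file
#'
#' YAML configuration mirroring the package's constructors. Recognized top
#' level sections: `relaxation` (t1, t2star, tissue_label), `protocol`
#' (arguments of [epi_protocol()]), `protocol_grid` (te/tr/fa lists plus
#' etl, n_slices, voxel_mm, fov_mm, acq_bandwidth_hz), and `phantom`
#' (arguments of [phantom_spec()]). See
#' `system.file("extdata", "protocols.yaml", package = "epieff")` for a
#' complete annotated example reproducing both reference families.
#'
#' @param path YAML file path.
#' @return Named list of parsed sections.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config Parsed config list (or a path).
#' @export
protocol_from_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  pc <- config$protocol
  if (is.null(pc)) stop("config has no 'protocol' section")
  args <- pc[intersect(names(pc), names(formals(epi_protocol)))]
  do.call(epi_protocol, args)
}

#' @rdname read_config
#' @export
relaxation_from_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  rc <- config$relaxation
  if (is.null(rc)) return(default_relaxation("GM"))
  relaxation_params(rc$t1, rc$t2star,
                    if (is.null(rc$tissue_label)) "" else rc$tissue_label)
}

#' @rdname read_config
#' @export
grid_from_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  gc <- config$protocol_grid
  if (is.null(gc)) stop("config has no 'protocol_grid' section")
  out <- data.frame(te = gc$te, tr = gc$tr, fa = gc$fa)
  for (a in c("etl", "n_slices", "voxel_mm", "fov_mm", "acq_bandwidth_hz"))
    attr(out, a) <- gc[[a]]
  out
}

#' @rdname read_config
#' @export
phantom_from_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  pc <- config$phantom
  if (is.null(pc)) return(phantom_spec())
  if (!is.null(pc$relaxation))
    pc$relaxation <- lapply(pc$relaxation, function(r)
      relaxation_params(r$t1, r$t2star, r$tissue_label))
  for (nm in c("proton_density", "t2star_sd"))
    if (!is.null(pc[[nm]])) pc[[nm]] <- unlist(pc[[nm]])
  args <- pc[intersect(names(pc), names(formals(phantom_spec)))]
  do.call(phantom_spec, args)
}
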