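## End-to-end orchestration: validated configuration, stage commands, and
## a manifest (inputs, parameters, versions, content hashes) for
## reproducibility. The cmd_* functions are the programmatic surface; a
## thin command-line wrapper ships in inst/cli/borrownet.R.

PIPELINE_KEYS <- c("matrix", "metadata", "roots", "meanings", "evidence",
                   "policy", "out_dir", "seed",
                   "distance_variant", "split_threshold",
                   "adjacency_radius_km", "weighted_average", "denominator",
                   "drop_bantu", "drop_complex", "remove_singletons",
                   "lump_groups", "planar_coordinates", "sim", "log_level")

#' Build and validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list. Unknown keys are rejected.
#' Analysis thresholds default to the conventional values: `shared`
#' distance variant, split-weight filter 0.005, 250 km adjacency radius,
#' unweighted cluster averaging, attested-roots denominator.
#'
#' @param config path to a YAML file, or a named list.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(out_dir = "borrownet_out", seed = 1L,
                   distance_variant = "shared", split_threshold = 0.005,
                   adjacency_radius_km = 250, weighted_average = FALSE,
                   denominator = "attested", drop_bantu = TRUE,
                   drop_complex = TRUE, remove_singletons = FALSE,
                   planar_coordinates = FALSE, log_level = "info")
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (!config$distance_variant %in% c("shared", "mle"))
    stop("distance_variant must be 'shared' or 'mle'")
  if (config$split_threshold < 0) stop("split_threshold must be >= 0")
  if (!config$denominator %in% c("attested", "all"))
    stop("denominator must be 'attested' or 'all'")
  structure(config, class = "pipeline_config")
}

pipeline_log <- function(config, level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[config$log_level %||% "info"]])
    message(sprintf("[%s] %s", level, paste0(...)))
}

load_input_matrix <- function(config) {
  if (is.null(config$matrix) || is.null(config$metadata))
    stop("config must name 'matrix' and 'metadata' input files")
  m <- read_root_matrix(config$matrix, config$metadata,
                        roots_path = config$roots,
                        meanings_path = config$meanings)
  if (!is.null(config$lump_groups))
    m <- lump_doculects(m, lapply(config$lump_groups, unlist))
  m <- filter_roots(m, config$drop_bantu, config$drop_complex)
  if (isTRUE(config$remove_singletons)) m <- remove_singletons(m)
  m
}

finish_stage <- function(config, stage, files, extra = list()) {
  files <- files[file.exists(files)]
  manifest <- list(
    stage = stage,
    package = "borrownet",
    version = as.character(utils::packageVersion("borrownet")),
    seed = config$seed,
    parameters = unclass(config)[setdiff(names(config),
                                         c("sim", "lump_groups"))],
    files = lapply(setNames(nm = basename(files)), function(f)
      list(path = f, md5 = unname(tools::md5sum(files[basename(files) == f])))))
  manifest <- c(manifest, extra)
  path <- file.path(config$out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, path))
}

#' Pipeline stage commands
#'
#' Each command validates the configuration, runs one stage of the
#' analysis and writes its artifacts plus a JSON manifest listing every
#' output file with an md5 content hash:
#' \describe{
#'   \item{`cmd_validate`}{read and cross-check the inputs, write a
#'     validation report;}
#'   \item{`cmd_dist`}{GeneContent distance + similarity matrices (TSV and
#'     PHYLIP);}
#'   \item{`cmd_nnet`}{NeighborNet ordering, filtered circular split
#'     weights, NEXUS SPLITS file;}
#'   \item{`cmd_share`}{sharing records, pattern/origin proportions,
#'     cluster profiles, resolution decomposition, unresolved
#'     classification;}
#'   \item{`cmd_origins`}{criteria-based origin decisions from an evidence
#'     table;}
#'   \item{`cmd_simulate`}{synthetic data set + ground truth;}
#'   \item{`cmd_all`}{all applicable stages in order.}
#' }
#'
#' @param config a [pipeline_config()] (or path/list coercible to one).
#' @return invisibly, the files written.
#' @export
cmd_validate <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- load_input_matrix(config)
  rep <- utils::capture.output(print(m))
  p <- file.path(config$out_dir, "validation.txt")
  writeLines(c(rep, sprintf("inputs OK: %s, %s", config$matrix,
                            config$metadata)), p)
  pipeline_log(config, "info", "validation OK: ", nrow(m$state), " roots x ",
               ncol(m$state), " doculects")
  finish_stage(config, "validate", p)
}

#' @rdname cmd_validate
#' @export
cmd_dist <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- load_input_matrix(config)
  D <- gene_content_distance(m, config$distance_variant)
  files <- c(file.path(config$out_dir, "distance.tsv"),
             file.path(config$out_dir, "distance.phy"))
  write_square_tsv(D, files[1])
  write_phylip_dist(D, files[2])
  if (config$distance_variant == "shared") {
    S <- similarity_matrix(D, m$doculects)
    f <- file.path(config$out_dir, "similarity.tsv")
    write_square_tsv(S, f)
    files <- c(files, f)
  }
  finish_stage(config, "dist", files)
}

#' @rdname cmd_validate
#' @export
cmd_nnet <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- load_input_matrix(config)
  D <- gene_content_distance(m, config$distance_variant)
  ord <- neighbor_net_ordering(D)
  ss <- circular_split_weights(D, ord)
  ss <- filter_splits(ss, config$split_threshold)
  files <- c(file.path(config$out_dir, "splits.nex"),
             file.path(config$out_dir, "splits.tsv"))
  export_splits_nexus(ss, files[1])
  write_splits_tsv(ss, files[2])
  pipeline_log(config, "info", length(ss$splits), " splits >= ",
               config$split_threshold, ", fit ", round(ss$fit, 2), "%")
  finish_stage(config, "nnet", files,
               extra = list(fit = ss$fit, n_splits = length(ss$splits)))
}

#' @rdname cmd_validate
#' @export
cmd_share <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- load_input_matrix(config)
  rec <- detect_shared(m)
  unres <- NULL
  has_coords <- !any(is.na(m$doculects$latitude))
  if (has_coords && sum(rec$pattern != "NONE" &
                        rec$origin == "UNIDENTIFIED") > 0)
    unres <- classify_unresolved(rec, m$doculects,
                                 radius_km = config$adjacency_radius_km,
                                 planar = isTRUE(config$planar_coordinates))
  files <- write_sharing_report(m, rec, config$out_dir, unresolved = unres)
  finish_stage(config, "share", files)
}

#' @rdname cmd_validate
#' @export
cmd_origins <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config$evidence))
    stop("cmd_origins needs an 'evidence' table path in the config")
  policy <- if (!is.null(config$policy)) read_origin_policy(config$policy)
  else origin_policy()
  ev <- load_evidence(config$evidence, policy)
  dec <- batch_decide(ev, policy)
  p <- file.path(config$out_dir, "origin_decisions.tsv")
  write.table(dec, p, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  finish_stage(config, "origins", p)
}

#' @rdname cmd_validate
#' @export
cmd_simulate <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_args <- config$sim %||% list()
  sim_args$seed <- sim_args$seed %||% config$seed
  if (!is.null(sim_args$borrow_rate))
    sim_args$borrow_rate <- matrix(unlist(sim_args$borrow_rate), 3, 3,
                                   byrow = TRUE)
  cfg <- do.call(sim_config, sim_args)
  sim <- simulate_root_matrix(cfg)
  files <- file.path(config$out_dir,
                     c("sim_matrix.tsv", "sim_metadata.tsv", "sim_roots.tsv",
                       "sim_events.json"))
  write_root_matrix(sim$matrix, files[1], files[2], files[3])
  jsonlite::write_json(sim$truth$events, files[4], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  finish_stage(config, "simulate", files,
               extra = list(n_roots = nrow(sim$matrix$state),
                            n_events = nrow(sim$truth$events)))
}

#' @rdname cmd_validate
#' @export
cmd_all <- function(config) {
  config <- pipeline_config(config)
  if (is.null(config$matrix)) {
    ## no input data: simulate first, then analyse the simulation
    files <- cmd_simulate(config)
    config$matrix <- file.path(config$out_dir, "sim_matrix.tsv")
    config$metadata <- file.path(config$out_dir, "sim_metadata.tsv")
    config$roots <- file.path(config$out_dir, "sim_roots.tsv")
  } else files <- character(0)
  files <- c(files,
             cmd_validate(config), cmd_dist(config), cmd_nnet(config),
             cmd_share(config))
  if (!is.null(config$evidence)) files <- c(files, cmd_origins(config))
  invisible(files)
}
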