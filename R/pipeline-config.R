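#' Full pipeline configuration
#'
#' Bundles every tunable of the pipeline: simulation conditions,
#' preprocessing, splitting, both model stages and the training regime,
#' plus the master seed and output directory. Round-trips losslessly
#' through YAML via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param sim a [sim_config()].
#' @param prep a [prep_config()].
#' @param split a [split_spec()].
#' @param resnet a [resnet_config()].
#' @param transformer a [transformer_config()].
#' @param train a [train_config()].
#' @param n_subjects cohort size for simulation (default 30).
#' @param seed master seed; sub-seeds are derived from it.
#' @param out_dir output directory for command-level runs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), prep = prep_config(),
                            split = split_spec(), resnet = resnet_config(),
                            transformer = transformer_config(),
                            train = train_config(), n_subjects = 30L,
                            seed = 1L, out_dir = "radbp-out") {
  stopifnot(inherits(sim, "sim_config"), inherits(prep, "prep_config"),
            inherits(split, "split_spec"), inherits(resnet, "resnet_config"),
            inherits(transformer, "transformer_config"),
            inherits(train, "train_config"), n_subjects >= 1)
  structure(list(sim = sim, prep = prep, split = split, resnet = resnet,
                 transformer = transformer, train = train,
                 n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Write a pipeline configuration to YAML
#' @param cfg a [pipeline_config()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(strip_classes(unclass(cfg)), path, precision = 15L)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file written by [write_pipeline_config()].
#' @return a validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ctor <- list(sim = sim_config, prep = prep_config, split = split_spec,
               resnet = resnet_config, transformer = transformer_config,
               train = train_config)
  parts <- lapply(names(ctor), function(nm) {
    args <- raw[[nm]]
    args <- args[names(args) %in% names(formals(ctor[[nm]]))]
    do.call(ctor[[nm]], args)
  })
  names(parts) <- names(ctor)
  pipeline_config(sim = parts$sim, prep = parts$prep, split = parts$split,
                  resnet = parts$resnet, transformer = parts$transformer,
                  train = parts$train, n_subjects = raw$n_subjects,
                  seed = raw$seed, out_dir = raw$out_dir)
}

# Stable content hash for provenance logs (md5 of the serialized object).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(strip_classes(x), f, version = 2)
  unname(tools::md5sum(f))
}
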