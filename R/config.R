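# Flat run configuration: one YAML file holds every knob of a full
# experiment (paths, image side, architecture, strategies, training
# hyper-parameters, classical-method parameters, seed, aggregation,
# overlay palette), so a multi-hundred-launch run has a single provenance
# artifact. Unknown keys are rejected rather than ignored.

#' Default run configuration
#'
#' Every field of the flat experiment configuration with its default:
#' \describe{
#'   \item{dataDir, outDir}{dataset and output directories.}
#'   \item{side}{image side fed to the networks (250 at full scale).}
#'   \item{arch}{\code{"munet"}, \code{"unet"}, \code{"unet-mini"} or an
#'     [ablationPresets()] name.}
#'   \item{strategies}{augmentation strategy names.}
#'   \item{nOriginals, groupSize}{leave-one-out plan arithmetic.}
#'   \item{learningRate, batchSize, maxEpochs, patience, minDelta}{training
#'     hyper-parameters (see [TrainingConfig-class]).}
#'   \item{threshold, regionalThreshold, growthSize, kmeansK}{classical
#'     baseline parameters (threshold on the 0-255 scale).}
#'   \item{seed}{master seed.}
#'   \item{aggregate}{\code{"median"} or \code{"mean"}.}
#'   \item{palette}{overlay accent palette.}
#' }
#'
#' @return Named list of defaults.
#' @export
defaultRunConfig <- function() {
  list(dataDir = "data", outDir = "out", side = 250L, arch = "munet",
       strategies = strategyNames(), nOriginals = 40L, groupSize = 40L,
       learningRate = 1e-3, batchSize = 4L, maxEpochs = 200L,
       patience = 10L, minDelta = 1e-4, threshold = 185,
       regionalThreshold = 0.2, growthSize = 1L, kmeansK = 2L, seed = 1L,
       aggregate = "median", palette = "pink_green")
}

#' Read a run configuration from YAML
#'
#' Missing keys take their documented defaults; unknown keys are an error.
#'
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  def <- defaultRunConfig()
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  def[names(user)] <- user
  def
}

#' Write a run configuration to YAML
#'
#' @param config configuration list (validated against the known keys).
#' @param path output YAML file.
#' @return Invisibly, \code{path}.
#' @export
writeRunConfig <- function(config, path) {
  unknown <- setdiff(names(config), names(defaultRunConfig()))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a run manifest for reproducibility
#'
#' Records the configuration, its hash, the seed and the package/R
#' versions, so a run is reproducible from the manifest alone (modulo the
#' declared RNG backend).
#'
#' @param config configuration list.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
writeRunManifest <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- list(configHash = configHash(config), config = config,
              package = as.character(utils::packageVersion("munetseg")),
              rVersion = R.version.string,
              rngKind = paste(RNGkind(), collapse = "/"),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "run-manifest.yml")
  yaml::write_yaml(man, path)
  invisible(path)
}

#' Resolve an architecture name to a model spec
#'
#' Accepts \code{"unet"}, \code{"unet-mini"}, \code{"munet"}, any
#' [ablationPresets()] name, or \code{"variant:<flags>"} where flags are
#' \code{+}-separated among layer/filter/kernel/ewise/stride/softmax.
#'
#' @param arch architecture name.
#' @param side input side.
#' @return A [ModelSpec-class].
#' @export
resolveArchitecture <- function(arch, side = 250L) {
  if (arch %in% c("unet", "U-Net")) return(buildUNet(side))
  if (arch %in% c("unet-mini", "UNet-Mini")) return(buildUNetMini(side))
  if (arch %in% c("munet", "Mu-Net")) return(buildMuNet(side))
  if (arch %in% names(ablationPresets()))
    return(buildVariant(ablationPreset(arch), side, name = arch))
  if (startsWith(arch, "variant:")) {
    flags <- strsplit(sub("^variant:", "", arch), "+", fixed = TRUE)[[1]]
    known <- c("layer", "filter", "kernel", "ewise", "stride", "softmax")
    bad <- setdiff(flags, known)
    if (length(bad)) stop("unknown variant flag(s): ",
                          paste(bad, collapse = ", "))
    cfg <- ablationConfig(layerReduction = "layer" %in% flags,
                          filterReduction = "filter" %in% flags,
                          kernelReduction = "kernel" %in% flags,
                          ewiseSkip = "ewise" %in% flags,
                          strideDownsampling = "stride" %in% flags,
                          softmaxActivation = "softmax" %in% flags)
    return(buildVariant(cfg, side, name = arch))
  }
  stop("unknown architecture: ", arch)
}
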