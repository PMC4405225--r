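#' Read a pipeline configuration file
#'
#' YAML schema (all keys optional, defaults shown):
#' ```yaml
#' window_size: 8        # pixels per block side
#' s_max: 2              # intensity histogram bins (2 = bright/dark split)
#' channel_policy: green # green | luminance | gray
#' thresholds: [0.1, 0.25, 0.45, 0.7]
#' svm:
#'   kernel: rbf         # or hellinger_affinity
#'   cost: 1.0
#' lesion:
#'   fraction: 0.1       # top group-sparsity fraction of in-field blocks
#'   top_bins: 1         # pooled top-intensity bins
#'   fov_floor: 32       # mean intensity below which a block is off-aperture
#'   sigma_floor: 0.5    # clamp for degenerate spread
#' ```
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return a list with elements `window` ([WindowConfig-class]),
#'   `channelPolicy`, `ranking` ([RankingConfig-class]), `svm`, `lesion`.
#' @export
readPipelineConfig <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  pick <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else default
  svm <- raw$svm %||% list()
  lesion <- raw$lesion %||% list()
  list(
    window = WindowConfig(pick("window_size", 8L), pick("s_max", 2L)),
    channelPolicy = match.arg(pick("channel_policy", "green"),
                              c("green", "luminance", "gray")),
    ranking = RankingConfig(pick("thresholds", c(0.1, 0.25, 0.45, 0.7))),
    svm = list(kernel = match.arg(svm$kernel %||% "rbf",
                                  c("rbf", "hellinger_affinity")),
               cost = svm$cost %||% 1),
    lesion = list(fraction = lesion$fraction %||% 0.1,
                  topBins = as.integer(lesion$top_bins %||% 1L),
                  fovFloor = lesion$fov_floor %||% 32,
                  sigmaFloor = lesion$sigma_floor %||% 0.5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
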