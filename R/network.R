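#' Architecture of the interpolation-pooling segmentation network
#'
#' Describes the inverted-U-Net layer schedule: the input tile is first
#' enlarged twice by nearest-neighbour interpolation (each enlargement
#' preceded by two 3x3 same convolutions with batch normalisation and ReLU),
#' then reduced back twice by 2x2 max pooling, with concatenation skip
#' connections joining each down-sampled stage to the up-sampling stage of
#' matching resolution. A final 1x1 convolution and rectifier produce a
#' single-channel non-negative response map the same size as the input.
#'
#' For a 120 px input the spatial trace is 120 -> 240 -> 480 -> 240 -> 120.
#' The concrete channel schedule is \code{base_channels} (default 16) along
#' the up-sampling path and \code{2 * base_channels} after each
#' concatenation; both skip fusions use channel concatenation, so the two
#' down-path stages see 16+16 = 32 and 32+16 = 48 input channels.
#'
#' @param input_size side length in px of the (square) input tile; the
#'   default 120 is the context window used for tiled inference.
#' @param input_channels number of image channels (3 for RGB).
#' @param base_channels channels produced by the first convolution block.
#' @param tau binarisation threshold applied to the rectified output map.
#' @return an object of class \code{"glandnet_spec"}.
#' @seealso [build_network()], [glandnet_fit()]
#' @export
network_spec <- function(input_size = 120L, input_channels = 3L,
                         base_channels = 16L, tau = 0) {
  input_size <- as.integer(input_size)
  base_channels <- as.integer(base_channels)
  if (input_size < 4L) stop("input_size must be at least 4 px")
  if (base_channels < 1L) stop("base_channels must be positive")
  b <- base_channels
  spec <- list(
    input_size = input_size,
    input_channels = as.integer(input_channels),
    base_channels = b,
    up_blocks = 2L,
    down_blocks = 2L,
    kernel = 3L,
    # per-block output channels: 6 up/bottom blocks then 4 down blocks
    out_channels = c(b, b, b, b, b, b, 2L * b, 2L * b, 2L * b, 2L * b),
    tau = tau
  )
  class(spec) <- "glandnet_spec"
  spec
}

# input channels of each of the 10 conv blocks, given the spec
.block_in_channels <- function(spec) {
  oc <- spec$out_channels
  c(spec$input_channels, oc[1], # stage 1 (input resolution)
    oc[2], oc[3],               # stage 2 (x2)
    oc[4], oc[5],               # bottom (x4)
    oc[6] + oc[4], oc[7],       # down stage 1: concat(pool, stage-2 skip)
    oc[8] + oc[2], oc[9])       # down stage 2: concat(pool, stage-1 skip)
}

#' Initialise network parameters
#'
#' Allocates and seeds all layer parameters for a [network_spec()]:
#' He-uniform convolution kernels, unit batch-norm scales, zero shifts, and
#' zero-initialised running statistics (mean 0, variance 1). Building twice
#' with the same seed yields identical parameters.
#'
#' @param spec a \code{"glandnet_spec"}.
#' @param seed integer RNG seed for the weight draw.
#' @return an unfitted model of class \code{"glandnet"} holding the spec,
#'   the parameter list and the batch-norm running statistics.
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  stopifnot(inherits(spec, "glandnet_spec"))
  cin <- .block_in_channels(spec)
  cout <- spec$out_channels
  params <- list()
  running <- list()
  set.seed(as.integer(seed))
  for (l in 1:10) {
    fan_in <- 9L * cin[l]
    lim <- sqrt(6 / fan_in)
    params[[paste0("W", l)]] <-
      matrix(stats::runif(9L * cin[l] * cout[l], -lim, lim),
             nrow = 9L * cin[l], ncol = cout[l])
    params[[paste0("g", l)]] <- rep(1, cout[l])
    params[[paste0("be", l)]] <- rep(0, cout[l])
    running[[paste0("rm", l)]] <- rep(0, cout[l])
    running[[paste0("rv", l)]] <- rep(1, cout[l])
  }
  lim <- sqrt(6 / cout[10])
  params[["Wh"]] <- stats::runif(cout[10], -lim, lim)
  params[["bh"]] <- 0
  structure(list(spec = spec, params = params, running = running,
                 history = NULL, control = NULL, fitted = FALSE,
                 seed = as.integer(seed)),
            class = "glandnet")
}

#' Number of trainable parameters
#' @param object a \code{"glandnet"} model.
#' @noRd
.n_params <- function(object) {
  sum(vapply(object$params, length, integer(1)))
}

#' Forward pass through the network
#'
#' Runs tiles through the network in evaluation mode (batch-norm running
#' statistics frozen) and returns the rectified single-channel response
#' maps. Values are >= 0; apply [binarize()] to obtain a mask.
#'
#' @param object a \code{"glandnet"} model.
#' @param tiles a single H x W x C array with values in \[0, 1\], or a list
#'   of such arrays.
#' @return a numeric H x W matrix, or a list of them if \code{tiles} is a
#'   list.
#' @export
net_forward <- function(object, tiles) {
  stopifnot(inherits(object, "glandnet"))
  one <- function(x) {
    if (!(is.array(x) && length(dim(x)) == 3L))
      stop("each tile must be an H x W x C array")
    if (dim(x)[3] != object$spec$input_channels)
      stop("tile has ", dim(x)[3], " channels; network expects ",
           object$spec$input_channels)
    net_forward_cpp(object$params, object$running, x)
  }
  if (is.list(tiles)) lapply(tiles, one) else one(tiles)
}

#' Threshold a response map into a binary mask
#'
#' Pixels with value strictly greater than \code{tau} become foreground.
#' With the network's rectified output the literal published rule is
#' \code{tau = 0} (any positive activation is a gland pixel); \code{tau =
#' 0.5} is a more robust choice when the network is trained with mean
#' squared error against \{0, 1\} targets, and is what [glandnet_fit()]
#' uses for validation metrics by default.
#'
#' @param map numeric matrix (or array) of finite values.
#' @param tau threshold; default 0.
#' @return an integer matrix of 0/1 values with the dimensions of
#'   \code{map}.
#' @export
binarize <- function(map, tau = 0) {
  if (any(is.na(map))) stop("response map contains NA/NaN values")
  out <- (map > tau) + 0L
  storage.mode(out) <- "integer"
  dim(out) <- dim(map)
  out
}
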